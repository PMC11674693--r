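# The averaged horizontal multi-offset GLCM (AHMO-GLCM): grayscale
# conversion, 64-level quantisation, one horizontal co-occurrence matrix
# per offset d = 1..25, each normalised to unit mass, then averaged with
# equal weights into a single matrix. Normalising before averaging weights
# every spatial scale equally; otherwise small offsets (which contribute
# more pixel pairs) would dominate.

#' Convert an image to grayscale
#'
#' 3-channel input is collapsed with the standard luma weights
#' (0.2989 R + 0.5870 G + 0.1140 B, rounded); grayscale input passes
#' through unchanged.
#'
#' @param x pixel matrix, rows x cols x 3 array, or \code{LFAImage}.
#' @return numeric gray matrix in [0, 255].
#' @export
toGrayscale <- function(x) {
  if (methods::is(x, "LFAImage")) x <- pixels(x)
  nd <- length(dim(x))
  if (nd == 2L) return(x)
  if (nd == 3L && dim(x)[3] == 3L)
    return(round(0.2989 * x[, , 1] + 0.5870 * x[, , 2] + 0.1140 * x[, , 3]))
  stop(sprintf("expected 1 or 3 channels, got %s",
               paste(dim(x), collapse = " x ")))
}

#' Quantise a gray image to Ng discrete levels
#'
#' In \code{per_image} mode the observed gray range [gmin, gmax] is mapped
#' linearly onto levels 0..Ng-1, each value going to its closest level; a
#' constant image maps to level 0. \code{fixed_0_255} uses the full 8-bit
#' range instead, for cross-image comparability.
#'
#' @param gray numeric gray matrix.
#' @param nLevels number of quantisation levels Ng >= 2 (default 64).
#' @param rangeMode \code{"per_image"} (default) or \code{"fixed_0_255"}.
#' @return list of class \code{"QuantisedPatch"}: \code{levels} (integer
#'   matrix in 0..Ng-1), \code{nLevels}, \code{range} (gmin, gmax used).
#' @export
quantise <- function(gray, nLevels = 64L,
                     rangeMode = c("per_image", "fixed_0_255")) {
  rangeMode <- match.arg(rangeMode)
  if (nLevels < 2L) stop("nLevels must be >= 2")
  if (methods::is(gray, "Patch") || methods::is(gray, "LFAImage"))
    gray <- toGrayscale(gray)
  rng <- if (rangeMode == "per_image") range(gray) else c(0, 255)
  lev <- if (rng[2] > rng[1]) {
    matrix(as.integer(round((gray - rng[1]) / (rng[2] - rng[1]) *
                            (nLevels - 1))), nrow(gray), ncol(gray))
  } else matrix(0L, nrow(gray), ncol(gray))
  structure(list(levels = lev, nLevels = as.integer(nLevels), range = rng),
            class = "QuantisedPatch")
}

#' Horizontal co-occurrence counts at a single offset
#'
#' Counts ordered gray-level pairs (q[r, c], q[r, c + d]) over all valid
#' positions; the total count is rows x (cols - d). Symmetric mode adds
#' the transpose (each pair counted in both directions).
#'
#' @param q a \code{\link{quantise}} result.
#' @param d column offset in px, 1 <= d < ncol.
#' @param symmetric logical; default FALSE (ordered left-to-right pairs).
#' @return Ng x Ng integer count matrix.
#' @export
glcmSingleOffset <- function(q, d, symmetric = FALSE) {
  lev <- q$levels
  Ng <- q$nLevels
  nc <- ncol(lev)
  if (d < 1L || d >= nc)
    stop(sprintf("offset d = %d exceeds patch width; need 1 <= d <= %d",
                 d, nc - 1L))
  i <- lev[, seq_len(nc - d), drop = FALSE]
  j <- lev[, (d + 1L):nc, drop = FALSE]
  counts <- matrix(tabulate(as.integer(i) + Ng * as.integer(j) + 1L,
                            nbins = Ng * Ng), Ng, Ng)
  if (symmetric) counts <- counts + t(counts)
  counts
}

#' Averaged horizontal multi-offset GLCM
#'
#' Computes one horizontal GLCM per offset d = 1..dMax, normalises each to
#' unit mass, and averages them with equal weights (the default
#' normalise-then-average order gives every spatial scale the same
#' weight). The alternative order, averaging raw counts before a single
#' normalisation, is available via \code{average = "counts"}.
#'
#' @param q a \code{\link{quantise}} result.
#' @param dMax largest offset (default 25); must be < patch columns.
#' @param symmetric passed to \code{\link{glcmSingleOffset}}.
#' @param average \code{"normalised"} (default) or \code{"counts"}.
#' @return An \code{\link{AHMOMatrix}} whose entries sum to 1.
#' @export
ahmo <- function(q, dMax = 25L, symmetric = FALSE,
                 average = c("normalised", "counts")) {
  average <- match.arg(average)
  nc <- ncol(q$levels)
  if (dMax >= nc)
    stop(sprintf("dMax = %d too large for %d columns; maximum legal offset is %d",
                 dMax, nc, nc - 1L))
  if (dMax < 1L) stop("dMax must be >= 1")
  Ng <- q$nLevels
  acc <- matrix(0, Ng, Ng)
  for (d in seq_len(dMax)) {
    cnt <- glcmSingleOffset(q, d, symmetric = symmetric)
    acc <- acc + if (average == "normalised") cnt / sum(cnt) else cnt
  }
  p <- if (average == "normalised") acc / dMax else acc / sum(acc)
  methods::new("AHMOMatrix", p = p, nLevels = Ng,
               provenance = list(dMax = as.integer(dMax),
                                 symmetric = symmetric,
                                 normalisation = average,
                                 rangeMode = attr(q, "rangeMode")))
}

#' GLCM pipeline configuration
#'
#' @param levels quantisation levels Ng (default 64).
#' @param dMax largest horizontal offset (default 25).
#' @param symmetric symmetric pair counting (default FALSE).
#' @param rangeMode quantisation range mode (default "per_image").
#' @param average AHMO averaging order (default "normalised").
#' @return list of class \code{"glcmConfig"}.
#' @export
glcmConfig <- function(levels = 64L, dMax = 25L, symmetric = FALSE,
                       rangeMode = "per_image", average = "normalised") {
  structure(list(levels = as.integer(levels), dMax = as.integer(dMax),
                 symmetric = symmetric, rangeMode = rangeMode,
                 average = average), class = "glcmConfig")
}

#' AHMO matrix of one patch
#'
#' Convenience wrapper: grayscale conversion, quantisation and
#' \code{\link{ahmo}} under a \code{\link{glcmConfig}}.
#'
#' @param patch a \code{\link{Patch}}, \code{LFAImage} or pixel matrix.
#' @param config a \code{\link{glcmConfig}}.
#' @return An \code{\link{AHMOMatrix}}.
#' @export
ahmoForPatch <- function(patch, config = glcmConfig()) {
  gray <- toGrayscale(if (methods::is(patch, "Patch")) pixels(patch)
                      else patch)
  q <- quantise(gray, nLevels = config$levels, rangeMode = config$rangeMode)
  ahmo(q, dMax = config$dMax, symmetric = config$symmetric,
       average = config$average)
}
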