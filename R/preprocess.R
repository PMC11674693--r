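# Standardisation and per-half adaptive segmentation. Reader images are
# resized to 500 x 128 (width x height) by exact area averaging, split into
# two 250 x 128 halves, and thresholded independently per half so that
# intensity variation across the strip cannot defeat a single global
# threshold. The line is the largest 8-connected foreground component.

# overlap weights for exact area-averaged resampling: W (nOut x nIn) with
# rows summing to 1; constant inputs are preserved exactly.
areaWeights <- function(nIn, nOut) {
  s <- nIn / nOut
  lo <- (seq_len(nOut) - 1) * s
  hi <- seq_len(nOut) * s
  iLo <- matrix(seq_len(nIn) - 1, nOut, nIn, byrow = TRUE)
  W <- pmin(matrix(hi, nOut, nIn), iLo + 1) - pmax(matrix(lo, nOut, nIn), iLo)
  W[W < 0] <- 0
  W / s
}

#' Standardise a strip image to 500 x 128
#'
#' Normalises orientation (long axis becomes the width) and resizes to a
#' uniform 500 px wide x 128 px high grid by exact area-weighted averaging,
#' which preserves constant regions and the [0, 255] range. Inputs already
#' at the target size are returned unchanged.
#'
#' @param image an \code{\link{LFAImage}} (gray or RGB).
#' @param targetWidth,targetHeight target size in px.
#' @param allowUpscale if FALSE (default), inputs smaller than the target
#'   in either axis are refused with an error.
#' @return A standardised \code{LFAImage}.
#' @export
standardiseImage <- function(image, targetWidth = 500L, targetHeight = 128L,
                             allowUpscale = FALSE) {
  px <- pixels(image)
  rgb <- length(dim(px)) == 3L
  nr <- dim(px)[1]; nc <- dim(px)[2]
  if (nr > nc) {  # long axis = width
    px <- if (rgb) aperm(px, c(2, 1, 3)) else t(px)
    nr <- dim(px)[1]; nc <- dim(px)[2]
  }
  if (!allowUpscale && (nc < targetWidth || nr < targetHeight))
    stop(sprintf(paste0("input %d x %d is smaller than target %d x %d; ",
                        "upsampling refused (set allowUpscale = TRUE)"),
                 nc, nr, targetWidth, targetHeight))
  if (nr == targetHeight && nc == targetWidth)
    return(methods::new("LFAImage", pixels = px, label = image@label,
                        source = image@source))
  Wr <- areaWeights(nr, targetHeight)
  Wc <- areaWeights(nc, targetWidth)
  resize1 <- function(m) Wr %*% m %*% t(Wc)
  out <- if (rgb) {
    array(c(resize1(px[, , 1]), resize1(px[, , 2]), resize1(px[, , 3])),
          dim = c(targetHeight, targetWidth, 3))
  } else resize1(px)
  out <- pmax(pmin(out, 255), 0)
  methods::new("LFAImage", pixels = out, label = image@label,
               source = image@source)
}

#' Split a standardised image into left and right halves
#'
#' @param x an \code{LFAImage} or a pixel matrix of even width.
#' @return list with \code{left} and \code{right} pixel matrices (each half
#'   the input width); concatenating them column-wise reconstructs the
#'   input exactly.
#' @export
splitHalves <- function(x) {
  px <- if (methods::is(x, "LFAImage")) pixels(x) else x
  if (length(dim(px)) == 3L) px <- toGrayscale(px)
  nc <- ncol(px)
  if (nc %% 2L != 0L)
    stop(sprintf("image width %d is odd; cannot split into equal halves", nc))
  h <- nc %/% 2L
  list(left = px[, seq_len(h), drop = FALSE],
       right = px[, (h + 1):nc, drop = FALSE])
}

# Otsu's automatic threshold on an 8-bit histogram: exhaustive sweep over
# the 255 split points maximising between-class variance; first maximum
# wins (determinism). Returns a threshold between bins: foreground (line)
# pixels are those strictly below it.
otsuThreshold <- function(px) {
  v <- round(as.numeric(px))
  counts <- tabulate(v + 1L, nbins = 256L)
  n <- sum(counts)
  lev <- 0:255
  w0 <- cumsum(counts)[1:255]
  w1 <- n - w0
  m0 <- cumsum(counts * lev)[1:255]
  mu0 <- ifelse(w0 > 0, m0 / w0, 0)
  mu1 <- ifelse(w1 > 0, (sum(counts * lev) - m0) / w1, 0)
  sigma2 <- w0 * w1 * (mu0 - mu1)^2
  k <- which.max(sigma2)  # split after gray level k-1
  (k - 1) + 0.5
}

#' Threshold one image half
#'
#' Automatic between-class-variance (Otsu) threshold selected
#' independently on the given half; this per-window selection is what
#' makes the two-half scheme adaptive. Foreground is the line: pixels
#' darker than the threshold (or lighter, for \code{polarity = "light"}).
#'
#' @param half a pixel matrix (one image half).
#' @param method threshold selector; only \code{"otsu"} is implemented.
#' @param polarity \code{"dark"} (default; colorimetric lines are darker
#'   than the membrane) or \code{"light"}.
#' @return A \code{\link{BinaryMask}}.
#' @export
thresholdHalf <- function(half, method = "otsu", polarity = "dark") {
  method <- match.arg(method, "otsu")
  if (methods::is(half, "LFAImage")) half <- pixels(half)
  if (length(unique(round(as.numeric(half)))) < 2L)
    stop("segmentation failure: region is constant, no line found")
  y <- if (polarity == "light") 255 - half else half
  thr <- otsuThreshold(y)
  methods::new("BinaryMask", pixels = y < thr, polarity = polarity)
}

# 8-connected component labelling by row-run union-find. Returns an
# integer matrix: 0 = background, components numbered arbitrarily.
labelComponents8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  prevRuns <- NULL  # data.frame: from, to, lab
  for (r in seq_len(nr)) {
    row <- mask[r, ]
    runs <- NULL
    if (any(row)) {
      rl <- rle(row)
      ends <- cumsum(rl$lengths)
      starts <- ends - rl$lengths + 1L
      keep <- rl$values
      runs <- data.frame(from = starts[keep], to = ends[keep], lab = 0L)
      for (k in seq_len(nrow(runs))) {
        touching <- integer(0)
        if (!is.null(prevRuns) && nrow(prevRuns))
          touching <- prevRuns$lab[prevRuns$from <= runs$to[k] + 1L &
                                   prevRuns$to >= runs$from[k] - 1L]
        if (length(touching) == 0L) {
          parent[length(parent) + 1L] <- length(parent) + 1L
          runs$lab[k] <- length(parent)
        } else {
          roots <- unique(vapply(touching, find, integer(1)))
          runs$lab[k] <- roots[1]
          for (rt in roots[-1]) parent[rt] <- roots[1]
        }
        lab[r, runs$from[k]:runs$to[k]] <- runs$lab[k]
      }
    }
    prevRuns <- runs
  }
  if (length(parent)) {
    roots <- vapply(seq_along(parent), find, integer(1))
    compact <- match(roots, unique(roots))
    nz <- lab > 0L
    lab[nz] <- compact[lab[nz]]
  }
  lab
}

#' Detect the line ROI in a binary mask
#'
#' The region of interest is the largest 8-connected foreground component;
#' ties on size are broken towards the leftmost bounding box. Coordinates
#' are reported in the full-image frame via \code{colOffset} (1-based,
#' closed intervals).
#'
#' @param mask a \code{\link{BinaryMask}} (typically one half).
#' @param side \code{"test"} or \code{"control"}.
#' @param colOffset columns to add to map half coordinates into the
#'   full-image frame (0 for the left half, half-width for the right).
#' @return An \code{\link{ROI}}.
#' @export
detectROI <- function(mask, side = c("test", "control"), colOffset = 0L) {
  side <- match.arg(side)
  m <- pixels(mask)
  if (!any(m))
    stop(sprintf("segmentation failure: empty mask, no %s line found", side))
  lab <- labelComponents8(m)
  sizes <- tabulate(lab[lab > 0L])
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {  # leftmost bbox wins
    minCol <- vapply(best, function(b) min(col(lab)[lab == b]), numeric(1))
    best <- best[which.min(minCol)]
  }
  idx <- which(lab == best, arr.ind = TRUE)
  rows <- idx[, 1]; cols <- idx[, 2] + colOffset
  methods::new("ROI",
               bbox = c(min(rows), min(cols), max(rows), max(cols)),
               centroid = c(mean(rows), mean(cols)), side = side)
}

#' Merge two half masks into a full-size mask
#'
#' @param leftMask,rightMask \code{\link{BinaryMask}} halves of equal
#'   height and matching polarity.
#' @return A full-width \code{BinaryMask}; its foreground count is the sum
#'   of the halves' counts.
#' @export
mergeMasks <- function(leftMask, rightMask) {
  l <- pixels(leftMask); r <- pixels(rightMask)
  if (nrow(l) != nrow(r) || ncol(l) != ncol(r))
    stop(sprintf("shape mismatch: left %d x %d vs right %d x %d",
                 nrow(l), ncol(l), nrow(r), ncol(r)))
  if (leftMask@polarity != rightMask@polarity)
    stop("polarity mismatch between half masks")
  methods::new("BinaryMask", pixels = cbind(l, r),
               polarity = leftMask@polarity)
}

#' Segment a strip image into test- and control-line ROIs
#'
#' Full segmentation path: standardise to 500 x 128, convert to grayscale,
#' split into halves, threshold each half independently, and detect the
#' largest 8-connected component per half. Which half carries which line
#' is a configuration choice; by default the control line sits in the left
#' (sample-pad end) half.
#'
#' @param image an \code{\link{LFAImage}}.
#' @param polarity line polarity passed to \code{\link{thresholdHalf}}.
#' @param controlSide which half holds the control line ("left" default).
#' @param allowUpscale passed to \code{\link{standardiseImage}}.
#' @return list with \code{image} (standardised grayscale
#'   \code{LFAImage}), \code{mask} (merged \code{BinaryMask}), and
#'   \code{rois} (list with elements \code{control} and \code{test}).
#' @export
segmentStrip <- function(image, polarity = "dark",
                         controlSide = c("left", "right"),
                         allowUpscale = FALSE) {
  controlSide <- match.arg(controlSide)
  std <- standardiseImage(image, allowUpscale = allowUpscale)
  gray <- toGrayscale(pixels(std))
  std <- methods::new("LFAImage", pixels = gray, label = std@label,
                      source = std@source)
  halves <- splitHalves(gray)
  halfWidth <- ncol(halves$left)
  maskL <- thresholdHalf(halves$left, polarity = polarity)
  maskR <- thresholdHalf(halves$right, polarity = polarity)
  sides <- if (controlSide == "left") c("control", "test")
           else c("test", "control")
  roiL <- detectROI(maskL, side = sides[1], colOffset = 0L)
  roiR <- detectROI(maskR, side = sides[2], colOffset = halfWidth)
  rois <- list(roiL, roiR)
  names(rois) <- sides
  list(image = std, mask = mergeMasks(maskL, maskR),
       rois = rois[c("control", "test")])
}
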