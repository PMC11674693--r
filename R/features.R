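# Haralick-style scalar texture features of a normalised co-occurrence
# matrix. Gray-level indices run 1..Ng so the sum distribution p_{X+Y} has
# support k = 2..2Ng and the absolute-difference distribution p_{X-Y} has
# support k = 0..Ng-1. Logs are base 2; a machine-epsilon guard is applied
# to zero-probability elements only, so degenerate matrices give exact
# entropies.

.eps <- 2^-52

log2eps <- function(x) log2(x + (x <= 0) * .eps)

#' Names of the 22 texture features, in canonical order
#'
#' @return character(22) feature names: autocorrelation (autoc), contrast
#'   (contr), two correlation forms (corrm, corrp), cluster prominence
#'   (cprom), cluster shade (cshad), dissimilarity (dissi), energy
#'   (energ), entropy (entro), two homogeneity forms (homom, homop),
#'   maximum probability (maxpr), sum of squares variance (sosvh), sum
#'   average (savgh), sum variance (svarh), sum entropy (senth),
#'   difference variance (dvarh), difference entropy (denth), information
#'   measures of correlation (inf1h, inf2h), inverse difference (indnc)
#'   and inverse difference moment (idmnc) normalised forms.
#' @export
textureFeatureNames <- function() {
  c("autoc", "contr", "corrm", "corrp", "cprom", "cshad", "dissi", "energ",
    "entro", "homom", "homop", "maxpr", "sosvh", "savgh", "svarh", "senth",
    "dvarh", "denth", "inf1h", "inf2h", "indnc", "idmnc")
}

#' Marginal statistics of a normalised co-occurrence matrix
#'
#' @param p an \code{\link{AHMOMatrix}} or a normalised numeric matrix.
#' @return list with marginals \code{px}, \code{py}; moments \code{mux},
#'   \code{muy}, \code{sigx}, \code{sigy}; sum distribution
#'   \code{pXplusY} (names "2".."2Ng"); absolute-difference distribution
#'   \code{pXminusY} (names "0".."Ng-1"); and \code{eps}.
#' @export
glcmMarginals <- function(p) {
  if (methods::is(p, "AHMOMatrix")) p <- ahmoProb(p)
  if (abs(sum(p) - 1) > 1e-8)
    stop(sprintf("matrix is not normalised (sum = %.6g)", sum(p)))
  Ng <- nrow(p)
  i <- matrix(seq_len(Ng), Ng, Ng)
  j <- t(i)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(seq_len(Ng) * px); muy <- sum(seq_len(Ng) * py)
  sigx <- sqrt(sum((seq_len(Ng) - mux)^2 * px))
  sigy <- sqrt(sum((seq_len(Ng) - muy)^2 * py))
  ks <- 2:(2 * Ng)
  pXplusY <- vapply(ks, function(k) sum(p[i + j == k]), numeric(1))
  names(pXplusY) <- ks
  kd <- 0:(Ng - 1)
  pXminusY <- vapply(kd, function(k) sum(p[abs(i - j) == k]), numeric(1))
  names(pXminusY) <- kd
  list(px = px, py = py, mux = mux, muy = muy, sigx = sigx, sigy = sigy,
       pXplusY = pXplusY, pXminusY = pXminusY, eps = .eps)
}

#' Compute the 22 texture features of a co-occurrence matrix
#'
#' Nine of the features follow printed closed forms exactly: homogeneity
#' homom = sum p/(1+|i-j|); inverse difference indnc = sum p/(1+(i-j)^2)
#' (the library-standard Ng-normalised form replaces it when
#' \code{strictPrintedFormulas = FALSE}); cluster shade (cubic) and
#' cluster prominence (quartic) central moments of i+j; maximum
#' probability; sum and difference entropies (base-2 logs, epsilon-guarded,
#' the difference entropy over the true support k = 0..Ng-1); correlation
#' (0 when a marginal is degenerate); autocorrelation. The remaining
#' features follow the standard Haralick definitions. All 22 are finite
#' for any normalised matrix with Ng >= 2.
#'
#' @param p an \code{\link{AHMOMatrix}} or normalised numeric matrix.
#' @param strictPrintedFormulas if TRUE (default) indnc uses the printed
#'   unnormalised form; if FALSE the Ng-normalised library variant.
#' @return named numeric(22) in \code{\link{textureFeatureNames}} order.
#' @export
computeFeatures <- function(p, strictPrintedFormulas = TRUE) {
  if (methods::is(p, "AHMOMatrix")) p <- ahmoProb(p)
  Ng <- nrow(p)
  if (Ng < 2L) stop("need Ng >= 2 levels")
  m <- glcmMarginals(p)
  i <- matrix(seq_len(Ng), Ng, Ng)
  j <- t(i)
  dif <- i - j
  sumij <- i + j
  autoc <- sum(i * j * p)
  contr <- sum(dif^2 * p)
  denomC <- m$sigx * m$sigy
  corrm <- if (denomC == 0) 0 else
    sum((i - m$mux) * (j - m$muy) * p) / denomC
  corrp <- if (denomC == 0) 0 else (autoc - m$mux * m$muy) / denomC
  cprom <- sum((sumij - m$mux - m$muy)^4 * p)
  cshad <- sum((sumij - m$mux - m$muy)^3 * p)
  dissi <- sum(abs(dif) * p)
  energ <- sum(p^2)
  entro <- -sum(p * log2eps(p))
  homom <- sum(p / (1 + abs(dif)))
  homop <- sum(p / (1 + dif^2))
  maxpr <- max(p)
  sosvh <- sum((i - m$mux)^2 * p)
  ks <- as.numeric(names(m$pXplusY))
  savgh <- sum(ks * m$pXplusY)
  svarh <- sum((ks - savgh)^2 * m$pXplusY)
  senth <- -sum(m$pXplusY * log2eps(m$pXplusY))
  kd <- as.numeric(names(m$pXminusY))
  mud <- sum(kd * m$pXminusY)
  dvarh <- sum((kd - mud)^2 * m$pXminusY)
  denth <- -sum(m$pXminusY * log2eps(m$pXminusY))
  hx <- -sum(m$px * log2eps(m$px))
  hy <- -sum(m$py * log2eps(m$py))
  pxpy <- outer(m$px, m$py)
  hxy1 <- -sum(p * log2eps(pxpy))
  hxy2 <- -sum(pxpy * log2eps(pxpy))
  denomH <- max(hx, hy)
  inf1h <- if (denomH <= 0) 0 else (entro - hxy1) / denomH
  inf2h <- sqrt(max(0, 1 - exp(-2 * (hxy2 - entro))))
  indnc <- if (strictPrintedFormulas) sum(p / (1 + dif^2))
           else sum(p / (1 + abs(dif) / Ng))
  idmnc <- sum(p / (1 + dif^2 / Ng^2))
  out <- c(autoc = autoc, contr = contr, corrm = corrm, corrp = corrp,
           cprom = cprom, cshad = cshad, dissi = dissi, energ = energ,
           entro = entro, homom = homom, homop = homop, maxpr = maxpr,
           sosvh = sosvh, savgh = savgh, svarh = svarh, senth = senth,
           dvarh = dvarh, denth = denth, inf1h = inf1h, inf2h = inf2h,
           indnc = indnc, idmnc = idmnc)
  if (any(!is.finite(out)))
    stop(sprintf("internal error: non-finite feature(s): %s",
                 paste(names(out)[!is.finite(out)], collapse = ", ")))
  out
}

#' Texture feature table of a patch set
#'
#' Computes the AHMO-GLCM and the 22 texture features of every patch and
#' assembles them into a \code{SummarizedExperiment}: features as rows,
#' patches as columns, with the concentration label and patch provenance
#' in \code{colData}. Deterministic: re-running with the same patches and
#' config reproduces the table bitwise.
#'
#' @param patches list of \code{\link{Patch}} objects (or matrices).
#' @param config a \code{\link{glcmConfig}}.
#' @param strictPrintedFormulas passed to \code{\link{computeFeatures}}.
#' @return A \code{SummarizedExperiment} with assay \code{"features"}
#'   (22 x n) and colData columns label, source_image, side, patch_index.
#' @export
featuresForPatches <- function(patches, config = glcmConfig(),
                               strictPrintedFormulas = TRUE) {
  if (length(patches) == 0L) stop("no patches supplied")
  n <- length(patches)
  mat <- matrix(NA_real_, 22L, n,
                dimnames = list(textureFeatureNames(), NULL))
  label <- character(n); src <- character(n); side <- character(n)
  pidx <- integer(n)
  for (k in seq_len(n)) {
    pt <- patches[[k]]
    mat[, k] <- computeFeatures(ahmoForPatch(pt, config),
                                strictPrintedFormulas)
    if (methods::is(pt, "Patch")) {
      label[k] <- pt@label; src[k] <- pt@sourceImage
      side[k] <- pt@side; pidx[k] <- pt@patchIndex
    } else {
      label[k] <- NA_character_; src[k] <- NA_character_
      side[k] <- NA_character_; pidx[k] <- NA_integer_
    }
  }
  ids <- sprintf("%s_p%d", src, pidx)
  if (anyNA(src)) ids <- sprintf("patch%04d", seq_len(n))
  colnames(mat) <- ids
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = mat),
    colData = S4Vectors::DataFrame(
      label = factor(label, levels = tshLabels()),
      source_image = src, side = side, patch_index = pidx,
      row.names = ids))
}

#' Samples-by-features matrix of a feature table
#'
#' @param se a \code{SummarizedExperiment} from
#'   \code{\link{featuresForPatches}} or \code{\link{cnnFeatures}}.
#' @param assay assay name (default first assay).
#' @return numeric matrix, samples in rows, named features in columns.
#' @export
featureMatrix <- function(se, assay = 1L) {
  t(SummarizedExperiment::assay(se, assay))
}

#' Labels of a feature table
#'
#' @param se a feature-table \code{SummarizedExperiment}.
#' @return factor of concentration labels, one per sample.
#' @export
featureLabels <- function(se) {
  SummarizedExperiment::colData(se)$label
}
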