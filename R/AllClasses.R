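#' @import methods
NULL

#' Ordered TSH concentration labels
#'
#' The eight analyte concentration levels (mIU/L) that define the class
#' labels, in increasing order. Zero-concentration strips are excluded.
#'
#' @return Character vector of the eight ordered labels.
#' @export
#' @examples
#' tshLabels()
tshLabels <- function() c("0.5", "1", "2.5", "5", "10", "25", "50", "100")

setClassUnion("matrixOrArray", c("matrix", "array"))

#' LFAImage: a lateral flow assay strip image
#'
#' Holds a grayscale pixel matrix (rows x columns, gray levels in [0, 255])
#' or a 3-channel array, together with its concentration label and
#' provenance (synthetic generator parameters or a file path).
#'
#' @slot pixels numeric matrix (gray) or rows x cols x 3 array (RGB),
#'   values in [0, 255].
#' @slot label character(1), one of \code{tshLabels()}, or NA for unlabelled
#'   images.
#' @slot source list describing provenance (e.g. generator parameters and
#'   seed, or a file path).
#' @export
setClass("LFAImage",
  representation(pixels = "matrixOrArray", label = "character",
                 source = "list"),
  prototype(pixels = matrix(0, 1, 1), label = NA_character_, source = list())
)

setValidity("LFAImage", function(object) {
  px <- object@pixels
  if (!(length(dim(px)) %in% c(2L, 3L)))
    return("pixels must be a 2-D matrix or a 3-D (rows, cols, 3) array")
  if (length(dim(px)) == 3L && dim(px)[3] != 3L)
    return("3-D pixel arrays must have exactly 3 channels")
  if (anyNA(px) || min(px) < 0 || max(px) > 255)
    return("pixel values must lie in [0, 255]")
  if (length(object@label) != 1L)
    return("label must be a single character value")
  if (!is.na(object@label) && !object@label %in% tshLabels())
    return(sprintf("unknown label '%s'", object@label))
  TRUE
})

#' BinaryMask: a segmentation mask
#'
#' Logical pixel grid with the same shape as its source image; TRUE marks
#' foreground (line) pixels.
#'
#' @slot pixels logical matrix.
#' @slot polarity character(1), "dark" when foreground pixels are darker
#'   than background (colorimetric gold-nanoparticle lines) or "light".
#' @export
setClass("BinaryMask",
  representation(pixels = "matrix", polarity = "character"),
  prototype(pixels = matrix(FALSE, 1, 1), polarity = "dark")
)

setValidity("BinaryMask", function(object) {
  if (!is.logical(object@pixels)) return("mask pixels must be logical")
  if (!object@polarity %in% c("dark", "light"))
    return("polarity must be 'dark' or 'light'")
  TRUE
})

#' ROI: a detected test- or control-line region of interest
#'
#' Bounding box and pixel centroid of the largest 8-connected foreground
#' component in a segmented half, reported in full-image coordinates.
#' Intervals are 1-based and closed (R convention).
#'
#' @slot bbox integer(4): rowMin, colMin, rowMax, colMax (inclusive).
#' @slot centroid numeric(2): fractional (row, col) of the component
#'   centroid.
#' @slot side character(1), "test" or "control".
#' @export
setClass("ROI",
  representation(bbox = "integer", centroid = "numeric", side = "character"),
  prototype(bbox = c(1L, 1L, 1L, 1L), centroid = c(1, 1), side = "test")
)

setValidity("ROI", function(object) {
  b <- object@bbox
  if (length(b) != 4L) return("bbox must be length 4")
  if (b[3] < b[1] || b[4] < b[2]) return("bbox max must be >= min")
  if (!object@side %in% c("test", "control"))
    return("side must be 'test' or 'control'")
  ctr <- object@centroid
  if (length(ctr) != 2L) return("centroid must be length 2")
  if (ctr[1] < b[1] - 0.5 || ctr[1] > b[3] + 0.5 ||
      ctr[2] < b[2] - 0.5 || ctr[2] > b[4] + 0.5)
    return("centroid must lie inside the bounding box")
  TRUE
})

#' Patch: a 128 x 32 labelled sub-image
#'
#' A crop of a standardised strip image spanning the full 128-pixel image
#' height and 32 columns around a line ROI. Patch pixels are bitwise
#' sub-grids of the source image (no resampling).
#'
#' @slot pixels numeric 128 x 32 gray matrix.
#' @slot label character(1) concentration label of the source image.
#' @slot sourceImage character(1) identifier of the source image.
#' @slot side character(1), "test" or "control" line of origin.
#' @slot patchIndex integer(1) in 1..n_patches.
#' @export
setClass("Patch",
  representation(pixels = "matrix", label = "character",
                 sourceImage = "character", side = "character",
                 patchIndex = "integer"),
  prototype(pixels = matrix(0, 128, 32), label = NA_character_,
            sourceImage = NA_character_, side = "test", patchIndex = 1L)
)

setValidity("Patch", function(object) {
  if (!identical(dim(object@pixels), c(128L, 32L)))
    return(sprintf("patch must be 128 x 32, got %d x %d",
                   nrow(object@pixels), ncol(object@pixels)))
  if (!object@side %in% c("test", "control"))
    return("side must be 'test' or 'control'")
  TRUE
})

#' AHMOMatrix: averaged horizontal multi-offset co-occurrence matrix
#'
#' The Ng x Ng normalised gray-level co-occurrence matrix obtained by
#' averaging per-offset horizontal GLCMs (offsets d = 1..dMax), each
#' normalised to unit mass before averaging. Entries p(i, j) sum to 1.
#'
#' @slot p numeric Ng x Ng non-negative matrix summing to 1.
#' @slot nLevels integer(1), quantisation levels Ng.
#' @slot provenance list recording dMax, symmetric flag and normalisation
#'   order.
#' @export
setClass("AHMOMatrix",
  representation(p = "matrix", nLevels = "integer", provenance = "list"),
  prototype(p = matrix(1, 1, 1), nLevels = 1L, provenance = list())
)

setValidity("AHMOMatrix", function(object) {
  p <- object@p
  if (nrow(p) != ncol(p)) return("p must be square")
  if (nrow(p) != object@nLevels) return("p must be nLevels x nLevels")
  if (min(p) < 0) return("p entries must be non-negative")
  if (abs(sum(p) - 1) > 1e-12)
    return(sprintf("p must sum to 1 (got %.15g)", sum(p)))
  TRUE
})

setMethod("show", "LFAImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("LFAImage: %d x %d px%s, label = %s\n", d[1], d[2],
              if (length(d) == 3L) " (RGB)" else "",
              ifelse(is.na(object@label), "<none>", object@label)))
  if (length(object@source))
    cat("  source:", paste(names(object@source), collapse = ", "), "\n")
})

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask: %d x %d, %d foreground px (polarity %s)\n",
              nrow(object@pixels), ncol(object@pixels),
              sum(object@pixels), object@polarity))
})

setMethod("show", "ROI", function(object) {
  cat(sprintf("ROI (%s): rows [%d, %d], cols [%d, %d], centroid (%.2f, %.2f)\n",
              object@side, object@bbox[1], object@bbox[3], object@bbox[2],
              object@bbox[4], object@centroid[1], object@centroid[2]))
})

setMethod("show", "Patch", function(object) {
  cat(sprintf("Patch %d (%s line) of %s, label = %s, 128 x 32 px\n",
              object@patchIndex, object@side, object@sourceImage,
              object@label))
})

setMethod("show", "AHMOMatrix", function(object) {
  cat(sprintf("AHMOMatrix: %d levels, dMax = %s, %s\n", object@nLevels,
              ifelse(is.null(object@provenance$dMax), "?",
                     object@provenance$dMax),
              ifelse(isTRUE(object@provenance$symmetric), "symmetric",
                     "non-symmetric")))
})

#' @rdname pixels
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' Pixel grid accessors
#'
#' Extract the raw pixel grid from image-like objects.
#'
#' @param x an \code{LFAImage}, \code{BinaryMask}, or \code{Patch}.
#' @return The pixel matrix (or array for RGB images).
#' @name pixels
#' @export
setMethod("pixels", "LFAImage", function(x) x@pixels)

#' @rdname pixels
#' @export
setMethod("pixels", "BinaryMask", function(x) x@pixels)

#' @rdname pixels
#' @export
setMethod("pixels", "Patch", function(x) x@pixels)

#' @rdname imageLabel
#' @export
setGeneric("imageLabel", function(x) standardGeneric("imageLabel"))

#' Concentration label accessors
#'
#' @param x an \code{LFAImage} or \code{Patch}.
#' @return character(1) concentration label.
#' @name imageLabel
#' @export
setMethod("imageLabel", "LFAImage", function(x) x@label)

#' @rdname imageLabel
#' @export
setMethod("imageLabel", "Patch", function(x) x@label)

#' @rdname roiAccessors
#' @export
setGeneric("roiBbox", function(x) standardGeneric("roiBbox"))

#' ROI accessors
#'
#' @param x an \code{ROI}.
#' @return \code{roiBbox}: named integer(4) (rowMin, colMin, rowMax,
#'   colMax, 1-based inclusive); \code{roiCentroid}: numeric(2) (row, col);
#'   \code{roiSide}: character(1).
#' @name roiAccessors
#' @export
setMethod("roiBbox", "ROI", function(x) {
  stats::setNames(x@bbox, c("rowMin", "colMin", "rowMax", "colMax"))
})

#' @rdname roiAccessors
#' @export
setGeneric("roiCentroid", function(x) standardGeneric("roiCentroid"))

#' @rdname roiAccessors
#' @export
setMethod("roiCentroid", "ROI", function(x) x@centroid)

#' @rdname roiAccessors
#' @export
setGeneric("roiSide", function(x) standardGeneric("roiSide"))

#' @rdname roiAccessors
#' @export
setMethod("roiSide", "ROI", function(x) x@side)

#' @rdname ahmoAccessors
#' @export
setGeneric("ahmoProb", function(x) standardGeneric("ahmoProb"))

#' AHMOMatrix accessors
#'
#' @param x an \code{AHMOMatrix}.
#' @return \code{ahmoProb}: the Ng x Ng normalised probability matrix;
#'   \code{nLevels}: integer(1) quantisation level count.
#' @name ahmoAccessors
#' @export
setMethod("ahmoProb", "AHMOMatrix", function(x) x@p)

#' @rdname ahmoAccessors
#' @export
setGeneric("nLevels", function(x) standardGeneric("nLevels"))

#' @rdname ahmoAccessors
#' @export
setMethod("nLevels", "AHMOMatrix", function(x) x@nLevels)
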