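# Patch extraction: each segmented 500 x 128 strip image yields four
# 128 x 32 patches, two per line ROI, horizontally centred on the ROI
# centroid with column offsets {-8, +8} so every patch captures the line
# plus flanking membrane background. Placement is deterministic (derived
# from centroids), so the expansion is reproducible.

#' Extract fixed-size patches around the line ROIs
#'
#' Patches span the full 128-px image height and \code{patchWidth}
#' columns. With the default four patches, each ROI contributes two
#' patches whose column windows are centred on the ROI centroid shifted by
#' \code{offsets}; with \code{nPatches = 2}, one centred patch per ROI.
#' Crops are clamped to the image bounds; pixels are copied bitwise (no
#' resampling).
#'
#' @param image a standardised grayscale \code{\link{LFAImage}}
#'   (500 x 128).
#' @param rois list of \code{\link{ROI}} objects (one test, one control).
#' @param nPatches total patches per image; must be a multiple of
#'   \code{length(rois)} (default 4 = 2 per ROI).
#' @param offsets column offsets applied per ROI when two patches per ROI
#'   are requested.
#' @param patchWidth patch width in columns (default 32).
#' @param imageId identifier recorded in each patch.
#' @return list of \code{\link{Patch}} objects.
#' @export
extractPatches <- function(image, rois, nPatches = 4L,
                           offsets = c(-8L, 8L), patchWidth = 32L,
                           imageId = "image") {
  px <- pixels(image)
  W <- ncol(px)
  if (W < patchWidth)
    stop(sprintf("image '%s': width %d cannot fit a %d-column patch",
                 imageId, W, patchWidth))
  if (length(rois) == 0L) stop("no ROIs supplied")
  perRoi <- nPatches / length(rois)
  if (perRoi != round(perRoi) || perRoi < 1)
    stop("nPatches must be a positive multiple of the number of ROIs")
  offs <- if (perRoi == 1L) 0L else if (perRoi == 2L) offsets
          else stop("at most 2 patches per ROI are supported")
  patches <- list()
  k <- 0L
  for (roi in rois) {
    ctrCol <- roiCentroid(roi)[2]
    # centre a patchWidth window on the centroid pixel (1-based closed)
    base <- floor(ctrCol - 1) - (patchWidth %/% 2 - 1)
    for (off in offs) {
      start <- base + off
      start <- min(max(start, 1L), W - patchWidth + 1L)
      k <- k + 1L
      patches[[k]] <- methods::new("Patch",
        pixels = px[, start:(start + patchWidth - 1L), drop = FALSE],
        label = image@label, sourceImage = imageId,
        side = roiSide(roi), patchIndex = k)
    }
  }
  patches
}

#' Expand an image set into a labelled patch dataset
#'
#' Runs segmentation and patch extraction over a list of images,
#' quadrupling the dataset under defaults (800 images become 3200
#' patches). Per-image failures are recorded and the image skipped; more
#' than 1\% failures aborts.
#'
#' @param images list of \code{\link{LFAImage}} objects.
#' @param nPatches patches per image (default 4).
#' @param polarity,controlSide passed to \code{\link{segmentStrip}}.
#' @param offsets,patchWidth passed to \code{\link{extractPatches}}.
#' @return list with \code{patches} (list of \code{Patch}),
#'   \code{manifest} (data.frame: patch_id, label, source_image, side,
#'   patch_index), and \code{failures} (character vector of failed image
#'   ids).
#' @export
expandDataset <- function(images, nPatches = 4L, polarity = "dark",
                          controlSide = "left", offsets = c(-8L, 8L),
                          patchWidth = 32L) {
  patches <- list()
  rows <- list()
  failures <- character(0)
  for (i in seq_along(images)) {
    id <- sprintf("img%04d", i)
    res <- tryCatch({
      seg <- segmentStrip(images[[i]], polarity = polarity,
                          controlSide = controlSide)
      extractPatches(seg$image, seg$rois, nPatches = nPatches,
                     offsets = offsets, patchWidth = patchWidth,
                     imageId = id)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s", id, conditionMessage(res)))
      next
    }
    for (p in res) {
      rows[[length(rows) + 1L]] <- data.frame(
        patch_id = sprintf("%s_p%d", id, p@patchIndex), label = p@label,
        source_image = id, side = p@side, patch_index = p@patchIndex,
        stringsAsFactors = FALSE)
    }
    patches <- c(patches, res)
  }
  if (length(failures) > 0.01 * max(length(images), 1L))
    stop(sprintf("segmentation failed for %d of %d images:\n%s",
                 length(failures), length(images),
                 paste(utils::head(failures, 5), collapse = "\n")))
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patch_id = character(0), label = character(0),
               source_image = character(0), side = character(0),
               patch_index = integer(0), stringsAsFactors = FALSE)
  list(patches = patches, manifest = manifest, failures = failures)
}
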