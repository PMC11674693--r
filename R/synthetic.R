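# Synthetic LFA reader images: a light nitrocellulose membrane with grain
# noise, a control line of fixed darkness and a test line whose darkness and
# speckle texture vary monotonically with the concentration label.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded generation does not
#' disturb the caller's random stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  eval.parent(substitute(expr))
}

# deterministic per-item seed fan-out from a master seed
deriveSeed <- function(seed, index) {
  s <- (as.numeric(seed) %% 2147483647) * 7919 + as.numeric(index) * 104729
  as.integer(s %% 2147483647)
}

#' Synthetic strip generator parameters
#'
#' Defines the geometry and appearance statistics of synthetic LFA reader
#' images: a 700 x 145 px strip (width x height) with a control line of
#' fixed darkness and a test line whose mean darkness drop and speckle
#' texture increase with the concentration label. Defaults give a
#' high-signal dataset in which both intensity and texture carry class
#' information.
#'
#' @param imageWidth,imageHeight strip dimensions in px (reader output is
#'   700 x 145).
#' @param controlLineCenter,testLineCenter 1-based column centers of the
#'   control and test lines; the control line sits in the left half
#'   (sample-pad end) by default.
#' @param lineWidth line band width in px.
#' @param backgroundMean membrane background gray level in [0, 255].
#' @param backgroundGrainSd gray-level s.d. of i.i.d. membrane grain noise.
#' @param testLineDepthMap named numeric vector mapping each concentration
#'   label to the mean gray-level drop of the test line; must be
#'   non-decreasing over the ordered labels (strictly increasing under the
#'   defaults; a constant map gives a null configuration).
#' @param controlLineDepth gray-level drop of the control line at the
#'   lowest concentration.
#' @param controlDepletionRate fractional loss of control-line depth per
#'   label step (conjugate depletion: at high analyte more gold conjugate
#'   is captured at the test line, so less reaches the control line,
#'   which prints lighter and smoother). Effective control depth at label
#'   index l is controlLineDepth x (1 - rate x (l - 1)); 0 disables the
#'   effect (concentration-invariant control line).
#' @param illuminationGradientAmplitude peak-to-peak amplitude of a linear
#'   horizontal illumination ramp (gray levels); 0 disables it.
#' @param textureRoughness unitless >= 0 scale of the label-dependent
#'   speckle inside the test line (s.d. = roughness x label index, with a
#'   label-dependent correlation length); 0 removes all speckle.
#' @param labels ordered concentration labels.
#' @param rgb logical; if TRUE images are emitted as sepia-tinted 3-channel
#'   arrays (to exercise grayscale conversion), otherwise single-channel.
#' @return A validated list of class \code{"StripParams"}.
#' @export
#' @examples
#' p <- stripParams()
#' img <- generateStrip("0.5", p, seed = 7)
stripParams <- function(imageWidth = 700L, imageHeight = 145L,
                        controlLineCenter = 210L, testLineCenter = 490L,
                        lineWidth = 20L, backgroundMean = 205,
                        backgroundGrainSd = 3,
                        testLineDepthMap = NULL, controlLineDepth = 80,
                        controlDepletionRate = 0.05,
                        illuminationGradientAmplitude = 3,
                        textureRoughness = 1.5,
                        labels = tshLabels(), rgb = FALSE) {
  if (is.null(testLineDepthMap))
    testLineDepthMap <- stats::setNames(seq(25, 95, by = 10), labels)
  imageWidth <- as.integer(imageWidth); imageHeight <- as.integer(imageHeight)
  if (imageWidth <= 0 || imageHeight <= 0)
    stop("configuration error: image dimensions must be positive")
  if (lineWidth <= 0 || lineWidth >= imageWidth / 4)
    stop("configuration error: need 0 < lineWidth < imageWidth/4")
  for (ctr in c(controlLineCenter, testLineCenter))
    if (ctr - lineWidth / 2 < 1 || ctr + lineWidth / 2 > imageWidth)
      stop("configuration error: line band extends outside the image")
  if (abs(testLineCenter - controlLineCenter) < 2 * lineWidth)
    stop("configuration error: line centers closer than 2 x lineWidth")
  if (!all(labels %in% names(testLineDepthMap)))
    stop("testLineDepthMap must cover every label")
  d <- as.numeric(testLineDepthMap[labels])
  if (any(diff(d) < 0))
    stop("testLineDepthMap must be non-decreasing over the ordered labels")
  if (textureRoughness < 0) stop("textureRoughness must be >= 0")
  if (controlDepletionRate < 0 ||
      controlDepletionRate * (length(labels) - 1) >= 1)
    stop("controlDepletionRate must satisfy 0 <= rate * (nLabels - 1) < 1")
  structure(list(
    imageWidth = imageWidth, imageHeight = imageHeight,
    controlLineCenter = as.integer(controlLineCenter),
    testLineCenter = as.integer(testLineCenter),
    lineWidth = as.integer(lineWidth),
    backgroundMean = backgroundMean, backgroundGrainSd = backgroundGrainSd,
    testLineDepthMap = testLineDepthMap[labels],
    controlLineDepth = controlLineDepth,
    controlDepletionRate = controlDepletionRate,
    illuminationGradientAmplitude = illuminationGradientAmplitude,
    textureRoughness = textureRoughness, labels = labels, rgb = rgb),
    class = "StripParams")
}

#' Null-signal generator parameters
#'
#' A configuration in which per-label image distributions are exchangeable:
#' the test-line depth map is constant and the label-dependent speckle is
#' disabled, so no feature can carry class information and downstream
#' accuracy must sit at chance (12.5\% for 8 classes).
#'
#' @param depth constant test-line depth (gray levels).
#' @param ... further arguments passed to \code{\link{stripParams}}.
#' @return A \code{"StripParams"} object.
#' @export
nullStripParams <- function(depth = 60, ...) {
  stripParams(testLineDepthMap = stats::setNames(rep(depth, 8), tshLabels()),
              textureRoughness = 0, controlDepletionRate = 0, ...)
}

# 1-based column indices of a band of `width` px centred at `center`
bandCols <- function(center, width) {
  seq(center - floor((width - 1) / 2), length.out = width)
}

# spatially correlated speckle: box-smoothed white noise rescaled to `sd`
speckleField <- function(nr, nc, sd, halfwidth) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (halfwidth > 0) {
    k <- rep(1, 2 * halfwidth + 1)
    z <- t(apply(z, 1, function(r) as.numeric(
      stats::filter(c(rep(0, halfwidth), r, rep(0, halfwidth)), k,
                    sides = 2))[(halfwidth + 1):(halfwidth + nc)]))
    z <- apply(z, 2, function(cl) as.numeric(
      stats::filter(c(rep(0, halfwidth), cl, rep(0, halfwidth)), k,
                    sides = 2))[(halfwidth + 1):(halfwidth + nr)])
  }
  s <- stats::sd(as.numeric(z))
  if (s > 0) z <- z / s
  z * sd
}

#' Generate one synthetic strip image
#'
#' Renders a grainy membrane background with two darker vertical bands:
#' the control line at fixed depth and the test line at the depth mapped
#' from \code{label}, with concentration-dependent correlated speckle so
#' texture (not only mean intensity) discriminates the classes. Output is
#' bitwise deterministic for fixed (label, params, seed).
#'
#' @param label one of the configured concentration labels.
#' @param params a \code{\link{stripParams}} object.
#' @param seed integer seed.
#' @return An \code{\link{LFAImage}} with integer-valued 8-bit pixels.
#' @export
generateStrip <- function(label, params = stripParams(), seed = 1L) {
  label <- as.character(label)
  if (!label %in% names(params$testLineDepthMap))
    stop(sprintf("unknown label '%s'; expected one of %s", label,
                 paste(params$labels, collapse = ", ")))
  H <- params$imageHeight; W <- params$imageWidth
  labelIndex <- match(label, params$labels)
  withSeed(seed, {
    px <- matrix(params$backgroundMean, H, W)
    if (params$illuminationGradientAmplitude != 0) {
      ramp <- params$illuminationGradientAmplitude *
        (seq(0, 1, length.out = W) - 0.5)
      px <- px + matrix(ramp, H, W, byrow = TRUE)
    }
    px <- px + matrix(stats::rnorm(H * W, 0, params$backgroundGrainSd), H, W)
    nLab <- length(params$labels)
    cc <- bandCols(params$controlLineCenter, params$lineWidth)
    # conjugate depletion: the control line fades and smooths as more
    # conjugate is captured at the test line
    ctrlDepth <- params$controlLineDepth *
      (1 - params$controlDepletionRate * (labelIndex - 1))
    mirror <- nLab + 1L - labelIndex
    px[, cc] <- px[, cc] - ctrlDepth +
      if (params$textureRoughness > 0)
        speckleField(H, length(cc), params$textureRoughness * mirror,
                     round(mirror / 3)) else 0
    tc <- bandCols(params$testLineCenter, params$lineWidth)
    depth <- as.numeric(params$testLineDepthMap[label])
    px[, tc] <- px[, tc] - depth +
      if (params$textureRoughness > 0)
        speckleField(H, length(tc), params$textureRoughness * labelIndex,
                     round(labelIndex / 3)) else 0
    px <- round(pmax(pmin(px, 255), 0))
    if (params$rgb) {
      px <- array(c(px, round(px * 0.85), round(px * 0.65)), dim = c(H, W, 3))
    }
    methods::new("LFAImage", pixels = px, label = label,
                 source = list(type = "synthetic", seed = seed,
                               labelIndex = labelIndex))
  })
}

#' Generate a balanced labelled dataset of synthetic strips
#'
#' @param params a \code{\link{stripParams}} object.
#' @param nPerLabel images per concentration label (>= 1).
#' @param seed master seed; per-image seeds are derived deterministically.
#' @param outputDir optional directory; when given, 8-bit PNG images and a
#'   CSV manifest (\code{path,label}) are written there.
#' @return A list with \code{images} (list of \code{LFAImage}) and
#'   \code{manifest} (data.frame with columns \code{path}, \code{label}).
#' @export
generateDataset <- function(params = stripParams(), nPerLabel = 100L,
                            seed = 1L, outputDir = NULL) {
  if (nPerLabel < 1) stop("nPerLabel must be >= 1")
  labels <- params$labels
  n <- length(labels) * nPerLabel
  images <- vector("list", n)
  paths <- rep(NA_character_, n)
  labs <- character(n)
  if (!is.null(outputDir)) {
    ok <- dir.exists(outputDir) || dir.create(outputDir, recursive = TRUE,
                                              showWarnings = FALSE)
    if (!ok || file.access(outputDir, 2) != 0)
      stop(sprintf("I/O error: cannot write to output directory '%s'",
                   outputDir))
  }
  k <- 0L
  for (li in seq_along(labels)) {
    for (j in seq_len(nPerLabel)) {
      k <- k + 1L
      img <- generateStrip(labels[li], params, deriveSeed(seed, k))
      images[[k]] <- img
      labs[k] <- labels[li]
      if (!is.null(outputDir)) {
        fn <- file.path(outputDir,
                        sprintf("strip_%s_%03d.png", gsub("\\.", "p",
                                                          labels[li]), j))
        writeStripPNG(img, fn)
        paths[k] <- fn
      }
    }
  }
  manifest <- data.frame(path = paths, label = labs,
                         stringsAsFactors = FALSE)
  if (!is.null(outputDir))
    utils::write.csv(manifest, file.path(outputDir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
  list(images = images, manifest = manifest)
}

#' Write an LFAImage as an 8-bit PNG
#'
#' @param image an \code{LFAImage}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeStripPNG <- function(image, path) {
  px <- pixels(image) / 255
  png::writePNG(px, path)
  invisible(path)
}

#' Read a strip image from a PNG or TIFF file
#'
#' @param path image file path.
#' @param label optional concentration label.
#' @return An \code{\link{LFAImage}} with pixels scaled to [0, 255].
#' @export
readStripImage <- function(path, label = NA_character_) {
  ext <- tolower(tools::file_ext(path))
  px <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package")
    tiff::readTIFF(path)
  } else png::readPNG(path)
  if (length(dim(px)) == 3L && dim(px)[3] == 4L)
    px <- px[, , 1:3, drop = FALSE]  # drop alpha
  if (length(dim(px)) == 3L && dim(px)[3] == 1L) px <- px[, , 1]
  methods::new("LFAImage", pixels = round(px * 255),
               label = as.character(label),
               source = list(type = "file", path = path))
}
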