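# Pipeline orchestration. Two entry points: runEndToEnd() chains every
# stage in memory (the fast path used programmatically), and
# runPipeline() runs named stages against a working directory of plain
# artifacts (PNG images, CSV tables, JSON run manifests) so each stage is
# independently inspectable and re-runnable. A single master seed fans
# out deterministically to per-stage seeds.

#' Default pipeline configuration
#'
#' Nested list mirroring the JSON config consumed by
#' \code{\link{runPipeline}}; every stage reads only its own block.
#'
#' @return named nested list with blocks synthetic, preprocess, patches,
#'   glcm, features, mrmr, cnn, eval, io.
#' @export
defaultPipelineConfig <- function() {
  list(
    synthetic = list(n_per_label = 100L, image_width = 700L,
                     image_height = 145L, control_line_center = 210L,
                     test_line_center = 490L, line_width = 20L,
                     background_mean = 205, background_grain_sd = 3,
                     test_line_depth = as.list(stats::setNames(
                       seq(25, 95, by = 10), tshLabels())),
                     control_line_depth = 80,
                     control_depletion_rate = 0.05,
                     illumination_gradient_amplitude = 3,
                     texture_roughness = 1.5, rgb = FALSE),
    preprocess = list(target_width = 500L, target_height = 128L,
                      polarity = "dark", control_side = "left"),
    patches = list(n_patches = 4L, offsets = c(-8L, 8L), patch_width = 32L),
    glcm = list(levels = 64L, d_max = 25L, symmetric = FALSE,
                range_mode = "per_image", average = "normalised"),
    features = list(strict_printed_formulas = TRUE),
    mrmr = list(k = 9L, bins = 16L, criterion = "mid", train_only = TRUE),
    cnn = list(conv_filters = c(8L, 16L, 32L), fc_units = 8L, lr = 0.01,
               max_epochs = 10L, batch_size = 32L, momentum = 0.9,
               val_fraction = 0.15, shuffle_each_epoch = TRUE),
    eval = list(classifiers = classifierNames(),
                fractions = c(0.70, 0.15, 0.15)),
    io = list(workdir = "stripscan_run", log_level = "info"))
}

# reject config keys absent from the defaults, recursively
checkConfigKeys <- function(config, defaults = defaultPipelineConfig(),
                            path = "") {
  extra <- setdiff(names(config), names(defaults))
  if (length(extra))
    stop(sprintf("unknown config key(s)%s: %s",
                 if (nzchar(path)) paste0(" under ", path) else "",
                 paste(extra, collapse = ", ")))
  for (nm in names(config))
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) &&
        is.list(config[[nm]]))
      checkConfigKeys(config[[nm]], defaults[[nm]],
                      paste0(path, if (nzchar(path)) ".", nm))
  invisible(TRUE)
}

# merge user config over defaults (one level of nesting)
mergeConfig <- function(config) {
  def <- defaultPipelineConfig()
  checkConfigKeys(config, def)
  for (blk in names(config)) {
    if (is.list(config[[blk]]))
      for (k in names(config[[blk]])) def[[blk]][[k]] <- config[[blk]][[k]]
    else def[[blk]] <- config[[blk]]
  }
  def
}

#' Read a pipeline configuration from JSON
#'
#' Unknown keys are rejected; missing keys fall back to
#' \code{\link{defaultPipelineConfig}}.
#'
#' @param path JSON file path.
#' @return merged configuration list.
#' @export
readPipelineConfig <- function(path) {
  mergeConfig(jsonlite::read_json(path, simplifyVector = TRUE))
}

configToStripParams <- function(sc) {
  stripParams(imageWidth = sc$image_width, imageHeight = sc$image_height,
              controlLineCenter = sc$control_line_center,
              testLineCenter = sc$test_line_center,
              lineWidth = sc$line_width,
              backgroundMean = sc$background_mean,
              backgroundGrainSd = sc$background_grain_sd,
              testLineDepthMap = unlist(sc$test_line_depth),
              controlLineDepth = sc$control_line_depth,
              controlDepletionRate = sc$control_depletion_rate,
              illuminationGradientAmplitude =
                sc$illumination_gradient_amplitude,
              textureRoughness = sc$texture_roughness, rgb = isTRUE(sc$rgb))
}

configToGlcm <- function(gc) {
  glcmConfig(levels = gc$levels, dMax = gc$d_max, symmetric = gc$symmetric,
             rangeMode = gc$range_mode, average = gc$average)
}

#' Run the whole pipeline in memory
#'
#' Generates a balanced synthetic dataset, segments it, expands it into
#' patches, computes the 22 AHMO-GLCM texture features, ranks them by
#' mRMR on the training partition, trains the tabular CNN (monitored on
#' the validation partition) and evaluates the classifier battery on the
#' held-out test partition over the three feature sets (All, MRMR, CNN).
#'
#' @param config pipeline configuration (see
#'   \code{\link{defaultPipelineConfig}}); partial lists are merged over
#'   the defaults.
#' @param seed master seed; per-stage seeds are derived from it.
#' @param verbose print stage progress to stderr.
#' @return list with \code{features} (SummarizedExperiment), \code{split},
#'   \code{ranking}, \code{selected}, \code{cnn} (trained model),
#'   \code{cnnFeatures}, and \code{battery} (reports + summary).
#' @export
runEndToEnd <- function(config = list(), seed = 42L, verbose = FALSE) {
  cfg <- mergeConfig(config)
  say <- function(...) if (verbose) message(sprintf(...))
  params <- configToStripParams(cfg$synthetic)
  say("simulate: %d images x %d labels", cfg$synthetic$n_per_label, 8L)
  ds <- generateDataset(params, nPerLabel = cfg$synthetic$n_per_label,
                        seed = deriveSeed(seed, 1L))
  say("patches: segmenting %d images", length(ds$images))
  exp <- expandDataset(ds$images, nPatches = cfg$patches$n_patches,
                       polarity = cfg$preprocess$polarity,
                       controlSide = cfg$preprocess$control_side,
                       offsets = cfg$patches$offsets,
                       patchWidth = cfg$patches$patch_width)
  say("features: %d patches", length(exp$patches))
  se <- featuresForPatches(exp$patches, configToGlcm(cfg$glcm),
                           cfg$features$strict_printed_formulas)
  labels <- featureLabels(se)
  split <- stratifiedSplit(labels, fractions = cfg$eval$fractions,
                           seed = deriveSeed(seed, 2L))
  rankIdx <- if (isTRUE(cfg$mrmr$train_only)) split$train
             else seq_len(ncol(se))
  ranking <- rankFeatures(featureMatrix(se)[rankIdx, , drop = FALSE],
                          labels[rankIdx], bins = cfg$mrmr$bins,
                          criterion = cfg$mrmr$criterion)
  selected <- selectTop(ranking, k = cfg$mrmr$k)
  say("mrmr: top-%d = %s", cfg$mrmr$k, paste(selected, collapse = ", "))
  cnnCfg <- cnnConfig(convFilters = cfg$cnn$conv_filters,
                      fcUnits = cfg$cnn$fc_units, lr = cfg$cnn$lr,
                      maxEpochs = cfg$cnn$max_epochs,
                      batchSize = cfg$cnn$batch_size,
                      momentum = cfg$cnn$momentum,
                      valFraction = cfg$cnn$val_fraction,
                      shuffleEachEpoch = cfg$cnn$shuffle_each_epoch,
                      seed = deriveSeed(seed, 3L))
  model <- buildCNN(cnnCfg, inputHeight = nrow(se))
  model <- trainCNN(model, featureMatrix(se)[split$train, , drop = FALSE],
                    labels[split$train],
                    valX = featureMatrix(se)[split$val, , drop = FALSE],
                    valLabels = labels[split$val])
  say("cnn: final val accuracy %.2f%%",
      100 * utils::tail(model$history$val_acc, 1))
  seCNN <- cnnFeatures(model, se)
  battery <- runBattery(list(All = se, MRMR = se[selected, ], CNN = seCNN),
                        split, classifiers = cfg$eval$classifiers,
                        seed = deriveSeed(seed, 4L))
  say("evaluate: best test accuracy %.2f%%", max(battery$summary$accuracy))
  list(features = se, split = split, ranking = ranking,
       selected = selected, cnn = model, cnnFeatures = seCNN,
       battery = battery)
}

# ---- file-based stages ----

stageOrder <- function() c("simulate", "preprocess", "patches", "features",
                           "select", "cnn", "evaluate")

configHash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(cfg, f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

writeRunManifest <- function(workdir, stage, cfg, seed, outputs) {
  jsonlite::write_json(
    list(stage = stage, config_md5 = configHash(cfg), seed = seed,
         outputs = outputs, package = "stripscan",
         version = as.character(utils::packageVersion("stripscan")),
         time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    file.path(workdir, sprintf("run_%s.json", stage)), auto_unbox = TRUE)
}

requireUpstream <- function(workdir, stage, cfg, force) {
  mf <- file.path(workdir, sprintf("run_%s.json", stage))
  if (!file.exists(mf))
    stop(sprintf("missing upstream artifacts: run stage '%s' first", stage))
  info <- jsonlite::read_json(mf)
  if (!force && !identical(info$config_md5, unname(configHash(cfg))))
    stop(sprintf(paste0("stale artifacts: stage '%s' was produced under a ",
                        "different config (use force = TRUE to override)"),
                 stage))
  invisible(info)
}

featureTableFromCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(label = "character"))
  meta <- c("patch_id", "label", "source_image", "side", "patch_index")
  featCols <- setdiff(names(df), meta)
  mat <- t(as.matrix(df[, featCols, drop = FALSE]))
  colnames(mat) <- df$patch_id
  SummarizedExperiment::SummarizedExperiment(
    assays = stats::setNames(list(mat), if ("cnn001" %in% featCols) "cnn"
                             else "features"),
    colData = S4Vectors::DataFrame(
      label = factor(df$label, levels = tshLabels()),
      source_image = df$source_image, side = df$side,
      patch_index = df$patch_index, row.names = df$patch_id))
}

featureTableToCSV <- function(se, path) {
  cd <- SummarizedExperiment::colData(se)
  df <- cbind(data.frame(patch_id = colnames(se),
                         label = as.character(cd$label),
                         source_image = cd$source_image, side = cd$side,
                         patch_index = cd$patch_index,
                         stringsAsFactors = FALSE),
              as.data.frame(featureMatrix(se)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Run one pipeline stage against a working directory
#'
#' Stages (\code{simulate}, \code{preprocess}, \code{patches},
#' \code{features}, \code{select}, \code{cnn}, \code{evaluate}, or
#' \code{all}) exchange plain artifacts under \code{workdir}: PNG images,
#' CSV tables and JSON run manifests recording the config hash and seed.
#' A stage refuses to run on artifacts produced under a different config
#' unless \code{force = TRUE}.
#'
#' @param stage stage name or \code{"all"}.
#' @param config configuration list (merged over
#'   \code{\link{defaultPipelineConfig}}) or a JSON file path.
#' @param workdir working directory (default from the config's io block).
#' @param seed master seed.
#' @param force run even when upstream artifacts carry a different config
#'   hash.
#' @param verbose log stage progress to stderr.
#' @return invisibly, the path(s) of the stage's main artifact(s).
#' @export
runPipeline <- function(stage = "all", config = list(), workdir = NULL,
                        seed = 42L, force = FALSE, verbose = TRUE) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- mergeConfig(config)
  if (is.null(workdir)) workdir <- cfg$io$workdir
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  stage <- match.arg(stage, c("all", stageOrder()))
  if (stage == "all") {
    for (st in stageOrder())
      runPipeline(st, config, workdir, seed, force, verbose)
    return(invisible(file.path(workdir, "summary.csv")))
  }
  say <- function(...) if (verbose)
    message(sprintf("[%s] %s", stage, sprintf(...)))
  t0 <- Sys.time()
  out <- switch(stage,
    simulate = {
      imgDir <- file.path(workdir, "images")
      ds <- generateDataset(configToStripParams(cfg$synthetic),
                            nPerLabel = cfg$synthetic$n_per_label,
                            seed = deriveSeed(seed, 1L), outputDir = imgDir)
      say("%d images written", nrow(ds$manifest))
      file.path(imgDir, "manifest.csv")
    },
    preprocess = {
      requireUpstream(workdir, "simulate", cfg, force)
      man <- utils::read.csv(file.path(workdir, "images", "manifest.csv"),
                             colClasses = "character")
      stdDir <- file.path(workdir, "standardised")
      dir.create(stdDir, showWarnings = FALSE)
      rows <- list()
      for (i in seq_len(nrow(man))) {
        img <- readStripImage(man$path[i], man$label[i])
        seg <- segmentStrip(img, polarity = cfg$preprocess$polarity,
                            controlSide = cfg$preprocess$control_side)
        outPng <- file.path(stdDir, basename(man$path[i]))
        writeStripPNG(seg$image, outPng)
        for (roi in seg$rois) {
          b <- roiBbox(roi)
          rows[[length(rows) + 1L]] <- data.frame(
            image = basename(man$path[i]), label = man$label[i],
            side = roiSide(roi), row_min = b[1], col_min = b[2],
            row_max = b[3], col_max = b[4],
            centroid_row = roiCentroid(roi)[1],
            centroid_col = roiCentroid(roi)[2])
        }
      }
      roiCsv <- file.path(workdir, "rois.csv")
      utils::write.csv(do.call(rbind, rows), roiCsv, row.names = FALSE,
                       quote = FALSE)
      say("%d images standardised, ROIs written", nrow(man))
      roiCsv
    },
    patches = {
      requireUpstream(workdir, "preprocess", cfg, force)
      rois <- utils::read.csv(file.path(workdir, "rois.csv"),
                              colClasses = c(label = "character"))
      patchDir <- file.path(workdir, "patches")
      dir.create(patchDir, showWarnings = FALSE)
      rows <- list()
      for (imgName in unique(rois$image)) {
        sub <- rois[rois$image == imgName, ]
        img <- readStripImage(file.path(workdir, "standardised", imgName),
                              sub$label[1])
        roiList <- lapply(seq_len(nrow(sub)), function(r) methods::new(
          "ROI", bbox = as.integer(sub[r, c("row_min", "col_min",
                                            "row_max", "col_max")]),
          centroid = as.numeric(sub[r, c("centroid_row", "centroid_col")]),
          side = sub$side[r]))
        pts <- extractPatches(img, roiList, nPatches = cfg$patches$n_patches,
                              offsets = cfg$patches$offsets,
                              patchWidth = cfg$patches$patch_width,
                              imageId = tools::file_path_sans_ext(imgName))
        for (p in pts) {
          pid <- sprintf("%s_p%d", p@sourceImage, p@patchIndex)
          png::writePNG(pixels(p) / 255,
                        file.path(patchDir, paste0(pid, ".png")))
          rows[[length(rows) + 1L]] <- data.frame(
            patch_path = file.path(patchDir, paste0(pid, ".png")),
            patch_id = pid, label = p@label, source_image = p@sourceImage,
            side = p@side, patch_index = p@patchIndex)
        }
      }
      pman <- file.path(patchDir, "manifest.csv")
      utils::write.csv(do.call(rbind, rows), pman, row.names = FALSE,
                       quote = FALSE)
      say("%d patches written", length(rows))
      pman
    },
    features = {
      requireUpstream(workdir, "patches", cfg, force)
      man <- utils::read.csv(file.path(workdir, "patches", "manifest.csv"),
                             colClasses = c(label = "character"))
      patches <- lapply(seq_len(nrow(man)), function(i) {
        img <- readStripImage(man$patch_path[i], man$label[i])
        methods::new("Patch", pixels = pixels(img), label = man$label[i],
                     sourceImage = man$source_image[i], side = man$side[i],
                     patchIndex = as.integer(man$patch_index[i]))
      })
      se <- featuresForPatches(patches, configToGlcm(cfg$glcm),
                               cfg$features$strict_printed_formulas)
      featureTableToCSV(se, file.path(workdir, "features.csv"))
      say("feature table %d x %d written", ncol(se), nrow(se))
      file.path(workdir, "features.csv")
    },
    select = {
      requireUpstream(workdir, "features", cfg, force)
      se <- featureTableFromCSV(file.path(workdir, "features.csv"))
      labels <- featureLabels(se)
      split <- stratifiedSplit(labels, fractions = cfg$eval$fractions,
                               seed = deriveSeed(seed, 2L))
      idx <- if (isTRUE(cfg$mrmr$train_only)) split$train
             else seq_len(ncol(se))
      ranking <- rankFeatures(featureMatrix(se)[idx, , drop = FALSE],
                              labels[idx], bins = cfg$mrmr$bins,
                              criterion = cfg$mrmr$criterion)
      utils::write.csv(ranking, file.path(workdir, "mrmr.csv"),
                       row.names = FALSE, quote = FALSE)
      say("ranking written; top-%d: %s", cfg$mrmr$k,
          paste(selectTop(ranking, cfg$mrmr$k), collapse = ", "))
      file.path(workdir, "mrmr.csv")
    },
    cnn = {
      requireUpstream(workdir, "features", cfg, force)
      se <- featureTableFromCSV(file.path(workdir, "features.csv"))
      labels <- featureLabels(se)
      split <- stratifiedSplit(labels, fractions = cfg$eval$fractions,
                               seed = deriveSeed(seed, 2L))
      cnnCfg <- cnnConfig(convFilters = cfg$cnn$conv_filters,
                          fcUnits = cfg$cnn$fc_units, lr = cfg$cnn$lr,
                          maxEpochs = cfg$cnn$max_epochs,
                          batchSize = cfg$cnn$batch_size,
                          momentum = cfg$cnn$momentum,
                          valFraction = cfg$cnn$val_fraction,
                          shuffleEachEpoch = cfg$cnn$shuffle_each_epoch,
                          seed = deriveSeed(seed, 3L))
      model <- buildCNN(cnnCfg, inputHeight = nrow(se))
      model <- trainCNN(model,
                        featureMatrix(se)[split$train, , drop = FALSE],
                        labels[split$train],
                        valX = featureMatrix(se)[split$val, , drop = FALSE],
                        valLabels = labels[split$val])
      utils::write.csv(model$history, file.path(workdir, "cnn_history.csv"),
                       row.names = FALSE, quote = FALSE)
      featureTableToCSV(cnnFeatures(model, se),
                        file.path(workdir, "cnn_features.csv"))
      say("CNN trained; final val accuracy %.2f%%",
          100 * utils::tail(model$history$val_acc, 1))
      file.path(workdir, "cnn_features.csv")
    },
    evaluate = {
      requireUpstream(workdir, "features", cfg, force)
      requireUpstream(workdir, "select", cfg, force)
      requireUpstream(workdir, "cnn", cfg, force)
      se <- featureTableFromCSV(file.path(workdir, "features.csv"))
      ranking <- utils::read.csv(file.path(workdir, "mrmr.csv"))
      seCNN <- featureTableFromCSV(file.path(workdir, "cnn_features.csv"))
      labels <- featureLabels(se)
      split <- stratifiedSplit(labels, fractions = cfg$eval$fractions,
                               seed = deriveSeed(seed, 2L))
      selected <- selectTop(ranking, cfg$mrmr$k)
      battery <- runBattery(
        list(All = se, MRMR = se[selected, ], CNN = seCNN), split,
        classifiers = cfg$eval$classifiers, seed = deriveSeed(seed, 4L))
      utils::write.csv(battery$summary, file.path(workdir, "summary.csv"),
                       row.names = FALSE, quote = FALSE)
      for (nm in names(battery$reports))
        utils::write.csv(battery$reports[[nm]]$confusion,
                         file.path(workdir, sprintf("confusion_%s.csv", nm)))
      say("best test accuracy %.2f%%", max(battery$summary$accuracy))
      file.path(workdir, "summary.csv")
    })
  writeRunManifest(workdir, stage, cfg, seed, out)
  say("done in %.1fs", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(out)
}
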