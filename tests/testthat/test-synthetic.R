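# Synthetic strip generator: determinism, geometry, monotone signal.

test_that("generation is bitwise deterministic for fixed seed and params", {
  p <- stripParams()
  a <- generateStrip("0.5", p, seed = 7)
  b <- generateStrip("0.5", p, seed = 7)
  expect_identical(pixels(a), pixels(b))
  d1 <- generateDataset(p, nPerLabel = 2L, seed = 11)
  d2 <- generateDataset(p, nPerLabel = 2L, seed = 11)
  expect_identical(lapply(d1$images, pixels), lapply(d2$images, pixels))
  # different seed changes pixels
  expect_false(identical(pixels(a), pixels(generateStrip("0.5", p, 8))))
})

test_that("noise-free configuration gives a flat background outside the lines", {
  p <- stripParams(backgroundGrainSd = 0, illuminationGradientAmplitude = 0,
                   textureRoughness = 0)
  img <- generateStrip("5", p, seed = 1)
  px <- pixels(img)
  lineCols <- c(outer(-(p$lineWidth):p$lineWidth,
                      c(p$controlLineCenter, p$testLineCenter), `+`))
  bg <- px[, setdiff(seq_len(ncol(px)), lineCols)]
  expect_true(all(bg == p$backgroundMean))
  # the two bands are darker than the background
  expect_lt(mean(px[, p$testLineCenter]), p$backgroundMean)
  expect_lt(mean(px[, p$controlLineCenter]), p$backgroundMean)
})

test_that("test-line darkness increases monotonically with concentration", {
  p <- stripParams()
  tc <- seq(p$testLineCenter - 5, p$testLineCenter + 5)
  bandMean <- function(label, seed)
    mean(pixels(generateStrip(label, p, seed))[, tc])
  lowVsHigh <- vapply(1:20, function(s)
    bandMean("100", s) < bandMean("0.5", s), logical(1))
  expect_true(all(lowVsHigh))
  # full ordering of per-label band means, averaged over seeds
  avg <- vapply(tshLabels(), function(l)
    mean(vapply(1:5, function(s) bandMean(l, s), numeric(1))), numeric(1))
  expect_true(all(diff(avg) < 0))
})

test_that("dataset generation is balanced and writes a consistent manifest", {
  p <- stripParams()
  d <- generateDataset(p, nPerLabel = 1L, seed = 3)
  expect_length(d$images, 8L)
  expect_setequal(vapply(d$images, imageLabel, character(1)), tshLabels())
  out <- withr::local_tempdir()
  d5 <- generateDataset(p, nPerLabel = 5L, seed = 3, outputDir = out)
  expect_equal(nrow(d5$manifest), 40L)
  expect_true(all(file.exists(d5$manifest$path)))
  man <- read.csv(file.path(out, "manifest.csv"),
                  colClasses = "character")
  expect_identical(names(man), c("path", "label"))
  expect_equal(nrow(man), 40L)
  expect_equal(unname(table(man$label))[1], 5L)
  # PNG round trip preserves 8-bit pixels
  back <- readStripImage(d5$manifest$path[1], d5$manifest$label[1])
  expect_equal(pixels(back), pixels(d5$images[[1]]))
})

test_that("invalid configurations and labels raise labelled errors", {
  expect_error(generateStrip("7", stripParams(), 1), "unknown label")
  expect_error(stripParams(imageWidth = 0), "positive")
  expect_error(stripParams(lineWidth = 300), "lineWidth")
  expect_error(stripParams(controlLineCenter = 480), "2 x lineWidth")
  expect_error(stripParams(testLineDepthMap = setNames(
    seq(95, 25, by = -10), tshLabels())), "non-decreasing")
  expect_error(generateDataset(stripParams(), nPerLabel = 0), ">= 1")
})

test_that("null configuration removes every label-dependent signal source", {
  p <- nullStripParams()
  expect_true(all(diff(as.numeric(p$testLineDepthMap)) == 0))
  expect_identical(p$textureRoughness, 0)
  expect_identical(p$controlDepletionRate, 0)
  # identical seeds across labels give identical pixel distributions
  a <- pixels(generateStrip("0.5", p, seed = 5))
  b <- pixels(generateStrip("100", p, seed = 5))
  expect_identical(a, b)
})

test_that("RGB mode emits 3 channels that collapse back to the gray strip", {
  p <- stripParams(rgb = TRUE)
  img <- generateStrip("1", p, seed = 2)
  expect_identical(dim(pixels(img))[3], 3L)
  g <- toGrayscale(pixels(img))
  expect_identical(dim(g), dim(pixels(img))[1:2])
  expect_true(all(g >= 0 & g <= 255))
})
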