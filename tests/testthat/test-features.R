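# Marginal statistics and the 22 texture features.

test_that("marginal statistics match enumeration on small matrices", {
  # all mass at (1,1)
  p1 <- matrix(0, 3, 3); p1[1, 1] <- 1
  m1 <- glcmMarginals(p1)
  expect_equal(m1$mux, 1); expect_equal(m1$muy, 1)
  expect_equal(m1$sigx, 0); expect_equal(m1$sigy, 0)
  # uniform over Ng = 2
  p2 <- matrix(0.25, 2, 2)
  m2 <- glcmMarginals(p2)
  expect_equal(m2$mux, 1.5); expect_equal(m2$muy, 1.5)
  expect_equal(unname(m2$pXplusY), c(0.25, 0.5, 0.25))
  expect_identical(names(m2$pXplusY), c("2", "3", "4"))
  expect_equal(unname(m2$pXminusY), c(0.5, 0.5))
  # every distribution sums to 1
  set.seed(2)
  p3 <- randomNormalisedMatrix(6)
  m3 <- glcmMarginals(p3)
  for (d in list(m3$px, m3$py, m3$pXplusY, m3$pXminusY))
    expect_equal(sum(d), 1, tolerance = 1e-12)
  # sd two ways: definition vs E[X^2] - mu^2
  ex2 <- sum((1:6)^2 * m3$px)
  expect_equal(m3$sigx, sqrt(ex2 - m3$mux^2), tolerance = 1e-12)
  expect_error(glcmMarginals(p3 * 2), "not normalised")
})

test_that("degenerate texture yields the closed-form feature values", {
  p <- matrix(0, 4, 4); p[2, 2] <- 1
  f <- computeFeatures(p)
  expect_equal(unname(f["energ"]), 1)
  expect_equal(unname(f["entro"]), 0)
  expect_equal(unname(f["contr"]), 0)
  expect_equal(unname(f["homom"]), 1)
  expect_equal(unname(f["maxpr"]), 1)
  expect_equal(unname(f["dissi"]), 0)
  expect_equal(unname(f["corrm"]), 0)  # degenerate marginals rule
})

test_that("hand-derived values hold on the toy co-occurrence matrix", {
  p <- glcmSingleOffset(toyQuantised(), 1) / 12
  f <- computeFeatures(p)
  expect_equal(unname(f["homom"]), 9.8333 / 12, tolerance = 1e-4)
  expect_equal(unname(f["maxpr"]), 3 / 12)
  # checkerboard of two adjacent levels: every pair differs by exactly 1
  cb <- matrix(c(0L, 1L), 8, 8)
  cb[, seq(2, 8, 2)] <- 1L - cb[, seq(2, 8, 2)]
  qcb <- structure(list(levels = cb, nLevels = 2L, range = c(0, 1)),
                   class = "QuantisedPatch")
  pcb <- glcmSingleOffset(qcb, 1)
  expect_equal(unname(computeFeatures(pcb / sum(pcb))["contr"]), 1)
})

test_that("all 22 features match the naive oracle on random matrices", {
  set.seed(23)
  for (trial in 1:50) {
    Ng <- sample(2:8, 1)
    p <- randomNormalisedMatrix(Ng)
    f <- computeFeatures(p)
    ref <- naiveFeatures(p)
    expect_identical(names(f), textureFeatureNames())
    expect_lt(max(abs(f - ref[names(f)])), 1e-10)
  }
})

test_that("features respect their theoretical ranges", {
  set.seed(31)
  for (trial in 1:20) {
    p <- randomNormalisedMatrix(sample(2:8, 1))
    f <- computeFeatures(p)
    expect_true(all(is.finite(f)))
    for (nm in c("energ", "homom", "indnc", "idmnc", "maxpr")) {
      expect_gt(f[[nm]], 0)
      expect_lte(f[[nm]], 1)
    }
    for (nm in c("entro", "senth", "denth")) expect_gte(f[[nm]], 0)
    expect_gte(f[["corrm"]], -1); expect_lte(f[["corrm"]], 1)
  }
})

test_that("features of a symmetric matrix are transpose-invariant", {
  set.seed(37)
  m <- randomNormalisedMatrix(6)
  p <- (m + t(m)) / 2
  f <- computeFeatures(p)
  ft <- computeFeatures(t(p))
  expect_equal(f, ft, tolerance = 1e-12)
  expect_true(is.finite(f[["inf1h"]]) && is.finite(f[["inf2h"]]))
})

test_that("the printed inverse-difference form differs from the library form", {
  set.seed(43)
  p <- randomNormalisedMatrix(5)
  strict <- computeFeatures(p, strictPrintedFormulas = TRUE)
  loose <- computeFeatures(p, strictPrintedFormulas = FALSE)
  expect_equal(unname(strict["indnc"]), unname(strict["homop"]))
  expect_false(isTRUE(all.equal(strict["indnc"], loose["indnc"])))
  # only indnc is affected by the switch
  same <- setdiff(textureFeatureNames(), "indnc")
  expect_equal(strict[same], loose[same], tolerance = 1e-14)
})

test_that("the patch feature table carries labels and is reproducible", {
  p <- stripParams()
  seg <- segmentStrip(generateStrip("2.5", p, seed = 4))
  patches <- extractPatches(seg$image, seg$rois, imageId = "imgA")
  se <- featuresForPatches(patches)
  expect_identical(dim(se), c(22L, 4L))
  expect_identical(rownames(se), textureFeatureNames())
  expect_true(all(featureLabels(se) == "2.5"))
  expect_identical(SummarizedExperiment::colData(se)$side,
                   c("control", "control", "test", "test"))
  se2 <- featuresForPatches(patches)
  expect_identical(featureMatrix(se), featureMatrix(se2))
  expect_error(featuresForPatches(list()), "no patches")
})
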