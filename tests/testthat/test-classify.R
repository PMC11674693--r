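# Stratified splitting, the classifier battery, and micro-averaged
# evaluation metrics.

randomConfusion <- function(K = 8, diagWeight = 6) {
  cm <- matrix(rpois(K * K, 2), K, K) + diag(rpois(K, diagWeight), K)
  dimnames(cm) <- list(tshLabels()[1:K], tshLabels()[1:K])
  cm
}

test_that("stratified split matches fractions, is disjoint and seeded", {
  y <- factor(rep(tshLabels(), each = 400), levels = tshLabels())
  sp <- stratifiedSplit(y, seed = 42)
  expect_length(sp$train, 2240L)
  expect_length(sp$val, 480L)
  expect_length(sp$test, 480L)
  expect_identical(sort(c(sp$train, sp$val, sp$test)), seq_along(y))
  expect_identical(length(intersect(sp$train, sp$test)), 0L)
  for (part in sp)
    expect_true(all(table(y[part]) == length(part) / 8))
  expect_identical(stratifiedSplit(y, seed = 42), sp)
  expect_false(identical(stratifiedSplit(y, seed = 43), sp))
  tiny <- factor(c(rep("0.5", 2), rep("1", 40)), levels = tshLabels())
  expect_error(stratifiedSplit(tiny), "'0.5'")
  expect_error(stratifiedSplit(y, fractions = c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("every classifier separates well-separated clusters perfectly", {
  withr::with_seed(8, {
    y <- factor(rep(tshLabels()[1:2], each = 40),
                levels = tshLabels()[1:2])
    x <- matrix(rnorm(80 * 5), 80, 5) +
      outer(as.integer(y) * 10, rep(1, 5))
    colnames(x) <- letters[1:5]
  })
  for (clf in classifierNames()) {
    m <- trainClassifier(clf, x, y, seed = 1)
    expect_true(all(predict(m, x) == y), label = clf)
  }
  expect_error(trainClassifier("forest_of_doom", x, y), "valid names")
})

test_that("label-shuffled features score near chance on held-out data", {
  withr::with_seed(9, {
    y <- factor(rep(tshLabels(), each = 50), levels = tshLabels())
    x <- matrix(rnorm(400 * 10), 400, 10)
    colnames(x) <- letters[1:10]
    test <- sample(400, 100)
  })
  for (clf in c("lda", "knn")) {
    m <- trainClassifier(clf, x[-test, ], y[-test], seed = 2)
    acc <- mean(predict(m, x[test, ]) == y[test])
    expect_lt(abs(acc - 0.125), 0.125)  # generous chance band
  }
})

test_that("stochastic learners are reproducible under a fixed seed", {
  withr::with_seed(10, {
    y <- factor(rep(tshLabels(), each = 30), levels = tshLabels())
    x <- matrix(rnorm(240 * 8), 240, 8) +
      outer(as.integer(y), rep(0.5, 8))
    colnames(x) <- letters[1:8]
  })
  for (clf in c("wide_nn", "ensemble_bagged", "ensemble_boosted", "knn")) {
    p1 <- predict(trainClassifier(clf, x, y, seed = 3), x)
    p2 <- predict(trainClassifier(clf, x, y, seed = 3), x)
    expect_identical(p1, p2, label = clf)
  }
})

test_that("perfect predictions give 100% on all three metrics", {
  y <- factor(rep(tshLabels(), each = 5), levels = tshLabels())
  cm <- confusionMatrix(y, y)
  expect_identical(sum(diag(cm)), 40L)
  met <- confusionMetrics(cm)
  expect_equal(met$accuracy, 100)
  expect_equal(met$sensitivity, 100)
  expect_equal(met$specificity, 100)
  expect_error(confusionMetrics(matrix(0, 3, 3)), "empty")
})

test_that("micro metric identities hold on random confusion matrices", {
  set.seed(12)
  for (trial in 1:200) {
    cm <- randomConfusion()
    met <- confusionMetrics(cm)
    acc <- met$accuracy / 100
    expect_equal(met$sensitivity, met$accuracy, tolerance = 1e-12)
    expect_equal(met$specificity / 100, 1 - (1 - acc) / 7,
                 tolerance = 1e-12)
    expect_equal(sum(met$perClass$TP) + sum(met$perClass$FN), sum(cm))
  }
  # the published pairing: accuracy 97.29% implies specificity 99.61%
  expect_equal(round((1 - (1 - 0.9729) / 7) * 100, 2), 99.61)
})

test_that("evaluation reports are complete and reject unknown labels", {
  withr::with_seed(13, {
    y <- factor(rep(tshLabels()[1:3], each = 20),
                levels = tshLabels()[1:3])
    x <- matrix(rnorm(60 * 4), 60, 4) + outer(as.integer(y) * 4, rep(1, 4))
    colnames(x) <- letters[1:4]
  })
  m <- trainClassifier("lda", x, y, seed = 1)
  rep <- evaluateModel(m, x, y, featureSet = "All")
  expect_s3_class(rep, "evalReport")
  expect_identical(dim(rep$confusion), c(3L, 3L))
  expect_true(all(c(rep$accuracy, rep$sensitivity, rep$specificity) >= 0 &
                  c(rep$accuracy, rep$sensitivity, rep$specificity) <= 100))
  bad <- factor(rep("100", 60), levels = tshLabels())
  expect_error(evaluateModel(m, x, bad), "outside training schema")
})

test_that("the battery evaluates every classifier on every feature set", {
  p <- stripParams()
  imgs <- generateDataset(p, nPerLabel = 3L, seed = 21)$images
  exp <- expandDataset(imgs)
  se <- featuresForPatches(exp$patches)
  split <- stratifiedSplit(featureLabels(se), seed = 1)
  sets <- list(All = se, MRMR = se[1:9, ])
  bat <- runBattery(sets, split, classifiers = c("lda", "knn"), seed = 2)
  expect_length(bat$reports, 4L)
  expect_identical(nrow(bat$summary), 4L)
  expect_identical(sort(unique(bat$summary$feature_set)), c("All", "MRMR"))
  expect_true(all(bat$summary$sensitivity == bat$summary$accuracy))
  # misalignment is rejected
  seBad <- se[, c(2:ncol(se), 1)]
  expect_error(runBattery(list(All = se, MRMR = seBad), split),
               "misaligned")
  expect_error(runBattery(list(se), split), "named list")
})
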