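# Classifier battery and evaluation: stratified 70/15/15 split, eight
# classical classifiers over any feature set (all 22 texture features, the
# mRMR top-9, or CNN-derived features), and micro-averaged metrics. With
# pooled one-vs-rest counts over K classes, micro sensitivity equals
# accuracy (both are trace/total) and pooled specificity equals
# 1 - (1 - accuracy)/(K - 1); this is the structure visible in published
# multi-class confusion-matrix tables where every sensitivity column
# repeats the accuracy column.

# single-hidden-layer MLP (ReLU + softmax) trained by mini-batch SGDM;
# used for the wide (100-unit) and medium (25-unit) neural networks. Kept
# deliberately small and deterministic (seeded init and shuffling).
trainMLP <- function(x, labels, hidden, lr = 0.01, momentum = 0.9,
                     epochs = 60L, batchSize = 32L) {
  K <- nlevels(labels)
  n <- nrow(x); p <- ncol(x)
  yIdx <- as.integer(labels)
  W1 <- matrix(stats::rnorm(p * hidden) * sqrt(2 / p), p, hidden)
  b1 <- numeric(hidden)
  W2 <- matrix(stats::rnorm(hidden * K) * sqrt(2 / hidden), hidden, K)
  b2 <- numeric(K)
  vW1 <- W1 * 0; vb1 <- b1; vW2 <- W2 * 0; vb2 <- b2
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), yIdx)] <- 1
  for (ep in seq_len(epochs)) {
    ord <- sample(n)
    for (start in seq(1L, n, by = batchSize)) {
      idx <- ord[start:min(start + batchSize - 1L, n)]
      Xb <- x[idx, , drop = FALSE]
      A <- sweep(Xb %*% W1, 2, b1, `+`)
      H <- A * (A > 0)
      probs <- softmaxRows(sweep(H %*% W2, 2, b2, `+`))
      dL <- (probs - Y[idx, , drop = FALSE]) / length(idx)
      gW2 <- crossprod(H, dL); gb2 <- colSums(dL)
      dH <- (dL %*% t(W2)) * (A > 0)
      gW1 <- crossprod(Xb, dH); gb1 <- colSums(dH)
      vW1 <- momentum * vW1 - lr * gW1; W1 <- W1 + vW1
      vb1 <- momentum * vb1 - lr * gb1; b1 <- b1 + vb1
      vW2 <- momentum * vW2 - lr * gW2; W2 <- W2 + vW2
      vb2 <- momentum * vb2 - lr * gb2; b2 <- b2 + vb2
    }
  }
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

predictMLP <- function(fit, x) {
  A <- sweep(x %*% fit$W1, 2, fit$b1, `+`)
  softmaxRows(sweep((A * (A > 0)) %*% fit$W2, 2, fit$b2, `+`))
}

#' Names of the supported classifiers
#'
#' @return character(8): svm, wide_nn, medium_nn, lda, ensemble_bagged,
#'   knn, ensemble_boosted, naive_bayes.
#' @export
classifierNames <- function() {
  c("svm", "wide_nn", "medium_nn", "lda", "ensemble_bagged", "knn",
    "ensemble_boosted", "naive_bayes")
}

#' Stratified train/validation/test split
#'
#' Splits sample indices per class so each partition's class proportions
#' match the requested fractions within rounding; deterministic for a
#' fixed seed; partitions are disjoint and exhaustive, and every class is
#' present in every partition.
#'
#' @param labels class labels (factor or character).
#' @param fractions numeric(3) (train, val, test) summing to 1
#'   (default 0.70/0.15/0.15).
#' @param seed integer seed.
#' @return list with integer index vectors \code{train}, \code{val},
#'   \code{test}.
#' @export
stratifiedSplit <- function(labels, fractions = c(train = 0.70, val = 0.15,
                                                  test = 0.15), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  labels <- factor(labels)
  out <- list(train = integer(0), val = integer(0), test = integer(0))
  withSeed(seed, {
    for (cl in levels(labels)) {
      ix <- which(labels == cl)
      n <- length(ix)
      nVal <- round(fractions[2] * n)
      nTest <- round(fractions[3] * n)
      nTrain <- n - nVal - nTest
      if (min(nTrain, nVal, nTest) < 1L)
        stop(sprintf("class '%s' has too few samples (%d) to fill every partition",
                     cl, n))
      ix <- sample(ix)
      out$train <- c(out$train, ix[seq_len(nTrain)])
      out$val <- c(out$val, ix[nTrain + seq_len(nVal)])
      out$test <- c(out$test, ix[nTrain + nVal + seq_len(nTest)])
    }
  })
  lapply(out, sort)
}

#' Train one classifier of the battery
#'
#' Features are z-scored with the supplied training data's statistics
#' (stored in the returned model and re-applied at prediction).
#' Hyperparameters are fixed documented defaults: SVM = RBF, one-vs-one,
#' gamma = 1/p; wide/medium NN = single hidden layer of 100/25 ReLU units
#' trained by mini-batch SGDM (lr 0.01, momentum 0.9, 60 epochs); LDA with
#' pooled covariance; bagged trees = 30 trees with mtry = p; KNN with
#' k = 10 (Euclidean); boosted trees = 30 rounds of depth-3 trees;
#' Gaussian naive Bayes. Stochastic learners are seeded.
#'
#' @param name one of \code{\link{classifierNames}}.
#' @param x training samples-by-features matrix.
#' @param labels training class labels.
#' @param seed integer seed for stochastic learners.
#' @return list of class \code{"stripClassifier"}.
#' @export
trainClassifier <- function(name, x, labels, seed = 1L) {
  if (!name %in% classifierNames())
    stop(sprintf("unknown classifier '%s'; valid names: %s", name,
                 paste(classifierNames(), collapse = ", ")))
  labels <- droplevels(factor(labels))
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%d", seq_len(ncol(x)))
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0] <- 1
  xs <- standardiseX(x, center, scale)
  K <- nlevels(labels)
  ldaKeep <- NULL
  if (name == "lda") {  # LDA rejects features constant within groups
    withinSd <- sqrt(Reduce(`+`, lapply(split(seq_len(nrow(xs)), labels),
      function(ix) apply(xs[ix, , drop = FALSE], 2, stats::var))) / K)
    ldaKeep <- which(withinSd > 1e-8)
    if (length(ldaKeep) < 1L) stop("no non-constant features for lda")
    xs <- xs[, ldaKeep, drop = FALSE]
  }
  fit <- withSeed(seed, switch(name,
    svm = e1071::svm(xs, labels, kernel = "radial", scale = FALSE),
    wide_nn = trainMLP(xs, labels, hidden = 100),
    medium_nn = trainMLP(xs, labels, hidden = 25),
    lda = suppressWarnings(MASS::lda(xs, grouping = labels)),
    ensemble_bagged = randomForest::randomForest(xs, labels, ntree = 30,
                                                 mtry = ncol(xs)),
    knn = list(train = xs, cl = labels),  # lazy learner
    ensemble_boosted = xgboost::xgb.train(
      params = list(objective = "multi:softprob", num_class = K,
                    max_depth = 3, eta = 0.3, nthread = 1,
                    seed = seed),
      data = xgboost::xgb.DMatrix(xs, label = as.integer(labels) - 1L),
      nrounds = 30, verbose = 0),
    naive_bayes = e1071::naiveBayes(xs, labels)))
  structure(list(name = name, fit = fit, classes = levels(labels),
                 center = center, scale = scale, seed = seed,
                 ldaKeep = ldaKeep),
            class = "stripClassifier")
}

#' Predict labels from a trained battery classifier
#'
#' @param object a \code{\link{trainClassifier}} model.
#' @param newdata samples-by-features matrix (training schema).
#' @param ... unused.
#' @return factor of predicted labels over the training classes.
#' @export
predict.stripClassifier <- function(object, newdata, ...) {
  xs <- standardiseX(as.matrix(newdata), object$center, object$scale)
  colnames(xs) <- names(object$center)
  cls <- object$classes
  pred <- switch(object$name,
    svm = as.character(stats::predict(object$fit, xs)),
    wide_nn = ,
    medium_nn = cls[max.col(predictMLP(object$fit, xs), "first")],
    lda = as.character(stats::predict(
      object$fit, xs[, object$ldaKeep, drop = FALSE])$class),
    ensemble_bagged = as.character(stats::predict(object$fit, xs)),
    knn = as.character(withSeed(object$seed,
      class::knn(object$fit$train, xs, object$fit$cl, k = 10))),
    ensemble_boosted = {
      pr <- stats::predict(object$fit, xgboost::xgb.DMatrix(xs))
      if (!is.matrix(pr)) pr <- matrix(pr, ncol = length(cls), byrow = TRUE)
      cls[max.col(pr, "first")]
    },
    naive_bayes = as.character(stats::predict(object$fit, xs)))
  factor(pred, levels = cls)
}

#' Confusion matrix of predictions
#'
#' @param truth true labels.
#' @param predicted predicted labels.
#' @param classes ordered class levels (default: union of levels).
#' @return K x K integer matrix, rows = true class, cols = predicted.
#' @export
confusionMatrix <- function(truth, predicted, classes = NULL) {
  if (is.null(classes))
    classes <- union(levels(factor(truth)), levels(factor(predicted)))
  t0 <- factor(as.character(truth), levels = classes)
  p0 <- factor(as.character(predicted), levels = classes)
  unclass(table(truth = t0, predicted = p0))
}

#' Micro-averaged metrics of a multi-class confusion matrix
#'
#' Per-class one-vs-rest TP/FN/FP/TN counts are pooled over all classes
#' before forming each metric: sensitivity = sum TP / (sum TP + sum FN),
#' specificity = sum TN / (sum TN + sum FP), accuracy = trace / total,
#' all in percent. Algebraically, micro sensitivity equals accuracy, and
#' pooled specificity equals 1 - (1 - accuracy)/(K - 1). Macro averaging
#' (unweighted mean of per-class rates) is available.
#'
#' @param cm K x K confusion matrix (rows = true class).
#' @param averaging \code{"micro"} (default) or \code{"macro"}.
#' @return list with \code{accuracy}, \code{sensitivity},
#'   \code{specificity} (percent) and \code{perClass} (data.frame of
#'   one-vs-rest TP, FN, FP, TN per class).
#' @export
confusionMetrics <- function(cm, averaging = c("micro", "macro")) {
  averaging <- match.arg(averaging)
  cm <- as.matrix(cm)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  cls <- if (is.null(rownames(cm))) as.character(seq_len(nrow(cm)))
         else rownames(cm)
  perClass <- data.frame(class = cls, TP = tp, FN = fn, FP = fp,
                         TN = tn, row.names = NULL)
  if (averaging == "micro") {
    sens <- sum(tp) / (sum(tp) + sum(fn)) * 100
    spec <- sum(tn) / (sum(tn) + sum(fp)) * 100
  } else {
    sens <- mean(ifelse(tp + fn > 0, tp / (tp + fn), NA)) * 100
    spec <- mean(ifelse(tn + fp > 0, tn / (tn + fp), NA)) * 100
  }
  list(accuracy = sum(tp) / total * 100, sensitivity = sens,
       specificity = spec, perClass = perClass)
}

#' Evaluate a classifier on held-out data
#'
#' @param model a \code{\link{trainClassifier}} model or trained
#'   \code{tabularCNN}.
#' @param x test samples-by-features matrix.
#' @param labels true test labels.
#' @param featureSet feature-set name recorded in the report.
#' @param averaging passed to \code{\link{confusionMetrics}}.
#' @return list of class \code{"evalReport"}: classifier, featureSet,
#'   accuracy/sensitivity/specificity (percent, 2 dp), confusion matrix
#'   and per-class one-vs-rest counts.
#' @export
evaluateModel <- function(model, x, labels, featureSet = "All",
                          averaging = "micro") {
  if (length(labels) == 0L) stop("test set is empty")
  classes <- if (inherits(model, "tabularCNN")) model$classes
             else model$classes
  if (!all(as.character(labels) %in% classes))
    stop(sprintf("label(s) outside training schema: %s",
         paste(setdiff(unique(as.character(labels)), classes),
               collapse = ", ")))
  pred <- if (inherits(model, "tabularCNN"))
    stats::predict(model, x, type = "class") else stats::predict(model, x)
  cm <- confusionMatrix(labels, pred, classes = classes)
  met <- confusionMetrics(cm, averaging = averaging)
  structure(list(
    classifier = if (inherits(model, "tabularCNN")) "cnn" else model$name,
    featureSet = featureSet,
    accuracy = round(met$accuracy, 2),
    sensitivity = round(met$sensitivity, 2),
    specificity = round(met$specificity, 2),
    confusion = cm, perClass = met$perClass), class = "evalReport")
}

#' @export
print.evalReport <- function(x, ...) {
  cat(sprintf("%s on %s features: accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%\n",
              x$classifier, x$featureSet, x$accuracy, x$sensitivity,
              x$specificity))
  invisible(x)
}

#' Run the classifier battery over aligned feature sets
#'
#' Trains every requested classifier on the training partition of every
#' feature set and evaluates all of them on the same held-out test
#' partition, so all rows are comparable. Feature sets must be aligned:
#' identical sample ids and labels in identical order.
#'
#' @param featureSets named list of feature-table
#'   \code{SummarizedExperiment}s (e.g. All, MRMR, CNN).
#' @param split a \code{\link{stratifiedSplit}} result.
#' @param classifiers classifier names (default all eight).
#' @param seed integer seed for stochastic learners.
#' @return list with \code{reports} (one \code{evalReport} per classifier
#'   x feature set) and \code{summary} (data.frame: classifier,
#'   feature_set, accuracy, sensitivity, specificity).
#' @export
runBattery <- function(featureSets, split, classifiers = classifierNames(),
                       seed = 1L) {
  if (is.null(names(featureSets)) || any(names(featureSets) == ""))
    stop("featureSets must be a named list")
  ids <- lapply(featureSets, colnames)
  labs <- lapply(featureSets, function(se) as.character(featureLabels(se)))
  for (k in seq_along(featureSets)[-1]) {
    if (!identical(ids[[k]], ids[[1]]) || !identical(labs[[k]], labs[[1]]))
      stop("feature sets are misaligned: sample ids or labels differ")
  }
  labels <- featureLabels(featureSets[[1]])
  reports <- list()
  rows <- list()
  for (fs in names(featureSets)) {
    x <- featureMatrix(featureSets[[fs]])
    for (clf in classifiers) {
      model <- trainClassifier(clf, x[split$train, , drop = FALSE],
                               labels[split$train], seed = seed)
      rep <- evaluateModel(model, x[split$test, , drop = FALSE],
                           labels[split$test], featureSet = fs)
      reports[[sprintf("%s.%s", clf, fs)]] <- rep
      rows[[length(rows) + 1L]] <- data.frame(
        classifier = clf, feature_set = fs, accuracy = rep$accuracy,
        sensitivity = rep$sensitivity, specificity = rep$specificity,
        stringsAsFactors = FALSE)
    }
  }
  list(reports = reports, summary = do.call(rbind, rows))
}
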