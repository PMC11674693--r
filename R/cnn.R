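# A small convolutional network over tabular feature vectors: each
# 22-feature sample is treated as a (22, 1, 1) "image". Three conv blocks
# (3x3 kernels, "same" zero padding, batch normalisation, ReLU), 2x2 max
# pooling with stride 2 and padding (top, bottom, left, right) =
# (0, 1, 0, 1) after the first two blocks, then a fully connected layer
# with one unit per class and softmax. Trained with stochastic gradient
# descent with momentum on cross-entropy. Because the input width is 1 and
# "same" padding is zero padding, the outer columns of every 3x3 kernel
# only ever multiply zeros; the convolution is therefore implemented as
# its exact equivalent: a length-3 1-D convolution along the feature axis.
# Implemented in base R matrix operations (the network is tiny).

#' Max-pooling output size
#'
#' Closed-form output length of a pooling layer:
#' floor((size + padSum - window) / stride) + 1.
#'
#' @param size input length along the pooled axis.
#' @param window pooling window (default 2).
#' @param stride stride (default 2).
#' @param padSum total padding along the axis (default 1, i.e. pad
#'   (0, 1)).
#' @return integer output length.
#' @export
poolOutSize <- function(size, window = 2L, stride = 2L, padSum = 1L) {
  as.integer(floor((size + padSum - window) / stride) + 1L)
}

#' CNN configuration
#'
#' @param convFilters integer(3) filters per conv layer (default
#'   c(8, 16, 32); the filter counts are a conventional doubling scheme).
#' @param fcUnits fully connected output units = number of classes
#'   (default 8).
#' @param lr learning rate (default 0.01).
#' @param maxEpochs maximum epochs (default 10).
#' @param batchSize mini-batch size (default 32).
#' @param momentum SGDM momentum coefficient (default 0.9).
#' @param valFraction fraction held out for per-epoch validation when no
#'   explicit validation set is supplied (default 0.15).
#' @param shuffleEachEpoch reshuffle training order every epoch (default
#'   TRUE).
#' @param seed RNG seed for initialisation and shuffling.
#' @return list of class \code{"cnnConfig"}.
#' @export
cnnConfig <- function(convFilters = c(8L, 16L, 32L), fcUnits = 8L,
                      lr = 0.01, maxEpochs = 10L, batchSize = 32L,
                      momentum = 0.9, valFraction = 0.15,
                      shuffleEachEpoch = TRUE, seed = 1L) {
  stopifnot(length(convFilters) == 3L, batchSize >= 1L,
            valFraction > 0, valFraction < 1)
  structure(list(convFilters = as.integer(convFilters),
                 fcUnits = as.integer(fcUnits), lr = lr,
                 maxEpochs = as.integer(maxEpochs),
                 batchSize = as.integer(batchSize), momentum = momentum,
                 valFraction = valFraction,
                 shuffleEachEpoch = shuffleEachEpoch, seed = seed),
            class = "cnnConfig")
}

#' Build an untrained tabular CNN
#'
#' Lays out conv-BN-ReLU blocks with max pooling after the first and
#' second block (none after the third), followed by flatten, FC and
#' softmax. For a 22-long input the pooled sizes evolve 22 -> 11 -> 6, so
#' the penultimate representation has 6 x 1 x convFilters[3] activations
#' (192 under defaults). Weights are seeded He-normal.
#'
#' @param config a \code{\link{cnnConfig}}.
#' @param inputHeight input vector length (default 22 features).
#' @return list of class \code{"tabularCNN"} with the parameter store,
#'   layer dimensions and config.
#' @export
buildCNN <- function(config = cnnConfig(), inputHeight = 22L) {
  nf <- config$convFilters
  channels <- c(1L, nf)
  heights <- integer(4)
  heights[1] <- as.integer(inputHeight)
  heights[2] <- poolOutSize(heights[1])  # pool after block 1
  heights[3] <- poolOutSize(heights[2])  # pool after block 2
  heights[4] <- heights[3]               # no pool after block 3
  if (any(heights < 1L))
    stop("configuration error: pooling reduces a dimension below 1")
  params <- withSeed(config$seed, {
    ps <- list()
    for (l in 1:3) {
      fanIn <- 3 * channels[l]
      ps[[sprintf("convW%d", l)]] <-
        array(stats::rnorm(3 * channels[l] * channels[l + 1]) *
              sqrt(2 / fanIn), dim = c(3, channels[l], channels[l + 1]))
      ps[[sprintf("convB%d", l)]] <- numeric(channels[l + 1])
      ps[[sprintf("bnGamma%d", l)]] <- rep(1, channels[l + 1])
      ps[[sprintf("bnBeta%d", l)]] <- numeric(channels[l + 1])
    }
    flat <- heights[4] * channels[4]
    ps$fcW <- matrix(stats::rnorm(flat * config$fcUnits) * sqrt(2 / flat),
                     flat, config$fcUnits)
    ps$fcB <- numeric(config$fcUnits)
    ps
  })
  bnStats <- list()
  for (l in 1:3) {
    bnStats[[sprintf("mean%d", l)]] <- numeric(channels[l + 1])
    bnStats[[sprintf("var%d", l)]] <- rep(1, channels[l + 1])
  }
  structure(list(config = config, inputHeight = as.integer(inputHeight),
                 channels = channels, heights = heights, params = params,
                 bnStats = bnStats, center = NULL, scale = NULL,
                 classes = NULL, history = NULL, trained = FALSE),
            class = "tabularCNN")
}

# ---- internal layer machinery: activations are (B, H, C) arrays ----

# shift an activation array by delta along H, zero padding
shiftH <- function(A, delta) {
  if (delta == 0) return(A)
  d <- dim(A)
  out <- array(0, d)
  H <- d[2]
  if (delta > 0) out[, (1 + delta):H, ] <- A[, 1:(H - delta), , drop = FALSE]
  else out[, 1:(H + delta), ] <- A[, (1 - delta):H, , drop = FALSE]
  out
}

conv1dForward <- function(A, W, b) {
  d <- dim(A); B <- d[1]; H <- d[2]; Cin <- d[3]; Cout <- dim(W)[3]
  out <- matrix(rep(b, each = B * H), B * H, Cout)
  for (k in 1:3) {
    As <- shiftH(A, k - 2L)  # kernel tap k sees input at h + (k - 2)
    dim(As) <- c(B * H, Cin)
    out <- out + As %*% W[k, , , drop = TRUE]
  }
  array(out, c(B, H, Cout))
}

conv1dBackward <- function(A, W, dOut) {
  d <- dim(A); B <- d[1]; H <- d[2]; Cin <- d[3]; Cout <- dim(W)[3]
  dOutM <- dOut; dim(dOutM) <- c(B * H, Cout)
  dW <- array(0, dim(W))
  for (k in 1:3) {
    As <- shiftH(A, k - 2L)
    dim(As) <- c(B * H, Cin)
    dW[k, , ] <- crossprod(As, dOutM)
  }
  dB <- colSums(dOutM)
  dA <- array(0, d)
  for (k in 1:3) {
    Wk <- matrix(W[k, , ], Cin, Cout)
    dAk <- dOutM %*% t(Wk)
    dim(dAk) <- c(B, H, Cin)
    dA <- dA + shiftH(dAk, -(k - 2L))
  }
  list(dA = dA, dW = dW, dB = dB)
}

bnForward <- function(A, gamma, beta, training, runMean, runVar,
                      eps = 1e-5) {
  d <- dim(A); C <- d[3]
  M <- A; dim(M) <- c(d[1] * d[2], C)
  if (training) {
    mu <- colMeans(M)
    xc <- sweep(M, 2, mu)
    v <- colMeans(xc^2)
  } else {
    mu <- runMean; v <- runVar
    xc <- sweep(M, 2, mu)
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, inv, `*`)
  Y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  dim(Y) <- d
  list(Y = Y, xhat = xhat, inv = inv, mu = mu, var = v)
}

bnBackward <- function(cache, gamma, dOut) {
  d <- dim(dOut); C <- d[3]
  dY <- dOut; dim(dY) <- c(d[1] * d[2], C)
  N <- nrow(dY)
  xhat <- cache$xhat
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2, gamma, `*`)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  dX <- sweep(dxhat * N, 2, s1) - sweep(xhat, 2, s2, `*`)
  dX <- sweep(dX, 2, cache$inv / N, `*`)
  dim(dX) <- d
  list(dA = dX, dGamma = dgamma, dBeta = dbeta)
}

# 2-long max pool along H, stride 2, bottom pad (pad value -Inf)
poolForward <- function(A) {
  d <- dim(A); B <- d[1]; H <- d[2]; C <- d[3]
  Hout <- poolOutSize(H)
  out <- array(-Inf, c(B, Hout, C))
  fromSecond <- array(FALSE, c(B, Hout, C))
  for (h in seq_len(Hout)) {
    a1 <- A[, 2 * h - 1, , drop = FALSE]
    if (2 * h <= H) {
      a2 <- A[, 2 * h, , drop = FALSE]
      sel <- a2 > a1  # ties go to the first element (determinism)
      out[, h, ] <- ifelse(sel, a2, a1)
      fromSecond[, h, ] <- sel
    } else out[, h, ] <- a1
  }
  list(Y = out, fromSecond = fromSecond, Hin = H)
}

poolBackward <- function(cache, dOut) {
  d <- dim(dOut); B <- d[1]; Hout <- d[2]; C <- d[3]
  dA <- array(0, c(B, cache$Hin, C))
  for (h in seq_len(Hout)) {
    sel <- cache$fromSecond[, h, , drop = FALSE]
    g <- dOut[, h, , drop = FALSE]
    dA[, 2 * h - 1, ] <- dA[, 2 * h - 1, ] + g[, 1, ] * !sel[, 1, ]
    if (2 * h <= cache$Hin)
      dA[, 2 * h, ] <- dA[, 2 * h, ] + g[, 1, ] * sel[, 1, ]
  }
  dA
}

softmaxRows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# full forward pass; X is (B, F) already standardised
cnnForwardPass <- function(model, X, training = FALSE) {
  p <- model$params
  B <- nrow(X)
  A <- array(X, c(B, ncol(X), 1L))
  caches <- list()
  for (l in 1:3) {
    Ain <- A
    Z <- conv1dForward(Ain, p[[sprintf("convW%d", l)]],
                       p[[sprintf("convB%d", l)]])
    bn <- bnForward(Z, p[[sprintf("bnGamma%d", l)]],
                    p[[sprintf("bnBeta%d", l)]], training,
                    model$bnStats[[sprintf("mean%d", l)]],
                    model$bnStats[[sprintf("var%d", l)]])
    R <- bn$Y; R[R < 0] <- 0
    cache <- list(Ain = Ain, Z = Z, bn = bn, R = R)
    if (l < 3L) {
      pl <- poolForward(R)
      cache$pool <- pl
      A <- pl$Y
    } else A <- R
    caches[[l]] <- cache
  }
  dA <- dim(A)
  flat <- A; dim(flat) <- c(B, dA[2] * dA[3])
  logits <- sweep(flat %*% p$fcW, 2, p$fcB, `+`)
  probs <- softmaxRows(logits)
  list(probs = probs, flat = flat, flatDim = dA, caches = caches)
}

# backward pass; Y is one-hot (B, K). returns gradients named like params
cnnBackwardPass <- function(model, fwd, Y) {
  p <- model$params
  B <- nrow(Y)
  g <- list()
  dLogits <- (fwd$probs - Y) / B
  g$fcW <- crossprod(fwd$flat, dLogits)
  g$fcB <- colSums(dLogits)
  dFlat <- dLogits %*% t(p$fcW)
  dA <- array(dFlat, fwd$flatDim)
  for (l in 3:1) {
    cache <- fwd$caches[[l]]
    if (l < 3L) dA <- poolBackward(cache$pool, dA)
    dR <- dA * (cache$bn$Y > 0)
    bb <- bnBackward(cache$bn, p[[sprintf("bnGamma%d", l)]], dR)
    g[[sprintf("bnGamma%d", l)]] <- bb$dGamma
    g[[sprintf("bnBeta%d", l)]] <- bb$dBeta
    cb <- conv1dBackward(cache$Ain, p[[sprintf("convW%d", l)]], bb$dA)
    g[[sprintf("convW%d", l)]] <- cb$dW
    g[[sprintf("convB%d", l)]] <- cb$dB
    dA <- cb$dA
  }
  g
}

standardiseX <- function(X, center, scale) {
  sweep(sweep(X, 2, center), 2, scale, `/`)
}

#' Train the tabular CNN
#'
#' Optimises softmax cross-entropy with stochastic gradient descent with
#' momentum (batch normalisation in training mode, running statistics for
#' inference). Features are z-scored with training-split statistics stored
#' in the model. Deterministic for a fixed config seed.
#'
#' @param model an untrained \code{\link{buildCNN}} model.
#' @param x samples-by-features matrix or feature-table
#'   \code{SummarizedExperiment}.
#' @param labels class labels (factor); from \code{colData} when \code{x}
#'   is a \code{SummarizedExperiment}.
#' @param valX,valLabels optional explicit validation set; when absent, a
#'   stratified \code{valFraction} of the training data is held out for
#'   per-epoch monitoring.
#' @return The trained model, with \code{history} (per-epoch training and
#'   validation loss/accuracy) and class levels.
#' @export
trainCNN <- function(model, x, labels = NULL, valX = NULL,
                     valLabels = NULL) {
  if (methods::is(x, "SummarizedExperiment")) {
    if (is.null(labels)) labels <- featureLabels(x)
    x <- featureMatrix(x)
  }
  if (methods::is(valX, "SummarizedExperiment")) {
    if (is.null(valLabels)) valLabels <- featureLabels(valX)
    valX <- featureMatrix(valX)
  }
  cfg <- model$config
  labels <- droplevels(factor(labels))
  K <- nlevels(labels)
  if (K > cfg$fcUnits)
    stop(sprintf("model has %d output units but %d classes", cfg$fcUnits, K))
  if (nrow(x) < cfg$batchSize)
    stop("need at least one full mini-batch of samples")
  classes <- levels(labels)
  model$center <- colMeans(x)
  model$scale <- apply(x, 2, stats::sd)
  model$scale[model$scale == 0] <- 1
  X <- standardiseX(x, model$center, model$scale)
  yIdx <- as.integer(labels)
  withSeed(cfg$seed + 1L, {
    if (is.null(valX)) {
      holdout <- unlist(lapply(split(seq_len(nrow(X)), yIdx), function(ix) {
        nv <- max(1L, round(cfg$valFraction * length(ix)))
        sample(ix, nv)
      }), use.names = FALSE)
      valX <- X[holdout, , drop = FALSE]
      valIdx <- yIdx[holdout]
      X <- X[-holdout, , drop = FALSE]
      yIdx <- yIdx[-holdout]
    } else {
      valX <- standardiseX(valX, model$center, model$scale)
      valIdx <- as.integer(factor(as.character(valLabels),
                                  levels = classes))
    }
    n <- nrow(X)
    Y <- matrix(0, n, cfg$fcUnits)
    Y[cbind(seq_len(n), yIdx)] <- 1
    vel <- lapply(model$params, function(p) p * 0)
    hist <- NULL
    for (epoch in seq_len(cfg$maxEpochs)) {
      ord <- if (cfg$shuffleEachEpoch) sample(n) else seq_len(n)
      epLoss <- 0; epCorrect <- 0L
      for (start in seq(1L, n, by = cfg$batchSize)) {
        idx <- ord[start:min(start + cfg$batchSize - 1L, n)]
        Xb <- X[idx, , drop = FALSE]
        Yb <- Y[idx, , drop = FALSE]
        fwd <- cnnForwardPass(model, Xb, training = TRUE)
        loss <- -mean(log(pmax(fwd$probs[Yb > 0], 1e-12)))
        if (!is.finite(loss))
          stop(sprintf("non-finite loss at epoch %d; lr = %g may be too high",
                       epoch, cfg$lr))
        epLoss <- epLoss + loss * length(idx)
        epCorrect <- epCorrect +
          sum(max.col(fwd$probs, "first") == yIdx[idx])
        grads <- cnnBackwardPass(model, fwd, Yb)
        for (nm in names(grads)) {
          vel[[nm]] <- cfg$momentum * vel[[nm]] - cfg$lr * grads[[nm]]
          model$params[[nm]] <- model$params[[nm]] + vel[[nm]]
        }
        for (l in 1:3) {  # running BN statistics (momentum 0.9)
          bn <- fwd$caches[[l]]$bn
          model$bnStats[[sprintf("mean%d", l)]] <-
            0.9 * model$bnStats[[sprintf("mean%d", l)]] + 0.1 * bn$mu
          model$bnStats[[sprintf("var%d", l)]] <-
            0.9 * model$bnStats[[sprintf("var%d", l)]] + 0.1 * bn$var
        }
      }
      vf <- cnnForwardPass(model, valX, training = FALSE)
      valLoss <- -mean(log(pmax(
        vf$probs[cbind(seq_along(valIdx), valIdx)], 1e-12)))
      valAcc <- mean(max.col(vf$probs, "first") == valIdx)
      hist <- rbind(hist, data.frame(
        epoch = epoch, train_loss = epLoss / n, train_acc = epCorrect / n,
        val_loss = valLoss, val_acc = valAcc))
    }
    model$history <- hist
  })
  model$classes <- classes
  model$trained <- TRUE
  model
}

#' @export
print.tabularCNN <- function(x, ...) {
  ch <- x$channels; h <- x$heights
  cat("Tabular CNN:", if (x$trained) "trained" else "untrained", "\n")
  cat(sprintf("  input  %d x 1 x 1\n", x$inputHeight))
  for (l in 1:3)
    cat(sprintf("  conv%d-BN-ReLU  %d x 1 x %d%s\n", l, h[l], ch[l + 1],
                if (l < 3) sprintf("  -> pool -> %d x 1 x %d",
                                   h[l + 1], ch[l + 1]) else ""))
  cat(sprintf("  flatten  %d -> FC %d -> softmax\n",
              h[4] * ch[4], x$config$fcUnits))
  invisible(x)
}

#' Predict class probabilities or labels from a tabular CNN
#'
#' @param object a trained \code{tabularCNN}.
#' @param newdata samples-by-features matrix or feature-table
#'   \code{SummarizedExperiment}.
#' @param type \code{"prob"} (default) for the softmax matrix or
#'   \code{"class"} for hard labels.
#' @param ... unused.
#' @return probability matrix (rows sum to 1) or factor of labels.
#' @export
predict.tabularCNN <- function(object, newdata, type = c("prob", "class"),
                               ...) {
  type <- match.arg(type)
  if (methods::is(newdata, "SummarizedExperiment"))
    newdata <- featureMatrix(newdata)
  X <- if (is.null(object$center)) newdata
       else standardiseX(newdata, object$center, object$scale)
  probs <- cnnForwardPass(object, X, training = FALSE)$probs
  if (!is.null(object$classes) && ncol(probs) >= length(object$classes))
    colnames(probs) <- c(object$classes,
                         rep("", ncol(probs) - length(object$classes)))
  if (type == "prob") return(probs)
  factor(object$classes[max.col(probs[, seq_along(object$classes),
                                      drop = FALSE], "first")],
         levels = object$classes)
}

#' Extract penultimate CNN activations ("CNN features")
#'
#' Runs the trained network in inference mode and returns the flattened
#' activations feeding the fully connected layer, i.e. the penultimate
#' representation (6 x 1 x convFilters[3] = 192 columns under defaults).
#' A pure function of (weights, input): identical rows map to identical
#' feature rows.
#'
#' @param model a trained \code{tabularCNN}.
#' @param x samples-by-features matrix or feature-table
#'   \code{SummarizedExperiment} with the training feature schema.
#' @return matrix of CNN features (samples x activations), or a
#'   \code{SummarizedExperiment} with assay \code{"cnn"} and the input's
#'   colData when \code{x} is a \code{SummarizedExperiment}.
#' @export
cnnFeatures <- function(model, x) {
  se <- NULL
  if (methods::is(x, "SummarizedExperiment")) { se <- x; x <- featureMatrix(x) }
  if (!is.null(model$center)) {
    if (ncol(x) != length(model$center))
      stop(sprintf("schema mismatch: model expects %d feature columns, got %d",
                   length(model$center), ncol(x)))
    x <- standardiseX(x, model$center, model$scale)
  }
  flat <- cnnForwardPass(model, x, training = FALSE)$flat
  colnames(flat) <- sprintf("cnn%03d", seq_len(ncol(flat)))
  if (is.null(se)) return(flat)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(cnn = t(flat)),
    colData = SummarizedExperiment::colData(se))
}
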