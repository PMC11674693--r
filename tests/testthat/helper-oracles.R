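# Independent reference implementations used as oracles. All are naive
# double-loop versions written separately from the package's vectorised
# code paths.

# brute-force horizontal pair counting
naiveGLCM <- function(grid, Ng, d) {
  out <- matrix(0, Ng, Ng)
  for (r in seq_len(nrow(grid)))
    for (cc in seq_len(ncol(grid) - d)) {
      i <- grid[r, cc] + 1L
      j <- grid[r, cc + d] + 1L
      out[i, j] <- out[i, j] + 1
    }
  out
}

# naive loop implementation of all 22 texture features (indices 1..Ng,
# base-2 logs, epsilon only on zero probabilities)
naiveFeatures <- function(p, strict = TRUE) {
  Ng <- nrow(p)
  eps <- 2^-52
  lg <- function(x) log2(ifelse(x > 0, x, x + eps))
  px <- numeric(Ng); py <- numeric(Ng)
  for (i in 1:Ng) for (j in 1:Ng) {
    px[i] <- px[i] + p[i, j]
    py[j] <- py[j] + p[i, j]
  }
  mux <- sum((1:Ng) * px); muy <- sum((1:Ng) * py)
  sigx <- sqrt(sum((1:Ng - mux)^2 * px))
  sigy <- sqrt(sum((1:Ng - muy)^2 * py))
  psum <- setNames(numeric(2 * Ng - 1), 2:(2 * Ng))
  pdif <- setNames(numeric(Ng), 0:(Ng - 1))
  for (i in 1:Ng) for (j in 1:Ng) {
    psum[as.character(i + j)] <- psum[as.character(i + j)] + p[i, j]
    pdif[as.character(abs(i - j))] <- pdif[as.character(abs(i - j))] + p[i, j]
  }
  f <- list(autoc = 0, contr = 0, cprom = 0, cshad = 0, dissi = 0,
            energ = 0, entro = 0, homom = 0, homop = 0, sosvh = 0,
            indnc = 0, idmnc = 0, corrNum = 0)
  for (i in 1:Ng) for (j in 1:Ng) {
    v <- p[i, j]
    f$autoc <- f$autoc + i * j * v
    f$contr <- f$contr + (i - j)^2 * v
    f$cprom <- f$cprom + (i + j - mux - muy)^4 * v
    f$cshad <- f$cshad + (i + j - mux - muy)^3 * v
    f$dissi <- f$dissi + abs(i - j) * v
    f$energ <- f$energ + v^2
    f$entro <- f$entro - v * lg(v)
    f$homom <- f$homom + v / (1 + abs(i - j))
    f$homop <- f$homop + v / (1 + (i - j)^2)
    f$sosvh <- f$sosvh + (i - mux)^2 * v
    f$indnc <- f$indnc + if (strict) v / (1 + (i - j)^2)
               else v / (1 + abs(i - j) / Ng)
    f$idmnc <- f$idmnc + v / (1 + (i - j)^2 / Ng^2)
    f$corrNum <- f$corrNum + (i - mux) * (j - muy) * v
  }
  corrm <- if (sigx * sigy == 0) 0 else f$corrNum / (sigx * sigy)
  corrp <- if (sigx * sigy == 0) 0 else
    (f$autoc - mux * muy) / (sigx * sigy)
  ks <- as.numeric(names(psum))
  savgh <- sum(ks * psum)
  svarh <- sum((ks - savgh)^2 * psum)
  senth <- -sum(psum * lg(psum))
  kd <- as.numeric(names(pdif))
  mud <- sum(kd * pdif)
  dvarh <- sum((kd - mud)^2 * pdif)
  denth <- -sum(pdif * lg(pdif))
  hx <- -sum(px * lg(px)); hy <- -sum(py * lg(py))
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:Ng) for (j in 1:Ng) {
    hxy1 <- hxy1 - p[i, j] * lg(px[i] * py[j])
    hxy2 <- hxy2 - px[i] * py[j] * lg(px[i] * py[j])
  }
  inf1h <- if (max(hx, hy) <= 0) 0 else (f$entro - hxy1) / max(hx, hy)
  inf2h <- sqrt(max(0, 1 - exp(-2 * (hxy2 - f$entro))))
  c(autoc = f$autoc, contr = f$contr, corrm = corrm, corrp = corrp,
    cprom = f$cprom, cshad = f$cshad, dissi = f$dissi, energ = f$energ,
    entro = f$entro, homom = f$homom, homop = f$homop, maxpr = max(p),
    sosvh = f$sosvh, savgh = savgh, svarh = svarh, senth = senth,
    dvarh = dvarh, denth = denth, inf1h = inf1h, inf2h = inf2h,
    indnc = f$indnc, idmnc = f$idmnc)
}

randomNormalisedMatrix <- function(Ng) {
  m <- matrix(stats::rexp(Ng * Ng), Ng, Ng)
  m / sum(m)
}

# igraph-based 8-connected labelling (independent of the package's
# union-find implementation)
igraphComponents8 <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0) return(list())
  key <- paste(idx[, 1], idx[, 2])
  edges <- integer(0)
  lookup <- setNames(seq_len(n), key)
  for (k in seq_len(n)) {
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nb <- paste(idx[k, 1] + dr, idx[k, 2] + dc)
      if (!is.na(lookup[nb]) && lookup[nb] > k)
        edges <- c(edges, k, lookup[nb])
    }
  }
  g <- igraph::make_graph(edges = edges, n = n, directed = FALSE)
  comp <- igraph::components(g)$membership
  split(data.frame(row = idx[, 1], col = idx[, 2]), comp)
}

# the spec toy quantised grid used across GLCM and feature tests
toyGrid <- function() {
  matrix(c(0, 0, 1, 1,
           0, 0, 1, 1,
           0, 2, 2, 2,
           2, 2, 3, 3), 4, 4, byrow = TRUE)
}

toyQuantised <- function() {
  structure(list(levels = toyGrid(), nLevels = 4L, range = c(0, 3)),
            class = "QuantisedPatch")
}

# tiny high-signal dataset for pipeline-level tests
tinyConfig <- function(nPerLabel = 3L,
                       classifiers = c("lda", "knn")) {
  list(synthetic = list(n_per_label = nPerLabel),
       cnn = list(max_epochs = 2L),
       eval = list(classifiers = classifiers))
}
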