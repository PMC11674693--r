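# Grayscale conversion, quantisation, per-offset GLCMs and the averaged
# multi-offset matrix.

test_that("grayscale conversion uses luma weights and is idempotent", {
  white <- array(255, c(2, 2, 3))
  expect_true(all(toGrayscale(white) == 255))
  red <- array(0, c(1, 1, 3)); red[1, 1, 1] <- 255
  expect_equal(as.numeric(toGrayscale(red)), 76)
  g <- matrix(1:6, 2, 3)
  expect_identical(toGrayscale(g), g)
  expect_error(toGrayscale(array(0, c(2, 2, 2))), "channels")
})

test_that("quantisation maps the observed range onto 0..Ng-1", {
  # gray range 0..129 with 64 bins: endpoints map to extreme levels
  g <- matrix(0:129, 10, 13)
  q <- quantise(g, nLevels = 64)
  expect_identical(q$levels[g == 0][1], 0L)
  expect_identical(q$levels[g == 129][1], 63L)
  expect_identical(range(q$levels), c(0L, 63L))
  # closest-level mapping: value 65 of 0..129 -> round(65/129*63) = 32
  expect_identical(q$levels[g == 65][1], 32L)
  expect_true(all(quantise(matrix(42, 4, 4))$levels == 0L))
  q2 <- quantise(matrix(c(0, 255), 2, 2), nLevels = 2,
                 rangeMode = "fixed_0_255")
  expect_identical(sort(unique(as.integer(q2$levels))), c(0L, 1L))
  expect_error(quantise(matrix(1, 2, 2), nLevels = 1), ">= 2")
})

test_that("single-offset counts match hand-derived values on the toy grid", {
  q <- toyQuantised()
  cnt <- glcmSingleOffset(q, d = 1)
  expected <- matrix(0L, 4, 4)
  expected[1, 1] <- 2L; expected[1, 2] <- 2L; expected[2, 2] <- 2L
  expected[1, 3] <- 1L; expected[3, 3] <- 3L; expected[3, 4] <- 1L
  expected[4, 4] <- 1L
  expect_equal(cnt, expected)
  expect_equal(sum(cnt), 12)
  # symmetric mode adds the transpose
  sym <- glcmSingleOffset(q, d = 1, symmetric = TRUE)
  expect_equal(sym, expected + t(expected))
  expect_equal(sum(sym), 24)
  # constant grid: all mass in one cell
  qc <- quantise(matrix(9, 5, 5), nLevels = 4)
  cc <- glcmSingleOffset(qc, d = 2)
  expect_equal(cc[1, 1], 5 * 3)
  expect_identical(sum(cc != 0), 1L)
  expect_error(glcmSingleOffset(q, d = 4), "exceeds")
})

test_that("pair counts agree with a brute-force oracle on random grids", {
  set.seed(17)
  for (trial in 1:50) {
    nr <- sample(2:16, 1); nc <- sample(3:16, 1)
    Ng <- sample(2:8, 1)
    grid <- matrix(sample(0:(Ng - 1), nr * nc, replace = TRUE), nr, nc)
    q <- structure(list(levels = grid, nLevels = Ng, range = c(0, Ng - 1)),
                   class = "QuantisedPatch")
    d <- sample(seq_len(nc - 1), 1)
    cnt <- glcmSingleOffset(q, d)
    expect_lt(max(abs(cnt - naiveGLCM(grid, Ng, d))), 1e-10)
    # count conservation: total pairs = rows x (cols - d)
    expect_identical(sum(cnt), nr * (nc - d))
  }
})

test_that("multi-offset averaging normalises per offset then averages", {
  q <- toyQuantised()
  a1 <- ahmo(q, dMax = 1)
  expect_equal(ahmoProb(a1), glcmSingleOffset(q, 1) / 12)
  a3 <- ahmo(q, dMax = 3)
  manual <- Reduce(`+`, lapply(1:3, function(d) {
    m <- glcmSingleOffset(q, d); m / sum(m)
  })) / 3
  expect_equal(ahmoProb(a3), manual, tolerance = 1e-14)
  expect_equal(sum(ahmoProb(a3)), 1, tolerance = 1e-12)
  # count-averaging alternative weights offsets by pair count
  ac <- ahmo(q, dMax = 3, average = "counts")
  manualC <- Reduce(`+`, lapply(1:3, function(d) glcmSingleOffset(q, d)))
  expect_equal(ahmoProb(ac), manualC / sum(manualC), tolerance = 1e-14)
  expect_error(ahmo(q, dMax = 4), "maximum legal offset is 3")
})

test_that("25 offsets are computed and averaged on a 32-column patch", {
  set.seed(3)
  patch <- matrix(round(runif(128 * 32) * 255), 128, 32)
  q <- quantise(patch, nLevels = 64)
  a <- ahmo(q, dMax = 25)
  expect_identical(a@provenance$dMax, 25L)
  manual <- Reduce(`+`, lapply(1:25, function(d) {
    m <- glcmSingleOffset(q, d); m / sum(m)
  })) / 25
  expect_equal(ahmoProb(a), manual, tolerance = 1e-14)
  expect_equal(sum(ahmoProb(a)), 1, tolerance = 1e-12)
  expect_true(all(ahmoProb(a) >= 0))
})

test_that("row-constant texture concentrates all mass on the diagonal", {
  g <- matrix(rep(c(10, 80, 150, 220), each = 8), 4, 8, byrow = TRUE)
  q <- quantise(g, nLevels = 8)
  a <- ahmo(q, dMax = 5)
  expect_equal(sum(diag(ahmoProb(a))), 1, tolerance = 1e-12)
})

test_that("relabelling gray levels permutes the matrix rows and columns", {
  set.seed(5)
  Ng <- 5L
  grid <- matrix(sample(0:(Ng - 1), 60, replace = TRUE), 6, 10)
  qa <- structure(list(levels = grid, nLevels = Ng, range = c(0, Ng - 1)),
                  class = "QuantisedPatch")
  perm <- sample(0:(Ng - 1))
  qb <- structure(list(levels = matrix(perm[grid + 1L], 6, 10),
                       nLevels = Ng, range = c(0, Ng - 1)),
                  class = "QuantisedPatch")
  pa <- ahmoProb(ahmo(qa, dMax = 4))
  pb <- ahmoProb(ahmo(qb, dMax = 4))
  expect_equal(pb[perm + 1L, perm + 1L], pa, tolerance = 1e-14)
})

test_that("increasing speckle variance raises the averaged-matrix contrast", {
  for (s in 1:5) {
    withr::with_seed(s, {
      base <- matrix(150, 128, 32)
      lo <- base + matrix(rnorm(128 * 32, 0, 3), 128, 32)
      hi <- base + matrix(rnorm(128 * 32, 0, 25), 128, 32)
    })
    clamp <- function(m) round(pmax(pmin(m, 255), 0))
    cLo <- computeFeatures(ahmoForPatch(clamp(lo),
      glcmConfig(rangeMode = "fixed_0_255")))["contr"]
    cHi <- computeFeatures(ahmoForPatch(clamp(hi),
      glcmConfig(rangeMode = "fixed_0_255")))["contr"]
    expect_lt(cLo, cHi)
  }
})
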