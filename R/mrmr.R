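# Maximum-relevance minimum-redundancy feature ranking. Features are
# discretised by rank into equal-frequency bins (making the ranking
# invariant to strictly monotone transforms); relevance and redundancy are
# mutual information of the discretised variables. Greedy forward
# selection under the MI-difference (MID) criterion; the quotient (MIQ)
# variant is available.

# rank-based equal-frequency binning: deterministic, monotone-invariant
equalFreqBin <- function(x, bins) {
  r <- rank(x, ties.method = "average")
  as.integer(ceiling(r * bins / length(x)))
}

# mutual information (bits) between two discrete vectors
discreteMI <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  pxy <- tab / n
  px <- rowSums(pxy); py <- colSums(pxy)
  nz <- pxy > 0
  sum(pxy[nz] * log2(pxy[nz] / outer(px, py)[nz]))
}

#' Rank features by maximum relevance, minimum redundancy
#'
#' Greedy forward selection: the first pick maximises the mutual
#' information I(feature; label) after equal-frequency discretisation into
#' \code{bins} bins; each subsequent pick maximises relevance minus (MID)
#' or divided by (MIQ) the mean MI with the already-selected features.
#' Deterministic; ties break towards the earlier column.
#'
#' @param x samples-by-features numeric matrix, or a feature-table
#'   \code{SummarizedExperiment}.
#' @param labels class labels (factor); taken from \code{colData} when
#'   \code{x} is a \code{SummarizedExperiment}.
#' @param bins equal-frequency bins for discretisation (default 16).
#' @param criterion \code{"mid"} (default) or \code{"miq"}.
#' @return data.frame of class \code{"MRMRRanking"} with columns
#'   \code{rank}, \code{feature}, \code{score} (the MRMR score at
#'   selection time; the first entry's score is its relevance).
#' @export
rankFeatures <- function(x, labels = NULL, bins = 16L,
                         criterion = c("mid", "miq")) {
  criterion <- match.arg(criterion)
  if (methods::is(x, "SummarizedExperiment")) {
    if (is.null(labels)) labels <- featureLabels(x)
    x <- featureMatrix(x)
  }
  labels <- droplevels(factor(labels))
  if (nlevels(labels) < 2L) stop("need at least 2 classes to rank features")
  if (any(table(labels) < 2L)) stop("need >= 2 samples per class")
  p <- ncol(x)
  if (p < 2L) stop("need at least 2 features")
  featNames <- colnames(x)
  if (is.null(featNames)) featNames <- sprintf("f%d", seq_len(p))
  disc <- apply(x, 2, equalFreqBin, bins = bins)
  rel <- vapply(seq_len(p), function(f) discreteMI(disc[, f], labels),
                numeric(1))
  selected <- integer(0)
  scores <- numeric(0)
  redSum <- numeric(p)  # running sum of MI(candidate, selected)
  for (step in seq_len(p)) {
    remaining <- setdiff(seq_len(p), selected)
    sc <- if (step == 1L) rel[remaining] else {
      red <- redSum[remaining] / length(selected)
      if (criterion == "mid") rel[remaining] - red
      else rel[remaining] / pmax(red, .Machine$double.eps)
    }
    pick <- remaining[which.max(sc)]
    selected <- c(selected, pick)
    scores <- c(scores, max(sc))
    if (step < p)
      for (f in setdiff(remaining, pick))
        redSum[f] <- redSum[f] + discreteMI(disc[, f], disc[, pick])
  }
  structure(data.frame(rank = seq_len(p), feature = featNames[selected],
                       score = scores, stringsAsFactors = FALSE),
            class = c("MRMRRanking", "data.frame"))
}

#' Select the top-k ranked features
#'
#' @param ranking an \code{\link{rankFeatures}} result.
#' @param k number of features to keep (default 9).
#' @return character(k) feature names, rank order preserved.
#' @export
selectTop <- function(ranking, k = 9L) {
  if (k < 1L || k > nrow(ranking))
    stop(sprintf("k = %d out of range 1..%d", k, nrow(ranking)))
  ranking$feature[seq_len(k)]
}
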