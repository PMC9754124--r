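## External clustering agreement metrics and the silhouette coefficient.

.asLabels <- function(x) {
  if (is(x, "ClusterResult")) return(clusterLabels(x))
  if (is.factor(x)) return(as.integer(x))
  x
}

.checkPair <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("label vectors differ in length")
  if (length(pred) < 2L)
    stop("need at least two observations")
}

#' Adjusted Rand index
#'
#' Pair-counting agreement between two partitions with the Hubert-Arabie
#' chance adjustment: (Index - Expected) / (Max - Expected). 1 for
#' identical partitions (up to relabeling), about 0 for independent ones.
#'
#' @param pred,truth label vectors (or \linkS4class{ClusterResult}s) of
#'   equal length.
#' @return The ARI (a real number, at most 1).
#' @export
ari <- function(pred, truth) {
  pred <- .asLabels(pred); truth <- .asLabels(truth)
  .checkPair(pred, truth)
  C <- table(pred, truth)
  n <- length(pred)
  sumIJ <- sum(choose(C, 2))
  sumI <- sum(choose(rowSums(C), 2))
  sumJ <- sum(choose(colSums(C), 2))
  expected <- sumI * sumJ / choose(n, 2)
  maxIdx <- (sumI + sumJ) / 2
  if (maxIdx == expected) return(1)    # both partitions trivial
  (sumIJ - expected) / (maxIdx - expected)
}

#' Normalized mutual information
#'
#' Mutual information between the two partitions divided by the arithmetic
#' mean of their entropies. 1 for identical partitions; if both partitions
#' are trivial (a single cluster each) the value is defined as 1.
#'
#' @inheritParams ari
#' @return NMI in [0, 1].
#' @export
nmi <- function(pred, truth) {
  pred <- .asLabels(pred); truth <- .asLabels(truth)
  .checkPair(pred, truth)
  p <- table(pred, truth) / length(pred)
  rp <- rowSums(p); cp <- colSums(p)
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / outer(rp, cp)[nz]))
  h <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  denom <- (h(rp) + h(cp)) / 2
  if (denom == 0) return(1)
  max(0, min(1, mi / denom))
}

## Hungarian algorithm (shortest augmenting paths with potentials) for the
## square min-cost assignment problem; returns the column assigned to each
## row. O(n^3).
.hungarianMin <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1L); v <- numeric(n + 1L)
  p <- integer(n + 1L); way <- integer(n + 1L)   # index 1 = dummy column 0
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- logical(n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j + 1L]) next
        cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
        if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
        if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) assignment[p[j + 1L]] <- j
  assignment
}

#' Clustering accuracy under optimal cluster-class matching
#'
#' Fraction of points whose cluster maps to their class under the best
#' one-to-one matching of clusters to classes (optimal assignment on the
#' confusion matrix, zero-padded to square when the cluster and class
#' counts differ).
#'
#' @inheritParams ari
#' @return ACC in [0, 1].
#' @export
clusterAccuracy <- function(pred, truth) {
  pred <- .asLabels(pred); truth <- .asLabels(truth)
  .checkPair(pred, truth)
  C <- unclass(table(pred, truth))
  s <- max(dim(C))
  Cp <- matrix(0, s, s)
  Cp[seq_len(nrow(C)), seq_len(ncol(C))] <- C
  assignment <- .hungarianMin(max(Cp) - Cp)
  sum(Cp[cbind(seq_len(s), assignment)]) / length(pred)
}

#' Cluster purity
#'
#' Sum over clusters of the majority class count, divided by n.
#'
#' @inheritParams ari
#' @return Purity in [0, 1].
#' @export
purity <- function(pred, truth) {
  pred <- .asLabels(pred); truth <- .asLabels(truth)
  .checkPair(pred, truth)
  C <- table(pred, truth)
  sum(apply(C, 1L, max)) / length(pred)
}

#' Mean silhouette coefficient
#'
#' For each point, a is the mean Euclidean distance to its own cluster
#' (excluding itself) and b the smallest mean distance to any other
#' cluster; the silhouette is (b - a) / max(a, b), with the conventions
#' that singleton clusters score 0 and a = b = 0 scores 0. Returns the mean
#' over points.
#'
#' @param points numeric matrix, one row per point (e.g. the cell rows of a
#'   spectral embedding).
#' @param labels cluster labels, at least two distinct values.
#' @return Mean silhouette in [-1, 1].
#' @export
silhouetteScore <- function(points, labels) {
  labels <- .asLabels(labels)
  points <- as.matrix(points)
  if (nrow(points) != length(labels))
    stop("points and labels disagree in length")
  ulab <- unique(labels)
  if (length(ulab) < 2L)
    stop("silhouette requires at least two clusters")
  D <- as.matrix(stats::dist(points))
  n <- nrow(points)
  s <- numeric(n)
  sizes <- table(factor(labels, levels = ulab))
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    nOwn <- sum(own)
    if (nOwn == 1L) { s[i] <- 0; next }
    a <- sum(D[i, own]) / (nOwn - 1L)
    b <- min(vapply(ulab[ulab != labels[i]], function(cl) {
      mean(D[i, labels == cl])
    }, numeric(1L)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' Full metric report for a clustering
#'
#' @param pred predicted labels (or a \linkS4class{ClusterResult}).
#' @param truth ground-truth labels.
#' @param points optional embedding rows for the silhouette (one row per
#'   cell); if omitted the silhouette entry is NA.
#' @return Named numeric vector with ari, nmi, acc, purity, silhouette.
#' @export
evaluateClustering <- function(pred, truth, points = NULL) {
  out <- c(ari = ari(pred, truth), nmi = nmi(pred, truth),
           acc = clusterAccuracy(pred, truth), purity = purity(pred, truth),
           silhouette = NA_real_)
  if (!is.null(points))
    out["silhouette"] <- silhouetteScore(points, .asLabels(pred))
  out
}
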