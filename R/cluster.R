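## K-means on the spectral embedding and cluster-number estimation.

## k-means++ seeding. Assumes the RNG state is already set by the caller.
.kmeansppCenters <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- X[idx, ]
  if (k > 1L) {
    d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
    for (j in 2L:k) {
      tot <- sum(d2)
      idx <- if (tot <= 0) sample.int(n, 1L) else sample.int(n, 1L, prob = d2)
      centers[j, ] <- X[idx, ]
      d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[j, ])^2))
    }
  }
  centers
}

## Seeded Lloyd iteration with k-means++ starts and randomized tie-breaking
## in the assignment step, best of `restarts` runs by within-cluster sum of
## squares. Randomized tie-breaking makes degenerate inputs (exact duplicate
## points, coincident centers) behave like a genuinely random split instead
## of erroring or collapsing deterministically.
.lloydKMeans <- function(X, k, seed, restarts = 10L, maxIter = 50L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k > n) stop("more clusters than points")
  best <- NULL
  for (r in seq_len(restarts)) {
    res <- withr::with_seed(as.integer(seed) + r - 1L, {
      centers <- .kmeansppCenters(X, k)
      assign <- integer(n)
      xsq <- rowSums(X^2)
      for (it in seq_len(maxIter)) {
        D <- outer(xsq, rowSums(centers^2), "+") - 2 * X %*% t(centers)
        newAssign <- max.col(-D, ties.method = "random")
        if (identical(newAssign, assign)) break
        assign <- newAssign
        for (j in seq_len(k)) {
          members <- assign == j
          if (any(members))
            centers[j, ] <- colMeans(X[members, , drop = FALSE])
        }
      }
      D <- outer(xsq, rowSums(centers^2), "+") - 2 * X %*% t(centers)
      wss <- sum(pmax(D[cbind(seq_len(n), assign)], 0))
      list(assign = assign, centers = centers, wss = wss)
    })
    if (is.null(best) || res$wss < best$wss - 1e-12) best <- res
  }
  best
}

#' Cluster cells by K-means on the spectral embedding
#'
#' Applies seeded K-means (k-means++ starts, best of \code{restarts} runs by
#' within-cluster sum of squares) to the n cell rows of the embedding F.
#'
#' @param emb a \linkS4class{SpectralEmbedding}.
#' @param k number of clusters; defaults to the embedding dimension.
#' @param seed integer seed.
#' @param restarts number of restarts, default 10.
#' @return A \linkS4class{ClusterResult}.
#' @export
kmeansLabels <- function(emb, k = ncol(embeddingMatrix(emb)), seed = 1L,
                         restarts = 10L) {
  stopifnot(is(emb, "SpectralEmbedding"))
  X <- cellRows(emb)
  if (k > nrow(X)) stop("k exceeds the number of cells")
  km <- .lloydKMeans(X, k = as.integer(k), seed = as.integer(seed),
                     restarts = restarts)
  ClusterResult(km$assign, k = as.integer(k))
}

#' Estimate the number of clusters from replicate K-means stability
#'
#' Runs seeded K-means on the top principal components of the normalized
#' expression for each candidate k, several times with different seeds, and
#' scores each k by partition instability (one minus the mean pairwise
#' adjusted Rand index across replicates). Returns the largest k in the grid
#' whose instability stays within the budget: beyond the true cluster
#' number, K-means has to split homogeneous groups arbitrarily and replicate
#' partitions stop agreeing.
#'
#' @param x an \linkS4class{ExpressionMatrix}, normalized layer.
#' @param kGrid candidate cluster numbers, default 2:15.
#' @param seed integer seed.
#' @param nReps K-means replicates per k, default 5.
#' @param instabilityBudget maximum tolerated instability, default 0.05.
#' @param nPcs number of principal components, default 20 (capped by the
#'   data dimensions).
#' @param restarts restarts per K-means replicate, default 5.
#' @return The selected k (integer). If no k is stable, the smallest k in
#'   the grid is returned with a warning.
#' @export
estimateK <- function(x, kGrid = 2:15, seed = 1L, nReps = 5L,
                      instabilityBudget = 0.05, nPcs = 20L, restarts = 5L) {
  stopifnot(is(x, "ExpressionMatrix"))
  n <- ncol(x)
  if (length(kGrid) == 0L) stop("empty k grid")
  if (max(kGrid) > n) {
    warning("shrinking k grid to the number of cells")
    kGrid <- kGrid[kGrid <= n]
    if (length(kGrid) == 0L) stop("no feasible k in the grid")
  }
  X <- base::t(as.matrix(exprValues(x)))
  rank <- min(nPcs, dim(X) - c(1L, 0L))
  pcs <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = rank)$x
  stable <- vapply(sort(unique(as.integer(kGrid))), function(k) {
    reps <- lapply(seq_len(nReps), function(r)
      .lloydKMeans(pcs, k, seed = as.integer(seed) + 1000L * k + r,
                   restarts = restarts)$assign)
    pairs <- utils::combn(nReps, 2L)
    agree <- mean(apply(pairs, 2L, function(p) ari(reps[[p[1]]], reps[[p[2]]])))
    (1 - agree) <= instabilityBudget
  }, logical(1L))
  kGrid <- sort(unique(as.integer(kGrid)))
  if (!any(stable)) {
    warning("no candidate k is stable; returning the smallest")
    return(kGrid[1L])
  }
  max(kGrid[stable])
}
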