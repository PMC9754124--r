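## Building the dictionary matrix of reference (anchor) profiles: selected
## bulk samples, per-type means of labeled cells, or unsupervised centroids.

## Pearson correlation columns-vs-columns with the convention that any
## zero-variance vector correlates 0 with everything.
.safeColCor <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  cx <- sweep(x, 2L, colMeans(x))
  cy <- sweep(y, 2L, colMeans(y))
  sx <- sqrt(colSums(cx^2))
  sy <- sqrt(colSums(cy^2))
  num <- crossprod(cx, cy)
  den <- outer(sx, sy)
  out <- ifelse(den > 0, num / pmax(den, .Machine$double.xmin), 0)
  out[den == 0] <- 0
  out
}

#' Select the bulk samples that best explain at least one cell
#'
#' For every cell, computes the Pearson correlation to each bulk sample over
#' the shared genes and keeps exactly those bulk samples that are the best
#' match (argmax) for at least one cell. Zero-variance cells or samples
#' correlate 0 with everything; a cell whose correlations all tie contributes
#' no vote. Ties at the argmax go to the lowest sample index.
#'
#' @param x an \linkS4class{ExpressionMatrix}, normalized layer, gene order
#'   identical to \code{r}.
#' @param r a \linkS4class{BulkPanel} on the same genes.
#' @param bulkLog \code{"log1p"} to log-transform raw bulk values before
#'   correlating (default), \code{"none"} if the panel is already on a log
#'   scale.
#' @return A \linkS4class{ReferencePanel} (provenance \code{"bulk-selected"})
#'   holding the retained samples in their original order, on the same scale
#'   used for the correlations.
#' @export
selectBulkReferences <- function(x, r, bulkLog = c("log1p", "none")) {
  bulkLog <- match.arg(bulkLog)
  stopifnot(is(x, "ExpressionMatrix"))
  if (!identical(geneIds(x), geneIds(r)))
    stop("gene order of the expression matrix and bulk panel must match")
  if (ncol(r) < 1L) stop("bulk panel has no samples")
  rv <- as.matrix(exprValues(r))
  if (bulkLog == "log1p") rv <- log1p(rv)
  cc <- .safeColCor(exprValues(x), rv)      # cells x samples
  allZero <- apply(cc, 1L, function(z) all(z == 0))
  best <- max.col(cc, ties.method = "first")
  keep <- sort(unique(best[!allZero]))
  if (length(keep) == 0L)
    stop("all correlations are undefined; cannot select reference samples")
  ReferencePanel(rv[, keep, drop = FALSE], provenance = "bulk-selected",
                 cellTypes = cellTypes(r)[keep],
                 sampleIds = sampleIds(r)[keep])
}

#' Build reference profiles from labeled single cells
#'
#' For each cell type, draws ceiling(ratio * n_type) cells without
#' replacement (seeded) and averages their normalized profiles into one
#' reference sample. At \code{ratio = 1} this is the exact per-type mean and
#' is independent of the seed.
#'
#' @param x an \linkS4class{ExpressionMatrix}, normalized layer.
#' @param labels character vector, one cell-type label per cell.
#' @param ratio subsampling ratio in (0, 1], default 1.
#' @param seed integer seed for the subsampling.
#' @return A \linkS4class{ReferencePanel} (provenance \code{"sc-averaged"}),
#'   one sample per cell type, in order of first appearance of each label.
#' @export
buildSCReferences <- function(x, labels, ratio = 1.0, seed = 1L) {
  stopifnot(is(x, "ExpressionMatrix"))
  labels <- as.character(labels)
  if (length(labels) != ncol(x))
    stop("need one label per cell")
  if (anyNA(labels) || any(!nzchar(labels)))
    stop("unknown label encoding: labels must be non-empty strings")
  if (!(ratio > 0 && ratio <= 1)) stop("ratio must be in (0, 1]")
  types <- unique(labels)
  v <- exprValues(x)
  prof <- withr::with_seed(as.integer(seed), {
    vapply(types, function(ty) {
      idx <- which(labels == ty)
      nSub <- ceiling(ratio * length(idx))
      if (nSub < length(idx)) idx <- sample(idx, nSub)
      as.numeric(Matrix::rowSums(v[, idx, drop = FALSE])) / length(idx)
    }, numeric(nrow(v)))
  })
  prof <- matrix(prof, nrow = nrow(v),
                 dimnames = list(geneIds(x), paste0("ref_", seq_along(types))))
  ReferencePanel(prof, provenance = "sc-averaged", cellTypes = types)
}

#' Unsupervised anchors by K-means on cells
#'
#' Runs seeded K-means on cell profiles and uses the centroids as unlabeled
#' reference samples (ablation mode: no reference transcriptomes involved).
#'
#' @param x an \linkS4class{ExpressionMatrix}, normalized layer.
#' @param dPrime number of centroids, 1 <= dPrime <= number of cells.
#' @param seed integer seed.
#' @param restarts K-means restarts, default 5.
#' @return A \linkS4class{ReferencePanel} with provenance \code{"kmeans"}
#'   and no cell-type labels.
#' @export
kmeansAnchors <- function(x, dPrime, seed = 1L, restarts = 5L) {
  stopifnot(is(x, "ExpressionMatrix"))
  n <- ncol(x)
  if (dPrime < 1L || dPrime > n)
    stop("dPrime must lie between 1 and the number of cells")
  km <- .lloydKMeans(Matrix::t(exprValues(x)), k = as.integer(dPrime),
                     seed = as.integer(seed), restarts = restarts)
  centers <- base::t(km$centers)
  dimnames(centers) <- list(geneIds(x), paste0("anchor_", seq_len(dPrime)))
  ReferencePanel(centers, provenance = "kmeans")
}
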