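## Cluster-level cell-type annotation against labeled references.

#' Annotate clusters by correlation to labeled references
#'
#' Each cluster's mean normalized profile is correlated (Pearson, over the
#' shared genes) with every labeled reference sample. A cluster receives the
#' cell type of its best-matching reference if the correlation exceeds the
#' threshold strictly; otherwise it is labeled \code{"Unknown type"}. Ties
#' at the maximum go to the lowest reference index; zero-variance cluster
#' means correlate 0 with everything and fall through to the unknown label.
#' Every cell inherits its cluster's type.
#'
#' @param x an \linkS4class{ExpressionMatrix}, normalized layer, restricted
#'   to the genes shared with the reference.
#' @param clusters a \linkS4class{ClusterResult} over the cells of \code{x}.
#' @param ref a labeled \linkS4class{ReferencePanel} or
#'   \linkS4class{BulkPanel} on the same genes.
#' @param threshold correlation threshold, default 0.6 (strict: a best
#'   correlation exactly at the threshold stays unknown).
#' @param bulkLog \code{"log1p"} to log-transform the reference values
#'   before correlating, \code{"none"} if they are already on a log scale.
#'   Defaults to \code{"log1p"} for a \linkS4class{BulkPanel} and
#'   \code{"none"} otherwise.
#' @return An \linkS4class{AnnotationResult}.
#' @export
annotateClusters <- function(x, clusters, ref, threshold = 0.6,
                             bulkLog = NULL) {
  stopifnot(is(x, "ExpressionMatrix"), is(clusters, "ClusterResult"))
  if (length(clusterLabels(clusters)) != ncol(x))
    stop("cluster labels and cells disagree in length")
  if (!identical(geneIds(x), geneIds(ref)))
    stop("gene spaces must match; run intersectGenes() first")
  types <- cellTypes(ref)
  if (is.null(types))
    stop("reference has no cell-type labels; cannot annotate")
  if (is.null(bulkLog)) bulkLog <- if (is(ref, "BulkPanel")) "log1p" else "none"
  bulkLog <- match.arg(bulkLog, c("log1p", "none"))
  rv <- as.matrix(exprValues(ref))
  if (bulkLog == "log1p") rv <- log1p(rv)

  lab <- clusterLabels(clusters)
  K <- nClusters(clusters)
  v <- exprValues(x)
  means <- vapply(seq_len(K), function(cid) {
    idx <- which(lab == cid)
    as.numeric(Matrix::rowSums(v[, idx, drop = FALSE])) / max(length(idx), 1L)
  }, numeric(nrow(v)))
  means <- matrix(means, nrow = nrow(v))
  cc <- .safeColCor(means, rv)                       # K x refs
  best <- max.col(cc, ties.method = "first")
  bestCor <- cc[cbind(seq_len(K), best)]
  cellType <- ifelse(bestCor > threshold, types[best], "Unknown type")
  tab <- data.frame(cluster = seq_len(K),
                    cellType = cellType,
                    bestCorrelation = bestCor,
                    bestReference = sampleIds(ref)[best],
                    stringsAsFactors = FALSE)
  new("AnnotationResult", clusters = tab,
      cellTypes = tab$cellType[lab])
}
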