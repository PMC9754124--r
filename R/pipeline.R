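## End-to-end convenience wrapper: preprocessing -> reference panel ->
## anchor-graph fit -> K-means labels -> annotation.

#' Run the full clustering pipeline
#'
#' Chains the individual stages: gene QC and log-normalization,
#' highly-variable-gene selection, gene intersection with the reference
#' source, reference-panel construction (bulk correlation selection,
#' labeled-cell averaging, or unsupervised K-means anchors), the
#' k-connected anchor-graph fit, K-means on the cell rows of the spectral
#' embedding, and (when the panel is labeled) cluster annotation.
#'
#' @param counts raw \linkS4class{ExpressionMatrix}.
#' @param bulk optional \linkS4class{BulkPanel} (required for
#'   \code{anchors = "bulk"}; also used as the annotation reference).
#' @param scLabels optional per-cell labels (required for
#'   \code{anchors = "labeled-sc"}).
#' @param anchors reference-panel mode.
#' @param k number of clusters, or \code{"auto"} to estimate it with
#'   \code{\link{estimateK}}.
#' @param qc,hvg logical switches for gene QC and HVG selection.
#' @param nHvg number of highly variable genes, default 2000.
#' @param lowFrac,highFrac QC band, defaults 0.05 / 0.95.
#' @param downsampleRatio cell subsampling ratio for labeled-sc references.
#' @param dPrime number of anchors for \code{anchors = "kmeans"} (defaults
#'   to k).
#' @param delta,beta0,maxIter,tol anchor-graph fit controls (see
#'   \code{\link{fitLFSC}}).
#' @param threshold annotation correlation threshold, default 0.6.
#' @param bulkLog log-handling of the bulk panel values; default
#'   \code{"log1p"} (use \code{"none"} for panels already on a log scale,
#'   e.g. from \code{\link{makeBulkFromTruth}}).
#' @param restarts K-means restarts for the final labeling, default 10.
#' @param seed integer seed driving every stochastic stage.
#' @return A list with \code{clusters} (\linkS4class{ClusterResult}),
#'   \code{annotation} (\linkS4class{AnnotationResult} or NULL),
#'   \code{fit} (\linkS4class{LFSCFit}), \code{x} (the processed
#'   \linkS4class{ExpressionMatrix} the fit consumed), \code{reference}
#'   (the \linkS4class{ReferencePanel}) and \code{k}.
#' @examples
#' sim <- makeClusters(nCells = 90, nGenes = 120, k = 3, separation = 5,
#'                     dropoutRate = 0.2, seed = 7)
#' res <- lfscPipeline(sim$counts, scLabels = sim$trueLabels,
#'                     anchors = "labeled-sc", k = 3, seed = 7)
#' ari(res$clusters, sim$trueLabels)
#' @export
lfscPipeline <- function(counts, bulk = NULL, scLabels = NULL,
                         anchors = c("bulk", "labeled-sc", "kmeans"),
                         k = "auto", qc = TRUE, hvg = TRUE, nHvg = 2000,
                         lowFrac = 0.05, highFrac = 0.95,
                         downsampleRatio = 1.0, dPrime = NULL,
                         delta = 1.0, beta0 = 0.01, maxIter = 30L,
                         tol = 1e-6, threshold = 0.6,
                         bulkLog = c("log1p", "none"), restarts = 10L,
                         seed = 1L) {
  anchors <- match.arg(anchors)
  bulkLog <- match.arg(bulkLog)
  stopifnot(is(counts, "ExpressionMatrix"))
  if (anchors == "bulk" && is.null(bulk))
    stop("anchors = 'bulk' requires a bulk panel")
  if (anchors == "labeled-sc" && is.null(scLabels))
    stop("anchors = 'labeled-sc' requires per-cell labels")

  x <- counts
  if (qc) x <- qcFilterGenes(x, lowFrac, highFrac)
  keep <- if (hvg) selectHVGs(x, nHvg = nHvg)$keptGeneIds else geneIds(x)
  xn <- logNormalize(x)
  if (!is.null(bulk)) {
    both <- intersectGenes(xn, bulk, keep)
    xn <- both$x
    bulk <- both$r
  } else {
    xn <- xn[intersect(keep, geneIds(xn)), ]
  }

  if (identical(k, "auto")) k <- estimateK(xn, seed = seed)
  k <- as.integer(k)

  ref <- switch(anchors,
    "bulk" = selectBulkReferences(xn, bulk, bulkLog = bulkLog),
    "labeled-sc" = buildSCReferences(xn, scLabels, ratio = downsampleRatio,
                                     seed = seed),
    "kmeans" = kmeansAnchors(xn, dPrime = if (is.null(dPrime)) k else dPrime,
                             seed = seed))

  fit <- fitLFSC(xn, ref, k = k, delta = delta, beta0 = beta0,
                 maxIter = maxIter, tol = tol, seed = seed)
  clusters <- kmeansLabels(spectralEmbedding(fit), k = k, seed = seed,
                           restarts = restarts)

  annotation <- NULL
  annRef <- if (!is.null(bulk)) bulk else ref
  if (!is.null(cellTypes(annRef))) {
    annotation <- annotateClusters(
      xn, clusters, annRef, threshold = threshold,
      bulkLog = if (is(annRef, "BulkPanel")) bulkLog else "none")
  }
  list(clusters = clusters, annotation = annotation, fit = fit, x = xn,
       reference = ref, k = k)
}
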