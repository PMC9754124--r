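## Central S4 containers. Expression-like objects extend SummarizedExperiment
## so the usual [ , dim, dimnames machinery comes for free; solver-state
## objects (graph, embedding, fit) are plain S4 with validity methods.

.matMin <- function(m) {
  if (is(m, "sparseMatrix")) {
    x <- m@x
    if (length(x) == 0L) return(0)
    min(min(x), 0)
  } else {
    min(m)
  }
}

.matAllFinite <- function(m) {
  if (is(m, "sparseMatrix")) all(is.finite(m@x)) else all(is.finite(m))
}

#' ExpressionMatrix: genes-by-cells expression values
#'
#' A thin SummarizedExperiment subclass holding one assay, tagged as either
#' raw counts (\code{layer = "raw"}) or log-normalized values
#' (\code{layer = "normalized"}). Rows are genes, columns are cells.
#'
#' @slot .	inherits all SummarizedExperiment slots.
#' @export
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

setValidity("ExpressionMatrix", function(object) {
  msg <- character()
  if (length(assays(object)) != 1L)
    msg <- c(msg, "ExpressionMatrix must carry exactly one assay")
  ly <- assayNames(object)[1L]
  if (!ly %in% c("raw", "normalized"))
    msg <- c(msg, "assay name (layer) must be 'raw' or 'normalized'")
  if (is.null(rownames(object)) || is.null(colnames(object)))
    msg <- c(msg, "gene ids (rownames) and cell ids (colnames) are required")
  if (!is.null(rownames(object)) && anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate gene ids")
  v <- assay(object, 1L)
  if (!.matAllFinite(v))
    msg <- c(msg, "expression values must be finite")
  if (identical(ly, "raw") && .matMin(v) < 0)
    msg <- c(msg, "negative expression value in raw layer")
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix (base or Matrix sparse), genes in rows,
#'   cells in columns.
#' @param geneIds,cellIds character vectors of row/column identifiers;
#'   default to the dimnames of \code{values}.
#' @param layer \code{"raw"} for counts, \code{"normalized"} for
#'   log-normalized values.
#' @return An \linkS4class{ExpressionMatrix}.
#' @examples
#' m <- matrix(rpois(6, 5), 3, 2,
#'             dimnames = list(paste0("g", 1:3), paste0("c", 1:2)))
#' ExpressionMatrix(m)
#' @export
ExpressionMatrix <- function(values, geneIds = rownames(values),
                             cellIds = colnames(values),
                             layer = c("raw", "normalized")) {
  layer <- match.arg(layer)
  if (is.null(geneIds) || is.null(cellIds))
    stop("geneIds and cellIds must be supplied when 'values' has no dimnames")
  dimnames(values) <- list(as.character(geneIds), as.character(cellIds))
  al <- list(values)
  names(al) <- layer
  new("ExpressionMatrix", SummarizedExperiment(assays = al))
}

#' BulkPanel: genes-by-samples reference transcriptomes with cell-type labels
#'
#' Rows are genes, columns are bulk samples; \code{colData$cellType} carries
#' one cell-type label per sample (labels need not be unique).
#'
#' @export
setClass("BulkPanel", contains = "SummarizedExperiment")

setValidity("BulkPanel", function(object) {
  msg <- character()
  if (length(assays(object)) != 1L)
    msg <- c(msg, "BulkPanel must carry exactly one assay")
  if (is.null(rownames(object)) || is.null(colnames(object)))
    msg <- c(msg, "gene ids and sample ids are required")
  if (!is.null(rownames(object)) && anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate gene ids")
  if (!"cellType" %in% colnames(colData(object))) {
    msg <- c(msg, "colData must contain a 'cellType' column")
  } else {
    ct <- colData(object)$cellType
    if (anyNA(ct) || any(!nzchar(ct)))
      msg <- c(msg, "every sample needs a non-empty cell-type label")
  }
  v <- assay(object, 1L)
  if (!.matAllFinite(v) || .matMin(v) < 0)
    msg <- c(msg, "bulk values must be finite and nonnegative")
  if (length(msg)) msg else TRUE
})

#' Construct a BulkPanel
#'
#' @param values numeric genes-by-samples matrix.
#' @param cellTypes character vector, one label per sample.
#' @param geneIds,sampleIds identifiers; default to dimnames.
#' @return A \linkS4class{BulkPanel}.
#' @export
BulkPanel <- function(values, cellTypes, geneIds = rownames(values),
                      sampleIds = colnames(values)) {
  if (is.null(geneIds) || is.null(sampleIds))
    stop("geneIds and sampleIds must be supplied when 'values' has no dimnames")
  dimnames(values) <- list(as.character(geneIds), as.character(sampleIds))
  if (length(cellTypes) != ncol(values))
    stop("need one cell-type label per sample")
  new("BulkPanel", SummarizedExperiment(
    assays = list(bulk = values),
    colData = DataFrame(cellType = as.character(cellTypes),
                        row.names = colnames(values))))
}

#' ReferencePanel: the dictionary matrix of anchor profiles
#'
#' Genes-by-d' matrix of reference (anchor) profiles against which every cell
#' is reconstructed. \code{metadata()$provenance} records how the panel was
#' built: \code{"bulk-selected"} (correlation-argmax selection from a bulk
#' panel), \code{"sc-averaged"} (per-type means of labeled cells) or
#' \code{"kmeans"} (unsupervised centroids; no cell-type labels).
#'
#' @export
setClass("ReferencePanel", contains = "SummarizedExperiment")

setValidity("ReferencePanel", function(object) {
  msg <- character()
  prov <- metadata(object)$provenance
  if (is.null(prov) || !prov %in% c("bulk-selected", "sc-averaged", "kmeans"))
    msg <- c(msg, "provenance must be one of bulk-selected, sc-averaged, kmeans")
  if (ncol(object) < 1L)
    msg <- c(msg, "need at least one reference sample")
  if (is.null(rownames(object)) || is.null(colnames(object)))
    msg <- c(msg, "gene ids and sample ids are required")
  if (!identical(prov, "kmeans") && !"cellType" %in% colnames(colData(object)))
    msg <- c(msg, "labeled provenance requires colData$cellType")
  if (length(msg)) msg else TRUE
})

#' Construct a ReferencePanel
#'
#' @param values numeric genes-by-d' matrix of anchor profiles.
#' @param provenance how the panel was derived.
#' @param cellTypes optional per-sample labels (required unless kmeans).
#' @param geneIds,sampleIds identifiers.
#' @return A \linkS4class{ReferencePanel}.
#' @export
ReferencePanel <- function(values, provenance = c("sc-averaged",
                                                  "bulk-selected", "kmeans"),
                           cellTypes = NULL, geneIds = rownames(values),
                           sampleIds = colnames(values)) {
  provenance <- match.arg(provenance)
  dimnames(values) <- list(as.character(geneIds), as.character(sampleIds))
  cd <- if (is.null(cellTypes)) {
    DataFrame(row.names = colnames(values))
  } else {
    DataFrame(cellType = as.character(cellTypes), row.names = colnames(values))
  }
  se <- SummarizedExperiment(assays = list(reference = values), colData = cd)
  metadata(se)$provenance <- provenance
  new("ReferencePanel", se)
}

#' AnchorGraph: the learned bipartite affinity between anchors and cells
#'
#' Holds the d'-by-n matrix A; every entry is nonnegative and each cell's
#' column lies on the probability simplex (sums to one). The implied
#' bipartite adjacency is B = [[0, A], [A', 0]].
#'
#' @slot A numeric d'-by-n matrix (anchors in rows, cells in columns).
#' @export
setClass("AnchorGraph", representation(A = "matrix"))

setValidity("AnchorGraph", function(object) {
  A <- object@A
  msg <- character()
  if (!all(is.finite(A))) msg <- c(msg, "non-finite entries in A")
  if (length(A) && min(A) < -1e-8) msg <- c(msg, "negative entries in A")
  if (ncol(A) && any(abs(colSums(A) - 1) > 1e-8))
    msg <- c(msg, "columns of A must sum to 1 within 1e-8")
  if (length(msg)) msg else TRUE
})

#' @param A numeric d'-by-n matrix on the per-column simplex.
#' @rdname AnchorGraph-class
#' @export
AnchorGraph <- function(A) new("AnchorGraph", A = as.matrix(A))

#' BipartiteLaplacian: degrees of the bipartite graph, Laplacian implicit
#'
#' Stores the degree vector of B (anchor degrees = row sums of A, cell
#' degrees = column sums of A, exactly 1 for a valid AnchorGraph) and the
#' graph itself. The normalized Laplacian L = I - D^{-1/2} B D^{-1/2} is
#' never materialized by the solver; \code{\link{laplacianMatrix}} builds the
#' explicit (d'+n) x (d'+n) matrix for small problems and tests.
#'
#' @slot degrees numeric vector of length d'+n, anchors first.
#' @slot graph the underlying \linkS4class{AnchorGraph}.
#' @export
setClass("BipartiteLaplacian",
         representation(degrees = "numeric", graph = "AnchorGraph"))

setValidity("BipartiteLaplacian", function(object) {
  d <- object@degrees
  A <- object@graph@A
  if (length(d) != nrow(A) + ncol(A))
    return("degree vector must have length d' + n")
  if (any(!is.finite(d)) || any(d < 0))
    return("degrees must be finite and nonnegative")
  TRUE
})

#' SpectralEmbedding: eigenvectors of the normalized bipartite Laplacian
#'
#' The matrix F of the k eigenvectors of L for its k smallest eigenvalues,
#' with orthonormal columns; the first d' rows embed the anchors, the
#' remaining n rows embed the cells.
#'
#' @slot F numeric (d'+n)-by-k matrix with orthonormal columns.
#' @slot nAnchors number of anchor rows (d').
#' @slot eigenvalues the k smallest Laplacian eigenvalues, ascending.
#' @export
setClass("SpectralEmbedding",
         representation(F = "matrix", nAnchors = "integer",
                        eigenvalues = "numeric"))

setValidity("SpectralEmbedding", function(object) {
  msg <- character()
  F <- object@F
  k <- ncol(F)
  if (length(object@eigenvalues) != k)
    msg <- c(msg, "need one eigenvalue per embedding column")
  if (any(object@eigenvalues < -1e-8))
    msg <- c(msg, "eigenvalues must be nonnegative")
  if (is.unsorted(object@eigenvalues + 1e-10))
    msg <- c(msg, "eigenvalues must be ascending")
  if (object@nAnchors < 1L || object@nAnchors > nrow(F))
    msg <- c(msg, "nAnchors out of range")
  if (k && max(abs(crossprod(F) - diag(k))) > 1e-6)
    msg <- c(msg, "embedding columns must be orthonormal")
  if (length(msg)) msg else TRUE
})

#' ClusterResult: a hard partition of cells
#'
#' @slot labels integer vector, one label in 1..k per cell.
#' @slot k number of clusters.
#' @export
setClass("ClusterResult", representation(labels = "integer", k = "integer"))

setValidity("ClusterResult", function(object) {
  if (object@k < 1L) return("k must be >= 1")
  if (length(object@labels) &&
      (min(object@labels) < 1L || max(object@labels) > object@k))
    return("labels must lie in 1..k")
  TRUE
})

#' @param labels integer cluster labels in 1..k.
#' @param k number of clusters (defaults to max label).
#' @rdname ClusterResult-class
#' @export
ClusterResult <- function(labels, k = max(labels, 1L)) {
  new("ClusterResult", labels = as.integer(labels), k = as.integer(k))
}

#' AnnotationResult: per-cluster and per-cell cell-type calls
#'
#' @slot clusters data.frame with columns cluster, cellType, bestCorrelation,
#'   bestReference (one row per cluster).
#' @slot cellTypes character vector, each cell inheriting its cluster's type.
#' @export
setClass("AnnotationResult",
         representation(clusters = "data.frame", cellTypes = "character"))

setValidity("AnnotationResult", function(object) {
  cl <- object@clusters
  need <- c("cluster", "cellType", "bestCorrelation", "bestReference")
  if (!all(need %in% names(cl)))
    return(paste("clusters table needs columns:", paste(need, collapse = ", ")))
  bc <- cl$bestCorrelation
  if (any(is.finite(bc) & (bc < -1 - 1e-8 | bc > 1 + 1e-8)))
    return("correlations must lie in [-1, 1]")
  TRUE
})

#' LFSCFit: result of the alternating anchor-graph optimization
#'
#' @slot graph the learned \linkS4class{AnchorGraph}.
#' @slot embedding the final \linkS4class{SpectralEmbedding}.
#' @slot k target number of connected components.
#' @slot delta ridge penalty on A.
#' @slot beta0,beta initial and final spectral-penalty weights.
#' @slot objectiveTrace objective value after each outer iteration.
#' @slot iterations number of outer iterations run.
#' @slot converged TRUE if the relative objective change dropped below the
#'   tolerance while the graph had exactly k components.
#' @slot componentCount connected components of the final graph.
#' @export
setClass("LFSCFit",
         representation(graph = "AnchorGraph", embedding = "SpectralEmbedding",
                        k = "integer", delta = "numeric", beta0 = "numeric",
                        beta = "numeric", objectiveTrace = "numeric",
                        iterations = "integer", converged = "logical",
                        componentCount = "integer"))

setValidity("LFSCFit", function(object) {
  if (any(!is.finite(object@objectiveTrace)))
    return("objective trace must be finite")
  if (object@componentCount < 1L)
    return("componentCount must be >= 1")
  TRUE
})
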