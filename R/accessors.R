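## Accessors and show() methods. Slot access stays inside the package.

#' @name accessors
#' @title Accessors for lfsc containers
#' @description Small accessor layer over the S4 containers: expression
#'   values and identifiers, anchor-graph matrix, embedding rows, fit state.
#' @param x,object an lfsc S4 object.
#' @return The extracted component (see individual accessors).
NULL

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setMethod("exprValues", "SummarizedExperiment", function(x) assay(x, 1L))

#' @rdname accessors
#' @export
setGeneric("exprLayer", function(x) standardGeneric("exprLayer"))
#' @rdname accessors
#' @export
setMethod("exprLayer", "ExpressionMatrix", function(x) assayNames(x)[1L])

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setMethod("geneIds", "SummarizedExperiment", function(x) rownames(x))

#' @rdname accessors
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))
#' @rdname accessors
#' @export
setMethod("cellIds", "ExpressionMatrix", function(x) colnames(x))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setMethod("sampleIds", "SummarizedExperiment", function(x) colnames(x))

#' @rdname accessors
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))
#' @rdname accessors
#' @export
setMethod("cellTypes", "SummarizedExperiment", function(x) {
  cd <- colData(x)
  if (!"cellType" %in% colnames(cd)) NULL else as.character(cd$cellType)
})
#' @rdname accessors
#' @export
setMethod("cellTypes", "AnnotationResult", function(x) x@cellTypes)

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setMethod("provenance", "ReferencePanel", function(x) metadata(x)$provenance)

#' @rdname accessors
#' @export
setGeneric("anchorMatrix", function(x) standardGeneric("anchorMatrix"))
#' @rdname accessors
#' @export
setMethod("anchorMatrix", "AnchorGraph", function(x) x@A)
#' @rdname accessors
#' @export
setMethod("anchorMatrix", "LFSCFit", function(x) x@graph@A)

#' @rdname accessors
#' @export
setGeneric("nAnchors", function(x) standardGeneric("nAnchors"))
#' @rdname accessors
#' @export
setMethod("nAnchors", "AnchorGraph", function(x) nrow(x@A))
#' @rdname accessors
#' @export
setMethod("nAnchors", "SpectralEmbedding", function(x) x@nAnchors)

#' @rdname accessors
#' @export
setGeneric("degreeVector", function(x) standardGeneric("degreeVector"))
#' @rdname accessors
#' @export
setMethod("degreeVector", "BipartiteLaplacian", function(x) x@degrees)

#' @rdname accessors
#' @export
setGeneric("anchorRows", function(x) standardGeneric("anchorRows"))
#' @rdname accessors
#' @export
setMethod("anchorRows", "SpectralEmbedding", function(x)
  x@F[seq_len(x@nAnchors), , drop = FALSE])

#' @rdname accessors
#' @export
setGeneric("cellRows", function(x) standardGeneric("cellRows"))
#' @rdname accessors
#' @export
setMethod("cellRows", "SpectralEmbedding", function(x)
  x@F[-seq_len(x@nAnchors), , drop = FALSE])

#' @rdname accessors
#' @export
setGeneric("embeddingMatrix", function(x) standardGeneric("embeddingMatrix"))
#' @rdname accessors
#' @export
setMethod("embeddingMatrix", "SpectralEmbedding", function(x) x@F)

#' @rdname accessors
#' @export
setGeneric("laplacianEigenvalues",
           function(x) standardGeneric("laplacianEigenvalues"))
#' @rdname accessors
#' @export
setMethod("laplacianEigenvalues", "SpectralEmbedding",
          function(x) x@eigenvalues)

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusterResult", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))
#' @rdname accessors
#' @export
setMethod("nClusters", "ClusterResult", function(x) x@k)

#' @rdname accessors
#' @export
setGeneric("annotationTable", function(x) standardGeneric("annotationTable"))
#' @rdname accessors
#' @export
setMethod("annotationTable", "AnnotationResult", function(x) x@clusters)

#' @rdname accessors
#' @export
setGeneric("spectralEmbedding",
           function(x) standardGeneric("spectralEmbedding"))
#' @rdname accessors
#' @export
setMethod("spectralEmbedding", "LFSCFit", function(x) x@embedding)

#' @rdname accessors
#' @export
setGeneric("anchorGraph", function(x) standardGeneric("anchorGraph"))
#' @rdname accessors
#' @export
setMethod("anchorGraph", "LFSCFit", function(x) x@graph)

#' @rdname accessors
#' @export
setGeneric("objectiveTrace", function(x) standardGeneric("objectiveTrace"))
#' @rdname accessors
#' @export
setMethod("objectiveTrace", "LFSCFit", function(x) x@objectiveTrace)

#' @rdname accessors
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))
#' @rdname accessors
#' @export
setMethod("isConverged", "LFSCFit", function(x) x@converged)

#' @rdname accessors
#' @export
setGeneric("componentCount", function(x) standardGeneric("componentCount"))
#' @rdname accessors
#' @export
setMethod("componentCount", "LFSCFit", function(x) x@componentCount)

setMethod("show", "ExpressionMatrix", function(object) {
  cat("ExpressionMatrix:", nrow(object), "genes x", ncol(object), "cells,",
      "layer =", exprLayer(object), "\n")
})

setMethod("show", "BulkPanel", function(object) {
  cat("BulkPanel:", nrow(object), "genes x", ncol(object), "samples,",
      length(unique(cellTypes(object))), "cell types\n")
})

setMethod("show", "ReferencePanel", function(object) {
  cat("ReferencePanel (", provenance(object), "): ", nrow(object),
      " genes x ", ncol(object), " reference samples\n", sep = "")
})

setMethod("show", "AnchorGraph", function(object) {
  A <- object@A
  cat("AnchorGraph:", nrow(A), "anchors x", ncol(A), "cells;",
      sprintf("%.1f%% entries > 1e-8\n", 100 * mean(A > 1e-8)))
})

setMethod("show", "SpectralEmbedding", function(object) {
  cat("SpectralEmbedding: k =", ncol(object@F), "columns over",
      object@nAnchors, "anchors +", nrow(object@F) - object@nAnchors,
      "cells\n  smallest eigenvalues:",
      paste(signif(object@eigenvalues, 3), collapse = ", "), "\n")
})

setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult:", length(object@labels), "cells in", object@k,
      "clusters\n")
})

setMethod("show", "AnnotationResult", function(object) {
  cat("AnnotationResult:", nrow(object@clusters), "clusters ->",
      length(unique(object@clusters$cellType)), "cell types (",
      sum(object@clusters$cellType == "Unknown type"), "unknown )\n")
})

setMethod("show", "LFSCFit", function(object) {
  cat("LFSCFit: k =", object@k, "| components =", object@componentCount,
      "| iterations =", object@iterations,
      "| converged =", object@converged, "\n  delta =", object@delta,
      "beta:", object@beta0, "->", object@beta, "\n  final objective =",
      signif(tail(object@objectiveTrace, 1), 6), "\n")
})
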