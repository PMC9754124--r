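## Readers and writers for the standard on-disk formats: MatrixMarket
## coordinate triplets with genes.tsv/barcodes.tsv sidecars, dense TSV with
## genes in rows, and the results/label TSVs.

.readIdColumn <- function(path, what) {
  if (!file.exists(path)) stop("missing ", what, " sidecar file: ", path)
  ids <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)[[1L]]
  as.character(ids)
}

#' Read an expression matrix
#'
#' MatrixMarket (\code{fmt = "mtx"}) expects \code{genes.tsv} and
#' \code{barcodes.tsv} sidecars next to the matrix file (first column used
#' as identifier); 1-based MatrixMarket indices are the on-disk convention.
#' Dense TSV (\code{fmt = "tsv"}) expects genes in rows, a header row of
#' cell ids and gene ids in the first column; \code{transpose = TRUE}
#' covers the cells-in-rows dialect.
#'
#' @param path path to the .mtx or .tsv file.
#' @param fmt \code{"mtx"} or \code{"tsv"}.
#' @param transpose for TSV input, transpose after reading.
#' @return A raw-layer \linkS4class{ExpressionMatrix}.
#' @export
readExpression <- function(path, fmt = c("mtx", "tsv"), transpose = FALSE) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("file not found: ", path)
  if (fmt == "mtx") {
    m <- tryCatch(Matrix::readMM(path),
                  error = function(e) stop("malformed MatrixMarket file: ",
                                           conditionMessage(e)))
    genes <- .readIdColumn(file.path(dirname(path), "genes.tsv"), "gene")
    cells <- .readIdColumn(file.path(dirname(path), "barcodes.tsv"),
                           "barcode")
    if (length(genes) != nrow(m) || length(cells) != ncol(m))
      stop("sidecar lengths do not match the matrix dimensions")
    m <- as(m, "CsparseMatrix")
    vals <- m
  } else {
    tab <- read.delim(path, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) stop("malformed header: need gene ids plus cells")
    genes <- as.character(tab[[1L]])
    vals <- as.matrix(tab[, -1L, drop = FALSE])
    if (!is.numeric(vals)) stop("non-numeric expression values")
    cells <- colnames(tab)[-1L]
    if (transpose) {
      tmp <- genes; genes <- cells; cells <- tmp
      vals <- base::t(vals)
    }
  }
  if (anyDuplicated(genes)) stop("duplicate gene ids")
  if (.matMin(vals) < 0) stop("negative expression value")
  ExpressionMatrix(vals, geneIds = genes, cellIds = cells, layer = "raw")
}

#' Write an expression matrix
#'
#' Inverse of \code{\link{readExpression}}: MatrixMarket plus sidecars, or
#' dense TSV with genes in rows.
#'
#' @param x an \linkS4class{ExpressionMatrix}.
#' @param path output path (.mtx or .tsv).
#' @param fmt \code{"mtx"} or \code{"tsv"}.
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(x, path, fmt = c("mtx", "tsv")) {
  fmt <- match.arg(fmt)
  stopifnot(is(x, "ExpressionMatrix"))
  v <- exprValues(x)
  if (fmt == "mtx") {
    Matrix::writeMM(as(as(v, "CsparseMatrix"), "generalMatrix"), path)
    dirn <- dirname(path)
    writeLines(geneIds(x), file.path(dirn, "genes.tsv"))
    writeLines(cellIds(x), file.path(dirn, "barcodes.tsv"))
  } else {
    tab <- data.frame(gene_id = geneIds(x), as.matrix(v),
                      check.names = FALSE, stringsAsFactors = FALSE)
    colnames(tab) <- c("gene_id", cellIds(x))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a bulk reference panel
#'
#' The matrix is a dense TSV with genes in rows (same dialect as
#' \code{\link{readExpression}}); per-sample cell-type labels come from a
#' two-column TSV (sample_id, cell_type) next to it, by default
#' \code{<path>.labels}. Every sample must have a label; labels need not be
#' unique.
#'
#' @param path path to the bulk TSV.
#' @param labelsPath path to the label TSV, default \code{paste0(path,
#'   ".labels")}.
#' @return A \linkS4class{BulkPanel}.
#' @export
readBulk <- function(path, labelsPath = paste0(path, ".labels")) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("malformed header: need gene ids plus samples")
  genes <- as.character(tab[[1L]])
  if (anyDuplicated(genes)) stop("duplicate gene ids")
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  samples <- colnames(tab)[-1L]
  if (!file.exists(labelsPath)) stop("missing label file: ", labelsPath)
  lab <- read.delim(labelsPath, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(lab) < 2L) stop("label file needs sample_id and cell_type columns")
  m <- match(samples, as.character(lab[[1L]]))
  if (anyNA(m))
    stop("missing label for sample(s): ",
         paste(samples[is.na(m)], collapse = ", "))
  BulkPanel(vals, cellTypes = as.character(lab[[2L]])[m],
            geneIds = genes, sampleIds = samples)
}

#' Write a bulk panel (matrix TSV plus label sidecar)
#'
#' @param r a \linkS4class{BulkPanel}.
#' @param path output TSV path; labels go to \code{paste0(path, ".labels")}.
#' @return \code{path}, invisibly.
#' @export
writeBulk <- function(r, path) {
  stopifnot(is(r, "BulkPanel"))
  tab <- data.frame(gene_id = geneIds(r), as.matrix(exprValues(r)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(tab) <- c("gene_id", sampleIds(r))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  lab <- data.frame(sample_id = sampleIds(r), cell_type = cellTypes(r),
                    stringsAsFactors = FALSE)
  write.table(lab, paste0(path, ".labels"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write per-cell results
#'
#' TSV with columns cell_id, cluster, cell_type, one row per cell in the
#' input cell order. Re-running on the same inputs produces a
#' byte-identical file.
#'
#' @param clusters a \linkS4class{ClusterResult}.
#' @param annotation an \linkS4class{AnnotationResult}, or NULL (then
#'   cell_type is NA).
#' @param path output TSV path.
#' @param cellIds character vector of cell identifiers, one per cell.
#' @return \code{path}, invisibly.
#' @export
writeResults <- function(clusters, annotation, path, cellIds) {
  stopifnot(is(clusters, "ClusterResult"))
  lab <- clusterLabels(clusters)
  if (length(lab) != length(cellIds))
    stop("cluster labels and cell ids disagree in length")
  ct <- if (is.null(annotation)) rep(NA_character_, length(lab))
        else cellTypes(annotation)
  if (length(ct) != length(lab))
    stop("annotation and cluster labels disagree in length")
  tab <- data.frame(cell_id = cellIds, cluster = lab, cell_type = ct,
                    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
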