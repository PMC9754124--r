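## Quality control, log-normalization, highly-variable-gene selection, and
## gene-set intersection with a reference panel.

#' Filter genes by their fraction of non-zero cells
#'
#' Removes genes expressed in strictly fewer than \code{lowFrac} or strictly
#' more than \code{highFrac} of cells. Boundary genes (exactly at either
#' fraction) are kept: removal requires the fraction to be strictly outside
#' the band.
#'
#' @param x an \linkS4class{ExpressionMatrix} (raw layer).
#' @param lowFrac,highFrac bounds on the non-zero fraction, defaults 0.05
#'   and 0.95.
#' @return An \linkS4class{ExpressionMatrix} with the retained genes.
#' @export
qcFilterGenes <- function(x, lowFrac = 0.05, highFrac = 0.95) {
  stopifnot(is(x, "ExpressionMatrix"))
  if (exprLayer(x) != "raw")
    stop("qcFilterGenes expects the raw layer")
  if (!(lowFrac >= 0 && lowFrac < highFrac && highFrac <= 1))
    stop("need 0 <= lowFrac < highFrac <= 1")
  v <- exprValues(x)
  frac <- Matrix::rowSums(v != 0) / ncol(v)
  keep <- frac >= lowFrac & frac <= highFrac
  if (!any(keep))
    stop("no genes pass the QC filter; consider disabling it (--no-qc)")
  x[keep, ]
}

#' Log-normalize raw counts
#'
#' Each entry m_ij becomes log(m_ij * scale / s_j + 1), where s_j is the
#' total count of cell j over the genes in the matrix and the log is
#' natural. Zero counts map to zero for any cell total.
#'
#' @param x an \linkS4class{ExpressionMatrix} (raw layer).
#' @param scale library-size scale factor, default 10000.
#' @return An \linkS4class{ExpressionMatrix} with layer \code{"normalized"}.
#' @export
logNormalize <- function(x, scale = 10000) {
  stopifnot(is(x, "ExpressionMatrix"))
  if (exprLayer(x) != "raw")
    stop("logNormalize expects the raw layer")
  v <- exprValues(x)
  tot <- Matrix::colSums(v)
  if (any(tot <= 0)) {
    bad <- colnames(v)[which(tot <= 0)[1L]]
    stop("cell '", bad, "' has zero total count; cannot normalize")
  }
  if (is(v, "sparseMatrix")) {
    v <- as(v, "CsparseMatrix")
    fac <- rep.int(scale / tot, diff(v@p))
    v@x <- log1p(v@x * fac)
    out <- v
  } else {
    out <- log1p(sweep(v, 2L, tot / scale, "/"))
  }
  ExpressionMatrix(out, layer = "normalized")
}

#' Select highly variable genes
#'
#' Variance-stabilizing selection on raw counts: per-gene means and variances
#' are computed, a smooth of log10(variance) on log10(mean) is fitted
#' (loess; degree-2 polynomial fallback for degenerate inputs), each gene's
#' counts are standardized by its fitted standard deviation with standardized
#' values clipped at sqrt(n), and genes are ranked by the variance of the
#' clipped standardized values.
#'
#' @param x an \linkS4class{ExpressionMatrix} (raw layer).
#' @param nHvg number of genes to keep (default 2000); capped at the number
#'   of non-constant genes.
#' @param loessSpan span of the mean-variance smooth, default 0.3.
#' @return A list with \code{keptGeneIds} (ordered by decreasing
#'   standardized variance) and \code{dispersionScores} (the standardized
#'   variances, same order).
#' @export
selectHVGs <- function(x, nHvg = 2000, loessSpan = 0.3) {
  stopifnot(is(x, "ExpressionMatrix"))
  if (exprLayer(x) != "raw")
    stop("selectHVGs expects raw counts")
  if (nHvg < 1) stop("nHvg must be >= 1")
  v <- exprValues(x)
  n <- ncol(v)
  mu <- as.numeric(Matrix::rowSums(v)) / n
  ex2 <- if (is(v, "sparseMatrix")) {
    v2 <- v
    v2@x <- v2@x^2
    as.numeric(Matrix::rowSums(v2)) / n
  } else {
    rowSums(v^2) / n
  }
  sigma2 <- (ex2 - mu^2) * n / max(n - 1, 1)
  nonconst <- sigma2 > 0 & mu > 0
  if (sum(nonconst) < 3L)
    stop("fewer than 3 non-constant genes; cannot rank variability")
  lmu <- log10(mu[nonconst])
  lvar <- log10(sigma2[nonconst])
  fitted <- NULL
  if (sum(nonconst) >= 30L) {        # loess needs enough genes to be sane
    fitted <- tryCatch({
      fit <- stats::loess(lvar ~ lmu, span = loessSpan, degree = 2,
                          family = "gaussian")
      stats::predict(fit, lmu)
    }, error = function(e) NULL, warning = function(w) NULL)
  }
  if (is.null(fitted) || anyNA(fitted)) {
    fit <- stats::lm(lvar ~ stats::poly(lmu, degree = min(2L, length(unique(lmu)) - 1L)))
    fitted <- stats::predict(fit)
  }
  sdFit <- sqrt(10^fitted)
  clipMax <- sqrt(n)
  vd <- as.matrix(v[nonconst, , drop = FALSE])
  z <- (vd - mu[nonconst]) / sdFit
  z <- pmin(pmax(z, -clipMax), clipMax)
  stdVar <- apply(z, 1L, var)
  ord <- order(stdVar, decreasing = TRUE)
  nKeep <- min(nHvg, length(ord))
  kept <- ord[seq_len(nKeep)]
  list(keptGeneIds = rownames(v)[nonconst][kept],
       dispersionScores = unname(stdVar[kept]))
}

#' Restrict expression and reference data to a shared gene set
#'
#' Intersects a gene selection with the genes of a bulk panel and subsets
#' both the expression matrix and the panel to that intersection, in the
#' same gene order (the order of the selection).
#'
#' @param x an \linkS4class{ExpressionMatrix}.
#' @param r a \linkS4class{BulkPanel} (or \linkS4class{ReferencePanel}).
#' @param selection character vector of gene ids (e.g. from
#'   \code{\link{selectHVGs}}), or the list returned by that function;
#'   defaults to all genes of \code{x}.
#' @return A list with elements \code{x} and \code{r}, both restricted to
#'   the shared genes.
#' @export
intersectGenes <- function(x, r, selection = geneIds(x)) {
  if (is.list(selection)) selection <- selection$keptGeneIds
  selection <- intersect(selection, geneIds(x))
  shared <- selection[selection %in% geneIds(r)]
  if (length(shared) == 0L)
    stop("no genes shared between the selection and the reference panel")
  list(x = x[shared, ], r = r[shared, ])
}
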