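## Synthetic clustered scRNA-seq-like data with a matched bulk panel, for
## end-to-end testing without downloads.

#' Simulate clustered single-cell count data
#'
#' Each cluster gets a disjoint block of marker genes whose log-mean is
#' elevated by \code{separation} over a shared baseline; counts are drawn
#' from a negative binomial around the cell's library-size-scaled expected
#' expression and then zeroed independently with probability
#' \code{dropoutRate}. Cluster sizes are balanced up to rounding, cluster
#' assignment is a seeded shuffle. Regeneration with the same parameters is
#' bit-identical.
#'
#' @param nCells,nGenes dimensions of the simulated matrix.
#' @param k number of clusters, k <= nCells.
#' @param separation log-scale elevation of each cluster's marker block
#'   (> 0); around 2 gives moderately separated clusters, 5 and above is
#'   essentially noiseless structure.
#' @param dropoutRate probability in [0, 1) of zeroing any count.
#' @param seed integer seed.
#' @param dispersion negative-binomial dispersion (variance = mu +
#'   dispersion * mu^2), default 0.3.
#' @param libMeanlog,libSdlog log-normal library-size parameters, defaults
#'   9.2 and 0.3 (median library about 10,000 counts).
#' @param markerFrac fraction of genes used as markers per cluster, default
#'   0.05 (at least 3, capped so blocks stay disjoint).
#' @return A list with \code{counts} (raw \linkS4class{ExpressionMatrix}),
#'   \code{trueLabels} (integer per cell) and \code{params}.
#' @export
makeClusters <- function(nCells, nGenes, k, separation, dropoutRate = 0,
                         seed = 1L, dispersion = 0.3, libMeanlog = 9.2,
                         libSdlog = 0.3, markerFrac = 0.05) {
  if (k < 1L || k > nCells) stop("need 1 <= k <= nCells")
  if (!(separation > 0)) stop("separation must be > 0")
  if (dropoutRate < 0 || dropoutRate >= 1)
    stop("dropoutRate must be in [0, 1)")
  nMark <- max(3L, floor(markerFrac * nGenes))
  nMark <- min(nMark, floor(nGenes / k))
  if (nMark < 1L) stop("too few genes for k disjoint marker blocks")
  params <- list(nCells = nCells, nGenes = nGenes, k = k,
                 separation = separation, dropoutRate = dropoutRate,
                 seed = as.integer(seed), dispersion = dispersion,
                 libMeanlog = libMeanlog, libSdlog = libSdlog,
                 nMarkersPerCluster = nMark)
  out <- withr::with_seed(as.integer(seed), {
    labels <- sample(rep_len(seq_len(k), nCells))
    baseline <- rnorm(nGenes, 0, 1)
    logMeans <- matrix(baseline, nGenes, k)
    markers <- vector("list", k)
    for (c in seq_len(k)) {
      block <- ((c - 1L) * nMark + 1L):(c * nMark)
      logMeans[block, c] <- logMeans[block, c] + separation
      markers[[c]] <- block
    }
    rates <- exp(logMeans)
    props <- sweep(rates, 2L, colSums(rates), "/")
    lib <- rlnorm(nCells, meanlog = libMeanlog, sdlog = libSdlog)
    mu <- props[, labels, drop = FALSE] * rep(lib, each = nGenes)
    counts <- matrix(rnbinom(nGenes * nCells, mu = mu, size = 1 / dispersion),
                     nGenes, nCells)
    if (dropoutRate > 0) {
      drop <- matrix(runif(nGenes * nCells) < dropoutRate, nGenes, nCells)
      counts[drop] <- 0L
    }
    empty <- which(colSums(counts) == 0)
    if (length(empty))                    # keep every cell normalizable
      counts[markers[[1L]][1L], empty] <- 1L
    list(counts = counts, labels = labels, markers = markers)
  })
  dimnames(out$counts) <- list(sprintf("gene_%d", seq_len(nGenes)),
                               sprintf("cell_%d", seq_len(nCells)))
  list(counts = ExpressionMatrix(out$counts, layer = "raw"),
       trueLabels = out$labels,
       markerBlocks = out$markers,
       params = params)
}

#' Derive a matched bulk panel from a simulated dataset
#'
#' One sample per true cluster: the cluster's mean log-normalized profile
#' plus i.i.d. Gaussian noise, labeled \code{type_<c>}. Optionally adds
#' decoy samples (seeded permutations of the global mean profile) that are
#' uncorrelated with every cell, labeled \code{decoy_<i>}. The panel is on
#' the log scale, so downstream correlation steps should use
#' \code{bulkLog = "none"}.
#'
#' @param d a dataset from \code{\link{makeClusters}}.
#' @param nDecoys number of decoy samples, default 0.
#' @param noiseSd Gaussian noise standard deviation, default 0.
#' @param seed integer seed.
#' @return A \linkS4class{BulkPanel}.
#' @export
makeBulkFromTruth <- function(d, nDecoys = 0L, noiseSd = 0, seed = 1L) {
  xn <- logNormalize(d$counts)
  v <- exprValues(xn)
  k <- d$params$k
  labels <- d$trueLabels
  nGenes <- nrow(v)
  vals <- withr::with_seed(as.integer(seed), {
    refs <- vapply(seq_len(k), function(c) {
      idx <- which(labels == c)
      m <- as.numeric(Matrix::rowSums(v[, idx, drop = FALSE])) / length(idx)
      m + rnorm(nGenes, 0, noiseSd)
    }, numeric(nGenes))
    refs <- matrix(refs, nrow = nGenes)
    if (nDecoys > 0) {
      global <- rowMeans(refs)
      decoys <- vapply(seq_len(nDecoys), function(i) sample(global),
                       numeric(nGenes))
      refs <- cbind(refs, matrix(decoys, nrow = nGenes))
    }
    refs
  })
  vals <- pmax(vals, 0)
  types <- c(sprintf("type_%d", seq_len(k)),
             if (nDecoys > 0) sprintf("decoy_%d", seq_len(nDecoys)))
  dimnames(vals) <- list(geneIds(xn), make.unique(types))
  BulkPanel(vals, cellTypes = types)
}
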