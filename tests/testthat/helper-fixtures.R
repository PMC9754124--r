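# Shared fixtures and independent oracles used across test files.

# Small dense ExpressionMatrix from explicit values.
em <- function(values, layer = "raw", genes = NULL, cells = NULL) {
  values <- as.matrix(values)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(values)))
  if (is.null(cells)) cells <- paste0("c", seq_len(ncol(values)))
  ExpressionMatrix(values, geneIds = genes, cellIds = cells, layer = layer)
}

# Random valid anchor graph: each cell connects to a random subset of
# anchors within a random "block" structure when nBlocks > 1, with
# Dirichlet-like weights summing to one.
randomAnchorGraph <- function(d, n, seed, nBlocks = 1L, density = 0.6) {
  nBlocks <- min(nBlocks, d, n)
  withr::with_seed(seed, {
    A <- matrix(0, d, n)
    anchorBlock <- rep_len(seq_len(nBlocks), d)
    cellBlock <- rep_len(seq_len(nBlocks), n)
    for (i in seq_len(n)) {
      pool <- which(anchorBlock == cellBlock[i])
      nsel <- max(1L, rbinom(1L, length(pool), density))
      sel <- pool[sample.int(length(pool), nsel)]
      w <- rgamma(nsel, 1) + 0.05   # keep every edge well above zero_tol
      A[sel, i] <- w / sum(w)
    }
    # every anchor needs some support so no isolated-vertex surprises
    for (j in which(rowSums(A) == 0)) {
      i <- which(cellBlock == anchorBlock[j])[1L]
      A[, i] <- 0
      A[j, i] <- 1
    }
    AnchorGraph(A)
  })
}

# Dense eigendecomposition of the explicit normalized Laplacian (oracle).
denseLaplacianEigen <- function(a) {
  L <- laplacianMatrix(bipartiteLaplacian(a))
  eigen((L + t(L)) / 2, symmetric = TRUE)
}

# Exhaustive simplex-grid minimizer (oracle) for
# min ||x - R a||^2 + delta ||a||^2 + beta v'a, d' = 3, grid step `step`.
gridSimplexMin <- function(x, R, delta, beta = 0, v = rep(0, ncol(R)),
                           step = 0.01) {
  stopifnot(ncol(R) == 3L)
  g <- seq(0, 1, by = step)
  best <- Inf
  for (a1 in g) for (a2 in g[g <= 1 - a1 + 1e-12]) {
    a <- c(a1, a2, 1 - a1 - a2)
    val <- sum((x - R %*% a)^2) + delta * sum(a^2) + beta * sum(v * a)
    if (val < best) best <- val
  }
  best
}

# Objective of one simplex-QP column (shared by solver tests).
colObjective <- function(a, x, R, delta, beta = 0, v = rep(0, length(a))) {
  sum((x - R %*% a)^2) + delta * sum(a^2) + beta * sum(v * a)
}

# Pair-counting ARI oracle: enumerate all pairs directly.
ariPairOracle <- function(pred, truth) {
  n <- length(pred)
  sameP <- outer(pred, pred, "==")[upper.tri(diag(n))]
  sameT <- outer(truth, truth, "==")[upper.tri(diag(n))]
  a <- sum(sameP & sameT); b <- sum(sameP & !sameT)
  c <- sum(!sameP & sameT); d <- sum(!sameP & !sameT)
  idx <- a
  expected <- (a + b) * (a + c) / (a + b + c + d)
  maxIdx <- ((a + b) + (a + c)) / 2
  (idx - expected) / (maxIdx - expected)
}

# Brute-force optimal cluster-class matching accuracy (oracle, small k).
accPermOracle <- function(pred, truth) {
  C <- unclass(table(pred, truth))
  s <- max(dim(C))
  Cp <- matrix(0, s, s)
  Cp[seq_len(nrow(C)), seq_len(ncol(C))] <- C
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- 0
  for (p in perms(seq_len(s)))
    best <- max(best, sum(Cp[cbind(seq_len(s), p)]))
  best / length(pred)
}

# Standard small simulated dataset used by several files.
standardSim <- function(seed = 11, nCells = 200, nGenes = 300, k = 3,
                        separation = 2, dropoutRate = 0.3) {
  makeClusters(nCells = nCells, nGenes = nGenes, k = k,
               separation = separation, dropoutRate = dropoutRate,
               seed = seed)
}

# QC + HVG + normalization, returning the matrix the solver consumes.
preprocessSim <- function(sim, nHvg = 2000) {
  raw <- qcFilterGenes(sim$counts)
  keep <- selectHVGs(raw, nHvg = nHvg)$keptGeneIds
  logNormalize(raw)[keep, ]
}
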