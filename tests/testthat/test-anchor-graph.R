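# Laplacian structure, spectral embedding, component counting, objective,
# and the alternating fit.

test_that("the 1-anchor/1-cell Laplacian is [[1,-1],[-1,1]]", {
  a <- AnchorGraph(matrix(1, 1, 1))
  L <- laplacianMatrix(bipartiteLaplacian(a))
  expect_equal(L, matrix(c(1, -1, -1, 1), 2, 2), ignore_attr = TRUE)
  expect_equal(sort(eigen(L)$values), c(0, 2), tolerance = 1e-12)
})

test_that("cell degrees are exactly one and anchor degrees are row sums", {
  a <- randomAnchorGraph(4, 15, seed = 1)
  deg <- degreeVector(bipartiteLaplacian(a))
  expect_equal(deg[5:19], rep(1, 15), ignore_attr = TRUE)
  expect_equal(deg[1:4], rowSums(anchorMatrix(a)), ignore_attr = TRUE)
})

test_that("zero-eigenvalue multiplicity equals the block count", {
  blockA <- matrix(0, 4, 10)
  blockA[1:2, 1:5] <- 0.5
  blockA[3:4, 6:10] <- 0.5
  a <- AnchorGraph(blockA)
  ev <- denseLaplacianEigen(a)$values
  expect_equal(sum(ev < 1e-10), 2L)
  expect_true(all(ev > -1e-10 & ev < 2 + 1e-10))
})

test_that("any valid graph has spectrum in [0,2] with a zero eigenvalue", {
  for (s in 1:5) {
    a <- randomAnchorGraph(5, 12, seed = s)
    ev <- denseLaplacianEigen(a)$values
    expect_true(all(ev > -1e-8 & ev < 2 + 1e-8))
    expect_lt(min(ev), 1e-8)
  }
})

test_that("SVD embedding matches dense eigendecomposition of the explicit L", {
  for (s in 1:6) {
    d <- sample(3:8, 1)
    n <- sample(10:50, 1)
    a <- randomAnchorGraph(d, n, seed = 200 + s)
    k <- sample(seq_len(d - 1), 1) + 1L
    emb <- embedSpectral(a, k)
    eig <- denseLaplacianEigen(a)
    dn <- d + n
    expect_equal(laplacianEigenvalues(emb), rev(eig$values)[seq_len(k)],
                 tolerance = 1e-8, ignore_attr = TRUE)
    # compare subspaces through projectors (sign/rotation free)
    Fhat <- embeddingMatrix(emb)
    Fref <- eig$vectors[, dn - seq_len(k) + 1L, drop = FALSE]
    gap <- rev(eig$values)[k + 1L] - rev(eig$values)[k]
    if (gap > 1e-6) {   # subspace only identifiable across a spectral gap
      expect_lt(max(abs(tcrossprod(Fhat) - tcrossprod(Fref))), 1e-6)
    }
    expect_equal(crossprod(Fhat), diag(k), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("the k = 1 eigenvector of a connected graph is D^{1/2} 1", {
  a <- randomAnchorGraph(3, 9, seed = 31)
  stopifnot(countComponents(a) == 1L)
  emb <- embedSpectral(a, 1)
  expect_lt(laplacianEigenvalues(emb)[1], 1e-10)
  f <- embeddingMatrix(emb)[, 1]
  ref <- sqrt(degreeVector(bipartiteLaplacian(a)))
  ref <- ref / sqrt(sum(ref^2))
  expect_equal(abs(f), ref, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("a k-block graph embeds with zero spectral energy", {
  blockA <- matrix(0, 6, 12)
  blockA[1:2, 1:4] <- 0.5; blockA[3:4, 5:8] <- 0.5; blockA[5:6, 9:12] <- 0.5
  a <- AnchorGraph(blockA)
  emb <- embedSpectral(a, 3)
  expect_equal(sum(laplacianEigenvalues(emb)), 0, tolerance = 1e-10)
})

test_that("component counting by traversal agrees with the spectral count", {
  for (s in 1:20) {
    d <- sample(3:7, 1)
    nb <- sample(seq_len(min(4, d)), 1)
    a <- randomAnchorGraph(d, sample(8:25, 1), seed = 300 + s,
                           nBlocks = nb)
    byGraph <- countComponents(a)
    ev <- denseLaplacianEigen(a)$values
    expect_identical(byGraph, as.integer(sum(ev < 1e-8)))
    expect_gte(byGraph, nb)   # blocks never connect; they may split further
  }
  expect_identical(countComponents(AnchorGraph(matrix(0.25, 4, 8))), 1L)
})

test_that("the objective decomposes exactly and vanishes at perfect fit", {
  # X = R'A exactly, beta = 0, delta -> 0 limit checked at delta = 0 terms
  withr::with_seed(55, {
    R <- matrix(runif(15, 0.5, 2), 5, 3)
    A <- anchorMatrix(randomAnchorGraph(3, 8, seed = 2))
  })
  X <- R %*% A
  x <- em(X, layer = "normalized", genes = paste0("g", 1:5))
  rp <- ReferencePanel(R, provenance = "kmeans", geneIds = geneIds(x),
                       sampleIds = paste0("r", 1:3))
  ag <- AnchorGraph(A)
  emb <- embedSpectral(ag, 2)
  expect_equal(lfscObjective(x, rp, ag, emb, delta = 0, beta = 0), 0,
               tolerance = 1e-10)

  # the ridge term alone: one cell with column (0.5, 0.5), delta = 2 -> 1.0
  expect_equal(lfscObjective(x, rp, ag, emb, delta = 2, beta = 0),
               2 * sum(A^2), tolerance = 1e-10)
})

test_that("the objective matches a naive dense recomputation", {
  withr::with_seed(77, {
    R <- matrix(runif(5 * 4), 5, 4)
    X <- matrix(runif(5 * 10), 5, 10)
  })
  a <- randomAnchorGraph(4, 10, seed = 9)
  x <- em(X, layer = "normalized")
  rp <- ReferencePanel(R, provenance = "kmeans", geneIds = geneIds(x),
                       sampleIds = paste0("r", 1:4))
  emb <- embedSpectral(a, 2)
  delta <- 0.7; beta <- 1.3
  A <- anchorMatrix(a)
  L <- laplacianMatrix(bipartiteLaplacian(a))
  F <- embeddingMatrix(emb)
  naive <- sum((X - R %*% A)^2) + delta * sum(A^2) +
    beta * sum(diag(t(F) %*% L %*% F))
  expect_equal(lfscObjective(x, rp, a, emb, delta, beta), naive,
               tolerance = 1e-10)
})

test_that("the fit reaches k components on separated data, deterministically", {
  sim <- standardSim(seed = 23, nCells = 120, nGenes = 150, separation = 5)
  xn <- logNormalize(sim$counts)
  rp <- buildSCReferences(xn, sim$trueLabels)
  f1 <- fitLFSC(xn, rp, k = 3, seed = 1)
  f2 <- fitLFSC(xn, rp, k = 3, seed = 1)
  expect_identical(componentCount(f1), 3L)
  expect_true(isConverged(f1))
  expect_identical(objectiveTrace(f1), objectiveTrace(f2))
  expect_error(fitLFSC(xn, rp, k = 10), "at least k reference samples")

  # embedding rows collapse to k points: K-means reproduces the graph's
  # component structure exactly, and that structure matches the truth up
  # to the few genuinely ambiguous dropout-heavy cells
  A <- anchorMatrix(f1)
  sup <- which(A > 1e-8, arr.ind = TRUE)
  g <- igraph::graph_from_edgelist(
    cbind(sup[, 1], 3 + sup[, 2]), directed = FALSE)
  membership <- igraph::components(g)$membership[3 + seq_len(ncol(A))]
  cl <- kmeansLabels(spectralEmbedding(f1), k = 3, seed = 1)
  expect_equal(ari(cl, membership), 1)
  expect_gte(ari(cl, sim$trueLabels), 0.9)
})

test_that("every anchor graph the fit touches satisfies the simplex constraint", {
  sim <- standardSim(seed = 29, nCells = 60, nGenes = 80)
  xn <- logNormalize(sim$counts)
  rp <- buildSCReferences(xn, sim$trueLabels)
  graph <- initAnchorGraph(xn, rp, delta = 1)
  checkSimplex <- function(g) {
    A <- anchorMatrix(g)
    expect_true(all(A >= -1e-12))
    expect_equal(colSums(A), rep(1, ncol(A)), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  checkSimplex(graph)
  beta <- 0.01
  for (it in 1:10) {
    deg <- degreeVector(bipartiteLaplacian(graph))
    emb <- embedSpectral(graph, 3)
    graph <- updateAnchorGraph(xn, rp, emb, deg, delta = 1, beta = beta)
    checkSimplex(graph)
    beta <- beta * 2
  }
})

test_that("A-updates never increase the frozen-degree objective", {
  sim <- standardSim(seed = 37, nCells = 80, nGenes = 100)
  xn <- logNormalize(sim$counts)
  rp <- buildSCReferences(xn, sim$trueLabels)
  delta <- 1; beta <- 0.5
  graph <- initAnchorGraph(xn, rp, delta)
  R <- as.matrix(exprValues(rp)); X <- as.matrix(exprValues(xn))
  frozenObj <- function(A, V) {
    sum((X - R %*% A)^2) + delta * sum(A^2) + beta * sum(A * V)
  }
  for (it in 1:12) {
    deg <- degreeVector(bipartiteLaplacian(graph))
    emb <- embedSpectral(graph, 3)
    V <- anchorCellDistances(emb, deg)
    before <- frozenObj(anchorMatrix(graph), V)
    graph <- updateAnchorGraph(xn, rp, emb, deg, delta, beta)
    after <- frozenObj(anchorMatrix(graph), V)
    expect_lte(after, before + 1e-9)
  }
})

test_that("non-convergence is reported honestly", {
  sim <- standardSim(seed = 41, nCells = 40, nGenes = 60)
  xn <- logNormalize(sim$counts)
  rp <- buildSCReferences(xn, sim$trueLabels)
  expect_warning(f <- fitLFSC(xn, rp, k = 3, maxIter = 1L, tol = 0),
                 "did not converge")
  expect_false(isConverged(f))
  expect_length(objectiveTrace(f), 1L)
})
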