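## The core solver: learn the anchor graph A by alternating simplex-
## constrained quadratic programs (one per cell) with spectral updates of
## the embedding F, adapting the spectral weight beta until the bipartite
## graph has exactly k connected components.

.checkAligned <- function(x, rp) {
  if (!identical(geneIds(x), geneIds(rp)))
    stop("gene spaces of the expression matrix and reference panel differ; ",
         "run intersectGenes() first")
}

## Quadratic pieces shared by every per-cell subproblem:
## min ||x_i - R'a||^2 + delta ||a||^2 + beta v_i'a
##   = 0.5 a' [2(R''R' + delta I)] a + (-2 R''x_i + beta v_i)' a + const
.qpPieces <- function(x, rp, delta) {
  Rv <- as.matrix(exprValues(rp))
  Xv <- exprValues(x)
  G0 <- crossprod(Rv)
  P <- as.matrix(base::t(Rv) %*% Xv)                # d' x n, = R''X
  list(Q = 2 * (G0 + delta * diag(nrow(G0))), P = P, G0 = G0,
       sumX2 = sum(Xv^2))
}

#' Initialize the anchor graph
#'
#' Solves the beta = 0 subproblem for every cell: each column of A minimizes
#' the ridge-regularized reconstruction error of that cell from the
#' reference profiles over the probability simplex.
#'
#' @param x an \linkS4class{ExpressionMatrix} (normalized), genes aligned
#'   with \code{rp}.
#' @param rp a \linkS4class{ReferencePanel}.
#' @param delta ridge penalty, > 0.
#' @return An \linkS4class{AnchorGraph}.
#' @export
initAnchorGraph <- function(x, rp, delta = 1.0) {
  .checkAligned(x, rp)
  if (ncol(rp) == 0L) stop("reference panel has no samples")
  if (delta <= 0) stop("delta must be > 0")
  qp <- .qpPieces(x, rp, delta)
  A <- .simplexQPcols(qp$Q, -2 * qp$P)
  dimnames(A) <- list(sampleIds(rp), cellIds(x))
  AnchorGraph(A)
}

#' Degrees of the bipartite graph
#'
#' Builds the degree vector of the bipartite adjacency B = [[0, A], [A', 0]]:
#' anchor degrees are row sums of A, cell degrees are column sums (exactly 1
#' for a valid anchor graph). Degrees below 1e-12 are floored at 1e-12 so
#' D^{-1/2} stays finite for isolated anchors.
#'
#' @param a an \linkS4class{AnchorGraph}.
#' @return A \linkS4class{BipartiteLaplacian}.
#' @export
bipartiteLaplacian <- function(a) {
  stopifnot(is(a, "AnchorGraph"))
  A <- anchorMatrix(a)
  deg <- c(rowSums(A), colSums(A))
  deg[deg < 1e-12] <- 1e-12
  new("BipartiteLaplacian", degrees = deg, graph = a)
}

#' Materialize the normalized Laplacian (small problems only)
#'
#' Builds the explicit (d'+n) x (d'+n) matrix L = I - D^{-1/2} B D^{-1/2}.
#' Intended for inspection and testing; the solver never forms this matrix.
#'
#' @param bl a \linkS4class{BipartiteLaplacian}.
#' @return A dense symmetric matrix.
#' @export
laplacianMatrix <- function(bl) {
  stopifnot(is(bl, "BipartiteLaplacian"))
  A <- anchorMatrix(bl@graph)
  d <- nrow(A); n <- ncol(A)
  B <- matrix(0, d + n, d + n)
  B[seq_len(d), d + seq_len(n)] <- A
  B[d + seq_len(n), seq_len(d)] <- base::t(A)
  s <- 1 / sqrt(bl@degrees)
  diag(d + n) - (s %o% s) * B
}

#' Spectral embedding of the anchor graph
#'
#' Computes the k eigenvectors of the normalized bipartite Laplacian for its
#' k smallest eigenvalues without forming L: with the degree-normalized
#' graph Abar = D_anchor^{-1/2} A D_cell^{-1/2}, each singular triplet
#' (sigma, u, v) of Abar yields the Laplacian eigenvalue 1 - sigma with
#' eigenvector (u, v)/sqrt(2).
#'
#' @param a an \linkS4class{AnchorGraph}.
#' @param k embedding dimension, 1 <= k <= d'.
#' @return A \linkS4class{SpectralEmbedding} (anchor rows first).
#' @export
embedSpectral <- function(a, k) {
  stopifnot(is(a, "AnchorGraph"))
  A <- anchorMatrix(a)
  d <- nrow(A)
  if (k < 1L || k > d)
    stop("need at least k reference samples (k <= d')")
  deg <- bipartiteLaplacian(a)@degrees
  dr <- deg[seq_len(d)]
  dc <- deg[d + seq_len(ncol(A))]
  Abar <- (A / sqrt(dr)) / rep(sqrt(dc), each = d)
  sv <- svd(Abar, nu = k, nv = k)
  evals <- pmax(1 - sv$d[seq_len(k)], 0)
  F <- rbind(sv$u, sv$v) / sqrt(2)
  new("SpectralEmbedding", F = F, nAnchors = as.integer(d),
      eigenvalues = evals)
}

#' Squared embedding distances between anchors and cells
#'
#' The linear term of the spectral penalty: v_ij = 0.5 * || f_anchor_j /
#' sqrt(d_j) - f_cell_i / sqrt(d_i) ||^2, with the degrees frozen at the
#' supplied values. Summing a_ji * v_ij over the graph reproduces
#' Tr(F' L F) for the frozen degrees, which makes the spectral penalty
#' separable across cells.
#'
#' @param emb a \linkS4class{SpectralEmbedding}.
#' @param degrees the degree vector the penalty is linearized at (length
#'   d'+n, anchors first).
#' @return A d'-by-n matrix of nonnegative distances.
#' @export
anchorCellDistances <- function(emb, degrees) {
  stopifnot(is(emb, "SpectralEmbedding"))
  F <- embeddingMatrix(emb)
  if (length(degrees) != nrow(F))
    stop("degree vector length must be d' + n")
  d <- nAnchors(emb)
  Ft <- F / sqrt(pmax(degrees, 1e-12))
  Fa <- Ft[seq_len(d), , drop = FALSE]
  Fc <- Ft[-seq_len(d), , drop = FALSE]
  V <- 0.5 * (outer(rowSums(Fa^2), rep(1, nrow(Fc))) +
              outer(rep(1, d), rowSums(Fc^2)) -
              2 * tcrossprod(Fa, Fc))
  if (any(!is.finite(V))) stop("non-finite spectral linear term")
  pmax(V, 0)
}

#' One A-update of the alternating optimization
#'
#' With the embedding F and the degrees frozen, solves for every cell i the
#' convex quadratic program
#' min ||x_i - R'a||^2 + delta ||a||^2 + beta * sum_j a_j v_ij
#' over the probability simplex, where v is computed by
#' \code{\link{anchorCellDistances}}. At beta = 0 this reduces exactly to
#' \code{\link{initAnchorGraph}}.
#'
#' @param x an \linkS4class{ExpressionMatrix} (normalized).
#' @param rp a \linkS4class{ReferencePanel} on the same genes.
#' @param emb the current \linkS4class{SpectralEmbedding}.
#' @param degrees degree vector of the current iterate (frozen).
#' @param delta ridge penalty.
#' @param beta spectral penalty weight.
#' @return An \linkS4class{AnchorGraph}.
#' @export
updateAnchorGraph <- function(x, rp, emb, degrees, delta, beta) {
  .checkAligned(x, rp)
  qp <- .qpPieces(x, rp, delta)
  V <- anchorCellDistances(emb, degrees)
  A <- .simplexQPcols(qp$Q, -2 * qp$P + beta * V)
  dimnames(A) <- list(sampleIds(rp), cellIds(x))
  AnchorGraph(A)
}

#' Count connected components of the anchor graph
#'
#' Components of the bipartite graph on the support {(j, i) : a_ji >
#' zeroTol}; isolated vertices count as components. By the standard
#' spectral result, this equals the multiplicity of the zero eigenvalue of
#' the normalized Laplacian of the thresholded graph.
#'
#' @param a an \linkS4class{AnchorGraph}.
#' @param zeroTol support threshold, default 1e-8.
#' @return Integer component count.
#' @export
countComponents <- function(a, zeroTol = 1e-8) {
  stopifnot(is(a, "AnchorGraph"))
  A <- anchorMatrix(a)
  d <- nrow(A); n <- ncol(A)
  sup <- which(A > zeroTol, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = d + n, directed = FALSE)
  if (nrow(sup)) {
    edges <- rbind(sup[, 1L], d + sup[, 2L])
    g <- igraph::add_edges(g, as.vector(edges))
  }
  as.integer(igraph::components(g)$no)
}

#' Objective of the anchor-graph model
#'
#' The three-term objective ||X - R'A||^2 + delta ||A||^2 +
#' beta Tr(F' L F), with L the normalized Laplacian of the graph in
#' \code{a} and F the supplied embedding. When F holds the bottom-k
#' eigenvectors of L, the trace term equals the sum of the k smallest
#' eigenvalues. Computed from O(d'n) pieces; neither L nor the dense
#' residual matrix is formed.
#'
#' @param x an \linkS4class{ExpressionMatrix} (normalized).
#' @param rp a \linkS4class{ReferencePanel}.
#' @param a an \linkS4class{AnchorGraph}.
#' @param emb a \linkS4class{SpectralEmbedding}.
#' @param delta,beta model hyperparameters.
#' @return The scalar objective value.
#' @export
lfscObjective <- function(x, rp, a, emb, delta, beta) {
  .checkAligned(x, rp)
  qp <- .qpPieces(x, rp, delta)
  A <- anchorMatrix(a)
  recon <- qp$sumX2 - 2 * sum(qp$P * A) + sum(A * (qp$G0 %*% A))
  ridge <- delta * sum(A^2)
  d <- nrow(A)
  deg <- bipartiteLaplacian(a)@degrees
  dr <- deg[seq_len(d)]
  dc <- deg[d + seq_len(ncol(A))]
  Abar <- (A / sqrt(dr)) / rep(sqrt(dc), each = d)
  F <- embeddingMatrix(emb)
  Fa <- F[seq_len(d), , drop = FALSE]
  Fc <- F[-seq_len(d), , drop = FALSE]
  trFLF <- sum(F^2) - 2 * sum(Abar * tcrossprod(Fa, Fc))
  recon + ridge + beta * trFLF
}

#' Fit the k-connected anchor graph
#'
#' Alternates per-cell simplex QPs (A-update) with spectral updates of F,
#' starting from the beta = 0 solution. After every iteration beta is
#' adapted toward the connectivity target: doubled while the graph has
#' fewer than k components, halved while it has more, left alone at exactly
#' k. The fit stops when the relative objective change drops below
#' \code{tol} while the graph has exactly k components, or after
#' \code{maxIter} iterations (then the best iterate is returned with
#' \code{converged = FALSE} and a warning).
#'
#' @param x an \linkS4class{ExpressionMatrix}, normalized layer, genes
#'   aligned with \code{rp}.
#' @param rp a \linkS4class{ReferencePanel}.
#' @param k target number of connected components (clusters), k <= d'.
#' @param delta ridge penalty, default 1.
#' @param beta0 initial spectral weight, default 0.01.
#' @param maxIter maximum outer iterations, default 30.
#' @param tol relative objective-change tolerance, default 1e-6.
#' @param seed integer seed (the solver itself is deterministic; kept so
#'   every pipeline stage shares one seeding convention).
#' @return An \linkS4class{LFSCFit}.
#' @examples
#' sim <- makeClusters(nCells = 60, nGenes = 80, k = 2, separation = 5,
#'                     dropoutRate = 0.1, seed = 1)
#' xn <- logNormalize(sim$counts)
#' rp <- buildSCReferences(xn, sim$trueLabels)
#' fit <- fitLFSC(xn, rp, k = 2)
#' componentCount(fit)
#' @export
fitLFSC <- function(x, rp, k, delta = 1.0, beta0 = 0.01, maxIter = 30L,
                    tol = 1e-6, seed = 1L) {
  .checkAligned(x, rp)
  d <- ncol(rp)
  k <- as.integer(k)
  if (k > d) stop("need at least k reference samples (k <= d')")
  if (exprLayer(x) != "normalized")
    stop("fitLFSC expects log-normalized expression")
  qp <- .qpPieces(x, rp, delta)
  n <- ncol(x)
  A <- .simplexQPcols(qp$Q, -2 * qp$P)
  dimnames(A) <- list(sampleIds(rp), cellIds(x))
  graph <- AnchorGraph(A)

  beta <- beta0
  trace <- numeric(0)
  prevObj <- Inf
  converged <- FALSE
  best <- NULL
  comp <- countComponents(graph)
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    deg <- bipartiteLaplacian(graph)@degrees
    emb <- embedSpectral(graph, k)
    V <- anchorCellDistances(emb, deg)
    A <- .simplexQPcols(qp$Q, -2 * qp$P + beta * V)
    dimnames(A) <- list(sampleIds(rp), cellIds(x))
    graph <- AnchorGraph(A)
    comp <- countComponents(graph)

    recon <- qp$sumX2 - 2 * sum(qp$P * A) + sum(A * (qp$G0 %*% A))
    embNew <- embedSpectral(graph, k)
    obj <- recon + delta * sum(A^2) +
      beta * sum(laplacianEigenvalues(embNew))
    trace <- c(trace, obj)
    if (is.null(best) || obj < best$obj)
      best <- list(graph = graph, emb = embNew, obj = obj, comp = comp,
                   beta = beta)

    if (comp == k && abs(obj - prevObj) <= tol * max(1, abs(prevObj))) {
      converged <- TRUE
      break
    }
    prevObj <- obj
    if (comp < k) beta <- 2 * beta
    else if (comp > k) beta <- beta / 2
  }
  if (!converged) {
    warning("anchor-graph fit did not converge in ", maxIter,
            " iterations; returning the best iterate")
    graph <- best$graph
    embNew <- best$emb
    comp <- best$comp
  }
  new("LFSCFit", graph = graph, embedding = embNew, k = k,
      delta = as.numeric(delta), beta0 = as.numeric(beta0),
      beta = as.numeric(beta), objectiveTrace = trace,
      iterations = iter, converged = converged,
      componentCount = as.integer(comp))
}
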