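## Brain-graph construction and the spectral machinery behind the GCN:
## the renormalized operator used by every layer, plus the exact spectral
## filter and Chebyshev polynomial filters that serve as verification
## oracles for the first-order simplification.

## Exactly-symmetric D^-1/2 M D^-1/2 for a symmetric sparse M: scaling each
## triplet by s[i] * s[j] keeps the (i,j)/(j,i) values bit-identical.
symScale <- function(M, s) {
  tm <- as(as(M, "generalMatrix"), "TsparseMatrix")
  i <- tm@i + 1L; j <- tm@j + 1L
  Matrix::sparseMatrix(i = i, j = j, x = tm@x * (s[i] * s[j]),
                       dims = dim(M))
}

#' Build the brain graph of a surface mesh
#'
#' Every mesh vertex becomes a graph node; every triangle edge becomes an
#' undirected binary graph edge (duplicate edges collapse).  A self-loop is
#' added to each node and the renormalized propagation operator
#' \eqn{\hat A = \tilde D^{-1/2} \tilde A \tilde D^{-1/2}} with
#' \eqn{\tilde A = A + I} is precomputed; its spectrum lies in
#' \eqn{[-1, 1]}.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @return A \linkS4class{BrainGraph}.
#' @export
buildBrainGraph <- function(mesh) {
  validObject(mesh)
  f <- mesh@faces
  i <- c(f[, 1L], f[, 2L], f[, 1L], f[, 2L], f[, 3L], f[, 3L])
  j <- c(f[, 2L], f[, 1L], f[, 3L], f[, 3L], f[, 1L], f[, 2L])
  n <- nVertices(mesh)
  brainGraphFromEdges(i, j, n)
}

#' Build a brain graph from an explicit edge list or adjacency
#'
#' \code{brainGraphFromEdges} takes parallel endpoint vectors (1-based,
#' duplicates and both orientations allowed); \code{brainGraphFromAdjacency}
#' takes a symmetric 0/1 matrix with zero diagonal.  Useful for oracle tests
#' on random graphs.
#'
#' @param i,j integer endpoint vectors.
#' @param n number of vertices.
#' @return A \linkS4class{BrainGraph}.
#' @export
brainGraphFromEdges <- function(i, j, n) {
  keep <- i != j
  i <- i[keep]; j <- j[keep]
  if (length(i) == 0L) stop("cannot build graph from edgeless mesh")
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1, dims = c(n, n))
  A@x[] <- 1                            # collapse duplicate entries to binary
  A <- Matrix::drop0(A)
  Atilde <- A + Matrix::Diagonal(n)
  deg <- Matrix::rowSums(Atilde)
  Ahat <- symScale(Atilde, 1 / sqrt(deg))
  new("BrainGraph", adjacency = A, selfloopAdjacency = Atilde,
      degrees = as.numeric(deg), normOperator = Ahat)
}

#' @rdname brainGraphFromEdges
#' @param A symmetric binary adjacency matrix (zero diagonal).
#' @export
brainGraphFromAdjacency <- function(A) {
  A <- as(as(Matrix::Matrix(A, sparse = TRUE), "generalMatrix"), "TsparseMatrix")
  brainGraphFromEdges(A@i + 1L, A@j + 1L, nrow(A))
}

#' Renormalized propagation operator
#'
#' Recomputes \eqn{\hat A = \tilde D^{-1/2} \tilde A \tilde D^{-1/2}} from
#' the graph's self-looped adjacency.  Identical to
#' \code{\link{normOperator}}, which returns the cached copy.
#'
#' @param graph a \linkS4class{BrainGraph}.
#' @return sparse symmetric matrix with spectrum in \eqn{[-1, 1]}.
#' @export
normalizeAdjacency <- function(graph) {
  symScale(graph@selfloopAdjacency, 1 / sqrt(graph@degrees))
}

#' Normalized graph Laplacian
#'
#' \eqn{L = I - D^{-1/2} A D^{-1/2}} using the degrees of the *plain*
#' adjacency (no self-loops) — deliberately a different degree convention
#' from the renormalized operator.  A degree-0 vertex (possible in corrupted
#' meshes) contributes an isolated unit diagonal entry and triggers a
#' warning.
#'
#' @param graph a \linkS4class{BrainGraph}.
#' @return sparse symmetric matrix with spectrum in \eqn{[0, 2]}.
#' @export
normalizedLaplacian <- function(graph) {
  A <- graph@adjacency
  d <- Matrix::rowSums(A)
  s <- numeric(length(d))
  if (any(d == 0)) {
    warning("graph has degree-0 vertices; their Laplacian rows reduce to the identity")
    s[d > 0] <- 1 / sqrt(d[d > 0])
  } else s <- 1 / sqrt(d)
  Matrix::Diagonal(nrow(A)) - symScale(A, s)
}

#' Dense eigendecomposition of a normalized Laplacian
#'
#' For oracle-scale graphs only (dense \code{eigen}); refuses matrices with
#' more than \code{maxN} rows.
#'
#' @param L Laplacian matrix (from \code{\link{normalizedLaplacian}}).
#' @param maxN largest size to factor densely.
#' @return A \linkS4class{SpectralDecomposition}.
#' @export
spectralDecompose <- function(L, maxN = 4096L) {
  n <- nrow(L)
  if (n > maxN) stop(sprintf("refusing dense eigendecomposition for n = %d > %d", n, maxN))
  e <- eigen(as.matrix(L), symmetric = TRUE)
  new("SpectralDecomposition", vectors = e$vectors, values = e$values,
      lambdaMax = max(e$values))
}

#' Exact spectral graph filtering
#'
#' Applies a filter defined eigenvalue-wise in the graph Fourier domain:
#' \eqn{U g(\Lambda) U^T x}.  The \eqn{O(N^2)} reference against which the
#' Chebyshev and first-order filters are verified.
#'
#' @param decomp a \linkS4class{SpectralDecomposition}.
#' @param x length-N signal.
#' @param g vectorized function of the eigenvalues.
#' @return filtered length-N signal.
#' @export
exactSpectralFilter <- function(decomp, x, g) {
  if (length(x) != nrow(decomp@vectors)) stop("signal length mismatch")
  U <- decomp@vectors
  as.numeric(U %*% (g(decomp@values) * crossprod(U, x)))
}

#' Chebyshev polynomial graph filter
#'
#' Truncated Chebyshev expansion
#' \eqn{\sum_{k=0}^K \theta'_k T_k(\tilde L) x} with
#' \eqn{\tilde L = (2/\lambda_{max}) L - I}, computed with the standard
#' three-term recurrence \eqn{T_k = 2 x T_{k-1} - T_{k-2}}.  The default
#' \eqn{\lambda_{max} = 2} is the approximation the first-order GCN layer
#' inherits; pass the exact value for oracle comparisons.
#'
#' @param graph a \linkS4class{BrainGraph}.
#' @param x length-N signal.
#' @param theta coefficient vector \eqn{\theta'_0 .. \theta'_K}.
#' @param lambdaMax spectral scale (default 2).
#' @return filtered length-N signal.
#' @export
chebyshevFilter <- function(graph, x, theta, lambdaMax = 2) {
  if (length(theta) < 1L) stop("need at least the order-0 coefficient (K >= 0)")
  if (!all(is.finite(theta))) stop("Chebyshev coefficients must be finite")
  n <- nVertices(graph)
  if (length(x) != n) stop("signal length mismatch")
  L <- normalizedLaplacian(graph)
  Lt <- (2 / lambdaMax) * L - Matrix::Diagonal(n)
  tPrev <- x                            # T_0(Lt) x
  out <- theta[1L] * tPrev
  if (length(theta) > 1L) {
    tCur <- as.numeric(Lt %*% x)        # T_1(Lt) x
    out <- out + theta[2L] * tCur
    for (k in seq_len(length(theta) - 2L)) {
      tNext <- as.numeric(2 * (Lt %*% tCur)) - tPrev
      out <- out + theta[k + 2L] * tNext
      tPrev <- tCur; tCur <- tNext
    }
  }
  as.numeric(out)
}

#' Random connected graph (test/oracle utility)
#'
#' A uniformly ordered random spanning chain plus independent extra edges,
#' so the result is always connected, binary and symmetric; deterministic
#' given \code{seed}.
#'
#' @param n number of vertices.
#' @param p extra-edge probability.
#' @param seed RNG seed.
#' @return A \linkS4class{BrainGraph}.
#' @export
randomConnectedGraph <- function(n, p = 0.2, seed = 1L) {
  withSeed(seed, {
    perm <- sample.int(n)
    i <- perm[-n]; j <- perm[-1L]       # spanning chain
    if (n > 2L) {
      pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      extra <- pairs[stats::runif(nrow(pairs)) < p, , drop = FALSE]
      i <- c(i, extra[, 1L]); j <- c(j, extra[, 2L])
    }
    brainGraphFromEdges(i, j, n)
  })
}
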