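# Fixtures are built in code; nothing binary ships with the package.

# Unit equilateral triangle in the z = 0 plane.
triangleMesh <- function() {
  SurfaceMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0)),
              rbind(c(1L, 2L, 3L)))
}

# Star graph: vertex 1 adjacent to vertices 2..k+1 (edge list, no mesh).
starGraph <- function(k = 4L) {
  brainGraphFromEdges(rep(1L, k), seq_len(k) + 1L, k + 1L)
}

# Chebyshev coefficients matching the monomial polynomial sum(a[j+1] * x^j)
# on [0, lambdaMax]: solve the (K+1)-point collocation system in the
# T_k((2/lambdaMax) x - 1) basis.  Independent of chebyshevFilter's
# recurrence (uses the cos/acos closed form).
chebyCoefFromPoly <- function(a, lambdaMax = 2) {
  K <- length(a) - 1L
  lam <- seq(0, lambdaMax, length.out = K + 1L)
  xs <- pmin(pmax(2 * lam / lambdaMax - 1, -1), 1)
  M <- outer(xs, 0:K, function(x, k) cos(k * acos(x)))
  rhs <- vapply(lam, function(l) sum(a * l^seq(0, K)), 0)
  solve(M, rhs)
}

# Dense evaluation of the polynomial filter matrix sum(a[j+1] * L^j).
densePolyFilter <- function(L, a, x) {
  Ld <- as.matrix(L)
  out <- a[1] * x
  P <- diag(nrow(Ld))
  for (j in seq_len(length(a) - 1L)) {
    P <- P %*% Ld
    out <- out + a[j + 1L] * as.numeric(P %*% x)
  }
  out
}

writeBE <- function(con, ints = NULL, floats = NULL, raws = NULL) {
  if (!is.null(raws)) writeBin(as.raw(raws), con)
  if (!is.null(ints)) writeBin(as.integer(ints), con, size = 4L, endian = "big")
  if (!is.null(floats)) writeBin(as.numeric(floats), con, size = 4L, endian = "big")
}
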