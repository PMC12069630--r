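## Synthetic stand-ins for the real inputs: subdivided-icosahedron meshes,
## graph-Voronoi parcellations and 6-channel per-vertex feature matrices
## with parcel-level signal plus spatially smoothed noise.  Everything is
## deterministic given the spec seed.

#' Synthetic benchmark specification
#'
#' @param level icosphere subdivision order (level 5 matches the 10,242
#'   vertices of a standard fsaverage5 hemisphere).
#' @param nParcels number of graph-Voronoi parcels.
#' @param nChannels feature channels (6, matching the morphological set).
#' @param signalStrength separation of per-parcel channel means, in units
#'   of the noise standard deviation.
#' @param noiseSd per-vertex noise scale before smoothing.
#' @param smoothingSteps row-stochastic neighbourhood-averaging passes
#'   applied to the noise (spatial correlation, as real curvature and depth
#'   maps have).
#' @param subjectJitter cross-subject variability: parcel seed vertices
#'   take a random walk with this expected hop count, and parcel means are
#'   perturbed with sd \code{0.1 * subjectJitter}.
#' @param seed master seed of the generator.
#' @return list, class \code{"synthetic_spec"}.
#' @export
syntheticSpec <- function(level = 4L, nParcels = 8L, nChannels = 6L,
                          signalStrength = 3, noiseSd = 1,
                          smoothingSteps = 2L, subjectJitter = 1,
                          seed = 1L) {
  if (level < 0L) stop("level must be >= 0")
  if (nParcels < 1L) stop("need at least one parcel")
  if (any(c(signalStrength, noiseSd, smoothingSteps, subjectJitter) < 0))
    stop("scales must be >= 0")
  structure(list(level = as.integer(level), nParcels = as.integer(nParcels),
                 nChannels = as.integer(nChannels),
                 signalStrength = signalStrength, noiseSd = noiseSd,
                 smoothingSteps = as.integer(smoothingSteps),
                 subjectJitter = subjectJitter, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a unit icosphere mesh
#'
#' Regular icosahedron subdivided \code{level} times: each triangle splits
#' into 4, edge midpoints are deduplicated by exact index-pair keys and
#' projected to the unit sphere.  Vertex count is \eqn{10 \cdot 4^L + 2},
#' face count \eqn{20 \cdot 4^L}; level 5 gives the 10,242 vertices of a
#' standard template hemisphere.  Deterministic.
#'
#' @param level subdivision order \eqn{L \ge 0}.
#' @return A \linkS4class{SurfaceMesh} on the unit sphere.
#' @export
generateIcosphere <- function(level = 0L) {
  if (level < 0L) stop("level must be >= 0")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v * v))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(level)) {
    nv <- nrow(v)
    midKey <- new.env(hash = TRUE, size = 4L * nrow(f))
    verts <- vector("list", 3L * nrow(f))
    nNew <- 0L
    midpoint <- function(a, b) {
      key <- if (a < b) paste0(a, "_", b) else paste0(b, "_", a)
      idx <- midKey[[key]]
      if (!is.null(idx)) return(idx)
      nNew <<- nNew + 1L
      m <- v[a, ] + v[b, ]
      verts[[nNew]] <<- m / sqrt(sum(m * m))
      idx <- nv + nNew
      midKey[[key]] <- idx
      idx
    }
    newF <- matrix(0L, 4L * nrow(f), 3L)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1L]; b <- f[t, 2L]; c <- f[t, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newF[4L * t - 3L, ] <- c(a, ab, ca)
      newF[4L * t - 2L, ] <- c(b, bc, ab)
      newF[4L * t - 1L, ] <- c(c, ca, bc)
      newF[4L * t, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, verts[seq_len(nNew)]))
    f <- newF
  }
  SurfaceMesh(v, f)
}

## Multi-source breadth-first search: labels every vertex with the index of
## its hop-nearest seed, ties to the lowest seed index.  Exact, because the
## per-round minimum over frontier neighbours propagates the lexicographic
## (distance, seed index) minimum.
geodesicVoronoi <- function(graph, seeds) {
  A <- as(as(graph@adjacency, "generalMatrix"), "TsparseMatrix")
  ei <- A@i + 1L; ej <- A@j + 1L
  n <- nVertices(graph)
  lab <- rep(NA_integer_, n)
  lab[seeds] <- seq_along(seeds) - 1L
  ## a vertex sampled as two seeds cannot happen (sampling w/o replacement)
  frontier <- seeds
  while (length(frontier)) {
    inF <- logical(n); inF[frontier] <- TRUE
    sel <- inF[ei] & is.na(lab[ej])
    if (!any(sel)) break
    src <- ei[sel]; dst <- ej[sel]
    ord <- order(lab[src])
    dst <- dst[ord]; src <- src[ord]
    first <- !duplicated(dst)
    lab[dst[first]] <- lab[src[first]]
    frontier <- dst[first]
  }
  lab
}

#' Graph-Voronoi parcellation of a mesh
#'
#' Seed vertices are sampled without replacement (seeded); every vertex is
#' labeled by its hop-distance-nearest seed under breadth-first search on
#' the mesh graph, ties broken toward the lowest seed index.  Every parcel
#' is nonempty and connected.
#'
#' @param mesh a \linkS4class{SurfaceMesh} (or a \linkS4class{BrainGraph}).
#' @param nParcels number of parcels (\eqn{\le} vertex count).
#' @param seed RNG seed for seed-vertex sampling.
#' @return integer vector of 0-based parcel labels.
#' @export
generateParcellation <- function(mesh, nParcels, seed = 1L) {
  graph <- if (is(mesh, "BrainGraph")) mesh else buildBrainGraph(mesh)
  n <- nVertices(graph)
  if (nParcels > n) stop("more parcels than vertices")
  seeds <- withSeed(seed, sample.int(n, nParcels))
  geodesicVoronoi(graph, seeds)
}

## Row-stochastic neighbourhood averaging D^-1 (A + I): conserves the
## all-vertex mean of each channel, unlike the symmetric operator.
smoothingOperator <- function(graph) {
  Matrix::Diagonal(x = 1 / graph@degrees) %*% graph@selfloopAdjacency
}

#' Synthetic per-vertex features
#'
#' \eqn{X_{ic} = \mu_{label(i), c} + \epsilon_{ic}}: per-parcel channel
#' means drawn as \code{signalStrength} times standard normals (or supplied
#' as a template for cohort generation), plus noise of sd \code{noiseSd}
#' smoothed by \code{smoothingSteps} passes of row-stochastic
#' neighbourhood averaging.
#'
#' @param graph a \linkS4class{BrainGraph}.
#' @param labels 0-based parcel labels.
#' @param spec a \code{\link{syntheticSpec}}.
#' @param seed RNG seed (defaults to \code{spec$seed}).
#' @param mu optional \code{nParcels x nChannels} template mean matrix.
#' @return \code{N x nChannels} feature matrix.
#' @export
generateFeatures <- function(graph, labels, spec, seed = spec$seed, mu = NULL) {
  k <- max(labels) + 1L
  withSeed(seed, {
    if (is.null(mu))
      mu <- matrix(stats::rnorm(k * spec$nChannels), k) * spec$signalStrength
    eps <- matrix(stats::rnorm(nVertices(graph) * spec$nChannels), ncol = spec$nChannels) *
      spec$noiseSd
    if (spec$smoothingSteps > 0L) {
      P <- smoothingOperator(graph)
      for (s in seq_len(spec$smoothingSteps)) eps <- as.matrix(P %*% eps)
    }
    mu[labels + 1L, , drop = FALSE] + eps
  })
}

#' Per-vertex surface area
#'
#' One third of the summed areas of the triangles incident to each vertex;
#' the per-vertex areas sum exactly to the total mesh surface area.
#' Degenerate zero-area faces contribute nothing.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @return numeric length-N vector of areas.
#' @export
vertexArea <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
  cy <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
  cz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  fa <- 0.5 * sqrt(cx * cx + cy * cy + cz * cz)
  out <- numeric(nVertices(mesh))
  acc <- rowsum(rep(fa / 3, 3L), group = c(f[, 1L], f[, 2L], f[, 3L]))
  out[as.integer(rownames(acc))] <- acc[, 1L]
  out
}

## One random-walk jitter of seed vertices (expected steps = jitter).
jitterSeeds <- function(graph, seeds, jitter) {
  if (jitter <= 0) return(seeds)
  A <- graph@adjacency
  steps <- stats::rpois(length(seeds), jitter)
  for (i in seq_along(seeds)) {
    s <- seeds[i]
    if (steps[i] > 0L) for (k in seq_len(steps[i])) {
      nb <- which(A[s, ] > 0)
      s <- nb[sample.int(length(nb), 1L)]
    }
    seeds[i] <- s
  }
  ## collisions would merge parcels; nudge duplicates to a free neighbour
  while (anyDuplicated(seeds)) {
    d <- which(duplicated(seeds))[1L]
    nb <- setdiff(which(A[seeds[d], ] > 0), seeds)
    if (length(nb) == 0L) nb <- setdiff(seq_len(nVertices(graph)), seeds)
    seeds[d] <- nb[sample.int(length(nb), 1L)]
  }
  seeds
}

#' Generate a synthetic cohort
#'
#' All subjects share one template mesh, template parcel seeds and template
#' parcel means (drawn from \code{spec$seed}); each subject perturbs the
#' seeds by a random walk and the means by noise of sd
#' \code{0.1 * subjectJitter} (seeded per subject), then regenerates its
#' features.  Labels are the subject's own jittered Voronoi assignment.
#'
#' @param nSubjects cohort size.
#' @param spec a \code{\link{syntheticSpec}}.
#' @return list of \linkS4class{CortexSubject}.
#' @export
makeDataset <- function(nSubjects, spec = syntheticSpec()) {
  if (nSubjects < 1L) stop("need at least one subject")
  mesh <- generateIcosphere(spec$level)
  graph <- buildBrainGraph(mesh)
  n <- nVertices(graph)
  tmpl <- withSeed(spec$seed, list(
    seeds = sample.int(n, spec$nParcels),
    mu = matrix(stats::rnorm(spec$nParcels * spec$nChannels),
                spec$nParcels) * spec$signalStrength))
  lapply(seq_len(nSubjects), function(si) {
    sSeed <- subSeed(spec$seed, 1000 + si)
    dat <- withSeed(sSeed, {
      seeds <- jitterSeeds(graph, tmpl$seeds, spec$subjectJitter)
      mu <- tmpl$mu + matrix(stats::rnorm(length(tmpl$mu)),
                             nrow(tmpl$mu)) * 0.1 * spec$subjectJitter
      list(seeds = seeds, mu = mu)
    })
    labels <- geodesicVoronoi(graph, dat$seeds)
    X <- generateFeatures(graph, labels, spec, seed = subSeed(sSeed, 7),
                          mu = dat$mu)
    new("CortexSubject", id = sprintf("sub-%03d", si), mesh = mesh,
        graph = graph, features = X, labels = labels)
  })
}
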