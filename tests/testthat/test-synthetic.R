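test_that("icosphere subdivision obeys the vertex/face count law", {
  for (L in 0:5) {
    mesh <- generateIcosphere(L)
    expect_identical(nVertices(mesh), as.integer(10 * 4^L + 2))
    expect_identical(nFaces(mesh), as.integer(20 * 4^L))
    # closed genus-0 surface: V - E + F = 2
    f <- meshFaces(mesh)
    e <- unique(rbind(cbind(pmin(f[, 1], f[, 2]), pmax(f[, 1], f[, 2])),
                      cbind(pmin(f[, 2], f[, 3]), pmax(f[, 2], f[, 3])),
                      cbind(pmin(f[, 1], f[, 3]), pmax(f[, 1], f[, 3]))))
    expect_identical(nVertices(mesh) - nrow(e) + nFaces(mesh), 2L)
  }
  v <- meshVertices(generateIcosphere(3))
  expect_lt(max(abs(sqrt(rowSums(v^2)) - 1)), 1e-12)
  expect_identical(generateIcosphere(2), generateIcosphere(2))
})

test_that("graph-Voronoi parcels are nonempty, connected and exhaustive", {
  mesh <- generateIcosphere(3)
  graph <- buildBrainGraph(mesh)
  lab <- generateParcellation(graph, 7L, seed = 13)
  expect_identical(sort(unique(lab)), 0:6)
  A <- adjacencyMatrix(graph)
  for (c in 0:6) {
    inC <- which(lab == c)
    # breadth-first flood inside the parcel reaches every member
    reached <- logical(length(inC))
    names(reached) <- inC
    frontier <- inC[1]
    reached[as.character(frontier)] <- TRUE
    while (length(frontier)) {
      nb <- unique(unlist(lapply(frontier, function(v) which(A[v, ] > 0))))
      nb <- intersect(nb, inC)
      new <- nb[!reached[as.character(nb)]]
      reached[as.character(new)] <- TRUE
      frontier <- new
    }
    expect_true(all(reached))
  }
  # degenerate ends of the parcel-count range
  expect_identical(unique(generateParcellation(graph, 1L)), 0L)
  g0 <- buildBrainGraph(generateIcosphere(0))
  labN <- generateParcellation(g0, 12L, seed = 1)
  expect_identical(sort(labN), 0:11)    # each vertex its own seed
  expect_error(generateParcellation(g0, 13L), "more parcels than vertices")
})

test_that("features are piecewise-constant without noise and smoothing conserves means", {
  mesh <- generateIcosphere(2)
  graph <- buildBrainGraph(mesh)
  lab <- generateParcellation(graph, 4L, seed = 3)
  spec <- syntheticSpec(level = 2L, nParcels = 4L, noiseSd = 0, seed = 3L)
  X <- generateFeatures(graph, lab, spec)
  for (c in 0:3) {
    rowsC <- X[lab == c, , drop = FALSE]
    expect_equal(rowsC, rowsC[rep(1, nrow(rowsC)), ], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # the row-stochastic averaging operator is a convex combination per row
  # and conserves the degree-weighted channel mean exactly
  P <- cortexgcn:::smoothingOperator(graph)
  expect_equal(as.numeric(Matrix::rowSums(P)), rep(1, nVertices(graph)))
  set.seed(9); z <- rnorm(nVertices(graph))
  d <- graphDegrees(graph)
  sm <- as.numeric(P %*% z)
  expect_equal(sum(d * sm) / sum(d), sum(d * z) / sum(d), tolerance = 1e-12)
  # on a degree-regular mesh the plain all-vertex mean is conserved too
  g0 <- buildBrainGraph(generateIcosphere(0))
  P0 <- cortexgcn:::smoothingOperator(g0)
  z0 <- rnorm(12)
  expect_equal(mean(as.numeric(P0 %*% z0)), mean(z0), tolerance = 1e-12)
})

test_that("zero signal strength leaves parcel means indistinguishable", {
  mesh <- generateIcosphere(3)
  graph <- buildBrainGraph(mesh)
  lab <- generateParcellation(graph, 3L, seed = 21)
  spec <- syntheticSpec(level = 3L, nParcels = 3L, signalStrength = 0,
                        noiseSd = 1, smoothingSteps = 0L, seed = 21L)
  X <- generateFeatures(graph, lab, spec)
  big <- order(tabulate(lab + 1L), decreasing = TRUE)[1:2] - 1L
  p <- t.test(X[lab == big[1], 1], X[lab == big[2], 1])$p.value
  expect_gt(p, 0.01)
})

test_that("per-vertex areas are exact on a triangle and converge on the sphere", {
  va <- vertexArea(triangleMesh())
  expect_equal(va, rep(sqrt(3) / 12, 3), tolerance = 1e-12)
  mesh <- generateIcosphere(4)
  va4 <- vertexArea(mesh)
  # conservation: vertex areas sum to the summed face areas
  f <- meshFaces(mesh); v <- meshVertices(mesh)
  e1 <- v[f[, 2], ] - v[f[, 1], ]; e2 <- v[f[, 3], ] - v[f[, 1], ]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  faceTotal <- sum(0.5 * sqrt(rowSums(cr^2)))
  expect_equal(sum(va4), faceTotal, tolerance = 1e-12)
  # unit-sphere area within 1%
  expect_lt(abs(sum(va4) - 4 * pi) / (4 * pi), 0.01)
})

test_that("cohorts are deterministic and jitter drives subject variability", {
  spec <- syntheticSpec(level = 1L, nParcels = 3L, seed = 17L)
  d1 <- makeDataset(3, spec)
  d2 <- makeDataset(3, spec)
  expect_identical(d1, d2)
  labs <- vapply(d1, function(s) s@labels, integer(42))
  expect_true(any(labs[, 1] != labs[, 2]) || any(labs[, 1] != labs[, 3]))
  # no jitter, no noise: all subjects identical
  spec0 <- syntheticSpec(level = 1L, nParcels = 3L, noiseSd = 0,
                         subjectJitter = 0, seed = 17L)
  d0 <- makeDataset(3, spec0)
  expect_identical(d0[[1]]@labels, d0[[2]]@labels)
  expect_identical(d0[[1]]@features, d0[[3]]@features)
})

test_that("held-out Dice is non-decreasing in signal strength", {
  # desk-scale learnability gradient: same seeds, signal 0 / 1 / 3; one
  # inversion of at most 0.02 tolerated (stochastic)
  dice <- vapply(c(0, 1, 3), function(ss) {
    spec <- syntheticSpec(level = 2L, nParcels = 5L, signalStrength = ss,
                          noiseSd = 1, smoothingSteps = 2L, seed = 19L)
    subjects <- makeDataset(4, spec)
    cfg <- adgcnConfig(inChannels = 6L, hiddenWidths = c(16L, 16L),
                       nClasses = 5L, seRatio = 4L)
    model <- trainModel(subjects[1:3], cfg, trainConfig(epochs = 60L, seed = 19L))
    evaluateModel(model, subjects[4])$meanDice
  }, 0)
  expect_true(all(diff(dice) > -0.02))
  expect_gt(dice[3], dice[1])
})
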