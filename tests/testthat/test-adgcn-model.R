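test_that("initialization is seed-deterministic and validates its config", {
  cfg <- adgcnPreset("adgcn", nClasses = 8L)
  m1 <- initParams(cfg, seed = 33)
  m2 <- initParams(cfg, seed = 33)
  expect_identical(m1$params, m2$params)
  m3 <- initParams(cfg, seed = 34)
  expect_false(identical(m1$params, m3$params))
  expect_error(adgcnConfig(hiddenWidths = c(16, 32, 16), seRatio = 5),
               "seRatio")
  expect_error(adgcnConfig(hiddenWidths = c(16, 32), longSkips = TRUE),
               "palindromic")
  expect_error(adgcnConfig(dropout = 1), "dropout")
})

test_that("parameter count equals the closed-form sum over declared shapes", {
  cfg <- adgcnPreset("adgcn", nClasses = 31L, inChannels = 6L)
  model <- initParams(cfg)
  w <- c(6L, cfg$hiddenWidths)
  expected <- 0L
  for (l in seq_along(cfg$hiddenWidths)) {
    expected <- expected + w[l] * w[l + 1L]          # W
    if (w[l] != w[l + 1L]) expected <- expected + w[l] * w[l + 1L]  # proj
    expected <- expected + 2L * w[l + 1L]            # gamma, beta
  }
  c0 <- cfg$hiddenWidths[cfg$sePosition]
  expected <- expected + 2L * c0 * (c0 %/% cfg$seRatio)   # SE pair
  expected <- expected + tail(cfg$hiddenWidths, 1) * 31L  # output head
  expect_identical(countParams(model), as.integer(expected))
})

test_that("a GCN layer reproduces analytic compositions", {
  # identity operator, identity weights, BN off, residual on, nonnegative
  # input: pre-activation is H + H and ReLU keeps 2H
  H <- matrix(abs(rnorm(12)), 4)
  lay <- list(W = diag(3))
  out <- gcnLayerForward(Matrix::Diagonal(4), H, lay, batchNorm = FALSE,
                         residual = TRUE)
  expect_equal(out, 2 * H)
  # two-vertex graph: Ahat is all 1/2, plain aggregation averages
  g <- brainGraphFromEdges(1L, 2L, 2L)
  out2 <- gcnLayerForward(normOperator(g), matrix(c(2, 0), 2), list(W = matrix(1)),
                          batchNorm = FALSE, residual = FALSE)
  expect_equal(out2, matrix(c(1, 1), 2))
  expect_error(gcnLayerForward(normOperator(g), matrix(1, 3, 1), list(W = matrix(1))),
               "match graph size")
})

test_that("squeeze-and-excitation obeys its closed forms and bounds", {
  set.seed(5)
  H <- matrix(rnorm(80), 5)             # C = 16
  W1 <- matrix(0, 4, 16); W2 <- matrix(0, 16, 4)
  # zero weights: every gate is sigmoid(0) = 1/2, output exactly H/2
  expect_equal(seForward(H, W1, W2)$out, H / 2)
  # constant channels squeeze to the constant
  Hc <- matrix(rep(seq_len(16), each = 5), 5)
  expect_equal(seForward(Hc, W1, W2)$z, as.numeric(seq_len(16)))
  # generic weights: strict (0,1) gates, elementwise attenuation
  W1 <- matrix(rnorm(64), 4, 16); W2 <- matrix(rnorm(64), 16, 4)
  se <- seForward(H, W1, W2)
  expect_identical(dim(W1), c(4L, 16L))  # C/r x C with r = 4, C = 16
  expect_identical(dim(W2), c(16L, 4L))
  expect_true(all(se$s > 0 & se$s < 1))
  expect_true(all(abs(se$out) <= abs(H)))
  expect_error(seForward(H, W1[, -1], W2), "shapes")
})

test_that("the forward pass is row-stochastic for random inputs", {
  g <- buildBrainGraph(generateIcosphere(1))
  cfg <- adgcnPreset("adgcn", nClasses = 5L, inChannels = 6L)
  model <- initParams(cfg, seed = 2)
  set.seed(2); X <- matrix(rnorm(42 * 6), 42)
  Z <- modelForward(g, X, model)
  expect_true(all(Z > 0 & Z < 1))
  expect_lt(max(abs(rowSums(Z) - 1)), 1e-6)
})

test_that("the forward pass is vertex-permutation equivariant", {
  n <- 30L
  g <- randomConnectedGraph(n, p = 0.2, seed = 12)
  cfg <- adgcnPreset("adgcn", nClasses = 4L, inChannels = 6L)
  model <- initParams(cfg, seed = 3)
  set.seed(3); X <- matrix(rnorm(n * 6), n)
  perm <- sample(n)
  gP <- brainGraphFromAdjacency(adjacencyMatrix(g)[perm, perm])
  Z <- modelForward(g, X, model)
  ZP <- modelForward(gP, X[perm, ], model)
  expect_equal(ZP, Z[perm, ], tolerance = 1e-10)
})

test_that("the two-layer degenerate model equals the literal closed form", {
  # SE off, dropout 0, BN off, residual off: softmax(Ahat relu(Ahat X W0) W1)
  n <- 20L
  g <- randomConnectedGraph(n, p = 0.3, seed = 6)
  cfg <- adgcnConfig(inChannels = 3L, hiddenWidths = 16L, nClasses = 4L,
                     seEnabled = FALSE, dropout = 0, longSkips = FALSE,
                     batchNorm = FALSE, residual = FALSE)
  model <- initParams(cfg, seed = 10)
  set.seed(10); X <- matrix(rnorm(n * 3), n)
  Z <- modelForward(g, X, model, training = TRUE)
  Ahat <- as.matrix(normOperator(g))
  hidden <- pmax(Ahat %*% X %*% model$params$layers[[1]]$W, 0)
  logits <- Ahat %*% hidden %*% model$params$out$W
  ref <- exp(logits) / rowSums(exp(logits))
  expect_equal(Z, ref, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("hard labels take the argmax with low-index tie-breaks", {
  Z <- rbind(c(1, 0, 0), c(0, 0, 1), c(0.5, 0.5, 0), c(1 / 3, 1 / 3, 1 / 3))
  expect_identical(predictLabels(Z), c(0L, 2L, 0L, 0L))
  expect_error(predictLabels(rbind(c(0.9, 0.3))), "not a probability matrix")
})

test_that("reverse-mode gradients agree with finite differences", {
  g <- randomConnectedGraph(12L, p = 0.4, seed = 5)
  cfg <- adgcnConfig(inChannels = 3L, hiddenWidths = c(8L, 16L, 8L),
                     nClasses = 4L, seRatio = 4L, dropout = 0, seed = 7)
  model <- initParams(cfg)
  set.seed(42)
  X <- matrix(rnorm(36), 12)
  y <- sample(0:3, 12, replace = TRUE)
  y[1] <- -1L                           # one ignored vertex
  lg <- cortexgcn:::lossAndGradient(g, X, model, y, lambda = 1e-3,
                                    training = TRUE)
  fl <- lg$flat
  h <- 1e-5
  idx <- sort(sample(length(fl$vec), 80))
  lossAt <- function(vec) {
    m <- model
    m$params <- cortexgcn:::unflattenParams(vec, fl$skeleton, model$params)
    cortexgcn:::lossAndGradient(g, X, m, y, lambda = 1e-3, training = TRUE)$loss
  }
  for (i in idx) {
    vp <- fl$vec; vp[i] <- vp[i] + h
    vm <- fl$vec; vm[i] <- vm[i] - h
    num <- (lossAt(vp) - lossAt(vm)) / (2 * h)
    expect_equal(lg$grad[i], num, tolerance = 1e-4)
  }
})
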