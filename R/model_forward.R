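## Forward pass of the network.  One graph is one batch: batch normalization
## statistics are taken per channel over the N nodes, the only well-defined
## reading at batch size 1.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

rowRep <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

#' Squeeze-and-excitation block on graph features
#'
#' Squeeze: global average pool per channel, \eqn{z_c = (1/N) \sum_i H_{ic}};
#' excitation: \eqn{s = sigmoid(W_2\,ReLU(W_1 z))} through a bottleneck of
#' ratio r (no bias terms); scale: channel c of the output is
#' \eqn{s_c H_{\cdot c}}.  Every gate lies strictly in (0, 1), so the block
#' can only attenuate channels.
#'
#' @param H \code{N x C} feature matrix.
#' @param W1 \code{C/r x C} reduction weights.
#' @param W2 \code{C x C/r} restoration weights.
#' @return list with \code{out} (\code{N x C}), the gates \code{s}, and the
#'   squeeze vector \code{z}.
#' @export
seForward <- function(H, W1, W2) {
  C <- ncol(H)
  if (ncol(W1) != C || nrow(W2) != C || nrow(W1) != ncol(W2))
    stop("SE weight shapes inconsistent with the channel count")
  z <- colMeans(H)
  u1 <- as.numeric(W1 %*% z)
  a <- relu(u1)
  s <- sigmoid(as.numeric(W2 %*% a))
  list(out = H * rowRep(s, nrow(H)), s = s, z = z, a = a, u1 = u1)
}

## One GCN layer: aggregate -> linear -> batch-norm -> + residual -> ReLU.
## Returns activations plus everything the backward pass needs.
layerForwardCore <- function(Ahat, Hin, lay, training, running,
                             batchNorm, residual, mask = NULL) {
  Hd <- if (is.null(mask)) Hin else Hin * mask
  agg <- as.matrix(Ahat %*% Hd)
  lin <- agg %*% lay$W
  n <- nrow(lin)
  if (batchNorm) {
    if (training) {
      mu <- colMeans(lin)
      v <- colMeans(lin * lin) - mu * mu
      v[v < 0] <- 0
      newRun <- list(
        mean = (1 - BN_MOMENTUM) * running$mean + BN_MOMENTUM * mu,
        var = (1 - BN_MOMENTUM) * running$var +
          BN_MOMENTUM * v * n / max(n - 1L, 1L))
    } else {
      mu <- running$mean; v <- running$var; newRun <- running
    }
    xhat <- (lin - rowRep(mu, n)) * rowRep(1 / sqrt(v + BN_EPS), n)
    y <- xhat * rowRep(lay$gamma, n) + rowRep(lay$beta, n)
  } else {
    xhat <- NULL; v <- NULL; y <- lin; newRun <- NULL
  }
  pre <- y
  if (residual) pre <- pre + (if (is.null(lay$proj)) Hin else Hin %*% lay$proj)
  list(out = relu(pre), Hin = Hin, mask = mask, agg = agg, xhat = xhat,
       var = v, pre = pre, running = newRun)
}

#' Single GCN layer forward (renormalized first-order propagation)
#'
#' \eqn{H^{(l+1)} = \sigma(BN(\hat A H^{(l)} W^{(l)}) + R(H^{(l)}))} where
#' R is the identity when the widths match, a learned projection otherwise,
#' and BN uses node statistics in training mode, running statistics in
#' inference mode.
#'
#' @param Ahat renormalized operator (from \code{\link{normOperator}}).
#' @param H \code{N x C_in} input features.
#' @param layer list with \code{W} and optionally \code{gamma}, \code{beta},
#'   \code{proj}.
#' @param training logical; batch statistics vs. running statistics.
#' @param running list(mean, var) of running statistics (batch-norm only).
#' @param batchNorm,residual enable the corresponding sub-blocks.
#' @return \code{N x C_out} activation matrix.
#' @export
gcnLayerForward <- function(Ahat, H, layer, training = TRUE, running = NULL,
                            batchNorm = !is.null(layer$gamma),
                            residual = FALSE) {
  if (nrow(H) != nrow(Ahat)) stop("feature rows must match graph size")
  if (batchNorm && is.null(running))
    running <- list(mean = rep(0, ncol(layer$W)), var = rep(1, ncol(layer$W)))
  layerForwardCore(Ahat, H, layer, training, running, batchNorm, residual)$out
}

## Mirror-layer source feeding the input of layer l (l in 2..Lh+1), or NA.
skipSource <- function(l, widths, longSkips) {
  if (!longSkips) return(NA_integer_)
  m <- (length(widths) + 1L) - (l - 1L)
  if (m >= 1L && m < l - 1L && widths[m] == widths[l - 1L]) m else NA_integer_
}

## Full forward pass with cache.  `training` enables dropout (fresh masks
## from the current RNG stream) and batch statistics.
forwardPass <- function(graph, X, model, training = FALSE) {
  cfg <- model$config; params <- model$params
  Ahat <- graph@normOperator
  n <- nrow(X)
  if (ncol(X) != cfg$inChannels) stop("input channel count mismatch")
  if (n != nrow(Ahat)) stop("feature rows must match graph size")
  w <- cfg$hiddenWidths; Lh <- length(w)
  p <- if (training) cfg$dropout else 0
  makeMask <- function(d) {
    if (p <= 0) NULL
    else matrix((stats::runif(n * d) >= p) / (1 - p), n, d)
  }
  outs <- vector("list", Lh)
  caches <- vector("list", Lh)
  bnNew <- model$bn
  seCache <- NULL
  inp <- X
  for (l in seq_len(Lh)) {
    if (l > 1L) {
      inp <- outs[[l - 1L]]
      m <- skipSource(l, w, cfg$longSkips)
      if (!is.na(m)) inp <- inp + outs[[m]]
    }
    lc <- layerForwardCore(Ahat, inp, params$layers[[l]], training,
                           if (cfg$batchNorm) model$bn[[l]] else NULL,
                           cfg$batchNorm, cfg$residual, makeMask(ncol(inp)))
    if (cfg$batchNorm && training) bnNew[[l]] <- lc$running
    out <- lc$out
    if (cfg$seEnabled && l == cfg$sePosition) {
      seCache <- seForward(out, params$se$W1, params$se$W2)
      seCache$H <- out
      out <- seCache$out
    }
    outs[[l]] <- out
    caches[[l]] <- lc
  }
  headIn <- outs[[Lh]]
  mHead <- skipSource(Lh + 1L, w, cfg$longSkips)
  if (!is.na(mHead)) headIn <- headIn + outs[[mHead]]
  maskH <- makeMask(ncol(headIn))
  Hd <- if (is.null(maskH)) headIn else headIn * maskH
  aggH <- as.matrix(Ahat %*% Hd)
  logits <- aggH %*% params$out$W
  Z <- rowSoftmax(logits)
  list(Z = Z, outs = outs, caches = caches, se = seCache,
       head = list(inp = headIn, mask = maskH, agg = aggH, skip = mHead),
       bnNew = bnNew)
}

#' Full network forward pass
#'
#' Dropout, the GCN stack with SE attention and long skips, and the softmax
#' graph-convolution output head.  Every row of the returned matrix is a
#' probability distribution over the K classes.
#'
#' @param graph a \linkS4class{BrainGraph}.
#' @param X \code{N x C} feature matrix (standardized).
#' @param model an \code{"adgcn_model"} from \code{\link{initParams}} or
#'   \code{\link{trainModel}}.
#' @param training logical: dropout + batch statistics (TRUE) vs. the
#'   deterministic inference path (FALSE).
#' @return \code{N x K} class-probability matrix.
#' @export
modelForward <- function(graph, X, model, training = FALSE) {
  forwardPass(graph, X, model, training)$Z
}

#' Hard labels from a class-probability matrix
#'
#' Row-wise argmax with ties broken toward the lowest class index; input is
#' checked to be row-stochastic.
#'
#' @param Z \code{N x K} probability matrix.
#' @param tol tolerance on the row sums.
#' @return integer vector of 0-based class labels.
#' @export
predictLabels <- function(Z, tol = 1e-6) {
  if (any(!is.finite(Z)) || any(Z < -tol) || any(abs(rowSums(Z) - 1) > tol))
    stop("not a probability matrix")
  max.col(Z, ties.method = "first") - 1L
}
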