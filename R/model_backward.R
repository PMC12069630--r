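## Hand-derived reverse-mode gradients for the full network.  The layout of
## the returned gradient object mirrors `model$params` exactly so it can be
## flattened with the same skeleton; verified against central finite
## differences in the test suite.

## Cross-entropy over labeled vertices (ignore sentinel excluded).
crossEntropy <- function(Z, labels, ignoreIndex = -1L) {
  lab <- which(labels != ignoreIndex)
  if (length(lab) == 0L) stop("no labeled vertices")
  if (any(labels[lab] < 0L) || any(labels[lab] >= ncol(Z)))
    stop("label out of range")
  -mean(log(pmax(Z[cbind(lab, labels[lab] + 1L)], 1e-12)))
}

#' Composite training loss
#'
#' Mean cross-entropy of the predicted class probabilities over non-ignored
#' vertices, plus an L2 penalty \eqn{\lambda \sum \|W\|^2} over all weight
#' matrices (batch-norm affine parameters excluded).
#'
#' @param Z \code{N x K} probability matrix.
#' @param labels integer labels (0-based, ignore sentinel allowed).
#' @param model optional \code{"adgcn_model"} supplying the weights for the
#'   penalty; with \code{model = NULL} or \code{lambda = 0} the loss is the
#'   pure cross-entropy.
#' @param lambda L2 coefficient.
#' @param ignoreIndex unlabeled sentinel.
#' @return scalar loss.
#' @export
compositeLoss <- function(Z, labels, model = NULL, lambda = 0,
                          ignoreIndex = -1L) {
  ce <- crossEntropy(Z, labels, ignoreIndex)
  if (lambda > 0 && !is.null(model)) {
    fl <- flattenParams(model$params)
    ce <- ce + lambda * sum(fl$vec[fl$isWeight]^2)
  }
  ce
}

## Backward through batch normalization (training mode, biased variance).
bnBackward <- function(g, xhat, v, gamma) {
  n <- nrow(g)
  dGamma <- colSums(g * xhat)
  dBeta <- colSums(g)
  dXhat <- g * rowRep(gamma, n)
  invStd <- 1 / sqrt(v + BN_EPS)
  dLin <- rowRep(invStd, n) *
    (dXhat - rowRep(colMeans(dXhat), n) - xhat * rowRep(colMeans(dXhat * xhat), n))
  list(dLin = dLin, dGamma = dGamma, dBeta = dBeta)
}

## Gradient of the cross-entropy (no L2) w.r.t. every trainable parameter.
backwardPass <- function(graph, fw, model, labels, ignoreIndex = -1L) {
  cfg <- model$config; params <- model$params
  Ahat <- graph@normOperator
  Z <- fw$Z; n <- nrow(Z)
  lab <- which(labels != ignoreIndex)
  if (length(lab) == 0L) stop("no labeled vertices")
  dLogits <- Z
  dLogits[cbind(lab, labels[lab] + 1L)] <-
    dLogits[cbind(lab, labels[lab] + 1L)] - 1
  unlab <- setdiff(seq_len(n), lab)
  if (length(unlab)) dLogits[unlab, ] <- 0
  dLogits <- dLogits / length(lab)

  w <- cfg$hiddenWidths; Lh <- length(w)
  grads <- list(layers = vector("list", Lh), out = list(), se = NULL)

  ## output head: logits = (Ahat %*% drop(headIn)) %*% Wout
  hd <- fw$head
  grads$out$W <- crossprod(hd$agg, dLogits)
  dAgg <- dLogits %*% t(params$out$W)
  dHd <- as.matrix(Ahat %*% dAgg)
  dInp <- if (is.null(hd$mask)) dHd else dHd * hd$mask
  dOut <- vector("list", Lh)
  dOut[[Lh]] <- dInp
  if (!is.na(hd$skip))
    dOut[[hd$skip]] <- dInp

  addGrad <- function(cur, inc) if (is.null(cur)) inc else cur + inc

  for (l in rev(seq_len(Lh))) {
    g <- dOut[[l]]
    if (cfg$seEnabled && l == cfg$sePosition) {
      se <- fw$se
      H <- se$H; s <- se$s
      dH <- g * rowRep(s, n)
      ds <- colSums(g * H)
      du2 <- ds * s * (1 - s)
      grads$se <- list()
      grads$se$W2 <- du2 %o% se$a
      da <- as.numeric(crossprod(params$se$W2, du2))
      du1 <- da * (se$u1 > 0)
      grads$se$W1 <- du1 %o% se$z
      dz <- as.numeric(crossprod(params$se$W1, du1))
      g <- dH + rowRep(dz / n, n)
    }
    lc <- fw$caches[[l]]
    g <- g * (lc$pre > 0)                       # ReLU
    lay <- params$layers[[l]]
    gl <- list()
    dInpRes <- NULL
    if (cfg$residual) {
      if (is.null(lay$proj)) dInpRes <- g
      else {
        gl$proj <- crossprod(lc$Hin, g)
        dInpRes <- g %*% t(lay$proj)
      }
    }
    if (cfg$batchNorm) {
      bb <- bnBackward(g, lc$xhat, lc$var, lay$gamma)
      gl$gamma <- bb$dGamma; gl$beta <- bb$dBeta
      dLin <- bb$dLin
    } else dLin <- g
    gl$W <- crossprod(lc$agg, dLin)
    dAgg <- dLin %*% t(lay$W)
    dHd <- as.matrix(Ahat %*% dAgg)
    dInp <- if (is.null(lc$mask)) dHd else dHd * lc$mask
    if (!is.null(dInpRes)) dInp <- dInp + dInpRes
    grads$layers[[l]] <- gl
    if (l > 1L) {
      dOut[[l - 1L]] <- addGrad(dOut[[l - 1L]], dInp)
      m <- skipSource(l, w, cfg$longSkips)
      if (!is.na(m)) dOut[[m]] <- addGrad(dOut[[m]], dInp)
    }
  }
  grads
}

## Loss and flattened gradient in one sweep (used by the trainer and the
## finite-difference check).  lambda enters both.
lossAndGradient <- function(graph, X, model, labels, lambda = 0,
                            training = TRUE, ignoreIndex = -1L) {
  fw <- forwardPass(graph, X, model, training = training)
  grads <- backwardPass(graph, fw, model, labels, ignoreIndex)
  fl <- flattenParams(model$params)
  gfl <- flattenParams(grads)
  gvec <- gfl$vec + 2 * lambda * fl$vec * fl$isWeight
  loss <- crossEntropy(fw$Z, labels, ignoreIndex) +
    lambda * sum(fl$vec[fl$isWeight]^2)
  list(loss = loss, grad = gvec, flat = fl, bnNew = fw$bnNew)
}
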