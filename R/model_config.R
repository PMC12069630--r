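#' Network configuration
#'
#' Describes the attention-guided deep GCN: a stack of first-order graph
#' convolution layers over a U-shaped (palindromic) hidden-width schedule at
#' full mesh resolution, batch normalization and residual connections in
#' every layer, one squeeze-and-excitation (SE) channel-attention block
#' after the first layer, optional additive long skip connections between
#' width-matched mirror layers, and a softmax graph-convolution output head.
#'
#' @param inChannels input feature channels (6 morphological features).
#' @param hiddenWidths hidden layer widths; default the 7-layer U-shaped
#'   schedule \code{c(16, 32, 64, 128, 64, 32, 16)}.  Must be palindromic
#'   when \code{longSkips} is on.
#' @param nClasses number of output classes (31 for DKT parcels).
#' @param seEnabled apply the SE block.
#' @param seRatio SE bottleneck reduction ratio r (default 4); must divide
#'   the width at \code{sePosition}.
#' @param sePosition 1-based index of the hidden layer whose output feeds
#'   the SE block (default 1 = after the first GCN layer).
#' @param dropout dropout rate applied to node features before each layer's
#'   aggregation (default 0.1).
#' @param longSkips additive skips between width-matched mirror layers.
#' @param batchNorm per-channel batch normalization over the N nodes of the
#'   (single-graph) batch.
#' @param residual per-layer residual connections; identity when the widths
#'   match, a learned linear projection otherwise.
#' @param seed default parameter-initialization seed.
#' @return A validated config (list, class \code{"adgcn_config"}).
#' @export
adgcnConfig <- function(inChannels = 6L,
                        hiddenWidths = c(16L, 32L, 64L, 128L, 64L, 32L, 16L),
                        nClasses = 31L,
                        seEnabled = TRUE, seRatio = 4L, sePosition = 1L,
                        dropout = 0.1, longSkips = TRUE,
                        batchNorm = TRUE, residual = TRUE,
                        seed = 1L) {
  cfg <- list(inChannels = as.integer(inChannels),
              hiddenWidths = as.integer(hiddenWidths),
              nClasses = as.integer(nClasses),
              seEnabled = isTRUE(seEnabled), seRatio = as.integer(seRatio),
              sePosition = as.integer(sePosition),
              dropout = dropout, longSkips = isTRUE(longSkips),
              batchNorm = isTRUE(batchNorm), residual = isTRUE(residual),
              seed = as.integer(seed))
  class(cfg) <- "adgcn_config"
  validateConfig(cfg)
  cfg
}

validateConfig <- function(cfg) {
  w <- cfg$hiddenWidths
  if (length(w) < 1L || any(w < 1L)) stop("hiddenWidths must be positive")
  if (cfg$nClasses < 2L) stop("need at least 2 classes")
  if (cfg$dropout < 0 || cfg$dropout >= 1) stop("dropout must be in [0, 1)")
  if (cfg$longSkips && !identical(w, rev(w)))
    stop("hiddenWidths must be palindromic when longSkips is on")
  if (cfg$seEnabled) {
    if (cfg$sePosition < 1L || cfg$sePosition > length(w))
      stop("sePosition outside the hidden stack")
    if (cfg$seRatio < 1L || w[cfg$sePosition] %% cfg$seRatio != 0L)
      stop("seRatio must divide the width at sePosition")
  }
  invisible(cfg)
}

#' Named architecture presets
#'
#' The ablation family of the method: plain deep GCNs with 1..7 hidden
#' layers along the ramp 16, 32, 64, 128, 64, 32, 16, with or without the
#' SE block.  \code{"adgcn"} is the full model (7 hidden layers, SE with
#' r = 4); \code{"gcn<k>"} is the k-hidden-layer baseline without SE.
#'
#' @param name preset name: \code{"adgcn"}, \code{"gcn1"} .. \code{"gcn7"},
#'   or \code{"se1"} (1 hidden layer + SE).
#' @param ... overrides passed to \code{\link{adgcnConfig}} (e.g.
#'   \code{nClasses}, \code{inChannels}, \code{seRatio}).
#' @return A config list.
#' @export
adgcnPreset <- function(name = "adgcn", ...) {
  ramp <- c(16L, 32L, 64L, 128L, 64L, 32L, 16L)
  base <- switch(name,
    adgcn = list(hiddenWidths = ramp, seEnabled = TRUE, longSkips = TRUE),
    se1   = list(hiddenWidths = 16L, seEnabled = TRUE, longSkips = FALSE),
    gcn1 = , gcn2 = , gcn3 = , gcn4 = , gcn5 = , gcn6 = , gcn7 = {
      k <- as.integer(substring(name, 4L))
      list(hiddenWidths = ramp[seq_len(k)], seEnabled = FALSE,
           longSkips = identical(ramp[seq_len(k)], rev(ramp[seq_len(k)])))
    },
    stop(sprintf("unknown preset '%s'", name)))
  do.call(adgcnConfig, utils::modifyList(base, list(...)))
}

glorot <- function(fanIn, fanOut) {
  a <- sqrt(6 / (fanIn + fanOut))
  matrix(stats::runif(fanIn * fanOut, -a, a), fanIn, fanOut)
}

#' Initialize model parameters
#'
#' Variance-preserving (uniform Glorot) initialization of every weight
#' matrix, unit/zero batch-norm affine parameters and fresh running
#' statistics.  Deterministic given \code{seed}: the same seed yields
#' bit-identical parameters.
#'
#' @param config an \code{\link{adgcnConfig}}.
#' @param seed RNG seed (defaults to \code{config$seed}).
#' @return list with elements \code{params} (trainable), \code{bn} (running
#'   batch-norm statistics) and \code{config}; class \code{"adgcn_model"}.
#' @export
initParams <- function(config, seed = config$seed) {
  validateConfig(config)
  w <- config$hiddenWidths
  widths <- c(config$inChannels, w)
  withSeed(seed, {
    layers <- vector("list", length(w))
    for (l in seq_along(w)) {
      lay <- list(W = glorot(widths[l], widths[l + 1L]))
      if (config$batchNorm) {
        lay$gamma <- rep(1, w[l]); lay$beta <- rep(0, w[l])
      }
      if (config$residual && widths[l] != widths[l + 1L])
        lay$proj <- glorot(widths[l], widths[l + 1L])
      layers[[l]] <- lay
    }
    params <- list(layers = layers,
                   out = list(W = glorot(w[length(w)], config$nClasses)))
    if (config$seEnabled) {
      c0 <- w[config$sePosition]
      params$se <- list(W1 = glorot(c0 %/% config$seRatio, c0),
                        W2 = glorot(c0, c0 %/% config$seRatio))
    }
    bn <- if (config$batchNorm)
      lapply(w, function(ww) list(mean = rep(0, ww), var = rep(1, ww)))
    else NULL
    structure(list(params = params, bn = bn, config = config),
              class = "adgcn_model")
  })
}

#' Count trainable parameters
#' @param model an \code{"adgcn_model"}.
#' @return integer number of trainable scalars.
#' @export
countParams <- function(model) {
  length(flattenParams(model$params)$vec)
}

#' @export
print.adgcn_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("adgcn_model: %d hidden layers (%s), %d classes, SE %s, %d parameters\n",
              length(cfg$hiddenWidths), paste(cfg$hiddenWidths, collapse = ","),
              cfg$nClasses, if (cfg$seEnabled) sprintf("r=%d", cfg$seRatio) else "off",
              countParams(x)))
  invisible(x)
}

## ---- parameter flattening (used by Adam and the L2 penalty) --------------

## Returns vec (all trainables), skeleton (shapes) and isWeight (TRUE for
## weight matrices, FALSE for batch-norm affine parameters: only weights
## enter the L2 penalty).
flattenParams <- function(params) {
  vec <- numeric(0); skel <- list(); isW <- logical(0)
  addOne <- function(path, val, weight) {
    skel[[length(skel) + 1L]] <<- list(path = path, dim = dim(val), len = length(val))
    vec <<- c(vec, as.numeric(val))
    isW <<- c(isW, rep(weight, length(val)))
  }
  for (l in seq_along(params$layers)) {
    lay <- params$layers[[l]]
    addOne(c("layers", l, "W"), lay$W, TRUE)
    if (!is.null(lay$proj)) addOne(c("layers", l, "proj"), lay$proj, TRUE)
    if (!is.null(lay$gamma)) {
      addOne(c("layers", l, "gamma"), lay$gamma, FALSE)
      addOne(c("layers", l, "beta"), lay$beta, FALSE)
    }
  }
  if (!is.null(params$se)) {
    addOne(c("se", 1, "W1"), params$se$W1, TRUE)
    addOne(c("se", 1, "W2"), params$se$W2, TRUE)
  }
  addOne(c("out", 1, "W"), params$out$W, TRUE)
  list(vec = vec, skeleton = skel, isWeight = isW)
}

unflattenParams <- function(vec, skeleton, template) {
  pos <- 0L
  for (s in skeleton) {
    chunk <- vec[(pos + 1L):(pos + s$len)]
    pos <- pos + s$len
    val <- if (is.null(s$dim)) chunk else matrix(chunk, s$dim[1L], s$dim[2L])
    p <- s$path
    if (p[1L] == "layers") template$layers[[as.integer(p[2L])]][[p[3L]]] <- val
    else if (p[1L] == "se") template$se[[p[3L]]] <- val
    else template$out[[p[3L]]] <- val
  }
  template
}
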