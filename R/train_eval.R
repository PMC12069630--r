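#' Training configuration
#'
#' Defaults are the method's printed protocol: learning rate 0.01, 200
#' epochs, batch size 1 (one graph per optimizer step), dropout 0.1 (held in
#' the model config), 5 folds.  The L2 coefficient is not printed anywhere;
#' 5e-4 is the conventional GCN default.
#'
#' @param learningRate Adam step size.
#' @param epochs training epochs.
#' @param weightDecay L2 coefficient \eqn{\lambda}.
#' @param folds cross-validation folds.
#' @param seed seed for subject shuffling and dropout streams.
#' @param ignoreIndex unlabeled-vertex sentinel.
#' @param standardize standardize each subject's features before training.
#' @return list, class \code{"train_config"}.
#' @export
trainConfig <- function(learningRate = 0.01, epochs = 200L,
                        weightDecay = 5e-4, folds = 5L, seed = 1L,
                        ignoreIndex = -1L, standardize = TRUE) {
  if (learningRate < 0) stop("learning rate must be non-negative")
  if (epochs < 1L) stop("need at least one epoch")
  if (folds < 2L) stop("need at least 2 folds")
  structure(list(learningRate = learningRate, epochs = as.integer(epochs),
                 weightDecay = weightDecay, folds = as.integer(folds),
                 seed = as.integer(seed), ignoreIndex = as.integer(ignoreIndex),
                 standardize = isTRUE(standardize)),
            class = "train_config")
}

#' Per-subject feature standardization
#'
#' Each channel is centred and scaled to unit variance over the subject's N
#' vertices; constant channels map to all zeros.  Idempotent.
#'
#' @param X \code{N x C} feature matrix, finite.
#' @return standardized matrix.
#' @export
standardizeFeatures <- function(X) {
  if (!all(is.finite(X))) stop("non-finite feature values")
  mu <- colMeans(X)
  sd <- sqrt(colMeans(X * X) - mu * mu)
  sd[sd < 1e-12] <- Inf                 # constant channel -> 0
  (X - rowRep(mu, nrow(X))) * rowRep(1 / sd, nrow(X))
}

#' Subject-level k-fold split
#'
#' Disjoint test folds covering all ids, sizes differing by at most one,
#' deterministic given the seed.
#'
#' @param ids subject identifiers.
#' @param folds number of folds.
#' @param seed RNG seed.
#' @return list of \code{list(train, test)} pairs.
#' @export
kfoldSplit <- function(ids, folds = 5L, seed = 1L) {
  if (length(ids) < folds) stop("fewer subjects than folds")
  perm <- withSeed(seed, sample(ids))
  grp <- rep(seq_len(folds), length.out = length(perm))
  grp <- sort(grp)                      # sizes differ by <= 1, in order
  lapply(seq_len(folds), function(f)
    list(train = perm[grp != f], test = perm[grp == f]))
}

adamInit <- function(nPar) list(m = numeric(nPar), v = numeric(nPar), t = 0L)

adamStep <- function(state, vec, grad, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad * grad
  mh <- state$m / (1 - beta1^state$t)
  vh <- state$v / (1 - beta2^state$t)
  list(state = state, vec = vec - lr * mh / (sqrt(vh) + eps))
}

#' Train the network
#'
#' Adam on the composite loss, one graph per step, subject order reshuffled
#' each epoch (seeded).  Deterministic given seeds and configs up to
#' floating-point reduction order.
#'
#' @param subjects list of \linkS4class{CortexSubject}.
#' @param modelConfig an \code{\link{adgcnConfig}}.
#' @param train a \code{\link{trainConfig}}.
#' @return the trained \code{"adgcn_model"} with a \code{history}
#'   data.frame (epoch, mean training loss) attached.
#' @export
trainModel <- function(subjects, modelConfig, train = trainConfig()) {
  if (length(subjects) < 1L) stop("need at least one training subject")
  feats <- lapply(subjects, function(s)
    if (train$standardize) standardizeFeatures(s@features) else s@features)
  labs <- lapply(subjects, function(s) s@labels)
  model <- initParams(modelConfig, seed = subSeed(train$seed, 1))
  fl <- flattenParams(model$params)
  vec <- fl$vec
  adam <- adamInit(length(vec))
  history <- numeric(train$epochs)
  withSeed(subSeed(train$seed, 2), {
    for (epoch in seq_len(train$epochs)) {
      order <- sample.int(length(subjects))
      lossSum <- 0
      for (si in order) {
        model$params <- unflattenParams(vec, fl$skeleton, model$params)
        lg <- lossAndGradient(subjects[[si]]@graph, feats[[si]], model,
                              labs[[si]], lambda = train$weightDecay,
                              training = TRUE,
                              ignoreIndex = train$ignoreIndex)
        if (!is.finite(lg$loss))
          stop(sprintf("non-finite loss at epoch %d (subject %s): training aborted",
                       epoch, subjects[[si]]@id))
        model$bn <- lg$bnNew
        st <- adamStep(adam, vec, lg$grad, train$learningRate)
        adam <- st$state; vec <- st$vec
        lossSum <- lossSum + lg$loss
      }
      history[epoch] <- lossSum / length(subjects)
    }
  })
  model$params <- unflattenParams(vec, fl$skeleton, model$params)
  model$history <- data.frame(epoch = seq_len(train$epochs), loss = history)
  model$trainConfig <- train
  model
}

#' Predict labels for one subject
#'
#' @param model trained \code{"adgcn_model"}.
#' @param subject a \linkS4class{CortexSubject} (its labels are ignored).
#' @param standardize standardize features first (must match training).
#' @return integer vector of 0-based predicted labels.
#' @export
predictSubject <- function(model, subject, standardize = TRUE) {
  X <- if (standardize) standardizeFeatures(subject@features) else subject@features
  predictLabels(modelForward(subject@graph, X, model, training = FALSE))
}

## ---- metrics --------------------------------------------------------------

#' Dice coefficient for one class
#'
#' \eqn{2 |G_c \cap P_c| / (|G_c| + |P_c|)}; symmetric in its arguments,
#' bounded in \code{[0, 1]}, \code{NaN} when the class is absent from both.
#'
#' @param G,P integer label vectors of equal length (ignored vertices
#'   removed via \code{ignoreIndex} on \code{G}).
#' @param class class index.
#' @param ignoreIndex unlabeled sentinel (vertices dropped from both).
#' @return Dice coefficient.
#' @export
diceCoefficient <- function(G, P, class, ignoreIndex = -1L) {
  if (length(G) != length(P)) stop("label vectors must have equal length")
  keep <- G != ignoreIndex
  G <- G[keep]; P <- P[keep]
  g <- G == class; p <- P == class
  denom <- sum(g) + sum(p)
  if (denom == 0L) return(NaN)
  2 * sum(g & p) / denom
}

#' Macro-average Dice over ground-truth classes
#'
#' Mean of the per-class Dice over the classes present in \code{G}; classes
#' absent from both label vectors are excluded (0/0 undefined).
#'
#' @inheritParams diceCoefficient
#' @return mean Dice in \code{[0, 1]}.
#' @export
meanDice <- function(G, P, ignoreIndex = -1L) {
  keep <- G != ignoreIndex
  cls <- sort(unique(G[keep]))
  mean(vapply(cls, function(c) diceCoefficient(G, P, c, ignoreIndex), 0))
}

#' Overall vertex accuracy
#'
#' Fraction of non-ignored vertices whose predicted label matches the truth.
#'
#' @inheritParams diceCoefficient
#' @return accuracy in \code{[0, 1]}.
#' @export
labelAccuracy <- function(G, P, ignoreIndex = -1L) {
  if (length(G) != length(P)) stop("label vectors must have equal length")
  keep <- G != ignoreIndex
  if (!any(keep)) stop("no labeled vertices")
  mean(G[keep] == P[keep])
}

#' Evaluate a trained model on a test set
#'
#' Per-class vertex counts are pooled (summed) across the test subjects
#' before the Dice ratio is taken (micro pooling), then macro-averaged over
#' the classes present in the pooled ground truth; accuracy is pooled over
#' all labeled vertices.  Per-subject accuracies are reported alongside.
#'
#' @param model trained \code{"adgcn_model"}.
#' @param subjects list of \linkS4class{CortexSubject} with ground truth.
#' @param standardize standardize features before prediction.
#' @param ignoreIndex unlabeled sentinel.
#' @return list (class \code{"metrics_report"}): \code{perClassDice},
#'   \code{meanDice}, \code{accuracy}, \code{perSubjectAccuracy},
#'   \code{meanSubjectAccuracy}.
#' @export
evaluateModel <- function(model, subjects, standardize = TRUE,
                          ignoreIndex = -1L) {
  K <- model$config$nClasses
  gCount <- pCount <- oCount <- numeric(K)
  correct <- 0; total <- 0
  perSubj <- numeric(length(subjects))
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    P <- predictSubject(model, s, standardize)
    G <- s@labels
    keep <- G != ignoreIndex
    G <- G[keep]; P <- P[keep]
    for (c in seq_len(K) - 1L) {
      gCount[c + 1L] <- gCount[c + 1L] + sum(G == c)
      pCount[c + 1L] <- pCount[c + 1L] + sum(P == c)
      oCount[c + 1L] <- oCount[c + 1L] + sum(G == c & P == c)
    }
    correct <- correct + sum(G == P)
    total <- total + length(G)
    perSubj[i] <- mean(G == P)
  }
  dice <- ifelse(gCount + pCount > 0, 2 * oCount / (gCount + pCount), NaN)
  present <- gCount > 0
  structure(list(perClassDice = stats::setNames(dice, seq_len(K) - 1L),
                 meanDice = mean(dice[present]),
                 accuracy = correct / total,
                 perSubjectAccuracy = perSubj,
                 meanSubjectAccuracy = mean(perSubj)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report: mean Dice %.4f, accuracy %.4f (%d classes scored)\n",
              x$meanDice, x$accuracy, sum(is.finite(x$perClassDice))))
  invisible(x)
}

#' Write a metrics report as a tab-separated table
#'
#' One (class, dice) row per class plus a summary block.
#'
#' @param report a \code{"metrics_report"}.
#' @param path output path.
#' @export
writeMetricsReport <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("class\tdice", con)
  for (i in seq_along(report$perClassDice))
    writeLines(sprintf("%s\t%.6f", names(report$perClassDice)[i],
                       report$perClassDice[i]), con)
  writeLines(sprintf("# mean_dice\t%.6f", report$meanDice), con)
  writeLines(sprintf("# accuracy\t%.6f", report$accuracy), con)
  invisible(path)
}

#' Subject-level cross-validation
#'
#' Seeded k-fold split of the cohort; each fold trains on the remaining
#' subjects and is evaluated on its held-out test set.
#'
#' @param subjects list of \linkS4class{CortexSubject}.
#' @param modelConfig an \code{\link{adgcnConfig}}.
#' @param train a \code{\link{trainConfig}}.
#' @param foldIndices which folds to run (default all).
#' @return list of per-fold lists \code{(fold, model, report, test)}.
#' @export
crossValidate <- function(subjects, modelConfig, train = trainConfig(),
                          foldIndices = seq_len(train$folds)) {
  ids <- vapply(subjects, function(s) s@id, "")
  splits <- kfoldSplit(ids, train$folds, train$seed)
  lapply(foldIndices, function(f) {
    sp <- splits[[f]]
    tr <- subjects[ids %in% sp$train]
    te <- subjects[ids %in% sp$test]
    foldTrain <- train
    foldTrain$seed <- as.integer(subSeed(train$seed, 100 + f))
    model <- trainModel(tr, modelConfig, foldTrain)
    list(fold = f, model = model, report = evaluateModel(model, te),
         test = sp$test)
  })
}
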