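.CLICK_LABELS <- c("regular_click", "buzz", "noise")
.VESSEL_LABELS <- c("vessel", "non_vessel")

#' Random-forest hyperparameters for the event classifiers
#'
#' Both branch models use the same forest settings: 100 trees, a maximum
#' tree depth of 30 and a minimum node size to split of 7, with all other
#' forest parameters at the library defaults. The seed fixes the forest's
#' bootstrap and split randomness so training is bit-for-bit reproducible.
#'
#' @param nEstimators number of trees.
#' @param maxDepth maximum tree depth.
#' @param minSamplesSplit minimum samples a node needs to be split.
#' @param seed integer training seed.
#' @return named list with class `"RFHyperparams"`.
#' @export
rfHyperparams <- function(nEstimators = 100, maxDepth = 30,
                          minSamplesSplit = 7, seed = 1) {
  hp <- list(nEstimators = nEstimators, maxDepth = maxDepth,
             minSamplesSplit = minSamplesSplit, seed = seed)
  if (any(unlist(hp) %% 1 != 0) || nEstimators < 1 || maxDepth < 1 ||
      minSamplesSplit < 1)
    .schema_error("random-forest hyperparameters must be positive integers")
  structure(hp, class = "RFHyperparams")
}

#' Stratified train/validation split
#'
#' Splits a labeled dataset into disjoint, exhaustive train and validation
#' parts, stratified by label so each side preserves the class ratio within
#' rounding: per class, `round(trainFraction * n_class)` rows (at least one)
#' go to training. A class with fewer than two members cannot be split and
#' is kept whole in the training side, with a warning. Reproducible given
#' `seed`; the caller's RNG stream is left untouched.
#'
#' @param labels character or factor vector of row labels.
#' @param trainFraction proportion of rows to train on (0 < f < 1).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `valid`.
#' @export
splitTrainValidation <- function(labels, trainFraction = 0.7, seed = 1) {
  if (length(labels) == 0) .schema_error("cannot split an empty dataset")
  if (trainFraction <= 0 || trainFraction >= 1)
    .schema_error("trainFraction must be strictly between 0 and 1")
  labels <- as.character(labels)
  train <- integer()
  .with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      if (length(idx) < 2) {
        warning(sprintf("class '%s' has fewer than 2 members; kept whole in train",
                        cls))
        train <- c(train, idx)
      } else {
        n_tr <- min(length(idx) - 1L, max(1L, round(trainFraction * length(idx))))
        train <- c(train, sample(idx, n_tr))
      }
    }
  })
  train <- sort(train)
  list(train = train, valid = setdiff(seq_along(labels), train))
}

#' Train a random-forest event classifier
#'
#' Fits the branch model on a labeled feature table: three classes
#' (`regular_click`, `buzz`, `noise`) for the click branch, two (`vessel`,
#' `non_vessel`) for the vessel branch. The feature columns must follow the
#' fixed [featureNames()] layout of the branch (the click branch includes
#' `BuzzCheck`, the vessel branch does not). Training is deterministic given
#' the hyperparameter seed.
#'
#' @param features data.frame of feature columns (extra `event_id`/`kind`
#'   columns are dropped).
#' @param labels vector of branch-appropriate labels, one per row.
#' @param branch `"click"` or `"vessel"`.
#' @param hp an [rfHyperparams()] list.
#' @param importance `"impurity"` (mean decrease in impurity, the default
#'   random-forest importance) or `"permutation"`.
#' @return a [TrainedEventModel-class].
#' @export
trainEventModel <- function(features, labels, branch = c("click", "vessel"),
                            hp = rfHyperparams(),
                            importance = c("impurity", "permutation")) {
  branch <- match.arg(branch)
  importance <- match.arg(importance)
  vocab <- if (branch == "click") .CLICK_LABELS else .VESSEL_LABELS
  labels <- as.character(labels)
  if (nrow(features) != length(labels))
    .schema_error("features and labels must have the same number of rows")
  if (!all(labels %in% vocab))
    .schema_error(sprintf("labels outside the %s-branch vocabulary: %s", branch,
                          paste(setdiff(labels, vocab), collapse = ", ")))
  if (length(unique(labels)) < 2)
    .schema_error("training requires at least two classes")
  cols <- featureNames(branch)
  missing <- setdiff(cols, names(features))
  if (length(missing) > 0)
    .schema_error(sprintf("feature table is missing column(s): %s",
                          paste(missing, collapse = ", ")))
  x <- features[, cols, drop = FALSE]
  y <- factor(labels, levels = intersect(vocab, unique(labels)))
  fit <- ranger::ranger(x = x, y = y,
                        num.trees = hp$nEstimators,
                        max.depth = hp$maxDepth,
                        min.node.size = hp$minSamplesSplit,
                        importance = importance,
                        seed = hp$seed, num.threads = 1)
  new("TrainedEventModel", fit = fit, branch = branch, featureNames = cols,
      hyperparams = unclass(hp), levels = levels(y))
}

#' Predict event classes
#'
#' Applies a trained branch model to a feature table with the same column
#' layout it was trained on; a column-order mismatch is a schema error, and
#' an empty input yields an empty factor.
#'
#' @param object a [TrainedEventModel-class].
#' @param newdata data.frame of features (extra `event_id`/`kind` columns
#'   are ignored).
#' @return factor of predicted labels, one per row.
#' @export
setMethod("predict", "TrainedEventModel", function(object, newdata) {
  missing <- setdiff(object@featureNames, names(newdata))
  if (length(missing) > 0)
    .schema_error(sprintf("prediction input is missing column(s): %s",
                          paste(missing, collapse = ", ")))
  x <- newdata[, object@featureNames, drop = FALSE]
  if (nrow(x) == 0) return(factor(character(), levels = object@levels))
  pred <- stats::predict(object@fit, data = x, num.threads = 1)
  factor(as.character(pred$predictions), levels = object@levels)
})

setMethod("show", "TrainedEventModel", function(object) {
  cat(sprintf("TrainedEventModel (%s branch): %d trees, depth <= %d, %d features\n",
              object@branch, object@hyperparams$nEstimators,
              object@hyperparams$maxDepth, length(object@featureNames)))
  cat(sprintf("  classes: %s\n", paste(object@levels, collapse = ", ")))
  invisible(NULL)
})

#' Ranked feature importances
#'
#' Importances of a fitted model (mean decrease in impurity unless the model
#' was trained with permutation importance), normalized to sum to one and
#' sorted in decreasing order.
#'
#' @param model a [TrainedEventModel-class].
#' @param ... unused.
#' @return data.frame with columns `feature` and `importance`.
#' @export
setMethod("featureImportances", "TrainedEventModel", function(model, ...) {
  imp <- model@fit$variable.importance
  if (is.null(imp)) .schema_error("model was trained without importance")
  imp <- pmax(imp, 0)
  imp <- imp / sum(imp)
  ord <- order(imp, decreasing = TRUE)
  data.frame(feature = names(imp)[ord], importance = unname(imp[ord]))
})
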