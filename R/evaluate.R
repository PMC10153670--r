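#' Cross-validation configuration
#'
#' @param folds number of folds. Default 5.
#' @param repeats independent repetitions (fresh fold split and fresh model
#'   initialization each). Default 5.
#' @param seed base RNG seed; repeat `r` derives its seed as
#'   `seed + 1000 * r`.
#' @param stratified keep class proportions equal across folds (default);
#'   set `FALSE` for plain random folds.
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(folds = 5, repeats = 5, seed = 1, stratified = TRUE) {
  stopifnot(folds >= 2, repeats >= 1)
  structure(list(folds = folds, repeats = repeats, seed = seed,
                 stratified = stratified), class = "cv_config")
}

#' Assign samples to cross-validation folds
#'
#' Stratified assignment shuffles each class separately and deals its
#' samples round-robin over the folds, so every sample lands in exactly one
#' test fold and class proportions stay balanced. Falls back to plain random
#' folds (with a warning) if some class has fewer samples than folds.
#'
#' @param y 0-based labels.
#' @param folds number of folds.
#' @param stratified stratify by class.
#' @return Integer fold id (1..folds) per sample.
#' @export
make_folds <- function(y, folds, stratified = TRUE) {
  n <- length(y)
  if (stratified && min(table(y)) < folds) {
    warning("some class has fewer samples than folds; using unstratified folds")
    stratified <- FALSE
  }
  fold <- integer(n)
  if (stratified) {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  } else {
    fold <- sample(rep_len(seq_len(folds), n))
  }
  fold
}

#' Repeated k-fold cross-validation of a hybrid network
#'
#' Runs `repeats` independent `folds`-fold cross-validations: each repeat
#' draws a fresh seeded fold split, and each fold trains a freshly
#' initialized model on the remaining folds and evaluates on the held-out
#' one. Reported accuracies are the mean (and sd) over all
#' `repeats * folds` runs, in percent, together with the mean epochs to
#' stopping.
#'
#' @param dataset an [stnet_dataset()] with normalized features.
#' @param model_fn factory `function(n_features, n_classes, seed)` returning
#'   an untrained `stnet_model` (e.g. a wrapper around [cstnet()]).
#' @param cv a [cv_config()].
#' @param learning a [learning_config()].
#' @param max_epoch,min_mse stopping parameters passed to [train_stnet()].
#' @param approach label for result tables. Default `"stnet"`.
#' @return An object of class `stnet_cv`: a one-row data frame with mean/sd
#'   training and testing accuracy, mean epochs and the generalization gap,
#'   plus per-run detail in attribute `runs`.
#' @export
cross_validate <- function(dataset, model_fn, cv = cv_config(),
                           learning = learning_config(),
                           max_epoch = 100, min_mse = 0,
                           approach = "stnet") {
  stopifnot(inherits(dataset, "stnet_dataset"))
  runs <- list()
  for (r in seq_len(cv$repeats)) {
    rseed <- cv$seed + 1000L * r
    set.seed(rseed)
    fold <- make_folds(dataset$y, cv$folds, cv$stratified)
    for (f in seq_len(cv$folds)) {
      tr <- subset_dataset(dataset, fold != f)
      te <- subset_dataset(dataset, fold == f)
      model <- model_fn(ncol(dataset$x), dataset$n_classes,
                        seed = rseed + f)
      model <- train_stnet(model, tr, learning = learning,
                           max_epoch = max_epoch, min_mse = min_mse,
                           seed = rseed + 100L * f)
      runs[[length(runs) + 1L]] <- data.frame(
        repeat_id = r, fold = f,
        train_accuracy = stnet_accuracy(model, tr),
        test_accuracy = stnet_accuracy(model, te),
        epochs = nrow(model$history))
    }
  }
  runs <- do.call(rbind, runs)
  res <- data.frame(
    approach = approach,
    train_accuracy = mean(runs$train_accuracy),
    train_sd = stats::sd(runs$train_accuracy),
    test_accuracy = mean(runs$test_accuracy),
    test_sd = stats::sd(runs$test_accuracy),
    epochs = mean(runs$epochs))
  res$generalization_gap <- generalization_gap(res)
  attr(res, "runs") <- runs
  class(res) <- c("stnet_cv", "data.frame")
  res
}

#' @export
print.stnet_cv <- function(x, ...) {
  cat(sprintf("%s: train %.1f (%.1f) %%, test %.1f (%.1f) %%, mean epochs %.0f, gap %.1f\n",
              x$approach, x$train_accuracy, x$train_sd,
              x$test_accuracy, x$test_sd, x$epochs, x$generalization_gap))
  invisible(x)
}

subset_dataset <- function(ds, keep) {
  out <- ds
  out$x <- ds$x[keep, , drop = FALSE]
  out$y <- ds$y[keep]
  out
}

#' Generalization gap
#'
#' Training accuracy minus testing accuracy, in percentage points.
#'
#' @param result a result row with `train_accuracy` and `test_accuracy`
#'   columns (e.g. from [cross_validate()]), or a numeric training accuracy.
#' @param test_accuracy testing accuracy when `result` is numeric.
#' @return Scalar gap in percentage points.
#' @examples
#' generalization_gap(97.8, 84.3)  # 13.5
#' @export
generalization_gap <- function(result, test_accuracy = NULL) {
  if (is.numeric(result) && !is.null(test_accuracy))
    return(result - test_accuracy)
  result$train_accuracy - result$test_accuracy
}

#' Holdout evaluation with repeated independent trainings
#'
#' For datasets with a predefined train/test split there is no folding;
#' instead the model is trained `repeats` times from independent
#' initializations and evaluated on the fixed test set.
#'
#' @param train,test [stnet_dataset()]s with normalized features.
#' @param model_fn factory as in [cross_validate()].
#' @param repeats number of independent trainings. Default 5.
#' @param seed base seed.
#' @inheritParams cross_validate
#' @return An `stnet_cv` result row.
#' @export
evaluate_holdout <- function(train, test, model_fn, repeats = 5, seed = 1,
                             learning = learning_config(),
                             max_epoch = 100, min_mse = 0,
                             approach = "stnet") {
  runs <- lapply(seq_len(repeats), function(r) {
    model <- model_fn(ncol(train$x), train$n_classes, seed = seed + r)
    model <- train_stnet(model, train, learning = learning,
                         max_epoch = max_epoch, min_mse = min_mse,
                         seed = seed + 100L * r)
    data.frame(repeat_id = r,
               train_accuracy = stnet_accuracy(model, train),
               test_accuracy = stnet_accuracy(model, test),
               epochs = nrow(model$history))
  })
  runs <- do.call(rbind, runs)
  res <- data.frame(
    approach = approach,
    train_accuracy = mean(runs$train_accuracy),
    train_sd = stats::sd(runs$train_accuracy),
    test_accuracy = mean(runs$test_accuracy),
    test_sd = stats::sd(runs$test_accuracy),
    epochs = mean(runs$epochs))
  res$generalization_gap <- generalization_gap(res)
  attr(res, "runs") <- runs
  class(res) <- c("stnet_cv", "data.frame")
  res
}

#' Competition-rank aggregation of test accuracies
#'
#' Ranks approaches within each dataset by descending test accuracy using
#' competition ("min") ranking — tied accuracies share the smallest rank and
#' the next distinct accuracy skips accordingly — then averages each
#' approach's rank over the datasets. This is the standard way to compare
#' classifiers across benchmark collections before a Friedman-type test.
#'
#' @param accuracy matrix of test accuracies, approaches in rows (named),
#'   datasets in columns. `NA` cells exclude the approach with a warning.
#' @return List with `ranks` (per-dataset rank matrix) and `average`
#'   (named mean rank per approach).
#' @examples
#' m <- rbind(a = c(90, 80), b = c(85, 85), c = c(90, 70))
#' rank_approaches(m)$average
#' @export
rank_approaches <- function(accuracy) {
  accuracy <- as.matrix(accuracy)
  if (is.null(rownames(accuracy)))
    rownames(accuracy) <- paste0("approach", seq_len(nrow(accuracy)))
  incomplete <- apply(accuracy, 1, anyNA)
  if (any(incomplete)) {
    warning("excluding approaches with missing cells: ",
            paste(rownames(accuracy)[incomplete], collapse = ", "))
    accuracy <- accuracy[!incomplete, , drop = FALSE]
  }
  ranks <- apply(accuracy, 2, function(col)
    vapply(col, function(a) 1L + sum(col > a), integer(1)))
  ranks <- matrix(ranks, nrow = nrow(accuracy),
                  dimnames = dimnames(accuracy))
  list(ranks = ranks, average = rowMeans(ranks))
}

#' Published benchmark test accuracies for rank aggregation
#'
#' Loads the table of reported mean test accuracies (percent) of eight
#' classification approaches — six spiking-network methods, a plain sigmoid
#' ANN and the two hybrid networks implemented here — on five small UCI
#' benchmark datasets, as printed in the comparison literature. Used to
#' demonstrate and test [rank_approaches()].
#'
#' @return Matrix of accuracies, approaches in rows, datasets in columns.
#' @export
benchmark_accuracies <- function() {
  path <- system.file("extdata", "benchmark_test_accuracy.csv",
                      package = "stnet")
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  m
}
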