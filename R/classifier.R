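# RBF-kernel maximum-margin classification of PSH vs noPSH feature
# vectors: random-forest feature selection, a 10 x 10 log-spaced
# hyperparameter grid (C in [0.5, 10], gamma in [0.01, 10]) evaluated by
# stratified tenfold cross-validation, pooled out-of-fold confusion
# matrices, and leave-one-feature-out ablation. Standardization parameters
# are always estimated on the training folds only.

POSITIVE_CLASS <- "PSH"

#' Classification metrics from a confusion matrix
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), balanced accuracy
#' (sensitivity + specificity)/2, F1 = 2 * precision * sensitivity /
#' (precision + sensitivity), and the misclassification rate
#' (fn + fp)/total. PSH is the positive class. F1 is `NA` when precision
#' is undefined (tp + fp = 0).
#'
#' @param tp,fn,fp,tn Nonnegative counts.
#' @return A `class_metrics` (named list).
#' @export
compute_metrics <- function(tp, fn, fp, tn) {
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0)
  if (tp + fn == 0 || tn + fp == 0) stop("both classes must be represented")
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && (prec + sens) > 0) 2 * prec * sens / (prec + sens) else NA_real_
  structure(
    list(
      tp = tp, fn = fn, fp = fp, tn = tn,
      sensitivity = sens, specificity = spec,
      balanced_accuracy = (sens + spec) / 2,
      precision = prec, f1 = f1,
      misclassification_rate = (fn + fp) / (tp + fn + fp + tn)
    ),
    class = "class_metrics"
  )
}

#' Rank features with a random forest
#'
#' Mean-decrease-in-impurity importance from a seeded 500-tree random
#' forest; the default subset is the smallest top-ranked set covering at
#' least `cum_importance` of the total importance.
#'
#' @param x data.frame or matrix of features (complete cases only are
#'   used).
#' @param y Class labels.
#' @param ntree Number of trees (default 500).
#' @param cum_importance Cumulative-importance coverage for the selected
#'   subset (default 0.8).
#' @param seed Integer seed.
#' @return List with `ranking` (data.frame: feature, importance) and
#'   `selected` (character vector).
#' @export
select_features <- function(x, y, ntree = 500, cum_importance = 0.8, seed = 1L) {
  x <- as.data.frame(x)
  if (ncol(x) < 2) stop("need at least 2 features")
  if (nrow(x) < 10) stop("need at least 10 rows")
  y <- factor(y)
  set.seed(seed)
  rf <- randomForest::randomForest(x = x, y = y, ntree = ntree, importance = FALSE)
  imp <- randomForest::importance(rf)[, "MeanDecreaseGini"]
  ord <- order(imp, decreasing = TRUE)
  ranking <- data.frame(
    feature = names(imp)[ord],
    importance = unname(imp[ord]),
    stringsAsFactors = FALSE
  )
  total <- sum(ranking$importance)
  k <- if (total > 0) which(cumsum(ranking$importance) / total >= cum_importance)[1] else nrow(ranking)
  list(ranking = ranking, selected = ranking$feature[seq_len(k)])
}

# Standardize train columns; apply the train parameters to test.
standardize_split <- function(train, test) {
  mu <- colMeans(train)
  sdv <- apply(train, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(
    train = scale(train, center = mu, scale = sdv),
    test = scale(test, center = mu, scale = sdv)
  )
}

cm_from_pred <- function(pred, truth) {
  pos <- POSITIVE_CLASS
  list(
    tp = sum(pred == pos & truth == pos),
    fn = sum(pred != pos & truth == pos),
    fp = sum(pred == pos & truth != pos),
    tn = sum(pred != pos & truth != pos)
  )
}

#' Stratified k-fold cross-validation of one RBF-SVM configuration
#'
#' Folds are stratified by class and seeded. Within each fold the features
#' are standardized with training-fold parameters only. Out-of-fold
#' predictions are pooled into one validation confusion matrix; training
#' metrics pool each fold's resubstitution predictions.
#'
#' @param x Feature matrix / data.frame (numeric columns).
#' @param y Class labels (`"PSH"` positive).
#' @param cost_c,gamma RBF-SVM hyperparameters.
#' @param k Number of folds (default 10); must not exceed the smaller
#'   class count.
#' @param seed Fold seed.
#' @param average `"pooled"` (default) pools out-of-fold predictions;
#'   `"folds"` averages per-fold metrics instead.
#' @return List with `validation` and `train` `class_metrics`, plus the
#'   pooled validation confusion matrix.
#' @export
crossvalidate <- function(x, y, cost_c = 1, gamma = 0.1, k = 10, seed = 1L,
                          average = c("pooled", "folds")) {
  average <- match.arg(average)
  x <- as.matrix(as.data.frame(x))
  y <- factor(y)
  if (k > min(table(y))) {
    stop(sprintf(
      "k = %d exceeds the smaller class count (%d); consider leave-one-out",
      k, min(table(y))
    ))
  }
  fold <- stratified_folds(as.character(y), k, seed = seed)
  val_pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  train_cm <- list(tp = 0, fn = 0, fp = 0, tn = 0)
  fold_ba <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    std <- standardize_split(x[tr, , drop = FALSE], x[!tr, , drop = FALSE])
    fit <- e1071::svm(
      x = std$train, y = y[tr], kernel = "radial",
      cost = cost_c, gamma = gamma, scale = FALSE
    )
    val_pred[!tr] <- stats::predict(fit, std$test)
    ptr <- stats::predict(fit, std$train)
    cm_tr <- cm_from_pred(ptr, y[tr])
    train_cm <- Map(`+`, train_cm, cm_tr)
    if (average == "folds") {
      cmv <- cm_from_pred(stats::predict(fit, std$test), y[!tr])
      sens <- if (cmv$tp + cmv$fn > 0) cmv$tp / (cmv$tp + cmv$fn) else NA
      spc <- if (cmv$tn + cmv$fp > 0) cmv$tn / (cmv$tn + cmv$fp) else NA
      fold_ba[f] <- mean(c(sens, spc), na.rm = TRUE)
    }
  }
  cm <- cm_from_pred(val_pred, y)
  val <- compute_metrics(cm$tp, cm$fn, cm$fp, cm$tn)
  if (average == "folds") val$balanced_accuracy <- mean(fold_ba)
  list(
    validation = val,
    train = compute_metrics(train_cm$tp, train_cm$fn, train_cm$fp, train_cm$tn),
    confusion = cm
  )
}

#' Hyperparameter grid search for the RBF-SVM
#'
#' Evaluates a log-spaced `grid_size` x `grid_size` grid of (C, gamma)
#' configurations (default 10 x 10 = 100 models over C in \[0.5, 10\] and
#' gamma in \[0.01, 10\]) by stratified tenfold cross-validation. The best
#' configuration maximizes validation balanced accuracy; ties break toward
#' smaller C, then smaller gamma. A seeded random search over the same
#' ranges is available as an alternative mode.
#'
#' @param x,y Features and labels.
#' @param grid_size Grid resolution per axis (default 10).
#' @param c_range,gamma_range Hyperparameter ranges.
#' @param k Folds (default 10).
#' @param seed Fold (and random-search) seed.
#' @param mode `"grid"` (default) or `"random"`.
#' @return A `search_result`: `results` (data.frame per config), `best`
#'   (list with `cost_c`, `gamma`), `n_models`.
#' @export
grid_search <- function(x, y, grid_size = 10,
                        c_range = c(0.5, 10), gamma_range = c(0.01, 10),
                        k = 10, seed = 1L, mode = c("grid", "random")) {
  mode <- match.arg(mode)
  if (mode == "grid") {
    cs <- exp(seq(log(c_range[1]), log(c_range[2]), length.out = grid_size))
    gs <- exp(seq(log(gamma_range[1]), log(gamma_range[2]), length.out = grid_size))
    grid <- expand.grid(cost_c = cs, gamma = gs)
  } else {
    set.seed(seed)
    n <- grid_size^2
    grid <- data.frame(
      cost_c = exp(stats::runif(n, log(c_range[1]), log(c_range[2]))),
      gamma = exp(stats::runif(n, log(gamma_range[1]), log(gamma_range[2])))
    )
  }
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cv <- crossvalidate(x, y, cost_c = grid$cost_c[i], gamma = grid$gamma[i],
                        k = k, seed = seed)
    res[[i]] <- data.frame(
      cost_c = grid$cost_c[i], gamma = grid$gamma[i],
      train_balanced_accuracy = cv$train$balanced_accuracy,
      train_misclassification = cv$train$misclassification_rate,
      validation_balanced_accuracy = cv$validation$balanced_accuracy,
      validation_misclassification = cv$validation$misclassification_rate
    )
  }
  results <- do.call(rbind, res)
  ord <- order(-results$validation_balanced_accuracy, results$cost_c, results$gamma)
  best <- results[ord[1], ]
  structure(
    list(
      results = results,
      best = list(cost_c = best$cost_c, gamma = best$gamma,
                  validation_balanced_accuracy = best$validation_balanced_accuracy),
      n_models = nrow(results)
    ),
    class = "search_result"
  )
}

#' Leave-one-feature-out ablation
#'
#' Repeats the cross-validation with each feature removed and reports the
#' change in misclassification rate and balanced accuracy, overall and per
#' class.
#'
#' @param x,y Features and labels.
#' @param cost_c,gamma Fixed hyperparameters.
#' @param k Folds.
#' @param seed Fold seed.
#' @return data.frame: one `full` baseline row plus one row per ablated
#'   feature, with overall / PSH / noPSH misclassification rates and the
#'   balanced-accuracy drop.
#' @export
feature_ablation <- function(x, y, cost_c = 1, gamma = 0.1, k = 10, seed = 1L) {
  x <- as.data.frame(x)
  if (ncol(x) < 2) stop("need at least 2 features")
  row_for <- function(label, cv) {
    cm <- cv$confusion
    data.frame(
      ablated = label,
      misclassification = cv$validation$misclassification_rate,
      misclassification_psh = cm$fn / (cm$tp + cm$fn),
      misclassification_nopsh = cm$fp / (cm$tn + cm$fp),
      balanced_accuracy = cv$validation$balanced_accuracy,
      train_misclassification = cv$train$misclassification_rate,
      stringsAsFactors = FALSE
    )
  }
  base <- crossvalidate(x, y, cost_c, gamma, k = k, seed = seed)
  rows <- list(row_for("full", base))
  for (j in seq_len(ncol(x))) {
    cv <- crossvalidate(x[, -j, drop = FALSE], y, cost_c, gamma, k = k, seed = seed)
    rows[[length(rows) + 1L]] <- row_for(names(x)[j], cv)
  }
  out <- do.call(rbind, rows)
  out$delta_misclassification <- out$misclassification - out$misclassification[1]
  out$delta_balanced_accuracy <- out$balanced_accuracy - out$balanced_accuracy[1]
  out
}
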