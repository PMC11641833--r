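# Dataset splitting, gradient-boosted-tree classification, 5-fold CV and
# confusion-matrix evaluation.

#' Split a feature table into train / validation / test sets
#'
#' Partition sizes follow cumulative rounding of the fractions: with `n`
#' rows the first boundary is `round(n * f1)` and the second
#' `round(n * (f1 + f2))`, so 7399 rows at 0.64/0.16/0.20 give
#' 4735/1184/1480. `unit = "window"` assigns individual windows (the
#' scheme used with overlapping windows, which leaks shared samples
#' between partitions -- see the vignette); `unit = "subject"` keeps all
#' windows of a subject in one partition, erroring if no subject
#' assignment lands within +/- 5 percentage points of every fraction.
#'
#' @param table Feature table (needs `subject_id` for subject-unit
#'   splits).
#' @param fractions Numeric length-3 train/validation/test fractions
#'   summing to 1.
#' @param unit `"window"` or `"subject"`.
#' @param seed Integer seed for the random assignment.
#' @return Named list of three data.frames: `train`, `validation`,
#'   `test`.
#' @export
split_dataset <- function(table, fractions = c(0.64, 0.16, 0.20),
                          unit = c("window", "subject"), seed = 1L) {
  unit <- match.arg(unit)
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8)
    ppgci_error("ppgci_parameter_error", "`fractions` must sum to 1")
  n <- nrow(table)
  if (!n) ppgci_error("ppgci_input_error", "empty feature table")
  b1 <- round(n * fractions[1L])
  b2 <- round(n * (fractions[1L] + fractions[2L]))
  if (unit == "window") {
    ord <- with_seed(seed, sample.int(n))
    parts <- list(train = ord[seq_len(b1)],
                  validation = if (b2 > b1) ord[(b1 + 1L):b2] else integer(0),
                  test = if (n > b2) ord[(b2 + 1L):n] else integer(0))
  } else {
    subj <- unique(table$subject_id)
    ord_s <- with_seed(seed, sample(subj))
    counts <- table(table$subject_id)[ord_s]
    cum <- cumsum(as.numeric(counts)) / n
    # subject boundaries closest to the cumulative fraction targets
    k1 <- which.min(abs(cum - fractions[1L]))
    k2 <- which.min(abs(cum - (fractions[1L] + fractions[2L])))
    if (k2 <= k1 || k2 >= length(ord_s))
      ppgci_error("ppgci_split_error",
                  "too few subjects for a subject-unit split")
    got <- c(cum[k1], cum[k2] - cum[k1], 1 - cum[k2])
    if (any(abs(got - fractions) > 0.05))
      ppgci_error("ppgci_split_error", sprintf(
        "subject-unit split %.3f/%.3f/%.3f deviates more than 5%% from target",
        got[1], got[2], got[3]))
    grp <- list(train = ord_s[seq_len(k1)],
                validation = ord_s[(k1 + 1L):k2],
                test = ord_s[(k2 + 1L):length(ord_s)])
    parts <- lapply(grp, function(g) which(table$subject_id %in% g))
  }
  lapply(parts, function(ix) {
    out <- table[ix, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

# defaults sized for feature tables of a few hundred to a few thousand
# windows: shallow (pairwise-interaction) trees, light shrinkage and a
# minimum-hessian leaf constraint (~80 rows per leaf under the 0.25
# binary-logistic hessian) keep the ensemble from chasing label noise,
# so a label-permuted fit reverts to the base rate
default_gbdt_params <- function() {
  list(nrounds = 60L, max_depth = 2L, eta = 0.05, subsample = 1,
       colsample_bytree = 1, min_child_weight = 20, nthread = 1L)
}

#' Train a gradient-boosted decision-tree classifier
#'
#' Fits an additive ensemble of decision trees whose summed scores are
#' converted to a class by the argmax (for two classes: a 0.5 probability
#' threshold). The boosting engine is pluggable: the default uses
#' xgboost; any engine can be supplied as a list with elements
#' `fit(X, y01, params)` and `predict(fit, X)` returning P(Low).
#'
#' @param train_table Feature table with a `label` column containing both
#'   classes.
#' @param params Named list overriding [default_gbdt_params()] entries.
#' @param features Feature columns to use (default all twenty).
#' @param seed Training seed (deterministic with the default single
#'   thread).
#' @param engine `"xgboost"` or a custom fit/predict list.
#' @return Object of class `ci_classifier`.
#' @export
train_classifier <- function(train_table, params = list(),
                             features = ppg_feature_names, seed = 0L,
                             engine = "xgboost") {
  y <- factor(train_table$label, levels = c("Low", "NonLow"))
  if (any(is.na(y)))
    ppgci_error("ppgci_input_error", "labels must be Low / NonLow")
  if (nlevels(droplevels(y)) < 2L)
    ppgci_error("ppgci_training_error",
                "training set contains a single class")
  missing <- setdiff(features, names(train_table))
  if (length(missing))
    ppgci_error("ppgci_schema_error",
                paste("missing feature columns:",
                      paste(missing, collapse = ", ")))
  pars <- utils::modifyList(default_gbdt_params(), params)
  X <- as.matrix(train_table[, features, drop = FALSE])
  y01 <- as.integer(y == "Low")
  fit <- if (identical(engine, "xgboost")) {
    with_seed(seed, xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = pars$max_depth, eta = pars$eta,
                    subsample = pars$subsample,
                    colsample_bytree = pars$colsample_bytree,
                    min_child_weight = pars$min_child_weight,
                    nthread = pars$nthread),
      data = xgboost::xgb.DMatrix(X, label = y01, nthread = pars$nthread),
      nrounds = pars$nrounds, verbose = 0))
  } else {
    if (!is.list(engine) || !is.function(engine$fit) ||
        !is.function(engine$predict))
      ppgci_error("ppgci_parameter_error",
                  "custom `engine` needs fit() and predict() functions")
    engine$fit(X, y01, pars)
  }
  structure(list(engine = engine, fit = fit, features = features,
                 params = pars, seed = seed,
                 levels = c("Low", "NonLow")),
            class = "ci_classifier")
}

#' Predict Low / NonLow labels
#'
#' @param object A `ci_classifier`.
#' @param newdata Feature table containing the model's feature columns.
#' @param type `"label"` (default) or `"prob"` for P(Low).
#' @param ... Unused.
#' @return Factor of predictions, or numeric probabilities.
#' @export
predict.ci_classifier <- function(object, newdata, type = c("label", "prob"),
                                  ...) {
  type <- match.arg(type)
  missing <- setdiff(object$features, names(newdata))
  if (length(missing))
    ppgci_error("ppgci_schema_error",
                paste("newdata is missing feature columns:",
                      paste(missing, collapse = ", ")))
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  prob <- if (identical(object$engine, "xgboost"))
    predict(object$fit,
            xgboost::xgb.DMatrix(X, nthread = object$params$nthread))
  else object$engine$predict(object$fit, X)
  if (type == "prob") return(prob)
  factor(ifelse(prob > 0.5, "Low", "NonLow"), levels = object$levels)
}

#' Stratified k-fold cross-validation accuracy
#'
#' Folds are stratified by label; every row is tested exactly once.
#'
#' @param table Feature table.
#' @param folds Number of folds.
#' @param params,features,engine Passed to [train_classifier()].
#' @param seed Seed controlling fold assignment and training.
#' @return List with `fold_accuracy` (length `folds`) and
#'   `mean_accuracy`.
#' @export
cross_validate <- function(table, folds = 5L, params = list(),
                           features = ppg_feature_names, seed = 1L,
                           engine = "xgboost") {
  n <- nrow(table)
  if (n < 2L * folds)
    ppgci_error("ppgci_input_error", "too few rows for this many folds")
  y <- factor(table$label, levels = c("Low", "NonLow"))
  fold_id <- integer(n)
  with_seed(seed, for (lv in levels(y)) {
    ix <- sample(which(y == lv))
    fold_id[ix] <- rep_len(seq_len(folds), length(ix))
  })
  acc <- vapply(seq_len(folds), function(f) {
    tr <- table[fold_id != f, , drop = FALSE]
    te <- table[fold_id == f, , drop = FALSE]
    mod <- train_classifier(tr, params, features, seed = seed,
                            engine = engine)
    mean(predict(mod, te) == te$label)
  }, numeric(1L))
  list(fold_accuracy = acc, mean_accuracy = mean(acc))
}

#' Confusion-matrix evaluation of Low / NonLow predictions
#'
#' Computes the 2x2 confusion matrix, per-class precision
#' (TP / (TP + FP)), recall (TP / (TP + FN)) and F1 (harmonic mean), and
#' overall accuracy; each metric is reported raw and rounded to the
#' conventional reporting precision (metrics to 2 decimals, accuracy as a
#' percentage with 2 decimals).
#'
#' @param truth,predicted Factors or characters in `{Low, NonLow}`, equal
#'   length.
#' @return Object of class `evaluation_report`: `confusion` (2x2 integer
#'   matrix, rows = truth), `per_class` data.frame, `accuracy`,
#'   `accuracy_pct_rounded`, `per_class_rounded`.
#' @export
evaluate_predictions <- function(truth, predicted) {
  lv <- c("Low", "NonLow")
  truth <- factor(truth, levels = lv)
  predicted <- factor(predicted, levels = lv)
  if (length(truth) != length(predicted))
    ppgci_error("ppgci_input_error", "truth/predicted length mismatch")
  if (any(is.na(truth)) || any(is.na(predicted)))
    ppgci_error("ppgci_input_error", "labels must be Low / NonLow")
  cm <- table(truth = truth, predicted = predicted)
  per_class <- do.call(rbind, lapply(lv, function(cl) {
    tp <- cm[cl, cl]
    fp <- sum(cm[, cl]) - tp
    fn <- sum(cm[cl, ]) - tp
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0)
      2 * precision * recall / (precision + recall) else 0
    data.frame(class = cl, total = sum(cm[cl, ]), correct = tp,
               precision = precision, recall = recall, f1 = f1)
  }))
  accuracy <- sum(diag(cm)) / sum(cm)
  rounded <- per_class
  rounded[, c("precision", "recall", "f1")] <-
    round(rounded[, c("precision", "recall", "f1")], 2)
  structure(
    list(confusion = cm, per_class = per_class, accuracy = accuracy,
         accuracy_pct_rounded = round(100 * accuracy, 2),
         per_class_rounded = rounded, n = sum(cm)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report>  n = %d, accuracy = %.2f%%\n",
              x$n, 100 * x$accuracy))
  print(x$confusion)
  print(x$per_class_rounded, row.names = FALSE)
  invisible(x)
}
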