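# Leave-one-subject-out random-forest classification and regression with
# the pooled out-of-fold metrics.

#' Leave-one-subject-out folds
#'
#' One fold per subject: all of that subject's visits form the test set and
#' every other visit the training set, so no subject ever appears on both
#' sides of a fold.
#'
#' @param visits data.frame with a `subject_id` column.
#' @return list of folds, each a list with `subject`, `train` and `test`
#'   row indices into `visits`.
#' @export
losoFolds <- function(visits) {
  stopifnot(is.data.frame(visits), "subject_id" %in% names(visits))
  subjects <- unique(visits$subject_id)
  if (length(subjects) < 2) stop("leave-one-subject-out needs >= 2 subjects")
  lapply(subjects, function(s) {
    test <- which(visits$subject_id == s)
    list(subject = s, train = setdiff(seq_len(nrow(visits)), test),
         test = test)
  })
}

# median imputation fitted on the training fold only
.imputeByTrain <- function(x, trainIdx) {
  for (j in seq_len(ncol(x))) {
    med <- median(x[trainIdx, j], na.rm = TRUE)
    if (is.na(med)) med <- 0
    x[is.na(x[, j]), j] <- med
  }
  x
}

#' Leave-one-subject-out random-forest classification
#'
#' Fits one probability random forest per fold (balanced class weighting via
#' inverse-frequency case weights) and pools the out-of-fold predictions.
#' Reports weighted accuracy (support-weighted mean per-class recall, i.e.
#' overall accuracy), balanced accuracy (unweighted mean per-class recall),
#' per-class recall, the macro-averaged one-vs-rest AUC from the pooled
#' class probabilities, the confusion matrix, and impurity-based feature
#' importances averaged over folds (normalized to sum 1 within each fold).
#' Missing feature values are imputed with the training-fold median.
#'
#' @param visits data.frame with `subject_id`, the label column and feature
#'   columns.
#' @param features character vector of feature column names.
#' @param labelField name of the class column (e.g. `"group"` or
#'   `"dysarthria"`). Default `"group"`.
#' @param nTrees trees per forest. Default 500.
#' @param seed integer; per-fold forest seeds are derived from it, so
#'   identical seed and inputs give identical reports.
#' @return list with `weighted_accuracy` and `balanced_accuracy` (percent),
#'   `per_class_recall` (percent, named), `auc` (macro one-vs-rest),
#'   `confusion` (true x predicted counts), `importances`, `predictions`
#'   (data.frame of out-of-fold class probabilities and calls), `folds`.
#' @export
classifyLoso <- function(visits, features, labelField = "group",
                         nTrees = 500, seed = 1) {
  stopifnot(is.data.frame(visits), labelField %in% names(visits),
            all(features %in% names(visits)))
  y <- factor(visits[[labelField]])
  if (nlevels(y) < 2) stop("need at least 2 classes in ", labelField)
  x <- as.matrix(visits[, features, drop = FALSE])
  folds <- losoFolds(visits)
  classes <- levels(y)
  prob <- matrix(NA_real_, nrow(visits), length(classes),
                 dimnames = list(NULL, classes))
  imp <- matrix(0, length(folds), length(features),
                dimnames = list(NULL, features))

  for (k in seq_along(folds)) {
    tr <- folds[[k]]$train; te <- folds[[k]]$test
    stopifnot(length(intersect(visits$subject_id[tr],
                               visits$subject_id[te])) == 0)
    xi <- .imputeByTrain(x, tr)
    ytr <- droplevels(y[tr])
    if (nlevels(ytr) < nlevels(y))
      warning(sprintf("fold %d: class(es) %s absent from training data", k,
                      paste(setdiff(classes, levels(ytr)), collapse = ", ")))
    w <- 1 / table(ytr)[as.character(ytr)]
    fit <- ranger::ranger(x = xi[tr, , drop = FALSE], y = ytr,
                          num.trees = nTrees, probability = TRUE,
                          importance = "impurity",
                          case.weights = as.numeric(w),
                          seed = seed + k, num.threads = 1)
    p <- predict(fit, data = xi[te, , drop = FALSE],
                 num.threads = 1)$predictions
    prob[te, colnames(p)] <- p
    prob[te, setdiff(classes, colnames(p))] <- 0
    tot <- sum(fit$variable.importance)
    imp[k, ] <- if (tot > 0) fit$variable.importance / tot else
      1 / length(features)
  }

  pred <- factor(classes[max.col(prob, ties.method = "first")],
                 levels = classes)
  confusion <- table(true = y, predicted = pred)
  recall <- 100 * diag(confusion) / rowSums(confusion)
  aucs <- vapply(classes, function(cl) {
    resp <- as.integer(y == cl)
    if (length(unique(resp)) < 2) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(resp, prob[, cl], quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  }, numeric(1))

  list(weighted_accuracy = 100 * mean(pred == y),
       balanced_accuracy = mean(recall),
       per_class_recall = recall,
       auc = mean(aucs, na.rm = TRUE),
       per_class_auc = aucs,
       confusion = confusion,
       importances = colMeans(imp),
       predictions = data.frame(subject_id = visits$subject_id,
                                true = y, predicted = pred,
                                prob, check.names = FALSE),
       folds = folds)
}

#' Leave-one-subject-out random-forest regression
#'
#' Fits one random-forest regressor per fold and pools the out-of-fold
#' predictions; reports mean squared error, mean absolute error and the
#' explained variance `1 - var(residual) / var(target)`.
#'
#' @param visits data.frame with `subject_id`, the target column and
#'   feature columns.
#' @param features character vector of feature column names.
#' @param target name of the numeric clinical-score column.
#' @param nTrees trees per forest. Default 500.
#' @param seed integer seed, as in [classifyLoso()].
#' @return list with `target`, `mse`, `mae`, `explained_variance`,
#'   `importances`, `predictions`, `folds`.
#' @export
regressLoso <- function(visits, features, target, nTrees = 500, seed = 1) {
  stopifnot(is.data.frame(visits), target %in% names(visits),
            all(features %in% names(visits)))
  y <- as.numeric(visits[[target]])
  if (anyNA(y)) stop("target '", target, "' has missing values")
  x <- as.matrix(visits[, features, drop = FALSE])
  folds <- losoFolds(visits)
  pred <- rep(NA_real_, nrow(visits))
  imp <- matrix(0, length(folds), length(features),
                dimnames = list(NULL, features))

  for (k in seq_along(folds)) {
    tr <- folds[[k]]$train; te <- folds[[k]]$test
    xi <- .imputeByTrain(x, tr)
    fit <- ranger::ranger(x = xi[tr, , drop = FALSE], y = y[tr],
                          num.trees = nTrees, importance = "impurity",
                          seed = seed + k, num.threads = 1)
    pred[te] <- predict(fit, data = xi[te, , drop = FALSE],
                        num.threads = 1)$predictions
    tot <- sum(fit$variable.importance)
    imp[k, ] <- if (tot > 0) fit$variable.importance / tot else
      1 / length(features)
  }

  resid <- y - pred
  ev <- if (var(y) > 0) 1 - var(resid) / var(y) else NA_real_
  list(target = target,
       mse = mean(resid^2),
       mae = mean(abs(resid)),
       explained_variance = ev,
       importances = colMeans(imp),
       predictions = data.frame(subject_id = visits$subject_id,
                                true = y, predicted = pred),
       folds = folds)
}
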