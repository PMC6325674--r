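# Evaluation machinery: confusion-matrix metrics, regression metrics,
# ROC/AUC, decision-threshold selection, k-fold cross-validation and grid
# search.
#
# Label convention used throughout the package: toxicity labels are 0/1
# integers with 1 = toxic, and the POSITIVE class is NON-TOXIC (0). TP is a
# non-toxic compound classified as non-toxic; FP is a toxic compound
# over-predicted as non-toxic. TPR/FPR/MCC all follow this convention.

#' Confusion counts (positive = non-toxic)
#'
#' @param truth,pred Binary 0/1 vectors (1 = toxic) of equal length.
#' @return Object of class `confusion_counts`: named list with `TP`, `TN`,
#'   `FP`, `FN`.
#' @export
confusion_counts <- function(truth, pred) {
  if (length(truth) != length(pred)) {
    stopf("label length mismatch: %d vs %d", length(truth), length(pred))
  }
  if (!all(truth %in% c(0, 1)) || !all(pred %in% c(0, 1))) {
    stopf("labels must be binary 0/1 (1 = toxic)")
  }
  out <- list(TP = sum(truth == 0 & pred == 0),
              TN = sum(truth == 1 & pred == 1),
              FP = sum(truth == 1 & pred == 0),
              FN = sum(truth == 0 & pred == 1))
  class(out) <- "confusion_counts"
  out
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts (positive = non-toxic): TP=%d TN=%d FP=%d FN=%d\n",
              x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

.as_counts <- function(c) {
  stopifnot(all(c(c$TP, c$TN, c$FP, c$FN) >= 0))
  lapply(c[c("TP", "TN", "FP", "FN")], as.numeric)
}

#' Classification metrics from confusion counts
#'
#' `acc` = (TP+TN)/(TP+FP+TN+FN); `tpr` = TP/(TP+FN); `fpr` = FP/(FP+TN).
#' A zero denominator yields `NA` with a message rather than an error.
#'
#' @param c A `confusion_counts` object (or list with TP/TN/FP/FN).
#' @return A single numeric value.
#' @export
acc <- function(c) {
  k <- .as_counts(c)
  d <- k$TP + k$FP + k$TN + k$FN
  if (d == 0) { message("accuracy undefined: no instances"); return(NA_real_) }
  (k$TP + k$TN) / d
}

#' @rdname acc
#' @export
tpr <- function(c) {
  k <- .as_counts(c)
  if (k$TP + k$FN == 0) { message("TPR undefined: no positives"); return(NA_real_) }
  k$TP / (k$TP + k$FN)
}

#' @rdname acc
#' @export
fpr <- function(c) {
  k <- .as_counts(c)
  if (k$FP + k$TN == 0) { message("FPR undefined: no negatives"); return(NA_real_) }
  k$FP / (k$FP + k$TN)
}

#' Matthews correlation coefficient
#'
#' `(TN*TP - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, a balanced
#' quality measure in `[-1, 1]` (1 = perfect, 0 = random, -1 =
#' anti-correlated). If any of the four marginal sums is zero the
#' coefficient is defined as 0, the usual convention.
#'
#' @param c A `confusion_counts` object.
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(c) {
  k <- .as_counts(c)
  den <- (k$TP + k$FP) * (k$TP + k$FN) * (k$TN + k$FP) * (k$TN + k$FN)
  if (den == 0) return(0)
  (k$TN * k$TP - k$FP * k$FN) / sqrt(den)
}

#' Regression metrics
#'
#' `mse` is the mean squared error between predicted and actual values;
#' `pcc` is the Pearson correlation coefficient. `pcc` on a constant input
#' is undefined and returns `NA` with a message.
#'
#' @param yhat,y Numeric vectors of equal length.
#' @return A single numeric value.
#' @export
mse <- function(yhat, y) {
  if (length(yhat) != length(y)) stopf("length mismatch in mse")
  mean((yhat - y)^2)
}

#' @rdname mse
#' @export
pcc <- function(yhat, y) {
  if (length(yhat) != length(y)) stopf("length mismatch in pcc")
  if (length(y) < 2L) stopf("pcc needs at least 2 observations")
  if (stats::sd(yhat) == 0 || stats::sd(y) == 0) {
    message("PCC undefined: constant input")
    return(NA_real_)
  }
  stats::cor(yhat, y)
}

#' ROC curve and AUC for Tox-scores
#'
#' Sweeps the decision rule "non-toxic iff score <= t" over all distinct
#' score values (tied scores are grouped at one threshold). Points run from
#' (0, 0) to (1, 1) with non-decreasing FPR; the area under the curve is
#' computed by trapezoidal integration. With only one class present the AUC
#' is undefined (`NA`, with a message).
#'
#' @param scores Numeric scores (higher = more toxic).
#' @param truth Binary 0/1 labels (1 = toxic).
#' @return Object of class `roc_curve`: list with `points` (data frame of
#'   `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_curve <- function(scores, truth) {
  if (length(scores) != length(truth)) stopf("length mismatch in roc_curve")
  pos <- truth == 0   # non-toxic = positive
  neg <- truth == 1
  if (!any(pos) || !any(neg)) {
    message("AUC undefined: only one class present")
    ts <- sort(unique(scores))
    pts <- data.frame(threshold = c(-Inf, ts), fpr = NA_real_, tpr = NA_real_)
    out <- list(points = pts, auc = NA_real_)
    class(out) <- "roc_curve"
    return(out)
  }
  ts <- sort(unique(scores))
  tprv <- vapply(ts, function(t) mean(scores[pos] <= t), numeric(1))
  fprv <- vapply(ts, function(t) mean(scores[neg] <= t), numeric(1))
  pts <- data.frame(threshold = c(-Inf, ts),
                    fpr = c(0, fprv), tpr = c(0, tprv))
  n <- nrow(pts)
  auc <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-n]) / 2)
  out <- list(points = pts, auc = auc)
  class(out) <- "roc_curve"
  out
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %s\n", nrow(x$points),
              format(x$auc, digits = 4)))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "l",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey")
  invisible(x)
}

#' Select the MCC-maximizing Tox-score threshold
#'
#' Evaluates the MCC of [classify_tox()] at every threshold on the grid
#' `seq(0, 1, by = grid_step)` and returns the maximizer; ties go to the
#' smallest threshold. The default grid step 0.01 matches the two-decimal
#' resolution at which operational thresholds are usually reported.
#'
#' @param scores Tox-scores in `[0, 1]`.
#' @param truth Binary 0/1 labels (1 = toxic); both classes must be present.
#' @param grid_step Grid spacing in `(0, 0.5]`.
#' @return Object of class `threshold_selection`: list with `threshold`,
#'   `mcc` and `sweep` (data frame of `threshold`, `mcc` over the grid).
#' @export
select_threshold <- function(scores, truth, grid_step = 0.01) {
  if (grid_step <= 0 || grid_step > 0.5) stopf("grid_step must be in (0, 0.5]")
  if (length(unique(truth)) < 2L) stopf("threshold selection needs both classes")
  grid <- seq(0, 1, by = grid_step)
  mccs <- vapply(grid, function(t) mcc(confusion_counts(truth, classify_tox(scores, t))),
                 numeric(1))
  best <- which.max(mccs)  # which.max returns the first (smallest t) maximum
  out <- list(threshold = grid[best], mcc = mccs[best],
              sweep = data.frame(threshold = grid, mcc = mccs))
  class(out) <- "threshold_selection"
  out
}

#' @export
print.threshold_selection <- function(x, ...) {
  cat(sprintf("selected Tox-score threshold %.2f (MCC = %.3f over %d grid points)\n",
              x$threshold, x$mcc, nrow(x$sweep)))
  invisible(x)
}

#' k-fold cross-validation
#'
#' Splits the data into `k` folds (sizes differing by at most one),
#' stratified by class for binary 0/1 labels so fold class ratios match the
#' data within one instance, unstratified otherwise. Each fold is held out
#' once; `trainer` is fit on the remainder and `predictor` scores the
#' held-out rows.
#'
#' @param x Feature matrix.
#' @param y Labels aligned with `x`.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for fold assignment.
#' @param trainer `function(x, y)` returning a fitted model.
#' @param predictor `function(model, x)` returning numeric predictions;
#'   defaults to [predict()].
#' @param metrics Named list of `function(truth, pred)` metric functions
#'   evaluated per fold.
#' @param stratified `TRUE`/`FALSE`, or `NULL` to stratify exactly when `y`
#'   is binary 0/1.
#' @return Object of class `cv_result`: `folds` (assignment per row),
#'   `fold_metrics` (data frame, one row per fold), `summary` (mean and sd
#'   per metric) and `oof` (pooled out-of-fold predictions, input order).
#' @export
kfold_cv <- function(x, y, k = 5, seed = 42, trainer, predictor = predict,
                     metrics = list(), stratified = NULL) {
  n <- if (is.matrix(x)) nrow(x) else length(x)
  if (k < 2) stopf("k must be >= 2")
  if (k > n) stopf("k (%d) exceeds the number of instances (%d)", k, n)
  if (is.null(stratified)) stratified <- all(y %in% c(0, 1))

  folds <- with_seed(derive_seed(seed, 1L), {
    f <- integer(n)
    if (stratified) {
      for (cls in unique(y)) {
        idx <- which(y == cls)
        idx <- idx[sample.int(length(idx))]
        f[idx] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      idx <- sample.int(n)
      f[idx] <- rep_len(seq_len(k), n)
    }
    f
  })

  oof <- rep(NA_real_, n)
  rows <- vector("list", k)
  for (fold in seq_len(k)) {
    test <- folds == fold
    model <- trainer(x[!test, , drop = FALSE], y[!test])
    p <- predictor(model, x[test, , drop = FALSE])
    oof[test] <- p
    vals <- vapply(metrics, function(fn) fn(y[test], p), numeric(1))
    rows[[fold]] <- c(fold = fold, vals)
  }
  fold_metrics <- as.data.frame(do.call(rbind, rows))
  metric_cols <- setdiff(names(fold_metrics), "fold")
  summ <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(fold_metrics[[m]]), numeric(1)),
    sd = vapply(metric_cols, function(m) stats::sd(fold_metrics[[m]]), numeric(1)),
    row.names = NULL
  )
  out <- list(folds = folds, fold_metrics = fold_metrics, summary = summ, oof = oof)
  class(out) <- "cv_result"
  out
}

#' @export
print.cv_result <- function(x, ...) {
  k <- length(unique(x$folds))
  cat(sprintf("%d-fold cross-validation\n", k))
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-6s %.4f +/- %.4f\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$sd[i]))
  }
  invisible(x)
}

#' Exhaustive hyperparameter grid search
#'
#' Evaluates every row of `grid` by [kfold_cv()] and ranks configurations by
#' mean MCC, breaking ties by mean AUC and then by grid order. MCC is
#' computed on each fold at the fixed score threshold 0.5 (calibration-free
#' comparison); AUC is threshold-free.
#'
#' @param grid Data frame, one row per candidate configuration.
#' @param x,y Training data (binary 0/1 labels, 1 = toxic).
#' @param k,seed Cross-validation settings (same folds for every candidate).
#' @param trainer_factory `function(params)` (a one-row list of `grid`)
#'   returning a `trainer` for [kfold_cv()].
#' @param predictor Prediction function, as in [kfold_cv()].
#' @return List with `best` (the winning row of `grid`), `best_index` and
#'   `table` (grid plus `mean_mcc`, `mean_auc` and `rank` columns).
#' @export
grid_search <- function(grid, x, y, k = 5, seed = 42, trainer_factory,
                        predictor = predict) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1)
  mets <- list(
    mcc = function(truth, s) mcc(confusion_counts(truth, classify_tox(clamp(s, 0, 1), 0.5))),
    auc = function(truth, s) roc_curve(s, truth)$auc
  )
  res <- lapply(seq_len(nrow(grid)), function(i) {
    params <- as.list(grid[i, , drop = FALSE])
    cv <- kfold_cv(x, y, k = k, seed = seed, trainer = trainer_factory(params),
                   predictor = predictor, metrics = mets)
    c(mean_mcc = mean(cv$fold_metrics$mcc), mean_auc = mean(cv$fold_metrics$auc))
  })
  scores <- as.data.frame(do.call(rbind, res))
  ord <- order(-scores$mean_mcc, -scores$mean_auc, seq_len(nrow(grid)))
  tab <- cbind(grid, scores)
  tab$rank <- match(seq_len(nrow(grid)), ord)
  list(best = grid[ord[1], , drop = FALSE], best_index = ord[1], table = tab)
}
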