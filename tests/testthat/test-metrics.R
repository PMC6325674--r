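# Confusion-matrix metrics, ROC/AUC, threshold selection, CV, grid search.

test_that("confusion counts follow the positive = non-toxic convention", {
  truth <- rep(c(0, 1), each = 10)
  cc <- confusion_counts(truth, truth)
  expect_equal(unclass(cc)[c("TP", "TN", "FP", "FN")],
               list(TP = 10L, TN = 10L, FP = 0L, FN = 0L))
  all_nontox <- confusion_counts(truth, rep(0, 20))
  expect_equal(all_nontox$TP, 10L)
  expect_equal(all_nontox$FP, 10L)
  expect_equal(all_nontox$TN, 0L)
  expect_error(confusion_counts(0:1, 0), "mismatch")
  expect_error(confusion_counts(c(0, 2), c(0, 1)), "binary")
})

test_that("confusion counts equal a brute-force tally on random labels", {
  for (s in 1:10) {
    set.seed(s)
    truth <- rbinom(50, 1, 0.4)
    pred <- rbinom(50, 1, 0.5)
    cc <- confusion_counts(truth, pred)
    ok <- oracle_confusion(truth, pred)
    expect_equal(c(TP = cc$TP, TN = cc$TN, FP = cc$FP, FN = cc$FN), ok)
  }
})

test_that("ACC/TPR/FPR match direct arithmetic and handle zero denominators", {
  cc <- list(TP = 40, TN = 30, FP = 10, FN = 20)
  expect_equal(acc(cc), 0.7)
  expect_equal(tpr(cc), 2 / 3)
  expect_equal(fpr(cc), 0.25)
  perfect <- list(TP = 10, TN = 10, FP = 0, FN = 0)
  expect_equal(acc(perfect), 1.0)
  expect_equal(acc(list(TP = 0, TN = 0, FP = 10, FN = 10)), 0.0)
  expect_message(v <- tpr(list(TP = 0, TN = 5, FP = 5, FN = 0)), "undefined")
  expect_true(is.na(v))
  expect_message(v <- fpr(list(TP = 5, TN = 0, FP = 0, FN = 5)), "undefined")
  expect_true(is.na(v))
})

test_that("MCC matches the formula, with the zero-denominator convention", {
  expect_equal(mcc(list(TP = 10, TN = 10, FP = 0, FN = 0)), 1.0)
  expect_equal(mcc(list(TP = 25, TN = 25, FP = 25, FN = 25)), 0.0)
  expect_equal(mcc(list(TP = 0, TN = 0, FP = 0, FN = 5)), 0)  # zero marginal
  cc <- list(TP = 40, TN = 30, FP = 10, FN = 20)
  expect_equal(mcc(cc), oracle_mcc(c(40, 30, 10, 20)))
  for (s in 1:20) {
    k <- random_confusion(s)
    expect_equal(mcc(k), oracle_mcc(c(k$TP, k$TN, k$FP, k$FN)))
  }
})

test_that("MSE and PCC match their definitions", {
  y <- c(1, 2, 3, 4)
  expect_equal(mse(y, y), 0)
  expect_equal(pcc(y, y), 1)
  z <- c(-2, -1, 1, 2)
  expect_equal(pcc(-z, z), -1)
  set.seed(21)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(mse(a, b), oracle_mse(a, b))
  expect_equal(pcc(a, b), oracle_pcc(a, b), tolerance = 1e-12)
  expect_message(v <- pcc(rep(1, 5), 1:5), "constant")
  expect_true(is.na(v))
  expect_error(pcc(1, 1), "at least 2")
})

test_that("ROC runs (0,0) to (1,1) and AUC matches concordance", {
  truth <- rep(c(0, 1), each = 5)
  r <- roc_curve(c(runif(5, 0, 0.4), runif(5, 0.6, 1)), truth)
  expect_equal(r$auc, 1.0)
  r2 <- roc_curve(rep(0.5, 10), truth)
  expect_equal(r2$auc, 0.5)
  for (s in 1:15) {
    set.seed(s)
    n <- sample(10:50, 1)
    tr <- c(0, 1, rbinom(n - 2, 1, 0.5))
    sc <- round(runif(n), 2)  # rounding forces ties
    r <- roc_curve(sc, tr)
    expect_equal(r$auc, oracle_auc(sc, tr), tolerance = 1e-9)
    expect_equal(r$points$fpr[1], 0)
    expect_equal(r$points$tpr[1], 0)
    expect_equal(tail(r$points$fpr, 1), 1)
    expect_equal(tail(r$points$tpr, 1), 1)
    expect_true(all(diff(r$points$fpr) >= 0))
  }
  expect_message(r3 <- roc_curve(runif(5), rep(1, 5)), "one class")
  expect_true(is.na(r3$auc))
})

test_that("threshold selection is the exhaustive argmax with smallest-t ties", {
  sep <- select_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(sep$threshold, 0.2)  # smallest grid point reaching MCC 1
  expect_equal(sep$mcc, 1.0)
  expect_equal(nrow(sep$sweep), 101L)
  for (s in 1:10) {
    set.seed(s)
    sc <- round(runif(40), 2)
    tr <- c(0, 1, rbinom(38, 1, 0.5))
    got <- select_threshold(sc, tr, grid_step = 0.01)
    ok <- oracle_best_threshold(sc, tr, seq(0, 1, by = 0.01))
    expect_equal(got$mcc, ok$mcc, tolerance = 1e-12)
    expect_equal(got$threshold, ok$threshold)
  }
  expect_error(select_threshold(runif(5), rep(0, 5)), "both classes")
  expect_error(select_threshold(runif(5), rep(c(0, 1), length.out = 5), 0.7),
               "grid_step")
})

test_that("CV folds partition the data with balanced, stratified sizes", {
  x <- matrix(rnorm(100), 10)
  cv <- kfold_cv(x, rnorm(10), k = 5, seed = 1,
                 trainer = function(xt, yt) mean(yt),
                 predictor = function(m, xn) rep(m, nrow(xn)),
                 metrics = list(mse = function(t, p) mse(p, t)))
  expect_equal(unname(table(cv$folds)), rep(2L, 5), ignore_attr = TRUE)
  expect_false(anyNA(cv$oof))
  y <- rep(c(0, 1), c(6, 4))
  cv2 <- kfold_cv(matrix(0, 10, 2), y, k = 2, seed = 2,
                  trainer = function(xt, yt) mean(yt),
                  predictor = function(m, xn) rep(m, nrow(xn)))
  for (f in 1:2) {
    expect_equal(sum(y == 0 & cv2$folds == f), 3)
    expect_equal(sum(y == 1 & cv2$folds == f), 2)
  }
  cv3 <- kfold_cv(matrix(0, 10, 2), y, k = 2, seed = 2,
                  trainer = function(xt, yt) mean(yt),
                  predictor = function(m, xn) rep(m, nrow(xn)))
  expect_identical(cv2$folds, cv3$folds)
  expect_error(kfold_cv(x, rnorm(10), k = 11, trainer = identity), "exceeds")
  expect_error(kfold_cv(x, rnorm(10), k = 1, trainer = identity), ">= 2")
})

test_that("grid search ranks by mean MCC and finds a planted optimum", {
  d <- gen_tox_data(n_per_class = 60, n_bits = 64, n_informative = 1,
                    flip_noise = 0, background_p = 0.3, seed = 13)
  grid <- data.frame(k_features = c(1, 64))
  gs <- grid_search(grid, d$x, d$y, k = 3, seed = 13,
                    trainer_factory = function(p) {
                      function(xt, yt) tox_et(xt, yt, n_trees = 15,
                                              k_features = p$k_features, seed = 13)
                    })
  expect_equal(gs$best$k_features, 64)  # full draw always finds the signal bit
  expect_equal(nrow(gs$table), 2L)
  expect_equal(sort(gs$table$rank), 1:2)
  one <- grid_search(data.frame(k_features = 8), d$x, d$y, k = 2, seed = 1,
                     trainer_factory = function(p) {
                       function(xt, yt) tox_et(xt, yt, n_trees = 5,
                                               k_features = p$k_features, seed = 1)
                     })
  expect_equal(one$best_index, 1L)
})
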