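# Extremely randomized trees over binary fingerprints.
#
# Each tree is grown on the FULL training sample (no bootstrap). At every
# node a fixed number of candidate features is drawn uniformly at random
# without replacement; for a binary feature the only possible cut is the 0/1
# split, so the randomized cut-point of the generic algorithm degenerates to
# the feature choice itself. Among the candidates the split with the largest
# Gini impurity decrease is taken (ties broken by the lowest feature index
# for determinism). Leaves store the FRACTION of toxic training samples, so
# the ensemble score — the mean leaf fraction over trees — is a smooth
# probability in [0, 1]; hard majority voting is recovered by growing trees
# to purity and thresholding the mean at 0.5.

# One tree as parallel vectors: feature[i] is NA for a leaf, otherwise the
# split feature; left/right are child node ids; value is the toxic fraction.
.grow_tree <- function(x, y, k, max_depth, min_leaf, min_split, gini_thr) {
  feature <- integer(0); left <- integer(0); right <- integer(0); value <- numeric(0)
  p_all <- ncol(x)

  new_node <- function(val) {
    feature[length(feature) + 1L] <<- NA_integer_
    left[length(left) + 1L] <<- NA_integer_
    right[length(right) + 1L] <<- NA_integer_
    value[length(value) + 1L] <<- val
    length(value)
  }

  build <- function(idx, depth) {
    ys <- y[idx]
    n <- length(idx)
    p <- mean(ys)
    g <- 2 * p * (1 - p)
    if (depth >= max_depth || n < min_split || g <= gini_thr) {
      return(new_node(p))
    }
    feats <- sample.int(p_all, min(k, p_all))
    xs <- x[idx, feats, drop = FALSE]
    n1 <- colSums(xs)
    n0 <- n - n1
    valid <- n1 >= min_leaf & n0 >= min_leaf
    if (!any(valid)) return(new_node(p))
    t1 <- as.vector(crossprod(xs, ys))
    t0 <- sum(ys) - t1
    g1 <- 2 * (t1 / n1) * (1 - t1 / n1)
    g0 <- 2 * (t0 / n0) * (1 - t0 / n0)
    dec <- g - (n0 * g0 + n1 * g1) / n
    dec[!valid] <- -Inf
    best <- order(-dec, feats)[1L]

    id <- new_node(p)
    go_right <- xs[, best] == 1
    li <- build(idx[!go_right], depth + 1L)
    ri <- build(idx[go_right], depth + 1L)
    feature[id] <<- feats[best]
    left[id] <<- li
    right[id] <<- ri
    id
  }

  root <- build(seq_len(nrow(x)), 0L)
  list(feature = feature, left = left, right = right, value = value, root = root)
}

.tree_scores <- function(tree, x) {
  node <- rep(tree$root, nrow(x))
  repeat {
    act <- which(!is.na(tree$feature[node]))
    if (length(act) == 0L) break
    f <- tree$feature[node[act]]
    bit <- x[cbind(act, f)]
    node[act] <- ifelse(bit == 0, tree$left[node[act]], tree$right[node[act]])
  }
  tree$value[node]
}

#' Fit an extremely randomized trees toxicity classifier
#'
#' Trains `n_trees` extra-trees on binary fingerprints and 0/1 toxicity
#' labels (1 = toxic). Defaults follow the standard fingerprint
#' configuration: 500 trees, `k_features = log2(fingerprint length)`
#' (10 for 1024 bits), maximum depth 70, at least 3 samples to create and 19
#' to split a node. A single-class training set yields a warning and a
#' constant model.
#'
#' @param x Binary 0/1 fingerprint matrix.
#' @param y Binary 0/1 labels (1 = toxic) aligned with `x`.
#' @param n_trees Number of trees.
#' @param k_features Candidate features drawn (without replacement) at each
#'   node; `NULL` = `max(1, floor(log2(ncol(x))))`.
#' @param max_depth Maximum tree depth.
#' @param min_samples_leaf Minimum samples in a child node; smaller children
#'   are never created.
#' @param min_samples_split Minimum node size eligible for splitting.
#' @param gini_threshold Stop splitting once node Gini impurity is at or
#'   below this value (0 = grow until pure or size/depth limits).
#' @param seed Integer seed; equal seed, data and settings give an identical
#'   forest.
#' @return Object of class `tox_et` with elements `trees`, `config`,
#'   `n_features` and the fingerprint `scheme` (if `x` carries one).
#' @examples
#' d <- gen_tox_data(n_per_class = 50, n_bits = 32, n_informative = 4,
#'                   flip_noise = 0, seed = 3)
#' fit <- tox_et(d$x, d$y, n_trees = 25, seed = 3)
#' summary(predict(fit, d$x))
#' @export
tox_et <- function(x, y, n_trees = 500, k_features = NULL, max_depth = 70,
                   min_samples_leaf = 3, min_samples_split = 19,
                   gini_threshold = 0, seed = 42) {
  stopifnot(is.matrix(x))
  if (nrow(x) == 0L) stopf("empty training set")
  if (nrow(x) != length(y)) stopf("x and y lengths differ")
  if (!all(y %in% c(0, 1))) stopf("toxicity labels must be 0/1 (1 = toxic)")
  if (is.null(k_features)) k_features <- max(1L, floor(log2(ncol(x))))
  if (k_features < 1 || k_features > ncol(x)) {
    stopf("k_features must be in [1, %d]", ncol(x))
  }
  if (min_samples_leaf >= min_samples_split) {
    stopf("min_samples_leaf must be smaller than min_samples_split")
  }
  if (length(unique(y)) < 2L) {
    warning("single-class training set: returning a constant model", call. = FALSE)
  }

  trees <- with_seed(seed, {
    lapply(seq_len(n_trees), function(i) {
      .grow_tree(x, y, k_features, max_depth, min_samples_leaf,
                 min_samples_split, gini_threshold)
    })
  })

  out <- list(trees = trees, n_features = ncol(x),
              config = list(n_trees = n_trees, k_features = k_features,
                            max_depth = max_depth,
                            min_samples_leaf = min_samples_leaf,
                            min_samples_split = min_samples_split,
                            gini_threshold = gini_threshold, seed = seed),
              class_counts = c(non_toxic = sum(y == 0), toxic = sum(y == 1)),
              scheme = attr(x, "scheme"))
  class(out) <- "tox_et"
  out
}

#' Predict Tox-scores or toxicity classes
#'
#' The Tox-score of a molecule is the mean, over trees, of the toxic class
#' fraction stored in the leaf the molecule falls into: 0 = low and 1 = high
#' probability of being toxic. With `type = "class"` scores are thresholded
#' by [classify_tox()].
#'
#' @param object A `tox_et` model.
#' @param newdata Binary fingerprint matrix with the training width.
#' @param type `"score"` (default) or `"class"`.
#' @param threshold Decision threshold for `type = "class"`; defaults to the
#'   threshold stored on the model by [satox_train_tox()], else 0.58.
#' @param ... Unused.
#' @return Numeric Tox-scores in `[0, 1]`, or 0/1 labels (1 = toxic).
#' @export
predict.tox_et <- function(object, newdata, type = c("score", "class"),
                           threshold = NULL, ...) {
  type <- match.arg(type)
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != object$n_features) {
    stopf("fingerprint width %d does not match model (%d)",
          ncol(newdata), object$n_features)
  }
  per_tree <- vapply(object$trees, .tree_scores, numeric(nrow(newdata)),
                     x = newdata)
  if (is.null(dim(per_tree))) per_tree <- matrix(per_tree, nrow = nrow(newdata))
  scores <- rowMeans(per_tree)
  if (type == "score") return(scores)
  if (is.null(threshold)) threshold <- object$threshold %||% 0.58
  classify_tox(scores, threshold)
}

#' Classify Tox-scores at a threshold
#'
#' A molecule is labeled non-toxic (the positive class, 0) iff its Tox-score
#' is at or below the threshold, toxic (1) otherwise. The default threshold
#' 0.58 is the MCC-optimal operating point reported for drug/hazardous
#' compound screening.
#'
#' @param scores Tox-scores in `[0, 1]`.
#' @param threshold Decision threshold in `[0, 1]`.
#' @return Integer 0/1 labels (1 = toxic).
#' @export
classify_tox <- function(scores, threshold = 0.58) {
  if (any(scores < 0 | scores > 1, na.rm = TRUE)) {
    stopf("Tox-scores must lie in [0, 1]")
  }
  if (threshold < 0 || threshold > 1) stopf("threshold must lie in [0, 1]")
  as.integer(scores > threshold)
}

#' @export
print.tox_et <- function(x, ...) {
  cat(sprintf("extra-trees toxicity classifier: %d trees, k=%d of %d features\n",
              x$config$n_trees, x$config$k_features, x$n_features))
  cat(sprintf("  trained on %d non-toxic / %d toxic molecules\n",
              x$class_counts["non_toxic"], x$class_counts["toxic"]))
  if (!is.null(x$threshold)) {
    cat(sprintf("  embedded Tox-score threshold: %.2f\n", x$threshold))
  }
  invisible(x)
}

#' @export
summary.tox_et <- function(object, ...) {
  print(object)
  depths <- vapply(object$trees, function(t) {
    d <- integer(length(t$value))
    for (i in seq_along(t$value)) {
      if (!is.na(t$feature[i])) {
        d[t$left[i]] <- d[i] + 1L
        d[t$right[i]] <- d[i] + 1L
      }
    }
    max(d)
  }, integer(1))
  leaves <- vapply(object$trees, function(t) sum(is.na(t$feature)), integer(1))
  cat(sprintf("  tree depth      : median %d (max %d)\n",
              as.integer(stats::median(depths)), max(depths)))
  cat(sprintf("  leaves per tree : median %d\n", as.integer(stats::median(leaves))))
  invisible(object)
}
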