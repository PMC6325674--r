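# Deep Belief Network regression of the synthetic accessibility score.
#
# The network is a stack of RBMs pre-trained greedily (each layer learns to
# model the mean-field hidden activations of the layer below) followed by a
# linear regression head on the top hidden layer. Fine-tuning minimizes the
# mean squared error plus an L2 weight penalty by mini-batch gradient
# descent backpropagated through all layers (optionally head-only), with the
# same inverse-time learning-rate decay as pre-training. Predictions are
# deterministic mean-field forward passes clamped to the SAscore domain
# [1, 10].

#' Training configuration for the DBN regressor
#'
#' Defaults follow the standard settings for fingerprint-based SAscore
#' regression: initial learning rate 0.01, decay rate 1e-4 per update,
#' mini-batches of 100, 20 pre-training and 1000 fine-tuning epochs.
#'
#' @param lr0 Initial learning rate.
#' @param decay Inverse-time decay rate: `lr_t = lr0 / (1 + decay * t)`.
#' @param batch Mini-batch size.
#' @param pretrain_epochs CD epochs per RBM layer.
#' @param finetune_epochs Supervised fine-tuning epochs.
#' @param l2 L2 penalty on weights (never biases).
#' @param cd_steps Gibbs steps k of CD-k pre-training.
#' @param seed Integer seed; layer-wise pre-training, fine-tuning batch
#'   order and weight initialization all derive their streams from it.
#' @param finetune_layers If `TRUE` (default) fine-tuning backpropagates
#'   through all pre-trained layers; if `FALSE` only the regression head is
#'   updated.
#' @return A `dbn_control` list.
#' @export
dbn_control <- function(lr0 = 0.01, decay = 1e-4, batch = 100,
                        pretrain_epochs = 20, finetune_epochs = 1000,
                        l2 = 1e-4, cd_steps = 1, seed = 42,
                        finetune_layers = TRUE) {
  stopifnot(lr0 > 0, decay >= 0, batch >= 1, pretrain_epochs >= 0,
            finetune_epochs >= 0, l2 >= 0, cd_steps >= 1)
  out <- list(lr0 = lr0, decay = decay, batch = batch,
              pretrain_epochs = pretrain_epochs,
              finetune_epochs = finetune_epochs, l2 = l2,
              cd_steps = cd_steps, seed = seed,
              finetune_layers = finetune_layers)
  class(out) <- "dbn_control"
  out
}

#' Greedy layer-wise pre-training of a DBN stack
#'
#' Trains the first RBM on the (binary) data, then each subsequent RBM on
#' the mean-field hidden probabilities of the layer below. Layer `i` uses
#' the derived seed `derive_seed(seed, i)`, so any single layer's training
#' can be reproduced in isolation with [rbm_train()].
#'
#' @param x Binary 0/1 matrix of fingerprints (rows = molecules).
#' @param layer_sizes Integer vector, visible size first; must be strictly
#'   decreasing after the visible layer. Default `c(1024, 512, 128, 32)`.
#' @param control A [dbn_control()].
#' @return Object of class `dbn_stack`: list of `rbm` layers plus the size
#'   schedule.
#' @export
dbn_pretrain <- function(x, layer_sizes = c(1024, 512, 128, 32),
                         control = dbn_control()) {
  if (!is_binary_matrix(x)) stopf("bottom-layer training data must be a binary 0/1 matrix")
  if (length(layer_sizes) < 2L) stopf("layer_sizes needs a visible and at least one hidden layer")
  if (ncol(x) != layer_sizes[1]) {
    stopf("data width %d does not match visible layer size %d", ncol(x), layer_sizes[1])
  }
  if (any(diff(layer_sizes) >= 0)) stopf("layer sizes must be strictly decreasing")

  layers <- vector("list", length(layer_sizes) - 1L)
  act <- x
  for (i in seq_along(layers)) {
    layers[[i]] <- rbm_train(act, layer_sizes[i + 1L],
                             epochs = control$pretrain_epochs,
                             lr0 = control$lr0, decay = control$decay,
                             batch = control$batch, cd_steps = control$cd_steps,
                             l2 = control$l2, seed = derive_seed(control$seed, i))
    act <- rbm_hidden(layers[[i]], act)
  }
  out <- list(layers = layers, layer_sizes = layer_sizes, control = control)
  class(out) <- "dbn_stack"
  out
}

# Forward pass through the stack; returns the list of activations per layer
# (first element = input) and the head output (unclamped).
.dbn_forward <- function(params, x) {
  acts <- vector("list", length(params$W) + 1L)
  acts[[1L]] <- x
  for (i in seq_along(params$W)) {
    acts[[i + 1L]] <- sigmoid(sweep(acts[[i]] %*% params$W[[i]], 2, params$b[[i]], "+"))
  }
  yhat <- as.vector(acts[[length(acts)]] %*% params$head_w) + params$head_b
  list(acts = acts, yhat = yhat)
}

# Loss and analytic gradients of one batch: mean squared error plus
# l2 * sum of squared weights (layers + head, biases excluded).
.dbn_grads <- function(params, x, y, l2, layers_too = TRUE) {
  fw <- .dbn_forward(params, x)
  nb <- length(y)
  err <- fw$yhat - y
  loss <- mean(err^2) +
    l2 * (sum(vapply(params$W, function(w) sum(w^2), numeric(1))) +
            sum(params$head_w^2))

  d <- 2 * err / nb
  top <- fw$acts[[length(fw$acts)]]
  g <- list(head_w = as.vector(crossprod(top, d)) + 2 * l2 * params$head_w,
            head_b = sum(d),
            W = vector("list", length(params$W)),
            b = vector("list", length(params$W)))
  if (layers_too) {
    delta <- outer(d, params$head_w) * top * (1 - top)
    for (i in rev(seq_along(params$W))) {
      g$W[[i]] <- crossprod(fw$acts[[i]], delta) + 2 * l2 * params$W[[i]]
      g$b[[i]] <- colSums(delta)
      if (i > 1L) {
        a <- fw$acts[[i]]
        delta <- tcrossprod(delta, params$W[[i]]) * a * (1 - a)
      }
    }
  }
  list(loss = loss, grads = g)
}

#' Supervised fine-tuning of a pre-trained DBN
#'
#' Attaches a linear regression head (initialized to zero) to the top hidden
#' layer and minimizes mean squared error plus the L2 weight penalty by
#' mini-batch gradient descent, backpropagating through all layers unless
#' `control$finetune_layers` is `FALSE`. The learning-rate schedule
#' restarts: `lr_t = lr0 / (1 + decay * t)` over fine-tuning updates.
#'
#' @param stack A `dbn_stack` from [dbn_pretrain()].
#' @param x Binary fingerprint matrix.
#' @param y SAscore labels in `[1, 10]` aligned with `x`.
#' @param control A [dbn_control()]; defaults to the stack's own.
#' @return Object of class `sa_dbn` (see [sa_dbn()]).
#' @export
dbn_finetune <- function(stack, x, y, control = stack$control) {
  stopifnot(inherits(stack, "dbn_stack"))
  if (nrow(x) == 0L || length(y) == 0L) stopf("empty training set")
  if (nrow(x) != length(y)) stopf("x and y lengths differ")
  if (any(y < 1 | y > 10)) stopf("SAscore labels must lie in [1, 10]")

  params <- list(W = lapply(stack$layers, `[[`, "W"),
                 b = lapply(stack$layers, `[[`, "b_hid"),
                 head_w = numeric(utils::tail(stack$layer_sizes, 1)),
                 head_b = 0)
  n <- nrow(x)
  batch <- max(1L, min(control$batch, n))
  trace <- numeric(control$finetune_epochs)

  with_seed(derive_seed(control$seed, 1000L), {
    t_step <- 0
    for (ep in seq_len(control$finetune_epochs)) {
      ord <- sample.int(n)
      tot <- 0
      for (s in seq(1, n, by = batch)) {
        rows <- ord[s:min(s + batch - 1, n)]
        gr <- .dbn_grads(params, x[rows, , drop = FALSE], y[rows],
                         control$l2, control$finetune_layers)
        lr <- control$lr0 / (1 + control$decay * t_step)
        params$head_w <- params$head_w - lr * gr$grads$head_w
        params$head_b <- params$head_b - lr * gr$grads$head_b
        if (control$finetune_layers) {
          for (i in seq_along(params$W)) {
            params$W[[i]] <- params$W[[i]] - lr * gr$grads$W[[i]]
            params$b[[i]] <- params$b[[i]] - lr * gr$grads$b[[i]]
          }
        }
        t_step <- t_step + 1
        tot <- tot + gr$loss * length(rows)
      }
      trace[ep] <- tot / n
    }
  })

  model <- list(W = params$W, b = params$b,
                head_w = params$head_w, head_b = params$head_b,
                layer_sizes = stack$layer_sizes, control = control,
                pretrain_recon = lapply(stack$layers, `[[`, "recon_error"),
                loss_trace = trace, scheme = attr(x, "scheme"))
  class(model) <- "sa_dbn"
  model
}

#' Fit a DBN synthetic-accessibility regressor
#'
#' The one-call interface: greedy RBM pre-training ([dbn_pretrain()])
#' followed by supervised fine-tuning ([dbn_finetune()]). The SAscore runs
#' from 1 (easy to synthesize) to 10 (very hard); predictions are clamped to
#' that range.
#'
#' @param x Binary 0/1 fingerprint matrix (rows = molecules).
#' @param y Numeric SAscore labels in `[1, 10]`.
#' @param layer_sizes Size schedule, visible layer first; default
#'   `c(1024, 512, 128, 32)`.
#' @param control A [dbn_control()].
#' @return Object of class `sa_dbn` with elements `W`, `b` (per layer),
#'   `head_w`, `head_b`, `layer_sizes`, `control`, `pretrain_recon`,
#'   `loss_trace` and the fingerprint `scheme` the model was trained on.
#' @examples
#' \donttest{
#' d <- gen_sascore_data(n = 300, n_bits = 64, noise_sd = 0.3, seed = 7)
#' fit <- sa_dbn(d$x, d$y, layer_sizes = c(64, 16, 8),
#'               control = dbn_control(pretrain_epochs = 2,
#'                                     finetune_epochs = 30, seed = 7))
#' head(predict(fit, d$x))
#' }
#' @export
sa_dbn <- function(x, y, layer_sizes = c(1024, 512, 128, 32),
                   control = dbn_control()) {
  stack <- dbn_pretrain(x, layer_sizes, control)
  dbn_finetune(stack, x, y, control)
}

#' Predict SAscores from fingerprints
#'
#' Deterministic mean-field forward pass through the fitted network; the
#' head output is clamped to `[1, 10]`.
#'
#' @param object An `sa_dbn` model.
#' @param newdata Fingerprint matrix with the model's visible width.
#' @param ... Unused.
#' @return Numeric vector of SAscores in `[1, 10]`.
#' @export
predict.sa_dbn <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != object$layer_sizes[1]) {
    stopf("fingerprint width %d does not match model visible size %d",
          ncol(newdata), object$layer_sizes[1])
  }
  fw <- .dbn_forward(list(W = object$W, b = object$b,
                          head_w = object$head_w, head_b = object$head_b),
                     newdata)
  clamp(fw$yhat, 1, 10)
}

#' @export
print.sa_dbn <- function(x, ...) {
  cat(sprintf("DBN SAscore regressor: layers [%s], %d pre-training + %d fine-tuning epoch(s)\n",
              paste(x$layer_sizes, collapse = ", "),
              x$control$pretrain_epochs, x$control$finetune_epochs))
  if (length(x$loss_trace) > 0) {
    cat(sprintf("  final training loss (MSE + L2): %.4f\n", utils::tail(x$loss_trace, 1)))
  }
  invisible(x)
}

#' @export
summary.sa_dbn <- function(object, ...) {
  cat("DBN synthetic-accessibility regressor\n")
  cat(sprintf("  layer sizes     : %s\n", paste(object$layer_sizes, collapse = " -> ")))
  cat(sprintf("  fingerprints    : %s\n", object$scheme %||% "unspecified"))
  cat(sprintf("  lr0 / decay     : %g / %g\n", object$control$lr0, object$control$decay))
  cat(sprintf("  batch / L2      : %d / %g\n", object$control$batch, object$control$l2))
  cat(sprintf("  epochs          : %d pre-train, %d fine-tune\n",
              object$control$pretrain_epochs, object$control$finetune_epochs))
  for (i in seq_along(object$pretrain_recon)) {
    re <- object$pretrain_recon[[i]]
    if (length(re) > 0) {
      cat(sprintf("  layer %d recon   : %.4g -> %.4g\n", i, re[1], utils::tail(re, 1)))
    }
  }
  invisible(object)
}

#' @export
plot.sa_dbn <- function(x, ...) {
  if (length(x$loss_trace) == 0) {
    message("no fine-tuning trace to plot")
    return(invisible(x))
  }
  graphics::plot(seq_along(x$loss_trace), x$loss_trace, type = "l",
                 xlab = "fine-tuning epoch", ylab = "training loss",
                 main = "DBN fine-tuning", ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
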