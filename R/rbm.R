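# Restricted Boltzmann Machine trained by contrastive divergence.
#
# An RBM is a two-layer energy model (visible units v, hidden units h, no
# intra-layer connections) with joint energy
#   E(v, h) = -v' W h - b_vis' v - b_hid' h.
# CD-k approximates the likelihood gradient by k steps of block Gibbs
# sampling started at the data: the positive statistics use the data-driven
# hidden probabilities, the negative statistics the reconstruction after k
# alternations. Hidden states are sampled binary during the chain; visible
# reconstructions use mean-field probabilities, which keeps the estimator's
# variance low for the short chains used here.

#' Train one RBM layer by contrastive divergence
#'
#' Mini-batch CD-k with inverse-time learning-rate decay
#' `lr_t = lr0 / (1 + decay * t)` (t counts parameter updates) and an L2
#' penalty on the weights (not the biases). Weights start at N(0, 0.01^2),
#' biases at zero. Rows are shuffled every epoch; everything is
#' deterministic given `seed`.
#'
#' @param v Numeric matrix of visible data in `[0, 1]` (binary for a bottom
#'   layer, activation probabilities for stacked layers).
#' @param n_hidden Number of hidden units.
#' @param epochs Training epochs; 0 returns the untouched initialization.
#' @param lr0 Initial learning rate.
#' @param decay Inverse-time decay rate per update step.
#' @param batch Mini-batch size (clipped to the number of rows).
#' @param cd_steps Gibbs alternations k in CD-k.
#' @param l2 L2 penalty strength on weights (gradient `2 * l2 * W`).
#' @param seed Integer seed.
#' @return Object of class `rbm`: `W` (visible x hidden), `b_vis`, `b_hid`,
#'   `recon_error` (per-epoch mean squared reconstruction error) and the
#'   training settings.
#' @export
rbm_train <- function(v, n_hidden, epochs = 20, lr0 = 0.01, decay = 1e-4,
                      batch = 100, cd_steps = 1, l2 = 1e-4, seed = 42) {
  stopifnot(is.matrix(v), n_hidden >= 1)
  if (any(v < 0 | v > 1)) stopf("RBM visible data must lie in [0, 1]")
  n <- nrow(v)
  nv <- ncol(v)
  batch <- max(1L, min(batch, n))

  with_seed(seed, {
    W <- matrix(stats::rnorm(nv * n_hidden, sd = 0.01), nv, n_hidden)
    b_vis <- numeric(nv)
    b_hid <- numeric(n_hidden)
    recon <- numeric(epochs)
    t_step <- 0

    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = batch)
      sse <- 0
      for (s in starts) {
        rows <- ord[s:min(s + batch - 1, n)]
        vb <- v[rows, , drop = FALSE]
        nb <- nrow(vb)

        h0 <- sigmoid(sweep(vb %*% W, 2, b_hid, "+"))
        hk <- h0
        for (step in seq_len(cd_steps)) {
          hs <- (matrix(stats::runif(nb * n_hidden), nb) < hk) * 1
          vk <- sigmoid(sweep(tcrossprod(hs, W), 2, b_vis, "+"))
          hk <- sigmoid(sweep(vk %*% W, 2, b_hid, "+"))
        }

        lr <- lr0 / (1 + decay * t_step)
        W <- W + lr * ((crossprod(vb, h0) - crossprod(vk, hk)) / nb - 2 * l2 * W)
        b_vis <- b_vis + lr * colMeans(vb - vk)
        b_hid <- b_hid + lr * colMeans(h0 - hk)
        t_step <- t_step + 1
        sse <- sse + sum((vb - vk)^2)
      }
      recon[ep] <- sse / (n * nv)
    }

    out <- list(W = W, b_vis = b_vis, b_hid = b_hid, recon_error = recon,
                n_visible = nv, n_hidden = n_hidden,
                config = list(epochs = epochs, lr0 = lr0, decay = decay,
                              batch = batch, cd_steps = cd_steps, l2 = l2,
                              seed = seed))
    class(out) <- "rbm"
    out
  })
}

#' Hidden activation probabilities of an RBM
#'
#' Deterministic mean-field forward pass `sigmoid(v W + b_hid)`; used both
#' for prediction and as the training input of the next layer when stacking.
#'
#' @param rbm An `rbm` object.
#' @param v Visible data matrix.
#' @return Matrix of hidden probabilities in `(0, 1)`.
#' @export
rbm_hidden <- function(rbm, v) {
  stopifnot(inherits(rbm, "rbm"))
  if (ncol(v) != rbm$n_visible) {
    stopf("visible width %d does not match RBM (%d)", ncol(v), rbm$n_visible)
  }
  sigmoid(sweep(v %*% rbm$W, 2, rbm$b_hid, "+"))
}

#' @export
print.rbm <- function(x, ...) {
  cat(sprintf("RBM %d x %d, %d CD-%d epoch(s)", x$n_visible, x$n_hidden,
              x$config$epochs, x$config$cd_steps))
  if (length(x$recon_error) > 0) {
    cat(sprintf(", final reconstruction error %.4g", utils::tail(x$recon_error, 1)))
  }
  cat("\n")
  invisible(x)
}
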