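# Synthetic labeled fingerprint generators.
#
# Both generators produce data with the statistical structure the models
# assume — separable class-specific bit patterns for toxicity, a skewed
# SAscore distribution whose signal lives in the set-bit count — so every
# model, resampling and evaluation routine is testable without any external
# compound database. The generators are pure functions of their arguments
# (seed included).

#' Generate a synthetic binary-toxicity fingerprint set
#'
#' Produces exactly `n_per_class` non-toxic (label 0) and `n_per_class`
#' toxic (label 1) records. Bits `1..n_informative` carry the class signal:
#' they equal the class label and are then flipped independently with
#' probability `flip_noise` (0 = perfectly separable, 0.5 = no information).
#' All remaining bits are background noise, set independently with
#' probability `background_p` in both classes.
#'
#' Defaults emulate a moderately hard screening problem: a handful of
#' informative substructure bits against a sparse background, with enough
#' flip noise that a good classifier reaches an AUC near — not at — 1.
#'
#' @param n_per_class Records per class.
#' @param n_bits Fingerprint length.
#' @param n_informative Number of class-signature bits (first bits).
#' @param background_p Set probability of non-informative bits.
#' @param flip_noise Flip probability of informative bits.
#' @param seed Integer seed.
#' @return List with `x` (0/1 matrix, rows `synth1..n`), `y` (0/1 labels,
#'   1 = toxic), `ids` and `informative_bits` (the signal bit indices).
#' @export
gen_tox_data <- function(n_per_class = 200, n_bits = 1024, n_informative = 8,
                         background_p = 0.1, flip_noise = 0.2, seed = 42) {
  stopifnot(n_per_class >= 1, n_bits >= 1, n_informative >= 0,
            n_informative <= n_bits,
            background_p >= 0, background_p <= 1,
            flip_noise >= 0, flip_noise <= 1)
  n <- 2L * n_per_class
  y <- rep(c(0L, 1L), each = n_per_class)
  with_seed(seed, {
    x <- matrix((stats::runif(n * n_bits) < background_p) * 1L, n, n_bits)
    if (n_informative > 0L) {
      sig <- matrix(rep(y, n_informative), n, n_informative)
      flips <- matrix((stats::runif(n * n_informative) < flip_noise) * 1L,
                      n, n_informative)
      x[, seq_len(n_informative)] <- (sig + flips) %% 2L
    }
    ids <- paste0("synth", seq_len(n))
    rownames(x) <- ids
    list(x = x, y = y, ids = ids,
         informative_bits = seq_len(n_informative))
  })
}

#' Default SAscore bin weights
#'
#' Target probability mass per unit score bin `[1,2), [2,3), ..., [9,10]`,
#' mimicking the strongly skewed SAscore distribution of screening
#' collections: 28.3% of molecules fall in `[2,3)`, the bulk lies below 5
#' and scores above 7 are rare.
#'
#' @return Numeric vector of 9 weights summing to 1.
#' @export
default_sa_bin_weights <- function() {
  c(0.060, 0.283, 0.250, 0.170, 0.100, 0.060, 0.040, 0.025, 0.012)
}

#' Generate a synthetic SAscore-labeled fingerprint set
#'
#' Draws a unit score bin from `bin_weights`, a score uniformly inside the
#' bin, and builds a fingerprint whose set-bit count is the affine map
#' `n_set = round(n_bits/8 + n_bits/16 * score)` (invertible, range safely
#' inside `[0, n_bits]`); set-bit positions are uniform. The recorded label
#' is the score implied by the realized bit count plus Gaussian noise of sd
#' `noise_sd`, clamped to `[1, 10]` — so at `noise_sd = 0` the label is
#' exactly recoverable from the set-bit count via the inverse map.
#'
#' @param n Number of records.
#' @param n_bits Fingerprint length.
#' @param noise_sd Gaussian label noise, in score units.
#' @param bin_weights Probability per unit bin `[1,2) .. [9,10]`; must sum
#'   to 1. Default [default_sa_bin_weights()].
#' @param seed Integer seed.
#' @return List with `x` (0/1 matrix), `y` (noisy labels in `[1, 10]`),
#'   `score` (noise-free quantized scores), `ids` and `map`
#'   (`c(alpha, beta)` of the affine bit-count map).
#' @export
gen_sascore_data <- function(n = 2000, n_bits = 1024, noise_sd = 0.5,
                             bin_weights = default_sa_bin_weights(),
                             seed = 42) {
  stopifnot(n >= 1, n_bits >= 16, noise_sd >= 0, length(bin_weights) == 9)
  if (abs(sum(bin_weights) - 1) > 1e-9) stopf("bin_weights must sum to 1")
  alpha <- n_bits / 8
  beta <- n_bits / 16
  with_seed(seed, {
    bin <- sample.int(9L, n, replace = TRUE, prob = bin_weights)
    s_cont <- bin + stats::runif(n)
    n_set <- as.integer(round(alpha + beta * s_cont))
    score <- (n_set - alpha) / beta
    y <- clamp(score + stats::rnorm(n, sd = noise_sd), 1, 10)

    x <- matrix(0L, n, n_bits)
    pos_i <- rep.int(seq_len(n), n_set)
    pos_j <- unlist(lapply(n_set, function(k) sample.int(n_bits, k)),
                    use.names = FALSE)
    x[cbind(pos_i, pos_j)] <- 1L
    ids <- paste0("synth", seq_len(n))
    rownames(x) <- ids
    list(x = x, y = y, score = score, ids = ids, map = c(alpha = alpha, beta = beta))
  })
}
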