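# Internal helpers shared across modules.

#' @keywords internal
sigmoid <- function(x) 1 / (1 + exp(-x))

#' @keywords internal
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Evaluate `expr` under a fixed, fully specified RNG state, restoring the
# caller's state afterwards. All stochastic code in the package goes through
# this so results are reproducible across sessions and platforms.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

# Deterministic sub-seed for independent random streams (layer-wise
# pre-training, fine-tuning, fold assignment) derived from one user seed.
#' @keywords internal
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(stream) * 10007) %% 2147483629) + 1L
}

#' @keywords internal
is_binary_matrix <- function(x) {
  is.matrix(x) && is.numeric(x) && all(x %in% c(0, 1))
}

#' @keywords internal
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
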