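# Bin-wise over/under-sampling of skewed SAscore label distributions.
#
# Reference SAscore values concentrate heavily in the easy-to-synthesize
# range (roughly a quarter of typical screening collections score between 2
# and 3) while hard-to-make molecules above 6 are rare. Training a regressor
# on the raw distribution starves the tails, so under-represented score bins
# are duplicated and the over-represented middle is uniformly subsampled
# before training.

#' Construct a resampling plan
#'
#' A plan is a table of disjoint, ordered score bins jointly covering
#' `[1, 10]`; each bin carries an action: `"oversample"` (duplicate every
#' record `value` times), `"undersample"` (keep at most `value` records,
#' drawn uniformly without replacement) or `"unchanged"`. Bins are half-open
#' `[lower, upper)` except the final bin, which is closed.
#'
#' @param lower,upper Numeric bin edges.
#' @param action Character vector: `"oversample"`, `"undersample"` or
#'   `"unchanged"`.
#' @param value Positive integer ratio (oversample) or cap (undersample);
#'   `NA` for unchanged bins.
#' @return A `resample_plan` data frame.
#' @export
resample_plan <- function(lower, upper, action, value) {
  stopifnot(length(lower) == length(upper),
            length(action) == length(lower),
            length(value) == length(lower))
  if (any(!action %in% c("oversample", "undersample", "unchanged"))) {
    stopf("unknown resampling action")
  }
  if (any(upper <= lower)) stopf("each bin must have lower < upper")
  o <- order(lower)
  lower <- lower[o]; upper <- upper[o]; action <- action[o]; value <- value[o]
  if (lower[1] != 1 || upper[length(upper)] != 10 ||
      any(abs(upper[-length(upper)] - lower[-1]) > 1e-12)) {
    stopf("bins must be disjoint and jointly cover [1, 10]")
  }
  need <- action != "unchanged"
  if (any(need & (is.na(value) | value < 1 | value != round(value)))) {
    stopf("oversample ratios and undersample caps must be positive integers")
  }
  plan <- data.frame(lower = lower, upper = upper, action = action,
                     value = as.numeric(value), stringsAsFactors = FALSE)
  class(plan) <- c("resample_plan", "data.frame")
  plan
}

#' Default SAscore resampling plan
#'
#' The standard balancing scheme for SAscore-labeled screening collections:
#' scores in `[1,2)` are duplicated twice, the heavily populated `[2,5)`
#' range is uniformly undersampled to 90,000 records, `[5,6)` passes through
#' unchanged, and the rare high bins `[6,7)`, `[7,8)`, `[8,9)` and `[9,10]`
#' are oversampled 2-, 5-, 20- and 100-fold.
#'
#' @param undersample_cap Cap for the `[2,5)` bin; the default 90,000 suits
#'   library-scale data and can be lowered for small studies.
#' @return A `resample_plan`.
#' @export
default_sa_plan <- function(undersample_cap = 90000) {
  resample_plan(
    lower  = c(1, 2, 5, 6, 7, 8, 9),
    upper  = c(2, 5, 6, 7, 8, 9, 10),
    action = c("oversample", "undersample", "unchanged",
               "oversample", "oversample", "oversample", "oversample"),
    value  = c(2, undersample_cap, NA, 2, 5, 20, 100)
  )
}

#' @export
print.resample_plan <- function(x, ...) {
  cat("SAscore resampling plan:\n")
  for (i in seq_len(nrow(x))) {
    close_br <- if (i == nrow(x)) "]" else ")"
    what <- switch(x$action[i],
                   oversample  = sprintf("oversample x%g", x$value[i]),
                   undersample = sprintf("undersample to %g", x$value[i]),
                   unchanged   = "unchanged")
    cat(sprintf("  [%g, %g%s  %s\n", x$lower[i], x$upper[i], close_br, what))
  }
  invisible(x)
}

# Bin index of each label under the plan; final bin closed above.
.plan_bin <- function(y, plan) {
  b <- rep(NA_integer_, length(y))
  for (i in seq_len(nrow(plan))) {
    hi_ok <- if (i == nrow(plan)) y <= plan$upper[i] else y < plan$upper[i]
    b[y >= plan$lower[i] & hi_ok] <- i
  }
  b
}

#' Resample an SAscore-labeled fingerprint set
#'
#' Applies a [resample_plan()]: every record in an oversampled bin appears
#' exactly `ratio` times (whole-copy duplication, no jitter), undersampled
#' bins keep `min(cap, size)` records drawn uniformly without replacement,
#' unchanged bins pass through. The result is shuffled; everything is
#' deterministic given `seed`.
#'
#' @param x Fingerprint matrix (rows = molecules).
#' @param y Numeric SAscore labels in `[1, 10]`, aligned with `x`.
#' @param plan A `resample_plan`; defaults to [default_sa_plan()].
#' @param seed Integer seed controlling subsampling and the final shuffle.
#' @return List with the resampled `x`, `y` and `idx`, the original row
#'   index of every output record.
#' @export
resample_sascore <- function(x, y, plan = default_sa_plan(), seed = 42) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  bad <- which(y < 1 | y > 10 | is.na(y))
  if (length(bad) > 0L) {
    nm <- if (!is.null(rownames(x))) rownames(x)[bad] else as.character(bad)
    stopf("SAscore outside [1, 10] for record(s): %s",
          paste(utils::head(nm, 5), collapse = ", "))
  }
  bins <- .plan_bin(y, plan)
  with_seed(seed, {
    sel <- integer(0)
    for (i in seq_len(nrow(plan))) {
      idx <- which(bins == i)
      m <- length(idx)
      if (m == 0L) next
      sel <- c(sel, switch(plan$action[i],
        oversample  = rep(idx, times = plan$value[i]),
        undersample = if (m <= plan$value[i]) idx else sort(sample(idx, plan$value[i])),
        unchanged   = idx))
    }
    sel <- sel[sample.int(length(sel))]
    list(x = x[sel, , drop = FALSE], y = y[sel], idx = sel)
  })
}
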