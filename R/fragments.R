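# Chemical-fragment composition comparison between a non-toxic and a toxic
# molecule set.
#
# Input is a list of fragment occurrences (canonical SMILES keys) per
# molecule set, typically produced by an external fragmentation tool. Each
# set is summarized as a frequency table (occurrences of a fragment divided
# by total fragment occurrences in the set); the two tables are aligned on
# the union of keys and compared by Pearson correlation and a major-axis
# regression line. Fragments below the line are relatively enriched in the
# first (non-toxic) set, fragments above it in the second (toxic) set. The
# major axis (first principal component of the paired frequencies) is used
# rather than an ordinary regression of y on x because neither set is a
# predictor of the other: the fit — and every signed residual — is then
# exactly antisymmetric under swapping the two sets.

#' Read a fragment occurrence file
#'
#' Tab-separated, one row per fragment occurrence:
#' `molecule_id<TAB>fragment_smiles`. Lines starting with `#` are ignored.
#'
#' @param path Path to the file.
#' @return Data frame with columns `id` and `fragment`.
#' @export
read_fragment_list <- function(path) {
  if (!file.exists(path)) stopf("cannot read fragment list '%s': no such file", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          col.names = c("id", "fragment"),
                          stringsAsFactors = FALSE, quote = "")
  df
}

#' Fragment frequency table
#'
#' The frequency of a fragment is its number of occurrences divided by the
#' total number of fragment occurrences in the set (a molecule containing a
#' fragment twice contributes two occurrences).
#'
#' @param fragments Character vector of fragment keys, one element per
#'   occurrence (e.g. the `fragment` column of [read_fragment_list()]).
#' @return Data frame with columns `fragment`, `count`, `freq`, sorted by
#'   decreasing frequency, with attribute `total_occurrences`.
#' @export
fragment_frequencies <- function(fragments) {
  if (is.data.frame(fragments)) fragments <- fragments$fragment
  fragments <- as.character(fragments)
  if (length(fragments) == 0L) stopf("no fragment occurrences")
  tab <- table(fragments)
  out <- data.frame(fragment = names(tab), count = as.integer(tab),
                    freq = as.numeric(tab) / sum(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$freq, out$fragment), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total_occurrences") <- sum(tab)
  out
}

# Major-axis line through paired points: direction = leading eigenvector of
# the 2x2 covariance matrix, oriented with a positive x-component.
.major_axis <- function(xf, yf) {
  cv <- stats::cov(cbind(xf, yf))
  e <- eigen(cv, symmetric = TRUE)
  u <- e$vectors[, 1]
  if (u[1] < 0) u <- -u
  if (u[1] == 0) stopf("degenerate fragment frequencies: vertical major axis")
  slope <- u[2] / u[1]
  intercept <- mean(yf) - slope * mean(xf)
  list(u = u, slope = slope, intercept = intercept)
}

#' Compare fragment composition of non-toxic and toxic molecule sets
#'
#' Aligns the two frequency tables on the union of fragment keys (absent
#' fragments get frequency 0), computes the Pearson correlation of the
#' aligned frequencies, fits a major-axis line, and ranks fragments by their
#' signed perpendicular residual: negative (below the line) = enriched in
#' the non-toxic set, positive (above) = enriched in the toxic set.
#'
#' @param non_toxic,toxic Frequency tables from [fragment_frequencies()]
#'   (or raw occurrence vectors, converted automatically).
#' @return Object of class `fragment_comparison`: `table` (fragment,
#'   `freq_non_toxic`, `freq_toxic`, `residual`, `rank`; rank 1 = most
#'   toxic-enriched), `pcc`, `slope`, `intercept`, `n_fragments`.
#' @export
fragment_compare <- function(non_toxic, toxic) {
  if (!is.data.frame(non_toxic) || is.null(non_toxic$freq)) {
    non_toxic <- fragment_frequencies(non_toxic)
  }
  if (!is.data.frame(toxic) || is.null(toxic$freq)) {
    toxic <- fragment_frequencies(toxic)
  }
  keys <- union(non_toxic$fragment, toxic$fragment)
  if (length(keys) < 3L) {
    stopf("fragment comparison needs at least 3 distinct fragments, got %d",
          length(keys))
  }
  xf <- non_toxic$freq[match(keys, non_toxic$fragment)]
  yf <- toxic$freq[match(keys, toxic$fragment)]
  xf[is.na(xf)] <- 0
  yf[is.na(yf)] <- 0

  r <- pcc(yf, xf)
  ax <- .major_axis(xf, yf)
  # signed perpendicular distance; positive = above the line (toxic side)
  resid <- (yf - mean(yf)) * ax$u[1] - (xf - mean(xf)) * ax$u[2]

  tab <- data.frame(fragment = keys, freq_non_toxic = xf, freq_toxic = yf,
                    residual = resid, stringsAsFactors = FALSE)
  tab <- tab[order(-tab$residual, tab$fragment), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL

  out <- list(table = tab, pcc = r, slope = ax$slope, intercept = ax$intercept,
              n_fragments = length(keys))
  class(out) <- "fragment_comparison"
  out
}

#' @export
print.fragment_comparison <- function(x, n = 5, ...) {
  cat(sprintf("fragment composition comparison: %d fragments, PCC = %.3f\n",
              x$n_fragments, x$pcc))
  cat(sprintf("  major-axis line: toxic = %.3f + %.3f * non-toxic\n",
              x$intercept, x$slope))
  n <- min(n, nrow(x$table))
  cat("  most toxic-enriched:\n")
  top <- utils::head(x$table, n)
  for (i in seq_len(n)) {
    cat(sprintf("    %-20s %.4f vs %.4f\n", top$fragment[i],
                top$freq_non_toxic[i], top$freq_toxic[i]))
  }
  cat("  most non-toxic-enriched:\n")
  bot <- utils::tail(x$table, n)
  for (i in rev(seq_len(n))) {
    cat(sprintf("    %-20s %.4f vs %.4f\n", bot$fragment[i],
                bot$freq_non_toxic[i], bot$freq_toxic[i]))
  }
  invisible(x)
}

#' @export
plot.fragment_comparison <- function(x, label_n = 3, ...) {
  tab <- x$table
  graphics::plot(tab$freq_non_toxic, tab$freq_toxic,
                 xlab = "frequency in non-toxic set",
                 ylab = "frequency in toxic set",
                 main = sprintf("fragment composition (PCC = %.2f)", x$pcc), ...)
  graphics::abline(x$intercept, x$slope, lty = 2)
  if (label_n > 0 && nrow(tab) > 2 * label_n) {
    ext <- rbind(utils::head(tab, label_n), utils::tail(tab, label_n))
    graphics::text(ext$freq_non_toxic, ext$freq_toxic, ext$fragment,
                   pos = 3, cex = 0.7)
  }
  invisible(x)
}
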