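# Independent oracles and small fixture builders used across test files.
# Every oracle is a literal, definition-level recomputation, kept free of
# the package code paths it checks.

# Brute-force confusion tally (positive = non-toxic = 0).
oracle_confusion <- function(truth, pred) {
  tp <- 0; tn <- 0; fp <- 0; fn <- 0
  for (i in seq_along(truth)) {
    if (truth[i] == 0 && pred[i] == 0) tp <- tp + 1
    if (truth[i] == 1 && pred[i] == 1) tn <- tn + 1
    if (truth[i] == 1 && pred[i] == 0) fp <- fp + 1
    if (truth[i] == 0 && pred[i] == 1) fn <- fn + 1
  }
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

oracle_acc <- function(k) (k["TP"] + k["TN"]) / sum(k)
oracle_tpr <- function(k) unname(k["TP"] / (k["TP"] + k["FN"]))
oracle_fpr <- function(k) unname(k["FP"] / (k["FP"] + k["TN"]))
oracle_mcc <- function(k) {
  k <- as.numeric(k)  # TP TN FP FN
  den <- sqrt((k[1] + k[3]) * (k[1] + k[4]) * (k[2] + k[3]) * (k[2] + k[4]))
  if (den == 0) return(0)
  (k[2] * k[1] - k[3] * k[4]) / den
}

oracle_mse <- function(yhat, y) sum((yhat - y)^2) / length(y)
oracle_pcc <- function(yhat, y) {
  cv <- sum((yhat - mean(yhat)) * (y - mean(y))) / (length(y) - 1)
  cv / (sqrt(sum((yhat - mean(yhat))^2) / (length(y) - 1)) *
          sqrt(sum((y - mean(y))^2) / (length(y) - 1)))
}

# Mann-Whitney concordance: P(score_nontoxic < score_toxic), ties = 1/2,
# over all (non-toxic, toxic) pairs.
oracle_auc <- function(scores, truth) {
  s_pos <- scores[truth == 0]
  s_neg <- scores[truth == 1]
  tot <- 0
  for (a in s_pos) for (b in s_neg) {
    tot <- tot + if (a < b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(s_pos) * length(s_neg))
}

# Exhaustive MCC sweep over a fixed threshold grid.
oracle_best_threshold <- function(scores, truth, grid) {
  best_t <- NA
  best_m <- -Inf
  for (t in grid) {
    pred <- as.integer(scores > t)
    m <- oracle_mcc(oracle_confusion(truth, pred))
    if (m > best_m + 1e-15) {
      best_m <- m
      best_t <- t
    }
  }
  list(threshold = best_t, mcc = best_m)
}

# Literal greedy redundancy scan using pairwise tanimoto().
oracle_greedy_filter <- function(x, threshold) {
  kept <- integer(0)
  for (i in seq_len(nrow(x))) {
    ok <- TRUE
    for (j in kept) {
      if (tanimoto(x[i, ], x[j, ]) >= threshold) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  kept
}

random_fps <- function(n, n_bits, p = 0.3, seed = 1) {
  set.seed(seed)
  matrix(rbinom(n * n_bits, 1, p), n, n_bits)
}

random_confusion <- function(seed, max_n = 50) {
  set.seed(seed)
  as.list(setNames(rpois(4, lambda = sample(1:max_n, 1)), c("TP", "TN", "FP", "FN")))
}

write_smi <- function(lines) {
  f <- tempfile(fileext = ".smi")
  writeLines(lines, f)
  f
}

# Aromatic / kekulized spellings of the same 20 molecules, for the
# fingerprint canonical-equivalence check.
smiles_pairs <- function() {
  data.frame(
    aromatic = c(
      "c1ccccc1", "Cc1ccccc1", "c1ccncc1", "c1ccoc1", "c1ccsc1",
      "Oc1ccccc1", "Nc1ccccc1", "c1ccc2ccccc2c1", "C=Cc1ccccc1",
      "O=Cc1ccccc1", "O=[N+]([O-])c1ccccc1", "Clc1ccccc1",
      "c1cc[nH]c1", "c1c[nH]cn1", "COc1ccccc1", "OC(=O)c1ccccc1",
      "Cc1ccc(C)cc1", "c1ccc2ncccc2c1", "c1cncnc1", "Cn1ccnc1"
    ),
    kekulized = c(
      "C1=CC=CC=C1", "CC1=CC=CC=C1", "C1=CC=NC=C1", "C1=CC=CO1", "C1=CC=CS1",
      "OC1=CC=CC=C1", "NC1=CC=CC=C1", "C1=CC=C2C=CC=CC2=C1", "C=CC1=CC=CC=C1",
      "O=CC1=CC=CC=C1", "O=[N+]([O-])C1=CC=CC=C1", "ClC1=CC=CC=C1",
      "C1=CC=CN1", "C1=CNC=N1", "COC1=CC=CC=C1", "OC(=O)C1=CC=CC=C1",
      "CC1=CC=C(C)C=C1", "C1=CC=C2N=CC=CC2=C1", "C1=CN=CN=C1", "CN1C=CN=C1"
    ),
    stringsAsFactors = FALSE
  )
}
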