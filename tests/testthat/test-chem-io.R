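# Molecule input, fingerprints and curation filters.

test_that("read_smiles_file parses ids, comments and auto-names", {
  f <- write_smi(c("# header comment", "c1ccccc1 benzene", "", "CCO ethanol", "CCN"))
  rec <- read_smiles_file(f)
  expect_equal(rec$id, c("benzene", "ethanol", "mol5"))
  expect_equal(rec$smiles[1], "c1ccccc1")
})

test_that("read_smiles_file skips unparseable lines and reports the count", {
  f <- write_smi(c("c1ccccc1 a", "xx((( bad", "CCO b"))
  expect_message(rec <- read_smiles_file(f), "skipped 1")
  expect_equal(rec$id, c("a", "b"))
})

test_that("read_smiles_file rejects empty or all-invalid input", {
  expect_error(read_smiles_file(write_smi(character(0))), "empty")
  expect_error(read_smiles_file(write_smi("# only a comment")), "empty")
  expect_error(suppressMessages(read_smiles_file(write_smi("xx((( bad"))),
               "no valid molecules")
  expect_error(read_smiles_file(tempfile()), "no such file")
})

test_that("fingerprints are 1024-bit, non-empty and deterministic", {
  fp <- compute_fingerprints(c(benzene = "c1ccccc1", ethanol = "CCO"))
  expect_identical(dim(fp), c(2L, 1024L))
  expect_true(all(rowSums(fp) >= 1))
  expect_true(all(fp %in% 0:1))
  expect_identical(rownames(fp), c("benzene", "ethanol"))
  fp2 <- compute_fingerprints(c(benzene = "c1ccccc1", ethanol = "CCO"))
  expect_identical(unclass(fp), unclass(fp2))
})

test_that("fingerprints are invariant to SMILES re-spelling (20 pairs)", {
  pairs <- smiles_pairs()
  # oracle: the chemistry backend canonicalizes both spellings identically
  cansmi <- function(s) {
    ChemmineOB::forEachMol("SMILES", s,
                           function(m) ChemmineOB::prop_OB(m)$cansmiNS)[[1]]
  }
  expect_equal(vapply(pairs$aromatic, cansmi, character(1), USE.NAMES = FALSE),
               vapply(pairs$kekulized, cansmi, character(1), USE.NAMES = FALSE))
  fa <- compute_fingerprints(setNames(pairs$aromatic, paste0("m", 1:20)))
  fk <- compute_fingerprints(setNames(pairs$kekulized, paste0("m", 1:20)))
  expect_identical(unclass(fa), unclass(fk))
})

test_that("unparseable SMILES in fingerprinting names the record", {
  expect_error(compute_fingerprints(c(ok = "CCO", broken = "not_a_smiles")),
               "broken")
})

test_that("tanimoto matches set arithmetic and its conventions", {
  a <- integer(1024); a[1:5] <- 1L
  expect_equal(tanimoto(a, a), 1.0)
  b <- integer(1024); b[c(1, 2)] <- 1L
  d <- integer(1024); d[c(3, 4)] <- 1L
  expect_equal(tanimoto(b, d), 0.0)
  e <- integer(1024); e[1:3] <- 1L
  f <- integer(1024); f[2:4] <- 1L
  expect_equal(tanimoto(e, f), 0.5)           # |int|=2, |union|=4
  expect_equal(tanimoto(integer(8), integer(8)), 1.0)  # all-zero convention
  expect_error(tanimoto(integer(8), integer(9)), "mismatch")
})

test_that("tanimoto is symmetric and bounded on random fingerprints", {
  x <- random_fps(20, 64, seed = 3)
  for (i in 1:10) {
    s <- tanimoto(x[2 * i - 1, ], x[2 * i, ])
    expect_identical(s, tanimoto(x[2 * i, ], x[2 * i - 1, ]))
    expect_gte(s, 0); expect_lte(s, 1)
  }
})

test_that("weight filter keeps [100, 600] Da and preserves order", {
  rec <- data.frame(id = c("water", "caffeine"),
                    smiles = c("O", "CN1C=NC2=C1C(=O)N(C(=O)N2C)C"),
                    stringsAsFactors = FALSE)
  out <- filter_by_weight(rec)
  expect_equal(out$id, "caffeine")
  # oracle from atomic masses: C8H10N4O2
  expect_equal(out$mol_weight, 8 * 12.011 + 10 * 1.008 + 4 * 14.007 + 2 * 15.999,
               tolerance = 1e-3)
  # identity bounds keep everything
  expect_equal(filter_by_weight(rec, lo = 0, hi = Inf)$id, rec$id)
  # empty input passes through
  expect_equal(nrow(filter_by_weight(rec[integer(0), ])), 0L)
  expect_error(filter_by_weight(rec, lo = 600, hi = 100), "lo")
})

test_that("redundancy filter removes duplicates and keeps dissimilar sets", {
  x <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(redundancy_filter(x, 0.8), c(1L, 3L))
  # all pairwise TC < threshold: no-op
  y <- diag(4)
  expect_equal(redundancy_filter(y, 0.8), 1:4)
  expect_error(redundancy_filter(y, 0), "threshold")
})

test_that("redundancy filter equals the brute-force greedy scan", {
  for (s in 1:8) {
    x <- random_fps(10, 16, p = 0.4, seed = s)
    expect_identical(redundancy_filter(x, 0.5), oracle_greedy_filter(x, 0.5))
  }
})

test_that("redundancy filter survivors verify post-hoc", {
  for (s in 1:10) {
    x <- random_fps(15, 24, p = 0.5, seed = 100 + s)
    keep <- redundancy_filter(x, 0.7)
    if (length(keep) > 1) {
      sims <- combn(keep, 2, function(ij) tanimoto(x[ij[1], ], x[ij[2], ]))
      expect_true(max(sims) < 0.7)
    }
  }
})

test_that("label tables validate columns and ranges", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("id,sascore,tox", "m1,2.5,0", "m2,7.1,1"), f)
  tab <- read_label_table(f)
  expect_equal(tab$sascore, c(2.5, 7.1))
  writeLines(c("id\tsascore", "m1\t11"), f)
  expect_error(read_label_table(f), "outside")
  writeLines(c("id,tox", "m1,2"), f)
  expect_error(read_label_table(f), "tox labels")
  writeLines(c("foo,bar", "1,2"), f)
  expect_error(read_label_table(f), "id")
})

test_that("fingerprint CSV round-trips", {
  x <- random_fps(5, 1024, seed = 9)
  rownames(x) <- paste0("m", 1:5)
  f <- tempfile(fileext = ".csv")
  write_fingerprints_csv(x, f)
  x2 <- read_fingerprints_csv(f)
  expect_identical(unname(`attr<-`(x2, "scheme", NULL)), unname(x))
  expect_identical(rownames(x2), rownames(x))
  expect_identical(attr(x2, "scheme"), satox:::FP_SCHEME)
})
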