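# Molecule input, fingerprint computation and dataset curation.
#
# Molecules are handled as plain data frames with columns `id` and `smiles`
# (plus `mol_weight` once computed). Fingerprints are 0/1 integer matrices
# with one row per molecule and ids as row names. All chemistry (SMILES
# parsing, canonicalization, molecular weight, path fingerprints) is
# delegated to Open Babel through ChemmineOB (Open Babel bindings).

# Identifier of the fingerprint scheme stamped on every fingerprint matrix
# and every trained model, so that a model is never applied to fingerprints
# computed under a different convention.
FP_SCHEME <- "openbabel-FP2-1024"

# Parse each SMILES independently through Open Babel; a record that fails to
# parse yields NULL instead of aborting the batch. Each parsed entry carries
# the FP2 fingerprint bits and the (average) molecular weight.
.parse_molecules <- function(smiles, ids) {
  out <- lapply(smiles, function(s) {
    res <- tryCatch(
      suppressWarnings(ChemmineOB::forEachMol("SMILES", s, function(m) {
        list(fp = as.integer(round(ChemmineOB::fingerprint_OB(list(m), "FP2"))),
             mw = ChemmineOB::prop_OB(m)$MW)
      })),
      error = function(e) NULL)
    if (is.null(res) || length(res) != 1L || length(res[[1L]]$fp) != 1024L) {
      return(NULL)
    }
    res[[1L]]
  })
  names(out) <- ids
  out
}

#' Read molecules from a SMILES (.smi) file
#'
#' Each non-blank, non-comment (`#`) line holds a SMILES string optionally
#' followed by whitespace and an identifier. Lines whose SMILES cannot be
#' parsed by Open Babel are skipped with a message reporting the count;
#' records without an identifier get `mol<line-number>`.
#'
#' @param path Path to a .smi file.
#' @return A data frame with columns `id` and `smiles`, one row per valid
#'   molecule.
#' @examples
#' f <- tempfile(fileext = ".smi")
#' writeLines(c("c1ccccc1 benzene", "CCO ethanol"), f)
#' read_smiles_file(f)
#' @export
read_smiles_file <- function(path) {
  if (!file.exists(path)) stopf("cannot read SMILES file '%s': no such file", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stopf("no molecules in '%s': file is empty", path)

  toks <- strsplit(trimws(lines), "\\s+")
  smiles <- vapply(toks, `[`, character(1), 1L)
  ids <- vapply(toks, function(t) if (length(t) >= 2L) t[2L] else NA_character_, character(1))
  ids[is.na(ids)] <- paste0("mol", lineno[is.na(ids)])
  if (anyDuplicated(ids)) {
    warning("duplicated molecule ids made unique with suffixes", call. = FALSE)
    ids <- make.unique(ids, sep = "_")
  }

  mols <- .parse_molecules(smiles, ids)
  bad <- vapply(mols, is.null, logical(1))
  if (any(bad)) {
    message(sprintf("skipped %d line(s) with unparseable SMILES: %s",
                    sum(bad), paste(ids[bad], collapse = ", ")))
  }
  if (all(bad)) stopf("no valid molecules in '%s'", path)
  data.frame(id = ids[!bad], smiles = smiles[!bad], stringsAsFactors = FALSE)
}

#' Compute 1024-bit path fingerprints
#'
#' Computes the Open Babel FP2 fingerprint — a 1024-bit hash of linear
#' atom/bond fragments up to 7 atoms — for each molecule. The fingerprint is
#' deterministic and invariant to SMILES re-spelling of the same molecule
#' (aromatic vs. kekulized forms give identical bits).
#'
#' @param x A data frame with columns `id` and `smiles` (as returned by
#'   [read_smiles_file()]), or a character vector of SMILES (optionally
#'   named by molecule id).
#' @return Integer 0/1 matrix, one row per molecule (row names = ids,
#'   1024 columns), with attribute `scheme` identifying the fingerprint
#'   convention.
#' @export
compute_fingerprints <- function(x) {
  if (is.data.frame(x)) {
    smiles <- x$smiles
    ids <- x$id
  } else {
    smiles <- as.character(x)
    ids <- names(x)
    if (is.null(ids)) ids <- paste0("mol", seq_along(smiles))
  }
  if (length(smiles) == 0L) stopf("no molecules to fingerprint")
  mols <- .parse_molecules(smiles, ids)
  bad <- vapply(mols, is.null, logical(1))
  if (any(bad)) {
    stopf("cannot parse SMILES for: %s", paste(ids[bad], collapse = ", "))
  }
  m <- do.call(rbind, lapply(mols, `[[`, "fp"))
  rownames(m) <- ids
  attr(m, "scheme") <- FP_SCHEME
  m
}

#' Tanimoto similarity of two fingerprints
#'
#' `|a AND b| / |a OR b|` over the set bits. By convention two all-zero
#' fingerprints have similarity 1 (empty fingerprints are treated as
#' duplicates by the redundancy filter).
#'
#' @param a,b Binary vectors of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) {
    stopf("fingerprint length mismatch: %d vs %d", length(a), length(b))
  }
  inter <- sum(a == 1 & b == 1)
  union <- sum(a == 1 | b == 1)
  if (union == 0L) return(1.0)
  inter / union
}

#' Filter molecules by molecular weight
#'
#' Keeps records whose molecular weight (computed by Open Babel from the
#' parsed structure, hydrogens included) lies in `[lo, hi]`, inclusive on
#' both ends. Default range 100-600 Da, the usual drug-like window.
#'
#' @param records Data frame with columns `id` and `smiles`.
#' @param lo,hi Weight bounds in daltons.
#' @return The filtered data frame, input order preserved, with a
#'   `mol_weight` column added. Unparseable records are skipped with a
#'   message.
#' @export
filter_by_weight <- function(records, lo = 100, hi = 600) {
  stopifnot(is.data.frame(records))
  if (lo >= hi) stopf("invalid weight bounds: lo (%g) must be < hi (%g)", lo, hi)
  if (nrow(records) == 0L) {
    records$mol_weight <- numeric(0)
    return(records)
  }
  mols <- .parse_molecules(records$smiles, records$id)
  bad <- vapply(mols, is.null, logical(1))
  if (any(bad)) {
    message(sprintf("skipped %d unparseable record(s) in weight filter", sum(bad)))
  }
  mw <- vapply(mols, function(m) if (is.null(m)) NA_real_ else m$mw, numeric(1))
  keep <- !is.na(mw) & mw >= lo & mw <= hi
  out <- records[keep, , drop = FALSE]
  out$mol_weight <- mw[keep]
  rownames(out) <- NULL
  out
}

#' Remove redundant fingerprints at a Tanimoto cutoff
#'
#' Greedy scan in input order: a row is kept iff its Tanimoto similarity to
#' every previously kept row is strictly below `threshold`. All pairwise
#' similarities among survivors are therefore `< threshold`. The default
#' cutoff 0.8 is the customary redundancy threshold for compound libraries.
#'
#' @param x Binary fingerprint matrix (rows = molecules).
#' @param threshold Tanimoto cutoff in `(0, 1]`.
#' @return Integer vector of kept row indices (use it to subset the
#'   fingerprint matrix, labels and records).
#' @export
redundancy_filter <- function(x, threshold = 0.8) {
  stopifnot(is.matrix(x))
  if (threshold <= 0 || threshold > 1) stopf("threshold must be in (0, 1]")
  n <- nrow(x)
  if (n == 0L) return(integer(0))
  kept <- integer(0)
  kept_mat <- matrix(0, nrow = 0, ncol = ncol(x))
  kept_card <- numeric(0)
  for (i in seq_len(n)) {
    xi <- x[i, ]
    ci <- sum(xi)
    if (length(kept) > 0L) {
      inter <- as.vector(kept_mat %*% xi)
      union <- kept_card + ci - inter
      sims <- ifelse(union == 0, 1.0, inter / union)
      if (any(sims >= threshold)) next
    }
    kept <- c(kept, i)
    kept_mat <- rbind(kept_mat, xi)
    kept_card <- c(kept_card, ci)
  }
  kept
}

#' Read a molecule label table
#'
#' CSV or TSV (sniffed from the header line) with an `id` column and a
#' `sascore` column (values in `[1, 10]`) and/or a `tox` column
#' (0 = non-toxic, 1 = toxic).
#'
#' @param path Path to the table.
#' @return Data frame with the validated columns.
#' @export
read_label_table <- function(path) {
  if (!file.exists(path)) stopf("cannot read label table '%s': no such file", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (!"id" %in% names(tab)) stopf("label table must have an 'id' column")
  if (!any(c("sascore", "tox") %in% names(tab))) {
    stopf("label table must have a 'sascore' and/or 'tox' column")
  }
  if ("sascore" %in% names(tab)) {
    bad <- tab$sascore < 1 | tab$sascore > 10 | is.na(tab$sascore)
    if (any(bad)) stopf("sascore outside [1, 10] for id(s): %s",
                        paste(tab$id[bad], collapse = ", "))
  }
  if ("tox" %in% names(tab) && !all(tab$tox %in% c(0, 1))) {
    stopf("tox labels must be 0 (non-toxic) or 1 (toxic)")
  }
  tab
}

#' Write / read fingerprints as CSV
#'
#' Plain interchange format: column `id` followed by 1024 columns of 0/1
#' values, so fingerprints can round-trip between runs and tools without a
#' chemistry backend.
#'
#' @param x Fingerprint matrix with ids as row names.
#' @param path Output path.
#' @export
write_fingerprints_csv <- function(x, path) {
  stopifnot(is.matrix(x))
  df <- data.frame(id = rownames(x), x, check.names = FALSE)
  names(df) <- c("id", paste0("b", seq_len(ncol(x))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fingerprints_csv
#' @return `read_fingerprints_csv` returns the fingerprint matrix with the
#'   package's scheme attribute attached.
#' @export
read_fingerprints_csv <- function(path) {
  if (!file.exists(path)) stopf("cannot read fingerprints '%s': no such file", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$id
  colnames(m) <- NULL
  if (ncol(m) == 1024L) attr(m, "scheme") <- FP_SCHEME
  m
}
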