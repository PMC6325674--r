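# End-to-end workflows tying the modules together, and model persistence.
# These functions back the command-line interface (inst/cli/satox.R) but are
# ordinary exported functions, usable directly from R.

MODEL_FORMAT_VERSION <- "satox-model-1"

#' Save / load a fitted model
#'
#' Models are stored with a format-version tag and the fingerprint-scheme
#' identifier they were trained on; [satox_load_model()] refuses a file
#' written under a different format version, and the prediction pipeline
#' refuses a model whose fingerprint scheme does not match the run.
#'
#' @param model An `sa_dbn` or `tox_et` object.
#' @param path Destination file.
#' @export
satox_save_model <- function(model, path) {
  if (!inherits(model, c("sa_dbn", "tox_et"))) {
    stopf("can only save sa_dbn or tox_et models")
  }
  saveRDS(list(format = MODEL_FORMAT_VERSION,
               scheme = model$scheme,
               class = class(model)[1],
               model = model),
          path)
  invisible(path)
}

#' @rdname satox_save_model
#' @return `satox_load_model` returns the stored model object.
#' @export
satox_load_model <- function(path) {
  if (!file.exists(path)) stopf("cannot read model '%s': no such file", path)
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, MODEL_FORMAT_VERSION)) {
    stopf("'%s' is not a %s file", path, MODEL_FORMAT_VERSION)
  }
  obj$model
}

.check_scheme <- function(model, fps) {
  ms <- model$scheme
  fs <- attr(fps, "scheme")
  if (!is.null(ms) && !is.null(fs) && !identical(ms, fs)) {
    stopf("fingerprint scheme mismatch: model trained on '%s', input is '%s'",
          ms, fs)
  }
}

# Resolve molecule input: a .smi path, a fingerprint CSV path, a fingerprint
# matrix, or a data frame of records. Returns list(fps, ids).
.resolve_input <- function(input) {
  if (is.matrix(input)) {
    return(list(fps = input, ids = rownames(input)))
  }
  if (is.data.frame(input)) {
    fps <- compute_fingerprints(input)
    return(list(fps = fps, ids = rownames(fps)))
  }
  if (is.character(input) && length(input) == 1L && file.exists(input)) {
    if (grepl("\\.csv$", input, ignore.case = TRUE)) {
      fps <- read_fingerprints_csv(input)
    } else {
      fps <- compute_fingerprints(read_smiles_file(input))
    }
    return(list(fps = fps, ids = rownames(fps)))
  }
  stopf("cannot interpret molecule input")
}

.align_labels <- function(fps, labels, column) {
  if (is.character(labels) && length(labels) == 1L) labels <- read_label_table(labels)
  if (is.data.frame(labels)) {
    if (!column %in% names(labels)) stopf("label table has no '%s' column", column)
    m <- match(rownames(fps), labels$id)
    if (anyNA(m)) {
      stopf("missing %s label(s) for: %s", column,
            paste(utils::head(rownames(fps)[is.na(m)], 5), collapse = ", "))
    }
    labels[[column]][m]
  } else {
    if (length(labels) != nrow(fps)) stopf("label length does not match molecules")
    labels
  }
}

#' Train and cross-validate the SAscore regressor
#'
#' Full training workflow: fingerprint the input, balance the skewed score
#' distribution with a resampling plan, report k-fold cross-validated MSE
#' and PCC, then fit the final model on all (resampled) data.
#'
#' @param input Molecules: `.smi` path, fingerprint CSV path, fingerprint
#'   matrix, or record data frame.
#' @param labels SAscore labels: label-table path/data frame (column
#'   `sascore`) or numeric vector aligned with the input.
#' @param plan Resampling plan (`NULL` to skip resampling); default
#'   [default_sa_plan()].
#' @param layer_sizes,control Passed to [sa_dbn()]; the visible layer is set
#'   to the fingerprint width.
#' @param folds Cross-validation folds (default 5).
#' @param seed Integer seed for resampling and fold assignment.
#' @param model_path If non-`NULL`, the final model is saved there.
#' @return List with `model` (`sa_dbn`), `cv` (`cv_result`) and `n_input` /
#'   `n_trained` record counts.
#' @export
satox_train_sa <- function(input, labels, plan = default_sa_plan(),
                           layer_sizes = NULL, control = dbn_control(),
                           folds = 5, seed = 42, model_path = NULL) {
  inp <- .resolve_input(input)
  fps <- inp$fps
  y <- .align_labels(fps, labels, "sascore")
  n_input <- nrow(fps)

  if (!is.null(plan)) {
    rs <- resample_sascore(fps, y, plan, seed = seed)
    scheme <- attr(fps, "scheme")
    fps <- rs$x
    attr(fps, "scheme") <- scheme
    y <- rs$y
  }
  if (is.null(layer_sizes)) {
    layer_sizes <- if (ncol(fps) == 1024L) c(1024, 512, 128, 32) else
      unique(pmax(1L, c(ncol(fps), ncol(fps) %/% 4L, ncol(fps) %/% 16L)))
  }
  control$seed <- seed

  cv <- kfold_cv(fps, y, k = folds, seed = seed,
                 trainer = function(xt, yt) sa_dbn(xt, yt, layer_sizes, control),
                 metrics = list(mse = function(truth, p) mse(p, truth),
                                pcc = function(truth, p) pcc(p, truth)),
                 stratified = FALSE)
  model <- sa_dbn(fps, y, layer_sizes, control)
  if (!is.null(model_path)) satox_save_model(model, model_path)
  list(model = model, cv = cv, n_input = n_input, n_trained = nrow(fps))
}

#' Train and cross-validate the Tox-score classifier
#'
#' Fingerprints the input, runs stratified k-fold cross-validation of the
#' extra-trees classifier (ACC/TPR/FPR/MCC at the default threshold plus
#' AUC, per fold), selects the MCC-maximizing Tox-score threshold on the
#' pooled out-of-fold scores, and fits the final model on all data with the
#' selected threshold embedded.
#'
#' @param input Molecules, as in [satox_train_sa()].
#' @param labels Toxicity labels: table path/data frame (column `tox`,
#'   1 = toxic) or 0/1 vector.
#' @param folds,seed Cross-validation settings.
#' @param model_path Optional path to save the final model.
#' @param ... Passed to [tox_et()] (n_trees, k_features, ...).
#' @return List with `model` (`tox_et`, threshold embedded), `cv`,
#'   `threshold` (a `threshold_selection`) and `n_input`.
#' @export
satox_train_tox <- function(input, labels, folds = 5, seed = 42,
                            model_path = NULL, ...) {
  inp <- .resolve_input(input)
  fps <- inp$fps
  y <- .align_labels(fps, labels, "tox")
  if (length(unique(y)) < 2L) stopf("toxicity training needs both classes")

  trainer <- function(xt, yt) tox_et(xt, yt, seed = seed, ...)
  cv <- kfold_cv(fps, y, k = folds, seed = seed, trainer = trainer,
                 metrics = list(
                   acc = function(truth, s) acc(confusion_counts(truth, classify_tox(s, 0.58))),
                   tpr = function(truth, s) tpr(confusion_counts(truth, classify_tox(s, 0.58))),
                   fpr = function(truth, s) fpr(confusion_counts(truth, classify_tox(s, 0.58))),
                   mcc = function(truth, s) mcc(confusion_counts(truth, classify_tox(s, 0.58))),
                   auc = function(truth, s) roc_curve(s, truth)$auc))
  thr <- select_threshold(cv$oof, y)
  model <- trainer(fps, y)
  model$threshold <- thr$threshold
  if (!is.null(model_path)) satox_save_model(model, model_path)
  list(model = model, cv = cv, threshold = thr, n_input = nrow(fps))
}

#' Predict SAscore and/or Tox-score for molecules
#'
#' Reads molecules, applies the given model(s) and returns one row per input
#' molecule in input order. Molecules whose SMILES cannot be parsed get an
#' `NA` row rather than being dropped.
#'
#' @param input A `.smi` path or record data frame (`id`, `smiles`).
#' @param sa_model `sa_dbn` object or saved model path, or `NULL`.
#' @param tox_model `tox_et` object or saved model path, or `NULL`.
#' @param threshold Tox-score decision threshold; defaults to the one
#'   embedded in the toxicity model, else 0.58.
#' @param output Optional CSV path for the prediction table.
#' @return Data frame with columns `id`, `sascore` (if `sa_model`),
#'   `toxscore` and `tox_label` (if `tox_model`).
#' @export
satox_predict <- function(input, sa_model = NULL, tox_model = NULL,
                          threshold = NULL, output = NULL) {
  if (is.character(sa_model)) sa_model <- satox_load_model(sa_model)
  if (is.character(tox_model)) tox_model <- satox_load_model(tox_model)
  if (is.null(sa_model) && is.null(tox_model)) stopf("no model given")

  if (is.character(input) && length(input) == 1L) {
    records <- read_smiles_file(input)
  } else if (is.data.frame(input)) {
    records <- input
  } else {
    stopf("input must be a .smi path or a data frame of id + smiles")
  }

  parsed <- tryCatch(compute_fingerprints(records), error = function(e) NULL)
  if (is.null(parsed)) {
    ok <- vapply(records$smiles, function(s) {
      !is.null(tryCatch(compute_fingerprints(stats::setNames(s, "x")),
                        error = function(e) NULL))
    }, logical(1))
    if (!any(ok)) stopf("no parseable molecules in input")
    parsed <- compute_fingerprints(records[ok, , drop = FALSE])
  }

  out <- data.frame(id = records$id, stringsAsFactors = FALSE)
  m <- match(records$id, rownames(parsed))
  if (!is.null(sa_model)) {
    .check_scheme(sa_model, parsed)
    sa <- predict(sa_model, parsed)
    out$sascore <- sa[m]
  }
  if (!is.null(tox_model)) {
    .check_scheme(tox_model, parsed)
    ts <- predict(tox_model, parsed)
    if (is.null(threshold)) threshold <- tox_model$threshold %||% 0.58
    out$toxscore <- ts[m]
    lbl <- rep(NA_integer_, nrow(out))
    good <- !is.na(out$toxscore)
    lbl[good] <- classify_tox(out$toxscore[good], threshold)
    out$tox_label <- lbl
  }
  if (!is.null(output)) utils::write.csv(out, output, row.names = FALSE)
  out
}

#' Compare fragment composition of two molecule sets
#'
#' Reads two fragment occurrence files (non-toxic first), builds frequency
#' tables and runs [fragment_compare()].
#'
#' @param non_toxic_file,toxic_file Fragment list files
#'   (see [read_fragment_list()]).
#' @param output Optional CSV path for the comparison table.
#' @return A `fragment_comparison` object.
#' @export
satox_compare_fragments <- function(non_toxic_file, toxic_file, output = NULL) {
  f1 <- fragment_frequencies(read_fragment_list(non_toxic_file))
  f2 <- fragment_frequencies(read_fragment_list(toxic_file))
  cmp <- fragment_compare(f1, f2)
  if (!is.null(output)) {
    utils::write.csv(cmp$table, output, row.names = FALSE)
  }
  cmp
}
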