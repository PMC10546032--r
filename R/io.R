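# Readers and writers for the package's on-disk dialects:
# expression matrices and clinical tables as TSV, signatures and reports
# as JSON. All writers are deterministic (stable key order, 10 significant
# digits) so outputs are diffable across runs.

SIGNATURE_SCHEMA <- "lactpair-signature/1"

#' Read an expression matrix from TSV
#'
#' Expects genes x samples: first column gene symbols, header row sample
#' ids, tab-separated numeric cells. Duplicate gene symbols and
#' non-numeric cells are rejected with the offending location. A matrix
#' that looks transposed (its row names overlap the clinical sample ids
#' supplied via `clinical_ids`) is rejected rather than silently fixed.
#'
#' @param path TSV file path.
#' @param clinical_ids optional sample ids used for the orientation check.
#' @return genes x samples numeric matrix.
#' @export
read_expression <- function(path, clinical_ids = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop2("expression file needs a gene column plus samples")
  genes <- df[[1]]
  if (anyDuplicated(genes))
    stop2("duplicated gene symbol(s) in ", path, ": ",
          paste(unique(genes[duplicated(genes)]), collapse = ", "))
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(genes, colnames(vals))))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad))
    stop2("non-numeric cell at gene ", genes[bad[1, 1]], ", sample ",
          colnames(vals)[bad[1, 2]])
  if (anyNA(num)) {
    na <- which(is.na(num), arr.ind = TRUE)
    stop2("missing value at gene ", genes[na[1, 1]], ", sample ",
          colnames(num)[na[1, 2]])
  }
  if (!is.null(clinical_ids) &&
      !any(colnames(num) %in% clinical_ids) &&
      any(genes %in% clinical_ids))
    stop2("expression matrix appears transposed (gene column contains ",
          "clinical sample ids); expected genes x samples")
  check_expression_matrix(num)
}

#' Write an expression matrix to TSV
#' @param expr genes x samples matrix.
#' @param path output file.
#' @export
write_expression <- function(expr, path) {
  check_expression_matrix(expr)
  df <- data.frame(gene = rownames(expr),
                   signif(expr, 10), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table from TSV
#'
#' Requires columns `sample_id`, `time_months`, `event`; any further
#' columns are kept as covariates. Negative times and events outside
#' \{0, 1\} are rejected.
#'
#' @param path TSV file path.
#' @return validated clinical data frame.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  df$sample_id <- as.character(df$sample_id)
  check_clinical(df)
}

#' Write a clinical table to TSV
#' @param clinical clinical data frame.
#' @param path output file.
#' @export
write_clinical <- function(clinical, path) {
  check_clinical(clinical)
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a pair signature to JSON
#'
#' Serializes pairs, coefficients, penalties, ridge stage, configuration
#' and package version; the round trip through [read_signature()] is
#' lossless.
#'
#' @param signature a `pair_signature`.
#' @param path output JSON file.
#' @export
write_signature <- function(signature, path) {
  if (!inherits(signature, "pair_signature"))
    stop2("signature must be a pair_signature")
  obj <- list(
    schema = SIGNATURE_SCHEMA,
    version = as.character(utils::packageVersion("lactpair")),
    pairs = lapply(seq_len(nrow(signature$pairs)), function(i)
      list(first = signature$pairs$first[i],
           second = signature$pairs$second[i],
           coefficient = round_sig(as.numeric(signature$coefficients[i])))),
    lambda_selected = round_sig(signature$lambda_selected),
    lambda_ridge = round_sig(signature$lambda_ridge),
    ridge_betas = as.list(round_sig(stats::setNames(
      as.numeric(signature$ridge_betas), names(signature$ridge_betas)))),
    config = signature$config,
    n_candidates = signature$n_candidates)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Read a pair signature from JSON
#' @param path JSON file written by [write_signature()].
#' @return a `pair_signature`.
#' @export
read_signature <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$schema, SIGNATURE_SCHEMA))
    stop2("unsupported signature schema: ",
          if (is.null(obj$schema)) "<missing>" else obj$schema)
  nm <- vapply(obj$pairs, function(p)
    paste(p$first, p$second, sep = "|"), character(1))
  coefs <- vapply(obj$pairs, function(p) as.numeric(p$coefficient), numeric(1))
  ridge <- vapply(obj$ridge_betas, function(v)
    if (is.null(v)) NA_real_ else as.numeric(v), numeric(1))
  cfg <- obj$config
  config <- adaptive_lasso_config(
    n_folds = cfg$n_folds, weight_cap = cfg$weight_cap,
    fold_seed = cfg$fold_seed, selection_rule = cfg$selection_rule,
    standardize = isTRUE(cfg$standardize))
  as_na <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  new_pair_signature(nm, coefs, as_na(obj$lambda_selected),
                     as_na(obj$lambda_ridge),
                     ridge, config, as.integer(obj$n_candidates),
                     ridge_names = names(obj$ridge_betas))
}

#' Write a training/evaluation report (with run manifest) to JSON
#'
#' Flattens the report of [train_lrgpi()] — stage counts, cutoff,
#' log-rank, AUC, concordance — together with a small run manifest
#' (package version, seed, timestamp optional) into deterministic JSON.
#'
#' @param fit an `lrgpi_fit`.
#' @param path output JSON file.
#' @param timestamp include the wall-clock time (default `FALSE`, keeping
#'   repeated runs byte-identical).
#' @export
write_report <- function(fit, path, timestamp = FALSE) {
  if (!inherits(fit, "lrgpi_fit")) stop2("fit must be an lrgpi_fit")
  rep <- fit$report
  ev <- rep$evaluation
  obj <- list(
    manifest = list(
      package = "lactpair",
      version = as.character(utils::packageVersion("lactpair")),
      seed = rep$seed,
      timestamp = if (timestamp) format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
                  else NULL),
    stage_counts = rep$stage_counts,
    degenerate = rep$degenerate,
    cutoff = round_sig(rep$cutoff),
    logrank = if (!is.null(ev)) round_sig(ev$logrank),
    auc = if (!is.null(ev) && !is.null(ev$auc))
      as.list(round_sig(ev$auc)),
    c_index = if (!is.null(ev)) round_sig(ev$c_index))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Write a synthetic cohort to a directory
#'
#' Expression as `expression.tsv`, clinical as `clinical.tsv`, planted
#' truth as `truth.json`.
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "synthetic_cohort"))
    stop2("cohort must be a synthetic_cohort")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  write_clinical(cohort$clinical, file.path(dir, "clinical.tsv"))
  jsonlite::write_json(
    list(pairs = cohort$truth$pairs,
         censoring_bound = round_sig(cohort$truth$censoring_bound)),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE,
    dataframe = "rows")
  invisible(dir)
}
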