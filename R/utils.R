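# Internal helpers: validation and seeded evaluation.

stop2 <- function(...) stop(..., call. = FALSE)

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so library code never
#' clobbers a user's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

check_expression_matrix <- function(expr, arg = "expr") {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop2(arg, " must be a numeric matrix (genes x samples)")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop2(arg, " must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(expr)))
    stop2(arg, " has duplicated gene symbols: ",
          paste(unique(rownames(expr)[duplicated(rownames(expr))]), collapse = ", "))
  if (anyDuplicated(colnames(expr)))
    stop2(arg, " has duplicated sample ids")
  invisible(expr)
}

check_clinical <- function(clinical, arg = "clinical") {
  if (!is.data.frame(clinical))
    stop2(arg, " must be a data frame")
  need <- c("sample_id", "time_months", "event")
  miss <- setdiff(need, names(clinical))
  if (length(miss))
    stop2(arg, " is missing required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(clinical$sample_id))
    stop2(arg, " has duplicated sample ids")
  if (any(!is.finite(clinical$time_months)) || any(clinical$time_months < 0))
    stop2(arg, "$time_months must be finite and nonnegative")
  if (!all(clinical$event %in% c(0L, 1L)))
    stop2(arg, "$event must be 0 or 1")
  invisible(clinical)
}

# Align a clinical table to a vector of sample ids (error on mismatch).
align_clinical <- function(clinical, sample_ids) {
  idx <- match(sample_ids, clinical$sample_id)
  if (anyNA(idx))
    stop2("samples missing from clinical table: ",
          paste(utils::head(sample_ids[is.na(idx)], 5), collapse = ", "))
  clinical[idx, , drop = FALSE]
}

# Deterministic numeric formatting used by all JSON writers (10 significant
# digits) so outputs are diffable across runs.
round_sig <- function(x, digits = 10) {
  if (is.numeric(x)) return(signif(x, digits))
  if (is.list(x)) return(lapply(x, round_sig, digits = digits))
  x
}
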