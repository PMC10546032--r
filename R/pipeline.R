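#' Configuration for the end-to-end index pipeline
#'
#' @param gene_screen_alpha,pair_screen_alpha univariate-Cox Wald p-value
#'   cutoffs for the gene and pair screens (raw, no multiplicity
#'   correction — intentional: the screens are feature pre-selection, not
#'   inference, and the downstream penalized fit does the real selection).
#' @param consistency_threshold majority-frequency cutoff of the
#'   consistency filter, in \[0.5, 1).
#' @param min_followup_months samples followed up for less than this are
#'   excluded before training or scoring (short-followup records carry
#'   almost no information and destabilize the index). Strict: a sample at
#'   exactly the bound is kept.
#' @param evaluation_horizons months at which time-dependent AUC is
#'   reported.
#' @param adaptive an [adaptive_lasso_config()].
#' @param seed pipeline seed; also the default fold seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(gene_screen_alpha = 0.05,
                            pair_screen_alpha = 0.05,
                            consistency_threshold = 0.70,
                            min_followup_months = 1.0,
                            evaluation_horizons = c(12, 36, 60),
                            adaptive = NULL,
                            seed = 1L) {
  if (gene_screen_alpha < 0 || gene_screen_alpha > 1 ||
      pair_screen_alpha < 0 || pair_screen_alpha > 1)
    stop2("screen alphas must be in [0, 1]")
  if (consistency_threshold < 0.5 || consistency_threshold >= 1)
    stop2("consistency_threshold must be in [0.5, 1)")
  if (is.null(adaptive)) adaptive <- adaptive_lasso_config(fold_seed = seed)
  structure(list(gene_screen_alpha = gene_screen_alpha,
                 pair_screen_alpha = pair_screen_alpha,
                 consistency_threshold = consistency_threshold,
                 min_followup_months = min_followup_months,
                 evaluation_horizons = evaluation_horizons,
                 adaptive = adaptive,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Exclude samples with short follow-up
#'
#' Retains samples whose follow-up time is at least `min_months`
#' ("shorter than" is strict).
#'
#' @param clinical clinical table.
#' @param min_months months; default 1.
#' @return filtered clinical table; errors if nothing remains.
#' @export
exclude_short_followup <- function(clinical, min_months = 1.0) {
  check_clinical(clinical)
  keep <- clinical$time_months >= min_months
  if (!any(keep)) stop2("all samples excluded by the follow-up filter")
  if (any(!keep))
    message("excluded ", sum(!keep), " sample(s) with follow-up < ",
            min_months, " months")
  clinical[keep, , drop = FALSE]
}

#' Screen genes for univariate prognostic association
#'
#' Fits a univariate Cox model per gene on its expression vector and
#' retains genes with two-sided Wald p below `alpha`. No multiplicity
#' correction is applied (pre-selection, not inference). Constant genes
#' are skipped with a warning, never passed to the Cox fitter.
#'
#' @param expr genes x samples matrix.
#' @param clinical clinical table covering the matrix samples.
#' @param alpha p-value cutoff.
#' @return character vector of prognostic genes, with per-gene p-values as
#'   attribute `p_values` (named, screened genes only).
#' @export
screen_prognostic_genes <- function(expr, clinical, alpha = 0.05) {
  check_expression_matrix(expr)
  clinical <- align_clinical(clinical, colnames(expr))
  keep <- apply(expr, 1, stats::var) > 0
  if (any(!keep))
    warning("skipping constant gene(s): ",
            paste(rownames(expr)[!keep], collapse = ", "))
  genes <- rownames(expr)[keep]
  p <- vapply(genes, function(g) {
    fit <- fit_cox(expr[g, ], clinical)
    if (fit$converged) as.numeric(fit$p_value) else NA_real_
  }, numeric(1))
  hits <- genes[!is.na(p) & p < alpha]
  structure(hits, p_values = p)
}

#' Screen gene pairs for univariate prognostic association
#'
#' Retains pairs whose binary score has univariate Cox Wald p below
#' `alpha`. Expects an already consistency-filtered matrix (a near-constant
#' pair would make the Cox fit fragile).
#'
#' @param pair_matrix binary pair-score matrix (pairs x samples).
#' @param clinical clinical table covering the matrix samples.
#' @param alpha p-value cutoff.
#' @return the retained rows of `pair_matrix`, original order preserved,
#'   with per-pair p-values as attribute `p_values`.
#' @export
screen_prognostic_pairs <- function(pair_matrix, clinical, alpha = 0.05) {
  clinical <- align_clinical(clinical, colnames(pair_matrix))
  if (!nrow(pair_matrix)) {
    return(structure(pair_matrix, p_values = stats::setNames(numeric(), character())))
  }
  p <- vapply(seq_len(nrow(pair_matrix)), function(i) {
    fit <- fit_cox(pair_matrix[i, ], clinical)
    if (fit$converged) as.numeric(fit$p_value) else NA_real_
  }, numeric(1))
  names(p) <- rownames(pair_matrix)
  keep <- !is.na(p) & p < alpha
  structure(pair_matrix[keep, , drop = FALSE], p_values = p)
}

#' Compute the gene-pair index for each sample
#'
#' The index is the coefficient-weighted sum of a sample's binary pair
#' scores: `index_s = sum_k coef_k * score_k(s)`. An empty signature gives
#' an all-zero vector.
#'
#' @param pair_matrix binary pair-score matrix containing at least the
#'   signature's pairs (rownames `"FIRST|SECOND"`).
#' @param signature a `pair_signature`.
#' @return named numeric vector, one index value per sample.
#' @export
compute_lrgpi <- function(pair_matrix, signature) {
  if (!inherits(signature, "pair_signature"))
    stop2("signature must be a pair_signature")
  if (!length(signature$coefficients))
    return(stats::setNames(rep(0, ncol(pair_matrix)), colnames(pair_matrix)))
  nm <- names(signature$coefficients)
  missing <- setdiff(nm, rownames(pair_matrix))
  if (length(missing))
    stop2("signature pair(s) missing from pair matrix: ",
          paste(missing, collapse = ", "))
  as.numeric(signature$coefficients %*%
               pair_matrix[nm, , drop = FALSE]) |>
    stats::setNames(colnames(pair_matrix))
}

#' Score a cohort's expression matrix with a frozen signature
#'
#' Builds only the signature's pair scores from the cohort expression and
#' returns the weighted sum. Because scoring uses within-sample orderings
#' only, the result is unchanged by any monotone per-sample transformation
#' of `expr`.
#'
#' @param expr genes x samples matrix (any within-sample-comparable scale).
#' @param signature a `pair_signature`.
#' @return named numeric index vector.
#' @export
score_cohort <- function(expr, signature) {
  if (!length(signature$coefficients))
    return(stats::setNames(rep(0, ncol(expr)), colnames(expr)))
  missing <- setdiff(unique(c(signature$pairs$first, signature$pairs$second)),
                     rownames(expr))
  if (length(missing))
    stop2("signature gene(s) missing from cohort: ",
          paste(missing, collapse = ", "))
  compute_lrgpi(build_pair_matrix(expr, signature$pairs), signature)
}

#' Dichotomize risk scores at a cutoff
#'
#' Splits scores into low/high risk groups. With `cutoff = "median"` the
#' median of `scores` is used (for an external cohort this is its own
#' median; pass the frozen training cutoff to reuse it). Samples exactly at
#' the cutoff go to the low group — conservative for the high-risk claim.
#'
#' @param scores numeric risk scores.
#' @param cutoff `"median"` or a numeric cutoff.
#' @return list of class `risk_profile`: `sample_ids`, `lrgpi`, `cutoff`,
#'   `group` (factor low/high).
#' @export
stratify <- function(scores, cutoff = "median") {
  if (length(scores) < 2) stop2("need at least 2 samples to stratify")
  if (identical(cutoff, "median")) cutoff <- stats::median(scores)
  if (!is.numeric(cutoff) || length(cutoff) != 1)
    stop2("cutoff must be \"median\" or a single number")
  if (length(unique(scores)) == 1)
    stop2("degenerate stratification: all scores identical")
  group <- factor(ifelse(scores > cutoff, "high", "low"),
                  levels = c("low", "high"))
  structure(list(sample_ids = names(scores), lrgpi = scores,
                 cutoff = cutoff, group = group),
            class = "risk_profile")
}

#' Train a gene-pair prognostic index end to end
#'
#' Runs the full construction: short-follow-up exclusion, univariate gene
#' screen, candidate-pair enumeration, binary pair encoding, consistency
#' filter, univariate pair screen, two-stage adaptive-LASSO fit, index
#' computation, median stratification, and evaluation. Per-stage feature
#' counts are recorded for provenance.
#'
#' @param expr genes x samples expression matrix (any scale comparable
#'   within a sample).
#' @param clinical clinical table; only samples present in both inputs are
#'   used.
#' @param genes optional candidate gene universe (default: all matrix
#'   rows); genes with missing values are dropped with a warning.
#' @param config a [pipeline_config()].
#' @return object of class `lrgpi_fit`: `signature`, `profile` (a
#'   `risk_profile`, `NULL` when the signature is empty/degenerate),
#'   `report` (stage counts, evaluation metrics, flags), `config`.
#' @export
train_lrgpi <- function(expr, clinical, genes = NULL,
                        config = pipeline_config()) {
  check_expression_matrix(expr)
  check_clinical(clinical)
  shared <- intersect(colnames(expr), clinical$sample_id)
  if (!length(shared)) stop2("no overlapping samples between expr and clinical")
  if (is.null(genes)) genes <- rownames(expr)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing))
    stop2("candidate gene(s) absent from expression matrix: ",
          paste(missing, collapse = ", "))
  expr <- expr[genes, shared, drop = FALSE]
  has_na <- apply(expr, 1, anyNA)
  if (any(has_na)) {
    warning("dropping gene(s) with missing values: ",
            paste(rownames(expr)[has_na], collapse = ", "))
    expr <- expr[!has_na, , drop = FALSE]
  }
  clinical <- align_clinical(clinical, shared)

  run <- function(stage, fun) {
    tryCatch(fun(), error = function(e)
      stop2("[", stage, "] ", conditionMessage(e)))
  }
  clin <- run("exclude_short_followup", function()
    exclude_short_followup(clinical, config$min_followup_months))
  expr <- expr[, clin$sample_id, drop = FALSE]

  prog <- run("screen_prognostic_genes", function()
    screen_prognostic_genes(expr, clin, config$gene_screen_alpha))
  gene_p <- attr(prog, "p_values")
  pairs <- run("enumerate_candidate_pairs", function()
    enumerate_candidate_pairs(as.character(prog), rownames(expr), gene_p))
  pm <- run("build_pair_matrix", function() build_pair_matrix(expr, pairs))
  pm_f <- run("consistency_filter", function()
    consistency_filter(pm, config$consistency_threshold))
  pm_s <- run("screen_prognostic_pairs", function()
    screen_prognostic_pairs(pm_f, clin, config$pair_screen_alpha))
  signature <- run("fit_signature", function()
    fit_signature(pm_s, clin, config$adaptive))

  counts <- list(samples_in = length(shared),
                 samples_after_followup_filter = nrow(clin),
                 genes_in = nrow(expr),
                 prognostic_genes = length(prog),
                 pairs_generated = nrow(pairs),
                 pairs_after_consistency_filter = nrow(pm_f),
                 pairs_after_cox_screen = nrow(pm_s),
                 pairs_in_signature = length(signature$coefficients))

  lrgpi <- compute_lrgpi(pm, signature)
  degenerate <- length(signature$coefficients) == 0L ||
    length(unique(lrgpi)) == 1L
  profile <- NULL
  evaluation <- NULL
  if (!degenerate) {
    profile <- stratify(lrgpi, "median")
    evaluation <- evaluate(profile, clin,
                           horizons = config$evaluation_horizons)
  }
  report <- list(stage_counts = counts,
                 degenerate = degenerate,
                 cutoff = if (!degenerate) profile$cutoff else NA_real_,
                 evaluation = evaluation,
                 seed = config$seed)
  if (degenerate)
    warning("degenerate fit: empty signature or constant index; ",
            "stratification and evaluation skipped")
  structure(list(signature = signature, profile = profile,
                 report = report, config = config),
            class = "lrgpi_fit")
}

#' @export
print.lrgpi_fit <- function(x, ...) {
  cat("Gene-pair prognostic index fit\n")
  cnt <- x$report$stage_counts
  cat(sprintf("  %d genes -> %d prognostic -> %d pairs -> %d filtered -> %d screened -> %d in signature\n",
              cnt$genes_in, cnt$prognostic_genes, cnt$pairs_generated,
              cnt$pairs_after_consistency_filter, cnt$pairs_after_cox_screen,
              cnt$pairs_in_signature))
  if (x$report$degenerate) {
    cat("  DEGENERATE: empty or constant index\n")
  } else {
    ev <- x$report$evaluation
    cat(sprintf("  log-rank chi2 = %.3f (p = %.3g); C-index = %.3f\n",
                ev$logrank$chi2, ev$logrank$p, ev$c_index))
    cat("  AUC:", paste(sprintf("%s = %.3f", names(ev$auc), ev$auc),
                        collapse = ", "), "\n")
  }
  invisible(x)
}

#' Evaluate a risk profile against censored outcomes
#'
#' Kaplan-Meier curves and log-rank test for the high/low groups,
#' time-dependent AUC and concordance of the continuous index, and —
#' when covariate names are supplied — a multivariable Cox model of the
#' index adjusted for those covariates, with its linear predictor (the
#' nomogram score) and a calibration table of model-predicted versus
#' observed survival at each horizon.
#'
#' @param profile a `risk_profile` (see [stratify()]).
#' @param clinical clinical table covering the profile's samples.
#' @param covariates optional character vector of clinical column names to
#'   adjust for; missing columns skip the adjusted model with a warning.
#' @param horizons AUC/calibration horizons (months); horizons beyond the
#'   observed follow-up are dropped with a warning.
#' @return list: `logrank`, `km` (per-group curves), `auc`, `c_index`,
#'   and optionally `adjusted` (Cox table, linear predictor, calibration).
#' @export
evaluate <- function(profile, clinical, covariates = NULL,
                     horizons = c(12, 36, 60)) {
  if (!inherits(profile, "risk_profile")) stop2("profile must be a risk_profile")
  clin <- align_clinical(clinical, profile$sample_ids)
  ok <- horizons <= max(clin$time_months)
  if (!all(ok)) {
    warning("dropping horizon(s) beyond observed follow-up: ",
            paste(horizons[!ok], collapse = ", "))
    horizons <- horizons[ok]
  }
  auc <- tryCatch(time_dependent_auc(profile$lrgpi, clin, horizons),
                  error = function(e) {
                    warning("AUC unavailable: ", conditionMessage(e))
                    NULL
                  })
  out <- list(
    logrank = logrank_test(profile$group, clin),
    km = lapply(split(clin, profile$group), km_curve),
    auc = auc,
    c_index = concordance_index(profile$lrgpi, clin))
  if (!is.null(covariates)) {
    missing <- setdiff(covariates, names(clin))
    if (length(missing)) {
      warning("covariate(s) missing from clinical table, adjusted model ",
              "skipped: ", paste(missing, collapse = ", "))
    } else {
      x <- cbind(lrgpi = profile$lrgpi,
                 as.matrix(clin[, covariates, drop = FALSE]))
      fit <- fit_cox(x, clin)
      lp <- as.numeric(x %*% fit$beta)
      pred <- lapply(horizons, function(h)
        predicted_survival_at(h, lp, clin))
      names(pred) <- paste0("t", horizons)
      calib <- lapply(seq_along(horizons), function(i)
        calibration_at(horizons[i], pred[[i]], clin))
      names(calib) <- paste0("t", horizons)
      out$adjusted <- list(cox = fit, linear_predictor = lp,
                           auc = if (length(horizons))
                             time_dependent_auc(lp, clin, horizons) else NULL,
                           calibration = calib)
    }
  }
  out
}

# Breslow baseline + linear predictor -> per-sample predicted survival at t.
predicted_survival_at <- function(t, lp, clinical) {
  bh <- breslow_cumhaz(clinical$time_months, clinical$event, lp)
  H0 <- eval_curve(bh$time, bh$cumhaz, t, anchor = 0)
  exp(-H0 * exp(lp))
}

# Breslow estimator of the baseline cumulative hazard for a fixed linear
# predictor (uncentered, so H0 pairs with exp(lp) directly).
breslow_cumhaz <- function(time, event, lp) {
  r <- exp(lp)
  dt <- sort(unique(time[event == 1]))
  haz <- vapply(dt, function(t)
    sum(event == 1 & time == t) / sum(r[time >= t]), numeric(1))
  list(time = dt, cumhaz = cumsum(haz))
}
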