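#' Configuration for the two-stage adaptive LASSO Cox fit
#'
#' @param n_folds cross-validation folds (default 10).
#' @param weight_cap upper bound on adaptive penalty weights `1/|beta|`;
#'   ridge coefficients are never exactly zero, but near-zero ones would
#'   otherwise yield numerically infinite penalties. Default 1e6.
#' @param fold_seed seed for fold assignment. Folds are keyed to sorted
#'   sample ids within event strata, so permuting sample order cannot
#'   change the fit.
#' @param selection_rule `"lambda_min"` (penalty at the minimum mean
#'   cross-validated partial-likelihood deviance, the default) or
#'   `"lambda_1se"`.
#' @param lambda_grid,ridge_lambda_grid optional descending penalty grids
#'   for the LASSO and ridge stages; `NULL` lets glmnet derive a log-spaced
#'   grid from the data.
#' @param nlambda grid length when grids are data-derived.
#' @param standardize standardize features before penalization. Default
#'   `FALSE`: pair scores already share the common \{0, 1\} scale, and
#'   standardizing would reweight pairs by prevalence.
#' @return object of class `adaptive_lasso_config`.
#' @export
adaptive_lasso_config <- function(n_folds = 10L, weight_cap = 1e6,
                                  fold_seed = 1L,
                                  selection_rule = c("lambda_min", "lambda_1se"),
                                  lambda_grid = NULL,
                                  ridge_lambda_grid = NULL,
                                  nlambda = 100L,
                                  standardize = FALSE) {
  n_folds <- as.integer(n_folds)
  weight_cap <- as.numeric(weight_cap)
  if (n_folds < 2L) stop2("n_folds must be >= 2")
  if (weight_cap <= 0) stop2("weight_cap must be positive")
  check_grid <- function(g, nm) {
    if (!is.null(g) && (any(g <= 0) || is.unsorted(rev(g), strictly = TRUE)))
      stop2(nm, " must be strictly descending and positive")
  }
  check_grid(lambda_grid, "lambda_grid")
  check_grid(ridge_lambda_grid, "ridge_lambda_grid")
  structure(list(n_folds = n_folds, weight_cap = weight_cap,
                 fold_seed = as.integer(fold_seed),
                 selection_rule = match.arg(selection_rule),
                 lambda_grid = lambda_grid,
                 ridge_lambda_grid = ridge_lambda_grid,
                 nlambda = as.integer(nlambda),
                 standardize = isTRUE(standardize)),
            class = "adaptive_lasso_config")
}

# Event-stratified fold assignment keyed to sorted sample ids, so the
# result is invariant to the row order of the input.
make_foldid <- function(sample_ids, event, n_folds, seed) {
  foldid <- integer(length(sample_ids))
  with_seed(seed, {
    for (ev in c(1L, 0L)) {
      idx <- which(event == ev)
      if (!length(idx)) next
      idx <- idx[order(sample_ids[idx])]
      foldid[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  })
  foldid
}

cv_glmnet_cox <- function(x, clinical, alpha, config, penalty.factor = NULL) {
  if (ncol(x) < 2L)
    stop2("penalized Cox fit needs at least 2 features")
  n_events <- sum(clinical$event)
  if (n_events < config$n_folds)
    stop2("only ", n_events, " events for ", config$n_folds,
          "-fold CV; use fewer folds")
  y <- survival::Surv(clinical$time_months, clinical$event)
  foldid <- make_foldid(clinical$sample_id, clinical$event,
                        config$n_folds, config$fold_seed)
  lambda <- if (alpha == 0) config$ridge_lambda_grid else config$lambda_grid
  if (is.null(penalty.factor)) penalty.factor <- rep(1, ncol(x))
  args <- list(x = x, y = y, family = "cox", alpha = alpha,
               foldid = foldid, standardize = config$standardize,
               penalty.factor = penalty.factor,
               type.measure = "deviance", nlambda = config$nlambda,
               thresh = 1e-16, maxit = 1e6)
  if (!is.null(lambda)) args$lambda <- lambda
  do.call(glmnet::cv.glmnet, args)
}

selected_lambda <- function(cvfit, rule) {
  if (rule == "lambda_1se") cvfit$lambda.1se else cvfit$lambda.min
}

#' Cross-validated ridge Cox fit (stage 1)
#'
#' Fits an L2-penalized Cox model over a descending penalty grid and
#' returns the full coefficient vector at the penalty minimizing the mean
#' cross-validated partial-likelihood deviance. These coefficients define
#' the adaptive penalty weights of stage 2.
#'
#' @param pair_matrix binary pair-score matrix (pairs x samples).
#' @param clinical clinical table aligned with the matrix columns.
#' @param config an [adaptive_lasso_config()].
#' @return named numeric vector of ridge coefficients (one per pair), with
#'   the selected penalty as attribute `lambda`.
#' @export
cv_ridge_cox <- function(pair_matrix, clinical, config = adaptive_lasso_config()) {
  clinical <- align_clinical(clinical, colnames(pair_matrix))
  cvfit <- cv_glmnet_cox(t(pair_matrix), clinical, alpha = 0, config)
  lam <- selected_lambda(cvfit, config$selection_rule)
  beta <- as.numeric(stats::coef(cvfit, s = lam))
  names(beta) <- rownames(pair_matrix)
  attr(beta, "lambda") <- lam
  beta
}

#' Adaptive penalty weights from ridge coefficients
#'
#' `w_j = min(1 / |beta_j|, cap)`: features with large ridge effects get
#' small penalties and are easy to keep; near-null features are penalized
#' heavily. This differential penalty is what gives the adaptive LASSO its
#' oracle selection behaviour relative to the uniform penalty of plain
#' LASSO.
#'
#' @param beta_ridge finite numeric vector of stage-1 coefficients.
#' @param cap truncation bound for the weights.
#' @return numeric weight vector aligned with `beta_ridge`.
#' @export
adaptive_weights <- function(beta_ridge, cap = 1e6) {
  if (any(!is.finite(beta_ridge))) stop2("beta_ridge must be finite")
  if (cap <= 0) stop2("cap must be positive")
  w <- 1 / abs(beta_ridge)
  w[!is.finite(w)] <- cap
  pmin(w, cap)
}

#' Cross-validated weighted LASSO Cox fit (stage 2)
#'
#' Fits an L1-penalized Cox model with per-feature penalty factors and
#' selects the penalty at the minimum mean cross-validated
#' partial-likelihood deviance. An all-zero solution at every penalty is a
#' valid outcome under the null and returns an empty coefficient set with a
#' warning.
#'
#' @inheritParams cv_ridge_cox
#' @param weights positive finite per-pair penalty factors (stage-1 output
#'   through [adaptive_weights()]).
#' @return list with `lambda_selected` and `coefficients` (named vector of
#'   the nonzero coefficients only; length 0 under full shrinkage).
#' @export
cv_weighted_lasso_cox <- function(pair_matrix, clinical, weights,
                                  config = adaptive_lasso_config()) {
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop2("weights must be positive and finite")
  clinical <- align_clinical(clinical, colnames(pair_matrix))
  cvfit <- cv_glmnet_cox(t(pair_matrix), clinical, alpha = 1, config,
                         penalty.factor = weights)
  lam <- selected_lambda(cvfit, config$selection_rule)
  beta <- as.numeric(stats::coef(cvfit, s = lam))
  names(beta) <- rownames(pair_matrix)
  nz <- beta[beta != 0]
  if (!length(nz))
    warning("all coefficients zero at the selected penalty; empty signature")
  list(lambda_selected = lam, coefficients = nz)
}

#' Fit a gene-pair signature by adaptive LASSO
#'
#' Composes the two stages — cross-validated ridge for penalty weights,
#' then cross-validated weighted LASSO — and packages the selected pairs,
#' their coefficients and full provenance (penalties, seeds, stage counts)
#' into a frozen signature that can score any cohort.
#'
#' Degenerate candidate sets are handled explicitly: zero candidate pairs
#' give an empty signature; a single candidate pair is assigned its
#' unpenalized univariate Cox coefficient (penalized selection among one
#' feature is vacuous).
#'
#' @inheritParams cv_ridge_cox
#' @return object of class `pair_signature`: `pairs` (a `gene_pair_set`),
#'   `coefficients`, `lambda_selected`, `lambda_ridge`, `ridge_betas`,
#'   `config`, `n_candidates`.
#' @export
fit_signature <- function(pair_matrix, clinical, config = adaptive_lasso_config()) {
  n_pairs <- nrow(pair_matrix)
  if (n_pairs == 0L) {
    warning("no candidate pairs; returning empty signature")
    return(new_pair_signature(character(), numeric(), NA_real_, NA_real_,
                              numeric(), config, 0L))
  }
  clinical <- align_clinical(clinical, colnames(pair_matrix))
  if (n_pairs == 1L) {
    cf <- fit_cox(t(pair_matrix), clinical)
    beta <- stats::setNames(as.numeric(cf$beta), rownames(pair_matrix))
    return(new_pair_signature(rownames(pair_matrix), beta,
                              NA_real_, NA_real_, beta, config, 1L))
  }
  ridge <- cv_ridge_cox(pair_matrix, clinical, config)
  w <- adaptive_weights(ridge, config$weight_cap)
  lasso <- cv_weighted_lasso_cox(pair_matrix, clinical, w, config)
  new_pair_signature(names(lasso$coefficients), lasso$coefficients,
                     lasso$lambda_selected, attr(ridge, "lambda"),
                     as.numeric(ridge), config, n_pairs,
                     ridge_names = names(ridge))
}

new_pair_signature <- function(pair_nm, coefficients, lambda_selected,
                               lambda_ridge, ridge_betas, config,
                               n_candidates, ridge_names = names(ridge_betas)) {
  structure(list(
    pairs = pairs_from_names(pair_nm),
    coefficients = stats::setNames(as.numeric(coefficients), pair_nm),
    lambda_selected = lambda_selected,
    lambda_ridge = lambda_ridge,
    ridge_betas = stats::setNames(as.numeric(ridge_betas), ridge_names),
    config = list(n_folds = config$n_folds, weight_cap = config$weight_cap,
                  fold_seed = config$fold_seed,
                  selection_rule = config$selection_rule,
                  standardize = config$standardize),
    n_candidates = as.integer(n_candidates)),
    class = "pair_signature")
}

#' @export
print.pair_signature <- function(x, ...) {
  cat("Gene-pair signature:", length(x$coefficients), "pairs (of",
      x$n_candidates, "candidates)\n")
  if (length(x$coefficients)) {
    print(data.frame(pair = names(x$coefficients),
                     coefficient = as.numeric(x$coefficients),
                     row.names = NULL))
  }
  invisible(x)
}

#' @export
length.pair_signature <- function(x) length(x$coefficients)
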