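#' Fit a Cox proportional hazards model
#'
#' Thin, validated wrapper around the partial-likelihood maximizer of the
#' survival package (Efron tie handling), returning a flat result with a
#' convergence flag. Monotone-likelihood cases (perfect separation, where
#' the partial likelihood has no finite maximizer) are flagged as
#' `converged = FALSE` instead of silently returning a huge coefficient:
#' any coefficient exceeding 20 in absolute value is treated as divergent,
#' since |log hazard ratio| = 20 is far beyond anything estimable from
#' biological data.
#'
#' @param x covariate vector or matrix (samples x covariates), no missing
#'   values, no constant column.
#' @param clinical clinical table with `time_months` and `event`.
#' @param ties tie-handling method, `"efron"` (default) or `"breslow"`.
#' @return list of class `cox_fit`: `beta`, `se`, `hazard_ratio`
#'   (`= exp(beta)`), `wald_z`, `p_value` (two-sided Wald), `loglik`,
#'   `converged`, `n`, `n_events`.
#' @export
fit_cox <- function(x, clinical, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  check_clinical(clinical)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (nrow(x) != nrow(clinical))
    stop2("x and clinical have different numbers of samples")
  if (anyNA(x) || any(!is.finite(x))) stop2("x contains missing or non-finite values")
  if (sum(clinical$event) < 1) stop2("no events in clinical table")
  cv <- apply(x, 2, function(col) stats::var(col))
  if (any(cv == 0))
    stop2("covariate has no variation: ",
          paste(colnames(x)[cv == 0], collapse = ", "))
  y <- survival::Surv(clinical$time_months, clinical$event)
  fit <- suppressWarnings(
    survival::coxph.fit(x = x, y = y, strata = NULL, offset = NULL,
                        init = NULL,
                        control = survival::coxph.control(iter.max = 30),
                        weights = NULL, method = ties,
                        rownames = seq_len(nrow(x))))
  beta <- as.numeric(fit$coefficients)
  se <- sqrt(diag(as.matrix(fit$var)))
  names(beta) <- names(se) <- colnames(x)
  converged <- all(is.finite(beta)) && all(is.finite(se)) &&
    all(abs(beta) < 20)
  z <- beta / se
  structure(list(beta = beta, se = se, hazard_ratio = exp(beta),
                 wald_z = z,
                 p_value = 2 * stats::pnorm(-abs(z)),
                 loglik = fit$loglik,
                 converged = converged,
                 n = nrow(x), n_events = sum(clinical$event)),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox fit:", x$n, "samples,", x$n_events, "events",
      if (!x$converged) "(NOT converged)" else "", "\n")
  print(data.frame(beta = x$beta, HR = x$hazard_ratio, se = x$se,
                   z = x$wald_z, p = x$p_value))
  invisible(x)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate; deaths precede censorings at tied times (the
#' standard convention).
#'
#' @param clinical clinical table with `time_months` and `event`.
#' @return data frame of class `survival_curve` with columns `time`,
#'   `survival`, `n_risk`, `n_event`; begins with the (0, 1) anchor row.
#' @export
km_curve <- function(clinical) {
  check_clinical(clinical)
  if (!nrow(clinical)) stop2("clinical table is empty")
  fit <- survival::survfit(
    survival::Surv(time_months, event) ~ 1, data = clinical)
  structure(data.frame(time = c(0, fit$time),
                       survival = c(1, fit$surv),
                       n_risk = c(fit$n, fit$n.risk),
                       n_event = c(0, fit$n.event)),
            class = c("survival_curve", "data.frame"))
}

# Right-continuous step evaluation of a survival curve S(t); left = TRUE
# gives the left limit S(t-); anchor is the value before the first knot.
eval_curve <- function(times, surv, t, left = FALSE, anchor = 1) {
  if (!length(times)) return(rep(anchor, length(t)))
  f <- stats::stepfun(times, c(anchor, surv), right = left)
  f(t)
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic with hypergeometric variance, referred to a
#' chi-square distribution with one degree of freedom.
#'
#' @param groups two-level grouping vector aligned with `clinical` rows.
#' @param clinical clinical table with `time_months` and `event`.
#' @return list with `chi2` and `p`.
#' @export
logrank_test <- function(groups, clinical) {
  check_clinical(clinical)
  g <- as.factor(groups)
  if (nlevels(droplevels(g)) != 2)
    stop2("groups must contain exactly two nonempty groups")
  if (sum(clinical$event) < 1) stop2("no events in clinical table")
  d <- data.frame(time = clinical$time_months, event = clinical$event, g = g)
  sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = d)
  chi2 <- as.numeric(sd$chisq)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Time-dependent AUC under right-censoring
#'
#' Cumulative-case / dynamic-control AUC at each horizon t: cases are
#' samples with an observed event by t, controls are samples still under
#' observation beyond t. Both are weighted by inverse probabilities of
#' censoring (IPCW) from the Kaplan-Meier estimate of the censoring
#' distribution, so the estimate targets the censoring-free population.
#' With no censoring the weights are all 1 and the estimator reduces
#' exactly to the plain binary AUC of the event indicator against the
#' score. Tied scores count 1/2. The estimate depends on the scores only
#' through their ranks.
#'
#' @param scores continuous risk scores (higher = higher risk).
#' @param clinical clinical table with `time_months` and `event`.
#' @param horizons evaluation times (months) within observed follow-up.
#' @return named numeric vector, one AUC in \[0, 1\] per horizon.
#' @export
time_dependent_auc <- function(scores, clinical, horizons) {
  check_clinical(clinical)
  if (length(scores) != nrow(clinical))
    stop2("scores and clinical have different lengths")
  time <- clinical$time_months; event <- clinical$event
  if (any(horizons > max(time)))
    stop2("horizon beyond last observed time")
  # KM of the censoring distribution (event indicator flipped)
  cfit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  G_left <- function(t) pmax(eval_curve(cfit$time, cfit$surv, t, left = TRUE),
                             .Machine$double.eps)
  G_right <- function(t) pmax(eval_curve(cfit$time, cfit$surv, t, left = FALSE),
                              .Machine$double.eps)
  out <- vapply(horizons, function(h) {
    case <- time <= h & event == 1
    ctrl <- time > h
    if (!any(case) || !any(ctrl))
      stop2("no case or no control at horizon ", h)
    w_case <- 1 / G_left(time[case])
    w_ctrl <- rep(1 / G_right(h), sum(ctrl))
    sc <- scores[case]; st <- scores[ctrl]
    num <- 0
    for (i in seq_along(sc)) {
      num <- num + w_case[i] *
        sum(w_ctrl * ((sc[i] > st) + 0.5 * (sc[i] == st)))
    }
    num / (sum(w_case) * sum(w_ctrl))
  }, numeric(1))
  stats::setNames(out, paste0("t", horizons))
}

#' Harrell's concordance index for a risk score
#'
#' Probability that, of a usable (comparable) sample pair, the one with the
#' higher score fails first. Tied scores count 1/2; pairs with tied failure
#' times are not counted.
#'
#' @param scores risk scores (higher = higher risk).
#' @param clinical clinical table with `time_months` and `event`.
#' @return concordance in \[0, 1\].
#' @export
concordance_index <- function(scores, clinical) {
  check_clinical(clinical)
  if (length(scores) != nrow(clinical))
    stop2("scores and clinical have different lengths")
  d <- data.frame(time = clinical$time_months, event = clinical$event,
                  s = scores)
  cf <- survival::concordance(survival::Surv(time, event) ~ s, data = d)
  cnt <- cf$count
  usable <- cnt["concordant"] + cnt["discordant"] + cnt["tied.x"]
  if (usable == 0) stop2("no comparable pairs")
  # survival counts concordance as higher score ~ longer survival; a risk
  # score predicts shorter survival, so flip
  as.numeric((cnt["discordant"] + 0.5 * cnt["tied.x"]) / usable)
}

#' Calibration of predicted survival at a horizon
#'
#' Samples are binned into quantile bins of predicted survival at `t`; each
#' bin contributes its mean prediction and the Kaplan-Meier observed
#' survival at `t`. Empty or duplicate-quantile bins are merged with their
#' neighbours (a message reports the effective bin count).
#'
#' @param t horizon (months).
#' @param predicted_survival per-sample predicted survival probabilities at
#'   `t`, in \[0, 1\].
#' @param clinical clinical table with `time_months` and `event`.
#' @param n_bins requested number of quantile bins.
#' @return data frame with columns `bin`, `n`, `mean_predicted`,
#'   `observed_km`.
#' @export
calibration_at <- function(t, predicted_survival, clinical, n_bins = 5L) {
  check_clinical(clinical)
  p <- predicted_survival
  if (any(p < 0 | p > 1)) stop2("predictions must be in [0, 1]")
  if (length(p) != nrow(clinical))
    stop2("predictions and clinical have different lengths")
  breaks <- unique(stats::quantile(p, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(breaks) < 2) {
    bins <- factor(rep(1L, length(p)))
  } else {
    bins <- cut(p, breaks = breaks, include.lowest = TRUE, labels = FALSE)
    bins <- factor(bins)
  }
  if (nlevels(bins) < n_bins)
    message("calibration_at: ", n_bins, " bins requested, ",
            nlevels(bins), " effective after merging")
  res <- lapply(levels(bins), function(b) {
    idx <- bins == b
    km <- km_curve(clinical[idx, , drop = FALSE])
    data.frame(bin = as.integer(b), n = sum(idx),
               mean_predicted = mean(p[idx]),
               observed_km = eval_curve(km$time[-1], km$survival[-1], t))
  })
  do.call(rbind, res)
}
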