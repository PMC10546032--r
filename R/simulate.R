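#' Configuration for a synthetic survival cohort
#'
#' Describes a cohort whose hazard is driven by planted gene-pair ordering
#' indicators: expression is normal on the log2 scale with per-gene location
#' and scale, each sample's hazard is
#' \deqn{h_s = h_0 \exp\left(\sum_k \beta_k \, 1[x_{a_k,s} > x_{b_k,s}]\right)}
#' event times are exponential given that hazard (so proportional hazards
#' holds by construction), and censoring is uniform with an upper bound
#' calibrated by bisection to reach a target censoring fraction.
#'
#' Genes involved in a planted pair have their two means replaced by the
#' pair average, so the planted ordering indicator is balanced across
#' samples; a strongly unbalanced pair would be near-constant and removed by
#' the downstream consistency filter, leaving nothing to recover.
#'
#' @param n_genes,n_samples cohort dimensions.
#' @param planted_pairs data frame with columns `gene_a`, `gene_b`
#'   (1-based gene indices) and `beta` (log hazard ratio of the ordering
#'   indicator), or `NULL` for a pure-noise cohort.
#' @param gene_means,gene_sds per-gene log2-expression location and scale;
#'   defaults are drawn once from Uniform(4, 8) (means) and 1 (sds) under
#'   `seed`.
#' @param baseline_hazard baseline event rate, events per month.
#' @param censoring_rate_target desired realized censoring fraction in
#'   \[0, 1\].
#' @param max_followup starting upper bound of the uniform censoring
#'   distribution, months; the calibration widens it when the target asks
#'   for less censoring than the window can deliver.
#' @param with_covariates add outcome-independent clinical covariates
#'   (age, t_stage, grade, metastasis) to the clinical table, useful for
#'   adjusted-model tests.
#' @param seed integer seed; the cohort is a pure function of the config.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 50L, n_samples = 300L,
                              planted_pairs = NULL,
                              gene_means = NULL, gene_sds = NULL,
                              baseline_hazard = 0.02,
                              censoring_rate_target = 0.3,
                              max_followup = 120,
                              with_covariates = FALSE,
                              seed = 1L) {
  n_genes <- as.integer(n_genes); n_samples <- as.integer(n_samples)
  if (is.na(n_genes) || n_genes < 1L) stop2("n_genes must be a positive integer")
  if (is.na(n_samples) || n_samples < 1L) stop2("n_samples must be a positive integer")
  if (baseline_hazard <= 0) stop2("baseline_hazard must be positive")
  if (censoring_rate_target < 0 || censoring_rate_target > 1)
    stop2("censoring_rate_target must be in [0, 1]")
  if (max_followup <= 0) stop2("max_followup must be positive")
  if (is.null(gene_means))
    gene_means <- with_seed(seed, stats::runif(n_genes, 4, 8))
  if (is.null(gene_sds)) gene_sds <- rep(1, n_genes)
  if (length(gene_means) != n_genes || length(gene_sds) != n_genes)
    stop2("gene_means and gene_sds must have length n_genes")
  if (any(gene_sds <= 0)) stop2("gene_sds must be positive")
  if (!is.null(planted_pairs)) {
    planted_pairs <- as.data.frame(planted_pairs)
    need <- c("gene_a", "gene_b", "beta")
    if (!all(need %in% names(planted_pairs)))
      stop2("planted_pairs needs columns gene_a, gene_b, beta")
    if (nrow(planted_pairs)) {
      ok <- planted_pairs$gene_a != planted_pairs$gene_b &
        planted_pairs$gene_a >= 1 & planted_pairs$gene_a <= n_genes &
        planted_pairs$gene_b >= 1 & planted_pairs$gene_b <= n_genes
      if (!all(ok)) stop2("planted pair indices must be distinct and within 1..n_genes")
      # balance the planted indicator (see Details)
      m <- (gene_means[planted_pairs$gene_a] + gene_means[planted_pairs$gene_b]) / 2
      gene_means[planted_pairs$gene_a] <- m
      gene_means[planted_pairs$gene_b] <- m
    }
  } else {
    planted_pairs <- data.frame(gene_a = integer(), gene_b = integer(),
                                beta = numeric())
  }
  structure(list(n_genes = n_genes, n_samples = n_samples,
                 planted_pairs = planted_pairs,
                 gene_means = gene_means, gene_sds = gene_sds,
                 baseline_hazard = baseline_hazard,
                 censoring_rate_target = censoring_rate_target,
                 max_followup = max_followup,
                 with_covariates = isTRUE(with_covariates),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate a synthetic expression + survival cohort
#'
#' @param config a [simulation_config()].
#' @return a list of class `synthetic_cohort` with elements
#'   `expression` (genes x samples numeric matrix), `clinical`
#'   (data frame: sample_id, time_months, event, optional covariates),
#'   and `truth` (planted pairs with gene symbols, the per-sample true
#'   hazard, and the calibrated censoring bound).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "simulation_config"))
    stop2("config must be a simulation_config")
  ng <- config$n_genes; ns <- config$n_samples
  genes <- sprintf("G%03d", seq_len(ng))
  samples <- sprintf("S%04d", seq_len(ns))
  with_seed(config$seed, {
    expr <- matrix(stats::rnorm(ng * ns, mean = config$gene_means,
                                sd = config$gene_sds),
                   nrow = ng, ncol = ns, dimnames = list(genes, samples))
    lp <- numeric(ns)
    pp <- config$planted_pairs
    if (nrow(pp)) {
      for (k in seq_len(nrow(pp))) {
        z <- as.numeric(expr[pp$gene_a[k], ] > expr[pp$gene_b[k], ])
        lp <- lp + pp$beta[k] * z
      }
    }
    hazard <- config$baseline_hazard * exp(lp)
    t_event <- stats::rexp(ns, rate = hazard)
    u <- stats::runif(ns)
    cens <- calibrate_censoring(t_event, u, config$censoring_rate_target,
                                config$max_followup)
    time <- pmin(t_event, cens$times)
    event <- as.integer(t_event <= cens$times)
    clinical <- data.frame(sample_id = samples,
                           time_months = time, event = event,
                           stringsAsFactors = FALSE)
    if (config$with_covariates) {
      clinical$age <- stats::rnorm(ns, 60, 10)
      clinical$t_stage <- sample(1:4, ns, replace = TRUE,
                                 prob = c(0.45, 0.1, 0.35, 0.1))
      clinical$grade <- sample(1:4, ns, replace = TRUE,
                               prob = c(0.05, 0.4, 0.4, 0.15))
      clinical$metastasis <- stats::rbinom(ns, 1, 0.2)
    }
    truth <- list(
      pairs = if (nrow(pp)) data.frame(gene_a = genes[pp$gene_a],
                                       gene_b = genes[pp$gene_b],
                                       beta = pp$beta,
                                       stringsAsFactors = FALSE)
              else data.frame(gene_a = character(), gene_b = character(),
                              beta = numeric()),
      hazard = stats::setNames(hazard, samples),
      censoring_bound = cens$bound)
    structure(list(expression = expr, clinical = clinical, truth = truth),
              class = "synthetic_cohort")
  })
}

# Bisection on the uniform-censoring upper bound so the realized censoring
# fraction lands near the target without rejection sampling. C_s = u * U_s
# is monotone in u per sample, so the realized fraction is monotone too.
calibrate_censoring <- function(t_event, unif, target, max_followup) {
  if (target == 0)
    return(list(times = rep(Inf, length(t_event)), bound = Inf))
  frac_at <- function(u) mean(u * unif < t_event)
  lo <- 1e-9; hi <- max_followup
  # widen the bound when even censoring uniform on (0, max_followup] censors
  # more than the target (long event times relative to follow-up)
  while (frac_at(hi) > target && hi < 1e7) hi <- hi * 2
  # frac_at is nonincreasing in u: small bounds censor almost everyone
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (frac_at(mid) > target) lo <- mid else hi <- mid
  }
  u <- (lo + hi) / 2
  list(times = u * unif, bound = u)
}

#' Apply a per-sample monotone platform distortion
#'
#' Emulates cross-platform and normalisation differences: each sample's
#' expression vector is passed through its own strictly increasing map, so
#' within-sample gene orderings (and hence all pair scores) are unchanged
#' while absolute values, scales and even marginal shapes differ.
#'
#' @param expr genes x samples numeric matrix.
#' @param kind `"identity"`, `"affine"` (x -> a_s x + b_s, a_s > 0) or
#'   `"monotone_nonlinear"` (x -> a_s x^3 + b_s x + c_s with a_s, b_s > 0).
#' @param seed seed for the per-sample coefficients.
#' @return matrix of identical shape and dimnames.
#' @export
apply_platform_transform <- function(expr, kind = c("identity", "affine",
                                                    "monotone_nonlinear"),
                                     seed = 1L) {
  check_expression_matrix(expr)
  kind <- match.arg(kind)
  if (kind == "identity") return(expr)
  ns <- ncol(expr)
  with_seed(seed, {
    out <- expr
    if (kind == "affine") {
      a <- stats::runif(ns, 0.5, 2)
      b <- stats::runif(ns, -5, 5)
      for (s in seq_len(ns)) out[, s] <- a[s] * expr[, s] + b[s]
    } else {
      a <- stats::runif(ns, 0.2, 1)
      b <- stats::runif(ns, 0.1, 1)
      cc <- stats::runif(ns, -2, 2)
      for (s in seq_len(ns)) {
        x <- expr[, s]
        out[, s] <- a[s] * x^3 + b[s] * x + cc[s]
      }
    }
    out
  })
}
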