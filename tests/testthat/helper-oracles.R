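# Independent brute-force oracles used to pin expected values. These stay
# deliberately naive (loops, enumeration, 1-d optimization) and share no
# code with the implementation they check.

# Cox partial log-likelihood for a single covariate, Breslow form (equals
# Efron when event times are untied).
oracle_partial_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Golden-section/grid maximizer of the partial likelihood on [-25, 25].
# Returns the argmax; a maximizer at the boundary signals monotone
# likelihood (no finite optimum).
oracle_cox_beta <- function(time, event, x) {
  opt <- stats::optimize(function(b) oracle_partial_loglik(b, time, event, x),
                         interval = c(-25, 25), maximum = TRUE,
                         tol = 1e-10)
  opt$maximum
}

# Hand log-rank: sum of (O - E) over death times with hypergeometric
# variance, two groups.
oracle_logrank_chi2 <- function(time, event, group) {
  g <- as.integer(factor(group))
  dt <- sort(unique(time[event == 1]))
  OE <- 0; V <- 0
  for (t in dt) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g == 1)
    OE <- OE + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n - d) * n1 * (n - n1) / (n^2 * (n - 1))
  }
  OE^2 / V
}

# Exhaustive-pair Harrell C: higher score should fail first; tied scores
# count 1/2; tied failure times are not usable.
oracle_cindex <- function(time, event, score) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (time[i] == time[j]) next
    first <- if (time[i] < time[j]) i else j
    later <- if (first == i) j else i
    if (event[first] != 1) next   # earlier time censored: not comparable
    den <- den + 1
    if (score[first] > score[later]) num <- num + 1
    else if (score[first] == score[later]) num <- num + 0.5
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

# Plain binary AUC of labels (1 = case) against scores, ties 1/2.
oracle_binary_auc <- function(labels, scores) {
  cs <- scores[labels == 1]; ct <- scores[labels == 0]
  tot <- 0
  for (a in cs) tot <- tot + sum(a > ct) + 0.5 * sum(a == ct)
  tot / (length(cs) * length(ct))
}

# Hand product-limit estimator at the distinct event times.
oracle_km <- function(time, event) {
  dt <- sort(unique(time[event == 1]))
  s <- 1; out <- numeric(length(dt))
  for (k in seq_along(dt)) {
    n_at <- sum(time >= dt[k])
    d <- sum(event == 1 & time == dt[k])
    s <- s * (1 - d / n_at)
    out[k] <- s
  }
  data.frame(time = dt, survival = out)
}

# Small planted-pair cohort shared by several tests.
make_planted_cohort <- function(seed, n_samples = 300, n_genes = 50,
                                betas = c(1, -1, 1, -1, 1)) {
  k <- length(betas)
  pp <- data.frame(gene_a = seq(1, 2 * k, by = 2),
                   gene_b = seq(2, 2 * k, by = 2),
                   beta = betas)
  generate_cohort(simulation_config(
    n_genes = n_genes, n_samples = n_samples, planted_pairs = pp,
    seed = seed))
}

truth_pair_names <- function(cohort) {
  with(cohort$truth$pairs,
       list(fwd = paste(gene_a, gene_b, sep = "|"),
            rev = paste(gene_b, gene_a, sep = "|")))
}

n_recovered <- function(cohort, signature) {
  tn <- truth_pair_names(cohort)
  sel <- names(signature$coefficients)
  sum(tn$fwd %in% sel | tn$rev %in% sel)
}
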