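clin <- function(time, event, ids = sprintf("s%d", seq_along(time))) {
  data.frame(sample_id = ids, time_months = time, event = event,
             stringsAsFactors = FALSE)
}

test_that("fit_cox matches the brute-force partial-likelihood oracle", {
  # 4 subjects, all events, binary covariate with alternating deaths
  # (the finite-maximum case; both-early deaths are monotone, see below)
  cl <- clin(c(1, 2, 3, 4), c(1, 1, 1, 1))
  x <- c(1, 0, 1, 0)
  fit <- fit_cox(x, cl)
  expect_true(fit$converged)
  b0 <- oracle_cox_beta(cl$time_months, cl$event, x)
  expect_lt(abs(b0), 19)  # interior maximum
  expect_lt(abs(as.numeric(fit$beta) - b0), 1e-4)
  expect_equal(unname(fit$hazard_ratio), exp(unname(fit$beta)))

  # random continuous-covariate tables, untied times
  set.seed(17)
  for (rep in 1:10) {
    n <- sample(4:6, 1)
    cl <- clin(sample(seq(1, 40), n), rbinom(n, 1, 0.8))
    if (sum(cl$event) == 0) cl$event[1] <- 1L
    x <- rnorm(n)
    b0 <- oracle_cox_beta(cl$time_months, cl$event, x)
    if (abs(b0) > 19) next  # monotone case, covered below
    expect_lt(abs(as.numeric(fit_cox(x, cl)$beta) - b0), 1e-4)
  }
})

test_that("fit_cox agrees with Breslow on tie-free data and validates input", {
  cl <- clin(c(3, 1, 4, 2, 6, 5), c(1, 0, 1, 1, 0, 1))
  x <- c(0.3, -1, 2, 0.1, 0.8, -0.5)
  expect_equal(as.numeric(fit_cox(x, cl)$beta),
               as.numeric(fit_cox(x, cl, ties = "breslow")$beta),
               tolerance = 1e-10)
  expect_error(fit_cox(rep(1, 6), cl), "no variation")
  expect_error(fit_cox(x, clin(1:6, rep(0, 6))), "no events")
  expect_error(fit_cox(c(x[-1], NA), cl), "missing")
})

test_that("monotone likelihood is flagged, never returned as converged", {
  # two subjects, both events, the high-covariate one dies first: the
  # partial likelihood e^b / (e^b + 1) has no finite maximizer
  cl <- clin(c(1, 2), c(1, 1))
  fit <- fit_cox(c(1, 0), cl)
  expect_false(fit$converged)
  # both x=1 subjects dying before both x=0 subjects is monotone too:
  # the brute-force maximizer pushes to the search boundary
  cl4 <- clin(1:4, rep(1, 4)); x4 <- c(1, 1, 0, 0)
  expect_gt(oracle_cox_beta(cl4$time_months, cl4$event, x4), 24)
  expect_false(fit_cox(x4, cl4)$converged)
})

test_that("Wald p-values are approximately uniform under the null", {
  set.seed(99)
  pv <- replicate(60, {
    cl <- clin(rexp(120), rbinom(120, 1, 0.7))
    as.numeric(fit_cox(rnorm(120), cl)$p_value)
  })
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
})

test_that("km_curve matches closed forms and the hand product-limit oracle", {
  # all events at distinct times: S = 1, 3/4, 1/2, 1/4, 0
  km <- km_curve(clin(1:4, rep(1, 4)))
  expect_equal(km$survival, c(1, 0.75, 0.5, 0.25, 0))
  # all censored
  expect_true(all(km_curve(clin(1:5, rep(0, 5)))$survival == 1))
  # mixed table vs oracle
  cl <- clin(c(2, 3, 3, 5, 7, 8, 9), c(1, 1, 0, 1, 0, 1, 0))
  km <- km_curve(cl)
  orc <- oracle_km(cl$time_months, cl$event)
  got <- km$survival[match(orc$time, km$time)]
  expect_equal(got, orc$survival, tolerance = 1e-12)
  # conservation: S(t) = prod(1 - d/n) exactly
  expect_equal(km$survival[-1], cumprod(1 - km$n_event[-1] / km$n_risk[-1]),
               tolerance = 1e-12)
})

test_that("log-rank matches hand oracle, symmetry and the Cox score link", {
  # interleaved identical event-time multisets: O = E everywhere
  cl <- clin(c(1, 1, 2, 2, 3, 3), rep(1, 6))
  g <- c("a", "b", "a", "b", "a", "b")
  expect_equal(logrank_test(g, cl)$chi2, 0, tolerance = 1e-12)

  # hand-computed 4-sample example: chi2 = (2/3)^2 / (13/18) = 0.6154
  cl <- clin(1:4, rep(1, 4)); g <- c("A", "B", "A", "B")
  lr <- logrank_test(g, cl)
  expect_equal(lr$chi2, oracle_logrank_chi2(cl$time_months, cl$event, g),
               tolerance = 1e-10)
  expect_equal(lr$chi2, (2 / 3)^2 / (13 / 18), tolerance = 1e-10)
  # label-swap invariance
  expect_equal(logrank_test(rev(g), cl)$chi2, lr$chi2, tolerance = 1e-12)
  # equals the Cox score test on the group indicator (tie-free data)
  sc <- survival::coxph(survival::Surv(time_months, event) ~ I(g == "A"),
                        data = cl)$score
  expect_equal(lr$chi2, as.numeric(sc), tolerance = 1e-6)
  expect_error(logrank_test(rep("A", 4), cl), "two")
})

test_that("planted-signal cohorts separate with p < 0.001", {
  pp <- data.frame(gene_a = 1, gene_b = 2, beta = 2)
  co <- generate_cohort(simulation_config(n_genes = 10, n_samples = 300,
                                          planted_pairs = pp, seed = 77))
  z <- as.numeric(co$expression["G001", ] > co$expression["G002", ])
  expect_lt(logrank_test(ifelse(z == 1, "hi", "lo"), co$clinical)$p, 0.001)
})

test_that("time-dependent AUC is exact on perfect rankings and reduces to
           the binary AUC without censoring", {
  set.seed(6)
  t <- sort(runif(50, 1, 100))
  cl <- clin(t, rep(1, 50))
  expect_true(all(time_dependent_auc(-t, cl, c(12, 36, 60)) == 1))
  # no censoring: equals the plain binary AUC of 1[T <= t] vs score
  s <- rnorm(50)
  for (h in c(20, 50)) {
    expect_equal(unname(time_dependent_auc(s, cl, h)),
                 oracle_binary_auc(as.numeric(t <= h), s),
                 tolerance = 1e-12)
  }
  expect_error(time_dependent_auc(s, cl, 1e5), "beyond")
})

test_that("time-dependent AUC is rank-invariant in the score and ~0.5 under
           the null", {
  co <- generate_cohort(simulation_config(n_genes = 5, n_samples = 200,
                                          seed = 44))
  set.seed(55)
  s <- rnorm(200)
  a1 <- time_dependent_auc(s, co$clinical, c(12, 36))
  a2 <- time_dependent_auc(exp(3 * s) + 5, co$clinical, c(12, 36))
  expect_equal(a1, a2, tolerance = 1e-12)

  aucs <- sapply(1:20, function(seed) {
    co <- generate_cohort(simulation_config(n_genes = 5, n_samples = 400,
                                            seed = 300 + seed))
    set.seed(seed)
    mean(time_dependent_auc(rnorm(400), co$clinical, c(24, 48)))
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("concordance index matches exhaustive pair enumeration", {
  set.seed(12)
  t <- sample(1:100, 30); e <- rbinom(30, 1, 0.7); s <- rnorm(30)
  cl <- clin(t, e)
  expect_equal(concordance_index(s, cl), oracle_cindex(t, e, s),
               tolerance = 1e-12)
  # perfect and reversed rankings, no censoring
  cl2 <- clin(1:10, rep(1, 10))
  expect_equal(concordance_index(-(1:10), cl2), 1)
  expect_equal(concordance_index(1:10, cl2), 0)
  # constant scores: all usable pairs tied -> 1/2
  expect_equal(concordance_index(rep(0, 10), cl2), 0.5)
})

test_that("calibration recovers observed survival on calibrated predictions", {
  # exponential cohort where the true model survival is known
  set.seed(23)
  n <- 2000
  lp <- rnorm(n, sd = 0.7)
  t <- rexp(n, rate = 0.02 * exp(lp))
  cl <- clin(pmin(t, 120), as.integer(t <= 120))
  h <- 30
  pred <- exp(-0.02 * exp(lp) * h)
  cal <- calibration_at(h, pred, cl, n_bins = 5)
  expect_lt(max(abs(cal$mean_predicted - cal$observed_km)), 0.05)
  # constant predictions: single effective bin, message on merge
  expect_message(cal1 <- calibration_at(h, rep(0.5, n), cl, n_bins = 4),
                 "effective")
  expect_equal(nrow(cal1), 1L)
  # n_bins = 1 reproduces the overall KM at t
  km <- km_curve(cl)
  overall <- lactpair:::eval_curve(km$time[-1], km$survival[-1], h)
  expect_equal(calibration_at(h, pred, cl, n_bins = 1)$observed_km, overall,
               tolerance = 1e-12)
})
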