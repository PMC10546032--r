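# Pair matrix + clinical fixture with a single strong planted pair.
planted_fixture <- function(seed, beta = 1.5, n = 300, n_noise = 19) {
  co <- generate_cohort(simulation_config(
    n_genes = 2 * (n_noise + 1), n_samples = n,
    planted_pairs = data.frame(gene_a = 1, gene_b = 2, beta = beta),
    seed = seed))
  g <- rownames(co$expression)
  pairs <- lactpair:::new_gene_pair_set(g[seq(1, 2 * n_noise + 1, by = 2)],
                                        g[seq(2, 2 * n_noise + 2, by = 2)])
  list(pm = build_pair_matrix(co$expression, pairs), clinical = co$clinical,
       planted = paste(g[1], g[2], sep = "|"))
}

test_that("config validation enforces folds, caps and descending grids", {
  expect_error(adaptive_lasso_config(n_folds = 1), "folds")
  expect_error(adaptive_lasso_config(weight_cap = 0), "positive")
  expect_error(adaptive_lasso_config(lambda_grid = c(1, 2)), "descending")
  expect_error(adaptive_lasso_config(ridge_lambda_grid = c(2, -1)),
               "descending")
})

test_that("ridge coefficients shrink monotonically toward zero in lambda", {
  fx <- planted_fixture(1)
  x <- t(fx$pm)
  y <- survival::Surv(fx$clinical$time_months, fx$clinical$event)
  fit <- glmnet::glmnet(x, y, family = "cox", alpha = 0, standardize = FALSE,
                        lambda = c(100, 10, 1, 0.1))
  norms <- apply(as.matrix(fit$beta), 2, function(b) sum(abs(b)))
  # glmnet returns columns in the grid's (descending) order
  expect_true(all(diff(norms) > 0))
})

test_that("the planted pair carries the largest ridge coefficient", {
  hits <- sapply(1:10, function(s) {
    fx <- planted_fixture(s)
    beta <- cv_ridge_cox(fx$pm, fx$clinical,
                         adaptive_lasso_config(fold_seed = s))
    names(beta)[which.max(abs(beta))] == fx$planted
  })
  expect_gte(mean(hits), 0.9)
})

test_that("duplicated columns get equal ridge coefficients", {
  fx <- planted_fixture(3)
  pm <- rbind(fx$pm[1:4, ], dup = fx$pm[1, ])
  beta <- cv_ridge_cox(pm, fx$clinical, adaptive_lasso_config(fold_seed = 3))
  expect_lt(abs(beta[1] - beta["dup"]), 1e-6)
})

test_that("adaptive weights invert ridge magnitudes and truncate at the cap", {
  expect_equal(adaptive_weights(0.5), 2)
  expect_equal(adaptive_weights(0, cap = 1e6), 1e6)
  expect_equal(adaptive_weights(c(-0.25, 1e-9), cap = 100), c(4, 100))
  b <- c(a = 0.2, b = -0.5, c = 0.01)
  p <- c(3, 1, 2)
  expect_equal(unname(adaptive_weights(b[p])), unname(adaptive_weights(b)[p]))
  expect_error(adaptive_weights(c(1, NA)), "finite")
})

test_that("full shrinkage at a huge forced lambda empties the support", {
  fx <- planted_fixture(5)
  cfg <- adaptive_lasso_config(fold_seed = 5,
                               lambda_grid = c(50, 40, 30, 20, 10))
  expect_warning(
    res <- cv_weighted_lasso_cox(fx$pm, fx$clinical,
                                 rep(1, nrow(fx$pm)), cfg),
    "empty")
  expect_length(res$coefficients, 0)
})

test_that("support size is nonincreasing along the weighted-LASSO path", {
  fx <- planted_fixture(7)
  x <- t(fx$pm)
  y <- survival::Surv(fx$clinical$time_months, fx$clinical$event)
  w <- rep(1, ncol(x)); w[3] <- 5
  fit <- glmnet::glmnet(x, y, family = "cox", alpha = 1, standardize = FALSE,
                        penalty.factor = w, nlambda = 50)
  nz <- apply(as.matrix(fit$beta), 2, function(b) sum(b != 0))
  # along increasing lambda (reversed path) the support never grows
  expect_true(all(diff(rev(nz)) <= 0))
})

test_that("fit_signature is deterministic and recovers the planted pair with
           the right sign", {
  fx <- planted_fixture(11)
  cfg <- adaptive_lasso_config(fold_seed = 11)
  s1 <- fit_signature(fx$pm, fx$clinical, cfg)
  s2 <- fit_signature(fx$pm, fx$clinical, cfg)
  expect_identical(s1, s2)
  expect_true(fx$planted %in% names(s1$coefficients))
  expect_gt(s1$coefficients[fx$planted], 0)  # planted beta was +1.5
})

test_that("sample order cannot change the fitted signature", {
  fx <- planted_fixture(13)
  cfg <- adaptive_lasso_config(fold_seed = 13)
  s1 <- fit_signature(fx$pm, fx$clinical, cfg)
  perm <- sample(ncol(fx$pm))
  s2 <- fit_signature(fx$pm[, perm], fx$clinical[perm, ], cfg)
  expect_equal(s1$coefficients, s2$coefficients, tolerance = 1e-10)
  expect_equal(s1$lambda_selected, s2$lambda_selected)
})

test_that("degenerate candidate sets are handled explicitly", {
  fx <- planted_fixture(15)
  cfg <- adaptive_lasso_config(fold_seed = 15)
  expect_warning(s0 <- fit_signature(fx$pm[0, ], fx$clinical, cfg), "empty")
  expect_length(s0$coefficients, 0)
  s1 <- fit_signature(fx$pm[1, , drop = FALSE], fx$clinical, cfg)
  expect_length(s1$coefficients, 1)
  # single-pair coefficient is the unpenalized univariate Cox beta
  expect_equal(unname(s1$coefficients),
               unname(as.numeric(fit_cox(fx$pm[1, ], fx$clinical)$beta)))
  expect_error(
    cv_ridge_cox(fx$pm, fx$clinical[c(1:20), ][rep(1, 0), ],
                 adaptive_lasso_config()),
    "missing")
})

test_that("too few events for the requested folds is a clear error", {
  fx <- planted_fixture(17, n = 40)
  cl <- fx$clinical
  cl$event[-(1:5)] <- 0L
  expect_error(cv_ridge_cox(fx$pm[, ], cl, adaptive_lasso_config()),
               "fewer folds")
})
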