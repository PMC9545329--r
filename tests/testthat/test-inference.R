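# Bayesian estimation: the sampler's likelihood against the plain-R
# implementation, posterior summaries, and structural model identities.

test_that("the sampler's likelihood equals the per-subject R implementation", {
  sc <- jm_get_scenario("study1", n_subjects = 12)
  d <- simulate_dataset(sc, seed = 5)
  p <- sc$params_truth
  bs <- list(interior = p$baseline$interior_knots,
             boundary = p$baseline$boundary, degree = p$baseline$degree)
  prep <- serialjm:::jm_prepare(d, p$model, baseline_spec = bs)
  layout <- serialjm:::jm_layout(p$model, prep, jm_priors())
  theta <- serialjm:::pack_parameters(p, prep, layout)
  set.seed(9)
  b1 <- matrix(rnorm(24, 0, 0.3), 12)
  b2 <- matrix(rnorm(24, 0, 0.3), 12)
  cpp <- serialjm:::sjm_loglik(prep, layout$idx, layout$prior, theta, b1, b2)
  llR <- 0
  for (i in seq_along(d))
    llR <- llR + subject_loglik(d[[i]], p, jm_random_effects(b1[i, ], b2[i, ]))
  re_ll <- function(B, S) {
    Sinv <- solve(S)
    sum(apply(B, 1, function(b)
      -log(2 * pi) - 0.5 * determinant(S)$modulus - 0.5 * drop(b %*% Sinv %*% b)))
  }
  llR <- llR + re_ll(b1, p$Sigma_b1) + re_ll(b2, p$Sigma_b2)
  cpp_ll <- cpp$ll_long1 + cpp$ll_long2 + cpp$ll_surv1 + cpp$ll_surv2 +
    cpp$ll_re1 + cpp$ll_re2
  expect_equal(cpp_ll, llR, tolerance = 1e-10)
})

test_that("the log-posterior is higher at the truth than far from it", {
  sc <- jm_get_scenario("study1", n_subjects = 80)
  d <- simulate_dataset(sc, seed = 14)
  p <- sc$params_truth
  bs <- list(interior = p$baseline$interior_knots,
             boundary = p$baseline$boundary, degree = p$baseline$degree)
  prep <- serialjm:::jm_prepare(d, p$model, baseline_spec = bs)
  layout <- serialjm:::jm_layout(p$model, prep, jm_priors())
  theta <- serialjm:::pack_parameters(p, prep, layout)
  res <- attr(d, "random_effects")
  b1 <- t(vapply(res, function(b) b$b1, numeric(2)))
  b2 <- t(vapply(res, function(b) b$b2, numeric(2)))
  at_truth <- serialjm:::sjm_loglik(prep, layout$idx, layout$prior,
                                    theta, b1, b2)$lp_total
  far <- theta + 2
  at_far <- serialjm:::sjm_loglik(prep, layout$idx, layout$prior,
                                  far, b1, b2)$lp_total
  expect_true(is.finite(at_truth))
  expect_gt(at_truth, at_far)
})

test_that("posterior summaries reduce correctly on synthetic draws", {
  dr <- table_means_draws(n_draws = 120)
  sm <- jm_summarize(dr)
  # constant draws: mean = value, sd = 0, degenerate interval
  row <- sm[sm$parameter == "xi", ]
  expect_equal(row$mean, 0.354)
  expect_equal(row$sd, 0)
  expect_equal(c(row$lower, row$upper), c(0.354, 0.354))
  expect_setequal(sm$parameter, dr$parameters)
  # large standard-normal sample: central interval near +-1.96
  set.seed(3)
  dn <- table_means_draws(n_draws = 50000)
  dn$chains[[1]][, "xi"] <- rnorm(50000)
  smn <- jm_summarize(dn)
  row <- smn[smn$parameter == "xi", ]
  expect_equal(row$mean, 0, tolerance = 0.02)
  expect_equal(row$lower, -1.96, tolerance = 0.03)
  expect_equal(row$upper, 1.96, tolerance = 0.03)
  # too few draws is an error
  expect_error(jm_summarize(table_means_draws(n_draws = 10)), "100")
})

test_that("fit runs end to end, is seed-reproducible, and names all parameters", {
  sc <- jm_get_scenario("study1", n_subjects = 50)
  d <- simulate_dataset(sc, seed = 2)
  f1 <- jm_fit(d, mcmc = fast_mcmc(), seed = 99)
  f2 <- jm_fit(d, mcmc = fast_mcmc(), seed = 99)
  expect_identical(f1$chains, f2$chains)
  expect_true(all(c("beta1_intercept", "beta2_time", "xi", "sigma1", "sigma2",
                    "gamma1_intervention", "alpha11", "alpha12", "alpha21",
                    "alpha22", "sd_b1_intercept", "cor_b2")
                  %in% f1$parameters))
  expect_true(all(startsWith(grep("phi", f1$parameters, value = TRUE),
                             "phi")))
})

test_that("univariate fit is the one-outcome model configuration", {
  sc <- jm_get_scenario("study1", n_subjects = 50)
  d <- simulate_dataset(sc, seed = 2)
  # deleting outcome-2 series and fitting the generic entry point equals the
  # dedicated univariate fit
  d1 <- lapply(d, function(s) {
    jm_subject(s$id, s$intervention, s$covariates, s$series1, NULL,
               s$observed_time, s$event)
  })
  fa <- jm_fit_univariate(d, mcmc = fast_mcmc(), seed = 5)
  fb <- jm_fit(d1, mcmc = fast_mcmc(), seed = 5)
  expect_identical(fa$parameters, fb$parameters)
  expect_identical(fa$chains, fb$chains)
  expect_false(any(c("xi", "alpha12", "alpha22") %in% fa$parameters))
})
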