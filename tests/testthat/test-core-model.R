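# Core model mathematics: latent trajectories, B-spline baseline, hazards,
# quadrature cumulative hazards and the per-subject joint log-likelihood.

test_that("latent trajectory of outcome 1 reproduces hand arithmetic", {
  p <- sim_params()
  s0 <- survival_subject(intervention = 0, observed_time = 3)
  s1 <- survival_subject(intervention = 1, observed_time = 3)
  b0 <- zero_b()
  # intercept only at t = 0
  expect_equal(latent_m1(0, p, s0, b0), 0.07)
  # 0.07 + 2(-0.25) + 2(0.12) under intervention at t = 2
  expect_equal(latent_m1(2, p, s1, b0), -0.19)
  # zero coefficients give zero everywhere
  pz <- p; pz$beta1 <- c(0, 0, 0)
  expect_equal(latent_m1(c(0, 0.7, 2.4), pz, s1, b0), c(0, 0, 0))
  # random effects enter as intercept + slope * t
  b <- jm_random_effects(b1 = c(0.3, -0.1))
  expect_equal(latent_m1(2, p, s1, b), -0.19 + 0.3 - 0.2)
})

test_that("latent trajectory of outcome 2 chains on outcome 1 with slope xi", {
  p <- sim_params(xi = -0.5)
  s0 <- survival_subject(intervention = 0, observed_time = 3)
  b0 <- zero_b()
  # control arm at t = 1: m1 = 0.07 - 0.25, m2 = 0.15 + 0.45 - 0.5 * m1
  expect_equal(latent_m1(1, p, s0, b0), -0.18)
  expect_equal(latent_m2(1, p, s0, b0), 0.69)
  # linear in m1 with slope exactly xi (finite differences over xi grid)
  pz <- p; pz$beta2 <- c(0, 0, 0)
  for (xi in c(-2, 0, 1.3)) {
    pz$xi <- xi
    m1 <- latent_m1(1.7, pz, s0, b0)
    expect_equal(latent_m2(1.7, pz, s0, b0), xi * m1)
  }
  # missing covariate is reported by name
  pm <- p
  pm$model$long1 <- jm_longitudinal_spec(c("intercept", "time", "bmmse"))
  pm$model$long2$fixed <- c("intercept", "time", "intervention:time")
  expect_error(latent_m1(1, pm, s0, b0), "bmmse")
})

test_that("log baseline hazard matches an independent de Boor evaluation", {
  # textbook Cox-de Boor recursion, written independently of splineDesign
  deboor <- function(t, knots, degree, coefs) {
    nb <- length(knots) - degree - 1
    basis_fun <- function(j, d, x) {
      if (d == 0)
        return(as.numeric(knots[j] <= x &
                            (x < knots[j + 1] ||
                               (x == knots[length(knots)] &&
                                  knots[j + 1] == x))))
      w1 <- if (knots[j + d] > knots[j])
        (x - knots[j]) / (knots[j + d] - knots[j]) else 0
      w2 <- if (knots[j + d + 1] > knots[j + 1])
        (knots[j + d + 1] - x) / (knots[j + d + 1] - knots[j + 1]) else 0
      w1 * basis_fun(j, d - 1, x) + w2 * basis_fun(j + 1, d - 1, x)
    }
    vapply(t, function(x)
      sum(vapply(seq_len(nb), function(j)
        basis_fun(j, degree, x) * coefs[j], 0)), 0)
  }
  set.seed(2)
  spec <- jm_baseline(interior_knots = c(0.5, 1.1, 2.0), boundary = c(0, 3),
                      degree = 3, coefficients = matrix(rnorm(14), 7, 2))
  knots <- serialjm:::baseline_knots(spec)
  ts <- runif(50, 0, 3)
  for (k in 1:2)
    expect_equal(log_baseline_hazard(ts, k, spec),
                 deboor(ts, knots, 3, spec$coefficients[, k]),
                 tolerance = 1e-10)
  # partition of unity: equal coefficients give a flat log hazard
  spec$coefficients[] <- 0
  expect_equal(log_baseline_hazard(ts, 1, spec), rep(0, 50))
  spec$coefficients[] <- 1.7
  expect_equal(log_baseline_hazard(ts, 2, spec), rep(1.7, 50))
  # no extrapolation
  expect_error(log_baseline_hazard(3.5, 1, spec), "boundary")
})

test_that("hazard multiplies correctly and published risk reductions recover", {
  p <- const_hazard_params(h1 = 1, h2 = 1)
  p$baseline$coefficients[] <- 0
  s <- survival_subject(observed_time = 3)
  b <- zero_b()
  expect_equal(hazard(c(0.3, 1.5, 3), 1, p, s, b), rep(1, 3))
  # intervention multiplies the hazard by exactly exp(gamma_k1)
  p$gamma <- list(-0.7, 0.25)
  s1 <- survival_subject(intervention = 1, observed_time = 3)
  expect_equal(hazard(1.2, 1, p, s1, b) / hazard(1.2, 1, p, s, b), exp(-0.7))
  expect_equal(hazard(1.2, 2, p, s1, b) / hazard(1.2, 2, p, s, b), exp(0.25))
  # a one-SD increase in each latent trajectory moves the hazard by exp(alpha):
  # the fitted real-data associations translate to 34% and 66% risk reductions
  expect_equal(round(1 - exp(-0.416), 2), 0.34)
  expect_equal(round(1 - exp(-1.073), 2), 0.66)
  pa <- const_hazard_params(h1 = 1, h2 = 1)
  pa$baseline$coefficients[] <- 0
  pa$alpha <- matrix(c(-0.416, -1.073, 0, 0), 2, 2, byrow = TRUE)
  pa$beta1 <- c(1, 0, 0); pa$beta2 <- c(0, 0, 0); pa$xi <- 0
  pb <- pa; pb$beta1 <- c(0, 0, 0)
  expect_equal(hazard(1, 1, pa, s, b) / hazard(1, 1, pb, s, b), exp(-0.416))
  pa$beta1 <- c(0, 0, 0); pa$beta2 <- c(1, 0, 0)
  expect_equal(hazard(1, 1, pa, s, b) / hazard(1, 1, pb, s, b), exp(-1.073))
  # positivity under wild but finite parameters
  set.seed(4)
  pw <- sim_params()
  pw$alpha <- matrix(rnorm(4, sd = 2), 2)
  pw$gamma <- list(rnorm(1, sd = 2), rnorm(1, sd = 2))
  bw <- jm_random_effects(rnorm(2), rnorm(2))
  expect_true(all(hazard(seq(0, 3.2, by = 0.4), 1, pw, s1, bw) > 0))
})

test_that("quadrature cumulative hazard matches closed form and adaptive oracle", {
  p <- const_hazard_params(h1 = 0.4, h2 = 0.15)
  s <- survival_subject(observed_time = 3)
  b <- zero_b()
  expect_identical(cumulative_hazard(0, 1, p, s, b), 0)
  # constant hazard: Lambda(t) = h t exactly (within float error)
  for (t in c(0.3, 1, 2.7))
    expect_equal(cumulative_hazard(t, 1, p, s, b), 0.4 * t,
                 tolerance = 1e-10)
  expect_equal(cumulative_hazard(2, 2, p, s, b), 0.3, tolerance = 1e-10)
  # random parameter draws against stats::integrate
  set.seed(7)
  for (r in 1:20) {
    pr <- sim_params(xi = rnorm(1, sd = 0.7))
    pr$alpha <- matrix(rnorm(4, sd = 0.5), 2)
    pr$gamma <- list(rnorm(1, sd = 0.5), rnorm(1, sd = 0.5))
    # random per-risk baseline levels (the generative design's baselines are
    # constant; the integrand stays analytic so fixed-order quadrature is
    # effectively exact)
    for (kk in 1:2)
      pr$baseline$coefficients[, kk] <- rnorm(1, log(0.3), 0.4)
    br <- jm_random_effects(rnorm(2, sd = 0.4), rnorm(2, sd = 0.4))
    sr <- survival_subject(intervention = rbinom(1, 1, 0.5), observed_time = 3.2)
    t_end <- runif(1, 0.5, 3.2)
    k <- sample(1:2, 1)
    oracle <- integrate(function(u) hazard(u, k, pr, sr, br), 0, t_end,
                        rel.tol = 1e-10)$value
    expect_equal(cumulative_hazard(t_end, k, pr, sr, br), oracle,
                 tolerance = 1e-6)
  }
  # monotone nondecreasing in t
  pr <- sim_params()
  ts <- seq(0, 3.2, by = 0.2)
  lam <- vapply(ts, cumulative_hazard, 0, k = 1, params = pr,
                subject = s, b = b)
  expect_true(all(diff(lam) >= 0))
})

test_that("subject log-likelihood assembles its three parts", {
  p <- const_hazard_params(h1 = 0.4, h2 = 0.15)
  b <- zero_b()
  # no measurements, censored: survival-only term -sum_k Lambda_k(T)
  s <- survival_subject(observed_time = 2, event = 0L)
  expect_equal(subject_loglik(s, p, b), -(0.4 + 0.15) * 2, tolerance = 1e-9)
  # single measurement exactly at the latent mean: density at the mean
  p2 <- p
  m1_at_1 <- latent_m1(1, p2, s, b)
  s2 <- jm_subject("s2", 0, numeric(0),
                   series1 = data.frame(time = 1, value = m1_at_1),
                   series2 = NULL, observed_time = 2, event = 0L)
  expect_equal(subject_loglik(s2, p2, b),
               log(1 / (p2$sigma1 * sqrt(2 * pi))) - (0.4 + 0.15) * 2,
               tolerance = 1e-9)
  # random subjects: equals the independently assembled sum of pieces
  set.seed(11)
  sc <- jm_get_scenario("study1", n_subjects = 10)
  d <- simulate_dataset(sc, seed = 3)
  res <- attr(d, "random_effects")
  pt <- sc$params_truth
  for (i in seq_along(d)) {
    su <- d[[i]]; bi <- res[[i]]
    parts <- sum(dnorm(su$series1$value,
                       latent_m1(su$series1$time, pt, su, bi),
                       pt$sigma1, log = TRUE)) +
      sum(dnorm(su$series2$value,
                latent_m2(su$series2$time, pt, su, bi),
                pt$sigma2, log = TRUE)) -
      cumulative_hazard(su$observed_time, 1, pt, su, bi) -
      cumulative_hazard(su$observed_time, 2, pt, su, bi) +
      if (su$event > 0)
        log(hazard(su$observed_time, su$event, pt, su, bi)) else 0
    expect_equal(subject_loglik(su, pt, bi), parts, tolerance = 1e-12)
  }
})

test_that("outcome 2 decouples from survival when xi and alpha_k2 vanish", {
  sc <- jm_get_scenario("study1", n_subjects = 6)
  d <- simulate_dataset(sc, seed = 8)
  res <- attr(d, "random_effects")
  p <- sc$params_truth
  p$xi <- 0
  p$alpha[, 2] <- 0
  for (i in 1:3) {
    s <- d[[i]]; bi <- res[[i]]
    ll <- subject_loglik(s, p, bi)
    s_mod <- s
    s_mod$series2$value <- s_mod$series2$value + 0.37
    ll_mod <- subject_loglik(s_mod, p, bi)
    # the difference must equal the change in the outcome-2 normal terms only
    delta_normal <-
      sum(dnorm(s_mod$series2$value,
                latent_m2(s_mod$series2$time, p, s_mod, bi),
                p$sigma2, log = TRUE)) -
      sum(dnorm(s$series2$value,
                latent_m2(s$series2$time, p, s, bi),
                p$sigma2, log = TRUE))
    expect_equal(ll_mod - ll, delta_normal, tolerance = 1e-12)
  }
})

test_that("parameter and subject validation rejects malformed inputs", {
  p <- sim_params()
  expect_error(jm_subject("a", 1, series1 = data.frame(time = 2, value = 1),
                          series2 = NULL, observed_time = 1, event = 0),
               "after its observed time")
  expect_error(jm_subject("a", 2, series1 = NULL, series2 = NULL,
                          observed_time = 1, event = 0))
  expect_error(jm_baseline(c(2, 1), c(0, 3), 3, matrix(0, 6, 2)), "ordered")
  expect_error(jm_baseline(c(3.5), c(0, 3), 3, matrix(0, 5, 2)), "inside")
  expect_error(jm_parameters(p$model, beta1 = c(0, 0), beta2 = p$beta2,
                             xi = 0, sigma1 = 0.5, sigma2 = 0.5,
                             Sigma_b1 = diag(2), Sigma_b2 = diag(2),
                             gamma = p$gamma, alpha = p$alpha,
                             baseline = p$baseline),
               "beta1")
})
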