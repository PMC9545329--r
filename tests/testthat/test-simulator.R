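# Generative model: scenario registry, event-time inversion, dataset shape
# and distributional checks.

test_that("scenario registry carries the published generating values", {
  reg <- scenario_registry()
  expect_setequal(names(reg), c("study1", "study2_I", "study2_II",
                                "study2_III", "study2_IV"))
  expect_equal(reg$study1$params_truth$xi, -0.5)
  expect_equal(reg$study2_I$params_truth$xi, -0.01)
  expect_equal(reg$study2_II$params_truth$xi, -1)
  expect_equal(reg$study2_III$params_truth$xi, -2)
  expect_equal(reg$study2_IV$params_truth$xi, -3)
  for (sc in reg) {
    p <- sc$params_truth
    expect_equal(p$beta1, c(0.07, -0.25, 0.12))
    expect_equal(p$beta2, c(0.15, 0.45, -0.10))
    expect_equal(unlist(p$gamma), c(-0.2, 0.1))
    expect_equal(p$alpha, matrix(c(-0.6, 0.4, -0.1, 0.1), 2, 2, byrow = TRUE))
    expect_equal(sc$n_subjects, 500L)
    expect_equal(sc$n_visits, 10L)
    expect_equal(sc$max_followup, 3.2)
    expect_equal(sc$censoring_mean, 5)
  }
  expect_error(jm_get_scenario("study9"), "study1")
})

test_that("event-time inversion has the constant-hazard closed form", {
  p <- const_hazard_params(h1 = 0.3, h2 = 0.2)  # total hazard 0.5
  s <- survival_subject(observed_time = 3.2)
  b <- zero_b()
  set.seed(1)
  for (t0 in c(0.4, 1.5, 3.0)) {
    u <- exp(-0.5 * t0)
    ev <- sample_event_time(s, p, b, u)
    expect_equal(ev$time, t0, tolerance = 1e-6)
  }
  # negligible hazards: always administratively censored
  pz <- const_hazard_params(h1 = 1e-10, h2 = 1e-10)
  expect_null(sample_event_time(s, pz, b, 0.5))
})

test_that("cause attribution follows the competing-risks identity h1/(h1+h2)", {
  p <- const_hazard_params(h1 = 0.6, h2 = 0.2)
  s <- survival_subject(observed_time = 3.2)
  b <- zero_b()
  set.seed(42)
  n <- 8000
  u <- runif(n)
  causes <- integer(0)
  for (i in seq_len(n)) {
    ev <- sample_event_time(s, p, b, u[i])
    if (!is.null(ev)) causes <- c(causes, ev$cause)
  }
  frac1 <- mean(causes == 1)
  se <- sqrt(0.75 * 0.25 / length(causes))
  expect_lt(abs(frac1 - 0.6 / 0.8), 4 * se)
})

test_that("simulated datasets respect the design and are reproducible", {
  sc <- jm_get_scenario("study1", n_subjects = 150)
  d <- simulate_dataset(sc, seed = 31)
  expect_length(d, 150)
  expect_true(all(vapply(d, function(s) nrow(s$series1) <= 10, TRUE)))
  expect_true(all(vapply(d, function(s) nrow(s$series2) <= 10, TRUE)))
  # no measurement beyond the observed time; delta = 0 only for censoring
  for (s in d) {
    expect_lte(max(c(0, s$series1$time, s$series2$time)), s$observed_time)
    expect_true(s$event %in% 0:2)
    expect_lte(s$observed_time, 3.2)
  }
  # determinism
  d2 <- simulate_dataset(sc, seed = 31)
  expect_identical(d, d2)
  # visit counts are monotone in follow-up time
  Ti <- vapply(d, function(s) s$observed_time, 0)
  nv <- vapply(d, function(s) nrow(s$series1), 0L)
  ord <- order(Ti)
  expect_true(all(diff(nv[ord]) >= 0))
  # both events and censoring occur at realistic frequencies
  ev <- table(factor(vapply(d, function(s) s$event, 0L), levels = 0:2))
  expect_true(all(ev > 5))
})

test_that("xi = 0 decouples the subject-level random parts of the outcomes", {
  sc0 <- jm_scenario(sim_params(xi = 0), n_subjects = 2000)
  d <- simulate_dataset(sc0, seed = 9)
  res <- attr(d, "random_effects")
  p <- sc0$params_truth
  # conditional m1 deviation vs (m2 - fixed part of m2) at t = 1, over subjects
  m1dev <- vapply(res, function(b) b$b1[1] + b$b1[2], 0)
  m2dev <- vapply(res, function(b) b$b2[1] + b$b2[2], 0)
  expect_lt(abs(cor(m1dev, m2dev)), 3 / sqrt(length(res)) + 0.02)
})

test_that("simulated event times reproduce the model's survival function", {
  # Empirical all-cause event-time distribution (before censoring) vs the
  # Monte-Carlo average of S(t) = exp(-sum_k Lambda_k(t)) over random effects
  # and treatment assignment.
  p <- sim_params()
  L <- t(chol(p$Sigma_b1)); L2 <- t(chol(p$Sigma_b2))
  set.seed(77)
  n <- 10000
  times <- numeric(0)
  subj <- list(survival_subject(intervention = 0, observed_time = 3.2),
               survival_subject(intervention = 1, observed_time = 3.2))
  bs <- vector("list", n); trts <- integer(n)
  for (i in seq_len(n)) {
    trts[i] <- rbinom(1, 1, 0.5)
    bs[[i]] <- jm_random_effects(drop(L %*% rnorm(2)), drop(L2 %*% rnorm(2)))
    ev <- sample_event_time(subj[[trts[i] + 1]], p, bs[[i]], runif(1))
    times <- c(times, if (is.null(ev)) Inf else ev$time)
  }
  grid <- seq(0.2, 3.0, by = 0.2)
  emp <- vapply(grid, function(t) mean(times > t), 0)
  # reference: average survival over a fresh Monte-Carlo set of subjects
  set.seed(78)
  m <- 1500
  Sbar <- rowMeans(vapply(seq_len(m), function(i) {
    b <- jm_random_effects(drop(L %*% rnorm(2)), drop(L2 %*% rnorm(2)))
    s <- subj[[rbinom(1, 1, 0.5) + 1]]
    vapply(grid, function(t)
      exp(-cumulative_hazard(t, 1, p, s, b) -
            cumulative_hazard(t, 2, p, s, b)), 0)
  }, numeric(length(grid))))
  expect_lt(max(abs(emp - Sbar)), 0.03)
})
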