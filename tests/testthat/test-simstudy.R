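# Replication harness: true total-effect curve, single-replicate mechanics,
# aggregation, reporting and persistence.

test_that("true total effect evaluates the generating decomposition", {
  sc <- jm_get_scenario("study1")
  # at t = 0 only the direct path survives (interaction-only profiles)
  expect_equal(true_total_effect(sc, 0)$hr, exp(-0.2))
  # hand arithmetic at t = 1: exp{-0.2 + (-0.6)(0.12) + 0.4(-0.10)
  #                               + (-0.5)(0.4)(0.12)}
  expect_equal(true_total_effect(sc, 1)$hr, exp(-0.336), tolerance = 1e-12)
  expect_equal(true_total_effect(sc, 1)$hr, 0.7146, tolerance = 1e-4)
  # no effects at all: hazard ratio one everywhere
  p0 <- sim_params(xi = 0)
  p0$gamma <- list(0, 0); p0$alpha <- matrix(0, 2, 2)
  sc0 <- jm_scenario(p0)
  expect_equal(true_total_effect(sc0, seq(0, 3, 0.5))$hr, rep(1, 7))
  # the log curve is affine in t, hence monotone, for any generating values
  set.seed(13)
  for (r in 1:10) {
    pr <- sim_params(xi = rnorm(1))
    pr$alpha <- matrix(rnorm(4), 2); pr$gamma <- list(rnorm(1), rnorm(1))
    hr <- true_total_effect(jm_scenario(pr), seq(0, 3, by = 0.5))$hr
    slope <- diff(log(hr))
    expect_equal(max(slope) - min(slope), 0, tolerance = 1e-12)
  }
})

test_that("a single replicate reports bias = posterior mean - truth", {
  sc <- jm_get_scenario("study1", n_subjects = 60)
  res <- run_study(sc, "multivariate", n_replicates = 1, base_seed = 11,
                   mcmc = fast_mcmc(), rhat_limit = Inf)
  p <- res$parameters
  expect_equal(p$bias, p$mean - p$truth, tolerance = 1e-12)
  expect_true(all(p$coverage %in% c(0, 100)))
  expect_setequal(
    grep("^(beta|gamma|alpha|xi)", p$parameter, value = TRUE),
    c("beta1_intercept", "beta1_time", "beta1_intervention:time",
      "beta2_intercept", "beta2_time", "beta2_intervention:time", "xi",
      "gamma1_intervention", "gamma2_intervention",
      "alpha11", "alpha12", "alpha21", "alpha22"))
})

test_that("table report restricts to regression parameters and is faithful", {
  fake <- structure(list(
    parameters = data.frame(
      parameter = c("beta1_time", "xi", "sigma1"),
      truth = c(-0.25, -0.5, 0.5),
      mean = c(-0.24, -0.52, 0.51),
      bias = c(0.01, -0.02, 0.01),
      coverage = c(100, 94, 96)),
    curve = NULL, truth_curve = NULL, model_kind = "multivariate",
    n_replicates = 3, n_failed = 0, seeds = 1:3), class = "jm_simstudy")
  tab <- table2_report(fake)
  expect_equal(tab$parameter, c("beta1_time", "xi"))
  expect_equal(tab$bias, tab$mean - tab$truth)
  tab_all <- table2_report(fake, all = TRUE)
  expect_equal(nrow(tab_all), 3)
  expect_equal(tab_all$coverage[1], 100)
})

test_that("studies persist per replicate and resume bit-exactly", {
  sc <- jm_get_scenario("study1", n_subjects = 50)
  dir1 <- file.path(tempdir(), "study_a")
  res1 <- run_study(sc, "univariate", n_replicates = 2, base_seed = 4,
                    mcmc = fast_mcmc(), out_dir = dir1, rhat_limit = Inf)
  expect_length(list.files(dir1, pattern = "replicate_"), 2)
  # rerun resumes from the persisted files and reproduces the aggregates
  res2 <- run_study(sc, "univariate", n_replicates = 2, base_seed = 4,
                    mcmc = fast_mcmc(), out_dir = dir1, rhat_limit = Inf)
  expect_equal(res1$parameters, res2$parameters, tolerance = 1e-12)
  expect_equal(res1$curve, res2$curve, tolerance = 1e-12)
  # and a fresh in-memory run with the same seeds agrees too
  res3 <- run_study(sc, "univariate", n_replicates = 2, base_seed = 4,
                    mcmc = fast_mcmc(), rhat_limit = Inf)
  expect_equal(res1$parameters$mean, res3$parameters$mean, tolerance = 1e-9)
  fig <- file.path(tempdir(), "study.png")
  plot_study(res1, fig)
  expect_true(file.size(fig) > 0)
  unlink(dir1, recursive = TRUE); unlink(fig)
})

test_that("presets encode the desk and full study scales", {
  desk <- study_preset("desk")
  expect_equal(desk$n_replicates, 50L)
  expect_equal(desk$n_subjects, 500L)
  full <- study_preset("full")
  expect_equal(full$n_replicates, 200L)
  expect_equal(full$n_subjects, 500L)
})
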