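# Latent mediation decomposition: intervention profiles, path identities and
# the exported curve artifacts.

test_that("intervention profile reproduces the fitted-analysis arithmetic", {
  dr <- table_means_draws()
  # main effect at t = 0, main + interaction at t = 1 (outcome 1)
  expect_equal(unname(intervention_profile(dr, 1, 0)[1, 1]), -0.064)
  expect_equal(unname(intervention_profile(dr, 1, 1)[1, 1]), 0.007)
  expect_equal(unname(intervention_profile(dr, 2, 0.5)[1, 1]),
               0.060 + 0.5 * 0.051)
  # zero coefficients give a flat zero profile
  dz <- dr
  dz$chains[[1]][, c("beta1_intervention", "beta1_intervention:time")] <- 0
  expect_equal(unname(intervention_profile(dz, 1, c(0, 1, 2))[1, ]),
               c(0, 0, 0))
  # a model without intervention terms cannot form a profile
  mod <- jm_model(long1 = jm_longitudinal_spec(c("intercept", "time")),
                  long2 = NULL)
  expect_error(intervention_profile(c(beta1_intercept = 1), 1, 0, model = mod),
               "no intervention term")
})

test_that("the decomposition identity holds exactly per draw and time", {
  sc <- jm_get_scenario("study1", n_subjects = 60)
  d <- simulate_dataset(sc, seed = 21)
  f <- jm_fit(d, mcmc = fast_mcmc(), seed = 3)
  cv <- mediation_decompose(f, time_grid = seq(0, 3, by = 0.25))
  with(cv$components, {
    expect_identical(total - (direct + indirect_1 + indirect_2 + indirect_3),
                     matrix(0, nrow(total), ncol(total)))
    expect_equal(combined_via_outcome1, indirect_1 + indirect_3)
  })
  # combined path through outcome 1 equals B1(t) (alpha11 + xi alpha12)
  B1 <- intervention_profile(f, 1, cv$time_grid)
  a11 <- jm_extract(f, "alpha11"); a12 <- jm_extract(f, "alpha12")
  xi <- jm_extract(f, "xi")
  expect_equal(cv$components$combined_via_outcome1, B1 * (a11 + xi * a12),
               tolerance = 1e-12)
})

test_that("plug-in decomposition at published posterior means gives T(0) = 1.150", {
  dr <- table_means_draws()
  cv <- mediation_decompose(dr, time_grid = c(0, 1))
  t0 <- exp(cv$components$total[1, 1])
  # gamma11 + alpha11 B1(0) + alpha12 B2(0) + xi alpha12 B1(0)
  expect_equal(cv$components$total[1, 1],
               0.153 + (-0.416) * (-0.064) + (-1.073) * 0.060 +
                 0.354 * (-1.073) * (-0.064),
               tolerance = 1e-12)
  expect_equal(t0, 1.150, tolerance = 1e-3)
})

test_that("degenerate and shifted configurations reduce as expected", {
  dr <- table_means_draws()
  # all alpha and xi zero: constant hazard ratio exp(gamma11)
  dz <- dr
  dz$chains[[1]][, c("alpha11", "alpha12", "alpha21", "alpha22", "xi")] <- 0
  cv <- mediation_decompose(dz, time_grid = seq(0, 2, by = 0.5))
  expect_true(all(abs(cv$components$total - 0.153) < 1e-12))
  expect_equal(cv$summary$mean[cv$summary$component == "total"],
               rep(exp(0.153), 5))
  # constant intervention profiles make every curve time-constant
  dc <- dr
  dc$chains[[1]][, c("beta1_intervention:time", "beta2_intervention:time")] <- 0
  cvc <- mediation_decompose(dc, time_grid = seq(0, 3, by = 1))
  for (comp in cvc$components)
    expect_equal(apply(comp, 1, function(x) max(x) - min(x)), rep(0, nrow(comp)))
  # symmetric decomposition for the second competing risk uses gamma21, alpha2.
  cv2 <- mediation_decompose(dr, time_grid = 0, risk = 2)
  expect_equal(cv2$components$total[1, 1],
               -0.241 + 0.047 * (-0.064) + (-0.242) * 0.060 +
                 0.354 * (-0.242) * (-0.064),
               tolerance = 1e-12)
})

test_that("decomposition demands the multivariate parameter set", {
  sc <- jm_get_scenario("study1", n_subjects = 40)
  d <- simulate_dataset(sc, seed = 5)
  fu <- jm_fit_univariate(d, mcmc = fast_mcmc(), seed = 3)
  expect_error(mediation_decompose(fu), "univariate|xi")
})

test_that("curves render to file and export as tidy tables", {
  dr <- table_means_draws(n_draws = 50)
  dr$chains[[1]] <- dr$chains[[1]] +
    matrix(rnorm(length(dr$chains[[1]]), 0, 0.01), nrow(dr$chains[[1]]))
  cv <- mediation_decompose(dr, time_grid = seq(0, 3, by = 0.1))
  png_path <- file.path(tempdir(), "mediation.png")
  plot_mediation(cv, png_path)
  expect_true(file.exists(png_path) && file.size(png_path) > 0)
  # re-render with the same input leaves the curve data unchanged
  cv2 <- mediation_decompose(dr, time_grid = seq(0, 3, by = 0.1))
  expect_identical(cv$summary, cv2$summary)
  out <- file.path(tempdir(), c("draws.csv", "summary.csv"))
  write_mediation(cv, out[1], out[2])
  long <- read.csv(out[1]); sm <- read.csv(out[2])
  expect_setequal(unique(long$component),
                  c("direct", "indirect_1", "indirect_2", "indirect_3",
                    "combined_via_outcome1", "total"))
  expect_equal(nrow(sm), 6 * length(cv$time_grid))
  expect_true(all(sm$lower <= sm$upper))
  expect_error(plot_mediation(structure(list(time_grid = numeric(0)),
                                        class = "jm_mediation"), png_path),
               "empty")
  unlink(c(png_path, out))
})
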