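# Shared builders for small parameter sets and datasets.

# Generating parameters of the simulation design, with optional overrides.
sim_params <- function(xi = -0.5, ...) serialjm:::sim_truth(xi, ...)

# Parameters with constant baseline hazards h1, h2 and no covariate or
# latent effects on the hazards: closed forms are available for everything.
const_hazard_params <- function(h1 = 0.3, h2 = 0.2, tmax = 3.2) {
  p <- sim_params()
  p$gamma <- list(0, 0)
  p$alpha <- matrix(0, 2, 2)
  p$baseline$coefficients[, 1] <- log(h1)
  p$baseline$coefficients[, 2] <- log(h2)
  p
}

zero_b <- function() jm_random_effects()

# A bare subject with no measurements.
survival_subject <- function(id = "s1", intervention = 0, observed_time = 2,
                             event = 0L, covariates = numeric(0)) {
  jm_subject(id = id, intervention = intervention, covariates = covariates,
             series1 = NULL, series2 = NULL,
             observed_time = observed_time, event = event)
}

# Synthetic posterior-mean draw mirroring the fitted real-data analysis
# (used for plug-in decomposition checks; values are published posterior
# means, not data).
table_means_draws <- function(n_draws = 4) {
  model <- jm_model(
    long1 = jm_longitudinal_spec(c("intercept", "time", "intervention",
                                   "intervention:time")),
    long2 = jm_longitudinal_spec(c("intercept", "time", "intervention",
                                   "intervention:time"), upstream = TRUE),
    survival_terms = "intervention")
  vals <- c("beta1_intercept" = 0, "beta1_time" = -0.183,
            "beta1_intervention" = -0.064, "beta1_intervention:time" = 0.071,
            "beta2_intercept" = 0, "beta2_time" = -0.088,
            "beta2_intervention" = 0.060, "beta2_intervention:time" = 0.051,
            "xi" = 0.354, "gamma1_intervention" = 0.153,
            "gamma2_intervention" = -0.241,
            "alpha11" = -0.416, "alpha12" = -1.073,
            "alpha21" = 0.047, "alpha22" = -0.242)
  m <- matrix(rep(vals, each = n_draws), nrow = n_draws,
              dimnames = list(NULL, names(vals)))
  structure(list(chains = list(m), lp = NULL, model = model,
                 baseline_spec = NULL, parameters = colnames(m),
                 accept = NULL, mcmc = jm_mcmc(), n_subjects = NA),
            class = "jm_draws")
}

fast_mcmc <- function(...) jm_mcmc(n_iter = 200, n_burnin = 200, n_chains = 1,
                                   ...)
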