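# Bayesian estimation of the joint model by adaptive block
# Metropolis-within-Gibbs, with per-subject random-effect updates. The
# compiled sampler returns chains on the sampling scale (log SDs, atanh
# correlations); the draws exposed to the user are on the natural scale.

#' Prior specification
#'
#' Weakly informative defaults: mean-zero normal priors on all regression,
#' association and serial coefficients, a normal ridge on the baseline-spline
#' coefficients, half-t priors on the error and random-effect SDs and an
#' LKJ(2) prior on the within-outcome random-effect correlations.
#'
#' @param beta_sd,gamma_sd,alpha_sd,xi_sd normal prior SDs of the fixed
#'   effects, hazard coefficients, association parameters and the serial
#'   association.
#' @param spline_sd normal ridge SD of the log-baseline-hazard spline
#'   coefficients.
#' @param sd_prior_df,sd_prior_scale half-t degrees of freedom and scale for
#'   the error SDs and random-effect SDs.
#' @param lkj_eta LKJ shape of the 2x2 random-effect correlation priors.
#' @return an object of class `jm_priors`.
#' @export
jm_priors <- function(beta_sd = 10, gamma_sd = 10, alpha_sd = 10, xi_sd = 10,
                      spline_sd = 5, sd_prior_df = 3, sd_prior_scale = 2.5,
                      lkj_eta = 2) {
  stopifnot(beta_sd > 0, gamma_sd > 0, alpha_sd > 0, xi_sd > 0, spline_sd > 0,
            sd_prior_df > 0, sd_prior_scale > 0, lkj_eta > 0)
  structure(as.list(environment()), class = "jm_priors")
}

#' MCMC configuration
#'
#' @param n_iter retained iterations per chain (after burn-in).
#' @param n_burnin warm-up iterations per chain, discarded; adaptation of the
#'   proposal scales and covariances happens here and is frozen afterwards.
#' @param n_chains number of chains.
#' @param thin thinning interval.
#' @param n_re_sweeps random-effect refresh sweeps per iteration; extra
#'   sweeps speed up the mixing of the hyperparameters that condition on the
#'   random effects.
#' @param seed optional RNG seed applied by [jm_fit()].
#' @return an object of class `jm_mcmc`.
#' @export
jm_mcmc <- function(n_iter = 2000, n_burnin = 1000, n_chains = 2, thin = 1,
                    n_re_sweeps = 2, seed = NULL) {
  stopifnot(n_iter >= 1, n_burnin >= 0, n_chains >= 1, thin >= 1,
            n_re_sweeps >= 1)
  structure(list(n_iter = as.integer(n_iter), n_burnin = as.integer(n_burnin),
                 n_chains = as.integer(n_chains), thin = as.integer(thin),
                 n_re_sweeps = as.integer(n_re_sweeps), seed = seed),
            class = "jm_mcmc")
}

#' Fit the multivariate competing-risk joint model
#'
#' Samples the joint posterior of both longitudinal submodels (the second
#' loading on the latent process of the first with coefficient `xi`), the two
#' cause-specific hazards with B-spline log baseline hazards, and all
#' random effects.
#'
#' @param dataset list of [jm_subject()] records (e.g. from
#'   [simulate_dataset()] or [read_jm_data()]).
#' @param model a [jm_model()]; a univariate model (`long2 = NULL`) fits the
#'   restricted comparator. Defaults to the serial two-outcome model with
#'   intercept, slope and intervention-by-time fixed effects.
#' @param priors a [jm_priors()].
#' @param mcmc a [jm_mcmc()].
#' @param seed RNG seed (overrides `mcmc$seed`).
#' @param n_quad Gauss-Legendre order of the cumulative-hazard quadrature.
#' @param n_knots number of interior knots of the baseline spline, placed at
#'   equally spaced quantiles of the observed event times.
#' @return an object of class `jm_draws`: per-chain matrices of posterior
#'   draws on the natural scale, plus the model, baseline-spline and
#'   acceptance metadata.
#' @export
jm_fit <- function(dataset, model = NULL, priors = jm_priors(),
                   mcmc = jm_mcmc(), seed = mcmc$seed, n_quad = 15L,
                   n_knots = 5L) {
  stopifnot(length(dataset) >= 1)
  if (is.null(model)) {
    has2 <- nrow(dataset[[1]]$series2) > 0 ||
      any(vapply(dataset, function(s) nrow(s$series2) > 0, TRUE))
    model <- if (has2) jm_model() else
      jm_model(long2 = NULL)
  }
  if (!is.null(seed)) set.seed(seed)
  prep <- jm_prepare(dataset, model, n_quad = n_quad, n_knots = n_knots)
  layout <- jm_layout(model, prep, priors)
  init <- jm_init(prep, layout)

  chains <- vector("list", mcmc$n_chains)
  accept <- vector("list", mcmc$n_chains)
  lp <- vector("list", mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    init_ch <- init
    if (ch > 1)  # overdisperse chain starts slightly
      init_ch$theta <- init$theta + rnorm(layout$n_par, 0, init$init_step / 2)
    res <- sjm_run_chain(prep, layout$idx, layout$prior, layout$blocks,
                         init_ch[c("theta", "b1", "b2")],
                         list(n_warmup = mcmc$n_burnin, n_save = mcmc$n_iter,
                              thin = mcmc$thin, n_re_sweeps = mcmc$n_re_sweeps,
                              init_step = init$init_step))
    dr <- res$draws
    colnames(dr) <- layout$names
    for (j in seq_len(ncol(dr)))
      dr[, j] <- switch(layout$transf[j], exp = exp(dr[, j]),
                        tanh = tanh(dr[, j]), dr[, j])
    chains[[ch]] <- dr
    accept[[ch]] <- res$accept_blocks
    lp[[ch]] <- res$lp
  }
  structure(list(chains = chains, lp = lp, model = model,
                 baseline_spec = prep$baseline_spec,
                 parameters = layout$names, accept = accept,
                 mcmc = mcmc, n_subjects = prep$n),
            class = "jm_draws")
}

#' Fit the restricted univariate competing-risk joint model
#'
#' The comparator model of the misspecification study: outcome 2, the serial
#' association `xi` and the outcome-2 association parameters are removed;
#' outcome 1 and both cause-specific hazards are kept.
#'
#' @inheritParams jm_fit
#' @return a `jm_draws` object.
#' @export
jm_fit_univariate <- function(dataset, model = NULL, priors = jm_priors(),
                              mcmc = jm_mcmc(), seed = mcmc$seed,
                              n_quad = 15L, n_knots = 5L) {
  if (is.null(model)) {
    model <- jm_model(long2 = NULL)
  } else if (!is_univariate(model)) {
    model <- jm_model(long1 = model$long1, long2 = NULL,
                      survival_terms = model$survival_terms)
  }
  jm_fit(dataset, model, priors = priors, mcmc = mcmc, seed = seed,
         n_quad = n_quad, n_knots = n_knots)
}

#' Stack all chains of a parameter into one vector
#' @param draws a `jm_draws` object.
#' @param parameter parameter name.
#' @return numeric vector of pooled posterior draws.
#' @export
jm_extract <- function(draws, parameter) {
  stopifnot(inherits(draws, "jm_draws"))
  if (!parameter %in% draws$parameters)
    stop(sprintf("unknown parameter '%s'; available: %s", parameter,
                 paste(draws$parameters, collapse = ", ")))
  unlist(lapply(draws$chains, function(m) m[, parameter]), use.names = FALSE)
}

# Split R-hat (each chain halved) and a Geyer-style initial-positive-sequence
# effective sample size.
split_rhat <- function(mat_list) {
  halves <- list()
  for (m in mat_list) {
    n <- length(m); h <- floor(n / 2)
    halves <- c(halves, list(m[seq_len(h)], m[(n - h + 1):n]))
  }
  n <- length(halves[[1]])
  mu <- vapply(halves, mean, 0)
  vr <- vapply(halves, var, 0)
  W <- mean(vr); B <- n * var(mu)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_one <- function(x) {
  n <- length(x)
  if (var(x) == 0) return(n)
  rho <- drop(stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE,
                         demean = TRUE)$acf)[-1]
  s <- 0
  for (t in seq(1, length(rho) - 1, by = 2)) {
    pair <- rho[t] + rho[t + 1]
    if (is.na(pair) || pair < 0) break
    s <- s + pair
  }
  max(1, n / (1 + 2 * s))
}

#' Posterior summary
#'
#' Per-parameter posterior mean, SD, central 95% credible interval, split
#' R-hat and effective sample size, pooling all chains.
#'
#' @param draws a `jm_draws` object (needs at least 100 retained draws).
#' @return data frame of class `jm_summary`, one row per parameter.
#' @export
jm_summarize <- function(draws) {
  stopifnot(inherits(draws, "jm_draws"))
  if (sum(vapply(draws$chains, nrow, 0L)) < 100)
    stop("at least 100 retained draws are required for a summary")
  out <- lapply(draws$parameters, function(p) {
    per_chain <- lapply(draws$chains, function(m) m[, p])
    x <- unlist(per_chain, use.names = FALSE)
    data.frame(parameter = p, mean = mean(x), sd = sd(x),
               lower = unname(quantile(x, 0.025)),
               upper = unname(quantile(x, 0.975)),
               rhat = split_rhat(per_chain),
               ess = sum(vapply(per_chain, ess_one, 0)))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("jm_summary", "data.frame")
  out
}

#' @rdname jm_summarize
#' @param object,... passed through to [jm_summarize()].
#' @export
summary.jm_draws <- function(object, ...) jm_summarize(object)

#' @export
print.jm_draws <- function(x, ...) {
  cat(sprintf("Joint model posterior draws: %d chain(s) x %d iterations, %d parameters\n",
              length(x$chains), nrow(x$chains[[1]]), length(x$parameters)))
  cat(sprintf("Model: %s; %d subjects\n",
              if (is_univariate(x$model)) "univariate (outcome 1 only)"
              else "multivariate serial", x$n_subjects))
  invisible(x)
}
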