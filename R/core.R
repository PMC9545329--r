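# Core model mathematics: latent trajectories, cause-specific hazards,
# cumulative hazards and the per-subject joint log-likelihood given the
# random effects. These are the reference implementations; the MCMC sampler
# uses an equivalent compiled path that is tested against these functions.

#' Latent trajectory of the first longitudinal outcome
#'
#' Evaluates \eqn{m_{i1}(t) = x_{i1}(t)^\top \beta_1 + z_{i1}(t)^\top b_{i1}},
#' the error-free subject-specific trajectory underlying the noisy
#' measurements of outcome 1.
#'
#' @param t time(s) in years, nonnegative.
#' @param params a [jm_parameters()] object.
#' @param subject a [jm_subject()].
#' @param b a [jm_random_effects()].
#' @return numeric vector of latent values, one per element of `t`.
#' @export
latent_m1 <- function(t, params, subject, b) {
  stopifnot(all(t >= 0))
  X <- design_matrix(params$model$long1$fixed, subject, t)
  drop(X %*% params$beta1) + b$b1[1] + b$b1[2] * t
}

#' Latent trajectory of the second longitudinal outcome
#'
#' Evaluates \eqn{m_{i2}(t) = x_{i2}(t)^\top \beta_2 + z_{i2}(t)^\top b_{i2}
#' + \xi m_{i1}(t)}: the latent process of outcome 1 enters outcome 2's mixed
#' model as a time-varying covariate with loading `xi`, making the model a
#' serial (chained) rather than parallel multivariate joint model.
#'
#' @inheritParams latent_m1
#' @return numeric vector of latent values, one per element of `t`.
#' @export
latent_m2 <- function(t, params, subject, b) {
  if (is_univariate(params$model))
    stop("latent_m2 is undefined for a univariate model")
  stopifnot(all(t >= 0))
  X <- design_matrix(params$model$long2$fixed, subject, t)
  drop(X %*% params$beta2) + b$b2[1] + b$b2[2] * t +
    params$xi * latent_m1(t, params, subject, b)
}

#' Log baseline hazard
#'
#' B-spline basis at `t` dotted with the coefficients of risk `k`. Values of
#' `t` outside the boundary knots raise an error; hazards are not
#' extrapolated.
#'
#' @param t time(s) within the boundary knots.
#' @param k risk index (1 or 2).
#' @param spec a [jm_baseline()].
#' @return numeric vector of log baseline hazard values.
#' @export
log_baseline_hazard <- function(t, k, spec) {
  stopifnot(k %in% 1:2)
  if (any(t < spec$boundary[1]) || any(t > spec$boundary[2]))
    stop(sprintf("time outside the baseline spline boundary [%g, %g]",
                 spec$boundary[1], spec$boundary[2]))
  B <- splines::splineDesign(baseline_knots(spec), t, ord = spec$degree + 1)
  drop(B %*% spec$coefficients[, k])
}

#' Cause-specific hazard
#'
#' \eqn{h_{ik}(t) = h_{0k}(t) \exp\{\gamma_k^\top w_i + \alpha_{k1} m_{i1}(t)
#' + \alpha_{k2} m_{i2}(t)\}}; strictly positive for all finite parameters.
#'
#' @inheritParams latent_m1
#' @param k risk index (1 or 2).
#' @return numeric vector of hazard values.
#' @export
hazard <- function(t, k, params, subject, b) {
  w <- survival_design(params$model, subject)
  eta <- log_baseline_hazard(t, k, params$baseline) +
    sum(params$gamma[[k]] * w) +
    params$alpha[k, 1] * latent_m1(t, params, subject, b)
  if (!is_univariate(params$model))
    eta <- eta + params$alpha[k, 2] * latent_m2(t, params, subject, b)
  exp(eta)
}

# Gauss-Legendre nodes/weights on [-1, 1], cached per order.
gauss_legendre <- local({
  cache <- list()
  function(n = 15L) {
    key <- as.character(n)
    if (is.null(cache[[key]]))
      cache[[key]] <<- pracma::gaussLegendre(n, -1, 1)
    cache[[key]]
  }
})

#' Cumulative cause-specific hazard
#'
#' \eqn{\Lambda_{ik}(t) = \int_0^t h_{ik}(s)\,ds} by fixed-order
#' Gauss-Legendre quadrature (15 nodes by default), the standard choice for
#' joint-model survival likelihoods.
#'
#' @inheritParams hazard
#' @param n_quad quadrature order.
#' @return scalar nonnegative cumulative hazard; exactly 0 at `t = 0`.
#' @export
cumulative_hazard <- function(t, k, params, subject, b, n_quad = 15L) {
  stopifnot(length(t) == 1, t >= 0)
  if (t == 0) return(0)
  gl <- gauss_legendre(n_quad)
  s <- t / 2 * (gl$x + 1)
  sum(t / 2 * gl$w * hazard(s, k, params, subject, b))
}

#' Per-subject joint log-likelihood given random effects
#'
#' Sum of the Gaussian measurement terms of both longitudinal outcomes, the
#' log hazard of the observed event (if any) at `T_i`, and minus the
#' cumulative hazards of both risks at `T_i`. The random effects themselves
#' are conditioned on, not integrated out.
#'
#' @inheritParams latent_m1
#' @return finite scalar log-likelihood.
#' @export
subject_loglik <- function(subject, params, b) {
  uni <- is_univariate(params$model)
  ll_long1 <- with(subject$series1,
                   sum(dnorm(value, latent_m1(time, params, subject, b),
                             params$sigma1, log = TRUE)))
  ll_long2 <- if (uni) 0 else
    with(subject$series2,
         sum(dnorm(value, latent_m2(time, params, subject, b),
                   params$sigma2, log = TRUE)))
  Ti <- subject$observed_time
  ll_surv <- -cumulative_hazard(Ti, 1, params, subject, b) -
    cumulative_hazard(Ti, 2, params, subject, b)
  if (subject$event > 0)
    ll_surv <- ll_surv + log(hazard(Ti, subject$event, params, subject, b))
  out <- ll_long1 + ll_long2 + ll_surv
  if (!is.finite(out)) {
    parts <- c(longitudinal_1 = ll_long1, longitudinal_2 = ll_long2,
               survival = ll_surv)
    bad <- names(parts)[!is.finite(parts)]
    stop(sprintf("non-finite log-likelihood for subject %s (component: %s)",
                 subject$id, paste(bad, collapse = ", ")))
  }
  out
}
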