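#' @useDynLib serialjm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dnorm lm.fit quantile rnorm rbinom rexp runif sd var
#'   acf cov2cor
#' @importFrom utils write.csv read.csv modifyList
NULL

# Term vocabulary for longitudinal fixed effects. "intercept", "time",
# "intervention" and "intervention:time" are resolved internally; any other
# term name must match a baseline covariate carried by the subject.
.jm_special_terms <- c("intercept", "time", "intervention", "intervention:time")

#' Specify a longitudinal submodel
#'
#' Describes the fixed-effect design of one longitudinal outcome. Random
#' effects are always a subject-level random intercept and random slope in
#' time. The second outcome may additionally load on the latent trajectory of
#' the first outcome (`upstream = TRUE`), which makes the two outcomes a
#' serial chain rather than merely correlated.
#'
#' @param fixed character vector of term names, in order. Recognised special
#'   terms are `"intercept"`, `"time"`, `"intervention"` and
#'   `"intervention:time"`; any other name refers to a subject-level baseline
#'   covariate.
#' @param upstream logical; include the latent trajectory of outcome 1 as a
#'   time-varying covariate (only allowed for outcome 2).
#' @return an object of class `jm_longitudinal_spec`.
#' @export
jm_longitudinal_spec <- function(fixed = c("intercept", "time", "intervention:time"),
                                 upstream = FALSE) {
  stopifnot(is.character(fixed), length(fixed) >= 1, !anyDuplicated(fixed))
  structure(list(fixed = fixed, random = c("intercept", "time"),
                 upstream = isTRUE(upstream)),
            class = "jm_longitudinal_spec")
}

#' Specify the model structure
#'
#' Bundles the two longitudinal submodels and the cause-specific hazard
#' design. Setting `long2 = NULL` gives the restricted univariate joint model
#' (one longitudinal outcome, two competing risks) used as the misspecified
#' comparator in the simulation studies.
#'
#' @param long1,long2 [jm_longitudinal_spec()] objects; `long2 = NULL` for the
#'   univariate model. Outcome 1 can never load on an upstream latent process.
#' @param survival_terms character vector of baseline covariates entering both
#'   cause-specific hazards (no intercept: the baseline hazard absorbs it).
#' @return an object of class `jm_model`.
#' @export
jm_model <- function(long1 = jm_longitudinal_spec(),
                     long2 = jm_longitudinal_spec(upstream = TRUE),
                     survival_terms = "intervention") {
  stopifnot(inherits(long1, "jm_longitudinal_spec"))
  if (long1$upstream)
    stop("outcome 1 cannot include an upstream latent process")
  if (!is.null(long2)) stopifnot(inherits(long2, "jm_longitudinal_spec"))
  stopifnot(is.character(survival_terms), length(survival_terms) >= 1)
  if ("intercept" %in% survival_terms)
    stop("survival_terms must not contain an intercept; the baseline hazard absorbs it")
  structure(list(long1 = long1, long2 = long2, survival_terms = survival_terms),
            class = "jm_model")
}

is_univariate <- function(model) is.null(model$long2)

#' Baseline hazard B-spline specification
#'
#' The log baseline hazard of each competing risk is a B-spline; working on
#' the log scale keeps the hazard strictly positive for any coefficient
#' values. Evaluation outside the boundary knots is an error: hazards are
#' never silently extrapolated.
#'
#' @param interior_knots strictly increasing knots inside the boundary.
#' @param boundary length-2 boundary knots, typically `c(0, t_max)`.
#' @param degree spline degree (cubic by default).
#' @param coefficients numeric matrix with one column per competing risk and
#'   one row per basis function.
#' @return an object of class `jm_baseline`.
#' @export
jm_baseline <- function(interior_knots, boundary, degree = 3, coefficients) {
  stopifnot(length(boundary) == 2, boundary[1] < boundary[2], degree >= 1)
  if (length(interior_knots) &&
      (any(interior_knots <= boundary[1]) || any(interior_knots >= boundary[2])))
    stop("interior knots must lie strictly inside the boundary knots")
  if (is.unsorted(interior_knots)) stop("interior knots must be ordered")
  nb <- length(interior_knots) + degree + 1
  coefficients <- as.matrix(coefficients)
  if (nrow(coefficients) != nb)
    stop(sprintf("expected %d spline coefficients per risk, got %d",
                 nb, nrow(coefficients)))
  structure(list(interior_knots = as.numeric(interior_knots),
                 boundary = as.numeric(boundary),
                 degree = as.integer(degree),
                 coefficients = coefficients),
            class = "jm_baseline")
}

# Full (padded) knot vector for splineDesign.
baseline_knots <- function(spec) {
  c(rep(spec$boundary[1], spec$degree + 1), spec$interior_knots,
    rep(spec$boundary[2], spec$degree + 1))
}

#' Joint model parameter set
#'
#' Container for every parameter of the joint model: fixed effects of both
#' longitudinal submodels, the serial association `xi` between the latent
#' processes, residual SDs, random-effect covariance matrices (the two
#' outcomes' random effects are independent of each other), hazard regression
#' coefficients `gamma` per risk, the 2x2 association matrix `alpha` (rows =
#' risk, columns = longitudinal outcome), and the baseline-spline
#' specification.
#'
#' @param model a [jm_model()] describing the designs the coefficients refer to.
#' @param beta1,beta2 fixed effects, ordered as in the model spec.
#' @param xi scalar loading of outcome 1's latent process in outcome 2.
#' @param sigma1,sigma2 positive residual SDs.
#' @param Sigma_b1,Sigma_b2 2x2 symmetric positive-definite random-effect
#'   covariance matrices (intercept, slope).
#' @param gamma list of per-risk coefficient vectors for the survival terms.
#' @param alpha 2x2 association matrix; `alpha[k, j]` is the log hazard ratio
#'   of risk `k` per unit of outcome `j`'s latent value.
#' @param baseline a [jm_baseline()].
#' @return an object of class `jm_parameters`.
#' @export
jm_parameters <- function(model, beta1, beta2 = NULL, xi = 0,
                          sigma1, sigma2 = NULL,
                          Sigma_b1, Sigma_b2 = NULL,
                          gamma, alpha, baseline) {
  stopifnot(inherits(model, "jm_model"), inherits(baseline, "jm_baseline"))
  uni <- is_univariate(model)
  if (length(beta1) != length(model$long1$fixed))
    stop("beta1 length does not match long1 fixed terms")
  if (!uni && length(beta2) != length(model$long2$fixed))
    stop("beta2 length does not match long2 fixed terms")
  stopifnot(sigma1 > 0)
  check_pd <- function(S, nm) {
    if (!isTRUE(all.equal(S, t(S))) || any(eigen(S, TRUE, TRUE)$values <= 0))
      stop(nm, " must be symmetric positive definite")
  }
  Sigma_b1 <- as.matrix(Sigma_b1); check_pd(Sigma_b1, "Sigma_b1")
  if (!uni) {
    stopifnot(sigma2 > 0)
    Sigma_b2 <- as.matrix(Sigma_b2); check_pd(Sigma_b2, "Sigma_b2")
  }
  stopifnot(is.list(gamma), length(gamma) == 2)
  if (any(lengths(gamma) != length(model$survival_terms)))
    stop("each gamma vector must match survival_terms")
  alpha <- as.matrix(alpha)
  if (nrow(alpha) != 2 || ncol(alpha) != (if (uni) 1 else 2))
    stop("alpha must be 2 x n_outcomes (rows = risks)")
  if (ncol(baseline$coefficients) != 2)
    stop("baseline coefficients must have one column per risk")
  structure(list(model = model, beta1 = as.numeric(beta1),
                 beta2 = if (!uni) as.numeric(beta2), xi = if (!uni) xi,
                 sigma1 = sigma1, sigma2 = if (!uni) sigma2,
                 Sigma_b1 = Sigma_b1, Sigma_b2 = if (!uni) Sigma_b2,
                 gamma = lapply(gamma, as.numeric), alpha = alpha,
                 baseline = baseline),
            class = "jm_parameters")
}

#' Random effects of one subject
#'
#' @param b1,b2 length-2 vectors (random intercept, random slope) for the two
#'   longitudinal outcomes.
#' @return an object of class `jm_random_effects`.
#' @export
jm_random_effects <- function(b1 = c(0, 0), b2 = c(0, 0)) {
  stopifnot(length(b1) == 2, length(b2) == 2, all(is.finite(c(b1, b2))))
  structure(list(b1 = as.numeric(b1), b2 = as.numeric(b2)),
            class = "jm_random_effects")
}

#' One subject's record
#'
#' Holds the subject-level data of the joint model: baseline covariates
#' including the randomized intervention arm, the two independently timed
#' measurement series, the observed time `T_i = min(T*_i1, T*_i2, C_i)` and
#' the event indicator (0 censored, 1 first competing event, 2 second).
#'
#' @param id subject identifier.
#' @param intervention 0/1 intervention arm.
#' @param covariates named numeric vector of baseline covariates (may be empty).
#' @param series1,series2 data frames with columns `time`, `value`;
#'   `series2 = NULL` only for univariate-model data.
#' @param observed_time nonnegative follow-up time in years.
#' @param event integer in 0, 1, 2.
#' @return an object of class `jm_subject`.
#' @export
jm_subject <- function(id, intervention, covariates = numeric(0),
                       series1, series2 = NULL, observed_time, event) {
  stopifnot(intervention %in% c(0, 1), observed_time >= 0, event %in% 0:2)
  fix_series <- function(s) {
    if (is.null(s)) return(data.frame(time = numeric(0), value = numeric(0)))
    s <- as.data.frame(s)[, c("time", "value")]
    if (any(s$time < 0)) stop("measurement times must be nonnegative")
    if (any(s$time > observed_time + 1e-9))
      stop(sprintf("subject %s has a measurement after its observed time", id))
    s
  }
  structure(list(id = id, intervention = as.numeric(intervention),
                 covariates = covariates,
                 series1 = fix_series(series1), series2 = fix_series(series2),
                 observed_time = as.numeric(observed_time),
                 event = as.integer(event)),
            class = "jm_subject")
}

# Resolve one fixed-effect design row x(t) for a subject; vectorized in t.
# Returns a length(t) x length(terms) matrix.
design_matrix <- function(terms, subject, t) {
  n <- length(t)
  out <- matrix(NA_real_, n, length(terms))
  for (j in seq_along(terms)) {
    tm <- terms[j]
    out[, j] <- switch(tm,
      "intercept" = 1,
      "time" = t,
      "intervention" = subject$intervention,
      "intervention:time" = subject$intervention * t,
      {
        if (!tm %in% names(subject$covariates))
          stop(sprintf("covariate '%s' required by the model is missing for subject %s",
                       tm, subject$id))
        subject$covariates[[tm]]
      })
  }
  colnames(out) <- terms
  out
}

survival_design <- function(model, subject) {
  drop(design_matrix(model$survival_terms, subject, 0))
}
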