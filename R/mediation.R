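# Latent mediation decomposition: the time-varying intervention effect on a
# competing risk splits, on the log-hazard scale, into a direct path and
# three indirect paths -- through outcome 1, through outcome 2, and serially
# through both. All hazard ratios are conditional on the random effects.

# Locate the intervention terms of one longitudinal submodel.
profile_terms <- function(model, outcome) {
  spec <- if (outcome == 1) model$long1 else model$long2
  if (is.null(spec)) stop("the model has no outcome ", outcome)
  main <- "intervention" %in% spec$fixed
  inter <- "intervention:time" %in% spec$fixed
  if (!main && !inter)
    stop(sprintf("outcome %d has no intervention term; cannot form an intervention profile",
                 outcome))
  list(main = if (main) paste0("beta", outcome, "_intervention"),
       inter = if (inter) paste0("beta", outcome, "_intervention:time"))
}

#' Time-varying intervention effect on a longitudinal outcome
#'
#' The intervention profile \eqn{\mathcal{B}_j(t)} of outcome `j`: the
#' intervention main effect (if present) plus the intervention-by-time
#' interaction (if present) times `t`.
#'
#' @param draws a `jm_draws` object, or a named numeric vector holding one
#'   parameter draw.
#' @param outcome 1 or 2.
#' @param t time(s) in years.
#' @param model the [jm_model()] the coefficients refer to (taken from
#'   `draws` when a `jm_draws` object is supplied).
#' @return for a single draw, a numeric vector over `t`; for a `jm_draws`
#'   object, a draws-by-time matrix.
#' @export
intervention_profile <- function(draws, outcome, t, model = NULL) {
  if (inherits(draws, "jm_draws")) {
    model <- draws$model
    tm <- profile_terms(model, outcome)
    n_draws <- sum(vapply(draws$chains, nrow, 0L))
    main <- if (is.null(tm$main)) rep(0, n_draws) else jm_extract(draws, tm$main)
    inter <- if (is.null(tm$inter)) rep(0, n_draws) else jm_extract(draws, tm$inter)
    return(outer(main, rep(1, length(t))) + outer(inter, t))
  }
  stopifnot(!is.null(model), !is.null(names(draws)))
  tm <- profile_terms(model, outcome)
  main <- if (is.null(tm$main)) 0 else unname(draws[tm$main])
  inter <- if (is.null(tm$inter)) 0 else unname(draws[tm$inter])
  main + inter * t
}

need_params <- function(draws, wanted) {
  missing <- setdiff(wanted, draws$parameters)
  if (length(missing))
    stop("mediation decomposition needs parameters not present in the draws: ",
         paste(missing, collapse = ", "),
         " (required: ", paste(wanted, collapse = ", "), ")")
}

#' Latent mediation decomposition of the intervention effect
#'
#' Per posterior draw and time point, computes the components of the
#' log hazard ratio of intervention versus control on risk `k`:
#' direct \eqn{\gamma_{k1}}; indirect through outcome 1
#' \eqn{\alpha_{k1}\mathcal{B}_1(t)}; indirect through outcome 2
#' \eqn{\alpha_{k2}\mathcal{B}_2(t)}; serial indirect through both
#' \eqn{\xi\alpha_{k2}\mathcal{B}_1(t)}. Their sum is the total time-varying
#' effect; the identity holds exactly per draw. The combined mediation
#' through outcome 1 is the sum of the first and third indirect paths.
#'
#' @param draws a `jm_draws` object from the multivariate model.
#' @param time_grid evaluation times in years.
#' @param risk competing risk index (1 by default; 2 gives the symmetric
#'   decomposition for the second event).
#' @param band_type `"mean_of_exp"` (default) summarizes the posterior of
#'   each exp-transformed component; `"exp_of_mean"` exponentiates the
#'   posterior mean of the log component.
#' @return an object of class `jm_mediation`: per-draw component matrices on
#'   the log-hazard scale and a tidy summary on the hazard-ratio scale with
#'   pointwise central 95% bands.
#' @export
mediation_decompose <- function(draws, time_grid = seq(0, 3, by = 0.05),
                                risk = 1, band_type = c("mean_of_exp",
                                                        "exp_of_mean")) {
  stopifnot(inherits(draws, "jm_draws"), length(time_grid) >= 1,
            risk %in% 1:2)
  band_type <- match.arg(band_type)
  if (is_univariate(draws$model))
    stop("mediation decomposition requires the multivariate model ",
         "(parameters xi and alpha_k2 are absent from a univariate fit)")
  if (!"intervention" %in% draws$model$survival_terms)
    stop("the survival submodel has no intervention term (direct effect undefined)")
  gname <- sprintf("gamma%d_intervention", risk)
  a1 <- sprintf("alpha%d1", risk); a2 <- sprintf("alpha%d2", risk)
  need_params(draws, c(gname, a1, a2, "xi"))
  gam <- jm_extract(draws, gname)
  ak1 <- jm_extract(draws, a1); ak2 <- jm_extract(draws, a2)
  xi <- jm_extract(draws, "xi")
  B1 <- intervention_profile(draws, 1, time_grid)
  B2 <- intervention_profile(draws, 2, time_grid)
  nt <- length(time_grid)
  comp <- list(direct = matrix(gam, length(gam), nt),
               indirect_1 = ak1 * B1,
               indirect_2 = ak2 * B2,
               indirect_3 = xi * ak2 * B1)
  comp$combined_via_outcome1 <- comp$indirect_1 + comp$indirect_3
  comp$total <- comp$direct + comp$indirect_1 + comp$indirect_2 +
    comp$indirect_3
  summary <- do.call(rbind, lapply(names(comp), function(nm) {
    hr <- exp(comp[[nm]])
    data.frame(time = time_grid, component = nm,
               mean = if (band_type == "mean_of_exp") colMeans(hr)
                      else exp(colMeans(comp[[nm]])),
               lower = apply(hr, 2, quantile, 0.025),
               upper = apply(hr, 2, quantile, 0.975))
  }))
  rownames(summary) <- NULL
  structure(list(time_grid = time_grid, components = comp, summary = summary,
                 risk = risk, band_type = band_type),
            class = "jm_mediation")
}

# Per-draw log total intervention effect on risk k; works for both model
# kinds (the univariate model has only the direct and outcome-1 paths).
total_effect_draws <- function(draws, time_grid, risk = 1) {
  gname <- sprintf("gamma%d_intervention", risk)
  a1 <- sprintf("alpha%d1", risk)
  need_params(draws, c(gname, a1))
  gam <- jm_extract(draws, gname)
  B1 <- intervention_profile(draws, 1, time_grid)
  out <- matrix(gam, length(gam), length(time_grid)) +
    jm_extract(draws, a1) * B1
  if (!is_univariate(draws$model)) {
    a2 <- sprintf("alpha%d2", risk)
    need_params(draws, c(a2, "xi"))
    ak2 <- jm_extract(draws, a2); xi <- jm_extract(draws, "xi")
    out <- out + ak2 * intervention_profile(draws, 2, time_grid) +
      xi * ak2 * B1
  }
  out
}

#' Plot the mediation decomposition
#'
#' One panel per path plus the total effect, on the hazard-ratio scale, with
#' shaded pointwise 95% bands, written to a PNG file.
#'
#' @param curves a `jm_mediation` object.
#' @param path output file path (`.png`).
#' @param width,height,res device settings.
#' @return `path`, invisibly.
#' @export
plot_mediation <- function(curves, path, width = 1400, height = 900,
                           res = 130) {
  stopifnot(inherits(curves, "jm_mediation"))
  if (length(curves$time_grid) == 0) stop("empty time grid; nothing to plot")
  labs <- c(direct = "Direct effect",
            indirect_1 = "Mediated via outcome 1",
            indirect_2 = "Mediated via outcome 2",
            indirect_3 = "Serial: via outcomes 1 and 2",
            combined_via_outcome1 = "Combined mediation via outcome 1",
            total = "Total intervention effect")
  grDevices::png(path, width = width, height = height, res = res)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2.5, 1))
  for (nm in names(labs)) {
    sm <- curves$summary[curves$summary$component == nm, ]
    ylim <- range(sm$lower, sm$upper, 1)
    plot(sm$time, sm$mean, type = "n", ylim = ylim, xlab = "Time (years)",
         ylab = "Hazard ratio", main = labs[[nm]])
    graphics::polygon(c(sm$time, rev(sm$time)), c(sm$lower, rev(sm$upper)),
                      col = grDevices::adjustcolor("steelblue", 0.25),
                      border = NA)
    graphics::lines(sm$time, sm$mean, col = "steelblue4", lwd = 2)
    graphics::abline(h = 1, lty = 3)
  }
  invisible(path)
}

#' Export mediation curves as tidy tables
#'
#' @param curves a `jm_mediation` object.
#' @param draws_path optional CSV path for the per-draw long table
#'   (draw, time, component, value on the log-hazard scale).
#' @param summary_path optional CSV path for the summary table
#'   (time, component, mean, lower, upper on the hazard-ratio scale).
#' @return list with the written paths, invisibly.
#' @export
write_mediation <- function(curves, draws_path = NULL, summary_path = NULL) {
  stopifnot(inherits(curves, "jm_mediation"))
  if (!is.null(draws_path)) {
    long <- do.call(rbind, lapply(names(curves$components), function(nm) {
      m <- curves$components[[nm]]
      data.frame(draw = rep(seq_len(nrow(m)), times = ncol(m)),
                 time = rep(curves$time_grid, each = nrow(m)),
                 component = nm, value = as.vector(m))
    }))
    write.csv(long, draws_path, row.names = FALSE)
  }
  if (!is.null(summary_path))
    write.csv(curves$summary, summary_path, row.names = FALSE)
  invisible(list(draws = draws_path, summary = summary_path))
}
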