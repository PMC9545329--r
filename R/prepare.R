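# Assembly of the flat design structures consumed by the compiled sampler:
# stacked longitudinal design matrices, the survival covariate matrix, and
# B-spline bases evaluated at the Gauss-Legendre quadrature nodes and the
# observed event times.

#' @keywords internal
choose_baseline_knots <- function(dataset, n_interior = 5, degree = 3) {
  Ti <- vapply(dataset, function(s) s$observed_time, 0)
  delta <- vapply(dataset, function(s) s$event, 0L)
  ev <- Ti[delta > 0]
  src <- if (length(unique(ev)) >= n_interior + 2) ev else Ti
  probs <- seq(0, 1, length.out = n_interior + 2)[-c(1, n_interior + 2)]
  interior <- unname(quantile(src, probs, type = 7))
  tmax <- max(Ti)
  # keep knots strictly interior
  interior <- pmin(pmax(interior, 1e-6 * tmax), tmax * (1 - 1e-6))
  interior <- sort(unique(interior))
  list(interior = interior, boundary = c(0, tmax), degree = degree)
}

jm_prepare <- function(dataset, model, n_quad = 15L, n_knots = 5L,
                       baseline_spec = NULL) {
  n <- length(dataset)
  uni <- is_univariate(model)
  if (is.null(baseline_spec))
    baseline_spec <- choose_baseline_knots(dataset, n_knots)
  degree <- baseline_spec$degree
  knots <- c(rep(baseline_spec$boundary[1], degree + 1), baseline_spec$interior,
             rep(baseline_spec$boundary[2], degree + 1))
  nb <- length(baseline_spec$interior) + degree + 1

  terms1 <- model$long1$fixed
  terms2 <- if (!uni) model$long2$fixed

  sl <- function(x) do.call(rbind, x)
  L1 <- L2 <- vector("list", n)
  X1 <- X2 <- X1a2 <- vector("list", n)
  Ti <- numeric(n); delta <- integer(n)
  W <- matrix(NA_real_, n, length(model$survival_terms))
  for (i in seq_len(n)) {
    s <- dataset[[i]]
    Ti[i] <- s$observed_time; delta[i] <- s$event
    W[i, ] <- survival_design(model, s)
    L1[[i]] <- cbind(id = i, time = s$series1$time, value = s$series1$value)
    X1[[i]] <- design_matrix(terms1, s, s$series1$time)
    if (!uni) {
      L2[[i]] <- cbind(id = i, time = s$series2$time, value = s$series2$value)
      X2[[i]] <- design_matrix(terms2, s, s$series2$time)
      X1a2[[i]] <- design_matrix(terms1, s, s$series2$time)
    }
  }
  A1 <- sl(L1)
  n_per1 <- vapply(L1, nrow, 0L)
  end1 <- cumsum(n_per1); start1 <- end1 - n_per1 + 1L

  gl <- gauss_legendre(n_quad)
  tq <- as.vector(vapply(Ti, function(T) T / 2 * (gl$x + 1), numeric(n_quad)))
  wq <- as.vector(vapply(Ti, function(T) T / 2 * gl$w, numeric(n_quad)))
  idq <- rep(seq_len(n), each = n_quad)

  Bq <- splines::splineDesign(knots, tq, ord = degree + 1)
  BT <- splines::splineDesign(knots, Ti, ord = degree + 1)
  X1q <- do.call(rbind, lapply(seq_len(n), function(i)
    design_matrix(terms1, dataset[[i]], tq[idq == i])))
  X1T <- do.call(rbind, lapply(seq_len(n), function(i)
    design_matrix(terms1, dataset[[i]], Ti[i])))

  # Translation-move structure: every supported fixed-effect term is either
  # subject-constant (c_i) or subject-constant times time (c_i * t), so a
  # shift of its coefficient can be absorbed exactly by the random intercepts
  # or slopes. Ctype: 0 = constant term, 1 = times-time term.
  term_shape <- function(terms) {
    type <- integer(length(terms))
    cval <- matrix(NA_real_, n, length(terms))
    for (j in seq_along(terms)) {
      tm <- terms[j]
      type[j] <- as.integer(tm %in% c("time", "intervention:time"))
      base <- sub(":time$", "", tm)
      cval[, j] <- vapply(dataset, function(s) switch(base,
        "intercept" = 1, "time" = 1, "intervention" = s$intervention,
        s$covariates[[base]]), 0)
    }
    list(type = type, cval = cval)
  }
  sh1 <- term_shape(terms1)

  out <- list(n = n, Q = as.integer(n_quad), has2 = !uni,
              Ct1 = sh1$type, Cv1 = sh1$cval,
              y1 = A1[, "value"], t1 = A1[, "time"], X1 = sl(X1),
              id1 = as.integer(A1[, "id"]),
              start1 = as.integer(start1), end1 = as.integer(end1),
              W = W, delta = delta, TT = Ti,
              Bq = Bq, X1q = X1q, tq = tq, wq = wq,
              BT = BT, X1T = X1T,
              baseline_spec = baseline_spec, nb = nb)
  if (!uni) {
    sh2 <- term_shape(terms2)
    out$Ct2 <- sh2$type; out$Cv2 <- sh2$cval
    A2 <- sl(L2)
    n_per2 <- vapply(L2, nrow, 0L)
    end2 <- cumsum(n_per2); start2 <- end2 - n_per2 + 1L
    X2q <- do.call(rbind, lapply(seq_len(n), function(i)
      design_matrix(terms2, dataset[[i]], tq[idq == i])))
    X2T <- do.call(rbind, lapply(seq_len(n), function(i)
      design_matrix(terms2, dataset[[i]], Ti[i])))
    out <- c(out, list(y2 = A2[, "value"], t2 = A2[, "time"], X2 = sl(X2),
                       X1a2 = sl(X1a2), id2 = as.integer(A2[, "id"]),
                       start2 = as.integer(start2), end2 = as.integer(end2),
                       X2q = X2q, X2T = X2T))
  }
  out
}

# Flat parameter layout: indices into the sampler's theta vector, the
# user-facing names, and the prior type/scale of every coordinate.
jm_layout <- function(model, prep, priors) {
  uni <- is_univariate(model)
  terms1 <- model$long1$fixed
  terms2 <- if (!uni) model$long2$fixed
  sterms <- model$survival_terms
  nb <- prep$nb

  nm <- list(); idx <- list(); pos <- 0L
  take <- function(k) { out <- pos + seq_len(k); pos <<- pos + k; out }
  idx$beta1 <- take(length(terms1)); nm$beta1 <- paste0("beta1_", terms1)
  if (!uni) {
    idx$beta2 <- take(length(terms2)); nm$beta2 <- paste0("beta2_", terms2)
    idx$xi <- take(1L); nm$xi <- "xi"
  }
  idx$lsig1 <- take(1L); nm$lsig1 <- "sigma1"
  if (!uni) { idx$lsig2 <- take(1L); nm$lsig2 <- "sigma2" }
  idx$gamma1 <- take(length(sterms)); nm$gamma1 <- paste0("gamma1_", sterms)
  idx$gamma2 <- take(length(sterms)); nm$gamma2 <- paste0("gamma2_", sterms)
  n_out <- if (uni) 1L else 2L
  idx$alpha1 <- take(n_out); nm$alpha1 <- paste0("alpha1", seq_len(n_out))
  idx$alpha2 <- take(n_out); nm$alpha2 <- paste0("alpha2", seq_len(n_out))
  idx$phi1 <- take(nb); nm$phi1 <- paste0("phi1_", seq_len(nb))
  idx$phi2 <- take(nb); nm$phi2 <- paste0("phi2_", seq_len(nb))
  idx$re1 <- take(3L); nm$re1 <- c("sd_b1_intercept", "sd_b1_slope", "cor_b1")
  if (!uni) {
    idx$re2 <- take(3L); nm$re2 <- c("sd_b2_intercept", "sd_b2_slope", "cor_b2")
  }
  n_par <- pos

  type <- integer(n_par); nsd <- rep(1, n_par)
  nsd[idx$beta1] <- priors$beta_sd
  if (!uni) { nsd[idx$beta2] <- priors$beta_sd; nsd[idx$xi] <- priors$xi_sd }
  nsd[c(idx$gamma1, idx$gamma2)] <- priors$gamma_sd
  nsd[c(idx$alpha1, idx$alpha2)] <- priors$alpha_sd
  nsd[c(idx$phi1, idx$phi2)] <- priors$spline_sd
  type[c(idx$lsig1, idx$lsig2, idx$re1[1:2],
         if (!uni) idx$re2[1:2])] <- 1L
  type[c(idx$re1[3], if (!uni) idx$re2[3])] <- 2L

  # transformation applied when exposing draws on the natural scale
  transf <- rep("identity", n_par)
  transf[type == 1L] <- "exp"
  transf[type == 2L] <- "tanh"

  blocks <- list(list(type = "beta1", id = idx$beta1))
  if (!uni)
    blocks <- c(blocks, list(list(type = "beta2xi", id = c(idx$beta2, idx$xi))))
  blocks <- c(blocks, list(list(type = "lsig1", id = idx$lsig1)))
  if (!uni) blocks <- c(blocks, list(list(type = "lsig2", id = idx$lsig2)))
  blocks <- c(blocks,
              list(list(type = "surv1", id = c(idx$gamma1, idx$alpha1, idx$phi1)),
                   list(type = "surv2", id = c(idx$gamma2, idx$alpha2, idx$phi2)),
                   list(type = "re1", id = idx$re1)))
  if (!uni) blocks <- c(blocks, list(list(type = "re2", id = idx$re2)))
  blocks <- c(blocks, list(list(type = "all", id = seq_len(n_par))))

  list(idx = idx, names = unlist(nm, use.names = FALSE), n_par = n_par,
       prior = list(type = type, nsd = nsd, t_df = priors$sd_prior_df,
                    t_scale = priors$sd_prior_scale, lkj_eta = priors$lkj_eta),
       transf = transf, blocks = blocks)
}

# Pack a jm_parameters object into the sampler's flat theta vector. The
# baseline spec of `prep` must match the parameters' own baseline.
pack_parameters <- function(params, prep, layout) {
  stopifnot(inherits(params, "jm_parameters"))
  theta <- numeric(layout$n_par)
  idx <- layout$idx
  theta[idx$beta1] <- params$beta1
  theta[idx$lsig1] <- log(params$sigma1)
  if (prep$has2) {
    theta[idx$beta2] <- params$beta2
    theta[idx$xi] <- params$xi
    theta[idx$lsig2] <- log(params$sigma2)
  }
  theta[idx$gamma1] <- params$gamma[[1]]
  theta[idx$gamma2] <- params$gamma[[2]]
  theta[idx$alpha1] <- params$alpha[1, ]
  theta[idx$alpha2] <- params$alpha[2, ]
  theta[idx$phi1] <- params$baseline$coefficients[, 1]
  theta[idx$phi2] <- params$baseline$coefficients[, 2]
  re_pack <- function(S) c(0.5 * log(S[1, 1]), 0.5 * log(S[2, 2]),
                           atanh(stats::cov2cor(S)[1, 2]))
  theta[idx$re1] <- re_pack(params$Sigma_b1)
  if (prep$has2) theta[idx$re2] <- re_pack(params$Sigma_b2)
  theta
}

# Least-squares initialization of the longitudinal fixed effects, crude-rate
# initialization of the log baseline hazard; associations start at zero.
jm_init <- function(prep, layout) {
  theta <- numeric(layout$n_par)
  f1 <- lm.fit(prep$X1, prep$y1)
  theta[layout$idx$beta1] <- f1$coefficients
  s1 <- sd(f1$residuals); if (!is.finite(s1) || s1 <= 0) s1 <- 0.5
  theta[layout$idx$lsig1] <- log(s1)
  if (prep$has2) {
    f2 <- lm.fit(prep$X2, prep$y2)
    theta[layout$idx$beta2] <- f2$coefficients
    s2 <- sd(f2$residuals); if (!is.finite(s2) || s2 <= 0) s2 <- 0.5
    theta[layout$idx$lsig2] <- log(s2)
    theta[layout$idx$xi] <- 0
  }
  risk_rate <- function(k) {
    r <- sum(prep$delta == k) / sum(prep$TT)
    log(max(r, 0.5 / sum(prep$TT)))
  }
  theta[layout$idx$phi1] <- risk_rate(1)
  theta[layout$idx$phi2] <- risk_rate(2)
  theta[layout$idx$re1] <- c(log(0.3), log(0.2), 0)
  if (prep$has2) theta[layout$idx$re2] <- c(log(0.3), log(0.2), 0)
  init_step <- rep(0.05, layout$n_par)
  init_step[c(layout$idx$phi1, layout$idx$phi2)] <- 0.1
  init_step[c(layout$idx$re1, if (prep$has2) layout$idx$re2)] <- 0.1
  list(theta = theta, init_step = init_step,
       b1 = matrix(0, prep$n, 2), b2 = matrix(0, prep$n, 2))
}
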