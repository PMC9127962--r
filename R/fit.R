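#' Dose-response datasets
#'
#' Kinetic dose-response data for operator characterization: for each
#' input condition (a supplement concentration, or a pair of
#' concentrations for two-input designs) a reporter time series measured
#' on a shared grid. Replicate assays are held as separate blocks and all
#' contribute residuals during fitting.
#'
#' @param conc Numeric vector of supplement concentrations (one input) or
#'   a two-column matrix of concentration pairs, one row per condition.
#' @param times Measurement times (h), at least 5, strictly increasing,
#'   starting at the assay start.
#' @param values Matrix of reporter values, `length(times)` rows and one
#'   column per condition.
#' @param biomass Optional biomass series on the same grid (used to
#'   reconstruct the growth profile when none is supplied to a fit).
#' @return An object of class `dose_response`.
#' @export
dose_response_data <- function(conc, times, values, biomass = NULL) {
  if (is.null(dim(conc))) conc <- matrix(conc, ncol = 1)
  values <- as.matrix(values)
  stopifnot(length(times) >= 5L, all(diff(times) > 0), all(conc >= 0),
            nrow(values) == length(times), ncol(values) == nrow(conc))
  ds <- structure(list(blocks = list(list(conc = conc, times = times,
                                          values = values,
                                          biomass = biomass))),
                  class = "dose_response")
  check_design(ds)
  ds
}

combine_dose_response <- function(datasets) {
  ds <- structure(list(blocks = unlist(lapply(datasets, `[[`, "blocks"),
                                       recursive = FALSE)),
                  class = "dose_response")
  check_design(ds)
  ds
}

check_design <- function(ds) {
  conc <- do.call(rbind, lapply(ds$blocks, `[[`, "conc"))
  for (j in seq_len(ncol(conc)))
    if (length(unique(conc[, j])) < 4L)
      stop(sprintf(
        "insufficient design: input axis %d has %d distinct concentrations (need >= 4)",
        j, length(unique(conc[, j]))), call. = FALSE)
  invisible(ds)
}

#' @export
print.dose_response <- function(x, ...) {
  conc <- do.call(rbind, lapply(x$blocks, `[[`, "conc"))
  cat(sprintf("<dose_response> %d input(s), %d condition(s) in %d block(s)\n",
              ncol(conc), nrow(conc), length(x$blocks)))
  invisible(x)
}

# ---- lean vectorised transfer functions (no validation; fitting hot path)
# inputs are capped so (r/K)^n never overflows; the cap is far beyond any
# saturated response and leaves the rational form within 1e-12 of its limit
vhill1 <- function(r, a0, a1, K, n) {
  x <- pmin((pmax(r, 0) / K)^n, 1e12)
  (a0 + a1 * x) / (1 + x)
}
vhill2 <- function(r1, r2, a0, a1, a2, a3, K1, K2, n1, n2) {
  x1 <- pmin((pmax(r1, 0) / K1)^n1, 1e12)
  x2 <- pmin((pmax(r2, 0) / K2)^n2, 1e12)
  (a0 + a1 * x1 + a2 * x2 + a3 * x1 * x2) / (1 + x1 + x2 + x1 * x2)
}

# ---- integrating-factor trajectory evaluation ----------------------------
# Every species in the characterization circuits obeys a linear ODE
#   dp/dt = f(t) - (gamma + mu(t)) p
# whose exact solution is p(t) = (p(0) + int_0^t f w dtau) / w(t) with the
# integrating factor w(t) = exp(gamma t) B(t)/B(0) (mu = d ln B/dt, so the
# dilution integral is analytic). Model trajectories therefore reduce to
# one composite-Simpson quadrature, vectorised over all dose conditions —
# this is what makes trajectory-level multi-start fitting cheap.

# fine quadrature grid: m (even) substeps per observation interval, plus
# the per-interval Simpson weight matrix W (n_intervals x n_fine)
make_quad <- function(times, m) {
  stopifnot(m %% 2 == 0, m >= 2)
  nint <- length(times) - 1L
  nf <- nint * m + 1L
  tf <- numeric(nf)
  W <- matrix(0, nint, nf)
  simp <- if (m == 2) c(1, 4, 1) else c(1, rep(c(4, 2), m / 2 - 1), 4, 1)
  for (i in seq_len(nint)) {
    h <- (times[i + 1L] - times[i]) / m
    idx <- ((i - 1L) * m + 1L):(i * m + 1L)
    tf[idx] <- seq(times[i], times[i + 1L], length.out = m + 1L)
    W[i, idx] <- W[i, idx] + h / 3 * simp
  }
  list(tf = tf, W = W, obs_idx = seq(1L, nf, by = m), nint = nint)
}

# integrating factor for one species: w at the fine grid and its
# cumulative integral (midpoint-refined Simpson, so the regulator
# trajectories built from Iw are accurate to O(h^5) per step)
species_weights <- function(gamma, growth, q) {
  dur <- growth$duration
  B0 <- biomass_at(growth, 0)
  lnw <- function(t) gamma * t +
    log(biomass_at(growth, pmin(pmax(t, 0), dur)) / B0)
  wf <- exp(lnw(q$tf))
  tm <- (q$tf[-1L] + q$tf[-length(q$tf)]) / 2
  wm <- exp(lnw(tm))
  h <- diff(q$tf)
  Iw <- c(0, cumsum(h / 6 * (wf[-length(wf)] + 4 * wm + wf[-1L])))
  list(w = wf, Iw = Iw, w_obs = wf[q$obs_idx], Iw_obs = Iw[q$obs_idx])
}

# species under constant synthesis rate (one rate per condition):
# full fine-grid trajectory matrix (n_fine x n_cond)
const_force_traj <- function(p0, rates, sw) {
  (matrix(p0, length(sw$w), length(rates), byrow = TRUE) +
     outer(sw$Iw, rates)) / sw$w
}

# same, evaluated at the observation times only
const_force_obs <- function(p0, rates, sw) {
  (matrix(p0, length(sw$w_obs), length(rates), byrow = TRUE) +
     outer(sw$Iw_obs, rates)) / sw$w_obs
}

# reporter under arbitrary forcing F (n_fine x n_cond), observed grid only
forced_obs <- function(s0, F, sw, q) {
  seg <- q$W %*% (F * sw$w)
  cum <- rbind(0, apply(seg, 2, cumsum))
  (matrix(s0, q$nint + 1L, ncol(F), byrow = TRUE) + cum) / sw$w_obs
}

mu_closure <- function(growth) {
  dur <- growth$duration
  function(t) growth_rate_at(growth, min(max(t, 0), dur))
}

#' Operator fit results
#'
#' The result of a characterization fit: the fitted parameter set (same
#' type as the operator kind), the residual sum of squares, per-parameter
#' identifiability flags (`TRUE` marks a parameter the data cannot
#' identify) and the number of optimization restarts used.
#'
#' @param x,object An `operator_fit`.
#' @param ... Unused.
#' @name operator_fit
NULL

new_operator_fit <- function(kind, params, residual_sse, flags, restarts) {
  structure(list(kind = kind, params = params,
                 residual_sse = residual_sse,
                 identifiability_flags = flags,
                 n_restarts_used = restarts),
            class = "operator_fit")
}

#' @rdname operator_fit
#' @export
print.operator_fit <- function(x, ...) {
  cat(sprintf("<operator_fit:%s>  SSE = %.4g  (%d restart(s))\n",
              x$kind, x$residual_sse, x$n_restarts_used))
  pv <- unlist(x$params)
  fl <- x$identifiability_flags[names(pv)]
  for (nm in names(pv))
    cat(sprintf("  %-7s %12.6g%s\n", nm, pv[[nm]],
                if (isTRUE(fl[[nm]])) "   [non-identifiable]" else ""))
  invisible(x)
}

#' @rdname operator_fit
#' @export
coef.operator_fit <- function(object, ...) unlist(object$params)

# ---- shared multi-start bounded Levenberg-Marquardt driver ----------------
# Parameters are fitted on the log10 scale (rates and K span decades and
# must stay positive); n is log10-bounded as well.
run_multistart <- function(resid_fun, starts, lower, upper) {
  best <- NULL
  used <- 0L
  for (s in starts) {
    used <- used + 1L
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = pmin(pmax(s, lower), upper),
                           fn = resid_fun, lower = lower, upper = upper,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 300, ftol = 1e-14, ptol = 1e-12))),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse)
      best <- list(par = fit$par, sse = sse)
  }
  if (is.null(best)) stop("all optimization starts failed", call. = FALSE)
  best$used <- used
  best
}

with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# profile-likelihood-style probe: restart from each parameter perturbed
# +-50 percent; a parameter is non-identifiable if a refit reaches the same
# SSE (within 1 percent) at a value differing by > 20 percent.
probe_identifiability <- function(resid_fun, par, lower, upper, sse,
                                  sse_scale) {
  k <- length(par)
  flags <- rep(FALSE, k)
  tol <- max(sse, 1e-12 * sse_scale) * 1.01 + 1e-3 * sse_scale
  for (j in seq_len(k)) {
    for (f in c(log10(1.5), log10(0.5))) {
      s <- par
      s[j] <- s[j] + f   # log10 scale: +-50 percent multiplicative
      fit <- tryCatch(
        suppressWarnings(
          minpack.lm::nls.lm(par = pmin(pmax(s, lower), upper),
                             fn = resid_fun, lower = lower, upper = upper,
                             control = minpack.lm::nls.lm.control(
                               maxiter = 80))),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (sum(fit$fvec^2) <= tol &&
          abs(fit$par[j] - par[j]) > log10(1.2)) {
        flags[j] <- TRUE
        break
      }
    }
  }
  flags
}

#' Fit a constitutive source rate
#'
#' Estimates the synthesis rate \eqn{\alpha} of a constitutive source
#' from a single kinetic reporter series by least squares against the
#' solution of \eqn{dp/dt = \alpha - (\gamma + \mu(t)) p}. The model is
#' linear in \eqn{\alpha}, so the estimate is closed-form (clipped at 0).
#'
#' @param data Data frame with columns `time` and `value` (at least 5
#'   timepoints), e.g. one sample/signal slice of a measurement table.
#' @param gamma Known reporter degradation rate (1/h).
#' @param growth Growth profile in force during the assay.
#' @param m Quadrature substeps per observation interval (even).
#' @return An [operator_fit] of kind `"source"`.
#' @export
fit_source <- function(data, gamma, growth, m = 20L) {
  stopifnot(all(c("time", "value") %in% names(data)), nrow(data) >= 5L)
  o <- order(data$time)
  times <- data$time[o] - data$time[o][1]
  obs <- data$value[o]
  q <- make_quad(times, m)
  sw <- species_weights(gamma, growth, q)
  p0 <- obs[1]
  h0 <- p0 / sw$w_obs           # initial-condition response
  h1 <- sw$Iw_obs / sw$w_obs    # unit-alpha response
  alpha <- max(sum((obs - h0) * h1) / sum(h1^2), 0)
  resid <- obs - (h0 + alpha * h1)
  flat <- all(obs == 0)
  if (flat) alpha <- 0
  new_operator_fit("source", source_params(alpha), sum(resid^2),
                   c(alpha = flat), 1L)
}

# shared skeleton for the Hill fits: residuals across all blocks, bounded
# multi-start LM, identifiability probe, response-spread heuristic
hill_fit_engine <- function(data, preds, starts, lower, upper, unpack,
                            flag_names, spread_flags = NULL) {
  resid_fun <- function(theta) {
    unlist(lapply(seq_along(data$blocks), function(i)
      as.numeric(preds[[i]](theta) - data$blocks[[i]]$values)))
  }
  best <- run_multistart(resid_fun, starts, lower, upper)
  sse_scale <- sum(unlist(lapply(data$blocks,
                                 function(b) sum(b$values^2))))
  flags <- probe_identifiability(resid_fun, best$par, lower, upper,
                                 best$sse, sse_scale)
  names(flags) <- flag_names
  means <- unlist(lapply(data$blocks, function(b) colMeans(b$values)))
  if (!is.null(spread_flags) &&
      diff(range(means)) < 0.05 * max(mean(means), 1e-12))
    flags[spread_flags] <- TRUE
  list(params = unpack(best$par), sse = best$sse, flags = flags,
       used = best$used)
}

hill1_starts <- function(data, rate_scale, k_range, n_restarts) {
  s1 <- log10(c(a0 = 0.1 * rate_scale, a1 = rate_scale,
                K = exp(mean(log(k_range))), n = 2))
  rest <- replicate(max(n_restarts - 1L, 0L), log10(c(
    a0 = rate_scale * 10^stats::runif(1, -3, 0.5),
    a1 = rate_scale * 10^stats::runif(1, -3, 0.5),
    K = exp(stats::runif(1, log(k_range[1]), log(k_range[2]))),
    n = stats::runif(1, 1, 4))), simplify = FALSE)
  c(list(s1), rest)
}

hill1_bounds <- function(rate_scale) {
  list(lower = c(-8, -8, -6, log10(0.2)),
       upper = c(log10(rate_scale) + 4, log10(rate_scale) + 4, 8, 1))
}

unpack_hill1 <- function(theta) {
  v <- unname(10^theta)
  hill1_params(alpha0 = v[1], alpha1 = v[2], K = v[3], n = v[4])
}

# crude synthesis-rate scale implied by the observed response levels:
# near steady state p ~ rate/(gamma + mu)
rate_scale_of <- function(data, gamma, growth) {
  vals <- unlist(lapply(data$blocks, `[[`, "values"))
  mu_bar <- mean(growth_rate_at(growth,
                                seq(0, min(growth$duration,
                                           max(data$blocks[[1]]$times)),
                                    length.out = 21)))
  max(mean(abs(vals)) * (gamma + mu_bar), 1e-6)
}

#' Characterize a receiver operator from dose-response kinetics
#'
#' Fits the Hill parameters \eqn{(\alpha_0, \alpha_1, K, n)} of a
#' receiver (supplement-sensing) operator driving a reporter, by
#' trajectory-level nonlinear least squares: for each supplement
#' concentration the model reporter solves
#' \eqn{dp/dt = \phi(c) - (\gamma + \mu(t)) p} and the summed squared
#' residuals across all concentrations and timepoints are minimized with
#' bounded multi-start Levenberg-Marquardt (rates and \eqn{K} fitted on
#' the log scale; \eqn{K} starts log-uniform over the tested
#' concentration range, \eqn{n} in \[1, 4\]).
#'
#' @param data A [dose_response_data()] over one supplement.
#' @param gamma Known reporter degradation rate (1/h).
#' @param growth Growth profile; if `NULL`, reconstructed from the
#'   dataset's biomass channel via [fit_growth()].
#' @param n_restarts Number of optimization starts (the first is a
#'   deterministic data-driven guess).
#' @param seed Seed for the randomized restarts.
#' @param m Quadrature substeps per observation interval (even).
#' @return An [operator_fit] of kind `"receiver"` with `hill1_params`.
#' @export
fit_receiver <- function(data, gamma, growth = NULL, n_restarts = 10L,
                         seed = 42L, m = 20L) {
  stopifnot(inherits(data, "dose_response"))
  check_design(data)
  growth <- resolve_growth(growth, data)
  conc <- do.call(rbind, lapply(data$blocks, `[[`, "conc"))[, 1]
  posc <- range(conc[conc > 0])
  preds <- lapply(data$blocks, function(b) {
    q <- make_quad(b$times - b$times[1], m)
    sw <- species_weights(gamma, growth, q)
    p0 <- b$values[1, ]
    cc <- b$conc[, 1]
    function(theta) {
      v <- 10^theta
      const_force_obs(p0, vhill1(cc, v[1], v[2], v[3], v[4]), sw)
    }
  })
  rs <- rate_scale_of(data, gamma, growth)
  starts <- with_local_seed(seed, hill1_starts(data, rs, posc, n_restarts))
  bounds <- hill1_bounds(rs)
  res <- hill_fit_engine(data, preds, starts, bounds$lower, bounds$upper,
                         unpack_hill1, c("alpha0", "alpha1", "K", "n"),
                         spread_flags = c("K", "n"))
  new_operator_fit("receiver", res$params, res$sse, res$flags, res$used)
}

#' Characterize a one-input operator downstream of a known receiver
#'
#' Fits the Hill parameters of a one-input operator from dose-response
#' kinetics of the cascade supplement → receiver → regulator → operator
#' → reporter. The previously characterized receiver parameters are held
#' fixed; only the downstream operator parameters are fitted, against
#' the full two-stage ODE solution.
#'
#' @inheritParams fit_receiver
#' @param receiver Fixed `hill1_params` of the upstream receiver.
#' @param gamma_regulator,gamma_reporter Known degradation rates (1/h).
#' @param init_regulator Initial regulator concentration (the cascade is
#'   assumed to start uninduced).
#' @return An [operator_fit] of kind `"hill1"`.
#' @export
fit_hill1 <- function(data, receiver, gamma_regulator, gamma_reporter,
                      growth = NULL, init_regulator = 0, n_restarts = 10L,
                      seed = 42L, m = 20L) {
  stopifnot(inherits(data, "dose_response"))
  receiver <- hill1_params_check(receiver)
  check_design(data)
  growth <- resolve_growth(growth, data)
  preds <- lapply(data$blocks, function(b) {
    q <- make_quad(b$times - b$times[1], m)
    sw_r <- species_weights(gamma_regulator, growth, q)
    sw_s <- species_weights(gamma_reporter, growth, q)
    rate_r <- vhill1(b$conc[, 1], receiver$alpha0, receiver$alpha1,
                     receiver$K, receiver$n)
    R <- const_force_traj(init_regulator, rate_r, sw_r)
    s0 <- b$values[1, ]
    function(theta) {
      v <- 10^theta
      forced_obs(s0, vhill1(R, v[1], v[2], v[3], v[4]), sw_s, q)
    }
  })
  # K of the downstream operator lives on the regulator concentration
  # scale: bracket it by the span the regulator actually reaches
  conc <- do.call(rbind, lapply(data$blocks, `[[`, "conc"))[, 1]
  rmax <- max(vhill1(conc, receiver$alpha0, receiver$alpha1, receiver$K,
                     receiver$n)) / max(gamma_regulator, 1e-6)
  rs <- rate_scale_of(data, gamma_reporter, growth)
  starts <- with_local_seed(seed,
    hill1_starts(data, rs, c(rmax * 1e-3, rmax), n_restarts))
  bounds <- hill1_bounds(rs)
  res <- hill_fit_engine(data, preds, starts, bounds$lower, bounds$upper,
                         unpack_hill1, c("alpha0", "alpha1", "K", "n"),
                         spread_flags = c("K", "n"))
  new_operator_fit("hill1", res$params, res$sse, res$flags, res$used)
}

#' Characterize a two-input operator from a concentration grid
#'
#' The last stage of the staged workflow: three auxiliary networks are
#' required — the two supplement → receiver → reporter circuits, which
#' yield the fixed receiver parameter sets, and the composed network in
#' which both receivers drive the two regulator inputs of the two-input
#' operator. This function fits the two-input Hill parameters
#' \eqn{(\alpha_0..\alpha_3, K_1, K_2, n_1, n_2)} to kinetic data from
#' the composed network over a 2-D supplement concentration grid, with
#' both receiver parameter sets held fixed.
#'
#' @inheritParams fit_hill1
#' @param receiver1,receiver2 Fixed `hill1_params` of the two receivers.
#' @param gamma_regulator1,gamma_regulator2 Regulator degradation rates.
#' @return An [operator_fit] of kind `"hill2"` with `hill2_params`.
#' @export
fit_hill2 <- function(data, receiver1, receiver2, gamma_regulator1,
                      gamma_regulator2, gamma_reporter, growth = NULL,
                      init_regulator = c(0, 0), n_restarts = 10L,
                      seed = 42L, m = 20L) {
  stopifnot(inherits(data, "dose_response"))
  if (missing(receiver1) || missing(receiver2) || is.null(receiver1) ||
      is.null(receiver2))
    stop("workflow order: both receivers must be characterized before fit_hill2",
         call. = FALSE)
  receiver1 <- hill1_params_check(receiver1)
  receiver2 <- hill1_params_check(receiver2)
  conc <- do.call(rbind, lapply(data$blocks, `[[`, "conc"))
  if (ncol(conc) != 2L)
    stop("fit_hill2 needs a two-input concentration grid", call. = FALSE)
  check_design(data)
  growth <- resolve_growth(growth, data)
  preds <- lapply(data$blocks, function(b) {
    q <- make_quad(b$times - b$times[1], m)
    sw_r1 <- species_weights(gamma_regulator1, growth, q)
    sw_r2 <- species_weights(gamma_regulator2, growth, q)
    sw_s <- species_weights(gamma_reporter, growth, q)
    rate1 <- vhill1(b$conc[, 1], receiver1$alpha0, receiver1$alpha1,
                    receiver1$K, receiver1$n)
    rate2 <- vhill1(b$conc[, 2], receiver2$alpha0, receiver2$alpha1,
                    receiver2$K, receiver2$n)
    R1 <- const_force_traj(init_regulator[1], rate1, sw_r1)
    R2 <- const_force_traj(init_regulator[2], rate2, sw_r2)
    s0 <- b$values[1, ]
    function(theta) {
      v <- 10^theta
      forced_obs(s0, vhill2(R1, R2, v[1], v[2], v[3], v[4],
                            v[5], v[6], v[7], v[8]), sw_s, q)
    }
  })
  rs <- rate_scale_of(data, gamma_reporter, growth)
  r1max <- max(vhill1(conc[, 1], receiver1$alpha0, receiver1$alpha1,
                      receiver1$K, receiver1$n)) /
    max(gamma_regulator1, 1e-6)
  r2max <- max(vhill1(conc[, 2], receiver2$alpha0, receiver2$alpha1,
                      receiver2$K, receiver2$n)) /
    max(gamma_regulator2, 1e-6)
  starts <- with_local_seed(seed, {
    s1 <- log10(c(a0 = rs, a1 = 0.1 * rs, a2 = 0.1 * rs, a3 = 0.1 * rs,
                  K1 = r1max / 10, K2 = r2max / 10, n1 = 2, n2 = 2))
    rest <- replicate(max(n_restarts - 1L, 0L), log10(c(
      rs * 10^stats::runif(4, -3, 0.5),
      r1max * 10^stats::runif(1, -3, 0),
      r2max * 10^stats::runif(1, -3, 0),
      stats::runif(2, 1, 4))), simplify = FALSE)
    c(list(s1), rest)
  })
  lower <- c(rep(-8, 4), -6, -6, log10(0.2), log10(0.2))
  upper <- c(rep(log10(rs) + 4, 4), 8, 8, 1, 1)
  res <- hill_fit_engine(data, preds, starts, lower, upper,
                         function(theta) {
                           v <- unname(10^theta)
                           hill2_params(v[1], v[2], v[3], v[4], v[5], v[6],
                                        v[7], v[8])
                         },
                         c("alpha0", "alpha1", "alpha2", "alpha3",
                           "K1", "K2", "n1", "n2"),
                         spread_flags = c("K1", "K2", "n1", "n2"))
  new_operator_fit("hill2", res$params, res$sse, res$flags, res$used)
}

#' Reconstruct a growth profile from a biomass series
#'
#' Fits both a constant-rate (log-linear) and a logistic profile to the
#' biomass channel of an assay and returns the better one by residual sum
#' of squares. Used by the characterization fits when no parametric
#' growth profile is supplied.
#'
#' @param times,values Biomass series (OD-like units).
#' @param duration Validity window of the returned profile; defaults to
#'   1.5 times the series span.
#' @return A `growth_profile`.
#' @export
fit_growth <- function(times, values, duration = max(times) * 1.5) {
  stopifnot(length(times) >= 3L, all(values > 0))
  lm0 <- stats::lm(log(values) ~ times)
  mu0 <- max(stats::coef(lm0)[[2]], 0)
  const <- growth_constant(mu0 = mu0, b0 = exp(stats::coef(lm0)[[1]]),
                           duration = duration)
  sse_const <- sum((biomass_at(const, times) - values)^2)
  logis <- tryCatch({
    st <- list(b0 = values[1], Bmax = max(values) * 1.2,
               mu_max = max(mu0, 0.1))
    ft <- suppressWarnings(
      stats::nls(values ~ Bmax / (1 + (Bmax - b0) / b0 *
                                    exp(-mu_max * times)),
                 start = st,
                 control = stats::nls.control(warnOnly = TRUE)))
    cf <- stats::coef(ft)
    if (cf[["b0"]] <= 0 || cf[["Bmax"]] <= cf[["b0"]] ||
        cf[["mu_max"]] <= 0) NULL
    else growth_logistic(b0 = cf[["b0"]], Bmax = cf[["Bmax"]],
                         mu_max = cf[["mu_max"]], duration = duration)
  }, error = function(e) NULL)
  if (!is.null(logis)) {
    sse_log <- sum((biomass_at(logis, times) - values)^2)
    if (sse_log < sse_const) return(logis)
  }
  const
}

resolve_growth <- function(growth, data) {
  if (!is.null(growth)) {
    stopifnot(is_growth_profile(growth))
    return(growth)
  }
  for (b in data$blocks)
    if (!is.null(b$biomass))
      return(fit_growth(b$times, b$biomass,
                        duration = max(b$times) * 1.5))
  stop("no growth profile supplied and the dataset has no biomass channel",
       call. = FALSE)
}
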