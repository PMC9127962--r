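#' Growth profiles (metabolism)
#'
#' A growth profile supplies the culture biomass \eqn{B(t)} and the
#' instantaneous growth rate \eqn{\mu(t) = d\,\ln B/dt} that dilutes every
#' gene product in the network ODEs and in the stochastic extinction
#' propensities. Three closed-form kinds are provided:
#'
#' * **constant** — exponential growth at fixed rate,
#'   \eqn{B(t) = b_0 e^{\mu_0 t}}, \eqn{\mu(t) = \mu_0};
#' * **logistic** — batch-culture sigmoid,
#'   \eqn{B(t) = B_{max} / (1 + ((B_{max} - b_0)/b_0) e^{-\mu_{max} t})},
#'   \eqn{\mu(t) = \mu_{max} (1 - B(t)/B_{max})};
#' * **gompertz** — lagged sigmoid
#'   \eqn{\ln(B(t)/b_0) = A \exp\{-\exp[\mu_{max} e (\lambda - t)/A + 1]\}}
#'   with \eqn{A = \ln(B_{max}/b_0)} and lag time \eqn{\lambda}.
#'
#' \eqn{\mu(t)} is derived analytically for each kind so that ODE
#' right-hand sides stay smooth.
#'
#' @param mu0 Constant growth rate (1/h), \eqn{\ge 0}.
#' @param b0 Initial biomass (OD-like arbitrary units), > 0.
#' @param Bmax Carrying capacity, > `b0`.
#' @param mu_max Maximum specific growth rate (1/h), > 0.
#' @param lambda Lag time (h), \eqn{\ge 0} (gompertz only).
#' @param duration Profile validity window (h), > 0; evaluation outside
#'   `[0, duration]` is an error.
#' @return An object of class `growth_profile`.
#' @examples
#' gp <- growth_constant(mu0 = 0.5)
#' growth_rate_at(gp, 3)   # 0.5
#' biomass_at(gp, 2)       # e^1
#' @export
growth_constant <- function(mu0 = 0, b0 = 1, duration = 24) {
  stopifnot(mu0 >= 0, b0 > 0, duration > 0)
  new_growth("constant", list(mu0 = mu0, b0 = b0), duration)
}

#' @rdname growth_constant
#' @export
growth_logistic <- function(b0 = 0.01, Bmax = 1, mu_max = 1, duration = 24) {
  stopifnot(b0 > 0, Bmax > b0, mu_max > 0, duration > 0)
  new_growth("logistic", list(b0 = b0, Bmax = Bmax, mu_max = mu_max), duration)
}

#' @rdname growth_constant
#' @export
growth_gompertz <- function(b0 = 0.01, Bmax = 1, mu_max = 1, lambda = 0,
                            duration = 24) {
  stopifnot(b0 > 0, Bmax > b0, mu_max > 0, lambda >= 0, duration > 0)
  new_growth("gompertz",
             list(b0 = b0, Bmax = Bmax, mu_max = mu_max, lambda = lambda),
             duration)
}

new_growth <- function(kind, params, duration)
  structure(list(kind = kind, params = params, duration = duration),
            class = "growth_profile")

is_growth_profile <- function(x) inherits(x, "growth_profile")

#' @export
print.growth_profile <- function(x, ...) {
  pv <- unlist(x$params)
  cat(sprintf("<growth_profile:%s> %s  (duration %g h)\n", x$kind,
              paste(sprintf("%s=%g", names(pv), pv), collapse = "  "),
              x$duration))
  invisible(x)
}

check_time <- function(profile, t) {
  if (any(t < 0) || any(t > profile$duration))
    stop(sprintf("time must lie in [0, %g] h", profile$duration),
         call. = FALSE)
}

gompertz_log_ratio <- function(p, t) {
  A <- log(p$Bmax / p$b0)
  A * exp(-exp(p$mu_max * exp(1) * (p$lambda - t) / A + 1))
}

#' Biomass at a time point
#'
#' @param profile A [growth_constant()] / [growth_logistic()] /
#'   [growth_gompertz()] profile.
#' @param t Time(s) in hours within `[0, duration]`; vectorised.
#' @return Biomass in the profile's (OD-like) units.
#' @export
biomass_at <- function(profile, t) {
  stopifnot(is_growth_profile(profile))
  check_time(profile, t)
  p <- profile$params
  switch(profile$kind,
    constant = p$b0 * exp(p$mu0 * t),
    logistic = p$Bmax / (1 + (p$Bmax - p$b0) / p$b0 * exp(-p$mu_max * t)),
    gompertz = p$b0 * exp(gompertz_log_ratio(p, t)))
}

#' Instantaneous growth rate at a time point
#'
#' Returns \eqn{\mu(t) = d\,\ln B(t)/dt}, evaluated from the closed form
#' of each profile kind.
#'
#' @inheritParams biomass_at
#' @return Growth rate(s) in 1/h, \eqn{\ge 0}.
#' @export
growth_rate_at <- function(profile, t) {
  stopifnot(is_growth_profile(profile))
  check_time(profile, t)
  p <- profile$params
  switch(profile$kind,
    constant = rep_len(p$mu0, length(t)),
    logistic = {
      B <- biomass_at(profile, t)
      p$mu_max * (1 - B / p$Bmax)
    },
    gompertz = {
      A <- log(p$Bmax / p$b0)
      u <- p$mu_max * exp(1) * (p$lambda - t) / A + 1
      gompertz_log_ratio(p, t) * exp(u) * p$mu_max * exp(1) / A
    })
}

# numeric vector encoding for the compiled SSA core:
# c(kind_code, p1..p4) with kinds 0=constant, 1=logistic, 2=gompertz
encode_growth <- function(profile) {
  p <- profile$params
  switch(profile$kind,
    constant = c(0, p$mu0, 0, 0, 0),
    logistic = c(1, p$b0, p$Bmax, p$mu_max, 0),
    gompertz = c(2, p$b0, p$Bmax, p$mu_max, p$lambda))
}
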