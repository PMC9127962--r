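#' Samples and assays
#'
#' A sample couples one genetic network to a growth context (metabolism)
#' and chemical conditions: the named supplement concentrations seen by
#' receiver operators. Supplements are assay conditions — held at fixed
#' external concentration, neither diluted nor consumed. An assay bundles
#' one or more samples with a simulation method and a measurement grid,
#' and produces a tidy measurement table via [run_assay()].
#'
#' @param network A `genetic_network`.
#' @param growth A `growth_profile`; defaults to constant growth at
#'   \eqn{\mu = 1}/h.
#' @param supplements Named numeric vector of supplement concentrations
#'   (\eqn{\ge 0}); receivers whose supplement is absent see concentration 0.
#' @return `circuit_sample()` returns a `circuit_sample`; `assay()` an
#'   `assay`.
#' @examples
#' net <- network_source_reporter(alpha = 10)
#' smp <- circuit_sample(net, growth_constant(mu0 = 1))
#' a <- assay(list(s1 = smp), duration = 10, interval = 0.5)
#' head(run_assay(a))
#' @export
circuit_sample <- function(network, growth = growth_constant(mu0 = 1),
                           supplements = numeric()) {
  stopifnot(inherits(network, "genetic_network"), is_growth_profile(growth))
  if (length(supplements)) {
    stopifnot(is.numeric(supplements), !is.null(names(supplements)),
              all(supplements >= 0))
  }
  structure(list(network = network, growth = growth,
                 supplements = supplements),
            class = "circuit_sample")
}

#' @rdname circuit_sample
#' @param samples Nonempty list of `circuit_sample` objects; names become
#'   sample ids (unnamed lists get `S1`, `S2`, ...).
#' @param duration Assay duration (h), > 0 and within every sample's
#'   growth-profile window.
#' @param interval Measurement interval (h), > 0 and \eqn{\le} duration;
#'   timepoints are `seq(0, duration, by = interval)`.
#' @param method `"ode"` (deterministic) or `"ssa"` (Gillespie).
#' @param seed Integer RNG seed used by the SSA method.
#' @param name Assay identifier.
#' @export
assay <- function(samples, duration, interval, method = c("ode", "ssa"),
                  seed = 1L, name = "assay") {
  method <- match.arg(method)
  if (inherits(samples, "circuit_sample")) samples <- list(samples)
  stopifnot(length(samples) >= 1L,
            all(vapply(samples, inherits, logical(1), "circuit_sample")),
            duration > 0, interval > 0, interval <= duration)
  if (is.null(names(samples)))
    names(samples) <- paste0("S", seq_along(samples))
  for (id in names(samples)) {
    if (duration > samples[[id]]$growth$duration)
      stop(sprintf(
        "assay duration %g h exceeds growth-profile window of sample '%s'",
        duration, id), call. = FALSE)
  }
  structure(list(samples = samples, duration = duration,
                 interval = interval, method = method,
                 seed = as.integer(seed), name = name),
            class = "assay")
}

#' Deterministic simulation of a sample
#'
#' Integrates the network ODE system
#' \eqn{dp/dt = \Psi(r) - (\Gamma + \mu(t) I) p} from the products'
#' initial concentrations with `deSolve::ode` (lsoda, relative tolerance
#' 1e-8). Integrator undershoots below zero smaller than 1e-12 are
#' clipped to exactly 0.
#'
#' @param sample A [circuit_sample()].
#' @param duration Simulation span (h).
#' @param timepoints Output grid; defaults to 201 evenly spaced points.
#' @param rtol,atol Solver tolerances.
#' @return A `circuit_trajectory`: data frame with column `time` and one
#'   concentration column per product.
#' @export
simulate_ode <- function(sample, duration, timepoints = NULL,
                         rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(sample, "circuit_sample"))
  if (is.null(timepoints)) timepoints <- seq(0, duration, length.out = 201)
  stopifnot(all(timepoints >= 0), all(timepoints <= duration))
  if (duration > sample$growth$duration)
    stop("duration exceeds the growth-profile window", call. = FALSE)
  compiled <- compile_network(sample$network, sample$supplements)
  growth <- sample$growth
  rhs <- function(t, p, parms) {
    mu <- growth_rate_at(growth, t)
    list(synthesis_rates(compiled, pmax(p, 0)) - (compiled$gamma + mu) * p)
  }
  tp <- sort(unique(c(0, timepoints)))
  sol <- deSolve::ode(y = compiled$init, times = tp, func = rhs,
                      parms = NULL, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed: ", paste(attr(sol, "istate"),
         collapse = " "), call. = FALSE)
  m <- sol[match(timepoints, tp), , drop = FALSE]
  vals <- m[, -1, drop = FALSE]
  vals[vals < 0 & vals > -1e-12] <- 0
  out <- data.frame(time = m[, 1], vals, check.names = FALSE)
  names(out) <- c("time", compiled$names)
  class(out) <- c("circuit_trajectory", "data.frame")
  attr(out, "network") <- sample$network$name
  attr(out, "method") <- "ode"
  out
}

#' @export
plot.circuit_trajectory <- function(x, ...) {
  cols <- setdiff(names(x), "time")
  graphics::matplot(x$time, as.matrix(x[cols]), type = "l", lty = 1,
                    xlab = "time (h)", ylab = "concentration", ...)
  graphics::legend("topright", legend = cols, col = seq_along(cols),
                   lty = 1, bty = "n")
  invisible(x)
}

#' Stochastic reaction propensities
#'
#' For an integer copy-number state \eqn{p}, the synthesis reactions
#' \eqn{* \rightarrow p_i} fire with propensity
#' \eqn{a_i = \sum_k \Phi_{k,i}(r)} (summing the transfer functions of
#' the operators that output product \eqn{i}) and the extinction reactions
#' \eqn{p_i \rightarrow *} with propensity
#' \eqn{b_i = (\gamma_i + \mu)\, p_i}.
#'
#' @inheritParams network_rhs
#' @param p Integer-valued copy-number state, \eqn{\ge 0}.
#' @return List with numeric vectors `a` (synthesis) and `b` (extinction).
#' @export
propensities <- function(net, p, mu, supplements = numeric()) {
  compiled <- compile_network(net, supplements)
  if (length(p) != compiled$n)
    stop("state length does not match the number of products", call. = FALSE)
  if (any(p < 0) || any(p != round(p)))
    stop("copy numbers must be nonnegative integers", call. = FALSE)
  list(a = synthesis_rates(compiled, p),
       b = (compiled$gamma + mu) * p)
}

#' Stochastic simulation of a sample (Gillespie direct method)
#'
#' Simulates the network as a jump process over the reactions
#' \eqn{* \rightarrow p_i} (rates \eqn{a_i}) and \eqn{p_i \rightarrow *}
#' (rates \eqn{b_i = (\gamma_i + \mu(t)) p_i}), recomputing all
#' propensities after every event. \eqn{\mu(t)} is evaluated at the
#' current time and frozen until the next event (quasi-static
#' approximation, accurate because growth varies on a much slower
#' timescale than the inter-event time). A fixed seed yields a
#' bit-identical event list.
#'
#' @inheritParams simulate_ode
#' @param seed Integer seed; `NULL` leaves the R RNG state untouched.
#' @param record_events Keep the full event list (time, product, +1/-1)?
#'   Disable for large ensembles.
#' @return List with elements `trajectory` (a `circuit_trajectory` of
#'   copy numbers sampled on the grid) and `events` (data frame, or
#'   `NULL` when not recorded).
#' @export
simulate_ssa <- function(sample, duration, seed = NULL, timepoints = NULL,
                         record_events = TRUE) {
  stopifnot(inherits(sample, "circuit_sample"))
  if (is.null(timepoints)) timepoints <- seq(0, duration, length.out = 101)
  stopifnot(all(timepoints >= 0), all(timepoints <= duration))
  if (duration > sample$growth$duration)
    stop("duration exceeds the growth-profile window", call. = FALSE)
  compiled <- compile_network(sample$network, sample$supplements)
  if (any(compiled$init != round(compiled$init)))
    stop("SSA requires integer-valued initial concentrations", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  res <- ssa_core(compiled$ops, compiled$gamma, compiled$init,
                  encode_growth(sample$growth), duration,
                  sort(unique(timepoints)), record_events)
  traj <- data.frame(time = sort(unique(timepoints)), res$trajectory,
                     check.names = FALSE)
  names(traj) <- c("time", compiled$names)
  class(traj) <- c("circuit_trajectory", "data.frame")
  attr(traj, "network") <- sample$network$name
  attr(traj, "method") <- "ssa"
  events <- NULL
  if (record_events)
    events <- data.frame(time = res$event_times,
                         product = compiled$names[res$event_product],
                         change = res$event_change)
  list(trajectory = traj, events = events)
}

#' Run an assay and collect tidy measurements
#'
#' Simulates every sample in the assay with the requested method and
#' returns a tidy kinetic measurement table with one row per (sample,
#' signal, timepoint). Reporter signals carry the simulated concentration
#' (ODE) or copy number (SSA); an additional `biomass` signal per sample
#' carries the growth profile evaluated on the same grid.
#'
#' @param x An [assay()].
#' @return A data frame with columns `assay`, `sample`, `signal`, `time`,
#'   `value` (the measurement-table dialect used throughout the package).
#' @export
run_assay <- function(x) {
  stopifnot(inherits(x, "assay"))
  grid <- seq(0, x$duration, by = x$interval)
  if (x$method == "ssa") set.seed(x$seed)
  rows <- lapply(names(x$samples), function(id) {
    smp <- x$samples[[id]]
    traj <- tryCatch(
      if (x$method == "ode") simulate_ode(smp, x$duration, grid)
      else simulate_ssa(smp, x$duration, seed = NULL, timepoints = grid,
                        record_events = FALSE)$trajectory,
      error = function(e)
        stop(sprintf("sample '%s': %s", id, conditionMessage(e)),
             call. = FALSE))
    reps <- Filter(function(p) p$kind == "reporter", smp$network$products)
    sig <- do.call(rbind, lapply(reps, function(p) {
      data.frame(assay = x$name, sample = id,
                 signal = if (is.null(p$signal_id)) p$name else p$signal_id,
                 time = grid, value = traj[[p$name]])
    }))
    bio <- data.frame(assay = x$name, sample = id, signal = "biomass",
                      time = grid, value = biomass_at(smp$growth, grid))
    rbind(sig, bio)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab
}

#' Read/write measurement tables
#'
#' Measurement tables are plain CSV files with header
#' `assay,sample,signal,time,value`.
#'
#' @param table A measurement-table data frame.
#' @param path File path.
#' @return `read_measurements()` returns the table; `write_measurements()`
#'   its path, invisibly.
#' @export
write_measurements <- function(table, path) {
  check_measurements(table)
  out <- table[c("assay", "sample", "signal", "time", "value")]
  # 17 significant digits keep the doubles bit-exact through the text form
  out$time <- sprintf("%.17g", out$time)
  out$value <- sprintf("%.17g", out$value)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(assay = "character",
                                        sample = "character",
                                        signal = "character",
                                        time = "numeric",
                                        value = "numeric"))
  check_measurements(tab)
  tab
}

check_measurements <- function(table) {
  need <- c("assay", "sample", "signal", "time", "value")
  if (!all(need %in% names(table)))
    stop("measurement table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (any(table$time < 0))
    stop("measurement times must be nonnegative", call. = FALSE)
  invisible(table)
}
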