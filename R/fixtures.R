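#' Built-in study networks
#'
#' Small genetic networks used throughout the package's examples, tests
#' and characterization workflow. They are ordinary [genetic_network()]
#' objects and can be modified freely.
#'
#' * `network_source_reporter()` — one constitutive source driving one
#'   reporter; the simplest possible circuit, with analytic steady state
#'   \eqn{\alpha / (\gamma + \mu)} under constant growth.
#' * `network_source_not()` — a source expressing a regulator that
#'   represses a reporter through a NOT-logic one-input operator.
#' * `network_receiver()` — supplement → receiver → reporter: the
#'   auxiliary circuit used to characterize a receiver from
#'   dose-response kinetics.
#' * `network_hill1_cascade()` — supplement → receiver → regulator →
#'   one-input operator → reporter.
#' * `network_hill2_composed()` — two receivers driving the two
#'   regulator inputs of a two-input operator that expresses the
#'   reporter; together with the two receiver circuits this forms the
#'   three auxiliary networks of the staged characterization workflow.
#' * `network_oscillator()` — a positive-plus-negative feedback loop:
#'   a two-input operator activated by its own product A and repressed
#'   by C, and two activated one-input operators relaying A → B → C.
#'   Each operator also expresses a fluorescent reporter (RFP, YFP,
#'   CFP). With the default parameters and zero dilution the system has
#'   a stable limit cycle of period ≈ 13.3 h; initial conditions are
#'   placed on the cycle.
#'
#' @param alpha,gamma,gamma_reporter Source rate and degradation rates
#'   (1/h).
#' @param receiver,receiver1,receiver2,hill1,hill2 Parameter sets
#'   ([hill1_params()] / [hill2_params()]) for the corresponding
#'   operators.
#' @param supplement,supplement1,supplement2 Supplement names sensed by
#'   the receiver operators.
#' @param signal Reporter signal identifier.
#' @return A `genetic_network`.
#' @name fixtures
NULL

#' @rdname fixtures
#' @export
network_source_reporter <- function(alpha = 10, gamma = 1, signal = "GFP") {
  genetic_network(
    "source_reporter",
    list(reporter("GFP", degradation_rate = gamma, signal_id = signal)),
    list(op_source("const", outputs = "GFP", alpha = alpha)))
}

#' @rdname fixtures
#' @export
network_source_not <- function(alpha = 1000, gamma = 1,
                               hill1 = hill1_params(alpha0 = 1000,
                                                    alpha1 = 10,
                                                    K = 500, n = 2),
                               signal = "CFP") {
  genetic_network(
    "source_not",
    list(regulator("R1", degradation_rate = gamma),
         reporter("CFP", degradation_rate = gamma, signal_id = signal)),
    list(op_source("const", outputs = "R1", alpha = alpha),
         op_hill1("not_gate", input = "R1", outputs = "CFP",
                  alpha0 = hill1$alpha0, alpha1 = hill1$alpha1,
                  K = hill1$K, n = hill1$n)))
}

#' @rdname fixtures
#' @export
network_receiver <- function(receiver = hill1_params(alpha0 = 0.1,
                                                     alpha1 = 10,
                                                     K = 1, n = 2),
                             supplement = "AHL", gamma = 1,
                             signal = "YFP") {
  genetic_network(
    paste0("receiver_", supplement),
    list(reporter("YFP", degradation_rate = gamma, signal_id = signal)),
    list(op_receiver("receiver", input = supplement, outputs = "YFP",
                     alpha0 = receiver$alpha0, alpha1 = receiver$alpha1,
                     K = receiver$K, n = receiver$n)))
}

#' @rdname fixtures
#' @export
network_hill1_cascade <- function(receiver = hill1_params(alpha0 = 0.1,
                                                          alpha1 = 10,
                                                          K = 1, n = 2),
                                  hill1 = hill1_params(alpha0 = 8,
                                                       alpha1 = 0.2,
                                                       K = 2, n = 2),
                                  supplement = "AHL",
                                  gamma = 1, gamma_reporter = 1,
                                  signal = "CFP") {
  genetic_network(
    "hill1_cascade",
    list(regulator("R1", degradation_rate = gamma),
         reporter("CFP", degradation_rate = gamma_reporter,
                  signal_id = signal)),
    list(op_receiver("receiver", input = supplement, outputs = "R1",
                     alpha0 = receiver$alpha0, alpha1 = receiver$alpha1,
                     K = receiver$K, n = receiver$n),
         op_hill1("gate", input = "R1", outputs = "CFP",
                  alpha0 = hill1$alpha0, alpha1 = hill1$alpha1,
                  K = hill1$K, n = hill1$n)))
}

#' @rdname fixtures
#' @export
network_hill2_composed <- function(receiver1 = hill1_params(alpha0 = 0.1,
                                                            alpha1 = 10,
                                                            K = 1, n = 2),
                                   receiver2 = hill1_params(alpha0 = 0.1,
                                                            alpha1 = 8,
                                                            K = 2, n = 2),
                                   hill2 = hill2_params(alpha0 = 10,
                                                        alpha1 = 0.3,
                                                        alpha2 = 0.3,
                                                        alpha3 = 0.3,
                                                        K1 = 1, K2 = 1,
                                                        n1 = 2, n2 = 2),
                                   supplement1 = "AHL1",
                                   supplement2 = "AHL2",
                                   gamma = 1, gamma_reporter = 1,
                                   signal = "CFP") {
  genetic_network(
    "hill2_composed",
    list(regulator("R1", degradation_rate = gamma),
         regulator("R2", degradation_rate = gamma),
         reporter("CFP", degradation_rate = gamma_reporter,
                  signal_id = signal)),
    list(op_receiver("receiver1", input = supplement1, outputs = "R1",
                     alpha0 = receiver1$alpha0, alpha1 = receiver1$alpha1,
                     K = receiver1$K, n = receiver1$n),
         op_receiver("receiver2", input = supplement2, outputs = "R2",
                     alpha0 = receiver2$alpha0, alpha1 = receiver2$alpha1,
                     K = receiver2$K, n = receiver2$n),
         op_hill2("gate", inputs = c("R1", "R2"), outputs = "CFP",
                  alpha0 = hill2$alpha0, alpha1 = hill2$alpha1,
                  alpha2 = hill2$alpha2, alpha3 = hill2$alpha3,
                  K1 = hill2$K1, K2 = hill2$K2,
                  n1 = hill2$n1, n2 = hill2$n2)))
}

#' @rdname fixtures
#' @export
network_oscillator <- function() {
  genetic_network(
    "oscillator",
    list(regulator("A", degradation_rate = 2, init_concentration = 0.0271),
         regulator("B", degradation_rate = 0.3, init_concentration = 1.176),
         regulator("C", degradation_rate = 0.3, init_concentration = 4.173),
         reporter("RFP", degradation_rate = 2, signal_id = "RFP"),
         reporter("YFP", degradation_rate = 0.3, signal_id = "YFP"),
         reporter("CFP", degradation_rate = 0.3, signal_id = "CFP")),
    list(op_hill2("op_A", inputs = c("A", "C"), outputs = c("A", "RFP"),
                  alpha0 = 1.2, alpha1 = 30, alpha2 = 0.05, alpha3 = 0.05,
                  K1 = 1, K2 = 1, n1 = 4, n2 = 4),
         op_hill1("op_B", input = "A", outputs = c("B", "YFP"),
                  alpha0 = 0, alpha1 = 3, K = 2, n = 2),
         op_hill1("op_C", input = "B", outputs = c("C", "CFP"),
                  alpha0 = 0, alpha1 = 3, K = 2, n = 2)))
}

#' Generate a dose-response assay
#'
#' Builds an [assay()] with one sample per supplement condition: for a
#' single input, one sample per concentration; for a two-input grid, one
#' sample per concentration pair. Sample ids record the conditions and
#' the sample supplements carry them, so measurement tables produced by
#' [run_assay()] and uploaded to a datastore keep the dose annotation.
#'
#' @param network A `genetic_network` containing receiver operator(s).
#' @param supplement Supplement name, or character vector of two names
#'   for a two-input grid.
#' @param concentrations Numeric vector of concentrations (single input),
#'   or a list of two vectors whose Cartesian product forms the grid.
#' @param growth Growth profile shared by all samples.
#' @param duration,interval Assay timing (h).
#' @param method,seed,name Passed to [assay()].
#' @return An `assay`.
#' @export
dose_response_assay <- function(network, supplement, concentrations,
                                growth = growth_constant(mu0 = 0.5),
                                duration = 8, interval = 0.5,
                                method = "ode", seed = 1L,
                                name = paste0("dose_", network$name)) {
  if (length(supplement) == 1L) {
    stopifnot(is.numeric(concentrations), all(concentrations >= 0))
    samples <- lapply(concentrations, function(cc)
      circuit_sample(network, growth,
                     stats::setNames(cc, supplement)))
    names(samples) <- sprintf("c%03d", seq_along(concentrations))
  } else if (length(supplement) == 2L) {
    stopifnot(is.list(concentrations), length(concentrations) == 2L)
    grid <- expand.grid(c1 = concentrations[[1]], c2 = concentrations[[2]])
    samples <- lapply(seq_len(nrow(grid)), function(i)
      circuit_sample(network, growth,
                     stats::setNames(c(grid$c1[i], grid$c2[i]), supplement)))
    names(samples) <- sprintf("c%03d", seq_len(nrow(grid)))
  } else stop("supplement must name one or two inputs", call. = FALSE)
  assay(samples, duration = duration, interval = interval, method = method,
        seed = seed, name = name)
}

#' Oscillation summary of a simulated trajectory
#'
#' Peak-to-trough amplitudes of the first and last quarter of the series
#' and the mean oscillation period (from successive maxima over the
#' second half, where transients have died out).
#'
#' @param traj A `circuit_trajectory` from [simulate_ode()] /
#'   [simulate_ssa()].
#' @param column Product column to analyse.
#' @return List with `amplitude_first`, `amplitude_last`, `ratio`
#'   (last/first) and `period` (h; `NA` if fewer than two maxima).
#' @export
oscillation_stats <- function(traj, column) {
  x <- traj[[column]]
  t <- traj$time
  n <- length(x)
  q <- n %/% 4L
  a1 <- diff(range(x[seq_len(q)]))
  a4 <- diff(range(x[(n - q + 1L):n]))
  half <- (n %/% 2L):n
  xs <- x[half]
  pk <- which(diff(sign(diff(xs))) == -2L) + 1L
  period <- if (length(pk) >= 2L) mean(diff(t[half][pk])) else NA_real_
  list(amplitude_first = a1, amplitude_last = a4,
       ratio = a4 / a1, period = period)
}
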