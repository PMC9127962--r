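#' Hill-type transfer functions
#'
#' The synthesis-rate response of one- and two-input operators. For one
#' input,
#' \deqn{\phi(r) = \frac{\alpha_0 + \alpha_1 (r/K)^n}{1 + (r/K)^n}}
#' so that \eqn{\alpha_0} is the non-regulated rate at \eqn{r = 0},
#' \eqn{\alpha_1} the fully regulated rate, \eqn{K} the switching
#' concentration (half-maximal response) and \eqn{n} the cooperativity.
#' For two inputs (two promoters in tandem), with
#' \eqn{x_j = (r_j/K_j)^{n_j}},
#' \deqn{\phi(r_1, r_2) =
#'   \frac{\alpha_0 + \alpha_1 x_1 + \alpha_2 x_2 + \alpha_3 x_1 x_2}
#'        {1 + x_1 + x_2 + x_1 x_2}}
#' where \eqn{\alpha_1}, \eqn{\alpha_2} are the single-promoter regulated
#' rates and \eqn{\alpha_3} the jointly regulated rate.
#'
#' Both functions are vectorised over the input concentrations.
#'
#' @param r,r1,r2 Input regulator concentrations, \eqn{\ge 0}.
#' @param params A validated parameter list, [hill1_params()] or
#'   [hill2_params()].
#' @return Synthesis rate(s), bounded between the smallest and largest
#'   \eqn{\alpha}.
#' @examples
#' hill1_rate(2, hill1_params(alpha0 = 0, alpha1 = 10, K = 2, n = 4)) # 5
#' @export
hill1_rate <- function(r, params) {
  params <- hill1_params_check(params)
  if (any(r < 0)) stop("input concentration must be >= 0", call. = FALSE)
  x <- (r / params$K)^params$n
  ifelse(is.infinite(x), params$alpha1,
         (params$alpha0 + params$alpha1 * x) / (1 + x))
}

#' @rdname hill1_rate
#' @export
hill2_rate <- function(r1, r2, params) {
  params <- hill2_params_check(params)
  if (any(r1 < 0) || any(r2 < 0))
    stop("input concentrations must be >= 0", call. = FALSE)
  x1 <- (r1 / params$K1)^params$n1
  x2 <- (r2 / params$K2)^params$n2
  num <- params$alpha0 + params$alpha1 * x1 + params$alpha2 * x2 +
    params$alpha3 * x1 * x2
  den <- 1 + x1 + x2 + x1 * x2
  out <- num / den
  # saturation limits where (r/K)^n overflows to Inf and num/den is NaN
  big <- which(is.infinite(x1) | is.infinite(x2))
  if (length(big)) {
    i1 <- rep_len(is.infinite(x1), length(out))[big]
    i2 <- rep_len(is.infinite(x2), length(out))[big]
    xx1 <- rep_len(x1, length(out))[big]
    xx2 <- rep_len(x2, length(out))[big]
    out[big] <- ifelse(i1 & i2, params$alpha3,
      ifelse(i1, (params$alpha1 + params$alpha3 * xx2) / (1 + xx2),
                 (params$alpha2 + params$alpha3 * xx1) / (1 + xx1)))
  }
  out
}

#' Operator parameter sets
#'
#' Constructors that validate the typed parameter sets of the operator
#' kinds: a constitutive source has a single rate `alpha`; one-input
#' operators (and receivers) use [hill1_params()]; two-input operators use
#' [hill2_params()]. All rates are in concentration units per hour; `K` is
#' a concentration (> 0) and `n` a dimensionless cooperativity (> 0).
#'
#' @param alpha,alpha0,alpha1,alpha2,alpha3 Synthesis rates, \eqn{\ge 0}.
#' @param K,K1,K2 Switching concentrations, > 0.
#' @param n,n1,n2 Cooperativity degrees, > 0.
#' @return A named list with class `hill1_params` / `hill2_params` /
#'   `source_params`.
#' @export
hill1_params <- function(alpha0, alpha1, K, n) {
  p <- list(alpha0 = alpha0, alpha1 = alpha1, K = K, n = n)
  hill1_params_check(p)
}

#' @rdname hill1_params
#' @export
hill2_params <- function(alpha0, alpha1, alpha2, alpha3, K1, K2, n1, n2) {
  p <- list(alpha0 = alpha0, alpha1 = alpha1, alpha2 = alpha2,
            alpha3 = alpha3, K1 = K1, K2 = K2, n1 = n1, n2 = n2)
  hill2_params_check(p)
}

#' @rdname hill1_params
#' @export
source_params <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha < 0)
    stop("alpha must be a single number >= 0", call. = FALSE)
  structure(list(alpha = alpha), class = "source_params")
}

num1 <- function(p, nm) {
  v <- p[[nm]]
  if (!is.numeric(v) || length(v) != 1L || is.na(v))
    stop(sprintf("parameter '%s' must be a single finite number", nm),
         call. = FALSE)
  v
}

hill1_params_check <- function(p) {
  for (nm in c("alpha0", "alpha1", "K", "n")) num1(p, nm)
  if (p$alpha0 < 0 || p$alpha1 < 0) stop("alpha0, alpha1 must be >= 0", call. = FALSE)
  if (p$K <= 0) stop("K must be > 0", call. = FALSE)
  if (p$n <= 0) stop("n must be > 0", call. = FALSE)
  structure(p[c("alpha0", "alpha1", "K", "n")], class = "hill1_params")
}

hill2_params_check <- function(p) {
  for (nm in c("alpha0", "alpha1", "alpha2", "alpha3", "K1", "K2", "n1", "n2"))
    num1(p, nm)
  if (any(unlist(p[c("alpha0", "alpha1", "alpha2", "alpha3")]) < 0))
    stop("all alpha must be >= 0", call. = FALSE)
  if (p$K1 <= 0 || p$K2 <= 0) stop("K1, K2 must be > 0", call. = FALSE)
  if (p$n1 <= 0 || p$n2 <= 0) stop("n1, n2 must be > 0", call. = FALSE)
  structure(p[c("alpha0", "alpha1", "alpha2", "alpha3",
                "K1", "K2", "n1", "n2")], class = "hill2_params")
}

#' Operators: genetic devices mapping inputs to synthesis rates
#'
#' An operator is the abstraction of a promoter (plus upstream elements and
#' RBS) that maps the concentration of zero, one or two inputs to the
#' synthesis rate of its output gene products. Four kinds are supported:
#'
#' * `op_source()` — constitutive, zero inputs, constant rate `alpha`;
#' * `op_hill1()` — one internal regulator input, Hill transfer function;
#' * `op_receiver()` — like `op_hill1` but its input is an external
#'   chemical supplement (e.g. an acyl-homoserine lactone) held at the
#'   concentration set by the sample conditions;
#' * `op_hill2()` — two regulator inputs (two promoters in tandem).
#'
#' Operators may drive any number of outputs; all outputs of one operator
#' are expressed at the same rate. Networks with more than two inputs per
#' node cannot be represented.
#'
#' @param name Identifier, unique within a network.
#' @param input,inputs Input regulator name(s) (`op_hill2` takes exactly
#'   two) or, for `op_receiver`, the supplement name. `gene_product`
#'   objects are accepted and reduced to their names.
#' @param outputs Output gene product name(s); at least one.
#' @param alpha,alpha0,alpha1,alpha2,alpha3,K,K1,K2,n,n1,n2 Transfer
#'   function parameters, see [hill1_params()].
#' @return An object of class `operator`.
#' @examples
#' op_hill1("not_gate", input = "LacI", outputs = "CFP",
#'          alpha0 = 10, alpha1 = 0.1, K = 1, n = 2)
#' @export
op_source <- function(name, outputs, alpha) {
  new_operator(name, "source", character(), as_names(outputs),
               source_params(alpha))
}

#' @rdname op_source
#' @export
op_hill1 <- function(name, input, outputs, alpha0, alpha1, K, n) {
  new_operator(name, "hill1", as_names(input), as_names(outputs),
               hill1_params(alpha0, alpha1, K, n))
}

#' @rdname op_source
#' @export
op_receiver <- function(name, input, outputs, alpha0, alpha1, K, n) {
  new_operator(name, "receiver", as_names(input), as_names(outputs),
               hill1_params(alpha0, alpha1, K, n))
}

#' @rdname op_source
#' @export
op_hill2 <- function(name, inputs, outputs,
                     alpha0, alpha1, alpha2, alpha3, K1, K2, n1, n2) {
  new_operator(name, "hill2", as_names(inputs), as_names(outputs),
               hill2_params(alpha0, alpha1, alpha2, alpha3, K1, K2, n1, n2))
}

as_names <- function(x) {
  if (is_gene_product(x)) return(x$name)
  if (is.list(x)) return(vapply(x, function(e)
    if (is_gene_product(e)) e$name else as.character(e), character(1)))
  as.character(x)
}

operator_arity <- c(source = 0L, hill1 = 1L, receiver = 1L, hill2 = 2L)

new_operator <- function(name, kind, inputs, outputs, params) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (length(inputs) != operator_arity[[kind]])
    stop(sprintf("operator '%s' (%s) requires exactly %d input(s), got %d",
                 name, kind, operator_arity[[kind]], length(inputs)),
         call. = FALSE)
  if (length(outputs) < 1L)
    stop(sprintf("operator '%s' must drive at least one output", name),
         call. = FALSE)
  structure(list(name = name, kind = kind, inputs = inputs,
                 outputs = outputs, params = params),
            class = "operator")
}

is_operator <- function(x) inherits(x, "operator")

#' @export
print.operator <- function(x, ...) {
  ins <- if (length(x$inputs)) paste(x$inputs, collapse = ", ") else "(none)"
  cat(sprintf("<operator:%s> %s  inputs: %s -> outputs: %s\n", x$kind,
              x$name, ins, paste(x$outputs, collapse = ", ")))
  pv <- unlist(x$params)
  cat("  params:", paste(sprintf("%s=%g", names(pv), pv), collapse = "  "), "\n")
  invisible(x)
}

#' Discrete logic label of an operator
#'
#' Classifies the transfer function of a one- or two-input operator by the
#' ordering of its synthesis rates: a one-input operator encodes NOT logic
#' when \eqn{\alpha_0 > \alpha_1} and a buffer when
#' \eqn{\alpha_0 < \alpha_1}; a two-input operator encodes NOR when
#' \eqn{\alpha_0 > \alpha_1, \alpha_2, \alpha_3}. Anything else (including
#' exact ties, which the strict inequalities leave undefined) is `"OTHER"`.
#' The label depends only on rate ratios, so it is invariant to scaling all
#' \eqn{\alpha} by a common positive factor.
#'
#' @param op An `operator` of kind `hill1` or `hill2`, or a bare
#'   `hill1_params` / `hill2_params` set. Sources and receivers are not
#'   classified: a source has no input and a receiver's input is an assay
#'   condition, not a network species.
#' @return One of `"NOT"`, `"BUFFER"`, `"NOR"`, `"OTHER"`.
#' @export
classify_logic <- function(op) {
  p <- if (is_operator(op)) {
    if (!op$kind %in% c("hill1", "hill2"))
      stop(sprintf("logic classification is unsupported for %s operators",
                   op$kind), call. = FALSE)
    op$params
  } else op
  if (inherits(p, "hill1_params")) {
    if (p$alpha0 > p$alpha1) "NOT"
    else if (p$alpha0 < p$alpha1) "BUFFER"
    else "OTHER"
  } else if (inherits(p, "hill2_params")) {
    if (p$alpha0 > max(p$alpha1, p$alpha2, p$alpha3)) "NOR" else "OTHER"
  } else stop("cannot classify this operator kind", call. = FALSE)
}
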