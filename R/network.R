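#' Genetic networks
#'
#' A genetic network wires operators to gene products. Writing the product
#' concentration vector as \eqn{p}, the network model is
#' \deqn{\frac{dp}{dt} = \Psi(r) - (\Gamma + \mu(t) I)\, p}
#' where \eqn{\Psi} is the sum of the operators' transfer functions
#' \eqn{\Phi_k} evaluated on the regulator sub-vector \eqn{r},
#' \eqn{\Gamma} the diagonal matrix of degradation rates and \eqn{\mu(t)}
#' the instantaneous growth rate that dilutes every product.
#'
#' Operator inputs must reference declared regulators (receiver inputs
#' reference external supplements, which are not network products);
#' outputs must reference declared products.
#'
#' @param name Network identifier (used as the "vector" id in datastore
#'   metadata).
#' @param products List of [gene_product()] objects.
#' @param operators List of operators, see [op_source()].
#' @return An object of class `genetic_network`.
#' @seealso [validate_network()], [network_rhs()], [simulate_ode()]
#' @export
genetic_network <- function(name, products, operators) {
  if (is_gene_product(products)) products <- list(products)
  if (is_operator(operators)) operators <- list(operators)
  stopifnot(all(vapply(products, is_gene_product, logical(1))),
            all(vapply(operators, is_operator, logical(1))))
  net <- structure(list(name = name, products = products,
                        operators = operators),
                   class = "genetic_network")
  v <- validate_network(net)
  if (length(v))
    stop("invalid network:\n  ", paste(v, collapse = "\n  "), call. = FALSE)
  net
}

#' Validate a genetic network
#'
#' Checks the structural invariants — unique product and operator names,
#' every operator input resolving to a declared regulator (receivers
#' except: their input names an external supplement), every output
#' resolving to a declared product, input arities (at most two inputs per
#' node), and at least one output per operator — and returns one message
#' per violation.
#'
#' @param net A `genetic_network` (or a bare list with the same fields,
#'   so that malformed candidates can be diagnosed).
#' @return Character vector of violation descriptions; empty when valid.
#' @export
validate_network <- function(net) {
  out <- character()
  pn <- vapply(net$products, function(p) p$name, character(1))
  on <- vapply(net$operators, function(o) o$name, character(1))
  if (anyDuplicated(pn))
    out <- c(out, sprintf("duplicate product name(s): %s",
                          paste(unique(pn[duplicated(pn)]), collapse = ", ")))
  if (anyDuplicated(on))
    out <- c(out, sprintf("duplicate operator name(s): %s",
                          paste(unique(on[duplicated(on)]), collapse = ", ")))
  kinds <- stats::setNames(
    vapply(net$products, function(p) p$kind, character(1)), pn)
  for (op in net$operators) {
    arity <- operator_arity[[op$kind]]
    if (length(op$inputs) != arity)
      out <- c(out, sprintf(
        "operator '%s': %s takes %d input(s), has %d%s", op$name, op$kind,
        arity, length(op$inputs),
        if (length(op$inputs) > 2L) " (no node may have more than two inputs)"
        else ""))
    if (length(op$outputs) < 1L)
      out <- c(out, sprintf("operator '%s': no outputs", op$name))
    if (op$kind %in% c("hill1", "hill2")) {
      for (i in op$inputs) {
        if (!i %in% pn)
          out <- c(out, sprintf(
            "operator '%s': input '%s' does not resolve to a declared product",
            op$name, i))
        else if (kinds[[i]] != "regulator")
          out <- c(out, sprintf(
            "operator '%s': input '%s' is a %s, not a regulator",
            op$name, i, kinds[[i]]))
      }
    }
    if (op$kind == "receiver" && op$inputs %in% pn)
      out <- c(out, sprintf(
        "operator '%s': receiver input '%s' must be an external supplement, not a declared product",
        op$name, op$inputs))
    for (o in op$outputs)
      if (!o %in% pn)
        out <- c(out, sprintf(
          "operator '%s': output '%s' does not resolve to a declared product",
          op$name, o))
  }
  out
}

#' @export
print.genetic_network <- function(x, ...) {
  nr <- sum(vapply(x$products, function(p) p$kind == "regulator", logical(1)))
  cat(sprintf("<genetic_network> %s: %d products (%d regulators), %d operators\n",
              x$name, length(x$products), nr, length(x$operators)))
  for (op in x$operators) print(op)
  invisible(x)
}

product_names <- function(net)
  vapply(net$products, function(p) p$name, character(1))

degradation_rates <- function(net)
  vapply(net$products, function(p) p$degradation_rate, numeric(1))

init_state <- function(net)
  stats::setNames(vapply(net$products, function(p) p$init_concentration,
                         numeric(1)), product_names(net))

kind_code <- c(source = 0L, hill1 = 1L, hill2 = 2L, receiver = 3L)

# Internal numeric form consumed by the R rhs/propensity code and by the
# compiled SSA core: per operator the kind code, input state indices
# (0 = external), constant input values (receiver supplements), the
# parameter vector and 1-based output indices.
compile_network <- function(net, supplements = numeric()) {
  pn <- product_names(net)
  ops <- lapply(net$operators, function(op) {
    in1 <- 0L; in2 <- 0L; c1 <- 0; c2 <- 0
    if (op$kind %in% c("hill1", "hill2")) {
      in1 <- match(op$inputs[[1]], pn)
      if (op$kind == "hill2") in2 <- match(op$inputs[[2]], pn)
    } else if (op$kind == "receiver") {
      c1 <- if (op$inputs %in% names(supplements))
        unname(supplements[[op$inputs]]) else 0
    }
    par <- switch(op$kind,
      source = c(op$params$alpha, rep(0, 7)),
      hill1 = ,
      receiver = c(op$params$alpha0, op$params$alpha1, op$params$K,
                   op$params$n, rep(0, 4)),
      hill2 = unlist(op$params, use.names = FALSE))
    list(kind = kind_code[[op$kind]], in1 = as.integer(in1),
         in2 = as.integer(in2), c1 = c1, c2 = c2, par = as.numeric(par),
         outs = match(op$outputs, pn))
  })
  list(n = length(pn), names = pn, gamma = degradation_rates(net),
       init = unname(init_state(net)), ops = ops)
}

# Per-operator synthesis rates at state p (numeric vector, compiled form).
operator_rates <- function(compiled, p) {
  vapply(compiled$ops, function(op) {
    if (op$kind == 0L) op$par[1]
    else if (op$kind == 1L)
      hill_raw1(p[op$in1], op$par)
    else if (op$kind == 3L)
      hill_raw1(op$c1, op$par)
    else
      hill_raw2(p[op$in1], p[op$in2], op$par)
  }, numeric(1))
}

hill_raw1 <- function(r, par) {
  x <- (r / par[3])^par[4]
  if (is.infinite(x)) par[2] else (par[1] + par[2] * x) / (1 + x)
}

hill_raw2 <- function(r1, r2, par) {
  x1 <- (r1 / par[5])^par[7]
  x2 <- (r2 / par[6])^par[8]
  if (is.infinite(x1) || is.infinite(x2)) {
    if (is.infinite(x1) && is.infinite(x2)) return(par[4])
    if (is.infinite(x1)) return((par[2] + par[4] * x2) / (1 + x2))
    return((par[3] + par[4] * x1) / (1 + x1))
  }
  (par[1] + par[2] * x1 + par[3] * x2 + par[4] * x1 * x2) /
    (1 + x1 + x2 + x1 * x2)
}

# Total synthesis rate per product: a_i = sum of operator rates over the
# operators that output product i.
synthesis_rates <- function(compiled, p) {
  rates <- operator_rates(compiled, p)
  a <- numeric(compiled$n)
  for (k in seq_along(compiled$ops)) {
    outs <- compiled$ops[[k]]$outs
    a[outs] <- a[outs] + rates[k]
  }
  a
}

#' Network right-hand side
#'
#' Evaluates the time derivative
#' \eqn{dp_i/dt = \sum_k \Phi_{k,i}(r) - (\gamma_i + \mu)\, p_i}
#' of the network ODE system at a given state and growth rate. This is the
#' pure function integrated by [simulate_ode()]; it is exposed for
#' inspection, testing and custom solvers.
#'
#' @param net A `genetic_network`.
#' @param p Numeric state vector, one nonnegative concentration per
#'   declared product (declaration order).
#' @param mu Instantaneous growth rate (1/h), \eqn{\ge 0}.
#' @param supplements Named numeric vector of supplement concentrations
#'   seen by receiver operators; missing names count as 0.
#' @return Numeric derivative vector of length `length(p)`.
#' @export
network_rhs <- function(net, p, mu, supplements = numeric()) {
  compiled <- compile_network(net, supplements)
  if (length(p) != compiled$n)
    stop(sprintf("state has length %d but the network declares %d products",
                 length(p), compiled$n), call. = FALSE)
  if (any(p < 0)) stop("state entries must be >= 0", call. = FALSE)
  if (mu < 0) stop("growth rate must be >= 0", call. = FALSE)
  synthesis_rates(compiled, p) - (compiled$gamma + mu) * p
}
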