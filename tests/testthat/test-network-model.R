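test_that("one-input Hill transfer function matches its closed form", {
  expect_equal(hill1_rate(0, hill1_params(1, 0, 1, 2)), 1.0)
  expect_equal(hill1_rate(2, hill1_params(0, 10, 2, 4)), 5.0)
  # direct-evaluation oracle: (2 + 8*10)/(1 + 10) = 82/11
  expect_equal(hill1_rate(10, hill1_params(2, 8, 1, 1)), 82 / 11)
  expect_error(hill1_rate(-1, hill1_params(1, 2, 1, 1)), "must be >= 0")
})

test_that("one-input Hill rate is bounded and monotone for random draws", {
  set.seed(101)
  r <- sort(c(0, 10^seq(-3, 3, length.out = 40)))
  for (i in 1:25) {
    p <- hill1_params(alpha0 = runif(1, 0, 20), alpha1 = runif(1, 0, 20),
                      K = 10^runif(1, -2, 2), n = runif(1, 0.3, 6))
    y <- hill1_rate(r, p)
    expect_true(all(is.finite(y)))
    expect_true(all(y >= min(p$alpha0, p$alpha1) - 1e-12))
    expect_true(all(y <= max(p$alpha0, p$alpha1) + 1e-12))
    d <- diff(y)
    if (p$alpha1 > p$alpha0) expect_true(all(d >= -1e-12))
    if (p$alpha1 < p$alpha0) expect_true(all(d <= 1e-12))
  }
})

test_that("two-input Hill reduces to one input and saturates jointly", {
  set.seed(102)
  for (i in 1:20) {
    p2 <- hill2_params(alpha0 = runif(1, 0, 10), alpha1 = runif(1, 0, 10),
                       alpha2 = runif(1, 0, 10), alpha3 = runif(1, 0, 10),
                       K1 = 10^runif(1, -1, 1), K2 = 10^runif(1, -1, 1),
                       n1 = runif(1, 0.5, 4), n2 = runif(1, 0.5, 4))
    expect_equal(hill2_rate(0, 0, p2), p2$alpha0)
    r1 <- 10^seq(-2, 2, length.out = 9)
    p1 <- hill1_params(p2$alpha0, p2$alpha1, p2$K1, p2$n1)
    expect_equal(hill2_rate(r1, 0, p2), hill1_rate(r1, p1))
  }
  psat <- hill2_params(1, 2, 3, 7, K1 = 1, K2 = 1, n1 = 2, n2 = 2)
  expect_equal(hill2_rate(1e6, 1e6, psat), 7, tolerance = 1e-6)
})

test_that("logic labels follow the synthesis-rate ordering and scale out", {
  not_op <- op_hill1("g", "R", "P", alpha0 = 10, alpha1 = 1, K = 1, n = 2)
  buf_op <- op_hill1("g", "R", "P", alpha0 = 1, alpha1 = 10, K = 1, n = 2)
  nor_op <- op_hill2("g", c("R1", "R2"), "P", 10, 0.5, 0.5, 0.5,
                     1, 1, 2, 2)
  expect_identical(classify_logic(not_op), "NOT")
  expect_identical(classify_logic(buf_op), "BUFFER")
  expect_identical(classify_logic(nor_op), "NOR")
  expect_identical(classify_logic(hill1_params(5, 5, 1, 2)), "OTHER")
  expect_identical(classify_logic(hill2_params(1, 2, 1, 1, 1, 1, 2, 2)),
                   "OTHER")
  # scale invariance of the labels
  for (s in c(0.01, 3, 1e4)) {
    expect_identical(classify_logic(hill1_params(10 * s, 1 * s, 1, 2)),
                     "NOT")
    expect_identical(
      classify_logic(hill2_params(10 * s, 0.5 * s, 0.5 * s, 0.5 * s,
                                  1, 1, 2, 2)), "NOR")
  }
  src <- op_source("s", "P", alpha = 1)
  expect_error(classify_logic(src), "unsupported")
  rec <- op_receiver("r", "AHL", "P", 1, 2, 1, 2)
  expect_error(classify_logic(rec), "unsupported")
})

test_that("network right-hand side assembles synthesis minus dilution", {
  net <- network_source_reporter(alpha = 10, gamma = 1)
  expect_equal(network_rhs(net, 5, mu = 1), 0)       # alpha/(gamma+mu)
  expect_equal(network_rhs(net, 0, mu = 1), 10)
  # all-off network: origin is absorbing
  net0 <- network_source_reporter(alpha = 0, gamma = 1)
  expect_equal(network_rhs(net0, 0, mu = 0), 0)
  # NOT gate driven at r = K: output synthesis is the Hill midpoint
  net2 <- network_source_not()
  h <- net2$operators[[2]]$params
  p <- c(h$K, 3)
  rhs <- network_rhs(net2, p, mu = 0.2)
  expect_equal(rhs[2], (h$alpha0 + h$alpha1) / 2 - (1 + 0.2) * 3)
  expect_error(network_rhs(net2, c(1, 2, 3), mu = 0), "declares 2 products")
  expect_error(network_rhs(net2, c(-1, 2), mu = 0), ">= 0")
})

test_that("dilution acts linearly on the state for frozen synthesis", {
  # with operator inputs held constant the rhs is affine in p; check
  # superposition of the dilution term
  net <- network_source_reporter(alpha = 7, gamma = 0.8)
  f <- function(p) network_rhs(net, p, mu = 0.4)
  p1 <- 2.5; p2 <- 9
  expect_equal(f(p1) + f(p2) - f(0), f(p1 + p2))
})

test_that("network validation reports unresolved references and arity", {
  expect_length(validate_network(network_oscillator()), 0)
  bad <- list(name = "bad",
              products = list(regulator("R"), reporter("P")),
              operators = list(op_hill1("g", "X", "P", 1, 2, 1, 2)))
  v <- validate_network(bad)
  expect_length(v, 1)
  expect_match(v, "input 'X' does not resolve")
  # three-input node: constructors refuse it, and validation flags a
  # hand-built one
  expect_error(op_hill2("g", c("a", "b", "c"), "P", 1, 1, 1, 1, 1, 1, 1, 1),
               "exactly 2")
  tri <- list(name = "tri",
              products = list(regulator("a"), regulator("b"),
                              regulator("c"), reporter("P")),
              operators = list(structure(
                list(name = "g3", kind = "hill2",
                     inputs = c("a", "b", "c"), outputs = "P",
                     params = hill2_params(1, 1, 1, 1, 1, 1, 1, 1)),
                class = "operator")))
  expect_match(paste(validate_network(tri), collapse = " "),
               "more than two inputs")
  dup <- list(name = "dup",
              products = list(reporter("P"), reporter("P")),
              operators = list(op_source("s", "P", 1)))
  expect_match(paste(validate_network(dup), collapse = " "), "duplicate")
})

test_that("invalid parameter sets and products are refused", {
  expect_error(hill1_params(-1, 1, 1, 1), "alpha")
  expect_error(hill1_params(1, 1, 0, 1), "K")
  expect_error(hill2_params(1, 1, 1, 1, 1, 1, 0, 1), "n1")
  expect_error(gene_product("x", degradation_rate = -1), "degradation")
  expect_error(regulator("x", signal_id = "S"), "reporters")
})
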