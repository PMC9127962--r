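test_that("ODE simulation reaches the analytic steady state and is exact
           for pure accumulation", {
  s <- circuit_sample(network_source_reporter(alpha = 10, gamma = 1),
                      growth_constant(mu0 = 1))
  tr <- simulate_ode(s, 20, seq(0, 20, 1))
  expect_equal(tail(tr$GFP, 1), 10 / (1 + 1), tolerance = 1e-6)
  s0 <- circuit_sample(network_source_reporter(alpha = 10, gamma = 0),
                       growth_constant(mu0 = 0))
  tr0 <- simulate_ode(s0, 5, seq(0, 5, 0.5))
  expect_equal(tr0$GFP, 10 * tr0$time, tolerance = 1e-8)
})

test_that("ODE trajectories stay nonnegative and are grid-invariant", {
  fixtures <- list(
    circuit_sample(network_oscillator(),
                   growth_constant(mu0 = 0, duration = 200)),
    circuit_sample(network_source_not(), growth_constant(mu0 = 0.3)),
    circuit_sample(network_receiver(), growth_constant(mu0 = 0.5),
                   supplements = c(AHL = 2)))
  for (s in fixtures) {
    tr <- simulate_ode(s, 20, seq(0, 20, 0.25))
    expect_true(all(as.matrix(tr[-1]) >= -1e-9))
  }
  # halving the measurement interval leaves shared timepoints unchanged
  s <- fixtures[[2]]
  coarse <- simulate_ode(s, 10, seq(0, 10, 1))
  fine <- simulate_ode(s, 10, seq(0, 10, 0.5))
  expect_equal(coarse$CFP, fine$CFP[fine$time %in% coarse$time],
               tolerance = 1e-6)
})

test_that("propensities follow Eqs for synthesis and extinction", {
  net <- network_source_not()
  pr <- propensities(net, c(0, 0), mu = 0.5)
  expect_equal(pr$b, c(0, 0))               # no molecules, no extinction
  expect_equal(pr$a[1], 1000)               # constitutive source
  h <- net$operators[[2]]$params
  pr2 <- propensities(net, c(h$K, 7), mu = 0.25)
  expect_equal(pr2$a[2], (h$alpha0 + h$alpha1) / 2)
  expect_equal(pr2$b, (c(1, 1) + 0.25) * c(h$K, 7))
  expect_error(propensities(net, c(-1, 0), mu = 0), "nonnegative integers")
  expect_error(propensities(net, c(0.5, 0), mu = 0), "nonnegative integers")
  s4 <- network_source_reporter(alpha = 4)
  expect_equal(propensities(s4, 123, mu = 0)$a, 4)
})

test_that("SSA is bit-reproducible under a fixed seed", {
  s <- circuit_sample(network_source_not(), growth_constant(mu0 = 0))
  r1 <- simulate_ssa(s, 0.5, seed = 11)
  r2 <- simulate_ssa(s, 0.5, seed = 11)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$trajectory, r2$trajectory)
  r3 <- simulate_ssa(s, 0.5, seed = 12)
  expect_false(identical(r1$events, r3$events))
  bad <- circuit_sample(
    genetic_network("x", list(gene_product("P", 1, 0.5, "reporter", "P")),
                    list(op_source("s", "P", 1))),
    growth_constant(mu0 = 0))
  expect_error(simulate_ssa(bad, 1), "integer-valued")
})

test_that("compiled SSA waiting times agree with R-level propensities", {
  # first-event times are Exp(a_tot) with a_tot from the independent
  # R-side propensity calculation
  s <- pure_death_sample(p0 = 100, gamma = 1)
  atot <- with(propensities(s$network, 100, mu = 0), sum(a) + sum(b))
  expect_equal(atot, 100)
  set.seed(21)
  first <- replicate(800, simulate_ssa(s, 1)$events$time[1])
  se <- 1 / atot / sqrt(800)
  expect_lt(abs(mean(first) - 1 / atot), 4 * se)
})

test_that("SSA ensemble mean tracks the pure-death decay law", {
  s <- pure_death_sample(p0 = 100, gamma = 1)
  set.seed(31)
  finals <- replicate(400, tail(simulate_ssa(s, 1, timepoints = c(0, 1),
                                             record_events = FALSE)
                                $trajectory$X, 1))
  expected <- 100 * exp(-1)
  se <- sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - expected), 3 * se)
})

test_that("assays emit one row per signal per timepoint plus biomass", {
  net <- network_source_reporter()
  a <- assay(list(s1 = circuit_sample(net, growth_constant(mu0 = 0.5))),
             duration = 10, interval = 0.5, name = "counting")
  tab <- run_assay(a)
  expect_equal(nrow(tab[tab$signal == "GFP", ]), 21)
  expect_equal(nrow(tab[tab$signal == "biomass", ]), 21)
  expect_equal(tab$value[tab$signal == "biomass"],
               biomass_at(a$samples[[1]]$growth, seq(0, 10, 0.5)))
  # 12-sample dose response with 2 reporters
  net2 <- genetic_network(
    "two_rep",
    list(reporter("G1", 1, 0, signal_id = "G1"),
         reporter("G2", 1, 0, signal_id = "G2")),
    list(op_source("c1", "G1", 5), op_source("c2", "G2", 2)))
  samples <- replicate(12, circuit_sample(net2, growth_constant(mu0 = 0.2)),
                       simplify = FALSE)
  a2 <- assay(samples, duration = 6, interval = 1)
  tab2 <- run_assay(a2)
  expect_equal(sum(tab2$signal != "biomass"), 12 * 2 * 7)
  # measurement CSV round trip is lossless
  f <- tempfile(fileext = ".csv")
  write_measurements(tab2, f)
  expect_equal(read_measurements(f), tab2)
})

test_that("assay construction enforces its timing invariants", {
  s <- circuit_sample(network_source_reporter(), growth_constant(mu0 = 0.1))
  expect_error(assay(list(s), duration = 5, interval = 6), "interval")
  expect_error(assay(list(s), duration = 48, interval = 1),
               "growth-profile window")
})
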