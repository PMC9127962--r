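gp <- const_growth(0.5)
concs <- c(0, 0.01, 0.1, 0.3, 1, 3, 10, 100)

test_that("source rate is recovered from its own kinetics", {
  s <- circuit_sample(network_source_reporter(alpha = 10, gamma = 1), gp)
  tr <- simulate_ode(s, 8, seq(0, 8, 0.5))
  fit <- fit_source(data.frame(time = tr$time, value = tr$GFP),
                    gamma = 1, growth = gp)
  expect_lt(abs(coef(fit) - 10) / 10, 0.01)
  # identically zero series
  z <- fit_source(data.frame(time = 0:7, value = rep(0, 8)), 1, gp)
  expect_equal(unname(coef(z)), 0)
  expect_true(z$identifiability_flags[["alpha"]])
  # 5 percent multiplicative noise, fixed seed
  set.seed(99)
  noisy <- tr$GFP * (1 + 0.05 * rnorm(length(tr$GFP)))
  fn <- fit_source(data.frame(time = tr$time, value = noisy), 1, gp)
  expect_lt(abs(coef(fn) - 10) / 10, 0.10)
})

test_that("receiver Hill parameters are recovered from noiseless
           dose-response kinetics", {
  truth <- hill1_params(alpha0 = 0.1, alpha1 = 10, K = 1, n = 2)
  a <- dose_response_assay(network_receiver(receiver = truth), "AHL",
                           concs, growth = gp, duration = 8,
                           interval = 0.5)
  ds <- dr_from_assay(a, run_assay(a), "YFP")
  fit <- fit_receiver(ds, gamma = 1, growth = gp)
  expect_lt(rel_err(fit, truth), 0.05)
  vals <- ds$blocks[[1]]$values
  expect_lt(fit$residual_sse, 1e-6 * sum(vals^2))
  expect_false(any(fit$identifiability_flags[c("alpha0", "alpha1")]))
})

test_that("flat and monotone-decreasing responses are diagnosed", {
  flat_truth <- hill1_params(alpha0 = 5, alpha1 = 5, K = 1, n = 2)
  a <- dose_response_assay(network_receiver(receiver = flat_truth), "AHL",
                           concs, growth = gp, duration = 8,
                           interval = 0.5)
  ds <- dr_from_assay(a, run_assay(a), "YFP")
  fit <- fit_receiver(ds, gamma = 1, growth = gp, n_restarts = 4L)
  expect_lt(abs(fit$params$alpha0 - 5) / 5, 0.05)
  expect_lt(abs(fit$params$alpha1 - 5) / 5, 0.05)
  expect_true(all(fit$identifiability_flags[c("K", "n")]))
  # NOT-type receiver: decreasing response forces alpha0 > alpha1
  not_truth <- hill1_params(alpha0 = 10, alpha1 = 0.1, K = 1, n = 2)
  a2 <- dose_response_assay(network_receiver(receiver = not_truth), "AHL",
                            concs, growth = gp, duration = 8,
                            interval = 0.5)
  ds2 <- dr_from_assay(a2, run_assay(a2), "YFP")
  fit2 <- fit_receiver(ds2, gamma = 1, growth = gp, n_restarts = 4L)
  expect_gt(fit2$params$alpha0, fit2$params$alpha1)
})

test_that("downstream one-input operator is recovered with the receiver
           held fixed", {
  recv <- hill1_params(0.1, 10, 1, 2)
  truth <- hill1_params(alpha0 = 8, alpha1 = 0.2, K = 2, n = 2)
  a <- dose_response_assay(
    network_hill1_cascade(receiver = recv, hill1 = truth), "AHL", concs,
    growth = gp, duration = 8, interval = 0.5)
  ds <- dr_from_assay(a, run_assay(a), "CFP")
  fit <- fit_hill1(ds, recv, gamma_regulator = 1, gamma_reporter = 1,
                   growth = gp)
  expect_lt(rel_err(fit, truth), 0.10)
  expect_identical(classify_logic(fit$params), "NOT")
  # buffer generator gives alpha1 > alpha0
  buf <- hill1_params(alpha0 = 0.2, alpha1 = 8, K = 2, n = 2)
  ab <- dose_response_assay(
    network_hill1_cascade(receiver = recv, hill1 = buf), "AHL", concs,
    growth = gp, duration = 8, interval = 0.5)
  dsb <- dr_from_assay(ab, run_assay(ab), "CFP")
  fitb <- fit_hill1(dsb, recv, 1, 1, growth = gp, n_restarts = 5L)
  expect_gt(fitb$params$alpha1, fitb$params$alpha0)
})

test_that("a switching threshold the regulator never approaches is
           flagged non-identifiable", {
  # receiver output caps the regulator at ~0.005, operator K sits at 10
  weak <- hill1_params(alpha0 = 0.001, alpha1 = 0.005, K = 1, n = 2)
  far <- hill1_params(alpha0 = 6, alpha1 = 1, K = 10, n = 2)
  a <- dose_response_assay(
    network_hill1_cascade(receiver = weak, hill1 = far), "AHL", concs,
    growth = gp, duration = 8, interval = 0.5)
  ds <- dr_from_assay(a, run_assay(a), "CFP")
  fit <- fit_hill1(ds, weak, 1, 1, growth = gp, n_restarts = 4L)
  expect_true(fit$identifiability_flags[["K"]])
})

test_that("two-input fit is symmetric under input exchange", {
  r1 <- hill1_params(0.1, 10, 1, 2)
  r2 <- hill1_params(0.1, 8, 2, 2)
  truth <- hill2_params(alpha0 = 6, alpha1 = 0.5, alpha2 = 2, alpha3 = 0.2,
                        K1 = 1, K2 = 3, n1 = 2, n2 = 3)
  g5 <- c(0, 0.03, 0.3, 3, 30)
  net <- network_hill2_composed(r1, r2, truth)
  a <- dose_response_assay(net, c("AHL1", "AHL2"), list(g5, g5),
                           growth = gp, duration = 8, interval = 1)
  tab <- run_assay(a)
  ds <- dr_from_assay(a, tab, "CFP", n_axes = 2L)
  fit <- fit_hill2(ds, r1, r2, 1, 1, 1, growth = gp, n_restarts = 6L)
  expect_lt(rel_err(fit, truth), 0.10)
  # swap the two input axes (and the receivers): fitted parameter pairs
  # must exchange
  swapped <- ds
  for (i in seq_along(swapped$blocks))
    swapped$blocks[[i]]$conc <- swapped$blocks[[i]]$conc[, 2:1]
  fit_sw <- fit_hill2(swapped, r2, r1, 1, 1, 1, growth = gp,
                      n_restarts = 6L)
  expect_equal(fit_sw$params$alpha1, fit$params$alpha2, tolerance = 1e-2)
  expect_equal(fit_sw$params$alpha2, fit$params$alpha1, tolerance = 1e-2)
  expect_equal(fit_sw$params$K1, fit$params$K2, tolerance = 1e-2)
  expect_equal(fit_sw$params$K2, fit$params$K1, tolerance = 1e-2)
  expect_equal(fit_sw$params$n1, fit$params$n2, tolerance = 1e-2)
  expect_equal(fit_sw$params$alpha0, fit$params$alpha0, tolerance = 1e-2)
})

test_that("multi-start refits are seed-stable on well-identified data", {
  truth <- hill1_params(0.1, 10, 1, 2)
  a <- dose_response_assay(network_receiver(receiver = truth), "AHL",
                           concs, growth = gp, duration = 8,
                           interval = 0.5)
  ds <- dr_from_assay(a, run_assay(a), "YFP")
  f1 <- fit_receiver(ds, 1, gp, n_restarts = 5L, seed = 1)
  f2 <- fit_receiver(ds, 1, gp, n_restarts = 5L, seed = 2)
  expect_lt(max(abs(coef(f1) - coef(f2)) / coef(f1)), 0.01)
})

test_that("design requirements are enforced", {
  expect_error(dose_response_data(c(0, 1, 2), seq(0, 4),
                                  matrix(0, 5, 3)),
               "insufficient design")
  expect_error(dose_response_data(c(0, 1, 2, 3), c(0, 1, 2),
                                  matrix(0, 3, 4)), "length")
  recv <- hill1_params(0.1, 10, 1, 2)
  ds <- dose_response_data(c(0, 1, 2, 4), seq(0, 4), matrix(1, 5, 4))
  expect_error(fit_hill2(ds, recv, recv, 1, 1, 1, growth = gp),
               "two-input")
  expect_error(fit_hill2(ds, NULL, NULL, 1, 1, 1, growth = gp),
               "workflow order")
})

test_that("growth reconstruction recovers constant and logistic profiles", {
  t <- seq(0, 10, 0.5)
  gc_ <- fit_growth(t, 0.05 * exp(0.6 * t))
  expect_identical(gc_$kind, "constant")
  expect_equal(gc_$params$mu0, 0.6, tolerance = 1e-6)
  gl <- growth_logistic(b0 = 0.02, Bmax = 1.2, mu_max = 0.8, duration = 30)
  gfit <- fit_growth(t, biomass_at(gl, t))
  expect_identical(gfit$kind, "logistic")
  expect_equal(gfit$params$mu_max, 0.8, tolerance = 1e-3)
})
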