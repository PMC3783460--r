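# Model equations, unit conversions and literature-anchored parameter
# derivations.

test_that("leptin clearance rate from half-life", {
  expect_equal(signif(gamma_from_halflife(24.9), 3), 40.1)
  expect_equal(gamma_from_halflife(1440), log(2), tolerance = 1e-12)
  expect_equal(gamma_from_halflife(720), 2 * log(2), tolerance = 1e-12)
  expect_error(gamma_from_halflife(0), "positive")
  expect_error(gamma_from_halflife(-5), "positive")
})

test_that("beta calibration from the quasi-steady reference state", {
  # subject B: printed inputs reproduce the printed beta
  expect_equal(signif(beta_from_reference(20.3, 40.1, 3500, 0.316, 127.4), 3),
               5.78e-3)
  # subject A: direct arithmetic lands ~0.6% below the printed 3.68e-3
  # (printed-input rounding); assert the computed value
  bA <- beta_from_reference(20.3, 40.1, 3500, 0.405, 157.0)
  expect_equal(bA, 3.6578e-3, tolerance = 1e-4)
  expect_lt(abs(bA - 3.68e-3) / 3.68e-3, 0.01)
  # linear in the reference leptin level
  expect_equal(beta_from_reference(2 * 20.3, 40.1, 3500, 0.316, 127.4),
               2 * beta_from_reference(20.3, 40.1, 3500, 0.316, 127.4),
               tolerance = 1e-12)
  expect_error(beta_from_reference(20.3, 40.1, 3500, 1.2, 127.4), "delta")
})

test_that("alpha from the composite rate and the algebraic round trip", {
  expect_equal(signif(alpha_from_eta(2.78e-5, 40.1, 3.68e-3), 3), 0.303)
  aB <- alpha_from_eta(1.17e-4, 40.1, 5.78e-3)
  expect_equal(aB, 0.8117, tolerance = 1e-3)
  expect_lt(abs(aB - 0.816) / 0.816, 0.01)
  # eta -> alpha -> eta is an exact algebraic identity
  for (eta in c(1e-6, 2.78e-5, 1.17e-4, 1e-2)) {
    alpha <- alpha_from_eta(eta, 40.1, 3.68e-3)
    expect_equal(alpha * 3.68e-3 / 40.1, eta, tolerance = 1e-12)
  }
})

test_that("printed alpha, beta, gamma reproduce the printed eta", {
  # subject A exact to printed precision, subject B within 1%
  etaA <- subject_A_printed$alpha * subject_A_printed$beta / 40.1
  expect_equal(signif(etaA, 3), subject_A_printed$eta)
  etaB <- subject_B_printed$alpha * subject_B_printed$beta / 40.1
  expect_lt(abs(etaB - subject_B_printed$eta) / subject_B_printed$eta, 0.01)
})

test_that("quasi-steady-state leptin", {
  expect_identical(qss_leptin(0, 3.68e-3, 40.1), 0)
  # calibration consistency: reference store gives back ~the reference level
  C_ref <- 3500 * 0.405 * 157.0
  expect_equal(qss_leptin(C_ref, 3.68e-3, 40.1), 20.42, tolerance = 1e-3)
  expect_equal(qss_leptin(2 * C_ref, 3.68e-3, 40.1),
               2 * qss_leptin(C_ref, 3.68e-3, 40.1), tolerance = 1e-12)
  expect_error(qss_leptin(-1, 3.68e-3, 40.1), "non-negative")
})

test_that("piecewise expenditure is continuous and anchored", {
  expect_equal(expenditure(c(0, 50, 500), 2571, 0), rep(2571, 3))
  expect_equal(expenditure(0, 2571, 1e-7), 2571)
  # continuity across a transition to 10 significant digits and beyond
  ts <- 1217.5
  lo <- expenditure(ts - 1e-9, 2100, c(2.06e-6, 8.3e-7), ts)
  hi <- expenditure(ts + 1e-9, 2100, c(2.06e-6, 8.3e-7), ts)
  expect_equal(lo, hi, tolerance = 1e-12)
  expect_error(expenditure(5, 2100, c(1e-6, 1e-7), numeric(0)), "transition")
  expect_error(expenditure(5, 2100, c(1e-6, 1e-7, 1e-8), c(100, 50)),
               "increasing")
})

test_that("closed-form weight trajectory", {
  pA <- subject_A_params()
  # level at the record start from the printed subject-A parameters
  expect_equal(weight_closed_form(0, pA), 145.11, tolerance = 1e-4)
  # eps = 0 freezes the trajectory at (D - Q0)/(eta*rho*delta)
  p0 <- model_params(D = 2586, Q0 = 2571, delta = 0.405, eta = 2.78e-5,
                     epsilon = 0)
  w0 <- (2586 - 2571) / (2.78e-5 * 3500 * 0.405)
  expect_equal(weight_closed_form(c(0, 500, 5000), p0), rep(w0, 3),
               tolerance = 1e-12)
  # nondecreasing when expenditure decays
  t <- seq(0, 3000, by = 10)
  expect_true(all(diff(weight_closed_form(t, pA)) >= 0))
  # closed form invalid when eta <= eps
  expect_error(
    model_params(D = 2586, Q0 = 2571, delta = 0.405, eta = 1e-8,
                 epsilon = 1e-7),
    "eta must exceed"
  )
})

test_that("closed form converges to the eps = 0 solution as eps -> 0", {
  t <- seq(0, 100 * DAYS_PER_MONTH, length.out = 101)
  p_small <- model_params(D = 2152, Q0 = 2100, delta = 0.316, eta = 1.17e-4,
                          epsilon = 1e-12)
  p_zero <- model_params(D = 2152, Q0 = 2100, delta = 0.316, eta = 1.17e-4,
                         epsilon = 0)
  rel <- abs(weight_closed_form(t, p_small) - weight_closed_form(t, p_zero)) /
    weight_closed_form(t, p_zero)
  expect_lt(max(rel), 1e-6)
})

test_that("calorie/weight conversions are exact inverses", {
  expect_equal(calories_to_weight(3500, 3500, 1 - 1e-15), 1,
               tolerance = 1e-9)
  expect_equal(weight_to_calories(157.0, 3500, 0.405), 222547.5)
  w <- c(101.3, 157.0, 203.7)
  expect_equal(calories_to_weight(weight_to_calories(w, 3500, 0.405),
                                  3500, 0.405), w, tolerance = 1e-12)
  expect_error(calories_to_weight(100, 0, 0.4), "positive")
})

test_that("full-system right-hand side vanishes at equilibrium", {
  p <- subject_A_full_params()
  C_star <- weight_to_calories(157, 3500, 0.405)
  L_star <- qss_leptin(C_star, p$beta, p$gamma)
  # equilibrium: drive balances leptin-damped intake against expenditure
  p_eq <- model_params(D = p$D, alpha = p$alpha, beta = p$beta,
                       gamma = p$gamma, delta = p$delta, eta = p$eta,
                       Q0 = 2571, epsilon = 0)
  D_eq <- 2571 + p$alpha * L_star
  d <- ode_rhs(c(C_star, L_star), 0, p_eq, function(t) D_eq)
  expect_equal(d[1], 0, tolerance = 1e-9)
  expect_equal(d[2], 0, tolerance = 1e-9)
  # empty state: no store, no leptin, drive = expenditure
  d0 <- ode_rhs(c(0, 0), 0, p_eq, function(t) 2571)
  expect_equal(d0, c(0, 0), tolerance = 1e-12)
})

test_that("printed subject-A calibration is near the leptin nullcline", {
  p <- subject_A_printed
  C <- weight_to_calories(157, 3500, p$delta)
  dL <- p$beta * C - 40.1 * 20.3
  expect_lt(abs(dL), 0.01 * 40.1 * 20.3)
})

test_that("parameter container enforces its invariants", {
  expect_error(model_params(D = -1), "positive")
  expect_error(model_params(delta = 1.5), "delta")
  expect_error(
    model_params(alpha = 0.3, beta = 3.68e-3, gamma = 40.1, eta = 1e-3),
    "alpha \\* beta / gamma"
  )
  # consistent quadruple passes
  expect_s3_class(
    model_params(alpha = 0.303, beta = 3.68e-3, gamma = 40.1,
                 eta = 0.303 * 3.68e-3 / 40.1),
    "model_params"
  )
  expect_error(
    model_params(eta = 1e-5, epsilon = c(1e-7, 1e-8)),
    "transition"
  )
})

test_that("parameters round-trip through the key-value file", {
  p <- subject_B_params()
  path <- withr::local_tempfile(fileext = ".txt")
  write_params(p, path)
  q <- read_params(path)
  for (nm in c("D", "Q0", "delta", "eta", "rho", "L_ref", "W_ref")) {
    expect_identical(q[[nm]], p[[nm]])
  }
  expect_identical(q$epsilon, p$epsilon)
  expect_identical(q$t_transition, p$t_transition)
})
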