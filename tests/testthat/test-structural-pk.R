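# Two-compartment closed form, covariate submodels and residual error.

test_that("covariate submodels evaluate the published functional forms", {
  # power law of the final model: identity at the reference
  expect_equal(apply_covariate("power", 245, -0.58, 617.96, 617.96), 245)
  # log-space cross-check of the power law at an off-reference value
  expect_equal(apply_covariate("power", 245, -0.58, 350.1, 617.96),
               exp(log(245) - 0.58 * (log(350.1) - log(617.96))),
               tolerance = 1e-12)
  expect_equal(apply_covariate("power", 245, -0.58, 350.1, 617.96),
               340.637, tolerance = 1e-4)
  # null effects leave theta1 untouched
  expect_equal(apply_covariate("linear", 10, 0, 3, 2), 10)
  expect_equal(apply_covariate("exponential", 10, 1, 3, 2), 10)
  expect_equal(apply_covariate("categorical", 10, 1, 1), 10)
  expect_equal(apply_covariate("power", 10, 0, 3, 2), 10)
  # linear form exactly as written (theta1 + theta2 * cov/ref)
  expect_equal(apply_covariate("linear", 10, 2, 6, 3), 14)
  # nonpositive results are rejected
  expect_error(apply_covariate("linear", 1, -2, 5, 2), "non-positive")
})

test_that("individual parameters combine covariates and exponential BSV", {
  m <- nalbuphine_final_model()
  ref <- list(HNF = 617.96)
  expect_equal(unname(individual_params(m, ref)),
               unname(final_theta))
  # exponential link: eta = ln 2 doubles the parameter
  p <- individual_params(m, ref, eta = c(CL = log(2)))
  expect_equal(p[["CL"]], 2 * 32.9)
  # high fluid-load subject: Q scales by the power law
  p <- individual_params(m, list(HNF = 973.4))
  expect_equal(p[["Q"]], 245 * (973.4 / 617.96)^-0.58, tolerance = 1e-12)
  expect_equal(p[["Q"]], 188.241, tolerance = 1e-4)
  # missing covariate is a hard error
  expect_error(typical_params(m, list(WT = 60)), "HNF")
})

test_that("micro constants satisfy the Vieta identities", {
  mc <- micro_constants(32.9, 32.5, 245, 83.5)
  expect_equal(mc$k10, 32.9 / 32.5, tolerance = 1e-12)
  expect_equal(mc$alpha * mc$beta, mc$k10 * mc$k21, tolerance = 1e-12)
  expect_equal(mc$alpha + mc$beta, mc$k10 + mc$k12 + mc$k21,
               tolerance = 1e-12)
  expect_gt(mc$alpha, mc$beta)
  # one-compartment limit
  mc0 <- micro_constants(10, 20, 0, 50)
  expect_equal(mc0$k12, 0)
  expect_equal(mc0$k21, 0)
  expect_equal(mc0$alpha, mc0$k10)
  expect_equal(mc0$beta, 0)
})

test_that("closed-form concentrations handle null inputs and scale linearly", {
  expect_equal(conc_2cmt(0, 15, 0.0417, 32.9, 32.5, 245, 83.5), 0)
  expect_equal(conc_2cmt(c(0.1, 1, 4), 0, 0, 32.9, 32.5, 245, 83.5),
               c(0, 0, 0))
  expect_error(conc_2cmt(-1, 15, 0, 32.9, 32.5, 245, 83.5), "negative time")
  t <- c(0.05, 0.25, 1, 4, 12)
  c1 <- conc_2cmt(t, 12, 0.0417, 32.9, 32.5, 245, 83.5)
  c2 <- conc_2cmt(t, 24, 0.0417, 32.9, 32.5, 245, 83.5)
  expect_equal(c2, 2 * c1, tolerance = 1e-12)
})

test_that("closed form matches adaptive ODE integration to 1e-6 relative", {
  skip_if_not_installed("deSolve")
  # published typical parameters, induction infusion
  t <- c(0.05, 0.0833, 0.25, 0.5, 1, 2, 4, 8, 12)
  cf <- conc_2cmt(t, 15, 0.0417, 32.9, 32.5, 245, 83.5)
  oc <- ode_conc(t, 15, 0.0417, 32.9, 32.5, 245, 83.5)
  expect_lt(max(abs(cf - oc) / oc), 1e-6)
  # property: random parameter draws, bolus and infusion, log-spaced grid
  set.seed(42)
  tg <- 10^seq(-2, 1.1, length.out = 12)
  for (i in 1:25) {
    CL <- exp(runif(1, log(5), log(100)))
    V1 <- exp(runif(1, log(10), log(80)))
    Q <- exp(runif(1, log(10), log(400)))
    V2 <- exp(runif(1, log(30), log(300)))
    tinf <- sample(c(0, 0.0417, 0.5), 1)
    cf <- conc_2cmt(tg, 15, tinf, CL, V1, Q, V2)
    oc <- ode_conc(tg, 15, tinf, CL, V1, Q, V2)
    expect_lt(max(abs(cf - oc) / pmax(oc, 1e-12)), 1e-6)
  }
})

test_that("AUC conservation: trapezoid integral approximates dose/CL", {
  tg <- c(seq(0, 1, by = 0.002), seq(1.01, 96, by = 0.01))
  cc <- conc_2cmt(tg, 15, 0.0417, 32.9, 32.5, 245, 83.5) / 1000 # mg/L
  auc <- sum(diff(tg) * (head(cc, -1) + tail(cc, -1)) / 2)
  expect_equal(auc, 15 / 32.9, tolerance = 0.005)
})

test_that("Q -> 0 converges to the one-compartment solution", {
  t <- c(0.1, 0.5, 2, 6)
  CL <- 30; V1 <- 40
  one_cmt_bolus <- 1000 * 15 / V1 * exp(-CL / V1 * t)
  expect_equal(conc_2cmt(t, 15, 0, CL, V1, 1e-9, 50), one_cmt_bolus,
               tolerance = 1e-6)
  # infusion: analytic one-compartment post-infusion solution
  k <- CL / V1; tinf <- 0.5; R0 <- 15 / tinf
  tt <- c(1, 2, 6)
  one_cmt_inf <- 1000 * R0 / (k * V1) * (1 - exp(-k * tinf)) *
    exp(-k * (tt - tinf))
  expect_equal(conc_2cmt(tt, 15, tinf, CL, V1, 1e-9, 50), one_cmt_inf,
               tolerance = 1e-6)
})

test_that("profiles decline monotonically after distribution and vanish", {
  t <- c(seq(1, 48, by = 0.5))
  cc <- conc_2cmt(t, 15, 0.0417, 32.9, 32.5, 245, 83.5)
  expect_true(all(diff(cc) < 0))
  expect_lt(conc_2cmt(300, 15, 0.0417, 32.9, 32.5, 245, 83.5), 1e-6)
})

test_that("superposition over multiple doses adds single-dose solutions", {
  doses <- data.frame(time = c(0, 4), amt = c(15, 10), dur = c(0.0417, 0))
  p <- list(CL = 32.9, V1 = 32.5, Q = 245, V2 = 83.5)
  t <- c(1, 4.5, 8)
  expect_equal(conc_profile(t, doses, p),
               conc_2cmt(t, 15, 0.0417, 32.9, 32.5, 245, 83.5) +
                 c(0, conc_2cmt(c(0.5, 4), 10, 0, 32.9, 32.5, 245, 83.5)))
})

test_that("combined residual variance follows the two-component form", {
  expect_equal(residual_variance(0, 0.139, 2.88), 2.88^2)
  expect_equal(residual_variance(100, 0.139, 2.88),
               (0.139 * 100)^2 + 2.88^2)   # ~201.50
  expect_equal(residual_variance(50, 0.1, 0), 25)
})
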