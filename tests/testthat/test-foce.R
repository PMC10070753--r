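# FOCE-I estimation: conditional objective, EBEs, marginal OFV, outer
# fit, shrinkage.

test_that("conditional objective reduces to the prior with no observations", {
  m <- toy_model()
  subj <- list(id = "z", doses = data.frame(time = 0, amt = 15, dur = 0),
               times = numeric(0), dv = numeric(0), covs = NULL)
  om <- m$omega
  eta <- c(0.3, -0.2)
  expect_equal(conditional_objective(eta, subj, m),
               sum(eta^2 / om) + sum(log(2 * pi * om)),
               tolerance = 1e-12)
  # minimized at zero
  expect_equal(estimate_etas(subj, m)$eta, c(0, 0), tolerance = 1e-6)
})

test_that("conditional objective matches its written form for one observation", {
  m <- toy_model()
  subj <- list(id = "z", doses = data.frame(time = 0, amt = 15, dur = 0),
               times = 1, dv = 150, covs = NULL)
  eta <- c(0.1, -0.3)
  p <- c(30 * exp(eta[1]), 30 * exp(eta[2]), 100, 80)
  f <- conc_2cmt(1, 15, 0, p[1], p[2], p[3], p[4])
  g <- 0^2 * f^2 + 2^2
  manual <- log(2 * pi * g) + (150 - f)^2 / g +
    sum(eta^2 / m$omega) + sum(log(2 * pi * m$omega))
  expect_equal(conditional_objective(eta, subj, m), manual,
               tolerance = 1e-12)
})

test_that("perfect fit at eta = 0 leaves only the constants", {
  m <- pop_model(theta = c(CL = 30, V1 = 30, Q = 100, V2 = 80),
                 omega = c(CL = 1, V1 = 1), sigma = c(prop = 0, add = 1))
  tt <- c(0.5, 2)
  f <- conc_2cmt(tt, 15, 0, 30, 30, 100, 80)
  subj <- list(id = "z", doses = data.frame(time = 0, amt = 15, dur = 0),
               times = tt, dv = f, covs = NULL)
  expect_equal(conditional_objective(c(0, 0), subj, m),
               2 * log(2 * pi) + 2 * log(2 * pi),
               tolerance = 1e-12)
})

test_that("empirical Bayes estimates respect the prior and the data", {
  # near-degenerate prior pins the mode at zero
  m_tight <- toy_model(omega = c(CL = 1e-8, V1 = 1e-8))
  d <- toy_dataset(toy_model(), n = 1, seed = 2)
  subj <- subject_data(d, subject_ids(d)[1])
  expect_lt(max(abs(estimate_etas(subj, m_tight)$eta)), 1e-3)
  # near-noiseless data recover the generating eta
  m_gen <- toy_model(sigma = c(prop = 0.001, add = 1e-4))
  d <- toy_dataset(m_gen, n = 6, seed = 3)
  truth <- attr(d, "truth")$etas
  for (id in subject_ids(d)) {
    est <- estimate_etas(subject_data(d, id), m_gen)
    expect_lt(max(abs(est$eta - truth[id, ])), 0.05)
  }
})

test_that("the conditional mode matches an exhaustive 1-d search", {
  m <- pop_model(theta = c(CL = 30, V1 = 30, Q = 100, V2 = 80),
                 omega = c(CL = 0.09), sigma = c(prop = 0, add = 2))
  d <- toy_dataset(m, n = 1, seed = 4, times = c(0.5, 2))
  subj <- subject_data(d, subject_ids(d)[1])
  brute <- stats::optimize(function(e)
    conditional_objective(e, subj, m), c(-2, 2), tol = 1e-10)
  est <- estimate_etas(subj, m)
  expect_equal(est$eta, brute$minimum, tolerance = 1e-6)
  expect_equal(est$value, brute$objective, tolerance = 1e-9)
})

test_that("FOCE OFV agrees with adaptive Gauss-Hermite quadrature", {
  skip_if_not_installed("pracma")
  m <- toy_model()
  d <- toy_dataset(m, n = 3, seed = 5)
  expect_lt(abs(as.numeric(foce_ofv(m, d)) - gh_ofv(m, d)), 0.5)
  # proportional + additive error (interaction active)
  m2 <- toy_model(sigma = c(prop = 0.15, add = 1))
  d2 <- toy_dataset(m2, n = 3, seed = 6)
  expect_lt(abs(as.numeric(foce_ofv(m2, d2)) - gh_ofv(m2, d2)), 0.5)
})

test_that("OFV is additive over subjects and order-invariant", {
  m <- toy_model()
  d <- toy_dataset(m, n = 4, seed = 7)
  ofv <- as.numeric(foce_ofv(m, d))
  # duplicate every subject under new IDs
  ev2 <- d$events
  ev2$ID <- paste0("dup_", ev2$ID)
  ddup <- pk_dataset(rbind(d$events, ev2), lloq = d$lloq)
  expect_equal(as.numeric(foce_ofv(m, ddup)), 2 * ofv, tolerance = 1e-8)
  # permute subject order
  ids <- subject_ids(d)
  perm <- d$events[order(match(d$events$ID, rev(ids))), ]
  dperm <- pk_dataset(perm, lloq = d$lloq)
  expect_equal(as.numeric(foce_ofv(m, dperm)), ofv, tolerance = 1e-8)
})

test_that("optimization does not worsen a fit started at the truth", {
  m <- toy_model()
  d <- toy_dataset(m, n = 6, seed = 8)
  ofv0 <- as.numeric(foce_ofv(m, d))
  fit <- fit_model(d, m, covariance = FALSE,
                   control = list(iter.max = 80, rel.tol = 1e-7))
  expect_lte(fit$ofv, ofv0 + 1e-4)
  expect_equal(fit$aic, fit$ofv + 2 * fit$n_params)
})

test_that("a small fit recovers parameters and reports standard errors", {
  m <- toy_model(sigma = c(prop = 0.1, add = 1))
  d <- toy_dataset(m, n = 12, seed = 9,
                   times = c(0.1, 0.25, 0.5, 1, 2, 4, 8))
  start <- m
  start$theta[] <- start$theta * c(1.25, 0.8, 1.2, 0.85)
  fit <- fit_model(d, start, covariance = TRUE,
                   control = list(iter.max = 120, rel.tol = 1e-7))
  expect_true(fit$convergence)
  est <- setNames(fit$estimates$estimate, fit$estimates$parameter)
  expect_equal(est[["CL"]], 30, tolerance = 0.15)
  expect_equal(est[["V1"]], 30, tolerance = 0.2)
  expect_true(fit$cov_ok)
  expect_true(all(is.finite(fit$estimates$rse_pct)))
  # EBEs exist for every subject
  expect_equal(rownames(fit$etas), subject_ids(d))
})

test_that("two-compartment data strongly favor the two-compartment fit", {
  m <- toy_model(sigma = c(prop = 0.1, add = 1))
  d <- toy_dataset(m, n = 10, seed = 10,
                   times = c(0.1, 0.25, 0.5, 1, 2, 4, 8))
  f2 <- fit_model(d, m, covariance = FALSE,
                  control = list(iter.max = 80, rel.tol = 1e-7))
  m1 <- pop_model(theta = c(CL = 30, V1 = 60, Q = 1e-4, V2 = 100),
                  omega = c(CL = 0.09, V1 = 0.16),
                  sigma = c(prop = 0.1, add = 1))
  f1 <- fit_model(d, m1, covariance = FALSE, fix = c("Q", "V2"),
                  control = list(iter.max = 80, rel.tol = 1e-7))
  expect_gt(f1$aic - f2$aic, 10)
})

test_that("shrinkage tracks the information content of the design", {
  # rich sampling, small residual error: shrinkage near zero
  m <- toy_model(sigma = c(prop = 0.02, add = 0.1))
  d <- toy_dataset(m, n = 20, seed = 11,
                   times = c(0.1, 0.25, 0.5, 1, 2, 4, 8))
  ofv <- foce_ofv(m, d)
  shr <- shrinkage_eta(attr(ofv, "etas"), m$omega)
  expect_lt(max(abs(shr)), 20)
  # single late observation, uninformative: shrinkage near 100%
  d1 <- toy_dataset(m, n = 20, seed = 12, times = 12)
  m_wide <- toy_model(sigma = c(prop = 0, add = 50),
                      omega = c(CL = 0.09, V1 = 0.16))
  ofv1 <- foce_ofv(m_wide, d1)
  shr1 <- shrinkage_eta(attr(ofv1, "etas"), m_wide$omega)
  expect_gt(min(shr1), 70)
  # zero variance is undefined
  expect_true(is.na(shrinkage_eta(matrix(0, 3, 1), c(CL = 0))[["CL"]]))
})

test_that("singular Omega is rejected with guidance", {
  m <- toy_model(omega = c(CL = 0, V1 = 0.1))
  d <- toy_dataset(toy_model(), n = 1, seed = 13)
  expect_error(foce_ofv(m, d), "singular Omega")
})
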