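# Monte Carlo simulation engine: population simulation, covariate
# profiles and the dosing-regimen comparison.

test_that("degenerate variability collapses every replicate to the typical profile", {
  m <- nalbuphine_final_model()
  m$omega[] <- 0
  covs <- data.frame(HNF = rep(617.96, 3))
  des <- sim_design(dose = 12, n_replicates = 5)
  sim <- simulate_population(m, covs, des, seed = 1, residual = FALSE)
  typ <- conc_2cmt(des$times, 12, 0, 32.9, 32.5, 245, 83.5)
  for (r in 1:5) for (i in 1:3)
    expect_equal(sim$conc[r, i, ], typ, tolerance = 1e-12)
})

test_that("doubling the dose doubles every draw under a common seed", {
  m <- nalbuphine_final_model()
  m$sigma <- c(prop = 0.139, add = 0)  # proportional error scales too
  covs <- data.frame(HNF = c(400, 700))
  d1 <- sim_design(dose = 6, n_replicates = 20)
  d2 <- sim_design(dose = 12, n_replicates = 20)
  s1 <- simulate_population(m, covs, d1, seed = 2)
  s2 <- simulate_population(m, covs, d2, seed = 2)
  expect_equal(s2$conc, 2 * s1$conc, tolerance = 1e-12)
})

test_that("summaries recomputed from the raw array match exactly", {
  m <- nalbuphine_final_model()
  covs <- data.frame(HNF = c(400, 600, 900))
  des <- sim_design(n_replicates = 30)
  sim <- simulate_population(m, covs, des, seed = 3)
  k <- which(des$times == 4)
  x <- as.numeric(sim$conc[, , k])
  expect_equal(sim$summary$mean[k], mean(x))
  expect_equal(sim$summary$median[k], stats::median(x))
  expect_equal(sim$summary$min[k], min(x))
  expect_equal(sim$summary$max[k], max(x))
  expect_equal(sim$summary$p25[k],
               stats::quantile(x, 0.25, names = FALSE))
})

test_that("Monte Carlo means converge to the analytic log-normal mean", {
  # single subject, BSV on CL only, no residual: at a late time the
  # concentration is ~ B*exp(-beta(CL_i) t); convergence checked
  # against a large-replicate empirical reference via sqrt(n) scaling
  m <- nalbuphine_final_model()
  m$omega <- c(CL = 0.0767)
  covs <- data.frame(HNF = 617.96)
  des <- sim_design(n_replicates = 4000, times = c(1, 4))
  sim <- simulate_population(m, covs, des, seed = 4, residual = FALSE)
  # independent analytic oracle: expectation over eta by quadrature
  gh <- pracma::gaussHermite(61)
  f_eta <- function(e) conc_2cmt(4, 12, 0, 32.9 * exp(e), 32.5, 245, 83.5)
  mu <- sum(gh$w / sqrt(pi) *
            vapply(sqrt(2 * 0.0767) * gh$x, f_eta, 0))
  x <- as.numeric(sim$conc[, 1, 2])
  se <- stats::sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - mu), 4 * se)
})

test_that("covariate-effect profiles order by fluid load with limited impact", {
  m <- nalbuphine_final_model()
  des <- sim_design(dose = 15, tinf = 0.0417, n_replicates = 200)
  prof <- covariate_effect_profiles(
    m, "HNF", c(p10 = 350.1, p50 = 563.6, p90 = 973.4), des, seed = 5)
  # typical Q at the three fluid levels follows the power law
  qs <- vapply(c(350.1, 563.6, 973.4), function(h)
    typical_params(m, list(HNF = h))[["Q"]], 0)
  expect_equal(qs, 245 * (c(350.1, 563.6, 973.4) / 617.96)^-0.58,
               tolerance = 1e-12)
  # distribution-phase typical concentrations order monotonically with
  # the covariate: higher fluid load -> lower Q -> slower distribution
  # out of the central compartment -> higher early concentrations
  early <- des$times > 0.0417 & des$times <= 0.25
  t10 <- prof$typical[prof$level == "p10"][early]
  t50 <- prof$typical[prof$level == "p50"][early]
  t90 <- prof$typical[prof$level == "p90"][early]
  expect_true(all(t90 >= t50 & t50 >= t10))
  # a covariate with no effect gives identical bands under a common seed
  m0 <- m
  m0$effects[[1]]$theta2 <- 0
  expect_warning(
    prof0 <- covariate_effect_profiles(m0, "WT", c(a = 50, b = 80), des,
                                       base_covs = list(HNF = 617.96),
                                       seed = 5),
    "no active effect")
  expect_equal(prof0$median[prof0$level == "a"],
               prof0$median[prof0$level == "b"], tolerance = 1e-12)
})

test_that("equal 60 kg weights make the two regimens identical", {
  m <- nalbuphine_final_model()
  covs <- data.frame(WT = rep(60, 5), HNF = c(350, 500, 618, 800, 1000))
  rc <- regimen_comparison(m, covs, fixed_dose = 12, perkg_dose = 0.2,
                           design = sim_design(n_replicates = 50), seed = 6)
  expect_equal(rc$bias$bias_pct, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(rc$fixed$conc, rc$perkg$conc, tolerance = 1e-12)
})

test_that("fixed dosing shows no more PK variability than weight-based dosing", {
  m <- nalbuphine_final_model()
  ch <- sample_covariates(cohort_spec(), 27, seed = 7)
  rc <- regimen_comparison(m, ch[, c("WT", "HNF")],
                           design = sim_design(n_replicates = 150), seed = 8)
  for (k in c(2, 8, 11)) {   # 0.05, 1, 4 h
    lf <- log(rc$fixed$conc[, , k][rc$fixed$conc[, , k] > 0])
    lw <- log(rc$perkg$conc[, , k][rc$perkg$conc[, , k] > 0])
    expect_lte(stats::var(lf), stats::var(lw) * 1.05)
  }
})

test_that("regimen bias is invariant to replicate count beyond noise", {
  m <- nalbuphine_final_model()
  ch <- sample_covariates(cohort_spec(), 27, seed = 9)
  r1 <- regimen_comparison(m, ch[, c("WT", "HNF")],
                           design = sim_design(n_replicates = 100), seed = 10)
  r2 <- regimen_comparison(m, ch[, c("WT", "HNF")],
                           design = sim_design(n_replicates = 400), seed = 11)
  expect_lt(max(abs(r1$bias$bias_pct - r2$bias$bias_pct)), 0.6)
  # expectation: mean dose ratio drives the bias at every compared time
  expected <- 100 * (mean(0.2 * ch$WT) / 12 - 1)
  expect_lt(max(abs(r2$bias$bias_pct - expected)), 0.8)
})
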