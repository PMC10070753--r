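# Stepwise covariate modeling: correlation pruning, forward/backward
# steps, impact filter and the orchestrated search.

# compact covariate-effect scenario shared across the fit-based tests.
# The machinery needs a decisively detectable effect at desk scale, so
# the generating model carries a strong power effect of fluid load on
# clearance (theta2 = -1.5; clearance is the best-identified parameter
# under a design with a terminal sample), plus a permuted-HNF decoy
# covariate with the same marginal and no information.
scm_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    gen <- pop_model(
      theta = final_theta,
      effects = list(covariate_effect("CL", "HNF", "power",
                                      theta2 = -1.5, ref = 563.6)),
      omega = c(CL = 0.0225, V1 = 0.04, Q = 0.0225, V2 = 0.04),
      sigma = c(prop = 0.1, add = 1))
    ch <- representative_cohort(cohort_spec(), 12, seed = 21)
    set.seed(23)
    ch$NOISE <- sample(ch$HNF)     # decoy: same marginal, no link
    des <- study_design("rich")
    des$times <- c(0.05, 0.25, 1, 4, 12)
    d <- generate_dataset(ch, des, gen, seed = 22)
    base <- pop_model(theta = final_theta,
                      omega = c(CL = 0.09, V1 = 0.04, Q = 0.0225, V2 = 0.04),
                      sigma = c(prop = 0.1, add = 1))
    ctrl <- list(iter.max = 60, rel.tol = 1e-6)
    base_fit <- fit_model(d, base, covariance = FALSE, control = ctrl)
    cache <<- list(data = d, base = base, base_fit = base_fit, ctrl = ctrl)
    cache
  }
})

test_that("correlation screening prunes collinear covariates by preference", {
  set.seed(31)
  n <- 60
  wt <- rnorm(n, 63, 9)
  tab <- data.frame(
    WT = wt,
    BMI = wt / 2.7 + rnorm(n, 0, 1),      # strongly correlated with WT
    ALT = exp(rnorm(n, 3, 0.8)),
    DUP = wt)                              # perfect duplicate
  sc <- correlation_screen(tab, prefer = c("WT", "ALT"))
  expect_true("WT" %in% sc$keep)
  expect_false(any(c("BMI", "DUP") %in% sc$keep))
  expect_true("ALT" %in% sc$keep)
  expect_match(sc$dropped[["BMI"]], "WT")
  # independent covariates are all retained
  ind <- data.frame(A = rnorm(n), B = rnorm(n), C = rnorm(n))
  expect_setequal(correlation_screen(ind)$keep, c("A", "B", "C"))
  # constants excluded with a warning
  expect_warning(sc2 <- correlation_screen(cbind(ind, K = 1)), "constant")
  expect_false("K" %in% sc2$keep)
  expect_error(correlation_screen(ind[1:2, ]), "at least 3 subjects")
})

test_that("impact filter applies the strict 20% rule over the covariate range", {
  m <- nalbuphine_final_model()
  # published power effect over the 10th-90th percentile fluid range
  imp <- impact_filter(m, 1, c(350.1, 973.4))
  expect_true(imp$keep)
  expect_equal(imp$deviation[["low"]],
               (350.1 / 617.96)^-0.58 - 1, tolerance = 1e-12)  # ~ +39%
  expect_equal(imp$deviation[["high"]],
               (973.4 / 617.96)^-0.58 - 1, tolerance = 1e-12)  # ~ -23%
  # a null coefficient has zero impact
  m0 <- m
  m0$effects[[1]]$theta2 <- 0
  expect_false(impact_filter(m0, 1, c(350.1, 973.4))$keep)
  # exactly-20% deviation is dropped (strict inequality)
  mlin <- pop_model(theta = c(CL = 1, V1 = 30, Q = 100, V2 = 80),
                    effects = list(covariate_effect("CL", "X", "linear",
                                                    theta2 = 0.25, ref = 10)),
                    omega = c(CL = 0.1), sigma = c(prop = 0.1, add = 1))
  imp20 <- impact_filter(mlin, 1, c(10, 20))
  expect_equal(max(abs(imp20$deviation)), 0.2, tolerance = 1e-12)
  expect_false(imp20$keep)
})

test_that("forward inclusion finds the true fluid effect and rejects noise", {
  fx <- scm_fixture()
  cand <- data.frame(param = c("CL", "CL"),
                     covariate = c("HNF", "NOISE"))
  fw <- forward_step(fx$data, fx$base_fit, cand, threshold = 6.63,
                     control = fx$ctrl)
  # the true effect ranks first with the largest OFV drop and is accepted
  expect_equal(fw$covariate[1], "HNF")
  expect_equal(fw$param[1], "CL")
  expect_true(fw$accepted[1])
  expect_gt(fw$dofv[1], 6.63)
  # the decoy is not accepted
  expect_false(fw$accepted[fw$covariate == "NOISE"])
  # empty candidate list
  empty <- forward_step(fx$data, fx$base_fit,
                        data.frame(param = character(),
                                   covariate = character()), 6.63)
  expect_equal(nrow(empty), 0)
})

test_that("backward elimination retains a strong effect", {
  fx <- scm_fixture()
  cand <- data.frame(param = "CL", covariate = "HNF")
  fw <- forward_step(fx$data, fx$base_fit, cand, threshold = 6.63,
                     control = fx$ctrl)
  full_fit <- attr(fw, "fits")[[1]]
  bw <- backward_step(fx$data, full_fit, threshold = 7.88,
                      control = fx$ctrl)
  expect_equal(length(bw$fit$model$effects), 1L)
  expect_equal(bw$fit$model$effects[[1]]$covariate, "HNF")
  expect_false(any(bw$trace$removed))
  expect_gt(bw$trace$dofv[1], 7.88)
})

test_that("stepwise search assembles a consistent trace and final model", {
  fx <- scm_fixture()
  cand <- data.frame(param = c("CL", "CL"),
                     covariate = c("HNF", "NOISE"))
  res <- stepwise_search(fx$data, fx$base, cand, control = fx$ctrl)
  # the true effect survives to the final model
  effs <- vapply(res$final_fit$model$effects,
                 function(e) paste(e$covariate, e$param), "")
  expect_true("HNF CL" %in% effs)
  expect_false(any(grepl("NOISE", effs)))
  # accepted steps all satisfy their thresholds
  tr <- res$trace
  added <- tr[tr$step == "forward" & tr$decision == "added", ]
  if (nrow(added)) expect_true(all(added$dofv > 6.63))
  retained <- tr[tr$step == "backward" & tr$decision == "retained", ]
  if (nrow(retained)) expect_true(all(retained$dofv > 7.88))
  # unreachable thresholds return the base model unchanged
  cfg_inf <- scm_config(screen_in = 1e6, forward = 1e6, backward = 1e6,
                        forms = "power")
  res0 <- stepwise_search(fx$data, fx$base, cand, config = cfg_inf,
                          control = fx$ctrl)
  expect_equal(length(res0$final_fit$model$effects), 0L)
})
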