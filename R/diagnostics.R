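# Model-evaluation suite: goodness-of-fit quantities (PRED/IPRED/CWRES),
# nonparametric bootstrap, and prediction-corrected visual predictive
# check.

#' Goodness-of-fit quantities per observation
#'
#' PRED is the population prediction (eta = 0); IPRED the individual
#' prediction at the empirical Bayes estimates; CWRES the conditional
#' weighted residuals from the FOCE linearization: residuals around the
#' linearized population mean \eqn{f(\hat\eta) - G\hat\eta} decorrelated
#' by the model-implied covariance \eqn{G \Omega G' + diag(g(\hat\eta))}
#' evaluated at the conditional mode.
#'
#' @param fit A `pk_fit` from [fit_model()] (or a [pop_model()]
#'   together with `data`, in which case EBEs are re-estimated).
#' @param data A [pk_dataset()]; defaults to the fit's data.
#' @return data.frame with columns `ID`, `TIME`, `DV`, `PRED`, `IPRED`,
#'   `RES_VAR`, `IWRES`, `CWRES`.
#' @export
gof_quantities <- function(fit, data = NULL) {
  if (inherits(fit, "pk_fit")) {
    model <- fit$model
    if (is.null(data)) data <- fit$data
    etas <- fit$etas
  } else {
    model <- fit
    stopifnot(!is.null(data))
    etas <- NULL
  }
  out <- list()
  for (id in subject_ids(data)) {
    subj <- subject_data(data, id)
    ctx <- .subject_context(subj, model)
    if (!length(ctx$dv)) next
    eta <- if (!is.null(etas) && id %in% rownames(etas)) etas[id, ]
           else .estimate_etas(ctx)$eta
    f0 <- .cond_f(rep(0, ctx$d), ctx)           # PRED
    fi <- .cond_f(eta, ctx)                     # IPRED
    gi <- ctx$sp2 * fi * fi + ctx$sa2
    # gradient of f wrt eta at the mode
    J <- matrix(0, length(fi), ctx$d)
    h <- 1e-4
    for (k in seq_len(ctx$d)) {
      ep <- eta; ep[k] <- ep[k] + h
      em <- eta; em[k] <- em[k] - h
      J[, k] <- (.cond_f(ep, ctx) - .cond_f(em, ctx)) / (2 * h)
    }
    V <- J %*% (diag(1 / ctx$oinv, ctx$d)) %*% t(J) + diag(gi, length(gi))
    mu <- fi - as.numeric(J %*% eta)            # linearized population mean
    r <- ctx$dv - mu
    ee <- eigen((V + t(V)) / 2, symmetric = TRUE)
    vals <- ee$values
    if (any(vals < 1e-8 * max(vals))) {         # ridge stabilization
      warning("near-singular subject covariance for subject ", id,
              "; ridge-stabilized")
      vals <- pmax(vals, 1e-8 * max(vals))
    }
    Vinv_sqrt <- ee$vectors %*% (t(ee$vectors) / sqrt(vals))
    cwres <- as.numeric(Vinv_sqrt %*% r)
    out[[id]] <- data.frame(ID = id, TIME = ctx$times, DV = ctx$dv,
                            PRED = f0, IPRED = fi, RES_VAR = gi,
                            IWRES = (ctx$dv - fi) / sqrt(gi), CWRES = cwres)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Nonparametric bootstrap of a population model fit
#'
#' Resamples subjects with replacement (same N), refits the model on
#' each resample, and summarizes the successful replicates by the
#' median and 2.5th/97.5th percentiles per parameter, the robustness
#' rate (fraction of replicates that minimized successfully) and the
#' relative bias of the bootstrap medians against the original
#' estimates.
#'
#' @param data A [pk_dataset()].
#' @param fit Original `pk_fit` (its fitted model is the refit start).
#' @param n_resamples Number of bootstrap replicates (the study
#'   convention is 1000; scale down for quick checks).
#' @param seed Integer seed.
#' @param control Optimizer control for the replicate fits.
#' @return List of class `pk_bootstrap`: `summary` data.frame
#'   (`parameter`, `original`, `median`, `p2.5`, `p97.5`,
#'   `rel_bias_pct`), `robustness_pct`, `estimates` matrix
#'   (replicate x parameter, successful replicates only).
#' @export
pk_bootstrap <- function(data, fit, n_resamples = 1000, seed = 1,
                         control = list(iter.max = 100, rel.tol = 1e-6)) {
  ids <- subject_ids(data)
  est_rows <- list()
  ok <- 0L
  with_seed_(seed, {
    for (b in seq_len(n_resamples)) {
      take <- sample(ids, length(ids), replace = TRUE)
      bd <- resample_subjects(data, take)
      bf <- try(fit_model(bd, fit$model, covariance = FALSE,
                          control = control), silent = TRUE)
      if (inherits(bf, "try-error") || !isTRUE(bf$convergence)) next
      ok <- ok + 1L
      est_rows[[ok]] <- stats::setNames(bf$estimates$estimate,
                                        bf$estimates$parameter)
    }
  })
  if (!ok) stop("no bootstrap replicate converged")
  est <- do.call(rbind, est_rows)
  orig <- stats::setNames(fit$estimates$estimate, fit$estimates$parameter)
  qs <- apply(est, 2, stats::quantile, probs = c(0.025, 0.5, 0.975))
  summary <- data.frame(parameter = colnames(est),
                        original = as.numeric(orig[colnames(est)]),
                        median = qs[2, ], p2.5 = qs[1, ], p97.5 = qs[3, ])
  summary$rel_bias_pct <- 100 * (summary$median - summary$original) /
    summary$original
  rownames(summary) <- NULL
  structure(list(summary = summary,
                 robustness_pct = 100 * (1 - (n_resamples - ok) / n_resamples),
                 estimates = est),
            class = "pk_bootstrap")
}

#' Resample subjects (with replacement) into a new dataset
#'
#' Bootstrap helper: replicated subjects get fresh unique IDs.
#' @param data A [pk_dataset()].
#' @param take Character vector of subject IDs (possibly repeated).
#' @return A [pk_dataset()].
#' @export
resample_subjects <- function(data, take) {
  ev <- list(); cv <- list()
  for (i in seq_along(take)) {
    id <- take[i]
    e <- data$events[data$events$ID == id, ]
    e$ID <- sprintf("B%03d_%s", i, id)
    ev[[i]] <- e
    if (!is.null(data$covariates)) {
      cc <- data$covariates[data$covariates$ID == id, , drop = FALSE]
      cc$ID <- e$ID[1]
      cv[[i]] <- cc
    }
  }
  pk_dataset(do.call(rbind, ev),
             if (length(cv)) do.call(rbind, cv) else NULL,
             lloq = data$lloq)
}

#' Prediction-corrected visual predictive check
#'
#' Simulates `n_sim` replicates of the observed design from the model,
#' prediction-corrects observed and simulated concentrations by
#' \eqn{pcY_{ij} = Y_{ij} \cdot median(PRED_{bin}) / PRED_{ij}}, and
#' compares observed percentiles (5th/50th/95th) per time bin with the
#' 95% confidence bands of the same percentiles across simulated
#' replicates. Also reports the fraction of observations falling
#' outside the simulation-based 90% prediction interval (< 10% is the
#' conventional acceptance rule).
#'
#' @param fit A `pk_fit` (or [pop_model()] with `data` supplied).
#' @param data A [pk_dataset()]; defaults to the fit's data.
#' @param n_sim Number of simulated replicates (study convention 1000).
#' @param bins Numeric vector of bin edges, or NULL to bin on the
#'   distinct nominal observation times.
#' @param seed Integer seed.
#' @return List of class `pc_vpc`: `bands` data.frame per bin
#'   (observed and simulated-CI percentiles), `outside_fraction`,
#'   `n_obs`.
#' @export
pc_vpc <- function(fit, data = NULL, n_sim = 1000, bins = NULL, seed = 1) {
  if (inherits(fit, "pk_fit")) {
    model <- fit$model
    if (is.null(data)) data <- fit$data
  } else model <- fit
  gof <- gof_quantities(model, data)
  times <- gof$TIME
  if (is.null(bins)) {
    centers <- sort(unique(times))
    bin_of <- match(times, centers)
  } else {
    bin_of <- findInterval(times, bins, all.inside = TRUE)
    centers <- tapply(times, bin_of, stats::median)
  }
  # merge empty/singleton handling happens naturally: bins come from data
  pred <- gof$PRED
  pc_obs <- gof$DV
  med_pred_bin <- tapply(pred, bin_of, stats::median)
  pc_obs <- gof$DV * med_pred_bin[as.character(bin_of)] / pred

  probs <- c(0.05, 0.5, 0.95)
  obs_pct <- t(vapply(split(pc_obs, bin_of), stats::quantile, numeric(3),
                      probs = probs))

  sim_pct <- array(NA_real_, c(n_sim, nrow(obs_pct), 3))
  pc_sim_all <- vector("list", n_sim)
  with_seed_(seed, {
    for (s in seq_len(n_sim)) {
      sim_dv <- .simulate_design_dv(model, data)
      pc_sim <- sim_dv * med_pred_bin[as.character(bin_of)] / pred
      pc_sim_all[[s]] <- pc_sim
      sim_pct[s, , ] <- t(vapply(split(pc_sim, bin_of), stats::quantile,
                                 numeric(3), probs = probs))
    }
  })
  ci_lo <- apply(sim_pct, c(2, 3), stats::quantile, probs = 0.025)
  ci_hi <- apply(sim_pct, c(2, 3), stats::quantile, probs = 0.975)
  sim_med <- apply(sim_pct, c(2, 3), stats::median)

  # simulation-based 90% PI per bin, pooled over replicates
  pool <- split(unlist(pc_sim_all), rep(bin_of, n_sim))
  pi90 <- t(vapply(pool, stats::quantile, numeric(2), probs = c(0.05, 0.95)))
  outside <- mapply(function(y, b) y < pi90[b, 1] | y > pi90[b, 2],
                    pc_obs, as.character(bin_of))
  bands <- data.frame(
    bin_time = as.numeric(centers), n = as.integer(table(bin_of)),
    obs_p5 = obs_pct[, 1], obs_p50 = obs_pct[, 2], obs_p95 = obs_pct[, 3],
    sim_p5_lo = ci_lo[, 1], sim_p5_med = sim_med[, 1], sim_p5_hi = ci_hi[, 1],
    sim_p50_lo = ci_lo[, 2], sim_p50_med = sim_med[, 2],
    sim_p50_hi = ci_hi[, 2],
    sim_p95_lo = ci_lo[, 3], sim_p95_med = sim_med[, 3],
    sim_p95_hi = ci_hi[, 3])
  rownames(bands) <- NULL
  structure(list(bands = bands, outside_fraction = mean(outside),
                 n_obs = length(pc_obs)),
            class = "pc_vpc")
}

# simulate one replicate of DV at the observed design under the model
.simulate_design_dv <- function(model, data) {
  out <- numeric(0)
  om <- model$omega
  for (id in subject_ids(data)) {
    ctx <- .subject_context(subject_data(data, id), model)
    if (!length(ctx$dv)) next
    eta <- stats::rnorm(ctx$d, 0, sqrt(om))
    f <- .cond_f(eta, ctx)
    g <- ctx$sp2 * f * f + ctx$sa2
    out <- c(out, f + stats::rnorm(length(f), 0, sqrt(g)))
  }
  out
}

# evaluate a function under a temporary RNG state
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
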