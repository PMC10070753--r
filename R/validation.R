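# External validation: relative prediction errors and the
# MDPE / MAPE / F20 / F30 acceptance criteria, under population
# prediction and MAP-forecasting scenarios.

#' Relative prediction-error metrics
#'
#' \eqn{PE\%_j = 100 (pred_j - obs_j) / obs_j}; MDPE is the median PE%
#' (bias), MAPE the median |PE%| (precision), and F20/F30 the
#' percentage of PE% within +/-20% and +/-30%. The conventional
#' clinical acceptance criteria are MDPE within +/-20%, MAPE <= 30%,
#' F20 >= 35% and F30 >= 50%.
#'
#' @param obs Observed concentrations (> 0; zeros are excluded with a
#'   warning).
#' @param pred Predicted concentrations, same length.
#' @return List of class `validation_metrics`: `pe` (PE% vector),
#'   `mdpe`, `mape`, `f20`, `f30`, `pass` (logical, all four criteria),
#'   `criteria` (named logical vector).
#' @export
#' @examples
#' prediction_errors(obs = c(10, 20, 10), pred = c(9, 21, 13))
prediction_errors <- function(obs, pred) {
  stopifnot(length(obs) == length(pred))
  bad <- obs <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive observation(s) excluded from PE%")
    obs <- obs[!bad]
    pred <- pred[!bad]
  }
  pe <- 100 * (pred - obs) / obs
  mdpe <- stats::median(pe)
  mape <- stats::median(abs(pe))
  f20 <- 100 * mean(abs(pe) <= 20)
  f30 <- 100 * mean(abs(pe) <= 30)
  criteria <- c(MDPE = abs(mdpe) <= 20, MAPE = mape <= 30,
                F20 = f20 >= 35, F30 = f30 >= 50)
  structure(list(pe = pe, mdpe = mdpe, mape = mape, f20 = f20, f30 = f30,
                 pass = all(criteria), criteria = criteria),
            class = "validation_metrics")
}

#' @export
print.validation_metrics <- function(x, ...) {
  cat(sprintf("MDPE %.2f%%, MAPE %.2f%%, F20 %.1f%%, F30 %.1f%% -> %s\n",
              x$mdpe, x$mape, x$f20, x$f30,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' External validation of a fitted model on an independent cohort
#'
#' Two scenarios: `"none"` predicts every observation from the
#' population model (eta = 0, covariates only); `"first_obs"` performs
#' MAP Bayesian forecasting, estimating each subject's random effects
#' from their first post-dose observation alone and predicting the
#' remaining observations at the conditional mode. In the `first_obs`
#' scenario metrics are computed over the post-first observations only.
#' Subjects missing a covariate required by the model are excluded with
#' a message, as are subjects without usable observations.
#'
#' @param fit A `pk_fit` or [pop_model()].
#' @param ext_data External [pk_dataset()].
#' @param scenario `"none"` or `"first_obs"`.
#' @return A `validation_metrics` object; attributes `n_subjects`,
#'   `n_pairs`, `excluded` (IDs), `scenario`.
#' @export
external_validate <- function(fit, ext_data, scenario = c("none", "first_obs")) {
  scenario <- match.arg(scenario)
  model <- if (inherits(fit, "pk_fit")) fit$model else fit
  obs_all <- numeric(0)
  pred_all <- numeric(0)
  excluded <- character(0)
  used <- 0L
  for (id in subject_ids(ext_data)) {
    subj <- subject_data(ext_data, id)
    needed <- vapply(model$effects, function(e) e$covariate, "")
    if (length(needed) &&
        any(vapply(needed, function(nm)
          is.null(subj$covs[[nm]]) || is.na(subj$covs[[nm]]), TRUE))) {
      message("subject ", id, " excluded: missing covariate(s) ",
              paste(needed, collapse = ", "))
      excluded <- c(excluded, id)
      next
    }
    if (!length(subj$dv) ||
        (scenario == "first_obs" && length(subj$dv) < 2)) {
      excluded <- c(excluded, id)
      next
    }
    ctx <- .subject_context(subj, model)
    if (scenario == "none") {
      pred <- .cond_f(rep(0, ctx$d), ctx)
      obs_all <- c(obs_all, ctx$dv)
      pred_all <- c(pred_all, pred)
    } else {
      ctx1 <- ctx
      ctx1$times <- ctx$times[1]
      ctx1$dv <- ctx$dv[1]
      eta_hat <- .estimate_etas(ctx1)$eta
      pred <- .cond_f(eta_hat, ctx)
      obs_all <- c(obs_all, ctx$dv[-1])
      pred_all <- c(pred_all, pred[-1])
    }
    used <- used + 1L
  }
  if (!length(obs_all)) stop("no usable external observations")
  out <- prediction_errors(obs_all, pred_all)
  attr(out, "n_subjects") <- used
  attr(out, "n_pairs") <- length(out$pe)
  attr(out, "excluded") <- excluded
  attr(out, "scenario") <- scenario
  out
}
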