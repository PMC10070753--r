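#' Covariate effect on a structural parameter
#'
#' Constructs the description of one covariate-parameter relationship.
#' Continuous covariates are scaled by a reference value (typically the
#' population median); binary covariates enter as 0/1 indicators.
#'
#' @param param Target structural parameter: "CL", "V1", "Q" or "V2".
#' @param covariate Covariate column name (e.g. "HNF").
#' @param form One of "linear", "power", "exponential", "categorical".
#' @param theta2 Effect coefficient.
#' @param ref Reference covariate value (required and > 0 for the
#'   continuous forms; ignored for "categorical").
#'
#' @return An object of class `covariate_effect`.
#' @export
#' @examples
#' covariate_effect("Q", "HNF", "power", theta2 = -0.58, ref = 617.96)
covariate_effect <- function(param, covariate, form, theta2 = 0, ref = NULL) {
  form <- match.arg(form, c("linear", "power", "exponential", "categorical"))
  stopifnot(param %in% c("CL", "V1", "Q", "V2"))
  if (form != "categorical") {
    if (is.null(ref) || ref <= 0)
      stop("continuous covariate forms require a positive reference value")
  } else {
    ref <- NA_real_
  }
  structure(list(param = param, covariate = covariate, form = form,
                 theta2 = theta2, ref = ref),
            class = "covariate_effect")
}

#' Apply a covariate submodel to a typical parameter value
#'
#' Functional forms for covariate effects:
#' linear \eqn{\theta_1 + \theta_2 (cov/ref)};
#' power \eqn{\theta_1 (cov/ref)^{\theta_2}};
#' exponential \eqn{\theta_1 \theta_2^{cov/ref}};
#' categorical \eqn{\theta_1 \theta_2^{cov}} with cov in \{0, 1\}.
#' The linear form is applied exactly as written, so it does not return
#' \eqn{\theta_1} at the reference covariate (its null coefficient is 0;
#' the multiplicative forms are null at \eqn{\theta_2 = 1} for
#' exponential/categorical and \eqn{\theta_2 = 0} for power).
#'
#' @param form Effect form (see [covariate_effect()]).
#' @param theta1 Base (typical) parameter value.
#' @param theta2 Effect coefficient.
#' @param cov Individual covariate value.
#' @param ref Reference covariate value (continuous forms).
#'
#' @return Adjusted parameter value (vectorized over `cov`).
#' @export
#' @examples
#' apply_covariate("power", 245, -0.58, cov = 617.96, ref = 617.96) # 245
apply_covariate <- function(form, theta1, theta2, cov, ref = NULL) {
  form <- match.arg(form, c("linear", "power", "exponential", "categorical"))
  val <- switch(form,
    linear = theta1 + theta2 * (cov / ref),
    power = theta1 * (cov / ref)^theta2,
    exponential = theta1 * theta2^(cov / ref),
    categorical = theta1 * theta2^cov)
  if (any(!is.finite(val)) || any(val <= 0))
    stop("covariate effect drove the parameter non-positive or non-finite")
  val
}

#' Typical individual parameters given covariates
#'
#' Applies every covariate effect in a model to its target structural
#' parameter for one subject's covariate record.
#'
#' @param model A [pop_model()] object.
#' @param covs Named list / one-row data.frame of covariate values; only
#'   covariates referenced by the model's effects are required.
#'
#' @return Named numeric vector `c(CL=, V1=, Q=, V2=)` (L/h, L, L/h, L).
#' @export
typical_params <- function(model, covs = NULL) {
  p <- model$theta
  for (ef in model$effects) {
    x <- covs[[ef$covariate]]
    if (is.null(x) || is.na(x))
      stop("covariate '", ef$covariate, "' required by the model is missing")
    p[ef$param] <- apply_covariate(ef$form, p[ef$param], ef$theta2, x, ef$ref)
  }
  p
}

#' Individual parameters from typical values and random effects
#'
#' Between-subject variability enters through an exponential model,
#' \eqn{P_i = P_{typ} e^{\eta_P}}, so parameters are log-normally
#' distributed across subjects.
#'
#' @param model A [pop_model()] object.
#' @param covs Covariate record for the subject (see [typical_params()]).
#' @param eta Named or positional numeric vector of random effects in the
#'   order CL, V1, Q, V2 (missing entries treated as 0).
#'
#' @return Named numeric vector of individual `CL`, `V1`, `Q`, `V2`.
#' @export
individual_params <- function(model, covs = NULL, eta = c(0, 0, 0, 0)) {
  p <- typical_params(model, covs)
  e <- rep(0, 4)
  names(e) <- names(p)
  if (!is.null(names(eta))) e[names(eta)] <- eta else e[seq_along(eta)] <- eta
  p * exp(e)
}
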