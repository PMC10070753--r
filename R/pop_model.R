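#' Population pharmacokinetic model specification
#'
#' Bundles the fixed effects (typical two-compartment parameters and
#' covariate-effect coefficients), the diagonal between-subject
#' variance matrix Omega (variances of log-scale random effects) and the
#' combined residual-error model.
#'
#' @param theta Named numeric vector `c(CL=, V1=, Q=, V2=)`, all > 0.
#' @param effects List of [covariate_effect()] objects (may be empty).
#' @param omega Named numeric vector of BSV variances (omega^2) for a
#'   subset of `c("CL","V1","Q","V2")`; parameters absent from `omega`
#'   carry no random effect. Reported as %CV via `100*sqrt(omega^2)`.
#' @param sigma Named numeric vector `c(prop=, add=)`: proportional SD
#'   fraction and additive SD (ng/mL); not both zero.
#'
#' @return An object of class `pop_model`.
#' @export
#' @examples
#' m <- pop_model(theta = c(CL = 32.9, V1 = 32.5, Q = 245, V2 = 83.5),
#'                effects = list(covariate_effect("Q", "HNF", "power",
#'                                                -0.58, 617.96)),
#'                omega = c(CL = 0.0767, V1 = 0.1608, Q = 0.032, V2 = 0.1664),
#'                sigma = c(prop = 0.139, add = 2.88))
pop_model <- function(theta, effects = list(), omega, sigma) {
  stopifnot(all(c("CL", "V1", "Q", "V2") %in% names(theta)),
            all(theta > 0),
            all(names(omega) %in% c("CL", "V1", "Q", "V2")),
            all(omega >= 0),
            all(c("prop", "add") %in% names(sigma)),
            all(sigma >= 0), any(sigma > 0))
  if (inherits(effects, "covariate_effect")) effects <- list(effects)
  theta <- theta[c("CL", "V1", "Q", "V2")]
  structure(list(theta = theta, effects = effects,
                 omega = omega, sigma = sigma),
            class = "pop_model")
}

#' @export
print.pop_model <- function(x, ...) {
  cat("Population PK model (two-compartment IV)\n")
  cat("  theta:", paste(sprintf("%s=%.4g", names(x$theta), x$theta),
                        collapse = ", "), "\n")
  for (ef in x$effects)
    cat(sprintf("  effect: %s on %s (%s), theta2=%.4g, ref=%.4g\n",
                ef$covariate, ef$param, ef$form, ef$theta2, ef$ref))
  if (length(x$omega))
    cat("  BSV %CV:", paste(sprintf("%s=%.1f", names(x$omega),
                                    100 * sqrt(x$omega)), collapse = ", "), "\n")
  cat(sprintf("  residual: prop=%.4g (CV), add=%.4g ng/mL\n",
              x$sigma["prop"], x$sigma["add"]))
  invisible(x)
}

# %CV (as printed in parameter tables) -> variance of log-normal eta
cv_to_omega2 <- function(cv_pct) (cv_pct / 100)^2

#' Published basic (covariate-free) nalbuphine model
#'
#' Typical two-compartment parameters, BSV and combined residual error
#' for intravenous nalbuphine during anesthesia induction, before any
#' covariate is added (CL 32.9 L/h, V1 31 L, Q 261 L/h, V2 85.9 L).
#'
#' @return A [pop_model()] object.
#' @export
nalbuphine_basic_model <- function() {
  pop_model(
    theta = c(CL = 32.9, V1 = 31, Q = 261, V2 = 85.9),
    effects = list(),
    omega = c(CL = cv_to_omega2(27.7), V1 = cv_to_omega2(38.9),
              Q = cv_to_omega2(35.5), V2 = cv_to_omega2(36.5)),
    sigma = c(prop = 0.137, add = 2.90))
}

#' Published final nalbuphine model (HNF power effect on Q)
#'
#' Final covariate model: CL 32.9 L/h, V1 32.5 L, V2 83.5 L and
#' Q = 245 * (HNF / 617.96)^-0.58 L/h, where HNF is the hourly net fluid
#' volume infused during surgery (mL/h) referenced to the study
#' population mean. BSV %CV: CL 27.7, V1 40.1, Q 17.9, V2 40.8;
#' residual error: proportional 0.139 (CV), additive 2.88 ng/mL.
#'
#' @param hnf_ref Reference HNF value (mL/h); defaults to the study mean
#'   617.96 used in the published model equation (the study median was
#'   563.6).
#'
#' @return A [pop_model()] object.
#' @export
nalbuphine_final_model <- function(hnf_ref = 617.96) {
  pop_model(
    theta = c(CL = 32.9, V1 = 32.5, Q = 245, V2 = 83.5),
    effects = list(covariate_effect("Q", "HNF", "power",
                                    theta2 = -0.58, ref = hnf_ref)),
    omega = c(CL = cv_to_omega2(27.7), V1 = cv_to_omega2(40.1),
              Q = cv_to_omega2(17.9), V2 = cv_to_omega2(40.8)),
    sigma = c(prop = 0.139, add = 2.88))
}
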