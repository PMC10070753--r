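# Stepwise covariate modeling: missingness screen, correlation pruning,
# two-stage forward inclusion (screen-in at dOFV 3.84 one-by-one, then
# sequential addition to the running base at 6.63), backward elimination
# at 7.88, and a 20%-impact retention filter.

#' Default stepwise selection configuration
#'
#' Thresholds of the covariate analysis: covariates with more than 20%
#' missingness are dropped; covariate pairs with |r| > 0.7 are pruned to
#' one clinically preferred member; forward screen-in requires an OFV
#' drop > 3.84 (p < 0.05, df 1), sequential forward addition > 6.63
#' (p < 0.01), backward elimination retains an effect only if its
#' removal raises the OFV by > 7.88 (p < 0.005); a retained effect must
#' move its parameter by strictly more than 20% across the observed
#' covariate range.
#'
#' @param missing_max Maximum missingness fraction (default 0.2).
#' @param cor_max Correlation ceiling (default 0.7).
#' @param screen_in,forward,backward Delta-OFV thresholds (3.84, 6.63,
#'   7.88).
#' @param impact Impact threshold as a fraction (default 0.2).
#' @param forms Continuous-covariate forms tried per candidate pair.
#' @param binary_forms Forms tried for binary covariates.
#' @return A list of class `scm_config`.
#' @export
scm_config <- function(missing_max = 0.2, cor_max = 0.7, screen_in = 3.84,
                       forward = 6.63, backward = 7.88, impact = 0.2,
                       forms = c("linear", "power", "exponential"),
                       binary_forms = "categorical") {
  stopifnot(screen_in > 0, forward >= screen_in, backward > 0)
  structure(list(missing_max = missing_max, cor_max = cor_max,
                 screen_in = screen_in, forward = forward,
                 backward = backward, impact = impact, forms = forms,
                 binary_forms = binary_forms),
            class = "scm_config")
}

#' Prune collinear covariates
#'
#' Computes pairwise Pearson correlations (point-biserial for
#' binary/continuous pairs), groups covariates connected by
#' |r| > `cor_max`, and keeps a single member per group: the first in
#' `prefer` order (clinical preference), falling back to column order.
#' Constant columns and columns with missingness above `missing_max`
#' are excluded with a warning.
#'
#' @param cov_table data.frame of per-subject covariates (no ID column
#'   needed; non-numeric columns are ignored).
#' @param prefer Character vector of covariate names in decreasing
#'   clinical preference.
#' @param cor_max Correlation ceiling.
#' @param missing_max Maximum missingness fraction.
#' @return List with `keep` (character vector), `dropped`
#'   (named character vector, value = reason) and `correlation` matrix.
#' @export
correlation_screen <- function(cov_table, prefer = character(),
                               cor_max = 0.7, missing_max = 0.2) {
  num <- cov_table[vapply(cov_table, is.numeric, TRUE)]
  if (nrow(num) < 3) stop("need at least 3 subjects for correlation screening")
  dropped <- character(0)
  miss <- vapply(num, function(x) mean(is.na(x)), 0)
  for (nm in names(num)[miss > missing_max])
    dropped[nm] <- sprintf("missingness %.0f%% exceeds %.0f%%",
                           100 * miss[nm], 100 * missing_max)
  num <- num[setdiff(names(num), names(dropped))]
  const <- vapply(num, function(x) stats::var(x, na.rm = TRUE), 0) == 0
  if (any(const)) {
    warning("constant covariates excluded: ",
            paste(names(num)[const], collapse = ", "))
    for (nm in names(num)[const]) dropped[nm] <- "constant"
    num <- num[!const]
  }
  cm <- suppressWarnings(stats::cor(num, use = "pairwise.complete.obs"))
  # union-find over |r| > cor_max edges
  nms <- colnames(cm)
  parent <- seq_along(nms)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(nms)) for (j in seq_len(i - 1L))
    if (isTRUE(abs(cm[i, j]) > cor_max)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  roots <- vapply(seq_along(nms), find, 0L)
  keep <- character(0)
  rank_of <- function(nm) {
    r <- match(nm, prefer)
    if (is.na(r)) length(prefer) + match(nm, nms) else r
  }
  for (r in unique(roots)) {
    members <- nms[roots == r]
    best <- members[order(vapply(members, rank_of, 0))][1]
    keep <- c(keep, best)
    for (nm in setdiff(members, best))
      dropped[nm] <- paste0("|r| > ", cor_max, " with ", best)
  }
  list(keep = keep, dropped = dropped, correlation = cm)
}

# fit base + one extra effect, warm-started from the base estimates
.fit_with_effect <- function(data, base_fit, effect, control) {
  m <- base_fit$model
  m$effects <- c(m$effects, list(effect))
  fit_model(data, m, covariance = FALSE, control = control)
}

# null coefficient and starting value per form
.null_theta2 <- function(form) if (form %in% c("exponential", "categorical")) 1 else 0
.start_theta2 <- function(form) {
  switch(form, linear = 0.05, power = 0.1, exponential = 1.1,
         categorical = 1.1)
}

# build the candidate effect for a (param, covariate, form) triple
.candidate_effect <- function(param, covariate, form, data) {
  ref <- NULL
  if (form != "categorical") {
    x <- data$covariates[[covariate]]
    ref <- stats::median(x, na.rm = TRUE)
  }
  covariate_effect(param, covariate, form, theta2 = .start_theta2(form),
                   ref = ref)
}

.is_binary <- function(x) all(stats::na.omit(x) %in% c(0, 1))

#' Test candidate covariate effects against a base model
#'
#' Each candidate covariate-parameter pair is fitted as base + effect
#' under every configured functional form; the best form (lowest OFV)
#' represents the pair. A candidate is accepted when its OFV drop
#' exceeds `threshold`.
#'
#' @param data A [pk_dataset()].
#' @param base_fit A `pk_fit` of the base model.
#' @param candidates data.frame with columns `param`, `covariate`.
#' @param threshold Delta-OFV acceptance threshold.
#' @param config An [scm_config()].
#' @param control Outer-optimizer control passed to [fit_model()].
#' @return data.frame sorted by decreasing OFV drop with columns
#'   `param`, `covariate`, `form`, `ofv`, `dofv`, `accepted`; attribute
#'   `fits` holds the winning `pk_fit` per candidate row.
#' @export
forward_step <- function(data, base_fit, candidates, threshold,
                         config = scm_config(),
                         control = list(iter.max = 150, rel.tol = 1e-7)) {
  if (!nrow(candidates))
    return(data.frame(param = character(), covariate = character(),
                      form = character(), ofv = numeric(),
                      dofv = numeric(), accepted = logical()))
  rows <- list()
  fits <- list()
  for (i in seq_len(nrow(candidates))) {
    pa <- candidates$param[i]
    cv <- candidates$covariate[i]
    forms <- if (.is_binary(data$covariates[[cv]]))
      config$binary_forms else config$forms
    best <- NULL
    for (fo in forms) {
      ef <- .candidate_effect(pa, cv, fo, data)
      fit <- try(.fit_with_effect(data, base_fit, ef, control), silent = TRUE)
      if (inherits(fit, "try-error")) next
      if (is.null(best) || fit$ofv < best$ofv) best <- fit
    }
    if (is.null(best)) {
      rows[[i]] <- data.frame(param = pa, covariate = cv, form = NA_character_,
                              ofv = NA_real_, dofv = NA_real_,
                              accepted = FALSE)
      fits[i] <- list(NULL)
      next
    }
    ef_win <- best$model$effects[[length(best$model$effects)]]
    rows[[i]] <- data.frame(param = pa, covariate = cv, form = ef_win$form,
                            ofv = best$ofv, dofv = base_fit$ofv - best$ofv,
                            accepted = (base_fit$ofv - best$ofv) > threshold)
    fits[[i]] <- best
  }
  out <- do.call(rbind, rows)
  ord <- order(-ifelse(is.na(out$dofv), -Inf, out$dofv))
  out <- out[ord, ]
  rownames(out) <- NULL
  attr(out, "fits") <- fits[ord]
  out
}

#' Backward elimination of covariate effects
#'
#' Repeatedly removes the least-supported effect from a full model:
#' each effect is deleted in turn and refitted; an effect is retained
#' only when its removal raises the OFV by more than `threshold`.
#' Iterates until all remaining effects are supported.
#'
#' @param data A [pk_dataset()].
#' @param full_fit A `pk_fit` of the full covariate model.
#' @param threshold Delta-OFV retention threshold (7.88 by default).
#' @param control Optimizer control.
#' @return List with `fit` (final `pk_fit`), `trace` data.frame of
#'   removal tests (`effect`, `ofv_without`, `dofv`, `removed`).
#' @export
backward_step <- function(data, full_fit, threshold = 7.88,
                          control = list(iter.max = 150, rel.tol = 1e-7)) {
  fit <- full_fit
  trace <- list()
  repeat {
    effects <- fit$model$effects
    if (!length(effects)) break
    worst <- NULL
    for (i in seq_along(effects)) {
      m <- fit$model
      m$effects <- m$effects[-i]
      # restart reduced model from its own natural start
      red <- try(fit_model(data, m, covariance = FALSE, control = control),
                 silent = TRUE)
      if (inherits(red, "try-error")) next
      dofv <- red$ofv - fit$ofv   # increase on removal
      lab <- paste0(effects[[i]]$covariate, " on ", effects[[i]]$param)
      trace[[length(trace) + 1L]] <-
        data.frame(effect = lab, ofv_without = red$ofv, dofv = dofv,
                   removed = NA)
      if (is.null(worst) || dofv < worst$dofv)
        worst <- list(i = i, dofv = dofv, fit = red,
                      trace_row = length(trace))
    }
    if (is.null(worst)) break
    if (worst$dofv <= threshold) {
      trace[[worst$trace_row]]$removed <- TRUE
      fit <- worst$fit
    } else break
  }
  tr <- if (length(trace)) do.call(rbind, trace) else
    data.frame(effect = character(), ofv_without = numeric(),
               dofv = numeric(), removed = logical())
  tr$removed[is.na(tr$removed)] <- FALSE
  list(fit = fit, trace = tr)
}

#' Clinical-impact filter for a fitted covariate effect
#'
#' Evaluates the target parameter at the extremes of the observed
#' covariate range (conventionally the 10th and 90th percentiles)
#' relative to the reference value, and keeps the effect only when the
#' maximum deviation strictly exceeds `impact` (20% by default).
#'
#' @param model A [pop_model()] containing the effect.
#' @param effect_index Index of the effect in `model$effects`.
#' @param cov_range Length-2 numeric: lower/upper covariate values
#'   (for categorical effects use c(0, 1)).
#' @param impact Deviation threshold as a fraction.
#' @return List with `keep` (logical) and `deviation` (named vector of
#'   fractional deviations at the two extremes).
#' @export
impact_filter <- function(model, effect_index, cov_range, impact = 0.2) {
  ef <- model$effects[[effect_index]]
  base <- model$theta[[ef$param]]
  ref_val <- if (ef$form == "categorical") {
    base * ef$theta2^0
  } else {
    apply_covariate(ef$form, base, ef$theta2, ef$ref, ef$ref)
  }
  at <- vapply(cov_range, function(x)
    apply_covariate(ef$form, base, ef$theta2, x, ef$ref), 0)
  dev <- at / ref_val - 1
  names(dev) <- c("low", "high")
  list(keep = max(abs(dev)) > impact, deviation = dev)
}

#' Full stepwise covariate search
#'
#' Orchestrates the covariate analysis on a fitted base model:
#' correlation pruning of the candidate covariates, one-by-one
#' screen-in against the base model (dOFV > `screen_in`), sequential
#' forward addition of the remaining screened candidates to the running
#' base (dOFV > `forward`, largest drop first), backward elimination
#' (dOFV > `backward` to retain), and the strict 20%-impact filter over
#' the 10th-90th percentile covariate range.
#'
#' @param data A [pk_dataset()] carrying the candidate covariates.
#' @param base_model Starting [pop_model()] without covariate effects.
#' @param candidates data.frame with columns `param`, `covariate`; row
#'   order breaks delta-OFV ties deterministically.
#' @param config An [scm_config()].
#' @param prefer Clinical preference order for [correlation_screen()].
#' @param control Optimizer control for the candidate fits.
#' @return List with `final_fit` (`pk_fit`), `trace` (data.frame of all
#'   tested models: `step`, `description`, `form`, `ofv`, `dofv`,
#'   `comparator`, `decision`), `screen` (correlation screen result).
#' @export
stepwise_search <- function(data, base_model, candidates,
                            config = scm_config(), prefer = character(),
                            control = list(iter.max = 150, rel.tol = 1e-7)) {
  screen <- correlation_screen(
    data$covariates[unique(candidates$covariate)],
    prefer = prefer, cor_max = config$cor_max,
    missing_max = config$missing_max)
  candidates <- candidates[candidates$covariate %in% screen$keep, ,
                           drop = FALSE]
  base_fit <- fit_model(data, base_model, covariance = FALSE,
                        control = control)
  trace <- list()
  note <- function(step, description, form, ofv, dofv, comparator, decision)
    trace[[length(trace) + 1L]] <<- data.frame(
      step = step, description = description, form = form, ofv = ofv,
      dofv = dofv, comparator = comparator, decision = decision)
  note("base", "base two-compartment model", NA, base_fit$ofv, NA, NA, "kept")

  # stage 1: screen each candidate one-by-one against the base model
  fw <- forward_step(data, base_fit, candidates, config$screen_in,
                     config, control)
  for (i in seq_len(nrow(fw)))
    note("screen-in",
         paste0("add ", fw$covariate[i], " on ", fw$param[i], " to base"),
         fw$form[i], fw$ofv[i], fw$dofv[i], "base",
         if (isTRUE(fw$accepted[i])) "candidate" else "rejected")
  pool <- fw[fw$accepted %in% TRUE, c("param", "covariate")]

  # stage 2: sequential addition to the running base at the stricter
  # threshold, largest drop first
  run_fit <- base_fit
  while (nrow(pool)) {
    st <- forward_step(data, run_fit, pool, config$forward, config, control)
    best <- which(st$accepted)[1]
    for (i in seq_len(nrow(st)))
      note("forward",
           paste0("add ", st$covariate[i], " on ", st$param[i]),
           st$form[i], st$ofv[i], st$dofv[i], "running base",
           if (!is.na(best) && i == best) "added"
           else if (isTRUE(st$accepted[i])) "deferred" else "rejected")
    if (is.na(best)) break
    run_fit <- attr(st, "fits")[[best]]
    pool <- pool[!(pool$param == st$param[best] &
                   pool$covariate == st$covariate[best]), , drop = FALSE]
    rejected <- st[st$accepted %in% FALSE, c("param", "covariate")]
    pool <- pool[!paste(pool$param, pool$covariate) %in%
                 paste(rejected$param, rejected$covariate), , drop = FALSE]
  }

  # backward elimination
  bw <- backward_step(data, run_fit, config$backward, control)
  for (i in seq_len(nrow(bw$trace)))
    note("backward", paste0("remove ", bw$trace$effect[i]), NA,
         bw$trace$ofv_without[i], bw$trace$dofv[i], "full model",
         if (bw$trace$removed[i]) "removed" else "retained")
  fit <- bw$fit

  # impact filter at final-model assembly (strict > 20% over 10th-90th
  # percentile covariate range)
  i <- 1L
  while (i <= length(fit$model$effects)) {
    ef <- fit$model$effects[[i]]
    x <- data$covariates[[ef$covariate]]
    rng <- if (.is_binary(x)) c(0, 1) else
      stats::quantile(x, c(0.1, 0.9), na.rm = TRUE, names = FALSE)
    imp <- impact_filter(fit$model, i, rng, config$impact)
    lab <- paste0(ef$covariate, " on ", ef$param)
    if (!imp$keep) {
      m <- fit$model
      m$effects <- m$effects[-i]
      fit <- fit_model(data, m, covariance = FALSE, control = control)
      note("impact", paste0("drop ", lab, " (max deviation ",
                            sprintf("%.1f%%", 100 * max(abs(imp$deviation))),
                            " <= 20%)"), NA, fit$ofv, NA, "final", "dropped")
    } else {
      note("impact", paste0("keep ", lab, " (max deviation ",
                            sprintf("%.1f%%", 100 * max(abs(imp$deviation))),
                            " > 20%)"), NA, fit$ofv, NA, "final", "kept")
      i <- i + 1L
    }
  }
  list(final_fit = fit, trace = do.call(rbind, trace), screen = screen)
}
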