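# FOCE with eta-epsilon interaction: inner per-subject conditional-mode
# search, Laplace-type marginal -2LL with a Fisher (Gauss-Newton)
# curvature term, outer maximum-likelihood optimization on transformed
# parameters, finite-difference covariance step, EBEs and shrinkage.

# expand an eta vector over BSV'd parameters into the 4-vector multiplier
.eta_expand <- function(eta, bsv_idx) {
  e <- c(0, 0, 0, 0)
  e[bsv_idx] <- eta
  e
}

#' Conditional (penalized) objective for one subject
#'
#' The -2 log joint density of a subject's observations and random
#' effects, up to no additive constant:
#' \deqn{\sum_j [\log 2\pi g_j(\eta) + (y_j - f_j(\eta))^2 / g_j(\eta)]
#'       + \eta' \Omega^{-1} \eta + \log\det 2\pi\Omega,}
#' with the residual variance \eqn{g} evaluated at \eqn{\eta} itself
#' (the eta-epsilon interaction). Minimizing over \eqn{\eta} yields the
#' empirical Bayes estimate.
#'
#' @param eta Numeric vector of random effects, one per BSV'd parameter
#'   (order of `model$omega`).
#' @param subject Subject record from [subject_data()].
#' @param model A [pop_model()].
#' @return Scalar objective value.
#' @export
conditional_objective <- function(eta, subject, model) {
  ctx <- .subject_context(subject, model)
  .cond_obj(eta, ctx)
}

# precompute everything constant in eta for one subject
.subject_context <- function(subject, model) {
  typ <- typical_params(model, subject$covs)
  bsv_names <- names(model$omega)
  bsv_idx <- match(bsv_names, c("CL", "V1", "Q", "V2"))
  om <- model$omega
  if (any(om <= 0))
    stop("singular Omega: BSV variance is zero for ",
         paste(bsv_names[om <= 0], collapse = ", "),
         "; fix it or drop the random effect")
  d <- length(om)
  list(typ = as.numeric(typ), bsv_idx = as.integer(bsv_idx), d = d,
       om = as.numeric(om),
       oinv = as.numeric(1 / om), ldet2piO = sum(log(2 * pi * om)),
       sp2 = model$sigma[["prop"]]^2, sa2 = model$sigma[["add"]]^2,
       times = as.numeric(subject$times), dv = as.numeric(subject$dv),
       doses = subject$doses,
       dt = as.numeric(subject$doses$time),
       da = as.numeric(subject$doses$amt),
       dd = as.numeric(subject$doses$dur))
}

.cond_f <- function(eta, ctx) {
  p <- ctx$typ * exp(.eta_expand(eta, ctx$bsv_idx))
  .conc_profile_cpp(ctx$times, ctx$dt, ctx$da, ctx$dd,
                    p[1L], p[2L], p[3L], p[4L])
}

.cond_obj <- function(eta, ctx) {
  .cond_obj_cpp(eta, ctx$typ, ctx$bsv_idx, ctx$oinv, ctx$ldet2piO,
                ctx$sp2, ctx$sa2, ctx$times, ctx$dv,
                ctx$dt, ctx$da, ctx$dd)
}

# Jacobian of the concentration profile wrt eta, central differences
.cond_jac <- function(eta, ctx, h = 1e-4) {
  J <- matrix(0, length(ctx$dv), ctx$d)
  for (k in seq_len(ctx$d)) {
    ep <- eta; ep[k] <- ep[k] + h
    em <- eta; em[k] <- em[k] - h
    J[, k] <- (.cond_f(ep, ctx) - .cond_f(em, ctx)) / (2 * h)
  }
  J
}

# Fisher-type curvature of .cond_obj/2 at eta (the FOCE-I linearization):
# Omega^-1 + sum_j [ f'f'^T / g + 0.5 g'g'^T / g^2 ].
.cond_fisher <- function(eta, ctx, h = 1e-4) {
  d <- ctx$d
  M <- diag(ctx$oinv, d)
  if (!length(ctx$dv)) return(M)
  f0 <- .cond_f(eta, ctx)
  J <- .cond_jac(eta, ctx, h)
  g <- ctx$sp2 * f0 * f0 + ctx$sa2
  Jg <- 2 * ctx$sp2 * f0 * J            # dg/deta rows
  M + crossprod(J / sqrt(g)) + 0.5 * crossprod(Jg / g)
}

#' Empirical Bayes estimate of a subject's random effects
#'
#' Minimizes [conditional_objective()] by quasi-Newton (BFGS) search
#' from `start` (default 0) and returns the conditional mode together
#' with the Fisher curvature matrix used by the Laplace/FOCE marginal
#' approximation. A non-positive-definite curvature is floored on its
#' eigenvalues.
#'
#' @param subject Subject record from [subject_data()].
#' @param model A [pop_model()].
#' @param start Starting eta (warm start).
#' @return List with `eta` (the mode), `value` (objective at the mode),
#'   `fisher` (curvature of objective/2), `converged` flag.
#' @export
estimate_etas <- function(subject, model, start = NULL) {
  ctx <- .subject_context(subject, model)
  est <- .estimate_etas(ctx, start)
  M <- .cond_fisher(est$eta, ctx)
  ev <- eigen(M, symmetric = TRUE)
  if (any(ev$values < 1e-10)) {   # eigenvalue flooring
    vals <- pmax(ev$values, 1e-10)
    M <- ev$vectors %*% (vals * t(ev$vectors))
  }
  est$fisher <- M
  est
}

# inner solver: damped Newton in compiled code, quasi-Newton fallback
.estimate_etas <- function(ctx, start = NULL) {
  d <- ctx$d
  if (d == 0L)
    return(list(eta = numeric(0), value = .cond_obj(numeric(0), ctx),
                fisher = matrix(0, 0, 0), converged = TRUE))
  if (is.null(start)) start <- rep(0, d)
  res <- .inner_newton_cpp(as.numeric(start), ctx$typ, ctx$bsv_idx,
                           ctx$oinv, ctx$ldet2piO, ctx$sp2, ctx$sa2,
                           ctx$times, ctx$dv, ctx$dt, ctx$da, ctx$dd,
                           100L, 1e-8)
  if (!isTRUE(res$converged)) {
    opt <- stats::optim(rep(0, d), .cond_obj, ctx = ctx, method = "BFGS",
                        control = list(maxit = 200, reltol = 1e-12,
                                       ndeps = rep(1e-6, d)))
    if (opt$value < res$value)
      res <- list(eta = opt$par, value = opt$value,
                  converged = opt$convergence == 0)
  }
  list(eta = as.numeric(res$eta), value = res$value,
       converged = isTRUE(res$converged))
}

#' FOCE-I objective function value for a whole dataset
#'
#' Sum over subjects of the first-order-conditional approximation to
#' \eqn{-2 \log \int p(y_i | \eta) p(\eta) d\eta}: the model is
#' linearized at each subject's conditional mode \eqn{\hat\eta} (with
#' the residual variance evaluated there - the interaction), giving
#' \deqn{OFV_i = \log\det 2\pi V_i +
#'       \tilde r_i^\top V_i^{-1} \tilde r_i,}
#' with \eqn{V_i = J \Omega J^\top + \mathrm{diag}\, g(\hat\eta)},
#' \eqn{\tilde r_i = y_i - f(\hat\eta) + J \hat\eta} and \eqn{J} the
#' Jacobian of the profile at the mode. Deterministic given data and
#' parameters.
#'
#' @param model A [pop_model()].
#' @param data A [pk_dataset()]; every subject needs >= 1 usable
#'   observation.
#' @param eta_cache Optional environment holding per-subject warm-start
#'   etas (used internally by the outer optimizer).
#' @return Scalar OFV (attribute `etas`: matrix of conditional modes).
#' @export
foce_ofv <- function(model, data, eta_cache = NULL) {
  .foce_ofv_core(model, .subject_list(data), eta_cache)
}

# subject records extracted once so the hot loop avoids repeated
# data.frame subsetting
.subject_list <- function(data) {
  ids <- subject_ids(data)
  stats::setNames(lapply(ids, function(id) subject_data(data, id)), ids)
}

.foce_ofv_core <- function(model, subjects, eta_cache = NULL) {
  ids <- names(subjects)
  total <- 0
  etas <- NULL
  for (id in ids) {
    ctx <- .subject_context(subjects[[id]], model)
    start <- if (!is.null(eta_cache)) eta_cache[[id]] else NULL
    if (is.null(start) || length(start) != ctx$d) start <- rep(0, ctx$d)
    res <- .subject_foce_cpp(start, ctx$typ, ctx$bsv_idx, ctx$oinv,
                             ctx$ldet2piO, ctx$sp2, ctx$sa2,
                             ctx$times, ctx$dv, ctx$dt, ctx$da, ctx$dd,
                             ctx$om, 100L, 1e-8)
    if (!isTRUE(res$converged) && length(ctx$dv)) {
      # fall back to a quasi-Newton mode search from zero
      est <- .estimate_etas(ctx, NULL)
      res2 <- .subject_foce_cpp(est$eta, ctx$typ, ctx$bsv_idx, ctx$oinv,
                                ctx$ldet2piO, ctx$sp2, ctx$sa2,
                                ctx$times, ctx$dv, ctx$dt, ctx$da, ctx$dd,
                                ctx$om, 10L, 1e-8)
      if (is.finite(res2$ofv) &&
          (!is.finite(res$ofv) || res2$ofv < res$ofv)) res <- res2
    }
    if (!is.finite(res$ofv))
      stop("non-finite OFV contribution for subject ", id)
    if (!is.null(eta_cache)) eta_cache[[id]] <- as.numeric(res$eta)
    if (is.null(etas)) etas <- matrix(0, length(ids), ctx$d,
                                      dimnames = list(ids, names(model$omega)))
    etas[id, ] <- as.numeric(res$eta)
    total <- total + res$ofv
  }
  attr(total, "etas") <- etas
  total
}

## ---- parameter packing --------------------------------------------------

# Transformed parameter vector: log theta (4), one entry per covariate
# effect coefficient (raw for linear/power, log for exponential and
# categorical, which must stay positive), log omega^2 per BSV term, and
# log sigma for each non-zero residual component. Zero residual
# components in the starting model stay fixed at zero.
.pack_model <- function(model) {
  p <- log(model$theta)
  names(p) <- paste0("l", names(model$theta))
  for (i in seq_along(model$effects)) {
    ef <- model$effects[[i]]
    v <- if (ef$form %in% c("exponential", "categorical"))
      log(ef$theta2) else ef$theta2
    p <- c(p, stats::setNames(v, paste0("ef", i, "_", ef$covariate,
                                        "_", ef$param)))
  }
  if (length(model$omega))
    p <- c(p, stats::setNames(log(model$omega),
                              paste0("lo2_", names(model$omega))))
  for (s in c("prop", "add"))
    if (model$sigma[[s]] > 0)
      p <- c(p, stats::setNames(log(model$sigma[[s]]), paste0("ls_", s)))
  p
}

# human-readable labels aligned with the packed vector
.packed_labels <- function(model) {
  lab <- names(model$theta)
  for (ef in model$effects)
    lab <- c(lab, paste0(ef$covariate, " on ", ef$param))
  lab <- c(lab, paste0("omega_", names(model$omega)))
  for (s in c("prop", "add"))
    if (model$sigma[[s]] > 0) lab <- c(lab, paste0("sigma_", s))
  lab
}

.unpack_model <- function(packed, template) {
  m <- template
  m$theta[] <- exp(packed[1:4])
  k <- 4L
  for (i in seq_along(m$effects)) {
    k <- k + 1L
    v <- packed[k]
    if (m$effects[[i]]$form %in% c("exponential", "categorical")) v <- exp(v)
    m$effects[[i]]$theta2 <- v
  }
  if (length(m$omega)) {
    m$omega[] <- exp(packed[k + seq_along(m$omega)])
    k <- k + length(m$omega)
  }
  for (s in c("prop", "add"))
    if (template$sigma[[s]] > 0) {
      k <- k + 1L
      m$sigma[[s]] <- exp(packed[k])
    }
  m
}

## ---- outer estimation ---------------------------------------------------

#' Fit a population PK model by FOCE-I
#'
#' Outer maximum-likelihood optimization of [foce_ofv()] over
#' log-transformed structural, BSV-variance and residual parameters
#' (covariate coefficients on their natural scale), with warm-started
#' inner conditional modes. Optionally follows with a finite-difference
#' covariance step for relative standard errors.
#'
#' @param data A [pk_dataset()].
#' @param model Starting [pop_model()]; its structure (covariate
#'   effects, BSV terms, residual components) defines what is estimated.
#' @param covariance Run the covariance step (default TRUE). Skipping it
#'   leaves RSEs as NA; useful inside stepwise searches and bootstraps.
#' @param fix Character vector of parameter labels held at their
#'   starting values, e.g. `c("Q", "V2")` or `"omega_Q"`; labels match
#'   the fit's `estimates$parameter` column (a reduced one-compartment
#'   fit fixes `Q` near zero and `V2`).
#' @param control List: `iter.max`, `rel.tol` for the outer optimizer.
#'
#' @return An object of class `pk_fit`: `model` (fitted), `ofv`, `aic`,
#'   `n_params`, `estimates` (data.frame with natural-scale estimates,
#'   RSE%, shrinkage%), `etas` (EBE matrix), `eps_shrinkage`,
#'   `convergence` flag, `cov_ok` flag, and the `data`.
#' @export
fit_model <- function(data, model, covariance = TRUE, fix = character(),
                      control = list(iter.max = 300, rel.tol = 1e-8)) {
  ids <- subject_ids(data)
  start_full <- .pack_model(model)
  labels <- .packed_labels(model)
  unknown <- setdiff(fix, labels)
  if (length(unknown))
    stop("unknown parameter label(s) in `fix`: ",
         paste(unknown, collapse = ", "))
  free <- !(labels %in% fix)
  np <- sum(free)
  if (np >= length(ids))
    warning("estimating ", np, " parameters from ", length(ids),
            " subjects; the model may be poorly identifiable")
  cache <- new.env(parent = emptyenv())
  subjects <- .subject_list(data)
  expand <- function(p_free) {
    p <- start_full
    p[free] <- p_free
    p
  }
  obj_free <- function(p_free) {
    m <- try(.unpack_model(expand(p_free), model), silent = TRUE)
    if (inherits(m, "try-error")) return(1e10)
    v <- try(as.numeric(.foce_ofv_core(m, subjects, eta_cache = cache)),
             silent = TRUE)
    if (inherits(v, "try-error") || !is.finite(v)) return(1e10)
    v
  }
  # explicit FD gradient with steps well above the warm-start noise
  # floor (~1e-6 OFV units); PORT's internal machine-precision steps
  # would otherwise drown small gradients in that noise and stall
  grad_free <- function(p_free) {
    f0 <- obj_free(p_free)
    vapply(seq_along(p_free), function(i) {
      h <- 1e-4 * max(abs(p_free[i]), 0.5)
      xp <- p_free; xp[i] <- xp[i] + h
      (obj_free(xp) - f0) / h
    }, 0)
  }
  opt <- stats::nlminb(start_full[free], obj_free, gradient = grad_free,
                       control = list(iter.max = control$iter.max %||% 300,
                                      eval.max = 4 * (control$iter.max %||% 300),
                                      rel.tol = control$rel.tol %||% 1e-8))
  opt$par <- expand(opt$par)
  obj <- function(p) obj_free(p[free])
  fitted_model <- .unpack_model(opt$par, model)
  ofv <- foce_ofv(fitted_model, data, eta_cache = cache)
  etas <- attr(ofv, "etas")
  ofv <- as.numeric(ofv)
  converged <- opt$convergence == 0 ||
    grepl("relative convergence|both X|absolute function",
          opt$message %||% "")
  if (!converged) {
    # PORT may stop with "false convergence" on the warm-start noise
    # floor; accept the optimum when no appreciable descent direction
    # remains: probe a few steps along the FD steepest-descent direction
    gr <- vapply(which(free), function(i) {
      h <- 1e-3 * max(abs(opt$par[i]), 1)
      xp <- opt$par; xp[i] <- xp[i] + h
      xm <- opt$par; xm[i] <- xm[i] - h
      (obj(xp) - obj(xm)) / (2 * h)
    }, 0)
    gn <- sqrt(sum(gr^2))
    if (gn < 2) {
      converged <- TRUE
    } else {
      probes <- vapply(c(1e-4, 1e-3, 1e-2), function(s)
        obj_free(opt$par[free] - s * gr / gn), 0)
      converged <- (obj_free(opt$par[free]) - min(probes)) < 0.5
    }
  }

  se_packed <- rep(NA_real_, length(start_full))
  cov_ok <- FALSE
  if (covariance) {
    # deterministic objective (inner modes re-solved from zero) so the
    # finite differences are free of warm-start path dependence
    obj_det <- function(p_free) {
      m <- .unpack_model(expand(p_free), model)
      as.numeric(.foce_ofv_core(m, subjects))
    }
    H <- try(.fd_hessian(obj_det, opt$par[free],
                         f0 = obj_det(opt$par[free]), h = 2e-3),
             silent = TRUE)
    if (!inherits(H, "try-error")) {
      Vc <- try(2 * solve(H), silent = TRUE)  # var = inv(H(-LL)) = 2*inv(H(OFV))
      if (!inherits(Vc, "try-error") && all(diag(Vc) > 0)) {
        se_packed[free] <- sqrt(diag(Vc))
        cov_ok <- TRUE
      }
    }
  }

  res <- .fit_result(data, fitted_model, model, ofv, np, etas,
                     se_packed, opt$par)
  res$convergence <- converged
  res$cov_ok <- cov_ok
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# central-difference Hessian of fn at x
.fd_hessian <- function(fn, x, f0 = NULL, h = 1e-4) {
  n <- length(x)
  hh <- pmax(abs(x), 1) * h
  H <- matrix(0, n, n)
  fp <- fm <- numeric(n)
  if (is.null(f0)) f0 <- fn(x)
  for (i in seq_len(n)) {
    xp <- x; xp[i] <- x[i] + hh[i]
    xm <- x; xm[i] <- x[i] - hh[i]
    fp[i] <- fn(xp); fm[i] <- fn(xm)
    H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / hh[i]^2
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    xpp <- x; xpp[i] <- x[i] + hh[i]; xpp[j] <- x[j] + hh[j]
    xmm <- x; xmm[i] <- x[i] - hh[i]; xmm[j] <- x[j] - hh[j]
    H[i, j] <- H[j, i] <-
      (fn(xpp) - fp[i] - fp[j] + 2 * f0 - fm[i] - fm[j] + fn(xmm)) /
      (2 * hh[i] * hh[j])
  }
  (H + t(H)) / 2
}

# assemble the pk_fit object: natural-scale estimate table with RSEs
# and shrinkages
.fit_result <- function(data, fitted_model, template, ofv, np, etas,
                        se_packed, packed) {
  m <- fitted_model
  rows <- list()
  k <- 0L
  add_row <- function(name, est, rse, shrink = NA_real_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      parameter = name, estimate = est, rse_pct = rse,
      shrinkage_pct = shrink, stringsAsFactors = FALSE)
  }
  for (nm in names(m$theta)) {
    k <- k + 1L
    add_row(nm, m$theta[[nm]], 100 * se_packed[k])  # log scale: RSE ~ SE_log
  }
  for (i in seq_along(m$effects)) {
    k <- k + 1L
    ef <- m$effects[[i]]
    est <- ef$theta2
    rse <- if (ef$form %in% c("exponential", "categorical"))
      100 * se_packed[k] else 100 * se_packed[k] / abs(est)
    add_row(paste0(ef$covariate, " on ", ef$param), est, rse)
  }
  eta_shr <- shrinkage_eta(etas, m$omega)
  for (nm in names(m$omega)) {
    k <- k + 1L
    add_row(paste0("omega_", nm, " (%CV)"), 100 * sqrt(m$omega[[nm]]),
            50 * se_packed[k], eta_shr[[nm]])
  }
  iw <- .iwres(data, m, etas)
  eps_shr <- 100 * (1 - stats::sd(iw))
  for (s in c("prop", "add"))
    if (template$sigma[[s]] > 0) {
      k <- k + 1L
      add_row(paste0("sigma_", s), m$sigma[[s]], 100 * se_packed[k], eps_shr)
    }
  structure(list(model = m, ofv = ofv, aic = ofv + 2 * np, n_params = np,
                 estimates = do.call(rbind, rows), etas = etas,
                 eta_shrinkage = eta_shr, eps_shrinkage = eps_shr,
                 data = data, packed = packed),
            class = "pk_fit")
}

#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf("FOCE-I fit: OFV %.3f, AIC %.3f, %d parameters, %s\n",
              x$ofv, x$aic, x$n_params,
              if (isTRUE(x$convergence)) "converged" else "NOT converged"))
  est <- x$estimates
  est$estimate <- signif(est$estimate, 4)
  est$rse_pct <- signif(est$rse_pct, 3)
  est$shrinkage_pct <- signif(est$shrinkage_pct, 3)
  print(est, row.names = FALSE)
  invisible(x)
}

# individual weighted residuals at the EBEs
.iwres <- function(data, model, etas) {
  out <- numeric(0)
  for (id in subject_ids(data)) {
    ctx <- .subject_context(subject_data(data, id), model)
    if (!length(ctx$dv)) next
    f <- .cond_f(etas[id, ], ctx)
    g <- ctx$sp2 * f * f + ctx$sa2
    out <- c(out, (ctx$dv - f) / sqrt(g))
  }
  out
}

#' Shrinkage of empirical Bayes estimates
#'
#' Eta-shrinkage per parameter, on the SD scale:
#' \eqn{100 (1 - SD(\hat\eta_k) / \omega_k)}. Undefined (NA) when the
#' BSV variance is zero.
#'
#' @param etas EBE matrix (subjects x BSV parameters).
#' @param omega Named vector of BSV variances.
#' @return Named vector of shrinkage percentages.
#' @export
shrinkage_eta <- function(etas, omega) {
  out <- stats::setNames(rep(NA_real_, length(omega)), names(omega))
  for (k in seq_along(omega))
    if (omega[[k]] > 0)
      out[k] <- 100 * (1 - stats::sd(etas[, k]) / sqrt(omega[[k]]))
  out
}
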