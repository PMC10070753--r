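# Shared fixtures and independent oracles for the test suite.

# small two-eta model for estimation toys (additive error only keeps
# the likelihood well-behaved at low concentrations)
toy_model <- function(sigma = c(prop = 0, add = 2),
                      omega = c(CL = 0.09, V1 = 0.16)) {
  pop_model(theta = c(CL = 30, V1 = 30, Q = 100, V2 = 80),
            omega = omega, sigma = sigma)
}

# tiny dataset: n subjects on a reduced sampling grid
toy_dataset <- function(model, n = 3, seed = 5,
                        times = c(0.1, 0.5, 1, 2, 6)) {
  des <- study_design("rich")
  des$times <- times
  generate_dataset(data.frame(ID = sprintf("T%02d", seq_len(n))),
                   des, model, seed = seed)
}

# independent ODE oracle for the two-compartment infusion model
# (adaptive lsoda integration of the amount equations)
ode_conc <- function(times, dose, tinf, CL, V1, Q, V2) {
  k10 <- CL / V1; k12 <- Q / V1; k21 <- Q / V2
  rhs <- function(t, y, p) {
    inp <- if (tinf > 0 && t <= tinf) dose / tinf else if (tinf == 0) 0 else 0
    list(c(inp - (k10 + k12) * y[1] + k21 * y[2],
           k12 * y[1] - k21 * y[2]))
  }
  y0 <- if (tinf > 0) c(0, 0) else c(dose, 0)
  grid <- sort(unique(c(0, if (tinf > 0) tinf, times)))
  out <- deSolve::ode(y0, grid, rhs, NULL, rtol = 1e-10, atol = 1e-12)
  1000 * out[match(times, grid), 2] / V1
}

# adaptive Gauss-Hermite marginal -2LL oracle (d <= 2), tensor grid
# centered at the conditional mode and scaled by its curvature
gh_ofv <- function(model, data, nodes = 41) {
  gh <- pracma::gaussHermite(nodes)
  total <- 0
  for (id in subject_ids(data)) {
    subj <- subject_data(data, id)
    est <- estimate_etas(subj, model)
    d <- length(est$eta)
    L <- t(chol(solve(est$fisher)))
    lik <- 0
    if (d == 1) {
      for (i in seq_along(gh$x)) {
        eta <- est$eta + sqrt(2) * as.numeric(L) * gh$x[i]
        lik <- lik + gh$w[i] * exp(gh$x[i]^2) *
          exp(-conditional_objective(eta, subj, model) / 2)
      }
      lik <- lik * sqrt(2) * abs(as.numeric(L))
    } else if (d == 2) {
      for (i in seq_along(gh$x)) for (j in seq_along(gh$x)) {
        z <- c(gh$x[i], gh$x[j])
        eta <- est$eta + sqrt(2) * as.numeric(L %*% z)
        lik <- lik + gh$w[i] * gh$w[j] * exp(sum(z^2)) *
          exp(-conditional_objective(eta, subj, model) / 2)
      }
      lik <- lik * 2 * abs(det(L))
    } else stop("gh_ofv supports 1-2 dimensions")
    total <- total - 2 * log(lik)
  }
  total
}

# published final-model parameter set used across tests
final_theta <- c(CL = 32.9, V1 = 32.5, Q = 245, V2 = 83.5)
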