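#' Envelopment probability under boundary-restricted growth
#'
#' When proliferation and dispersal are restricted to the expansion front, a
#' mutant cannot replace the wildtype interior; the sweep analogue is the
#' first front mutant *enveloping* the wildtype front. Mutations arise on the
#' (d-1)-dimensional front in proportion to its size, so the front radius at
#' first arrival is Weibull with shape `d`. The mutant patch then spreads
#' laterally along the expanding front at speed `c_m` (angular rate
#' `c_m / R(tau)`), enveloping at the finite time where its angular radius
#' reaches `pi`; envelopment succeeds if no second surviving front mutation
#' arises in the shrinking wildtype front before then. The marginalised
#' probability reduces to `1 / (1 + J / V_d)` where `J` is a dimensionless
#' quadrature over the envelopment window — in particular it is independent of
#' the mutation rate, like the sweep probability of the main model.
#'
#' @inheritParams arrival_time_density
#' @return The envelopment probability.
#' @export
envelopment_probability <- function(params) {
  stopifnot(inherits(params, "macro_params"))
  d <- params$d
  if (d == 1) {
    stop("envelopment is undefined in 1D: the front is two points and cannot be enveloped")
  }
  cw <- params$c_wt
  cm <- params$c_m
  if (cm <= cw) return(0)
  1 / (1 + envelopment_window_integral(cw, cm, d) / unit_ball_volume(d))
}

# J = integral over the scaled envelopment window of the remaining wildtype
# front size; u = c_wt * tau / x, angular radius phi = (c_m/c_wt) log(1 + u)
envelopment_window_integral <- function(cw, cm, d) {
  u_end <- exp(pi * cw / cm) - 1
  f <- if (d == 3) {
    function(u) 2 * pi * (1 + u)^2 * (1 + cos(cm / cw * log(1 + u)))
  } else {
    function(u) (1 + u) * (2 * pi - 2 * pmin(cm / cw * log(1 + u), pi))
  }
  stats::integrate(f, 0, u_end, rel.tol = 1e-10)$value
}

# remaining wildtype front size at scaled time u after the first front mutant
envelopment_front_remaining <- function(u, x, cw, cm, d) {
  r <- x * (1 + u)
  phi <- pmin(cm / cw * log(1 + u), pi)
  if (d == 3) 2 * pi * r^2 * (1 + cos(phi)) else r * (2 * pi - 2 * phi)
}

#' Monte-Carlo oracle for the envelopment probability
#'
#' Simulates the boundary-growth model directly: the first surviving front
#' mutation is drawn by inverting the cumulative front intensity, and
#' interfering second mutations are generated by Poisson thinning against the
#' shrinking wildtype front. Serves as an independent check of
#' [envelopment_probability()].
#'
#' @inheritParams arrival_time_density
#' @param reps Number of replicates.
#' @return A list with `estimate`, `se` and `reps`.
#' @export
envelopment_probability_mc <- function(params, reps = 1e4) {
  stopifnot(inherits(params, "macro_params"))
  d <- params$d
  if (d == 1) stop("envelopment is undefined in 1D")
  cw <- params$c_wt
  cm <- params$c_m
  mu <- params$mu
  vd <- unit_ball_volume(d)
  u_end <- exp(pi * cw / cm) - 1
  # front radius at first arrival: Lambda(x) = mu * V_d * x^d / c_wt
  x1 <- (stats::rexp(reps) * cw / (mu * vd))^(1 / d)
  env <- logical(reps)
  for (i in seq_len(reps)) {
    x <- x1[i]
    tau_end <- x * u_end / cw
    bound <- mu * max(envelopment_front_remaining(
      seq(0, u_end, length.out = 200L), x, cw, cm, d))
    tau <- 0
    hit <- FALSE
    repeat {
      tau <- tau + stats::rexp(1, bound)
      if (tau >= tau_end) break
      a <- mu * envelopment_front_remaining(cw * tau / x, x, cw, cm, d)
      if (stats::runif(1) < a / bound) {
        hit <- TRUE
        break
      }
    }
    env[i] <- !hit
  }
  p <- mean(env)
  list(estimate = p, se = sqrt(p * (1 - p) / reps), reps = reps)
}

#' Sweep probability in a static wildtype ball
#'
#' The wildtype occupies a fixed d-ball of radius `x0` (no expansion); the
#' first surviving mutant arises uniformly in the ball and expands at speed
#' `c_m`, replacing the wildtype after `tau2 = (x0 + y) / c_m`. The sweep
#' succeeds if no second surviving mutation arises in the shrinking wildtype
#' before then. Unlike the expanding-population case, this probability
#' depends on both the mutation rate and the population radius.
#'
#' @param x0 Fixed wildtype radius (> 0).
#' @param mu Effective mutation rate per individual per generation.
#' @param c_m Mutant expansion speed.
#' @param d Spatial dimension.
#' @param n_nodes Gauss-Legendre nodes for each quadrature level.
#' @return A probability.
#' @export
sweep_probability_fixed_radius <- function(x0, mu, c_m, d = 3, n_nodes = 64L) {
  stopifnot(x0 > 0, mu >= 0, c_m > 0)
  if (!d %in% 1:3) stop("'d' must be 1, 2 or 3")
  gl <- pracma::gaussLegendre(n_nodes, 0, x0)
  py <- exp(-fixed_radius_intensity(gl$x, x0, mu, c_m, d))
  fy <- location_density_conditional(gl$x, x0, d)
  sum(gl$w * py * fy)
}

# mu * integral of the remaining wildtype volume for mutant origins y (vector)
fixed_radius_intensity <- function(y, x0, mu, c_m, d, n_nodes = 48L) {
  tau2 <- (x0 + y) / c_m
  gl <- pracma::gaussLegendre(n_nodes, 0, 1)
  taus <- outer(tau2, gl$x)                      # ny x nodes
  yy <- matrix(y, nrow = length(y), ncol = n_nodes)
  ov <- ball_overlap_volume(x0, c_m * taus, yy, d)
  remaining <- pmax(ball_volume(x0, d) - ov, 0)
  mu * tau2 * as.vector(matrix(remaining, ncol = n_nodes) %*% gl$w)
}

#' Monte-Carlo oracle for the fixed-radius sweep probability
#'
#' Direct stochastic simulation: mutant origin drawn uniformly in the ball,
#' interfering mutations by Poisson thinning against the remaining wildtype.
#'
#' @inheritParams sweep_probability_fixed_radius
#' @param reps Number of replicates.
#' @return A list with `estimate`, `se` and `reps`.
#' @export
sweep_probability_fixed_radius_mc <- function(x0, mu, c_m, d = 3, reps = 1e4) {
  y <- x0 * stats::runif(reps)^(1 / d)
  tau2 <- (x0 + y) / c_m
  n_tot <- ball_volume(x0, d)
  bound <- mu * n_tot
  n_cand <- stats::rpois(reps, bound * tau2)
  swept <- logical(reps)
  for (i in seq_len(reps)) {
    if (n_cand[i] == 0L) {
      swept[i] <- TRUE
      next
    }
    taus <- stats::runif(n_cand[i], 0, tau2[i])
    remaining <- n_tot - ball_overlap_volume(x0, c_m * taus, y[i], d)
    swept[i] <- all(stats::runif(n_cand[i]) >= remaining / n_tot)
  }
  p <- mean(swept)
  list(estimate = p, se = sqrt(p * (1 - p) / reps), reps = reps)
}

#' Sweep (dominance) probability under pure exponential growth
#'
#' Well-mixed wildtype growing exponentially at rate `r_wt` from a single
#' individual, with surviving mutations arising at per-capita rate `mu`. The
#' first surviving mutant grows at `r_m > r_wt` and is said to sweep once its
#' frequency reaches `dominance_threshold` before a second surviving mutation
#' arises in the wildtype. Both clones grow deterministically; arrivals follow
#' the inhomogeneous Poisson law. The result is relatively insensitive to the
#' mutation rate: a higher rate makes the first mutant arrive in a smaller
#' population (shortening its path to dominance) but also hastens competitors.
#'
#' @param r_wt,r_m Wildtype and mutant exponential growth rates, `r_m > r_wt`.
#' @param mu Effective mutation rate.
#' @param dominance_threshold Mutant frequency defining dominance, in (0, 1).
#' @return A probability.
#' @export
sweep_probability_exponential <- function(r_wt, r_m, mu,
                                          dominance_threshold = 0.5) {
  stopifnot(r_wt > 0, r_m > r_wt, mu > 0)
  if (dominance_threshold <= 0 || dominance_threshold >= 1) {
    stop("'dominance_threshold' must lie in (0, 1)")
  }
  lf <- log(dominance_threshold / (1 - dominance_threshold))
  cum <- function(t) mu * (exp(r_wt * t) - 1) / r_wt
  integrand <- function(t) {
    tau_d <- pmax((r_wt * t + lf) / (r_m - r_wt), 0)
    out <- exp(log(mu) + r_wt * t - cum(t) - (cum(t + tau_d) - cum(t)))
    # beyond floating range the arrival density has no mass left
    out[!is.finite(out)] <- 0
    out
  }
  stats::integrate(integrand, 0, Inf, rel.tol = 1e-9)$value
}

#' Monte-Carlo oracle for the exponential-growth dominance probability
#'
#' Simulates first and second surviving-mutation arrival times by inverting
#' the cumulative intensity of the exponentially growing wildtype, and checks
#' dominance directly.
#'
#' @inheritParams sweep_probability_exponential
#' @param reps Number of replicates.
#' @return A list with `estimate`, `se` and `reps`.
#' @export
sweep_probability_exponential_mc <- function(r_wt, r_m, mu,
                                             dominance_threshold = 0.5,
                                             reps = 1e5) {
  stopifnot(r_wt > 0, r_m > r_wt, mu > 0)
  lf <- log(dominance_threshold / (1 - dominance_threshold))
  e1 <- stats::rexp(reps)
  e2 <- stats::rexp(reps)
  t1 <- log(1 + r_wt * e1 / mu) / r_wt
  t2 <- log(exp(r_wt * t1) + r_wt * e2 / mu) / r_wt
  tau_d <- pmax((r_wt * t1 + lf) / (r_m - r_wt), 0)
  p <- mean(t2 - t1 > tau_d)
  list(estimate = p, se = sqrt(p * (1 - p) / reps), reps = reps)
}

#' Sweep probability with fixed population size and logistic mutant growth
#'
#' A well-mixed population of constant size `N0` in which the first surviving
#' mutant grows logistically (deterministic frequency dynamics with selective
#' advantage `a = r_m - r_wt`), fixing at time `2 log(N0 - 1) / a`. A sweep
#' occurs if no second surviving mutation arises among the shrinking wildtype
#' before fixation; the wildtype-decay integral evaluates in closed form,
#' giving `exp(-mu * N0 * log(N0 - 1) / a)`. This probability is sensitive to
#' both population size and mutation rate, in contrast to the expanding-
#' population models.
#'
#' @param N0 Fixed total population size (> 1).
#' @param r_wt,r_m Wildtype and mutant proliferation rates, `r_m > r_wt`.
#' @param mu Effective mutation rate.
#' @return A probability.
#' @export
sweep_probability_logistic_fixed_N <- function(N0, r_wt, r_m, mu) {
  stopifnot(N0 > 1, r_wt > 0, r_m > r_wt, mu >= 0)
  a <- r_m - r_wt
  exp(-mu * N0 * log(N0 - 1) / a)
}

#' Monte-Carlo oracle for the fixed-size logistic sweep probability
#'
#' Poisson thinning of interfering mutations against the deterministically
#' shrinking wildtype over the fixation window.
#'
#' @inheritParams sweep_probability_logistic_fixed_N
#' @param reps Number of replicates.
#' @return A list with `estimate`, `se` and `reps`.
#' @export
sweep_probability_logistic_fixed_N_mc <- function(N0, r_wt, r_m, mu,
                                                  reps = 1e4) {
  stopifnot(N0 > 1, r_wt > 0, r_m > r_wt, mu >= 0)
  a <- r_m - r_wt
  tau_fix <- 2 * log(N0 - 1) / a
  n_wt <- function(tau) {
    g <- (N0 - 1) * exp(-a * tau)
    N0 * g / (1 + g)
  }
  bound <- mu * (N0 - 1)
  n_cand <- stats::rpois(reps, bound * tau_fix)
  swept <- logical(reps)
  for (i in seq_len(reps)) {
    if (n_cand[i] == 0L) {
      swept[i] <- TRUE
      next
    }
    taus <- stats::runif(n_cand[i], 0, tau_fix)
    swept[i] <- all(stats::runif(n_cand[i]) >= mu * n_wt(taus) / bound)
  }
  p <- mean(swept)
  list(estimate = p, se = sqrt(p * (1 - p) / reps), reps = reps)
}
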