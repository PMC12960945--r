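#' Effective mutation rate
#'
#' Collapses the per-capita mutation rate and the probability of surviving
#' genetic drift into the single compound rate that drives the macroscopic
#' model: only mutations that escape stochastic extinction contribute to the
#' macroscopic dynamics, so the rate of *surviving* mutations per individual
#' per generation is `mu = rho * mu_tilde`.
#'
#' @param mu_tilde Per-capita mutation rate (per individual per generation).
#' @param rho Probability that a new mutant lineage survives genetic drift,
#'   in `[0, 1]`.
#' @return The effective mutation rate `rho * mu_tilde`.
#' @seealso [moran_survival_probability()] for the deme-model value of `rho`.
#' @export
#' @examples
#' effective_mutation_rate(1e-5, 0.23)
effective_mutation_rate <- function(mu_tilde, rho) {
  stopifnot(is.numeric(mu_tilde), is.numeric(rho))
  if (any(mu_tilde < 0)) stop("'mu_tilde' must be non-negative")
  if (any(rho < 0 | rho > 1)) stop("'rho' must lie in [0, 1]")
  rho * mu_tilde
}

#' Convert a per-division mutation rate to a per-capita rate
#'
#' Provisional helper for translating a mutation probability per cell division
#' into a per-capita rate per unit time: an individual dividing at rate `r`
#' accrues mutations at rate `mu_per_division * r`. One generation is the time
#' in which an individual with proliferation rate 1 divides once, matching the
#' agent-based model's clock. The authoritative general conversion involves the
#' full division-rate structure of the population; this helper covers the
#' constant-division-rate case used throughout this package.
#'
#' @param mu_per_division Mutation probability per division.
#' @param division_rate Per-capita division rate (divisions per generation).
#' @return Per-capita mutation rate per generation.
#' @export
mutation_rate_per_capita <- function(mu_per_division, division_rate) {
  stopifnot(mu_per_division >= 0, division_rate >= 0)
  mu_per_division * division_rate
}

#' Cumulative intensity of surviving mutations
#'
#' The expected number of surviving mutations arising in `[0, t]` in a
#' population of size `N(s)` is `lambda = mu * integral_0^t N(s) ds`; the count
#' is Poisson distributed with this mean. `population_size` may be given either
#' as a numeric vector of polynomial coefficients `c(a0, a1, a2, ...)`, meaning
#' `N(s) = a0 + a1 s + a2 s^2 + ...`, in which case the integral is evaluated
#' in closed form, or as a function of time, in which case adaptive quadrature
#' is used.
#'
#' @param population_size Polynomial coefficients (numeric vector) or a
#'   vectorised function `N(s) >= 0`.
#' @param mu Effective mutation rate per individual per generation.
#' @param t Time horizon (generations), `t >= 0`.
#' @param rel_tol Relative tolerance for the quadrature path.
#' @return An object of class `intensity_integral` with fields `lambda_value`,
#'   `t_max` and `mu`.
#' @export
#' @examples
#' cumulative_intensity(c(0, 0, 0, 4 / 3 * pi * 0.15^3), mu = 2.3e-6, t = 100)
cumulative_intensity <- function(population_size, mu, t, rel_tol = 1e-8) {
  stopifnot(is.numeric(mu), length(mu) == 1L, mu >= 0,
            is.numeric(t), length(t) == 1L, t >= 0)
  if (is.numeric(population_size)) {
    a <- population_size
    p <- seq_along(a)  # antiderivative exponents
    lambda <- mu * sum(a * t^p / p)
  } else if (is.function(population_size)) {
    probe_t <- seq(0, t, length.out = 21L)
    probe <- vapply(probe_t, function(s) population_size(s)[1L], numeric(1L))
    bad <- which(!is.finite(probe))
    if (length(bad) > 0L) {
      stop(sprintf("population size is not finite at time %g", probe_t[bad[1L]]))
    }
    if (any(probe < 0)) {
      stop(sprintf("population size is negative at time %g",
                   probe_t[which(probe < 0)[1L]]))
    }
    lambda <- if (t == 0) 0 else
      mu * stats::integrate(function(s) population_size(s), 0, t,
                            rel.tol = rel_tol)$value
  } else {
    stop("'population_size' must be a coefficient vector or a function")
  }
  structure(list(lambda_value = lambda, t_max = t, mu = mu),
            class = "intensity_integral")
}

#' @export
print.intensity_integral <- function(x, ...) {
  cat(sprintf(
    "Surviving-mutation intensity: lambda = %.6g over [0, %g] at mu = %g\n",
    x$lambda_value, x$t_max, x$mu))
  invisible(x)
}

#' Probability of k surviving mutations
#'
#' Poisson probability mass for the number of mutations that arise and survive
#' drift in a time window with cumulative intensity `lambda`. In particular the
#' probability that no successful mutant arises is `exp(-lambda)`.
#'
#' @param lambda_value Cumulative intensity (`>= 0`), or an
#'   `intensity_integral` object.
#' @param k Non-negative integer count (vectorised).
#' @return `exp(-lambda) * lambda^k / k!`.
#' @export
prob_k_mutations <- function(lambda_value, k) {
  if (inherits(lambda_value, "intensity_integral")) {
    lambda_value <- lambda_value$lambda_value
  }
  stopifnot(is.numeric(lambda_value), all(lambda_value >= 0))
  if (any(k < 0) || any(k != round(k))) {
    stop("'k' must be a non-negative integer")
  }
  stats::dpois(k, lambda_value)
}
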