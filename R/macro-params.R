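#' Parameters of the macroscopic range-expansion model
#'
#' Bundles the parameters of the constant-radial-speed model: the wildtype
#' expands spherically at speed `c_wt` (cell diameters per generation), a
#' beneficial mutant spreads within the wildtype at speed `c_m > c_wt`, and
#' surviving mutations arise at effective per-capita rate `mu` in `d` spatial
#' dimensions. `mu` may be supplied directly, or as the pair
#' (`mu_tilde`, `rho`) of raw mutation rate and drift-survival probability.
#'
#' `c_m = c_wt` is permitted and yields sweep probability 0 (the mutant can
#' never catch the front); `c_m < c_wt` is rejected.
#'
#' @param c_wt Wildtype radial expansion speed (> 0).
#' @param c_m Mutant radial speed within the wildtype (`>= c_wt`).
#' @param mu Effective mutation rate per individual per generation.
#' @param mu_tilde,rho Alternative specification: `mu = rho * mu_tilde`.
#' @param d Spatial dimension, one of 1, 2, 3.
#' @return An object of class `macro_params`.
#' @export
#' @examples
#' macro_params(c_wt = 0.15, c_m = 0.31, mu_tilde = 1e-5, rho = 0.23, d = 3)
macro_params <- function(c_wt, c_m, mu = NULL, mu_tilde = NULL, rho = NULL,
                         d = 3) {
  if (is.null(mu)) {
    if (is.null(mu_tilde) || is.null(rho)) {
      stop("supply either 'mu' or both 'mu_tilde' and 'rho'")
    }
    mu <- effective_mutation_rate(mu_tilde, rho)
  }
  stopifnot(length(c_wt) == 1L, length(c_m) == 1L, length(mu) == 1L,
            length(d) == 1L)
  if (!d %in% 1:3) stop("'d' must be 1, 2 or 3")
  if (c_wt <= 0) stop("'c_wt' must be positive")
  if (c_m < c_wt) stop("'c_m' must be >= 'c_wt'")
  if (mu <= 0) stop("'mu' must be positive")
  structure(list(c_wt = c_wt, c_m = c_m, mu = mu, d = as.integer(d)),
            class = "macro_params")
}

#' @export
print.macro_params <- function(x, ...) {
  cat(sprintf(
    "Macroscopic range-expansion model (%dD): c_wt = %g, c_m = %g, mu = %g\n",
    x$d, x$c_wt, x$c_m, x$mu))
  sc <- characteristic_scales(x)
  cat(sprintf("  scales: kappa = %.4g, theta = %.4g, alpha = %.4g, beta = %.4g\n",
              sc$kappa, sc$theta, sc$alpha, sc$beta))
  invisible(x)
}

# volume of the unit d-ball; V_d * r^d is the d-volume of a ball of radius r
unit_ball_volume <- function(d) {
  c(2, pi, 4 / 3 * pi)[d]
}

#' Characteristic scales of the macroscopic model
#'
#' Derives the four characteristic scales of the constant-speed model in
#' dimension `d`:
#' \describe{
#'   \item{kappa}{arrival-time scale: the cumulative intensity of surviving
#'     mutations in the growing wildtype d-ball is `(t / kappa)^(d+1)`, so
#'     `kappa = ((d+1) / (mu * V_d * c_wt^d))^(1/(d+1))` with `V_d` the unit
#'     d-ball volume. In 3D this is `(3 / (mu * pi * c_wt^3))^(1/4)`.}
#'   \item{theta}{arrival-radius scale `theta = c_wt * kappa`; the wildtype
#'     radius at first-mutant arrival is Weibull with shape `d + 1` and scale
#'     `theta`. In 3D, `theta = (3 c_wt / (pi mu))^(1/4)`.}
#'   \item{alpha}{sweep length: with the mutant placed at the wildtype centre,
#'     the conditional sweep probability is `exp(-(x / alpha)^(d+1))`. The
#'     general-d constant follows from integrating the remaining-wildtype
#'     volume over the replacement interval; in 3D it reduces to
#'     `alpha^4 = 3 (c_m - c_wt)^3 / (pi mu (c_wt^2 - 3 c_wt c_m + 3 c_m^2))`.}
#'   \item{beta}{relative speed advantage `(c_m - c_wt) / c_m`.}
#' }
#' The scales satisfy the algebraic identity
#' `alpha^(d+1) / (alpha^(d+1) + theta^(d+1)) = beta^d`, which is exactly the
#' closed-form unconditional sweep probability.
#'
#' When `c_m = c_wt` a sweep is impossible: `alpha = Inf` is returned as a
#' sentinel together with `beta = 0` and `sweep_possible = FALSE`.
#'
#' @param params A [macro_params()] object.
#' @return An object of class `characteristic_scales` with fields `kappa`,
#'   `theta`, `alpha`, `beta`, `sweep_possible` and `d`.
#' @export
characteristic_scales <- function(params) {
  stopifnot(inherits(params, "macro_params"))
  d <- params$d
  vd <- unit_ball_volume(d)
  cw <- params$c_wt
  cm <- params$c_m
  mu <- params$mu
  kappa <- ((d + 1) / (mu * vd * cw^d))^(1 / (d + 1))
  theta <- cw * kappa
  if (cm > cw) {
    beta <- (cm - cw) / cm
    # G = integral over the y = 0 replacement window of the remaining wildtype
    # d-volume, divided by V_d * x^(d+1) / (d+1); alpha^(d+1) = (d+1)/(mu Vd G)
    g_const <- ((cm / (cm - cw))^(d + 1) - 1) / cw -
      cm^d / (cm - cw)^(d + 1)
    alpha <- ((d + 1) / (mu * vd * g_const))^(1 / (d + 1))
  } else {
    beta <- 0
    alpha <- Inf
  }
  structure(list(kappa = kappa, theta = theta, alpha = alpha, beta = beta,
                 sweep_possible = cm > cw, d = d),
            class = "characteristic_scales")
}

#' @export
print.characteristic_scales <- function(x, ...) {
  cat(sprintf(
    "Characteristic scales (%dD): kappa = %.4g gen, theta = %.4g, alpha = %.4g, beta = %.4g\n",
    x$d, x$kappa, x$theta, x$alpha, x$beta))
  if (!x$sweep_possible) cat("  (c_m <= c_wt: sweeps impossible)\n")
  invisible(x)
}
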