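#' Density of the arrival time of the first surviving mutant
#'
#' In the growing wildtype d-ball the cumulative intensity of surviving
#' mutations is `(t / kappa)^(d+1)`, so the first arrival time follows a
#' Weibull distribution with shape `d + 1` and scale `kappa` (shape 4 in 3D).
#'
#' @param t Time since the wildtype expansion started (generations, `>= 0`).
#' @param params A [macro_params()] object.
#' @return Density values `f_T(t)`.
#' @export
arrival_time_density <- function(t, params) {
  stopifnot(inherits(params, "macro_params"))
  if (any(t < 0)) stop("'t' must be non-negative")
  sc <- characteristic_scales(params)
  stats::dweibull(t, shape = params$d + 1, scale = sc$kappa)
}

#' Density of the wildtype radius at first-mutant arrival
#'
#' Change of variables `x = c_wt * t` in the arrival-time law: the wildtype
#' radius `X` when the first surviving mutant arises is Weibull with shape
#' `d + 1` and scale `theta`.
#'
#' @param x Radius (cell diameters, `>= 0`).
#' @inheritParams arrival_time_density
#' @return Density values `f_X(x)`.
#' @export
radius_density <- function(x, params) {
  stopifnot(inherits(params, "macro_params"))
  if (any(x < 0)) stop("'x' must be non-negative")
  sc <- characteristic_scales(params)
  stats::dweibull(x, shape = params$d + 1, scale = sc$theta)
}

#' Moments of the arrival-radius distribution
#'
#' Closed-form Weibull moments: `E[X] = theta * gamma(1 + 1/(d+1))` and
#' `Var[X] = theta^2 * (gamma(1 + 2/(d+1)) - gamma(1 + 1/(d+1))^2)`. In 3D
#' these evaluate to approximately `0.91 theta` and `0.065 theta^2`.
#'
#' @inheritParams arrival_time_density
#' @return A list with `mean` and `variance`.
#' @export
radius_moments <- function(params) {
  stopifnot(inherits(params, "macro_params"))
  k <- params$d + 1
  th <- characteristic_scales(params)$theta
  g1 <- gamma(1 + 1 / k)
  g2 <- gamma(1 + 2 / k)
  list(mean = th * g1, variance = th^2 * (g2 - g1^2))
}

#' Conditional density of the first mutant's distance from the origin
#'
#' Mutants arise in proportion to the number of wildtype cells, i.e. uniformly
#' in the wildtype d-ball, so the distance `Y` of the mutant origin from the
#' wildtype centre given radius `x` has density `d y^(d-1) / x^d` on `[0, x]`
#' (`3y^2/x^3` in 3D, `2y/x^2` in 2D, uniform in 1D).
#'
#' @param y Distance values (`>= 0`).
#' @param x Wildtype radius (> 0).
#' @param d Spatial dimension (1, 2 or 3).
#' @return Density values `f_Y(y | X = x)`.
#' @export
location_density_conditional <- function(y, x, d) {
  if (!d %in% 1:3) stop("'d' must be 1, 2 or 3")
  if (any(x <= 0)) stop("'x' must be positive")
  ifelse(y >= 0 & y <= x, d * y^(d - 1) / x^d, 0)
}

#' Marginal density of the first mutant's distance from the origin
#'
#' Marginalises the conditional location law over the Weibull arrival-radius
#' distribution. For general dimension the integral evaluates to
#' `f_Y(y) = (d y^(d-1) / theta^d) * igamma(1/(d+1), (y/theta)^(d+1))`,
#' where `igamma(a, z)` is the upper incomplete gamma function; in 3D this is
#' `(3 y^2 / theta^3) * igamma(1/4, y^4 / theta^4)`.
#'
#' @param y Distance values (`>= 0`).
#' @inheritParams arrival_time_density
#' @return Density values `f_Y(y)`.
#' @export
location_density <- function(y, params) {
  stopifnot(inherits(params, "macro_params"))
  if (any(y < 0)) stop("'y' must be non-negative")
  d <- params$d
  th <- characteristic_scales(params)$theta
  a <- 1 / (d + 1)
  z <- (y / th)^(d + 1)
  d * y^(d - 1) / th^d * gamma(a) * stats::pgamma(z, a, lower.tail = FALSE)
}

#' Moments of the mutant-location distribution
#'
#' Mean and variance of the marginal distance `Y`, computed by adaptive
#' quadrature of the marginal density. In 3D these are approximately
#' `0.68 theta` and `0.070 theta^2`.
#'
#' @inheritParams arrival_time_density
#' @return A list with `mean` and `variance`.
#' @export
location_moments <- function(params) {
  stopifnot(inherits(params, "macro_params"))
  th <- characteristic_scales(params)$theta
  m1 <- stats::integrate(function(y) y * location_density(y, params),
                         0, Inf, rel.tol = 1e-10)$value
  m2 <- stats::integrate(function(y) y^2 * location_density(y, params),
                         0, Inf, rel.tol = 1e-10)$value
  list(mean = m1, variance = m2 - m1^2)
}

# times at which the mutant reaches the wildtype boundary (tau1) and has
# entirely replaced the wildtype (tau2), measured from the mutant's birth
replacement_times <- function(x, y, params) {
  dv <- params$c_m - params$c_wt
  if (dv <= 0) return(list(tau1 = Inf, tau2 = Inf))
  list(tau1 = (x - y) / dv, tau2 = (x + y) / dv)
}

#' Remaining wildtype population during a replacement
#'
#' Size of the wildtype population at time `tau` after the first mutant arose
#' at distance `y` from the centre of a wildtype ball of radius `x`. The
#' wildtype keeps expanding at `c_wt` while the mutant ball grows at `c_m`
#' around its origin; the remaining wildtype is the expanding d-ball minus its
#' intersection with the mutant ball (a spherical/circular lens once the
#' mutant breaches the boundary), reaching zero at
#' `tau2 = (x + y) / (c_m - c_wt)`.
#'
#' @param tau Time since the mutant arose (generations, `>= 0`, vectorised).
#' @param x Wildtype radius when the mutant arose (> 0).
#' @param y Distance of the mutant origin from the wildtype centre,
#'   `0 <= y <= x`.
#' @inheritParams arrival_time_density
#' @return Remaining wildtype d-volume (population count at unit density).
#' @export
wildtype_remaining <- function(tau, x, y, params) {
  stopifnot(inherits(params, "macro_params"))
  if (any(tau < 0)) stop("'tau' must be non-negative")
  if (y < 0 || y > x) stop("'y' must lie in [0, x]")
  d <- params$d
  r_wt <- x + params$c_wt * tau
  r_m <- params$c_m * tau
  pmax(ball_volume(r_wt, d) - ball_overlap_volume(r_wt, r_m, y, d), 0)
}

# mu * integral over tau of the remaining wildtype volume, for scalar x and
# vector y; the straight-growth and interior-replacement parts are closed
# form, the lens part uses Gauss-Legendre quadrature on [tau1, tau2]
sweep_intensity <- function(x, y, params, n_nodes = 32L) {
  d <- params$d
  cw <- params$c_wt
  cm <- params$c_m
  mu <- params$mu
  vd <- unit_ball_volume(d)
  if (cm <= cw) return(rep(Inf, length(y)))
  tau1 <- (x - y) / (cm - cw)
  tau2 <- (x + y) / (cm - cw)
  # untouched wildtype growth over [0, tau2]
  grow <- vd * ((x + cw * tau2)^(d + 1) - x^(d + 1)) / (cw * (d + 1))
  # interior mutant ball over [0, tau1]
  interior <- vd * cm^d * tau1^(d + 1) / (d + 1)
  # lens phase over [tau1, tau2]
  lens <- numeric(length(y))
  pos <- tau2 > tau1
  if (any(pos)) {
    gl <- pracma::gaussLegendre(n_nodes, -1, 1)
    half <- (tau2[pos] - tau1[pos]) / 2
    mid <- (tau2[pos] + tau1[pos]) / 2
    taus <- outer(half, gl$x) + mid              # n_pos x n_nodes
    yy <- matrix(y[pos], nrow = sum(pos), ncol = n_nodes)
    ov <- ball_overlap_volume(x + cw * taus, cm * taus, yy, d)
    lens[pos] <- half * as.vector(matrix(ov, ncol = n_nodes) %*% gl$w)
  }
  mu * pmax(grow - interior - lens, 0)
}

#' Conditional sweep probability
#'
#' Probability that the first surviving mutant, born at distance `y` inside a
#' wildtype ball of radius `x`, replaces the entire wildtype before a second
#' surviving mutation arises. The `"exact"` method integrates the remaining
#' wildtype population over the replacement window and exponentiates
#' (`exp(-mu * integral N_wt(tau) dtau)`); the `"approx"` method is the
#' closed form `exp(-(x / alpha)^(d+1))` obtained by placing the mutant at the
#' centre (`y = 0`), which upper-bounds the exact probability because a
#' central mutant completes its sweep soonest.
#'
#' @param x Wildtype radius at mutant arrival (vectorised, `>= 0`).
#' @param y Mutant origin distance, `0 <= y <= x` (recycled; ignored by the
#'   approximation).
#' @inheritParams arrival_time_density
#' @param method `"exact"` or `"approx"`.
#' @return Sweep probabilities.
#' @export
conditional_sweep_prob <- function(x, y = 0, params,
                                   method = c("exact", "approx")) {
  stopifnot(inherits(params, "macro_params"))
  method <- match.arg(method)
  n <- max(length(x), length(y))
  x <- rep_len(x, n)
  y <- rep_len(y, n)
  if (any(x < 0) || any(y < 0) || any(y > x & x > 0)) {
    stop("require 0 <= y <= x")
  }
  sc <- characteristic_scales(params)
  if (!sc$sweep_possible) return(ifelse(x == 0, 1, 0))
  if (method == "approx") {
    return(exp(-(x / sc$alpha)^(params$d + 1)))
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- if (x[i] == 0) 1 else
      exp(-sweep_intensity(x[i], y[i], params))
  }
  out
}

# probability of a sweep given X = x, with the mutant location integrated out
# exactly (trapezoid in y on the theta-scaled protocol grid)
conditional_sweep_prob_given_x <- function(x, params, grid = protocol_grid(params)) {
  sc <- characteristic_scales(params)
  vapply(x, function(xi) {
    if (xi <= 0) return(1)
    yg <- grid_to(grid, xi)
    if (length(yg) < 2L) {
      return(conditional_sweep_prob(xi, 0, params, method = "exact"))
    }
    p <- exp(-sweep_intensity(xi, yg, params))
    f <- location_density_conditional(yg, xi, params$d)
    pracma::trapz(yg, p * f) / pracma::trapz(yg, f)
  }, numeric(1L))
}

# theta-scaled trapezoid grid: widths 0.001*theta up to 0.5*theta and
# 0.01*theta beyond, bounds [0.001*theta, 3*theta]
protocol_grid <- function(params, upper = 3) {
  th <- characteristic_scales(params)$theta
  c(seq(0.001, 0.5, by = 0.001), seq(0.51, upper, by = 0.01)) * th
}

grid_to <- function(grid, xmax) {
  g <- grid[grid < xmax]
  c(g, xmax)
}

#' Unconditional sweep probability
#'
#' Probability that the first surviving mutation achieves a selective sweep,
#' with the arrival radius and mutant location integrated out. The
#' `"closed_form"` method evaluates the central-mutant upper bound, which
#' collapses to the strikingly simple `beta^d = ((c_m - c_wt)/c_m)^d`; the
#' `"numeric"` method performs the full double marginalisation of the exact
#' conditional probability by trapezoid integration on a theta-scaled grid
#' (bounds `0.001 theta` to `3 theta`, widths `0.001 theta` below `0.5 theta`
#' and `0.01 theta` above). The numeric value is always below the closed form
#' and is independent of the mutation rate.
#'
#' @inheritParams arrival_time_density
#' @param method `"closed_form"` or `"numeric"`.
#' @return A probability.
#' @export
#' @examples
#' p <- macro_params(c_wt = 0.15, c_m = 0.30, mu = 2.3e-6, d = 3)
#' sweep_probability(p)  # (0.5)^3 = 0.125
sweep_probability <- function(params, method = c("closed_form", "numeric")) {
  stopifnot(inherits(params, "macro_params"))
  method <- match.arg(method)
  sc <- characteristic_scales(params)
  if (!sc$sweep_possible) return(0)
  if (method == "closed_form") return(sc$beta^params$d)
  xg <- protocol_grid(params)
  px <- conditional_sweep_prob_given_x(xg, params, grid = xg)
  pracma::trapz(xg, px * radius_density(xg, params))
}

#' Sweep probability from proliferation rates (FKPP mapping)
#'
#' Maps local proliferation rates to the closed-form sweep probability via the
#' Fisher-KPP wave speed `c = 2 sqrt(a D)`: with wildtype advantage
#' `a_wt = r_wt - r_re` over the resident and mutant advantage
#' `a_m = r_m - r_wt` over the wildtype, the diffusion coefficient cancels and
#' `Pr(sweep) = (1 - sqrt(a_wt / a_m))^d`, clipped to 0 when `a_wt >= a_m`.
#'
#' @param r_re,r_wt,r_m Proliferation rates of resident, wildtype invader and
#'   mutant invader; requires `r_m > r_wt > r_re`.
#' @param d Spatial dimension.
#' @return A probability.
#' @export
#' @examples
#' sweep_probability_from_rates(0.91, 1, 1.36, d = 2)  # 0.25
sweep_probability_from_rates <- function(r_re, r_wt, r_m, d) {
  if (!d %in% 1:3) stop("'d' must be 1, 2 or 3")
  if (!(r_m > r_wt && r_wt > r_re)) {
    stop("rate ordering must satisfy r_m > r_wt > r_re")
  }
  ratio <- (r_wt - r_re) / (r_m - r_wt)
  if (ratio >= 1) return(0)
  (1 - sqrt(ratio))^d
}

#' Posterior density of the arrival radius given a sweep
#'
#' Distribution of the wildtype radius at the time the first mutant arose,
#' conditioned on that mutant achieving a selective sweep (Bayes' theorem).
#' The `"approx"` method uses the central-mutant conditional probability and
#' yields a Weibull density with shape `d + 1` and scale
#' `beta^(d/(d+1)) * theta` (in 3D: `(4x^3 / (beta^3 theta^4))
#' exp(-x^4 / (beta^3 theta^4))`); the `"numeric"` method evaluates
#' `Pr(sweep | X = x) f_X(x) / Pr(sweep)` with the exact conditional
#' probability.
#'
#' @param x Radius values (`>= 0`).
#' @inheritParams arrival_time_density
#' @param method `"approx"` or `"numeric"`.
#' @return Density values `f_X(x | sweep)`.
#' @export
posterior_radius_density <- function(x, params, method = c("approx", "numeric")) {
  stopifnot(inherits(params, "macro_params"))
  method <- match.arg(method)
  if (any(x < 0)) stop("'x' must be non-negative")
  sc <- characteristic_scales(params)
  if (!sc$sweep_possible) {
    stop("c_m <= c_wt: conditioning on a sweep is conditioning on a zero-probability event")
  }
  d <- params$d
  if (method == "approx") {
    scale <- sc$beta^(d / (d + 1)) * sc$theta
    return(stats::dweibull(x, shape = d + 1, scale = scale))
  }
  p_sweep <- sweep_probability(params, method = "numeric")
  conditional_sweep_prob_given_x(x, params) * radius_density(x, params) / p_sweep
}

#' Posterior mean radius given a sweep
#'
#' Mean of the central-mutant posterior radius law,
#' `gamma(1 + 1/(d+1)) * beta^(d/(d+1)) * theta`.
#'
#' @inheritParams arrival_time_density
#' @return Expected radius (cell diameters).
#' @export
posterior_radius_mean <- function(params) {
  sc <- characteristic_scales(params)
  d <- params$d
  gamma(1 + 1 / (d + 1)) * sc$beta^(d / (d + 1)) * sc$theta
}

#' Tumour-scale propagation speed estimate
#'
#' Converts a gross tumour growth observation (final volume after a growth
#' time) into a radial propagation speed. The radius of a sphere of volume `V`
#' is `(3V / 4 pi)^(1/3)`, so the speed is `c~ = (3V / 4 pi)^(1/3) / T` in
#' micrometres per day, and `c = c~ * tau_G / l` in cell diameters per
#' generation for cell diameter `l` and generation (cell-cycle) time `tau_G`.
#' With a typical solid tumour (1-10 cm^3 over 5-20 years, l = 20 um,
#' tau_G = 4 days) this arithmetic gives roughly 0.85-7.3 um/day, i.e. about
#' 0.17-1.5 cell diameters per generation.
#'
#' @param volume_cm3 Final tumour volume in cubic centimetres.
#' @param years Growth time in years.
#' @param cell_diameter_um Cell diameter in micrometres (default 20).
#' @param generation_days Cell-cycle time in days (default 4).
#' @return A list with `c_um_per_day` and `c_cells_per_generation`.
#' @export
cancer_speed_estimate <- function(volume_cm3, years, cell_diameter_um = 20,
                                  generation_days = 4) {
  stopifnot(volume_cm3 > 0, years > 0, cell_diameter_um > 0,
            generation_days > 0)
  radius_um <- (3 * volume_cm3 / (4 * pi))^(1 / 3) * 1e4
  days <- years * 365.25
  c_tilde <- radius_um / days
  list(c_um_per_day = c_tilde,
       c_cells_per_generation = c_tilde * generation_days / cell_diameter_um)
}
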