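test_that("arrival time follows the Weibull law implied by the intensity", {
  pars <- default_params()
  sc <- characteristic_scales(pars)
  tt <- c(10, 50, 120, 300)
  expect_equal(arrival_time_density(tt, pars),
               4 * tt^3 / sc$kappa^4 * exp(-(tt / sc$kappa)^4))
  expect_error(arrival_time_density(-1, pars), "non-negative")
  # CDF equals 1 - P0 from the Poisson machinery, across dimensions
  set.seed(3)
  for (rep in 1:20) {
    d <- sample(1:3, 1)
    pars <- random_params(d = d)
    sc <- characteristic_scales(pars)
    tt <- runif(1, 0.1, 3) * sc$kappa
    vd <- c(2, pi, 4 / 3 * pi)[d]
    lam <- cumulative_intensity(c(rep(0, d), vd * pars$c_wt^d),
                                mu = pars$mu, t = tt)
    expect_equal(pweibull(tt, shape = d + 1, scale = sc$kappa),
                 1 - prob_k_mutations(lam, 0), tolerance = 1e-10)
  }
})

test_that("radius density is the arrival density under x = c_wt t", {
  set.seed(4)
  for (d in 1:3) {
    pars <- random_params(d = d)
    x <- runif(5, 0, 3) * characteristic_scales(pars)$theta
    expect_equal(radius_density(x, pars),
                 arrival_time_density(x / pars$c_wt, pars) / pars$c_wt,
                 tolerance = 1e-12)
  }
})

test_that("all densities integrate to one at the canonical parameters", {
  for (d in 1:3) {
    pars <- default_params(d = d)
    for (f in list(function(x) arrival_time_density(x, pars),
                   function(x) radius_density(x, pars),
                   function(x) location_density(x, pars),
                   function(x) posterior_radius_density(x, pars))) {
      expect_equal(integrate(f, 0, Inf, rel.tol = 1e-9)$value, 1,
                   tolerance = 1e-6)
    }
  }
})

test_that("radius moments match the printed 3D values and a sampling oracle", {
  pars <- default_params()
  th <- characteristic_scales(pars)$theta
  mom <- radius_moments(pars)
  expect_equal(mom$mean / th, gamma(5 / 4))
  expect_equal(signif(mom$mean / th, 2), 0.91)
  expect_equal(mom$variance / th^2, gamma(3 / 2) - gamma(5 / 4)^2)
  expect_equal(signif(mom$variance / th^2, 2), 0.065)
  # 1D: Rayleigh-type closed form (Weibull shape 2)
  pars1 <- default_params(d = 1)
  th1 <- characteristic_scales(pars1)$theta
  expect_equal(radius_moments(pars1)$mean, th1 * gamma(3 / 2))
  # Monte-Carlo oracle
  set.seed(11)
  draws <- rweibull(1e6, shape = 4, scale = th)
  expect_lt(abs(mean(draws) - mom$mean), 3 * sd(draws) / 1e3)
  expect_lt(abs(var(draws) - mom$variance), 3 * mom$variance * sqrt(2 / 1e6) * 2)
})

test_that("conditional location density is the shell measure", {
  x <- 7.3
  y <- c(1, 3, 6.9)
  expect_equal(location_density_conditional(y, x, 3), 3 * y^2 / x^3)
  expect_equal(location_density_conditional(y, x, 2), 2 * y / x^2)
  expect_equal(location_density_conditional(y, x, 1), rep(1 / x, 3))
  expect_equal(location_density_conditional(x + 1, x, 3), 0)
  expect_error(location_density_conditional(1, 0, 3), "positive")
  for (d in 1:3) {
    expect_equal(integrate(location_density_conditional, 0, x, x = x,
                           d = d)$value, 1, tolerance = 1e-10)
  }
})

test_that("marginal location density agrees with direct marginalisation", {
  set.seed(5)
  for (d in 1:3) {
    pars <- random_params(d = d)
    th <- characteristic_scales(pars)$theta
    for (y in runif(4, 0.05, 2) * th) {
      direct <- integrate(function(x) {
        location_density_conditional(y, x, d) * radius_density(x, pars)
      }, y, Inf, rel.tol = 1e-10)$value
      expect_equal(location_density(y, pars), direct, tolerance = 1e-7)
    }
  }
})

test_that("location moments match the printed values and the shell identity", {
  pars <- default_params()
  th <- characteristic_scales(pars)$theta
  mom <- location_moments(pars)
  expect_equal(signif(mom$mean / th, 2), 0.68)
  expect_equal(signif(mom$variance / th^2, 2), 0.07)
  # E[Y | X] = d/(d+1) X gives an independent closed-form route
  for (d in 1:3) {
    p <- default_params(d = d)
    m <- location_moments(p)
    rm <- radius_moments(p)
    expect_equal(m$mean, d / (d + 1) * rm$mean, tolerance = 1e-6)
    ex2 <- d / (d + 2) * (rm$variance + rm$mean^2)
    expect_equal(m$variance, ex2 - m$mean^2, tolerance = 1e-5)
  }
})

test_that("posterior radius given a sweep is the rescaled Weibull", {
  pars <- default_params()
  sc <- characteristic_scales(pars)
  x <- c(2, 5, 9)
  expect_equal(posterior_radius_density(x, pars),
               4 * x^3 / (sc$beta^3 * sc$theta^4) *
                 exp(-x^4 / (sc$beta^3 * sc$theta^4)))
  expect_equal(posterior_radius_mean(pars),
               gamma(5 / 4) * sc$beta^(3 / 4) * sc$theta)
  expect_error(
    posterior_radius_density(1, macro_params(c_wt = 1, c_m = 1, mu = 1e-6)),
    "zero-probability")
})

test_that("numeric posterior satisfies Bayes' rule with independent factors", {
  pars <- default_params()
  sc <- characteristic_scales(pars)
  xs <- seq(0.2, 1.4, length.out = 10) * sc$theta
  post <- posterior_radius_density(xs, pars, method = "numeric")
  # independent assembly: conditional probability by adaptive quadrature in y,
  # prior from the Weibull law, evidence from the numeric double integral
  p_sweep <- sweep_probability(pars, method = "numeric")
  for (i in seq_along(xs)) {
    p_cond <- integrate(function(y) {
      conditional_sweep_prob(rep(xs[i], length(y)), y, pars, "exact") *
        location_density_conditional(y, xs[i], 3)
    }, 0, xs[i], rel.tol = 1e-8)$value
    expect_equal(post[i], p_cond * radius_density(xs[i], pars) / p_sweep,
                 tolerance = 0.02)
  }
  # posterior mass concentrates below the prior mean (sweeps start early)
  expect_lt(sum(xs * post) / sum(post), radius_moments(pars)$mean)
})

test_that("tumour-scale unit conversion follows the volume arithmetic", {
  est <- cancer_speed_estimate(1, 20)
  expect_equal(est$c_um_per_day, (3 / (4 * pi))^(1 / 3) * 1e4 / (20 * 365.25))
  expect_equal(signif(est$c_um_per_day, 2), 0.85)
  # doubling the generation time doubles the per-generation speed
  expect_equal(cancer_speed_estimate(1, 20, generation_days = 8)$c_cells_per_generation,
               2 * est$c_cells_per_generation)
  # when the cell diameter equals the daily generation distance the two
  # speeds coincide numerically
  est2 <- cancer_speed_estimate(5, 10, cell_diameter_um = 13,
                                generation_days = 13 / 1)
  expect_equal(est2$c_cells_per_generation, est2$c_um_per_day * 1)
})
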