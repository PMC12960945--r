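test_that("envelopment probability is mutation-rate free and oracle-consistent", {
  pars <- default_params()
  p <- envelopment_probability(pars)
  expect_gt(p, 0)
  expect_lt(p, 1)
  # independence of the mutation rate
  pars10 <- macro_params(pars$c_wt, pars$c_m, mu = pars$mu * 10, d = 3)
  expect_lt(abs(envelopment_probability(pars10) - p), 1e-6)
  # degenerate cases
  expect_equal(envelopment_probability(macro_params(0.3, 0.3, 1e-6, d = 3)), 0)
  expect_error(envelopment_probability(default_params(d = 1)), "1D")
  # Monte-Carlo oracle in 2D and 3D
  set.seed(41)
  for (d in 2:3) {
    pd <- default_params(d = d)
    pe <- envelopment_probability(pd)
    mc <- envelopment_probability_mc(pd, reps = 4000)
    expect_lt(abs(mc$estimate - pe), 3 * mc$se + 1e-6)
  }
})

test_that("fixed-radius sweep probability shrinks with radius and mutation rate", {
  mu <- 0.23e-5
  c_m <- 0.31
  # vanishing wildtype: nothing to replace
  expect_gt(sweep_probability_fixed_radius(0.05, mu, c_m), 0.999)
  p_x <- vapply(c(10, 15, 20, 30), sweep_probability_fixed_radius,
                numeric(1), mu = mu, c_m = c_m)
  expect_true(all(diff(p_x) < 0))
  p_mu <- vapply(mu * c(0.3, 1, 3, 10), function(m) {
    sweep_probability_fixed_radius(20, m, c_m)
  }, numeric(1))
  expect_true(all(diff(p_mu) < 0))
  # Monte-Carlo oracle
  set.seed(42)
  p <- sweep_probability_fixed_radius(20, mu, c_m)
  mc <- sweep_probability_fixed_radius_mc(20, mu, c_m, reps = 2e4)
  expect_lt(abs(mc$estimate - p), 3 * mc$se + 1e-4)
})

test_that("exponential-growth dominance needs a large rate advantage", {
  mu <- 1e-5
  r_wt <- 0.01
  # enormous advantage: immediate dominance
  expect_gt(sweep_probability_exponential(r_wt, 1e4 * r_wt, mu), 0.99)
  # increasing in the mutant rate
  p <- vapply(r_wt * c(1.5, 2, 3, 5, 10), function(rm) {
    sweep_probability_exponential(r_wt, rm, mu)
  }, numeric(1))
  expect_true(all(diff(p) > 0))
  # relative insensitivity: 100-fold change in mutation rate moves the
  # dominance probability by a bounded factor, while the bounded-population
  # model responds by orders of magnitude
  p_exp <- vapply(c(1e-6, 1e-5, 1e-4), function(m) {
    sweep_probability_exponential(r_wt, 10 * r_wt, m)
  }, numeric(1))
  expect_lt(max(p_exp) / min(p_exp), 5)
  p_log <- vapply(c(1e-6, 1e-4), function(m) {
    sweep_probability_logistic_fixed_N(5e4, 1, 6, m)
  }, numeric(1))
  expect_gt(p_log[1] / p_log[2], 1e3)
  # Monte-Carlo oracle
  set.seed(43)
  p3 <- sweep_probability_exponential(r_wt, 3 * r_wt, mu)
  mc <- sweep_probability_exponential_mc(r_wt, 3 * r_wt, mu, reps = 1e5)
  expect_lt(abs(mc$estimate - p3), 3 * mc$se + 1e-4)
  expect_error(sweep_probability_exponential(0.01, 0.03, 1e-5, 1.2), "0, 1")
})

test_that("fixed-size logistic sweeps are sensitive to N and mu", {
  r_wt <- 1
  r_m <- 6
  expect_gt(sweep_probability_logistic_fixed_N(2.5, r_wt, r_m, 1e-5), 0.999)
  p_N <- vapply(c(1e3, 1e4, 5e4, 2e5), function(n0) {
    sweep_probability_logistic_fixed_N(n0, r_wt, r_m, 1e-5)
  }, numeric(1))
  expect_true(all(diff(p_N) < 0))
  p_mu <- vapply(c(1e-6, 1e-5, 1e-4), function(m) {
    sweep_probability_logistic_fixed_N(5e4, r_wt, r_m, m)
  }, numeric(1))
  expect_true(all(diff(p_mu) < 0))
  # Monte-Carlo oracle at the canonical size
  set.seed(44)
  p <- sweep_probability_logistic_fixed_N(5e4, r_wt, r_m, 1e-5)
  mc <- sweep_probability_logistic_fixed_N_mc(5e4, r_wt, r_m, 1e-5, reps = 1e4)
  expect_lt(abs(mc$estimate - p), 3 * mc$se + 1e-4)
})

test_that("mutation-rate sensitivity separates growing from bounded models", {
  # expanding models: mutation-rate invariant
  pars <- default_params()
  pars10 <- macro_params(pars$c_wt, pars$c_m, mu = pars$mu * 10, d = 3)
  expect_equal(sweep_probability(pars10), sweep_probability(pars))
  expect_equal(envelopment_probability(pars10), envelopment_probability(pars))
  # bounded models: strictly decreasing in the mutation rate
  expect_lt(sweep_probability_fixed_radius(20, 2.3e-5, 0.31),
            sweep_probability_fixed_radius(20, 2.3e-6, 0.31))
  expect_lt(sweep_probability_logistic_fixed_N(5e4, 1, 6, 1e-4),
            sweep_probability_logistic_fixed_N(5e4, 1, 6, 1e-5))
})
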