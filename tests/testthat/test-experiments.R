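test_that("sweep-frequency estimates carry exact binomial intervals", {
  none <- estimate_sweep_probability(rep(FALSE, 1000))
  expect_equal(none$frequency, 0)
  expect_equal(none$ci_upper, 0.003682084, tolerance = 1e-5)
  all_s <- estimate_sweep_probability(rep(TRUE, 50))
  expect_equal(all_s$frequency, 1)
  set.seed(51)
  x <- sample(c(TRUE, FALSE), 400, replace = TRUE)
  expect_identical(estimate_sweep_probability(x),
                   estimate_sweep_probability(rev(x)))
  expect_error(estimate_sweep_probability(logical(0)), "empty")
})

test_that("truncated-gamma ML recovers known parameters", {
  set.seed(52)
  shape <- 8
  scale <- 30
  trunc <- 300
  x <- rgamma(5000, shape = shape, scale = scale)
  x <- x[x <= trunc][1:1000]
  fit <- fit_truncated_gamma(x, trunc)
  expect_lt(abs(fit$shape - shape) / shape, 0.1)
  expect_lt(abs(fit$scale - scale) / scale, 0.1)
  true_tail <- pgamma(trunc, shape, scale = scale, lower.tail = FALSE)
  adj <- undercount_adjustment(x, trunc, n_replicates = 2000)
  se_tail <- 3 * sqrt(true_tail * (1 - true_tail) / 1000)
  expect_lt(abs(adj$missing_fraction - true_tail), se_tail + 0.02)
  expect_gte(adj$adjusted_probability, adj$raw_frequency)
})

test_that("samples far below the truncation imply no missing mass", {
  set.seed(53)
  x <- rgamma(800, shape = 8, scale = 30)
  x <- x[x <= 1000]
  adj <- undercount_adjustment(x, 1000, n_replicates = 1000)
  expect_lt(adj$missing_fraction, 0.01)
  expect_equal(adj$adjusted_probability, adj$raw_frequency, tolerance = 0.02)
})

test_that("artificial truncation of a fully observed batch overestimates", {
  # radii of a batch whose sweeps were all observed (no real truncation)
  set.seed(54)
  n_rep <- 1000
  radii <- rgamma(420, shape = 10, scale = 18)
  full_freq <- length(radii) / n_rep
  trunc <- quantile(radii, 0.8)
  kept <- radii[radii <= trunc]
  adj <- undercount_adjustment(kept, trunc, n_replicates = n_rep)
  expect_gte(adj$adjusted_probability, full_freq * 0.999)
})

test_that("adjustment input validation works", {
  expect_error(undercount_adjustment(runif(5, 1, 2), 3, 100), "at least")
  expect_error(undercount_adjustment(rep(4, 30), 3, 100), "lie in")
})

test_that("surviving-effect summary averages established mutations only", {
  toy <- data.frame(id = 0:3, parent = c(-1, -1, 1, 1),
                    r = c(0.91, 1, 1.3, 1.05),
                    max_abundance = c(1e5, 1e5, 50, 3))
  expect_equal(mean_surviving_fitness_effect(toy), 0.3)
  toy$max_abundance[3] <- 4
  expect_true(is.na(mean_surviving_fitness_effect(toy)))
  # selection bias: surviving mutations have larger mean effect than raw draws
  set.seed(55)
  s <- 0.1
  eff <- s * rexp(1e4)
  surv <- runif(1e4) < moran_survival_probability(1, 1 + eff, 16)
  recs <- data.frame(id = seq_len(1e4) + 1, parent = 1,
                     r = 1 + eff,
                     max_abundance = ifelse(surv, 10, 1))
  recs <- rbind(data.frame(id = c(0, 1), parent = c(-1, -1), r = c(0.91, 1),
                           max_abundance = c(1e5, 1e5)), recs)
  s_tilde <- mean_surviving_fitness_effect(recs)
  expect_gt(s_tilde, mean(eff))
})

test_that("theory comparison table evaluates both prediction routes", {
  fake_batch <- function(r_m, sweeps, n) {
    structure(list(
      results = data.frame(sweep = c(rep(TRUE, sweeps), rep(FALSE, n - sweeps))),
      config = sim_config(r_m = r_m, stop_N = 1e4),
      n = n), class = "batch_result")
  }
  speeds <- data.frame(r_m = c(1.3, 1.5), c_m = c(0.30, 0.40))
  tab <- compare_abm_to_theory(list(fake_batch(1.3, 25, 100),
                                    fake_batch(1.5, 40, 100)),
                               speeds, c_wt = 0.15, d = 2)
  expect_equal(tab$theory_speeds[1], 0.25)  # c_m = 2 c_wt in 2D
  expect_equal(tab$a_ratio, c(0.09 / 0.3, 0.09 / 0.5))
  expect_equal(tab$theory_rates,
               c(sweep_probability_from_rates(0.91, 1, 1.3, 2),
                 sweep_probability_from_rates(0.91, 1, 1.5, 2)))
  # observed 0.25 equals theory at r_m = 1.3: not flagged
  expect_false(tab$excluded[1])
  expect_error(compare_abm_to_theory(list(fake_batch(2, 10, 100)), speeds,
                                     c_wt = 0.15), "no measured speed")
})

test_that("the full pipeline is reproducible end to end from one seed", {
  cfg <- sim_config(stop_N = 5e3, mu_tilde = 1e-4)
  run <- function() {
    b <- run_batch(cfg, n = 4, seed = 314)
    estimate_sweep_probability(b)$frequency
  }
  expect_identical(run(), run())
})
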