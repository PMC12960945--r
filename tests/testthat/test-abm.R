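test_that("Moran survival probability matches its closed form and limits", {
  expect_equal(moran_survival_probability(1, 1.3, 16),
               (1 - 1 / 1.3) / (1 - (1 / 1.3)^16))
  expect_equal(round(moran_survival_probability(1, 1.3, 16), 2), 0.23)
  expect_equal(round(moran_survival_probability(1, 2, 16), 2), 0.5)
  expect_equal(moran_survival_probability(1, 1, 16), 1 / 16)
  # continuity at the neutral point
  expect_equal(moran_survival_probability(1, 1 + 1e-10, 16), 1 / 16,
               tolerance = 1e-6)
})

test_that("empirical within-deme fixation matches the Moran formula", {
  for (r_m in c(1.15, 1.3)) {
    sim <- moran_fixation_sim(1, r_m, 16, reps = 4e4, seed = 101)
    expect_lt(abs(sim$estimate - moran_survival_probability(1, r_m, 16)),
              3 * sim$se)
  }
  # neutral invader fixes with probability ~ 1/K
  sim0 <- moran_fixation_sim(1, 1, 16, reps = 4e4, seed = 102)
  expect_lt(abs(sim0$estimate - 1 / 16), 3 * sim0$se)
})

test_that("random mutation effects respect the epistatic ceiling", {
  set.seed(7)
  expect_equal(draw_mutation_effect(10, s = 1, M = 10, n = 5), rep(10, 5))
  r <- draw_mutation_effect(1, s = 50, M = 10, n = 1e4)
  expect_true(all(r <= 10))
  expect_error(draw_mutation_effect(11, 1, 10), "ceiling")
  # pre-cap regime: mean relative gain is s (1 - r/M) since E[X] = 1
  r0 <- 2
  s <- 0.05
  gains <- draw_mutation_effect(r0, s, 10, n = 1e6) / r0 - 1
  expect_equal(mean(gains), s * (1 - r0 / 10),
               tolerance = 3 * sd(gains) / sqrt(1e6) / (s * (1 - r0 / 10)))
})

test_that("effective radius is the unit-density disc radius", {
  expect_equal(effective_radius(0), 0)
  expect_equal(round(effective_radius(1e6)), 564)
  expect_equal(effective_radius(pi * 100^2), 100)
  expect_error(effective_radius(-1), "non-negative")
})

test_that("simulations are bit-reproducible under a fixed seed", {
  cfg <- sim_config(stop_N = 5e3, mu_tilde = 1e-4)
  a <- run_simulation(cfg, seed = 2024)
  b <- run_simulation(cfg, seed = 2024)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$series, b$series)
  expect_identical(a$outcome, b$outcome)
})

test_that("without mutation no replicate ever reports a sweep", {
  cfg <- sim_config(mu_tilde = 0, stop_N = 3e3, stop_generations = 300)
  for (seed in 1:10) {
    res <- run_simulation(cfg, seed = seed)
    expect_false(res$outcome$sweep)
    expect_equal(nrow(res$genotypes), 2L)  # only resident and wildtype
  }
})

test_that("population counts are conserved in the recorded series", {
  cfg <- sim_config(stop_N = 2e4, mu_tilde = 1e-4)
  res <- run_simulation(cfg, seed = 31)
  ser <- res$series
  # the invader clade grows from one individual and never goes negative
  expect_true(all(ser[, "N_inv"] >= 0))
  expect_true(all(ser[, "N_wt"] <= ser[, "N_inv"]))
  expect_equal(unname(ser[1, "N_inv"]), 1)
  # recorded genotype abundances sum to the final clade size
  g <- res$genotypes
  expect_equal(sum(g$abundance[g$id >= 1]), res$outcome$N_inv)
})

test_that("sweep detection is consistent and monotone in stringency", {
  cfg <- sim_config(stop_N = 2e4, mu_tilde = 2e-4, sweep_stringency = 1)
  hits <- 0L
  for (seed in 1:8) {
    res <- run_simulation(cfg, seed = seed + 100)
    if (res$outcome$stop_reason == "extinct") next
    d1 <- detect_sweep(res)
    expect_identical(d1$sweep, res$outcome$sweep)
    d_half <- detect_sweep(res, stringency = 0.5)
    # relaxing the definition can only add sweeps
    expect_true(d_half$sweep >= d1$sweep)
    hits <- hits + d1$sweep
    if (d1$sweep) {
      expect_true(is.finite(d1$sweep_radius))
      expect_lte(d1$sweep_radius, effective_radius(cfg$stop_N) + 1)
    }
  }
})

test_that("first-survivor records identify the earliest established lineage", {
  cfg <- sim_config(stop_N = 2e4, mu_tilde = 2e-4)
  found <- FALSE
  for (seed in 1:40) {
    if (found) break
    res <- run_simulation(cfg, seed = seed + 500)
    g <- res$genotypes
    surv <- g[g$id >= 2 & g$max_abundance >= 10, , drop = FALSE]
    if (nrow(surv) == 0) next
    found <- TRUE
    fs <- record_first_survivor(res)
    idx <- which.min(surv$birth_time)
    expect_equal(fs$radius, sqrt(surv$birth_N_wt[idx] / pi))
    expect_equal(fs$distance, surv$origin_dist_demes[idx] * 4)
    # an unreachable threshold returns the sentinel
    fs_hi <- record_first_survivor(res, survival_abundance = Inf)
    expect_true(is.na(fs_hi$radius))
  }
  expect_true(found)
})

test_that("batches are reproducible and resample extinct attempts", {
  cfg <- sim_config(stop_N = 5e3, mu_tilde = 1e-5)
  b1 <- run_batch(cfg, n = 5, seed = 77)
  b2 <- run_batch(cfg, n = 5, seed = 77)
  expect_identical(b1$results, b2$results)
  expect_equal(nrow(b1$results), 5L)
  expect_true(all(b1$results$stop_reason != "extinct"))
  expect_gte(b1$extinct_attempts, 0L)
})

test_that("expansion speed increases with the invader's advantage", {
  sp_small <- measure_expansion_speed(1.1, 1, max_radius = 60, replicates = 3,
                                      background_migrates = TRUE, seed = 5)
  sp_big <- measure_expansion_speed(1.5, 1, max_radius = 60, replicates = 3,
                                    background_migrates = TRUE, seed = 5)
  expect_gt(sp_big$c, sp_small$c)
  expect_gt(sp_small$c, 0)
})

test_that("thinned and explicit scheduling sample the same process", {
  base <- list(stop_N = 6e3, r_m = 1.3, mu_tilde = 1e-4, grid_extent = 35L,
               stop_generations = 800)
  stats <- lapply(c(TRUE, FALSE), function(mode) {
    cfg <- do.call(sim_config, c(base, list(use_thinning = mode)))
    b <- run_batch(cfg, n = 60, seed = 4242)
    list(freq = mean(b$results$sweep),
         muts = sapply(b$genotypes, nrow) - 2,
         t_end = b$results$t_end)
  })
  n <- 60
  se_freq <- sqrt(sum(sapply(stats, function(s) {
    max(s$freq * (1 - s$freq), 0.01) / n
  })))
  expect_lt(abs(stats[[1]]$freq - stats[[2]]$freq), 3 * se_freq)
  se_mut <- sqrt(var(stats[[1]]$muts) / n + var(stats[[2]]$muts) / n)
  expect_lt(abs(mean(stats[[1]]$muts) - mean(stats[[2]]$muts)), 3 * se_mut)
  se_t <- sqrt(var(stats[[1]]$t_end) / n + var(stats[[2]]$t_end) / n)
  expect_lt(abs(mean(stats[[1]]$t_end) - mean(stats[[2]]$t_end)), 3 * se_t)
})
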