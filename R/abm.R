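#' Configuration for the deme-based agent-based model
#'
#' Parameters of the two-dimensional spatial Moran (stepping-stone) simulator.
#' Space is a square lattice of well-mixed demes of carrying capacity `K`,
#' initially filled with residents (proliferation rate `r_re`, never
#' dispersing); a single wildtype invader (rate `r_wt`) is introduced at the
#' central deme. At each event an individual is chosen at random, weighted by
#' its proliferation rate, and replaced by two offspring; each offspring
#' migrates with probability `m` to a neighbouring deme; any deme above `K`
#' immediately loses uniformly chosen individuals until back at capacity.
#' Mutation is coupled to reproduction of mutation-capable genotypes: each
#' division yields a mutated offspring with probability `mu_tilde`.
#'
#' With `effect_mode = "fixed"` every mutant has proliferation rate `r_m` and
#' at most one mutation can accumulate. With `effect_mode = "random"` each
#' mutation multiplies fitness by an Exp(1)-distributed factor scaled by `s`
#' under diminishing-returns epistasis with birth-rate ceiling `M`:
#' `r_child = min(r_parent * (1 + s X (1 - r_parent / M)), M)`; up to
#' `max_mutations` (or unlimited, `Inf`) mutations can accumulate.
#'
#' One generation is the time in which a rate-1 individual divides once.
#' Lengths are measured in units in which one individual occupies unit area,
#' so the effective radius of N individuals is `sqrt(N / pi)` and one deme
#' width is `sqrt(K)` of these units.
#'
#' @param K Deme carrying capacity.
#' @param m Offspring migration probability.
#' @param mu_tilde Per-division mutation probability.
#' @param r_re,r_wt Resident and wildtype proliferation rates.
#' @param effect_mode `"fixed"` or `"random"`.
#' @param r_m Mutant proliferation rate (fixed mode).
#' @param s Mean-effect scale (random mode).
#' @param M Maximum birth rate under diminishing returns (random mode).
#' @param max_mutations Maximum mutations per lineage (`Inf` = unlimited;
#'   forced to 1 in fixed mode).
#' @param stop_N Stop once the invader clade reaches this size.
#' @param stop_generations Stop at this time if `stop_N` was not reached.
#' @param grid_extent Lattice half-width in demes; `NULL` sizes the grid to
#'   contain the expansion up to `stop_N` with a safety margin.
#' @param neighbourhood 4 (von Neumann) or 8 (Moore) migration neighbourhood.
#' @param sweep_stringency Fraction of the invader clade that must share a
#'   mutation for a sweep to be called (1 = all individuals).
#' @param record_interval Time between recorded population snapshots
#'   (generations).
#' @param use_thinning If `TRUE` (default), demes that are homogeneous and at
#'   capacity are scheduled by an exactly marginalised thinned process; if
#'   `FALSE` every deme is simulated explicitly. The two settings sample the
#'   same process; the explicit mode exists for validation and is far slower.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(K = 16, m = 0.05, mu_tilde = 1e-5,
                       r_re = 0.91, r_wt = 1,
                       effect_mode = c("fixed", "random"),
                       r_m = 1.3, s = 0.1, M = 10,
                       max_mutations = NULL,
                       stop_N = 1e6, stop_generations = 2000,
                       grid_extent = NULL, neighbourhood = 4,
                       migration_coupling = c("single", "both"),
                       sweep_stringency = 1, record_interval = 1,
                       use_thinning = TRUE) {
  migration_coupling <- match.arg(migration_coupling)
  effect_mode <- match.arg(effect_mode)
  stopifnot(K >= 1, m >= 0, m <= 1, mu_tilde >= 0, r_re > 0, r_wt > 0,
            stop_N > 0, stop_generations > 0, neighbourhood %in% c(4, 8),
            sweep_stringency > 0, sweep_stringency <= 1, record_interval > 0)
  if (effect_mode == "fixed") {
    if (!(r_m > r_wt)) stop("fixed mode requires r_m > r_wt")
    if (!(r_wt > r_re)) stop("require r_wt > r_re")
    max_mutations <- 1
  } else {
    stopifnot(s > 0, M > r_wt)
    if (is.null(max_mutations)) max_mutations <- 1
    if (!is.infinite(max_mutations)) stopifnot(max_mutations >= 1)
  }
  if (is.null(grid_extent)) {
    # contain the final effective radius (in deme widths) with headroom for
    # the rough front and for an off-centre mutant lobe outrunning the
    # wildtype front (its origin can lie up to the arrival radius off-centre)
    grid_extent <- ceiling(2 * sqrt(stop_N / pi) / sqrt(K)) + 10L
  }
  structure(list(K = as.integer(K), m = m, mu_tilde = mu_tilde,
                 r_re = r_re, r_wt = r_wt, effect_mode = effect_mode,
                 r_m = r_m, s = s, M = M,
                 max_mutations = max_mutations,
                 stop_N = stop_N, stop_generations = stop_generations,
                 grid_extent = as.integer(grid_extent),
                 neighbourhood = as.integer(neighbourhood),
                 migration_coupling = migration_coupling,
                 sweep_stringency = sweep_stringency,
                 record_interval = record_interval,
                 use_thinning = use_thinning),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Deme-model configuration: K = %d, m = %g, mu_tilde = %g, r_re = %g, r_wt = %g\n",
    x$K, x$m, x$mu_tilde, x$r_re, x$r_wt))
  if (x$effect_mode == "fixed") {
    cat(sprintf("  fixed mutation effects: r_m = %g (at most one mutation)\n", x$r_m))
  } else {
    cat(sprintf("  random multiplicative effects: s = %g, M = %g, max mutations = %s\n",
                x$s, x$M, format(x$max_mutations)))
  }
  cat(sprintf("  stop: N = %g or %g generations; grid extent %d demes\n",
              x$stop_N, x$stop_generations, x$grid_extent))
  invisible(x)
}

#' Run one agent-based replicate
#'
#' Simulates the deme model from a single wildtype invader until the invader
#' clade reaches `stop_N` individuals, `stop_generations` elapse, the clade
#' goes extinct, or the expansion hits the lattice boundary (an error
#' advising a larger `grid_extent`).
#'
#' @param config A [sim_config()] object.
#' @param seed Integer RNG seed (runs are reproducible bit-for-bit).
#' @param snapshot If `TRUE`, also return the final lattice as a matrix of
#'   locally dominant genotype ids.
#' @return An object of class `sim_result`: a list with `outcome` (stop
#'   reason, end time, clade sizes, sweep call, sweep radius/time, number of
#'   completed sweeps), `genotypes` (lineage table with per-genotype origin,
#'   rate, abundance and fixation records), `series` (time series of clade
#'   sizes) and the `config`.
#' @export
run_simulation <- function(config, seed = 1L, snapshot = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  max_mut <- if (is.infinite(config$max_mutations)) -1L else
    as.integer(config$max_mutations)
  raw <- .run_abm_cpp(config$K, config$m, config$mu_tilde,
                      config$r_re, config$r_wt,
                      config$effect_mode == "fixed",
                      config$r_m, config$s, config$M, max_mut,
                      config$stop_N, config$stop_generations,
                      config$grid_extent, config$neighbourhood,
                      config$sweep_stringency, config$record_interval,
                      FALSE, snapshot,
                      if (config$migration_coupling == "both") 2L else 1L,
                      isTRUE(config$use_thinning))
  if (identical(raw$stop_reason, "boundary")) {
    stop("expansion reached the lattice boundary before stopping; ",
         "increase 'grid_extent'")
  }
  structure(list(
    outcome = list(stop_reason = raw$stop_reason, t_end = raw$t_end,
                   N_inv = raw$N_inv, N_wt = raw$N_wt, sweep = raw$sweep,
                   sweep_radius = raw$sweep_radius,
                   sweep_time = raw$sweep_time, n_sweeps = raw$n_sweeps),
    genotypes = raw$genotypes,
    series = raw$series,
    snapshot = raw$snapshot,
    config = config, seed = seed), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  o <- x$outcome
  cat(sprintf(
    "Deme-model replicate (seed %s): stopped by %s at t = %.1f, invader clade N = %g\n",
    format(x$seed), o$stop_reason, o$t_end, o$N_inv))
  cat(sprintf("  sweep: %s%s; genotypes recorded: %d\n",
              ifelse(o$sweep, "yes", "no"),
              if (o$sweep) sprintf(" (radius %.1f at t = %.0f)",
                                   o$sweep_radius, o$sweep_time) else "",
              nrow(x$genotypes)))
  invisible(x)
}

#' Run a batch of replicates
#'
#' Runs `n` replicates of [run_simulation()] with sub-seeds derived from a
#' single master seed. Replicates in which the invader clade went extinct
#' before establishing are resampled (a batch is a set of realised
#' expansions); the number of extinct attempts is recorded.
#'
#' @inheritParams run_simulation
#' @param n Number of (surviving) replicates.
#' @param max_attempts Safety cap on total attempts.
#' @return An object of class `batch_result` with per-replicate outcome rows,
#'   the genotype tables, and the attempt log.
#' @export
run_batch <- function(config, n = 200, seed = 1L, max_attempts = 100 * n) {
  stopifnot(inherits(config, "sim_config"), n >= 1)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, max_attempts)
  rows <- vector("list", n)
  genos <- vector("list", n)
  kept <- 0L
  attempts <- 0L
  extinct <- 0L
  while (kept < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("exceeded 'max_attempts' before collecting n surviving replicates")
    }
    res <- run_simulation(config, seed = sub_seeds[attempts])
    if (res$outcome$stop_reason == "extinct") {
      extinct <- extinct + 1L
      next
    }
    kept <- kept + 1L
    fs <- record_first_survivor(res)
    rows[[kept]] <- data.frame(
      replicate = kept, seed = sub_seeds[attempts],
      stop_reason = res$outcome$stop_reason,
      t_end = res$outcome$t_end, N_inv = res$outcome$N_inv,
      sweep = res$outcome$sweep, sweep_radius = res$outcome$sweep_radius,
      sweep_time = res$outcome$sweep_time, n_sweeps = res$outcome$n_sweeps,
      first_survivor_radius = fs$radius,
      first_survivor_distance = fs$distance)
    genos[[kept]] <- res$genotypes
  }
  structure(list(results = do.call(rbind, rows), genotypes = genos,
                 config = config, seed = seed, n = n,
                 attempts = attempts, extinct_attempts = extinct),
            class = "batch_result")
}

#' @export
print.batch_result <- function(x, ...) {
  cat(sprintf(
    "Batch of %d replicates (%d extinct attempts resampled): %d sweeps\n",
    x$n, x$extinct_attempts, sum(x$results$sweep)))
  invisible(x)
}

#' Moran fixation (drift-survival) probability
#'
#' Probability that a single mutant with proliferation rate `r_m` fixes in a
#' well-mixed deme of `K` individuals otherwise at rate `r_wt`:
#' `rho = (1 - r_wt/r_m) / (1 - (r_wt/r_m)^K)`, with the neutral limit `1/K`.
#' For small migration probabilities this local fixation probability is the
#' probability that a new mutant survives genetic drift in the spatial model.
#'
#' @param r_wt Rate of the established type.
#' @param r_m Rate of the new mutant.
#' @param K Deme size.
#' @return A probability (vectorised over the rate arguments).
#' @export
#' @examples
#' moran_survival_probability(1, 1.3, 16)  # about 0.23
moran_survival_probability <- function(r_wt, r_m, K) {
  stopifnot(all(r_wt > 0), all(r_m > 0), K >= 1)
  g <- r_wt / r_m
  ifelse(abs(g - 1) < 1e-12, 1 / K, (1 - g) / (1 - g^K))
}

#' Empirical single-deme Moran fixation frequency
#'
#' Simulates the within-deme dynamics of the agent-based model (fitness-
#' weighted division followed by a uniform death among the K + 1 present)
#' from a single mutant, and returns the fixation frequency. Cross-checks
#' [moran_survival_probability()].
#'
#' @inheritParams moran_survival_probability
#' @param reps Number of replicates.
#' @param seed RNG seed.
#' @return A list with `estimate`, `se`, `fixed` and `reps`.
#' @export
moran_fixation_sim <- function(r_wt, r_m, K, reps = 1e5, seed = 1L) {
  set.seed(seed)
  fixed <- .moran_fix_cpp(r_wt, r_m, as.integer(K), as.integer(reps))
  p <- fixed / reps
  list(estimate = p, se = sqrt(p * (1 - p) / reps), fixed = fixed,
       reps = reps)
}

#' Draw random multiplicative mutation effects
#'
#' Birth rate of a mutant offspring under exponentially distributed
#' multiplicative effects with diminishing-returns epistasis:
#' `r_child = min(r_parent (1 + s X (1 - r_parent / M)), M)` with `X ~ Exp(1)`.
#'
#' @param r_parent Parent birth rate (`0 < r_parent <= M`).
#' @param s Mean-effect scale (> 0).
#' @param M Maximum birth rate.
#' @param n Number of draws.
#' @return `n` mutant birth rates.
#' @export
draw_mutation_effect <- function(r_parent, s, M, n = 1) {
  stopifnot(s > 0, M > 0)
  if (any(r_parent > M)) stop("'r_parent' must not exceed the ceiling 'M'")
  if (any(r_parent <= 0)) stop("'r_parent' must be positive")
  x <- stats::rexp(n)
  pmin(r_parent * (1 + s * x * (1 - r_parent / M)), M)
}

#' Effective radius of a population
#'
#' Radius of a disc holding `N` individuals at unit density: `sqrt(N / pi)`.
#' This is the length scale in which the deme model's expansion speeds are
#' measured.
#'
#' @param N Population size (`>= 0`).
#' @return Effective radius.
#' @export
effective_radius <- function(N) {
  if (any(N < 0)) stop("'N' must be non-negative")
  sqrt(N / pi)
}

#' Measure a radial expansion speed
#'
#' Simulates the expansion of an invader (rate `r_invader`) into a uniform
#' background population (rate `r_background`) without mutation, and
#' estimates the radial speed by linear regression of the effective radius
#' `sqrt(N / pi)` of the invader clade against time, per replicate, after the
#' propagation front is established (radius above `fit_min_radius`).
#' Replicates in which the invader went extinct are resampled and counted.
#'
#' Residents in the main model cannot disperse, so measuring the wildtype
#' speed uses `background_migrates = FALSE`; measuring the mutant speed within
#' the wildtype uses `background_migrates = TRUE`.
#'
#' @param r_invader,r_background Proliferation rates (`r_invader` >
#'   `r_background`).
#' @param K,m,neighbourhood As in [sim_config()].
#' @param max_radius Effective radius at which each replicate stops.
#' @param replicates Number of surviving replicates.
#' @param fit_min_radius Start of the regression window; defaults to 10 deme
#'   widths (`10 * sqrt(K)` radius units).
#' @param background_migrates Whether background offspring may disperse.
#' @param seed Master seed.
#' @param max_generations Time cap per replicate.
#' @return An object of class `speed_estimate` with the mean speed `c`, the
#'   per-replicate slopes, their standard deviation and relative SD, and the
#'   extinct-attempt count.
#' @export
measure_expansion_speed <- function(r_invader, r_background, K = 16, m = 0.05,
                                    max_radius = 160, replicates = 10,
                                    fit_min_radius = 10 * sqrt(K),
                                    background_migrates = FALSE,
                                    neighbourhood = 4,
                                    migration_coupling = c("single", "both"),
                                    seed = 1L, max_generations = 1e4) {
  migration_coupling <- match.arg(migration_coupling)
  stopifnot(r_invader > r_background, max_radius > fit_min_radius)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 100 * replicates)
  stop_N <- pi * max_radius^2
  extent <- ceiling(1.25 * max_radius / sqrt(K)) + 10L
  slopes <- numeric(replicates)
  kept <- 0L
  attempts <- 0L
  extinct <- 0L
  while (kept < replicates) {
    attempts <- attempts + 1L
    if (attempts > length(sub_seeds)) stop("too many extinct attempts")
    set.seed(sub_seeds[attempts])
    raw <- .run_abm_cpp(as.integer(K), m, 0, r_background, r_invader,
                        TRUE, r_invader + 1, 0.1, 10, 1L,
                        stop_N, max_generations, extent,
                        as.integer(neighbourhood), 1, 1,
                        background_migrates, FALSE,
                        if (migration_coupling == "both") 2L else 1L, TRUE)
    if (identical(raw$stop_reason, "boundary")) {
      stop("expansion reached the lattice boundary; increase 'max_radius' margin")
    }
    if (identical(raw$stop_reason, "extinct") ||
        raw$N_inv < pi * fit_min_radius^2) {
      extinct <- extinct + 1L
      next
    }
    ser <- raw$series
    radius <- sqrt(ser[, "N_inv"] / pi)
    keep <- radius >= fit_min_radius
    if (sum(keep) < 10L) {
      extinct <- extinct + 1L
      next
    }
    kept <- kept + 1L
    slopes[kept] <- stats::coef(
      stats::lm(radius[keep] ~ ser[keep, "t"]))[[2L]]
  }
  c_hat <- mean(slopes)
  structure(list(c = c_hat, slopes = slopes, sd = stats::sd(slopes),
                 relative_sd = stats::sd(slopes) / c_hat,
                 replicates = replicates, extinct_attempts = extinct,
                 r_invader = r_invader, r_background = r_background),
            class = "speed_estimate")
}

#' @export
print.speed_estimate <- function(x, ...) {
  cat(sprintf(
    "Expansion speed: c = %.4f radius units per generation (relative SD %.2f%%, %d replicates)\n",
    x$c, 100 * x$relative_sd, x$replicates))
  invisible(x)
}

#' Call a sweep from a simulation result
#'
#' A sweep is called when a single mutation is carried by at least
#' `stringency` of the living invader clade (all individuals for
#' `stringency = 1`, the default definition). When `stringency` matches the
#' value tracked during the run, the effective radius at the first time the
#' condition held is returned; for other stringencies the condition is
#' evaluated on the final state and the radius at stop is reported.
#'
#' @param result A `sim_result`.
#' @param stringency Fraction in (0, 1]; defaults to the tracked value.
#' @return A list with `sweep` (logical) and `sweep_radius`.
#' @export
detect_sweep <- function(result, stringency = NULL) {
  stopifnot(inherits(result, "sim_result"))
  tracked <- is.null(stringency) ||
    isTRUE(all.equal(stringency, result$config$sweep_stringency))
  if (tracked) {
    return(list(sweep = result$outcome$sweep,
                sweep_radius = result$outcome$sweep_radius))
  }
  stopifnot(stringency > 0, stringency <= 1)
  g <- result$genotypes
  n_inv <- result$outcome$N_inv
  if (n_inv <= 0 || nrow(g) <= 2) return(list(sweep = FALSE, sweep_radius = NA_real_))
  cov <- mutation_clade_abundance(g)
  hit <- cov >= stringency * n_inv - 1e-9 & cov > 0 & g$id >= 2
  list(sweep = any(hit),
       sweep_radius = if (any(hit)) effective_radius(n_inv) else NA_real_)
}

# abundance of each mutation's carrier clade (self plus all descendants)
mutation_clade_abundance <- function(genotypes) {
  cov <- genotypes$abundance
  for (i in rev(seq_len(nrow(genotypes)))) {
    p <- genotypes$parent[i]
    if (!is.na(p) && p >= 0) cov[p + 1L] <- cov[p + 1L] + cov[i]
  }
  cov
}

#' Birth statistics of the first surviving mutant
#'
#' Identifies the earliest-born mutant lineage whose abundance ever reached
#' `survival_abundance` individuals and returns the wildtype effective radius
#' at its birth and the distance of its origin deme from the grid centre
#' (both in radius units; one deme width is `sqrt(K)` units).
#'
#' @param result A `sim_result`.
#' @param survival_abundance Abundance a lineage must reach to count as
#'   having survived drift (default 10).
#' @return A list with `radius`, `distance` and the genotype `id`, or `NA`
#'   sentinels if no lineage qualified.
#' @export
record_first_survivor <- function(result, survival_abundance = 10) {
  stopifnot(inherits(result, "sim_result"))
  g <- result$genotypes
  cand <- g[g$id >= 2 & g$max_abundance >= survival_abundance, , drop = FALSE]
  if (nrow(cand) == 0L) {
    return(list(radius = NA_real_, distance = NA_real_, id = NA_integer_))
  }
  first <- cand[which.min(cand$birth_time), ]
  list(radius = effective_radius(first$birth_N_wt),
       distance = first$origin_dist_demes * sqrt(result$config$K),
       id = first$id)
}
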