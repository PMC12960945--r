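#' Sweep frequency with exact binomial confidence interval
#'
#' Observed sweep frequency of a batch with a Clopper-Pearson 95% interval
#' (exact intervals behave sensibly at the frequencies near zero that are
#' common here).
#'
#' @param batch A [run_batch()] result, or a logical vector of per-replicate
#'   sweep calls.
#' @param conf_level Confidence level.
#' @return A list with `frequency`, `n_sweeps`, `n`, `ci_lower`, `ci_upper`.
#' @export
estimate_sweep_probability <- function(batch, conf_level = 0.95) {
  sweeps <- if (inherits(batch, "batch_result")) batch$results$sweep else batch
  if (length(sweeps) == 0L) stop("empty batch")
  stopifnot(is.logical(sweeps))
  n <- length(sweeps)
  k <- sum(sweeps)
  ci <- stats::binom.test(k, n, conf.level = conf_level)$conf.int
  list(frequency = k / n, n_sweeps = k, n = n,
       ci_lower = ci[1L], ci_upper = ci[2L])
}

#' Maximum-likelihood fit of a right-truncated gamma distribution
#'
#' Fits shape and scale of a gamma distribution to observations known to lie
#' below a truncation point, by direct maximisation of the truncated
#' log-likelihood (moment-based initialisation, optimisation on log
#' parameters, convergence tolerance 1e-8).
#'
#' @param x Observations in `(0, truncation]`.
#' @param truncation Right-truncation point.
#' @return A list with `shape`, `scale`, `logLik` and `convergence`.
#' @export
fit_truncated_gamma <- function(x, truncation) {
  stopifnot(length(x) >= 2L, all(x > 0), all(x <= truncation))
  mx <- mean(x)
  vx <- stats::var(x)
  start <- log(c(shape = max(mx^2 / vx, 1e-3), scale = max(vx / mx, 1e-8)))
  nll <- function(p) {
    sh <- exp(p[1L])
    sc <- exp(p[2L])
    -(sum(stats::dgamma(x, shape = sh, scale = sc, log = TRUE)) -
        length(x) * stats::pgamma(truncation, shape = sh, scale = sc,
                                  log.p = TRUE))
  }
  fit <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(reltol = 1e-8, maxit = 5000L))
  list(shape = exp(fit$par[[1L]]), scale = exp(fit$par[[2L]]),
       logLik = -fit$value, convergence = fit$convergence)
}

#' Undercount adjustment for sweeps unfinished at the stop radius
#'
#' Simulations stopped at a fixed population size cannot observe sweeps that
#' would have completed at a larger radius. Fitting a right-truncated gamma
#' distribution to the observed sweep-completion radii and evaluating the
#' upper tail of the untruncated fit beyond the truncation radius estimates
#' the fraction of sweeps missed; dividing the raw frequency by one minus
#' this fraction gives the adjusted sweep probability. The correction
#' typically overestimates the missing fraction, so adjusted values are upper
#' bounds on the true sweep probability.
#'
#' @param sweep_radii Completion radii of the observed sweeps, in
#'   `(0, truncation_radius]`.
#' @param truncation_radius Effective radius at which simulations stopped
#'   (`sqrt(stop_N / pi)`).
#' @param n_replicates Total number of replicates in the batch.
#' @param min_n Minimum number of observed sweeps required for a fit.
#' @return An object of class `undercount_adjustment` with the gamma fit, the
#'   estimated `missing_fraction`, the `raw_frequency`, the
#'   `adjusted_probability` and a reliability flag.
#' @export
undercount_adjustment <- function(sweep_radii, truncation_radius,
                                  n_replicates, min_n = 20L) {
  stopifnot(n_replicates >= length(sweep_radii))
  if (length(sweep_radii) < min_n) {
    stop(sprintf("need at least %d observed sweeps to fit (got %d)",
                 min_n, length(sweep_radii)))
  }
  if (any(sweep_radii <= 0) || any(sweep_radii > truncation_radius)) {
    stop("sweep radii must lie in (0, truncation_radius]")
  }
  fit <- fit_truncated_gamma(sweep_radii, truncation_radius)
  missing_fraction <- stats::pgamma(truncation_radius, shape = fit$shape,
                                    scale = fit$scale, lower.tail = FALSE)
  raw <- length(sweep_radii) / n_replicates
  adjusted <- min(raw / (1 - missing_fraction), 1)
  # degenerate when the sample piles up against the truncation point
  unreliable <- fit$convergence != 0L ||
    mean(sweep_radii) > 0.95 * truncation_radius ||
    missing_fraction > 0.9
  structure(list(shape = fit$shape, scale = fit$scale,
                 truncation_radius = truncation_radius,
                 missing_fraction = missing_fraction,
                 raw_frequency = raw,
                 adjusted_probability = adjusted,
                 n_sweeps = length(sweep_radii),
                 n_replicates = n_replicates,
                 unreliable = unreliable),
            class = "undercount_adjustment")
}

#' @export
print.undercount_adjustment <- function(x, ...) {
  cat(sprintf(
    "Truncated-gamma undercount adjustment (truncation %.1f):\n", x$truncation_radius))
  cat(sprintf("  shape %.3g, scale %.3g; estimated missing fraction %.3g\n",
              x$shape, x$scale, x$missing_fraction))
  cat(sprintf("  raw frequency %.4g -> adjusted %.4g (upper bound)%s\n",
              x$raw_frequency, x$adjusted_probability,
              if (x$unreliable) " [unreliable fit]" else ""))
  invisible(x)
}

#' Mean fitness effect of drift-surviving mutations
#'
#' Under random mutation effects the drift-survival probability increases
#' with the effect size, so the mutations that matter macroscopically are a
#' biased sample of all mutations. This summary is the arithmetic mean effect
#' (birth-rate gain over the parent) of mutations whose lineage abundance
#' ever reached `abundance_threshold` individuals; it is the effect scale at
#' which random-effect batches are compared with fixed-effect theory.
#'
#' @param batch A [run_batch()] result, a single `sim_result`, or a genotype
#'   data frame with columns `id`, `parent`, `r` and `max_abundance`.
#' @param abundance_threshold Survival threshold (default 10 individuals).
#' @return The mean surviving effect, or `NA` if no mutation survived.
#' @export
mean_surviving_fitness_effect <- function(batch, abundance_threshold = 10) {
  genos <- if (inherits(batch, "batch_result")) {
    do.call(rbind, batch$genotypes)
  } else if (inherits(batch, "sim_result")) {
    batch$genotypes
  } else {
    batch
  }
  muts <- genos[genos$id >= 2, , drop = FALSE]
  if (nrow(muts) == 0L) return(NA_real_)
  parent_r <- genos$r[match(muts$parent, genos$id)]
  eff <- muts$r - parent_r
  keep <- muts$max_abundance >= abundance_threshold
  if (!any(keep)) return(NA_real_)
  mean(eff[keep])
}

#' Compare agent-based sweep frequencies with macroscopic theory
#'
#' Builds the comparison table between observed batch sweep frequencies and
#' the two theoretical routes: `beta^d` with `beta` from measured expansion
#' speeds, and the FKPP proliferation-rate mapping. A batch is flagged when
#' its exact binomial confidence interval excludes the speed-based
#' prediction.
#'
#' @param batches A list of [run_batch()] results (fixed effect mode), one
#'   per mutant rate.
#' @param speeds A data frame with columns `r_m` and `c_m` (measured mutant
#'   speeds) covering every batch, plus attribute-free column `c_wt` or a
#'   separate `c_wt` argument.
#' @param c_wt Measured wildtype speed.
#' @param d Spatial dimension of the simulations (2 for the deme model).
#' @return A data frame with one row per batch: rate ratio, observed
#'   frequency and confidence interval, the two theoretical predictions, and
#'   an exclusion flag.
#' @export
compare_abm_to_theory <- function(batches, speeds, c_wt, d = 2) {
  stopifnot(is.list(batches), length(batches) > 0L)
  rows <- lapply(batches, function(b) {
    stopifnot(inherits(b, "batch_result"))
    cfg <- b$config
    idx <- which(abs(speeds$r_m - cfg$r_m) < 1e-9)
    if (length(idx) != 1L) {
      stop(sprintf("no measured speed for r_m = %g", cfg$r_m))
    }
    c_m <- speeds$c_m[idx]
    est <- estimate_sweep_probability(b)
    beta <- (c_m - c_wt) / c_m
    theory_speeds <- max(beta, 0)^d
    theory_rates <- sweep_probability_from_rates(cfg$r_re, cfg$r_wt, cfg$r_m, d)
    data.frame(
      r_m = cfg$r_m,
      a_ratio = (cfg$r_wt - cfg$r_re) / (cfg$r_m - cfg$r_wt),
      observed = est$frequency,
      ci_lower = est$ci_lower, ci_upper = est$ci_upper,
      theory_speeds = theory_speeds,
      theory_rates = theory_rates,
      excluded = theory_speeds < est$ci_lower | theory_speeds > est$ci_upper)
  })
  do.call(rbind, rows)
}
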