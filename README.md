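# rangesweep

Probabilities and timings of selective sweeps in spatially expanding
populations — analytic theory plus a deme-based spatial Moran simulator.

## The problem

A wildtype population expands its range at constant radial speed
`c_wt` (a growing tumour, a biofilm, an invasive species displacing a
resident). Beneficial mutations arise at per-capita rate `mu_tilde`, survive
genetic drift with probability `rho`, and spread within the wildtype at
speed `c_m > c_wt`. Does the first surviving mutation replace the whole
population (a selective sweep), or do later mutations interfere?

With `mu = rho * mu_tilde`, the number of surviving mutations in `[0, t]` is
Poisson with mean `mu * integral N(s) ds`. From this single ingredient the
package derives, in 1, 2 and 3 dimensions:

- the arrival time, arrival radius `X` and origin distance `Y` of the first
  surviving mutant (Weibull and incomplete-gamma laws with characteristic
  scales `kappa`, `theta`);
- exact and closed-form conditional sweep probabilities, and the strikingly
  simple unconditional upper bound
  `Pr(sweep) <= beta^d`, `beta = (c_m - c_wt)/c_m`, independent of the
  mutation rate;
- the posterior arrival radius given a sweep (sweeps happen early);
- the FKPP mapping `Pr(sweep) = (1 - sqrt((r_wt - r_re)/(r_m - r_wt)))^d`
  from proliferation rates, and tumour-scale unit conversions;
- sweep/envelopment probabilities for alternative growth laws (boundary
  growth, fixed radius, exponential, fixed-size logistic), each with a
  Monte-Carlo oracle.

The theory is validated in-package by a two-dimensional deme-based spatial
Moran (stepping-stone) agent-based model with an exact-thinning Gillespie
core (`run_simulation`, `run_batch`, `measure_expansion_speed`), plus the
batch statistics used to compare the two: exact binomial sweep-frequency
intervals, the mean surviving fitness effect, and a right-truncated-gamma
correction for sweeps unfinished at the simulation stop size
(`undercount_adjustment`).

## Worked example

Canonical 3D parameters (`c_wt = 0.15` cell diameters/generation,
`mu_tilde = 1e-5`, `rho = 0.23`, `c_m = 0.31`):

```r
library(rangesweep)
pars <- macro_params(c_wt = 0.15, c_m = 0.31, mu_tilde = 1e-5, rho = 0.23, d = 3)
pars
#> Macroscopic range-expansion model (3D): c_wt = 0.15, c_m = 0.31, mu = 2.3e-06
#>   scales: kappa = 105.3, theta = 15.8, alpha = 9.982, beta = 0.5161

c(closed_form = sweep_probability(pars),
  numeric     = sweep_probability(pars, method = "numeric"))
#> closed_form     numeric
#>  0.13749119  0.08906858
```

The first surviving mutant arises when the wildtype radius is about
`E[X] = 14.3` cell diameters (0.91 theta), at distance `E[Y] = 10.7` from
the origin; even though the mutant spreads twice as fast as the wildtype, its
sweep probability is at most `beta^3 = 0.137` (exact marginalisation: 0.089),
no matter how small or large the mutation rate. Conditioned on sweeping, the
mutation arose at radius `E[X | sweep] = 8.7` — sweeps start early or not at
all.

On the simulation side:

```r
sp <- measure_expansion_speed(r_invader = 1, r_background = 0.91, seed = 42)
sp
#> Expansion speed: c = 0.1463 radius units per generation (relative SD 1.72%, 10 replicates)
```

which reproduces the model's published speed benchmark (`c_wt ~ 0.15`) for
the canonical deme parameters `K = 16`, `m = 0.05`.

A command-line front end over the same functions lives in
`inst/cli/rangesweep.R` (subcommands `theory`, `altmodel`, `abm`,
`experiment`, YAML/JSON configs).

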