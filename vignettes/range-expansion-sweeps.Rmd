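---
title: "Selective sweeps in expanding populations: model, simulator and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selective sweeps in expanding populations: model, simulator and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rangesweep)
```

## The question

When a population expands its range — a tumour invading tissue, a bacterial
colony spreading under antibiotic stress, an invasive species displacing a
resident competitor — beneficial mutations keep arising in the growing
wildtype. Will the first mutation that survives genetic drift replace the
entire population (a selective sweep), or will competing mutations arise first
and force clonal interference? `rangesweep` implements a macroscopic model
that answers this with closed-form and numerical probabilities, a
two-dimensional agent-based simulator that checks the theory against a
discrete spatial Moran process, and the statistical machinery linking the two.

## The macroscopic model

The wildtype is a d-ball whose radius grows at constant speed $c_{wt}$ (in
cell diameters per generation, taking unit cell density). Surviving mutations
arise at effective per-capita rate $\mu = \rho\,\tilde\mu$, where $\tilde\mu$
is the raw mutation rate and $\rho$ the drift-survival probability; the
mutant spreads within the wildtype at constant speed $c_m > c_{wt}$.

The number of surviving mutations in $[0,t]$ is Poisson with mean
$\mu\int_0^t N(s)\,ds$. Applied to the growing d-ball this yields, for the
first mutant:

* arrival time $T$: Weibull, shape $d+1$, scale
  $\kappa = ((d+1)/(\mu V_d c_{wt}^d))^{1/(d+1)}$;
* arrival radius $X = c_{wt} T$: Weibull, shape $d+1$, scale
  $\theta = c_{wt}\kappa$ (in 3D, $\theta = (3c_{wt}/\pi\mu)^{1/4}$, with
  $E[X] \approx 0.91\,\theta$ and $Var[X] \approx 0.065\,\theta^2$);
* origin distance $Y$ given $X=x$: the shell measure $d\,y^{d-1}/x^d$ on
  $[0,x]$; marginally
  $f_Y(y) = (d\,y^{d-1}/\theta^d)\,\Gamma\!\left(\tfrac1{d+1},
  (y/\theta)^{d+1}\right)$, so in 3D $E[Y] \approx 0.68\,\theta$ and
  $Var[Y] \approx 0.070\,\theta^2$.

A sweep succeeds if no second surviving mutation arises among the remaining
wildtype while the mutant replaces it. The remaining wildtype is the growing
wildtype ball minus its intersection with the growing mutant ball (a lens once
the mutant breaches the front); replacement completes at
$\tau_2 = (x+y)/(c_m - c_{wt})$. Exponentiating the integrated remaining
population gives the exact conditional sweep probability
(`conditional_sweep_prob(..., method = "exact")`). Placing the mutant at the
centre ($y=0$) gives the closed-form upper bound $e^{-(x/\alpha)^{d+1}}$ with
sweep length $\alpha$, and averaging that bound over $f_X$ collapses to

$$\Pr(\text{sweep}) \le \beta^d, \qquad
\beta = \frac{c_m - c_{wt}}{c_m},$$

independent of the mutation rate. The identity
$\alpha^{d+1}/(\alpha^{d+1}+\theta^{d+1}) = \beta^d$ holds to machine
precision and is what pins down the 1D and 2D $\alpha$ constants, which the
package derives from the same recipe rather than transcribing them.
Conditioning on a sweep, the arrival radius becomes Weibull with scale
$\beta^{d/(d+1)}\theta$ — sweeps that happen, happen early.

```{r}
pars <- macro_params(c_wt = 0.15, c_m = 0.31, mu_tilde = 1e-5, rho = 0.23, d = 3)
characteristic_scales(pars)
c(closed_form = sweep_probability(pars),
  numeric = sweep_probability(pars, method = "numeric"))
```

### Numerical integration protocol

The exact unconditional probability is a double marginalisation of the exact
conditional probability. It is computed by trapezoid integration on a
$\theta$-scaled grid: bounds $[0.001\theta,\,3\theta]$ in $x$ (outside which
$f_X$ is negligible at double precision), lower bound $0.001\theta$ in $y$,
grid widths $0.001\theta$ up to $0.5\theta$ and $0.01\theta$ beyond. The
width threshold is read as $0.5\theta$ since the whole protocol is
$\theta$-scaled. The inner replacement integral uses closed forms for the
pre-breach phase and 32-node Gauss–Legendre quadrature for the lens phase;
the lens volumes themselves are validated against a uniform-sampling
Monte-Carlo volume oracle in the test suite. Truncating $y$ below $0.001\theta$
removes $O(10^{-3d})$ of conditional mass; the conditional density is
renormalised on the retained grid so that the small-$x$ limit of the
conditional sweep probability is exactly 1.

The numeric value lies below $\beta^d$ (the $y=0$ bound) and is invariant
under two orders of magnitude of $\mu$ to better than $10^{-3}$ relative —
the two structural properties that make the closed form useful.

### Degenerate inputs and sentinels

`c_m = c_wt` is allowed everywhere: the sweep probability is 0, $\alpha$ is
returned as `Inf` with `sweep_possible = FALSE`, and the arrival laws remain
defined. Conditioning on a sweep in that regime raises an error, since it
conditions on a zero-probability event. `x = 0` returns conditional sweep
probability 1 (no wildtype left to replace).

## Alternative growth laws

Four variants isolate which ingredients drive the result (all built from the
same Poisson recipe, each validated against a direct Monte-Carlo oracle):

* **Boundary growth** (`envelopment_probability`): proliferation restricted
  to the front; sweeps are impossible and the analogue is the first front
  mutant *enveloping* the wildtype. The mutant patch edge moves at $c_m$
  along the inflating front, so its angular radius is
  $(c_m/c_{wt})\log(1+c_{wt}\tau/x)$ and envelopment completes in finite
  time; the marginalised probability is again mutation-rate free.
* **Fixed radius** (`sweep_probability_fixed_radius`): a static wildtype
  ball; the probability depends on both $\mu$ and $x_0$ and decreases in
  both.
* **Exponential growth** (`sweep_probability_exponential`): well-mixed,
  no competition; "sweep" means the first surviving mutant reaches a
  dominance threshold (default frequency 0.5 — the criterion is exposed as a
  parameter because reasonable definitions differ) before a second surviving
  mutation arises. Dominance requires a several-fold growth-rate advantage,
  and a 100-fold change in $\mu$ moves the probability by only a bounded
  factor.
* **Fixed size, logistic mutant** (`sweep_probability_logistic_fixed_N`):
  the wildtype-decay integral has the closed form
  $\exp(-\mu N_0 \log(N_0-1)/(r_m-r_{wt}))$ — strongly sensitive to both
  $N_0$ and $\mu$.

The sign pattern — expanding models mutation-rate free, bounded models
mutation-rate sensitive — is the module's headline property and is asserted
in the tests.

## The agent-based simulator

The simulator is a two-dimensional deme-based spatial Moran (stepping-stone)
process: square lattice of well-mixed demes with carrying capacity $K$,
filled with residents (rate $r_{re}$, never dispersing), one wildtype
invader (rate $r_{wt}$) at the centre. Events: a fitness-weighted individual
is replaced by two offspring; dispersal moves an offspring with probability
$m$ to a von Neumann neighbour (a Moore neighbourhood is available); any deme
above $K$ immediately loses uniformly chosen individuals until it is back at
capacity — the limit of the "very high death rate above capacity" rule,
chosen because it is deterministic in its effect and reproducible. One
generation is the time in which a rate-1 individual divides once. Mutation
is coupled to reproduction: a division of a mutation-capable genotype yields
one mutated offspring with probability $\tilde\mu$; in the fixed-effect model
mutants have rate $r_m$ and mutate no further, in the random-effect model
effects are exponential with diminishing returns near the ceiling $M$, with
a configurable cap (1, 2, 3 or unlimited) on mutations per lineage.

### Dispersal coupling

Whether dispersal at division applies to one daughter or to both
independently is a real degree of freedom of this model family. We calibrate
it against the model's own published speed benchmarks for the canonical
parameter set ($K=16$, $m=0.05$, $r_{re}=0.91$, $r_{wt}=1$, $r_m=1.3$):
single-daughter dispersal reproduces $c_{wt}\approx 0.15$ and
$c_m \approx 0.31$ (we measure $0.146$ and $0.297$ with relative SD
below 2%), whereas independent dispersal of both daughters gives
$c_{wt}\approx 0.25$ and $c_m\approx 0.47$. The default is therefore
`migration_coupling = "single"`, with `"both"` available.

### Exact thinning

A deme that is homogeneous and exactly at capacity cannot change any deme's
composition except through a division that mutates, exports an offspring to
a non-equivalent deme, or exports both offspring; every other event is an
identity map on the state. The simulator therefore schedules such demes with
the exact marginal rate of the relevant outcomes and samples the outcome
conditioned on relevance (two Fenwick trees over deme rates drive the
Gillespie selection). This is a reformulation, not an approximation: the
process distribution is unchanged, but wave-front simulations with $10^5$ to
$10^6$ individuals run in seconds because the inert bulk is never iterated.
The machinery is validated by the Moran-fixation oracle (the within-deme
dynamics reproduce $\rho = (1-r_{wt}/r_m)/(1-(r_{wt}/r_m)^K)$ to Monte-Carlo
precision), by the speed benchmarks, and by bit-reproducibility under a fixed
seed.

### Measurement conventions

* Lengths are reported in units where one individual occupies unit area: the
  effective radius of a clade of $N$ individuals is $\sqrt{N/\pi}$ and one
  deme width is $\sqrt K$ units.
* Speeds are the slope of a per-replicate linear regression of effective
  radius against time after the front is established (default: radius above
  10 deme widths), averaged over replicates; replicates whose invader went
  extinct are resampled and counted. Speeds are defined for advantageous
  invaders; a neutral "invasion" has no travelling front to measure.
* A sweep is called when one mutation is carried by at least a stringency
  fraction (default 1, i.e. all) of the living invader clade — the displaced
  resident species, which persists outside the front at any stop time, is
  not part of the sweeping population. The radius at the first time the
  condition holds is recorded.
* The first surviving mutant is the earliest-born lineage whose abundance
  ever reached 10 individuals; its birth radius and origin distance are the
  quantities compared with $f_X$ and $f_Y$.
* Batches resample replicates in which the invader clade went extinct before
  establishing: the theory conditions on an expansion actually happening,
  and the observed sweep frequencies (about $\beta^2$) are only comparable
  under that conditioning — unconditional frequencies would carry an extra
  factor of the wildtype's own establishment probability ($\approx 0.12$
  against the resident at the default rates).

## Problem sizes and what the tests show

The package's quantitative checks run at desk scale, documented here as the
package's own study conditions:

* Speed benchmarks: 10 replicates, front travel to effective radius 160
  (40 deme widths).
* Sweep-frequency validation at $r_m = 1.3$: 200 replicates stopped at
  $N = 10^5$ invaders; the exact binomial CI is compared with $\beta^2$
  computed from the measured speeds.
* Mutation-rate independence: batches at $\tilde\mu = 10^{-4}$ and $10^{-6}$
  (100 and 75 replicates). The stop size of an arm must keep the truncation
  radius $\sqrt{N_{stop}/\pi}$ above the sweep-completion scale
  ($\approx 2.4\,\theta$, and $\theta \propto \mu^{-1/(d+1)}$ grows as the
  mutation rate falls); the $10^{-6}$ arm therefore runs at $N = 3\times10^5$.
  At a stop of $10^5$ that arm's frequency collapses to $\approx 0.08$ purely
  through censoring — a truncation artifact, not a mutation-rate effect.
* The geometric Monte-Carlo oracle uses $10^6$ uniform points per volume.
* Undercount adjustment: parameter recovery at $n = 1000$ observations. The
  truncated-gamma MLE at this size has sampling SD near 7% per parameter, so
  recovery is asserted on the median over 10 synthetic datasets rather than
  on a single draw.

What passing these tests shows: the analytic machinery agrees with
independent oracles, and the discrete stochastic model agrees with the
macroscopic theory under the canonical parameters *when speeds are measured
from the simulation itself*. What it does not show: agreement for parameter
regimes where the front is only a few demes wide (strong discreteness),
behaviour of real biological systems with heterogeneous environments, or the
3D agent-based case (out of scope; the simulator is two-dimensional).

## Undercount correction

Simulations stopped at a fixed population size miss sweeps that would have
completed later. Fitting a right-truncated gamma distribution to the
observed sweep-completion radii (direct maximisation of the truncated
log-likelihood, moment-based start, tolerance $10^{-8}$) and measuring the
fitted mass beyond the truncation estimates the missed fraction; dividing
the raw frequency by the retained mass gives an adjusted probability,
treated as an upper bound. In our hands the fitted tail can under- as well
as over-shoot the true censored mass when the truncation cuts deep into the
distribution (removing 25–40% of sweeps); the correction is reliable in its
intended regime, where the stop radius clips only the tail (of order 10% of
sweeps or less), and `undercount_adjustment()` flags fits with large
estimated missing fractions as unreliable.

## Tumour-scale numbers

`cancer_speed_estimate()` converts a gross growth observation into model
units: a tumour reaching 1–10 cm$^3$ over 5–20 years gives
$\tilde c \approx 0.85$–$7.3\,\mu$m/day (the arithmetic of the volume-to-
radius conversion; note this is narrower than the 1–40 $\mu$m/day sometimes
quoted for the same inputs), i.e. $c_{wt}\approx 0.17$–1.5 cell diameters
per generation at a 20 $\mu$m cell and 4-day cycle. With
$\tilde\mu = 10^{-5}$ and $\rho$ between 0.09 and 0.5, $\theta$ is tens of
cells: a mutant 10% faster than its host tumour sweeps with probability
below $10^{-3}$; even a 10-fold speed advantage leaves sweep probability
below 0.73, with sweeps confined to the first $\sim$50-cell radius of
growth. This is the quantitative sense in which late tumour evolution is
expected to be branched rather than linear.
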