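---
title: "Methods: site frequency spectra in the two-type branching model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: site frequency spectra in the two-type branching model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twotypeSFS)
```

## The model

`twotypeSFS` studies the cumulative site frequency spectrum (SFS) — the
number `M(f)` of mutations carried by at least a fraction `f` of a
population — in the two-type branching model of clonal tumor evolution. A
resident *type-0* population grows as a supercritical birth–death process
(birth `a0`, death `b0`, net growth `lambda0 = a0 - b0 > 0`). Each type-0
cell mutates at rate `u1` into a fitter *type 1* (birth `a1`, death `b1`,
net growth `lambda1 > lambda0`). Neutral mutations arrive continuously over
every cell's lifetime at rate `nu`, each one unique (infinite-sites) and
inherited by all descendants.

Three mutation classes result:

* **type 0** — neutral mutations in type-0 cells,
* **type 1A** — the driver mutations that found type-1 families,
* **type 1** — neutral mutations inside type-1 families.

The neutral classes obey the familiar `1/f` law: for continuous lifetime
mutation at rate `nu` in a population growing at rate `lambda`,
`M(f) = nu/(lambda f)` (`neutral_sfs()`, mode `"continuous"`); for mutation
only at birth at rate `mu` per division, `M(f) = mu/f` regardless of the
growth rate (mode `"at_birth"`). The driver class does not: conditioned on
type-0 survival (`Z0(t) = V0 e^{lambda0 t}`, `V0 ~ Exp(lambda0/a0)`),
successful families arrive as an inhomogeneous Poisson process, each grows
as `W e^{lambda1 (t - s)}` with `W ~ Exp(lambda1/a1)`, and the rescaled
family sizes converge to the points of a Poisson process with tail measure
`C V0 x^{-alpha}`, `alpha = lambda0/lambda1` and
`C = lambda0 Gamma(alpha) / lambda1^alpha` (`limit_intensity_constant()`).
The ranked family fractions therefore follow the Poisson–Dirichlet
distribution `PD(alpha, 0)`, and the expected driver spectrum is

```
SFS_1A(f) = sin(pi alpha) / (pi alpha) * (1/f - 1)^alpha
```

(`sfs_1a()`; the leading constant is `2/pi = 0.6366` at `alpha = 1/2`).
A fitted cumulative spectrum `C/f^beta` with `beta < 1` thus separates
two-type selection (`beta ~ alpha`) from neutral growth (`beta = 1`) — the
package's headline discriminator.

A note on the intensity constant: with the default rates
(`lambda0 = 0.02`, `lambda1 = 0.04`, `alpha = 1/2`) the constant evaluates
to `0.02 * Gamma(1/2) / 0.04^{1/2} = 0.17725`. We adopt this form, which is
the one consistent with the worked numerical value used throughout the
package's checks.

```{r constants}
p <- two_type_params()
median_first_success_time(p)   # median time of the first successful driver
limit_intensity_constant(p)    # the constant C above
sfs_1a(0.5, p$alpha)           # driver spectrum at f = 1/2: sin(pi a)/(pi a)
```

## Default parameters

All defaults form one concrete, internally consistent example:
`a0 = a1 = 1`, `lambda0 = 0.02`, `lambda1 = 0.04` (time measured in cell
cycles; multiply by ~4 days/division for a colon-cancer-like clock),
`u1 = 1e-6` per cell per unit time for drivers, and `nu = 1e-4` for neutral
mutations. These are deliberately generic rather than fitted to any tumor
type. Two derived anchors are worth keeping in mind: the first successful
driver appears around time 460 (about 5 years at 4 days/division), and a
fitter subclone sweeps from 20% to 80% of the tumor in
`ln(16)/(lambda1 - lambda0)` time units — only 185 at a growth-rate gap of
0.015, which is why subclones are rarely caught at intermediate frequency.

The SFS simulation experiments use a deliberately *higher* mutation regime
(`u1 = 2e-4`, `nu = 0.02`) so that a few hundred runs produce dense,
well-resolved spectra; growth rates are unchanged, so the shape theory
(which depends only on `alpha`) is untouched.

## Simulators

**Exact engine.** `simulate_exact()` is an exact Gillespie simulation of the
full jump process. Cells are aggregated by genotype; genotypes form a tree
in which each node adds one mutation to its parent, so carrier counts come
from a single upward pass at the end. Event selection is O(1) per event
(per-cell rates are constant within a type, so a uniform cell of the chosen
type is picked). It is intended for up to ~10^6 cells; a `cell_cap` guard
aborts gracefully with partial history beyond that.

**Hybrid engine.** `simulate_hybrid_type1()` /`simulate_random_fitness()`
replace the type-0 mass and the within-family demography by their
large-population limits: deterministic `V0 e^{lambda0 t}` type-0 growth
(with `V0` sampled or fixed at its mean `a0/lambda0`), Poisson founder
times, exponential family amplitudes, founder passengers
`Poisson(nu * s_i)`, and within-family neutral mutations placed by a
homogeneous Poisson process on the inverse-frequency axis at rate
`nu/lambda` (the within-family `1/f` law). Mutation counts are
Poisson-sampled rather than set to their expectations; averaged over a few
hundred runs the two choices are indistinguishable, but sampling keeps
single-run spectra honest. The constant-fitness simulator is implemented as
the random-fitness engine with a degenerate `Normal(lambda1, 0)`
distribution, so the two agree draw-for-draw at `d = 0`.

Two approximations are built into the hybrid engine and should be kept in
mind when interpreting matches with the exact engine:

* founder passengers are private to each founder — shared type-0 ancestry
  between founders is ignored. This is justified by the dominance
  calculation `second_family_dominance_prob()`: a family founded
  `4/lambda1` after the first overtakes it with probability
  `1/(1 + e^4) = 0.018`, so all important families arise close together and
  carry statistically equivalent passenger loads;
* the type-0 population is conditioned on survival and treated as
  deterministic given `V0`.

**Random fitness.** Each successful family draws its own growth rate from
`Normal(m, d)`. A candidate with rate `l` succeeds with probability
`min(max(l, 0), a1)/a1` (negative draws never succeed), so successful
families carry the size-biased density proportional to
`min(max(l, 0), a1) * phi(l)`. We sample it by rejection from
`Normal(m + d^2/m, d)` using the envelope `l <= m e^{(l-m)/m}`; the
acceptance rate is `~e^{-d^2/(2m^2)}`, essentially 1 for `d << m`, which is
what makes runs with tens of thousands of families per replicate cheap.
The matching closed form `random_fitness_family_tail()` gives the expected
number of families with size proxy `lambda_i (t_end - s_i) > x`, using the
normal partial-expectation identity for the inner tail integral; the
degenerate `d = 0` case is evaluated analytically rather than by quadrature
because the integrand then has a step discontinuity.

**Fixed final size.** `simulate_driver_frequency()` grows the tumor to a
prescribed total size `M` and records the subclone fraction `f_sub`, either
with only the first successful driver (`single_1A`, the classical
one-driver assumption behind `bozic_subclonal_cdf()`) or with every
successful family (`multiple_1A`). The stopping time is found by bisection
on the monotone total-size path to relative tolerance 1e-6. One genuine
finding of the package's cross-checks: the two modes agree closely in the
upper tail (fixation probabilities), and `multiple_1A` agrees with the
exact engine by a Kolmogorov–Smirnov test on a down-scaled regime, but the
single-driver assumption visibly *understates* `f_sub` at low thresholds —
with many successful families the subclonal mass is never as small as the
first family alone would suggest. The headline detectability bound (below)
concerns the window `[0.2, 0.8]` and survives this.

## The subclonal-driver detectability formula

In the fixed-final-size notation (`bozic_params()`: type-0 birth `b`, death
`d`, `r = b - d`; subclone `b1`, `d1`, `r1`; `c = r1/r > 1`), the type-0
population at the first successful driver is `X0 ~ Exp(uc/b1)` and the
subclone amplitude is `W1 ~ Exp(cr/b1)`, giving

```
P(f_sub <= y) = Int_0^M (uc/b1) e^{-uc x0/b1}
                [1 - exp(-(cr/b1) y (1-y)^{-c} x0^c M^{1-c})] dx0.
```

The inner exponent's grouping — `(1-y)` raised to `-c` — follows from the
boundary decomposition `Y_t <= (y/(1-y)) X_t` with `X_t = (1-y) M`; the
code documents this next to the formula. Quadrature is adaptive with
absolute tolerance 1e-10 after substituting `z = (uc/b1) x0` so the
exponential weight is O(1); a fixed midpoint Riemann mode with a 500-cell
step is provided as well, to reproduce the coarser tabulation sometimes
used for theory curves (it drifts near `y -> 1`, where the integrand's
small-`x0` rise is under-resolved). Probabilities are clamped to `[0, 1]`
after evaluation. `detectable_driver_probability()` is the difference of
two CDF values; at moderate selection (`g = 0.3`, `u = 1e-5`,
`b = b1 = 0.14`, `r = 0.01`) it stays below 15% for all `M` up to 10^9
cells:

```{r detect}
vapply(c(1e7, 1e8, 1e9), function(M) {
  detectable_driver_probability(
    bozic_params(b = 0.14, d = 0.13, b1 = 0.14, d1 = 0.127,
                 u = 1e-5, M = M))
}, numeric(1))
```

## Poisson–Dirichlet sampling

`sample_pd()` uses GEM(`alpha`, 0) stick-breaking — residual fractions
`Beta(1 - alpha, i * alpha)` in size-biased order, sorted — with 100 atoms
by default; the unbroken remainder bounds the omitted mass and is reported.
`sample_poisson_atoms()` is an independent construction: ranked points
`x_k = (Gamma_k / (C v0))^{-1/alpha}` of the limiting Poisson process,
generated until the expected omitted mass is below a requested fraction of
the realized sum, then normalized. The two constructions are used as
mutual oracles in the tests (two-sample KS on the largest fraction; count
law of raw points; agreement of the empirical atom spectrum with
`sfs_1a()`). Only the one-parameter family `PD(alpha, 0)` is provided —
that is the one the family-size limit produces.

## Fitting and analysis windows

`fit_inverse_f()` regresses `M(f)` on `1/f`; `fit_power_law()` regresses
`log M(f)` on `log f`. Both report `R^2` and their window, and the window
genuinely matters because both laws are *asymptotic as f → 0*:

* the driver spectrum's `(1 - f)^alpha` factor steepens the log–log slope;
  the local slope is `alpha/(1 - f)`, so on the display window
  `[0.05, 0.5]` the fitted exponent of the exact closed form is ~0.62 at
  `alpha = 0.5`. We therefore quote driver exponents from `[0.01, 0.2]`
  (closed-form value 0.53) when comparing against `alpha`, and keep
  `[0.05, 0.5]` as the default display window;
* adding the founder passengers steepens the slope further, by roughly
  `(nu/lambda1) / (1 + nu * s_mean)` at every window: passenger counts grow
  linearly in the founding time while family sizes shrink exponentially in
  it, so late (low-frequency) families carry more hitchhikers. In the
  high-mutation experiment this adds ~0.08 to the driver-only exponent on
  moderate windows; the combined driver+passenger exponent is read off at
  `[0.005, 0.05]`, where it sits within 0.1 of `alpha`;
* the aggregate type-1 neutral spectrum has slope
  `(nu/lambda1) * (expected family mass above f)`; the mass deficit decays
  only like `f^{1/2}` at `alpha = 1/2`, so the neutral-rate recovery is fit
  on `[0.002, 0.05]`, where the fitted slope of the corrected closed form
  is within ~5% of `nu/lambda1`;
* in the exact simulator, carrier-count discreteness additionally depresses
  the spectrum at frequencies corresponding to only a handful of cells.

Cumulative (not binned) spectra are the primary object throughout; the grid
is 200 log-spaced points by default. Empirical spectra can be averaged over
runs and decomposed by mutation class (`empirical_sfs()`).

## Problem sizes used in the checks

The test suite and the reproduction script run entirely from generated
data: 200 replicates for the high-mutation SFS experiment (run to
`t = 500`, where a run holds ~450 successful families and the large-time
regime `t - s_med ~ 300` applies; materialized mutation frequencies are cut
at `f_min = 5e-4`, far below every fitting window); 5000 Poisson–Dirichlet
draws for the spectrum check; 10^4 extinction replicates; ~10^2 exact runs
of a down-scaled regime (`lambda0 = 0.2`, `lambda1 = 0.4`, `u1 = 0.01`,
~10^4 cells) for the exact-vs-hybrid comparison; and 200–400 replicates per
setting for the random-fitness and fixed-final-size experiments. Where a
published-scale experiment would use more replicates (e.g. 1000), the
scaled-down counts were chosen so all Monte-Carlo comparisons still resolve
their targets at 3 standard errors.

## Known limitations

* No spatial structure, no sequencing noise, no sampling model: frequencies
  are true population fractions, so passing tests say nothing about
  read-depth or purity artifacts in real variant-allele-frequency data.
* Only two fitness classes (plus the normal random-fitness variant); no
  second-wave drivers inside type-1 families.
* The hybrid engine's private-passenger approximation slightly misstates
  the correlation structure of founder passengers; it does not affect the
  spectrum's shape (the dominance calculation above), which is what the
  package measures.
* The exact engine is memory-bound around 10^6 cells; beyond that only the
  hybrid limits are available, and they assume the large-time asymptotics
  have set in (`t_end` well past the median first-success time).
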