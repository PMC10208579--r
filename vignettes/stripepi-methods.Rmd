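---
title: "Models and methods behind stripepi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stripepi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stripepi)
```

`stripepi` quantifies environment-dependent epistasis between
cis-regulatory mutations in a three-node stripe-forming circuit. This
vignette explains the models the package implements, the choices behind
its defaults, and what its synthetic-data tests do and do not establish.

## The circuit model

The network is an incoherent feedforward loop: an arabinose-activated
sensor represses both a regulator and the output; the regulator also
represses the output. At low inducer the free regulator silences the
output, at high inducer the sensor does, and in between neither
dominates — the output peaks, forming a stripe along the gradient.

The experimental system this design emulates is characterized only by
measurement, with no published rate equations, so the generator is the
package's own model: an algebraic steady state with standard Hill
terms. With `rep(x; K, n) = K^n / (K^n + x^n)`:

```
S(a)    = beta_S [ b_S + (1 - b_S) a^n_a / (K_a^n_a + a^n_a) ]
R(S)    = beta_R [ b_R + (1 - b_R) rep(S; K_SR, n_SR) ]
O(S, R) = scale * beta_O [ b_O + (1 - b_O) rep(S; K_SO, n_SO) rep(R; K_RO, n_RO) ]
```

This is the simplest generative model that reproduces the low–high–low
mechanism. Defaults (`circuit_params()`): promoter rates `beta` =
100/50/1000 a.u., basal fractions 0.01, `K_a = 5e-4` % arabinose
(`n_a = 1`), `K_SR = 10`, `K_SO = 30`, `K_RO = 5` a.u. (Hill
coefficients 2). The half-repression constants are ordered
`K_SR < K_SO` so the sensor shuts the regulator off at lower inducer
than it shuts the output off — that window is the stripe. At the three
assay concentrations (0, 0.0002, 0.2 % w/v) the wild type evaluates to
roughly 20, 232 and 89 a.u.: the medium value is strictly the largest,
which is the package's operational stripe criterion (`is_stripe()`).

A mutant allele perturbs only the cis-region of its own node:
multiplicatively on that node's `beta` (promoter) and on the binding
constants of inputs acting there (operators): `K_a` for the sensor,
`K_SR` for the regulator, `K_SO` and `K_RO` for the output.
`draw_mutant_effects()` samples multipliers log-uniformly on
[1/2.5, 2.5] and rejects alleles whose single-mutant network loses the
stripe, emulating a library from which only stripe-retaining mutants
were kept. The range is a free choice: wide enough to move expression
several-fold, narrow enough that stripe-retaining draws are common.

## Replicate noise and generation modes

Replicate noise is multiplicative log-normal with unit mean and
coefficient of variation `cv` (default 0.10 — the source study reports
replicate variability only graphically, so the default is the package's
choice of a typical plate-reader CV; it is a config field, not a
constant). The wild-type reference of a replicate is the mean of
`n_wt_wells = 3` simulated control wells, mirroring the plate layout
used for normalization.

Three generation modes make every downstream stage testable:

* `mechanistic` — combinations simulated from the circuit with all
  constituent effects applied; epistasis arises from the Hill
  nonlinearities.
* `multiplicative_null` — a combination's noiseless expression is
  *exactly* the product of its singles' fold changes times WT; all true
  epistasis is zero by construction.
* `multiplicative_plus_interactions` — the null plus `10^delta` on
  chosen combinations at chosen levels; the injected `delta` *is* the
  true epistasis, enabling recovery tests.

## Plate processing

The raw-plate path mirrors a kinetic plate-reader assay: per-well OD
(logistic growth over a media blank) and fluorescence (proportional to
cell density, rising then slowly decaying). Processing follows the
assay's published protocol: read all wells at the time the WT
fluorescence at medium inducer peaks (`select_timepoint()`; ties break
to the earliest time, a maximum on the last time point is flagged
`no_peak`); correct as `(gfp - mean blank gfp) / (od - mean blank od)`
(whether the protocol subtracts a blank OD in the denominator is
unstated, so `subtract_blank_od = FALSE` is available); scale each
plate so its WT wells average exactly 1, then re-apply the WT scaling
across plates — the second stage is an identity after the first, which
makes the normalization idempotent (a tested invariant). Replicates
whose OD deviates from the plate's WT mean by more than 0.2 in any
condition are excluded; genotypes left with fewer than two replicates
are flagged `needs_repeat`. A metabolic-load condition, when present,
passes through as a QC column only: the source protocol reports no
decision rule for it.

`run_all()` consumes the tidy normalized dataset directly; the
raw-plate stages are exercised on genotype subsets in the tests and
here, since a full raw-plate simulation of all 1331 genotypes adds data
volume but no additional code path.

## Epistasis statistics

Log fold changes are computed per replicate against the
replicate-matched WT mean and then summarized (mean, sample SD with the
n−1 denominator, n) — not as a ratio of means. The expected G of a
combination is the sum of its singles' G.

**Error propagation.** The study's printed propagation multiplies the
root-sum-of-squares of the singles' SDs by the mean of the expected
value itself: `sigma_exp = |G_exp| * sqrt(sum sigma_i^2)`, and
analogously `sigma_epistasis = |epsilon| * sqrt(sigma_obs^2 +
sigma_exp^2)`. This form is dimensionally unusual (it vanishes when the
expectation or the epistasis is 0) and may be a relative-error
convention; whether it is intended cannot be decided from the text.
Both are therefore implemented: `sigma_mode = "as_printed"` is the
default for fidelity, `"sum_of_variances"` is the standard choice. The
practical consequences, visible in the package's own null simulations,
are that the as-printed mode is anticonservative for records whose
expectation is near zero, and that it makes the inducer-dependence
Welch tests liberal wherever epsilon changes strongly across levels —
in mechanistic runs essentially every combination is called
inducer-dependent. Calibration-style checks in the test suite
therefore bound the FDR behaviour (calls at q < 0.05 under a global
null must not exceed the binomial 99% envelope of the nominal rate),
which any correctly controlling procedure satisfies in either mode.

**Testing.** Each epsilon is tested with a two-sided pooled-variance t
test on summary statistics (replicate n on both sides, df = n1+n2−2),
the form the study used. When both SDs are zero the test is degenerate:
means equal up to round-off give p = 1, genuinely different means give
p = 0 with a warning. P values are adjusted within each order's family
(900 pairwise, 3000 triplet at M = 10; pooling is available) — by
default Storey q values with the smoother π0 estimate (λ grid
0.05–0.95 step 0.05, spline df 3, π0 clamped to (0, 1]), matching the
named procedure's base parameters; the `qvalue` estimator is
re-implemented in-package. Significance is q < 0.05.

**Inducer dependence** runs Welch tests between the epsilon estimates
at each pair of levels and applies the two-stage
Benjamini-Krieger-Yekutieli step-up at q < 0.1 within each order's
family (stage one: BH at α/(1+α) to estimate m0; stage two: BH scaled
by m0/m). `p.adjust` offers no BKY option, so the procedure is
implemented directly; reported q values are the m0/m-scaled BH adjusted
p values and flags are the two-stage decisions.

**Third order.** The pair-based expectation subtracts the singles once
so no contribution is double-counted; the decomposition
`epsilon = epsilon3 + sum of pairwise epsilons` is an algebraic
identity and is enforced to 1e-9 over arbitrary random tables in the
tests (observed deviations are at machine precision).

## Classification rules

Type classes formalize the ordering definitions: single *i* is
*reversed* in a combination when the combined G lies on the opposite
side of G_i from the summed effect of the remaining singles. No
reversal is magnitude epistasis, some-but-not-all is sign epistasis,
all reversed is reciprocal sign epistasis (RSE). For singles that all
raise (all lower) expression this reduces exactly to the familiar
rules — combined beyond every single: magnitude; between the extremes:
sign; opposite side of every single: RSE — verified against a
brute-force ordering oracle on 10,000 random instances. Mixed-direction
groups cannot oppose *every* single's own direction, so they cap at
sign epistasis and are reported with `direction_group = "mixed"`; this
triplet/mixed extension goes beyond the pairwise prose it generalizes.
Only significant records are classified by default (`significant_only`).

Categories A–D bin each combination by where its epistasis extremum
sits: A medium-maximum, B increasing, C decreasing, D medium-minimum;
exact ties (which have measure zero in data) break towards the
medium-extremum categories and carry a `tie` flag. Trajectories
(`always_positive` / `always_negative` / `switching`) use point
estimates regardless of significance, and categories are assigned to
all combinations with the dependence flag alongside — the source
figures quantify all combinations, not only dependent ones.

## Phenotype space

`(Mx, My) = (G_medium − G_low, G_high − G_medium)` with G the log10
**normalized fluorescence** (not the fold change versus WT): absolute
coordinates place the WT and all stripe-retaining singles in the stripe
quadrant, as the phenotype plots require; distances are unaffected by
the choice because per-level constants cancel in the differences (a
tested invariant). Quadrants: increase (Mx>0, My>0), anti-stripe
(Mx≤0, My>0), decrease (Mx≤0, My≤0), stripe (Mx>0, My≤0); the half-open
convention makes boundary points deterministic and flags them;
`flat_radius` (default 0, strict quadrants) optionally classes
near-origin points as flat since no numeric "near the origin" threshold
is published. Expected points put each combination at
`G_WT + sum of singles' log fold changes` per level. Observed and
expected distances to the WT point are compared with a two-sided
Wilcoxon matched-pairs signed-rank test; when all paired differences
vanish the test is degenerate and p is reported as 1 with a flag. The
direct displacement `||M_exp − M_obs||` per genotype is also emitted as
a supplementary column, since the published distance formula is written
in that form while the accompanying analysis compares distances to WT.

## Problem sizes and determinism

The test suite runs the decomposition identity on 100 random M = 2
tables, classification oracles on 10,000 random instances, effect
recovery (deltas −0.5, −0.2, +0.3) over 50 seeded M = 2 replicates, and
the null calibration and determinism checks at the full M = 10 scale
(1300 combinations, 3900 tests) — sizes chosen so the whole suite and
the acceptance script each complete in a few minutes on a single CPU
while still exercising the full design. All randomness flows through
explicit integer seeds; rerunning `run_all()` with the same
configuration writes byte-identical tables.

## What the synthetic tests do and do not show

The generator provides exact ground truth (a null mode in which the
multiplicative model holds by construction, and injectable interaction
terms), which is what makes correctness testable: zero epistasis must
be recovered as zero, injected deltas must be recovered without bias,
and identities must hold to numerical precision. It does not emulate
several features of real data: non-log-normal measurement error,
plate-position and edge effects, growth–expression coupling beyond a
scale factor, intrinsic gene-expression noise, or saturation of the
detector. Passing tests therefore certify the analysis pipeline, not
any biological claim about a particular measured dataset; rates
reported on mechanistic simulations (e.g. the fraction of significant
or inducer-dependent combinations) describe the simulator under its
documented defaults, not the wet-lab system.

Known limitations: epistasis orders above 3 are out of scope;
fitness-based epistasis is not computed; the circuit is steady-state
algebraic (no ODE time courses); instrument-specific export parsers are
not provided.
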