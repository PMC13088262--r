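---
title: "Closed-loop optimization of nucleic-acid extraction formulations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop optimization of nucleic-acid extraction formulations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ctloop` simulates and orchestrates closed-loop, batch design-of-experiments
campaigns for magnetic-nanoparticle (MNP) based viral nucleic-acid
extraction products. The quantity being optimized is the qPCR cycle
threshold (Ct) measured at a fixed template concentration: lower Ct means
more template recovered, i.e. a better extraction formulation. This
vignette explains the models behind each component, the parameters that
matter, and the design choices that were genuinely open.

## The condition space

A formulation ("scheme") assigns one sub-condition to each of ten
optimization categories. The default space has one numeric axis,
particle size (200-1000 nm), and nine categorical reagent axes (surface
functional group, surfactant, salting-out reagent, buffer, molecular
crowding agent, chaotrope, binding alcohol, wash composition, elution
condition) with 3-6 named levels each. Reagent names are standard for
this chemistry (Triton X-100, guanidine isothiocyanate, PEG2000,
isopropanol, ...); the exact menu is a stand-in for a proprietary
catalogue and is fully overridable through `condition_space()` or a YAML
space file.

Schemes are encoded as fixed-length feature vectors: one-hot blocks for
categorical levels and min-max scaling to [0, 1] for numerics (dimension
33 for the default space). This encoding is what every surrogate model,
distance computation and PCA consumes. One-hot plus min-max was chosen
over integer coding because distances and variance decompositions in the
encoded space then treat levels symmetrically, which the diversity filter
and the compactness statistic rely on. Encoding and decoding are exact
inverses on valid schemes (numerics up to floating-point round-trip,
tested at 1e-9).

## The simulated Ct benchmark

Robotic synthesis and PCR testing are replaced by a calibrated response
surface, `ct_oracle`. The true Ct of a scheme is

    ct(s) = ct_opt + sum_c g_c(s_c) + sum_(i,j) h_ij(s_i, s_j)

with `ct_opt = 26.0` attained at a single optimal formulation (390 nm,
poly-carboxyl, matched reagent system). Each `g_c` is a nonnegative
penalty, zero at the optimal sub-condition: a table per categorical
level, and a convex quadratic `coef * ((x - x_opt)/range)^2` for particle
size. The interaction terms `h_ij` encode *reagent matching*: the optimal
surfactant, binding alcohol and elution chemistry each carry a 1.2-1.8 Ct
penalty when paired with the wrong chaotrope, wash or buffer. All
interaction penalties are nonnegative and never fire at the matched
optimal pair, so the global minimum is unmoved; but marginal
(one-category-at-a-time) statistics over dispersed data now point at the
wrong sub-conditions. This is deliberate: a purely additive surface turned
out to be solvable in one or two rounds from *any* starting dataset, which
erases the difference between initial-data regimes that the simulation is
meant to study. Matching interactions are also what formulation chemistry
actually looks like. The oracle is a benchmark surface, not a mechanistic
model of binding or lysis.

Measured Ct adds a concentration term and replicate noise:

    measure(s) = ct(s) + slope * log10(ref_conc / conc) + N(0, sigma)

The default slope is `log2(10) = 3.3219` Ct per decade, the analytically
forced value for perfect per-cycle doubling; real standard curves deviate
slightly and the slope is configurable. The reference concentration is
1e5 copies/mL.

Two noise regimes reflect who ran the experiment. The automated platform
regime uses `sigma_auto = 0.065` Ct, calibrated so that a 5-replicate
panel's consistency score `1 - sd` is at least 0.9 with probability
about 0.95: since `(n-1) sd^2 / sigma^2` is chi-squared with 4 degrees
of freedom, `P(sd <= 0.1)` at `sigma = 0.065` is `P(chisq_4 <= 9.47) =
0.95`, whereas a seemingly natural `sigma = 0.08` would already fail the
0.9 bar in 18% of panels. The manual (human-in-the-loop) regime uses
`sigma_hitl = 0.40`, which puts mean consistency scores in the 0.5-0.7
band. Extraction efficiency is reported through the standard PCR
assumption `eff = base^-(ct - ct_ref)`, capped at 1, with `base = 2` and
a configurable no-loss reference; a Ct of 26.0 against a 25.99 reference
is 99.3%.

## Initial datasets: industrial vs literature

The central comparison is between two kinds of pre-campaign data.

**Industrial-style data** emulate a proprietary development table: a
compact cluster around an anchor recipe, measured on the automated
platform. Each record flips each categorical away from the anchor with
probability `anchor_spread = 0.06` and jitters particle size by a
Gaussian with sd `0.06 * range`. The anchor is placed on the surface so
the *best generated label* lands at 35.5 +/- 0.5 Ct: a mediocre but
manufacturable starting recipe. Internally the anchor builder loads
penalty onto the high-impact categories first and lets particle size
absorb the residual exactly, so the anchor keeps the *matched* reagent
context while the key parameters are off; the calibration is a bracketed
bisection on the anchor's true Ct against the realized best-of-n label,
with all perturbation randomness pre-drawn so the search is
deterministic per seed. It errors with its attempt history if the window
cannot be reached.

**Literature-style data** emulate mining heterogeneous published studies:
schemes are drawn widely across the whole space, divided among 24
"source labs" that each contribute a persistent Gaussian offset (sd
`lab_sigma = 1.0` Ct), and measured under the manual noise regime. Two
features make these data a poor guide despite their breadth. First, the
label heterogeneity. Second, a calibrated *quality floor*: the draw is
restricted to schemes whose true Ct lies above a floor that is adjusted
until the best literature label also sits at 35.5 +/- 0.75 - published
formulations scatter across combinations that are interesting but
practically suboptimal, and in particular do not include the compact
optimum basin. A pure uniform draw (no floor) is available with
`target_best = NULL` and is used by the unit tests of the label
mechanics. What the generators do *not* emulate: real vendor recipes,
publication bias beyond the additive lab offsets, or any text-mining
noise in recovering conditions from papers; conclusions about real
literature corpora do not follow from these tests.

## Surrogate models and selection

Each round, every model in a pluggable registry is fit to (encoded
scheme, measured Ct) pairs under 5-fold cross-validation; the winner
maximizes mean per-fold R-squared, with ties broken by lower CV MSE and
then registry order. The default registry holds ten representative
regressors (constant baseline, linear, ridge, lasso, CART, random
forest, gradient boosting, RBF SVM, Gaussian-process/kernel ridge,
shallow MLP), all behind a uniform fit/predict contract; `registry_core()`
is a fast forest + linear + baseline subset used for multi-campaign
experiments, reflecting that tree ensembles are the reliable workhorse
once the loop is underway. Which family wins is a property of the
surface, not of the selector: on smooth low-noise additive data the
kernel and linear models win, while sharp sparse reagent-matching
structure hands the win to tree ensembles - the test suite demonstrates
both regimes. Overfitting is monitored by tracking train and CV MSE per
round; a train/CV ratio below 0.25 for two consecutive rounds raises a
flag.

## Batch proposal

Candidates for the next robot batch (up to 48 schemes) come from a
genetic algorithm over schemes: tournament selection (size 3), uniform
per-category crossover, per-category mutation (level resample, or
Gaussian jitter with sd 10% of range for numerics), elitism, defaults of
192 individuals for 40 generations. Every individual ever encountered is
archived; the final batch is the archive's fitness ranking filtered by a
never-repropose rule against already-evaluated schemes and a pairwise
categorical Hamming diversity floor (default 1, i.e. all distinct).
Fitness ties are broken lexicographically on the encoded vector, so
proposals are deterministic per seed. On fully categorical spaces of at
most `exhaustive_limit` (default 1000) schemes the GA is bypassed and
the batch is computed by exact exhaustive scoring under the same
ordering rules - on an enumerable space there is no reason to accept
heuristic error, and this guarantees the top-k equivalence property
exactly; the pure GA path is kept and property-tested on a small space.

A deterministic rule-based advisor stands in for external
parameter-suggestion services: from the lowest-Ct quarter of the store
it recombines per-category best marginal levels (median for numerics)
and injects a handful of such suggestions into the GA's initial
population. On a separable additive surface the pure marginal
recombination provably matches or beats the best observed record; on the
matching-interaction surface it is misled in exactly the way
one-at-a-time reasoning is, which is part of what the loop has to
overcome.

The campaign's fitness mode is `"minimize"` by default: a requirement of
the form "Ct below 26.5" is one-sided, so the loop maximizes margin
rather than aiming at the threshold value. The alternative `"closest"`
mode (minimize |prediction - target|) is implemented and appropriate
when a product must hit a Ct window; used against a one-sided
requirement it stalls just above the bound, because schemes predicted
*at* the target outrank the optimum.

## The closed loop

`run_campaign()` first checks whether the store already contains a
record meeting the requirement (zero rounds if so). Each round then
trains and selects a surrogate on all accumulated data, proposes a
batch, "measures" each proposal as the mean of 3 replicates at the
requirement concentration under the automated regime (the sd is stored
for consistency analysis), appends the records, and stops on success or
budget exhaustion. Stopping uses measured, not true, Ct - that is all a
real platform observes. All randomness flows through a documented
seed-splitting rule (`derive_seed`), so campaigns are bit-reproducible
and a campaign saved mid-flight (versioned JSON, numerics serialized at
full precision) resumes to exactly the state of an uninterrupted run.

Under the default conditions (industrial start, n = 192 = four
48-scheme batches, batch 48, replicate triplets), campaigns typically
meet the 26.5 requirement in 1-5 rounds, comfortably inside a 9-round
budget; literature starts typically spend the full 9 rounds stuck in the
high 26s-27s. The absolute round counts are a property of this
calibrated benchmark, faster than a wet-lab campaign; it is the ordering
and the gap between the two regimes that the simulation is designed to
reproduce, not wet-lab round counts or endpoint values.

## Weighting factors

Per-category importance ("weighting factors") is computed by permutation
importance evaluated through the surrogate: on a uniform probe of the
space (default 2,000 schemes), each category's whole feature block is
jointly permuted (3 repeats averaged) and the mean squared change in
predictions is normalized across categories. For an additive surface
this estimator is proportional to twice the category's effect variance
under the uniform measure, so normalized weights recover planted
variance shares; `calibrate_variance_shares()` plants such shares
analytically (categorical table variances and the uniform moments of the
quadratic are available in closed form) and verifies them by Monte Carlo
(20,000 samples, 2% tolerance). Calibration zeroes the interaction terms
by default so the planted shares are exact.

One identifiability caveat matters in practice: a *converged campaign's*
data concentrate on a few islands of the space, and no model family we
tried (trees, kernels, linear, MLP) can recover uniform-measure shares
from such data - the particle-size profile is simply not observed across
its range. The package's post-campaign protocol, `weighting_experiment()`,
therefore appends a small diagnostic design - two 48-scheme uniformly
sampled batches measured on the platform - before training the registry
and probing the winner. With the diagnostic batches the four leading
planted weights are recovered within about +/-0.05; without them errors
on the particle-size weight alone reach 0.1-0.6. Reports can be compared
against externally supplied reference profiles with
`weighting_profile_report()`, which also attaches a Gini sharpness
statistic (zero exactly for uniform weights).

## Analysis utilities

The consistency score of a replicate panel is `1 - sd` with the sample
(n-1) denominator - the conservative choice at 3-5 replicates; the
score is shift-invariant and deliberately not clamped. Dataset geometry
is compared by PCA of the encoded union (centered, unscaled, two
components, sign fixed by making each component's largest-magnitude
loading positive) for visualization, while *compactness* - the mean
Euclidean distance to the dataset's own centroid - is computed in the
full encoded space, because a 2D compactness would depend on the
projection. Constant columns are dropped before the PCA and only an
entirely constant union is an error, so a degenerate dataset inside a
varied union still gets its (zero) compactness. Campaign trajectories
are aligned by carrying each campaign's last best-so-far value forward
to the longest round count.

## Numerical choices and degenerate inputs

Zero-variance labels abort surrogate training; an all-zero importance
vector aborts weighting (a constant surrogate carries no information).
Fold R-squared is undefined on a zero-variance held-out fold and is
dropped from the mean. Scheme JSON uses sorted keys and full-precision
numbers so serialization is byte-stable; dataset CSV writes numerics
with `%.17g` for lossless round trips. Generator calibration failures
raise errors carrying the full attempt history. The problem sizes used
throughout the documentation and tests - 192-record initial datasets,
48-scheme batches, 9-15 round budgets, 1,000-2,000-point probes, 20,000
Monte Carlo samples - were chosen as the smallest sizes at which the
studied effects are stable across seeds.

## Known limitations

The oracle's penalty magnitudes, the ten-category menu and both
generators are calibrated stand-ins, not fitted to any proprietary
dataset; absolute Ct trajectories and round counts should not be read as
predictions about a physical platform. The advisor is a deterministic
heuristic, not a language-model integration. The GA is single-objective;
validity, dedup and diversity are its only constraints. Weighting
recovery guarantees hold for (near-)additive calibrated surfaces; on
strongly interacting surfaces permutation weights measure uniform-measure
total sensitivity, which need not match any single reference profile.
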