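---
title: "Multi-site turnover analysis with zetascape: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-site turnover analysis with zetascape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zetascape)
```

## The problem

Island floras mix widespread non-endemic species with narrow-ranged
endemics, and the endemics themselves split into recently diverged
neo-endemics and relict palaeo-endemics.  Pairwise beta-diversity
indices see only two sites at a time and therefore confound the
contributions of rare and widespread species to compositional change.
Zeta diversity resolves this: `zeta_i` is the mean number of species
shared by `i` sites, so low orders are dominated by rare species and
high orders by widespread ones.  `zetascape` implements the full
analysis chain around this statistic — decline-curve model fitting,
multi-site generalized dissimilarity modelling (MS-GDM), co-occurrence
and range statistics, and spatially corrected richness models —
together with a synthetic island-flora generator with known assembly
rules, so that every stage can be validated without access to any
proprietary atlas data.

## Zeta diversity and the retention rate

For a binary site-by-species matrix with `N` sites, the exact zeta
value of order `i` has a closed form: a species occupying `n_s` sites
is shared by a uniformly drawn `i`-combination with probability
`choose(n_s, i) / choose(N, i)`, so

`zeta_i = sum_s choose(n_s, i) / choose(N, i)`.

`zeta_exact()` uses this `O(S)` form; full enumeration is retained as a
test oracle for small matrices.  `zeta_montecarlo()` samples
combinations uniformly (vectorized partial Fisher–Yates) and returns
per-combination records, which are the regression units of MS-GDM.
`zeta_1` is mean per-site richness; `zeta_2` relates to pairwise
similarity, and the Sørensen-normalized order-2 value equals the
classic pairwise Sørensen similarity (asserted in the tests).

Two normalizations rescale a shared-species count to [0, 1]: Sørensen
divides by the mean richness of the combination's sites
(richness-dependent turnover) and Simpson by the minimum richness
("true" turnover).  A combination of empty sites is defined as 0.
Normalized decline curves report the mean of per-combination
normalized values — what a regression on records requires — rather
than the ratio of means; the two agree when all sites have equal
richness.

The retention rate is the ratio of consecutive zeta values: the
probability that a species shared by `i − 1` sites is still shared
when an `i`-th site is added.  The literature's subscript convention
is ambiguous (the ratio is printed "larger-over-smaller" while being
described, and plotted, as a proportion at the denominator-plus-one
order); `retention_rate()` reports the proportion
`zeta_i / zeta_{i−1}` indexed at order `i`, which is bounded by 1 and
matches the plotted curves.  Ratios over a zero denominator are
returned as missing values, not errors.

## Decline forms as a process diagnosis

If every species has the same chance `p` of occurring in any site
(stochastic assembly), `E[zeta_i] = S p^i`: an exponential decline.
If chances are species- and site-specific (niche assembly), the
occupancy-probability distribution acquires a long tail and the
decline flattens toward a power law.  `fit_decline()` fits
exponential (`log zeta ~ i`), power-law (`log zeta ~ log i`) and
combined (`log zeta ~ i + log i`) forms by ordinary least squares on
the log scale — the standard practice, and what stabilizes the
combined model — reporting both coefficients with two-sided t-tests
and AIC.  Coefficients are not sign-constrained: a fitted negative
coefficient is reported with its p-value.

Two deliberate choices need stating:

* **Form selection** (`select_decline_form()`) compares only the two
  2-parameter hypotheses by AIC.  The 3-parameter combined model nests
  both, and on decline curves of ≤ 12 points its extra parameter wins
  AIC comparisons spuriously whenever the curve is nearly noise-free;
  the exponential-vs-power-law contrast is the actual process
  diagnosis, while the combined form is used for coefficient
  reporting, in particular piece-wise.
* **Inference about a generative rate needs real sampling error.**
  The exact closed-form decline of one realized matrix is almost
  deterministic: its OLS residuals measure lack of fit only, so
  confidence intervals computed from them say nothing about the
  across-assembly variability of the realized occupancy probability.
  When the aim is to recover a generative rate (e.g. `−log p` of a
  neutral community), the decline should be estimated by combination
  sampling (`mode = "montecarlo"`), whose per-order errors are honest
  and approximately independent.  The validation suite does exactly
  this, with 1000 sampled combinations per order on 160-site,
  500-species neutral pools — sizes chosen by a prior power analysis
  so that sampling error dominates the small convexity that binomial
  occupancy spread induces on the log scale.

`find_breakpoint()` splits orders into a "rare" regime (the increasing
limb of the retention curve) and a "widespread" regime (the decreasing
limb) at the retention maximum, taking the first maximum under ties —
matching the "increased sharply up to order b" reading — and flagging
monotone curves as peakless (midpoint fallback).  `fit_piecewise()`
then fits the combined form on each segment, widening a too-short
segment with a warning rather than failing.

## MS-GDM: monotone splines under non-negativity

`build_design()` turns sampled combinations into a regression design:
the response is the normalized zeta of the focal category; each
covariate is summarized as the mean pairwise absolute difference
among the combination's sites (a symmetric, order-consistent
generalization of the pairwise GDM distance; `max` is available as a
switch), min–max rescaled to [0, 1] across records; geographic
distance is the mean pairwise Euclidean distance, likewise rescaled.
Constant columns cannot be rescaled and are dropped with a warning.

A biotic predictor adds the turnover of another category *on the
identical site tuples*: we use `1 −` its normalized zeta, i.e. a
dissimilarity orientation, rescaled to [0, 1].  The orientation is a
package decision (the convention is not fixed in the MS-GDM
literature); orienting the biotic column as a dissimilarity keeps the
monotone non-negative fit interpretable — sites that differ in
non-endemic composition are allowed only to *increase* predicted
endemic dissimilarity.

Predictors are transformed with I-splines: integrated M-splines,
monotone non-decreasing from 0 at `x = 0` to 1 at `x = 1`.  We
evaluate them as partial sums of B-splines one order higher
(`splines::splineDesign`), and the tests verify the identity against
numerical integration of the M-spline recursion.  The default basis —
order 2 with 3 functions per predictor, one internal knot at 0.5 —
matches the "first/second/third I-spline" reporting convention.
`fit_msgdm()` regresses dissimilarity (`1 −` normalized zeta) on the
transformed predictors by Lawson–Hanson non-negative least squares
(unconstrained intercept via a signed column pair), which with the
monotone basis guarantees a fitted surface monotone in every
predictor.  Variance explained is the squared Pearson correlation of
observed and predicted response; predictor importance is the maximum
of the fitted spline, i.e. the sum of its coefficients.  Rank-deficient
designs are fitted anyway (NNLS is well defined) with the affected
predictors flagged.

`run_model_suite()` fits, per order, the abiotic model (covariates +
distance), biotic model I (+ non-endemic zeta; undefined when the
focal category is the non-endemics themselves, and refused) and biotic
model II (+ the other endemic category's zeta), reusing one
combination sample per order across models so that
variance-explained comparisons are paired.  Default: 1000 sampled
combinations per order.

## Range statistics, permutation tests and co-occurrence

`range_stats()` summarizes each species' occupied-site elevations
(mean, min, max, range) and its geographic range ratio
(occupied / total sites); zero-occupancy species get missing
elevational statistics and ratio 0.  `perm_anova()` compares
categories by a permutational one-way ANOVA: the classical F statistic
(asserted identical to `aov`'s) referenced to its label-permutation
distribution, with the add-one estimator `(1 + #{F* ≥ F}) / (1 +
n_perm)` so p can never be zero; default 4999 permutations, seeded.
Post-hoc comparisons are pairwise permutation tests on the absolute
mean difference with Holm step-down — chosen over parametric Tukey HSD
for consistency with the permutational framework.

The C-score uses the normalized checkerboard unit
`(r_i − S)(r_j − S) / (r_i r_j)` per species pair, averaged over pairs
of species with positive occupancy, so values lie in [0, 1] — the
variant consistent with published values in that range.  NODF follows
the canonical decreasing-fill/paired-overlap definition on the matrix
as given (no resorting), computed via `vegan::nestednodf` and checked
against a from-scratch implementation in the tests.  No null-model
ensembles are provided: the workflow reports raw index values.
`vif_screen()` iteratively removes the covariate with the largest
variance inflation factor (`1/(1 − R²)`) until all fall below the
threshold (default 10), treating exact collinearity as unbounded.

## Spatial eigenvectors and richness models

`dbmem()` builds distance-based Moran eigenvector maps: Euclidean
distances truncated at the longest minimum-spanning-tree edge (the
conventional default; distances beyond it are replaced by 4× the
threshold), Gower double-centring, eigendecomposition, and retention
of all positive-eigenvalue eigenvectors in decreasing order.  The
eigenvectors are orthonormal and centred; on a regular transect the
leading ones are broad-scale waves.  All positive eigenvectors are
included downstream by default (forward selection is deliberately not
performed; the subset used in the original workflow is unstated, and
including all positive vectors is the conservative choice for
absorbing autocorrelation).

`fit_richness()` models per-site counts with a log-link Poisson GAM:
an unpenalized cubic regression spline with 3 knots per covariate
(`fx = TRUE`; at 3 knots the cubic and thin-plate families are
practically equivalent, and the unpenalized basis keeps the model
exactly as specified; `ridge = TRUE` restores mgcv's penalization) plus
linear spatial eigenvector terms.  It reports deviance explained,
pseudo-R² (squared correlation of observed and fitted) and a
likelihood-ratio p-value per covariate from refitting without its
smooth.  `richness_relationship()` applies the same engine with one
category's richness as the single smooth predictor of another's and
flags a "hump" when the fitted curve has an interior maximum.

## The synthetic generator: what it emulates, and what it does not

`generate_landscape()` builds a 16 × 10 grid of 8.25 km cells (160
sites) with three mountain massifs (Gaussian bumps peaking at
2450/2400/2150 m, west–centre–east) plus smooth noise, and covariates
with the qualitative structure of a large Mediterranean island: coastal
mean temperature near 19 °C falling to about 10 °C on summit cells
(6.5 °C/km lapse), precipitation increasing westward and with
elevation, seasonality and human pressure (population density, % human
land use) decreasing with elevation, slope from the elevation gradient,
and a smooth aspect stand-in.  Smooth fields are white noise averaged
with Gaussian distance weights — qualitative spatial autocorrelation
only.

`assemble_community()` draws each species' occurrences from occurrence
probabilities built per category:

* a per-species occupancy target drawn from a Beta distribution with
  the category's stated mean and spread, **calibrated** so the sample
  reproduces those marginals (standardize, clip to (0, 1], iterate):
  the printed mean ± sd of a study system is treated as the definition
  of the category's range-size distribution, not merely its
  expectation — without this, 74-species pools drift far enough from
  their marginals that cross-category orderings become irreproducible;
* a **neutral** field (the target, constant across sites), a **niche**
  field (Gaussian response to a covariate at the species' optimum,
  multiplicatively rescaled — capped at 1 — to the same target within
  1%), or their **mixture** with weight `w` on the neutral component;
  the pure modes are the mixture endpoints, so same-seed runs
  coincide exactly.

Because each species is calibrated to its target, the realized zeta
decline depends only on the occupancy-frequency distribution: constant
targets give the exponential (stochastic) signature regardless of
niche breadth, and a long-tailed target distribution — many
specialists, few generalists, the classic niche signature — gives the
power-law one.  Niche structure proper (where species occur) is what
the MS-GDM stage detects.  `generate_crete_like()` wires defaults to
the study system: 1482/91/74 species (scalable) with target range
fractions 0.08/0.06/0.05 and spreads 0.09/0.06/0.05, neo-endemic
elevation optima biased above palaeo-endemic ones (650 m vs 500 m vs
350 m for non-endemics), mixture weight 0.5.

The generator emulates marginal and gradient structure only.  It does
not reproduce the real species list, real climate surfaces, dispersal
limitation, phylogenetic structure, or the fine spatial grain of real
occupancy aggregation — so passing tests demonstrate that the
*methods* behave correctly under known assembly rules, not that the
real flora satisfies those rules.

## Numerical choices and degenerate inputs

* Zero-occupancy species are retained and flagged; they contribute 0
  to every shared-species count and keep gamma counts aligned with
  the input checklist.  Empty sites are retained; richness-0 sites
  give normalized zeta 0 by convention.
* `lchoose` arithmetic keeps the closed-form zeta stable at any order;
  `choose(n_s, i)` with `n_s < i` contributes exactly 0.
* Combination sampling uses a vectorized partial Fisher–Yates swap, so
  a decline over many orders costs a few vector operations per order.
* Permutation p-values use the add-one estimator; breakpoint ties take
  the first maximum; piece-wise segments too short for the model are
  widened with a warning; VIF treats `R² ≥ 1 − 1e−12` as unbounded.
* All randomness flows through explicit integer seeds; `run_study()`
  embeds the seed and a config fingerprint in its summary so reruns
  are exactly reproducible.

## Validation-suite problem sizes

The test suite validates each stage at sizes chosen to make the checks
sharp yet quick: zeta oracle equivalence on 100 random 10 × 20
matrices at all orders (Monte Carlo at 10⁴ samples, 3-SE band enforced
in aggregate because ~3 exceedances per 1000 comparisons are the
expected tail); neutral-rate recovery and AIC form diagnosis on 50
seeds of 160-site pools (500 species at p = 0.4; niche arm 300 species
with target 0.15, spread 0.25, breadth 200 m); MS-GDM signal recovery
at 1200 records and the null at 1000; the biotic-nestedness contrast
on 60-site communities at order 2 with 800 records; permutation
calibration over 200 null draws at 999 permutations; Poisson-slope
recovery on 50 seeds at n = 160; and the palaeo-endemic turnover
ordering on 20 full-scale Crete-like seeds.

## Known limitations

Combination sampling is uniform (no nearest-neighbour schemes);
MS-GDM fits use NNLS on the transformed scale rather than a
constrained binomial IRLS; decline forms beyond
exponential/power-law/combined and multimodel averaging are out of
scope; geodesic distances are not supported (coordinates are planar);
and the N*-style β-diversity index is pluggable but defaults to
Whittaker's β, since its published formula is not restated here.
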