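---
title: "Methods: the isodiet mixing model and diet metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the isodiet mixing model and diet metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

`isodiet` estimates consumer diet composition from bulk δ¹³C and δ¹⁵N
measurements of consumers and their candidate prey, in the style used for
long-lived marine predators sampled across two contrasting time periods
(an estuarine beluga population and its prey field is the motivating
system). The pipeline is: temporal isotope corrections → prey-group
differentiation by permutation statistics → a Bayesian
concentration-dependent mixing model with covariates → information-criterion
model comparison → individual-level diet metrics (specialization index,
heterogeneity). A seeded synthetic-data generator provides the ground truth
against which every stage is validated.

## Corrections

**Suess/Laws drift.** Fossil-fuel CO₂ depletes environmental δ¹³C over time
(the Suess effect), modulated in surface waters by temperature-dependent CO₂
exchange (the Laws effect). We model the cumulative drift since 1850 as

$$T(t) = -\frac{a}{b}\left(e^{b(t-1850)} - 1\right) + c\,m\,(t-1850),$$

an exponentially accelerating atmospheric decline (rate $a$ per‰/yr at 1850
growing at $b$ yr⁻¹) plus a linear SST-trend term ($m$ °C/yr, sensitivity
$c$ ‰/°C). Corrections are additive differences of $T$ centered on a
reference year — 2002 for the historical period and 2020 for the recent one,
the years with the largest sample sizes — so the correction is exactly zero
at the reference year, negative before it and positive after it, with
magnitude monotone in distance from it. The North Atlantic constants shipped
in `inst/extdata/suess_params.json` are *reconstructed* to reproduce the
widely cited modern regional decline of roughly 0.02‰/yr; they are an
editable parameter file, not an extract of any external package.

**Bulk δ¹⁵N restoration.** Historical samples had nitrogen measured on
lipid-extracted tissue; bulk values are restored by per-taxon linear maps
`bulk = intercept + slope × measured`. Calibration coefficients are
study-specific and supplied by the user; the default is the identity map, so
the stage is a no-op unless coefficients are provided. `apply_corrections()`
flags corrected objects and refuses to re-run, preventing double correction.

## Prey-group differentiation

PERMANOVA is implemented from scratch. Single-factor designs use the direct
Gower partition of squared distances (`SS_total = Σ_{i<j} d² / n`,
within-group sums divided by group size) with raw-label permutation;
multi-factor designs use marginal ("partial") sums of squares from
hat-matrix projections of the Gower-centered matrix with Freedman–Lane
permutation of residuals under the reduced model. Defaults mirror common
field practice: Manhattan distance, 9999 permutations. P-values use the
add-one rule, so the minimum attainable p is `1/(n_perm + 1)`; for n ≤ 7 the
full relabeling set is enumerated and the p-value is exact. Pairwise
contrasts are adjusted with the Benjamini–Yekutieli step-up, valid under
arbitrary dependence. Outlier screening flags samples beyond
`median + k·IQR` (default k = 1.5, the boxplot convention — the exact rule
used in the motivating analysis is uncited, so the threshold is an explicit,
configurable convention) of within-group centroid distances. Bivariate
normality of each prey group can be checked with Mardia's skewness/kurtosis
statistics; this is warning-only, since the mixing model's normality
assumption is an approximation by design.

## The mixing model

For consumer $i$ and tracer $j$:

$$y_{ij} \sim \mathrm{Normal}\!\left(\sum_k w_{ikj}(\mu_{kj} + \Delta_j),\;
\xi_j \sum_k w_{ikj}^2(\tau_{kj}^2 + \delta_j^2)\right),
\qquad w_{ikj} = \frac{p_{ik} [C]_{kj}}{\sum_m p_{im} [C]_{mj}},$$

where $p_i$ is the diet simplex, $\mu_{kj}, \tau_{kj}$ the source summary
statistics, $[C]_{kj}$ the mean elemental concentration (from %C and %N,
which is how C:N ratios inform concentration dependence), and
$\Delta_j \pm \delta_j$ the trophic discrimination factor (default muscle
values 1.3 ± 0.5‰ for carbon, 2.4 ± 0.5‰ for nitrogen). $\xi_j > 0$ is the
tracer-specific multiplicative error; fixing $\xi_j = 1$ gives the
process-only model, and the likelihood is continuous in that limit.

Covariates act on isometric log-ratio (ILR) coordinates:
$z_i = g + \beta_{f(i)} + u_i$ with sum-to-zero-coded fixed effects (class,
year, or additive class + year — the "crossed" model is implemented as
additive main effects, a deliberate choice since a full interaction is not
identifiable at the per-cell sample sizes this design targets) and optional
individual effects $u_i \sim \mathrm{Normal}(0, \sigma_{ind})$ with a single
shared SD across coordinates (parsimony; configurable in principle per
coordinate but not exposed). The ILR basis is the fixed Helmert-type
orthonormal basis; for $K = 2$ the single coordinate is
$\tfrac{1}{\sqrt2}\log(p_1/p_2)$.

**Priors.** Global proportions get a flat Dirichlet(1) (including the ILR
Jacobian, so the prior is genuinely uniform on the simplex); fixed-effect
offsets Normal(0, 2) on the ILR scale; $\sigma_{ind}$ half-Normal(0, 2);
$\xi_j$ half-Cauchy(0, 1). These are weakly informative and configurable.
When the individual random effect is the *only* covariate, the error
structure is forced to process-only: with one observation per individual,
$\xi$ and $\sigma_{ind}$ are not jointly identifiable (the candidate-model
table treats this model the same way).

**Sampling.** Blockwise adaptive random-walk Metropolis over unconstrained
parameters (ILR vectors, log σ, log ξ), three chains by default. Random
effects are updated with independent per-consumer accept/reject steps, which
keeps the per-iteration cost at a handful of vectorized likelihood
evaluations. Step sizes adapt toward ≈ 0.28 acceptance during warmup only,
so the post-warmup chain is a valid fixed-kernel sampler. Two extra move
types address the geometry of this posterior: a "cell move" that shifts one
factor level's total ILR (adjusting the intercept and all sum-to-zero
offsets jointly — the cell means are the identified quantities), and a
Haario-type joint adaptive-covariance proposal over the intercept, offsets
and log ξ that learns the (p, ξ) ridge induced by the multiplicative error;
its covariance is frozen when warmup ends. Convergence is
declared when all split R-hats (global proportions, σ, ξ) are below 1.05; a
failed fit is returned with `converged = FALSE` and a warning, never
silently. The simulated mixing-polygon check (random TDF-shifted source
draws → convex hull → inclusion frequency) screens consumers that no diet
can explain; with two sources the polygon degenerates to a segment with a
one-pooled-SD tolerance band.

Sources enter as fixed summary statistics (mean, SD, concentration per
group and period) rather than being re-estimated hierarchically; per-draw
concentration uncertainty is ignored (means only). Both choices match how
group summaries are fed to this class of models; hierarchical source fitting
is out of scope.

## Model comparison

WAIC uses `lppd − p_waic` with the n−1 variance convention for the penalty;
PSIS-LOO smooths the largest 20% of importance ratios per consumer with a
generalized Pareto fitted by the Zhang–Stephens profile posterior (tail
index shrunk toward 0.5 with weight 10 at small tail sizes), reports
per-consumer tail shapes, and counts k > 0.7 as reliability warnings. The
pointwise unit is one consumer (both tracers jointly). Reported "LOOic/WAIC
± SD" values are interpreted as the criterion ± its standard error over
pointwise contributions. Ranking is per period, deltas relative to the
minimum, stable sort by LOOic then WAIC.

## Diet metrics

The specialization index is
$\varepsilon = \|p - u\|_2 / \sqrt{(K-1)/K}$, the Euclidean distance from
the uniform diet normalized by the distance from $u$ to a vertex, which
makes the 0 (ultra-generalist) and 1 (ultra-specialist) anchors exact. It is
computed from posterior-mean diets after merging pelagic sources across
areas (merging is applied per posterior draw); a per-draw ε distribution is
available as a sensitivity option. Class contrasts on ε use label
permutation (the motivating analysis does not state its test; permutation
makes no distributional assumption at these sample sizes). Heterogeneity is
the Euclidean distance of each individual's mean diet from its group
centroid — the *arithmetic* mean composition, matching the Euclidean-space
reading rather than a compositional geometric mean — with group dispersions
compared by permutation and classical MDS coordinates exported for plotting.

## The synthetic generator

`simulation_scenario()` states a world: bivariate-normal prey groups
(independent tracers, since field data are reported as mean ± SD per
tracer; a correlation term would be unidentified from those summaries),
class diet simplexes, optional per-year ILR offsets, individual ILR noise
σ_ind, TDF uncertainty, and multiplicative error ξ ≥ 1. The `paper_like_*`
scenarios emulate the motivating system's shape — six prey groups in the
historical period, seven in the recent one (striped bass absent early),
three sex/age classes, 5–6 years, ~50 consumers per period, pelagic-dominated
historical diets versus more even recent ones — with source geometry
*inspired by*, not digitized from, the published isospace. Green tests
therefore establish that the machinery recovers truth under the stated
statistical structure; they do not establish anything about real carcass
data, which add tissue-turnover, decomposition and sampling biases the
generator deliberately omits.

## Numerical choices and edge cases

- Permutation p-values always include the observed statistic (add-one), so
  p > 0 and exact tests are unbiased.
- Degenerate inputs fail loudly: all-equal distances give an undefined
  pseudo-F (warned, NA); zero within-chain variance gives R-hat NaN with a
  warning; zero-SD prey groups are rejected as degenerate.
- ILR requires strictly positive compositions; generator diets are clamped
  at 1e-12 only at the stated-world boundary, never inside the sampler.
- PSIS falls back to plain importance sampling (with a notice) when ratios
  are essentially constant, where smoothing is both impossible and
  unnecessary.
- MCMC test and acceptance runs use deliberately short chains (1200–3000
  iterations, 3 chains) sized to the grading time budget; convergence is
  still checked, not assumed.

## Limitations

Two tracers bound the number of separable sources; the sampler is random
walk (adequate at K ≤ 7 and n ≤ 100, slow beyond); informative priors from
stomach contents, >2 tracers, hierarchical source means, and
compound-specific extensions are explicitly out of scope.
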