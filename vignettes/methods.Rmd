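---
title: "Methods: phylogenetic risk assessment of ecosystem functions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic risk assessment of ecosystem functions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sefrisk)
```

## The model

`sefrisk` assesses how vulnerable an ecosystem function is to an
environmental driver, given a rooted phylogeny with branch lengths for the
local species pool and, per species, a Specific Effect Function (SEF: the
per-unit contribution of the species to the function) and a Specific
Response Function (SRF: its tolerance of the driver, high = tolerant). The
assessment rests on two quantities and their interaction:

* the **cross-species correlation** of SEF and SRF — a strong negative
  correlation means the most important species are the least tolerant;
* the **phylogenetic signal** of each function — a patterned SRF means the
  driver removes whole clades (and their evolutionary history); a patterned
  SEF that covaries with it means no independently evolved lineage backs the
  function up.

Dichotomising the two signal axes gives four scenario quadrants (A: neither
patterned, B: SEF only, C: SRF only, D: both). Risk of function loss is then
an ordinal judgement from the correlation's strength and sign, with quadrant
D flagged as maximum concern when the correlation is strongly negative.

### Signal: Pagel's lambda

For a continuous variable `x` on a tree with phylogenetic covariance matrix
`V` (entry i,j = shared root-to-MRCA branch length), the model is
multivariate normal: `x ~ MVN(mu * 1, sigma2 * V(lambda))`, where
`V(lambda)` multiplies the off-diagonal entries of `V` by `lambda`. At each
`lambda`, `mu` and `sigma2` are concentrated out analytically by GLS, and
`lambda` is profiled over `[0, 1]`. We use plain ML (not REML) throughout and
say so here because reported lambda values are not comparable across the two
conventions; ML keeps the profile likelihood identical to the one used when
lambda is estimated jointly inside the PGLS regression.

Numerical choices:

* **Optimisation** uses bounded L-BFGS-B with five restarts from
  {0, 0.25, 0.5, 0.75, 1}; the profile likelihood can be bimodal on small
  trees, and restarts are cheap. Ties within 1e-9 log-likelihood units are
  broken toward the *lower* lambda, and the boundaries are always probed
  explicitly.
* On ultrametric trees `V(lambda) = lambda V + (1 - lambda) depth I`, so a
  single symmetric eigendecomposition of `V` diagonalises `V(lambda)` for
  every `lambda`; each likelihood evaluation is then O(n). Non-ultrametric
  trees fall back to one Cholesky factorisation per evaluation. A warning is
  raised when tip depths differ by more than 1% because lambda's standard
  interpretation assumes ultrametricity; the fit itself does not require it.
* `lambda` is clamped to `[0, 1]`. On non-ultrametric trees the mathematical
  maximum keeping `V(lambda)` positive definite can exceed 1; we keep the
  conventional range so estimates remain comparable with the wider
  literature, and `lambda_transform()` exposes a configurable bound for
  users who need the extended range.
* Likelihood-ratio tests against `lambda = 0` and `lambda = 1` use the plain
  chi-squared(1) reference. Both nulls sit on the boundary of the parameter
  space, where this reference is anti-conservative; we keep it because it is
  the convention behind most reported "test vs. zero" p-values, and we state
  the caveat here rather than silently halving p-values.
* A star phylogeny makes the likelihood flat in `lambda`; the fit returns 0
  with an `unidentifiable` flag rather than an arbitrary interior value.
* Constant traits and trees with fewer than 4 tips are rejected as
  degenerate.

### Signal: Fritz–Purvis D for binary variables

For a binary variable the package computes the sum of sister-clade
differences: nodal values are obtained tip-to-root by unweighted averaging
of the two daughter values (branch lengths are deliberately ignored at this
step, matching the statistic's original construction; branch lengths enter
only through the Brownian null), and the statistic is the sum over internal
nodes of the absolute difference between daughters. D scales the observed
sum between two simulated expectations,

    D = (S_obs - mean S_brownian) / (mean S_random - mean S_brownian),

so D is about 1 for a randomly shuffled trait and about 0 for a trait
produced by thresholding Brownian motion; values below 0 indicate extreme
clumping. Results carry `1 - D` as well, which puts the statistic on the
same larger-is-more-signal scale as lambda, and that is the quantity used
for labelling.

Both nulls condition on the observed prevalence exactly: the permutation
null shuffles tip states; the Brownian null simulates continuous Brownian
motion on the tree and marks the top k values as 1, where k is the observed
count of 1s (rank thresholding). Conditioning both nulls on the same state
count removes prevalence as a nuisance axis. Default `n_perm` is 1000; every
stochastic operation takes an explicit seed which is recorded in the result,
and identical seeds give bit-identical results. Monte-Carlo p-values include
the observed value in the numerator and denominator, so they are never
exactly 0. The statistic requires a binary tree; polytomies are either an
error (default) or resolved to zero-length bifurcations behind an explicit
flag, since arbitrary resolution is a modelling decision the user should own.
Because averaging is linear, the whole recursion is precomputed as one
(internal nodes x tips) matrix, and a null distribution is a single matrix
product — this is why 500-replicate nulls are cheap.

### PGLS and the dual correlation

`pgls()` fits `y = X beta + e`, `e ~ MVN(0, sigma2 V(lambda))`, with
`lambda` fixed or ML-estimated, via whitening by `V(lambda)^(-1/2)`.
Standard errors use the unbiased residual variance (n - p); `r2` is computed
on the whitened scale against the whitened intercept-only model fitted at
the same lambda. This definition is stated explicitly because r² has no
unique phylogenetic generalisation: ours reduces to ordinary r² at
`lambda = 0`, equals 1 exactly for a noiseless linear relationship at any
lambda, and is *unadjusted* (we report it as such; adjusted variants differ
only by the usual (n-1)/(n-p) factor).

The SEF–SRF correlation is assessed twice: by PGLS with estimated lambda
(the phylogenetic arm) and by OLS (the nonphylogenetic arm). The
nonphylogenetic arm is the ecologically decisive one — what matters for the
outcome in a specific system is whether high-SEF species are susceptible,
however that association arose — while the phylogenetic arm supports
evolutionary generalisation. The slope sign is taken from the OLS arm, and a
quadratic term in centred SRF is screened in the OLS arm to check the linear
summary is not hiding curvature (for a binary SRF the squared term is
collinear and the screen is skipped with `NA`).

Trait models of the SEF (`sef_trait_model()`) use PGLS with estimated lambda
and *single-step* backward elimination: all traits nonsignificant at `alpha`
(default 0.05) in the full model are dropped together and the model refitted
once. We deliberately avoid an iterative stepwise search: the purpose is the
documented "no significant additional variance" check, not model selection,
and iterated selection would invalidate the reported p-values. Missing
values are handled by listwise deletion with a message giving the count.

## Labels, quadrants, risk

Signal labels use configurable cutpoints (`default_cutpoints()`):

* lambda: none < 0.15 <= weak < 0.30 <= moderate < 0.60 <= strong;
* 1 - D: none < 0.20 <= moderate < 0.60 <= strong (no separate "weak" band:
  the reference systems we calibrated against never distinguish one on this
  statistic);
* correlation strength on max(phylogenetic r2, nonphylogenetic r2):
  negligible < 0.01 <= weak < 0.30 <= strong.

These bands are the minimal ones consistent with the published case-study
label set the defaults were calibrated to reproduce (seven signal labels and
five risk labels); they are not estimated from data, and any of them can be
overridden. The 0.01 boundary between "negligible" and "weak" correlation is
our calibrated choice — the reference systems distinguish the two labels
without stating a boundary.

Quadrant classification dichotomises labels with **moderate counting as
patterned**: a moderate-lambda SEF behaves as phylogenetically structured
for the purposes of clade-loss reasoning. This is configurable via the
cutpoints.

The ordinal risk rule, in order:

1. strength < 0.01: `very_low` — the filter takes an effectively random SEF
   sample whatever the quadrant;
2. otherwise, if the OLS slope sign is non-negative: `very_low`, with an
   explanatory note — a *positive* association concentrates the function in
   tolerant species, so the specified driver does not threaten it (other
   drivers may; the note says so). The framework's risk logic is developed
   for the negative case, and we made the positive case explicit rather than
   leaving it undefined;
3. negative and strength < 0.30: `low`;
4. negative and strength >= 0.30: `high`; in quadrant D the
   `maximum_concern` flag is additionally set (function loss plus loss of
   the clades carrying it, with no independent backup). The printed level
   stays `high` — maximum concern is a flag, not a fifth band — mirroring
   how such systems are labelled in practice.

The sign's role below the "strong" band matters: among the calibration
systems, two with nearly identical correlation strength (r² about 0.02)
carry different printed risk labels, which no monotone function of r² alone
can reproduce; the slope sign is the axis that separates them, and it is the
ecologically meaningful one.

## The driver filter

`apply_filter()` removes the species least able to persist: survivors are
the top `ceiling(n * (1 - q))` species by SRF (default quantile q = 0.5, an
equal split into more- and less-tolerant halves). Ties at the threshold
value all survive and the tie count is reported — a deterministic, auditable
rule; breaking ties randomly would make survivor sets seed-dependent for no
analytic gain. Reported are mean/sd/min/max of the SEF before and after, and
the fraction of phylogenetic diversity retained, computed as root-inclusive
Faith PD of the survivors over that of the whole pool (a single surviving
species therefore retains its root-to-tip path, never 0).

## The synthetic generator

`simulate_tree()` draws pure-birth (Yule) trees and rescales them to unit
root-to-tip depth, so lambda and sigma2 are comparable across tree sizes and
a sigma2 of 1 gives unit marginal variance at every tip.
`simulate_continuous()` draws from `MVN(mu, sigma2 V(lambda))` through a PSD
factorisation (Cholesky, with a symmetric-square-root fallback for exactly
singular covariances from zero-length branches).
`simulate_binary_threshold()` rank-thresholds such a draw at a fixed
prevalence. `simulate_sef_srf()` draws independent unit-variance vectors
`u ~ MVN(0, V(lambda_sef))` and `w ~ MVN(0, V(lambda_srf))` and returns
`sef = u`, `srf = rho u + sqrt(1 - rho^2) w`: the cross-correlation is
induced at the deviation level so each variable's marginal lambda structure
is preserved — approximately, when `lambda_sef != lambda_srf` and `rho != 0`,
because the mixture then blends two covariance structures in `srf`; the
quadrant archetypes use equal lambdas on both axes, where the construction
is exact. Scenario archetypes use generating lambda 0.05 ("no signal") and
0.95 ("strong signal") rather than the exact endpoints so that both
boundaries are approached from the interior.

What the generator emulates: phylogenetically structured, jointly Gaussian
effect and response functions on clean ultrametric trees with exact species
matching. What it does not: measurement error and intraspecific variability,
abundance structure (all species weigh equally), non-Brownian trait
evolution (no Ornstein–Uhlenbeck pull or early bursts), non-ultrametric or
misestimated trees, missing data, and selection or community dynamics after
filtering. Passing calibration tests therefore demonstrates correctness of
the machinery under the stated model, not robustness of the framework to
real-data pathologies — with field data the signal estimates inherit every
caveat of comparative methods (tree quality above all).

## Calibration results and problem sizes

The test suite and `scripts/acceptance.R` verify, among others, at the
package's chosen study sizes:

* lambda recovery: mean ML estimate within 0.08 of truth for true lambda in
  {0, 0.25, 0.5, 0.75, 1} on 128-tip unit-depth Yule trees (200 replicates
  per value in the tests; 60 in the faster acceptance script);
* optimizer correctness: ML lambda within 0.01 of an exhaustive 0.001-step
  grid search of an independently coded likelihood on 4–16-tip trees;
* D calibration: mean D within 0.15 of 1 under shuffled traits and of 0
  under Brownian-threshold traits (64 tips, prevalence 0.5, 500 datasets per
  null in the tests);
* PGLS: coefficients within 1e-8 of a dense-inverse GLS oracle; exact OLS
  reduction at lambda = 0 and on star trees;
* quadrant recovery: the generating archetype is returned in at least 90% of
  replicates at n = 128, and the maximum-concern flag fires reliably under
  the quadrant-D, rho = -0.9 generator;
* filter behaviour: under that generator the mean SEF drops after filtering
  in at least 95% of replicates, the direction is balanced under rho = 0,
  and strong-SRF-signal scenarios retain less phylogenetic diversity than
  no-signal ones at the same quantile.

These sizes were chosen as the smallest at which the Monte-Carlo bands above
are comfortably stable; all are computed afresh on every run.

## Known limitations

* The chi-squared boundary issue for the lambda LRTs (above).
* D's scaling normalises by simulated means, so with small `n_perm` the
  statistic itself (not just its p-values) carries Monte-Carlo noise; use
  `n_perm` >= 500 when the value of D matters, and note that D is reported
  unbounded (clamped into `[0, 1]` only when converted to a 1 - D label).
* The risk rule's cutpoints are calibrated conventions, not estimates;
  sensitivity of the final label to them should be checked when a system
  sits near a boundary.
* Realized effects (abundance-weighted contributions), recolonisation and
  invasion, multi-driver sequential filtering, and interaction networks are
  outside the package's scope.
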