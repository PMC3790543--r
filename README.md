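# sefrisk

Phylogenetic risk assessment for ecosystem-function vulnerability.

## The problem

Ecosystem properties and the services people derive from them depend on what
the species in a local pool *do* — their **Specific Effect Functions (SEFs)**,
the per-unit capacity of each species to influence an ecosystem property
(litter decomposability, long-distance seed dispersal, bushmeat provision).
Which species persist when the environment changes depends instead on their
**Specific Response Functions (SRFs)** — their ability to maintain or enhance
their populations under a specified driver (disturbance, hunting, drought).
Both functions are built from combinations of heritable traits, so each may
carry phylogenetic signal, and they may or may not be correlated across
species.

The risk to a function under a driver follows from two questions:

1. **Are SEF and SRF correlated across species?** A strong *negative*
   correlation means the species contributing most are the least tolerant —
   the function itself is at risk.
2. **Are SEF and SRF phylogenetically patterned?** If the SRF carries strong
   signal, the driver removes whole clades and with them much of the pool's
   evolutionary history; if the SEF is patterned too and correlated with the
   SRF, there is no independently evolved backup for the function.

Crossing the two signal axes yields four scenario quadrants (A: neither
patterned, B: SEF only, C: SRF only, D: both), from minimum concern (A,
uncorrelated) to maximum concern (D with strong negative correlation).
`sefrisk` operationalises this assessment for a species pool given a rooted
phylogeny and a trait table. It is aimed at comparative ecologists and
conservation scientists with standard trait/phylogeny data.

## Methods in brief

* **Phylogenetic signal.** Continuous variables: maximum-likelihood Pagel's
  λ — the multiplier of off-diagonal phylogenetic covariance that maximises
  the Brownian-motion multivariate-normal likelihood, with μ and σ²
  concentrated out by GLS at each λ (0 = phylogenetically random, 1 =
  Brownian). Binary variables: the Fritz–Purvis D statistic — the observed
  sum of sister-clade differences scaled between its permutation expectation
  (D ≈ 1) and its Brownian-threshold expectation (D ≈ 0) — reported as
  1 − D to place it on the λ scale.
* **Trait models and correlations.** Phylogenetic GLS,
  β̂ = (XᵀV(λ)⁻¹X)⁻¹XᵀV(λ)⁻¹y, with λ fixed or jointly estimated by ML; OLS
  for the nonphylogenetic arm; r² on the whitened scale against the
  whitened intercept-only model; a quadratic-term screen for curvature.
* **Risk.** Signal labels (none/weak/moderate/strong) from configurable
  cutpoints, quadrant classification, and an ordinal risk of function loss
  (very_low / low / high, with a maximum-concern flag in quadrant D) driven
  by the strength and sign of the SEF–SRF correlation.
* **Driver filter.** Species whose SRF falls below a quantile threshold are
  removed; the SEF distribution before and after and the fraction of
  phylogenetic diversity (root-inclusive Faith PD) retained by survivors
  summarise the consequence.
* **Synthetic scenarios.** Unit-depth Yule trees, λ-structured Brownian
  traits, threshold binary traits, and SEF/SRF pairs with controlled
  cross-correlation generate the four quadrant archetypes for calibration
  and testing.

## Worked example

Generate the maximum-concern archetype (quadrant D, strongly negative
SEF–SRF correlation) and assess it:

```r
library(sefrisk)
sc <- generate_scenario("D", n_tips = 64, rho = -0.9, seed = 42)
ra <- risk_assessment(sc$tree, sc$data, sef = "sef", srf = "srf", seed = 1)
summary(ra)
```

```
Ecosystem-function risk assessment (64 species)
  SEF signal: Strong (lambda = 0.96)
  SRF signal: Strong (lambda = 0.94)
  Scenario quadrant: D
  Correlation: phylogenetic r2 = 0.821, nonphylogenetic r2 = 0.892, sign -1
Risk of function loss: high [maximum concern] (max r2 = 0.892)
  note: Strong negative SEF-SRF correlation with both functions phylogenetically
  patterned: loss of function would be accompanied by loss of the clades providing
  it, leaving no independent backup (maximum concern).

Driver filter at SRF quantile 0.50: 32 of 64 species persist
  SEF before: mean -0.467 (sd 1.160, range -3.317..1.457)
  SEF after : mean -1.334 (sd 0.890, range -3.317..0.132)
  phylogenetic diversity retained: 65.4%
```

Both functions were generated with strong phylogenetic signal (λ ≈ 0.95) and
the fitted λ values recover that; the system lands in quadrant D. The r² of
the SEF-on-SRF regression is high in both arms and the slope is negative, so
the risk is high with the maximum-concern flag: the filter that removes the
less-tolerant half of the pool drags the mean SEF from −0.47 down to −1.33
(the large-effect species are lost) and strips a third of the pool's
evolutionary history.

The same analysis runs from the shell on Newick + CSV inputs:

```sh
Rscript inst/cli/sefrisk.R simulate --quadrant D --rho -0.9 --n 64 --seed 42 --out demo/
Rscript inst/cli/sefrisk.R assess --tree demo/tree.nwk --table demo/traits.csv \
    --sef sef --srf srf --seed 1 --out demo/report/
```

which writes `report.json`, `summary.txt` and `sef_histogram.csv` (the
"SEF before filter" / "SEF after filter" panel data). SRF proxies are
declared with `--srf-transform` (e.g. `neglog` for negated log body mass as
a hunting-tolerance proxy).

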