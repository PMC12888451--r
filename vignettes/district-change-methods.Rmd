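---
title: "Methods: district-level small-area estimation of healthcare-access problems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: district-level small-area estimation of healthcare-access problems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pahc)
```

# The problem

National household surveys of the DHS/NFHS type interview hundreds of
thousands of women aged 15–49 about barriers they face in reaching
healthcare. Four self-reported problems are tracked here: **affordability**
(getting money for treatment), **proximity** (distance to a facility),
**permission** (getting permission to go) and **support/companionship** (not
wanting to go alone). Each survey item has three response levels; the
package works with the binary recode in which "any problem" pools the "big
problem" and "not a big problem" answers.

A district is the administrative unit where health policy is implemented,
but a district's raw sample — a handful of clusters (rural villages or urban
wards) with 20–30 women each — is too small for a stable direct estimate.
The package therefore treats district estimation as a small-area problem:
borrow strength across the nested design (women in clusters in districts in
states), shrink noisy cluster estimates toward the grand mean in proportion
to their precision, and average the shrunken cluster estimates within
districts. Comparing two survey rounds on a harmonized district geometry
then yields a change classification per district.

# The model

For woman $i$ in cluster $j$, district $k$, state $l$, the binary outcome is
Bernoulli with

$$\operatorname{logit}(P_{ijkl}) = \beta_0 + C_{0jkl} + D_{0kl} + S_{0l},$$

where $C_{0jkl} \sim N(0, \sigma^2_C)$, $D_{0kl} \sim N(0, \sigma^2_D)$ and
$S_{0l} \sim N(0, \sigma^2_S)$ are exchangeable random intercepts. There are
no covariates: the model is an estimation device for geography, not an
explanatory regression. One model is fitted per outcome per survey round
(eight fits for a two-round, four-outcome analysis; stratified rural/urban
runs refit on the filtered records).

Because the linear predictor is constant within a cluster, the likelihood
depends on the data only through each cluster's problem count and size.
`fit_pahc()` exploits this: after one pass over the records the sampler
works entirely on cluster sufficient statistics, which is what makes the
full NFHS scale (tens of thousands of clusters) tractable in plain R.

## Priors, starting values, sampler

* **Priors.** $\beta_0 \sim N(0, 10^6)$;
  $\sigma^2 \sim \text{Inv-Gamma}(0.001, 0.001)$ for each level. These are
  the conventional diffuse choices for multilevel MCMC of this model class.
  Both are settable in `mcmc_control()`, and any variance can be pinned with
  `fix_variances` (used by the validation suite to compare against numerical
  integration).
* **Starting values.** `fit_initial()` places the chain where a
  quasi-likelihood fit would: $\beta_0$ at the logit of the pooled
  prevalence (clamped to $[10^{-3}, 1-10^{-3}]$), level variances by
  method-of-moments on empirical group log-odds (with the binomial sampling
  variance of a cluster's log-odds subtracted at the cluster level, and a
  floor of $10^{-4}$), and residuals at empirical deviations shrunk halfway
  to zero.
* **Sampler.** Metropolis-within-Gibbs, single chain: univariate random-walk
  Metropolis for $\beta_0$ and for every residual (clusters are
  conditionally independent and updated as one vectorized block, likewise
  districts and states via per-group likelihood sums), and conjugate
  inverse-gamma Gibbs draws for each variance given its residuals. Proposal
  scales adapt every 50 iterations toward 44% acceptance — the classic
  one-dimensional random-walk target — during burn-in only, and are frozen
  afterwards so the monitored chain is a fixed kernel. Defaults: burn-in
  500, 5,000 monitored iterations, thinning 1. Sampled variances are floored
  at $10^{-6}$ to avoid numerical collapse of a level.
* **Diagnostics.** `ess()` reports an autocorrelation-time effective sample
  size per scalar chain using Geyer's initial positive sequence (sums of
  autocorrelation pairs truncated at the first non-positive pair), capped at
  the chain length; a constant chain is flagged rather than failing.
* **Weights.** Survey weights deliberately do **not** enter the likelihood;
  they are used only in the descriptive tabulations. This mirrors standard
  practice for MCMC multilevel fits of DHS data and keeps the posterior a
  genuine Bayesian object; the divergence risk (model-based district
  estimates are unweighted) is a known limitation shared with the source
  methodology.

## From residuals to district estimates

The precision-weighted share of an outcome in cluster $j$ is the inverse
logit of the summed point estimates,

$$\hat p_{jkl} = \frac{\exp(\beta_0 + C_{0jkl} + D_{0kl} + S_{0l})}
                      {1 + \exp(\beta_0 + C_{0jkl} + D_{0kl} + S_{0l})},$$

with posterior means plugged in (`cluster_estimates(fit)`). Because the
inverse logit is nonlinear, the plug-in differs from the posterior mean of
the inverse logit by a Jensen gap; `method = "drawwise"` averages the
inverse logit over the monitored draws instead. The two agree to well under
0.02 whenever residual posterior SDs are below about 0.3 (checked in the
test suite); the plug-in is the default because it matches the standard
printed formula. District estimates are the unweighted arithmetic mean of
their clusters' $\hat p$ (`district_average()`; a woman-count-weighted mean
is available but off by default). Districts absent from a stratum (say, no
urban clusters) are simply absent from the stratified table — missing, not
zero.

## Variance partitioning

`vpc_shares()` computes the share of the combined random-intercept variance
at each level, $\sigma^2_{\text{level}} / (\sigma^2_C + \sigma^2_D +
\sigma^2_S)$; the default excludes the woman level because three-level
shares of this form are what sum to 100% in the source-style reporting.
`include_individual = TRUE` switches to the latent-variable convention,
adding $\pi^2/3$ (the variance of a standard logistic) to the denominator.

For a fitted model, `vpc(fit)` reports the **posterior mean of the VPC**:
the share is formed inside every monitored draw and then averaged. This is
the proper posterior expectation of the quantity of interest. The
alternative — plugging posterior-mean variances into the formula — inherits
the right skew of a variance posterior estimated from few units (e.g. 20–36
states) and systematically overstates that level's share by a couple of
percentage points on recovery experiments; the draw-wise mean centres on the
generating value.

# Descriptive tables

* `weighted_prevalence()` reports $100\sum w_i y_i / \sum w_i$ per outcome,
  round and stratum with a Wald 95% CI, $\pm 1.96 \cdot 100\sqrt{\hat p(1 -
  \hat p)/n}$, using the **unweighted** count as $n$. The CI method is a
  deliberate, documented choice: with mean-one weights and $n$ near 700{,}000
  it reproduces the tightness of published national tables, and no
  design-based variance structure (strata/PSU) is modelled.
* `combination_table()` assigns each woman to exactly one of the $2^4 = 16$
  mutually exclusive problem subsets and reports weighted shares with the
  same CI convention; `combination_margins()` sums member cells into the
  exactly-4/3/2/1/0-problem margins. Pre-rounding, the 16 cells sum to 100
  exactly and the any-problem margin per outcome equals the corresponding
  sum of cells — both are enforced by tests. Reported percentages are
  rounded half-up to 2 decimals only at the output edge.

# Change classification

Decile thresholds are the nine 10th–90th percentiles of the **baseline**
district estimates per outcome, computed with the linear-interpolation
quantile (R type 7) — the definition matters and is fixed. Both rounds are
binned with these baseline cuts; a value equal to a cut stays in the lower
bin, and values beyond the baseline range clamp to bins 1 or 10, so fully
tied cuts send everything to bin 1.

The improvement category bands the percentage-point decline $\delta =
p_{\text{baseline}} - p_{\text{endline}}$: Very Low $[0,5)$, Low $[5,10)$,
Moderate $[10,15)$, High $[15,20)$, Very High $[20,\infty)$. The printed
band edges overlap in the source convention, so the half-open-left rule is
this package's documented tie-break: exactly 5.0 is Low and exactly 10.0 is
Moderate. Districts whose prevalence rose get an explicit **Worsened**
category rather than being mis-binned as Very Low. "More than a 10-point
decline" in `count_districts()` is a strict inequality.

# Boundary harmonization

Between rounds the district map changes by refinement: districts split, and
a small set of baseline clusters cannot be assigned to any endline district.
The crosswalk is a plain table — one row per baseline cluster, mapping it to
an endline-vintage district or marking it `drop` — because the underlying
geospatial derivation is out of scope and clusters are points that fall in
exactly one polygon (no fractional splitting, no merges). `apply_crosswalk()`
enforces exact accounting ($n_{\text{input}} = n_{\text{retained}} +
n_{\text{dropped}}$), fails loudly on any cluster without an entry, and a
real-world mapping (such as a 13-to-26 within-state split) is required as
data rather than inferred.

# The synthetic population

`simulate_round()` draws from exactly the model above, plus the survey
furniture the model ignores:

* **Frame defaults.** 36 states × 18 districts × 44 clusters × 25 women
  (~712k women), matching the scale and shape of the NFHS frame; baseline
  intercepts at the national any-problem logits (54.75 / 63.20 / 40.12 /
  51.38 percent), endline at (50.57 / 56.79 / 34.73 / 48.17).
* **Level variances** default to (0.25, 0.05, 0.25) for state, district and
  cluster on the log-odds² scale — the state ≫ district, cluster ≫ district
  ordering seen in variance-partitioning reports for these outcomes.
* **Cross-outcome dependence.** The four outcomes share one standard-normal
  woman-level factor scaled by `outcome_coupling` (default 0.75). The
  separate-outcomes model does not represent this, but real combination
  tables are far from independent (the all-four cell is ~25%, not the ~6%
  independence would give), and without coupling the combination machinery
  would be tested on an unrealistically flat table.
* **Weights** are lognormal (right-skewed positive, like DHS design
  weights), normalized to mean one within each round; the normalization is a
  documented package choice since the source weight construction is not
  specified.
* **Residence** is a cluster attribute (whole villages/wards are rural or
  urban), with 30% urban clusters by default.
* **Rounds** are independent cross-sections: intercepts shift per outcome,
  random effects and clusters are redrawn. `simulate_panel()` adds a
  refinement-only boundary scenario and emits the matching crosswalk.

What the generator does **not** emulate: probability-proportional-to-size
cluster sampling, spatial autocorrelation between neighbouring districts,
item nonresponse (the source data have none for these items), and
within-cluster correlation beyond what the cluster intercept induces.
Passing tests therefore demonstrate correctness of the estimation machinery
under the stated generative model, not robustness to design features the
generator omits.

# Validation design and problem sizes

The test suite checks every computational claim against an independent
route, at sizes chosen to keep a full run around a minute:

* the tiny fixed-variance model (1 state, 1 district, 2 clusters, 20 women)
  against dense grid quadrature of the exact posterior (agreement within
  0.05 on the posterior mean of $\beta_0$);
* `ess()` against iid chains and the AR(1) closed form
  $n(1-\rho)/(1+\rho)$;
* variance recovery at 20 states × 8 districts × 12 clusters × 40 women
  with generating variances (1.06, 0.14, 0.80) — the state share of an
  exclude-individual VPC must average 53% ± 5pp over 5 seeds, the scale at
  which `scripts/acceptance.R` recomputes the headline quantity;
* tabulation identities (cells summing to 100 at $10^{-9}$, margins as cell
  sums, cross-path margin agreement) and published-table margin arithmetic;
* exact crosswalk accounting at the published sample sizes (699,689 −
  1,310 = 698,379; pooled 1,422,494);
* end-to-end byte-determinism of the pipeline under a fixed seed.

# Known limitations

* Point estimates only at district level: no credible intervals or MSE for
  the shrunken district means.
* Survey weights are excluded from the model likelihood (descriptive tables
  only), so model-based and design-based national means can differ.
* A single chain is monitored; between-chain diagnostics (R-hat) are out of
  scope, with ESS as the mixing check. The intercept mixes slowly when state
  effects are large (it is weakly identified against the state-mean), which
  is visible in its ESS and is why district estimates — sums of intercept
  and residuals — are the quantity to trust, not the intercept alone.
* Districts only split between vintages; merges are not representable in
  the crosswalk.
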