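---
title: "Risk estimation and budgeted targeting for early-life mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk estimation and budgeted targeting for early-life mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elmtarget)
```

## The problem

Most programs that aim to reduce infant mortality target births by a single
risk factor — usually household poverty. Because mortality risk varies widely
*within* any group defined by one factor, such programs cover many low-risk
births and miss many high-risk ones. `elmtarget` implements a two-step
alternative:

1. **Estimate** each birth's latent probability of death before age one with
   a hierarchical Bayesian logistic model over four risk factors — maternal
   age category, maternal education, household wealth quintile and district
   of birth — including all their interactions.
2. **Allocate** a fixed intervention budget (a share of all births, 20% by
   default to match the size of the conventional poorest-quintile target) to
   the subgroups with the highest average estimated risk, under the
   geographic flexibility the policymaker actually has.

Plans are scored by their **capture rate**: the share of all infant deaths
that fall inside the targeted set.

## The risk model

For birth $i$ with outcome $Y_i \in \{0, 1\}$ (death before age one) the
model is

$$
Y_i \sim \mathrm{Bernoulli}(\pi_i), \qquad
\operatorname{logit}(\pi_i) = \beta_0 + \sum_{t \in \mathcal{T}}
  u^{(t)}_{\ell_t(i)},
$$

where $\mathcal{T}$ holds the 15 effect terms — the 4 main effects and all
6 two-way, 4 three-way and 1 four-way interactions of the factors — and
$\ell_t(i)$ is the level combination birth $i$ occupies in term $t$.

Every term is coded symmetrically: each observed level combination gets its
own coefficient with a zero-mean Gaussian prior, with no reference cell.
This matches the variance-component view of interactions and treats fixed
and random terms uniformly; the model is overparameterised in the classical
sense, but the proper priors make the posterior proper, and all risk
predictions depend only on the identified sums $\beta_0 + \sum_t u^{(t)}$.

A term is a **random effect** when it has more than 20 *observed* unique
level combinations, and a fixed effect otherwise. We count observed
combinations rather than the theoretical product of level counts because
only observed cells are estimable and indexable at fit time; for cohorts of
realistic size the two coincide for the low-order terms, and the
high-order terms are random either way. At national scale the district main
effect (hundreds of levels) and every term containing district are random,
as is the age x education x wealth three-way term (up to 60 levels).

Priors:

* fixed-term coefficients and the intercept:
  $\mathcal{N}(0, \sigma^2_{\text{fixed}})$ with
  $\sigma^2_{\text{fixed}} = 10$ on the logit scale — weakly informative,
  wide enough to leave odds ratios essentially unconstrained while keeping
  separated cells finite;
* random-term coefficients: $\mathcal{N}(0, \sigma^2_t)$ with the
  term-level standard deviation $\sigma_t$ given a half-Cauchy(2.5) prior,
  the standard weakly-informative choice for hierarchical scales. An
  inverse-gamma prior on $\sigma^2_t$ is available via
  `variance_prior("inv_gamma")` for parity with classical Gibbs samplers
  for variance components.

### Computation

`fit_posterior()` samples the posterior with JAGS (via `rjags`). Two
implementation choices matter:

* **Collapsed likelihood.** Births sharing a full covariate cell are
  exchangeable under the model, so the Bernoulli likelihood is collapsed to
  binomial counts per observed cell — an exact reformulation that reduces
  tens of thousands of unit records to at most a few thousand cells.
* **Reproducibility.** Each chain's RNG is seeded deterministically from
  the `mcmc_control()` seed, so the same settings always return identical
  draws.

Gibbs-type sampling is a natural fit here: the crossed random effects make
the joint posterior high-dimensional but each conditional is
well-behaved, and the collapsed likelihood keeps iterations cheap.
Convergence is monitored with split-$\widehat{R}$ (computed per parameter
over half-chains) and effective sample size; any split-$\widehat{R}$ above
1.05 triggers a loud warning, never a silent pass. Complete separation — a
fixed-term level that is all deaths or all survivals — is also flagged as a
warning, since the Gaussian prior regularises those coefficients rather
than letting them diverge.

`predict_risk()` applies the inverse logit per draw and summarises each
birth by the posterior mean and the empirical 2.5–97.5 percentile interval.
A prediction-time level combination unseen at fit time is marginalised over
its random term's fitted variance (a fresh standard normal per unseen
level, scaled by the posterior draws of $\sigma_t$ and seeded for
reproducibility); an unseen level of a *fixed* term indicates a
spec/data mismatch and is an error.

## The allocation step

`define_subgroups()` cross-classifies births by geographic unit and the
full demographic cell (wealth x education x age). The three scenarios
differ only in the unit: each district may target its own cells
(`district`), all districts in a state must target the same cells
(`state`), or the whole country must (`national`). The budget is global in
every scenario — 20% of *all* births, matching the size of the
poorest-quintile group — not 20% within each unit; a per-unit budget is a
different policy and can be emulated by running units separately.

`allocate()` ranks subgroups by mean estimated member risk (descending)
and fills the budget greedily. The marginal subgroup is included
*fractionally* so that total coverage equals the budget exactly; expected
deaths captured from a fraction $f$ of a group scale as $f$ times the
group's deaths. Ties in mean risk break by larger group first, then by a
lexicographic unit/cell key, so plans are fully deterministic and invariant
to row order. A `stop_before` mode that only takes whole subgroups is
available for policies that cannot split a group.

Two structural facts follow from this design and are enforced by tests:

* **Optimality.** With value density equal to mean member risk, greedy
  fractional filling attains the optimum of the fractional-knapsack
  relaxation over the partition (verified against exhaustive enumeration
  of all LP vertices on instances with up to 12 subgroups).
* **Refinement monotonicity.** District subgroups refine state subgroups
  refine national subgroups, and the optimal expected capture over a finer
  partition can never be smaller. Hence, measured in expected capture under
  the risk estimates themselves (`expected_capture()`), district >= state
  >= national holds *exactly* on every input. Realised capture
  (`capture_rate()`, which counts actual deaths) obeys the same ordering up
  to sampling noise.

The conventional comparator, `baseline_poorest_quintile()`, targets exactly
the births in the lowest wealth quintile; its covered share is the
quintile's empirical share of births (near 20% by construction of wealth
quintiles, not forced).

## The synthetic cohort generator

National birth-history microdata with district identifiers are
restricted-access, so validation runs on synthetic cohorts with *known*
ground truth. `generate_cohort()` emulates the structure of the 1998–1999
India national family health survey cohort: 73,320 births in 436 districts
nested in 26 states (the survey's state count), demographic marginals
equal to the survey's published frequencies, and a marginal infant
mortality rate of 65 per 1,000 births
(`default_india_config()`).

The generative model is deliberately the simplest structure exhibiting the
within-group heterogeneity that motivates multi-factor targeting:

* the three demographic factors are drawn independently from their
  marginals, and the district uniformly — no covariate correlation;
* every term's level effects are independent zero-mean Gaussians on the
  logit scale, centred exactly; the default scales are 0.5 (main), 0.25
  (two-way), 0.15 (three-way) and 0.10 (four-way), chosen once so that
  district median risks span roughly 0–15% at the India-like baseline,
  comparable to the between-district spread reported for national DHS
  cohorts;
* the intercept is calibrated by 1-D root-finding so the cohort mean of
  the true risk matches the target baseline within $10^{-4}$ (the solver
  itself is run to $10^{-12}$); if the effect scales are so large that no
  intercept in $[-35, 35]$ can hit the baseline, generation fails loudly;
* outcomes are Bernoulli draws in the true risk.

One master seed drives four deterministic sub-streams (covariates,
district assignment, effect draws, outcomes), so any stage can be
regenerated stably.

What the simulator does *not* emulate — and therefore what passing tests do
not establish about real data: correlated risk factors (wealth and
education are strongly associated in real surveys), spatial autocorrelation
between neighbouring districts, survey design weights, non-Gaussian or
heavy-tailed effect distributions, and any form of unmeasured confounding.
Results on synthetic cohorts demonstrate that the machinery is correct and
that multi-factor targeting dominates single-factor targeting *when risk
genuinely depends on interacting factors*; they do not reproduce any
published survey's numbers.

## Validation studies and problem sizes

The test suite runs fixed-seed replicate studies at sizes chosen to balance
statistical resolution against a laptop-scale run:

* **Targeting dominance:** 20 cohorts of 20,000 births at the India-like
  configuration, scored in oracle mode (true risks stand in for the
  estimates, isolating the allocation step); district-scenario capture must
  beat the poorest-quintile baseline in at least 18 of 20, and the
  district >= state >= national ordering in expected capture must hold in
  all 20 exactly.
* **Allocator optimality:** 1,000 random instances with 2–12 subgroups
  against the exhaustive fractional-knapsack oracle, exact equality.
* **Variance recovery:** 20 cohorts of 50 districts x 400 births with a
  single district random effect of standard deviation 0.5 (variance 0.25);
  the 95% credible interval for the district variance must cover 0.25 in at
  least 18 of 20 replicates, and the mean posterior risk must match the
  empirical death rate within three binomial standard errors
  (calibration-in-the-large).
* **Rank fidelity:** on a 20,000-birth cohort with all 15 terms active, the
  Spearman correlation between posterior mean risk and true risk must
  exceed 0.6 even with deliberately short chains.

`scripts/acceptance.R` re-runs the headline computation end to end — the
census projection, oracle-mode targeting on a full-size India-like cohort,
and a fitted pipeline on a 10,000-birth, 30-district cohort with 2 chains
of 500 kept draws — and writes the resulting numbers as JSON.

## Numerical and design notes

* The logit link is used throughout (canonical for Bernoulli outcomes).
* Census projections round half-up on the *unrounded* products
  (`round(rate x births)`), which is how published absolute counts are
  conventionally derived from rates.
* Exceedance shares use a strict inequality: the share of births outside a
  reference group whose risk is *strictly higher* than the group's mean;
  an optional `reference_mean` override supports comparisons against a
  published rounded value.
* The budget equality `total_covered_fraction == budget_fraction` holds to
  1e-9 whenever the cohort is at least `1/budget_fraction` births; smaller
  cohorts may be unable to fill the budget.
* District-to-state assignment in the simulator is by contiguous blocks of
  near-equal size; real administrative geographies are unbalanced, which
  affects nothing downstream (the pipeline takes the observed map as
  data).

## Known limitations

* The fitted model is only as good as its factors: four categorical
  factors cannot capture risk variation from, e.g., sanitation, birth
  spacing or care access. The framework accepts any factors that define
  the subgroup cells, but the current surface fixes the four.
* Ranking subgroups by the mean of members' posterior-mean risks ignores
  posterior uncertainty in the ranking itself; a decision-theoretic
  extension would rank by the posterior distribution of group means.
* MCMC over all 15 terms at national scale (hundreds of districts) is
  minutes-to-hours work, not seconds; oracle mode exists precisely so the
  allocation and evaluation layers can be exercised and validated without
  it.
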