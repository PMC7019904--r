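---
title: "Modeling nutrient intakes under updated Daily Values"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling nutrient intakes under updated Daily Values}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fortiscope)
```

## The question the package answers

US Nutrition Facts Labels express a serving's nutrient content as a
percent of a Daily Value (%DV), computed on the FDA's Reference Amount
Customarily Consumed (RACC). When the FDA revises the DVs, every %DV
and every "good source" (10–19% DV per RACC) or "excellent source"
(≥ 20% DV per RACC) claim moves with it. Manufacturers who fortify
voluntarily have a simple way to keep their labels unchanged: adjust
the added amount so the printed %DV stays the same. `fortiscope` models
the population-level consequences of exactly that behavioral
assumption. It takes a food composition database in which each food ×
nutrient amount is partitioned into intrinsic (naturally occurring),
enriched (mandatory restoration, fixed by regulation), and fortified
(voluntary) sources, rewrites the fortified component for a new DV
table, pushes both databases through the same two-day 24-h recall
records, and compares the resulting usual-intake distributions.

## The fortification rewrite

For one food × nutrient entry let $I$, $E$, $F$ be the intrinsic,
enriched and fortified amounts and $T = I + E + F$. Under old and new
Daily Values $DV_{old}$, $DV_{new}$, maintaining
$T'/DV_{new} = T/DV_{old}$ while holding $I$ and $E$ fixed gives

$$F' = \max\!\left(0,\; T\cdot\frac{DV_{new}}{DV_{old}} - I - E\right),
\qquad T' = I + E + F'.$$

Three rules complete the construction:

* **Zeroing.** If $I + E$ alone already reach (or exceed) the target
  total, voluntary fortification is assumed to be discontinued: $F' = 0$
  and the food is re-categorized as non-fortified. This is the only
  fortification-status change the rewrite can make; a non-fortified
  food never becomes fortified, so for nutrients whose DV rises the
  count of fortified foods is constant by construction.
* **Frozen nutrients.** Vitamin E and folate are copied unchanged: the
  chemical form added to foods (natural vs. synthetic tocopherol; folic
  acid vs. food folate) cannot be resolved from label data, so their
  DV-ratio arithmetic is not well defined. The frozen set is an
  argument, not a constant.
* **Identity short-circuit.** A DV ratio of exactly 1 is an algebraic
  identity on every entry, and the implementation skips the arithmetic
  so unchanged nutrients stay bit-identical — paired scenarios can then
  be compared with `identical()`.

The rewrite is per-100 g, but %DV maintenance is invariant to the
reference quantity because the ratio cancels; claims are evaluated per
RACC (`total_per_100g * racc_g / 100`). Claim classification uses the
unrounded %DV by default; `fda_rounding = TRUE` rounds to the nearest
whole percent first, as printed panels do. A residual fortified amount
below $10^{-12}\,T'$ is truncated to zero so floating-point dust cannot
re-classify a food as fortified.

All amounts live in canonical units per nutrient (µg RAE for vitamin A,
mg NE for niacin, µg DFE for folate, plain mass otherwise) and label
units are converted once at load time: 40 IU vitamin D per µg, 1 IU
vitamin A (as retinol) = 0.3 µg RAE, 30 IU vitamin E = 15 mg, 60 mg
tryptophan = 1 mg NE, 0.6 µg folic acid = 1 µg DFE. Unsupported pairs
raise an error rather than passing through — a unit mix-up in an input
file should fail loudly.

## Usual-intake estimation

A person's two recall days are noisy realizations of their long-run
("usual") intake. Ignoring that separates poorly: day-to-day variance
inflates the tails of the intake distribution and biases cut-point
prevalences. `fit_usual_intake()` implements a one-part (amount-only)
measurement-error model in the spirit of the NCI method, appropriate
because all thirteen modeled nutrients are consumed nearly every day;
no consumption-probability part is fitted and episodically consumed
foods are out of scope.

Daily amounts $y_{ij}$ are Box-Cox transformed,
$z_{ij} = (y_{ij}^\lambda - 1)/\lambda$, with $\lambda \in (0, 1]$
selected on a 0.01-spaced grid by the Gaussian profile log-likelihood
$-\tfrac n2 \log \hat\sigma^2(\lambda) + (\lambda - 1)\sum \log y$; the
Jacobian term makes the criterion scale invariant, so the selected
exponent does not depend on the nutrient's unit. The transformed
amounts follow a linear mixed model fitted by REML (via `lme4`):

$$z_{ij} = x_{ij}'\beta + b_i + \epsilon_{ij},\qquad
b_i \sim N(0, \sigma_b^2),\ \epsilon_{ij} \sim N(0, \sigma_w^2),$$

with fixed effects for a weekend indicator, an interview-sequence
indicator (day 2 vs day 1 — recall attenuation, treated as a nuisance),
and age-group terms when available. Usual intake for a person with
linear predictor $\mu$ and random effect $b$ is the expectation of the
back-transformed day intake over the within-person error,

$$UI(\mu, b) = \mathbb{E}_\epsilon\,
g^{-1}(\mu + b + \epsilon), \qquad
g^{-1}(z) = (\lambda z + 1)_+^{1/\lambda},$$

computed with 9-point Gauss–Hermite quadrature (nodes from `pracma`).
Prediction conventions: the interview-sequence effect is set to its
day-1 level, and the weekend covariate is integrated with weights 4/7
weekday and 3/7 weekend, so usual intake refers to a generic week.
`simulate()` performs the distribution step: each person contributes
`nsim` pseudo-persons with random effects drawn from
$N(0, \hat\sigma_b^2)$, each carrying the person's survey weight
divided by `nsim`. Prevalences use the cut-point conventions strictly
below the EAR and at-or-above the UL; a nutrient without an established
UL reports `NA`, never 0.

Numerical choices worth knowing:

* Zero-intake days get a half-minimum offset before transformation,
  removed after back-transformation (flagged with a message).
* The response is standardized before the REML fit and the estimates
  rescaled afterwards — exact for a linear model, and it keeps the
  optimizer well conditioned for nutrients whose transformed scale is
  large (calcium, folate).
* When the pooled day-to-day variance of the OLS residuals is
  numerically zero the REML profile is ill-posed (the likelihood is
  unbounded on the singular boundary, and optimizers return an
  arbitrary split). The fit then falls back to OLS fixed effects with
  moment variance estimators, which reproduce the exact degenerate
  decomposition ($\sigma_w^2 = 0$, $\sigma_b^2$ = variance of person
  means).
* A back-transformation argument below the Box-Cox branch point maps to
  intake 0 rather than NaN; with realistic parameters this is rare.

## Fortification-exposure subgroups

Persons are partitioned, per nutrient and per DV table, by the share of
the DV they obtain from fortified foods: exactly 0%, >0–50%, or >50%.
The share is the mean of the available recall days' fortified intake
divided by the DV (a raw two-day mean, not a model-based quantity, so
subgroup sizes are integer head-counts). The boundary at 50 belongs to
the middle band.

## Survey design and variance

The design model is the standard two-PSUs-per-stratum public-use
layout. Balanced Repeated Replication builds half-samples from a
Sylvester Hadamard matrix of order $R = \max(4, 2^{\lceil \log_2 H\rceil})$
for $H$ strata, perturbing weights by Fay's coefficient (default 0.3,
the NHANES convention; 0 gives classical BRR):
$SE^2 = \frac{1}{R(1-f)^2}\sum_r (\theta_r - \theta)^2$. Weights pooled
over multiple survey cycles are divided by the number of cycles. By
default the replicate weights re-evaluate only the final weighted
statistics over the simulated usual-intake distribution — fast, and
exact for the weighted-mean component; `brr_full = TRUE` instead
refits the measurement-error model under each replicate weight set
(as prior weights) and re-simulates, which propagates model-fitting
variability at roughly $R$ times the cost.

## The synthetic generator and what it does (not) emulate

Every validation in the package runs on synthetic data with known
ground truth. The generator's defaults are the study conditions used
throughout: 200 foods, 500 persons, 13 nutrients, 16 strata with 2 PSUs
each, lognormal survey weights, weekend probability 3/7, and a
transformed-scale person model with Box-Cox exponent 0.35,
between-person CV 25%, within-person CV 40%, a +10% weekend effect, a
−5% second-interview effect and mild age-group effects — values a
dietary-survey analyst would recognize as typical for ubiquitously
consumed micronutrients. Small fractions of the roster are minors (5%),
pregnant (2%) or have an incomplete second recall (3%) so the exclusion
cascade is exercised; the analytic sample is adults (≥ 19 y) with two
complete days, not pregnant or lactating. The distribution step uses
100 pseudo-persons per person; recovery checks average 20 generator
seeds. These sizes complete the whole suite in about a minute on a
single core while leaving Monte-Carlo error well inside the tolerances
tested.

Fortified foods are constructed backwards from discrete %DV-per-RACC
targets (10, 25, 50, 100% of the current DV) with intrinsic shares
drawn from 10–50% of the total, which guarantees exact combinatorial
oracles for claim counts and places entries on both sides of the
fortification-zeroing boundary by construction. Per-person usual-intake
truth is computed analytically from the generating parameters with a
dense (41-node) quadrature, and EAR/UL references are placed at chosen
weighted quantiles of that truth, so estimated prevalences have exact
targets.

Two deliberate simplifications matter when reading test results as
evidence about real data. First, each synthetic food carries exactly
one nutrient: with multi-nutrient foods, allocating grams so that
merged totals hit model-drawn targets for all nutrients simultaneously
is an over-determined system. Single-carrier foods keep the
end-to-end identity `merge_recalls(generate(...)) == intended totals`
exact, at the price of no co-consumption structure — a rewrite of one
nutrient's DV cannot move another nutrient's intake here, whereas real
foods couple nutrients. Second, the generator model and the estimation
model share their functional form (Box-Cox, Gaussian random effects),
so parameter-recovery results certify the estimation machinery, not
robustness to model misspecification. Supplements, demographic realism
beyond age and sex, and consumer behavioral response to relabeling are
all out of scope.

## Known limitations

* The distribution step draws person effects unconditionally from
  $N(0, \hat\sigma_b^2)$ rather than from each person's conditional
  (empirical-Bayes) distribution; population-level means and
  prevalences are unaffected, but person-level usual-intake estimates
  would be.
* Upper-tail prevalences (%≥UL) carry more Monte-Carlo and model error
  than central quantities; at the default scale they are indicative
  only.
* The rewrite rule is reconstructed from the stated behavioral
  assumptions (intrinsic and enriched amounts fixed; %DV maintained;
  fortification discontinued when redundant); regulatory constraints
  such as standards of identity or palatability caps on added nutrients
  are deliberately ignored.
* Food counts are per database instance; foods appearing in several
  survey cycles are not deduplicated.
* Published population-scale results for the real US food supply
  require the restricted survey and fortification databases and cannot
  be reproduced synthetically; what the pipeline certifies at desk
  scale are the exact label arithmetic, the rewrite invariants, and the
  qualitative directions of every DV contrast.

## A worked pair of scenarios

```{r, eval = FALSE}
cfg <- generator_config(seed = 1L)
pair <- run_scenario_pair(cfg, dv_cur = dv_current(), dv_upd = dv_updated())
print(pair)
scenario_table(pair)
```

The printed table reports, per nutrient, the overall weighted mean
usual intake and the EAR/UL cut-point prevalences under both DV tables;
`pair$current$estimates` holds the long-format results (nutrient ×
subgroup × statistic with BRR standard errors), and
`pair$current$counts` / `$claims` the food-level tallies.
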