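---
title: "Methods: linking 24-h recall diets to greenhouse-gas emissions"
author: "dietfootprint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking 24-h recall diets to greenhouse-gas emissions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietfootprint)
```

## The model

The carbon footprint of a person-day of eating is the production-phase
greenhouse-gas emission (GHGE, kg CO₂-equivalents) behind everything that
person reported eating in a 24-h recall, including the mass lost between
farm gate and plate. For a reported food $f$ consumed in mass $m_f$ grams,
decomposed by a recipe into commodities $c$ with $r_{fc}$ grams of
commodity per 100 g of food, the footprint contribution is

$$
G_f \;=\; \sum_c \frac{m_f \, r_{fc}/100}
  {(1-\ell^{\text{retail}}_c)(1-\ell^{\text{consumer}}_c)}
  \cdot \frac{E_c}{1000},
$$

where $E_c$ is the commodity's emission factor in kg CO₂-eq per kg and the
$\ell$ are retail- and consumer-level loss fractions. Direct-linked
processed foods (cheese, tofu, sodas) use the same formula with the food's
own mass and factor. Person-day totals are sums over foods; every
compositional quantity (GHGE, nutrients, food-pattern equivalents) is also
expressed as a *density* per 1000 kcal, which separates what a diet is made
of from how much of it was eaten.

Assumptions worth stating explicitly:

* **Factors are point means.** A commodity with several LCA studies gets
  the unweighted arithmetic mean of the study values; each input record is
  one vote. No uncertainty interval is propagated.
* **Substitution is one-step.** Commodities without studies borrow either
  a group mean (group proxy) or a single similar food's factor (similar
  proxy), and proxies are resolved against *measured* factors only — no
  chains of proxies.
* **Cradle-to-farm-gate scope.** Factors cover production (sometimes
  primary processing); post-farm-gate processing, packaging, and transport
  are out of scope, so absolute footprints are underestimates.
* **One recall day per person.** No usual-intake (measurement-error)
  modeling; the unit of analysis is the reported day.

## Loss adjustment

Loss data give the *fraction lost* at retail and consumer stages, so the
production-side mass behind a consumed mass is the back-calculation
$m/((1-\ell_r)(1-\ell_c))$; with retail loss 0.10 and consumer loss 0.20,
72 g consumed requires exactly 100 g produced. Losses attach where the
emission factor attaches: at the commodity level for recipe foods, at the
food level for direct links. The ordering question — losses before or after
recipe decomposition for mixed dishes — is not settled by the source
material; this package applies them after decomposition, per commodity,
because the loss tables are commodity-keyed. Commodities without loss
entries default to zero loss with a logged warning, and the adjustment can
be switched off (`loss_adjust = FALSE`) for sensitivity runs; disabling it
can only lower footprints, a property the tests check pairwise.

## HEI-2010 scoring

The Healthy Eating Index 2010 awards up to 100 points over 12 components.
Nine encouraged components score linearly up to a density standard
(`min(max, max·density/standard)`); three discouraged components — refined
grains, sodium, empty calories — score `max` at or below one bound, zero at
or above another, linearly in between. The fatty-acids component scores the
ratio (MUFA+PUFA)/SFA between its zero- and full-score thresholds, with the
convention that a diet with unsaturated fat but no saturated fat takes the
maximum and a diet with no fat at all takes zero. Empty calories are the
energy share of solid fats (9 kcal/g), added sugars (16 kcal/tsp eq), and
alcohol *in excess of* 13 g/1000 kcal (7 kcal/g).

Every number in the previous paragraph — standards, bounds, maxima, energy
conversions, the alcohol threshold — ships in
`inst/extdata/hei2010_standards.yaml` and is validated at load time (the
twelve maxima must sum to 100, moderation bounds must be ordered). The
standards are configuration, not code: scoring variants are a YAML edit,
not a fork.

One numerical subtlety matters for probing the alcohol threshold: the
moderation curve has a flat full-score plateau (empty calories ≤ 19% of
energy). A probe diet with no other empty-calorie sources sits on that
plateau and small alcohol excesses do not move the score. The acceptance
probe therefore fixes solid fats at 30% of energy — inside the linear
region — so the score responds to the first gram of counted alcohol, and a
grid sweep recovers the threshold exactly.

## Survey-weighted quintiles

Diets are ranked on GHGE/1000 kcal and cut at the weighted 20/40/60/80th
percentiles, where the weighted quantile is the smallest observed density
whose cumulative weight share reaches the target. A density equal to a cut
point falls in the lower quintile — a deterministic tie rule — and with
equal weights and $n$ divisible by 5 the procedure reduces exactly to
unweighted quintiles. Ranking is invariant to rescaling all weights and to
adding a constant to all densities. Fewer than five distinct densities is a
degenerate distribution and an error, not a silent collapse.

## Design-based estimation

The comparison battery treats the sample as a stratified, clustered,
weighted survey. All variances are Taylor linearizations with PSUs taken
with replacement within strata; p-values refer to a t distribution with
(PSUs − strata) degrees of freedom. Concretely:

* **Means.** $\hat\mu = \sum w_i x_i / \sum w_i$ with linearized scores
  $z_i = w_i(x_i-\hat\mu)/\sum w_i$ summed to PSU totals; the variance is
  the standard between-PSU formula $\sum_h \frac{n_h}{n_h-1}\sum_j
  (Z_{hj}-\bar Z_h)^2$. With equal weights, one stratum, and one PSU per
  observation this is exactly $s^2/n$.
* **Subgroup t tests.** Each group's mean and variance are computed over
  the PSUs in which the group is present (the behaviour of subsetting a
  design in standard survey software); the difference uses the combined
  SE. This choice makes the equal-weight, one-PSU-per-person case collapse
  to the classical unequal-variance t statistic exactly, which the tests
  assert to 1e-10. Subgroup analyses can leave a stratum with a single
  represented PSU; the low-level functions treat that as an error by
  default, while the pipeline applies the standard fix of centering such
  strata at the grand PSU mean (`lonely = "centre"`).
* **Chi-square.** Pearson's statistic on the weighted group × category
  proportions, divided by a first-order Rao–Scott generalized design
  effect assembled from the linearized variances of cell and marginal
  proportions, referred to $\chi^2_{(R-1)(C-1)}$.
* **Regression.** Survey-weighted least squares with sandwich variance:
  bread $(X'WX)^{-1}$, meat the between-PSU variance of weighted score
  totals. With a single binary regressor the coefficient equals the
  weighted group-mean difference exactly. Behavior models come in three
  nested tiers (unadjusted; + age/gender/race-ethnicity; + income/
  education). Quintile trends use dummy contrasts against quintile 1 and
  orthogonal-polynomial linear/quadratic terms on the quintile index.

No multiplicity correction is applied anywhere; every test is reported at
its own α = 0.05, and downstream users should interpret batteries of
p-values accordingly.

## What the generator emulates — and what it does not

The synthetic-data module exists so that every stage of the pipeline can be
exercised, end to end, on data whose truth is known. Its defaults describe
the emulated study conditions, chosen once:

* **Commodity world.** 60 commodities in 14 classes (meat, poultry,
  seafood, dairy, solid fats; fruit, vegetables, greens and beans, whole
  and refined grains, plant proteins, oils, added sugars, alcohol), with
  emission factors drawn from two lognormal families — animal-source
  around 6 kg CO₂-eq/kg (spanning dairy-like to ruminant-like values),
  plant-source around 0.7 — and 1–5 studies per measured commodity with
  15% multiplicative study noise. Ten percent of commodities lack studies
  and carry substitution rules. Retail losses are uniform on
  (0.02, 0.15), consumer losses on (0.05, 0.35) — the span seen in
  loss-accounting tables.
* **Foods.** 120 foods of 1–8 ingredients around a main commodity, mixing
  families the way mixed dishes do; 10% are direct-linked processed foods.
  Per-food nutrient and pattern profiles are propagated from commodity
  profiles through the recipes, so nutrient densities and footprints share
  a common cause rather than being drawn independently.
* **Population.** 2000 persons, one recall day each, 6–12 foods per day
  with gamma-distributed grams; a latent two-pattern structure (meat-heavy
  vs plant-heavy, equal mix) tilts food choice by the food's animal-mass
  share. This is the minimal mechanism that reproduces the observed sign
  structure: meat-heavy diets higher in saturated fat and sodium, lower in
  fiber, with higher footprints. Gender, age, and race-ethnicity are
  mildly pattern-correlated; education and income are not. Four behavior
  flags (label use, guidance awareness and use, meal preparing) are
  pattern-correlated through a logit shift.
* **Survey design.** 15 strata × 2 PSUs with lognormal weights
  (log-SD 0.5), every cell populated by construction.
* **The vegetarian effect.** The self-perceived-vegetarian flag is drawn
  *independently* of the latent pattern, and its configured effect
  (−0.80 kg CO₂-eq/1000 kcal) is injected exactly, person by person, by
  iso-caloric substitution: grams of the person's most emission-intensive
  foods are exchanged for energy-equivalent grams of the lowest-intensity
  staple until the person's density drops by the configured amount. The
  independence is deliberate: a pattern-correlated flag would confound the
  *unadjusted* regression and no injected value could be recovered from
  it. A diet cannot go below the staple's own density, so the cleanest
  diets are capped short of the full effect; the generator reports these
  persons (`substitution_truncated`), and at the default settings the
  resulting attenuation is small relative to the estimator's sampling
  error.
* **Ground truth.** Every person's footprint is recomputed by a plain
  naive loop — its own factor averaging, its own loss arithmetic — kept
  deliberately separate from the vectorized pipeline code, and the two
  must agree exactly.

What the generator does **not** emulate: real food-code vocabularies,
NHANES weighting postures beyond strata/PSU/weight columns, day-2 recalls,
item nonresponse, or the long right tail of real emission factors. Passing
tests therefore demonstrate the *correctness of the machinery* — linkage,
conservation, scoring, design-based inference — not the numerical values
of any real population's footprint.

## Problem sizes and numerical choices

The test and acceptance workloads are scaled for a single CPU: conservation
and oracle-equivalence checks run on 500-person populations; the
vegetarian-recovery study uses 100 seeded populations of 2000 sharing one
commodity world; the null-calibration study uses 1000 populations of 240 in
a 40-commodity world with pattern separation and injected effects switched
off. Equality at machine precision is asserted where algebra guarantees it
(linearity, classical reductions); accumulation-order differences are
allowed 1e-9 relative or better (conservation ledgers, oracle agreement at
1e-12). Ties at quintile cuts go to the lower quintile; duplicate
(study, commodity) records and foods with both a recipe and a direct link
are validation errors, never silently resolved; unlinked foods abort the
run by default because silently dropping them would bias footprints
downward.

## Known limitations

* Absolute footprints depend on the synthetic emission-factor scale; only
  signs, orderings, and injected effects are meaningful test targets.
* The Rao–Scott correction is first-order; second-order (Satterthwaite)
  refinements are not implemented.
* Replicate-weight variance estimation (BRR, jackknife) is out of scope;
  Taylor linearization is the only engine.
* HEI-2010 only; other index versions would be new standards files plus,
  for structurally new components, new scoring types.
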