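# dietfootprint

Estimating the carbon footprint of individual self-selected diets from
24-hour dietary recall data, and asking whether low-footprint diets are
healthier diets.

## The problem

National dietary surveillance records what people actually ate on a given
day — thousands of *foods as eaten* (a slice of pepperoni pizza, a glass of
soda), each with grams consumed and energy. Life-cycle assessment (LCA)
measures greenhouse-gas emissions (GHGE, in kg CO₂-equivalents) per kg of
*raw commodity* (wheat flour, tomato, pork). Connecting the two requires a
chain of transformations, each of which this package implements as a
tested, reusable step:

1. **Commodity impact table.** Per-study emission factors are averaged per
   commodity (a simple unweighted mean over studies). Commodities with no
   study receive a one-step proxy: the mean of a group of related foods
   (stone fruits for nectarines) or a copy of a similar food (banana for
   plantain).
2. **Recipe decomposition.** Each food as eaten is decomposed into
   commodity grams through a recipe (grams of each ingredient per 100 g of
   food); processed foods studied as such (cheese, tofu, sodas) link
   directly to their own factor.
3. **Loss adjustment.** Delivering a gram to the plate requires more mass
   upstream: consumed mass is scaled by `1 / ((1 − retail)(1 − consumer))`
   using retail- and consumer-level loss fractions.
4. **Per-person aggregation.** A person-day's footprint is
   `Σ massᵢ × factorᵢ` over all loss-adjusted commodity contributions,
   expressed both per day and per 1000 kcal (a *density*, isolating diet
   composition from diet quantity).
5. **Diet quality.** The same intake yields per-1000 kcal nutrient and
   food-pattern densities and the 12-component Healthy Eating Index 2010
   (HEI-2010, 100 points; nine adequacy components scored
   `min(max, max · density/standard)`, three moderation components scored
   linearly between a full-score and a zero-score bound; empty calories
   count solid fats, added sugars, and alcohol above 13 g/1000 kcal).
6. **Design-based comparison.** Diets are ranked into survey-weighted
   quintiles of GHGE/1000 kcal; bottom and top quintiles are compared with
   Taylor-linearized means and t tests, Rao–Scott adjusted chi-squares for
   demographic composition, quintile trend tests, and nested
   survey-weighted regressions of footprint density on behaviors
   (food-label use, dietary-guidance awareness, vegetarianism, ...).

A synthetic-data generator emulates every input table (per-study factors,
recipes, losses, profiles, intake, demographics, behaviors, survey design)
with known ground truth, so the full pipeline runs and is tested without
any external data.

## Worked example

```r
library(dietfootprint)

cfg <- generator_config(seed = 2025, n_persons = 500, n_strata = 10)
generate_fixtures(cfg, "demo_in")          # writes the CSV input set
res <- run_pipeline("demo_in", "demo_out") # writes results + manifest
```

With this seed the run prints (see `demo_out/*.csv`):

```
persons: 500
weighted mean footprint: 4.99 kg CO2-eq/day, 2.77 kg CO2-eq/1000 kcal
quintile GHGE shares: 3% 6% 14% 29% 48%
HEI total, low vs high quintile: 63.9 vs 54.2 (p = 3.1e-05)
fiber density, low vs high: 15.00 vs 3.51 g/1000 kcal (p = 6e-07)
       model estimate    se p_value
  unadjusted   -0.886 0.434  0.0685
 demographic   -0.791 0.405  0.0791
        full   -0.783 0.393  0.0746
```

Reading this: the average synthetic diet emits ~5 kg CO₂-eq/day; the top
footprint quintile carries almost half of all diet emissions while the
bottom quintile carries 3%. Low-footprint diets score higher on the
HEI-2010 and are much richer in fiber — the meat-heavy/plant-heavy contrast
the generator builds in. The last table shows the three nested regressions
of footprint density on the vegetarian flag (unadjusted, plus demographics,
plus socioeconomics); the generator injects a −0.80 kg CO₂-eq/1000 kcal
vegetarian effect and the unadjusted coefficient estimates it.

A command-line wrapper with `generate` and `run` subcommands is installed
at `inst/cli/dietfootprint.R`.

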