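# Shared in-code fixtures. Everything is built programmatically; no files.

tiny_studies <- function() {
  data.frame(
    study_id = c("s1", "s2", "s3", "s4", "s5", "s6"),
    commodity_code = c("beef", "beef", "beef", "apple", "peach", "plum"),
    ghge_kgco2e_per_kg = c(20, 30, 40, 0.4, 0.5, 0.7),
    stringsAsFactors = FALSE)
}

tiny_impacts <- function(codes, values) {
  data.frame(commodity_code = codes, ghge_per_kg = values,
             n_studies = 1L, provenance = "measured",
             source = NA_character_, stringsAsFactors = FALSE)
}

pizza_recipe <- function() {
  data.frame(food_code = "pizza",
             commodity_code = c("wheat", "tomato", "pork"),
             grams_per_100g = c(30, 20, 10), stringsAsFactors = FALSE)
}

no_losses <- function() {
  data.frame(code = character(), retail_loss = numeric(),
             consumer_loss = numeric(), stringsAsFactors = FALSE)
}

# density profile meeting every adequacy standard and sitting at every
# moderation full-score bound (per 1000 kcal)
perfect_profile <- function(std = hei_standards()) {
  cm <- std$components
  data.frame(
    total_fruit_cup = cm$total_fruit$standard,
    whole_fruit_cup = cm$whole_fruit$standard,
    total_veg_cup = cm$total_vegetables$standard,
    greens_beans_cup = cm$greens_and_beans$standard,
    whole_grains_oz = cm$whole_grains$standard,
    dairy_cup = cm$dairy$standard,
    total_protein_oz = cm$total_protein$standard,
    seafood_plant_oz = cm$seafood_plant_protein$standard,
    mufa_g = 15, pufa_g = 10 * cm$fatty_acids$max_standard - 15, sat_fat_g = 10,
    refined_grains_oz = cm$refined_grains$max_standard,
    sodium_mg = cm$sodium$max_standard / cm$sodium$field_scale,
    solid_fats_g = 0, added_sugars_tsp = 0, alcohol_g = 0)
}

# all-zero encouraged groups, every moderation density at/above its zero bound
worst_profile <- function(std = hei_standards()) {
  cm <- std$components
  data.frame(
    total_fruit_cup = 0, whole_fruit_cup = 0, total_veg_cup = 0,
    greens_beans_cup = 0, whole_grains_oz = 0, dairy_cup = 0,
    total_protein_oz = 0, seafood_plant_oz = 0,
    mufa_g = 0, pufa_g = 0, sat_fat_g = 10,
    refined_grains_oz = cm$refined_grains$zero_standard,
    sodium_mg = cm$sodium$zero_standard / cm$sodium$field_scale,
    solid_fats_g = 60, added_sugars_tsp = 0, alcohol_g = 0)
}

small_config <- function(seed = 1L, ...) {
  generator_config(seed = seed, n_persons = 200L, n_foods = 60L,
                   n_commodities = 40L, n_strata = 8L, ...)
}

# independent single-stratum/arbitrary design mean+SE oracle used by the
# survey tests: direct transcription of the linearized ratio-mean formula
oracle_mean_se <- function(x, w, stratum, psu) {
  m <- sum(w * x) / sum(w)
  z <- w * (x - m) / sum(w)
  v <- 0
  for (h in unique(stratum)) {
    zh <- tapply(z[stratum == h], psu[stratum == h], sum)
    v <- v + length(zh) / (length(zh) - 1) * sum((zh - mean(zh))^2)
  }
  c(mean = m, se = sqrt(v))
}
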