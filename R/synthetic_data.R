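## Synthetic survey-shaped fixtures with known ground truth.
##
## The generator emulates the structure of the real data sources — per-study
## commodity emission factors, recipe files mapping foods as eaten to
## commodity grams, retail/consumer loss fractions, per-food nutrient and
## food-pattern profiles, per-person 24-h intake records, demographics,
## behavior flags, and stratified two-PSU-per-stratum survey design — so the
## whole pipeline is testable offline. Two latent dietary patterns
## (meat-heavy vs plant-heavy) drive food selection, giving the familiar
## sign structure: meat-heavy diets higher in saturated fat and sodium and
## lower in fiber, with higher footprints.

COMMODITY_CLASSES <- data.frame(
  class = c("meat", "poultry", "seafood", "dairy", "solid_fat",
            "fruit", "vegetable", "greens_beans", "whole_grain",
            "refined_grain", "plant_protein", "oil", "added_sugar",
            "alcohol"),
  family = c(rep("animal", 5L), rep("plant", 9L)),
  frac = c(0.08, 0.05, 0.05, 0.09, 0.04,
           0.10, 0.12, 0.05, 0.08, 0.11, 0.09, 0.05, 0.05, 0.04),
  stringsAsFactors = FALSE)

## per-100 g class-typical nutrient profile (means; per-commodity noise on top)
CLASS_NUTRIENTS <- local({
  m <- rbind(
    #          energy fiber vitA vitC vitD vitE chol iron   ca   mg    k   na  sfa mufa pufa  alc
    meat          = c(250, 0.0,   5,  0, 0.3, 0.2,  90, 2.0,  15,  20, 300, 500, 6.0, 5.0, 1.0, 0),
    poultry       = c(180, 0.0,  10,  0, 0.2, 0.3,  70, 1.0,  12,  22, 250, 400, 2.5, 3.0, 1.5, 0),
    seafood       = c(150, 0.0,  30,  0, 5.0, 1.0,  80, 1.0,  20,  30, 350, 400, 1.2, 2.0, 2.5, 0),
    dairy         = c(120, 0.0,  60,  1, 1.0, 0.1,  30, 0.1, 180,  15, 180, 120, 4.5, 2.0, 0.3, 0),
    solid_fat     = c(750, 0.0,  80,  0, 0.5, 1.0,  20, 0.0,  15,   2,  20, 600, 45 , 30 , 5.0, 0),
    fruit         = c( 60, 2.5,  20, 30, 0.0, 0.5,   8, 0.3,  12,  10, 180,   2, 0.1, 0.05,0.1, 0),
    vegetable     = c( 35, 2.5,  50, 20, 0.0, 0.8,  10, 0.8,  40,  20, 300,  30, 0.1, 0.05,0.15,0),
    greens_beans  = c( 60, 5.0, 100, 15, 0.0, 1.5,  25, 2.5,  80,  50, 400,  15, 0.2, 0.1, 0.4, 0),
    whole_grain   = c(340, 9.0,   0,  0, 0.0, 1.2,  25, 3.5,  30, 120, 300,   5, 0.7, 1.0, 1.8, 0),
    refined_grain = c(360, 2.5,   0,  0, 0.0, 0.3,  15, 4.0,  20,  25, 120,   5, 0.5, 0.8, 1.5, 0),
    plant_protein = c(400, 8.0,   0,  1, 0.0, 4.0,  40, 4.0, 100, 150, 700,  10, 2.5, 8.0, 8.0, 0),
    oil           = c(880, 0.0,   0,  0, 0.0, 15 ,   0, 0.0,   0,   0,   0,   0, 12 , 45 , 35 , 0),
    added_sugar   = c(390, 0.0,   0,  0, 0.0, 0.0,   0, 0.1,   2,   1,   5,   5, 0.0, 0.0, 0.0, 0),
    alcohol       = c(250, 0.0,   0,  0, 0.0, 0.0,   5, 0.1,   5,   5,  50,   5, 0.0, 0.0, 0.0, 36))
  colnames(m) <- c("energy_kcal", "fiber_g", "vitamin_a_ug", "vitamin_c_mg",
                   "vitamin_d_ug", "vitamin_e_mg", "choline_mg", "iron_mg",
                   "calcium_mg", "magnesium_mg", "potassium_mg", "sodium_mg",
                   "sat_fat_g", "mufa_g", "pufa_g", "alcohol_g")
  m
})

## per-100 g class-typical food-pattern equivalents
CLASS_PATTERNS <- local({
  cols <- c("total_fruit_cup", "whole_fruit_cup", "total_veg_cup",
            "greens_beans_cup", "whole_grains_oz", "refined_grains_oz",
            "dairy_cup", "meat_oz", "poultry_oz", "seafood_oz",
            "plant_protein_oz", "oils_g", "solid_fats_g", "added_sugars_tsp")
  m <- matrix(0, nrow = nrow(COMMODITY_CLASSES), ncol = length(cols),
              dimnames = list(COMMODITY_CLASSES$class, cols))
  m["fruit", c("total_fruit_cup", "whole_fruit_cup")] <- c(0.60, 0.45)
  m["vegetable", "total_veg_cup"] <- 0.55
  m["greens_beans", c("total_veg_cup", "greens_beans_cup")] <- 0.55
  m["whole_grain", "whole_grains_oz"] <- 3.5
  m["refined_grain", "refined_grains_oz"] <- 3.5
  m["dairy", "dairy_cup"] <- 0.41
  m["meat", "meat_oz"] <- 3.5
  m["poultry", "poultry_oz"] <- 3.5
  m["seafood", "seafood_oz"] <- 3.5
  m["plant_protein", "plant_protein_oz"] <- 3.5
  m["oil", "oils_g"] <- 100
  m["solid_fat", "solid_fats_g"] <- 100
  m["added_sugar", "added_sugars_tsp"] <- 24
  m
})

#' Configuration for the synthetic fixture generator
#'
#' Defaults are the study conditions the generator emulates: a two-pattern
#' (meat-heavy vs plant-heavy) population of 2000 adults with one 24-h
#' recall each, a commodity emission-factor table built from 1-5 studies
#' per commodity with a fraction of commodities resolved by substitution,
#' an injected self-perceived-vegetarian effect of -0.80 kg CO2-eq/
#' 1000 kcal, and a 15-stratum, 2-PSUs-per-stratum weighted design.
#'
#' @param seed integer seed; every generated table is reproducible given it.
#' @param n_persons number of persons (>= 10).
#' @param n_foods,n_commodities sizes of the food and commodity vocabularies.
#' @param pattern_mix probability of the meat-heavy latent pattern.
#' @param pattern_separation strength (log-odds scale) with which pattern
#'   drives food selection; 0 removes all pattern structure.
#' @param vegetarian_effect injected effect of the vegetarian flag on GHGE
#'   density, kg CO2-eq/1000 kcal (negative lowers the footprint).
#' @param vegetarian_prevalence probability of the vegetarian flag (drawn
#'   independently of pattern so the unadjusted effect is the injected one).
#' @param behavior_effect log-odds shift tying the other behavior flags to
#'   the plant pattern.
#' @param substitution_frac fraction of commodities with no study that
#'   receive a substitution rule.
#' @param direct_link_frac fraction of foods linked directly (own factor,
#'   no recipe).
#' @param unlinked_frac fraction of foods intentionally left without recipe
#'   or direct link, to exercise error paths.
#' @param n_strata,psus_per_stratum survey design layout.
#' @param weight_sdlog log-SD of the lognormal survey weights.
#' @param foods_per_person inclusive range of foods per recall day.
#' @param grams_shape,grams_scale gamma parameters for grams per food.
#' @param retail_loss_range,consumer_loss_range uniform ranges for the loss
#'   fractions.
#' @param animal_ghge_meanlog,animal_ghge_sdlog,plant_ghge_meanlog,plant_ghge_sdlog
#'   lognormal parameters of the two emission-factor families
#'   (kg CO2-eq/kg); the animal family mean is far above the plant family.
#' @return a list of class `"generator_config"`.
#' @export
generator_config <- function(seed = 1L,
                             n_persons = 2000L,
                             n_foods = 120L,
                             n_commodities = 60L,
                             pattern_mix = 0.5,
                             pattern_separation = 3,
                             vegetarian_effect = -0.80,
                             vegetarian_prevalence = 0.10,
                             behavior_effect = 0.8,
                             substitution_frac = 0.10,
                             direct_link_frac = 0.10,
                             unlinked_frac = 0,
                             n_strata = 15L,
                             psus_per_stratum = 2L,
                             weight_sdlog = 0.5,
                             foods_per_person = c(6L, 12L),
                             grams_shape = 4,
                             grams_scale = 30,
                             retail_loss_range = c(0.02, 0.15),
                             consumer_loss_range = c(0.05, 0.35),
                             animal_ghge_meanlog = log(6),
                             animal_ghge_sdlog = 0.8,
                             plant_ghge_meanlog = log(0.7),
                             plant_ghge_sdlog = 0.6) {
  cfg <- as.list(environment())
  probs <- c(pattern_mix, vegetarian_prevalence, substitution_frac,
             direct_link_frac, unlinked_frac)
  if (any(probs < 0 | probs > 1)) {
    stop("generator probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (n_persons < 10L) stop("n_persons must be at least 10", call. = FALSE)
  if (n_persons < 2L * n_strata * psus_per_stratum) {
    stop("n_persons too small for the stratum/PSU layout", call. = FALSE)
  }
  if (foods_per_person[1L] < 1L || foods_per_person[2L] > n_foods) {
    stop("foods_per_person range incompatible with n_foods", call. = FALSE)
  }
  structure(cfg, class = "generator_config")
}

#' Generate per-study commodity emission factors, rules, and losses
#'
#' Draws commodity factors from two lognormal families (animal-source high,
#' plant-source low), with 1-5 studies per measured commodity; a configured
#' fraction of commodities have no study and receive a substitution rule
#' (group proxy against their commodity class, or similar-food proxy).
#'
#' @param config a [generator_config()].
#' @return list with `studies`, `substitutions`, `groups`, `losses`, and a
#'   `commodities` metadata table (class, family, per-100 g profiles).
#' @export
generate_commodities <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_commodities
  n_class <- pmax(1L, round(COMMODITY_CLASSES$frac * n))
  classes <- rep(COMMODITY_CLASSES$class, n_class)
  classes <- if (length(classes) >= n) classes[seq_len(n)] else
    c(classes, rep("vegetable", n - length(classes)))
  family <- COMMODITY_CLASSES$family[match(classes, COMMODITY_CLASSES$class)]
  code <- sprintf("C%03d", seq_len(n))

  true_ghge <- ifelse(
    family == "animal",
    stats::rlnorm(n, config$animal_ghge_meanlog, config$animal_ghge_sdlog),
    stats::rlnorm(n, config$plant_ghge_meanlog, config$plant_ghge_sdlog))

  ## per-commodity nutrient / pattern profiles: class profile with noise
  noise <- matrix(stats::runif(n * ncol(CLASS_NUTRIENTS), 0.7, 1.3), nrow = n)
  nut <- CLASS_NUTRIENTS[classes, , drop = FALSE] * noise
  pat <- CLASS_PATTERNS[classes, , drop = FALSE] *
    stats::runif(n, 0.85, 1.15)
  commodities <- data.frame(commodity_code = code, class = classes,
                            family = family, true_ghge = true_ghge,
                            stringsAsFactors = FALSE)
  commodities <- cbind(commodities, as.data.frame(nut, row.names = FALSE),
                       as.data.frame(pat, row.names = FALSE))

  measured <- stats::runif(n) >= config$substitution_frac
  ## keep every class resolvable: first commodity of each class stays measured
  first_of_class <- !duplicated(classes)
  measured[first_of_class] <- TRUE

  n_studies <- ifelse(measured, sample(1:5, n, replace = TRUE), 0L)
  studies <- do.call(rbind, lapply(which(measured), function(i) {
    k <- n_studies[i]
    data.frame(study_id = sprintf("S%03d_%d", i, seq_len(k)),
               commodity_code = code[i],
               ghge_kgco2e_per_kg = true_ghge[i] *
                 exp(stats::rnorm(k, 0, 0.15)),
               stringsAsFactors = FALSE)
  }))

  groups <- data.frame(commodity_code = code[measured],
                       group = classes[measured], stringsAsFactors = FALSE)
  unmeasured <- which(!measured)
  substitutions <- if (length(unmeasured) == 0L) {
    data.frame(target_commodity_code = character(), kind = character(),
               source = character(), stringsAsFactors = FALSE)
  } else {
    kind <- sample(c("group_proxy", "similar_proxy"), length(unmeasured),
                   replace = TRUE)
    src <- character(length(unmeasured))
    for (j in seq_along(unmeasured)) {
      i <- unmeasured[j]
      if (kind[j] == "group_proxy") {
        src[j] <- classes[i]
      } else {
        same <- code[measured & classes == classes[i]]
        src[j] <- sample(same, 1L)
      }
    }
    data.frame(target_commodity_code = code[unmeasured], kind = kind,
               source = src, stringsAsFactors = FALSE)
  }

  losses <- data.frame(
    code = code,
    retail_loss = stats::runif(n, config$retail_loss_range[1L],
                               config$retail_loss_range[2L]),
    consumer_loss = stats::runif(n, config$consumer_loss_range[1L],
                                 config$consumer_loss_range[2L]),
    stringsAsFactors = FALSE)

  list(commodities = commodities, studies = studies,
       substitutions = substitutions, groups = groups, losses = losses)
}

#' Generate recipes, direct links, and per-food profiles
#'
#' Each recipe food has 1-8 ingredients around a main commodity, mixing
#' commodity families the way mixed dishes do; a configured fraction of
#' foods are direct-linked processed foods carrying their own emission
#' factor. Per-food nutrient and food-pattern profiles (per 100 g as eaten)
#' are propagated from the commodity profiles through the recipes, so
#' nutrient densities and footprints share a common cause.
#'
#' @param config a [generator_config()].
#' @param commodities output of [generate_commodities()].
#' @return list with `recipes`, `direct_links`, `food_nutrients`,
#'   `food_patterns`, `losses` (commodity losses plus direct-linked food
#'   losses), and a `foods` metadata table.
#' @export
generate_recipes <- function(config, commodities) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + 1L)
  com <- commodities$commodities
  nF <- config$n_foods
  food_code <- sprintf("F%03d", seq_len(nF))
  n_direct <- round(config$direct_link_frac * nF)
  n_unlinked <- round(config$unlinked_frac * nF)
  kind <- rep("recipe", nF)
  if (n_direct > 0L) kind[sample(which(kind == "recipe"), n_direct)] <- "direct"
  if (n_unlinked > 0L) {
    kind[sample(which(kind == "recipe"), n_unlinked)] <- "unlinked"
  }

  nut_cols <- colnames(CLASS_NUTRIENTS)
  pat_cols <- colnames(CLASS_PATTERNS)
  recipes <- list(); prof_n <- list(); prof_p <- list()
  main_class <- character(nF)
  for (f in seq_len(nF)) {
    main <- sample(nrow(com), 1L)
    main_class[f] <- com$class[main]
    if (kind[f] == "direct") {
      ing <- main; g <- 100
    } else {
      k <- sample(1:8, 1L)
      others <- if (k > 1L) sample(setdiff(seq_len(nrow(com)), main), k - 1L)
                else integer()
      ing <- c(main, others)
      g <- c(stats::runif(1, 30, 70),
             if (k > 1L) stats::runif(k - 1L, 2, 15))
    }
    if (kind[f] == "recipe") {
      recipes[[f]] <- data.frame(food_code = food_code[f],
                                 commodity_code = com$commodity_code[ing],
                                 grams_per_100g = g, stringsAsFactors = FALSE)
    }
    w <- g / 100
    prof_n[[f]] <- colSums(as.matrix(com[ing, nut_cols, drop = FALSE]) * w)
    prof_p[[f]] <- colSums(as.matrix(com[ing, pat_cols, drop = FALSE]) * w)
  }
  recipes <- do.call(rbind, recipes)
  food_nutrients <- cbind(data.frame(food_code = food_code,
                                     stringsAsFactors = FALSE),
                          as.data.frame(do.call(rbind, prof_n)))
  food_patterns <- cbind(data.frame(food_code = food_code,
                                    stringsAsFactors = FALSE),
                         as.data.frame(do.call(rbind, prof_p)))
  ## derived protein aggregates used by the HEI scorer
  food_patterns$total_protein_oz <- food_patterns$meat_oz +
    food_patterns$poultry_oz + food_patterns$seafood_oz +
    food_patterns$plant_protein_oz
  food_patterns$seafood_plant_oz <- food_patterns$seafood_oz +
    food_patterns$plant_protein_oz

  direct_idx <- which(kind == "direct")
  fam <- com$family[match(main_class, com$class)]
  direct_links <- data.frame(
    food_code = food_code[direct_idx],
    ghge_per_kg = ifelse(
      fam[direct_idx] == "animal",
      stats::rlnorm(length(direct_idx), config$animal_ghge_meanlog,
                    config$animal_ghge_sdlog),
      stats::rlnorm(length(direct_idx), config$plant_ghge_meanlog,
                    config$plant_ghge_sdlog)),
    stringsAsFactors = FALSE)

  direct_losses <- data.frame(
    code = food_code[direct_idx],
    retail_loss = stats::runif(length(direct_idx),
                               config$retail_loss_range[1L],
                               config$retail_loss_range[2L]),
    consumer_loss = stats::runif(length(direct_idx),
                                 config$consumer_loss_range[1L],
                                 config$consumer_loss_range[2L]),
    stringsAsFactors = FALSE)

  ## animal share of each recipe's mass drives pattern-specific selection
  animal_share <- vapply(seq_len(nF), function(f) {
    if (kind[f] != "recipe") {
      as.numeric(fam[f] == "animal")
    } else {
      rec <- recipes[recipes$food_code == food_code[f], , drop = FALSE]
      fa <- com$family[match(rec$commodity_code, com$commodity_code)]
      sum(rec$grams_per_100g[fa == "animal"]) / sum(rec$grams_per_100g)
    }
  }, numeric(1))

  foods <- data.frame(food_code = food_code, kind = kind,
                      main_class = main_class, family = fam,
                      animal_share = animal_share,
                      energy_per_100g = food_nutrients$energy_kcal,
                      stringsAsFactors = FALSE)
  list(recipes = recipes, direct_links = direct_links,
       food_nutrients = food_nutrients, food_patterns = food_patterns,
       losses = direct_losses, foods = foods)
}

## per-gram GHGE and energy rates of each linked food, via the pipeline route
food_rates <- function(recipe_set, impacts, losses) {
  linked <- recipe_set$foods[recipe_set$foods$kind != "unlinked", ,
                             drop = FALSE]
  intake0 <- data.frame(person_id = linked$food_code,
                        food_code = linked$food_code,
                        grams_consumed = 100,
                        energy_kcal = linked$energy_per_100g,
                        stringsAsFactors = FALSE)
  res <- suppressWarnings(
    link_ghge(intake0, recipe_set$recipes, recipe_set$direct_links,
              impacts, losses))
  data.frame(food_code = res$intake$food_code,
             ghge_kg_per_g = res$intake$ghge_kg / 100,
             kcal_per_g = res$intake$energy_kcal / 100,
             stringsAsFactors = FALSE)
}

#' Generate a survey population with known footprint ground truth
#'
#' Persons belong to one of two latent dietary patterns which drives their
#' food selection; demographics and four behavior flags are correlated with
#' the pattern. The self-perceived-vegetarian flag is drawn independently
#' and its configured effect on GHGE density is injected exactly, person by
#' person, by iso-caloric substitution: grams of the person's most
#' emission-intensive foods are exchanged for energy-equivalent grams of
#' the lowest-intensity staple food until the person's footprint density is
#' lower by the configured amount (capped at the staple's own density).
#' Every person's footprint is also computed by an independent naive loop
#' and returned as ground truth.
#'
#' @param config a [generator_config()].
#' @param commodities,recipe_set outputs of [generate_commodities()] and
#'   [generate_recipes()]; generated from `config` when `NULL`.
#' @param ground_truth logical; skip the (slower) naive-loop oracle when
#'   `FALSE`.
#' @return list with `intake`, `demographics`, `behaviors`, `design`,
#'   `ground_truth` (or `NULL`), `pattern` (latent truth), and
#'   `substitution_truncated` (persons whose injected effect was capped).
#' @export
generate_population <- function(config, commodities = NULL,
                                recipe_set = NULL, ground_truth = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(commodities)) commodities <- generate_commodities(config)
  if (is.null(recipe_set)) recipe_set <- generate_recipes(config, commodities)
  set.seed(config$seed + 2L)
  n <- config$n_persons
  person_id <- sprintf("P%04d", seq_len(n))
  foods <- recipe_set$foods
  losses <- rbind(commodities$losses, recipe_set$losses)

  pattern <- stats::rbinom(n, 1L, config$pattern_mix)  # 1 = meat-heavy
  sep <- config$pattern_separation
  w_meat <- exp(sep * foods$animal_share)
  w_plant <- exp(-sep * foods$animal_share)

  k <- sample(config$foods_per_person[1L]:config$foods_per_person[2L], n,
              replace = TRUE)
  picks <- lapply(seq_len(n), function(i) {
    sample(nrow(foods), k[i],
           prob = if (pattern[i] == 1L) w_meat else w_plant)
  })
  idx <- unlist(picks)
  grams <- stats::rgamma(length(idx), shape = config$grams_shape,
                         scale = config$grams_scale)
  intake <- data.frame(person_id = rep(person_id, k),
                       food_code = foods$food_code[idx],
                       grams_consumed = grams,
                       energy_kcal = grams * foods$energy_per_100g[idx] / 100,
                       stringsAsFactors = FALSE)

  ## survey design: every stratum x PSU cell populated, lognormal weights
  cells <- expand.grid(psu = seq_len(config$psus_per_stratum),
                       stratum = seq_len(config$n_strata))
  cell_i <- rep_len(seq_len(nrow(cells)), n)[sample.int(n)]
  design <- data.frame(person_id = person_id,
                       weight = stats::rlnorm(n, 0, config$weight_sdlog),
                       stratum = sprintf("H%02d", cells$stratum[cell_i]),
                       psu = sprintf("U%d", cells$psu[cell_i]),
                       stringsAsFactors = FALSE)

  ## demographics: mild pattern correlation for gender/age/race; none for
  ## education/income (mirrors the null findings for those)
  plant <- pattern == 0L
  gender <- ifelse(stats::runif(n) < ifelse(plant, 0.56, 0.46),
                   "female", "male")
  age_probs <- function(p) if (p) c(0.26, 0.36, 0.24, 0.14)
                           else c(0.20, 0.37, 0.26, 0.17)
  age_group <- vapply(plant, function(p) {
    sample(c("18-29", "30-49", "50-65", "66+"), 1L, prob = age_probs(p))
  }, character(1))
  race_probs <- function(p) if (p) c(0.13, 0.66, 0.15, 0.06)
                            else c(0.125, 0.71, 0.10, 0.065)
  race <- vapply(plant, function(p) {
    sample(c("latino", "white", "african_american", "other"), 1L,
           prob = race_probs(p))
  }, character(1))
  education <- sample(c("lt_highschool", "highschool", "some_college",
                        "college"), n, replace = TRUE,
                      prob = c(0.19, 0.25, 0.31, 0.25))
  income_group <- sample(c("missing", "lt1", "1to2", "2to5", "ge5"), n,
                         replace = TRUE,
                         prob = c(0.06, 0.13, 0.19, 0.37, 0.25))
  demographics <- data.frame(person_id = person_id, gender = gender,
                             age_group = age_group, race_ethnicity = race,
                             education = education,
                             income_group = income_group,
                             stringsAsFactors = FALSE)

  ## behavior flags: four pattern-correlated, vegetarian independent
  be <- config$behavior_effect
  flag <- function(base) {
    stats::rbinom(n, 1L, stats::plogis(stats::qlogis(base) + be * plant))
  }
  behaviors <- data.frame(
    person_id = person_id,
    used_food_labels = flag(0.60),
    heard_guidance = flag(0.55),
    used_guidance = flag(0.25),
    meal_preparer = flag(0.50),
    vegetarian = stats::rbinom(n, 1L, config$vegetarian_prevalence),
    stringsAsFactors = FALSE)

  ## inject the vegetarian effect exactly by iso-caloric substitution
  truncated <- character()
  if (config$vegetarian_effect != 0 && any(behaviors$vegetarian == 1L)) {
    impacts <- apply_substitutions(average_impacts(commodities$studies),
                                   commodities$substitutions,
                                   commodities$groups)
    rates <- food_rates(recipe_set, impacts, losses)
    ri <- match(intake$food_code, rates$food_code)
    a <- rates$ghge_kg_per_g[ri]   # NA for unlinked foods: left untouched
    kk <- rates$kcal_per_g[ri]
    ref <- rates[which.min(rates$ghge_kg_per_g / rates$kcal_per_g), ]
    r_ref <- ref$ghge_kg_per_g / ref$kcal_per_g
    extra <- list()
    for (p in which(behaviors$vegetarian == 1L)) {
      rows <- which(intake$person_id == person_id[p] & !is.na(a))
      E <- sum(intake$energy_kcal[rows])
      need <- -config$vegetarian_effect * E / 1000  # kg CO2-eq to remove
      ord <- rows[order(a[rows] / kk[rows], decreasing = TRUE)]
      moved_kcal <- 0
      for (i in ord) {
        if (need <= 1e-12) break
        if (intake$food_code[i] == ref$food_code) next
        delta <- a[i] - r_ref * kk[i]  # kg removed per gram swapped out
        if (delta <= 0) next
        x <- min(intake$grams_consumed[i], need / delta)
        intake$grams_consumed[i] <- intake$grams_consumed[i] - x
        intake$energy_kcal[i] <- intake$energy_kcal[i] - x * kk[i]
        moved_kcal <- moved_kcal + x * kk[i]
        need <- need - x * delta
      }
      if (moved_kcal > 0) {
        extra[[length(extra) + 1L]] <- data.frame(
          person_id = person_id[p], food_code = ref$food_code,
          grams_consumed = moved_kcal / ref$kcal_per_g,
          energy_kcal = moved_kcal, stringsAsFactors = FALSE)
      }
      if (need > 1e-9) truncated <- c(truncated, person_id[p])
    }
    if (length(extra) > 0L) {
      intake <- rbind(intake, do.call(rbind, extra))
      intake <- intake[order(intake$person_id, intake$food_code), ,
                       drop = FALSE]
      rownames(intake) <- NULL
    }
  }

  gt <- if (ground_truth) {
    naive_ground_truth(intake, commodities, recipe_set, losses)
  } else {
    NULL
  }

  list(intake = intake, demographics = demographics, behaviors = behaviors,
       design = design, ground_truth = gt, pattern = pattern,
       substitution_truncated = truncated)
}

## Independent naive-loop oracle: recomputes each person's footprint with
## plain loops and its own factor resolution (mean of study values; group
## mean or source copy for substitutions), deliberately avoiding the
## vectorized pipeline code paths.
naive_ground_truth <- function(intake, commodities, recipe_set, losses) {
  studies <- commodities$studies
  subs <- commodities$substitutions
  groups <- commodities$groups
  factor_of <- new.env()
  for (cc in unique(studies$commodity_code)) {
    assign(cc, mean(studies$ghge_kgco2e_per_kg[studies$commodity_code == cc]),
           envir = factor_of)
  }
  if (nrow(subs) > 0L) {
    for (i in seq_len(nrow(subs))) {
      if (subs$kind[i] == "similar_proxy") {
        val <- get(subs$source[i], envir = factor_of)
      } else {
        members <- groups$commodity_code[groups$group == subs$source[i]]
        val <- mean(vapply(members, function(m) get(m, envir = factor_of),
                           numeric(1)))
      }
      assign(subs$target_commodity_code[i], val, envir = factor_of)
    }
  }
  loss_of <- function(code) {
    j <- which(losses$code == code)
    if (length(j) == 0L) c(0, 0)
    else c(losses$retail_loss[j[1L]], losses$consumer_loss[j[1L]])
  }
  direct <- recipe_set$direct_links
  recipes <- recipe_set$recipes

  ids <- unique(intake$person_id)
  row_of <- split(seq_len(nrow(intake)), intake$person_id)
  tot_g <- numeric(length(ids)); tot_e <- numeric(length(ids))
  for (pi in seq_along(ids)) {
    rows <- row_of[[ids[pi]]]
    G <- 0; E <- 0
    for (i in rows) {
      fc <- intake$food_code[i]
      g <- intake$grams_consumed[i]
      E <- E + intake$energy_kcal[i]
      if (fc %in% direct$food_code) {
        l <- loss_of(fc)
        adj <- g / ((1 - l[1L]) * (1 - l[2L]))
        G <- G + adj / 1000 * direct$ghge_per_kg[direct$food_code == fc]
      } else {
        rec <- recipes[recipes$food_code == fc, , drop = FALSE]
        if (nrow(rec) == 0L) next  # unlinked food
        for (j in seq_len(nrow(rec))) {
          gc <- g * rec$grams_per_100g[j] / 100
          l <- loss_of(rec$commodity_code[j])
          adj <- gc / ((1 - l[1L]) * (1 - l[2L]))
          G <- G + adj / 1000 * get(rec$commodity_code[j], envir = factor_of)
        }
      }
    }
    tot_g[pi] <- G; tot_e[pi] <- E
  }
  data.frame(person_id = ids, ghge_total_kg = tot_g, energy_kcal = tot_e,
             ghge_density = ifelse(tot_e > 0, 1000 * tot_g / tot_e, NA_real_),
             stringsAsFactors = FALSE)
}

#' Write the complete synthetic fixture set to CSV
#'
#' Emits every table the pipeline consumes (`studies.csv`,
#' `substitutions.csv`, `groups.csv`, `losses.csv`, `recipes.csv`,
#' `direct_links.csv`, `food_nutrients.csv`, `food_patterns.csv`,
#' `intake.csv`, `demographics.csv`, `behaviors.csv`, `design.csv`) plus
#' `ground_truth.csv` with the naive-loop footprints.
#'
#' @param config a [generator_config()].
#' @param dir output directory (created if needed).
#' @param ground_truth logical; include the naive-loop oracle output.
#' @return invisibly, a named list of file paths; the generated tables are
#'   attached as the `"data"` attribute.
#' @export
generate_fixtures <- function(config, dir, ground_truth = TRUE) {
  commodities <- generate_commodities(config)
  recipe_set <- generate_recipes(config, commodities)
  pop <- generate_population(config, commodities, recipe_set,
                             ground_truth = ground_truth)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- list(studies = commodities$studies,
               substitutions = commodities$substitutions,
               groups = commodities$groups,
               losses = rbind(commodities$losses, recipe_set$losses),
               recipes = recipe_set$recipes,
               direct_links = recipe_set$direct_links,
               food_nutrients = recipe_set$food_nutrients,
               food_patterns = recipe_set$food_patterns,
               intake = pop$intake,
               demographics = pop$demographics,
               behaviors = pop$behaviors,
               design = pop$design)
  if (ground_truth) tabs$ground_truth <- pop$ground_truth
  paths <- lapply(names(tabs), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    write_table_csv(tabs[[nm]], p)
    p
  })
  names(paths) <- names(tabs)
  out <- paths
  attr(out, "data") <- c(tabs, list(pattern = pop$pattern,
                                    substitution_truncated =
                                      pop$substitution_truncated))
  invisible(out)
}
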