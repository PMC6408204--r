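#' Load and validate Healthy Eating Index 2010 scoring standards
#'
#' The HEI-2010 scores a diet on 12 components whose maxima sum to 100
#' points: nine adequacy components (food groups to encourage, scored
#' proportionally up to a density standard), and three moderation components
#' (refined grains, sodium, empty calories, scored down between two density
#' bounds). The numeric standards, the fatty-acid ratio thresholds, the
#' empty-calorie energy conversions, and the 13 g/1000 kcal alcohol
#' threshold are all configuration and ship in an editable YAML file.
#'
#' @param path YAML standards file; default is the file installed with the
#'   package.
#' @return a list of class `"hei_standards"`; component maxima are asserted
#'   to sum to 100 at load time.
#' @export
hei_standards <- function(path = NULL) {
  path <- path %||% system.file("extdata", "hei2010_standards.yaml",
                                package = "dietfootprint")
  std <- yaml::read_yaml(path)
  comps <- std$components
  if (length(comps) != 12L) {
    stop(sprintf("HEI standards: expected 12 components, found %d",
                 length(comps)), call. = FALSE)
  }
  total_max <- sum(vapply(comps, function(cc) cc$max_points, numeric(1)))
  if (abs(total_max - 100) > 1e-9) {
    stop(sprintf("HEI standards: component maxima sum to %g, not 100",
                 total_max), call. = FALSE)
  }
  for (nm in names(comps)) {
    cc <- comps[[nm]]
    if (cc$type == "adequacy" && cc$standard <= 0) {
      stop(sprintf("HEI standards: nonpositive adequacy standard for %s", nm),
           call. = FALSE)
    }
    if (cc$type %in% c("moderation", "empty_calories") &&
        cc$zero_standard <= cc$max_standard) {
      stop(sprintf("HEI standards: inverted moderation bounds for %s", nm),
           call. = FALSE)
    }
  }
  structure(std, class = "hei_standards")
}

#' Score an adequacy component
#'
#' Linear in the density up to the standard, then capped at the maximum:
#' `min(max_points, max_points * density / standard)`. Vectorized over
#' `density`.
#'
#' @param density intake density per 1000 kcal (nonnegative).
#' @param standard density at or above which the maximum is awarded (> 0).
#' @param max_points component maximum.
#' @return points in `[0, max_points]`.
#' @export
score_adequacy <- function(density, standard, max_points) {
  if (any(standard <= 0)) {
    stop("adequacy standard must be positive", call. = FALSE)
  }
  check_nonneg(density, "density")
  pmin(max_points, max_points * density / standard)
}

#' Score a moderation component
#'
#' Full points at or below `max_standard`, zero at or above `zero_standard`,
#' linear in between. Vectorized over `density`.
#'
#' @param density intake density per 1000 kcal.
#' @param max_standard density at/below which the maximum is awarded.
#' @param zero_standard density at/above which zero is awarded
#'   (must exceed `max_standard`).
#' @param max_points component maximum.
#' @return points in `[0, max_points]`.
#' @export
score_moderation <- function(density, max_standard, zero_standard,
                             max_points) {
  if (any(zero_standard <= max_standard) || any(max_standard < 0)) {
    stop("moderation standards must satisfy 0 <= max_standard < zero_standard",
         call. = FALSE)
  }
  frac <- (zero_standard - density) / (zero_standard - max_standard)
  pmin(max_points, pmax(0, max_points * frac))
}

#' Unsaturated-to-saturated fatty-acid ratio
#'
#' `(MUFA + PUFA) / SFA`. When no saturated fat is present the ratio is
#' taken as `Inf` if any unsaturated fat is present (best possible) and 0
#' if the diet has no fat at all.
#'
#' @param mufa,pufa,sfa fatty-acid amounts (same units; grams/1000 kcal in
#'   this package).
#' @return the ratio, vectorized.
#' @export
fatty_acid_ratio <- function(mufa, pufa, sfa) {
  check_nonneg(sfa, "saturated fat")
  num <- mufa + pufa
  ifelse(sfa > 0, num / sfa, ifelse(num > 0, Inf, 0))
}

#' Energy share of empty calories
#'
#' Empty calories are the energy from solid fats, added sugars, and alcohol
#' in excess of 13 g per 1000 kcal (alcohol at or below the threshold does
#' not influence scoring), expressed as a percentage of total energy.
#' Because every term is a ratio to energy, calling this with per-1000 kcal
#' densities and `energy = 1000` gives the same answer as daily totals.
#'
#' @param solid_fat_g grams of solid fats.
#' @param added_sugar_tsp teaspoon equivalents of added sugars.
#' @param alcohol_g grams of alcohol.
#' @param energy_kcal total energy (> 0).
#' @param standards an [hei_standards()] object supplying the energy
#'   conversions and the alcohol threshold.
#' @return percent of energy from empty calories.
#' @export
empty_calories_energy <- function(solid_fat_g, added_sugar_tsp, alcohol_g,
                                  energy_kcal, standards = hei_standards()) {
  if (any(energy_kcal <= 0)) {
    stop("energy must be positive to express empty calories as a share",
         call. = FALSE)
  }
  check_nonneg(c(solid_fat_g, added_sugar_tsp, alcohol_g), "empty-calorie inputs")
  conv <- standards$energy_conversions
  thr <- standards$alcohol_threshold_g_per_1000kcal
  alcohol_excess <- pmax(0, alcohol_g - thr * energy_kcal / 1000)
  kcal <- conv$solid_fat_kcal_per_g * solid_fat_g +
    conv$added_sugar_kcal_per_tsp * added_sugar_tsp +
    conv$alcohol_kcal_per_g * alcohol_excess
  100 * kcal / energy_kcal
}

#' Score diets on the Healthy Eating Index 2010
#'
#' Computes the 12 HEI-2010 component scores and their total (0-100) from a
#' per-1000 kcal density profile. Scoring is entirely density-based, so it
#' is invariant to scaling all intakes and energy by a common factor.
#'
#' @param profile data.frame of density profiles (one row per diet) with the
#'   columns named in the standards file: `total_fruit_cup`,
#'   `whole_fruit_cup`, `total_veg_cup`, `greens_beans_cup`,
#'   `whole_grains_oz`, `dairy_cup`, `total_protein_oz`, `seafood_plant_oz`,
#'   `refined_grains_oz`, `sodium_mg`, `mufa_g`, `pufa_g`, `sat_fat_g`,
#'   `solid_fats_g`, `added_sugars_tsp`, `alcohol_g` — all per 1000 kcal.
#'   A `person_id` column, if present, is carried through.
#' @param standards an [hei_standards()] object.
#' @return data.frame with one column per component (`hei_<component>`),
#'   and `hei_total`.
#' @export
score_hei <- function(profile, standards = hei_standards()) {
  comps <- standards$components
  needed <- unique(unlist(lapply(comps, function(cc) c(cc$field, cc$fields))))
  check_columns(profile, needed, "HEI density profile")
  out <- if ("person_id" %in% names(profile)) {
    profile[, "person_id", drop = FALSE]
  } else {
    data.frame(row.names = seq_len(nrow(profile)))
  }
  total <- 0
  for (nm in names(comps)) {
    cc <- comps[[nm]]
    score <- switch(
      cc$type,
      adequacy = score_adequacy(profile[[cc$field]] * (cc$field_scale %||% 1),
                                cc$standard, cc$max_points),
      moderation = score_moderation(profile[[cc$field]] * (cc$field_scale %||% 1),
                                    cc$max_standard, cc$zero_standard,
                                    cc$max_points),
      ratio = {
        ## full points at/above max_standard, zero at/below zero_standard,
        ## linear in between; Inf (no saturated fat) caps at full points
        ratio <- fatty_acid_ratio(profile[[cc$fields[1L]]],
                                  profile[[cc$fields[2L]]],
                                  profile[[cc$fields[3L]]])
        ratio <- pmin(ratio, cc$max_standard)
        pmax(0, cc$max_points * (ratio - cc$zero_standard) /
                  (cc$max_standard - cc$zero_standard))
      },
      empty_calories = {
        pct <- empty_calories_energy(profile[[cc$fields[1L]]],
                                     profile[[cc$fields[2L]]],
                                     profile[[cc$fields[3L]]],
                                     energy_kcal = 1000,
                                     standards = standards)
        score_moderation(pct, cc$max_standard, cc$zero_standard,
                         cc$max_points)
      },
      stop(sprintf("unknown HEI component type '%s'", cc$type), call. = FALSE))
    out[[paste0("hei_", nm)]] <- score
    total <- total + score
  }
  out$hei_total <- total
  rownames(out) <- NULL
  out
}
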