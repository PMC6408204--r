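#' Per-food nutrient and food-pattern amounts from per-100 g profiles
#'
#' Multiplies each intake record's consumed grams into the food's nutrient
#' (or food-pattern equivalent) profile per 100 g.
#'
#' @param intake intake table (`person_id`, `food_code`, `grams_consumed`).
#' @param profiles data.frame with `food_code` plus numeric per-100 g columns.
#' @return data.frame with `person_id`, `food_code` and the profile columns
#'   scaled to amounts for the consumed grams.
#' @keywords internal
food_amounts <- function(intake, profiles) {
  check_columns(profiles, "food_code", "profiles")
  i <- match(intake$food_code, profiles$food_code)
  if (anyNA(i)) {
    miss <- sort(unique(intake$food_code[is.na(i)]))
    stop(sprintf("no profile for food code(s): %s",
                 paste(utils::head(miss, 5L), collapse = ", ")),
         call. = FALSE)
  }
  num <- setdiff(names(profiles), "food_code")
  out <- intake[, c("person_id", "food_code"), drop = FALSE]
  for (col in num) {
    out[[col]] <- intake$grams_consumed * profiles[[col]][i] / 100
  }
  out
}

#' Aggregate linked foods to per-person diet summaries
#'
#' Sums daily greenhouse-gas emissions, energy, nutrients, and food-pattern
#' equivalents over each person's reported foods and expresses everything
#' but energy as a density per 1000 kcal, isolating diet composition from
#' diet quantity. Persons with zero total energy have undefined densities
#' and are excluded with a warning (their ids are kept in the
#' `"excluded"` attribute).
#'
#' @param linked_intake intake table with a `ghge_kg` column, as produced by
#'   [link_ghge()] (`$intake`); must also carry `energy_kcal`.
#' @param food_nutrients,food_patterns per-100 g profile tables keyed by
#'   `food_code` (optional; densities are produced for whatever is given).
#' @param energy_floor_kcal persons below this daily energy are flagged in
#'   the `low_energy` column but never excluded.
#' @return data.frame, one row per person: `person_id`, `ghge_total_kg`,
#'   `energy_kcal`, `ghge_density` (kg CO2-eq/1000 kcal), one density column
#'   per profile column (per 1000 kcal), and `low_energy`.
#' @export
aggregate_person <- function(linked_intake, food_nutrients = NULL,
                             food_patterns = NULL, energy_floor_kcal = 100) {
  check_columns(linked_intake, c("person_id", "food_code", "grams_consumed",
                                 "energy_kcal", "ghge_kg"), "linked intake")
  ids <- sort(unique(linked_intake$person_id))
  f <- factor(linked_intake$person_id, levels = ids)
  total <- data.frame(
    person_id = ids,
    ghge_total_kg = as.numeric(tapply(linked_intake$ghge_kg, f, sum)),
    energy_kcal = as.numeric(tapply(linked_intake$energy_kcal, f, sum)),
    stringsAsFactors = FALSE)

  dens_cols <- character()
  for (profiles in list(food_nutrients, food_patterns)) {
    if (is.null(profiles)) next
    am <- food_amounts(linked_intake, profiles)
    fa <- factor(am$person_id, levels = ids)
    for (col in setdiff(names(am), c("person_id", "food_code"))) {
      if (col == "energy_kcal") next  # energy comes from the intake records
      total[[col]] <- as.numeric(tapply(am[[col]], fa, sum))
      dens_cols <- c(dens_cols, col)
    }
  }

  zero <- total$energy_kcal <= 0
  if (any(zero)) {
    warning(sprintf("excluding %d person(s) with zero total energy: %s",
                    sum(zero),
                    paste(utils::head(total$person_id[zero], 5L),
                          collapse = ", ")), call. = FALSE)
  }
  excluded <- total$person_id[zero]
  total <- total[!zero, , drop = FALSE]
  total$ghge_density <- 1000 * total$ghge_total_kg / total$energy_kcal
  for (col in dens_cols) {
    total[[col]] <- 1000 * total[[col]] / total$energy_kcal
  }
  total$low_energy <- total$energy_kcal < energy_floor_kcal
  rownames(total) <- NULL
  attr(total, "excluded") <- excluded
  total
}

#' Weighted quantiles of type "lowest value reaching the target share"
#'
#' @param x numeric values.
#' @param w positive weights.
#' @param probs probabilities in (0, 1).
#' @return the smallest `x` whose cumulative weight share is `>= p`.
#' @keywords internal
weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  vapply(probs, function(p) x[o][which(cw >= p - 1e-12)[1L]], numeric(1))
}

#' Rank diets into survey-weighted footprint quintiles
#'
#' Diets are ranked on GHGE per 1000 kcal and cut at the weighted 20/40/60/
#' 80th percentiles. A diet whose density equals a cut point falls in the
#' lower quintile, deterministically. With equal weights and `n` divisible
#' by 5 this reduces to ordinary unweighted quintiles.
#'
#' @param summaries diet summaries from [aggregate_person()] (needs
#'   `ghge_density`).
#' @param weights survey weights (positive), recycled checkably against rows;
#'   `NULL` or `weighted = FALSE` uses equal weights.
#' @param weighted logical switch for unweighted ranking.
#' @return `summaries` with an integer `quintile` column in 1..5.
#' @export
assign_quintiles <- function(summaries, weights = NULL, weighted = TRUE) {
  check_columns(summaries, "ghge_density", "diet summaries")
  x <- summaries$ghge_density
  if (any(!is.finite(x))) stop("ghge_density must be finite", call. = FALSE)
  if (length(unique(x)) < 5L) {
    stop("degenerate footprint distribution: fewer than 5 distinct densities",
         call. = FALSE)
  }
  if (!weighted || is.null(weights)) {
    w <- rep(1, length(x))
  } else {
    if (length(weights) != length(x)) {
      stop("weights must match the number of summaries", call. = FALSE)
    }
    if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
    w <- weights
  }
  cuts <- weighted_quantile(x, w, c(0.2, 0.4, 0.6, 0.8))
  summaries$quintile <- 1L + rowSums(outer(x, cuts, `>`))
  summaries
}

#' Share of total dietary emissions carried by each footprint quintile
#'
#' The weighted sum of GHGE density within a quintile divided by the
#' weighted sum over everyone; the five shares sum to one.
#'
#' @param summaries diet summaries with a `quintile` column.
#' @param weights survey weights (default equal).
#' @param q quintile(s) to report; default all five.
#' @return named numeric vector of shares.
#' @export
quintile_ghge_share <- function(summaries, weights = NULL, q = 1:5) {
  check_columns(summaries, c("ghge_density", "quintile"), "diet summaries")
  w <- weights %||% rep(1, nrow(summaries))
  tot <- sum(w * summaries$ghge_density)
  shares <- vapply(q, function(k) {
    in_q <- summaries$quintile == k
    sum(w[in_q] * summaries$ghge_density[in_q]) / tot
  }, numeric(1))
  names(shares) <- paste0("Q", q)
  shares
}
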