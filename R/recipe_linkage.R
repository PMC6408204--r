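#' Decompose one reported food into commodity gram quantities
#'
#' A recipe lists the grams of each raw commodity needed to make 100 g of a
#' food as eaten (entries need not sum to 100 g because cooking gains or
#' loses water). Consuming `grams_consumed` of the food therefore implies
#' `grams_consumed * grams_per_100g / 100` grams of each commodity.
#'
#' @param food a one-row data.frame (or list) with `food_code` and
#'   `grams_consumed`.
#' @param recipes data.frame with `food_code`, `commodity_code`,
#'   `grams_per_100g`.
#' @return data.frame `commodity_code`, `grams`, sorted by commodity code.
#' @export
decompose_food <- function(food, recipes) {
  check_columns(recipes, c("food_code", "commodity_code", "grams_per_100g"),
                "recipes")
  rec <- recipes[recipes$food_code == food$food_code, , drop = FALSE]
  if (nrow(rec) == 0L) {
    stop(sprintf("unlinked food: no recipe for food_code '%s'",
                 food$food_code), call. = FALSE)
  }
  check_nonneg(rec$grams_per_100g, "recipes grams_per_100g")
  out <- data.frame(commodity_code = rec$commodity_code,
                    grams = food$grams_consumed * rec$grams_per_100g / 100,
                    stringsAsFactors = FALSE)
  out[order(out$commodity_code), , drop = FALSE]
}

#' Back-calculate the production-side mass behind a consumed mass
#'
#' Retail- and consumer-level losses mean that delivering `grams` of food to
#' the plate requires more mass upstream. With loss fractions `retail` and
#' `consumer`, the production mass is `grams / ((1 - retail) * (1 - consumer))`.
#' Vectorized over all arguments.
#'
#' @param grams consumed mass in grams (nonnegative).
#' @param retail_loss,consumer_loss loss fractions in `[0, 1)`.
#' @return production-side grams.
#' @examples
#' loss_adjusted_mass(72, 0.10, 0.20) # 100
#' @export
loss_adjusted_mass <- function(grams, retail_loss, consumer_loss) {
  check_nonneg(grams, "grams")
  if (any(retail_loss < 0) || any(retail_loss >= 1) ||
      any(consumer_loss < 0) || any(consumer_loss >= 1)) {
    stop("loss fractions must lie in [0, 1)", call. = FALSE)
  }
  grams / ((1 - retail_loss) * (1 - consumer_loss))
}

## loss lookup with zero-loss default; warns once per call for missing codes
lookup_losses <- function(codes, losses, loss_adjust = TRUE) {
  if (!loss_adjust || is.null(losses) || nrow(losses) == 0L) {
    return(data.frame(retail_loss = rep(0, length(codes)),
                      consumer_loss = rep(0, length(codes))))
  }
  check_columns(losses, c("code", "retail_loss", "consumer_loss"), "losses")
  i <- match(codes, losses$code)
  misses <- unique(codes[is.na(i)])
  if (length(misses) > 0L) {
    warning(sprintf("no loss factors for %d code(s) (e.g. %s); assuming zero loss",
                    length(misses),
                    paste(utils::head(misses, 3L), collapse = ", ")),
            call. = FALSE)
  }
  data.frame(retail_loss = ifelse(is.na(i), 0, losses$retail_loss[i]),
             consumer_loss = ifelse(is.na(i), 0, losses$consumer_loss[i]))
}

#' Greenhouse-gas emissions of one reported food
#'
#' Sums, over the food's recipe ingredients, the loss-adjusted commodity mass
#' (kg) times the commodity's emission factor (kg CO2-eq/kg). Foods carrying
#' a direct link (processed foods studied as such, e.g. cheese or sodas) use
#' their own factor applied to the food's own mass instead of a recipe.
#'
#' @inheritParams decompose_food
#' @param direct_links data.frame `food_code`, `ghge_per_kg`, or `NULL`.
#' @param impacts commodity impact table ([average_impacts()]).
#' @param losses data.frame `code`, `retail_loss`, `consumer_loss`; `code` is
#'   a commodity code (recipe foods) or a food code (direct links). Missing
#'   codes default to zero loss with a warning.
#' @param loss_adjust logical; `FALSE` disables loss adjustment.
#' @return GHGE in kg CO2-eq for the consumed amount.
#' @export
food_ghge <- function(food, recipes, direct_links = NULL, impacts,
                      losses = NULL, loss_adjust = TRUE) {
  intake <- data.frame(person_id = "p", food_code = food$food_code,
                       grams_consumed = food$grams_consumed,
                       energy_kcal = food$energy_kcal %||% 0,
                       stringsAsFactors = FALSE)
  res <- link_ghge(intake, recipes, direct_links, impacts, losses,
                   loss_adjust = loss_adjust)
  res$intake$ghge_kg[1L]
}

#' Link a whole intake table to commodity emission factors
#'
#' The workhorse of the footprint pipeline: every reported food is either
#' decomposed through its recipe into commodity masses, each loss-adjusted
#' and multiplied by its commodity emission factor, or (for direct-linked
#' foods) priced with the food's own factor. Foods with neither a recipe nor
#' a direct link are collected and reported in a single run-level error, so
#' no food is ever silently dropped unless explicitly requested.
#'
#' @param intake data.frame `person_id`, `food_code`, `grams_consumed`,
#'   `energy_kcal` (one row per reported food for one person-day).
#' @inheritParams food_ghge
#' @param on_unlinked `"error"` aborts listing every unlinked food code;
#'   `"skip"` excludes those records and reports them in the result.
#' @return list with components:
#'   * `intake`: the input with a `ghge_kg` column appended;
#'   * `contributions`: record-by-commodity detail (`person_id`, `food_code`,
#'     `commodity_code`, `grams`, `adjusted_grams`, `ghge_kg`);
#'   * `unlinked`: character vector of food codes without any linkage.
#' @export
link_ghge <- function(intake, recipes, direct_links = NULL, impacts,
                      losses = NULL, loss_adjust = TRUE,
                      on_unlinked = c("error", "skip")) {
  on_unlinked <- match.arg(on_unlinked)
  check_columns(intake, c("person_id", "food_code", "grams_consumed"),
                "intake")
  check_columns(recipes, c("food_code", "commodity_code", "grams_per_100g"),
                "recipes")
  check_columns(impacts, c("commodity_code", "ghge_per_kg"), "impacts")
  check_nonneg(intake$grams_consumed, "intake grams_consumed")
  check_nonneg(recipes$grams_per_100g, "recipes grams_per_100g")
  key <- paste(recipes$food_code, recipes$commodity_code, sep = "\r")
  if (anyDuplicated(key)) {
    stop("recipes: duplicate (food_code, commodity_code) entry", call. = FALSE)
  }
  has_direct <- !is.null(direct_links) && nrow(direct_links) > 0L
  if (has_direct) {
    check_columns(direct_links, c("food_code", "ghge_per_kg"), "direct_links")
    both <- intersect(direct_links$food_code, unique(recipes$food_code))
    if (length(both) > 0L) {
      stop(sprintf("food(s) have both a recipe and a direct link: %s",
                   paste(utils::head(both, 5L), collapse = ", ")),
           call. = FALSE)
    }
  }

  intake$.record <- seq_len(nrow(intake))
  linked_recipe <- intake$food_code %in% recipes$food_code
  linked_direct <- if (has_direct) intake$food_code %in% direct_links$food_code
                   else rep(FALSE, nrow(intake))
  unlinked <- sort(unique(intake$food_code[!linked_recipe & !linked_direct]))
  if (length(unlinked) > 0L && on_unlinked == "error") {
    stop(sprintf("unlinked food code(s) with neither recipe nor direct link: %s",
                 paste(unlinked, collapse = ", ")), call. = FALSE)
  }

  ## recipe route: expand record x ingredient
  ri <- intake[linked_recipe, , drop = FALSE]
  contrib <- merge(ri, recipes, by = "food_code", sort = FALSE)
  contrib$grams <- contrib$grams_consumed * contrib$grams_per_100g / 100
  lf <- lookup_losses(contrib$commodity_code, losses, loss_adjust)
  contrib$adjusted_grams <- loss_adjusted_mass(contrib$grams, lf$retail_loss,
                                               lf$consumer_loss)
  fi <- match(contrib$commodity_code, impacts$commodity_code)
  if (anyNA(fi)) {
    miss <- sort(unique(contrib$commodity_code[is.na(fi)]))
    stop(sprintf("unresolved commodity code(s) in impact table: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  contrib$ghge_kg <- contrib$adjusted_grams / 1000 * impacts$ghge_per_kg[fi]

  ## direct route: the food is its own "commodity"
  if (any(linked_direct)) {
    di <- intake[linked_direct, , drop = FALSE]
    dj <- match(di$food_code, direct_links$food_code)
    lfd <- lookup_losses(di$food_code, losses, loss_adjust)
    adj <- loss_adjusted_mass(di$grams_consumed, lfd$retail_loss,
                              lfd$consumer_loss)
    dcontrib <- data.frame(.record = di$.record,
                           person_id = di$person_id,
                           food_code = di$food_code,
                           commodity_code = di$food_code,
                           grams = di$grams_consumed,
                           adjusted_grams = adj,
                           ghge_kg = adj / 1000 * direct_links$ghge_per_kg[dj],
                           stringsAsFactors = FALSE)
  } else {
    dcontrib <- NULL
  }
  keep <- c(".record", "person_id", "food_code", "commodity_code", "grams",
            "adjusted_grams", "ghge_kg")
  contributions <- rbind(contrib[, keep, drop = FALSE], dcontrib)
  contributions <- contributions[order(contributions$.record,
                                       contributions$commodity_code), ,
                                 drop = FALSE]

  per_record <- rowsum(contributions$ghge_kg, contributions$.record)
  out <- intake
  out$ghge_kg <- 0
  out$ghge_kg[as.integer(rownames(per_record))] <- per_record[, 1L]
  if (length(unlinked) > 0L) {
    out <- out[linked_recipe | linked_direct, , drop = FALSE]
  }
  out$.record <- NULL
  rownames(out) <- NULL
  rownames(contributions) <- NULL
  list(intake = out,
       contributions = contributions,
       unlinked = unlinked)
}
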