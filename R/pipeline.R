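#' Run the full diet carbon-footprint pipeline on a directory of CSV inputs
#'
#' End-to-end orchestration of the linkage schematic: build the commodity
#' impact table (study averaging plus substitutions), decompose every
#' reported food through recipes or direct links with loss adjustment,
#' aggregate to per-person footprints and per-1000 kcal densities, rank into
#' weighted footprint quintiles, score the HEI-2010, and run the comparison
#' battery (demographic chi-squares, low-vs-high t tests on nutrient,
#' food-group and HEI outcomes, quintile trend tests, and nested behavior
#' regressions). Every intermediate table is written to `output_dir` so
#' stages can be inspected or rerun, together with a JSON run manifest
#' carrying row counts, exclusions, and a three-way GHGE conservation
#' ledger (person totals vs food totals vs commodity contributions).
#'
#' @param input_dir directory containing `studies.csv`, `substitutions.csv`,
#'   `groups.csv`, `losses.csv`, `recipes.csv`, `direct_links.csv`,
#'   `food_nutrients.csv`, `food_patterns.csv`, `intake.csv`,
#'   `demographics.csv`, `behaviors.csv`, `design.csv` (the layout written
#'   by [generate_fixtures()]).
#' @param output_dir directory for result tables and the manifest.
#' @param weighted_quintiles use survey-weighted quintile cut points
#'   (`FALSE` ranks unweighted).
#' @param loss_adjust apply retail/consumer loss adjustment.
#' @param skip_unlinked exclude (and count) foods without recipe or direct
#'   link instead of aborting.
#' @param standards_path optional path to an HEI-2010 standards YAML.
#' @param lonely single-PSU stratum handling for variance estimation.
#'   Subgroup comparisons (e.g. bottom vs top quintile) routinely leave a
#'   stratum with only one represented PSU, so the pipeline defaults to the
#'   standard fix of centering such strata at the grand PSU mean; pass
#'   `"error"` to abort instead.
#' @return invisibly, a list with every result table and the manifest.
#' @export
run_pipeline <- function(input_dir, output_dir,
                         weighted_quintiles = TRUE,
                         loss_adjust = TRUE,
                         skip_unlinked = FALSE,
                         standards_path = NULL,
                         lonely = c("centre", "error")) {
  lonely <- match.arg(lonely)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  inp <- function(nm, required = character()) {
    read_table_csv(file.path(input_dir, paste0(nm, ".csv")), required)
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  studies <- inp("studies", c("study_id", "commodity_code",
                              "ghge_kgco2e_per_kg"))
  substitutions <- inp("substitutions")
  groups <- inp("groups")
  losses <- inp("losses", c("code", "retail_loss", "consumer_loss"))
  recipes <- inp("recipes", c("food_code", "commodity_code",
                              "grams_per_100g"))
  direct_links <- inp("direct_links", c("food_code", "ghge_per_kg"))
  food_nutrients <- inp("food_nutrients", "food_code")
  food_patterns <- inp("food_patterns", "food_code")
  intake <- inp("intake", c("person_id", "food_code", "grams_consumed",
                            "energy_kcal"))
  demographics <- inp("demographics", "person_id")
  behaviors <- inp("behaviors", "person_id")
  design <- inp("design", c("person_id", "weight", "stratum", "psu"))

  impacts <- stage("impact_table", {
    apply_substitutions(average_impacts(studies), substitutions, groups)
  })
  write_impact_table(impacts, file.path(output_dir, "impact_table.csv"))

  linked <- stage("recipe_linkage", {
    link_ghge(intake, recipes, direct_links, impacts, losses,
              loss_adjust = loss_adjust,
              on_unlinked = if (skip_unlinked) "skip" else "error")
  })

  summaries <- stage("diet_metrics", {
    aggregate_person(linked$intake, food_nutrients, food_patterns)
  })
  excluded <- attr(summaries, "excluded")

  design <- design[match(summaries$person_id, design$person_id), ,
                   drop = FALSE]
  if (anyNA(design$weight)) {
    stop("pipeline stage 'diet_metrics' failed: persons missing from design",
         call. = FALSE)
  }
  summaries <- stage("quintiles", {
    assign_quintiles(summaries,
                     weights = if (weighted_quintiles) design$weight,
                     weighted = weighted_quintiles)
  })
  write_table_csv(summaries, file.path(output_dir, "diet_summaries.csv"))

  shares <- quintile_ghge_share(summaries,
                                weights = if (weighted_quintiles)
                                  design$weight)
  write_table_csv(data.frame(quintile = 1:5, ghge_share = as.numeric(shares)),
                  file.path(output_dir, "quintile_shares.csv"))

  standards <- hei_standards(standards_path)
  hei <- stage("hei2010", score_hei(summaries, standards))
  write_table_csv(hei, file.path(output_dir, "hei_scores.csv"))

  ## comparison battery: bottom vs top footprint quintile
  low_high <- summaries$quintile %in% c(1L, 5L)
  grp <- factor(ifelse(summaries$quintile == 1L, "low", "high"),
                levels = c("low", "high"))[low_high]
  des_lh <- design[low_high, , drop = FALSE]

  demo <- demographics[match(summaries$person_id, demographics$person_id), ,
                       drop = FALSE]
  chisq_rows <- lapply(setdiff(names(demo), "person_id"), function(v) {
    r <- stage("demographics_chisq",
               design_chisq(grp, demo[[v]][low_high], des_lh, lonely))
    data.frame(variable = v, statistic = r$statistic,
               design_effect = r$design_effect, df = r$df,
               p_value = r$p_value, stringsAsFactors = FALSE)
  })
  demo_tab <- do.call(rbind, chisq_rows)
  write_table_csv(demo_tab, file.path(output_dir, "demographics_chisq.csv"))

  ttest_battery <- function(cols, dat) {
    rows <- lapply(cols, function(v) {
      r <- group_ttest(dat[[v]][low_high], grp, des_lh, lonely)
      cbind(data.frame(outcome = v, stringsAsFactors = FALSE), r)
    })
    do.call(rbind, rows)
  }
  nutrient_cols <- intersect(setdiff(names(food_nutrients),
                                     c("food_code", "energy_kcal")),
                             names(summaries))
  pattern_cols <- intersect(setdiff(names(food_patterns), "food_code"),
                            names(summaries))
  nut_tab <- stage("nutrient_comparisons",
                   ttest_battery(nutrient_cols, summaries))
  pat_tab <- stage("pattern_comparisons",
                   ttest_battery(pattern_cols, summaries))
  hei_tab <- stage("hei_comparisons",
                   ttest_battery(grep("^hei_", names(hei), value = TRUE),
                                 hei))
  write_table_csv(nut_tab, file.path(output_dir,
                                     "comparisons_nutrients.csv"))
  write_table_csv(pat_tab, file.path(output_dir, "comparisons_patterns.csv"))
  write_table_csv(hei_tab, file.path(output_dir, "comparisons_hei.csv"))

  trend_rows <- lapply(nutrient_cols, function(v) {
    r <- stage("quintile_trends",
               quintile_trend_test(summaries[[v]], summaries$quintile,
                                   design, lonely))
    data.frame(outcome = v, linear_p = r$linear_p,
               quadratic_p = r$quadratic_p, stringsAsFactors = FALSE)
  })
  trend_tab <- do.call(rbind, trend_rows)
  write_table_csv(trend_tab, file.path(output_dir, "quintile_trends.csv"))

  beh <- behaviors[match(summaries$person_id, behaviors$person_id), ,
                   drop = FALSE]
  reg_data <- cbind(summaries[, c("person_id", "ghge_density")],
                    demo[, setdiff(names(demo), "person_id"), drop = FALSE],
                    beh[, setdiff(names(beh), "person_id"), drop = FALSE])
  reg_rows <- lapply(setdiff(names(beh), "person_id"), function(b) {
    r <- stage("behavior_regressions",
               behavior_regression(reg_data, design, b, lonely = lonely))
    cbind(data.frame(behavior = b, stringsAsFactors = FALSE), r$table)
  })
  reg_tab <- do.call(rbind, reg_rows)
  write_table_csv(reg_tab, file.path(output_dir, "regression_table.csv"))

  ## three-way conservation ledger
  ledger <- list(
    person_total_kg = sum(summaries$ghge_total_kg),
    food_total_kg = sum(linked$intake$ghge_kg[
      linked$intake$person_id %in% summaries$person_id]),
    commodity_total_kg = sum(linked$contributions$ghge_kg[
      linked$contributions$person_id %in% summaries$person_id]))

  manifest <- list(
    package = "dietfootprint",
    version = as.character(utils::packageVersion("dietfootprint")),
    options = list(weighted_quintiles = weighted_quintiles,
                   loss_adjust = loss_adjust,
                   skip_unlinked = skip_unlinked),
    rows = list(intake = nrow(intake), persons_in = length(unique(intake$person_id)),
                persons_summarized = nrow(summaries),
                contributions = nrow(linked$contributions)),
    excluded_zero_energy = as.list(excluded),
    unlinked_food_codes = as.list(linked$unlinked),
    conservation = ledger)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(impacts = impacts, linked = linked, summaries = summaries,
                 shares = shares, hei = hei, demographics_chisq = demo_tab,
                 comparisons_nutrients = nut_tab,
                 comparisons_patterns = pat_tab, comparisons_hei = hei_tab,
                 quintile_trends = trend_tab, regressions = reg_tab,
                 manifest = manifest))
}
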