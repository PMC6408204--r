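#' Average per-study emission factors into one factor per commodity
#'
#' Life-cycle assessment (LCA) studies report greenhouse-gas emissions (GHGE)
#' for a food commodity in kg CO2-equivalents per kg of commodity. When a
#' commodity has been studied more than once, the commodity's emission factor
#' is the unweighted arithmetic mean of the study values; each input record
#' counts as one vote.
#'
#' @param studies data.frame with columns `study_id`, `commodity_code`,
#'   `ghge_kgco2e_per_kg`. `(study_id, commodity_code)` pairs must be unique
#'   and factors nonnegative; violations are errors, never silently fixed.
#' @return data.frame with one row per commodity: `commodity_code`,
#'   `ghge_per_kg`, `n_studies`, `provenance` (`"measured"`), `source` (`NA`).
#' @examples
#' studies <- data.frame(study_id = c("s1", "s2", "s3"),
#'                       commodity_code = "beef",
#'                       ghge_kgco2e_per_kg = c(20, 30, 40))
#' average_impacts(studies)
#' @export
average_impacts <- function(studies) {
  check_columns(studies, c("study_id", "commodity_code", "ghge_kgco2e_per_kg"),
                "studies")
  if (nrow(studies) == 0L) stop("studies: at least one record is required",
                                call. = FALSE)
  bad <- which(is.na(studies$ghge_kgco2e_per_kg) | studies$ghge_kgco2e_per_kg < 0)
  if (length(bad) > 0L) {
    stop(sprintf("studies: negative or missing GHGE in record(s): %s",
                 paste(sprintf("(%s, %s)", studies$study_id[bad],
                               studies$commodity_code[bad]), collapse = ", ")),
         call. = FALSE)
  }
  key <- paste(studies$study_id, studies$commodity_code, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop(sprintf("studies: duplicate (study_id, commodity_code) record: (%s)",
                 gsub("\r", ", ", dup)), call. = FALSE)
  }
  means <- tapply(studies$ghge_kgco2e_per_kg, studies$commodity_code, mean)
  counts <- tapply(studies$ghge_kgco2e_per_kg, studies$commodity_code, length)
  out <- data.frame(commodity_code = names(means),
                    ghge_per_kg = as.numeric(means),
                    n_studies = as.integer(counts),
                    provenance = "measured",
                    source = NA_character_,
                    stringsAsFactors = FALSE)
  out[order(out$commodity_code), , drop = FALSE]
}

#' Fill unmeasured commodities by group or similar-food substitution
#'
#' Commodities without any LCA study receive a proxy factor: either the mean
#' of a group of measured foods (e.g. stone fruits standing in for
#' nectarines) or a copy of a single measured food of similar form (e.g.
#' banana standing in for plantain). Substitution is one-step only: proxies
#' are resolved against measured factors, never against other proxies.
#'
#' @param impacts measured impact table from [average_impacts()].
#' @param rules data.frame with columns `target_commodity_code`,
#'   `kind` (`"group_proxy"` or `"similar_proxy"`), `source` (group label or
#'   commodity code). May have zero rows.
#' @param groups data.frame mapping `commodity_code` to `group`; required
#'   only when group-proxy rules are present.
#' @return impact table with proxy rows appended; `provenance` records the
#'   rule kind and `source` the group label or source commodity;
#'   `n_studies` for proxies is 0.
#' @export
apply_substitutions <- function(impacts, rules, groups = NULL) {
  check_columns(impacts, c("commodity_code", "ghge_per_kg", "provenance"),
                "impacts")
  if (is.null(rules) || nrow(rules) == 0L) return(impacts)
  check_columns(rules, c("target_commodity_code", "kind", "source"), "rules")
  if (!all(rules$kind %in% c("group_proxy", "similar_proxy"))) {
    stop("rules: kind must be 'group_proxy' or 'similar_proxy'", call. = FALSE)
  }
  measured <- impacts[impacts$provenance == "measured", , drop = FALSE]
  clash <- intersect(rules$target_commodity_code, measured$commodity_code)
  if (length(clash) > 0L) {
    stop(sprintf("rules: target(s) already have measured impacts: %s",
                 paste(clash, collapse = ", ")), call. = FALSE)
  }
  ## idempotence: drop targets already resolved by an identical earlier pass
  rules <- rules[!(rules$target_commodity_code %in% impacts$commodity_code), ,
                 drop = FALSE]
  if (nrow(rules) == 0L) return(impacts)

  value <- numeric(nrow(rules))
  unresolved <- character()
  for (i in seq_len(nrow(rules))) {
    if (rules$kind[i] == "similar_proxy") {
      j <- match(rules$source[i], measured$commodity_code)
      if (is.na(j)) {
        unresolved <- c(unresolved, rules$target_commodity_code[i])
      } else {
        value[i] <- measured$ghge_per_kg[j]
      }
    } else {
      if (is.null(groups)) {
        stop("group_proxy rules present but no groups table supplied",
             call. = FALSE)
      }
      check_columns(groups, c("commodity_code", "group"), "groups")
      members <- groups$commodity_code[groups$group == rules$source[i]]
      vals <- measured$ghge_per_kg[measured$commodity_code %in% members]
      if (length(vals) == 0L) {
        unresolved <- c(unresolved, rules$target_commodity_code[i])
      } else {
        value[i] <- mean(vals)
      }
    }
  }
  if (length(unresolved) > 0L) {
    stop(sprintf("unresolved substitution(s): no measured source for %s",
                 paste(unique(unresolved), collapse = ", ")), call. = FALSE)
  }
  proxies <- data.frame(commodity_code = rules$target_commodity_code,
                        ghge_per_kg = value,
                        n_studies = 0L,
                        provenance = rules$kind,
                        source = rules$source,
                        stringsAsFactors = FALSE)
  out <- rbind(impacts, proxies)
  out[order(out$commodity_code), , drop = FALSE]
}

#' Write / read a commodity impact table
#'
#' Round-trips the impact table through CSV, preserving every field for
#' decimal-representable values.
#'
#' @param impacts impact table as returned by [average_impacts()] /
#'   [apply_substitutions()].
#' @param path file path of the CSV.
#' @return `read_impact_table()` returns the impact table; `write_impact_table()`
#'   returns `path` invisibly.
#' @export
write_impact_table <- function(impacts, path) {
  check_columns(impacts,
                c("commodity_code", "ghge_per_kg", "n_studies", "provenance"),
                "impacts")
  write_table_csv(impacts, path)
}

#' @rdname write_impact_table
#' @export
read_impact_table <- function(path) {
  df <- read_table_csv(path,
                       c("commodity_code", "ghge_per_kg", "n_studies",
                         "provenance"),
                       what = "impact table")
  df$n_studies <- as.integer(df$n_studies)
  if (!"source" %in% names(df)) df$source <- NA_character_
  check_nonneg(df$ghge_per_kg, "impact table ghge_per_kg")
  df
}
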