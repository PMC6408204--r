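## Design-based estimation for stratified, clustered, weighted samples.
## Variance estimation is Taylor linearization with PSUs drawn with
## replacement within strata (the standard national-survey default);
## replicate weights are out of scope.

validate_design <- function(design, n = NULL) {
  check_columns(design, c("weight", "stratum", "psu"), "survey design")
  if (any(design$weight <= 0) || anyNA(design$weight)) {
    stop("survey design: weights must be positive", call. = FALSE)
  }
  if (!is.null(n) && nrow(design) != n) {
    stop("survey design rows must align one-to-one with the values",
         call. = FALSE)
  }
  invisible(design)
}

## between-PSU variance of a total from per-observation score vectors.
## scores: n x k matrix already on the total scale (weights folded in).
taylor_var <- function(scores, stratum, psu, lonely = c("error", "centre")) {
  lonely <- match.arg(lonely)
  scores <- as.matrix(scores)
  k <- ncol(scores)
  cl <- paste(stratum, psu, sep = "\r")
  psu_tot <- rowsum(scores, cl, reorder = TRUE)
  psu_str <- sub("\r.*$", "", rownames(psu_tot))
  V <- matrix(0, k, k)
  grand <- colMeans(psu_tot)
  for (h in unique(psu_str)) {
    Zh <- psu_tot[psu_str == h, , drop = FALSE]
    nh <- nrow(Zh)
    if (nh < 2L) {
      if (lonely == "error") {
        stop(sprintf("stratum '%s' has a single PSU; cannot estimate variance (set lonely = 'centre' to centre at the grand mean)",
                     h), call. = FALSE)
      }
      d <- Zh[1L, ] - grand
      V <- V + tcrossprod(d)
      next
    }
    ctr <- sweep(Zh, 2L, colMeans(Zh))
    V <- V + nh / (nh - 1) * crossprod(ctr)
  }
  V
}

design_df <- function(design) {
  length(unique(paste(design$stratum, design$psu, sep = "\r"))) -
    length(unique(design$stratum))
}

#' Design-based (Taylor-linearized) weighted mean and standard error
#'
#' Estimates the population mean as the weighted ratio
#' `sum(w * x) / sum(w)` and its standard error by Taylor linearization over
#' strata and primary sampling units (PSUs), treating PSUs as sampled with
#' replacement within strata. With equal weights, a single stratum, and one
#' PSU per observation this reduces exactly to `sd(x)/sqrt(n)`.
#'
#' @param x numeric values, aligned row-by-row with `design`.
#' @param design data.frame with `weight` (positive), `stratum`, `psu`.
#' @param lonely handling of single-PSU strata: `"error"` (default) or
#'   `"centre"` (centre the stratum at the grand PSU mean).
#' @return list with `mean`, `se`, `df` (PSUs minus strata), `n`.
#' @export
weighted_mean_se <- function(x, design, lonely = c("error", "centre")) {
  lonely <- match.arg(lonely)
  if (any(!is.finite(x))) stop("values must be finite", call. = FALSE)
  validate_design(design, length(x))
  w <- design$weight
  m <- sum(w * x) / sum(w)
  z <- w * (x - m) / sum(w)
  v <- taylor_var(z, design$stratum, design$psu, lonely)[1L, 1L]
  list(mean = m, se = sqrt(v), df = design_df(design), n = length(x))
}

#' Design-based t test between two diet groups
#'
#' Compares two subpopulations (e.g. the lowest and highest footprint
#' quintiles) on a continuous outcome: the difference of their
#' design-weighted means, a combined linearized standard error, and a
#' two-sided p-value referred to a t distribution with (PSUs - strata)
#' degrees of freedom. Each group's variance is computed over the PSUs in
#' which the group is present, so with equal weights and one PSU per person
#' the statistic collapses to the classical unequal-variance t.
#'
#' @param x outcome values aligned with `design` rows.
#' @param group a vector with exactly two levels; the difference is
#'   first level minus second level.
#' @param design survey design data.frame (see [weighted_mean_se()]).
#' @param lonely single-PSU stratum handling.
#' @return data.frame with group means and SEs, `difference`, `se`,
#'   `statistic`, `df`, `p_value`.
#' @export
group_ttest <- function(x, group, design, lonely = c("error", "centre")) {
  lonely <- match.arg(lonely)
  validate_design(design, length(x))
  group <- as.factor(group)
  lv <- levels(droplevels(group))
  if (length(lv) != 2L) stop("group must have exactly two levels",
                             call. = FALSE)
  est <- lapply(lv, function(g) {
    keep <- which(group == g)
    weighted_mean_se(x[keep], design[keep, , drop = FALSE], lonely)
  })
  diff <- est[[1L]]$mean - est[[2L]]$mean
  se <- sqrt(est[[1L]]$se^2 + est[[2L]]$se^2)
  df <- design_df(design)
  stat <- if (se > 0) diff / se else 0
  p <- if (se > 0) 2 * stats::pt(-abs(stat), df) else 1
  data.frame(group1 = lv[1L], mean1 = est[[1L]]$mean, se1 = est[[1L]]$se,
             group2 = lv[2L], mean2 = est[[2L]]$mean, se2 = est[[2L]]$se,
             difference = diff, se = se, statistic = stat, df = df,
             p_value = p, stringsAsFactors = FALSE)
}

#' Rao-Scott design-adjusted chi-square test of homogeneity
#'
#' Pearson's chi-square computed on the design-weighted group-by-category
#' proportions, divided by a first-order Rao-Scott correction (a
#' generalized design effect built from the linearized design variances of
#' the cell and marginal proportions) and referred to a chi-square with
#' `(R-1)(C-1)` degrees of freedom. With equal weights and one PSU per
#' observation the correction is ~1 and the statistic reduces toward the
#' classical Pearson chi-square.
#'
#' @param group,category categorical vectors aligned with `design` rows.
#' @param design survey design data.frame.
#' @param lonely single-PSU stratum handling.
#' @return list with `statistic` (adjusted), `raw_statistic`,
#'   `design_effect`, `df`, `p_value`, and the weighted proportion table.
#' @export
design_chisq <- function(group, category, design,
                         lonely = c("error", "centre")) {
  lonely <- match.arg(lonely)
  validate_design(design, length(group))
  g <- as.factor(group); cat <- as.factor(category)
  n <- length(g)
  w <- design$weight
  W <- sum(w)
  tab <- tapply(w, list(g, cat), sum, default = 0) / W
  pr <- rowSums(tab); pc <- colSums(tab)
  expected <- outer(pr, pc)
  X2 <- n * sum((tab - expected)^2 / expected)

  deff_of <- function(ind, p) {
    if (p <= 0 || p >= 1) return(NA_real_)
    v <- weighted_mean_se(as.numeric(ind), design, lonely)$se^2
    v / (p * (1 - p) / n)
  }
  dsum <- function(probs, indfun) {
    tot <- 0
    for (i in seq_along(probs)) {
      d <- deff_of(indfun(i), probs[i])
      if (!is.na(d)) tot <- tot + d * (1 - probs[i])
    }
    tot
  }
  cells <- expand.grid(r = levels(g), c = levels(cat),
                       stringsAsFactors = FALSE)
  pcell <- mapply(function(r, c) tab[r, c], cells$r, cells$c)
  cell_term <- dsum(pcell, function(i) g == cells$r[i] & cat == cells$c[i])
  row_term <- dsum(pr, function(i) g == levels(g)[i])
  col_term <- dsum(pc, function(i) cat == levels(cat)[i])
  df <- (nlevels(g) - 1L) * (nlevels(cat) - 1L)
  delta <- unname((cell_term - row_term - col_term) / df)
  if (!is.finite(delta) || delta <= 0) delta <- 1
  stat <- X2 / delta
  list(statistic = stat, raw_statistic = X2, design_effect = delta,
       df = df, p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       proportions = tab)
}

#' Weighted least squares with design-based (sandwich) standard errors
#'
#' Fits the regression by survey-weighted least squares and estimates the
#' coefficient covariance with the linearization sandwich: the bread is
#' `(X'WX)^-1` and the meat is the between-PSU variance of the weighted
#' score totals. P-values use a t distribution with (PSUs - strata)
#' degrees of freedom.
#'
#' @param formula model formula.
#' @param data data.frame holding the model variables, aligned with
#'   `design` rows.
#' @param design survey design data.frame.
#' @param lonely single-PSU stratum handling.
#' @return list with `coefficients` (term, estimate, se, statistic,
#'   p_value), `vcov`, `df`, and the underlying `lm` fit.
#' @export
svy_lm <- function(formula, data, design, lonely = c("error", "centre")) {
  lonely <- match.arg(lonely)
  validate_design(design, nrow(data))
  data$.w <- design$weight
  fit <- stats::lm(formula, data = data, weights = .w)
  X <- stats::model.matrix(fit)
  if (nrow(X) != nrow(data)) {
    stop("missing values in model variables are not supported", call. = FALSE)
  }
  e <- stats::residuals(fit)
  w <- design$weight
  bread <- solve(crossprod(X * sqrt(w)))
  scores <- X * (w * e)
  meat <- taylor_var(scores, design$stratum, design$psu, lonely)
  V <- bread %*% meat %*% bread
  est <- stats::coef(fit)
  se <- sqrt(diag(V))
  df <- design_df(design)
  stat <- est / se
  coef_tab <- data.frame(term = names(est), estimate = unname(est),
                         se = unname(se), statistic = unname(stat),
                         p_value = unname(2 * stats::pt(-abs(stat), df)),
                         stringsAsFactors = FALSE)
  list(coefficients = coef_tab, vcov = V, df = df, fit = fit)
}

#' Effect of a behavior on dietary GHGE density, with nested adjustment
#'
#' Three nested survey-weighted regressions of footprint density on a
#' dichotomous behavior flag: unadjusted; adjusted for demographics; and
#' adjusted for demographics plus socioeconomic status. The behavior
#' coefficient is the mean difference in GHGE density (kg CO2-eq/1000 kcal)
#' between those with and without the behavior. With no covariates the
#' coefficient equals the weighted group-mean difference exactly.
#'
#' @param data data.frame with the outcome, behavior, and covariates,
#'   aligned with `design` rows.
#' @param design survey design data.frame.
#' @param behavior name of the dichotomous behavior column (0/1 or logical).
#' @param outcome name of the outcome column (default `"ghge_density"`).
#' @param demographics,socioeconomic character vectors of covariate column
#'   names for the two adjustment stages.
#' @param lonely single-PSU stratum handling.
#' @return list with `table` (one row per model: the behavior coefficient,
#'   SE, p) and `models` (the three [svy_lm()] fits).
#' @export
behavior_regression <- function(data, design, behavior,
                                outcome = "ghge_density",
                                demographics = c("age_group", "gender",
                                                 "race_ethnicity"),
                                socioeconomic = c("income_group", "education"),
                                lonely = c("error", "centre")) {
  lonely <- match.arg(lonely)
  check_columns(data, c(outcome, behavior), "behavior data")
  data[[behavior]] <- as.numeric(data[[behavior]])
  covs <- list(unadjusted = character(),
               demographic = demographics,
               full = c(demographics, socioeconomic))
  models <- lapply(covs, function(cv) {
    check_columns(data, cv, "behavior data")
    for (v in cv) if (!is.numeric(data[[v]])) data[[v]] <- as.factor(data[[v]])
    rhs <- paste(c(behavior, cv), collapse = " + ")
    svy_lm(stats::as.formula(paste(outcome, "~", rhs)), data, design, lonely)
  })
  rows <- lapply(names(models), function(nm) {
    ct <- models[[nm]]$coefficients
    r <- ct[ct$term == behavior, , drop = FALSE]
    r$model <- nm
    r
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab[, c("model", "term", "estimate", "se", "statistic",
                       "p_value")],
       models = models)
}

#' Quintile contrasts and linear/quadratic trend tests
#'
#' Two design-based regressions of an outcome on the footprint quintile:
#' (a) dummy-coded contrasts of quintiles 2-5 against quintile 1, and
#' (b) orthogonal-polynomial linear and quadratic terms on the quintile
#' index.
#'
#' @param x outcome values aligned with `design` rows.
#' @param quintile integer quintile labels in 1..5.
#' @param design survey design data.frame.
#' @param lonely single-PSU stratum handling.
#' @return list with `contrasts` (coefficient table vs quintile 1),
#'   `trend` (linear and quadratic rows), `linear_p`, `quadratic_p`.
#' @export
quintile_trend_test <- function(x, quintile, design,
                                lonely = c("error", "centre")) {
  lonely <- match.arg(lonely)
  if (!all(quintile %in% 1:5)) stop("quintile labels must be in 1..5",
                                    call. = FALSE)
  d <- data.frame(y = x, q = factor(quintile, levels = 1:5),
                  qi = as.numeric(quintile))
  contr <- svy_lm(y ~ q, d, design, lonely)
  if (stats::sd(x) == 0) {
    ## constant outcome: no trend, by convention p = 1
    trend_tab <- data.frame(term = c("linear", "quadratic"),
                            estimate = 0, se = 0, statistic = 0, p_value = 1)
  } else {
    poly_fit <- svy_lm(y ~ poly(qi, 2), d, design, lonely)
    trend_tab <- poly_fit$coefficients[-1L, , drop = FALSE]
    trend_tab$term <- c("linear", "quadratic")
  }
  rownames(trend_tab) <- NULL
  list(contrasts = contr$coefficients, trend = trend_tab,
       linear_p = trend_tab$p_value[1L], quadratic_p = trend_tab$p_value[2L])
}
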