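simple_design <- function(n, weight = rep(1, n)) {
  data.frame(person_id = sprintf("p%02d", 1:n), weight = weight,
             stratum = "s1", psu = sprintf("u%02d", 1:n),
             stringsAsFactors = FALSE)
}

test_that("self-weighting single-stratum design reproduces textbook mean and SE", {
  set.seed(21)
  x <- stats::rnorm(10)
  est <- weighted_mean_se(x, simple_design(10))
  expect_equal(est$mean, mean(x), tolerance = 1e-12)
  expect_equal(est$se, stats::sd(x) / sqrt(10), tolerance = 1e-12)
  expect_equal(est$df, 9)
  # all values identical: zero variance
  expect_equal(weighted_mean_se(rep(3.3, 10), simple_design(10))$se, 0)
  # scale invariance in the weights
  w <- stats::rlnorm(10)
  a <- weighted_mean_se(x, simple_design(10, w))
  b <- weighted_mean_se(x, simple_design(10, 2 * w))
  expect_equal(a$mean, b$mean)
  expect_equal(a$se, b$se)
})

test_that("linearized mean/SE matches the closed-form oracle on clustered designs", {
  set.seed(22)
  for (rep in 1:5) {
    n <- 20
    des <- data.frame(person_id = sprintf("p%02d", 1:n),
                      weight = stats::rlnorm(n),
                      stratum = sample(c("h1", "h2"), n, replace = TRUE),
                      psu = sample(c("u1", "u2", "u3"), n, replace = TRUE),
                      stringsAsFactors = FALSE)
    # guarantee >= 2 PSUs per stratum
    des$psu[1:4] <- c("u1", "u2", "u1", "u2")
    des$stratum[1:4] <- c("h1", "h1", "h2", "h2")
    x <- stats::rnorm(n)
    est <- weighted_mean_se(x, des)
    orc <- oracle_mean_se(x, des$weight, des$stratum, des$psu)
    expect_equal(est$mean, unname(orc["mean"]), tolerance = 1e-12)
    expect_equal(est$se, unname(orc["se"]), tolerance = 1e-12)
  }
})

test_that("lonely PSUs error by default and can be centred explicitly", {
  des <- simple_design(6)
  des$stratum <- c("h1", "h1", "h1", "h1", "h1", "h2")
  expect_error(weighted_mean_se(rnorm(6), des), "single PSU")
  est <- weighted_mean_se(rnorm(6), des, lonely = "centre")
  expect_true(is.finite(est$se))
})

test_that("group t-test collapses to the classical unequal-variance t", {
  x <- c(3.1, 4.7, 2.2, 5.0, 6.1, 3.3, 9.1, 7.4, 6.6, 5.9, 8.1, 7.7)
  g <- rep(c("low", "high"), each = 6)
  res <- group_ttest(x, factor(g, levels = c("low", "high")),
                     simple_design(12))
  welch <- stats::t.test(x[1:6], x[7:12])
  expect_equal(res$statistic, unname(welch$statistic), tolerance = 1e-10)
  expect_equal(res$difference, mean(x[1:6]) - mean(x[7:12]), tolerance = 1e-12)
  # identical groups: no difference, p ~ 1
  same <- group_ttest(rep(x[1:6], 2), g, simple_design(12))
  expect_equal(same$difference, 0)
  expect_gt(same$p_value, 0.999)
})

test_that("the quintile fiber contrast is detected at generator settings", {
  ## power property: the built-in meat/plant pattern separation produces a
  ## fiber-density contrast between bottom and top footprint quintiles that
  ## the design-based t-test detects essentially always
  hits <- 0; n_rep <- 20
  for (s in seq_len(n_rep)) {
    cfg <- generator_config(seed = 100 + s, n_persons = 300, n_foods = 60,
                            n_commodities = 40, n_strata = 8)
    com <- generate_commodities(cfg)
    rec <- generate_recipes(cfg, com)
    pop <- generate_population(cfg, com, rec, ground_truth = FALSE)
    impacts <- apply_substitutions(average_impacts(com$studies),
                                   com$substitutions, com$groups)
    lk <- link_ghge(pop$intake, rec$recipes, rec$direct_links, impacts,
                    rbind(com$losses, rec$losses))
    sm <- aggregate_person(lk$intake, rec$food_nutrients)
    des <- pop$design[match(sm$person_id, pop$design$person_id), ]
    sm <- assign_quintiles(sm, des$weight)
    lh <- sm$quintile %in% c(1, 5)
    grp <- factor(ifelse(sm$quintile[lh] == 1, "low", "high"),
                  levels = c("low", "high"))
    tt <- group_ttest(sm$fiber_g[lh], grp, des[lh, ], lonely = "centre")
    if (tt$p_value < 0.05 && tt$difference > 0) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("design chi-square reduces toward Pearson and detects real contrasts", {
  set.seed(23)
  # identical category distributions: statistic ~ 0
  g <- rep(c("a", "b"), each = 40)
  cat0 <- rep(rep(c("x", "y"), each = 20), 2)
  r0 <- design_chisq(g, cat0, simple_design(80))
  expect_lt(r0$statistic, 1e-9)
  expect_gt(r0$p_value, 0.999)

  # equal weights, PSU = person: close to classical Pearson
  cat1 <- sample(c("x", "y"), 80, replace = TRUE, prob = c(0.6, 0.4))
  cat1[g == "b"] <- sample(c("x", "y"), 40, replace = TRUE,
                           prob = c(0.35, 0.65))
  r1 <- design_chisq(g, cat1, simple_design(80))
  classical <- stats::chisq.test(table(g, cat1), correct = FALSE)
  expect_equal(r1$raw_statistic, unname(classical$statistic),
               tolerance = 1e-9)
  expect_equal(r1$statistic, unname(classical$statistic), tolerance = 0.05)

  # female shares like 56% vs 46.5% at large n: rejected at alpha = 0.05
  n <- 2000
  g2 <- rep(c("low", "high"), each = n / 2)
  sex <- c(sample(c("f", "m"), n / 2, TRUE, prob = c(0.561, 0.439)),
           sample(c("f", "m"), n / 2, TRUE, prob = c(0.465, 0.535)))
  des2 <- data.frame(person_id = as.character(1:n),
                     weight = stats::rlnorm(n, 0, 0.3),
                     stratum = rep(sprintf("h%d", 1:10), length.out = n),
                     psu = rep(sprintf("u%d", 1:4), length.out = n))
  r2 <- design_chisq(g2, sex, des2)
  expect_lt(r2$p_value, 0.05)
})

test_that("unadjusted behavior regression equals the weighted mean difference", {
  set.seed(24)
  n <- 60
  des <- data.frame(person_id = as.character(1:n),
                    weight = stats::rlnorm(n),
                    stratum = rep(c("h1", "h2"), each = n / 2),
                    psu = rep(sprintf("u%d", 1:6), length.out = n))
  dat <- data.frame(ghge_density = stats::rlnorm(n),
                    flag = stats::rbinom(n, 1, 0.4),
                    age_group = sample(c("young", "old"), n, TRUE),
                    gender = sample(c("f", "m"), n, TRUE),
                    race_ethnicity = sample(c("a", "b"), n, TRUE),
                    income_group = sample(c("lo", "hi"), n, TRUE),
                    education = sample(c("hs", "col"), n, TRUE))
  reg <- behavior_regression(dat, des, "flag")
  w <- des$weight
  wdiff <- with(dat, sum(w * ghge_density * flag) / sum(w * flag) -
                  sum(w * ghge_density * (1 - flag)) / sum(w * (1 - flag)))
  expect_equal(reg$table$estimate[reg$table$model == "unadjusted"], wdiff,
               tolerance = 1e-10)
  expect_equal(reg$table$model, c("unadjusted", "demographic", "full"))
})

test_that("null behavior flags are recovered as near-zero coefficients", {
  set.seed(25)
  cover <- 0; n_rep <- 40
  for (r in seq_len(n_rep)) {
    n <- 150
    des <- data.frame(person_id = as.character(1:n),
                      weight = stats::rlnorm(n, 0, 0.4),
                      stratum = rep(sprintf("h%d", 1:5), length.out = n),
                      psu = rep(sprintf("u%d", 1:3), length.out = n))
    dat <- data.frame(ghge_density = stats::rlnorm(n),
                      flag = stats::rbinom(n, 1, 0.5))
    f <- svy_lm(ghge_density ~ flag, dat, des)
    co <- f$coefficients[f$coefficients$term == "flag", ]
    if (abs(co$estimate) < 2 * co$se) cover <- cover + 1
  }
  expect_gte(cover / n_rep, 0.85)
})

test_that("adding an uncorrelated covariate barely moves the coefficient", {
  set.seed(26)
  n <- 400
  des <- data.frame(person_id = as.character(1:n), weight = stats::rlnorm(n),
                    stratum = rep(sprintf("h%d", 1:8), length.out = n),
                    psu = rep(sprintf("u%d", 1:5), length.out = n))
  dat <- data.frame(flag = stats::rbinom(n, 1, 0.5),
                    noise = stats::rnorm(n))
  dat$ghge_density <- 2 - 0.5 * dat$flag + stats::rnorm(n)
  f1 <- svy_lm(ghge_density ~ flag, dat, des)
  f2 <- svy_lm(ghge_density ~ flag + noise, dat, des)
  c1 <- f1$coefficients[f1$coefficients$term == "flag", ]
  c2 <- f2$coefficients[f2$coefficients$term == "flag", ]
  expect_lt(abs(c1$estimate - c2$estimate), 2 * c1$se)
})

test_that("trend tests separate linear, quadratic, and flat quintile shapes", {
  set.seed(27)
  n <- 500
  des <- data.frame(person_id = as.character(1:n), weight = stats::rlnorm(n),
                    stratum = rep(sprintf("h%d", 1:10), length.out = n),
                    psu = rep(sprintf("u%d", 1:4), length.out = n))
  q <- sample(1:5, n, replace = TRUE)

  inc <- q + stats::rnorm(n, 0, 0.5)          # strictly increasing in quintile
  r_inc <- quintile_trend_test(inc, q, des)
  expect_lt(r_inc$linear_p, 0.001)
  expect_gt(r_inc$quadratic_p, 0.01)
  # dummy contrasts vs quintile 1 are increasing
  est <- r_inc$contrasts$estimate[-1]
  expect_true(all(diff(est) > 0))

  ush <- (q - 3)^2 + stats::rnorm(n, 0, 0.5)  # symmetric U-shape
  r_u <- quintile_trend_test(ush, q, des)
  expect_lt(r_u$quadratic_p, 0.001)
  expect_gt(r_u$linear_p, 0.01)

  r_const <- quintile_trend_test(rep(2.5, n), q, des)
  expect_equal(r_const$linear_p, 1)
  expect_equal(r_const$quadratic_p, 1)
})
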