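test_that("recipe decomposition scales ingredient grams by amount eaten", {
  food <- list(food_code = "pizza", grams_consumed = 200)
  out <- decompose_food(food, pizza_recipe())
  expect_equal(out$commodity_code, c("pork", "tomato", "wheat")) # sorted
  expect_equal(out$grams, c(20, 40, 60))

  zero <- decompose_food(list(food_code = "pizza", grams_consumed = 0),
                         pizza_recipe())
  expect_equal(zero$grams, c(0, 0, 0))

  rice <- decompose_food(
    list(food_code = "rice_bowl", grams_consumed = 100),
    data.frame(food_code = "rice_bowl", commodity_code = "rice",
               grams_per_100g = 100))
  expect_equal(rice$grams, 100)
})

test_that("loss adjustment back-calculates production-side mass", {
  expect_equal(loss_adjusted_mass(90, 0.10, 0), 100)
  expect_equal(loss_adjusted_mass(72, 0.10, 0.20), 100)
  expect_equal(loss_adjusted_mass(123.4, 0, 0), 123.4)
  expect_error(loss_adjusted_mass(10, 1, 0), "\\[0, 1\\)")
  expect_error(loss_adjusted_mass(-1, 0, 0), "negative")
})

test_that("food GHGE is the loss-adjusted factor-weighted ingredient sum", {
  impacts <- tiny_impacts(c("wheat", "tomato", "pork"), c(0.5, 1.0, 5.0))
  food <- list(food_code = "pizza", grams_consumed = 100, energy_kcal = 250)
  expect_equal(food_ghge(food, pizza_recipe(), NULL, impacts, no_losses()),
               0.03 * 0.5 + 0.02 * 1.0 + 0.01 * 5.0)

  soda_links <- data.frame(food_code = "soda", ghge_per_kg = 0.5)
  soda <- list(food_code = "soda", grams_consumed = 330, energy_kcal = 140)
  expect_equal(food_ghge(soda, pizza_recipe(), soda_links, impacts,
                         no_losses()), 0.165)

  none <- list(food_code = "pizza", grams_consumed = 0, energy_kcal = 0)
  expect_equal(food_ghge(none, pizza_recipe(), NULL, impacts, no_losses()), 0)
})

test_that("linkage is linear in grams and nondecreasing in loss fractions", {
  impacts <- tiny_impacts(c("wheat", "tomato", "pork"), c(0.5, 1.0, 5.0))
  base <- list(food_code = "pizza", grams_consumed = 137.5, energy_kcal = 0)
  doubled <- list(food_code = "pizza", grams_consumed = 275, energy_kcal = 0)
  expect_identical(2 * food_ghge(base, pizza_recipe(), NULL, impacts),
                   food_ghge(doubled, pizza_recipe(), NULL, impacts))

  g0 <- food_ghge(base, pizza_recipe(), NULL, impacts)
  for (rl in c(0, 0.1, 0.3)) {
    for (cl in c(0, 0.2, 0.4)) {
      losses <- data.frame(code = c("wheat", "tomato", "pork"),
                           retail_loss = rl, consumer_loss = cl)
      g <- food_ghge(base, pizza_recipe(), NULL, impacts, losses)
      expect_gte(g + 1e-15, g0)
      expect_equal(g, g0 / ((1 - rl) * (1 - cl)))
    }
  }
})

test_that("vectorized linkage matches a naive nested-loop reference exactly", {
  set.seed(11)
  n_foods <- 20; n_com <- 10
  fcodes <- sprintf("f%02d", 1:n_foods)
  ccodes <- sprintf("c%02d", 1:n_com)
  recipes <- do.call(rbind, lapply(fcodes, function(f) {
    k <- sample(1:10, 1)
    data.frame(food_code = f, commodity_code = sample(ccodes, k),
               grams_per_100g = round(runif(k, 1, 80), 3))
  }))
  impacts <- tiny_impacts(ccodes, round(stats::rlnorm(n_com), 3))
  losses <- data.frame(code = ccodes,
                       retail_loss = round(runif(n_com, 0, 0.2), 3),
                       consumer_loss = round(runif(n_com, 0, 0.3), 3))
  intake <- data.frame(person_id = rep(c("a", "b"), each = 15),
                       food_code = sample(fcodes, 30, replace = TRUE),
                       grams_consumed = round(runif(30, 0, 300), 2),
                       energy_kcal = 100)
  res <- link_ghge(intake, recipes, NULL, impacts, losses)

  for (i in seq_len(nrow(intake))) {          # naive reference
    g <- 0
    for (j in seq_len(nrow(recipes))) {
      if (recipes$food_code[j] == intake$food_code[i]) {
        gc <- intake$grams_consumed[i] * recipes$grams_per_100g[j] / 100
        l <- losses[losses$code == recipes$commodity_code[j], ]
        adj <- gc / ((1 - l$retail_loss) * (1 - l$consumer_loss))
        f <- impacts$ghge_per_kg[impacts$commodity_code ==
                                   recipes$commodity_code[j]]
        g <- g + adj / 1000 * f
      }
    }
    expect_equal(res$intake$ghge_kg[i], g)
  }
})

test_that("diet, food, and commodity bookkeepings agree", {
  cfg <- small_config(seed = 3)
  fx <- generate_fixtures(cfg, withr::local_tempdir(), ground_truth = FALSE)
  d <- attr(fx, "data")
  impacts <- apply_substitutions(average_impacts(d$studies),
                                 d$substitutions, d$groups)
  res <- link_ghge(d$intake, d$recipes, d$direct_links, impacts, d$losses)
  total_diet <- sum(tapply(res$intake$ghge_kg, res$intake$person_id, sum))
  total_food <- sum(res$intake$ghge_kg)
  total_commodity <- sum(res$contributions$ghge_kg)
  expect_equal(total_food, total_commodity, tolerance = 1e-9)
  expect_equal(total_diet, total_commodity, tolerance = 1e-9)
})

test_that("unlinked foods abort by default and are reported when skipped", {
  impacts <- tiny_impacts(c("wheat", "tomato", "pork"), c(0.5, 1.0, 5.0))
  intake <- data.frame(person_id = "p1",
                       food_code = c("pizza", "mystery1", "mystery2"),
                       grams_consumed = 100, energy_kcal = 100)
  expect_error(link_ghge(intake, pizza_recipe(), NULL, impacts, no_losses()),
               "mystery1, mystery2")
  res <- link_ghge(intake, pizza_recipe(), NULL, impacts, no_losses(),
                   on_unlinked = "skip")
  expect_equal(res$unlinked, c("mystery1", "mystery2"))
  expect_equal(nrow(res$intake), 1L)
})

test_that("a food cannot carry both a recipe and a direct link", {
  impacts <- tiny_impacts("wheat", 0.5)
  dl <- data.frame(food_code = "pizza", ghge_per_kg = 1)
  intake <- data.frame(person_id = "p", food_code = "pizza",
                       grams_consumed = 10, energy_kcal = 10)
  expect_error(link_ghge(intake, pizza_recipe(), dl, impacts, no_losses()),
               "both")
})

test_that("missing loss factors fall back to zero loss with a warning", {
  impacts <- tiny_impacts(c("wheat", "tomato", "pork"), c(0.5, 1.0, 5.0))
  losses <- data.frame(code = "wheat", retail_loss = 0.1, consumer_loss = 0)
  intake <- data.frame(person_id = "p", food_code = "pizza",
                       grams_consumed = 100, energy_kcal = 100)
  expect_warning(
    res <- link_ghge(intake, pizza_recipe(), NULL, impacts, losses),
    "zero loss")
  expect_equal(res$intake$ghge_kg,
               0.03 / 0.9 * 0.5 + 0.02 * 1.0 + 0.01 * 5.0)
})
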