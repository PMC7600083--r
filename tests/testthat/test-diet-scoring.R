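test_that("component densities follow the per-1000-kcal convention", {
  std <- hei_standards()
  d <- component_density(c(total_fruits = 250), kcal = 1000, std)
  expect_equal(unname(d["total_fruits"]), 1.0)  # 250 g = 1 cup portion

  expect_equal(unname(component_density(c(), 2000, std)),
               rep(0, nrow(std)))

  # energy-density scale invariance
  d2 <- component_density(c(total_fruits = 500), kcal = 2000, std)
  expect_equal(unname(d2["total_fruits"]), 1.0)

  # percent-energy unit: 10 g saturated fat in 1800 kcal = 5% energy
  d3 <- component_density(c(saturated_fats = 10), kcal = 1800, std)
  expect_equal(unname(d3["saturated_fats"]), 100 * 10 * 9 / 1800)

  expect_error(component_density(c(total_fruits = 1), 0, std), "positive")
  expect_error(component_density(c(bogus = 1), 1000, std), "unknown")
})

test_that("adapted HEI scores the ideal diet at 75 and the worst at 0", {
  std <- hei_standards()
  # at/beyond every adequacy target, at/below every moderation floor
  ideal <- setNames(std$density_for_max, std$component)
  s <- score_adapted_hei(ideal, std)
  expect_equal(s$total, 75)
  expect_equal(sum(std$max_points), 75)

  worst <- setNames(ifelse(std$kind == "moderation", std$density_for_zero, 0),
                    std$component)
  expect_equal(score_adapted_hei(worst, std)$total, 0)

  # linearity at half density for a zero-floor adequacy component
  half <- setNames(rep(0, nrow(std)), std$component)
  half["total_fruits"] <- std$density_for_max[std$component == "total_fruits"] / 2
  half[std$component[std$kind == "moderation"]] <- 0
  s_half <- score_adapted_hei(half, std)
  expect_equal(unname(s_half$partial["total_fruits"]), 5 / 2)

  expect_error(score_adapted_hei(c(bogus = 1), std), "unknown")
})

test_that("adapted HEI is monotone and bounded over random diets", {
  std <- hei_standards()
  set.seed(42)
  for (rep in 1:200) {
    dens <- setNames(runif(nrow(std), 0, 3 * std$density_for_max),
                     std$component)
    s <- score_adapted_hei(dens, std)$total
    expect_gte(s, 0); expect_lte(s, 75)
    # adding adequacy-component density never lowers the score
    bump <- dens
    adeq <- std$component[std$kind == "adequacy"]
    pick <- sample(adeq, 1)
    bump[pick] <- bump[pick] + runif(1, 0, 1)
    expect_gte(score_adapted_hei(bump, std)$total, s - 1e-12)
  }
})

test_that("GABA index caps at 70 when all recommendations are met", {
  std <- gaba_standards()
  male_std <- std[std$sex == "male" & std$age_group == "18-40", ]
  kcal <- male_std$reference_kcal[1]
  grams <- setNames(male_std$recommended_portions * male_std$grams_per_portion,
                    male_std$component)
  s <- score_gaba(as.list(grams), kcal, "male", "18-40", std)
  expect_equal(s$total, 70)
  expect_equal(sum(male_std$max_points), 70)

  expect_equal(score_gaba(list(), kcal, "male", "18-40", std)$total, 0)

  # doubling intake at the caps cannot exceed 70
  s2 <- score_gaba(as.list(grams * 2), kcal, "male", "18-40", std)
  expect_equal(s2$total, 70)

  # half of one recommendation scores half of that component's points
  one <- list(fruits = grams[["fruits"]] / 2)
  expect_equal(unname(score_gaba(one, kcal, "male", "18-40", std)$partial["fruits"]), 5)

  expect_error(score_gaba(list(), 2000, "male", "63+", std), "no standards")
})

test_that("ultraprocessed calorie share respects the ambiguity policy", {
  db <- data.frame(item_id = c("a", "b", "c"),
                   upf_status = c("ultraprocessed", "not_ultraprocessed",
                                  "ambiguous"),
                   kcal = c(100, 100, 100), stringsAsFactors = FALSE)
  all_upf <- data.frame(item_id = "a", grams = 300)
  expect_equal(upf_percentage(all_upf, db), 100)

  rec <- data.frame(item_id = c("a", "b"), grams = c(300, 700))
  expect_equal(upf_percentage(rec, db), 30)  # 300 of 1000 kcal

  amb <- data.frame(item_id = c("c", "b"), grams = c(100, 900))
  expect_equal(upf_percentage(amb, db, "as_upf"), 10)
  expect_equal(upf_percentage(amb, db, "as_not_upf"), 0)

  # scale invariance: grams doubled, share unchanged
  expect_equal(upf_percentage(transform(rec, grams = grams * 2), db), 30)

  expect_error(upf_percentage(data.frame(item_id = "a", grams = 0), db),
               "zero")
  expect_error(upf_percentage(data.frame(item_id = "zz", grams = 1), db),
               "not in database")
})

test_that("AMDR classification uses inclusive 50-65/14-20/20-35 bands", {
  # interior point: 57.5 / 17 / 25.5 percent of energy
  r <- amdr_classify(carb_g = 287.5, protein_g = 85, fat_g = 56.67,
                     kcal = 2000)
  expect_true(r$acceptable)
  expect_equal(unname(r$flags), c("ok", "ok", "ok"))

  lo <- amdr_classify(carb_g = 249.5, protein_g = 85, fat_g = 56.67,
                      kcal = 2000)
  expect_false(lo$acceptable)
  expect_equal(unname(lo$flags["carb"]), "low")

  # closed interval: exactly 35% fat is acceptable
  edge <- amdr_classify(carb_g = 57.5 / 4 * 20, protein_g = 17 / 4 * 20,
                        fat_g = 35 / 9 * 20, kcal = 2000)
  expect_equal(unname(edge$flags["fat"]), "ok")

  expect_error(amdr_classify(-1, 10, 10), "negative")
})

test_that("quality scores are invariant to uniform intake scaling", {
  cov <- generate_covariates(12, seed = 3)
  db <- generate_food_database(40, seed = 3)
  rec <- generate_recalls(cov, db, seed = 3, repeat_fraction = 0)
  q1 <- score_diet_cohort(rec, db, cov)
  rec2 <- transform(rec, grams = grams * 2.5)
  q2 <- score_diet_cohort(rec2, db, cov)
  expect_equal(q2$hei, q1$hei, tolerance = 1e-10)
  expect_equal(q2$gaba, q1$gaba, tolerance = 1e-10)
  expect_equal(q2$upf_pct, q1$upf_pct, tolerance = 1e-10)
})

test_that("cohort scores stay within their bounds (fuzz)", {
  set.seed(99)
  hei_std <- hei_standards(); gaba_std <- gaba_standards()
  for (i in 1:300) {
    dens <- setNames(rexp(nrow(hei_std), 1), hei_std$component)
    h <- score_adapted_hei(dens, hei_std)$total
    expect_true(h >= 0 && h <= 75)
    gg <- as.list(setNames(rexp(7, 1 / 200), unique(gaba_std$component)))
    g <- score_gaba(gg, runif(1, 800, 3500), sample(c("male", "female"), 1),
                    sample(c("18-40", "41-62"), 1), gaba_std)$total
    expect_true(g >= 0 && g <= 70)
  }
})
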