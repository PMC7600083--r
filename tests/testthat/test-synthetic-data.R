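test_that("covariate generator balances the design and bounds ses mass", {
  cov <- generate_covariates(60, seed = 1)
  expect_equal(nrow(cov), 60)
  expect_true(all(table(cov$city) == 12))
  cells <- table(cov$city, cov$sex, cov$age_group, cov$bmi_class)
  expect_lte(diff(range(cells)), 1)
  expect_setequal(unique(cov$sex), c("male", "female"))
  expect_true(all(cov$ses %in% 1:6))
  expect_false(any(duplicated(cov$person_id)))

  big <- generate_covariates(441, seed = 7)
  expect_gt(mean(big$ses %in% 2:4), 0.80)

  expect_identical(generate_covariates(60, seed = 1), cov)
  expect_error(generate_covariates(0), "n must")
})

test_that("food database covers groups and obeys the 4/4/9 energy rule", {
  db11 <- generate_food_database(11, seed = 0)
  expect_equal(sort(unique(db11$food_group)), sort(food_groups()))
  expect_equal(nrow(db11), 11)

  db <- generate_food_database(100, seed = 3, ambiguous_frac = 0.07)
  expect_equal(sum(db$upf_status == "ambiguous"), 7)
  expect_true(all(table(factor(db$food_group, levels = food_groups())) >= 1))
  macro_kcal <- 4 * db$carb_g + 4 * db$protein_g + 9 * db$fat_g
  expect_true(all(abs(db$kcal - macro_kcal) / macro_kcal <= 0.10))
  nut_cols <- setdiff(names(db), c("item_id", "food_group", "upf_status"))
  expect_true(all(as.matrix(db[nut_cols]) >= 0))

  expect_error(generate_food_database(10), "11")
})

test_that("recall generator honours repeat-count conventions", {
  cov <- generate_covariates(441, seed = 7)
  db <- generate_food_database(60, seed = 3)
  rec <- generate_recalls(cov, db, seed = 2, repeat_fraction = 0.21)
  days_per_person <- tapply(rec$day, rec$person_id, function(d) length(unique(d)))
  expect_equal(sum(days_per_person == 2), ceiling(0.21 * 441))  # 93
  expect_true(all(rec$grams >= 0))
  expect_true(all(tapply(rec$day, rec$person_id, min) == 1))

  rec94 <- generate_recalls(cov, db, seed = 2, n_repeat = 94)
  expect_equal(sum(tapply(rec94$day, rec94$person_id,
                          function(d) length(unique(d))) == 2), 94)

  rec0 <- generate_recalls(cov, db, seed = 2, repeat_fraction = 0)
  expect_true(all(table(rec0$person_id, rec0$day)[, "1"] > 0))
  expect_equal(max(rec0$day), 1L)

  expect_error(generate_recalls(cov, db[0, ], seed = 1), "empty")
  expect_identical(generate_recalls(cov, db, seed = 2), rec)
})

test_that("day-1 caloric intake centres on the configured sex means", {
  # Monte-Carlo check of the generator against its own configured mean
  cov <- generate_covariates(10000, seed = 5)
  db <- generate_food_database(60, seed = 3)
  rec <- generate_recalls(cov, db, seed = 9, repeat_fraction = 0)
  kcal_db <- setNames(db$kcal, db$item_id)
  day_kcal <- tapply(rec$grams * kcal_db[rec$item_id] / 100, rec$person_id, sum)
  males <- cov$person_id[cov$sex == "male"]
  mk <- day_kcal[males]
  se <- sd(mk) / sqrt(length(mk))
  expect_lt(abs(mean(mk) - 2135), 3 * se)
})

test_that("tree generator produces valid round-tripping phylogenies", {
  t2 <- generate_tree(2, seed = 1)
  expect_equal(length(t2$tip.label), 2)
  expect_equal(t2$Nnode, 1)

  t100 <- generate_tree(100, seed = 4)
  expect_equal(t100$Nnode, 99)  # rooted bifurcating: n - 1 internal nodes
  expect_true(all(t100$edge.length > 0))

  rt <- ape::read.tree(text = ape::write.tree(t100))
  expect_setequal(rt$tip.label, t100$tip.label)
  expect_equal(sum(rt$edge.length), sum(t100$edge.length), tolerance = 1e-8)

  expect_error(generate_tree(1), "n_leaves")
})

test_that("microbiome generator plants recoverable effects and exact depths", {
  cov <- generate_covariates(200, seed = 11)
  tree <- generate_tree(80, seed = 11)
  set.seed(11)
  drivers <- data.frame(fiber = rnorm(200))

  # fixed depth: all sample sums exact
  mb_fix <- generate_microbiome(cov, drivers, tree, list(), seed = 1,
                                depth_range = c(3667, 3667))
  expect_true(all(rowSums(mb_fix$counts) == 3667))
  expect_equal(sort(colnames(mb_fix$counts)), sort(tree$tip.label))

  # planted effect separates targets from non-targets
  targets <- mb_fix$guilds$scfa_producers[1:5]
  eff <- list(planted_effect(targets, "fiber", 1.0, "+"))
  mb_eff <- generate_microbiome(cov, drivers, tree, eff, seed = 1,
                                depth_range = c(3667, 3667))
  rel2 <- mb_eff$counts / rowSums(mb_eff$counts)
  rho2 <- apply(rel2, 2, cor, y = drivers$fiber, method = "spearman")
  expect_gt(mean(rho2[targets]), mean(rho2[setdiff(colnames(rel2), targets)]))
  expect_gt(mean(rho2[targets]), 0.3)

  # taxonomy guilds as designated
  tax <- mb_fix$taxonomy
  expect_true(all(tax$class[match(mb_fix$guilds$scfa_producers, tax$otu_id)]
                  == "Clostridia"))
  expect_true(all(tax$class[match(mb_fix$guilds$bile_tolerant, tax$otu_id)]
                  %in% c("Bacteroidia", "Gammaproteobacteria")))

  expect_error(generate_microbiome(cov, drivers, tree,
                                   list(planted_effect("nope", "fiber", 1)),
                                   seed = 1),
               "not in tree")
  expect_identical(generate_microbiome(cov, drivers, tree, eff, seed = 1,
                                       depth_range = c(3667, 3667))$counts,
                   mb_eff$counts)
})

test_that("without planted effects the driver-OTU correlations stay in the null envelope", {
  cov <- generate_covariates(200, seed = 11)
  tree <- generate_tree(150, seed = 11)
  set.seed(11)
  drivers <- data.frame(fiber = rnorm(200))
  mb <- generate_microbiome(cov, drivers, tree, list(), seed = 1,
                            depth_range = c(10000, 10000))
  rel <- mb$counts / rowSums(mb$counts)
  rho <- apply(rel, 2, cor, y = drivers$fiber, method = "spearman")
  expect_gte(mean(abs(rho) <= 0.15, na.rm = TRUE), 0.95)
})

test_that("planted-signal strength increases with effect size", {
  cov <- generate_covariates(500, seed = 21)
  tree <- generate_tree(60, seed = 21)
  drivers <- data.frame(fiber = rnorm(500))
  targets <- paste0("OTU", sprintf("%04d", 1:5))
  mean_rho <- vapply(c(0.25, 0.75, 1.5), function(es) {
    mb <- generate_microbiome(cov, drivers, tree,
                              list(planted_effect(targets, "fiber", es, "+")),
                              seed = 3, depth_range = c(3667, 3667))
    rel <- mb$counts / rowSums(mb$counts)
    mean(abs(apply(rel[, targets], 2, cor, y = drivers$fiber,
                   method = "spearman")))
  }, numeric(1))
  expect_true(all(diff(mean_rho) > 0))
})
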