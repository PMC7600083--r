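test_that("min_depth is the minimum row sum", {
  m <- rbind(a = c(3000, 2000), b = c(1667, 2000), c = c(4500, 4500))
  expect_equal(min_depth(m), 3667)
  expect_equal(min_depth(m[1, , drop = FALSE]), 5000)
  expect_equal(min_depth(matrix(10, 3, 2)), 20)
  expect_error(min_depth(m[0, , drop = FALSE]), "empty")
})

test_that("rarefaction subsamples without replacement, reproducibly", {
  set.seed(1)
  cnt <- matrix(rpois(60, 30), 6, 10,
                dimnames = list(paste0("S", 1:6), paste0("O", 1:10)))

  r <- rarefy_table(cnt, depth = 50, seed = 2)
  expect_true(all(rowSums(r) == 50))
  expect_true(all(r <= cnt))                       # cellwise bound
  expect_identical(rarefy_table(cnt, depth = 50, seed = 2), r)
  r3 <- rarefy_table(cnt, depth = 50, seed = 3)
  expect_false(identical(r3, r))
  expect_true(all(rowSums(r3) == 50))

  # sample already exactly at depth is returned unchanged
  one <- matrix(c(5L, 3L, 2L), 1, dimnames = list("S1", paste0("O", 1:3)))
  expect_equal(unname(rarefy_table(one, depth = 10, seed = 1)[1, ]),
               c(5L, 3L, 2L))

  d1 <- rarefy_table(cnt, depth = 1, seed = 4)
  expect_true(all(rowSums(d1) == 1) && all(rowSums(d1 > 0) == 1))

  shallow <- cnt; shallow[2, ] <- 0L; shallow[2, 1] <- 10L
  expect_error(rarefy_table(shallow, depth = 50), "S2")
})

test_that("alpha diversity matches closed forms", {
  uni <- matrix(25L, 1, 4, dimnames = list("S1", paste0("O", 1:4)))
  a <- alpha_diversity(uni)
  expect_equal(a$shannon, log(4))
  expect_equal(a$evenness, 1)
  expect_equal(a$observed_otus, 4L)

  single <- matrix(c(10L, 0L), 1, 2, dimnames = list("S1", c("O1", "O2")))
  a1 <- alpha_diversity(single)
  expect_equal(a1$shannon, 0)
  expect_equal(a1$observed_otus, 1L)
  expect_equal(a1$evenness, 0)

  # hand computation: counts (1,1,2) -> H = 1.5 ln 2
  tri <- matrix(c(1L, 1L, 2L), 1, 3, dimnames = list("S1", paste0("O", 1:3)))
  expect_equal(alpha_diversity(tri)$shannon, 1.5 * log(2))

  # J = H / ln S invariant on random tables
  set.seed(5)
  cnt <- matrix(rpois(80, 8), 8, 10, dimnames = list(paste0("S", 1:8),
                                                     paste0("O", 1:10)))
  cnt[rowSums(cnt) == 0, 1] <- 1L
  a8 <- alpha_diversity(cnt)
  s_multi <- a8$observed_otus > 1
  expect_equal(a8$evenness[s_multi],
               (a8$shannon / log(a8$observed_otus))[s_multi])

  expect_error(alpha_diversity(matrix(0L, 1, 3)), "all-zero")
})

test_that("unifrac reproduces the worked three-leaf examples", {
  tr <- toy_tree()
  # disjoint supports: no shared branch -> unweighted 1
  ab <- toy_counts(c(10, 0, 0), c(0, 0, 10))
  expect_equal(unifrac(ab, tr, "unweighted")[1, 2], 1.0)

  # sister leaves, equal mass: internal branch shared -> weighted 0.5
  cd <- toy_counts(c(1, 0, 0), c(0, 1, 0))
  expect_equal(unifrac(cd, tr, "weighted")[1, 2], 0.5)
  # unweighted for the same pair: unique length 2 of union length 3
  expect_equal(unifrac(cd, tr, "unweighted")[1, 2], 2 / 3)

  same <- toy_counts(c(3, 2, 1), c(6, 4, 2))
  expect_equal(unifrac(same, tr, "weighted")[1, 2], 0)
  expect_equal(unifrac(same, tr, "unweighted")[1, 2], 0)

  bad <- cbind(toy_counts(c(1, 1, 1)), X = 1)
  expect_error(unifrac(bad, tr), "absent from tree")
})

test_that("unifrac matrices satisfy metric sanity on random data", {
  set.seed(31)
  tr <- generate_tree(20, seed = 31)
  cnt <- matrix(rbinom(15 * 20, 1, 0.5) * rpois(15 * 20, 10), 15, 20,
                dimnames = list(paste0("S", 1:15), tr$tip.label))
  cnt[rowSums(cnt) == 0, 1] <- 5
  for (mode in c("weighted", "unweighted")) {
    D <- unifrac(cnt, tr, mode)
    expect_true(isSymmetric(unname(D)))
    expect_true(all(diag(D) == 0))
    expect_true(all(D >= 0 & D <= 1))
  }
  # triangle inequality for unweighted on random triples
  D <- unifrac(cnt, tr, "unweighted")
  for (k in 1:200) {
    t3 <- sample(nrow(D), 3)
    expect_lte(D[t3[1], t3[2]],
               D[t3[1], t3[3]] + D[t3[3], t3[2]] + 1e-12)
  }
})

test_that("unifrac agrees with the phyloseq reference implementation", {
  skip_if_not_installed("phyloseq")
  set.seed(8)
  tr <- generate_tree(12, seed = 8)
  cnt <- matrix(rbinom(96, 1, 0.6) * rpois(96, 15), 8, 12,
                dimnames = list(paste0("S", 1:8), tr$tip.label))
  cnt[rowSums(cnt) == 0, 1] <- 5
  ps <- phyloseq::phyloseq(phyloseq::otu_table(cnt, taxa_are_rows = FALSE),
                           phyloseq::phy_tree(tr))
  pw <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE, normalized = TRUE))
  pu <- as.matrix(phyloseq::UniFrac(ps, weighted = FALSE))
  expect_equal(unclass(unifrac(cnt, tr, "weighted"))[rownames(pw), colnames(pw)],
               pw, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(unclass(unifrac(cnt, tr, "unweighted"))[rownames(pu), colnames(pu)],
               pu, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("abundant-OTU filter ranks, bounds and median-filters", {
  set.seed(17)
  n <- 40
  # 100 designed-abundant + 50 designed-rare OTUs
  abundant <- matrix(rpois(n * 100, 50), n, 100,
                     dimnames = list(NULL, sprintf("A%03d", 1:100)))
  rare <- matrix(rbinom(n * 50, 1, 0.2), n, 50,
                 dimnames = list(NULL, sprintf("R%03d", 1:50)))
  cnt <- cbind(abundant, rare)
  sel <- filter_top_otus(cnt, n = 100, min_median_rel = 1e-4)
  expect_setequal(sel, colnames(abundant))
  expect_gt(attr(sel, "retained_fraction"), 0.99)

  # n larger than the OTU count returns everything passing the median rule
  sel_all <- filter_top_otus(cnt, n = 1000, min_median_rel = 0)
  expect_equal(length(sel_all), 150)

  # an OTU present in under half the samples has median 0 -> excluded
  half <- cbind(matrix(20L, 10, 2, dimnames = list(NULL, c("X1", "X2"))),
                Y = c(rep(0L, 6), rep(30L, 4)))
  expect_setequal(filter_top_otus(half, n = 3, min_median_rel = 1e-4),
                  c("X1", "X2"))
})

test_that("class profiles pool median-zero classes into Other", {
  tax <- data.frame(otu_id = c("O1", "O2", "O3"),
                    class = c("Clostridia", "Bacteroidia", "Clostridia"))
  cnt <- matrix(c(30, 10, 30, 30, 10, 30), 2, 3, byrow = TRUE,
                dimnames = list(c("S1", "S2"), c("O1", "O2", "O3")))
  cp <- class_profile(cnt, tax)
  expect_equal(rowSums(cp), c(S1 = 1, S2 = 1))
  expect_equal(unname(cp[, "Clostridia"]), c(6 / 7, 6 / 7))
  expect_equal(unname(cp[, "Bacteroidia"]), c(1 / 7, 1 / 7))

  # single-class table
  cp1 <- class_profile(cnt[, c("O1", "O3")], tax)
  expect_equal(unname(cp1[, "Clostridia"]), c(1, 1))

  # a class detected in under half the samples has median zero -> Other
  tax2 <- rbind(tax, data.frame(otu_id = "O4", class = "Rare"))
  cnt2 <- rbind(cbind(cnt, O4 = c(0, 0)),
                S3 = c(30, 10, 30, 5))
  colnames(cnt2) <- c("O1", "O2", "O3", "O4")
  cp2 <- class_profile(cnt2, tax2)
  expect_true("Other" %in% colnames(cp2))
  expect_false("Rare" %in% colnames(cp2))
  expect_equal(unname(cp2["S3", "Other"]), 5 / 75)
})
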