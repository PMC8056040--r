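test_that("importance values handle the degenerate and symmetric cases", {
  plots <- data.frame(plot = "A", width = 20, height = 10, quadrat = 10)
  one <- make_cell_census(data.frame(species = "oak", plot = "A",
                                     cell_ix = 0, cell_iy = 0, n = 7), plots)
  iv1 <- importance_values(grid_stems(one), one, "A")
  expect_equal(iv1$iv, 100)

  # two species identical in abundance, frequency, and basal area
  two <- make_cell_census(data.frame(
    species = c("oak", "pine"), plot = "A",
    cell_ix = c(0, 1), cell_iy = 0, n = c(4, 4)), plots)
  iv2 <- importance_values(grid_stems(two), two, "A")
  expect_equal(iv2$iv, c(50, 50))

  expect_error(importance_values(grid_stems(two), two, "Z"),
               "unknown community")
})

test_that("importance values match a hand-computed three-species census", {
  plots <- data.frame(plot = "A", width = 40, height = 10, quadrat = 10)
  # counts 6 / 3 / 1 over 4 quadrats, fixed DBHs via make_cell_census (5 cm)
  pl <- data.frame(
    species = c("a", "a", "a", "b", "b", "c"),
    plot = "A", cell_ix = c(0, 1, 2, 0, 3, 2), cell_iy = 0,
    n = c(2, 2, 2, 2, 1, 1))
  cns <- make_cell_census(pl, plots)
  iv <- importance_values(grid_stems(cns), cns, "A")
  iv <- iv[order(iv$species), ]
  # relative abundance: 60 / 30 / 10.  occupied quadrats: 3 / 2 / 1 -> rel
  # frequency 50 / 33.33 / 16.67.  identical dbh -> rel basal area equals
  # relative abundance.
  ba <- c(6, 3, 1) * pi * 2.5^2
  expected <- (c(60, 30, 10) + 100 * c(3, 2, 1) / 6 + 100 * ba / sum(ba)) / 3
  expect_equal(iv$iv, expected)
  expect_equal(iv$basal_area_cm2, ba)
  expect_equal(iv$basal_area_m2, ba / 1e4)
})

test_that("importance-value components each sum to 100 per community", {
  cfg <- study_config(seed = 8)
  cns <- generate_census(cfg)
  qm <- grid_stems(cns)
  for (cm in c("plantation", "old_growth")) {
    iv <- importance_values(qm, cns, cm)
    expect_equal(sum(iv$rel_abundance), 100)
    expect_equal(sum(iv$rel_frequency), 100)
    expect_equal(sum(iv$rel_basal_area), 100)
    expect_equal(sum(iv$iv), 100)
  }
})

test_that("species accumulation matches closed-form endpoints and the
           all-orderings oracle", {
  set.seed(21)
  ab <- matrix(rpois(8 * 5, 0.9), nrow = 8)  # 8 species x 5 sites
  ab[1, ] <- c(1, 0, 0, 0, 0)
  qm <- make_qm(ab)
  acc <- species_accumulation(qm)
  occ <- ab > 0
  occ <- occ[rowSums(occ) > 0, , drop = FALSE]

  expect_equal(acc$mean_richness[5], sum(rowSums(occ) > 0))   # n = T
  expect_equal(acc$mean_richness[1], mean(colSums(occ)))      # n = 1
  expect_true(all(diff(acc$mean_richness) >= -1e-12))

  # exact estimator equals the mean over all 5! site orderings
  expect_equal(acc$mean_richness, oracle_accum_orderings(occ))
  # and mean/sd over all size-n subsets
  for (n in 1:5) {
    sub <- oracle_accum_subsets(occ, n)
    expect_equal(acc$mean_richness[n], unname(sub["mean"]))
    expect_equal(acc$sd_richness[n], unname(sub["sd"]))
  }
})

test_that("species accumulation mean agrees with vegan's exact method", {
  set.seed(33)
  ab <- matrix(rpois(15 * 24, 0.6), nrow = 15)
  qm <- make_qm(ab)
  acc <- species_accumulation(qm)
  sa <- vegan::specaccum(t(ab), method = "exact")
  expect_equal(acc$mean_richness, unname(sa$richness), tolerance = 1e-12)
  # vegan approximates the covariance term of the sd; agreement is loose
  expect_equal(acc$sd_richness, unname(sa$sd), tolerance = 0.15)
})

test_that("kruskal_wallis matches hand-ranked arithmetic and handles ties", {
  # groups {1,2} vs {3,4}: ranks 1,2 | 3,4, no ties
  # H = 12/(N(N+1)) * sum n_i (Rbar_i - (N+1)/2)^2 = 2.4
  res <- kruskal_wallis(list(c(1, 2), c(3, 4)))
  N <- 4
  H_hand <- 12 / (N * (N + 1)) * (2 * (1.5 - 2.5)^2 + 2 * (3.5 - 2.5)^2)
  expect_equal(res$H, H_hand)
  expect_equal(res$df, 1)

  # invariant to permuting values within a group
  expect_equal(kruskal_wallis(list(c(7, 1, 4), c(2, 9)))$H,
               kruskal_wallis(list(c(4, 7, 1), c(9, 2)))$H)

  # invariant to strictly monotone transforms of the pooled data
  s <- list(rlnorm(10), rlnorm(12) * 2, rlnorm(8))
  expect_equal(kruskal_wallis(s)$H,
               kruskal_wallis(lapply(s, log))$H)

  # fully degenerate data
  res0 <- kruskal_wallis(list(c(2, 2), c(2, 2, 2)))
  expect_equal(res0$H, 0)
  expect_equal(res0$p, 1)

  expect_error(kruskal_wallis(list(1)), "length")
  expect_error(kruskal_wallis(list(numeric(0), 1)), "at least one value")
})

test_that("kruskal_wallis holds its level under an exchangeable null", {
  set.seed(13)
  ps <- replicate(400, {
    kruskal_wallis(split(rnorm(60), rep(1:3, each = 20)))$p
  })
  rate <- mean(ps <= 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("occurrence overlap counts match brute force over species", {
  set.seed(4)
  ab <- matrix(rbinom(12 * 8, 1, 0.5) * rpois(12 * 8, 2), nrow = 12)
  qm <- make_qm(ab, plot = rep(c("A", "B", "C", "D"), each = 2))
  ov <- occurrence_overlap(qm)
  comms <- c("A", "B", "C", "D")
  pres <- sapply(comms, function(cm)
    rowSums(ab[, rep(comms, each = 2) == cm, drop = FALSE]) > 0)
  # brute force each subset count
  for (nm in names(ov$subset_counts)) {
    ss <- strsplit(nm, "&")[[1]]
    want <- sum(apply(pres, 1, function(v)
      all(v[ss]) && !any(v[setdiff(comms, ss)])))
    expect_equal(unname(ov$subset_counts[nm]), want)
  }
  expect_equal(sum(ov$subset_counts), sum(rowSums(pres) > 0))
  expect_equal(unname(ov$n_at_least[">=1"]), sum(rowSums(pres) >= 1))
  expect_equal(unname(ov$n_at_least[">=4"]),
               unname(ov$subset_counts["A&B&C&D"]))
})

test_that("occurrence overlap trivial cases land in the right cells", {
  ab <- rbind(everywhere = rep(1, 4), only_a = c(1, 0, 0, 0),
              only_d = c(0, 0, 0, 2))
  qm <- make_qm(ab, plot = c("A", "B", "C", "D"))
  ov <- occurrence_overlap(qm)
  expect_equal(unname(ov$subset_counts["A&B&C&D"]), 1L)
  expect_equal(unname(ov$subset_counts["A"]), 1L)
  expect_equal(unname(ov$subset_counts["D"]), 1L)
  expect_equal(sum(ov$subset_counts), 3L)
})
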