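basic_pool <- function(n = 1, life_form = "tree")
  data.frame(species = sprintf("sp%02d", seq_len(n)), life_form = life_form,
             stringsAsFactors = FALSE)

test_that("generation is deterministic in the seed and stable per stream", {
  cfg <- synthetic_config(basic_pool(3), matrix(30, 3, 4), seed = 42)
  c1 <- generate_census(cfg)
  c2 <- generate_census(cfg)
  expect_identical(c1$stems, c2$stems)
  c3 <- generate_census(synthetic_config(basic_pool(3), matrix(30, 3, 4),
                                         seed = 43))
  expect_false(identical(c1$stems, c3$stems))

  # hierarchical streams: dropping a species leaves the others untouched
  cfg2 <- synthetic_config(basic_pool(2), matrix(30, 2, 4), seed = 42)
  c4 <- generate_census(cfg2)
  keep <- c1$stems$species %in% c("sp01", "sp02")
  expect_identical(c1$stems[keep, ], c4$stems)
})

test_that("stems respect plot bounds and the DBH truncation", {
  cfg <- synthetic_config(basic_pool(2), matrix(c(200, 0, 0, 150), 2, 2),
                          plot_ids = c("A", "B"),
                          clustering = data.frame(
                            species = c("sp01", "sp02"),
                            type = c("uniform", "thomas"),
                            kappa = c(NA, 10), sigma = c(NA, 2)),
                          seed = 9)
  cns <- generate_census(cfg)
  expect_true(all(cns$stems$x >= 0 & cns$stems$x < 100))
  expect_true(all(cns$stems$y >= 0 & cns$stems$y < 100))
  expect_true(all(cns$stems$dbh >= 1))
  expect_equal(sum(cns$stems$species == "sp02" & cns$stems$plot == "A"), 0)
})

test_that("realized counts match the Poisson intensity", {
  # 1000 replicate draws of one species x plot cell with lambda = 100
  counts <- vapply(1:1000, function(i) {
    cfg <- synthetic_config(basic_pool(1), matrix(100, 1, 1),
                            plot_ids = "A", seed = i)
    nrow(generate_census(cfg)$stems)
  }, numeric(1))
  se <- sqrt(100 / 1000)
  expect_lt(abs(mean(counts) - 100), 3 * se)
  expect_lt(abs(var(counts) / 100 - 1), 0.2)   # Poisson variance ~ mean
})

test_that("apply_preferences rescales intensities preserving the total", {
  cfg <- synthetic_config(basic_pool(1), matrix(130 / 4, 1, 4), seed = 1)
  # fold 10, 4 plots, total 130 -> preferred 100, others 10
  out <- apply_preferences(cfg, data.frame(
    species = "sp01", preferred_plot = "B", fold = 10))
  expect_equal(unname(out$intensity[1, ]), c(10, 100, 10, 10))
  expect_equal(sum(out$intensity), 130)

  # fold 4 on 2 plots, total 50 -> 40 / 10
  cfg2 <- synthetic_config(basic_pool(1), matrix(25, 1, 2),
                           plot_ids = c("A", "B"), seed = 1)
  out2 <- apply_preferences(cfg2, data.frame(
    species = "sp01", preferred_plot = "A", fold = 4))
  expect_equal(unname(out2$intensity[1, ]), c(40, 10))

  # fold 1 is a no-op up to the total-preserving rescale
  cfg3 <- synthetic_config(basic_pool(1), matrix(c(5, 10, 15, 20), 1, 4),
                           seed = 1)
  out3 <- apply_preferences(cfg3, data.frame(
    species = "sp01", preferred_plot = "C", fold = 1))
  expect_equal(unname(out3$intensity[1, ]), rep(12.5, 4))

  expect_error(apply_preferences(cfg, data.frame(
    species = "nope", preferred_plot = "A", fold = 2)), "unknown species")
  expect_error(apply_preferences(cfg, data.frame(
    species = "sp01", preferred_plot = "Z", fold = 2)), "unknown plot")
})

test_that("null censuses equalize expected totals across plots", {
  cfg <- synthetic_config(basic_pool(3), matrix(c(0, 40, 80), 3, 4), seed = 5)
  cfg <- apply_preferences(cfg, data.frame(
    species = "sp03", preferred_plot = "A", fold = 9))
  n1 <- generate_null_census(cfg)
  expect_identical(n1$stems, generate_null_census(cfg)$stems)
  # equal intensities: realized per-plot totals of sp03 within Poisson range
  tab <- table(factor(n1$stems$plot[n1$stems$species == "sp03"],
                      levels = cfg$plot_ids))
  expect_true(all(abs(tab - 80) < 5 * sqrt(80)))
})

test_that("Thomas-process species cluster beyond the CSR envelope", {
  cfg <- synthetic_config(basic_pool(1), matrix(600, 1, 1), plot_ids = "A",
                          clustering = data.frame(species = "sp01",
                                                  type = "thomas",
                                                  kappa = 10, sigma = 2),
                          seed = 31)
  pts <- generate_census(cfg)$stems[, c("x", "y")]
  set.seed(31)
  env <- mc_envelope(pts, window = c(100, 100), n_sim = 199,
                     coverage = 0.99, r = c(1, 2, 3))
  expect_gt(env$g[env$r == 2], env$hi[env$r == 2])
})

test_that("configurations round-trip through YAML to the same census", {
  cfg <- study_config(seed = 6)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_synthetic_config(cfg, path)
  cfg2 <- read_synthetic_config(path)
  expect_equal(cfg2$intensity, cfg$intensity)
  expect_equal(cfg2$clustering, cfg$clustering)
  expect_identical(generate_census(cfg2)$stems, generate_census(cfg)$stems)
})

test_that("the baseline study configuration matches its stated magnitudes", {
  cfg <- study_config(seed = 2)
  expect_equal(colSums(cfg$intensity),
               c(plantation = 1165, twice_cut = 3065,
                 once_cut = 4302, old_growth = 2490))
  expect_equal(nrow(cfg$species_pool), 89L)
  expect_equal(sum(cfg$species_pool$life_form == "tree"), 58L)
  cns <- generate_census(cfg)
  tot <- table(cns$stems$plot)
  expect_true(all(abs(tot[colnames(cfg$intensity)] -
                        colSums(cfg$intensity)) <
                    5 * sqrt(colSums(cfg$intensity))))
})
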