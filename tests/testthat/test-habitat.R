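four_plot_census <- function(seed = 1, n_sp = 5, lam = 30) {
  pool <- data.frame(species = sprintf("sp%02d", seq_len(n_sp)),
                     life_form = "tree")
  cfg <- synthetic_config(pool, matrix(lam, n_sp, 4), seed = seed)
  generate_census(cfg)
}

test_that("the combined map concatenates plots along x with full label
           coverage", {
  cns <- four_plot_census()
  map <- build_combined_map(cns)
  expect_equal(map$W, 40L)
  expect_equal(map$H, 10L)
  expect_equal(as.integer(table(map$labels)[map$habitats]), rep(100L, 4))
  expect_equal(unname(map$x_offset), c(0, 10, 20, 30))

  # layout permutation preserves per-habitat cell counts
  map2 <- build_combined_map(cns, layout = c("C", "A", "D", "B"))
  expect_equal(sort(table(map2$labels)), sort(table(map$labels)))
  expect_equal(unname(map2$x_offset["C"]), 0)

  # single plot: 10 x 10 single-label map
  one <- census(cns$stems[cns$stems$plot == "A", ],
                cns$plots[cns$plots$plot == "A", ])
  m1 <- build_combined_map(one)
  expect_equal(c(m1$W, m1$H), c(10L, 10L))
  expect_equal(unique(m1$labels), "A")

  bad <- cns$plots; bad$quadrat <- c(10, 10, 10, 20)
  expect_error(build_combined_map(census(cns$stems, bad)),
               "quadrat size")
})

test_that("the transform family has size 4WH with conserved habitat areas", {
  cns <- four_plot_census()
  maps <- enumerate_null_maps(build_combined_map(cns))
  expect_equal(nrow(maps$labels), 1600L)          # 1 real + 1599 null
  expect_equal(maps$transforms$variant[1], "identity")
  expect_equal(maps$transforms$dx[1], 0L)
  # conservation: every transform preserves each habitat's cell count
  counts <- t(apply(maps$labels, 1, tabulate, nbins = 4))
  expect_true(all(counts == 100L))
  # no duplicated transform tags
  expect_equal(anyDuplicated(maps$transforms), 0L)

  # tiny grids: 4WH - 1 null maps
  tiny <- census(data.frame(stem_id = "s", plot = "A", species = "x",
                            life_form = "tree", x = 1, y = 1, dbh = 5),
                 data.frame(plot = "A", width = 10, height = 10,
                            quadrat = 10))
  expect_equal(nrow(enumerate_null_maps(build_combined_map(tiny))$labels),
               4L)   # W = H = 1: 3 null transforms
})

test_that("relative density follows its definition", {
  plots <- data.frame(plot = c("A", "B"), width = c(40, 40), height = 10,
                      quadrat = 10)
  cns <- make_cell_census(data.frame(species = "x", plot = "A",
                                     cell_ix = 0, cell_iy = 0, n = 1), plots)
  map <- build_combined_map(cns)   # 8 x 1 cells, A = first 4
  expect_equal(c(map$W, map$H), c(8L, 1L))

  # uniform stems: RD = 1 everywhere
  expect_equal(relative_density(rep(3, 8), map, "A"), 1)
  expect_equal(relative_density(rep(3, 8), map, "B"), 1)

  # all stems inside a habitat occupying half the cells -> RD = 2
  expect_equal(relative_density(c(2, 1, 1, 1, 0, 0, 0, 0), map, "A"), 2)
  expect_equal(relative_density(c(5, 0, 0, 0, 0, 0, 0, 0), map, "A"), 2)

  # 8-cell toy: counts (3,1,0,0,2,0,1,1), habitat = first 4 cells
  counts <- c(3, 1, 0, 0, 2, 0, 1, 1)
  expect_equal(relative_density(counts, map, "A"),
               (4 / 4) / (8 / 8))
  expect_equal(relative_density(counts, map, "B"), 1)

  expect_error(relative_density(rep(0, 8), map, "A"), "no stems")
  expect_error(relative_density(rep(1, 8), map, "Z"), "unknown habitat")
})

test_that("torus p-values on a 2x2 grid equal exhaustive enumeration", {
  plots <- data.frame(plot = c("A", "B"), width = 10, height = 20,
                      quadrat = 10)
  # counts: A column (cells x=0): 3 and 1; B column (x=1): 0 and 2
  pl <- data.frame(species = "x", plot = c("A", "A", "B"),
                   cell_ix = 0, cell_iy = c(0, 1, 1), n = c(3, 1, 2))
  cns <- make_cell_census(pl, plots)
  map <- build_combined_map(cns)
  expect_equal(c(map$W, map$H), c(2L, 2L))
  qm <- grid_stems(cns)
  at <- torus_test(qm, map, alpha = 0.5)
  expect_equal(attr(at, "n_maps"), 16L)

  # reconstruct per-cell counts directly from quadrat meta
  counts_by_cell <- numeric(4)
  for (j in seq_len(ncol(qm$abundance))) {
    ix <- map$x_offset[qm$quadrat_meta$plot[j]] + qm$quadrat_meta$cell_ix[j]
    iy <- qm$quadrat_meta$cell_iy[j]
    counts_by_cell[iy * map$W + ix + 1] <- qm$abundance["x", j]
  }
  for (h in c("A", "B")) {
    oracle <- oracle_torus(counts_by_cell, map$labels, map$W, map$H, h)
    row <- at[at$habitat == h, ]
    expect_equal(row$observed_rd, oracle$obs)
    expect_equal(row$p_pos, oracle$p_pos)
    expect_equal(row$p_neg, oracle$p_neg)
  }
})

test_that("exactly uniform species are classified none everywhere", {
  plots <- data.frame(plot = c("A", "B"), width = c(20, 20), height = 20,
                      quadrat = 10)
  pl <- expand.grid(cell_ix = 0:1, cell_iy = 0:1, plot = c("A", "B"),
                    stringsAsFactors = FALSE)
  pl$species <- "u"; pl$n <- 3
  cns <- make_cell_census(pl, plots)
  at <- torus_test(grid_stems(cns), build_combined_map(cns))
  expect_true(all(at$observed_rd == 1))
  expect_true(all(at$class == "none"))
  expect_true(all(at$p_pos == 1 & at$p_neg == 1))
})

test_that("torus p-values live on the discrete null grid and tails are
           consistent", {
  cns <- four_plot_census(seed = 23, n_sp = 6, lam = 25)
  qm <- filter_min_abundance(grid_stems(cns), 5)
  at <- torus_test(qm, build_combined_map(cns))
  n_maps <- attr(at, "n_maps")
  expect_equal(n_maps, 1600L)
  on_grid <- function(p) abs(p * n_maps - round(p * n_maps)) < 1e-9
  expect_true(all(on_grid(at$p_pos)))
  expect_true(all(on_grid(at$p_neg)))
  expect_true(all(at$p_pos >= 1 / n_maps & at$p_pos <= 1))
  # discrete two-sided consistency
  expect_true(all(at$p_pos + at$p_neg >= 1 + 1 / n_maps - 1e-12))
  # at most one signed call per species x habitat
  expect_false(any(at$p_pos <= 0.025 & at$p_neg <= 0.025))
})

test_that("relabeling species permutes association rows only", {
  cns <- four_plot_census(seed = 29, n_sp = 4, lam = 40)
  qm <- filter_min_abundance(grid_stems(cns), 5)
  map <- build_combined_map(cns)
  at1 <- torus_test(qm, map)
  qm2 <- qm
  relabel <- setNames(sprintf("zz%02d", seq_len(nrow(qm$abundance))),
                      rownames(qm$abundance))
  rownames(qm2$abundance) <- unname(relabel[rownames(qm$abundance)])
  qm2$species_meta$species <- rownames(qm2$abundance)
  at2 <- torus_test(qm2, map)
  at1$species <- unname(relabel[at1$species])
  at1 <- at1[order(at1$species, at1$habitat), ]
  rownames(at1) <- NULL
  expect_equal(as.data.frame(at1), as.data.frame(at2))
})

test_that("format_associations renders sign strings", {
  at <- data.frame(
    species = c("x", "x", "x", "y"), life_form = "tree",
    habitat = c("A", "B", "D", "A"),
    observed_rd = 1, p_pos = 1, p_neg = 1,
    class = c("positive", "none", "negative", "none"))
  fa <- format_associations(at)
  expect_equal(fa$association[fa$species == "x"], "A(+) D(-)")
  expect_true(is.na(fa$association[fa$species == "y"]))
})
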