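# Builders and independent brute-force oracles shared across the suite.
# Oracles are written as plain enumerations, separate from the package's
# code paths, so expected values are computed and not assumed.

# Construct a quadrat_matrix directly from an abundance matrix. Quadrats
# are laid out along x within each plot (one row of cells per plot).
make_qm <- function(ab, plot = "A", life_form = "tree") {
  ab <- as.matrix(ab)
  if (is.null(rownames(ab))) rownames(ab) <- sprintf("sp%02d", seq_len(nrow(ab)))
  plot <- rep_len(plot, ncol(ab))
  cell_ix <- stats::ave(seq_len(ncol(ab)), plot, FUN = seq_along) - 1L
  meta <- data.frame(plot = plot, cell_ix = cell_ix, cell_iy = 0L,
                     stringsAsFactors = FALSE)
  colnames(ab) <- paste(meta$plot, meta$cell_ix, meta$cell_iy, sep = ":")
  widths <- table(plot) * 10
  plots <- data.frame(plot = names(widths), width = as.numeric(widths),
                      height = 10, quadrat = 10, stringsAsFactors = FALSE)
  structure(list(abundance = ab, quadrat_meta = meta,
                 species_meta = data.frame(
                   species = rownames(ab),
                   life_form = rep_len(life_form, nrow(ab)),
                   stringsAsFactors = FALSE),
                 plots = plots),
            class = "quadrat_matrix")
}

# A small census with stems placed at quadrat centers from a list of
# (species, plot, cell_ix, cell_iy, n) rows; DBH fixed at 5 cm.
make_cell_census <- function(placements, plots) {
  rows <- lapply(seq_len(nrow(placements)), function(i) {
    p <- placements[i, ]
    q <- plots$quadrat[match(p$plot, plots$plot)]
    data.frame(stem_id = sprintf("%s_%s_%d_%d_%d", p$plot, p$species,
                                 p$cell_ix, p$cell_iy, seq_len(p$n)),
               plot = p$plot, species = p$species,
               life_form = if ("life_form" %in% names(placements))
                 p$life_form else "tree",
               x = q * (p$cell_ix + 0.5), y = q * (p$cell_iy + 0.5),
               dbh = 5, stringsAsFactors = FALSE)
  })
  census(do.call(rbind, rows), plots = plots)
}

# Mean richness when sites are accumulated in every possible order.
oracle_accum_orderings <- function(occ) {
  Tt <- ncol(occ)
  perms <- all_permutations(seq_len(Tt))
  acc <- matrix(0, nrow = length(perms), ncol = Tt)
  for (k in seq_along(perms)) {
    seen <- rep(FALSE, nrow(occ))
    for (j in seq_len(Tt)) {
      seen <- seen | occ[, perms[[k]][j]]
      acc[k, j] <- sum(seen)
    }
  }
  colMeans(acc)
}

all_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(all_permutations(v[-i]), function(p) c(v[i], p)))
  out
}

# Mean and population sd of richness over all size-n site subsets.
oracle_accum_subsets <- function(occ, n) {
  subs <- utils::combn(ncol(occ), n)
  rich <- apply(subs, 2, function(ss)
    sum(rowSums(occ[, ss, drop = FALSE]) > 0))
  c(mean = mean(rich), sd = sqrt(mean((rich - mean(rich))^2)))
}

# All nonnegative integer matrices with the given margins, enumerated
# row by row (every composition of each row total bounded by the
# remaining column totals); returns their entropies.
oracle_entropies <- function(r, cs) {
  m <- sum(r)
  compositions <- function(total, bounds) {
    if (length(bounds) == 1L) {
      if (total <= bounds) return(list(total)) else return(list())
    }
    out <- list()
    for (a in 0:min(total, bounds[1]))
      out <- c(out, lapply(compositions(total - a, bounds[-1]),
                           function(rest) c(a, rest)))
    out
  }
  ents <- c()
  rec <- function(i, c_rem, rows) {
    if (i > length(r)) {
      if (all(c_rem == 0)) {
        mat <- do.call(rbind, rows)
        p <- mat[mat > 0] / m
        ents <<- c(ents, -sum(p * log(p)))
      }
      return(invisible())
    }
    for (row in compositions(r[i], c_rem))
      rec(i + 1L, c_rem - row, c(rows, list(row)))
  }
  rec(1L, cs, list())
  ents
}

# Exhaustive torus test on a W x H grid: explicit loops over the four
# variants and all translations, relative densities computed directly.
oracle_torus <- function(counts, labels, W, H, habitat) {
  lab_at <- function(ix, iy) labels[iy * W + ix + 1L]
  rd_for <- function(lab) {
    inh <- lab == habitat
    (sum(counts[inh]) / sum(inh)) / (sum(counts) / length(counts))
  }
  rds <- c()
  for (variant in c("identity", "rot180", "mirror", "mirror_rot180"))
    for (dy in 0:(H - 1)) for (dx in 0:(W - 1)) {
      lab <- character(W * H)
      for (ix in 0:(W - 1)) for (iy in 0:(H - 1)) {
        vv <- switch(variant,
                     identity = c(ix, iy),
                     rot180 = c(W - 1 - ix, H - 1 - iy),
                     mirror = c(W - 1 - ix, iy),
                     mirror_rot180 = c(ix, H - 1 - iy))
        lab[iy * W + ix + 1] <- lab_at((vv[1] + dx) %% W, (vv[2] + dy) %% H)
      }
      rds <- c(rds, rd_for(lab))
    }
  obs <- rds[1]                       # identity, dx = dy = 0 comes first
  null <- rds[-1]
  list(obs = obs,
       p_pos = (sum(null >= obs - 1e-12) + 1) / length(rds),
       p_neg = (sum(null <= obs + 1e-12) + 1) / length(rds))
}

# IndVal by direct formula for one group labeling.
oracle_indval_stat <- function(ab, groups) {
  g <- unique(groups)
  vapply(seq_len(nrow(ab)), function(s) {
    means <- vapply(g, function(gg) mean(ab[s, groups == gg]), 1)
    A <- means / sum(means)
    B <- vapply(g, function(gg) mean(ab[s, groups == gg] > 0), 1)
    max(sqrt(A * B))
  }, 1)
}

# Exact IndVal p by enumerating all distinct label arrangements.
oracle_indval_exact_p <- function(ab, groups) {
  arrangements <- unique(all_permutations(groups))
  obs <- oracle_indval_stat(ab, groups)
  stats <- vapply(arrangements, function(a) oracle_indval_stat(ab, a),
                  numeric(nrow(ab)))
  stats <- matrix(stats, nrow = nrow(ab))
  rowMeans(stats >= obs - 1e-12)
}
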