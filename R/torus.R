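# Torus-translation test of species-community association. The habitat
# map (not the stems) is transformed around a toroidal grid, preserving
# both the stems' spatial autocorrelation and the habitat patch
# structure. With the four 10 x 10-cell plots concatenated along x into
# one 40 x 10 torus, the transform family (all translations of the
# identity, 180-degree rotation, mirror, and mirrored rotation) yields
# 4 * 40 * 10 = 1600 maps: 1 real and 1599 null.

#' Build the combined habitat map from a multi-plot census
#'
#' Concatenates the plots along the x axis into a single toroidal grid of
#' quadrat cells, labeling each cell with its plot (community) id. All
#' plots must share the quadrat size and plot height.
#'
#' @param cns a [census()] object.
#' @param layout plot ids in concatenation order (default: plot-table
#'   order).
#' @return object of class `"habitat_map"`: list with `W`, `H` (cells),
#'   `labels` (character vector, cell order `iy * W + ix + 1`),
#'   `habitats`, `quadrat`, `x_offset` (named, cells, per plot).
#' @export
build_combined_map <- function(cns, layout = NULL) {
  stopifnot(inherits(cns, "census"))
  plots <- cns$plots
  if (is.null(layout)) layout <- plots$plot
  stopifnot(setequal(layout, plots$plot))
  plots <- plots[match(layout, plots$plot), ]
  if (length(unique(plots$quadrat)) != 1L)
    stop("plots differ in quadrat size", call. = FALSE)
  if (length(unique(plots$height)) != 1L)
    stop("plots differ in height; cannot concatenate along x", call. = FALSE)
  q <- plots$quadrat[1]
  H <- plots$height[1] / q
  wcells <- plots$width / q
  W <- sum(wcells)
  x_offset <- stats::setNames(cumsum(c(0, wcells[-length(wcells)])),
                              plots$plot)
  labels <- character(W * H)
  for (i in seq_len(nrow(plots))) {
    ix <- x_offset[i] + seq_len(wcells[i]) - 1L
    for (iy in 0:(H - 1L)) labels[iy * W + ix + 1L] <- plots$plot[i]
  }
  structure(list(W = as.integer(W), H = as.integer(H), labels = labels,
                 habitats = plots$plot, quadrat = q, x_offset = x_offset),
            class = "habitat_map")
}

#' @export
print.habitat_map <- function(x, ...) {
  cat("Habitat map:", x$W, "x", x$H, "cells (", x$quadrat,
      "m quadrats );", length(x$habitats), "habitats\n")
  cat("  null family:", 4L * x$W * x$H - 1L, "transformed maps\n")
  invisible(x)
}

#' Enumerate the torus-transform family of a habitat map
#'
#' Applies each of the four variants (identity, 180-degree rotation,
#' x-mirror, mirrored rotation) under every torus translation
#' `(dx, dy) in [0, W) x [0, H)`, giving `4 * W * H` maps in total. The
#' first row is always the untransformed map; the null set is the
#' remaining `4 * W * H - 1`. Every habitat's cell count is preserved by
#' every transform.
#'
#' @param map a [build_combined_map()] habitat map.
#' @return list with `labels` (integer matrix, transforms x cells; values
#'   index into `habitats`), `habitats`, and `transforms` (data frame
#'   `variant`, `dx`, `dy`).
#' @export
enumerate_null_maps <- function(map) {
  stopifnot(inherits(map, "habitat_map"))
  W <- map$W; H <- map$H
  base <- match(map$labels, map$habitats)
  ix <- rep(0:(W - 1L), H)
  iy <- rep(0:(H - 1L), each = W)
  variants <- list(
    identity      = cbind(ix, iy),
    rot180        = cbind(W - 1L - ix, H - 1L - iy),
    mirror        = cbind(W - 1L - ix, iy),
    mirror_rot180 = cbind(ix, H - 1L - iy))
  n_cells <- W * H
  n_tr <- 4L * n_cells
  L <- matrix(0L, nrow = n_tr, ncol = n_cells)
  meta <- data.frame(variant = character(n_tr), dx = integer(n_tr),
                     dy = integer(n_tr), stringsAsFactors = FALSE)
  row <- 0L
  for (v in names(variants)) {
    vx <- variants[[v]][, 1]; vy <- variants[[v]][, 2]
    for (dy in 0:(H - 1L)) for (dx in 0:(W - 1L)) {
      row <- row + 1L
      tx <- (vx + dx) %% W
      ty <- (vy + dy) %% H
      L[row, ] <- base[ty * W + tx + 1L]
      meta$variant[row] <- v
      meta$dx[row] <- dx
      meta$dy[row] <- dy
    }
  }
  # put the untransformed map first
  first <- which(meta$variant == "identity" & meta$dx == 0L & meta$dy == 0L)
  ord <- c(first, setdiff(seq_len(n_tr), first))
  list(labels = L[ord, , drop = FALSE], habitats = map$habitats,
       transforms = meta[ord, ])
}

#' Relative density of a species in a habitat
#'
#' `RD = (stems in habitat / habitat cells) / (total stems / total
#' cells)`; 1 under no association.
#'
#' @param counts per-cell stem counts of the species, in the map's cell
#'   order (`iy * W + ix + 1`).
#' @param map a habitat map.
#' @param habitat habitat (community) label.
#' @return numeric relative density.
#' @export
relative_density <- function(counts, map, habitat) {
  stopifnot(inherits(map, "habitat_map"),
            length(counts) == map$W * map$H)
  if (!habitat %in% map$habitats) stop("unknown habitat: ", habitat,
                                       call. = FALSE)
  total <- sum(counts)
  if (total <= 0) stop("species has no stems", call. = FALSE)
  inh <- map$labels == habitat
  n_cells_h <- sum(inh)
  if (n_cells_h == 0L) stop("habitat has no cells", call. = FALSE)
  (sum(counts[inh]) / n_cells_h) / (total / length(counts))
}

# Map quadrat-matrix columns onto combined-map cell indices.
cell_index_of_quadrats <- function(qm, map) {
  meta <- qm$quadrat_meta
  off <- map$x_offset[meta$plot]
  if (anyNA(off)) stop("quadrat matrix has plots absent from the map",
                       call. = FALSE)
  ix <- off + meta$cell_ix
  iy <- meta$cell_iy
  if (any(ix >= map$W) || any(iy >= map$H))
    stop("quadrat indices exceed map extent", call. = FALSE)
  as.integer(iy * map$W + ix + 1L)
}

#' Torus-translation habitat-association test
#'
#' For every species x habitat pair, the observed relative density is
#' compared against its distribution over all transformed maps (stems
#' fixed, habitat labels moved). With `n_maps = 4 W H` maps (1 real plus
#' the null family),
#' `p_pos = (1 + #[null RD >= observed]) / n_maps` and `p_neg`
#' analogously with `<=`; ties count toward both tails. A species is
#' classified `positive` for a habitat when `p_pos <= alpha / 2`,
#' `negative` when `p_neg <= alpha / 2`, else `none`.
#'
#' Species should normally be pre-filtered with
#' [filter_min_abundance()] (at least 5 individuals) so the null
#' distribution is informative.
#'
#' @param qm a quadrat matrix (typically filtered).
#' @param map a [build_combined_map()] habitat map covering its plots.
#' @param alpha two-sided significance level (default 0.05).
#' @return data frame of class `"association_table"`: `species`,
#'   `life_form`, `habitat`, `observed_rd`, `p_pos`, `p_neg`, `class`.
#'   Attributes `n_maps` and `alpha` record the null size and level.
#' @export
torus_test <- function(qm, map, alpha = 0.05) {
  stopifnot(inherits(qm, "quadrat_matrix"), inherits(map, "habitat_map"))
  if (nrow(qm$abundance) == 0L) {
    out <- data.frame(species = character(0), life_form = character(0),
                      habitat = character(0), observed_rd = numeric(0),
                      p_pos = numeric(0), p_neg = numeric(0),
                      class = character(0), stringsAsFactors = FALSE)
    class(out) <- c("association_table", "data.frame")
    attr(out, "n_maps") <- 4L * map$W * map$H
    attr(out, "alpha") <- alpha
    return(out)
  }
  n_cells <- map$W * map$H
  cellof <- cell_index_of_quadrats(qm, map)
  S <- nrow(qm$abundance)
  # N: cells x species counts
  N <- matrix(0, nrow = n_cells, ncol = S)
  for (j in seq_along(cellof)) N[cellof[j], ] <- N[cellof[j], ] + qm$abundance[, j]
  totals <- colSums(N)
  if (any(totals <= 0))
    stop("species with zero stems present; filter first", call. = FALSE)
  maps <- enumerate_null_maps(map)
  n_maps <- nrow(maps$labels)
  rows <- vector("list", length(map$habitats))
  for (hi in seq_along(map$habitats)) {
    h <- map$habitats[hi]
    Ih <- (maps$labels == match(h, maps$habitats)) * 1
    cells_h <- sum(Ih[1, ])
    counts_h <- Ih %*% N                       # transforms x species
    rd <- sweep(counts_h / cells_h, 2, totals / n_cells, "/")
    obs <- rd[1, ]
    eps <- 1e-12
    p_pos <- (colSums(rd[-1, , drop = FALSE] >=
                        matrix(obs - eps, n_maps - 1L, S, byrow = TRUE)) + 1) / n_maps
    p_neg <- (colSums(rd[-1, , drop = FALSE] <=
                        matrix(obs + eps, n_maps - 1L, S, byrow = TRUE)) + 1) / n_maps
    cls <- ifelse(p_pos <= alpha / 2, "positive",
                  ifelse(p_neg <= alpha / 2, "negative", "none"))
    rows[[hi]] <- data.frame(
      species = rownames(qm$abundance), life_form = qm$species_meta$life_form,
      habitat = h, observed_rd = obs, p_pos = p_pos, p_neg = p_neg,
      class = cls, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$species, out$habitat), ]
  rownames(out) <- NULL
  class(out) <- c("association_table", "data.frame")
  attr(out, "n_maps") <- n_maps
  attr(out, "alpha") <- alpha
  out
}

#' Render an association table in compact sign notation
#'
#' One row per species with its significant habitats written as e.g.
#' `"B(+) D(-)"`, or `NA` when no habitat is significant.
#'
#' @param at an [torus_test()] association table.
#' @return data frame `species`, `life_form`, `association`.
#' @export
format_associations <- function(at) {
  sp <- unique(at$species)
  assoc <- vapply(sp, function(s) {
    sub <- at[at$species == s & at$class != "none", , drop = FALSE]
    if (nrow(sub) == 0L) return(NA_character_)
    sub <- sub[order(sub$habitat), ]
    paste(sprintf("%s(%s)", sub$habitat,
                  ifelse(sub$class == "positive", "+", "-")),
          collapse = " ")
  }, character(1))
  lf <- at$life_form[match(sp, at$species)]
  data.frame(species = sp, life_form = lf, association = unname(assoc),
             stringsAsFactors = FALSE)
}
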