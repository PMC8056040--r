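# Synthetic stem-map generator: multi-plot censuses with controlled
# habitat preference, Thomas-process clustering, and lognormal DBH.
#
# Each species x plot cell is generated from its own deterministic random
# stream (a hash of the global seed, species label, and plot label), so
# adding or removing a species never perturbs the stems of another.

#' Configuration for the synthetic census generator
#'
#' Describes a multi-plot stem-mapped census to simulate: plot geometry,
#' a species pool, a matrix of expected abundances (Poisson intensities,
#' stems per plot), per-species spatial clustering, and per-species
#' lognormal DBH parameters.
#'
#' @param species_pool data frame with columns `species`, `life_form`.
#' @param intensity numeric matrix, species x plots, of expected stem
#'   counts per plot (`lambda >= 0`); dimnames taken from `species_pool`
#'   and `plot_ids` if absent.
#' @param n_plots number of plots (default 4, ignored when `plot_ids` given).
#' @param plot_ids character plot labels; default `"A".."D"` style letters.
#' @param plot_size plot side length in meters (default 100; plots are square).
#' @param quadrat quadrat size in meters (default 10).
#' @param clustering either `"uniform"`, or a data frame with columns
#'   `species`, `type` (`"uniform"`/`"thomas"`), `kappa` (cluster parents
#'   per hectare) and `sigma` (Gaussian offspring displacement sd, m).
#' @param dbh_meanlog,dbh_sdlog lognormal DBH parameters on the cm scale,
#'   recycled across species. Defaults `1.5` and `0.6` give mean DBH of
#'   roughly 3-25 cm across species once truncated at `min_dbh`.
#' @param min_dbh truncation threshold in cm (default 1, the tagging limit).
#' @param seed integer global seed; every draw is derived from it.
#' @return An object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(species_pool, intensity,
                             n_plots = 4, plot_ids = NULL,
                             plot_size = 100, quadrat = 10,
                             clustering = "uniform",
                             dbh_meanlog = 1.5, dbh_sdlog = 0.6,
                             min_dbh = 1, seed = 1L) {
  species_pool <- as.data.frame(species_pool)
  stopifnot(all(c("species", "life_form") %in% names(species_pool)))
  if (is.null(plot_ids)) plot_ids <- LETTERS[seq_len(n_plots)]
  intensity <- as.matrix(intensity)
  if (nrow(intensity) != nrow(species_pool) ||
      ncol(intensity) != length(plot_ids))
    stop("intensity must be a species x plot matrix", call. = FALSE)
  if (any(intensity < 0) || any(!is.finite(intensity)))
    stop("intensities must be finite and >= 0", call. = FALSE)
  dimnames(intensity) <- list(species_pool$species, plot_ids)
  if (identical(clustering, "uniform")) {
    clustering <- data.frame(species = species_pool$species,
                             type = "uniform", kappa = NA_real_,
                             sigma = NA_real_, stringsAsFactors = FALSE)
  }
  clustering <- as.data.frame(clustering)
  stopifnot(all(c("species", "type") %in% names(clustering)))
  if (!all(species_pool$species %in% clustering$species))
    stop("clustering spec missing species", call. = FALSE)
  th <- clustering$type == "thomas"
  if (any(th & (!is.finite(clustering$kappa) | clustering$kappa <= 0 |
                !is.finite(clustering$sigma) | clustering$sigma <= 0)))
    stop("thomas clustering needs kappa > 0 (parents/ha) and sigma > 0 (m)",
         call. = FALSE)
  structure(list(species_pool = species_pool, intensity = intensity,
                 plot_ids = plot_ids, plot_size = plot_size,
                 quadrat = quadrat, clustering = clustering,
                 dbh_meanlog = rep_len(dbh_meanlog, nrow(species_pool)),
                 dbh_sdlog = rep_len(dbh_sdlog, nrow(species_pool)),
                 min_dbh = min_dbh, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic census config:", nrow(x$species_pool), "species,",
      length(x$plot_ids), "plots of", x$plot_size, "x", x$plot_size,
      "m; expected total", round(sum(x$intensity), 1), "stems; seed",
      x$seed, "\n")
  invisible(x)
}

# Deterministic 31-bit stream seed from (seed, species, plot): djb2 hash.
stream_seed <- function(seed, species, plot) {
  bytes <- utf8ToInt(paste(seed, species, plot, sep = "\r"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  as.integer(h)
}

#' Impose plot preferences on a synthetic configuration
#'
#' Rescales a species' intensity row so its preferred plot carries `fold`
#' times the intensity of each other plot, while preserving the species'
#' total expected abundance. With total `L`, `P` plots and fold `f`, the
#' preferred plot gets `L f / (f + P - 1)` and every other plot
#' `L / (f + P - 1)`.
#'
#' @param config a [synthetic_config()].
#' @param prefs data frame with columns `species`, `preferred_plot`,
#'   `fold` (ratio >= 1).
#' @return The modified configuration.
#' @export
apply_preferences <- function(config, prefs) {
  stopifnot(inherits(config, "synthetic_config"))
  prefs <- as.data.frame(prefs)
  stopifnot(all(c("species", "preferred_plot", "fold") %in% names(prefs)))
  for (i in seq_len(nrow(prefs))) {
    sp <- prefs$species[i]
    pl <- prefs$preferred_plot[i]
    f <- prefs$fold[i]
    if (!sp %in% rownames(config$intensity))
      stop("unknown species in preferences: ", sp, call. = FALSE)
    if (!pl %in% colnames(config$intensity))
      stop("unknown plot in preferences: ", pl, call. = FALSE)
    if (!is.finite(f) || f < 1)
      stop("preference fold must be >= 1", call. = FALSE)
    L <- sum(config$intensity[sp, ])
    P <- ncol(config$intensity)
    base <- L / (f + P - 1)
    config$intensity[sp, ] <- base
    config$intensity[sp, pl] <- base * f
  }
  config
}

# Thomas process: Poisson(kappa * area_ha) parents uniform in the plot,
# offspring assigned to parents uniformly, isotropic Gaussian offsets.
# Offspring falling outside the plot are re-drawn (fresh parent choice and
# offset), keeping the plot physically bounded.
rthomas_positions <- function(n, size, kappa_per_ha, sigma) {
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  area_ha <- size * size / 1e4
  n_parents <- stats::rpois(1L, kappa_per_ha * area_ha)
  if (n_parents == 0L) n_parents <- 1L
  px <- stats::runif(n_parents, 0, size)
  py <- stats::runif(n_parents, 0, size)
  x <- numeric(n); y <- numeric(n)
  todo <- seq_len(n)
  for (iter in 1:100) {
    k <- length(todo)
    if (k == 0L) break
    par <- sample.int(n_parents, k, replace = TRUE)
    cx <- px[par] + stats::rnorm(k, 0, sigma)
    cy <- py[par] + stats::rnorm(k, 0, sigma)
    ok <- cx >= 0 & cx < size & cy >= 0 & cy < size
    x[todo[ok]] <- cx[ok]
    y[todo[ok]] <- cy[ok]
    todo <- todo[!ok]
  }
  if (length(todo) > 0L) { # pathological sigma >> size; fall back to uniform
    x[todo] <- stats::runif(length(todo), 0, size)
    y[todo] <- stats::runif(length(todo), 0, size)
  }
  cbind(x = x, y = y)
}

# Lognormal DBH truncated at min_dbh by inverse-CDF sampling above the
# truncation point (exact, no rejection loop).
rdbh <- function(n, meanlog, sdlog, min_dbh) {
  if (n == 0L) return(numeric(0))
  p0 <- stats::plnorm(min_dbh, meanlog, sdlog)
  u <- stats::runif(n, p0, 1)
  pmin(stats::qlnorm(u, meanlog, sdlog), 1e6)
}

#' Generate a synthetic stem-mapped census
#'
#' For every species x plot cell the stem count is drawn
#' `Poisson(lambda)`; positions are uniform or follow a Thomas cluster
#' process; DBH is lognormal truncated at the census minimum. The result
#' is fully reproducible from `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return A [census()] object.
#' @export
generate_census <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  sp_pool <- config$species_pool
  size <- config$plot_size
  pieces <- vector("list", nrow(sp_pool) * length(config$plot_ids))
  k <- 0L
  for (si in seq_len(nrow(sp_pool))) {
    sp <- sp_pool$species[si]
    cl <- config$clustering[match(sp, config$clustering$species), ]
    for (pl in config$plot_ids) {
      lam <- config$intensity[sp, pl]
      if (lam <= 0) next
      set.seed(stream_seed(config$seed, sp, pl))
      n <- stats::rpois(1L, lam)
      if (n == 0L) next
      pos <- if (identical(cl$type, "thomas"))
        rthomas_positions(n, size, cl$kappa, cl$sigma)
      else
        cbind(x = stats::runif(n, 0, size), y = stats::runif(n, 0, size))
      dbh <- rdbh(n, config$dbh_meanlog[si], config$dbh_sdlog[si],
                  config$min_dbh)
      k <- k + 1L
      pieces[[k]] <- data.frame(
        stem_id = sprintf("%s_%s_%04d", pl, sp, seq_len(n)),
        plot = pl, species = sp, life_form = sp_pool$life_form[si],
        x = pos[, "x"], y = pos[, "y"], dbh = dbh,
        stringsAsFactors = FALSE)
    }
  }
  stems <- if (k > 0L) do.call(rbind, pieces[seq_len(k)]) else
    data.frame(stem_id = character(0), plot = character(0),
               species = character(0), life_form = character(0),
               x = numeric(0), y = numeric(0), dbh = numeric(0))
  rownames(stems) <- NULL
  plots <- data.frame(plot = config$plot_ids, width = size, height = size,
                      quadrat = config$quadrat, stringsAsFactors = FALSE)
  census(stems, plots = plots, min_dbh = config$min_dbh)
}

#' Generate a census with no habitat preference
#'
#' Equalizes every species' intensity across plots (preserving its total
#' expected abundance) before generating, so plot identity carries no
#' information about where a species lives. Used for type-I-error studies
#' of the habitat-association tests.
#'
#' @param config a [synthetic_config()].
#' @return A [census()] object.
#' @export
generate_null_census <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  totals <- rowSums(config$intensity)
  config$intensity[] <- totals / ncol(config$intensity)
  generate_census(config)
}

#' Baseline configuration emulating a four-plot disturbance-gradient census
#'
#' Four square 1-ha plots gridded into 10 m quadrats, representing a
#' disturbance gradient (plantation, twice-cut, once-cut, old-growth).
#' The pool holds 89 woody species (58 trees, 31 shrubs) with a geometric
#' rank-abundance structure; per-plot expected totals are 1165, 3065,
#' 4302 and 2490 stems (sparsest in the plantation, densest in the
#' once-cut stand). Each species is given a moderate (fold = 6) intensity
#' preference for one plot, rotating through the four plots, and roughly
#' half the species are Thomas-clustered.
#'
#' @param seed integer seed.
#' @param fold preference strength applied to every species (default 6).
#' @return A [synthetic_config()].
#' @export
study_config <- function(seed = 1L, fold = 6) {
  n_tree <- 58; n_shrub <- 31
  pool <- data.frame(
    species = c(sprintf("tree_%02d", seq_len(n_tree)),
                sprintf("shrub_%02d", seq_len(n_shrub))),
    life_form = c(rep("tree", n_tree), rep("shrub", n_shrub)),
    stringsAsFactors = FALSE)
  S <- nrow(pool)
  plot_ids <- c("plantation", "twice_cut", "once_cut", "old_growth")
  totals_target <- c(plantation = 1165, twice_cut = 3065,
                     once_cut = 4302, old_growth = 2490)
  # geometric rank-abundance, species i expected share ~ 0.93^i
  base <- 0.93 ^ seq_len(S)
  intensity <- matrix(rep(base, 4), nrow = S,
                      dimnames = list(pool$species, plot_ids))
  cfg <- synthetic_config(pool, intensity, plot_ids = plot_ids, seed = seed)
  prefs <- data.frame(species = pool$species,
                      preferred_plot = plot_ids[(seq_len(S) - 1L) %% 4L + 1L],
                      fold = fold, stringsAsFactors = FALSE)
  cfg <- apply_preferences(cfg, prefs)
  # rescale each plot column to hit the target expected totals
  for (pl in plot_ids)
    cfg$intensity[, pl] <- cfg$intensity[, pl] *
      totals_target[[pl]] / sum(cfg$intensity[, pl])
  # alternate species between uniform and Thomas-clustered placement
  th <- seq_len(S) %% 2L == 0L
  cfg$clustering <- data.frame(
    species = pool$species,
    type = ifelse(th, "thomas", "uniform"),
    kappa = ifelse(th, 25, NA_real_),   # parents per ha
    sigma = ifelse(th, 5, NA_real_),    # offspring sd, m
    stringsAsFactors = FALSE)
  # shrubs smaller than trees on average
  is_shrub <- pool$life_form == "shrub"
  cfg$dbh_meanlog <- ifelse(is_shrub, 1.0, 1.9)
  cfg$dbh_sdlog <- ifelse(is_shrub, 0.5, 0.7)
  cfg
}

#' Serialize a synthetic configuration to YAML
#'
#' @param config a [synthetic_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_synthetic_config()]
#' @export
write_synthetic_config <- function(config, path) {
  stopifnot(inherits(config, "synthetic_config"))
  out <- list(
    species_pool = as.list(config$species_pool),
    plot_ids = config$plot_ids,
    plot_size = config$plot_size,
    quadrat = config$quadrat,
    intensity = apply(config$intensity, 1, as.list, simplify = FALSE),
    clustering = as.list(config$clustering),
    dbh_meanlog = config$dbh_meanlog,
    dbh_sdlog = config$dbh_sdlog,
    min_dbh = config$min_dbh,
    seed = config$seed)
  yaml::write_yaml(out, path, precision = 17L)
  invisible(path)
}

#' Read a synthetic configuration from YAML
#'
#' @param path a file written by [write_synthetic_config()].
#' @return a [synthetic_config()].
#' @export
read_synthetic_config <- function(path) {
  y <- yaml::read_yaml(path)
  pool <- as.data.frame(y$species_pool, stringsAsFactors = FALSE)
  intensity <- do.call(rbind, lapply(y$intensity, function(row)
    unlist(row)[y$plot_ids]))
  clustering <- as.data.frame(y$clustering, stringsAsFactors = FALSE)
  clustering$kappa <- as.numeric(clustering$kappa)
  clustering$sigma <- as.numeric(clustering$sigma)
  synthetic_config(pool, intensity, plot_ids = y$plot_ids,
                   plot_size = y$plot_size, quadrat = y$quadrat,
                   clustering = clustering,
                   dbh_meanlog = y$dbh_meanlog, dbh_sdlog = y$dbh_sdlog,
                   min_dbh = y$min_dbh, seed = y$seed)
}

#' Generate synthetic per-quadrat topography
#'
#' Smooth per-plot surfaces for elevation (m), slope (degrees), aspect
#' (degrees) and convexity (m), on the quadrat grid of a census. Elevation
#' combines a planar trend with a sinusoidal undulation; slope and
#' convexity derive from it with noise. Intended as covariate input for
#' [rda_marginal()] when no field topography is available.
#'
#' @param cns a [census()] object (only the plot table is used).
#' @param seed integer seed.
#' @return data frame `plot, cell_ix, cell_iy, elevation, slope, aspect,
#'   convexity`.
#' @export
generate_topography <- function(cns, seed = 1L) {
  stopifnot(inherits(cns, "census"))
  out <- lapply(seq_len(nrow(cns$plots)), function(i) {
    p <- cns$plots[i, ]
    set.seed(stream_seed(seed, "topography", p$plot))
    nx <- p$width / p$quadrat; ny <- p$height / p$quadrat
    g <- expand.grid(cell_ix = seq_len(nx) - 1L, cell_iy = seq_len(ny) - 1L)
    base <- stats::runif(1, 1500, 2000)
    ax <- stats::runif(1, -3, 3); ay <- stats::runif(1, -3, 3)
    elev <- base + ax * g$cell_ix + ay * g$cell_iy +
      8 * sin(g$cell_ix / 3) * cos(g$cell_iy / 4) + stats::rnorm(nrow(g), 0, 1)
    slope <- pmin(80, pmax(5, sqrt(ax^2 + ay^2) * 10 +
                             stats::rnorm(nrow(g), 40, 8)))
    aspect <- (atan2(ay, ax) * 180 / pi + stats::rnorm(nrow(g), 0, 30)) %% 360
    convex <- 8 * sin(g$cell_ix / 3) * cos(g$cell_iy / 4) / 4 +
      stats::rnorm(nrow(g), 0, 0.5)
    data.frame(plot = p$plot, g, elevation = elev, slope = slope,
               aspect = aspect, convexity = convex,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
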