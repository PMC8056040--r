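# Data model and I/O for stem-mapped censuses, quadrat gridding, and
# abundance filtering shared by every downstream analysis stage.

#' Construct a stem-mapped census
#'
#' A census couples a stem table (one row per tagged stem) with plot
#' descriptors. Coordinates are metric, 0-based, and half-open: a stem lies
#' in `[0, width)` x `[0, height)` within its plot. All stems must satisfy
#' the census DBH minimum (1 cm by default, the usual tagging threshold for
#' woody stems in forest dynamics plots).
#'
#' @param stems data frame with columns `stem_id`, `plot`, `species`,
#'   `life_form` (`"tree"` or `"shrub"`), `x`, `y` (meters), `dbh` (cm).
#' @param plots data frame with columns `plot`, `width`, `height` (meters)
#'   and `quadrat` (meters; must divide both dimensions). If `NULL`, one
#'   100 m x 100 m plot with 10 m quadrats is assumed per plot id present.
#' @param min_dbh minimum DBH (cm) a stem must reach to be tagged.
#' @return An object of class `"census"`: a list with elements `stems`,
#'   `plots`, `min_dbh`.
#' @examples
#' stems <- data.frame(stem_id = "s1", plot = "A", species = "sp1",
#'                     life_form = "tree", x = 5, y = 5, dbh = 10)
#' census(stems)
#' @export
census <- function(stems, plots = NULL, min_dbh = 1) {
  stems <- as.data.frame(stems)
  required <- c("stem_id", "plot", "species", "life_form", "x", "y", "dbh")
  missing_cols <- setdiff(required, names(stems))
  if (length(missing_cols) > 0L)
    stop("stem table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in c("plot", "species", "life_form", "stem_id"))
    stems[[col]] <- as.character(stems[[col]])
  if (is.null(plots)) {
    plots <- data.frame(plot = unique(stems$plot), width = 100, height = 100,
                        quadrat = 10, stringsAsFactors = FALSE)
  }
  plots <- as.data.frame(plots)
  stopifnot(all(c("plot", "width", "height", "quadrat") %in% names(plots)))
  plots$plot <- as.character(plots$plot)
  if (anyDuplicated(plots$plot))
    stop("duplicated plot id in plot table", call. = FALSE)
  bad_grid <- plots$width %% plots$quadrat != 0 | plots$height %% plots$quadrat != 0
  if (any(bad_grid))
    stop("plot dimensions must be integer multiples of the quadrat size: ",
         paste(plots$plot[bad_grid], collapse = ", "), call. = FALSE)
  obj <- structure(list(stems = stems, plots = plots, min_dbh = min_dbh),
                   class = "census")
  validate_census(obj)
  obj
}

validate_census <- function(x) {
  stems <- x$stems
  plots <- x$plots
  if (nrow(stems) == 0L) return(invisible(x))
  unknown <- !(stems$plot %in% plots$plot)
  pidx <- match(stems$plot, plots$plot)
  numeric_bad <- !is.finite(stems$x) | !is.finite(stems$y) | !is.finite(stems$dbh)
  oob <- !numeric_bad & !unknown &
    (stems$x < 0 | stems$x >= plots$width[pidx] |
     stems$y < 0 | stems$y >= plots$height[pidx])
  small <- !numeric_bad & stems$dbh < x$min_dbh
  bad_lf <- !(stems$life_form %in% c("tree", "shrub"))
  bad <- unknown | numeric_bad | oob | small | bad_lf
  if (any(bad)) {
    rows <- which(bad)
    why <- character(length(rows))
    why[unknown[rows]] <- "unknown plot id"
    why[numeric_bad[rows]] <- "non-numeric or non-finite coordinate/dbh"
    why[oob[rows]] <- "coordinate outside [0, width) x [0, height)"
    why[small[rows]] <- sprintf("dbh below census minimum (%g cm)", x$min_dbh)
    why[bad_lf[rows]] <- "life_form must be 'tree' or 'shrub'"
    msg <- paste(sprintf("  row %d: %s", rows, why), collapse = "\n")
    stop("invalid stem record(s):\n", msg, call. = FALSE)
  }
  invisible(x)
}

#' @export
print.census <- function(x, ...) {
  cat("Stem-mapped census:", nrow(x$stems), "stems,",
      length(unique(x$stems$species)), "species,",
      nrow(x$plots), "plot(s)\n")
  for (i in seq_len(nrow(x$plots))) {
    p <- x$plots[i, ]
    cat(sprintf("  %s: %g x %g m (quadrat %g m), %d stems\n", p$plot,
                p$width, p$height, p$quadrat, sum(x$stems$plot == p$plot)))
  }
  invisible(x)
}

#' Read a census from a delimited stem table
#'
#' Canonical dialect: comma-separated UTF-8 text with header
#' `stem_id,plot,species,life_form,x,y,dbh`. Rows violating the census
#' invariants are rejected with row-numbered diagnostics.
#'
#' @param path file path.
#' @param plots optional plot descriptor table (see [census()]).
#' @param min_dbh minimum DBH in cm (default 1).
#' @param sep field separator (default `","`).
#' @return A [census()] object.
#' @seealso [write_census()]
#' @export
read_census <- function(path, plots = NULL, min_dbh = 1, sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", stringsAsFactors = FALSE)
  required <- c("stem_id", "plot", "species", "life_form", "x", "y", "dbh")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L)
    stop("file ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) | is.na(raw[[col]]))
    if (length(bad) > 0L)
      stop("non-numeric ", col, " in data row(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    v
  }
  stems <- data.frame(stem_id = raw$stem_id, plot = raw$plot,
                      species = raw$species, life_form = raw$life_form,
                      x = num("x"), y = num("y"), dbh = num("dbh"),
                      stringsAsFactors = FALSE)
  census(stems, plots = plots, min_dbh = min_dbh)
}

#' Write a census in the canonical stem CSV dialect
#'
#' Numeric fields are printed with `%.17g` so that a written file, re-read
#' with [read_census()] and written again, is byte-identical.
#'
#' @param x a [census()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_census <- function(x, path) {
  stopifnot(inherits(x, "census"))
  s <- x$stems
  fmt <- function(v) sprintf("%.17g", v)
  lines <- c("stem_id,plot,species,life_form,x,y,dbh",
             paste(s$stem_id, s$plot, s$species, s$life_form,
                   fmt(s$x), fmt(s$y), fmt(s$dbh), sep = ","))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Grid stems into a species x quadrat abundance matrix
#'
#' Each stem at `(x, y)` is assigned to quadrat cell
#' `(floor(x / q), floor(y / q))` of its plot; cells are half-open so a
#' stem at exactly `y = 10` with `q = 10` falls in row 1, not row 0. The
#' matrix total always equals the number of stems.
#'
#' @param x a [census()] object.
#' @return An object of class `"quadrat_matrix"`: list with `abundance`
#'   (integer matrix, species rows x quadrat columns named `plot:ix:iy`),
#'   `quadrat_meta` (`plot`, `cell_ix`, `cell_iy` per column),
#'   `species_meta` (`species`, `life_form` per row) and `plots`.
#' @export
grid_stems <- function(x) {
  stopifnot(inherits(x, "census"))
  plots <- x$plots
  meta <- do.call(rbind, lapply(seq_len(nrow(plots)), function(i) {
    p <- plots[i, ]
    nx <- p$width / p$quadrat
    ny <- p$height / p$quadrat
    expand.grid(cell_ix = seq_len(nx) - 1L, cell_iy = seq_len(ny) - 1L,
                plot = p$plot, stringsAsFactors = FALSE)
  }))
  meta <- meta[, c("plot", "cell_ix", "cell_iy")]
  qid <- function(plot, ix, iy) paste(plot, ix, iy, sep = ":")
  col_ids <- qid(meta$plot, meta$cell_ix, meta$cell_iy)

  stems <- x$stems
  species <- sort(unique(stems$species))
  ab <- matrix(0L, nrow = length(species), ncol = nrow(meta),
               dimnames = list(species, col_ids))
  if (nrow(stems) > 0L) {
    q <- plots$quadrat[match(stems$plot, plots$plot)]
    sid <- qid(stems$plot, floor(stems$x / q), floor(stems$y / q))
    tab <- table(factor(stems$species, levels = species),
                 factor(sid, levels = col_ids))
    ab[] <- as.integer(tab)
  }
  lf <- species_life_forms(stems, species)
  structure(list(abundance = ab,
                 quadrat_meta = meta,
                 species_meta = data.frame(species = species, life_form = lf,
                                           stringsAsFactors = FALSE),
                 plots = plots),
            class = "quadrat_matrix")
}

# Majority life form per species; warns if a species is recorded under both.
species_life_forms <- function(stems, species) {
  if (length(species) == 0L) return(character(0))
  lf <- vapply(species, function(sp) {
    forms <- stems$life_form[stems$species == sp]
    tab <- sort(table(forms), decreasing = TRUE)
    if (length(tab) > 1L)
      warning("species ", sp, " recorded under multiple life forms; using '",
              names(tab)[1L], "'", call. = FALSE)
    names(tab)[1L]
  }, character(1))
  unname(lf)
}

#' @export
print.quadrat_matrix <- function(x, ...) {
  cat("Quadrat abundance matrix:", nrow(x$abundance), "species x",
      ncol(x$abundance), "quadrats;", sum(x$abundance), "stems\n")
  invisible(x)
}

#' Drop species below a minimum total abundance
#'
#' Habitat-association tests are restricted to species with enough
#' individuals for the null distribution to be informative; the
#' conventional cut is "more than four individuals", i.e. a total of at
#' least 5 stems across the census.
#'
#' @param qm a [grid_stems()] quadrat matrix.
#' @param min_n minimum total abundance to retain a species (default 5).
#' @return A `"quadrat_matrix"` restricted to the retained species.
#' @export
filter_min_abundance <- function(qm, min_n = 5) {
  stopifnot(inherits(qm, "quadrat_matrix"), min_n >= 1)
  keep <- rowSums(qm$abundance) >= min_n
  qm$abundance <- qm$abundance[keep, , drop = FALSE]
  qm$species_meta <- qm$species_meta[keep, , drop = FALSE]
  rownames(qm$species_meta) <- NULL
  qm
}

#' Write a quadrat matrix as wide CSV
#'
#' @param qm a quadrat matrix.
#' @param path output path. Columns are quadrats named `plot:ix:iy`; the
#'   first two columns carry species and life form.
#' @return `path`, invisibly.
#' @export
write_quadrat_matrix <- function(qm, path) {
  stopifnot(inherits(qm, "quadrat_matrix"))
  out <- cbind(qm$species_meta, as.data.frame(qm$abundance, check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
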