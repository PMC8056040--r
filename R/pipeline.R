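# Orchestration and reporting: parse compact association strings,
# summarize association tables into headline counts and percentages, and
# run the full analysis from one YAML configuration.

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Parse compact association strings into a long association table
#'
#' Turns rows like `species = "X", association = "B(+) D(-)"` into one
#' row per significant species x habitat pair, keeping species with no
#' association (`NA`) so they still count as tested.
#'
#' @param df data frame with columns `species`, `life_form`,
#'   `association` (`NA` or space-separated `habitat(+)` / `habitat(-)`
#'   terms; an en-dash is accepted as minus).
#' @return data frame of class `"association_table"`: `species`,
#'   `life_form`, `habitat`, `class` (`positive` / `negative` / `none`;
#'   `habitat` is `NA` on `none` rows).
#' @export
parse_associations <- function(df) {
  df <- as.data.frame(df)
  stopifnot(all(c("species", "life_form", "association") %in% names(df)))
  rows <- lapply(seq_len(nrow(df)), function(i) {
    a <- df$association[i]
    if (is.na(a) || a %in% c("", "NA"))
      return(data.frame(species = df$species[i],
                        life_form = df$life_form[i],
                        habitat = NA_character_, class = "none",
                        stringsAsFactors = FALSE))
    a <- gsub("–", "-", a)  # en-dash used for minus in print
    terms <- strsplit(trimws(a), "[[:space:]]+")[[1]]
    m <- regmatches(terms, regexec("^(.+)\\(([+-])\\)$", terms))
    if (any(vapply(m, length, 1L) != 3L))
      stop("cannot parse association string: ", df$association[i],
           call. = FALSE)
    data.frame(species = df$species[i], life_form = df$life_form[i],
               habitat = vapply(m, `[`, "", 2L),
               class = ifelse(vapply(m, `[`, "", 3L) == "+",
                              "positive", "negative"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("association_table", "data.frame")
  out
}

#' Published species-community association classifications
#'
#' A transcription of the published significance table of a four-plot
#' temperate deciduous forest census (57 woody species tested by
#' torus-translation against plantation (A), twice-cut (B), once-cut (C)
#' and old-growth (D) communities), shipped with the package so the
#' reporting logic can be exercised against printed results without the
#' raw census.
#'
#' @return a parsed association table (see [parse_associations()]).
#' @export
published_associations <- function() {
  path <- system.file("extdata", "published_associations.csv",
                      package = "forestspec", mustWork = TRUE)
  parse_associations(utils::read.csv(path, stringsAsFactors = FALSE,
                                     na.strings = "NA"))
}

#' Summarize an association table into headline counts
#'
#' Pairs count every significant species x habitat association
#' separately; species-level counts collapse per species. The percentage
#' `pct_pairs_over_species = 100 * n_pairs_significant /
#' n_species_tested` follows the convention of reporting the pair count
#' over the number of species tested. Percentages are rounded half-up to
#' 2 decimals. All counts are replicated per life form.
#'
#' @param at an association table from [torus_test()] or
#'   [parse_associations()].
#' @return object of class `"association_summary"`: list with `overall`,
#'   `tree`, `shrub`, each holding `n_species_tested`,
#'   `n_pairs_significant`, `n_pairs_positive`, `n_pairs_negative`,
#'   `n_species_with_any`, `n_species_positive`, `n_species_negative`,
#'   `n_species_dual`, `pct_pairs_over_species`,
#'   `pct_species_with_any`.
#' @export
summarize_associations <- function(at) {
  at <- as.data.frame(at)
  stopifnot(all(c("species", "life_form", "class") %in% names(at)))
  count_block <- function(sub) {
    sig <- sub[sub$class %in% c("positive", "negative"), , drop = FALSE]
    sp <- unique(sub$species)
    by_sp <- split(sig$class, factor(sig$species, levels = sp))
    n_any <- sum(vapply(by_sp, length, 1L) > 0L)
    n_dual <- sum(vapply(by_sp, length, 1L) >= 2L)
    n_tested <- length(sp)
    list(n_species_tested = n_tested,
         n_pairs_significant = nrow(sig),
         n_pairs_positive = sum(sig$class == "positive"),
         n_pairs_negative = sum(sig$class == "negative"),
         n_species_with_any = n_any,
         n_species_positive = sum(vapply(by_sp, function(v)
           any(v == "positive"), logical(1))),
         n_species_negative = sum(vapply(by_sp, function(v)
           any(v == "negative"), logical(1))),
         n_species_dual = n_dual,
         pct_pairs_over_species = if (n_tested > 0)
           round_half_up(100 * nrow(sig) / n_tested) else 0,
         pct_species_with_any = if (n_tested > 0)
           round_half_up(100 * n_any / n_tested) else 0)
  }
  out <- list(overall = count_block(at),
              tree = count_block(at[at$life_form == "tree", , drop = FALSE]),
              shrub = count_block(at[at$life_form == "shrub", , drop = FALSE]))
  class(out) <- "association_summary"
  out
}

#' @export
print.association_summary <- function(x, ...) {
  for (nm in names(x)) {
    b <- x[[nm]]
    cat(sprintf(
      "%s: %d/%d species with associations (%.2f%%); %d pairs (%d +, %d -), %d dual\n",
      nm, b$n_species_with_any, b$n_species_tested, b$pct_species_with_any,
      b$n_pairs_significant, b$n_pairs_positive, b$n_pairs_negative,
      b$n_species_dual))
  }
  invisible(x)
}

#' Run the full analysis pipeline from one configuration
#'
#' Executes the stages in dependency order on a synthetic census (or a
#' census CSV) and writes each stage's outputs under `out_dir`, together
#' with a JSON metadata record (config hash, seed, package version) and
#' a plain-text log of every stage's parameters.
#'
#' Config (YAML file or equivalent list) keys: `census_csv` (path) or
#' `synthetic` (`seed`, optional `fold`), `stages` (subset of
#' `simulate, grid, metrics, dispersion, rda, network, torus, indval,
#' pcf, summarize`; default all), `alpha`, `n_perm`, `min_abundance`.
#'
#' @param config path to a YAML file, or a list with the same structure.
#' @param out_dir output directory (created if missing).
#' @return named list of output file paths, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg_hash <- NA_character_
  if (is.character(config)) {
    cfg_hash <- unname(tools::md5sum(config))
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  stages_all <- c("simulate", "grid", "metrics", "dispersion", "rda",
                  "network", "torus", "indval", "pcf", "summarize")
  stages <- if (is.null(config$stages)) stages_all else config$stages
  unknown <- setdiff(stages, stages_all)
  if (length(unknown) > 0L)
    stop("unknown stage(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  alpha <- if (is.null(config$alpha)) 0.05 else config$alpha
  n_perm <- if (is.null(config$n_perm)) 199 else config$n_perm
  min_ab <- if (is.null(config$min_abundance)) 5 else config$min_abundance
  seed <- if (!is.null(config$synthetic$seed)) config$synthetic$seed else 1L

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  say <- function(stage, ...) writeLines(sprintf("[%s] %s", stage,
                                                 paste0(...)), log_con)
  outputs <- list()
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    outputs[[name]] <<- path
    path
  }

  # --- census -------------------------------------------------------
  if ("simulate" %in% stages && is.null(config$census_csv)) {
    sc <- study_config(seed = seed,
                       fold = if (is.null(config$synthetic$fold)) 6
                              else config$synthetic$fold)
    cns <- generate_census(sc)
    say("simulate", sprintf("seed=%d fold=%g stems=%d", seed,
                            if (is.null(config$synthetic$fold)) 6
                            else config$synthetic$fold, nrow(cns$stems)))
    emit("census.csv", function(p) write_census(cns, p))
  } else if (!is.null(config$census_csv)) {
    cns <- read_census(config$census_csv)
    say("read", sprintf("census_csv=%s stems=%d", config$census_csv,
                        nrow(cns$stems)))
  } else {
    stop("config must provide a census: enable stage 'simulate' or set ",
         "'census_csv'", call. = FALSE)
  }

  qm <- NULL
  if (any(c("grid", "metrics", "dispersion", "rda", "network", "torus",
            "indval", "summarize") %in% stages)) {
    qm <- grid_stems(cns)
    say("grid", sprintf("%d species x %d quadrats", nrow(qm$abundance),
                        ncol(qm$abundance)))
    if ("grid" %in% stages)
      emit("quadrat_matrix.csv", function(p) write_quadrat_matrix(qm, p))
  }

  if ("metrics" %in% stages) {
    iv <- do.call(rbind, lapply(cns$plots$plot, function(cm)
      importance_values(qm, cns, cm)))
    emit("importance_values.csv", function(p)
      utils::write.csv(iv, p, row.names = FALSE))
    acc <- do.call(rbind, lapply(cns$plots$plot, function(cm)
      cbind(community = cm, species_accumulation(qm, cm))))
    emit("species_accumulation.csv", function(p)
      utils::write.csv(acc, p, row.names = FALSE))
    by_plot_quadrat <- function(fun) lapply(
      stats::setNames(cns$plots$plot, cns$plots$plot), function(cm) {
        sub <- qm$abundance[, qm$quadrat_meta$plot == cm, drop = FALSE]
        fun(sub)
      })
    kw <- list(
      abundance = kruskal_wallis(by_plot_quadrat(colSums)),
      richness = kruskal_wallis(by_plot_quadrat(function(m) colSums(m > 0))))
    ov <- occurrence_overlap(qm)
    emit("community_tests.json", function(p)
      jsonlite::write_json(list(kruskal_wallis = kw,
                                overlap = list(
                                  subset_counts = as.list(ov$subset_counts),
                                  n_at_least = as.list(ov$n_at_least),
                                  n_species = ov$n_species)),
                           p, auto_unbox = TRUE, digits = NA))
    say("metrics", sprintf("kw_abundance_p=%.4g kw_richness_p=%.4g",
                           kw$abundance$p, kw$richness$p))
  }

  if ("dispersion" %in% stages) {
    d <- bray_curtis(qm)
    disp <- betadisper_test(d, n_perm = n_perm, seed = seed)
    emit("dispersion_distances.csv", function(p)
      utils::write.csv(disp$distances, p, row.names = FALSE))
    say("dispersion", sprintf("F=%.4f p_anova=%.4g p_perm=%.4g n_perm=%d",
                              disp$f_stat, disp$p_anova, disp$p_perm,
                              n_perm))
  }

  if ("rda" %in% stages) {
    topo <- if (!is.null(config$topography_csv))
      utils::read.csv(config$topography_csv, stringsAsFactors = FALSE)
    else generate_topography(cns, seed = seed)
    rda <- rda_marginal(qm, topo, n_perm = n_perm, seed = seed)
    emit("rda_marginal.csv", function(p)
      utils::write.csv(rda, p, row.names = FALSE))
    say("rda", paste(sprintf("%s=%.2f%%", rda$covariate, rda$explained_pct),
                     collapse = " "))
  }

  if ("network" %in% stages) {
    nets <- list(overall = build_network(qm),
                 tree = build_network(qm, species = qm$species_meta$species[
                   qm$species_meta$life_form == "tree"]),
                 shrub = build_network(qm, species = qm$species_meta$species[
                   qm$species_meta$life_form == "shrub"]))
    net_stats <- lapply(nets, function(nw) {
      b <- h2_bounds(nw)
      list(h2prime = as.numeric(h2prime(nw)),
           connectance = connectance(nw),
           H2 = h2_entropy(nw), H2min = b[["H2min"]], H2max = b[["H2max"]])
    })
    emit("network.json", function(p)
      jsonlite::write_json(net_stats, p, auto_unbox = TRUE, digits = NA))
    emit("network_edges.csv", function(p)
      utils::write.csv(network_edge_list(nets$overall), p,
                       row.names = FALSE))
    say("network", sprintf("H2prime=%.4f connectance=%.4f",
                           net_stats$overall$h2prime,
                           net_stats$overall$connectance))
  }

  at <- NULL
  if ("torus" %in% stages) {
    map <- build_combined_map(cns)
    at <- torus_test(filter_min_abundance(qm, min_ab), map, alpha = alpha)
    emit("associations.csv", function(p)
      utils::write.csv(as.data.frame(at), p, row.names = FALSE))
    emit("associations_signs.csv", function(p)
      utils::write.csv(format_associations(at), p, row.names = FALSE))
    say("torus", sprintf("alpha=%g n_maps=%d species=%d min_abundance=%g",
                         alpha, attr(at, "n_maps"),
                         length(unique(at$species)), min_ab))
  }

  if ("indval" %in% stages) {
    iv_res <- indval(filter_min_abundance(qm, min_ab), n_perm = n_perm,
                     seed = seed)
    emit("indval.csv", function(p)
      utils::write.csv(iv_res, p, row.names = FALSE))
    say("indval", sprintf("n_perm=%d n_species=%d", n_perm, nrow(iv_res)))
  }

  if ("pcf" %in% stages) {
    # univariate g(r) with a CSR envelope for the most abundant species
    top <- names(sort(table(cns$stems$species), decreasing = TRUE))[1]
    pts <- cns$stems[cns$stems$species == top &
                       cns$stems$plot == cns$plots$plot[1], c("x", "y")]
    if (nrow(pts) >= 10) {
      set.seed(seed)
      env <- mc_envelope(pts, window = c(cns$plots$width[1],
                                         cns$plots$height[1]),
                         n_sim = 199, coverage = 0.99)
      emit("pcf_top_species.csv", function(p)
        utils::write.csv(cbind(species = top, as.data.frame(env)), p,
                         row.names = FALSE))
      say("pcf", sprintf("species=%s n=%d n_sim=199 coverage=0.99", top,
                         nrow(pts)))
    } else {
      say("pcf", "skipped: fewer than 10 stems of the top species in plot 1")
    }
  }

  if ("summarize" %in% stages) {
    if (is.null(at))
      stop("stage 'summarize' needs the association table; enable stage ",
           "'torus' (its producing stage) in the config", call. = FALSE)
    summ <- summarize_associations(at)
    emit("association_summary.json", function(p)
      jsonlite::write_json(unclass(summ), p, auto_unbox = TRUE,
                           digits = NA))
    say("summarize", sprintf("pairs=%d species_with_any=%d/%d",
                             summ$overall$n_pairs_significant,
                             summ$overall$n_species_with_any,
                             summ$overall$n_species_tested))
  }

  meta <- list(config_hash = cfg_hash, seed = seed, alpha = alpha,
               n_perm = n_perm, min_abundance = min_ab, stages = stages,
               package_version = as.character(utils::packageVersion(
                 "forestspec")),
               r_version = as.character(getRversion()))
  meta_path <- file.path(out_dir, "run_metadata.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  outputs[["run_metadata.json"]] <- meta_path
  invisible(outputs)
}
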