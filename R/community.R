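# Per-community composition summaries: importance values, exact
# sample-based species accumulation, Kruskal-Wallis comparisons, and
# occurrence-overlap (Venn) counts.

#' Importance values for one community
#'
#' The importance value of a species in a community is
#' `IV = (relative abundance % + relative frequency % + relative basal
#' area %) / 3`, a 0-100 dominance score. Relative frequency uses the
#' number of occupied quadrats, with the sum of occupied-quadrat counts
#' over species as denominator, so each component sums to 100% within the
#' community and the IVs themselves sum to 100.
#'
#' Basal area is the breast-height sectional area `sum(pi * (dbh/2)^2)`
#' per species; it is reported both in cm^2 and m^2.
#'
#' @param qm a [grid_stems()] quadrat matrix.
#' @param cns the [census()] the matrix was gridded from (for DBH).
#' @param community plot id of the community to summarize.
#' @return data frame with one row per species present: `species`,
#'   `community`, `life_form`, `abundance`, `n_quadrats`, `mean_dbh`,
#'   `basal_area_cm2`, `basal_area_m2`, `rel_abundance`, `rel_frequency`,
#'   `rel_basal_area` (percent), `iv`.
#' @export
importance_values <- function(qm, cns, community) {
  stopifnot(inherits(qm, "quadrat_matrix"), inherits(cns, "census"))
  in_comm <- qm$quadrat_meta$plot == community
  if (!any(in_comm))
    stop("unknown community: ", community, call. = FALSE)
  sub <- qm$abundance[, in_comm, drop = FALSE]
  abund <- rowSums(sub)
  present <- abund > 0
  if (!any(present))
    stop("community ", community, " holds no stems", call. = FALSE)
  sub <- sub[present, , drop = FALSE]
  abund <- abund[present]
  n_quad <- rowSums(sub > 0)
  stems <- cns$stems[cns$stems$plot == community, ]
  ba <- vapply(rownames(sub), function(sp) {
    d <- stems$dbh[stems$species == sp]
    sum(pi * (d / 2)^2)
  }, numeric(1))
  mean_dbh <- vapply(rownames(sub), function(sp)
    mean(stems$dbh[stems$species == sp]), numeric(1))
  rel_ab <- 100 * abund / sum(abund)
  rel_fr <- 100 * n_quad / sum(n_quad)
  rel_ba <- 100 * ba / sum(ba)
  out <- data.frame(
    species = rownames(sub), community = community,
    life_form = qm$species_meta$life_form[present],
    abundance = abund, n_quadrats = n_quad, mean_dbh = mean_dbh,
    basal_area_cm2 = ba, basal_area_m2 = ba / 1e4,
    rel_abundance = rel_ab, rel_frequency = rel_fr, rel_basal_area = rel_ba,
    iv = (rel_ab + rel_fr + rel_ba) / 3,
    stringsAsFactors = FALSE)
  out <- out[order(-out$iv), ]
  rownames(out) <- NULL
  out
}

#' Exact sample-based species accumulation curve
#'
#' Expected richness when `n` of the `T` quadrats are drawn without
#' replacement, computed analytically:
#' `E[S(n)] = S_obs - sum_i C(T - T_i, n) / C(T, n)` where `T_i` is the
#' number of quadrats occupied by species `i`. The standard deviation
#' comes from the same hypergeometric model including between-species
#' covariances. Binomial coefficients are evaluated in log space.
#'
#' @param qm a quadrat matrix.
#' @param communities optional plot ids; restricts sites to those plots.
#' @return data frame of class `"accumulation_curve"`: `n_sites`,
#'   `mean_richness`, `sd_richness` for `n = 1..T`.
#' @export
species_accumulation <- function(qm, communities = NULL) {
  stopifnot(inherits(qm, "quadrat_matrix"))
  ab <- qm$abundance
  if (!is.null(communities)) {
    keep <- qm$quadrat_meta$plot %in% communities
    if (!any(keep)) stop("no quadrats in the requested communities",
                         call. = FALSE)
    ab <- ab[, keep, drop = FALSE]
  }
  occ <- ab > 0
  occ <- occ[rowSums(occ) > 0, , drop = FALSE]
  Tt <- ncol(occ)
  if (Tt < 1L) stop("need at least one site", call. = FALSE)
  Ti <- rowSums(occ)
  S <- length(Ti)
  # u_ij = number of sites occupied by species i OR j
  joint <- tcrossprod(occ * 1)          # sites occupied by both
  U <- outer(Ti, Ti, "+") - joint
  lchoose_safe <- function(a, n) ifelse(a >= n, lchoose(a, n), -Inf)
  mean_s <- numeric(Tt); sd_s <- numeric(Tt)
  for (n in seq_len(Tt)) {
    lq <- lchoose_safe(Tt - Ti, n) - lchoose(Tt, n)
    q <- exp(lq)                         # P(species i absent from n sites)
    mean_s[n] <- S - sum(q)
    qij <- exp(lchoose_safe(Tt - U, n) - lchoose(Tt, n))
    v <- sum(qij - outer(q, q))          # includes diagonal q_i - q_i^2
    sd_s[n] <- sqrt(max(0, v))
  }
  structure(data.frame(n_sites = seq_len(Tt), mean_richness = mean_s,
                       sd_richness = sd_s),
            class = c("accumulation_curve", "data.frame"))
}

#' Kruskal-Wallis rank test across groups
#'
#' Rank-based H statistic with tie correction and a chi-square reference
#' distribution on `groups - 1` degrees of freedom. The fully degenerate
#' case (every pooled value identical) is reported as `H = 0`, `p = 1`
#' rather than the 0/0 the tie correction would produce.
#'
#' @param samples named list of numeric vectors, one per group.
#' @return list with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(samples) {
  stopifnot(is.list(samples), length(samples) >= 2L)
  if (any(vapply(samples, length, 1L) < 1L))
    stop("every group needs at least one value", call. = FALSE)
  values <- unlist(samples, use.names = FALSE)
  groups <- factor(rep(seq_along(samples), vapply(samples, length, 1L)))
  if (length(unique(values)) == 1L)
    return(list(H = 0, df = length(samples) - 1L, p = 1))
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Occurrence overlap among communities
#'
#' Classifies each species by the exact set of communities it occurs in
#' (total abundance > 0) and tabulates all `2^C - 1` non-empty subsets,
#' plus the number of species present in at least `k` communities.
#'
#' @param qm a quadrat matrix with community (plot) labels on quadrats.
#' @return list with `subset_counts` (named integer vector, subset labels
#'   joined by `&`), `n_at_least` (named vector, species in >= k
#'   communities), `n_species`, and `membership` (logical species x
#'   community matrix).
#' @export
occurrence_overlap <- function(qm) {
  stopifnot(inherits(qm, "quadrat_matrix"))
  comms <- unique(qm$quadrat_meta$plot)
  pres <- vapply(comms, function(cm)
    rowSums(qm$abundance[, qm$quadrat_meta$plot == cm, drop = FALSE]) > 0,
    logical(nrow(qm$abundance)))
  pres <- matrix(pres, nrow = nrow(qm$abundance),
                 dimnames = list(rownames(qm$abundance), comms))
  C <- length(comms)
  subsets <- unlist(lapply(seq_len(C), function(k)
    utils::combn(comms, k, simplify = FALSE)), recursive = FALSE)
  labels <- vapply(subsets, paste, character(1), collapse = "&")
  counts <- vapply(subsets, function(ss) {
    inside <- rowSums(pres[, ss, drop = FALSE]) == length(ss)
    outside <- rowSums(pres[, setdiff(comms, ss), drop = FALSE]) == 0
    sum(inside & outside)
  }, integer(1))
  names(counts) <- labels
  n_comm <- rowSums(pres)
  n_at_least <- vapply(seq_len(C), function(k) sum(n_comm >= k), integer(1))
  names(n_at_least) <- paste0(">=", seq_len(C))
  list(subset_counts = counts, n_at_least = n_at_least,
       n_species = nrow(pres), membership = pres)
}
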