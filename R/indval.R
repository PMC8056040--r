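# IndVal indicator-species analysis: for each species and site group,
# specificity A (how concentrated the species' abundance is in the
# group) times fidelity B (how consistently it occurs there), tested by
# permuting group labels across sites.

#' Indicator species analysis (IndVal) with permutation p-values
#'
#' For species `s` and group `g`:
#' `A_gs = mean abundance of s in g / sum over groups of mean abundances`
#' (group-size equalized; with `equalized = FALSE` group sums are used
#' instead of means), `B_gs = fraction of sites in g occupied by s`, and
#' `IndVal_gs = sqrt(A_gs * B_gs)`. Each species is assigned its best
#' group (largest IndVal) and that maximum is tested by permuting the
#' site group labels: `p = (1 + #[perm >= observed]) / (n_perm + 1)`.
#' With `exact = TRUE` all distinct arrangements of the label vector are
#' enumerated instead and `p` is the exact tail fraction (including the
#' observed arrangement).
#'
#' @param qm a quadrat matrix; sites are quadrats.
#' @param groups group label per site (default: the quadrat's plot).
#' @param n_perm number of random permutations (default 999).
#' @param seed optional permutation seed.
#' @param equalized use group-equalized specificity (default TRUE).
#' @param exact enumerate all distinct label arrangements (feasible only
#'   for a handful of sites; guarded at 5000 arrangements).
#' @param p_adjust multiplicity correction passed to
#'   [stats::p.adjust()] (default `"none"`, reporting raw per-species
#'   p-values for the best group only).
#' @return data frame of class `"indval_result"`: `species`,
#'   `life_form`, `best_group`, `A`, `B`, `indval`, `p`.
#' @export
indval <- function(qm, groups = NULL, n_perm = 999, seed = NULL,
                   equalized = TRUE, exact = FALSE, p_adjust = "none") {
  stopifnot(inherits(qm, "quadrat_matrix"))
  if (is.null(groups)) groups <- qm$quadrat_meta$plot
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(qm$abundance), n_perm >= 1)
  ab <- qm$abundance
  empty <- rowSums(ab) == 0
  if (any(empty)) {
    warning(sum(empty), " species absent everywhere excluded",
            call. = FALSE)
    ab <- ab[!empty, , drop = FALSE]
  }
  if (nrow(ab) == 0L) stop("no species to analyze", call. = FALSE)
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least two groups", call. = FALSE)

  stat_of <- function(glab) {
    M <- stats::model.matrix(~ glab - 1)          # sites x groups
    sizes <- colSums(M)
    totals <- ab %*% M                            # species x groups sums
    spec <- if (equalized) sweep(totals, 2, sizes, "/") else totals
    A <- spec / rowSums(spec)
    B <- sweep((ab > 0) %*% M, 2, sizes, "/")
    iv <- sqrt(A * B)
    best <- max.col(iv, ties.method = "first")
    list(stat = iv[cbind(seq_len(nrow(iv)), best)], best = best,
         A = A[cbind(seq_len(nrow(iv)), best)],
         B = B[cbind(seq_len(nrow(iv)), best)])
  }
  obs <- stat_of(g)
  eps <- 1e-12
  if (exact) {
    arr <- distinct_permutations(g)
    if (is.null(arr))
      stop("too many distinct label arrangements for exact enumeration",
           call. = FALSE)
    stats_mat <- vapply(arr, function(a) stat_of(a)$stat,
                        numeric(nrow(ab)))
    p <- rowMeans(stats_mat >= obs$stat - eps)
  } else {
    if (!is.null(seed)) set.seed(seed)
    ge <- replicate(n_perm, stat_of(sample(g))$stat >= obs$stat - eps)
    ge <- matrix(ge, nrow = nrow(ab))
    p <- (rowSums(ge) + 1) / (n_perm + 1)
  }
  p <- stats::p.adjust(p, method = p_adjust)
  lf <- qm$species_meta$life_form[match(rownames(ab),
                                        qm$species_meta$species)]
  out <- data.frame(species = rownames(ab), life_form = lf,
                    best_group = levels(g)[obs$best],
                    A = obs$A, B = obs$B, indval = obs$stat, p = p,
                    stringsAsFactors = FALSE)
  out <- out[order(out$best_group, out$p, -out$indval), ]
  rownames(out) <- NULL
  class(out) <- c("indval_result", "data.frame")
  out
}

# All distinct arrangements of a factor's label multiset, or NULL when
# there are more than 5000.
distinct_permutations <- function(g, cap = 5000) {
  n <- length(g)
  counts <- table(g)
  n_arr <- exp(lgamma(n + 1) - sum(lgamma(counts + 1)))
  if (n_arr > cap + 0.5) return(NULL)
  lev <- levels(g)
  rec <- function(remaining, acc) {
    if (length(acc) == n) return(list(factor(acc, levels = lev)))
    out <- list()
    for (l in lev[remaining > 0]) {
      r2 <- remaining
      r2[l] <- r2[l] - 1L
      out <- c(out, rec(r2, c(acc, l)))
    }
    out
  }
  rem <- stats::setNames(as.integer(counts), names(counts))
  rec(rem, character(0))
}
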