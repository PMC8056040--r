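# Composition-dissimilarity analyses: Bray-Curtis distances, principal
# coordinates, multivariate dispersion (distances to group centroids in
# the PCoA embedding, with ANOVA and permutation tests), and marginal
# redundancy analysis of topographic covariates.

#' Bray-Curtis dissimilarity between quadrats
#'
#' `d(a, b) = sum|a_i - b_i| / sum(a_i + b_i)` over species. A pair of
#' quadrats that are both empty has an undefined quotient; it is defined
#' here as 0 (identical emptiness) with a warning.
#'
#' @param qm a quadrat matrix (quadrats become the objects compared).
#' @return a `stats::dist` object labeled by quadrat id, with the
#'   community (plot) of each quadrat attached as attribute `"groups"`.
#' @export
bray_curtis <- function(qm) {
  stopifnot(inherits(qm, "quadrat_matrix"))
  comm <- t(qm$abundance)
  d <- suppressWarnings(vegan::vegdist(comm, method = "bray"))
  if (anyNA(d)) {
    warning("both-empty quadrat pair(s): dissimilarity defined as 0",
            call. = FALSE)
    d[is.na(d)] <- 0
  }
  attr(d, "groups") <- stats::setNames(qm$quadrat_meta$plot,
                                       colnames(qm$abundance))
  d
}

#' Principal coordinates analysis
#'
#' Classical scaling of a dissimilarity matrix: the Gower-centered matrix
#' `-(1/2) J D^2 J` is eigendecomposed; axes are ordered by descending
#' eigenvalue. Negative eigenvalues (present whenever the dissimilarity
#' is non-Euclidean, as Bray-Curtis usually is) are retained and their
#' axes reported separately as imaginary coordinates scaled by
#' `sqrt(-lambda)`.
#'
#' @param d a `dist` object or square symmetric matrix of dissimilarities.
#' @return list with `coords` (n x p real coordinates), `imag_coords`
#'   (n x q imaginary-axis coordinates), `eigenvalues` (all, descending),
#'   `labels`.
#' @export
pcoa <- function(d) {
  m <- as.matrix(d)
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
    stop("dissimilarity matrix must be symmetric", call. = FALSE)
  n <- nrow(m)
  A <- -0.5 * m^2
  G <- A - rowMeans(A)
  G <- t(t(G) - colMeans(G))  # double centering (row means of A reused)
  G <- (G + t(G)) / 2
  e <- eigen(G, symmetric = TRUE)
  lam <- e$values
  tol <- max(abs(lam)) * 1e-9
  pos <- which(lam > tol)
  neg <- which(lam < -tol)
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(lam[pos]), length(pos))
  imag <- e$vectors[, neg, drop = FALSE] %*%
    diag(sqrt(-lam[neg]), length(neg))
  labels <- rownames(m)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  rownames(coords) <- labels
  if (ncol(coords) > 0) colnames(coords) <- paste0("PCoA", seq_len(ncol(coords)))
  rownames(imag) <- labels
  list(coords = coords, imag_coords = imag, eigenvalues = lam,
       labels = labels)
}

#' Multivariate dispersion test (betadisper-style)
#'
#' Embeds the dissimilarity matrix by [pcoa()], computes each object's
#' distance to its group centroid combining real and imaginary axes as
#' `z = sqrt(max(0, d_real^2 - d_imag^2))`, and tests whether mean
#' distances differ among groups by one-way ANOVA on `z`, optionally with
#' a permutation p-value obtained by shuffling group labels of the
#' distances.
#'
#' @param d dissimilarity (`dist` or symmetric matrix). If produced by
#'   [bray_curtis()], its `"groups"` attribute is the default grouping.
#' @param groups group label per object; groups of size 1 are excluded
#'   with a warning.
#' @param n_perm permutations for the permutation p (0 to skip).
#' @param seed optional seed for the permutation stream.
#' @return object of class `"dispersion_result"`: list with `distances`
#'   (data frame `label`, `group`, `dist`), `f_stat`, `df`, `p_anova`,
#'   `p_perm`, `pcoa`, `group_means`.
#' @export
betadisper_test <- function(d, groups = attr(d, "groups"), n_perm = 999,
                            seed = NULL) {
  m <- as.matrix(d)
  if (is.null(groups)) stop("group labels required", call. = FALSE)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(m))
  sizes <- table(groups)
  singles <- names(sizes)[sizes < 2]
  if (length(singles) > 0L) {
    warning("excluding group(s) of size 1: ",
            paste(singles, collapse = ", "), call. = FALSE)
    keep <- !(groups %in% singles)
    m <- m[keep, keep, drop = FALSE]
    groups <- groups[keep]
  }
  if (length(unique(groups)) < 2L)
    stop("need at least two groups with >= 2 members", call. = FALSE)
  pc <- pcoa(m)
  z <- centroid_distances(pc, groups)
  g <- factor(groups)
  fit <- stats::lm(z ~ g)
  an <- stats::anova(fit)
  f_obs <- an$`F value`[1]
  p_anova <- an$`Pr(>F)`[1]
  p_perm <- NA_real_
  if (n_perm > 0L) {
    if (!is.null(seed)) set.seed(seed)
    f_of <- function(zz, gg) {
      mu <- tapply(zz, gg, mean)
      nk <- tabulate(gg)
      ssb <- sum(nk * (mu - mean(zz))^2)
      ssw <- sum((zz - mu[as.integer(gg)])^2)
      dfb <- nlevels(gg) - 1L
      dfw <- length(zz) - nlevels(gg)
      (ssb / dfb) / (ssw / dfw)
    }
    f_null <- replicate(n_perm, f_of(sample(z), g))
    p_perm <- (sum(f_null >= f_obs - 1e-12) + 1) / (n_perm + 1)
  }
  structure(list(
    distances = data.frame(label = pc$labels, group = groups, dist = z,
                           stringsAsFactors = FALSE),
    f_stat = f_obs, df = unname(an$Df[1:2]), p_anova = p_anova,
    p_perm = p_perm, pcoa = pc,
    group_means = tapply(z, groups, mean)),
    class = "dispersion_result")
}

# Distance of each point to its group centroid, combining real axes
# positively and imaginary axes negatively (the standard PERMDISP
# treatment of non-Euclidean embeddings).
centroid_distances <- function(pc, groups) {
  dist2_to_centroid <- function(X) {
    if (ncol(X) == 0L) return(numeric(nrow(X)))
    ctr <- colMeans(X)
    rowSums((X - matrix(ctr, nrow(X), ncol(X), byrow = TRUE))^2)
  }
  z <- numeric(length(groups))
  for (gname in unique(groups)) {
    idx <- groups == gname
    d_real2 <- dist2_to_centroid(pc$coords[idx, , drop = FALSE])
    d_imag2 <- dist2_to_centroid(pc$imag_coords[idx, , drop = FALSE])
    z[idx] <- sqrt(pmax(0, d_real2 - d_imag2))
  }
  z
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat("Multivariate dispersion (distances to group centroids)\n")
  print(round(x$group_means, 4))
  cat(sprintf("ANOVA F(%d, %d) = %.4f, p = %.4g", x$df[1], x$df[2],
              x$f_stat, x$p_anova))
  if (!is.na(x$p_perm)) cat(sprintf(", permutation p = %.4g", x$p_perm))
  cat("\n")
  invisible(x)
}

#' Marginal redundancy analysis of topographic covariates
#'
#' For each covariate alone, regresses every (centered) species column of
#' the quadrat matrix on the covariate and reports the explained fraction
#' of total species variance, `100 * SS(fitted) / SS(total)`, with a
#' permutation p-value obtained by shuffling the covariate across
#' quadrats. Aspect (circular, degrees) is expanded internally to its
#' sine and cosine.
#'
#' @param qm a quadrat matrix.
#' @param topo data frame `plot, cell_ix, cell_iy` plus covariate columns
#'   (e.g. `elevation`, `slope`, `aspect`, `convexity`), one row per
#'   quadrat (see [generate_topography()]).
#' @param n_perm permutations (0 to skip p-values).
#' @param seed optional permutation seed.
#' @return data frame `covariate`, `explained_pct`, `p_perm`.
#' @export
rda_marginal <- function(qm, topo, n_perm = 999, seed = NULL) {
  stopifnot(inherits(qm, "quadrat_matrix"))
  topo <- as.data.frame(topo)
  key_q <- paste(qm$quadrat_meta$plot, qm$quadrat_meta$cell_ix,
                 qm$quadrat_meta$cell_iy, sep = ":")
  key_t <- paste(topo$plot, topo$cell_ix, topo$cell_iy, sep = ":")
  idx <- match(key_q, key_t)
  if (anyNA(idx))
    stop("topography table is missing ", sum(is.na(idx)), " quadrat(s)",
         call. = FALSE)
  covars <- setdiff(names(topo), c("plot", "cell_ix", "cell_iy"))
  if (length(covars) == 0L) stop("no covariate columns", call. = FALSE)
  Y <- t(qm$abundance)                      # quadrats x species
  Y <- scale(Y, center = TRUE, scale = FALSE)
  ss_tot <- sum(Y^2)
  if (!is.null(seed)) set.seed(seed)
  res <- lapply(covars, function(cv) {
    v <- topo[[cv]][idx]
    X <- if (identical(cv, "aspect"))
      cbind(sin(v * pi / 180), cos(v * pi / 180)) else cbind(v)
    if (any(apply(X, 2, stats::sd) == 0)) {
      warning("covariate ", cv, " is constant; 0% explained", call. = FALSE)
      return(data.frame(covariate = cv, explained_pct = 0,
                        p_perm = NA_real_))
    }
    frac <- function(Xm) {
      Xc <- scale(Xm, center = TRUE, scale = FALSE)
      qrx <- qr(Xc)
      fit <- qr.fitted(qrx, Y)
      100 * sum(fit^2) / ss_tot
    }
    obs <- frac(X)
    p <- NA_real_
    if (n_perm > 0L) {
      null <- replicate(n_perm, frac(X[sample(nrow(X)), , drop = FALSE]))
      p <- (sum(null >= obs - 1e-12) + 1) / (n_perm + 1)
    }
    data.frame(covariate = cv, explained_pct = obs, p_perm = p)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
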