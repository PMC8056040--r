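# Pair-correlation function g(r) for mapped stem patterns in a
# rectangular window, with translation edge correction, Epanechnikov
# kernel smoothing, and pointwise Monte-Carlo rank envelopes. g(r) is
# the density of point pairs at distance r relative to a Poisson process
# of the same intensity; g = 1 under complete spatial randomness (CSR).

epanechnikov <- function(u, h) {
  k <- numeric(length(u))
  inside <- abs(u) < h
  k[inside] <- 0.75 * (1 - (u[inside] / h)^2) / h
  k
}

# Sum of kernel-weighted, translation-corrected pair contributions for
# each r. `dx`, `dy` are signed coordinate differences of the
# contributing (ordered or cross) pairs.
pcf_sum <- function(dx, dy, r, h, W, Hh) {
  d <- sqrt(dx^2 + dy^2)
  w <- 1 / ((W - abs(dx)) * (Hh - abs(dy)))
  vapply(r, function(ri) sum(epanechnikov(ri - d, h) * w), numeric(1))
}

#' Pair-correlation function of a point pattern
#'
#' Kernel estimator with Epanechnikov kernel and translation edge
#' correction:
#' `g(r) = sum_{i != j} k_h(r - d_ij) / ((W - |dx|)(H - |dy|)) /
#' (2 pi r lambda^2)` with `lambda^2 = n (n - 1) / A^2`. The default
#' bandwidth (kernel half-width) follows Stoyan's rule
#' `h = 0.15 / sqrt(lambda)`.
#'
#' @param points two-column matrix or data frame of x, y coordinates (m).
#' @param window `c(width, height)` of the observation rectangle (m).
#' @param r strictly positive distance grid (default 40 values up to a
#'   quarter of the shorter window side).
#' @param bw kernel half-width in meters (default Stoyan's rule).
#' @return data frame of class `"pcf_estimate"`: `r`, `g`; attributes
#'   `bandwidth`, `correction`, `window`, `n`.
#' @export
pcf <- function(points, window, r = NULL, bw = NULL) {
  xy <- as.matrix(points)[, 1:2, drop = FALSE]
  n <- nrow(xy)
  if (n < 2L) stop("need at least 2 points", call. = FALSE)
  W <- window[1]; Hh <- window[2]
  A <- W * Hh
  lambda <- n / A
  if (is.null(bw)) bw <- 0.15 / sqrt(lambda)
  if (is.null(r)) r <- seq(bw, min(W, Hh) / 4, length.out = 40)
  if (any(r <= 0)) stop("r = 0 (and negative r) excluded from the grid",
                        call. = FALSE)
  pr <- pair_diffs(xy, xy, max(r) + bw, self = TRUE)
  s <- pcf_sum(pr$dx, pr$dy, r, bw, W, Hh)
  g <- s / (2 * pi * r * (n * (n - 1) / A^2))
  structure(data.frame(r = r, g = g),
            class = c("pcf_estimate", "data.frame"),
            bandwidth = bw, correction = "translate",
            window = window, n = n)
}

# Signed coordinate differences of all (ordered, or cross) pairs with
# distance below dmax. self = TRUE drops i == j pairs.
pair_diffs <- function(a, b, dmax, self = FALSE) {
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  keep <- dx^2 + dy^2 <= dmax^2
  if (self) diag(keep) <- FALSE
  list(dx = dx[keep], dy = dy[keep])
}

#' Bivariate (cross) pair-correlation function
#'
#' Same kernel and translation edge treatment as [pcf()], applied to
#' ordered pairs with one point from each pattern; under independence
#' `g_ab(r) = 1`. The default bandwidth uses the geometric mean of the
#' two intensities.
#'
#' @param points_a,points_b coordinate matrices of the two patterns
#'   (same window).
#' @inheritParams pcf
#' @return a `"pcf_estimate"` data frame.
#' @export
pcf_bivariate <- function(points_a, points_b, window, r = NULL, bw = NULL) {
  a <- as.matrix(points_a)[, 1:2, drop = FALSE]
  b <- as.matrix(points_b)[, 1:2, drop = FALSE]
  if (nrow(a) < 1L || nrow(b) < 1L)
    stop("both patterns must be nonempty", call. = FALSE)
  W <- window[1]; Hh <- window[2]
  A <- W * Hh
  lam <- sqrt(nrow(a) * nrow(b)) / A
  if (is.null(bw)) bw <- 0.15 / sqrt(lam)
  if (is.null(r)) r <- seq(bw, min(W, Hh) / 4, length.out = 40)
  if (any(r <= 0)) stop("r = 0 (and negative r) excluded from the grid",
                        call. = FALSE)
  pr <- pair_diffs(a, b, max(r) + bw)
  s <- pcf_sum(pr$dx, pr$dy, r, bw, W, Hh)
  g <- s / (2 * pi * r * (nrow(a) * nrow(b) / A^2))
  structure(data.frame(r = r, g = g),
            class = c("pcf_estimate", "data.frame"),
            bandwidth = bw, correction = "translate",
            window = window, n = c(nrow(a), nrow(b)))
}

#' Monte-Carlo simulation envelope for g(r)
#'
#' Pointwise rank envelope: the data's g(r) is compared against `n_sim`
#' simulations of a null model; with coverage `c`, the bounds are the
#' `k`-th extreme order statistics where `k = (1 - c)(n_sim + 1) / 2`
#' must be a positive integer (e.g. `n_sim = 199`, `k = 1` for a 99%
#' pointwise envelope). Null models: `"csr"` (complete spatial
#' randomness with the observed number of points; for bivariate input
#' both patterns are re-simulated) and `"label_permutation"` (bivariate
#' only: species labels are permuted among the fixed stem locations, the
#' standard null for interspecific association in mapped plots).
#'
#' @param points observed pattern (or pattern A for bivariate use).
#' @param window `c(width, height)` in meters.
#' @param points_b optional second pattern; switches to the cross g.
#' @param null null model, `"csr"` or `"label_permutation"`.
#' @param n_sim number of simulations (default 199).
#' @param coverage pointwise coverage (default 0.99).
#' @param r,bw as in [pcf()]; the bandwidth is frozen at the observed
#'   pattern's value so data and simulations are comparable.
#' @param seed optional seed.
#' @return a `"pcf_estimate"` data frame with columns `r`, `g`, `lo`,
#'   `hi`; attribute `n_sim`.
#' @export
mc_envelope <- function(points, window, points_b = NULL,
                        null = c("csr", "label_permutation"),
                        n_sim = 199, coverage = 0.99,
                        r = NULL, bw = NULL, seed = NULL) {
  null <- match.arg(null)
  k <- (1 - coverage) * (n_sim + 1) / 2
  if (abs(k - round(k)) > 1e-9 || round(k) < 1)
    stop(sprintf(paste0("coverage %g needs (1 - coverage) * (n_sim + 1) / 2 ",
                        "to be a positive integer; e.g. n_sim = %d"),
                 coverage, ceiling(2 / (1 - coverage)) - 1L), call. = FALSE)
  k <- as.integer(round(k))
  bivariate <- !is.null(points_b)
  if (null == "label_permutation" && !bivariate)
    stop("label_permutation null requires two patterns", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  obs <- if (bivariate) pcf_bivariate(points, points_b, window, r, bw)
         else pcf(points, window, r, bw)
  r_use <- obs$r
  bw_use <- attr(obs, "bandwidth")
  a <- as.matrix(points)[, 1:2, drop = FALSE]
  b <- if (bivariate) as.matrix(points_b)[, 1:2, drop = FALSE] else NULL
  sim_g <- matrix(NA_real_, nrow = n_sim, ncol = length(r_use))
  for (s in seq_len(n_sim)) {
    if (null == "csr") {
      sa <- cbind(stats::runif(nrow(a), 0, window[1]),
                  stats::runif(nrow(a), 0, window[2]))
      if (bivariate) {
        sb <- cbind(stats::runif(nrow(b), 0, window[1]),
                    stats::runif(nrow(b), 0, window[2]))
        sim_g[s, ] <- pcf_bivariate(sa, sb, window, r_use, bw_use)$g
      } else {
        sim_g[s, ] <- pcf(sa, window, r_use, bw_use)$g
      }
    } else {
      pool <- rbind(a, b)
      lab <- sample(rep(c(TRUE, FALSE), c(nrow(a), nrow(b))))
      sim_g[s, ] <- pcf_bivariate(pool[lab, , drop = FALSE],
                                  pool[!lab, , drop = FALSE],
                                  window, r_use, bw_use)$g
    }
  }
  lo <- apply(sim_g, 2, function(v) sort(v)[k])
  hi <- apply(sim_g, 2, function(v) sort(v, decreasing = TRUE)[k])
  out <- data.frame(r = r_use, g = obs$g, lo = lo, hi = hi)
  structure(out, class = c("pcf_estimate", "data.frame"),
            bandwidth = bw_use, correction = "translate",
            window = window, n = attr(obs, "n"), n_sim = n_sim,
            coverage = coverage, null = null)
}

#' Theoretical pair-correlation function of a Thomas cluster process
#'
#' `g(r) = 1 + exp(-r^2 / (4 sigma^2)) / (4 pi sigma^2 kappa)` for
#' parent intensity `kappa` (per m^2) and offspring displacement sd
#' `sigma` (m).
#'
#' @param r distances (m).
#' @param kappa parent intensity per square meter.
#' @param sigma Gaussian displacement sd in meters.
#' @return numeric vector g(r).
#' @export
pcf_thomas <- function(r, kappa, sigma) {
  1 + exp(-r^2 / (4 * sigma^2)) / (4 * pi * sigma^2 * kappa)
}
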