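# Bipartite species x community network: H2' specialization and
# connectance. H2' rescales the Shannon entropy of the interaction
# proportions between its minimum and maximum achievable under the
# observed row/column totals: 0 means interactions simply follow the
# marginals (no specialization), 1 means maximal specialization.

#' Build the species x community interaction matrix
#'
#' Cell `(s, c)` is the total number of stems of species `s` recorded in
#' community `c`; the grand total equals the stem total of the census.
#'
#' @param qm a quadrat matrix with community (plot) labels on quadrats.
#' @param species optional subset of species (e.g. one life form).
#' @return object of class `"bipartite_network"`: list with `matrix`
#'   (species x community integer totals) and `m` (grand total).
#' @export
build_network <- function(qm, species = NULL) {
  stopifnot(inherits(qm, "quadrat_matrix"))
  comms <- unique(qm$quadrat_meta$plot)
  mat <- vapply(comms, function(cm)
    rowSums(qm$abundance[, qm$quadrat_meta$plot == cm, drop = FALSE]),
    numeric(nrow(qm$abundance)))
  mat <- matrix(mat, nrow = nrow(qm$abundance),
                dimnames = list(rownames(qm$abundance), comms))
  if (!is.null(species)) mat <- mat[rownames(mat) %in% species, , drop = FALSE]
  mat <- mat[rowSums(mat) > 0, , drop = FALSE]
  as_network(mat)
}

#' Wrap a nonnegative matrix as a bipartite network
#' @param mat nonnegative species x community matrix.
#' @return a `"bipartite_network"` object.
#' @export
as_network <- function(mat) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("interaction matrix must be nonnegative",
                         call. = FALSE)
  structure(list(matrix = mat, m = sum(mat)), class = "bipartite_network")
}

#' Shannon entropy of the interaction proportions
#'
#' `H2 = -sum_ij p_ij ln p_ij` with `p_ij = a_ij / m`, natural
#' logarithms, zero cells contributing nothing.
#'
#' @param net a [build_network()] object.
#' @return numeric entropy (nats).
#' @export
h2_entropy <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  if (net$m <= 0) stop("empty network: grand total is 0", call. = FALSE)
  p <- net$matrix / net$m
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Entropy bounds under fixed marginal totals
#'
#' `H2max` is the entropy of the independence distribution
#' `r_i c_j / m^2` (the continuous upper bound given the marginals).
#' `H2min` is exact for small networks: when the grand total is at most
#' 12 stems, all nonnegative integer matrices with the observed
#' marginals are enumerated and the minimum entropy taken. For larger
#' networks (any real census) a greedy integer allocation is used:
#' repeatedly place `min(remaining row, remaining column)` stems into
#' the cell whose current row x column product of remaining totals is
#' largest, then take the entropy of that allocation. The greedy value
#' is an upper bound on the true minimum; the two can differ slightly on
#' awkward marginals, which only matters for toy-sized networks where
#' the exact search runs anyway. `exhaustive = TRUE` forces exact search
#' for both bounds (errors when infeasible); `exhaustive = FALSE` forces
#' the greedy/continuous pair.
#'
#' @param net a bipartite network with integer entries.
#' @param exhaustive `NA` (auto: exact when `m <= 12`), `TRUE`, or
#'   `FALSE`.
#' @return named numeric vector `c(H2min, H2max)`.
#' @export
h2_bounds <- function(net, exhaustive = NA) {
  stopifnot(inherits(net, "bipartite_network"))
  mat <- net$matrix
  m <- sum(mat)
  if (m <= 0) stop("empty network", call. = FALSE)
  r <- rowSums(mat)
  cs <- colSums(mat)
  if (is.na(exhaustive)) exhaustive <- m <= 12
  if (exhaustive) {
    if (m > 60) stop("exhaustive bounds are only feasible for small totals",
                     call. = FALSE)
    ent <- entropies_with_marginals(round(r), round(cs))
    return(c(H2min = min(ent), H2max = max(ent)))
  }
  p_ind <- outer(r / m, cs / m)
  p <- p_ind[p_ind > 0]
  h2max <- -sum(p * log(p))
  alloc <- greedy_min_allocation(r, cs)
  pa <- alloc[alloc > 0] / m
  h2min <- -sum(pa * log(pa))
  c(H2min = h2min, H2max = h2max)
}

greedy_min_allocation <- function(r, cs) {
  alloc <- matrix(0, length(r), length(cs))
  repeat {
    prod <- outer(r, cs)
    if (all(prod == 0)) break
    cell <- which(prod == max(prod), arr.ind = TRUE)[1, ]
    amt <- min(r[cell[1]], cs[cell[2]])
    alloc[cell[1], cell[2]] <- alloc[cell[1], cell[2]] + amt
    r[cell[1]] <- r[cell[1]] - amt
    cs[cell[2]] <- cs[cell[2]] - amt
  }
  alloc
}

# Entropies of every nonnegative integer matrix with the given marginals
# (depth-first over cells). Exponential; only for tiny networks.
entropies_with_marginals <- function(r, cs) {
  S <- length(r); C <- length(cs); m <- sum(r)
  ents <- numeric(0)
  cells <- as.matrix(expand.grid(i = seq_len(S), j = seq_len(C)))
  rec <- function(k, r_rem, c_rem, plogp) {
    if (k > nrow(cells)) {
      if (all(r_rem == 0) && all(c_rem == 0))
        ents[length(ents) + 1L] <<- -plogp
      return(invisible())
    }
    i <- cells[k, 1]; j <- cells[k, 2]
    hi <- min(r_rem[i], c_rem[j])
    for (a in 0:hi) {
      r2 <- r_rem; c2 <- c_rem
      r2[i] <- r2[i] - a; c2[j] <- c2[j] - a
      term <- if (a > 0) (a / m) * log(a / m) else 0
      rec(k + 1L, r2, c2, plogp + term)
    }
  }
  rec(1L, r, cs, 0)
  ents
}

#' Network-level specialization H2'
#'
#' `H2' = (H2max - H2) / (H2max - H2min)`, clipped to `[0, 1]`. When the
#' bounds coincide (e.g. a single row or column) the index is undefined
#' and reported as 0 with attribute `degenerate = TRUE`.
#'
#' @param net a bipartite network.
#' @return numeric in `[0, 1]` (attribute `degenerate` flags the
#'   undefined case).
#' @export
h2prime <- function(net) {
  h2 <- h2_entropy(net)
  b <- h2_bounds(net)
  if (b["H2max"] - b["H2min"] < 1e-12) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  unname(min(1, max(0, (b[["H2max"]] - h2) / (b[["H2max"]] - b[["H2min"]]))))
}

#' Network connectance
#'
#' Fraction of realized links: nonzero cells divided by
#' `species x communities`.
#'
#' @param net a bipartite network.
#' @return numeric in `(0, 1]`.
#' @export
connectance <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  sum(net$matrix > 0) / length(net$matrix)
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat("Bipartite network:", nrow(x$matrix), "species x", ncol(x$matrix),
      "communities,", x$m, "stems\n")
  b <- h2_bounds(x)
  cat(sprintf("  H2' = %.4f, connectance = %.4f (H2 = %.4f in [%.4f, %.4f])\n",
              h2prime(x), connectance(x), h2_entropy(x),
              b["H2min"], b["H2max"]))
  invisible(x)
}

#' Export the network as an edge list
#'
#' @param net a bipartite network.
#' @return data frame `species`, `community`, `weight` for nonzero cells.
#' @export
network_edge_list <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  idx <- which(net$matrix > 0, arr.ind = TRUE)
  data.frame(species = rownames(net$matrix)[idx[, 1]],
             community = colnames(net$matrix)[idx[, 2]],
             weight = net$matrix[idx], stringsAsFactors = FALSE)
}
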