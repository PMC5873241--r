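# Individual-resource network metrics: the diet-overlap network between
# individuals, its clustering-based modularity index Cws, and the nestedness
# index NODF ("nestedness based on overlap and decreasing fill") with a
# marginal-probability null model.

#' Pairwise diet-overlap network
#'
#' Edge weights are pairwise proportional similarities,
#' `w_ij = 1 - 0.5 * sum_k |p_ik - p_jk|`, the same overlap family as PS_i,
#' so identical diets have weight 1 and diets sharing no resource weight 0.
#' The diagonal is zero.
#'
#' @param diet A `diet_matrix` with at least 2 individuals.
#' @return An `overlap_network`: list with `individual_ids` and the symmetric
#'   `weights` matrix.
#' @export
overlap_network <- function(diet) {
  counts <- diet$counts
  if (nrow(counts) < 2L) stop_ds("need at least 2 individuals")
  props <- diet_proportions(counts)
  n <- nrow(props)
  w <- matrix(0, n, n, dimnames = list(rownames(props), rownames(props)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      w[i, j] <- w[j, i] <-
        min(max(1 - 0.5 * sum(abs(props[i, ] - props[j, ])), 0), 1)
    }
  }
  structure(list(individual_ids = rownames(props), weights = w),
            class = "overlap_network")
}

# Observed Cws statistic. Per-node weighted clustering uses the
# geometric-mean triangle form over all pairs of other nodes,
#   c_i = sum_{j<k; j,k != i} (w_ij w_jk w_ik)^(1/3) / ((N-1)(N-2)/2),
# so triangles broken by zero-weight edges pull c_i down. Cws compares mean
# clustering with network density on a signed relative scale:
# 0 when they coincide (no modularity), negative when clustering falls below
# density (discrete specialist groups), positive above it.
cws_stats <- function(w) {
  n <- nrow(w)
  if (n < 3L) stop_ds("Cws needs at least 3 individuals")
  w <- pmin(pmax(w, 0), 1)  # guard the [0, 1] range against rounding
  gw <- w^(1 / 3)
  denom <- (n - 1) * (n - 2) / 2
  c_i <- vapply(seq_len(n), function(i) {
    wi <- gw[i, -i]
    sub <- gw[-i, -i, drop = FALSE]
    sum((wi %o% wi) * sub) / 2 / denom  # sub diagonal is 0
  }, numeric(1))
  mean_cl <- mean(c_i)
  dens <- sum(w) / (n * (n - 1))
  cws <- if (max(mean_cl, dens) > 0) (mean_cl - dens) / max(mean_cl, dens)
         else 0
  list(cws = cws, mean_clustering = mean_cl, density = dens,
       clustering = c_i)
}

#' Clustering index Cws of a diet-overlap network
#'
#' @param network An [overlap_network()].
#' @return The Cws value in \[-1, 1\]. Values near 0 indicate no modularity
#'   (an all-generalist population, or specialists nested within
#'   generalists); values below 0 indicate discrete groups of specialists;
#'   values above 0 indicate idiosyncratic specialist diets.
#' @export
cws_index <- function(network) cws_stats(network$weights)$cws

#' Monte Carlo null test for Cws
#'
#' The null resamples each individual's diet as a multinomial draw from the
#' observed population diet (exactly as [psi_null_test()]), rebuilds the
#' overlap network and recomputes Cws. The p-value is two-sided
#' (`(count(|null| >= |observed|) + 1) / (R + 1)`), since departures in both
#' directions are interpretable.
#'
#' @param network An [overlap_network()] built from `diet`.
#' @param diet The `diet_matrix` the network came from (needed to resample).
#' @param replicates Number of null replicates (default 999).
#' @param seed Integer seed or `NULL`.
#' @param q_method Population-diet weighting passed to the resampler.
#' @return A `cws_result`: `cws`, `mean_clustering`, `density`, `null_cws`,
#'   `p_value`, `replicates`, `seed`.
#' @export
cws <- function(network, diet, replicates = 999L, seed = NULL,
                q_method = c("equal", "pooled")) {
  q_method <- match.arg(q_method)
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop_ds("replicates must be >= 1")
  obs <- cws_stats(network$weights)
  counts <- diet$counts
  n_i <- rowSums(counts)
  q <- population_diet(counts, q_method)
  k <- length(q)
  null_cws <- with_seed(seed, {
    vapply(seq_len(replicates), function(r) {
      sim <- t(vapply(n_i,
                      function(n) as.numeric(stats::rmultinom(1L, n, q)),
                      numeric(k)))
      props <- diet_proportions(sim)
      nw <- 1 - 0.5 * as.matrix(stats::dist(props, method = "manhattan"))
      diag(nw) <- 0
      cws_stats(nw)$cws
    }, numeric(1))
  })
  structure(
    list(cws = obs$cws, mean_clustering = obs$mean_clustering,
         density = obs$density, null_cws = null_cws,
         p_value = mc_pvalue(null_cws, obs$cws, "two_sided"),
         replicates = replicates, seed = seed),
    class = "cws_result"
  )
}

#' @export
print.cws_result <- function(x, digits = 3, ...) {
  cat("Diet-network clustering: Cws = ", round(x$cws, digits),
      ", P = ", format.pval(x$p_value, digits = digits),
      " (", x$replicates, " replicates, two-sided)\n", sep = "")
  invisible(x)
}

as_binary_matrix <- function(x) {
  m <- if (inherits(x, "diet_matrix")) x$counts else as.matrix(x)
  m <- (m >= 1) * 1L
  storage.mode(m) <- "double"
  m
}

# Sum of paired NODF scores over ordered row pairs (u, v) with
# fill(u) > fill(v) > 0: 100 * (shared presences) / fill(v).
nodf_pair_sum <- function(m) {
  f <- rowSums(m)
  n <- nrow(m)
  if (n < 2L) return(0)
  ov <- m %*% t(m)
  fu <- matrix(f, n, n)           # [u, v] = fill(u)
  fv <- t(fu)                     # [u, v] = fill(v)
  valid <- (fu > fv) & (fv > 0)
  sum((100 * ov / fv)[valid])
}

#' Nestedness index NODF
#'
#' NODF ("nestedness based on overlap and decreasing fill") scores every
#' ordered pair of rows whose fills strictly decrease by the percentage of
#' the sparser row's presences also present in the fuller row; pairs with
#' equal fills (or an empty sparser line) score zero. Column pairs are
#' scored the same way, and NODF is the sum of all pair scores divided by
#' `N(N-1)/2 + K(K-1)/2`. It ranges from 0 (no nestedness) to 100 (complete
#' nestedness: every sparser line a subset of every fuller one, all fills
#' distinct).
#'
#' @param x A binary matrix, or a `diet_matrix` (counts thresholded at >= 1).
#' @return The NODF value in \[0, 100\].
#' @export
nodf <- function(x) {
  m <- as_binary_matrix(x)
  if (sum(m) == 0) stop_ds("NODF undefined for an all-zero matrix")
  n <- nrow(m)
  k <- ncol(m)
  pairs <- n * (n - 1) / 2 + k * (k - 1) / 2
  if (pairs == 0) stop_ds("NODF needs at least 2 rows or 2 columns")
  (nodf_pair_sum(m) + nodf_pair_sum(t(m))) / pairs
}

#' Monte Carlo null test for NODF
#'
#' Null matrices follow the marginal-probability null model ("null model 2"):
#' each cell (i, j) is present independently with probability
#' `(rowfill_i / K + colfill_j / N) / 2`, the average of the observed row and
#' column fill proportions. Replicates with empty rows or columns are kept
#' (their pairs simply score zero). The p-value is one-tailed toward high
#' nestedness: `(count(null >= observed) + 1) / (R + 1)`.
#'
#' @param x A binary matrix or `diet_matrix`.
#' @param replicates Number of null replicates (default 999).
#' @param seed Integer seed or `NULL`.
#' @return A `nodf_result`: `nodf`, `null_nodf`, `null_mean`, `p_value`,
#'   `replicates`, `seed`.
#' @export
nodf_null_test <- function(x, replicates = 999L, seed = NULL) {
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop_ds("replicates must be >= 1")
  m <- as_binary_matrix(x)
  observed <- nodf(m)
  n <- nrow(m)
  k <- ncol(m)
  p_cell <- (matrix(rowSums(m) / k, n, k) +
             matrix(colSums(m) / n, n, k, byrow = TRUE)) / 2
  pairs <- n * (n - 1) / 2 + k * (k - 1) / 2
  null_nodf <- with_seed(seed, {
    vapply(seq_len(replicates), function(r) {
      sim <- (matrix(stats::runif(n * k), n, k) < p_cell) * 1
      if (sum(sim) == 0) return(0)
      (nodf_pair_sum(sim) + nodf_pair_sum(t(sim))) / pairs
    }, numeric(1))
  })
  structure(
    list(nodf = observed, null_nodf = null_nodf,
         null_mean = mean(null_nodf),
         p_value = mc_pvalue(null_nodf, observed, "upper"),
         replicates = replicates, seed = seed),
    class = "nodf_result"
  )
}

#' @export
print.nodf_result <- function(x, digits = 3, ...) {
  cat("Nestedness: NODF = ", round(x$nodf, 2),
      ", null mean = ", round(x$null_mean, 2),
      ", P = ", format.pval(x$p_value, digits = digits),
      " (", x$replicates, " replicates)\n", sep = "")
  invisible(x)
}

#' Export an overlap network
#'
#' @param network An [overlap_network()].
#' @param path Output path; `network_to_graphml()` writes GraphML for
#'   external visualisation, `network_edges()` returns (and optionally
#'   writes) the weighted edge list.
#' @return For `network_edges()`, a data frame with columns `from`, `to`,
#'   `weight` (positive-weight edges only).
#' @export
network_to_graphml <- function(network, path) {
  g <- igraph::graph_from_adjacency_matrix(network$weights, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname network_to_graphml
#' @export
network_edges <- function(network, path = NULL) {
  w <- network$weights
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  edges <- data.frame(
    from = rownames(w)[idx[, 1]],
    to = colnames(w)[idx[, 2]],
    weight = w[idx],
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) utils::write.csv(edges, path, row.names = FALSE)
  edges
}
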