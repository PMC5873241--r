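# Fixture builders and independent oracle implementations used across the
# test files. Oracles are deliberately literal translations of the
# definitions, independent of the package's vectorized code paths.

make_diet <- function(counts, level = "family") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("ind", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("res", seq_len(ncol(counts)))
  }
  storage.mode(counts) <- "integer"
  dietspec:::new_diet_matrix(counts, level)
}

make_records <- function(individual, cell, family,
                         genus = family,
                         guild = family,
                         body_length = 5, carapace_width = 1.5,
                         genus_unidentifiable = FALSE,
                         size_damaged = FALSE) {
  prey_records(data.frame(
    individual_id = individual, cell_id = cell, family = family,
    genus = genus, guild = guild,
    body_length_mm = body_length, carapace_width_mm = carapace_width,
    genus_unidentifiable = genus_unidentifiable,
    size_damaged = size_damaged,
    stringsAsFactors = FALSE
  ))
}

# records with n items per (individual, cell), all of one taxon per call
records_block <- function(individual, cell, family, n, ...) {
  make_records(rep(individual, n), rep(cell, n), rep(family, n), ...)
}

# ---- NODF oracle: literal pairwise translation of the definition --------
nodf_oracle <- function(m) {
  m <- (as.matrix(m) >= 1) * 1
  score_pairs <- function(mm) {
    fills <- rowSums(mm)
    total <- 0
    n <- nrow(mm)
    if (n < 2) return(0)
    for (u in seq_len(n)) {
      for (v in seq_len(n)) {
        if (u == v) next
        if (fills[u] > fills[v] && fills[v] > 0) {
          shared <- sum(mm[u, ] == 1 & mm[v, ] == 1)
          total <- total + 100 * shared / fills[v]
        }
      }
    }
    total  # only the decreasing-fill direction of each pair ever scores
  }
  npairs <- nrow(m) * (nrow(m) - 1) / 2 + ncol(m) * (ncol(m) - 1) / 2
  (score_pairs(m) + score_pairs(t(m))) / npairs
}

# ---- exact multinomial null distribution of IS ---------------------------
# All outcomes of redrawing each row of `counts` as multinomial(n_i, q),
# with q (and the replicate statistic) per the package's equal-weight
# convention. Returns exact P(IS_null <= is_obs + tol).
exact_psi_null_p <- function(counts, tol = 1e-12) {
  counts <- as.matrix(counts)
  k <- ncol(counts)
  props <- counts / rowSums(counts)
  q <- colMeans(props)
  is_of <- function(cnt) {
    pr <- cnt / rowSums(cnt)
    qq <- colMeans(pr)
    mean(1 - 0.5 * rowSums(abs(sweep(pr, 2, qq))))
  }
  is_obs <- is_of(counts)
  compositions <- function(n, k) {
    if (k == 1) return(matrix(n, 1, 1))
    out <- NULL
    for (first in 0:n) {
      rest <- compositions(n - first, k - 1)
      out <- rbind(out, cbind(first, rest))
    }
    out
  }
  row_outcomes <- lapply(rowSums(counts), function(n) {
    comp <- compositions(n, k)
    probs <- apply(comp, 1, function(x) stats::dmultinom(x, prob = q))
    list(comp = comp, probs = probs)
  })
  idx <- do.call(expand.grid, lapply(row_outcomes,
                                     function(o) seq_along(o$probs)))
  p_total <- 0
  p_le <- 0
  for (r in seq_len(nrow(idx))) {
    cnt <- t(vapply(seq_along(row_outcomes), function(i) {
      row_outcomes[[i]]$comp[idx[r, i], ]
    }, numeric(k)))
    pr <- prod(vapply(seq_along(row_outcomes), function(i) {
      row_outcomes[[i]]$probs[idx[r, i]]
    }, numeric(1)))
    p_total <- p_total + pr
    if (is_of(cnt) <= is_obs + tol) p_le <- p_le + pr
  }
  stopifnot(abs(p_total - 1) < 1e-9)
  p_le
}

# ---- exact permutation p for the WIC/TNW ratio, two individuals ----------
# Enumerates all assignments of the pooled values to groups of sizes
# (n1, n2) via combn; returns exact P(ratio_perm <= ratio_obs + tol).
exact_wic_perm_p <- function(x1, x2, tol = 1e-12) {
  values <- c(x1, x2)
  n1 <- length(x1)
  ratio_of <- function(a) {
    g <- rep(c("A", "B"), c(n1, length(values) - n1))
    s <- dietspec:::wic_tnw_stats(a, g)
    s$ratio
  }
  obs <- ratio_of(values)
  sets <- utils::combn(length(values), n1)
  ratios <- apply(sets, 2, function(ix) {
    ratio_of(c(values[ix], values[-ix]))
  })
  mean(ratios <= obs + tol)
}
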