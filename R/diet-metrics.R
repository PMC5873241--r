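# Proportional-similarity indices. For individual i with diet proportions
# p_ij and population diet q_j,
#     PS_i = 1 - 0.5 * sum_j | p_ij - q_j |,
# ranging from 0 (no overlap with the population diet) to 1 (identical to
# it). IS, the population-level index of similarity, is the mean of the
# PS_i. Significance comes from a multinomial Monte Carlo null in which each
# individual redraws its n_i items from the population diet.

diet_proportions <- function(counts) counts / rowSums(counts)

population_diet <- function(counts, q_method = c("equal", "pooled")) {
  q_method <- match.arg(q_method)
  if (q_method == "equal") {
    colMeans(diet_proportions(counts))
  } else {
    colSums(counts) / sum(counts)
  }
}

psi_from_props <- function(props, q) {
  1 - 0.5 * rowSums(abs(sweep(props, 2L, q)))
}

is_from_counts <- function(counts, q_method) {
  props <- diet_proportions(counts)
  q <- population_diet(counts, q_method)
  mean(psi_from_props(props, q))
}

#' Proportional similarity indices (PSi) and the population IS
#'
#' @param diet A `diet_matrix` (see [build_diet_matrix()]) with at least two
#'   individuals.
#' @param q_method How the population diet `q` is formed: `"equal"` (default)
#'   averages the individual proportion vectors so every individual counts
#'   equally regardless of how many items it contributed; `"pooled"` uses the
#'   pooled item counts.
#' @return A `psi_result` with elements `psi` (named vector of PS_i),
#'   `is_value` (their mean), `population_diet` (the q vector), `q_method`
#'   and `level`.
#' @details The equal-weight default is the convention under which a pure
#'   specialist on a resource nobody else uses has PS_i equal to that
#'   resource's share of the population diet, 1/N for N individuals.
#' @seealso [psi_null_test()] for the Monte Carlo significance test.
#' @export
psi <- function(diet, q_method = c("equal", "pooled")) {
  q_method <- match.arg(q_method)
  counts <- diet$counts
  if (is.null(counts)) stop_ds("psi() expects a diet_matrix")
  if (nrow(counts) < 2L) {
    stop_ds("PSi needs at least 2 individuals: overlap with the rest of ",
            "the population is undefined for a single individual")
  }
  props <- diet_proportions(counts)
  q <- population_diet(counts, q_method)
  ps <- psi_from_props(props, q)
  structure(
    list(psi = ps, is_value = mean(ps), population_diet = q,
         q_method = q_method, level = diet$level),
    class = "psi_result"
  )
}

#' Monte Carlo null test for the population IS
#'
#' Tests the null hypothesis that every individual samples its items from the
#' shared population diet. Each replicate redraws individual i's diet as an
#' n_i-trial multinomial over the observed population diet q, then recomputes
#' IS on the redrawn matrix (q re-estimated within the replicate, so the null
#' distribution is of the same estimator). The one-tailed p-value toward
#' small IS uses the (r + 1) / (R + 1) convention, so its floor at 999
#' replicates is 0.001.
#'
#' @inheritParams psi
#' @param replicates Number of Monte Carlo replicates (default 999).
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return A `psi_result` additionally carrying `null_is`, `p_value`,
#'   `replicates` and `seed`.
#' @export
psi_null_test <- function(diet, replicates = 999L, seed = NULL,
                          q_method = c("equal", "pooled")) {
  q_method <- match.arg(q_method)
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop_ds("replicates must be >= 1")
  obs <- psi(diet, q_method)
  counts <- diet$counts
  n_i <- rowSums(counts)
  q <- obs$population_diet
  k <- length(q)
  null_is <- with_seed(seed, {
    vapply(seq_len(replicates), function(r) {
      sim <- t(vapply(n_i,
                      function(n) as.numeric(stats::rmultinom(1L, n, q)),
                      numeric(k)))
      is_from_counts(sim, q_method)
    }, numeric(1))
  })
  obs$null_is <- null_is
  obs$p_value <- mc_pvalue(null_is, obs$is_value, "lower")
  obs$replicates <- replicates
  obs$seed <- seed
  obs
}

#' @export
print.psi_result <- function(x, digits = 3, ...) {
  cat("Individual specialization (PSi / IS)",
      if (!is.null(x$level)) paste0(" at ", x$level, " level"), "\n",
      sep = "")
  cat("  PSi range: ", round(min(x$psi), digits), "-",
      round(max(x$psi), digits),
      "  (", length(x$psi), " individuals)\n", sep = "")
  cat("  IS = ", round(x$is_value, digits), sep = "")
  if (!is.null(x$p_value)) {
    cat(", P = ", format.pval(x$p_value, digits = digits),
        " (", x$replicates, " replicates)", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Serialize an analysis result to JSON (and per-individual CSV)
#'
#' @param x A `psi_result`, `niche_width_result`, `cws_result` or
#'   `nodf_result`.
#' @param path Output JSON path. For `psi_result` a companion
#'   `<path stem>_psi.csv` with the per-individual PS_i values is written
#'   alongside.
#' @return `path`, invisibly.
#' @export
write_result <- function(x, path) {
  out <- unclass(x)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  if (inherits(x, "psi_result")) {
    csv <- sub("\\.json$", "", path)
    utils::write.csv(
      data.frame(individual_id = names(x$psi), psi = unname(x$psi)),
      paste0(csv, "_psi.csv"), row.names = FALSE
    )
  }
  invisible(path)
}
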