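# WIC/TNW decomposition of the population niche width on a continuous prey
# trait. With all items pooled (n total), the total niche width TNW is the
# population variance of the trait; it splits exactly into the mean
# within-individual variance WIC and the between-individual variance of
# means BIC by the law of total variance, each individual weighted by its
# share of items n_i/n and every variance using the n-denominator
# (maximum-likelihood) form so that WIC + BIC = TNW holds as an identity.
# The degree of individual specialization is WIC/TNW: 1 when individuals
# are interchangeable samples of the population, approaching 0 as each
# individual occupies a narrow, distinct slice of the trait axis.

wic_tnw_stats <- function(values, group) {
  n <- length(values)
  grand <- mean(values)
  tnw <- mean((values - grand)^2)
  mi <- tapply(values, group, mean)
  vi <- tapply(values, group, function(x) mean((x - mean(x))^2))
  wi <- tapply(values, group, length) / n
  wic <- sum(wi * vi)
  bic <- sum(wi * (mi - grand)^2)
  list(wic = wic, bic = bic, tnw = tnw, ratio = wic / tnw)
}

check_sizes <- function(sizes) {
  if (!is.list(sizes) || length(sizes) < 2L) {
    stop_ds("need per-individual size lists for at least 2 individuals")
  }
  values <- unlist(sizes, use.names = FALSE)
  if (length(values) < 2L) stop_ds("need at least 2 measurements in total")
  if (stats::var(values) == 0 || length(unique(values)) == 1L) {
    stop_ds("all trait values identical: niche width undefined")
  }
  if (is.null(names(sizes))) names(sizes) <- seq_along(sizes)
  sizes
}

#' Niche-width decomposition WIC / BIC / TNW
#'
#' @param sizes A named list of numeric vectors: one vector of trait values
#'   (e.g. prey body lengths, mm) per individual, as produced by
#'   [extract_sizes()]. At least 2 individuals, at least 2 values in total,
#'   not all identical.
#' @param log_transform If `TRUE`, trait values are log-transformed before
#'   the decomposition (off by default; results are then in squared log
#'   units).
#' @return A `niche_width_result` with `wic`, `bic`, `tnw` (squared trait
#'   units), and `ratio` = WIC/TNW in \[0, 1\].
#' @seealso [wic_tnw_null_test()] for the permutation significance test.
#' @export
wic_tnw <- function(sizes, log_transform = FALSE) {
  sizes <- check_sizes(sizes)
  values <- unlist(sizes, use.names = FALSE)
  if (log_transform) values <- log(values)
  group <- rep(names(sizes), lengths(sizes))
  s <- wic_tnw_stats(values, group)
  structure(
    c(s, list(n_individuals = length(sizes), n_items = length(values),
              log_transform = log_transform)),
    class = "niche_width_result"
  )
}

#' Permutation null test for WIC/TNW
#'
#' Tests the null hypothesis that all individuals sample from the same trait
#' distribution: each replicate reassigns the pooled trait values to
#' individuals at random without replacement, preserving every sample size
#' n_i, and recomputes WIC/TNW. The p-value is one-tailed toward small
#' ratios (strong specialization), `(count(null <= observed) + 1) / (R + 1)`.
#'
#' @inheritParams wic_tnw
#' @param replicates Number of permutation replicates (default 999).
#' @param seed Integer seed or `NULL`.
#' @return A `niche_width_result` additionally carrying `null_ratio`,
#'   `p_value`, `replicates` and `seed`.
#' @export
wic_tnw_null_test <- function(sizes, replicates = 999L, seed = NULL,
                              log_transform = FALSE) {
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop_ds("replicates must be >= 1")
  obs <- wic_tnw(sizes, log_transform = log_transform)
  sizes <- check_sizes(sizes)
  values <- unlist(sizes, use.names = FALSE)
  if (log_transform) values <- log(values)
  group <- rep(names(sizes), lengths(sizes))
  null_ratio <- with_seed(seed, {
    vapply(seq_len(replicates), function(r) {
      wic_tnw_stats(sample(values), group)$ratio
    }, numeric(1))
  })
  obs$null_ratio <- null_ratio
  obs$p_value <- mc_pvalue(null_ratio, obs$ratio, "lower")
  obs$replicates <- replicates
  obs$seed <- seed
  obs
}

#' @export
print.niche_width_result <- function(x, digits = 3, ...) {
  cat("Niche-width decomposition (", x$n_individuals, " individuals, ",
      x$n_items, " items", if (isTRUE(x$log_transform)) ", log scale",
      ")\n", sep = "")
  cat("  TNW = ", round(x$tnw, digits), " = WIC ", round(x$wic, digits),
      " + BIC ", round(x$bic, digits), "\n", sep = "")
  cat("  WIC/TNW = ", round(x$ratio, digits), sep = "")
  if (!is.null(x$p_value)) {
    cat(", P = ", format.pval(x$p_value, digits = digits),
        " (", x$replicates, " replicates)", sep = "")
  }
  cat("\n")
  invisible(x)
}
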