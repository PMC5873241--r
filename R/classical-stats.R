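# The two classical tests used around the specialization indices: a one-way
# ANOVA (do the common prey taxa differ in size?) and a paired t-test
# (do PSi values differ between one-bout and pooled three-bout diets?).
# Both are computed from their sum-of-squares / difference-score formulas;
# tail probabilities come from the F and t distribution functions.

new_test_result <- function(method, statistic, df1, df2, p_value, n,
                            estimate = NULL) {
  structure(
    list(method = method, statistic = statistic, df1 = df1, df2 = df2,
         p_value = p_value, n = n, estimate = estimate),
    class = "test_result"
  )
}

#' One-way analysis of variance
#'
#' @param groups A list of at least 2 numeric vectors (one per group), each
#'   with at least one value, with total n exceeding the number of groups
#'   and positive pooled within-group variance.
#' @return A `test_result` with `statistic` = F, `df1` = k - 1,
#'   `df2` = n - k, and the upper-tail `p_value`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop_ds("need at least 2 groups")
  }
  groups <- lapply(groups, as.numeric)
  if (any(lengths(groups) < 1L)) stop_ds("every group needs >= 1 value")
  k <- length(groups)
  n <- sum(lengths(groups))
  if (n <= k) stop_ds("total n must exceed the number of groups")
  values <- unlist(groups, use.names = FALSE)
  grand <- mean(values)
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(lengths(groups) * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  if (ssw <= 0) stop_ds("zero within-group variance: F undefined")
  df1 <- k - 1L
  df2 <- n - k
  f <- (ssb / df1) / (ssw / df2)
  new_test_result("one-way ANOVA", f, df1, df2,
                  stats::pf(f, df1, df2, lower.tail = FALSE), n)
}

#' Paired t-test
#'
#' @param x,y Numeric vectors of equal length (>= 2), paired by position;
#'   their differences must not all be zero.
#' @return A `test_result` with `statistic` = t, `df1` = n - 1 degrees of
#'   freedom (`df2` absent), the two-sided `p_value`, and `estimate` = mean
#'   difference x - y.
#' @export
paired_t <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop_ds("x and y must have equal length")
  if (length(x) < 2L) stop_ds("need at least 2 pairs")
  d <- x - y
  if (all(d == 0)) stop_ds("all differences zero: t undefined")
  n <- length(d)
  sd_d <- stats::sd(d)
  if (sd_d == 0) stop_ds("zero variance of differences: t undefined")
  t_stat <- mean(d) / (sd_d / sqrt(n))
  new_test_result("paired t-test", t_stat, n - 1L, NULL,
                  2 * stats::pt(abs(t_stat), n - 1L, lower.tail = FALSE),
                  n, estimate = mean(d))
}

#' @export
print.test_result <- function(x, digits = 3, ...) {
  lab <- if (x$method == "one-way ANOVA") {
    sprintf("F(%d, %d) = %s", x$df1, x$df2,
            format(round(x$statistic, digits)))
  } else {
    sprintf("t(%d) = %s", x$df1, format(round(x$statistic, digits)))
  }
  cat(x$method, ": ", lab, ", P = ",
      format.pval(x$p_value, digits = digits), ", n = ", x$n, "\n",
      sep = "")
  invisible(x)
}

#' Post hoc pairwise letter groupings
#'
#' A stand-in post hoc procedure for labelling groups that do not differ
#' significantly with a shared letter (as in figures annotating mean prey
#' sizes per individual): all pairwise Welch t-tests with Bonferroni
#' correction, then greedy letter assignment. The original analysis this
#' mirrors does not name its post hoc method, so treat these letters as
#' indicative only.
#'
#' @param groups A named list of numeric vectors (each length >= 2).
#' @param alpha Familywise significance level after Bonferroni correction
#'   (default 0.05).
#' @return A data frame with columns `group`, `mean` and `letters`.
#' @export
posthoc_letters <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop_ds("need at least 2 groups")
  }
  if (is.null(names(groups))) names(groups) <- seq_along(groups)
  if (any(lengths(groups) < 2L)) {
    stop_ds("every group needs >= 2 values for Welch tests")
  }
  k <- length(groups)
  pmat <- matrix(1, k, k)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      pmat[i, j] <- pmat[j, i] <-
        stats::t.test(groups[[i]], groups[[j]])$p.value
    }
  }
  m <- k * (k - 1) / 2
  differ <- pmin(pmat * m, 1) < alpha
  # greedy grouping in order of decreasing mean
  ord <- order(vapply(groups, mean, numeric(1)), decreasing = TRUE)
  letter_sets <- list()
  for (g in ord) {
    placed <- FALSE
    for (s in seq_along(letter_sets)) {
      if (!any(differ[g, letter_sets[[s]]])) {
        letter_sets[[s]] <- c(letter_sets[[s]], g)
        placed <- TRUE
      }
    }
    if (!placed) letter_sets[[length(letter_sets) + 1L]] <- g
  }
  lab <- vapply(seq_len(k), function(g) {
    paste0(letters[which(vapply(letter_sets, function(s) g %in% s,
                                logical(1)))], collapse = "")
  }, character(1))
  data.frame(
    group = names(groups),
    mean = vapply(groups, mean, numeric(1)),
    letters = lab,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
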