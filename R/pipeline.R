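# Orchestration of the full analysis: cell filtering, single-cell and
# pooled-cell designs, the four index families (PSi/IS, Cws, NODF, WIC/TNW),
# the single-resource subset analysis, and the two-temporal-scale
# consistency comparison.

#' Analysis configuration
#'
#' @param levels Classification levels to analyse (subset of `"family"`,
#'   `"genus"`, `"guild"`).
#' @param measures Size measures to analyse (subset of `"body_length"`,
#'   `"carapace_width"`).
#' @param replicates Monte Carlo / permutation replicates for every null
#'   test (default 999).
#' @param seed Integer seed for every random step (cell selection and null
#'   models), or `NULL`.
#' @param max_cells_per_individual,min_items_per_cell Cell-selection
#'   parameters (see [cell_selection()]).
#' @param subset_resource For [run_subset_size_analysis()]: the resource on
#'   which retained individuals must forage exclusively.
#' @param subset_level Classification level at which `subset_resource` is
#'   matched (default `"family"`).
#' @param q_method Population-diet weighting for PSi (see [psi()]).
#' @param out_dir Optional directory; when set, reports are written there as
#'   CSV and JSON.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(levels = c("family", "genus", "guild"),
                            measures = c("body_length", "carapace_width"),
                            replicates = 999L,
                            seed = NULL,
                            max_cells_per_individual = 3L,
                            min_items_per_cell = 5L,
                            subset_resource = NULL,
                            subset_level = "family",
                            q_method = "equal",
                            out_dir = NULL) {
  levels <- match.arg(levels, c("family", "genus", "guild"),
                      several.ok = TRUE)
  measures <- match.arg(measures, c("body_length", "carapace_width"),
                        several.ok = TRUE)
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop_ds("replicates must be >= 1")
  if (length(levels) + length(measures) == 0L) {
    stop_ds("select at least one level or measure")
  }
  structure(
    list(levels = levels, measures = measures, replicates = replicates,
         seed = seed,
         max_cells_per_individual = as.integer(max_cells_per_individual),
         min_items_per_cell = as.integer(min_items_per_cell),
         subset_resource = subset_resource, subset_level = subset_level,
         q_method = q_method, out_dir = out_dir),
    class = "analysis_config"
  )
}

# derive a per-step seed from the config master seed (kept < 2^31)
step_seed <- function(seed, offset) {
  if (is.null(seed)) NULL else (as.integer(seed) + offset) %% 2147483647L
}

#' Single-cell (or pooled-cell) specialization analysis
#'
#' Applies the cell-selection rules (`max_cells` cells per individual after
#' dropping small cells; `max_cells = 1` gives the single-bout design), then
#' for every classification level computes PSi/IS with its multinomial null,
#' Cws with its null, and NODF with the marginal-probability null, and for
#' every size measure the WIC/TNW decomposition with its permutation null.
#'
#' @param records A `prey_records` data frame.
#' @param config An [analysis_config()].
#' @param max_cells Number of cells pooled per individual (default 1, the
#'   single-bout design).
#' @return A `specialization_report`: list of data frames `diet` (columns
#'   `level`, `psi_min`, `psi_max`, `is`, `p`), `clustering` (`level`,
#'   `cws`, `p`), `nestedness` (`level`, `nodf`, `nodf_null`, `p`),
#'   `niche_width` (`measure`, `wic`, `bic`, `tnw`, `ratio`, `p`), plus
#'   `results` (the full result objects) and `provenance`.
#' @export
run_single_cell_analysis <- function(records, config = analysis_config(),
                                     max_cells = 1L) {
  records <- prey_records(records)
  filtered <- filter_cells(
    records,
    cell_selection(max_cells_per_individual = max_cells,
                   min_items_per_cell = config$min_items_per_cell,
                   seed = step_seed(config$seed, 0L))
  )
  if (length(unique(filtered$individual_id)) < 2L) {
    stop_ds("fewer than 2 individuals remain after cell filtering")
  }
  diet_tab <- clus_tab <- nest_tab <- NULL
  results <- list()
  for (li in seq_along(config$levels)) {
    level <- config$levels[li]
    dm <- build_diet_matrix(filtered, level)
    if (ncol(dm$counts) == 1L) {
      warning("only one resource category at ", level,
              " level: indices are degenerate (IS = 1)", call. = FALSE)
    }
    ps <- psi_null_test(dm, config$replicates,
                        step_seed(config$seed, 10L + li),
                        q_method = config$q_method)
    nw <- overlap_network(dm)
    cw <- if (nrow(dm$counts) >= 3L) {
      cws(nw, dm, config$replicates, step_seed(config$seed, 20L + li),
          q_method = config$q_method)
    } else NULL
    nd <- nodf_null_test(dm, config$replicates,
                         step_seed(config$seed, 30L + li))
    diet_tab <- rbind(diet_tab, data.frame(
      level = level, psi_min = min(ps$psi), psi_max = max(ps$psi),
      is = ps$is_value, p = ps$p_value, stringsAsFactors = FALSE
    ))
    if (!is.null(cw)) {
      clus_tab <- rbind(clus_tab, data.frame(
        level = level, cws = cw$cws, p = cw$p_value,
        stringsAsFactors = FALSE
      ))
    }
    nest_tab <- rbind(nest_tab, data.frame(
      level = level, nodf = nd$nodf, nodf_null = nd$null_mean,
      p = nd$p_value, stringsAsFactors = FALSE
    ))
    results[[level]] <- list(psi = ps, cws = cw, nodf = nd, network = nw)
  }
  size_tab <- NULL
  for (mi in seq_along(config$measures)) {
    measure <- config$measures[mi]
    sizes <- extract_sizes(filtered, measure)
    if (length(sizes) < 2L) next
    res <- wic_tnw_null_test(sizes, config$replicates,
                             step_seed(config$seed, 40L + mi))
    size_tab <- rbind(size_tab, data.frame(
      measure = measure, wic = res$wic, bic = res$bic, tnw = res$tnw,
      ratio = res$ratio, p = res$p_value, stringsAsFactors = FALSE
    ))
    results[[measure]] <- res
  }
  report <- structure(
    list(diet = diet_tab, clustering = clus_tab, nestedness = nest_tab,
         niche_width = size_tab, results = results,
         provenance = c(attr(filtered, "provenance"),
                        list(max_cells = max_cells,
                             replicates = config$replicates,
                             seed = config$seed))),
    class = "specialization_report"
  )
  maybe_write_report(report, config, "single_cell")
  report
}

#' Temporal-consistency analysis across foraging bouts
#'
#' Restricts the data to individuals with at least `n_cells` qualifying
#' cells, computes each individual's PSi twice — from one randomly chosen
#' cell and from `n_cells` randomly chosen cells pooled — and compares the
#' paired PSi values with a paired t-test per classification level. If
#' foraging is consistent across bouts the two agree (or the single-cell
#' values are higher); if individuals drift between bouts the single-cell
#' values are systematically lower.
#'
#' @param records A `prey_records` data frame.
#' @param config An [analysis_config()].
#' @param n_cells Number of cells an individual must possess (and that are
#'   pooled); default 3.
#' @return A `temporal_report`: data frame `comparison` with columns
#'   `level`, `n`, `mean_single`, `mean_pooled`, `mean_diff`
#'   (single - pooled), `t`, `df`, `p`, plus `psi_values` (per-level data
#'   frames of the paired PSi).
#' @export
run_temporal_analysis <- function(records, config = analysis_config(),
                                  n_cells = 3L) {
  records <- prey_records(records)
  # drop undersized cells, keep all remaining cells for eligibility check
  filtered <- filter_cells(
    records,
    cell_selection(max_cells_per_individual = .Machine$integer.max,
                   min_items_per_cell = config$min_items_per_cell)
  )
  cells_per_ind <- tapply(
    filtered$cell_id, first_appearance_factor(filtered$individual_id),
    function(x) length(unique(x))
  )
  eligible <- names(cells_per_ind)[cells_per_ind >= n_cells]
  if (length(eligible) < 2L) {
    stop_ds("temporal analysis needs >= 2 individuals with >= ", n_cells,
            " qualifying cells; found ", length(eligible))
  }
  sub <- filtered[filtered$individual_id %in% eligible, , drop = FALSE]
  pooled <- filter_cells(
    sub,
    cell_selection(max_cells_per_individual = n_cells,
                   min_items_per_cell = config$min_items_per_cell,
                   seed = step_seed(config$seed, 100L))
  )
  single <- filter_cells(
    pooled,
    cell_selection(max_cells_per_individual = 1L,
                   min_items_per_cell = config$min_items_per_cell,
                   seed = step_seed(config$seed, 101L))
  )
  comp <- NULL
  psi_values <- list()
  for (level in config$levels) {
    ps_pooled <- psi(build_diet_matrix(pooled, level),
                     q_method = config$q_method)
    ps_single <- psi(build_diet_matrix(single, level),
                     q_method = config$q_method)
    ids <- intersect(names(ps_single$psi), names(ps_pooled$psi))
    x <- ps_single$psi[ids]
    y <- ps_pooled$psi[ids]
    tt <- tryCatch(paired_t(x, y), error = function(e) NULL)
    comp <- rbind(comp, data.frame(
      level = level, n = length(ids),
      mean_single = mean(x), mean_pooled = mean(y),
      mean_diff = mean(x - y),
      t = if (is.null(tt)) NA_real_ else tt$statistic,
      df = if (is.null(tt)) NA_integer_ else tt$df1,
      p = if (is.null(tt)) NA_real_ else tt$p_value,
      stringsAsFactors = FALSE
    ))
    psi_values[[level]] <- data.frame(
      individual_id = ids, psi_single = unname(x), psi_pooled = unname(y),
      stringsAsFactors = FALSE
    )
  }
  report <- structure(
    list(comparison = comp, psi_values = psi_values,
         provenance = list(n_cells = n_cells, eligible = eligible,
                           seed = config$seed)),
    class = "temporal_report"
  )
  maybe_write_report(report, config, "temporal")
  report
}

#' Size specialization within a single-resource subset
#'
#' Selects the individuals whose usable diet consists exclusively of
#' `config$subset_resource` (at `config$subset_level`), then quantifies size
#' specialization inside that subset: the WIC/TNW permutation test per size
#' measure and a one-way ANOVA of sizes among individuals. This isolates
#' specialization on prey size from specialization on prey taxa.
#'
#' @param records A `prey_records` data frame.
#' @param config An [analysis_config()] with `subset_resource` set.
#' @return A `subset_report`: `n_retained`, `individuals`, data frame
#'   `niche_width` (as in [run_single_cell_analysis()]) and `anova` (columns
#'   `measure`, `f`, `df1`, `df2`, `p`).
#' @export
run_subset_size_analysis <- function(records, config) {
  if (is.null(config$subset_resource)) {
    stop_ds("config$subset_resource must name a resource")
  }
  records <- prey_records(records)
  filtered <- filter_cells(
    records,
    cell_selection(max_cells_per_individual = config$max_cells_per_individual,
                   min_items_per_cell = config$min_items_per_cell,
                   seed = step_seed(config$seed, 200L))
  )
  lab <- filtered[[config$subset_level]]
  ok_by_ind <- tapply(lab == config$subset_resource,
                      first_appearance_factor(filtered$individual_id),
                      function(x) all(x, na.rm = FALSE))
  keep <- names(ok_by_ind)[!is.na(ok_by_ind) & ok_by_ind]
  if (length(keep) < 2L) {
    stop_ds("subset rule '", config$subset_resource, "' retains ",
            length(keep), " individual(s); need >= 2")
  }
  sub <- filtered[filtered$individual_id %in% keep, , drop = FALSE]
  size_tab <- anova_tab <- NULL
  results <- list()
  for (mi in seq_along(config$measures)) {
    measure <- config$measures[mi]
    sizes <- extract_sizes(sub, measure)
    if (length(sizes) < 2L) next
    res <- wic_tnw_null_test(sizes, config$replicates,
                             step_seed(config$seed, 210L + mi))
    av <- tryCatch(one_way_anova(sizes), error = function(e) NULL)
    size_tab <- rbind(size_tab, data.frame(
      measure = measure, wic = res$wic, bic = res$bic, tnw = res$tnw,
      ratio = res$ratio, p = res$p_value, stringsAsFactors = FALSE
    ))
    anova_tab <- rbind(anova_tab, data.frame(
      measure = measure,
      f = if (is.null(av)) NA_real_ else av$statistic,
      df1 = if (is.null(av)) NA_integer_ else av$df1,
      df2 = if (is.null(av)) NA_integer_ else av$df2,
      p = if (is.null(av)) NA_real_ else av$p_value,
      stringsAsFactors = FALSE
    ))
    results[[measure]] <- list(niche_width = res, anova = av)
  }
  report <- structure(
    list(n_retained = length(keep), individuals = keep,
         niche_width = size_tab, anova = anova_tab, results = results,
         provenance = list(subset_resource = config$subset_resource,
                           subset_level = config$subset_level,
                           seed = config$seed)),
    class = "subset_report"
  )
  maybe_write_report(report, config, "subset")
  report
}

maybe_write_report <- function(report, config, name) {
  dir <- config$out_dir
  if (is.null(dir)) return(invisible(NULL))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tab in c("diet", "clustering", "nestedness", "niche_width",
                "comparison", "anova")) {
    if (!is.null(report[[tab]]) && is.data.frame(report[[tab]])) {
      utils::write.csv(report[[tab]],
                       file.path(dir, paste0(name, "_", tab, ".csv")),
                       row.names = FALSE)
    }
  }
  slim <- report[!vapply(report, function(x)
    is.list(x) && !is.data.frame(x), logical(1))]
  jsonlite::write_json(slim, file.path(dir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  invisible(NULL)
}

#' @export
print.specialization_report <- function(x, digits = 3, ...) {
  cat("Individual specialization report\n\nDiet (PSi / IS):\n")
  print(x$diet, digits = digits, row.names = FALSE)
  if (!is.null(x$clustering)) {
    cat("\nNetwork clustering (Cws):\n")
    print(x$clustering, digits = digits, row.names = FALSE)
  }
  cat("\nNestedness (NODF):\n")
  print(x$nestedness, digits = digits, row.names = FALSE)
  if (!is.null(x$niche_width)) {
    cat("\nNiche width (WIC/TNW):\n")
    print(x$niche_width, digits = digits, row.names = FALSE)
  }
  invisible(x)
}

#' @export
print.temporal_report <- function(x, digits = 3, ...) {
  cat("Temporal consistency (single cell vs pooled cells)\n")
  print(x$comparison, digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
print.subset_report <- function(x, digits = 3, ...) {
  cat("Single-resource subset analysis (", x$n_retained,
      " individuals)\n\nNiche width:\n", sep = "")
  print(x$niche_width, digits = digits, row.names = FALSE)
  cat("\nANOVA among individuals:\n")
  print(x$anova, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Stacked diet-proportion plot ordered by PSi
#'
#' Draws one stacked bar of resource proportions per individual, ordered
#' from the most specialized (lowest PSi, left) to the most generalist
#' (highest PSi, right).
#'
#' @param diet A `diet_matrix`.
#' @param psi_result Optional `psi_result` for the ordering; computed from
#'   `diet` when absent.
#' @param ... Passed to [graphics::barplot()].
#' @return The PSi ordering, invisibly.
#' @export
plot_diet_proportions <- function(diet, psi_result = NULL, ...) {
  if (is.null(psi_result)) psi_result <- psi(diet)
  ord <- order(psi_result$psi)
  props <- t(diet_proportions(diet$counts)[ord, , drop = FALSE])
  cols <- grDevices::hcl.colors(nrow(props), "Spectral")
  graphics::barplot(props, col = cols, border = NA, las = 2,
                    ylab = "Diet proportion",
                    legend.text = rownames(props),
                    args.legend = list(x = "topright", bty = "n",
                                       cex = 0.7), ...)
  invisible(colnames(props))
}
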