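# Prey-record data model, CSV I/O, and the inclusion/exclusion rules applied
# before any index is computed: small cells are dropped, at most a fixed
# number of cells per female is kept, larva-damaged specimens are excluded
# from size analyses, and genus-unidentifiable specimens from genus-level
# diet matrices.

RECORD_COLUMNS <- c(
  "individual_id", "cell_id", "family", "genus", "guild",
  "body_length_mm", "carapace_width_mm",
  "genus_unidentifiable", "size_damaged"
)

#' Construct and validate a table of prey records
#'
#' A prey record is one captured prey item: its provenance (which individual's
#' nest, which nest cell), its classification (taxonomic family, genus,
#' ecological guild), two size measurements in millimetres, and two condition
#' flags. `genus_unidentifiable` marks specimens too damaged to identify to
#' genus (they are excluded from genus-level diet matrices);
#' `size_damaged` marks specimens too damaged to measure reliably (they are
#' excluded from size analyses).
#'
#' @param df A data frame with (a subset of) the columns `individual_id`,
#'   `cell_id`, `family`, `genus`, `guild`, `body_length_mm`,
#'   `carapace_width_mm`, `genus_unidentifiable`, `size_damaged`. Missing
#'   classification/size columns are filled with `NA`; missing flag columns
#'   default to `FALSE`.
#' @return The validated data frame with class `prey_records`, all canonical
#'   columns present and typed.
#' @details Validation enforces: sizes, when present, are strictly positive;
#'   `genus_unidentifiable = TRUE` forces `genus = NA`; every record carries a
#'   non-missing family unless it is flagged `genus_unidentifiable`.
#' @export
prey_records <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c("individual_id", "cell_id")) {
    if (!col %in% names(df)) {
      stop_ds("prey records need a '", col, "' column")
    }
    df[[col]] <- as.character(df[[col]])
    if (anyNA(df[[col]])) {
      stop_ds("missing ", col, " in row(s) ",
              paste(which(is.na(df[[col]])), collapse = ", "))
    }
  }
  for (col in c("family", "genus", "guild")) {
    df[[col]] <- if (col %in% names(df)) as.character(df[[col]]) else
      NA_character_
  }
  for (col in c("body_length_mm", "carapace_width_mm")) {
    v <- if (col %in% names(df)) df[[col]] else NA_real_
    v <- suppressWarnings(as.numeric(v))
    if (col %in% names(df)) {
      bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "")
      if (length(bad)) {
        stop_ds("non-numeric ", col, " in row(s) ",
                paste(bad, collapse = ", "))
      }
    }
    nonpos <- which(!is.na(v) & v <= 0)
    if (length(nonpos)) {
      stop_ds(col, " must be > 0; violated in row(s) ",
              paste(nonpos, collapse = ", "))
    }
    df[[col]] <- v
  }
  for (col in c("genus_unidentifiable", "size_damaged")) {
    v <- if (col %in% names(df)) parse_flag(df[[col]], col) else FALSE
    df[[col]] <- v
  }
  df <- df[RECORD_COLUMNS]
  # invariant: unidentifiable-to-genus forces genus missing
  df$genus[df$genus_unidentifiable] <- NA_character_
  no_family <- which(is.na(df$family) & !df$genus_unidentifiable)
  if (length(no_family)) {
    stop_ds("family missing without genus_unidentifiable flag in row(s) ",
            paste(no_family, collapse = ", "))
  }
  class(df) <- c("prey_records", "data.frame")
  df
}

parse_flag <- function(x, name) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  v <- tolower(trimws(as.character(x)))
  out <- rep(FALSE, length(v))
  out[v %in% c("true", "t", "1", "yes")] <- TRUE
  bad <- which(!v %in% c("true", "t", "1", "yes",
                         "false", "f", "0", "no", "na", ""))
  if (length(bad)) {
    stop_ds("cannot parse ", name, " as logical in row(s) ",
            paste(bad, collapse = ", "))
  }
  out
}

#' Read prey records from CSV
#'
#' @param path Path to a UTF-8 CSV file with a header row. Empty strings and
#'   `"NA"` are read as missing.
#' @param dialect Optional named character vector mapping canonical column
#'   names (see [prey_records()]) to the column names used in the file, e.g.
#'   `c(individual_id = "nest", body_length_mm = "BL")`. Unmapped canonical
#'   names are looked up verbatim.
#' @return A `prey_records` data frame.
#' @export
read_records <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop_ds("no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"), check.names = FALSE)
  if (!is.null(dialect)) {
    unknown <- setdiff(names(dialect), RECORD_COLUMNS)
    if (length(unknown)) {
      stop_ds("dialect maps unknown column(s): ",
              paste(unknown, collapse = ", "))
    }
    missing_cols <- setdiff(unname(dialect), names(raw))
    if (length(missing_cols)) {
      stop_ds("mapped column(s) absent from header: ",
              paste(missing_cols, collapse = ", "))
    }
    for (canon in names(dialect)) {
      names(raw)[names(raw) == dialect[[canon]]] <- canon
    }
  }
  prey_records(raw)
}

#' Write prey records to CSV
#'
#' The written file round-trips through [read_records()].
#'
#' @param records A `prey_records` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  records <- prey_records(records)
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Cell-selection rule
#'
#' Nest cells with fewer than `min_items_per_cell` intact prey are excluded;
#' from the cells that remain, at most `max_cells_per_individual` are kept per
#' individual, chosen uniformly at random. The defaults reproduce the field
#' protocol of dropping cells with under 5 intact spiders and sampling up to
#' 3 cells per female.
#'
#' @param max_cells_per_individual Positive integer, default 3.
#' @param min_items_per_cell Positive integer, default 5.
#' @param seed Integer seed driving the random cell choice, or `NULL` to use
#'   the current RNG stream.
#' @return An object of class `cell_selection`.
#' @export
cell_selection <- function(max_cells_per_individual = 3L,
                           min_items_per_cell = 5L,
                           seed = NULL) {
  max_cells_per_individual <- as.integer(max_cells_per_individual)
  min_items_per_cell <- as.integer(min_items_per_cell)
  if (max_cells_per_individual < 1L) {
    stop_ds("max_cells_per_individual must be >= 1")
  }
  if (min_items_per_cell < 1L) stop_ds("min_items_per_cell must be >= 1")
  structure(
    list(max_cells_per_individual = max_cells_per_individual,
         min_items_per_cell = min_items_per_cell,
         seed = seed),
    class = "cell_selection"
  )
}

#' Apply the cell inclusion/selection rules
#'
#' @param records A `prey_records` data frame.
#' @param selection A [cell_selection()] object.
#' @return The retained records, with a `"provenance"` attribute listing the
#'   cells dropped for being too small, the cells sampled away, and the seed.
#'   An individual whose cells are all too small is simply absent from the
#'   output. Deterministic given `selection$seed`; idempotent (a second
#'   application never drops anything further).
#' @export
filter_cells <- function(records, selection = cell_selection()) {
  records <- prey_records(records)
  key <- paste(records$individual_id, records$cell_id, sep = "\r")
  n_per_cell <- table(first_appearance_factor(key))
  small <- names(n_per_cell)[n_per_cell < selection$min_items_per_cell]
  kept <- !(key %in% small)
  rec <- records[kept, , drop = FALSE]
  key <- key[kept]

  sampled_out <- character(0)
  cells_by_ind <- split(
    unique(key),
    vapply(strsplit(unique(key), "\r", fixed = TRUE), `[[`, "", 1L)
  )
  # individuals visited in first-appearance order so draws are reproducible
  ind_order <- unique(rec$individual_id)
  with_seed(selection$seed, {
    for (ind in ind_order) {
      cells <- cells_by_ind[[ind]]
      if (length(cells) > selection$max_cells_per_individual) {
        keep <- sample(cells, selection$max_cells_per_individual)
        sampled_out <- c(sampled_out, setdiff(cells, keep))
      }
    }
  })
  rec <- rec[!(key %in% sampled_out), , drop = FALSE]
  rownames(rec) <- NULL

  split_key <- function(k) {
    parts <- strsplit(k, "\r", fixed = TRUE)
    data.frame(
      individual_id = vapply(parts, `[[`, "", 1L),
      cell_id = vapply(parts, `[[`, "", 2L),
      stringsAsFactors = FALSE
    )
  }
  attr(rec, "provenance") <- list(
    min_items_per_cell = selection$min_items_per_cell,
    max_cells_per_individual = selection$max_cells_per_individual,
    seed = selection$seed,
    dropped_small_cells = split_key(small),
    sampled_out_cells = split_key(sampled_out)
  )
  rec
}

#' Build an individuals-by-resources diet count matrix
#'
#' @param records A filtered `prey_records` data frame.
#' @param level Classification level: `"family"`, `"genus"` or `"guild"`.
#' @return A `diet_matrix`: a list with `counts` (integer matrix, rows =
#'   individuals, columns = resource categories, both in first-appearance
#'   order) and `level`.
#' @details At `level = "genus"` records flagged `genus_unidentifiable` (or
#'   with missing genus) are excluded, mirroring the exclusion of specimens
#'   not identifiable to genus. At `level = "guild"` records with a missing
#'   guild are dropped with a warning. Individuals contributing no usable
#'   record and all-zero resource columns are absent from the matrix.
#' @export
build_diet_matrix <- function(records, level = c("family", "genus", "guild")) {
  level <- match.arg(level)
  records <- prey_records(records)
  lab <- records[[level]]
  usable <- !is.na(lab)
  if (level == "guild" && any(!usable)) {
    warning(sum(!usable), " record(s) with missing guild dropped from the ",
            "guild-level matrix", call. = FALSE)
  }
  rec <- records[usable, , drop = FALSE]
  if (nrow(rec) == 0L) stop_ds("no usable records at level '", level, "'")
  counts <- table(
    first_appearance_factor(rec$individual_id),
    first_appearance_factor(rec[[level]])
  )
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  new_diet_matrix(counts, level)
}

new_diet_matrix <- function(counts, level) {
  counts <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
  if (length(counts) == 0L) stop_ds("empty diet matrix")
  structure(
    list(counts = counts,
         individual_ids = rownames(counts),
         resource_labels = colnames(counts),
         level = level),
    class = "diet_matrix"
  )
}

#' @export
print.diet_matrix <- function(x, ...) {
  cat("Diet matrix (", x$level, " level): ", nrow(x$counts),
      " individuals x ", ncol(x$counts), " resources, ",
      sum(x$counts), " items\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' @export
as.matrix.diet_matrix <- function(x, ...) x$counts

#' Extract per-individual prey-size samples
#'
#' @param records A filtered `prey_records` data frame.
#' @param measure `"body_length"` or `"carapace_width"`.
#' @return A named list, one numeric vector of sizes (mm) per individual, in
#'   first-appearance order. Records flagged `size_damaged` and records with
#'   the measurement missing are excluded; an individual left with no usable
#'   measurement is dropped with a warning.
#' @export
extract_sizes <- function(records, measure = c("body_length",
                                               "carapace_width")) {
  measure <- match.arg(measure)
  records <- prey_records(records)
  col <- paste0(measure, "_mm")
  ok <- !records$size_damaged & !is.na(records[[col]])
  rec <- records[ok, , drop = FALSE]
  out <- split(rec[[col]], first_appearance_factor(rec$individual_id))
  empty <- setdiff(unique(records$individual_id), names(out))
  if (length(empty)) {
    warning("individual(s) without usable ", measure, " measurements ",
            "dropped: ", paste(empty, collapse = ", "), call. = FALSE)
  }
  out
}

#' Write a diet matrix as CSV with a JSON provenance sidecar
#'
#' @param diet A `diet_matrix`.
#' @param path Output CSV path (row label column `individual_id`, one column
#'   per resource).
#' @param provenance Optional provenance list (e.g. the `"provenance"`
#'   attribute of [filter_cells()] output); written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_diet_matrix <- function(diet, path, provenance = NULL) {
  df <- data.frame(individual_id = rownames(diet$counts),
                   as.data.frame(diet$counts), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(provenance)) {
    jsonlite::write_json(provenance, paste0(path, ".json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
  }
  invisible(path)
}
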