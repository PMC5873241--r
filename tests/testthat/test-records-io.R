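test_that("CSV round trip preserves records, missing tokens and flags", {
  rec <- make_records(
    individual = c("A", "A", "B"), cell = c("c1", "c1", "c1"),
    family = c("Araneidae", "Salticidae", "Araneidae"),
    genus = c("Argiope", NA, "Neoscona"),
    body_length = c(5.2, 3.1, 7.7),
    carapace_width = c(1.5, 0.9, 2.2),
    genus_unidentifiable = c(FALSE, TRUE, FALSE)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(rec, path)
  back <- read_records(path)
  expect_equal(as.data.frame(back), as.data.frame(rec))
  # the unidentifiable-to-genus flag forces genus missing
  expect_true(is.na(back$genus[2]))
})

test_that("dialect mapping adapts arbitrary headers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("nest,chamber,fam,BL",
               "n1,c1,Araneidae,5.5",
               "n1,c1,Salticidae,3.0"), path)
  rec <- read_records(path, dialect = c(individual_id = "nest",
                                        cell_id = "chamber",
                                        family = "fam",
                                        body_length_mm = "BL"))
  expect_equal(rec$individual_id, c("n1", "n1"))
  expect_equal(rec$body_length_mm, c(5.5, 3.0))
  expect_error(read_records(path, dialect = c(individual_id = "nope")),
               "absent from header")
})

test_that("invalid rows are rejected with their row numbers", {
  df <- data.frame(individual_id = "A", cell_id = "c1",
                   family = "Araneidae", body_length_mm = -1)
  expect_error(prey_records(df), "row\\(s\\) 1")
  df2 <- data.frame(individual_id = c("A", "B"), cell_id = "c1",
                    family = c("Araneidae", NA),
                    genus_unidentifiable = c(FALSE, FALSE))
  expect_error(prey_records(df2), "family missing.*row\\(s\\) 2")
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("individual_id,cell_id,family,body_length_mm",
               "A,c1,Araneidae,abc"), path)
  expect_error(read_records(path), "non-numeric body_length_mm")
})

test_that("small cells are dropped and cell sampling is seeded", {
  rec <- rbind(
    records_block("A", "c1", "Araneidae", 4),
    records_block("A", "c2", "Araneidae", 6),
    records_block("A", "c3", "Salticidae", 7)
  )
  out <- filter_cells(rec, cell_selection())
  expect_setequal(unique(out$cell_id), c("c2", "c3"))
  expect_equal(attr(out, "provenance")$dropped_small_cells$cell_id, "c1")

  # 5 qualifying cells, max 3: exactly 3 kept, identical on re-run
  rec5 <- do.call(rbind, lapply(1:5, function(i) {
    records_block("A", paste0("c", i), "Araneidae", 6)
  }))
  sel <- cell_selection(max_cells_per_individual = 3, seed = 42)
  out1 <- filter_cells(rec5, sel)
  out2 <- filter_cells(rec5, sel)
  expect_length(unique(out1$cell_id), 3)
  expect_identical(as.data.frame(out1), as.data.frame(out2))

  # idempotent: a second application (any seed) changes nothing
  out3 <- filter_cells(out1, cell_selection(max_cells_per_individual = 3,
                                            seed = 999))
  expect_equal(as.data.frame(out3), as.data.frame(out1),
               ignore_attr = TRUE)
  expect_equal(nrow(attr(out3, "provenance")$sampled_out_cells), 0)

  # all cells below threshold: individual absent
  expect_equal(nrow(filter_cells(records_block("A", "c1", "Araneidae", 3))),
               0)
})

test_that("diet matrices tabulate counts and honour exclusion rules", {
  rec <- rbind(
    make_records(rep("A", 3), "c1", rep("Fam1", 3)),
    make_records(c("B", "B"), "c1", c("Fam1", "Fam2"))
  )
  dm <- build_diet_matrix(rec, "family")
  expect_equal(unname(dm$counts), matrix(c(3L, 1L, 0L, 1L), 2))
  expect_equal(sum(dm$counts), nrow(rec))  # conservation

  # genus-unidentifiable records excluded only at genus level
  rec2 <- rbind(
    make_records("A", "c1", "Fam1", genus = "G1"),
    make_records("A", "c1", "Fam1", genus = NA,
                 genus_unidentifiable = TRUE),
    make_records("B", "c1", "Fam2", genus = "G2")
  )
  expect_equal(sum(build_diet_matrix(rec2, "genus")$counts), 2)
  expect_equal(sum(build_diet_matrix(rec2, "family")$counts), 3)

  # single shared taxon: one-column matrix
  rec3 <- rbind(records_block("A", "c1", "Fam1", 2),
                records_block("B", "c1", "Fam1", 2))
  expect_equal(ncol(build_diet_matrix(rec3, "family")$counts), 1)

  # missing guild records dropped with a warning at guild level
  rec4 <- rbind(
    make_records("A", "c1", "Fam1", guild = "orb"),
    make_records("A", "c1", "Fam1", guild = NA)
  )
  expect_warning(dm4 <- build_diet_matrix(rec4, "guild"), "missing guild")
  expect_equal(sum(dm4$counts), 1)

  # never more family columns than distinct family labels
  fams <- sample(paste0("F", 1:4), 30, replace = TRUE)
  rec5 <- make_records(rep(c("A", "B", "C"), each = 10),
                       "c1", fams)
  expect_lte(ncol(build_diet_matrix(rec5, "family")$counts),
             length(unique(fams)))
})

test_that("size extraction excludes damaged and missing measurements", {
  rec <- make_records(
    rep("A", 3), "c1", rep("Fam1", 3),
    body_length = c(5, 6, 7),
    size_damaged = c(FALSE, TRUE, FALSE)
  )
  expect_equal(extract_sizes(rec, "body_length")$A, c(5, 7))

  expect_warning(
    out <- extract_sizes(
      make_records("A", "c1", "Fam1", size_damaged = TRUE), "body_length"),
    "without usable"
  )
  expect_length(out, 0)

  # per-measure filtering: missing body length, present carapace width
  rec2 <- make_records("A", "c1", "Fam1",
                       body_length = NA, carapace_width = 1.4)
  expect_equal(extract_sizes(rec2, "carapace_width")$A, 1.4)
})

test_that("diet matrices export to CSV with a provenance sidecar", {
  rec <- rbind(records_block("A", "c1", "Fam1", 6),
               records_block("B", "c1", "Fam2", 6))
  filtered <- filter_cells(rec)
  dm <- build_diet_matrix(filtered, "family")
  path <- withr::local_tempfile(fileext = ".csv")
  write_diet_matrix(dm, path, provenance = attr(filtered, "provenance"))
  back <- utils::read.csv(path, check.names = FALSE)
  expect_equal(back$individual_id, c("A", "B"))
  expect_equal(back$Fam1, c(6L, 0L))
  sidecar <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(sidecar$min_items_per_cell, 5)
})
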