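test_that("configuration validates and normalizes its parameters", {
  cfg <- synthetic_config(seed = 1)
  expect_equal(sum(cfg$resources), 1)
  expect_equal(unname(cfg$resources[1]), 0.73, tolerance = 1e-12)
  expect_error(synthetic_config(concentration = 0), "concentration")
  expect_error(synthetic_config(drift = 1.5), "drift")
  expect_error(synthetic_config(structure = "modular", n_groups = 10),
               "n_groups")
  expect_error(synthetic_config(items_per_cell = c(9, 5)), "ranges")
})

test_that("generation is deterministic given the seed and respects ranges", {
  cfg <- synthetic_config(seed = 21)
  a <- generate_population(cfg)
  b <- generate_population(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  summ <- describe_population(a)
  expect_equal(nrow(summ), 30)
  expect_true(all(summ$min_items_per_cell >= 5))
  expect_true(all(summ$max_items_per_cell <= 25))
  expect_true(all(summ$n_cells >= 1 & summ$n_cells <= 3))
  expect_true(all(a$body_length_mm >= 0.1))
  # dominant resource structure carries through to the pooled diet
  expect_equal(attr(summ, "population_top_resource"), "Nephilidae")
  expect_gt(attr(summ, "population_top_prop"), 0.5)
})

test_that("high concentration with no drift pins diets to q0", {
  cfg <- synthetic_config(concentration = 1000, drift = 0, seed = 5,
                          items_per_cell = c(25, 25),
                          cells_per_individual = c(3, 3))
  rec <- generate_population(cfg)
  base <- attr(rec, "base_diets")
  tv <- apply(base, 1, function(p) 0.5 * sum(abs(p - cfg$resources)))
  expect_true(all(tv < 0.05))
})

test_that("nested populations build subset-chain diets", {
  cfg <- synthetic_config(structure = "nested", n_individuals = 8,
                          items_per_cell = c(300, 300),
                          cells_per_individual = c(1, 1), seed = 3)
  rec <- generate_population(cfg)
  m <- (build_diet_matrix(rec, "family")$counts >= 1) * 1
  # order rows by fill: every sparser diet is a subset of every fuller one
  ord <- order(rowSums(m), decreasing = TRUE)
  m <- m[ord, , drop = FALSE]
  for (u in seq_len(nrow(m) - 1)) {
    for (v in (u + 1):nrow(m)) {
      expect_true(all(m[u, ] >= m[v, ]))
    }
  }
})

test_that("modular populations occupy disjoint resource blocks", {
  cfg <- synthetic_config(structure = "modular", n_groups = 2,
                          n_individuals = 10, seed = 17,
                          items_per_cell = c(200, 200),
                          cells_per_individual = c(1, 1))
  rec <- generate_population(cfg)
  base <- attr(rec, "base_diets")
  supports <- unique(apply(base > 0, 1, paste, collapse = ""))
  expect_length(supports, 2)
  # groups share no resource
  s1 <- base[1, ] > 0
  s2 <- base[2, ] > 0
  expect_false(any(s1 & s2))
})

test_that("zero between-individual variance drives WIC/TNW toward 1", {
  cfg <- synthetic_config(
    resources = c(OneTaxon = 1), n_individuals = 10,
    cells_per_individual = c(1, 1), items_per_cell = c(200, 200),
    size_model = list(sigma_b = 0, sigma_w = 1.5), seed = 8
  )
  rec <- generate_population(cfg)
  ratio <- wic_tnw(extract_sizes(rec, "body_length"))$ratio
  expect_gt(ratio, 0.95)
})

test_that("configs round-trip through YAML and JSON files", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_individuals: 5",
               "concentration: 0.5",
               "structure: nested",
               "seed: 99",
               "resources:",
               "  A: 0.6",
               "  B: 0.4"), yml)
  cfg <- synthetic_config_from_file(yml)
  expect_equal(cfg$n_individuals, 5)
  expect_equal(cfg$structure, "nested")
  expect_equal(unname(cfg$resources), c(0.6, 0.4))

  jsn <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(n_individuals = 4, drift = 0.5,
                            resources = list(A = 0.5, B = 0.5)),
                       jsn, auto_unbox = TRUE)
  cfg2 <- synthetic_config_from_file(jsn)
  expect_equal(cfg2$drift, 0.5)
  # generated records flow straight back through the CSV dialect
  rec <- generate_population(synthetic_config_from_file(yml))
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(rec, path)
  expect_equal(nrow(read_records(path)), nrow(rec))
})
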