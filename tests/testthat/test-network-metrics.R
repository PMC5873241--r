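test_that("overlap network weights are pairwise proportional similarities", {
  # identical diets -> weight 1; disjoint diets -> weight 0
  nw <- overlap_network(make_diet(rbind(c(2, 2), c(4, 4), c(6, 0))))
  expect_equal(nw$weights[1, 2], 1)
  expect_equal(diag(nw$weights), rep(0, 3), ignore_attr = TRUE)
  expect_equal(nw$weights, t(nw$weights))
  nw2 <- overlap_network(make_diet(rbind(c(3, 0), c(0, 3))))
  expect_equal(nw2$weights[1, 2], 0)
  # p_i = (0.5, 0.5) vs p_j = (1, 0) -> w = 0.5
  nw3 <- overlap_network(make_diet(rbind(c(2, 2), c(4, 0))))
  expect_equal(nw3$weights[1, 2], 0.5)
})

test_that("Cws sign anchors: generalists 0, disjoint pairs -1, groups < 0", {
  # identical generalist diets: clustering = density = 1 -> Cws = 0
  ident <- make_diet(matrix(2, 4, 3))
  expect_equal(cws_index(overlap_network(ident)), 0)

  # two disjoint specialist pairs: no triangles, density 1/3 -> Cws = -1
  pairs <- make_diet(rbind(c(5, 0), c(5, 0), c(0, 5), c(0, 5)))
  expect_equal(cws_index(overlap_network(pairs)), -1)

  # two discrete groups of >= 3 specialists -> Cws < 0
  groups <- make_diet(rbind(c(5, 0), c(5, 0), c(5, 0),
                            c(0, 5), c(0, 5), c(0, 5)))
  expect_lt(cws_index(overlap_network(groups)), 0)

  expect_error(cws_index(overlap_network(make_diet(rbind(c(1, 0),
                                                         c(0, 1))))),
               "at least 3")
})

test_that("Cws null test is two-sided, seeded, and bounded in [-1, 1]", {
  dm <- make_diet(rbind(c(8, 0, 1), c(7, 1, 0), c(0, 8, 0),
                        c(1, 7, 0), c(0, 0, 9)))
  nw <- overlap_network(dm)
  a <- cws(nw, dm, replicates = 199, seed = 5)
  b <- cws(nw, dm, replicates = 199, seed = 5)
  expect_identical(a$null_cws, b$null_cws)
  expect_equal(a$p_value,
               (sum(abs(a$null_cws) >= abs(a$cws) - 1e-12) + 1) / 200)
  expect_true(all(abs(c(a$cws, a$null_cws)) <= 1))
  expect_equal(a$cws,
               (a$mean_clustering - a$density) /
                 max(a$mean_clustering, a$density))
})

test_that("NODF matches its definition on canonical matrices", {
  chain <- matrix(0, 3, 3)
  chain[lower.tri(chain, diag = TRUE)] <- 1
  expect_equal(nodf(chain), 100)
  expect_equal(nodf(diag(4)), 0)
  expect_equal(nodf(matrix(c(1, 1, 0, 0, 1, 1), 2, 3, byrow = TRUE)), 50)
  expect_error(nodf(matrix(0, 3, 3)), "all-zero")
  # a diet matrix is thresholded at >= 1
  dm <- make_diet(rbind(c(4, 2, 1), c(2, 1, 0), c(9, 0, 0)))
  expect_equal(nodf(dm), 100)
})

test_that("NODF is permutation invariant and transpose-consistent", {
  set.seed(3)
  for (rep in 1:20) {
    m <- matrix(rbinom(20, 1, 0.5), 4, 5)
    if (sum(m) == 0) next
    expect_equal(nodf(m[sample(4), sample(5)]), nodf(m))
  }
  for (rep in 1:20) {
    m <- matrix(rbinom(16, 1, 0.5), 4, 4)
    if (sum(m) == 0) next
    expect_equal(nodf(t(m)), nodf(m))
  }
})

test_that("NODF agrees with an exhaustive brute-force second coding", {
  # all 512 binary 3x3 matrices
  for (code in 1:511) {
    m <- matrix(as.integer(intToBits(code)[1:9]), 3, 3)
    expect_equal(nodf(m), nodf_oracle(m))
  }
})

test_that("NODF agrees with vegan's independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(8)
  for (rep in 1:15) {
    m <- matrix(rbinom(48, 1, runif(1, 0.2, 0.8)), 6, 8)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    ref <- unname(vegan::nestednodf(m)$statistic["NODF"])
    expect_equal(nodf(m), ref, tolerance = 1e-10)
  }
})

test_that("NODF null test seeds, reports the null mean, and handles
           degenerate fills", {
  m <- rbind(c(1, 1, 1, 1), c(1, 1, 1, 0), c(1, 1, 0, 0), c(1, 0, 0, 0))
  res <- nodf_null_test(m, replicates = 199, seed = 2)
  expect_equal(res$nodf, 100)
  expect_equal(res$null_mean, mean(res$null_nodf))
  expect_equal(res$p_value,
               (sum(res$null_nodf >= res$nodf - 1e-12) + 1) / 200)
  # strictly nested observed beats essentially every null replicate
  expect_lt(res$p_value, 0.05)

  # full matrix: every cell probability 1, all nulls identical -> p = 1
  full <- nodf_null_test(matrix(1, 3, 3), replicates = 49, seed = 1)
  expect_equal(full$p_value, 1)
  expect_true(all(full$null_nodf == full$nodf))
})

test_that("networks export to edge lists and GraphML", {
  dm <- make_diet(rbind(c(5, 1), c(1, 5), c(3, 3)))
  nw <- overlap_network(dm)
  edges <- network_edges(nw)
  expect_equal(nrow(edges), 3)
  expect_true(all(edges$weight > 0 & edges$weight <= 1))
  path <- withr::local_tempfile(fileext = ".graphml")
  network_to_graphml(nw, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::gsize(g), 3)
})
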