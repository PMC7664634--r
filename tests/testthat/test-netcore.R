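test_that("a minimal one-node BIF parses to a single-variable network", {
  tf <- withr::local_tempfile(fileext = ".bif")
  writeLines(c(
    "network toy {", "}",
    "variable A {",
    "  type discrete [ 2 ] { yes, no };",
    "}",
    "probability ( A ) {",
    "  table 0.5, 0.5;",
    "}"
  ), tf)
  net <- read_bif(tf)
  expect_identical(net$variables, "A")
  expect_identical(nrow(bn_edges(net)), 0L)
  expect_equal(net$cpts$A, matrix(c(0.5, 0.5), 1))
  expect_identical(net$states$A, c("yes", "no"))
})

test_that("a two-node BIF yields the edge and a two-row child CPT", {
  tf <- withr::local_tempfile(fileext = ".bif")
  writeLines(c(
    "variable A { type discrete [ 2 ] { a0, a1 }; }",
    "variable B { type discrete [ 2 ] { b0, b1 }; }",
    "probability ( A ) { table 0.3, 0.7; }",
    "probability ( B | A ) {",
    "  (a0) 0.9, 0.1;",
    "  (a1) 0.2, 0.8;",
    "}"
  ), tf)
  net <- read_bif(tf)
  expect_equal(unname(bn_edges(net)), matrix(c("A", "B"), 1))
  expect_identical(nrow(net$cpts$B), 2L)
  expect_equal(net$cpts$B[1, ], c(0.9, 0.1))
})

test_that("malformed CPT rows are rejected with a line number", {
  tf <- withr::local_tempfile(fileext = ".bif")
  writeLines(c(
    "variable A { type discrete [ 2 ] { a0, a1 }; }",
    "probability ( A ) { table 0.5, 0.6; }"
  ), tf)
  expect_error(read_bif(tf), "line 2.*sums to")
})

test_that("BIF write-then-read round-trips variables, edges and CPTs", {
  net <- generate_block_network(block_spec(2, 3, intra_density = 0.8,
                                           n_interblock = 1, seed = 13))
  tf <- withr::local_tempfile(fileext = ".bif")
  write_bif(net, tf)
  net2 <- read_bif(tf)
  expect_identical(net2$variables, net$variables)
  expect_identical(bn_edges(net2), bn_edges(net))
  expect_lt(max(abs(unlist(net2$cpts) - unlist(net$cpts))), 1e-9)
})

test_that("forward sampling of deterministic CPTs forces one configuration", {
  net <- bn_net(
    c("A", "B"), c(2L, 2L),
    parents = list(A = character(0), B = "A"),
    cpts = list(A = matrix(c(0, 1), 1),
                B = matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE))
  )
  d <- forward_sample(net, 50, seed = 3)
  expect_true(all(d$values[, "A"] == 1L))
  expect_true(all(d$values[, "B"] == 1L))
})

test_that("a fair binary root's empirical frequency obeys the binomial bound", {
  net <- bn_net("A", 2L, parents = list(A = character(0)),
                cpts = list(A = matrix(c(0.5, 0.5), 1)))
  d <- forward_sample(net, 10000, seed = 11)
  expect_lt(abs(mean(d$values[, 1]) - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("root marginals converge to CPT marginals (4-sigma at n = 50000)", {
  net <- random_net(4, edge_prob = 0.6, seed = 8)
  d <- forward_sample(net, 50000, seed = 9)
  roots <- net$variables[lengths(net$parents) == 0]
  for (v in roots) {
    pr <- net$cpts[[v]][1, ]
    for (s in seq_along(pr)) {
      emp <- mean(d$values[, v] == s - 1L)
      expect_lt(abs(emp - pr[s]), 4 * sqrt(pr[s] * (1 - pr[s]) / 50000) + 1e-12)
    }
  }
})

test_that("sampling is deterministic in (net, n, seed)", {
  net <- random_net(5, seed = 2)
  d1 <- forward_sample(net, 200, seed = 42)
  d2 <- forward_sample(net, 200, seed = 42)
  expect_identical(d1$values, d2$values)
})

test_that("block-network generation honours the spec partition and counts", {
  # single block at full density: complete DAG
  net <- generate_block_network(block_spec(1, 3, intra_density = 1.0,
                                           n_interblock = 0, seed = 1))
  expect_identical(nrow(bn_edges(net)), 3L)
  expect_silent(blmkm:::validate_bn_net(net))

  # 2 blocks x 3 nodes, exactly 1 crossing edge
  net2 <- generate_block_network(block_spec(2, 3, intra_density = 0.6,
                                            n_interblock = 1, seed = 4))
  blocks <- attr(net2, "blocks")
  block_of <- integer(6)
  for (b in seq_along(blocks)) block_of[blocks[[b]]] <- b
  idx <- stats::setNames(seq_along(net2$variables), net2$variables)
  e <- bn_edges(net2)
  crossing <- sum(block_of[idx[e[, 1]]] != block_of[idx[e[, 2]]])
  expect_identical(crossing, 1L)

  # determinism
  net3 <- generate_block_network(block_spec(2, 3, intra_density = 0.6,
                                            n_interblock = 1, seed = 4))
  expect_identical(bn_edges(net3), bn_edges(net2))
  expect_equal(net3$cpts, net2$cpts)

  # infeasible inter-block request
  expect_error(generate_block_network(block_spec(2, 2, n_interblock = 100, seed = 1)),
               "infeasible")
})

test_that("generated CPT rows stay away from uniform", {
  net <- generate_block_network(three_block_spec(seed = 6))
  for (v in net$variables) {
    cpt <- net$cpts[[v]]
    r <- ncol(cpt)
    tv <- apply(cpt, 1, function(pr) 0.5 * sum(abs(pr - 1 / r)))
    expect_true(all(tv >= 0.1 - 1e-9))
  }
})

test_that("data matrices round-trip through CSV and TSV with auto-detection", {
  d <- independent_data(20, 3, cards = 3L, seed = 5)
  fc <- withr::local_tempfile(fileext = ".csv")
  ft <- withr::local_tempfile(fileext = ".tsv")
  write_data_matrix(d, fc, delim = ",")
  write_data_matrix(d, ft, delim = "\t")
  expect_identical(read_data_matrix(fc)$values, d$values)
  expect_identical(read_data_matrix(ft)$values, d$values)
})

test_that("incomplete or out-of-range data is rejected at load time", {
  m <- matrix(c(0L, 1L, NA, 0L), 2, 2)
  expect_error(bn_data(m), "complete")
  expect_error(bn_data(matrix(c(0L, 3L), 2, 1), cardinalities = 2L), "cardinality")
})
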