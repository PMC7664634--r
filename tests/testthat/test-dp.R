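test_that("the MDL node score matches the closed form on hand counts", {
  # binary X with counts (3, 1), N = 4, no parents:
  # H = -(3 log(3/4) + 1 log(1/4)) = 4 log 4 - 3 log 3; K = 1;
  # MDL = H + (log 4 / 2) * 1
  d <- bn_data(matrix(c(0L, 0L, 0L, 1L), ncol = 1, dimnames = list(NULL, "X")))
  st <- mdl_node(d, 1)
  expect_equal(st$H, 4 * log(4) - 3 * log(3), tolerance = 1e-9)
  expect_identical(st$K, 1L)
  expect_equal(st$mdl, st$H + log(4) / 2, tolerance = 1e-9)
})

test_that("a deterministic child has zero conditional entropy", {
  x <- c(0L, 1L, 0L, 1L, 1L, 0L)
  d <- bn_data(cbind(A = x, B = x))
  expect_equal(mdl_node(d, 2, pa = 1)$H, 0)
})

test_that("the parameter count multiplies parent cardinalities", {
  set.seed(2)
  d <- bn_data(cbind(X = sample(0:1, 60, TRUE),
                     P1 = sample(0:2, 60, TRUE),
                     P2 = sample(0:2, 60, TRUE)),
               cardinalities = c(2L, 3L, 3L))
  expect_identical(mdl_node(d, 1, pa = c(2, 3))$K, 9L)
  expect_identical(mdl_node(d, 1)$K, 1L)
})

test_that("best_parents equals exhaustive subset minimization", {
  d <- forward_sample(random_net(7, edge_prob = 0.5, seed = 41), 1500, seed = 42)
  for (i in c(1L, 4L, 7L)) {
    cands <- setdiff(1:7, i)
    bp <- best_parents(d, i, cands)
    subs <- subsets_all <- unlist(lapply(0:6, function(s) {
      if (s == 0) list(integer(0)) else utils::combn(cands, s, simplify = FALSE)
    }), recursive = FALSE)
    scores <- vapply(subsets_all, function(S) mdl_node(d, i, S)$mdl, numeric(1))
    expect_equal(bp$score, min(scores), tolerance = 1e-9)
    expect_equal(mdl_node(d, i, bp$set)$mdl, bp$score, tolerance = 1e-9)
  }
})

test_that("empty candidates give the marginal score; strong parents are kept", {
  net <- chain_net(2, flip = 0.05)
  d <- forward_sample(net, 5000, seed = 43)
  bp0 <- best_parents(d, 1, integer(0))
  expect_identical(bp0$set, integer(0))
  expect_equal(bp0$score, mdl_node(d, 1)$mdl)

  bp <- best_parents(d, 2, candidates = 1)
  expect_identical(bp$set, 1L)
  # the entropy drop must beat the (log N / 2) * dK penalty
  expect_lt(mdl_node(d, 2, 1)$mdl, mdl_node(d, 2)$mdl)
})

test_that("forced parents appear in every evaluated set and in the score", {
  d <- forward_sample(random_net(5, seed = 44), 1000, seed = 45)
  bp <- best_parents(d, 3, candidates = c(1, 2), forced = 5)
  expect_true(5L %in% bp$set)
  expect_equal(mdl_node(d, 3, bp$set)$mdl, bp$score, tolerance = 1e-9)
})

test_that("dp_learn agrees with the direct all-DAGs oracle at 3 and 4 nodes", {
  for (s in 1:10) {
    p <- if (s %% 2 == 0) 3L else 4L
    net <- random_net(p, edge_prob = 0.5, seed = 100 + s)
    d <- forward_sample(net, 1000, seed = 200 + s)
    dp <- dp_learn(d, seq_len(p))
    or <- exhaustive_oracle(d, seq_len(p))
    expect_equal(dp$score, or$score, tolerance = 1e-9)
    expect_true(structure_in(dp$parents, or$structures))
    expect_identical(or$n_dags, if (p == 3L) 25L else 543L)
  }
})

test_that("the ordering oracle agrees with direct DAG enumeration", {
  # validate the 5-node oracle mode against the <=4-node one by brute-forcing
  # a 4-node problem both ways via a padded skeleton restriction
  d <- forward_sample(random_net(5, edge_prob = 0.5, seed = 61), 800, seed = 62)
  adj <- matrix(1L, 5, 5, dimnames = list(colnames(d$values), colnames(d$values)))
  diag(adj) <- 0L
  adj[5, ] <- adj[, 5] <- 0L  # isolate variable 5
  sk <- skeleton_from_adjacency(adj)
  or5 <- exhaustive_oracle(d, 1:5, skeleton = sk)
  d4 <- bn_data(d$values[, 1:4], cardinalities = d$cardinalities[1:4])
  or4 <- exhaustive_oracle(d4, 1:4)
  expect_identical(or5$method, "orderings")
  expect_equal(or5$score, or4$score + mdl_node(d, 5)$mdl, tolerance = 1e-9)
})

test_that("skeleton pruning with a complete skeleton changes nothing", {
  d <- forward_sample(random_net(5, edge_prob = 0.6, seed = 46), 1200, seed = 47)
  adj <- matrix(1L, 5, 5, dimnames = list(colnames(d$values), colnames(d$values)))
  diag(adj) <- 0L
  sk <- skeleton_from_adjacency(adj)
  r1 <- dp_learn(d, 1:5)
  r2 <- dp_learn(d, 1:5, skeleton = sk)
  expect_identical(r1$parents, r2$parents)
  expect_equal(r1$score, r2$score)
})

test_that("dp_learn respects the skeleton and forced external parents", {
  net <- chain_net(4, flip = 0.1)
  d <- forward_sample(net, 3000, seed = 48)
  adj <- matrix(0L, 4, 4, dimnames = list(colnames(d$values), colnames(d$values)))
  for (i in 1:3) adj[i, i + 1] <- adj[i + 1, i] <- 1L
  sk <- skeleton_from_adjacency(adj)
  res <- dp_learn(d, 2:4, skeleton = sk, forced = list(`2` = 1L))
  or <- exhaustive_oracle(d, 2:4, skeleton = sk, forced = list(`2` = 1L))
  expect_equal(res$score, or$score, tolerance = 1e-9)
  expect_true(structure_in(res$parents, or$structures))
  expect_identical(res$external[["2"]], 1L)
  # structural parents stay inside the skeleton
  for (v in names(res$parents)) {
    for (pa in res$parents[[v]]) {
      expect_identical(sk$adjacency[as.integer(v), pa], 1L)
    }
  }
})

test_that("degenerate sizes and the cap behave", {
  d <- forward_sample(random_net(3, seed = 49), 400, seed = 50)
  r1 <- dp_learn(d, 1L)
  expect_identical(r1$parents[["1"]], integer(0))
  expect_equal(r1$score, mdl_node(d, 1)$mdl)
  expect_identical(r1$n_subsets, 2L)
  expect_error(dp_learn(d, 1:3, cap = 2L), "cap")
})

test_that("order-graph bookkeeping expands 2^n subsets", {
  d <- forward_sample(random_net(4, seed = 51), 600, seed = 52)
  expect_identical(dp_learn(d, 1:4)$n_subsets, 16L)
})

test_that("total MDL decomposes as the sum of node scores", {
  d <- forward_sample(random_net(5, edge_prob = 0.5, seed = 53), 1000, seed = 54)
  res <- dp_learn(d, 1:5)
  total <- sum(vapply(names(res$parents), function(v) {
    mdl_node(d, as.integer(v), res$parents[[v]])$mdl
  }, numeric(1)))
  expect_equal(res$score, total, tolerance = 1e-9)
})

test_that("empirical conditional entropy never increases with conditioning", {
  d <- forward_sample(random_net(5, edge_prob = 0.5, seed = 55), 800, seed = 56)
  for (i in 1:5) {
    others <- setdiff(1:5, i)
    for (pa_size in 0:2) {
      for (S in utils::combn(others, pa_size + 1, simplify = FALSE)) {
        smaller <- S[-length(S)]
        expect_lte(mdl_node(d, i, S)$H, mdl_node(d, i, smaller)$H + 1e-9)
      }
    }
  }
})
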