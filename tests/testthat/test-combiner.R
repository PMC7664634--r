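# A 9-node skeleton mirroring the worked three-block example: blocks
# {1,2,3,4}, {5,6,7}, {8,9}, dense inside, with cross-block edges 2-5 and 7-8.
fig_skeleton <- function() {
  adj <- matrix(0L, 9, 9, dimnames = list(paste0("N", 1:9), paste0("N", 1:9)))
  und <- rbind(c(1, 2), c(1, 3), c(2, 4), c(3, 4),
               c(5, 6), c(6, 7), c(5, 7),
               c(8, 9),
               c(2, 5), c(7, 8))
  for (r in seq_len(nrow(und))) {
    adj[und[r, 1], und[r, 2]] <- adj[und[r, 2], und[r, 1]] <- 1L
  }
  skeleton_from_adjacency(adj)
}

fig_blocking <- function() {
  structure(list(k = 3L, clusters = list(1:4, 5:7, 8:9),
                 medoids = c(1L, 5L, 8L), cost = 0, iterations = 1L,
                 seed = 1L, variables = paste0("N", 1:9)),
            class = "bn_blocking")
}

test_that("inter-block edges are exactly the crossing skeleton edges", {
  sk <- fig_skeleton()
  bl <- fig_blocking()
  ib <- find_interblock_edges(sk, bl)
  expect_equal(unname(ib), rbind(c(2L, 5L), c(7L, 8L)))

  # no crossing edges -> empty
  adj0 <- sk$adjacency
  adj0[2, 5] <- adj0[5, 2] <- adj0[7, 8] <- adj0[8, 7] <- 0L
  expect_identical(nrow(find_interblock_edges(skeleton_from_adjacency(adj0), bl)), 0L)

  # k = 1 -> always empty
  bl1 <- structure(list(k = 1L, clusters = list(1:9), medoids = 1L, cost = 0,
                        iterations = 1L, seed = 1L, variables = paste0("N", 1:9)),
                   class = "bn_blocking")
  expect_identical(nrow(find_interblock_edges(sk, bl1)), 0L)
})

test_that("two inter-block edges enumerate the four worked orientations", {
  ib <- find_interblock_edges(fig_skeleton(), fig_blocking())
  os <- enumerate_orientations(ib)
  expect_length(os, 4L)
  got <- lapply(os, function(o) unname(o[, ]))
  expect_equal(got[[1]], rbind(c(2L, 5L), c(7L, 8L)))
  expect_equal(got[[2]], rbind(c(5L, 2L), c(7L, 8L)))
  expect_equal(got[[3]], rbind(c(2L, 5L), c(8L, 7L)))
  expect_equal(got[[4]], rbind(c(5L, 2L), c(8L, 7L)))
})

test_that("orientation counts follow 2^m with distinct assignments", {
  e0 <- matrix(integer(0), ncol = 2)
  expect_length(enumerate_orientations(e0), 1L)

  e3 <- rbind(c(1L, 4L), c(2L, 5L), c(3L, 6L))
  os <- enumerate_orientations(e3)
  expect_length(os, 8L)
  keys <- vapply(os, function(o) paste(t(o), collapse = ","), character(1))
  expect_identical(anyDuplicated(keys), 0L)

  expect_error(enumerate_orientations(e3, cap = 2L), "cap")
})

test_that("oriented cross-block edges become forced external parents", {
  sk <- fig_skeleton()
  bl <- fig_blocking()
  os <- enumerate_orientations(find_interblock_edges(sk, bl))

  cand1 <- build_candidate(bl, sk, os[[1]])  # (2->5, 7->8)
  expect_identical(cand1$blocks[[2]]$forced[["5"]], 2L)
  expect_identical(cand1$blocks[[3]]$forced[["8"]], 7L)
  expect_identical(cand1$blocks[[1]]$forced[["2"]], integer(0))

  cand4 <- build_candidate(bl, sk, os[[4]])  # reversed: (5->2, 8->7)
  expect_identical(cand4$blocks[[1]]$forced[["2"]], 5L)
  expect_identical(cand4$blocks[[2]]$forced[["7"]], 8L)
  expect_identical(cand4$blocks[[2]]$forced[["5"]], integer(0))
})

test_that("a node with two incoming inter-block edges gets both parents", {
  adj <- matrix(0L, 3, 3, dimnames = list(paste0("N", 1:3), paste0("N", 1:3)))
  adj[1, 3] <- adj[3, 1] <- adj[2, 3] <- adj[3, 2] <- 1L
  sk <- skeleton_from_adjacency(adj)
  bl <- structure(list(k = 3L, clusters = list(1L, 2L, 3L), medoids = 1:3,
                       cost = 0, iterations = 1L, seed = 1L,
                       variables = paste0("N", 1:3)),
                  class = "bn_blocking")
  ib <- find_interblock_edges(sk, bl)
  o <- enumerate_orientations(ib)[[1]]  # both point at 3
  cand <- build_candidate(bl, sk, o)
  expect_identical(cand$blocks[[3]]$forced[["3"]], c(1L, 2L))
})

test_that("forced-parent counts and flip closure hold over all candidates", {
  sk <- fig_skeleton()
  bl <- fig_blocking()
  ib <- find_interblock_edges(sk, bl)
  os <- enumerate_orientations(ib)
  keys <- character(0)
  for (o in os) {
    cand <- build_candidate(bl, sk, o)
    total_forced <- sum(vapply(cand$blocks,
                               function(b) sum(lengths(b$forced)), integer(1)))
    expect_identical(total_forced, nrow(ib))
    keys <- c(keys, paste(t(o), collapse = ","))
  }
  # flipping any one edge of any candidate yields another enumerated one
  for (o in os) {
    for (e in seq_len(nrow(o))) {
      fl <- o
      fl[e, ] <- rev(fl[e, ])
      expect_true(paste(t(fl), collapse = ",") %in% keys)
    }
  }
})
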