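# MDL scoring and exact structure search.
#
# Node score: MDL(X | PA) = H(X | PA) + (log N / 2) * K(X | PA), with
# H the empirical conditional entropy on raw counts,
#   H = -sum_{x,pa} N_{x,pa} log(N_{x,pa} / N_{pa}),   0 log 0 := 0,
# and K = (r_x - 1) * prod_{l in PA} r_l free parameters. Natural logs.
#
# Search: dynamic programming over the order graph (the subset lattice of the
# block's variables; 2^n entries, processed as layered hash tables) with
# per-variable parent graphs caching BestMDL over subsets of the skeleton
# neighbours. Forced external parents (from an inter-block orientation) are
# included in every evaluated parent set of their child: they contribute to
# the counts of H and to K, but are not nodes of the subproblem DAG.
#
# Tie-breaks: parent sets of equal score go to the smaller, then
# lexicographically smaller, set; score-tied *leaf* choices go to the
# higher-indexed variable, so lower-indexed variables enter the build order
# earlier. This fixes one canonical member of a score-equivalent set.

#' MDL node score
#'
#' @param data a `bn_data`.
#' @param i child variable index.
#' @param pa parent index set (must not contain `i`).
#' @return an object of class `bn_score_terms`: `H` (nats), `K` (free
#'   parameters), `mdl`, `N`, `i`, `parents`.
#' @export
mdl_node <- function(data, i, pa = integer(0)) {
  pa <- sort(as.integer(pa))
  if (i %in% pa) stop("a variable cannot parent itself")
  ri <- data$cardinalities[[i]]
  rpa <- if (length(pa)) prod(data$cardinalities[pa]) else 1L
  code_pa <- joint_code(data, pa)
  code_full <- data$values[, i] + ri * code_pa
  n_full <- tabulate(code_full + 1L, nbins = ri * rpa)
  n_pa <- tabulate(code_pa + 1L, nbins = rpa)
  pa_of_full <- rep(seq_len(rpa), each = ri)
  nz <- n_full > 0L
  H <- -sum(n_full[nz] * log(n_full[nz] / n_pa[pa_of_full[nz]]))
  K <- (ri - 1) * rpa
  if (K > .Machine$integer.max) stop("parameter count overflow; parent set too large")
  K <- as.integer(K)
  N <- data$n
  structure(
    list(H = H, K = K, mdl = H + log(N) / 2 * K, N = N, i = i, parents = pa),
    class = "bn_score_terms"
  )
}

# Parent graph of one variable: raw MDL for every subset of `candidates`
# (always unioned with `forced`) and the running minimum over the subset
# lattice, with tie-break propagation. Masks are local: bit b = candidates[b].
parent_tables <- function(data, i, candidates, forced = integer(0)) {
  forced <- sort(as.integer(forced))
  candidates <- sort(setdiff(as.integer(candidates), c(forced, i)))
  nc <- length(candidates)
  if (nc > 20L) stop("parent-candidate set too large (", nc, "); prune the skeleton")
  nsub <- bitwShiftL(1L, nc)
  raw <- numeric(nsub)
  for (m in seq_len(nsub) - 1L) {
    subset <- candidates[mask_bits(m, nc)]
    raw[m + 1L] <- mdl_node(data, i, c(forced, subset))$mdl
  }
  score <- raw
  arg <- seq_len(nsub) - 1L
  argsize <- vapply(arg, popcount, integer(1))
  for (m in seq_len(nsub) - 1L) {
    for (b in mask_bits(m, nc)) {
      sub <- m - bitwShiftL(1L, b - 1L)
      if (score[sub + 1L] < score[m + 1L] ||
          (score[sub + 1L] == score[m + 1L] &&
           (argsize[sub + 1L] < argsize[m + 1L] ||
            (argsize[sub + 1L] == argsize[m + 1L] && arg[sub + 1L] < arg[m + 1L])))) {
        score[m + 1L] <- score[sub + 1L]
        arg[m + 1L] <- arg[sub + 1L]
        argsize[m + 1L] <- argsize[sub + 1L]
      }
    }
  }
  list(candidates = candidates, forced = forced, raw = raw,
       score = score, arg = arg, argsize = argsize)
}

#' Best-scoring parent set of a variable
#'
#' Minimizes `MDL(X_i | forced U S)` over all subsets `S` of `candidates`
#' (evaluated bottom-up over the subset lattice with memoization). Ties go to
#' the smaller, then lexicographically smaller, subset.
#'
#' @param data a `bn_data`.
#' @param i child variable index.
#' @param candidates candidate parent indices (typically the skeleton
#'   neighbours of `i`).
#' @param forced indices always included in every evaluated parent set.
#' @return list with `set` (the chosen full parent set, forced included),
#'   `chosen` (the optional part), `score`, and the lattice `tables`.
#' @export
best_parents <- function(data, i, candidates, forced = integer(0)) {
  tab <- parent_tables(data, i, candidates, forced)
  full <- bitwShiftL(1L, length(tab$candidates))
  chosen <- tab$candidates[mask_bits(tab$arg[full], length(tab$candidates))]
  list(set = sort(c(tab$forced, chosen)), chosen = chosen,
       score = tab$score[full], i = i, tables = tab)
}

#' Exact MDL-optimal DAG over a variable set by pruned dynamic programming
#'
#' Order-graph DP: starting from the empty subnetwork, leaves are added
#' recursively; each subset keeps the best leaf and its BestMDL parent set,
#' looked up in the per-variable parent graph (restricted to skeleton
#' neighbours inside `variables`, with forced external parents always
#' present in the score). The full-set entry reconstructs the globally
#' optimal DAG from backpointers.
#'
#' @param data a `bn_data`.
#' @param variables global indices of the (block) variables to learn over.
#' @param skeleton optional `bn_skeleton`; `NULL` means unrestricted
#'   candidates (every other variable in the set).
#' @param forced named list (names = global variable indices as character) of
#'   forced external parent indices, all outside `variables`.
#' @param cap maximum block size (default 25); beyond it the subset lattice
#'   is intractable and the caller should re-block.
#' @param external_optional named list like `forced`, but the external
#'   variables are *optional* parent-graph candidates of their child rather
#'   than pinned members (they are always available regardless of the order
#'   mask, since they are not nodes of this subproblem).
#' @return list: `variables`, `parents` (named list, within-set structural
#'   parents per variable), `external` (chosen external parents per
#'   variable, forced plus any adopted optional ones), `score` (total MDL,
#'   external parents included in their children's terms), `n_subsets`
#'   (order-graph size).
#' @export
dp_learn <- function(data, variables, skeleton = NULL, forced = list(), cap = 25L,
                     external_optional = list()) {
  vn <- sort(as.integer(variables))
  nb <- length(vn)
  if (nb < 1L) return(list(variables = integer(0), parents = list(), external = list(),
                           score = 0, n_subsets = 1L))
  if (nb > cap) {
    stop(sprintf("block of %d variables exceeds the DP cap (%d); re-block with larger k", nb, cap))
  }
  tables <- vector("list", nb)
  candpos <- vector("list", nb)
  for (t in seq_len(nb)) {
    X <- vn[t]
    cands <- if (is.null(skeleton)) {
      setdiff(vn, X)
    } else {
      intersect(vn, which(skeleton$adjacency[X, ] == 1L))
    }
    fx <- forced[[as.character(X)]] %||% integer(0)
    ext <- setdiff(external_optional[[as.character(X)]] %||% integer(0), fx)
    if (length(intersect(c(fx, ext), vn))) {
      stop("forced/external parents must lie outside the learned variable set")
    }
    tables[[t]] <- parent_tables(data, X, c(cands, ext), fx)
    # NA marks an external candidate: always available in the order DP
    candpos[[t]] <- match(tables[[t]]$candidates, vn)
  }

  nsub <- bitwShiftL(1L, nb)
  score <- rep(Inf, nsub)
  score[1L] <- 0
  leaf <- integer(nsub)
  leaf_arg <- integer(nsub)     # local candidate mask of the chosen parent set

  for (mask in seq_len(nsub) - 1L) {
    base <- score[mask + 1L]
    if (!is.finite(base)) next
    for (t in seq_len(nb)) {
      if (bit_on(mask, t)) next
      cm <- 0L
      cp <- candpos[[t]]
      for (ci in seq_along(cp)) {
        if (is.na(cp[ci]) || bit_on(mask, cp[ci])) cm <- cm + bitwShiftL(1L, ci - 1L)
      }
      tab <- tables[[t]]
      s <- base + tab$score[cm + 1L]
      new <- mask + bitwShiftL(1L, t - 1L)
      ni <- new + 1L
      # score-equivalent orderings differ only by float summation noise, so
      # ties are detected with a relative tolerance; the stored score keeps
      # the minimum while the leaf follows the canonical-member preference
      tol <- 1e-9 * max(1, abs(s))
      take <- if (s < score[ni] - tol) TRUE else if (s <= score[ni] + tol) t > leaf[ni] else FALSE
      if (take) {
        score[ni] <- min(s, score[ni])
        leaf[ni] <- t
        leaf_arg[ni] <- tab$arg[cm + 1L]
      }
    }
  }

  parents <- stats::setNames(vector("list", nb), as.character(vn))
  external <- stats::setNames(vector("list", nb), as.character(vn))
  mask <- nsub - 1L
  while (mask > 0L) {
    t <- leaf[mask + 1L]
    tab <- tables[[t]]
    pa <- tab$candidates[mask_bits(leaf_arg[mask + 1L], length(tab$candidates))]
    key <- as.character(vn[t])
    parents[[key]] <- sort(intersect(pa, vn))
    external[[key]] <- sort(c(tab$forced, setdiff(pa, vn)))
    mask <- mask - bitwShiftL(1L, t - 1L)
  }
  res <- list(variables = vn, parents = parents, external = external,
              score = score[nsub], n_subsets = nsub)
  edges <- parents_to_edges(parents)
  if (nrow(edges)) {
    em <- matrix(match(as.vector(edges), as.character(vn)), ncol = 2L)
    if (!is_acyclic(nb, em)) stop("internal error: reconstructed structure is cyclic")
  }
  res
}

# all permutations of v, lexicographic
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  do.call(c, lapply(seq_along(v), function(i) {
    lapply(all_perms(v[-i]), function(rest) c(v[i], rest))
  }))
}

structure_key <- function(parents) {
  paste(vapply(names(parents), function(v) {
    paste0(v, "<-", paste(parents[[v]], collapse = "+"))
  }, character(1)), collapse = ";")
}

#' Brute-force exact search (test oracle)
#'
#' For up to 4 variables, enumerates every parent-set assignment under the
#' same skeleton/forced constraints, discards cyclic ones (25 DAGs at 3
#' unrestricted variables, 543 at 4), and scores each by the decomposable MDL
#' sum. For 5 variables, enumerates all 120 topological orderings and
#' minimizes each variable's score over candidate subsets drawn from its
#' predecessors, which visits every DAG's score without the layered DP
#' machinery. Returns the optimum and *all* optimal structures, so agreement
#' checks are robust to tie-break conventions.
#'
#' @inheritParams dp_learn
#' @param tol score tolerance for collecting co-optimal structures.
#' @return list: `score`, `structures` (all optimal parent lists),
#'   `n_dags` (DAGs enumerated; `NA` in ordering mode), `method`.
#' @export
exhaustive_oracle <- function(data, variables, skeleton = NULL, forced = list(),
                              tol = 1e-9) {
  vn <- sort(as.integer(variables))
  nb <- length(vn)
  if (nb > 5L) stop("oracle supports at most 5 variables")
  if (nb == 0L) return(list(score = 0, structures = list(stats::setNames(list(), character(0))),
                            n_dags = 1L, method = "direct"))
  cand_of <- lapply(vn, function(X) {
    cands <- if (is.null(skeleton)) setdiff(vn, X) else {
      intersect(vn, which(skeleton$adjacency[X, ] == 1L))
    }
    sort(cands)
  })
  fx_of <- lapply(vn, function(X) sort(as.integer(forced[[as.character(X)]] %||% integer(0))))
  score_cache <- new.env(parent = emptyenv())
  node_score <- function(t, pa) {
    key <- paste(t, paste(pa, collapse = ","), sep = ":")
    if (is.null(score_cache[[key]])) {
      score_cache[[key]] <- mdl_node(data, vn[t], c(fx_of[[t]], pa))$mdl
    }
    score_cache[[key]]
  }

  if (nb <= 4L) {
    subsets_of <- lapply(seq_len(nb), function(t) subsets_up_to(cand_of[[t]], nb))
    best <- Inf
    optimal <- list()
    n_dags <- 0L
    choice <- vector("list", nb)
    recurse <- function(t) {
      if (t > nb) {
        edges <- matrix(integer(0), ncol = 2L)
        for (u in seq_len(nb)) {
          for (pa in choice[[u]]) edges <- rbind(edges, c(match(pa, vn), u))
        }
        if (!is_acyclic(nb, edges)) return()
        n_dags <<- n_dags + 1L
        s <- sum(vapply(seq_len(nb), function(u) node_score(u, choice[[u]]), numeric(1)))
        if (s < best - tol) {
          best <<- s
          optimal <<- list()
        }
        if (s <= best + tol) {
          parents <- stats::setNames(lapply(choice, sort), as.character(vn))
          optimal[[structure_key(parents)]] <<- parents
        }
        return()
      }
      for (sub in subsets_of[[t]]) {
        choice[[t]] <<- sub
        recurse(t + 1L)
      }
    }
    recurse(1L)
    return(list(score = best, structures = unname(optimal), n_dags = n_dags,
                method = "direct"))
  }

  # nb == 5: ordering enumeration
  best <- Inf
  optimal <- list()
  for (ord in all_perms(seq_len(nb))) {
    total <- 0
    argmins <- vector("list", nb)
    for (pos in seq_len(nb)) {
      t <- ord[pos]
      preds <- vn[ord[seq_len(pos - 1L)]]
      subs <- Filter(function(s) all(s %in% preds), subsets_up_to(cand_of[[t]], nb))
      scores <- vapply(subs, function(s) node_score(t, s), numeric(1))
      mn <- min(scores)
      total <- total + mn
      argmins[[t]] <- subs[scores <= mn + tol]
    }
    if (total < best - tol) {
      best <- total
      optimal <- list()
    }
    if (total <= best + tol) {
      combos <- list(stats::setNames(vector("list", nb), as.character(vn)))
      for (t in seq_len(nb)) {
        combos <- do.call(c, lapply(combos, function(cm) {
          lapply(argmins[[t]], function(s) {
            cm[[as.character(vn[t])]] <- sort(s)
            cm
          })
        }))
        if (length(combos) > 512L) combos <- combos[seq_len(512L)]
      }
      for (cm in combos) optimal[[structure_key(cm)]] <- cm
    }
  }
  list(score = best, structures = unname(optimal), n_dags = NA_integer_,
       method = "orderings")
}

#' Per-node score ledger of a structure
#'
#' @param data a `bn_data`.
#' @param parents named list (character global indices or names matched to
#'   columns) of parent index vectors.
#' @return data.frame with one row per variable: H, K, mdl.
#' @export
score_ledger <- function(data, parents) {
  rows <- lapply(names(parents), function(v) {
    i <- as.integer(v)
    st <- mdl_node(data, i, parents[[v]])
    data.frame(variable = colnames(data$values)[i], H = st$H, K = st$K, mdl = st$mdl)
  })
  do.call(rbind, rows)
}
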