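# MMPC parents-and-children discovery. Association between X and a candidate
# Y given a subset S is measured by the G^2 p-value (smaller = stronger,
# ties broken by larger G^2). The forward phase adds the candidate that
# maximizes the minimum association over conditioning subsets of the current
# PC (max-min heuristic); the backward phase removes any member separable
# from X by some subset of the rest. The skeleton applies the conservative
# AND symmetry rule.

# worse (weaker) of two associations: larger p, ties by smaller g2
weaker_assoc <- function(a, b) {
  if (b$p_value > a$p_value ||
      (b$p_value == a$p_value && b$statistic < a$statistic)) b else a
}

#' MMPC parents-and-children set of one variable
#'
#' @param data a `bn_data`.
#' @param i target variable index.
#' @param alpha significance level in (0, 1) for the G^2 test (default 0.05).
#' @param max_cond maximum conditioning-set size (default 3).
#' @param pc_cap forward-phase size cap on PC (default 10); exceeding it
#'   stops growth with a warning.
#' @return sorted integer vector of PC member indices.
#' @export
mmpc_pc <- function(data, i, alpha = 0.05, max_cond = 3L, pc_cap = 10L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  p <- ncol(data$values)
  cand <- setdiff(seq_len(p), i)
  pc <- integer(0)

  # worst association seen so far per candidate, over all subsets tested
  worst <- vector("list", p)
  for (y in cand) worst[[y]] <- ci_test(data, i, y, integer(0))

  repeat {
    alive <- cand[vapply(cand, function(y) worst[[y]]$p_value < alpha, logical(1))]
    if (!length(alive)) break
    # max-min: strongest of the per-candidate weakest associations
    best <- alive[1L]
    for (y in alive[-1L]) {
      w <- worst[[y]]
      b <- worst[[best]]
      if (w$p_value < b$p_value ||
          (w$p_value == b$p_value && w$statistic > b$statistic)) best <- y
    }
    pc <- c(pc, best)
    cand <- setdiff(cand, best)
    if (length(pc) >= pc_cap) {
      warning(sprintf("PC(%d) reached the size cap (%d); forward phase stopped", i, pc_cap))
      break
    }
    if (!length(cand)) break
    # new subsets to account for are exactly those containing the new member
    base <- setdiff(pc, best)
    for (y in cand) {
      for (Tset in subsets_up_to(base, max_cond - 1L)) {
        S <- c(best, Tset)
        res <- ci_test(data, i, y, S)
        worst[[y]] <- weaker_assoc(worst[[y]], res)
        if (worst[[y]]$p_value >= alpha) break
      }
    }
  }

  # backward: drop Y if some subset of PC \ {Y} separates it from X_i
  keep <- pc
  for (y in pc) {
    others <- setdiff(keep, y)
    for (S in subsets_up_to(others, max_cond)) {
      res <- ci_test(data, i, y, S)
      if (res$p_value >= alpha) {
        keep <- setdiff(keep, y)
        break
      }
    }
  }
  sort(keep)
}

#' MMPC network skeleton
#'
#' Runs [mmpc_pc()] for every variable and keeps edge (i, j) only when each
#' endpoint is in the other's PC set (AND symmetry correction), yielding a
#' symmetric 0-1 adjacency matrix with zero diagonal.
#'
#' @inheritParams mmpc_pc
#' @return an object of class `bn_skeleton`: `adjacency` (0-1 matrix with
#'   variable dimnames) and `pc` (the raw per-variable PC sets).
#' @export
mmpc_skeleton <- function(data, alpha = 0.05, max_cond = 3L, pc_cap = 10L) {
  p <- ncol(data$values)
  vars <- colnames(data$values)
  pcs <- lapply(seq_len(p), function(i) mmpc_pc(data, i, alpha, max_cond, pc_cap))
  adj <- matrix(0L, p, p, dimnames = list(vars, vars))
  for (i in seq_len(p)) {
    for (j in pcs[[i]]) {
      if (i %in% pcs[[j]]) adj[i, j] <- 1L
    }
  }
  structure(list(adjacency = adj, pc = pcs, alpha = alpha, max_cond = max_cond),
            class = "bn_skeleton")
}

#' @export
print.bn_skeleton <- function(x, ...) {
  cat(sprintf("MMPC skeleton: %d variables, %d undirected edges (alpha = %g)\n",
              nrow(x$adjacency), sum(x$adjacency) / 2L, x$alpha))
  invisible(x)
}

#' Build a skeleton object from an adjacency matrix
#'
#' @param adjacency symmetric 0-1 matrix, zero diagonal.
#' @return a `bn_skeleton`.
#' @export
skeleton_from_adjacency <- function(adjacency) {
  adjacency <- as.matrix(adjacency)
  storage.mode(adjacency) <- "integer"
  if (!isTRUE(all.equal(adjacency, t(adjacency)))) stop("adjacency must be symmetric")
  if (any(diag(adjacency) != 0L)) stop("adjacency must have a zero diagonal")
  pcs <- lapply(seq_len(nrow(adjacency)), function(i) which(adjacency[i, ] == 1L))
  structure(list(adjacency = adjacency, pc = pcs, alpha = NA_real_, max_cond = NA_integer_),
            class = "bn_skeleton")
}

#' Write / read a skeleton as a 0-1 TSV matrix with a variable-name header
#'
#' @param skeleton a `bn_skeleton`.
#' @param path file path.
#' @export
write_skeleton_tsv <- function(skeleton, path) {
  utils::write.table(skeleton$adjacency, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_skeleton_tsv
#' @export
read_skeleton_tsv <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   check.names = FALSE))
  rownames(m) <- colnames(m)
  skeleton_from_adjacency(m)
}
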