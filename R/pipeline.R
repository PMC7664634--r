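# End-to-end block learning: MKM blocking -> MMPC skeleton -> orientation
# enumeration of inter-block edges -> per-candidate pruned DP per block ->
# assembly -> global acyclicity filter -> BIC-best selection.
#
# Because loglik = -sum_i H(X_i | PA_i) and d = sum_i K(X_i | PA_i) under the
# same count conventions, the raw BIC of an assembled candidate equals minus
# its total MDL, so maximizing BIC across candidates and minimizing MDL
# inside the DP are two faces of the same criterion; both are reported.

#' BIC score of a structure on data
#'
#' `BIC = loglik(theta_ML) - (d/2) log m`, decomposable per node, with
#' maximum-likelihood parameters from counts and `0 log 0 := 0`. The raw
#' value and the per-sample normalization `raw / m` are both returned.
#'
#' @param data a `bn_data`.
#' @param parents named list (names = global column indices as character) of
#'   parent index vectors covering the variables to score.
#' @return an object of class `bn_bic`: `loglik`, `d`, `m`, `raw`,
#'   `normalized`.
#' @export
bic_score <- function(data, parents) {
  H_total <- 0
  d <- 0L
  for (v in names(parents)) {
    st <- mdl_node(data, as.integer(v), parents[[v]])
    H_total <- H_total + st$H
    d <- d + st$K
  }
  m <- data$n
  loglik <- -H_total
  raw <- loglik - d / 2 * log(m)
  structure(
    list(loglik = loglik, d = d, m = m, raw = raw, normalized = raw / m),
    class = "bn_bic"
  )
}

#' @export
print.bn_bic <- function(x, ...) {
  cat(sprintf("BIC: raw = %.4f (loglik = %.4f, d = %d, m = %d); per-sample = %.4f\n",
              x$raw, x$loglik, x$d, x$m, x$normalized))
  invisible(x)
}

# canonical undirected pair keys of an edge matrix (character names)
pair_keys <- function(edges) {
  if (!nrow(edges)) return(character(0))
  apply(edges, 1L, function(e) paste(sort(e), collapse = "~"))
}

dir_keys <- function(edges) {
  if (!nrow(edges)) return(character(0))
  apply(edges, 1L, paste, collapse = ">")
}

as_name_edges <- function(x) {
  if (inherits(x, "bn_net")) return(bn_edges(x))
  if (inherits(x, "blmkm_fit")) return(x$edges)
  if (is.matrix(x)) {
    m <- matrix(as.character(x), ncol = 2L)
    colnames(m) <- c("parent", "child")
    return(m)
  }
  if (is.list(x)) {
    m <- parents_to_edges(x)
    colnames(m) <- c("parent", "child")
    return(m)
  }
  stop("cannot interpret object as a DAG edge list")
}

#' Structural Hamming decomposition between two DAGs
#'
#' `A` counts adjacencies present only in the learned graph (added), `M`
#' adjacencies present only in the truth (missing), `I` pairs adjacent in
#' both but with reversed direction (inverted); `H = A + M + I`.
#'
#' @param learned,truth DAGs over the same variables: a `bn_net`, a
#'   `blmkm_fit`, a 2-column (parent, child) edge matrix, or a named
#'   parents list.
#' @param variables optional character vector of the common variable set
#'   (checked when both inputs carry names).
#' @return an object of class `bn_hamming` with fields `A`, `M`, `I`, `H`.
#' @export
hamming <- function(learned, truth, variables = NULL) {
  le <- as_name_edges(learned)
  te <- as_name_edges(truth)
  if (!is.null(variables)) {
    bad <- setdiff(unique(c(le, te)), variables)
    if (length(bad)) stop("edges mention variables outside the common set: ",
                          paste(bad, collapse = ", "))
  }
  lp <- pair_keys(le)
  tp <- pair_keys(te)
  if (anyDuplicated(lp) || anyDuplicated(tp)) stop("duplicate adjacencies in a DAG")
  A <- sum(!lp %in% tp)
  M <- sum(!tp %in% lp)
  shared <- intersect(lp, tp)
  ld <- dir_keys(le)[match(shared, lp)]
  td <- dir_keys(te)[match(shared, tp)]
  I <- sum(ld != td)
  structure(list(A = A, M = M, I = I, H = A + M + I), class = "bn_hamming")
}

#' @export
print.bn_hamming <- function(x, ...) {
  cat(sprintf("Hamming: A = %d (added), M = %d (missing), I = %d (inverted), H = %d\n",
              x$A, x$M, x$I, x$H))
  invisible(x)
}

#' Learn a Bayesian network by block learning (end to end)
#'
#' Runs MKM blocking, the MMPC skeleton, orientation enumeration of the
#' inter-block skeleton edges, and one pruned-DP exact search per block per
#' orientation; assembles each candidate into a full network, discards
#' cyclic assemblies, and returns the BIC-maximal acyclic candidate.
#' Deterministic given `(data, k, config)`.
#'
#' Per-block DP results are cached by `(block, forced-parent map)`, so
#' orientation assignments differing only in edges touching other blocks
#' reuse each other's subproblems.
#'
#' @param data a `bn_data`.
#' @param k number of blocks (required; see [mkm_suggest_k()] for a
#'   heuristic).
#' @param config a [blmkm_config()].
#' @return an object of class `blmkm_fit`: learned `edges` (name matrix) and
#'   `parents` (global index lists), `score_mdl`, `bic`, the `blocking`,
#'   `skeleton`, `interblock` edges, the per-candidate table, and
#'   `provenance`.
#' @export
blmkm <- function(data, k, config = blmkm_config()) {
  stopifnot(inherits(data, "bn_data"))
  validate_config(config)
  vars <- colnames(data$values)
  p <- ncol(data$values)

  mi <- mi_matrix(data)
  blocking <- mkm(data, k, seed = config$seed, max_iter = config$mkm_max_iter,
                  init = config$mkm_init, mi = mi)
  skeleton <- mmpc_skeleton(data, alpha = config$alpha,
                            max_cond = config$max_cond, pc_cap = config$pc_cap)
  interblock <- find_interblock_edges(skeleton, blocking)
  orientations <- enumerate_orientations(interblock, cap = config$orientation_cap)

  dp_cache <- new.env(parent = emptyenv())
  solve_block <- function(members, forced) {
    key <- paste0(paste(members, collapse = ","), "|",
                  paste(vapply(names(forced), function(v) {
                    paste0(v, "<", paste(forced[[v]], collapse = "+"))
                  }, character(1)), collapse = ";"))
    if (is.null(dp_cache[[key]])) {
      res <- if (config$forced_mandatory) {
        dp_learn(data, members, skeleton, forced = forced, cap = config$dp_cap)
      } else {
        dp_learn(data, members, skeleton, forced = list(), cap = config$dp_cap,
                 external_optional = forced)
      }
      dp_cache[[key]] <- res
    }
    dp_cache[[key]]
  }

  n_cand <- length(orientations)
  cand_rows <- vector("list", n_cand)
  best <- NULL
  discarded <- 0L
  for (ci in seq_len(n_cand)) {
    cand <- build_candidate(blocking, skeleton, orientations[[ci]])
    mdl_total <- 0
    parents <- stats::setNames(vector("list", p), as.character(seq_len(p)))
    for (b in cand$blocks) {
      res <- solve_block(b$members, b$forced)
      mdl_total <- mdl_total + res$score
      for (v in names(res$parents)) {
        parents[[v]] <- sort(c(res$parents[[v]], res$external[[v]] %||% integer(0)))
      }
    }
    edges_idx <- parents_to_edges(parents,
                                  index_of = stats::setNames(seq_len(p), as.character(seq_len(p))))
    acyclic <- is_acyclic(p, edges_idx)
    bic <- if (acyclic) bic_score(data, parents) else NULL
    cand_rows[[ci]] <- data.frame(
      bitmask = cand$bitmask, mdl = mdl_total,
      bic_raw = if (acyclic) bic$raw else NA_real_, acyclic = acyclic
    )
    if (!acyclic) {
      discarded <- discarded + 1L
      next
    }
    stopifnot(abs(bic$raw + mdl_total) < 1e-6 * max(1, abs(mdl_total)))
    if (is.null(best) || bic$raw > best$bic$raw) {
      best <- list(parents = parents, bic = bic, mdl = mdl_total,
                   bitmask = cand$bitmask)
    }
  }
  if (is.null(best)) {
    stop(sprintf(paste0(
      "all %d candidates produced cyclic assemblies (%d discarded); ",
      "inspect the inter-block orientation space"), n_cand, discarded))
  }

  # structural consequence of skeleton pruning: no learned adjacency may
  # fall outside the MMPC skeleton
  learned_edges_idx <- parents_to_edges(
    best$parents, index_of = stats::setNames(seq_len(p), as.character(seq_len(p))))
  for (e in seq_len(nrow(learned_edges_idx))) {
    stopifnot(skeleton$adjacency[learned_edges_idx[e, 1L], learned_edges_idx[e, 2L]] == 1L)
  }

  name_parents <- stats::setNames(
    lapply(seq_len(p), function(i) vars[best$parents[[as.character(i)]]]), vars)
  edges <- parents_to_edges(name_parents)
  colnames(edges) <- c("parent", "child")
  structure(
    list(
      edges = edges, parents = best$parents, variables = vars,
      score_mdl = best$mdl, bic = best$bic,
      blocking = blocking, skeleton = skeleton, interblock = interblock,
      n_candidates = n_cand, discarded_cyclic = discarded,
      candidates = do.call(rbind, cand_rows),
      provenance = list(
        k = k, seed = config$seed, alpha = config$alpha,
        max_cond = config$max_cond, pc_cap = config$pc_cap,
        orientation_cap = config$orientation_cap, dp_cap = config$dp_cap,
        forced_mandatory = config$forced_mandatory, mkm_init = config$mkm_init,
        chosen_bitmask = best$bitmask, n_candidates = n_cand,
        discarded_cyclic = discarded, n_samples = data$n
      )
    ),
    class = "blmkm_fit"
  )
}

#' @export
print.blmkm_fit <- function(x, ...) {
  cat(sprintf("BLMKM fit: %d variables, %d edges\n",
              length(x$variables), nrow(x$edges)))
  cat(sprintf("  blocks: k = %d; inter-block edges: %d; candidates: %d (%d cyclic discarded)\n",
              x$blocking$k, nrow(x$interblock), x$n_candidates, x$discarded_cyclic))
  cat(sprintf("  total MDL = %.4f; raw BIC = %.4f (per-sample %.4f)\n",
              x$score_mdl, x$bic$raw, x$bic$normalized))
  invisible(x)
}
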