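# The combine step: identify skeleton edges whose endpoints lie in different
# MKM blocks, enumerate every orientation of those edges (2^m assignments),
# and emit one constrained per-block learning problem per assignment. An
# oriented cross-block edge u -> v makes u a forced external parent of v in
# v's block subproblem, so parents outside the block are never missed.

#' Inter-block skeleton edges
#'
#' @param skeleton a `bn_skeleton`.
#' @param blocking a `bn_blocking` over the same variables.
#' @return integer matrix with columns `i`, `j` (`i < j`), rows in
#'   lexicographic order; zero rows if no skeleton edge crosses blocks.
#' @export
find_interblock_edges <- function(skeleton, blocking) {
  p <- nrow(skeleton$adjacency)
  if (sum(lengths(blocking$clusters)) != p) {
    stop("skeleton and blocking cover different variable sets")
  }
  block_of <- integer(p)
  for (ci in seq_along(blocking$clusters)) block_of[blocking$clusters[[ci]]] <- ci
  out <- matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j")))
  for (i in seq_len(p - 1L)) {
    for (j in seq(i + 1L, p)) {
      if (skeleton$adjacency[i, j] == 1L && block_of[i] != block_of[j]) {
        out <- rbind(out, c(i, j))
      }
    }
  }
  out
}

#' Enumerate all orientations of the inter-block edges
#'
#' Each of the `2^m` assignments directs every edge either `i -> j` (bit 0)
#' or `j -> i` (bit 1), in deterministic binary-counting order over the
#' lexicographic edge list (bit 0 = first edge).
#'
#' @param edges matrix from [find_interblock_edges()].
#' @param cap maximum edge count (default 16, i.e. 65,536 candidates).
#' @return list of orientation assignments; each is a 2-column integer matrix
#'   `(parent, child)` with one row per edge, plus a `bitmask` attribute.
#' @export
enumerate_orientations <- function(edges, cap = 16L) {
  m <- nrow(edges)
  if (m > cap) {
    stop(sprintf(paste0(
      "%d inter-block edges exceed the orientation cap (%d): raise the cap ",
      "or use a finer blocking (larger k) so fewer skeleton edges cross blocks"),
      m, cap))
  }
  lapply(seq_len(bitwShiftL(1L, m)) - 1L, function(mask) {
    o <- matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("parent", "child")))
    for (e in seq_len(m)) {
      flipped <- bit_on(mask, e)
      o <- rbind(o, if (flipped) c(edges[e, 2L], edges[e, 1L]) else edges[e, ])
    }
    attr(o, "bitmask") <- mask
    o
  })
}

#' Build the constrained per-block problem for one orientation
#'
#' @param blocking a `bn_blocking`.
#' @param skeleton a `bn_skeleton`.
#' @param orientation one element of [enumerate_orientations()].
#' @return an object of class `bn_candidate`: the orientation and, per block,
#'   its member variables and each member's forced external parents.
#' @export
build_candidate <- function(blocking, skeleton, orientation) {
  p <- nrow(skeleton$adjacency)
  block_of <- integer(p)
  for (ci in seq_along(blocking$clusters)) block_of[blocking$clusters[[ci]]] <- ci
  blocks <- lapply(seq_along(blocking$clusters), function(ci) {
    members <- sort(blocking$clusters[[ci]])
    forced <- stats::setNames(vector("list", length(members)), as.character(members))
    for (v in members) forced[[as.character(v)]] <- integer(0)
    for (e in seq_len(nrow(orientation))) {
      ch <- unname(orientation[e, 2L])
      if (block_of[ch] == ci) {
        key <- as.character(ch)
        forced[[key]] <- sort(c(forced[[key]], unname(orientation[e, 1L])))
      }
    }
    list(members = members, forced = forced)
  })
  structure(
    list(orientation = orientation, bitmask = attr(orientation, "bitmask"),
         blocks = blocks),
    class = "bn_candidate"
  )
}

#' Dump a candidate list as JSON for audit
#'
#' @param candidates list of `bn_candidate`.
#' @param path output path.
#' @export
write_candidates_json <- function(candidates, path) {
  payload <- lapply(candidates, function(cand) {
    list(
      bitmask = cand$bitmask,
      orientation = apply(cand$orientation, 1L, function(r) {
        list(parent = r[[1]], child = r[[2]])
      }),
      forced = lapply(cand$blocks, function(b) {
        Filter(length, b$forced)
      })
    )
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
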