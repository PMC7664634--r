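# internal helpers shared across modules

# Kahn topological sort. `edges` is an integer matrix with columns
# (parent, child) over 1..p. Returns the order, or NULL on a cycle.
topo_sort <- function(p, edges) {
  edges <- as_edge_matrix(edges)
  indeg <- integer(p)
  adj <- vector("list", p)
  for (e in seq_len(nrow(edges))) {
    u <- edges[e, 1L]
    v <- edges[e, 2L]
    adj[[u]] <- c(adj[[u]], v)
    indeg[v] <- indeg[v] + 1L
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    out <- c(out, v)
    for (w in adj[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(out) < p) return(NULL)
  out
}

is_acyclic <- function(p, edges) !is.null(topo_sort(p, edges))

as_edge_matrix <- function(edges) {
  if (is.null(edges) || length(edges) == 0L) {
    return(matrix(integer(0), ncol = 2L))
  }
  m <- matrix(as.integer(edges), ncol = 2L)
  m
}

# parents: named list var -> parent vector; returns 2-col (parent, child)
parents_to_edges <- function(parents, index_of = NULL) {
  out <- list()
  for (ch in names(parents)) {
    for (pa in parents[[ch]]) {
      out[[length(out) + 1L]] <- c(pa, ch)
    }
  }
  if (!length(out)) {
    if (is.null(index_of)) return(matrix(character(0), ncol = 2L))
    return(matrix(integer(0), ncol = 2L))
  }
  m <- do.call(rbind, out)
  if (!is.null(index_of)) {
    m <- matrix(index_of[m], ncol = 2L)
  }
  m
}

# subsets of `set` of size 0..max_size, as a list of integer vectors
subsets_up_to <- function(set, max_size) {
  out <- list(integer(0))
  max_size <- min(max_size, length(set))
  if (max_size < 1L) return(out)
  if (length(set) == 1L) return(c(out, list(set)))  # combn(scalar, .) pitfall
  for (s in seq_len(max_size)) {
    cmb <- utils::combn(set, s, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

bit_on <- function(mask, pos) bitwAnd(mask, bitwShiftL(1L, pos - 1L)) != 0L

mask_bits <- function(mask, n) {
  which(vapply(seq_len(n), function(b) bit_on(mask, b), logical(1)))
}

popcount <- function(mask) {
  n <- 0L
  while (mask > 0L) {
    n <- n + bitwAnd(mask, 1L)
    mask <- bitwShiftR(mask, 1L)
  }
  n
}

`%||%` <- function(a, b) if (is.null(a)) b else a
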