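#' Construct a discrete Bayesian network
#'
#' A discrete Bayesian network is a DAG over named variables together with one
#' conditional probability table (CPT) per variable. CPT rows index parent-state
#' configurations with the *first parent varying fastest* (the `expand.grid`
#' convention); columns index the child's states, coded `0 .. r-1`.
#'
#' @param variables character vector of variable names, in order.
#' @param cardinalities integer vector (same length), each `>= 2`.
#' @param parents named list: for each variable, a character vector of parent
#'   names (possibly empty). Missing entries are treated as no parents.
#' @param cpts named list of numeric matrices; for variable `v` with parents
#'   `pa`, dimensions `prod(r[pa]) x r[v]`, each row summing to 1.
#' @param states optional named list of state labels (character) per variable;
#'   defaults to `"s0", "s1", ...`. Labels are metadata only; all computation
#'   uses 0-based integer codes.
#' @return an object of class `bn_net`.
#' @export
bn_net <- function(variables, cardinalities, parents, cpts, states = NULL) {
  variables <- as.character(variables)
  p <- length(variables)
  if (anyDuplicated(variables)) stop("duplicate variable names")
  cardinalities <- as.integer(cardinalities)
  if (length(cardinalities) != p || any(cardinalities < 2L)) {
    stop("cardinalities must match variables and be >= 2")
  }
  names(cardinalities) <- variables
  full_parents <- stats::setNames(vector("list", p), variables)
  for (v in variables) full_parents[[v]] <- as.character(parents[[v]] %||% character(0))
  if (is.null(states)) {
    states <- lapply(cardinalities, function(r) paste0("s", seq_len(r) - 1L))
  }
  net <- structure(
    list(
      variables = variables,
      cardinalities = cardinalities,
      parents = full_parents,
      cpts = cpts[variables],
      states = states[variables]
    ),
    class = "bn_net"
  )
  validate_bn_net(net)
  net
}

validate_bn_net <- function(net, tol = 1e-9) {
  p <- length(net$variables)
  idx <- stats::setNames(seq_len(p), net$variables)
  edges <- parents_to_edges(net$parents, index_of = idx)
  if (!is_acyclic(p, edges)) stop("network is cyclic: no topological order exists")
  for (v in net$variables) {
    pa <- net$parents[[v]]
    if (!all(pa %in% net$variables)) stop("unknown parent of ", v)
    cpt <- net$cpts[[v]]
    nrow_exp <- prod(net$cardinalities[pa])
    if (is.null(cpt) || nrow(cpt) != nrow_exp || ncol(cpt) != net$cardinalities[[v]]) {
      stop(sprintf("CPT of %s must be %d x %d", v, nrow_exp, net$cardinalities[[v]]))
    }
    if (any(cpt < -tol) || any(cpt > 1 + tol)) stop("CPT entries of ", v, " outside [0,1]")
    if (any(abs(rowSums(cpt) - 1) > tol)) stop("CPT rows of ", v, " do not sum to 1")
  }
  invisible(net)
}

#' @export
print.bn_net <- function(x, ...) {
  ne <- nrow(bn_edges(x))
  cat(sprintf("Discrete Bayesian network: %d variables, %d edges\n",
              length(x$variables), ne))
  cat("variables:", paste(utils::head(x$variables, 8L), collapse = ", "),
      if (length(x$variables) > 8L) "..." else "", "\n")
  invisible(x)
}

#' Edge list of a network
#'
#' @param net a `bn_net`.
#' @return a 2-column character matrix (parent, child).
#' @export
bn_edges <- function(net) {
  m <- parents_to_edges(net$parents)
  colnames(m) <- c("parent", "child")
  m
}

# row index (1-based) into a CPT for 0-based parent codes; first parent fastest
parent_config_index <- function(codes, cards) {
  if (length(cards) == 0L) return(rep(1L, max(1L, nrow(codes))))
  codes <- as.matrix(codes)
  stride <- cumprod(c(1L, cards[-length(cards)]))
  as.integer(codes %*% stride) + 1L
}

#' Construct a discrete data matrix
#'
#' Complete-case integer-coded sample matrix: `n` rows (samples) by `p`
#' columns (variables), values `0 .. r_i - 1`.
#'
#' @param values integer matrix with column names.
#' @param cardinalities optional per-column state counts; defaults to
#'   `max(column) + 1`, with a floor of 2.
#' @return an object of class `bn_data`.
#' @export
bn_data <- function(values, cardinalities = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (is.null(colnames(values))) colnames(values) <- paste0("V", seq_len(ncol(values)))
  if (anyNA(values)) stop("missing entries are not supported; complete cases only")
  if (nrow(values) < 1L) stop("need at least one sample")
  if (is.null(cardinalities)) {
    cardinalities <- pmax(apply(values, 2L, max) + 1L, 2L)
  }
  cardinalities <- as.integer(cardinalities)
  names(cardinalities) <- colnames(values)
  if (any(values < 0L) || any(t(values) >= cardinalities)) {
    stop("values must satisfy 0 <= v < cardinality in every column")
  }
  structure(
    list(values = values, cardinalities = cardinalities, n = nrow(values)),
    class = "bn_data"
  )
}

#' @export
print.bn_data <- function(x, ...) {
  cat(sprintf("Discrete data matrix: %d samples x %d variables\n",
              x$n, ncol(x$values)))
  invisible(x)
}

#' Forward (ancestral) sampling from a network
#'
#' Samples each variable given its parents in a fixed topological order from a
#' single seeded generator stream, so identical `(net, n, seed)` give
#' bit-identical matrices.
#'
#' @param net a `bn_net`.
#' @param n number of samples, `>= 1`.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a `bn_data` with the network's column order and cardinalities.
#' @export
forward_sample <- function(net, n, seed = NULL) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  p <- length(net$variables)
  idx <- stats::setNames(seq_len(p), net$variables)
  ord <- topo_sort(p, parents_to_edges(net$parents, index_of = idx))
  vals <- matrix(0L, nrow = n, ncol = p, dimnames = list(NULL, net$variables))
  for (vi in ord) {
    v <- net$variables[vi]
    pa <- net$parents[[v]]
    rows <- if (length(pa)) {
      parent_config_index(vals[, pa, drop = FALSE], net$cardinalities[pa])
    } else {
      rep(1L, n)
    }
    cpt <- net$cpts[[v]]
    cum <- t(apply(cpt, 1L, cumsum))
    cm <- cum[rows, -ncol(cum), drop = FALSE]
    u <- stats::runif(n)
    vals[, v] <- as.integer(rowSums(u > cm))
  }
  bn_data(vals, cardinalities = net$cardinalities)
}

#' Specification for a synthetic sparse block network
#'
#' Describes the study-style fixture: several densely connected blocks of
#' variables joined by a small number of inter-block edges, the regime the
#' block-learning strategy targets.
#'
#' @param n_blocks number of blocks.
#' @param nodes_per_block variables per block.
#' @param intra_density fraction in (0, 1] of the `choose(nb, 2)` possible
#'   within-block edges that are present (default 0.7).
#' @param n_interblock number of edges crossing blocks.
#' @param card_range integer range (min, max) of per-variable cardinalities.
#' @param seed integer seed.
#' @param concentration symmetric Dirichlet concentration for CPT rows
#'   (default 0.5).
#' @param min_tv minimum total-variation distance of every CPT row from the
#'   uniform distribution (default 0.1), so dependencies are detectable.
#' @return an object of class `block_spec`.
#' @export
block_spec <- function(n_blocks, nodes_per_block, intra_density = 0.7,
                       n_interblock = 1L, card_range = c(2L, 3L), seed = 1L,
                       concentration = 0.5, min_tv = 0.1) {
  if (intra_density <= 0 || intra_density > 1) stop("intra_density must be in (0, 1]")
  if (n_blocks < 1L || nodes_per_block < 1L) stop("need >= 1 block and node")
  structure(
    list(
      n_blocks = as.integer(n_blocks),
      nodes_per_block = as.integer(nodes_per_block),
      intra_density = intra_density,
      n_interblock = as.integer(n_interblock),
      card_range = as.integer(card_range),
      seed = as.integer(seed),
      concentration = concentration,
      min_tv = min_tv
    ),
    class = "block_spec"
  )
}

# one CPT row: symmetric Dirichlet, rejected while too close to uniform
rdirichlet_row <- function(r, concentration, min_tv, max_tries = 500L) {
  best <- NULL
  best_tv <- -1
  for (t in seq_len(max_tries)) {
    g <- stats::rgamma(r, shape = concentration) + 1e-12
    pr <- g / sum(g)
    tv <- 0.5 * sum(abs(pr - 1 / r))
    if (tv >= min_tv) return(pr)
    if (tv > best_tv) {
      best_tv <- tv
      best <- pr
    }
  }
  best
}

#' Generate a synthetic sparse block network
#'
#' Builds a DAG whose edges are dense within blocks and sparse across them
#' (edges always point from lower to higher variable index, which fixes a
#' topological order), then fills CPTs from a symmetric Dirichlet with
#' near-uniform rows rejected.
#'
#' @param spec a [block_spec()].
#' @return a `bn_net`; the block partition is attached as `attr(net, "blocks")`
#'   (a list of variable-index vectors).
#' @export
generate_block_network <- function(spec) {
  stopifnot(inherits(spec, "block_spec"))
  set.seed(spec$seed)
  nb <- spec$nodes_per_block
  p <- spec$n_blocks * nb
  vars <- sprintf("B%d_N%d", rep(seq_len(spec$n_blocks), each = nb),
                  rep(seq_len(nb), spec$n_blocks))
  block_of <- rep(seq_len(spec$n_blocks), each = nb)
  blocks <- split(seq_len(p), block_of)

  edges <- matrix(integer(0), ncol = 2L)
  for (b in blocks) {
    if (length(b) < 2L) next
    pairs <- t(utils::combn(b, 2L))
    m_b <- round(spec$intra_density * nrow(pairs))
    if (m_b > nrow(pairs)) stop("infeasible spec: density exceeds maximum DAG edges")
    take <- sample(nrow(pairs), m_b)
    edges <- rbind(edges, pairs[take, , drop = FALSE])
  }
  if (spec$n_interblock > 0L) {
    cross <- t(utils::combn(p, 2L))
    cross <- cross[block_of[cross[, 1L]] != block_of[cross[, 2L]], , drop = FALSE]
    if (spec$n_interblock > nrow(cross)) stop("infeasible spec: too many inter-block edges")
    take <- sample(nrow(cross), spec$n_interblock)
    edges <- rbind(edges, cross[take, , drop = FALSE])
  }

  card_pool <- seq(spec$card_range[1L], spec$card_range[2L])
  cards <- card_pool[sample.int(length(card_pool), p, replace = TRUE)]
  parents <- stats::setNames(vector("list", p), vars)
  for (v in vars) parents[[v]] <- character(0)
  for (e in seq_len(nrow(edges))) {
    ch <- vars[edges[e, 2L]]
    parents[[ch]] <- c(parents[[ch]], vars[edges[e, 1L]])
  }
  cpts <- stats::setNames(vector("list", p), vars)
  for (vi in seq_len(p)) {
    v <- vars[vi]
    nrows <- prod(cards[match(parents[[v]], vars)])
    cpt <- t(vapply(seq_len(nrows), function(r_) {
      rdirichlet_row(cards[vi], spec$concentration, spec$min_tv)
    }, numeric(cards[vi])))
    if (nrows == 1L) cpt <- matrix(cpt, nrow = 1L)
    cpts[[v]] <- cpt
  }
  net <- bn_net(vars, cards, parents, cpts)
  attr(net, "blocks") <- unname(blocks)
  net
}

#' Read a delimited discrete data matrix
#'
#' Expects a header row of variable names; the delimiter is auto-detected
#' (tab vs comma) unless given.
#'
#' @param path file path.
#' @param delim optional delimiter override.
#' @param cardinalities optional per-column state counts.
#' @return a `bn_data`.
#' @export
read_data_matrix <- function(path, delim = NULL, cardinalities = NULL) {
  if (is.null(delim)) {
    first <- readLines(path, n = 1L)
    delim <- if (grepl("\t", first)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          check.names = FALSE, colClasses = "integer")
  bn_data(as.matrix(df), cardinalities = cardinalities)
}

#' Write a data matrix as delimited text
#'
#' @param data a `bn_data`.
#' @param path output path.
#' @param delim delimiter (default comma).
#' @export
write_data_matrix <- function(data, path, delim = ",") {
  utils::write.table(data$values, path, sep = delim, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}
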