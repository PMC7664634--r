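# Fixture builders shared across the suite. Everything is generated in code;
# no binary fixtures.

# Random DAG with edges oriented low -> high index and Dirichlet CPTs.
random_net <- function(p, edge_prob = 0.5, card_range = c(2L, 3L), seed = 1L,
                       concentration = 0.5, min_tv = 0.1) {
  set.seed(seed)
  vars <- paste0("X", seq_len(p))
  card_pool <- seq(card_range[1], card_range[2])
  cards <- card_pool[sample.int(length(card_pool), p, replace = TRUE)]
  parents <- stats::setNames(lapply(seq_len(p), function(i) character(0)), vars)
  if (p >= 2) {
    for (j in 2:p) {
      for (i in 1:(j - 1)) {
        if (stats::runif(1) < edge_prob) {
          parents[[vars[j]]] <- c(parents[[vars[j]]], vars[i])
        }
      }
    }
  }
  cpts <- stats::setNames(vector("list", p), vars)
  for (i in seq_len(p)) {
    nrows <- prod(cards[match(parents[[vars[i]]], vars)])
    rows <- t(vapply(seq_len(nrows), function(r_) {
      g <- stats::rgamma(cards[i], shape = concentration) + 1e-12
      pr <- g / sum(g)
      while (0.5 * sum(abs(pr - 1 / cards[i])) < min_tv) {
        g <- stats::rgamma(cards[i], shape = concentration) + 1e-12
        pr <- g / sum(g)
      }
      pr
    }, numeric(cards[i])))
    if (nrows == 1L) rows <- matrix(rows, nrow = 1L)
    cpts[[vars[i]]] <- rows
  }
  bn_net(vars, cards, parents, cpts)
}

# Markov chain X1 -> X2 -> ... -> Xp of binary variables with flip noise.
chain_net <- function(p, flip = 0.1, p_root = 0.5) {
  vars <- paste0("X", seq_len(p))
  parents <- stats::setNames(lapply(seq_len(p), function(i) {
    if (i == 1) character(0) else vars[i - 1]
  }), vars)
  cpts <- stats::setNames(vector("list", p), vars)
  cpts[[vars[1]]] <- matrix(c(1 - p_root, p_root), 1)
  for (i in seq_len(p)[-1]) {
    cpts[[vars[i]]] <- matrix(c(1 - flip, flip, flip, 1 - flip), 2, 2, byrow = TRUE)
  }
  bn_net(vars, rep(2L, p), parents, cpts)
}

# Independent uniform discrete columns.
independent_data <- function(n, p, cards = 2L, seed = 1L) {
  set.seed(seed)
  vals <- matrix(sample.int(cards, n * p, replace = TRUE) - 1L, n, p,
                 dimnames = list(NULL, paste0("V", seq_len(p))))
  bn_data(vals, cardinalities = rep(cards, p))
}

# truth parents of a net as the index-keyed list bic_score()/hamming() expect
net_parents_idx <- function(net) {
  idx <- stats::setNames(seq_along(net$variables), net$variables)
  out <- stats::setNames(vector("list", length(idx)), as.character(idx))
  for (v in net$variables) {
    out[[as.character(idx[[v]])]] <- sort(unname(idx[net$parents[[v]]]))
  }
  out
}

# does `parents` appear among the oracle's optimal structures?
structure_in <- function(parents, structures) {
  any(vapply(structures, function(s) identical(s, parents), logical(1)))
}

# the standard 3-block study fixture (12 nodes, 2 inter-block edges)
three_block_spec <- function(seed) {
  block_spec(n_blocks = 3, nodes_per_block = 4, intra_density = 0.7,
             n_interblock = 2, card_range = c(2L, 3L), seed = seed)
}
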