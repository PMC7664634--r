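# MKM: K-medoid partitioning of network variables under mutual-information
# similarity. Higher MI = stronger dependence, so assignment maximizes MI to
# the medoid and medoid replacement is adopted when it strictly increases the
# cluster cost (the sum of member-to-medoid MI). Cost is monotonically
# non-decreasing across sweeps, which guarantees termination.

#' Cost of one cluster under a medoid
#'
#' The sum of mutual information between every non-medoid member and the
#' medoid; a singleton cluster has cost 0.
#'
#' @param mi symmetric `p x p` mutual-information matrix.
#' @param cluster integer vector of member indices.
#' @param medoid index of the medoid, which must belong to `cluster`.
#' @return the cluster cost (nats).
#' @export
cluster_cost <- function(mi, cluster, medoid) {
  if (!medoid %in% cluster) stop("medoid must belong to its cluster")
  others <- setdiff(cluster, medoid)
  if (!length(others)) return(0)
  sum(mi[others, medoid])
}

#' Partition variables into blocks by mutual-information K-medoids
#'
#' Precomputes the full pairwise MI matrix, seeds `k` distinct medoids,
#' assigns every variable to the medoid of maximal MI (ties to the
#' lower-indexed medoid; a variable with zero MI to every medoid goes to the
#' smallest-index medoid), then sweeps each cluster adopting any member whose
#' promotion to medoid strictly increases the cluster cost, iterating
#' assignment and replacement until the medoid set is stable.
#'
#' @param data a `bn_data`.
#' @param k number of blocks, `1 <= k <= p`.
#' @param seed integer seed for medoid initialization.
#' @param max_iter sweep cap (default 100; monotone cost makes this a safety
#'   net, not a convergence device).
#' @param init `"random"` (uniform distinct indices) or `"mi_weighted"`
#'   (first medoid uniform, later medoids sampled proportionally to their
#'   minimal dissimilarity `max(MI) - MI` to the chosen ones).
#' @param mi optional precomputed MI matrix.
#' @param init_medoids optional explicit initial medoid indices (distinct,
#'   length `k`); overrides `init`.
#' @return an object of class `bn_blocking`: `k`, `clusters` (list of index
#'   vectors), `medoids`, `cost`, `iterations`, `seed`.
#' @export
mkm <- function(data, k, seed = 1L, max_iter = 100L, init = c("random", "mi_weighted"),
                mi = NULL, init_medoids = NULL) {
  p <- ncol(data$values)
  k <- as.integer(k)
  if (k < 1L || k > p) stop("k must be between 1 and the number of variables")
  init <- match.arg(init)
  if (is.null(mi)) mi <- mi_matrix(data)

  set.seed(as.integer(seed))
  if (!is.null(init_medoids)) {
    medoids <- sort(as.integer(init_medoids))
    if (length(medoids) != k || anyDuplicated(medoids)) {
      stop("init_medoids must be k distinct indices")
    }
  } else if (init == "random") {
    medoids <- sort(sample.int(p, k))
  } else {
    medoids <- sample.int(p, 1L)
    while (length(medoids) < k) {
      dis <- apply(mi[, medoids, drop = FALSE], 1L, max)
      w <- max(dis) - dis + 1e-12
      w[medoids] <- 0
      medoids <- c(medoids, sample.int(p, 1L, prob = w / sum(w)))
    }
    medoids <- sort(medoids)
  }

  assign_all <- function(medoids) {
    cl <- integer(p)
    for (v in seq_len(p)) {
      if (v %in% medoids) {
        cl[v] <- match(v, medoids)
      } else {
        sims <- mi[v, medoids]
        cl[v] <- which.max(sims)  # ties -> lower medoid index
      }
    }
    cl
  }

  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    assignment <- assign_all(medoids)
    new_medoids <- medoids
    for (ci in seq_len(k)) {
      members <- which(assignment == ci)
      best_m <- new_medoids[ci]
      best_cost <- cluster_cost(mi, members, best_m)
      for (cand in setdiff(members, best_m)) {
        cc <- cluster_cost(mi, members, cand)
        if (cc > best_cost) {
          best_cost <- cc
          best_m <- cand
        }
      }
      new_medoids[ci] <- best_m
    }
    if (identical(sort(new_medoids), sort(medoids)) || iterations >= max_iter) {
      medoids <- new_medoids
      assignment <- assign_all(medoids)
      break
    }
    medoids <- new_medoids
  }

  clusters <- lapply(seq_len(k), function(ci) which(assignment == ci))
  cost <- sum(vapply(seq_len(k), function(ci) {
    cluster_cost(mi, clusters[[ci]], medoids[ci])
  }, numeric(1)))
  structure(
    list(k = k, clusters = clusters, medoids = medoids, cost = cost,
         iterations = iterations, seed = as.integer(seed),
         variables = colnames(data$values)),
    class = "bn_blocking"
  )
}

#' @export
print.bn_blocking <- function(x, ...) {
  cat(sprintf("MKM blocking: k = %d, cost = %.4f (%d sweeps)\n",
              x$k, x$cost, x$iterations))
  for (ci in seq_len(x$k)) {
    cat(sprintf("  block %d (medoid %d): %s\n", ci, x$medoids[ci],
                paste(x$clusters[[ci]], collapse = " ")))
  }
  invisible(x)
}

#' Convenience heuristic for the block count
#'
#' `round(sqrt(p / 2))`, floored at 1. Never applied silently; `k` is always
#' an explicit user input to [mkm()] and [blmkm()].
#'
#' @param p number of variables.
#' @return suggested `k`.
#' @export
mkm_suggest_k <- function(p) max(1L, as.integer(round(sqrt(p / 2))))

#' Serialize a blocking to JSON
#'
#' @param blocking a `bn_blocking`.
#' @param path output path.
#' @export
write_blocking_json <- function(blocking, path) {
  jsonlite::write_json(
    list(k = blocking$k, clusters = blocking$clusters,
         medoids = blocking$medoids, cost = blocking$cost,
         seed = blocking$seed),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
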