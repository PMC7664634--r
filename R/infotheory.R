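# Contingency counting, plug-in mutual information, and the G^2
# conditional-independence test that drives MMPC. Natural logarithms
# throughout, so information quantities are commensurate with the MDL and
# BIC scores. 0 * log(0) := 0 everywhere; no smoothing.

# 0-based joint code of columns `idx`, first index varying fastest
joint_code <- function(data, idx) {
  if (length(idx) == 0L) return(rep(0L, data$n))
  cards <- data$cardinalities[idx]
  stride <- cumprod(c(1L, cards[-length(cards)]))
  as.integer(data$values[, idx, drop = FALSE] %*% stride)
}

#' Plug-in mutual information between two variables (nats)
#'
#' Empirical estimate of `I(X;Y) = sum p(x,y) log[p(x,y) / (p(x) p(y))]` from
#' the joint contingency table, with `0 log 0 := 0`. Symmetric and
#' non-negative up to float slack.
#'
#' @param data a `bn_data`.
#' @param i,j distinct column indices.
#' @return mutual information in nats.
#' @export
mutual_information <- function(data, i, j) {
  p <- ncol(data$values)
  if (i < 1L || i > p || j < 1L || j > p) stop("variable index out of range")
  if (i == j) stop("i and j must differ")
  ri <- data$cardinalities[[i]]
  rj <- data$cardinalities[[j]]
  n_xy <- tabulate(data$values[, i] + ri * data$values[, j] + 1L, nbins = ri * rj)
  n_xy <- matrix(n_xy, nrow = ri, ncol = rj)
  n_x <- rowSums(n_xy)
  n_y <- colSums(n_xy)
  N <- data$n
  nz <- which(n_xy > 0, arr.ind = TRUE)
  cells <- n_xy[nz]
  sum(cells / N * log(cells * N / (n_x[nz[, 1L]] * n_y[nz[, 2L]])))
}

#' Pairwise mutual-information matrix
#'
#' @param data a `bn_data`.
#' @return symmetric `p x p` matrix (nats), zero diagonal.
#' @export
mi_matrix <- function(data) {
  p <- ncol(data$values)
  m <- matrix(0, p, p, dimnames = list(colnames(data$values), colnames(data$values)))
  for (i in seq_len(p - 1L)) {
    for (j in seq(i + 1L, p)) {
      m[i, j] <- m[j, i] <- mutual_information(data, i, j)
    }
  }
  m
}

#' G-squared conditional-independence test
#'
#' Tests X_i independent of X_j given the variables in `S`. The statistic is
#' `2 N * CMI` in nats; degrees of freedom are
#' `(r_i - 1)(r_j - 1) * #\{conditioning configurations with positive count\}`
#' (configurations never observed contribute nothing and reduce the effective
#' df), floored at 1. The p-value is the chi-square upper tail.
#'
#' @param data a `bn_data`.
#' @param i,j distinct column indices, not in `S`.
#' @param S conditioning set of column indices (possibly empty).
#' @param max_cond cap on `length(S)`.
#' @return an object of class `bn_citest`: statistic, df, p_value, S.
#' @export
ci_test <- function(data, i, j, S = integer(0), max_cond = Inf) {
  S <- as.integer(S)
  if (length(S) > max_cond) stop("conditioning set larger than the configured cap")
  if (i == j || i %in% S || j %in% S) stop("i, j must be distinct and outside S")
  ri <- data$cardinalities[[i]]
  rj <- data$cardinalities[[j]]
  rs <- if (length(S)) prod(data$cardinalities[S]) else 1L
  code_s <- joint_code(data, S)
  code <- data$values[, i] + ri * (data$values[, j] + rj * code_s)
  n_xys <- array(tabulate(code + 1L, nbins = ri * rj * rs), dim = c(ri, rj, rs))
  g2 <- 0
  nonzero_configs <- 0L
  for (s in seq_len(rs)) {
    slab <- n_xys[, , s, drop = FALSE]
    dim(slab) <- c(ri, rj)
    Ns <- sum(slab)
    if (Ns == 0L) next
    nonzero_configs <- nonzero_configs + 1L
    n_xs <- rowSums(slab)
    n_ys <- colSums(slab)
    nz <- which(slab > 0, arr.ind = TRUE)
    cells <- slab[nz]
    g2 <- g2 + 2 * sum(cells * log(cells * Ns / (n_xs[nz[, 1L]] * n_ys[nz[, 2L]])))
  }
  df <- max(1L, (ri - 1L) * (rj - 1L) * max(nonzero_configs, 1L))
  structure(
    list(
      statistic = max(g2, 0),
      df = df,
      p_value = stats::pchisq(max(g2, 0), df = df, lower.tail = FALSE),
      S = S
    ),
    class = "bn_citest"
  )
}

#' @export
print.bn_citest <- function(x, ...) {
  cat(sprintf("G^2 = %.4f, df = %d, p = %.4g (|S| = %d)\n",
              x$statistic, x$df, x$p_value, length(x$S)))
  invisible(x)
}
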