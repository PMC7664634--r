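# Interchange formats: edge-list TSV, DOT export, MI matrix dump.

#' Write / read a DAG as an edge-list TSV (`parent<TAB>child`, with header)
#'
#' @param x a `bn_net`, `blmkm_fit`, edge matrix, or parents list.
#' @param path file path.
#' @export
write_edges_tsv <- function(x, path) {
  edges <- as_name_edges(x)
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edges_tsv
#' @return for the reader: a 2-column character matrix (parent, child).
#' @export
read_edges_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) == 0L) m <- matrix(character(0), ncol = 2L)
  colnames(m) <- c("parent", "child")
  m
}

#' Export a DAG in DOT format for visualization
#'
#' @param x a `bn_net`, `blmkm_fit`, edge matrix, or parents list.
#' @param path output path.
#' @param variables optional full variable set, so isolated nodes appear.
#' @export
write_dot <- function(x, path, variables = NULL) {
  edges <- as_name_edges(x)
  lines <- c("digraph bn {")
  for (v in variables %||% unique(as.vector(edges))) {
    lines <- c(lines, sprintf("  \"%s\";", v))
  }
  for (e in seq_len(nrow(edges))) {
    lines <- c(lines, sprintf("  \"%s\" -> \"%s\";", edges[e, 1L], edges[e, 2L]))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

#' Dump a pairwise MI matrix as TSV
#'
#' @param mi matrix from [mi_matrix()].
#' @param path output path.
#' @export
write_mi_tsv <- function(mi, path) {
  utils::write.table(mi, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}
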