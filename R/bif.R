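# BIF (Bayesian Interchange Format) reading and writing.
#
# Supported dialect: `network`, `variable ... { type discrete [ r ] { labels }; }`
# and `probability ( X | P1, P2 ) { ... }` blocks, with either a `table` line
# (root nodes) or one `(label, label) p1, p2, ...;` line per parent
# configuration. Comments (`//`) are ignored.

bif_error <- function(msg, txt, pos) {
  line <- 1L + lengths(regmatches(substr(txt, 1L, pos),
                                  gregexpr("\n", substr(txt, 1L, pos), fixed = TRUE)))
  stop(sprintf("BIF parse error at line %d: %s", line, msg), call. = FALSE)
}

#' Read a Bayesian network from a BIF file
#'
#' Variable order is file order; state labels are preserved as metadata while
#' all computation uses 0-based state codes. CPT rows failing normalization by
#' more than 1e-6 are an error; smaller drift is renormalized.
#'
#' @param path path to a BIF file.
#' @return a `bn_net`.
#' @export
read_bif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("//.*$", "", lines)
  txt <- paste(lines, collapse = "\n")

  var_re <- "variable\\s+([A-Za-z0-9_.-]+)\\s*\\{\\s*type\\s+discrete\\s*\\[\\s*([0-9]+)\\s*\\]\\s*\\{([^}]*)\\}\\s*;\\s*\\}"
  vm <- gregexpr(var_re, txt, perl = TRUE)[[1]]
  if (vm[1] == -1L) bif_error("no variable blocks found", txt, 1L)
  vstr <- regmatches(txt, gregexpr(var_re, txt, perl = TRUE))[[1]]
  variables <- character(0)
  cards <- integer(0)
  states <- list()
  for (s in vstr) {
    parts <- regmatches(s, regexec(var_re, s, perl = TRUE))[[1]]
    name <- parts[2]
    r <- as.integer(parts[3])
    labs <- trimws(strsplit(parts[4], ",", fixed = TRUE)[[1]])
    labs <- labs[nzchar(labs)]
    if (length(labs) != r) {
      bif_error(sprintf("variable %s declares %d states but lists %d labels",
                        name, r, length(labs)), txt, vm[match(s, vstr)])
    }
    variables <- c(variables, name)
    cards <- c(cards, r)
    states[[name]] <- labs
  }
  names(cards) <- variables

  prob_re <- "probability\\s*\\(\\s*([A-Za-z0-9_.-]+)\\s*(\\|([^)]*))?\\)\\s*\\{([^}]*)\\}"
  pm <- gregexpr(prob_re, txt, perl = TRUE)[[1]]
  pstr <- if (pm[1] == -1L) character(0) else regmatches(txt, gregexpr(prob_re, txt, perl = TRUE))[[1]]
  parents <- stats::setNames(vector("list", length(variables)), variables)
  for (v in variables) parents[[v]] <- character(0)
  cpts <- stats::setNames(vector("list", length(variables)), variables)

  for (si in seq_along(pstr)) {
    s <- pstr[si]
    pos <- pm[si]
    parts <- regmatches(s, regexec(prob_re, s, perl = TRUE))[[1]]
    child <- parts[2]
    if (!child %in% variables) bif_error(paste0("probability block for undeclared variable ", child), txt, pos)
    pa <- character(0)
    if (nzchar(parts[4]) || nzchar(parts[3])) {
      pa <- trimws(strsplit(parts[4], ",", fixed = TRUE)[[1]])
      pa <- pa[nzchar(pa)]
    }
    if (!all(pa %in% variables)) bif_error(paste0("undeclared parent in block for ", child), txt, pos)
    parents[[child]] <- pa
    body <- parts[5]
    nrows <- prod(cards[pa])
    cpt <- matrix(NA_real_, nrow = nrows, ncol = cards[[child]])
    if (length(pa) == 0L) {
      tm <- regexec("table\\s*([^;]*);", body, perl = TRUE)[[1]]
      if (tm[1] == -1L) bif_error(paste0("root variable ", child, " needs a table line"), txt, pos)
      vals <- as.numeric(trimws(strsplit(regmatches(body, list(tm))[[1]][2], ",")[[1]]))
      if (length(vals) != cards[[child]]) bif_error(paste0("wrong table length for ", child), txt, pos)
      cpt[1L, ] <- vals
    } else {
      entries <- regmatches(body, gregexpr("\\(([^)]*)\\)\\s*([^;]*);", body, perl = TRUE))[[1]]
      if (length(entries) != nrows) {
        bif_error(sprintf("%s: expected %d parent configurations, found %d",
                          child, nrows, length(entries)), txt, pos)
      }
      for (en in entries) {
        ep <- regmatches(en, regexec("\\(([^)]*)\\)\\s*([^;]*);", en, perl = TRUE))[[1]]
        labs <- trimws(strsplit(ep[2], ",", fixed = TRUE)[[1]])
        if (length(labs) != length(pa)) bif_error(paste0("wrong parent-state count for ", child), txt, pos)
        codes <- mapply(function(l, pv) match(l, states[[pv]]) - 1L, labs, pa)
        if (anyNA(codes)) bif_error(paste0("unknown parent state label for ", child), txt, pos)
        row <- parent_config_index(matrix(codes, nrow = 1L), cards[pa])
        vals <- as.numeric(trimws(strsplit(ep[3], ",")[[1]]))
        if (length(vals) != cards[[child]]) bif_error(paste0("wrong probability count for ", child), txt, pos)
        cpt[row, ] <- vals
      }
    }
    if (anyNA(cpt)) bif_error(paste0("missing parent configuration for ", child), txt, pos)
    bad <- abs(rowSums(cpt) - 1) > 1e-6
    if (any(bad)) {
      bif_error(sprintf("CPT row of %s sums to %.8f, not 1", child,
                        rowSums(cpt)[which(bad)[1]]), txt, pos)
    }
    cpts[[child]] <- cpt / rowSums(cpt)
  }
  missing_cpt <- variables[vapply(cpts, is.null, logical(1))]
  if (length(missing_cpt)) {
    bif_error(paste0("no probability block for ", missing_cpt[1]), txt, nchar(txt))
  }
  bn_net(variables, cards, parents, cpts, states = states)
}

#' Write a Bayesian network to a BIF file
#'
#' @param net a `bn_net`.
#' @param path output path.
#' @export
write_bif <- function(net, path) {
  out <- c("network unknown {", "}")
  for (v in net$variables) {
    out <- c(out,
             sprintf("variable %s {", v),
             sprintf("  type discrete [ %d ] { %s };",
                     net$cardinalities[[v]], paste(net$states[[v]], collapse = ", ")),
             "}")
  }
  fmt <- function(x) paste(vapply(x, function(z) format(z, digits = 17), character(1)),
                           collapse = ", ")
  for (v in net$variables) {
    pa <- net$parents[[v]]
    cpt <- net$cpts[[v]]
    if (length(pa) == 0L) {
      out <- c(out,
               sprintf("probability ( %s ) {", v),
               sprintf("  table %s;", fmt(cpt[1L, ])),
               "}")
    } else {
      out <- c(out, sprintf("probability ( %s | %s ) {", v, paste(pa, collapse = ", ")))
      grid <- expand.grid(lapply(net$cardinalities[pa], function(r) seq_len(r) - 1L))
      for (row in seq_len(nrow(cpt))) {
        labs <- mapply(function(code, pv) net$states[[pv]][code + 1L],
                       as.integer(unlist(grid[row, , drop = FALSE])), pa)
        out <- c(out, sprintf("  (%s) %s;", paste(labs, collapse = ", "), fmt(cpt[row, ])))
      }
      out <- c(out, "}")
    }
  }
  writeLines(out, path)
  invisible(path)
}
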