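#' Construct a normalized gene set
#'
#' Symbols are uppercased, trimmed, de-duplicated; empty strings drop.
#'
#' @param symbols character vector of gene symbols.
#' @param label set label.
#' @return class `"pv_geneset"` with `label` and `symbols`.
#' @export
gene_set <- function(symbols, label = "") {
  symbols <- unique(norm_name(symbols))
  symbols <- symbols[nzchar(symbols) & !is.na(symbols)]
  structure(list(label = label, symbols = symbols), class = "pv_geneset")
}

#' Read a one-symbol-per-line gene list
#'
#' @param path file path; `#` starts a comment.
#' @param label set label; defaults to the file name.
#' @return a [gene_set()].
#' @export
read_gene_list <- function(path, label = basename(path)) {
  lines <- sub("#.*$", "", readLines(path, warn = FALSE))
  gene_set(lines, label = label)
}

#' Intersect two gene sets
#'
#' Exact set intersection after normalization; commutative and idempotent.
#'
#' @param x,y [gene_set()] objects (bare character vectors are accepted).
#' @return a [gene_set()] of the common symbols; its size is the overlap
#'   cardinality.
#' @export
intersect_sets <- function(x, y) {
  if (!inherits(x, "pv_geneset")) x <- gene_set(x)
  if (!inherits(y, "pv_geneset")) y <- gene_set(y)
  gene_set(intersect(x$symbols, y$symbols),
           label = paste0(x$label, " & ", y$label))
}

#' @export
print.pv_geneset <- function(x, ...) {
  cat("<gene set>", x$label, "-", length(x$symbols), "symbols\n")
  invisible(x)
}

#' Load an interaction edge list with a confidence floor
#'
#' Accepts STRING-style TSV with two symbol columns and an optional
#' `combined_score` column. Scores on the 0–1000 integer scale are
#' auto-detected (any value > 1) and divided by 1000, with a message. Edges
#' below `score_floor` are dropped; self loops are removed and duplicate
#' edges (either orientation) collapse to one undirected edge, keeping the
#' highest score.
#'
#' @param path TSV path (header with at least two columns).
#' @param score_floor minimum combined score on the 0–1 scale kept; the
#'   conventional permissive cutoff is 0.15.
#' @return class `"pv_graph"`: `edges` (`from`, `to`, `score`; `from < to`
#'   lexicographically) and `nodes`.
#' @export
load_edges <- function(path, score_floor = 0.15) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = "character", fill = TRUE)
  if (nrow(tab) == 0L)
    return(structure(list(edges = data.table(from = character(0),
                                             to = character(0),
                                             score = numeric(0)),
                          nodes = character(0), score_floor = score_floor),
                     class = "pv_graph"))
  if (ncol(tab) < 2L) stop("edge list needs at least two symbol columns")
  p1 <- norm_name(tab[[1]]); p2 <- norm_name(tab[[2]])
  bad <- which(is.na(p1) | is.na(p2) | !nzchar(p1) | !nzchar(p2))
  if (length(bad))
    stop("malformed edge row at line ", bad[1] + 1L,
         ": missing protein symbol")
  score <- if (ncol(tab) >= 3L) suppressWarnings(as.numeric(tab[[3]])) else rep(1, nrow(tab))
  bad <- which(is.na(score))
  if (length(bad))
    stop("malformed edge row at line ", bad[1] + 1L, ": non-numeric score")
  if (any(score > 1)) {
    score <- score / 1000
    message("edge scores look 0-1000 scaled; divided by 1000")
  }
  e <- data.table(from = pmin(p1, p2), to = pmax(p1, p2), score = score)
  e <- e[from != to & score >= score_floor]
  e <- e[order(-score)][!duplicated(paste(from, to))]
  setorder(e, from, to)
  structure(list(edges = e, nodes = sort(unique(c(e$from, e$to))),
                 score_floor = score_floor),
            class = "pv_graph")
}

#' @export
print.pv_graph <- function(x, ...) {
  cat("<interaction graph>", length(x$nodes), "nodes,", nrow(x$edges),
      "edges (score floor", x$score_floor, ")\n")
  invisible(x)
}

#' Rank hub genes by degree centrality
#'
#' Degree centrality is a node's undirected edge count. Ties are broken
#' lexicographically on the gene symbol (documented convention; the field's
#' plugin tooling leaves ties unspecified).
#'
#' @param g a [load_edges()] result.
#' @param k number of hubs to return (the conventional choice is 3). If `k`
#'   exceeds the node count all nodes are returned with a warning.
#' @return a `data.table` (`gene`, `degree`) sorted by descending degree then
#'   symbol.
#' @export
degree_hubs <- function(g, k = 3) {
  stopifnot(inherits(g, "pv_graph"), k >= 1)
  deg <- table(factor(c(g$edges$from, g$edges$to), levels = g$nodes))
  res <- data.table(gene = names(deg), degree = as.integer(deg))
  setorder(res, -degree, gene)
  if (k > nrow(res)) {
    warning("k = ", k, " exceeds node count ", nrow(res), "; returning all")
    k <- nrow(res)
  }
  res[seq_len(k)]
}
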