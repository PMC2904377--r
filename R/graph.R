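#' Read an undirected edge list
#'
#' Parses a plain-text edge list in which each non-empty line names two
#' linked nodes separated by a tab or space.  Lines beginning with `#` are
#' treated as comments.  Duplicate lines and reversed duplicates collapse to
#' a single undirected edge; self-edges are dropped with a warning; tokens
#' after the second on a line are ignored with a warning (so weighted edge
#' lists can be read as unweighted).
#'
#' @param path Path to the edge-list file.
#' @return A `netgraph` object: node labels in first-appearance order, the
#'   symmetric 0/1 adjacency matrix, and the edge list.
#' @export
#' @examples
#' f <- tempfile()
#' writeLines(c("a b", "b c"), f)
#' g <- read_edge_list(f)
#' g$num_edges
read_edge_list <- function(path) {
  if (length(path) != 1L || !is.character(path)) {
    stop("'path' must be a single file path")
  }
  if (!file.exists(path)) {
    stop("input file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  from <- character(0)
  to <- character(0)
  n_extra <- 0L
  n_self <- 0L
  ord_tokens <- character(0)
  for (i in idx) {
    tokens <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(tokens) < 2L) {
      stop("parse error at line ", i, ": expected two node labels, got ",
           sQuote(lines[i]))
    }
    if (length(tokens) > 2L) n_extra <- n_extra + 1L
    ord_tokens <- c(ord_tokens, tokens[1:2])
    if (tokens[1] == tokens[2]) {
      n_self <- n_self + 1L
    } else {
      from <- c(from, tokens[1])
      to <- c(to, tokens[2])
    }
  }
  if (n_extra > 0L) {
    warning(n_extra, " line(s) had extra tokens after the second; ignored")
  }
  if (n_self > 0L) {
    warning(n_self, " self-edge(s) dropped")
  }
  nodes <- unique(ord_tokens)
  new_netgraph(nodes, cbind(from, to))
}

#' Construct a graph from node labels and an edge list
#'
#' @param nodes Character vector of unique node labels (defines node order).
#' @param edges Two-column character matrix of undirected edges; duplicates
#'   (in either orientation) are collapsed.
#' @return A `netgraph` object.
#' @export
new_netgraph <- function(nodes, edges) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("node labels must be unique")
  n <- length(nodes)
  if (n < 1L) stop("graph must have at least one node")
  adjacency <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  if (NROW(edges) > 0L) {
    i <- match(edges[, 1], nodes)
    j <- match(edges[, 2], nodes)
    if (anyNA(i) || anyNA(j)) {
      stop("edge refers to unknown node label")
    }
    if (any(i == j)) stop("self-edges are not allowed in a netgraph")
    adjacency[cbind(i, j)] <- 1L
    adjacency[cbind(j, i)] <- 1L
  }
  eidx <- which(upper.tri(adjacency) & adjacency == 1L, arr.ind = TRUE)
  edge_mat <- cbind(from = nodes[eidx[, 1]], to = nodes[eidx[, 2]])
  structure(
    list(
      nodes = nodes,
      adjacency = adjacency,
      edges = edge_mat,
      num_nodes = n,
      num_edges = nrow(edge_mat)
    ),
    class = "netgraph"
  )
}

#' @export
print.netgraph <- function(x, ...) {
  cat("netgraph:", x$num_nodes, "nodes,", x$num_edges, "edges\n")
  invisible(x)
}

#' Principal adjacency submatrix
#'
#' @param g A `netgraph`.
#' @param members Character vector of node labels (a subset of `g$nodes`).
#' @return The 0/1 adjacency submatrix restricted to `members`, in the order
#'   given.
#' @export
adjacency_submatrix <- function(g, members) {
  stopifnot(inherits(g, "netgraph"))
  unknown <- setdiff(members, g$nodes)
  if (length(unknown) > 0L) {
    stop("unknown node label(s): ", paste(unknown, collapse = ", "))
  }
  g$adjacency[members, members, drop = FALSE]
}

#' Write a graph back to a two-column edge list
#'
#' @param g A `netgraph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "netgraph"))
  writeLines(paste(g$edges[, 1], g$edges[, 2], sep = "\t"), path)
  invisible(path)
}
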