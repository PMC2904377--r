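# round half away from zero (round() in R rounds half to even)
round_half_up <- function(x) trunc(x + 0.5 * sign(x))

#' Planted caveman graph
#'
#' Builds the disjoint union of `num_clusters` complete graphs of
#' `cluster_size` nodes each — a caveman graph with a known planted
#' community structure.  Each community of size k contributes k(k-1)/2
#' edges.  Node labels encode the community (`c<community>_<member>`).
#'
#' @param num_clusters Number of planted communities (>= 1).
#' @param cluster_size Nodes per community (>= 2).
#' @return A `planted_graph`: list with `graph` (a `netgraph`), `planted`
#'   (a `node_partition` giving the ground truth) and `degradation_pct`.
#' @export
#' @examples
#' pg <- make_caveman(2, 3)   # two disjoint triangles
#' pg$graph$num_edges         # 6
make_caveman <- function(num_clusters, cluster_size) {
  num_clusters <- as.integer(num_clusters)
  cluster_size <- as.integer(cluster_size)
  if (is.na(num_clusters) || num_clusters < 1L) {
    stop("num_clusters must be >= 1")
  }
  if (is.na(cluster_size) || cluster_size < 2L) {
    stop("cluster_size must be >= 2")
  }
  wid_c <- nchar(as.character(num_clusters))
  wid_m <- nchar(as.character(cluster_size))
  labels <- as.vector(t(outer(
    seq_len(num_clusters), seq_len(cluster_size),
    function(c, m) sprintf("c%0*d_%0*d", wid_c, c, wid_m, m)
  )))
  membership <- rep(seq_len(num_clusters), each = cluster_size)
  within <- t(utils::combn(cluster_size, 2))
  edges <- do.call(rbind, lapply(seq_len(num_clusters), function(c) {
    off <- (c - 1L) * cluster_size
    cbind(labels[within[, 1] + off], labels[within[, 2] + off])
  }))
  structure(
    list(
      graph = new_netgraph(labels, edges),
      planted = new_partition(stats::setNames(membership, labels)),
      degradation_pct = 0
    ),
    class = "planted_graph"
  )
}

#' @export
print.planted_graph <- function(x, ...) {
  cat(sprintf("planted graph: %d nodes, %d edges, %d communities, %g%% degraded\n",
              x$graph$num_nodes, x$graph$num_edges, max(x$planted),
              x$degradation_pct))
  invisible(x)
}

#' Degrade a planted graph
#'
#' Two-step corruption at a given percentage `pct`: first `round(pct% of
#' the edges)` are removed uniformly without replacement; then `round(pct%
#' of the remaining edges)` shuffle moves are performed, each deleting one
#' uniformly chosen existing edge and inserting an edge between a uniformly
#' chosen currently non-adjacent pair of distinct nodes.  Shuffling
#' preserves the post-removal edge count; the planted partition is left
#' unchanged.  Rounding is half-away-from-zero.  Uses R's global RNG.
#'
#' @param pg A `planted_graph`.
#' @param pct Degradation percentage in `[0, 100]`.
#' @return The degraded `planted_graph`.
#' @export
degrade <- function(pg, pct) {
  stopifnot(inherits(pg, "planted_graph"))
  if (!is.numeric(pct) || length(pct) != 1L || is.na(pct) ||
      pct < 0 || pct > 100) {
    stop("pct must be a percentage in [0, 100]")
  }
  if (pct == 0) return(pg)
  g <- pg$graph
  nodes <- g$nodes
  n <- g$num_nodes
  edges <- cbind(match(g$edges[, 1], nodes), match(g$edges[, 2], nodes))
  e0 <- nrow(edges)
  n_rm <- round_half_up(pct / 100 * e0)
  if (n_rm > 0L) {
    edges <- edges[-sample.int(e0, n_rm), , drop = FALSE]
  }
  e1 <- nrow(edges)
  n_sh <- round_half_up(pct / 100 * e1)
  if (n_sh > 0L && e1 > 0L) {
    adj <- matrix(FALSE, n, n)
    adj[edges] <- TRUE
    adj[edges[, 2:1, drop = FALSE]] <- TRUE
    free_pairs <- n * (n - 1) / 2 - e1
    for (mv in seq_len(n_sh)) {
      if (free_pairs < 1L) stop("graph saturated: no non-adjacent pair left")
      del <- sample.int(nrow(edges), 1L)
      adj[edges[del, 1], edges[del, 2]] <- FALSE
      adj[edges[del, 2], edges[del, 1]] <- FALSE
      repeat {
        ij <- sample.int(n, 2L)
        if (!adj[ij[1], ij[2]]) break
      }
      edges[del, ] <- sort(ij)
      adj[ij[1], ij[2]] <- TRUE
      adj[ij[2], ij[1]] <- TRUE
    }
  }
  out <- pg
  out$graph <- new_netgraph(nodes, cbind(nodes[edges[, 1]], nodes[edges[, 2]]))
  out$degradation_pct <- pct
  out
}

#' Minimum misclassified nodes between two partitions
#'
#' The smallest number of nodes whose reassignment makes the two partitions
#' identical, computed as `n` minus the weight of a maximum-weight matching
#' between the clusters of the two partitions, where the weight of a
#' cluster pair is the number of shared members.
#'
#' @param recovered,planted `node_partition` objects over the same node set.
#' @return A non-negative integer.
#' @export
misclassified_count <- function(recovered, planted) {
  stopifnot(inherits(recovered, "node_partition"),
            inherits(planted, "node_partition"))
  nodes <- names(planted)
  if (!setequal(names(recovered), nodes) ||
      length(recovered) != length(nodes)) {
    stop("partitions are over different node sets")
  }
  a <- unclass(recovered)[nodes]
  b <- unclass(planted)[nodes]
  tab <- table(a, b)
  nr <- nrow(tab); nc <- ncol(tab)
  idx <- which(tab > 0, arr.ind = TRUE)
  bip <- igraph::make_bipartite_graph(
    rep(c(FALSE, TRUE), c(nr, nc)),
    as.vector(rbind(idx[, 1], nr + idx[, 2]))
  )
  m <- igraph::max_bipartite_match(bip, weights = tab[idx])
  length(nodes) - as.integer(m$matching_weight)
}
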