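tip_descendants <- function(t) {
  # list of tip index sets per node, computed by a postorder sweep
  nt <- ape::Ntip(t)
  nn <- nt + t$Nnode
  po <- ape::reorder.phylo(t, "postorder")
  desc <- vector("list", nn)
  for (i in seq_len(nt)) desc[[i]] <- i
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

#' Nested partitions from a root-to-leaves scan of a dendrogram
#'
#' Scans the rooted dendrogram from the root towards the leaves: internal
#' nodes are opened in order of increasing distance from the root (the root
#' first; exact ties broken by preorder position, ancestors always before
#' descendants), and opening a node splits its cluster into the node's two
#' subtrees.  This yields one nested partition per cluster count, from the
#' single all-node cluster down to all singletons — as many partitions as
#' there are leaves.
#'
#' @param t A rooted binary tree of class [ape::phylo] whose tip labels are
#'   exactly `g$nodes`.
#' @param g A `netgraph`.
#' @return List of `node_partition` objects with 1, 2, ..., `num_nodes`
#'   clusters.
#' @export
scan_partitions <- function(t, g) {
  stopifnot(inherits(t, "phylo"), inherits(g, "netgraph"))
  if (!ape::is.rooted(t)) stop("tree must be rooted")
  if (!setequal(t$tip.label, g$nodes) ||
      length(t$tip.label) != g$num_nodes) {
    stop("tree leaves do not match graph nodes")
  }
  nt <- ape::Ntip(t)
  if (nt == 1L) {
    return(list(new_partition(stats::setNames(1L, t$tip.label))))
  }
  if (!ape::is.binary(t)) stop("tree must be binary")
  depths <- ape::node.depth.edgelength(t)
  root <- nt + 1L
  internal <- root:(nt + t$Nnode)
  pre <- ape::reorder.phylo(t, "cladewise")
  pre_pos <- match(internal, c(root, pre$edge[, 2]))
  ord <- internal[order(depths[internal], pre_pos)]
  desc <- tip_descendants(t)
  kids <- split(t$edge[, 2], t$edge[, 1])
  assign <- rep(1L, nt)
  out <- vector("list", nt)
  out[[1]] <- new_partition(stats::setNames(assign, t$tip.label))
  nxt <- 1L
  for (v in ord) {
    ch <- kids[[as.character(v)]]
    nxt <- nxt + 1L
    assign[desc[[ch[2]]]] <- nxt
    out[[nxt]] <- new_partition(stats::setNames(assign, t$tip.label))
  }
  out
}

#' Newman-Girvan modularity of a partition
#'
#' `Q = sum_c [ l_c / m - (d_c / 2m)^2 ]` where `m` is the total number of
#' edges, `l_c` the number of intra-cluster edges of cluster `c` and `d_c`
#' the sum of degrees of its members (intra-cluster edges counted twice).
#'
#' @param g A `netgraph` with at least one edge.
#' @param p A `node_partition` covering `g$nodes`.
#' @return The modularity, a real number in `[-1, 1)`.
#' @export
modularity_q <- function(g, p) {
  stopifnot(inherits(g, "netgraph"), inherits(p, "node_partition"))
  if (g$num_edges < 1L) stop("modularity is undefined for an edgeless graph")
  check_partition_covers(g, p)
  a <- unclass(p)[g$nodes]
  m <- g$num_edges
  ci <- a[g$edges[, 1]]
  cj <- a[g$edges[, 2]]
  nc <- max(a)
  l_c <- tabulate(ci[ci == cj], nbins = nc)
  deg <- rowSums(g$adjacency)
  d_c <- as.vector(tapply(deg[g$nodes], a, sum, default = 0))
  d_c[is.na(d_c)] <- 0
  sum(l_c / m - (d_c / (2 * m))^2)
}

check_partition_covers <- function(g, p) {
  if (!setequal(names(p), g$nodes) || length(p) != g$num_nodes) {
    stop("partition does not cover the graph's node set")
  }
  invisible(TRUE)
}

h_index_inputs <- function(g, p) {
  a <- unclass(p)[g$nodes]
  k <- g$num_nodes
  sizes <- tabulate(a)
  list(
    F = k * (k - 1) / 2,
    n_obs = g$num_edges,
    M = sum(sizes * (sizes - 1) / 2),
    p_intra = sum(a[g$edges[, 1]] == a[g$edges[, 2]])
  )
}

#' Hypergeometric surprise index H of a partition
#'
#' Measures how unexpected the observed concentration of edges inside
#' clusters is when the `n` observed edges are assumed to fall uniformly at
#' random among the `F = k(k-1)/2` possible node pairs, of which `M` are
#' intra-cluster in the given partition.  The upper-tail cumulative
#' hypergeometric probability `P = P(X >= p_intra)` of seeing at least the
#' observed number of intra-cluster edges is computed in log space, and
#' `H = -log10(P)` is returned: the larger H, the more unexpected (better)
#' the partition.  H is 0 for the trivial one-cluster and all-singleton
#' partitions.
#'
#' @param g A `netgraph`.
#' @param p A `node_partition` covering `g$nodes`.
#' @param details If `TRUE`, also return the inputs `F`, `n_obs`, `M`,
#'   `p_intra`.
#' @return The index H (non-negative), or a list when `details = TRUE`.
#' @export
hypergeometric_h <- function(g, p, details = FALSE) {
  stopifnot(inherits(g, "netgraph"), inherits(p, "node_partition"))
  check_partition_covers(g, p)
  hi <- h_index_inputs(g, p)
  if (hi$M > hi$F || hi$p_intra > hi$n_obs) {
    stop("inconsistent hypergeometric inputs")
  }
  log_p <- stats::phyper(hi$p_intra - 1, hi$M, hi$F - hi$M, hi$n_obs,
                         lower.tail = FALSE, log.p = TRUE)
  h <- max(0, -log_p / log(10))
  if (details) c(list(H = h, log10P = log_p / log(10)), hi) else h
}

#' Score a partition with both indices
#'
#' @param g A `netgraph`.
#' @param p A `node_partition`.
#' @return A `partition_score`: the partition, its cluster count, Q, H and
#'   the hypergeometric inputs.
#' @export
score_partition <- function(g, p) {
  hi <- hypergeometric_h(g, p, details = TRUE)
  structure(
    list(
      partition = p,
      num_clusters = max(p),
      Q = modularity_q(g, p),
      H = hi$H,
      h_inputs = hi[c("F", "n_obs", "M", "p_intra")]
    ),
    class = "partition_score"
  )
}

#' @export
print.partition_score <- function(x, ...) {
  cat(sprintf("partition of %d nodes into %d clusters: Q = %.6f, H = %.6f\n",
              length(x$partition), x$num_clusters, x$Q, x$H))
  invisible(x)
}

#' Optimal partitions of a dendrogram
#'
#' Scores every partition produced by [scan_partitions()] with both
#' modularity Q and the hypergeometric index H and returns the best
#' partition under each index.  Ties are resolved in favor of the fewest
#' clusters (equivalently, the first encountered in the root-to-leaf scan).
#'
#' @param t A rooted binary dendrogram over `g$nodes`.
#' @param g A `netgraph` with at least one edge.
#' @return A list with elements `best_q` and `best_h` (class
#'   `partition_score`) and `table`, a data frame of `num_clusters`, `Q`,
#'   `H` for every scanned partition.
#' @export
best_partitions <- function(t, g) {
  parts <- scan_partitions(t, g)
  scores <- lapply(parts, function(p) score_partition(g, p))
  qs <- vapply(scores, `[[`, numeric(1), "Q")
  hs <- vapply(scores, `[[`, numeric(1), "H")
  list(
    best_q = scores[[which.max(qs)]],
    best_h = scores[[which.max(hs)]],
    table = data.frame(
      num_clusters = vapply(scores, `[[`, numeric(1), "num_clusters"),
      Q = qs,
      H = hs
    )
  )
}
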