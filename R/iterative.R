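#' @useDynLib netdendro, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Node partitions
#'
#' A partition assigns every node of the graph to exactly one cluster.  It
#' is represented as a named integer vector (node -> block index, blocks
#' numbered from 1 in order of creation).
#'
#' @param assignment Named integer vector mapping every node to a block
#'   index; block indices must be `1..max` with no gaps.
#' @return An object of class `node_partition`.
#' @export
new_partition <- function(assignment) {
  assignment <- as.integer(assignment) |> stats::setNames(names(assignment))
  if (is.null(names(assignment)) || anyDuplicated(names(assignment))) {
    stop("assignment must be named with unique node labels")
  }
  if (anyNA(assignment) || any(assignment < 1L)) {
    stop("block indices must be positive integers")
  }
  ids <- sort(unique(assignment))
  if (!identical(ids, seq_along(ids))) {
    stop("block indices must be consecutive from 1")
  }
  structure(assignment, class = "node_partition")
}

#' @export
print.node_partition <- function(x, ...) {
  cat("partition of", length(x), "nodes into", max(x), "blocks\n")
  invisible(x)
}

#' Blocks of a partition
#'
#' @param p A `node_partition`.
#' @return List of character vectors, one per block.
#' @export
partition_blocks <- function(p) {
  unname(split(names(p), unclass(p)))
}

iter_alg_code <- function(algorithm) {
  match(match.arg(algorithm, c("uv", "r", "s")), c("uv", "r", "s"))
}

#' Single clustering iteration
#'
#' Runs one randomized partition of the graph.  `uvcluster_iteration` grows
#' greedy maximal cliques from a shuffled node list; `rcluster_iteration`
#' randomly merges blocks whose union is a clique (switching to an explicit
#' mergeability matrix after `num_nodes` consecutive failed picks);
#' `scluster_iteration` collapses a random seed with all its still-available
#' neighbors (star clusters, not necessarily cliques).  Randomness is drawn
#' from R's global RNG stream, so results are reproducible via [set.seed()].
#'
#' @param g A `netgraph`.
#' @return A `node_partition` covering all nodes of `g`.
#' @export
uvcluster_iteration <- function(g) {
  stopifnot(inherits(g, "netgraph"))
  new_partition(stats::setNames(iter_partition_cpp(g$adjacency, 1L), g$nodes))
}

#' @rdname uvcluster_iteration
#' @export
rcluster_iteration <- function(g) {
  stopifnot(inherits(g, "netgraph"))
  new_partition(stats::setNames(iter_partition_cpp(g$adjacency, 2L), g$nodes))
}

#' @rdname uvcluster_iteration
#' @export
scluster_iteration <- function(g) {
  stopifnot(inherits(g, "netgraph"))
  new_partition(stats::setNames(iter_partition_cpp(g$adjacency, 3L), g$nodes))
}

#' Pair-separation counts
#'
#' Accumulator for the number of iterations in which each pair of nodes was
#' clustered separately.
#'
#' @param nodes Character vector of node labels.
#' @return A `pair_counts` object with a zero count matrix and
#'   `iterations_done = 0`.
#' @export
new_pair_counts <- function(nodes) {
  n <- length(nodes)
  structure(
    list(
      counts = matrix(0L, n, n, dimnames = list(nodes, nodes)),
      iterations_done = 0L
    ),
    class = "pair_counts"
  )
}

#' Accumulate one partition into pair-separation counts
#'
#' @param counts A `pair_counts` object.
#' @param p A `node_partition` over the same node set.
#' @return The updated `pair_counts`: every pair in different blocks is
#'   incremented by one and `iterations_done` by one.
#' @export
accumulate <- function(counts, p) {
  stopifnot(inherits(counts, "pair_counts"), inherits(p, "node_partition"))
  nodes <- rownames(counts$counts)
  if (!setequal(nodes, names(p)) || length(p) != length(nodes)) {
    stop("partition does not cover the accumulator's node set")
  }
  a <- unclass(p)[nodes]
  sep <- outer(a, a, "!=")
  counts$counts <- counts$counts + (sep * 1L)
  counts$iterations_done <- counts$iterations_done + 1L
  counts
}

#' Secondary-distance matrix
#'
#' Runs the chosen iterative algorithm `iterations` times and returns, for
#' each pair of nodes, the fraction of iterations in which the pair was
#' clustered separately.  Pairs that are always co-clustered get distance 0;
#' pairs in different connected components get distance 1 under the
#' clique-based algorithms.  Deterministic given the state of R's RNG.
#'
#' @param g A `netgraph`.
#' @param algorithm One of `"uv"`, `"r"`, `"s"`.
#' @param iterations Positive number of iterations; the default is 10 times
#'   the number of nodes.
#' @return A symmetric numeric matrix of distances in `[0, 1]` with zero
#'   diagonal, carrying attributes `iterations` and `algorithm`.
#' @export
#' @examples
#' g <- new_netgraph(letters[1:3], cbind(c("a", "b"), c("b", "c")))
#' set.seed(1)
#' d <- secondary_distances(g, "s", 1000)
secondary_distances <- function(g, algorithm = c("uv", "r", "s"),
                                iterations = 10L * g$num_nodes) {
  stopifnot(inherits(g, "netgraph"))
  code <- iter_alg_code(algorithm)
  iterations <- as.integer(iterations)
  if (length(iterations) != 1L || is.na(iterations) || iterations < 1L) {
    stop("iterations must be a positive integer")
  }
  same <- cocluster_counts_cpp(g$adjacency, code, iterations)
  sep <- iterations - same
  diag(sep) <- 0L
  d <- sep / iterations
  dimnames(d) <- list(g$nodes, g$nodes)
  attr(d, "iterations") <- iterations
  attr(d, "algorithm") <- c("uv", "r", "s")[code]
  d
}

#' Secondary distances from explicit pair counts
#'
#' @param counts A `pair_counts` with at least one accumulated iteration.
#' @return The secondary-distance matrix `counts / iterations_done`.
#' @export
pair_counts_to_distances <- function(counts) {
  stopifnot(inherits(counts, "pair_counts"))
  if (counts$iterations_done < 1L) stop("no iterations accumulated")
  d <- counts$counts / counts$iterations_done
  attr(d, "iterations") <- counts$iterations_done
  d
}
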