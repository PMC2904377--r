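# Independent oracles and small fixtures used across the test files.
# Everything here is deliberately naive (enumeration, brute force) and
# shares no code with the package internals it checks.

graph_from_text <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  on.exit(unlink(f))
  read_edge_list(f)
}

# simple Erdos-Renyi graph as a netgraph (nodes kept even if isolated)
random_gnp_graph <- function(n, p) {
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(pairs)) < p
  new_netgraph(nodes, cbind(nodes[pairs[keep, 1]], nodes[pairs[keep, 2]]))
}

all_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_permutations(v[-i])) {
      out[[length(out) + 1L]] <- c(v[i], rest)
    }
  }
  out
}

# reference greedy-clique partition for a FIXED node order: first unassigned
# node seeds a block, later unassigned nodes in order join iff adjacent to
# every member
uv_partition_given_order <- function(g, ord) {
  assign <- stats::setNames(rep(0L, g$num_nodes), g$nodes)
  block <- 0L
  A <- g$adjacency
  for (k in seq_along(ord)) {
    seed <- ord[k]
    if (assign[seed] > 0L) next
    block <- block + 1L
    assign[seed] <- block
    members <- seed
    for (t in seq_along(ord)[-seq_len(k)]) {
      u <- ord[t]
      if (assign[u] > 0L) next
      if (all(A[u, members] == 1L)) {
        assign[u] <- block
        members <- c(members, u)
      }
    }
  }
  assign
}

# exact expected pair-separation probabilities for the greedy-clique
# algorithm, by enumerating every node ordering
uv_exact_separation <- function(g) {
  n <- g$num_nodes
  sep <- matrix(0, n, n, dimnames = list(g$nodes, g$nodes))
  perms <- all_permutations(g$nodes)
  for (ord in perms) {
    a <- uv_partition_given_order(g, ord)[g$nodes]
    sep <- sep + outer(a, a, "!=")
  }
  sep / length(perms)
}

# exact expected pair-separation probabilities for star collapse, by
# recursing over every sequence of uniformly chosen seeds
s_exact_separation <- function(g) {
  n <- g$num_nodes
  sep <- matrix(0, n, n, dimnames = list(g$nodes, g$nodes))
  A <- g$adjacency
  rec <- function(remaining, assign, block, prob) {
    if (length(remaining) == 0L) {
      a <- assign[g$nodes]
      sep <<- sep + prob * outer(a, a, "!=")
      return(invisible(NULL))
    }
    for (seed in remaining) {
      members <- c(seed, remaining[A[remaining, seed] == 1L])
      a2 <- assign
      a2[members] <- block
      rec(setdiff(remaining, members), a2, block + 1L,
          prob / length(remaining))
    }
  }
  rec(g$nodes, stats::setNames(rep(0L, n), g$nodes), 1L, 1)
  sep
}

binom_se <- function(p, n) sqrt(pmax(p * (1 - p), 0) / n)

# blocks of uv/r partitions must be cliques; blocks of s partitions must be
# stars (some member adjacent to all others)
is_clique <- function(g, members) {
  length(members) == 1L ||
    all(adjacency_submatrix(g, members)[upper.tri(diag(length(members)))] == 1L)
}

is_star <- function(g, members) {
  if (length(members) == 1L) return(TRUE)
  any(vapply(members, function(ctr) {
    all(g$adjacency[ctr, setdiff(members, ctr)] == 1L)
  }, logical(1)))
}

# brute-force minimum reassignment distance between two partitions: try
# every injective matching of the smaller side's clusters into the larger
# side's and count the best overlap
misclassified_oracle <- function(p1, p2) {
  nodes <- names(p1)
  a <- unclass(p1)[nodes]
  b <- unclass(p2)[nodes]
  tab <- unclass(table(a, b))
  if (nrow(tab) > ncol(tab)) tab <- t(tab)
  best <- 0
  for (perm in all_permutations(seq_len(ncol(tab)))) {
    sel <- perm[seq_len(nrow(tab))]
    best <- max(best, sum(tab[cbind(seq_len(nrow(tab)), sel)]))
  }
  length(nodes) - best
}

# exact rational upper-tail hypergeometric probabilities, precomputed with
# arbitrary-precision integer arithmetic (sum of C(M,x) C(F-M,n-x) / C(F,n)
# over x = p..min(n,M)) and frozen here
exact_hyper_tail_cases <- list(
  list(F = 15, M = 6, n = 6, p = 6, P = 1.99800199800199800e-04),
  list(F = 15, M = 6, n = 6, p = 4, P = 1.18881118881118880e-01),
  list(F = 21, M = 9, n = 10, p = 7, P = 2.41724220052393426e-02),
  list(F = 45, M = 12, n = 20, p = 9, P = 1.55097160202094971e-02),
  list(F = 190, M = 45, n = 60, p = 25, P = 1.12844857975561235e-04),
  list(F = 190, M = 45, n = 60, p = 14, P = 5.98403822700041110e-01),
  list(F = 190, M = 100, n = 30, p = 28, P = 2.73449751784259547e-07),
  list(F = 200, M = 10, n = 100, p = 10, P = 7.71026062717850296e-04),
  list(F = 66, M = 15, n = 33, p = 15, P = 3.86469767377461836e-06),
  list(F = 105, M = 52, n = 40, p = 30, P = 3.88959412781492961e-05)
)

# log10 of the upper-tail probability as the package computes it internally
pkg_log10_tail <- function(F, M, n, p) {
  stats::phyper(p - 1, M, F - M, n, lower.tail = FALSE, log.p = TRUE) / log(10)
}

# tree utilities ------------------------------------------------------------

root_to_leaf_depths <- function(t) {
  d <- ape::node.depth.edgelength(t)
  d[seq_len(ape::Ntip(t))]
}

is_ultrametric_tree <- function(t, tol = 1e-9) {
  d <- root_to_leaf_depths(t)
  max(d) - min(d) <= tol
}

# canonical set-of-leaf-sets comparison of partitions
same_partition <- function(p1, p2) {
  b1 <- lapply(partition_blocks(p1), sort)
  b2 <- lapply(partition_blocks(p2), sort)
  setequal(b1, b2)
}
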