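bridge_graph <- graph_from_text(c("a b", "b c", "a c", "d e", "e f", "d f",
                                  "c d"))

test_that("root-to-leaf scan produces the nested partition sequence", {
  g2 <- graph_from_text("A B")
  t2 <- upgma(matrix(c(0, 1, 1, 0), 2, dimnames = list(c("A", "B"),
                                                       c("A", "B"))))
  parts <- scan_partitions(t2, g2)
  expect_length(parts, 2)
  expect_equal(max(parts[[1]]), 1)
  expect_equal(max(parts[[2]]), 2)

  g3 <- graph_from_text(c("A B", "B C"))
  t3 <- ape::read.tree(text = "((A:0.1,B:0.1):0.2,C:0.3);")
  parts3 <- scan_partitions(t3, g3)
  expect_length(parts3, 3)
  expect_true(same_partition(parts3[[2]],
                             new_partition(c(A = 1L, B = 1L, C = 2L))))
  expect_true(same_partition(parts3[[3]],
                             new_partition(c(A = 1L, B = 2L, C = 3L))))

  # balanced quartet with tied internal heights: both tie orders give the
  # same first and last partitions and one partition per cluster count
  g4 <- graph_from_text(c("A B", "C D", "B C"))
  for (txt in c("((A:1,B:1):1,(C:1,D:1):1);",
                "((C:1,D:1):1,(A:1,B:1):1);")) {
    t4 <- ape::read.tree(text = txt)
    p4 <- scan_partitions(t4, g4)
    expect_length(p4, 4)
    expect_equal(vapply(p4, max, integer(1)), 1:4)
    expect_true(same_partition(p4[[1]],
                               new_partition(c(A = 1L, B = 1L, C = 1L, D = 1L))))
    expect_true(same_partition(p4[[2]],
                               new_partition(c(A = 1L, B = 1L, C = 2L, D = 2L))))
    expect_true(same_partition(p4[[4]],
                               new_partition(c(A = 1L, B = 2L, C = 3L, D = 4L))))
  }
  # nestedness: each partition refines the previous one
  refines <- function(fine, coarse) {
    all(tapply(unclass(coarse)[names(fine)], unclass(fine), function(v) {
      length(unique(v)) == 1
    }))
  }
  for (k in 2:4) expect_true(refines(p4[[k]], p4[[k - 1]]))

  expect_error(scan_partitions(t3, g4), "match")
})

test_that("modularity matches the Newman-Girvan formula and igraph", {
  one <- new_partition(stats::setNames(rep(1L, 6), bridge_graph$nodes))
  expect_equal(modularity_q(bridge_graph, one), 0)

  halves <- new_partition(stats::setNames(rep(1:2, each = 3),
                                          bridge_graph$nodes))
  expect_equal(modularity_q(bridge_graph, halves), 5 / 14)

  singl <- new_partition(stats::setNames(1:6, bridge_graph$nodes))
  deg <- rowSums(bridge_graph$adjacency)
  expect_equal(modularity_q(bridge_graph, singl), -sum((deg / 14)^2))
  expect_lt(modularity_q(bridge_graph, singl), 0)

  lonely <- new_netgraph(c("u", "v"), matrix(character(0), 0, 2))
  expect_error(modularity_q(lonely, new_partition(c(u = 1L, v = 2L))),
               "edgeless")

  # independent oracle on random graphs and random partitions
  set.seed(14)
  for (rep in 1:6) {
    g <- random_gnp_graph(10, 0.4)
    if (g$num_edges == 0) next
    a <- sample(1:3, 10, replace = TRUE)
    a <- match(a, unique(a))
    p <- new_partition(stats::setNames(a, g$nodes))
    ig <- igraph::graph_from_adjacency_matrix(g$adjacency, "undirected")
    expect_equal(modularity_q(g, p),
                 igraph::modularity(ig, unclass(p)[g$nodes]))
  }
})

test_that("H is the -log10 upper-tail hypergeometric and is 0 at the trivial ends", {
  g <- make_caveman(2, 3)$graph
  planted <- make_caveman(2, 3)$planted
  one <- new_partition(stats::setNames(rep(1L, 6), g$nodes))
  singl <- new_partition(stats::setNames(1:6, g$nodes))
  expect_equal(hypergeometric_h(g, one), 0)
  expect_equal(hypergeometric_h(g, singl), 0)

  # P = 1/C(15,6) = 1/5005 for the planted two-triangle split
  h <- hypergeometric_h(g, planted, details = TRUE)
  expect_equal(h$F, 15)
  expect_equal(h$n_obs, 6)
  expect_equal(h$M, 6)
  expect_equal(h$p_intra, 6)
  expect_equal(h$H, -log10(1 / 5005), tolerance = 1e-12)
})

test_that("log-space tail probabilities match exact rational values", {
  for (cs in exact_hyper_tail_cases) {
    got <- pkg_log10_tail(cs$F, cs$M, cs$n, cs$p)
    expect_equal(10^got, cs$P, tolerance = 1e-10)
  }
})

test_that("best_partitions picks the argmax of each index with fewest-cluster ties", {
  pg <- make_caveman(2, 3)
  set.seed(2)
  d <- secondary_distances(pg$graph, "uv", 200)
  for (tr in list(upgma(d), midpoint_root(neighbor_joining(d)))) {
    bp <- best_partitions(tr, pg$graph)
    expect_equal(bp$best_q$num_clusters, 2)
    expect_equal(bp$best_h$num_clusters, 2)
    expect_true(same_partition(bp$best_q$partition, pg$planted))
    expect_equal(bp$best_q$Q, 0.5)
    expect_equal(bp$best_h$H, -log10(1 / 5005), tolerance = 1e-12)
    expect_equal(nrow(bp$table), 6)
  }

  # single edge: Q best at 1 cluster (0 vs negative); H ties at 0 and the
  # fewest-clusters rule keeps 1 cluster
  g1 <- graph_from_text("A B")
  t1 <- upgma(matrix(c(0, 1, 1, 0), 2,
                     dimnames = list(c("A", "B"), c("A", "B"))))
  bp1 <- best_partitions(t1, g1)
  expect_equal(bp1$best_q$num_clusters, 1)
  expect_equal(bp1$best_q$Q, 0)
  expect_equal(bp1$best_h$num_clusters, 1)
  expect_equal(bp1$best_h$H, 0)

  # complete graph: any split lowers Q and cannot raise H above 0
  k4 <- new_netgraph(LETTERS[1:4], t(utils::combn(LETTERS[1:4], 2)))
  set.seed(4)
  bp4 <- best_partitions(upgma(secondary_distances(k4, "s", 100)), k4)
  expect_equal(bp4$best_q$num_clusters, 1)
  expect_equal(bp4$best_h$num_clusters, 1)
})
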