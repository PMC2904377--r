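k5 <- new_netgraph(LETTERS[1:5],
                   t(utils::combn(LETTERS[1:5], 2)))
two_triangles <- make_caveman(2, 3)$graph
path3 <- graph_from_text(c("a b", "b c"))

test_that("single iterations honor the block-structure contracts", {
  set.seed(1)
  for (i in 1:20) {
    # complete graph: always one block, whatever the shuffle
    expect_equal(max(uvcluster_iteration(k5)), 1)
    expect_equal(max(rcluster_iteration(k5)), 1)
    # two disjoint triangles: clique algorithms find exactly the triangles
    for (p in list(uvcluster_iteration(two_triangles),
                   rcluster_iteration(two_triangles))) {
      expect_true(same_partition(p, make_caveman(2, 3)$planted))
    }
  }
  # star graph seeded anywhere: scluster blocks are stars
  star <- graph_from_text(paste("hub", c("l1", "l2", "l3", "l4")))
  for (i in 1:10) {
    p <- scluster_iteration(star)
    expect_true(all(vapply(partition_blocks(p),
                           function(b) is_star(star, b), logical(1))))
  }
  # edgeless graph: all singletons under every algorithm
  lonely <- new_netgraph(c("u", "v", "w"), matrix(character(0), 0, 2))
  expect_equal(max(rcluster_iteration(lonely)), 3)
  expect_equal(max(scluster_iteration(lonely)), 3)
  expect_equal(max(uvcluster_iteration(lonely)), 3)
})

test_that("every iteration yields a valid partition with the right block type", {
  set.seed(42)
  for (rep in 1:8) {
    g <- random_gnp_graph(10, stats::runif(1, 0.2, 0.7))
    for (alg in c("uv", "r", "s")) {
      p <- switch(alg,
                  uv = uvcluster_iteration(g),
                  r = rcluster_iteration(g),
                  s = scluster_iteration(g))
      expect_setequal(names(p), g$nodes)
      blocks <- partition_blocks(p)
      expect_equal(sum(lengths(blocks)), g$num_nodes)
      expect_false(anyDuplicated(unlist(blocks)) > 0)
      check <- if (alg == "s") is_star else is_clique
      expect_true(all(vapply(blocks, function(b) check(g, b), logical(1))))
    }
  }
})

test_that("rcluster terminates only when no two blocks are mergeable", {
  set.seed(77)
  for (rep in 1:10) {
    g <- random_gnp_graph(9, stats::runif(1, 0.2, 0.8))
    blocks <- partition_blocks(rcluster_iteration(g))
    nb <- length(blocks)
    if (nb < 2) next
    for (i in seq_len(nb - 1)) {
      for (j in (i + 1):nb) {
        expect_false(is_clique(g, c(blocks[[i]], blocks[[j]])))
      }
    }
  }
})

test_that("accumulate counts pair separations", {
  cts <- new_pair_counts(c("a", "b", "c"))
  p <- new_partition(c(a = 1L, b = 1L, c = 2L))
  cts <- accumulate(cts, p)
  expect_equal(cts$iterations_done, 1)
  expect_equal(cts$counts["a", "b"], 0)
  expect_equal(cts$counts["a", "c"], 1)
  expect_equal(cts$counts["b", "c"], 1)

  cts <- accumulate(cts, new_partition(c(a = 1L, b = 2L, c = 3L)))
  expect_true(all(cts$counts[upper.tri(cts$counts)] >= 1))
  cts <- accumulate(cts, new_partition(c(a = 1L, b = 1L, c = 1L)))
  expect_equal(cts$iterations_done, 3)
  expect_equal(cts$counts["a", "c"], 2)

  expect_error(accumulate(cts, new_partition(c(x = 1L, y = 2L, z = 2L))),
               "node set")
  d <- pair_counts_to_distances(cts)
  expect_equal(d["a", "c"], 2 / 3)
})

test_that("secondary distances: exact cases, range, and determinism", {
  set.seed(3)
  expect_true(all(secondary_distances(k5, "uv", 50) == 0))
  expect_true(all(secondary_distances(k5, "r", 50) == 0))
  for (alg in c("uv", "r")) {
    d <- secondary_distances(two_triangles, alg, 100)
    a <- unclass(make_caveman(2, 3)$planted)[rownames(d)]
    expect_true(all(d[outer(a, a, "==")] == 0))
    expect_true(all(d[outer(a, a, "!=")] == 1))
  }
  d <- secondary_distances(path3, "s", 2000)
  expect_true(all(d >= 0 & d <= 1))

  set.seed(99)
  d1 <- secondary_distances(path3, "uv", 200)
  set.seed(99)
  d2 <- secondary_distances(path3, "uv", 200)
  expect_identical(d1, d2)
  expect_error(secondary_distances(path3, "uv", 0), "positive")
})

test_that("bulk accumulation matches composing single iterations", {
  g <- random_gnp_graph(9, 0.4)
  for (alg in c("uv", "r", "s")) {
    it <- switch(alg, uv = uvcluster_iteration, r = rcluster_iteration,
                 s = scluster_iteration)
    set.seed(17)
    d_bulk <- secondary_distances(g, alg, 40)
    set.seed(17)
    cts <- new_pair_counts(g$nodes)
    for (i in 1:40) cts <- accumulate(cts, it(g))
    expect_equal(unname(pair_counts_to_distances(cts)[g$nodes, g$nodes]),
                 unname(d_bulk[g$nodes, g$nodes]))
  }
})

test_that("Monte-Carlo distances match enumeration oracles on the 3-path", {
  # exhaustive enumeration: greedy clique growth keeps {a,b} together for
  # the orderings (a,b,c), (a,c,b), (b,a,c) and {b,c} for the other three,
  # so P(sep): uv = (1/2, 1/2, 1); star collapse seeded at a/b/c gives
  # s = (1/3, 1/3, 2/3) for (ab, bc, ac)
  uv_exp <- uv_exact_separation(path3)
  expect_equal(uv_exp["a", "b"], 1 / 2)
  expect_equal(uv_exp["b", "c"], 1 / 2)
  expect_equal(uv_exp["a", "c"], 1)
  s_exp <- s_exact_separation(path3)
  expect_equal(s_exp["a", "b"], 1 / 3)
  expect_equal(s_exp["b", "c"], 1 / 3)
  expect_equal(s_exp["a", "c"], 2 / 3)

  set.seed(8)
  iters <- 20000
  for (alg in c("uv", "s")) {
    d <- secondary_distances(path3, alg, iters)
    ex <- if (alg == "uv") uv_exp else s_exp
    se <- binom_se(ex, iters)
    expect_true(all(abs(d - ex) <= 4 * se + 1e-12))
  }
})
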