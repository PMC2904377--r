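iter_names <- c(uv = "UVCluster", r = "RCluster", s = "SCluster")
tree_names <- c(u = "Upgma", nj = "Nj")

#' Run the full analysis suite
#'
#' Orchestrates the whole pipeline: for each selected iterative algorithm a
#' secondary-distance matrix is accumulated; for each (iterative, tree)
#' pair a dendrogram is built (NJ trees are midpoint rooted); and for each
#' (iterative, tree, index) triple the optimal partition is extracted.
#' With `iterative = "all"` and `tree = "all"` this yields 3 matrices, 6
#' trees and 12 partition analyses.  When `output_dir` is given, the
#' standard output files are written: one `.nwk` per tree and one `.meg`,
#' `.att` and `.txt` per partition analysis, plus a run log.
#'
#' @param input A `netgraph`, or the path of an edge-list file.
#' @param iterative `"uv"`, `"r"`, `"s"` or `"all"`.
#' @param tree `"u"`, `"nj"` or `"all"`.
#' @param iterations Positive iteration count (default: 10 x nodes).
#' @param seed Optional integer seed; if `NULL` one is drawn from R's RNG
#'   and logged, so every run is reproducible after the fact.
#' @param output_dir Directory for output files, or `NULL` to skip writing.
#' @param basename Stem used for output file names (default: the input file
#'   name without extension, or `"network"` for in-memory graphs).
#' @return A `suite_result`: list with `distances` (per iterative
#'   algorithm), `trees` (per iterative x tree), `results` (per iterative x
#'   tree x index, each a `partition_score`), `files`, `seed`,
#'   `iterations`, `runtime`.
#' @export
#' @examples
#' pg <- make_caveman(2, 4)
#' res <- run_suite(pg$graph, "s", "u", iterations = 200, seed = 1)
#' res$results[["s_u_Q"]]$num_clusters
run_suite <- function(input, iterative = c("uv", "r", "s", "all"),
                      tree = c("u", "nj", "all"),
                      iterations = NULL, seed = NULL, output_dir = NULL,
                      basename = NULL) {
  iterative <- match.arg(iterative)
  tree <- match.arg(tree)
  if (inherits(input, "netgraph")) {
    g <- input
    if (is.null(basename)) basename <- "network"
  } else {
    g <- read_edge_list(input)
    if (is.null(basename)) {
      basename <- sub("\\.[^.]*$", "", base::basename(input))
    }
  }
  if (is.null(iterations)) iterations <- 10L * g$num_nodes
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 1L) {
    stop("iterations must be a positive integer")
  }
  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max, 1L)
  }
  set.seed(seed)

  iter_algs <- if (iterative == "all") c("uv", "r", "s") else iterative
  tree_algs <- if (tree == "all") c("u", "nj") else tree

  distances <- list()
  trees <- list()
  results <- list()
  runtime <- list()
  for (ia in iter_algs) {
    t0 <- proc.time()[["elapsed"]]
    distances[[ia]] <- secondary_distances(g, ia, iterations)
    runtime[[ia]] <- proc.time()[["elapsed"]] - t0
    for (ta in tree_algs) {
      tr <- if (ta == "u") {
        upgma(distances[[ia]])
      } else {
        midpoint_root(neighbor_joining(distances[[ia]]))
      }
      trees[[paste(ia, ta, sep = "_")]] <- tr
      best <- best_partitions(tr, g)
      results[[paste(ia, ta, "Q", sep = "_")]] <- best$best_q
      results[[paste(ia, ta, "H", sep = "_")]] <- best$best_h
    }
  }

  files <- character(0)
  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) {
      dir.create(output_dir, recursive = TRUE)
    }
    files <- write_suite_outputs(g, basename, output_dir, distances, trees,
                                 results, seed, iterations, runtime)
  }
  structure(
    list(distances = distances, trees = trees, results = results,
         files = files, seed = seed, iterations = iterations,
         runtime = runtime, graph = g),
    class = "suite_result"
  )
}

write_suite_outputs <- function(g, basename, output_dir, distances, trees,
                                results, seed, iterations, runtime) {
  files <- character(0)
  out <- function(name) file.path(output_dir, name)
  for (key in names(trees)) {
    parts <- strsplit(key, "_")[[1]]
    fn <- out(sprintf("%s_%s_%s.nwk", basename,
                      iter_names[[parts[1]]], tree_names[[parts[2]]]))
    writeLines(write_newick(trees[[key]]), fn)
    files <- c(files, fn)
  }
  for (key in names(results)) {
    parts <- strsplit(key, "_")[[1]]
    stem <- sprintf("%s_partition%s_%s_%s", basename, parts[3],
                    iter_names[[parts[1]]], tree_names[[parts[2]]])
    best <- results[[key]]
    fn_txt <- out(paste0(stem, ".txt"))
    write_partition_txt(best, fn_txt, parts[3])
    fn_att <- out(paste0(stem, ".att"))
    write_att(best, fn_att)
    fn_meg <- out(paste0(stem, ".meg"))
    write_meg(distances[[parts[1]]], best, fn_meg,
              title = sprintf("Secondary distances (%s)",
                              iter_names[[parts[1]]]))
    files <- c(files, fn_txt, fn_att, fn_meg)
  }
  log_fn <- out(paste0(basename, "_run.log"))
  log_lines <- c(
    sprintf("seed: %d", seed),
    sprintf("iterations: %d", iterations),
    sprintf("nodes: %d  edges: %d", g$num_nodes, g$num_edges),
    sprintf("runtime %s: %.2f s", names(runtime),
            unlist(runtime)),
    vapply(names(results), function(key) {
      b <- results[[key]]
      sprintf("optimum %s: %d clusters, Q = %.6f, H = %.6f",
              key, b$num_clusters, b$Q, b$H)
    }, character(1))
  )
  writeLines(log_lines, log_fn)
  c(files, log_fn)
}

#' @export
print.suite_result <- function(x, ...) {
  cat(sprintf("suite run: %d iterations, seed %d\n", x$iterations, x$seed))
  for (key in names(x$results)) {
    b <- x$results[[key]]
    cat(sprintf("  %-8s %3d clusters  Q = %.6f  H = %.6f\n",
                key, b$num_clusters, b$Q, b$H))
  }
  invisible(x)
}

#' Command-line entry point
#'
#' Implements the positional contract
#' `netdendro FILE {uv|r|s|all} {u|nj|all} N [--seed S] [--output-dir D]`:
#' an edge-list file, the iterative algorithm(s), the tree algorithm(s) and
#' the iteration count, with optional seed and output directory (default:
#' the input file's directory).
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status: 0 on success, 2 on a usage error.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste0(
    "usage: netdendro FILE {uv|r|s|all} {u|nj|all} ITERATIONS",
    " [--seed S] [--output-dir D]"
  )
  seed <- NULL
  output_dir <- NULL
  pos <- character(0)
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (a == "--seed") {
      if (i == length(args)) { message(usage); return(2L) }
      seed <- suppressWarnings(as.integer(args[i + 1L]))
      i <- i + 2L
    } else if (a == "--output-dir") {
      if (i == length(args)) { message(usage); return(2L) }
      output_dir <- args[i + 1L]
      i <- i + 2L
    } else {
      pos <- c(pos, a)
      i <- i + 1L
    }
  }
  if (length(pos) != 4L) { message(usage); return(2L) }
  iterations <- suppressWarnings(as.integer(pos[4]))
  ok <- tryCatch({
    if (!pos[2] %in% c("uv", "r", "s", "all")) {
      stop("unknown iterative algorithm: ", pos[2])
    }
    if (!pos[3] %in% c("u", "nj", "all")) {
      stop("unknown tree algorithm: ", pos[3])
    }
    if (is.na(iterations) || iterations < 1L) {
      stop("iterations must be a positive integer")
    }
    if (is.null(output_dir)) output_dir <- dirname(pos[1])
    res <- run_suite(pos[1], pos[2], pos[3], iterations, seed = seed,
                     output_dir = output_dir)
    message(sprintf("wrote %d files to %s (seed %d)",
                    length(res$files), output_dir, res$seed))
    TRUE
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    message(usage)
    FALSE
  })
  if (ok) 0L else 2L
}
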