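# cluster ids renumbered consecutively from 1 in order of first appearance
# over the node order carried by the partition (root-to-leaf order for
# partitions coming out of a dendrogram scan)
renumber_clusters <- function(p) {
  a <- unclass(p)
  stats::setNames(match(a, unique(a)), names(a))
}

fmt6 <- function(x) sprintf("%.6f", x)

#' Write a MEGA 4 distance file
#'
#' Serializes the secondary-distance matrix together with the optimal
#' cluster assignment in the MEGA 4 distance-data dialect: a `#mega` header,
#' `!Title` and `!Format DataType=Distance` statements, one `#label` line
#' per taxon carrying its cluster as a bracketed comment, then the
#' lower-left triangular matrix at 6 decimals.
#'
#' @param d Secondary-distance matrix (row names are the node labels).
#' @param best A `partition_score` over the same nodes.
#' @param path Output file path.
#' @param title Title recorded in the file.
#' @return `path`, invisibly.
#' @export
write_meg <- function(d, best, path, title = "Secondary distances") {
  nodes <- rownames(d)
  p <- best$partition
  if (!setequal(names(p), nodes)) {
    stop("matrix and partition are over different node sets")
  }
  cl <- renumber_clusters(p)[nodes]
  n <- length(nodes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#mega",
    paste0("!Title ", title, ";"),
    sprintf("!Format DataType=Distance DataFormat=LowerLeft NTaxa=%d;", n),
    ""
  ), con)
  writeLines(sprintf("#%s [cluster %d]", nodes, cl), con)
  writeLines("", con)
  for (i in seq_len(n)[-1]) {
    writeLines(paste(fmt6(d[i, seq_len(i - 1)]), collapse = " "), con)
  }
  invisible(path)
}

#' Write a Cytoscape 2.x node-attribute file
#'
#' First line is the attribute name, then one `node = cluster` line per
#' node; cluster ids are consecutive integers from 1.
#'
#' @param best A `partition_score`.
#' @param path Output file path.
#' @param attribute Attribute name (first line of the file).
#' @return `path`, invisibly.
#' @export
write_att <- function(best, path, attribute = "cluster") {
  cl <- renumber_clusters(best$partition)
  writeLines(c(attribute, paste(names(cl), "=", cl)), path)
  invisible(path)
}

#' Write a plain-text partition report
#'
#' Header with the cluster count and the value of the chosen index at 6
#' decimals, followed by one block per cluster listing its members.
#'
#' @param best A `partition_score`.
#' @param path Output file path.
#' @param index Which index value to report, `"Q"` or `"H"`.
#' @return `path`, invisibly.
#' @export
write_partition_txt <- function(best, path, index = c("Q", "H")) {
  index <- match.arg(index)
  cl <- renumber_clusters(best$partition)
  nc <- max(cl)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("Number of clusters: %d", nc),
    sprintf("%s = %s", index, fmt6(best[[index]])),
    ""
  ), con)
  for (k in seq_len(nc)) {
    writeLines(sprintf("Cluster %d: %s", k,
                       paste(names(cl)[cl == k], collapse = " ")), con)
  }
  invisible(path)
}

# helper used by tests and examples: parse a lower-left MEGA distance file
# back into a matrix
read_meg <- function(path) {
  lines <- readLines(path)
  lab_lines <- grep("^#[^m]", lines, value = TRUE)
  labs <- sub("^#(\\S+).*$", "\\1", lab_lines)
  n <- length(labs)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  rows <- lines[grep("^[0-9]", lines)]
  for (i in seq_len(n)[-1]) {
    vals <- as.numeric(strsplit(rows[i - 1], " +")[[1]])
    d[i, seq_len(i - 1)] <- vals
    d[seq_len(i - 1), i] <- vals
  }
  d
}
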