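fmt_bl <- function(x) sprintf("%.12g", x)

quote_label <- function(lab) {
  bad <- grepl("[](),:;'\\[[:space:]]", lab)
  lab[bad] <- paste0("'", gsub("'", "''", lab[bad]), "'")
  lab
}

check_dist_matrix <- function(d, min_leaves = 2L) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (nrow(d) < min_leaves) {
    stop("need at least ", min_leaves, " leaves")
  }
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  }
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have zero diagonal")
  d
}

# lowest (row, col) pair with row < col among positions where `m` attains its
# minimum over the upper triangle; ties broken by row then column so runs are
# reproducible
min_pair <- function(m) {
  m2 <- m
  m2[lower.tri(m2, diag = TRUE)] <- Inf
  hit <- which(m2 == min(m2), arr.ind = TRUE)
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
  hit[1, ]
}

#' UPGMA dendrogram from a distance matrix
#'
#' Classical size-weighted average-linkage agglomeration: the pair of
#' clusters at minimal average distance is joined at height equal to half
#' that distance, and distances to the merged cluster are size-weighted
#' averages.  The result is ultrametric.  Ties in the minimum search are
#' broken by the lowest index pair in the current matrix order.
#'
#' @param d Symmetric distance matrix with zero diagonal (typically a
#'   secondary-distance matrix); row names are the leaf labels.
#' @return A rooted ultrametric tree of class [ape::phylo].
#' @export
#' @examples
#' d <- matrix(c(0, .2, .6, .2, 0, .6, .6, .6, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' tr <- upgma(d)
upgma <- function(d) {
  d <- check_dist_matrix(d, 2L)
  n <- nrow(d)
  nwk <- quote_label(rownames(d))
  height <- rep(0, n)
  size <- rep(1L, n)
  D <- d
  while (length(nwk) > 1L) {
    ij <- min_pair(D)
    i <- ij[1]; j <- ij[2]
    h <- D[i, j] / 2
    nwk_new <- paste0("(", nwk[i], ":", fmt_bl(h - height[i]), ",",
                      nwk[j], ":", fmt_bl(h - height[j]), ")")
    drow <- (size[i] * D[i, ] + size[j] * D[j, ]) / (size[i] + size[j])
    D[i, ] <- drow
    D[, i] <- drow
    D[i, i] <- 0
    keep <- setdiff(seq_along(nwk), j)
    D <- D[keep, keep, drop = FALSE]
    nwk[i] <- nwk_new
    height[i] <- h
    size[i] <- size[i] + size[j]
    nwk <- nwk[keep]; height <- height[keep]; size <- size[keep]
  }
  ape::read.tree(text = paste0(nwk, ";"))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei neighbor joining: the pair minimizing the
#' Q-criterion is joined, branch lengths follow the standard formulas
#' (negative lengths clamped to zero), and the matrix is reduced until three
#' clusters remain, which are attached to a central node.  The returned tree
#' is unrooted (see [midpoint_root()]).  Ties in the minimum search are
#' broken by the lowest index pair in the current matrix order.
#'
#' @param d Symmetric distance matrix with zero diagonal; at least two
#'   leaves (with two, the single distance is split equally).
#' @return An unrooted tree of class [ape::phylo] with branch lengths.
#' @export
neighbor_joining <- function(d) {
  d <- check_dist_matrix(d, 2L)
  n <- nrow(d)
  labs <- quote_label(rownames(d))
  if (n == 2L) {
    txt <- paste0("(", labs[1], ":", fmt_bl(d[1, 2] / 2), ",",
                  labs[2], ":", fmt_bl(d[1, 2] / 2), ");")
    return(ape::read.tree(text = txt))
  }
  nwk <- labs
  D <- d
  while (length(nwk) > 3L) {
    m <- length(nwk)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    ij <- min_pair(Q)
    i <- ij[1]; j <- ij[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    li <- max(li, 0); lj <- max(lj, 0)
    nwk_new <- paste0("(", nwk[i], ":", fmt_bl(li), ",",
                      nwk[j], ":", fmt_bl(lj), ")")
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    D[i, ] <- dnew
    D[, i] <- dnew
    D[i, i] <- 0
    keep <- setdiff(seq_len(m), j)
    D <- D[keep, keep, drop = FALSE]
    nwk[i] <- nwk_new
    nwk <- nwk[keep]
  }
  # attach the last three clusters to a central node (three-point formulas)
  l1 <- max((D[1, 2] + D[1, 3] - D[2, 3]) / 2, 0)
  l2 <- max((D[1, 2] + D[2, 3] - D[1, 3]) / 2, 0)
  l3 <- max((D[1, 3] + D[2, 3] - D[1, 2]) / 2, 0)
  txt <- paste0("(", nwk[1], ":", fmt_bl(l1), ",", nwk[2], ":", fmt_bl(l2),
                ",", nwk[3], ":", fmt_bl(l3), ");")
  ape::read.tree(text = txt)
}

#' Midpoint rooting
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path of an
#' unrooted tree with branch lengths, yielding a rooted binary tree whose
#' two root children subtend that path.  A tree whose branch lengths are all
#' zero is rooted on an arbitrary edge with a warning.
#'
#' @param t An unrooted tree of class [ape::phylo] with branch lengths.
#' @return A rooted tree of class [ape::phylo].
#' @export
midpoint_root <- function(t) {
  stopifnot(inherits(t, "phylo"))
  if (is.null(t$edge.length)) stop("tree must have branch lengths")
  if (ape::Ntip(t) == 2L) {
    return(t)  # two-leaf trees are already rooted at their midpoint
  }
  if (all(t$edge.length == 0)) {
    warning("all branch lengths are zero; root placed on an arbitrary edge")
    return(ape::root(t, outgroup = t$tip.label[1], resolve.root = TRUE))
  }
  phangorn::midpoint(t)
}

#' Serialize a tree to Newick
#'
#' Writes a standard Newick string with branch lengths and a terminating
#' semicolon; labels containing Newick metacharacters are single-quoted.
#'
#' @param t A tree of class [ape::phylo].
#' @return A single Newick string.
#' @export
write_newick <- function(t) {
  stopifnot(inherits(t, "phylo"))
  nt <- ape::Ntip(t)
  root <- nt + 1L
  kids <- split(seq_len(nrow(t$edge)), t$edge[, 1])
  rec <- function(node) {
    ed <- kids[[as.character(node)]]
    if (is.null(ed)) {
      return(quote_label(t$tip.label[node]))
    }
    parts <- vapply(ed, function(e) {
      sub <- rec(t$edge[e, 2])
      if (!is.null(t$edge.length)) {
        paste0(sub, ":", fmt_bl(t$edge.length[e]))
      } else {
        sub
      }
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(rec(root), ";")
}
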