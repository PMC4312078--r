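# Neighbour joining (Saitou & Nei) with explicit tie-breaking and
# negative-branch clamping, returning an unrooted ape::phylo.

#' Build a neighbour-joining tree from a distance matrix
#'
#' Standard agglomerative neighbour joining: at each step the pair
#' minimizing `Q[i,j] = (n-2) d[i,j] - r[i] - r[j]` is joined. Ties in `Q`
#' are broken toward the lowest (row, column) index pair so results are
#' deterministic. Negative branch lengths (which arise on non-additive
#' input) are clamped to zero with the deficit transferred to the sister
#' branch, preserving the path length between the joined pair. On an
#' additive matrix the generating tree's topology and branch lengths are
#' recovered exactly.
#'
#' @param dm Symmetric numeric matrix of distances with taxon names as
#'   dimnames (or a `dist`). At least 3 taxa.
#' @param outgroup Optional leaf name; when given, the returned tree is
#'   rooted on that leaf, otherwise it is unrooted.
#' @return An `ape::phylo`.
#' @examples
#' d <- matrix(c(0, 3, 5, 6, 3, 0, 6, 7, 5, 6, 0, 7, 6, 7, 7, 0), 4, 4,
#'             dimnames = list(LETTERS[1:4], LETTERS[1:4]))
#' build_nj_tree(d)
#' @export
build_nj_tree <- function(dm, outgroup = NULL) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  n <- nrow(dm)
  if (n < 3) stop("neighbour joining needs at least 3 taxa", call. = FALSE)
  if (is.null(rownames(dm))) {
    rownames(dm) <- colnames(dm) <- sprintf("t%d", seq_len(n))
  }
  if (max(abs(dm - t(dm))) > 1e-8 || any(dm < 0) || any(diag(dm) != 0)) {
    stop("dm must be a symmetric non-negative distance matrix with zero ",
         "diagonal", call. = FALSE)
  }
  labels <- rownames(dm)
  # each active node is represented by its Newick subtree string
  sub <- as.list(labels)
  d <- dm
  eps <- 1e-12
  fmt <- function(x) sprintf("%.12g", max(x, 0))
  while (nrow(d) > 3) {
    m <- nrow(d)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    qmin <- min(q)
    # lowest (row, column) pair among ties
    best <- NULL
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        if (q[i, j] <= qmin + eps) {
          best <- c(i, j)
          break
        }
      }
      if (!is.null(best)) break
    }
    i <- best[1]
    j <- best[2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    if (li < 0) {
      lj <- lj + li
      li <- 0
    }
    if (lj < 0) {
      li <- li + lj
      lj <- 0
    }
    new_sub <- paste0("(", sub[[i]], ":", fmt(li), ",",
                      sub[[j]], ":", fmt(lj), ")")
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    sub <- c(sub[keep], new_sub)
    d <- d2
  }
  # terminal 3-node star
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  txt <- paste0("(", sub[[1]], ":", fmt(la), ",", sub[[2]], ":", fmt(lb),
                ",", sub[[3]], ":", fmt(lc), ");")
  tree <- ape::read.tree(text = txt)
  if (!is.null(outgroup)) {
    if (!outgroup %in% tree$tip.label) {
      stop("outgroup '", outgroup, "' is not a leaf of the tree",
           call. = FALSE)
    }
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  }
  tree
}
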