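# Guide trees are ape "phylo" objects (unrooted, leaf-labeled, branch
# lengths optional).  A one-leaf component produced by splitting is
# represented by a lightweight "singleton_tree" stub since phylo cannot
# hold it usefully.

tree_tips <- function(tree) {
  if (inherits(tree, "singleton_tree")) tree$tip.label else tree$tip.label
}

singleton_tree <- function(label) {
  structure(list(tip.label = label, Nnode = 0L), class = "singleton_tree")
}

# Leaf index set below each node (ape internal numbering; tips are
# 1..Ntip).  Computed by one postorder sweep.
node_tip_sets <- function(tree) {
  nt <- length(tree$tip.label)
  sets <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) sets[[i]] <- i
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(eo))) {
    p <- eo[k, 1L]; ch <- eo[k, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

#' Find the centroid edge of a guide tree
#'
#' The centroid edge is an edge whose removal splits the leaf set into two
#' parts A and B minimizing `abs(|A| - |B|)` (a maximally balanced split).
#' Ties are broken deterministically: by the lexicographically smallest
#' minimum leaf label on the smaller side, then by the smaller side's size.
#'
#' @param tree A `phylo` with at least 2 leaves.
#' @return An object of class `tree_split` with elements `edge` (row index
#'   into `tree$edge`), `left` and `right` (leaf label character vectors;
#'   `left` is the tie-break "smaller" side).
#' @export
centroid_edge <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  nt <- length(tree$tip.label)
  if (nt < 2L) stop("centroid edge needs a tree with >= 2 leaves", call. = FALSE)
  sets <- node_tip_sets(tree)
  labs <- tree$tip.label
  ne <- nrow(tree$edge)
  imb <- integer(ne); min_lab <- character(ne); small_sz <- integer(ne)
  small_side <- vector("list", ne); big_side <- vector("list", ne)
  for (k in seq_len(ne)) {
    a <- labs[sets[[tree$edge[k, 2L]]]]
    b <- setdiff(labs, a)
    imb[k] <- abs(length(a) - length(b))
    if (length(a) < length(b) ||
        (length(a) == length(b) && min(a) <= min(b))) {
      sm <- a; bg <- b
    } else {
      sm <- b; bg <- a
    }
    small_side[[k]] <- sm; big_side[[k]] <- bg
    min_lab[k] <- min(sm); small_sz[k] <- length(sm)
  }
  ord <- order(imb, min_lab, small_sz)
  k <- ord[1L]
  structure(list(edge = k, left = sort(small_side[[k]]), right = sort(big_side[[k]])),
            class = "tree_split")
}

#' Split a guide tree on an edge
#'
#' Deleting the edge yields two components whose leaf sets partition the
#' tree's leaves; each component keeps its original branch lengths.  A
#' one-leaf component is returned as a `singleton_tree` stub.
#'
#' @param tree A `phylo`.
#' @param e A `tree_split` (from [centroid_edge]) or an edge row index into
#'   `tree$edge`.
#' @return List of two subtrees, `left` and `right`.
#' @export
split_on_edge <- function(tree, e) {
  stopifnot(inherits(tree, "phylo"))
  if (inherits(e, "tree_split")) {
    left <- e$left; right <- e$right
    if (!setequal(c(left, right), tree$tip.label))
      stop("split does not belong to this tree", call. = FALSE)
  } else {
    e <- as.integer(e)
    if (length(e) != 1L || is.na(e) || e < 1L || e > nrow(tree$edge))
      stop("edge index out of range", call. = FALSE)
    sets <- node_tip_sets(tree)
    left <- tree$tip.label[sets[[tree$edge[e, 2L]]]]
    right <- setdiff(tree$tip.label, left)
  }
  take <- function(labs) {
    if (length(labs) == 1L) singleton_tree(labs) else ape::keep.tip(tree, labs)
  }
  list(left = take(left), right = take(right))
}

#' Obtain a guide tree for a seed alignment
#'
#' If `tree` is supplied (e.g. an externally estimated maximum likelihood
#' tree) it is validated against the alignment's row ids and returned.
#' Otherwise a neighbor-joining tree is built from the p-distance matrix
#' `d(a, b) = 1 - pairwise_identity(a, b)`; negative NJ branch lengths are
#' clamped to 0.  Identical rows give all-zero distances and a
#' deterministic NJ topology.
#'
#' @param aln A [protein_msa] with at least 2 rows.
#' @param tree Optional externally supplied `phylo`.
#' @return A `phylo` whose tip labels are the alignment's row ids.
#' @export
estimate_guide_tree <- function(aln, tree = NULL) {
  stopifnot(inherits(aln, "protein_msa"))
  ids <- msa_ids(aln)
  if (!is.null(tree)) {
    stopifnot(inherits(tree, "phylo"))
    if (!setequal(tree$tip.label, ids))
      stop("external tree leaves do not match alignment ids", call. = FALSE)
    return(tree)
  }
  n <- length(aln)
  if (n < 2L) stop("guide tree estimation needs >= 2 rows", call. = FALSE)
  m <- as.matrix.protein_msa(aln)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  pairs <- t(utils::combn(n, 2L))
  pid <- pairwise_identity_rows(m, pairs)
  for (k in seq_len(nrow(pairs))) {
    d[pairs[k, 1L], pairs[k, 2L]] <- 1 - pid[k]
    d[pairs[k, 2L], pairs[k, 1L]] <- 1 - pid[k]
  }
  if (n == 2L) {
    tr <- ape::read.tree(text = sprintf("(%s:%f,%s:%f);",
                                        ids[1], d[1, 2] / 2, ids[2], d[1, 2] / 2))
    return(tr)
  }
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}
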