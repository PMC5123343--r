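#' Decomposition parameters
#'
#' Controls the recursive centroid-edge decomposition of a family's guide
#' tree.  A subset is decomposed further unless it is both small enough
#' (at most `max_size_pct` percent of the initial seed size) and
#' homogeneous enough (mean pairwise identity at least `min_identity_pct`
#' percent); subsets of at most `hard_floor` sequences are never split.
#'
#' @param max_size_pct Maximum decomposition size X, percent in (0, 100].
#' @param min_identity_pct Minimum average identity threshold Y, percent in
#'   \[0, 100).
#' @param hard_floor Subsets with at most this many sequences are never
#'   split (default 10).
#' @return An object of class `decomposition_params`.
#' @export
decomposition_params <- function(max_size_pct = 10, min_identity_pct = 40,
                                 hard_floor = 10L) {
  stopifnot(is.numeric(max_size_pct), length(max_size_pct) == 1L,
            max_size_pct > 0, max_size_pct <= 100)
  stopifnot(is.numeric(min_identity_pct), length(min_identity_pct) == 1L,
            min_identity_pct >= 0, min_identity_pct < 100)
  stopifnot(is.numeric(hard_floor), length(hard_floor) == 1L, hard_floor >= 1)
  structure(list(max_size_pct = max_size_pct,
                 min_identity_pct = min_identity_pct,
                 hard_floor = as.integer(hard_floor)),
            class = "decomposition_params")
}

#' Recursively decompose a seed alignment along its guide tree
#'
#' Starting from the full seed alignment, a subset with taxa `S` is split
#' at the centroid edge of its induced guide tree iff
#' `|S| > hard_floor` and NOT (`|S| <= X% * n` and mean identity `>= Y%`),
#' where `n` is the initial seed size.  The same rule is applied
#' recursively to the two children.  Every node records the mean pairwise
#' identity of its induced alignment.
#'
#' @param aln The family's seed alignment (a [protein_msa]).
#' @param tree Optional guide tree (`phylo`, tips = row ids); estimated by
#'   [estimate_guide_tree] when `NULL`.
#' @param params A [decomposition_params].
#' @return An object of class `hmm_decomposition`: a list with `nodes`
#'   (each with `id`, `parent`, `children`, `depth`, `taxa`, `size`,
#'   `mean_identity`), the initial size `n`, and `params`.
#' @export
decompose <- function(aln, tree = NULL, params = decomposition_params()) {
  stopifnot(inherits(aln, "protein_msa"), inherits(params, "decomposition_params"))
  n <- length(aln)
  tree <- if (n >= 2L) estimate_guide_tree(aln, tree) else NULL
  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  env$next_id <- 1L

  size_cap <- params$max_size_pct / 100 * n
  min_id <- params$min_identity_pct / 100

  recurse <- function(taxa, subtree, parent, depth) {
    id <- env$next_id
    env$next_id <- id + 1L
    sub <- induced_alignment(aln, taxa)
    mid <- mean_pairwise_identity(sub)
    size <- length(taxa)
    node <- list(id = id, parent = parent, children = NULL, depth = depth,
                 taxa = taxa, size = size, mean_identity = mid)
    env$nodes[[id]] <- node
    stop_here <- size <= size_cap && mid >= min_id
    if (size > params$hard_floor && !stop_here) {
      sp <- centroid_edge(subtree)
      parts <- split_on_edge(subtree, sp)
      sides <- list(parts$left, parts$right)
      # deterministic child order: side with lexicographically smaller
      # minimum label first
      mins <- vapply(sides, function(s) min(tree_tips(s)), character(1))
      sides <- sides[order(mins)]
      kids <- vapply(sides, function(s) {
        labs <- tree_tips(s)
        recurse(msa_ids(aln)[msa_ids(aln) %in% labs], s, id, depth + 1L)
      }, integer(1))
      env$nodes[[id]]$children <- kids
    }
    id
  }

  recurse(msa_ids(aln), tree, NA_integer_, 0L)
  structure(list(nodes = env$nodes, n = n, params = params,
                 tree = tree),
            class = "hmm_decomposition")
}

#' @export
print.hmm_decomposition <- function(x, ...) {
  cat(sprintf("hmm_decomposition: %d nodes over %d sequences (X=%g%%, Y=%g%%, floor=%d)\n",
              length(x$nodes), x$n, x$params$max_size_pct,
              x$params$min_identity_pct, x$params$hard_floor))
  invisible(x)
}

#' Tabulate a decomposition's nodes
#'
#' @param x An `hmm_decomposition`.
#' @return data.frame with one row per subset node: `id`, `parent`,
#'   `depth`, `size`, `mean_identity`, `is_leaf`, `taxa`
#'   (comma-separated).
#' @export
decomposition_table <- function(x) {
  stopifnot(inherits(x, "hmm_decomposition"))
  data.frame(
    id = vapply(x$nodes, `[[`, integer(1), "id"),
    parent = vapply(x$nodes, `[[`, integer(1), "parent"),
    depth = vapply(x$nodes, `[[`, integer(1), "depth"),
    size = vapply(x$nodes, `[[`, integer(1), "size"),
    mean_identity = vapply(x$nodes, `[[`, numeric(1), "mean_identity"),
    is_leaf = vapply(x$nodes, function(nd) is.null(nd$children), logical(1)),
    taxa = vapply(x$nodes, function(nd) paste(nd$taxa, collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
}
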