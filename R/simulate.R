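#' Simulation parameters for synthetic protein families
#'
#' The simulator emulates a curated family database: each family is an
#' independent random tree along which a root sequence evolves under a
#' uniform-replacement substitution model with tracked indels, so the true
#' alignment is known by construction.  `divergence` is the target mean
#' leaf-to-leaf path length and is the dial controlling within-family
#' identity (identity is roughly `0.05 + 0.95 * exp(-20/19 * divergence)`
#' at the default substitution rate).
#'
#' @param n_families Number of families.
#' @param family_size Sequences per family (length-2 range or a scalar).
#' @param root_length Root sequence length (length-2 range or a scalar).
#' @param divergence Target mean pairwise path length between leaves.
#' @param sub_rate Substitution events per site per unit branch length.
#' @param indel_rate Indel events per site per unit branch length.
#' @param indel_mean_len Mean indel tract length (geometric).
#' @param seed Mandatory integer seed.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_families = 20L, family_size = 40L,
                       root_length = c(90L, 110L), divergence = 0.35,
                       sub_rate = 1, indel_rate = 0.01,
                       indel_mean_len = 2, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (length(family_size) == 1L) family_size <- rep(family_size, 2L)
  if (length(root_length) == 1L) root_length <- rep(root_length, 2L)
  stopifnot(n_families >= 1L, family_size[1] >= 2L,
            family_size[1] <= family_size[2],
            root_length[1] >= 1L, root_length[1] <= root_length[2],
            divergence > 0, sub_rate > 0, indel_rate >= 0, indel_mean_len >= 1)
  structure(list(n_families = as.integer(n_families),
                 family_size = as.integer(family_size),
                 root_length = as.integer(root_length),
                 divergence = divergence, sub_rate = sub_rate,
                 indel_rate = indel_rate, indel_mean_len = indel_mean_len,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Sample a random guide tree
#'
#' Random binary topology drawn uniformly over labeled unrooted
#' topologies, with i.i.d. exponential branch lengths rescaled so the mean
#' leaf-to-leaf path length equals `divergence`.
#'
#' @param n_leaves Number of leaves (>= 2).
#' @param divergence Target mean pairwise path length.
#' @param labels Optional leaf labels (default `t1..tn`).
#' @return A `phylo`.
#' @export
sample_tree <- function(n_leaves, divergence = 1, labels = NULL) {
  if (n_leaves < 2L) stop("a tree needs >= 2 leaves", call. = FALSE)
  if (is.null(labels)) labels <- sprintf("t%d", seq_len(n_leaves))
  stopifnot(length(labels) == n_leaves)
  if (n_leaves == 2L) {
    tr <- ape::read.tree(text = sprintf("(%s:%f,%s:%f);", labels[1],
                                        divergence / 2, labels[2],
                                        divergence / 2))
    return(tr)
  }
  tr <- ape::rtopology(n_leaves, rooted = FALSE, tip.label = labels,
                       br = stats::rexp)
  d <- ape::cophenetic.phylo(tr)
  mean_d <- mean(d[upper.tri(d)])
  tr$edge.length <- tr$edge.length * divergence / mean_d
  tr
}

# sample() treats a length-1 vector as 1:n; guard degenerate ranges
sample_range <- function(rng) {
  if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)
}

# Evolve one lineage along a branch: substitutions, deletions, insertions.
# A sequence is (ids, res): parallel vectors of global column ids and
# residues.  Insertions splice fresh column ids into env$col_order right
# after their anchor column (or at the front).
evolve_branch <- function(state, t, p, env) {
  ids <- state$ids; res <- state$res
  n <- length(ids)
  if (n > 0L) {
    # substitutions: uniform replacement to one of the other 19 residues
    p_sub <- 1 - exp(-p$sub_rate * t)
    hit <- which(stats::runif(n) < p_sub)
    if (length(hit) > 0L) {
      cur <- match(res[hit], AA_ALPHABET)
      shift <- sample.int(19L, length(hit), replace = TRUE)
      res[hit] <- AA_ALPHABET[((cur - 1L + shift) %% 20L) + 1L]
    }
    # deletions: each site may start a geometric-length deletion tract
    p_indel <- 1 - exp(-p$indel_rate * t)
    starts <- which(stats::runif(n) < p_indel)
    if (length(starts) > 0L) {
      drop <- integer(0)
      for (s in starts) {
        len <- 1L + stats::rgeom(1L, 1 / p$indel_mean_len)
        drop <- c(drop, s:min(n, s + len - 1L))
      }
      keep <- setdiff(seq_len(n), unique(drop))
      ids <- ids[keep]; res <- res[keep]
    }
  }
  # insertions: anchored after each remaining site (or at the front)
  n <- length(ids)
  p_indel <- 1 - exp(-p$indel_rate * t)
  anchors <- which(stats::runif(n + 1L) < p_indel) - 1L  # 0 = front
  for (a in rev(anchors)) {
    len <- 1L + stats::rgeom(1L, 1 / p$indel_mean_len)
    new_ids <- env$next_col + seq_len(len) - 1L
    env$next_col <- env$next_col + len
    anchor_id <- if (a == 0L) NA_integer_ else ids[a]
    pos <- if (is.na(anchor_id)) 0L else match(anchor_id, env$col_order)
    env$col_order <- append(env$col_order, new_ids, after = pos)
    new_res <- sample(AA_ALPHABET, len, replace = TRUE)
    ids <- append(ids, new_ids, after = a)
    res <- append(res, new_res, after = a)
  }
  list(ids = ids, res = res)
}

#' Evolve a family of sequences along a tree
#'
#' The root sequence is i.i.d. from the uniform amino-acid background.
#' Along each branch every site substitutes with probability
#' `1 - exp(-sub_rate * length)` to a uniformly chosen different residue;
#' insertion/deletion events are tracked as alignment events, so the true
#' alignment is produced by construction and never re-estimated.  Uses the
#' current RNG stream.
#'
#' @param tree A `phylo` with branch lengths.
#' @param p A [sim_params] (only the rate fields are used).
#' @return List with `alignment` (a [protein_msa] over the tree's tips)
#'   and `tree`.
#' @export
evolve_family <- function(tree, p) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  L0 <- sample_range(p$root_length)
  env <- new.env(parent = emptyenv())
  env$col_order <- seq_len(L0)
  env$next_col <- L0 + 1L
  root_state <- list(ids = seq_len(L0),
                     res = sample(AA_ALPHABET, L0, replace = TRUE))
  nt <- length(tree$tip.label)
  root <- nt + 1L  # arbitrary rooting of the unrooted tree
  states <- vector("list", nt + tree$Nnode)
  states[[root]] <- root_state
  eo <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  leaf_states <- vector("list", nt)
  for (k in seq_len(nrow(eo$edge))) {
    par <- eo$edge[k, 1L]; ch <- eo$edge[k, 2L]
    st <- evolve_branch(states[[par]], eo$edge.length[k], p, env)
    if (ch <= nt) leaf_states[[ch]] <- st else states[[ch]] <- st
  }
  # assemble rows over the global column order, dropping all-gap columns
  used <- sort(unique(unlist(lapply(leaf_states, `[[`, "ids"))))
  cols <- env$col_order[env$col_order %in% used]
  rows <- vapply(leaf_states, function(st) {
    v <- rep("-", length(cols))
    v[match(st$ids, cols)] <- st$res
    paste(v, collapse = "")
  }, character(1))
  names(rows) <- tree$tip.label
  list(alignment = protein_msa(rows), tree = tree)
}

#' Generate a synthetic benchmark: families, held-out queries, fragments
#'
#' Per family, 75\% of the simulated rows become the seed alignment (with
#' the true tree pruned to them as guide tree) and 25\% become full-length
#' queries, from which half- and quarter-length fragments are cut with
#' [make_fragment].  Query ids are `family|sequence|fraction`.
#'
#' @param p A [sim_params].
#' @return List with `db` (a [family_db]), `queries` (named list of named
#'   character vectors, one per fraction: `full`, `half`, `quarter`),
#'   `truth` (named character vector query id -> family id), and `params`.
#' @export
make_benchmark <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(p$seed)
  fam_ids <- sprintf("FAM%03d", seq_len(p$n_families))
  records <- list()
  fractions <- c(full = 1, half = 0.5, quarter = 0.25)
  queries <- list(full = character(), half = character(), quarter = character())
  truth <- character()
  for (fid in fam_ids) {
    n <- sample_range(p$family_size)
    tree <- sample_tree(n, p$divergence,
                        labels = sprintf("%s_s%02d", fid, seq_len(n)))
    fam <- evolve_family(tree, p)
    ids <- msa_ids(fam$alignment)
    n_test <- floor(n / 4)
    n_train <- n - n_test
    if (n_train < 10L)
      stop("family size ", n, " leaves fewer than 10 seed sequences after ",
           "the 75/25 split; increase family_size", call. = FALSE)
    shuffled <- sample(ids)
    train <- sort(shuffled[seq_len(n_train)])
    test <- sort(shuffled[-seq_len(n_train)])
    seed_aln <- induced_alignment(fam$alignment, train)
    records[[fid]] <- family_record(fid, seed_aln, threshold = 0,
                                    guide_tree = ape::keep.tip(tree, train))
    full <- degap(unclass(fam$alignment)[test])
    for (fr in names(fractions)) {
      qids <- paste0(fid, "|", test, "|", fr)
      frags <- vapply(seq_along(test), function(i)
        make_fragment(full[[i]], fractions[[fr]]), character(1))
      queries[[fr]][qids] <- frags
      truth[qids] <- fid
    }
  }
  list(db = family_db(records), queries = queries, truth = truth, params = p)
}

#' Write a benchmark to disk
#'
#' Emits `manifest.tsv` (family_id, alignment_path, tree_path, threshold),
#' one aligned FASTA and newick file per family, one query FASTA per
#' fragment length, and `truth.tsv`.
#'
#' @param bm A benchmark from [make_benchmark].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- data.frame(family_id = character(), alignment_path = character(),
                    tree_path = character(), threshold = numeric(),
                    stringsAsFactors = FALSE)
  for (fid in names(bm$db)) {
    fam <- bm$db[[fid]]
    afa <- paste0(fid, ".afa"); nwk <- paste0(fid, ".nwk")
    write_alignment(fam$seed, file.path(dir, afa))
    ape::write.tree(fam$guide_tree, file.path(dir, nwk))
    man[nrow(man) + 1L, ] <- list(fid, afa, nwk, fam$threshold)
  }
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (fr in names(bm$queries)) {
    q <- bm$queries[[fr]]
    writeLines(paste0(">", names(q), "\n", q),
               file.path(dir, sprintf("queries_%s.fasta", fr)))
  }
  utils::write.table(
    data.frame(query_id = names(bm$truth), family_id = unname(bm$truth)),
    file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
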