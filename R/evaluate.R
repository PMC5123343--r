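#' Four-fold (or n-fold) cross-validation splits per family
#'
#' Within each family, sequences are shuffled once (seeded) and dealt into
#' `n_folds` near-equal groups, any remainder spread one per fold; fold
#' `f`'s test set is group `f` and its training set the remaining groups.
#' Each sequence therefore appears in exactly one test set and `n_folds -
#' 1` training sets.  Families with fewer than 10 sequences are rejected:
#' removing even one or two sequences from a very small family can
#' substantially reduce its diversity.
#'
#' @param db A [family_db].
#' @param n_folds Number of folds (default 4).
#' @param seed Integer seed for the one-time shuffle.
#' @param min_family_size Smallest admissible family (default 10).
#' @return List of `n_folds` fold splits, each a list with `fold`,
#'   `train` and `test` (named lists of id vectors per family).
#' @export
make_folds <- function(db, n_folds = 4L, seed = 1L, min_family_size = 10L) {
  stopifnot(inherits(db, "family_db"), n_folds >= 2L)
  sizes <- vapply(db, function(f) length(f$seed), integer(1))
  if (any(sizes < min_family_size))
    stop("families smaller than ", min_family_size, " sequences: ",
         paste(names(db)[sizes < min_family_size], collapse = ", "),
         "; filter them out before making folds", call. = FALSE)
  groups <- list()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (fid in names(db)) {
    ids <- sample(msa_ids(db[[fid]]$seed))
    g <- rep(seq_len(n_folds), length.out = length(ids))
    groups[[fid]] <- split(ids, g)
  }
  lapply(seq_len(n_folds), function(f) {
    test <- lapply(groups, function(g) unname(g[[f]]))
    train <- lapply(groups, function(g) unname(unlist(g[-f], use.names = FALSE)))
    list(fold = f, train = train, test = test)
  })
}

#' Generate a fragmentary query
#'
#' A fragment is a uniformly placed contiguous substring of the de-gapped
#' source with length `max(1, floor(fraction * L))`; `fraction = 1`
#' returns the full sequence.  Uses the current RNG stream.
#'
#' @param seq Residue string (gaps stripped on entry).
#' @param fraction Length fraction in (0, 1].
#' @return Fragment string; the source's name is preserved.
#' @export
make_fragment <- function(seq, fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]", call. = FALSE)
  s <- gsub("[-.]", "", seq)
  L <- nchar(s)
  if (L < 1L) stop("empty sequence", call. = FALSE)
  if (fraction == 1) return(stats::setNames(s, names(seq)))
  len <- max(1L, floor(fraction * L))
  start <- sample.int(L - len + 1L, 1L)
  stats::setNames(substr(s, start, start + len - 1L), names(seq))
}

#' Precision and recall of an assignment table
#'
#' `recall = n_correct / n_queries` and
#' `precision = n_correct / n_assigned` (NA when nothing is assigned):
#' unassigned queries count against recall but not precision.
#'
#' @param assignments Assignment data.frame (as from [classify_batch]).
#' @param truth Named character vector mapping every query id to its true
#'   family.
#' @return One-row data.frame: `precision`, `recall`, `n_queries`,
#'   `n_assigned`, `n_correct`.
#' @export
precision_recall <- function(assignments, truth) {
  missing <- setdiff(assignments$query_id, names(truth))
  if (length(missing) > 0L)
    stop("queries missing from truth: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  assigned <- !is.na(assignments$family_id)
  correct <- assigned & assignments$family_id == truth[assignments$query_id]
  n_q <- nrow(assignments); n_a <- sum(assigned); n_c <- sum(correct)
  data.frame(precision = if (n_a > 0L) n_c / n_a else NA_real_,
             recall = if (n_q > 0L) n_c / n_q else 0,
             n_queries = n_q, n_assigned = n_a, n_correct = n_c)
}

#' Subgroup keys for families: size and identity bins
#'
#' Families are binned by seed size (at most 100 sequences vs more) and by
#' mean pairwise sequence identity (0-20\%, 20-30\%, above 30\%); the bins
#' are exhaustive and disjoint.
#'
#' @param db A [family_db].
#' @return data.frame: `family_id`, `size_bin`, `identity_bin`, `subgroup`
#'   (their interaction).
#' @export
family_subgroups <- function(db) {
  stopifnot(inherits(db, "family_db"))
  rows <- lapply(db, function(f) {
    n <- length(f$seed)
    pid <- mean_pairwise_identity(f$seed)
    size_bin <- if (n <= 100L) "size<=100" else "size>100"
    identity_bin <- if (pid < 0.20) "id0-20%" else if (pid < 0.30) "id20-30%" else "id>30%"
    data.frame(family_id = f$family_id, size_bin = size_bin,
               identity_bin = identity_bin,
               subgroup = paste(size_bin, identity_bin, sep = "/"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Precision/recall curve by threshold sweep
#'
#' Re-gates a raw score table (no re-scoring) at each grid value of the
#' gathering-cutoff scale and emits one precision/recall point per value,
#' globally and, when `subgroups` is given, per subgroup of the query's
#' true family.  The default grid yields the five-to-seven distinct points
#' typical of such curves.
#'
#' @param tab A [score_table] data.frame with raw best scores.
#' @param thresholds Named per-family gathering cutoffs `g_i` (unscaled).
#' @param truth Named character vector of true families per query.
#' @param query_ids All query ids scored (defaults to `names(truth)`).
#' @param grid Threshold scales to sweep (nonempty, in `[0, 1]`).
#' @param subgroups Optional [family_subgroups] table.
#' @return data.frame of PR points with columns `scale`, `subgroup`
#'   (`"all"` for the global row), `precision`, `recall`, `n_queries`,
#'   `n_assigned`, `n_correct`.
#' @export
pr_curve <- function(tab, thresholds, truth, query_ids = names(truth),
                     grid = c(0, 0.25, 0.5, 0.75, 0.9, 1.0),
                     subgroups = NULL) {
  if (length(grid) == 0L) stop("empty threshold grid", call. = FALSE)
  stopifnot(all(grid >= 0 & grid <= 1))
  out <- list()
  for (s in grid) {
    asg <- assign_from_scores(tab, thresholds * s, query_ids)
    p <- precision_recall(asg, truth)
    out[[length(out) + 1L]] <- cbind(scale = s, subgroup = "all", p)
    if (!is.null(subgroups)) {
      key <- subgroups$subgroup[match(truth[asg$query_id], subgroups$family_id)]
      for (sg in sort(unique(key))) {
        ps <- precision_recall(asg[key == sg, , drop = FALSE], truth)
        out[[length(out) + 1L]] <- cbind(scale = s, subgroup = sg, ps)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Select mutually confusable families via a probe graph
#'
#' From each family, `n_probe` seed sequences are chosen at random (all of
#' them when the family is smaller) and scored against every other
#' family's single root profile.  An undirected edge joins families `i`
#' and `j` when the mean probe bit score strictly exceeds `bit_cutoff` in
#' either direction (probes the engine reports no hit for contribute 0 to
#' the mean).  The selected set comprises all families of degree at least
#' `degree_cutoff` plus every family adjacent to one of them.
#'
#' @param db A [family_db].
#' @param cfg A [backend_config] used to build the root profiles.
#' @param bit_cutoff Mean bit score that must be exceeded (default 25).
#' @param degree_cutoff Minimum degree of a hub family (default 5).
#' @param n_probe Probe sequences per family (default 10).
#' @param seed Integer seed for probe sampling.
#' @return List with `selected` (sorted family ids), `edges` (data.frame
#'   `from`, `to` with `from < to`), and `degrees` (named integer vector).
#' @export
confusable_family_graph <- function(db, cfg = backend_config(),
                                    bit_cutoff = 25, degree_cutoff = 5L,
                                    n_probe = 10L, seed = 1L) {
  stopifnot(inherits(db, "family_db"))
  fids <- names(db)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  probes <- lapply(db, function(f) {
    ids <- msa_ids(f$seed)
    take <- if (length(ids) > n_probe) sample(ids, n_probe) else ids
    stats::setNames(degap(unclass(f$seed)[take]), take)
  })
  roots <- lapply(db, function(f) {
    if (cfg$engine == "hmmer")
      build_hmmer_profile(f$seed, cfg, model_id = paste0(f$family_id, ".root"),
                          family_id = f$family_id)
    else
      build_profile(f$seed, cfg, model_id = paste0(f$family_id, ".root"),
                    family_id = f$family_id)
  })
  k <- length(fids)
  mean_bits <- matrix(0, k, k, dimnames = list(fids, fids))
  for (j in seq_len(k)) {
    for (i in seq_len(k)) {
      if (i == j) next
      hits <- score_sequences(roots[[j]], probes[[i]], cfg = cfg)
      bits <- stats::setNames(rep(0, length(probes[[i]])), names(probes[[i]]))
      if (nrow(hits) > 0L)
        bits[hits$query_id] <- ifelse(is.finite(hits$bit_score),
                                      hits$bit_score, 0)
      mean_bits[i, j] <- mean(bits)
    }
  }
  c(confusable_selection(mean_bits, bit_cutoff, degree_cutoff),
    list(mean_bits = mean_bits))
}

# Selection rule on the probe-score matrix: symmetrize by OR over the two
# probe directions, edge iff the mean strictly exceeds the cutoff, select
# hubs of degree >= degree_cutoff plus all their neighbors.
confusable_selection <- function(mean_bits, bit_cutoff, degree_cutoff) {
  fids <- rownames(mean_bits)
  adj <- (mean_bits > bit_cutoff) | t(mean_bits > bit_cutoff)
  diag(adj) <- FALSE
  degrees <- rowSums(adj)
  hubs <- fids[degrees >= degree_cutoff]
  neighbors <- fids[colSums(adj[hubs, , drop = FALSE]) > 0L]
  edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
  list(selected = sort(unique(c(hubs, neighbors))),
       edges = data.frame(from = fids[edges[, 1L]], to = fids[edges[, 2L]],
                          stringsAsFactors = FALSE),
       degrees = stats::setNames(as.integer(degrees), fids))
}

#' Run the full cross-validation evaluation
#'
#' For each fold: build an ensemble database on the training rows of every
#' family (seed restricted via [induced_alignment], guide tree pruned when
#' supplied), generate full-length and fragmentary queries from the test
#' rows, score once, and sweep the threshold grid into precision/recall
#' tables (global and per subgroup).
#'
#' @param db A [family_db] (all families of size >= 10).
#' @param n_folds Number of folds (default 4).
#' @param fractions Query length fractions (default `c(1, 0.5, 0.25)`).
#' @param params,backend Ensemble-construction settings.
#' @param grid Threshold-scale grid for [pr_curve].
#' @param seed Integer seed driving folds, fragments and builds.
#' @param single_hmm Evaluate the single-HMM baseline instead.
#' @param folds_subset Optional integer vector of folds to run (e.g. `1`).
#' @return List with `assignments` (per fold/fraction, raw scores kept)
#'   and `pr` (PR points with fold, fraction, scale, subgroup columns).
#' @export
run_crossval <- function(db, n_folds = 4L, fractions = c(1, 0.5, 0.25),
                         params = decomposition_params(),
                         backend = backend_config(),
                         grid = c(0, 0.25, 0.5, 0.75, 0.9, 1.0),
                         seed = 1L, single_hmm = FALSE,
                         folds_subset = seq_len(n_folds)) {
  stopifnot(inherits(db, "family_db"))
  folds <- make_folds(db, n_folds, seed = seed)
  sub <- family_subgroups(db)
  pr <- list(); assignments <- list()
  for (f in folds_subset) {
    fold <- folds[[f]]
    train_db <- family_db(lapply(names(db), function(fid) {
      fam <- db[[fid]]
      tree <- if (!is.null(fam$guide_tree))
        ape::keep.tip(fam$guide_tree, fold$train[[fid]]) else NULL
      family_record(fid, induced_alignment(fam$seed, fold$train[[fid]]),
                    threshold = fam$threshold, guide_tree = tree)
    }))
    edb <- ensemble_db(train_db, params, backend, seed = seed,
                       single_hmm = single_hmm)
    thresholds <- vapply(edb$ensembles, `[[`, numeric(1), "threshold")
    for (frac in fractions) {
      queries <- character(); truth <- character()
      old <- .Random.seed_save()
      set.seed(seed + 7L * f)
      for (fid in names(db)) {
        full <- degap(unclass(db[[fid]]$seed)[fold$test[[fid]]])
        frags <- vapply(names(full), function(qid)
          make_fragment(stats::setNames(full[[qid]], qid), frac), character(1))
        qids <- paste0(fid, "|", names(full), "|f", frac)
        queries[qids] <- unname(frags)
        truth[qids] <- fid
      }
      .Random.seed_restore(old)
      tab <- score_table(edb, queries)
      asg <- classify_batch(queries, edb, threshold_policy("none"), tab = tab)
      assignments[[sprintf("fold%d_f%g", f, frac)]] <-
        list(fold = f, fraction = frac, scores = tab, assignments = asg,
             truth = truth)
      pts <- pr_curve(tab, thresholds, truth, names(queries), grid, sub)
      pr[[length(pr) + 1L]] <- cbind(fold = f, fraction = frac, pts)
    }
  }
  list(assignments = assignments, pr = do.call(rbind, pr),
       subgroups = sub, folds = folds)
}
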