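test_that("folds deal near-equal test sets that partition each family", {
  db <- family_db(list(uniform_family("A", 12), uniform_family("B", 10)))
  folds <- make_folds(db, seed = 3)
  sizes_a <- sort(vapply(folds, function(f) length(f$test$A), integer(1)))
  expect_identical(sizes_a, rep(3L, 4L))
  sizes_b <- sort(vapply(folds, function(f) length(f$test$B), integer(1)))
  expect_identical(sizes_b, c(2L, 2L, 3L, 3L))
  for (fid in names(db)) {
    all_test <- unlist(lapply(folds, function(f) f$test[[fid]]))
    expect_setequal(all_test, msa_ids(db[[fid]]$seed))   # exactly once
    expect_identical(anyDuplicated(all_test), 0L)
    for (f in folds) {
      expect_length(intersect(f$train[[fid]], f$test[[fid]]), 0L)
      expect_setequal(c(f$train[[fid]], f$test[[fid]]),
                      msa_ids(db[[fid]]$seed))
    }
  }
  small <- family_db(list(uniform_family("TINY", 9)))
  expect_error(make_folds(small), "filter")
})

test_that("fragments are exact-length substrings of their source", {
  set.seed(8)
  src <- random_query(100, seed = 8)
  half <- make_fragment(src, 0.5)
  expect_identical(nchar(half), 50L)
  expect_true(grepl(half, src, fixed = TRUE))

  expect_identical(make_fragment(src, 1), stats::setNames(src, NULL))
  expect_identical(nchar(make_fragment(random_query(7, 1), 0.25)), 1L)
  expect_error(make_fragment(src, 0), "fraction")
  expect_error(make_fragment(src, 1.2), "fraction")

  for (i in 1:50) {
    L <- sample(1:80, 1L)
    f <- sample(c(0.25, 0.5, 0.9), 1L)
    s <- random_query(L, seed = 5000 + i)
    frag <- make_fragment(s, f)
    expect_identical(nchar(frag), max(1L, as.integer(floor(f * L))))
    expect_true(grepl(frag, s, fixed = TRUE))
  }
})

test_that("precision/recall identities hold integer-exactly", {
  asg <- data.frame(query_id = sprintf("q%d", 1:10),
                    family_id = c(rep("A", 6), rep("B", 2), NA, NA),
                    stringsAsFactors = FALSE)
  truth <- stats::setNames(c(rep("A", 6), rep("C", 2), "A", "B"),
                           sprintf("q%d", 1:10))
  pr <- precision_recall(asg, truth)
  expect_identical(pr$n_queries, 10L)
  expect_identical(pr$n_assigned, 8L)
  expect_identical(pr$n_correct, 6L)
  expect_identical(pr$precision, 0.75)
  expect_identical(pr$recall, 0.6)
  expect_identical(pr$precision * pr$n_assigned, as.numeric(pr$n_correct))
  expect_identical(pr$recall * pr$n_queries, as.numeric(pr$n_correct))

  none <- asg; none$family_id <- NA_character_
  pr0 <- precision_recall(none, truth)
  expect_identical(pr0$precision, NA_real_)
  expect_identical(pr0$recall, 0)

  all_right <- asg[1:6, ]
  expect_identical(precision_recall(all_right, truth)[, c("precision", "recall")],
                   data.frame(precision = 1, recall = 1))

  expect_error(precision_recall(asg, truth[-1]), "missing from truth")
})

test_that("the PR curve re-gates monotonically and subgroups sum to global", {
  set.seed(66)
  fams <- sprintf("F%d", 1:6)
  qs <- sprintf("q%03d", 1:90)
  tab <- expand.grid(query_id = qs, family_id = fams, stringsAsFactors = FALSE)
  tab$model_id <- paste0(tab$family_id, ".m1")
  tab$bit_score <- stats::rnorm(nrow(tab), 30, 15)
  g <- stats::setNames(stats::runif(6, 10, 45), fams)
  truth <- stats::setNames(sample(fams, 90, replace = TRUE), qs)
  subgroups <- data.frame(
    family_id = fams,
    size_bin = rep(c("size<=100", "size>100"), 3),
    identity_bin = rep(c("id0-20%", "id20-30%", "id>30%"), each = 2),
    subgroup = paste0("sg", rep(1:3, each = 2)),
    stringsAsFactors = FALSE)

  pts <- pr_curve(tab, g, truth, qs, subgroups = subgroups)
  glob <- pts[pts$subgroup == "all", ]
  expect_identical(glob$scale, c(0, 0.25, 0.5, 0.75, 0.9, 1.0))
  expect_true(all(diff(glob$n_assigned) <= 0))
  # with a common cutoff, recall is maximal at scale 0 (no winner flips)
  g_eq <- stats::setNames(rep(30, 6), fams)
  glob_eq <- pr_curve(tab, g_eq, truth, qs)
  expect_identical(max(glob_eq$recall), glob_eq$recall[1])
  for (s in glob$scale) {
    sub <- pts[pts$subgroup != "all" & pts$scale == s, ]
    glo <- glob[glob$scale == s, ]
    expect_identical(sum(sub$n_queries), glo$n_queries)
    expect_identical(sum(sub$n_assigned), glo$n_assigned)
    expect_identical(sum(sub$n_correct), glo$n_correct)
  }
  expect_error(pr_curve(tab, g, truth, qs, grid = numeric()), "empty")
})

test_that("family subgroup bins are exhaustive and disjoint", {
  db <- family_db(list(uniform_family("SMALL", 12),
                       family_record("DIV", sim_family_aln(15, 2.5, seed = 61)$alignment)))
  sub <- family_subgroups(db)
  expect_identical(nrow(sub), 2L)
  expect_true(all(sub$size_bin %in% c("size<=100", "size>100")))
  expect_true(all(sub$identity_bin %in% c("id0-20%", "id20-30%", "id>30%")))
  expect_identical(sub$size_bin, c("size<=100", "size<=100"))
  expect_identical(sub$identity_bin[1], "id>30%")  # near-identical rows
})

test_that("confusable-family selection follows the strict-cutoff hub rule", {
  fids <- sprintf("F%d", 1:8)
  mb <- matrix(0, 8, 8, dimnames = list(fids, fids))
  # F1 is a hub: mean probe score 26 against five families
  for (j in 2:6) mb["F1", fids[j]] <- 26
  mb["F7", "F8"] <- 25        # exactly at the cutoff: no edge
  sel <- hmmensemble:::confusable_selection(mb, 25, 5)
  expect_identical(sel$selected, sort(c("F1", fids[2:6])))  # hub + neighbors
  expect_identical(sel$degrees[["F1"]], 5L)
  expect_false(any(c("F7", "F8") %in% sel$selected))
  expect_identical(nrow(sel$edges), 5L)
  # symmetric: the direction of the probe scoring does not matter
  sel_t <- hmmensemble:::confusable_selection(t(mb), 25, 5)
  expect_identical(sel_t$selected, sel$selected)
  # idempotent: applying the rule to the selected subgraph reselects it
  sub <- mb[sel$selected, sel$selected]
  expect_identical(hmmensemble:::confusable_selection(sub, 25, 5)$selected,
                   sel$selected)
  # nothing above the cutoff -> empty selection
  expect_length(hmmensemble:::confusable_selection(mb * 0, 25, 5)$selected, 0L)
})

test_that("the probe graph separates unrelated families and links clones", {
  # three unrelated families -> no edges
  bm <- tiny_benchmark(seed = 71, n_families = 3, family_size = 16)
  g <- confusable_family_graph(bm$db, bit_cutoff = 25, degree_cutoff = 1,
                               n_probe = 5, seed = 1)
  expect_identical(nrow(g$edges), 0L)
  expect_length(g$selected, 0L)

  # six near-copies of one family are mutually confusable
  fam <- sim_family_aln(16, 0.3, seed = 72)$alignment
  clones <- family_db(lapply(1:6, function(i) {
    ids <- sprintf("C%d_%s", i, msa_ids(fam))
    family_record(sprintf("C%d", i),
                  protein_msa(stats::setNames(unclass(fam), ids)))
  }))
  gc_ <- confusable_family_graph(clones, bit_cutoff = 25, degree_cutoff = 5,
                                 n_probe = 5, seed = 1)
  expect_identical(gc_$selected, sprintf("C%d", 1:6))
  expect_true(all(gc_$degrees == 5L))
})

test_that("run_crossval produces coherent per-fold PR tables", {
  bm <- tiny_benchmark(seed = 81, n_families = 3, family_size = 16)
  res <- run_crossval(bm$db, n_folds = 4, fractions = c(1, 0.25),
                      grid = c(0, 1), seed = 81, folds_subset = 1L)
  expect_identical(sort(unique(res$pr$fraction)), c(0.25, 1))
  glob <- res$pr[res$pr$subgroup == "all" & res$pr$fraction == 1 &
                   res$pr$scale == 0, ]
  expect_identical(glob$n_queries, 9L)   # 3 families x 3 test sequences
  expect_gte(glob$recall, 0.9)
  # raw scores retained: re-gating reproduces the stored assignments
  blk <- res$assignments[["fold1_f1"]]
  regated <- assign_from_scores(blk$scores,
                                stats::setNames(rep(0, 3), names(bm$db)),
                                names(blk$truth))
  expect_identical(regated$family_id, blk$assignments$family_id)
})
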