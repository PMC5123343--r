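make_tab <- function(...) {
  # rows: list(query, family, model, score)
  rows <- list(...)
  data.frame(query_id = vapply(rows, `[[`, character(1), 1L),
             family_id = vapply(rows, `[[`, character(1), 2L),
             model_id = vapply(rows, `[[`, character(1), 3L),
             bit_score = vapply(rows, `[[`, numeric(1), 4L),
             stringsAsFactors = FALSE)
}

test_that("assignment takes the best above-threshold family", {
  tab <- make_tab(list("q", "F1", "F1.m1", 50), list("q", "F2", "F2.m1", 30))
  asg <- assign_from_scores(tab, c(F1 = 25, F2 = 25), "q")
  expect_identical(asg$family_id, "F1")
  expect_identical(asg$bit_score, 50)
  expect_identical(asg$runner_up, "F2")

  # all below threshold -> unassigned
  asg2 <- assign_from_scores(tab, c(F1 = 60, F2 = 35), "q")
  expect_identical(asg2$family_id, NA_character_)

  # excluded families drop out of the argmax entirely
  asg3 <- assign_from_scores(tab, c(F1 = 60, F2 = 25), "q")
  expect_identical(asg3$family_id, "F2")
  expect_identical(asg3$bit_score, 30)

  # thresholds gate strictly: a score equal to the cutoff is excluded
  asg4 <- assign_from_scores(tab, c(F1 = 50, F2 = 30), "q")
  expect_identical(asg4$family_id, NA_character_)

  # score ties break to the lexicographically smallest family id
  tie <- make_tab(list("q", "F9", "F9.m1", 50), list("q", "F2", "F2.m1", 50))
  expect_identical(assign_from_scores(tie, c(F9 = 0, F2 = 0), "q")$family_id,
                   "F2")
})

test_that("assignments match a literal evaluation of the argmax formula", {
  set.seed(123)
  fams <- sprintf("F%02d", 1:6)
  for (trial in 1:200) {
    n_q <- sample(1:4, 1L)
    qs <- sprintf("q%d", seq_len(n_q))
    # per-profile scores: several profiles per family
    rows <- expand.grid(query_id = qs, family_id = fams,
                        profile = 1:2, stringsAsFactors = FALSE)
    rows$model_id <- paste0(rows$family_id, ".m", rows$profile)
    rows$bit_score <- round(stats::rnorm(nrow(rows), 20, 15), 2)
    thresholds <- stats::setNames(round(stats::runif(6, 0, 35), 2), fams)

    # package path: per-family best, then gating
    per_fam <- rows[order(rows$query_id, rows$family_id, -rows$bit_score), ]
    per_fam <- per_fam[!duplicated(per_fam[, c("query_id", "family_id")]), ]
    got <- assign_from_scores(per_fam[, c("query_id", "family_id",
                                          "model_id", "bit_score")],
                              thresholds, qs)
    want <- oracle_family_assign(rows, thresholds)
    expect_identical(got$family_id[match(want$query_id, got$query_id)],
                     want$family_id)
    expect_equal(got$bit_score[match(want$query_id, got$query_id)],
                 want$bit_score)
  }
})

test_that("raising the threshold scale only unassigns, never reassigns", {
  set.seed(321)
  fams <- sprintf("F%02d", 1:5)
  qs <- sprintf("q%03d", 1:60)
  tab <- expand.grid(query_id = qs, family_id = fams, stringsAsFactors = FALSE)
  tab$model_id <- paste0(tab$family_id, ".m1")
  tab$bit_score <- stats::rnorm(nrow(tab), 25, 20)
  g <- stats::setNames(stats::runif(5, 5, 40), fams)
  prev <- NULL
  n_assigned <- integer()
  for (s in c(0, 0.2, 0.4, 0.6, 0.8, 1)) {
    asg <- assign_from_scores(tab, g * s, qs)
    n_assigned <- c(n_assigned, sum(!is.na(asg$family_id)))
    if (!is.null(prev)) {
      # the assigned set shrinks weakly: unassigned never becomes assigned
      expect_true(all(is.na(asg$family_id[is.na(prev$family_id)])))
    }
    prev <- asg
  }
  expect_true(all(diff(n_assigned) <= 0))

  # with one common threshold the winner can never flip, only vanish:
  # gating before the argmax removes whole families, so heterogeneous
  # cutoffs may hand a query to the runner-up instead
  g_eq <- stats::setNames(rep(20, 5), fams)
  prev <- NULL
  for (s in c(0, 0.5, 1)) {
    asg <- assign_from_scores(tab, g_eq * s, qs)
    if (!is.null(prev)) {
      both <- !is.na(prev$family_id) & !is.na(asg$family_id)
      expect_identical(asg$family_id[both], prev$family_id[both])
    }
    prev <- asg
  }
})

test_that("with equal thresholds assignment is a plain argmax", {
  set.seed(555)
  fams <- sprintf("F%d", 1:4)
  qs <- sprintf("q%d", 1:40)
  tab <- expand.grid(query_id = qs, family_id = fams, stringsAsFactors = FALSE)
  tab$model_id <- paste0(tab$family_id, ".m1")
  tab$bit_score <- stats::rnorm(nrow(tab), 30, 10)
  asg <- assign_from_scores(tab, stats::setNames(rep(-Inf, 4), fams), qs)
  for (q in qs) {
    sq <- tab[tab$query_id == q, ]
    expect_identical(asg$family_id[asg$query_id == q],
                     sq$family_id[which.max(sq$bit_score)])
  }
})

test_that("classify and classify_batch agree and validate input", {
  bm <- tiny_benchmark(seed = 41)
  edb <- ensemble_db(bm$db, seed = 41)
  q1 <- bm$queries$full[1]
  single <- classify(q1, edb, threshold_policy("none"))
  batch <- classify_batch(bm$queries$full, edb, threshold_policy("none"))
  expect_identical(single$family_id, batch$family_id[1])
  expect_identical(single$bit_score, batch$bit_score[1])

  dup <- stats::setNames(c("ACDE", "ACDE"), c("same", "same"))
  expect_error(classify_batch(dup, edb), "unique")
  expect_error(classify("", edb), "empty")

  # predict() is the S3 face of classify_batch
  expect_identical(predict(edb, bm$queries$full, threshold_policy("none")),
                   batch)
})

test_that("threshold policy validates and mode none means scale zero", {
  expect_error(threshold_policy(scale = 1.5))
  expect_identical(threshold_policy("none", scale = 0.8)$scale, 0)
  expect_identical(threshold_policy("gathering-cutoff", 0.5)$scale, 0.5)
})
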