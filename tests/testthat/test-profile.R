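test_that("match columns follow the gap-fraction rule", {
  aln <- protein_msa(c(a = "ACDE", b = "ACDE"))
  expect_identical(match_columns(aln), rep(TRUE, 4L))

  # gap fraction 0.6 at threshold 0.5 -> non-match
  aln2 <- protein_msa(c(a = "A-", b = "A-", c = "A-", d = "AC", e = "AC"))
  expect_identical(unname(match_columns(aln2)), c(TRUE, FALSE))

  one <- protein_msa(c(a = "A-C"))
  expect_identical(unname(match_columns(one)), c(TRUE, FALSE, TRUE))

  allgap <- protein_msa(c(a = "--", b = "AC", c = "--"))
  expect_error(match_columns(allgap), "no consensus columns")
})

test_that("match emissions follow the pseudocount formula", {
  # single 'A', alpha = 1, uniform background: (1 + 0.05) / (1 + 1)
  m1 <- build_profile(protein_msa(c(x = "A")))
  expect_equal(unname(m1$e_match[1, "A"]), 0.525)
  # four 'C': (4 + 0.05) / (4 + 1)
  m4 <- build_profile(protein_msa(c(p = "C", q = "C", r = "C", s = "C")))
  expect_equal(unname(m4$e_match[1, "C"]), 0.81)
  # every emission and transition distribution sums to 1
  fam <- sim_family_aln(10, 0.8, seed = 2)$alignment
  mod <- build_profile(fam)
  expect_equal(unname(rowSums(mod$e_match)), rep(1, mod$M), tolerance = 1e-9)
  tr <- mod$trans
  M <- mod$M
  if (M > 1) {
    expect_equal(tr$tMM[-M] + tr$tMI[-M] + tr$tMD[-M] + tr$tME[-M],
                 rep(1, M - 1), tolerance = 1e-9)
    expect_equal(tr$tII[-M] + tr$tIM[-M], rep(1, M - 1), tolerance = 1e-9)
    expect_equal(tr$tDM[-M] + tr$tDD[-M], rep(1, M - 1), tolerance = 1e-9)
  }
  expect_equal(tr$tMI[M] + tr$tME[M], 1, tolerance = 1e-9)
  expect_equal(tr$tII[M] + tr$tIM[M], 1, tolerance = 1e-9)
  expect_identical(tr$tDM[M], 1)
  # ambiguity codes contribute to no residue count
  mx <- build_profile(protein_msa(c(x = "X", y = "A")))
  expect_equal(unname(mx$e_match[1, "A"]), 0.525)
})

test_that("a background model over one column scores zero bits", {
  m <- build_profile(protein_msa(c(x = "A")))
  m$e_match[1, ] <- m$background          # emissions = background
  m$trans$tME[1] <- 1; m$trans$tMI[1] <- 0  # always exit after the match
  expect_equal(forward_bitscore(m, "W"), 0, tolerance = 1e-12)
  expect_equal(viterbi_bitscore(m, "W"), 0, tolerance = 1e-12)
})

test_that("forward equals exhaustive path enumeration on small models", {
  for (case in 1:12) {
    M <- ((case - 1) %% 3) + 1
    mod <- random_ref_model(M, n_rows = 2 + (case %% 3), seed = 40 + case)
    for (L in 1:4) {
      q <- random_query(L, seed = 90 + case * 10 + L)
      orc <- oracle_phmm_scores(mod, q)
      expect_equal(forward_bitscore(mod, q), orc$forward, tolerance = 1e-6,
                   label = sprintf("forward M=%d L=%d", M, L))
      expect_equal(viterbi_bitscore(mod, q), orc$viterbi, tolerance = 1e-6,
                   label = sprintf("viterbi M=%d L=%d", M, L))
    }
  }
  # also a model built on a gapped alignment (non-trivial transitions)
  gapped <- protein_msa(c(a = "AC-D", b = "A-CD", c = "ACCD", d = "A--D"))
  mod <- build_profile(gapped)
  for (L in 1:4) {
    q <- random_query(L, seed = 400 + L)
    orc <- oracle_phmm_scores(mod, q)
    expect_equal(forward_bitscore(mod, q), orc$forward, tolerance = 1e-6)
  }
})

test_that("forward dominates Viterbi on random model/query pairs", {
  for (i in 1:100) {
    mod <- random_ref_model(2 + (i %% 7), n_rows = 2 + (i %% 4), seed = 1000 + i)
    q <- random_query(2 + (i %% 9), seed = 2000 + i)
    expect_gte(forward_bitscore(mod, q) + 1e-9, viterbi_bitscore(mod, q))
  }
})

test_that("scores are deterministic and invariant to query gaps and ids", {
  fam <- sim_family_aln(12, 0.6, seed = 9)$alignment
  mod <- build_profile(fam, model_id = "m", family_id = "F")
  q <- degap(unclass(fam)[3])
  expect_identical(forward_bitscore(mod, q), forward_bitscore(mod, q))
  gappy <- paste0(substr(q, 1, 10), "--..", substr(q, 11, nchar(q)))
  expect_identical(forward_bitscore(mod, gappy), forward_bitscore(mod, q))

  tab <- score_sequences(mod, c(idA = unname(q), idB = unname(q)))
  expect_equal(tab$bit_score[1], tab$bit_score[2])
  expect_identical(tab$family_id, c("F", "F"))
  expect_identical(nrow(score_sequences(mod, character())), 0L)
})

test_that("model-consistent sequences outscore random ones almost always", {
  fam <- sim_family_aln(15, 0.5, seed = 31)$alignment
  mod <- build_profile(fam)
  set.seed(77)
  wins <- 0L
  for (i in 1:200) {
    # sample a sequence along the match states from the model's emissions
    res <- vapply(seq_len(mod$M), function(k)
      sample(AA_ALPHABET, 1L, prob = mod$e_match[k, ]), character(1))
    s_mod <- paste(res, collapse = "")
    s_rand <- paste(sample(AA_ALPHABET, mod$M, replace = TRUE), collapse = "")
    if (forward_bitscore(mod, s_mod) > forward_bitscore(mod, s_rand))
      wins <- wins + 1L
  }
  expect_gte(wins, 190L)  # >= 95% of 200 trials
})
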