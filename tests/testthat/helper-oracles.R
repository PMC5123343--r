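# Independent oracles: brute-force implementations kept deliberately
# separate from the package's code paths.

# --- profile-HMM path enumeration ------------------------------------------
# Enumerates every state path through the reference model that consumes the
# query exactly, accumulating probability ratios against the i.i.d.
# background null.  Mirrors only the model DEFINITION (topology and
# parameters), not the DP.
oracle_phmm_scores <- function(model, residues) {
  q <- strsplit(toupper(gsub("[-.]", "", residues)), "")[[1]]
  L <- length(q)
  M <- model$M
  tr <- model$trans
  ratio <- function(k, i) {
    a <- match(q[i], AA_ALPHABET)
    if (is.na(a)) 1 else model$e_match[k, a] / model$background[a]
  }
  probs <- numeric(0)
  rec <- function(state, k, i, p) {
    if (p == 0) return(invisible())
    if (state == "M") {
      if (i == L) probs <<- c(probs, p * tr$tME[k])
      if (k < M) {
        if (i < L) {
          rec("M", k + 1L, i + 1L, p * tr$tMM[k] * ratio(k + 1L, i + 1L))
          rec("I", k, i + 1L, p * tr$tMI[k])
        }
        rec("D", k + 1L, i, p * tr$tMD[k])
      } else if (i < L) {
        rec("I", M, i + 1L, p * tr$tMI[M])
      }
    } else if (state == "I") {
      if (k < M) {
        if (i < L) {
          rec("I", k, i + 1L, p * tr$tII[k])
          rec("M", k + 1L, i + 1L, p * tr$tIM[k] * ratio(k + 1L, i + 1L))
        }
      } else {
        if (i == L) probs <<- c(probs, p * tr$tIM[M])
        if (i < L) rec("I", M, i + 1L, p * tr$tII[M])
      }
    } else {  # delete state D_k
      if (k < M) {
        if (i < L) rec("M", k + 1L, i + 1L, p * tr$tDM[k] * ratio(k + 1L, i + 1L))
        rec("D", k + 1L, i, p * tr$tDD[k])
      } else if (i == L) {
        probs <<- c(probs, p * tr$tDM[M])   # D_M -> E, probability 1
      }
    }
  }
  for (s in seq_len(M)) rec("M", s, 1L, (1 / M) * ratio(s, 1L))
  list(forward = log2(sum(probs)), viterbi = log2(max(probs)))
}

# --- exhaustive centroid search --------------------------------------------
# Split sizes for every edge via graph components (igraph), independent of
# the package's postorder bookkeeping.  Returns the minimum imbalance and
# the set of edges achieving it (as sorted "A|B" partition strings).
oracle_centroid <- function(tree) {
  nt <- length(tree$tip.label)
  g <- igraph::graph_from_edgelist(apply(tree$edge, 2L, as.character),
                                   directed = FALSE)
  res <- lapply(seq_len(nrow(tree$edge)), function(k) {
    gk <- igraph::delete_edges(g, igraph::get_edge_ids(
      g, as.character(tree$edge[k, ])))
    comp <- igraph::components(gk)$membership
    side <- names(comp)[comp == comp[[as.character(tree$edge[k, 2L])]]]
    tips_a <- sort(tree$tip.label[match(side, as.character(seq_len(nt)), nomatch = 0)])
    tips_b <- sort(setdiff(tree$tip.label, tips_a))
    list(imbalance = abs(length(tips_a) - length(tips_b)),
         split = canonical_split(tips_a, tips_b))
  })
  imb <- vapply(res, `[[`, numeric(1), "imbalance")
  list(min_imbalance = min(imb),
       best_splits = unique(vapply(res[imb == min(imb)], `[[`, character(1),
                                   "split")))
}

# canonical partition string: smaller side (ties: lexicographically
# smaller minimum label) first
canonical_split <- function(a, b) {
  if (length(a) < length(b) || (length(a) == length(b) && min(a) <= min(b)))
    paste(paste(sort(a), collapse = ","), paste(sort(b), collapse = ","), sep = "|")
  else
    paste(paste(sort(b), collapse = ","), paste(sort(a), collapse = ","), sep = "|")
}

# --- literal Family(q) evaluation ------------------------------------------
# Evaluates the assignment formula directly on a per-profile score table:
# per family, keep scores strictly above that family's threshold, take the
# max, then the argmax over families (lexicographic tie-break).
oracle_family_assign <- function(scores, thresholds) {
  # scores: data.frame(query_id, family_id, bit_score) -- one row per profile
  out <- list()
  for (q in unique(scores$query_id)) {
    sq <- scores[scores$query_id == q, ]
    best_fam <- NA_character_; best <- -Inf
    for (f in sort(unique(sq$family_id))) {
      cand <- sq$bit_score[sq$family_id == f]
      cand <- cand[cand > thresholds[[f]]]
      if (length(cand) == 0L) next
      m <- max(cand)
      if (m > best) { best <- m; best_fam <- f }
    }
    out[[q]] <- data.frame(query_id = q, family_id = best_fam,
                           bit_score = if (is.na(best_fam)) NA_real_ else best,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
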