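#' Scoring-backend configuration
#'
#' @param engine `"reference"` for the built-in profile-HMM engine, or
#'   `"hmmer"` for an external HMMER toolkit (`hmmbuild`/`hmmsearch` must
#'   be on the PATH).
#' @param gap_threshold A column is a match column iff its gap fraction is
#'   strictly below this value (default 0.5).
#' @param alpha Emission pseudocount weight (> 0, default 1).
#' @param background Named length-20 amino-acid background frequency
#'   vector summing to 1; default uniform 1/20.
#' @param hmmer_evalue Reporting E-value passed to `hmmsearch -E`; very
#'   permissive by default so weak hits remain observable for threshold
#'   sweeps.
#' @param hmmer_extra Extra command-line options for `hmmsearch` (e.g.
#'   `"--max"` to disable the acceleration filters).
#' @return An object of class `backend_config`.
#' @export
backend_config <- function(engine = c("reference", "hmmer"),
                           gap_threshold = 0.5, alpha = 1,
                           background = NULL,
                           hmmer_evalue = 1e6, hmmer_extra = character()) {
  engine <- match.arg(engine)
  stopifnot(gap_threshold > 0, gap_threshold < 1, alpha > 0)
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20L), AA_ALPHABET)
  } else {
    stopifnot(length(background) == 20L, abs(sum(background) - 1) < 1e-9,
              all(background > 0))
    if (is.null(names(background))) names(background) <- AA_ALPHABET
    background <- background[AA_ALPHABET]
  }
  structure(list(engine = engine, gap_threshold = gap_threshold,
                 alpha = alpha, background = background,
                 hmmer_evalue = hmmer_evalue, hmmer_extra = hmmer_extra),
            class = "backend_config")
}

#' Match-column mask of an alignment
#'
#' Column `c` is a match (consensus) column iff its gap fraction is
#' strictly below `cfg$gap_threshold`.
#'
#' @param aln A [protein_msa].
#' @param cfg A [backend_config].
#' @return Logical vector over columns.
#' @export
match_columns <- function(aln, cfg = backend_config()) {
  stopifnot(inherits(aln, "protein_msa"))
  m <- as.matrix.protein_msa(aln)
  gap_frac <- colMeans(is_gap(m))
  mask <- gap_frac < cfg$gap_threshold
  if (!any(mask))
    stop("no consensus columns: every column's gap fraction >= ",
         cfg$gap_threshold, call. = FALSE)
  mask
}

# Encode a residue string as 0-based indices into AA_ALPHABET; ambiguity
# codes and unknown letters become -1 (scored at background).
encode_residues <- function(s) {
  v <- strsplit(toupper(gsub("[-.]", "", s)), "", fixed = TRUE)[[1]]
  code <- match(v, AA_ALPHABET) - 1L
  code[is.na(code)] <- -1L
  code
}

#' Build a profile HMM on an alignment (reference engine)
#'
#' The model has one match state per consensus column (`M` states), insert
#' states `I_1..I_M`, delete states `D_2..D_M`, uniform free entry into any
#' match state, and exit-to-end transitions estimated from the data.
#' Match emissions use the pseudocount rule
#' `e_m(a) = (c_a + alpha * f_bg(a)) / (sum_b c_b + alpha)` with uniform
#' sequence weights; ambiguity codes contribute to no residue count.
#' Insert emissions equal the background.  Transitions are estimated from
#' per-sequence state paths with pseudocount 1 per allowed transition.
#'
#' @param aln A [protein_msa].
#' @param cfg A [backend_config] (`engine` is ignored here; this always
#'   builds a reference model — see [build_hmmer_profile] for the adapter).
#' @param model_id,family_id Identifiers stored in the model.
#' @param mean_identity,size Optional subset metadata to carry along.
#' @return An object of class `c("ref_profile_hmm", "profile_hmm")`.
#' @export
build_profile <- function(aln, cfg = backend_config(), model_id = "m1",
                          family_id = NA_character_,
                          mean_identity = NA_real_, size = length(aln)) {
  stopifnot(inherits(aln, "protein_msa"))
  mask <- match_columns(aln, cfg)
  m <- as.matrix.protein_msa(aln)
  mc <- which(mask)
  M <- length(mc)
  bg <- cfg$background

  # --- match emissions -------------------------------------------------
  e_match <- matrix(0, nrow = M, ncol = 20L,
                    dimnames = list(NULL, AA_ALPHABET))
  n_res <- 0L
  for (k in seq_len(M)) {
    col <- m[, mc[k]]
    counts <- table(factor(col[col %in% AA_ALPHABET], levels = AA_ALPHABET))
    n_res <- n_res + sum(counts)
    e_match[k, ] <- (as.numeric(counts) + cfg$alpha * bg) /
      (sum(counts) + cfg$alpha)
  }
  if (n_res == 0L)
    stop("alignment has zero usable residues in match columns", call. = FALSE)

  # --- transition counts from per-sequence state paths -----------------
  cMM <- cMI <- cMD <- cME <- numeric(M)
  cII <- cIM <- numeric(M)          # cIM[M] holds I_M -> E
  cDM <- cDD <- numeric(M)
  # residue counts in the insert region between match columns k and k+1
  ins_between <- function(row, k) {
    lo <- mc[k]; hi <- if (k < M) mc[k + 1L] else msa_width(aln) + 1L
    if (hi - lo <= 1L) return(0L)
    seg <- row[(lo + 1L):(hi - 1L)]
    sum(!is_gap(seg))
  }
  for (r in seq_len(nrow(m))) {
    row <- m[r, ]
    present <- !is_gap(row[mc])
    if (!any(present)) next
    s <- which(present)[1L]
    e <- which(present)[length(which(present))]
    cur_match <- TRUE  # state at column s is M_s
    if (s < e) {
      for (k in s:(e - 1L)) {
        nxt_match <- present[k + 1L]
        ni <- if (cur_match) ins_between(row, k) else 0L
        if (cur_match && ni > 0L && nxt_match) {
          cMI[k] <- cMI[k] + 1
          if (ni > 1L) cII[k] <- cII[k] + (ni - 1L)
          cIM[k] <- cIM[k] + 1
        } else if (cur_match) {
          if (nxt_match) cMM[k] <- cMM[k] + 1 else cMD[k] <- cMD[k] + 1
        } else {
          if (nxt_match) cDM[k] <- cDM[k] + 1 else cDD[k] <- cDD[k] + 1
        }
        cur_match <- nxt_match
      }
    }
    cME[e] <- cME[e] + 1
  }

  # --- normalize with pseudocount 1 per allowed transition -------------
  tMM <- tMI <- tMD <- tME <- numeric(M)
  tII <- tIM <- numeric(M)
  tDM <- tDD <- numeric(M)
  for (k in seq_len(M)) {
    if (k < M) {
      tot <- cMM[k] + cMI[k] + cMD[k] + cME[k] + 4
      tMM[k] <- (cMM[k] + 1) / tot
      tMI[k] <- (cMI[k] + 1) / tot
      tMD[k] <- (cMD[k] + 1) / tot
      tME[k] <- (cME[k] + 1) / tot
      toti <- cII[k] + cIM[k] + 2
      tII[k] <- (cII[k] + 1) / toti
      tIM[k] <- (cIM[k] + 1) / toti
      totd <- cDM[k] + cDD[k] + 2
      tDM[k] <- (cDM[k] + 1) / totd
      tDD[k] <- (cDD[k] + 1) / totd
    } else {
      tot <- cMI[M] + cME[M] + 2       # M_M -> {I_M, E}
      tMI[M] <- (cMI[M] + 1) / tot
      tME[M] <- (cME[M] + 1) / tot
      toti <- cII[M] + cIM[M] + 2      # I_M -> {I_M, E}
      tII[M] <- (cII[M] + 1) / toti
      tIM[M] <- (cIM[M] + 1) / toti    # stored I_M -> E
      tDM[M] <- 1                      # D_M -> E
      tDD[M] <- 0
    }
  }

  structure(list(model_id = model_id, family_id = family_id,
                 subset_ids = msa_ids(aln), M = M, match_cols = mc,
                 e_match = e_match, background = bg,
                 trans = list(tMM = tMM, tMI = tMI, tMD = tMD, tME = tME,
                              tII = tII, tIM = tIM, tDM = tDM, tDD = tDD),
                 size = size, mean_identity = mean_identity),
            class = c("ref_profile_hmm", "profile_hmm"))
}

#' @export
print.ref_profile_hmm <- function(x, ...) {
  cat(sprintf("ref_profile_hmm %s (family %s): %d match states, %d sequences\n",
              x$model_id, x$family_id, x$M, length(x$subset_ids)))
  invisible(x)
}

#' Forward bit score of a residue string against a reference model
#'
#' `bits = log2 P_fwd(q | model) - log2 P_null(q)` with an i.i.d.
#' background null.  The alignment is local with respect to the model
#' (uniform free entry to any match state, trained exit) and global with
#' respect to the query.  Gap characters in the query are stripped on
#' entry; ambiguity codes are emitted at background frequency.
#'
#' @param model A `ref_profile_hmm`.
#' @param residues Amino-acid string.
#' @return Bit score (finite for any nonempty query).
#' @export
forward_bitscore <- function(model, residues) {
  stopifnot(inherits(model, "ref_profile_hmm"))
  q <- encode_residues(residues)
  if (length(q) == 0L) stop("empty query after gap removal", call. = FALSE)
  phmm_score_cpp(model$e_match, unname(model$background),
                 model$trans$tMM, model$trans$tMI, model$trans$tMD,
                 model$trans$tME, model$trans$tII, model$trans$tIM,
                 model$trans$tDM, model$trans$tDD, q, FALSE)
}

#' Viterbi bit score (best single path) under the same model and null
#'
#' @inheritParams forward_bitscore
#' @return Bit score of the best state path (always `<=` the forward
#'   score).
#' @export
viterbi_bitscore <- function(model, residues) {
  stopifnot(inherits(model, "ref_profile_hmm"))
  q <- encode_residues(residues)
  if (length(q) == 0L) stop("empty query after gap removal", call. = FALSE)
  phmm_score_cpp(model$e_match, unname(model$background),
                 model$trans$tMM, model$trans$tMI, model$trans$tMD,
                 model$trans$tME, model$trans$tII, model$trans$tIM,
                 model$trans$tDM, model$trans$tDD, q, TRUE)
}

#' Score query sequences against one profile model
#'
#' @param model A `profile_hmm` (reference or HMMER-backed).
#' @param queries Named character vector of de-gapped sequences.
#' @param ... Passed to engine-specific methods.
#' @return data.frame with columns `query_id`, `model_id`, `family_id`,
#'   `bit_score`; queries for which the engine reports no hit are omitted
#'   (the reference engine always reports a finite score).
#' @export
score_sequences <- function(model, queries, ...) UseMethod("score_sequences")

#' @export
score_sequences.ref_profile_hmm <- function(model, queries, ...) {
  if (length(queries) == 0L)
    return(data.frame(query_id = character(), model_id = character(),
                      family_id = character(), bit_score = numeric(),
                      stringsAsFactors = FALSE))
  if (is.null(names(queries)) || anyDuplicated(names(queries)))
    stop("queries must have unique names", call. = FALSE)
  enc <- lapply(unname(queries), encode_residues)
  if (any(lengths(enc) == 0L))
    stop("empty query after gap removal", call. = FALSE)
  bits <- phmm_score_batch_cpp(model$e_match, unname(model$background),
                               model$trans$tMM, model$trans$tMI,
                               model$trans$tMD, model$trans$tME,
                               model$trans$tII, model$trans$tIM,
                               model$trans$tDM, model$trans$tDD, enc, FALSE)
  data.frame(query_id = names(queries), model_id = model$model_id,
             family_id = model$family_id, bit_score = bits,
             stringsAsFactors = FALSE)
}
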