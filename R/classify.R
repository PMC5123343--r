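#' Inclusion-threshold policy
#'
#' With mode `"gathering-cutoff"`, a hit to family `i` counts only if its
#' bit score strictly exceeds `scale * g_i`, where `g_i` is the family's
#' curated gathering-cutoff threshold; `scale` in `[0, 1]` sweeps from "no
#' minimum threshold" (0, the aggressive setting) to the full cutoff
#' (1, the conservative setting).  Mode `"none"` is equivalent to scale 0
#' for every family.
#'
#' @param mode `"gathering-cutoff"` or `"none"`.
#' @param scale Fraction in `[0, 1]` multiplying each family threshold.
#' @return An object of class `threshold_policy`.
#' @export
threshold_policy <- function(mode = c("gathering-cutoff", "none"), scale = 1.0) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(scale), length(scale) == 1L, scale >= 0, scale <= 1)
  if (mode == "none") scale <- 0
  structure(list(mode = mode, scale = scale), class = "threshold_policy")
}

effective_thresholds <- function(db, policy) {
  g <- vapply(db$ensembles, `[[`, numeric(1), "threshold")
  if (policy$mode == "none") g[] <- 0 else g <- policy$scale * g
  g
}

#' Score queries against every profile of every ensemble
#'
#' One scoring pass supports the whole precision/recall threshold sweep:
#' the table retains, per query and family, the best raw bit score over
#' the family's ensemble together with the winning profile.  Absence of a
#' (query, family) row means the engine reported no hit (treated as
#' `-Inf` downstream, never as 0).
#'
#' @param db An [ensemble_db].
#' @param queries Named character vector of de-gapped query sequences
#'   (unique ids).
#' @return data.frame with columns `query_id`, `family_id`, `model_id`,
#'   `bit_score` (best over the family's ensemble).
#' @export
score_table <- function(db, queries) {
  stopifnot(inherits(db, "ensemble_db"))
  if (length(db$ensembles) == 0L) stop("empty ensemble database", call. = FALSE)
  if (is.null(names(queries)) || anyDuplicated(names(queries)))
    stop("queries must have unique ids", call. = FALSE)
  per_model <- list()
  for (e in db$ensembles) {
    for (mod in e$models) {
      per_model[[length(per_model) + 1L]] <-
        score_sequences(mod, queries, cfg = db$backend)
    }
  }
  tab <- do.call(rbind, per_model)
  if (is.null(tab) || nrow(tab) == 0L)
    return(data.frame(query_id = character(), family_id = character(),
                      model_id = character(), bit_score = numeric(),
                      stringsAsFactors = FALSE))
  # keep the best-scoring profile per (query, family)
  tab <- tab[order(tab$query_id, tab$family_id, -tab$bit_score,
                   tab$model_id), , drop = FALSE]
  best <- !duplicated(tab[, c("query_id", "family_id")])
  out <- tab[best, c("query_id", "family_id", "model_id", "bit_score")]
  rownames(out) <- NULL
  out
}

#' Turn a score table into assignments under a threshold policy
#'
#' Implements the assignment rule: for each family `i`, let
#' `m_i = max_j { BS(q, h_ij) : BS(q, h_ij) > scale * g_i }`; the query is
#' assigned to `argmax_i m_i`, or left unassigned when every family's
#' candidate set is empty.  Because `g_i` is constant within a family,
#' gating the per-family best score is equivalent to gating every profile.
#' Ties on the best score are broken by the lexicographically smallest
#' family id.
#'
#' @param tab A [score_table] data.frame (raw scores).
#' @param thresholds Named numeric vector of effective per-family
#'   thresholds (already scaled).
#' @param query_ids All query ids (so queries with no hits still get an
#'   unassigned row).
#' @return data.frame with one row per query: `query_id`, `family_id`
#'   (`NA` when unassigned), `bit_score`, `model_id`, `runner_up`,
#'   `runner_up_score`.
#' @export
assign_from_scores <- function(tab, thresholds, query_ids) {
  keep <- tab$bit_score > thresholds[tab$family_id]
  tab <- tab[keep, , drop = FALSE]
  out <- data.frame(query_id = query_ids, family_id = NA_character_,
                    bit_score = NA_real_, model_id = NA_character_,
                    runner_up = NA_character_, runner_up_score = NA_real_,
                    stringsAsFactors = FALSE)
  if (nrow(tab) > 0L) {
    tab <- tab[order(tab$query_id, -tab$bit_score, tab$family_id), , drop = FALSE]
    first <- !duplicated(tab$query_id)
    win <- tab[first, , drop = FALSE]
    i <- match(win$query_id, out$query_id)
    out$family_id[i] <- win$family_id
    out$bit_score[i] <- win$bit_score
    out$model_id[i] <- win$model_id
    rest <- tab[!first, , drop = FALSE]
    if (nrow(rest) > 0L) {
      second <- rest[!duplicated(rest$query_id), , drop = FALSE]
      j <- match(second$query_id, out$query_id)
      out$runner_up[j] <- second$family_id
      out$runner_up_score[j] <- second$bit_score
    }
  }
  out
}

#' Classify a batch of query sequences
#'
#' @param queries Named character vector of de-gapped sequences (unique
#'   ids).
#' @param db An [ensemble_db].
#' @param policy A [threshold_policy].
#' @param tab Optionally a precomputed [score_table] (to re-gate without
#'   re-scoring).
#' @return Assignment data.frame, one row per query (see
#'   [assign_from_scores]).
#' @export
classify_batch <- function(queries, db, policy = threshold_policy(), tab = NULL) {
  stopifnot(inherits(db, "ensemble_db"), inherits(policy, "threshold_policy"))
  if (is.null(names(queries)) || anyDuplicated(names(queries)))
    stop("queries must have unique ids", call. = FALSE)
  if (is.null(tab)) tab <- score_table(db, queries)
  assign_from_scores(tab, effective_thresholds(db, policy), names(queries))
}

#' Classify a single query sequence
#'
#' @param q Residue string (gaps stripped on entry), or a length-1 named
#'   character vector.
#' @param db An [ensemble_db].
#' @param policy A [threshold_policy].
#' @return One-row assignment data.frame.
#' @export
classify <- function(q, db, policy = threshold_policy()) {
  if (is.null(names(q))) names(q) <- "query"
  stopifnot(length(q) == 1L)
  q <- stats::setNames(toupper(gsub("[-.]", "", q)), names(q))
  if (!nzchar(q)) stop("empty query after gap removal", call. = FALSE)
  classify_batch(q, db, policy)
}

#' @rdname classify_batch
#' @param object An [ensemble_db].
#' @param ... Unused.
#' @export
predict.ensemble_db <- function(object, queries,
                                policy = threshold_policy(), ...) {
  classify_batch(queries, object, policy)
}
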