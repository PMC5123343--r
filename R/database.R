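#' A protein family record
#'
#' Bundles a family's curated seed alignment with its id, its
#' gathering-cutoff bit-score threshold, and (optionally) a guide tree.
#'
#' @param family_id Nonempty string, unique within a database.
#' @param seed A [protein_msa] seed alignment.
#' @param threshold Gathering-cutoff bit score (finite, >= 0).  Families
#'   without a curated cutoff use 0, i.e. no minimum.
#' @param guide_tree Optional `phylo` guide tree whose tip labels match the
#'   seed row ids, or `NULL` to estimate one internally.
#' @return An object of class `family_record`.
#' @export
family_record <- function(family_id, seed, threshold = 0, guide_tree = NULL) {
  stopifnot(is.character(family_id), length(family_id) == 1L, nzchar(family_id))
  stopifnot(inherits(seed, "protein_msa"))
  threshold <- as.numeric(threshold)
  if (!is.finite(threshold) || threshold < 0)
    stop("threshold must be a finite bit score >= 0", call. = FALSE)
  if (!is.null(guide_tree)) {
    stopifnot(inherits(guide_tree, "phylo"))
    if (!setequal(guide_tree$tip.label, msa_ids(seed)))
      stop("guide tree tips do not match seed alignment ids for family ",
           family_id, call. = FALSE)
  }
  structure(list(family_id = family_id, seed = seed,
                 threshold = threshold, guide_tree = guide_tree),
            class = "family_record")
}

#' @export
print.family_record <- function(x, ...) {
  cat(sprintf("family %s: %d sequences x %d columns, threshold %.1f bits%s\n",
              x$family_id, length(x$seed), msa_width(x$seed), x$threshold,
              if (is.null(x$guide_tree)) "" else ", guide tree supplied"))
  invisible(x)
}

#' A database of protein families
#'
#' @param families List of [family_record] objects with unique ids.
#' @return An object of class `family_db` (a named list of records).
#' @export
family_db <- function(families) {
  if (length(families) < 1L) stop("a family database needs >= 1 family", call. = FALSE)
  stopifnot(all(vapply(families, inherits, logical(1), "family_record")))
  ids <- vapply(families, `[[`, character(1), "family_id")
  if (anyDuplicated(ids))
    stop("duplicate family ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(families) <- ids
  structure(families, class = "family_db")
}

#' @export
print.family_db <- function(x, ...) {
  sizes <- vapply(x, function(f) length(f$seed), integer(1))
  cat(sprintf("family_db: %d families, %d sequences total\n", length(x), sum(sizes)))
  invisible(x)
}

#' @export
`[.family_db` <- function(x, i) family_db(unclass(x)[i])

#' Load a family database from a manifest
#'
#' The manifest is a TSV with columns `family_id`, `alignment_path`, and
#' optionally `tree_path` and `threshold`.  Relative paths are resolved
#' against the manifest's directory.  A missing threshold defaults to 0
#' (no gathering cutoff); a missing tree path means the guide tree will be
#' estimated when needed.
#'
#' @param manifest_path Path to the manifest TSV.
#' @return A [family_db].
#' @export
load_family_database <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop("no such manifest: ", manifest_path, call. = FALSE)
  tab <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  need <- c("family_id", "alignment_path")
  if (!all(need %in% names(tab)))
    stop("manifest must have columns family_id and alignment_path", call. = FALSE)
  if (anyDuplicated(tab$family_id))
    stop("duplicate family_id in manifest: ",
         paste(unique(tab$family_id[duplicated(tab$family_id)]), collapse = ", "),
         call. = FALSE)
  base <- dirname(normalizePath(manifest_path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  recs <- lapply(seq_len(nrow(tab)), function(i) {
    fid <- tab$family_id[i]
    aln <- tryCatch(read_alignment(resolve(tab$alignment_path[i])),
                    error = function(e) stop("family ", fid, ": ",
                                             conditionMessage(e), call. = FALSE))
    tree <- NULL
    if ("tree_path" %in% names(tab) && !is.na(tab$tree_path[i]) &&
        nzchar(tab$tree_path[i])) {
      tree <- ape::read.tree(resolve(tab$tree_path[i]))
      if (is.null(tree)) stop("family ", fid, ": unreadable tree", call. = FALSE)
    }
    thr <- 0
    if ("threshold" %in% names(tab) && !is.na(tab$threshold[i]))
      thr <- as.numeric(tab$threshold[i])
    family_record(fid, aln, threshold = thr, guide_tree = tree)
  })
  family_db(recs)
}

#' Read query sequences from FASTA
#'
#' Queries are de-gapped on entry and uppercased; ids must be unique.
#'
#' @param path FASTA file of amino-acid sequences.
#' @return Named character vector of residue strings.
#' @export
read_queries <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no query sequences in ", path, call. = FALSE)
  seqs <- toupper(degap(as.character(set)))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(names(seqs)))
    stop("duplicate query ids in ", path, call. = FALSE)
  if (any(!nzchar(seqs)))
    stop("queries empty after gap removal: ",
         paste(names(seqs)[!nzchar(seqs)], collapse = ", "), call. = FALSE)
  seqs
}
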