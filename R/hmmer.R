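# Adapter to an external HMMER-compatible toolkit.  Models are built with
# `hmmbuild` (default mode) and queries scored with `hmmsearch --tblout`,
# taking the full-sequence bit score.  A very permissive reporting
# threshold keeps weak hits observable for threshold sweeps.

hmmer_available <- function() {
  nzchar(Sys.which("hmmbuild")) && nzchar(Sys.which("hmmsearch"))
}

run_tool <- function(cmd, args) {
  out <- suppressWarnings(system2(cmd, args, stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop(cmd, " failed (exit ", status, "):\n",
         paste(utils::tail(out, 15L), collapse = "\n"), call. = FALSE)
  out
}

#' Build a profile HMM with the external HMMER toolkit
#'
#' @param aln A [protein_msa].
#' @param cfg A [backend_config].
#' @param model_id,family_id Identifiers stored in the model.
#' @param hmm_dir Directory for the `.hmm` file (created if needed).
#' @param mean_identity,size Subset metadata to carry along.
#' @return An object of class `c("hmmer_profile_hmm", "profile_hmm")`
#'   holding the model file path as an opaque handle.
#' @export
build_hmmer_profile <- function(aln, cfg = backend_config(engine = "hmmer"),
                                model_id = "m1", family_id = NA_character_,
                                hmm_dir = tempdir(),
                                mean_identity = NA_real_, size = length(aln)) {
  if (!hmmer_available())
    stop("hmmbuild/hmmsearch not found on PATH", call. = FALSE)
  dir.create(hmm_dir, showWarnings = FALSE, recursive = TRUE)
  safe <- gsub("[^A-Za-z0-9._-]", "_", model_id)
  aln_path <- file.path(hmm_dir, paste0(safe, ".sto"))
  hmm_path <- file.path(hmm_dir, paste0(safe, ".hmm"))
  write_alignment(aln, aln_path, format = "stockholm")
  run_tool("hmmbuild", c("--amino", "-n", shQuote(safe),
                         shQuote(hmm_path), shQuote(aln_path)))
  unlink(aln_path)
  structure(list(model_id = model_id, family_id = family_id,
                 subset_ids = msa_ids(aln), hmm_path = hmm_path,
                 size = size, mean_identity = mean_identity),
            class = c("hmmer_profile_hmm", "profile_hmm"))
}

#' @export
print.hmmer_profile_hmm <- function(x, ...) {
  cat(sprintf("hmmer_profile_hmm %s (family %s): %d sequences, model %s\n",
              x$model_id, x$family_id, length(x$subset_ids), x$hmm_path))
  invisible(x)
}

parse_tblout <- function(lines) {
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(data.frame(query_id = character(), bit_score = numeric(),
                      stringsAsFactors = FALSE))
  fields <- strsplit(trimws(lines), "\\s+")
  data.frame(query_id = vapply(fields, `[[`, character(1), 1L),
             bit_score = as.numeric(vapply(fields, `[[`, character(1), 6L)),
             stringsAsFactors = FALSE)
}

#' @export
score_sequences.hmmer_profile_hmm <- function(model, queries,
                                              cfg = backend_config(engine = "hmmer"),
                                              ...) {
  if (length(queries) == 0L)
    return(data.frame(query_id = character(), model_id = character(),
                      family_id = character(), bit_score = numeric(),
                      stringsAsFactors = FALSE))
  if (is.null(names(queries)) || anyDuplicated(names(queries)))
    stop("queries must have unique names", call. = FALSE)
  if (!file.exists(model$hmm_path))
    stop("missing model file: ", model$hmm_path, call. = FALSE)
  qfa <- tempfile(fileext = ".fasta")
  tbl <- tempfile(fileext = ".tbl")
  on.exit(unlink(c(qfa, tbl)), add = TRUE)
  writeLines(paste0(">", names(queries), "\n", degap(queries)), qfa)
  run_tool("hmmsearch", c("--tblout", shQuote(tbl),
                          "-E", format(cfg$hmmer_evalue, scientific = FALSE),
                          cfg$hmmer_extra, "--noali",
                          shQuote(model$hmm_path), shQuote(qfa)))
  hits <- parse_tblout(readLines(tbl, warn = FALSE))
  # one best full-sequence score per query; queries without a hit omitted
  if (nrow(hits) > 0L) {
    hits <- hits[order(hits$query_id, -hits$bit_score), , drop = FALSE]
    hits <- hits[!duplicated(hits$query_id), , drop = FALSE]
  }
  data.frame(query_id = hits$query_id, model_id = model$model_id,
             family_id = model$family_id, bit_score = hits$bit_score,
             stringsAsFactors = FALSE)
}
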