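#' @useDynLib hmmensemble, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Gap characters accepted in alignments.  '-' and '.' are treated
# identically as gaps everywhere; both are preserved verbatim on I/O.
.GAP_CHARS <- c("-", ".")

# The 20 standard amino acids, in the fixed column order used by the
# reference engine's emission matrices.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Ambiguity / non-standard codes kept verbatim in storage; they never count
# as identity matches and are scored at background frequency.
AA_AMBIGUOUS <- c("B", "Z", "X", "U", "O", "J", "*")

#' Construct a protein multiple sequence alignment
#'
#' An alignment is stored as a named character vector of equal-length
#' aligned strings.  Residues are uppercased on construction; gap
#' characters (`-` and `.`) are preserved as given.
#'
#' @param seqs Named character vector of aligned sequences.
#' @return An object of class `protein_msa`.
#' @export
protein_msa <- function(seqs) {
  if (!is.character(seqs) || length(seqs) < 1L)
    stop("an alignment needs at least one sequence", call. = FALSE)
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every row must have a nonempty id", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate row ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  w <- nchar(seqs)
  if (length(unique(w)) != 1L)
    stop("ragged alignment: row lengths ", paste(sort(unique(w)), collapse = ", "),
         call. = FALSE)
  if (w[1] == 0L)
    stop("alignment has zero columns", call. = FALSE)
  out <- toupper(seqs)
  names(out) <- ids
  class(out) <- "protein_msa"
  out
}

#' @export
print.protein_msa <- function(x, ...) {
  cat(sprintf("protein_msa: %d sequences x %d columns\n", length(x), msa_width(x)))
  show <- utils::head(seq_along(x), 6L)
  for (i in show) {
    s <- unclass(x)[i]
    cat(sprintf("  %-20s %s%s\n", names(s),
                substr(s, 1, 50), if (nchar(s) > 50) "..." else ""))
  }
  if (length(x) > 6L) cat(sprintf("  ... and %d more\n", length(x) - 6L))
  invisible(x)
}

#' Alignment width (number of columns)
#' @param aln A `protein_msa`.
#' @export
msa_width <- function(aln) nchar(unclass(aln)[[1]])

#' Row ids of an alignment
#' @param aln A `protein_msa`.
#' @export
msa_ids <- function(aln) names(aln)

#' @export
as.matrix.protein_msa <- function(x, ...) {
  m <- do.call(rbind, strsplit(unclass(x), "", fixed = TRUE))
  rownames(m) <- names(x)
  m
}

#' Remove gap characters from sequences
#'
#' @param x Character vector (aligned rows or raw sequences).
#' @return Character vector with `-` and `.` removed; names preserved.
#' @export
degap <- function(x) {
  out <- gsub("[-.]", "", unclass(x))
  names(out) <- names(x)
  out
}

is_gap <- function(m) m == "-" | m == "."

#' Read a protein multiple sequence alignment
#'
#' Supports aligned FASTA and the Pfam Stockholm dialect.  Stockholm
#' markup lines (`#=GF`, `#=GC`, `#=GS`, `#=GR`) are ignored; sequence
#' lines split across blocks are concatenated.  Row order is preserved and
#' residues are uppercased; both `-` and `.` are retained as gaps.
#'
#' @param path File path.
#' @param format `"auto"` (sniff first non-blank character), `"fasta"` or
#'   `"stockholm"`.
#' @return A [protein_msa].
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    first <- readLines(path, n = 50L, warn = FALSE)
    first <- first[nzchar(trimws(first))]
    if (length(first) == 0L) stop("empty alignment file: ", path, call. = FALSE)
    format <- if (startsWith(first[1], "# STOCKHOLM") ) "stockholm"
              else if (startsWith(first[1], ">")) "fasta"
              else stop("cannot determine format of ", path, call. = FALSE)
  }
  if (format == "fasta") {
    set <- tryCatch(Biostrings::readBStringSet(path),
                    error = function(e) stop("cannot parse FASTA ", path, ": ",
                                             conditionMessage(e), call. = FALSE))
    if (length(set) == 0L) stop("empty alignment file: ", path, call. = FALSE)
    seqs <- as.character(set)
    names(seqs) <- sub("\\s.*$", "", names(set))
    protein_msa(seqs)
  } else {
    read_stockholm(path)
  }
}

read_stockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty alignment file: ", path, call. = FALSE)
  seqs <- character()
  for (ln in lines) {
    if (startsWith(ln, "#") || startsWith(ln, "//")) next
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2L)
      stop("malformed Stockholm sequence line: ", ln, call. = FALSE)
    id <- parts[1]
    if (id %in% names(seqs)) {
      seqs[[id]] <- paste0(seqs[[id]], parts[2])  # interleaved blocks
    } else {
      seqs[[id]] <- parts[2]
    }
  }
  if (length(seqs) == 0L) stop("no sequences in Stockholm file: ", path, call. = FALSE)
  protein_msa(seqs)
}

#' Write an alignment to disk
#'
#' @param aln A [protein_msa].
#' @param path Output file path.
#' @param format `"fasta"` or `"stockholm"`.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  stopifnot(inherits(aln, "protein_msa"))
  if (format == "fasta") {
    set <- Biostrings::BStringSet(unclass(aln))
    Biostrings::writeXStringSet(set, filepath = path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# STOCKHOLM 1.0", con)
    pad <- max(nchar(names(aln)))
    writeLines(sprintf(paste0("%-", pad, "s %s"), names(aln), unclass(aln)), con)
    writeLines("//", con)
  }
  invisible(path)
}

#' Restrict an alignment to a subset of its rows
#'
#' Rows are restricted to `subset` keeping the original row order, then
#' columns that are gaps in every retained row are removed; all other
#' columns are untouched.
#'
#' @param aln A [protein_msa].
#' @param subset Character vector of row ids (nonempty, all present).
#' @return A [protein_msa] on the subset.
#' @export
induced_alignment <- function(aln, subset) {
  stopifnot(inherits(aln, "protein_msa"))
  subset <- unique(as.character(subset))
  if (length(subset) == 0L) stop("empty subset", call. = FALSE)
  missing <- setdiff(subset, msa_ids(aln))
  if (length(missing) > 0L)
    stop("ids not in alignment: ", paste(missing, collapse = ", "), call. = FALSE)
  keep <- msa_ids(aln)[msa_ids(aln) %in% subset]
  m <- as.matrix.protein_msa(aln)[keep, , drop = FALSE]
  all_gap <- colSums(!is_gap(m)) == 0L
  m <- m[, !all_gap, drop = FALSE]
  if (ncol(m) == 0L) stop("induced alignment has zero columns", call. = FALSE)
  seqs <- apply(m, 1L, paste, collapse = "")
  names(seqs) <- keep
  protein_msa(seqs)
}
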