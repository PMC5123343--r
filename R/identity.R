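#' Pairwise sequence identity of two aligned rows
#'
#' Identity is the number of columns where both rows carry the same
#' standard amino acid, divided by the number of columns where both rows
#' are non-gap.  Ambiguity codes (B, Z, X, U, O, J) never count as matches,
#' though they do count toward the shared-column denominator.  Pairs with
#' no mutually non-gap column score 0.
#'
#' @param a,b Aligned rows (strings of equal length).
#' @return Fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("aligned rows differ in length (", nchar(a), " vs ", nchar(b), ")",
         call. = FALSE)
  va <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  vb <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  shared <- !is_gap(va) & !is_gap(vb)
  if (!any(shared)) return(0)
  match <- shared & va == vb & va %in% AA_ALPHABET
  sum(match) / sum(shared)
}

# Identity for many pairs at once on a pre-split character matrix.
# pairs: 2-column integer matrix of row indices.
pairwise_identity_rows <- function(m, pairs) {
  gaps <- is_gap(m)
  std <- matrix(m %in% AA_ALPHABET, nrow = nrow(m))
  vapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    shared <- !gaps[i, ] & !gaps[j, ]
    ns <- sum(shared)
    if (ns == 0L) return(0)
    sum(shared & m[i, ] == m[j, ] & std[i, ]) / ns
  }, numeric(1))
}

#' Mean pairwise sequence identity of an alignment
#'
#' The exact mean over all unordered row pairs when the alignment has at
#' most `exact_limit` rows; above that, the mean over `n_sample` distinct
#' pairs sampled without replacement (uses the current RNG stream, so seed
#' upstream for reproducibility).  A single-row alignment has identity 1.
#'
#' @param aln A [protein_msa].
#' @param exact_limit Row count up to which all pairs are enumerated.
#' @param n_sample Number of pairs sampled above `exact_limit`.
#' @return Fraction in `[0, 1]`.
#' @export
mean_pairwise_identity <- function(aln, exact_limit = 100L, n_sample = 1000L) {
  stopifnot(inherits(aln, "protein_msa"))
  n <- length(aln)
  if (n < 2L) return(1)
  m <- as.matrix.protein_msa(aln)
  n_pairs <- n * (n - 1) / 2
  if (n <= exact_limit) {
    pairs <- t(utils::combn(n, 2L))
  } else {
    take <- min(n_sample, n_pairs)
    idx <- sample.int(n_pairs, take)  # without replacement
    # map linear index 1..n(n-1)/2 to (i, j), i < j, column-major over j
    j <- ceiling((1 + sqrt(1 + 8 * idx)) / 2)
    i <- idx - (j - 1) * (j - 2) / 2
    pairs <- cbind(as.integer(i), as.integer(j))
  }
  mean(pairwise_identity_rows(m, pairs))
}
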