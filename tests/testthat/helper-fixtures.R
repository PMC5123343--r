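# Shared fixtures, all generated in code.

# A small hand-made alignment with known pairwise identities.
toy_alignment <- function() {
  protein_msa(c(a = "ACDE-G", b = "ACDE-G", c = "ACFEHG", d = "A-FEHG"))
}

# Perfectly balanced tree over n = 2^k leaves (unit branch lengths).
balanced_tree <- function(n, labels = sprintf("s%02d", seq_len(n))) {
  build <- function(labs) {
    if (length(labs) == 1L) return(paste0(labs, ":1"))
    half <- length(labs) / 2
    sprintf("(%s,%s):1", build(labs[seq_len(half)]), build(labs[-seq_len(half)]))
  }
  ape::read.tree(text = paste0(sub(":1$", "", build(labels)), ";"))
}

# n distinct ungapped rows (every row differs everywhere): identity 0
# between any pair, so identity never stops the decomposition.
distinct_alignment <- function(n, width = 24L) {
  stopifnot(n <= 20L)
  seqs <- vapply(seq_len(n), function(i)
    paste(rep(AA_ALPHABET[i], width), collapse = ""), character(1))
  protein_msa(stats::setNames(seqs, sprintf("s%02d", seq_len(n))))
}

# A family of near-identical rows (one substitution per row), identity
# close to 1; handy where content does not matter.
uniform_family <- function(id, n, width = 30L, threshold = 0) {
  base <- strsplit(paste(rep("ACDEFGHIKL", width / 10), collapse = ""), "")[[1]]
  seqs <- vapply(seq_len(n), function(i) {
    v <- base
    v[(i %% width) + 1L] <- AA_ALPHABET[(i %% 20L) + 1L]
    paste(v, collapse = "")
  }, character(1))
  family_record(id, protein_msa(stats::setNames(seqs, sprintf("%s_r%03d", id, seq_len(n)))),
                threshold = threshold)
}

# Simulated family via the package's own generator (fixed current-RNG use).
sim_family_aln <- function(n, divergence, seed) {
  set.seed(seed)
  tree <- sample_tree(n, divergence)
  evolve_family(tree, sim_params(seed = seed, divergence = divergence))
}

# Small benchmark used by several integration tests.
tiny_benchmark <- function(seed = 7, n_families = 3, family_size = 16,
                           divergence = 0.35) {
  make_benchmark(sim_params(n_families = n_families,
                            family_size = family_size,
                            divergence = divergence, seed = seed))
}

# Random reference model built on a random small alignment.
random_ref_model <- function(M_target, n_rows = 3L, seed = 1) {
  set.seed(seed)
  # ungapped alignment of width M_target -> M = M_target match columns
  seqs <- vapply(seq_len(n_rows), function(i)
    paste(sample(AA_ALPHABET, M_target, replace = TRUE), collapse = ""),
    character(1))
  build_profile(protein_msa(stats::setNames(seqs, sprintf("r%d", seq_len(n_rows)))),
                model_id = sprintf("rnd%d", seed), family_id = "RND")
}

random_query <- function(len, seed) {
  set.seed(seed)
  paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
}
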