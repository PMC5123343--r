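---
title: "Classifying protein sequences with ensembles of profile HMMs"
author: "hmmensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying protein sequences with ensembles of profile HMMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmmensemble)
```

## The problem and the model

Assigning a new amino-acid sequence to a known protein family is a basic
step in functional annotation and in marker-based metagenomic profiling.
The standard approach represents each family by a single profile hidden
Markov model (HMM) built on its curated seed alignment and assigns a query
to the family whose model yields the highest bit score.  A single HMM,
however, averages over the whole family: for large, evolutionarily
divergent families its match-state emission distributions become diffuse,
and sensitivity suffers — most visibly for short, fragmentary queries and
for families with low average pairwise sequence identity.

`hmmensemble` instead represents each family $\mathcal F_i$ by a *nested
ensemble* of profile HMMs $H_i = \{h_{i1}, \dots, h_{ip_i}\}$.  The
ensemble is built by recursively decomposing the family's guide tree:

1. Build a profile HMM on the full seed alignment and add it to the
   ensemble (so a single-model family is always a special case).
2. If the subset has more than `hard_floor` (default 10) sequences and is
   not yet *small and homogeneous*, delete the **centroid edge** of its
   guide tree — the edge whose removal splits the leaf set into two parts
   of maximally balanced size — and recurse into the two induced
   sub-alignments, adding one profile HMM per subset.

"Small and homogeneous" is the conjunction of two arms with tunable
parameters: the subset has at most $X\%$ of the initial seed size
(`max_size_pct`, default 10), **and** its mean pairwise sequence identity
is at least $Y\%$ (`min_identity_pct`, default 40).  A subset is therefore
split further either because it is still large or because it is still
heterogeneous; the identity arm is what lets compact, homogeneous families
stop early while divergent families of the same size keep decomposing.
With $Y = 0$ the rule degenerates to a pure size rule, and with
$X = 100, Y = 0$ no family is ever split — the classical one-HMM-per-family
baseline, exposed as `single_hmm = TRUE`.

A query $q$ is scored against every profile in every ensemble and assigned
by

$$\mathrm{Family}(q) = \arg\max_i \Big[\max_j \{BS(q, h_{ij}) :
BS(q, h_{ij}) > s\, g_i\}\Big],$$

where $BS$ is the bit score, $g_i$ the family's gathering-cutoff
threshold, and $s \in [0,1]$ a scale swept for precision/recall curves.
If every family's candidate set is empty the query is left unassigned.
Two consequences of gating *before* the argmax are worth knowing: the set
of assigned queries shrinks weakly as $s$ grows, but with heterogeneous
$g_i$ a query's winning family can flip to the runner-up when the winner
is gated away — so recall is not necessarily maximal at $s = 0$.  Ties on
the best score break to the lexicographically smallest family id, so runs
are reproducible.

## Scoring engines

Two interchangeable backends implement model building and scoring behind
one contract (`backend_config()`):

* **reference** — a self-contained profile-HMM engine.  Match columns are
  alignment columns with gap fraction below 0.5; match emissions use the
  pseudocount rule $e_m(a) = (c_a + \alpha f_{bg}(a)) / (\sum_b c_b +
  \alpha)$ with $\alpha = 1$, uniform sequence weights and a uniform 1/20
  background; insert states emit the background; transitions are estimated
  from per-sequence state paths with pseudocount 1 per allowed transition.
  The topology is Plan7-like (no D→I or I→D transitions; insert residues
  adjacent to a deleted match column are skipped when counting
  transitions).  Scoring is a scaled forward (or Viterbi) dynamic program
  over emission odds ratios, giving $\log_2 P_{\mathrm{fwd}} / P_{\mathrm{null}}$
  bits directly against an i.i.d. background null with no length
  correction.  Alignment is local in the model — uniform free entry into
  any match state, trained exits to the end state — and global in the
  query, which is what makes fragment scoring work.  Ambiguity codes
  (B, Z, X, U, O) emit at background frequency, i.e. score zero bits, and
  never count as identity matches.
* **hmmer** — an adapter to an external HMMER toolkit: `hmmbuild` in
  default mode per subset, `hmmsearch --tblout` per model with a very
  permissive reporting threshold (E = 10^6) so that weak hits remain
  observable for threshold sweeps; the full-sequence bit score is used.

The reference engine is a contract-faithful profile HMM, not a HMMER
clone: it omits position-specific sequence weighting, Dirichlet mixture
priors and E-value calibration, so its absolute bit scores differ from
HMMER's.  Everything downstream (classification, threshold sweeps,
evaluation) is engine-agnostic, and the test suite checks both engines
behind the same contract.

## Guide trees

Decomposition needs a guide tree per family.  An externally estimated
maximum-likelihood tree can be supplied through the family record or the
manifest's `tree_path` column and is validated against the seed's row
ids.  Otherwise the package builds a neighbor-joining tree (via `ape`)
from p-distances $d(a,b) = 1 - \mathrm{identity}(a,b)$, clamping negative
NJ branch lengths to zero.  Identity is computed over mutually non-gap
columns; pairs with no shared column score 0, a conservative choice that
pushes non-overlapping subsets toward further splitting.  For alignments
above 100 rows the mean pairwise identity is estimated from 1,000 pairs
sampled without replacement instead of all pairs — a threshold test does
not need the exact quadratic mean — and the sampling is driven by the
caller's seeded RNG stream.  The centroid-edge tie-break (smallest minimum
leaf label on the smaller side, then smaller side size) exists purely for
cross-platform determinism.

## The synthetic benchmark generator

All tests run without downloads: `make_benchmark()` simulates a Pfam-like
database with known ground truth.  Each family is an independent random
tree (uniform labeled topology, exponential branch lengths rescaled so the
mean leaf-to-leaf path length equals the `divergence` parameter) along
which a root sequence of 90–110 residues evolves under uniform replacement
over the 20 amino acids — substitution probability $1 - e^{-\lambda t}$
per site per branch — with geometric-length insertions and deletions
(rate 0.01/site, mean tract length 2) tracked as alignment events, so the
true alignment is exact by construction and never re-estimated.  Under
this model the expected pairwise identity at divergence $D$ is roughly
$0.05 + 0.95\,e^{-(20/19) D}$, which makes identity directly tunable:
the package's two standard conditions are `divergence = 0.35`
(≈ 0.7 within-family identity, an "easy" condition) and
`divergence = 1.3` (≈ 0.35 identity, below the 40% stopping threshold,
the regime where the identity arm of the stopping rule matters).  Per
family, 75% of rows become the seed alignment (the true tree pruned to
them serves as guide tree) and 25% become full-length queries, from which
half- and quarter-length fragments are cut uniformly at random, mirroring
the cross-validation geometry of the evaluation harness.

What the simulator deliberately does *not* emulate: empirical amino-acid
substitution matrices, site-rate heterogeneity, domain architecture, or
between-family homology.  Families are mutually unrelated (cross-family
identity sits at the ~5% coincidence level), so synthetic precision is
easier than on a curated corpus with genuinely confusable families; the
passing end-to-end tests demonstrate correct mechanics and the direction
of the ensemble effect, not field accuracy on real seed databases.

## Evaluation harness

`make_folds()` deals each family's sequences once (seeded shuffle) into
four near-equal groups — fold *f* tests on group *f* and trains on the
rest, so every sequence appears in exactly one test set; families under 10
sequences are rejected because removing even a few rows from a tiny family
changes its character.  `make_fragment()` cuts contiguous substrings of
length $\max(1, \lfloor f L \rfloor)$ at a uniform start.  Unassigned
queries count against recall but not precision (precision is NA when
nothing is assigned).  `pr_curve()` re-gates one raw score table along the
scale grid $\{0, 0.25, 0.5, 0.75, 0.9, 1\}$ — six points, in the
five-to-seven range typical of such curves — without re-scoring, globally
and within subgroups keyed by the true family's seed size (≤ 100 vs
> 100) and mean identity (0–20%, 20–30%, > 30%).
`confusable_family_graph()` reproduces the parameter-selection device:
10 random probe sequences per family are scored against every other
family's root profile; an undirected edge joins two families when the
mean probe score strictly exceeds 25 bits in either direction (probes
with no hit contribute 0), and the selection is all families of degree
≥ 5 plus their neighbors.

## Numerical and design choices

* **Stopping rule**: split iff `size > hard_floor` AND NOT
  (`size <= X% * n` AND `identity >= Y%`), with `n` fixed at the initial
  seed size.  The conjunctive stop is what makes the $(10\%, 0\%)$
  variant a pure-size decomposition rather than a no-op.
* **Strict threshold gating** (`>`, never `>=`): a hit exactly at the
  cutoff is excluded, and a 0-bit hit above a 0 threshold is still
  distinguishable from "no hit" because absence is $-\infty$, never 0.
* **Forward DP scaling**: per-row rescaling by the row maximum with the
  log accumulated separately keeps ~100×100 DPs in double range without
  per-cell logs; the enumeration oracle in the tests agrees to
  $10^{-6}$ bits on all models with ≤ 3 match states.
* **Serialization**: reference models round-trip through JSON at 17
  significant digits, so save → load → classify is bit-identical.
* **Determinism**: every stochastic step (simulation, pair sampling, fold
  dealing, fragment placement, probe choice) derives from explicit seeds;
  ensemble builds use per-family substreams hashed from the global seed
  and the family id, so adding a family never perturbs the others.
* **Degenerate inputs**: single-row alignments have identity 1 and are
  buildable; alignments whose every column is majority-gap raise a
  "no consensus columns" error naming the family; two-leaf trees split at
  their only edge; NJ falls back to a hand-built tree for 2 taxa.

## Problem sizes used by the checks

The packaged tests and the acceptance script run, per configuration,
20 families × 40 sequences (seed 30/queries 10 per family, 200 queries per
fragment length; ~140 profile HMMs), the low-identity condition over three
seeded replicates, plus property sweeps (100 random trees against an
exhaustive centroid search, 1,000 random score tables against a literal
evaluation of the assignment formula, 100 random fold layouts).  These
sizes were chosen so the whole suite runs in about a minute on one core
while still exercising every code path at realistic model dimensions.

## Known limitations

* Reference-engine bit scores are not comparable to HMMER bit scores;
  gathering cutoffs curated against HMMER only make sense with the
  `hmmer` backend.
* Guide trees from NJ on p-distances are cruder than maximum-likelihood
  trees; for real seed databases, supply ML trees through the manifest.
* Bit scores are not converted to membership probabilities, queries get
  at most one family (no multi-domain handling), and longest-edge or
  clade-based decompositions are out of scope.
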