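---
title: "Colored move-structure indexing and PML-based taxonomic classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colored move-structure indexing and PML-based taxonomic classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colorbwt)
```

# The index

The reference is a collection of *documents* `D = D_1, D_2, ...` — the most
specific classification units; typically each document groups all genomes of
one species. Documents are concatenated in ID order into a single text `S`
over `{A,C,G,T}` with one terminator `$` at the end (`$` sorts before every
base). By default the reverse complement of each document is appended under
the same document ID, so one query pass covers both strands.

From `S` we build the suffix array (prefix doubling — `O(n log^2 n)` with
rank-pair comparisons, so highly repetitive pangenomes do not degrade it),
the BWT (`bwt[i] = S[(sa[i]-1) mod n]`), the LCP array (Kasai), and the
document array (the document containing each sorted suffix's start; the
terminator row carries a no-document sentinel and contributes to nothing
downstream).

The BWT of a repetitive collection decomposes into `r ≪ n` maximal
equal-letter runs. The **move table** has one row per run: character,
length, and the LF image of the run head as a (destination run, offset)
pair. An LF step from `(i, j)` goes to `(ξ_i, f_i + j)` and fast-forwards
through subsequent runs while the offset exceeds the destination run's
length; this is exactly rank-based LF on the uncompressed BWT (tested
exhaustively against that oracle). We deliberately skip the row-splitting
normalization that gives worst-case constant-time steps; at the scales this
package targets the iterative fast-forward is simpler and the contract is
correctness, not cache behaviour.

Each run stores a **color**: the set of distinct documents among its rows.
Colors are deduplicated in first-occurrence order, runs store only a color
ID, and the color table can be encoded dense (`|D|` bits per color) or
sparse (one integer per member). `index_stats()` reports `n`, `r`, `|C|`,
`n/r`, `r/|C|`, the mean occupancy `b` and the color-frequency distribution
with cumulative run coverage; on redundant collections `r/|C|` runs into
the hundreds, which is the entire point of storing color IDs per run.

## Repositioning thresholds

During a query, a case-2 mismatch repositions the tracked offset onto the
nearest run of the required character, either up (landing on that run's last
row) or down (first row) — the landing rows maximize adjacency LCP. With
`lcp_thresholds`, the direction is precomputed: for each run and character,
the threshold is the first in-run offset at which the down candidate's
range-minimum LCP strictly exceeds the up candidate's (ties break upward,
consistent with the always-up fallback); offsets below the threshold go up.
`t = ℓ` when the character never occurs below, `t = 0` when never above,
and a character absent from the BWT is flagged (queries emit PML 0 for it
and do not move). Monotonicity of the two range minima across a run makes
the single-crossing threshold well defined. Two threshold-free strategies
are provided: `mid_run` (up iff the offset is below `⌈ℓ/2⌉`, with fallback
to the only available side) and `always_up`.

# Queries and classification

A read is processed right-to-left from the position of `BWT[n-1]`. Case 1
(run character equals the read base): the pseudo-matching length grows by
one. Case 2: reposition, length resets to 0. After fixing `L_k`, if
`L_k > 0` the color of the current run is looked up — at the tracked offset,
before the LF step for the next position — and every member document's
score is incremented. PMLs under-approximate matching statistics and every
positive `L_k` certifies that `R[k..k+L_k-1]` occurs in the reference; both
properties are enforced as tests against brute-force oracles for all three
strategies.

Per read we then compute:

* average PML `Σ L_k / m`; the binary gate calls a read in-index iff this is
  *strictly* above a cutoff. The cutoff is the nearest-rank
  `(1-α)`-percentile (order statistic of rank `⌈(1-α)n⌉`, not an
  interpolated quantile) of the average PMLs of user-supplied null reads;
  `α = 0.05` by default.
* the document report: `Dbest` (ties by smallest document ID, for
  determinism) plus at most `max_extra = 1` documents with score
  `≥ ratio = 0.95` of the best (inclusive).
* the assigned taxon: the LCA of the reported documents' taxa in a
  parent-pointer taxonomy (root points to itself). A read whose score map is
  all zero stays unclassified even if it passes the gate.

Scores are always computed; the gate only sets the status. Reads are
processed independently, so results never depend on scheduling.

## What the tallied colors mean, and fidelity

Color tallying makes two kinds of errors: a run's color may omit documents
that contain the match (their rows lie in other runs of the interval), and
it may include documents that only share the run's shorter common prefix.
Both shrink for longer matches. The document set the scoring scheme
consistently credits for a match is the set incremented at *every* step of
its case-1 streak — the running intersection of the encountered colors; the
true origin document is guaranteed to be in it. `color_fidelity()` therefore
reports, per read position, the Jaccard similarity between that tallied set
and the true set of documents containing the exact match (computed from the
match's suffix-array interval via backward search — an exact computation,
not an estimate), alongside the same comparison for the raw single-run
color. On the default synthetic pangenome the tallied-set Jaccard exceeds
0.95 for PMLs ≥ 16 and approaches 1 as the PML grows, while the single-run
color is substantially noisier — which is why scores, not individual colors,
drive classification.

# Evaluation

At a fixed rank, each read falls into exactly one of six categories: TP
(prediction and truth agree once both are lifted to their ancestors at the
rank), VP (prediction is a strict ancestor of the truth, above the rank),
FP (from the index, wrong node), FP* (not from the index but assigned), FN
(from the index, unclassified), TN (not from the index, unclassified).
Micro-averaged `PPV = TP/(TP+FP+FP*)` and
`sensitivity = TP/(TP+FP+FN+VP)`; F1 is their harmonic mean; zero
denominators yield `NA`. Lifting both sides to the evaluated rank makes TP
well defined for predictions below the rank; reads whose truth has no node
at the rank are excluded from the tally.

# The synthetic pangenome generator

`simulation_config()` / `simulate_pangenome()` emulate a held-out-strain
study: a random ancestor is mutated (substitutions only) into per-species
ancestors at `inter_divergence` per site (default 0.05), each into
`genomes_per_species` genomes at `intra_divergence` (default 0.001, strong
within-species redundancy); one genome per species is held out for positive
reads; a fresh, unrelated random clade supplies null reads. The taxonomy is
two-level (species, pairwise genera, one root). Defaults — 10 species × 5
genomes × 20 kb, 2 kb reads — are the package's reference study conditions
and are what `scripts/acceptance.R` rebuilds.

Design choices worth stating explicitly:

* **Document granularity.** By default all indexed genomes of a species form
  one document (`document_level = "species"`), which is how a colored index
  is deployed for taxonomic classification: colors then distinguish taxa,
  and the index cannot report below the chosen level. One-document-per-genome
  (`"genome"`) is available for multi-class, strain-style studies; note that
  with only a handful of genomes per species, per-genome truth sets are tiny
  and tallied-color fidelity is intrinsically lower — a granularity effect,
  not an indexing defect.
* **Substitution-only evolution.** No indels or rearrangements; sufficient
  to create run/color structure, but real pangenomes also differ by gene
  content, so absolute accuracy numbers here do not transfer to real data.
* **Read errors** are i.i.d. per base (substitution/insertion/deletion);
  there is no attempt to mimic a specific long-read chemistry's error
  profile.
* **Null reads** share no ancestry with the index, the cleanest version of
  the "absent at every taxonomic level" condition.
* The common-ancestor model at 5% per branch makes species far more similar
  (~90% identity) than real unrelated species; passing tests on this
  generator demonstrates algorithmic correctness and the calibration/fidelity
  mechanics, not field performance.

# Numerical and degenerate-input choices

* Coordinates are 0-based half-open throughout; document IDs are `0..|D|-1`.
* Threshold ties break upward everywhere.
* Reference sequences are upper-cased and split at non-`ACGT` characters
  (ambiguity codes removed, never replaced); non-`ACGT` read characters
  always behave as case 2 with no movement.
* `Dbest` ties break by smallest document ID; the runner-up rule is
  inclusive (`≥`).
* The binary gate is strict (`>`); an average PML exactly at the cutoff is
  unclassified.
* Degenerate inputs error early: empty collections or documents empty after
  sanitization, texts without a unique trailing `$`, empty reads, empty null
  samples, `α ∉ (0,1)`, reads longer than their source genome.
* Index bundles serialize to deterministic plain text (TSV + JSON) with a
  format version checked on load; derived tables (nearest-run links, color
  pointers) are rebuilt on load rather than stored.

# Problem sizes used by the test suite

The oracle-equivalence suite checks 200 random collections (texts up to
2 kb) against naive sorting, rank-based LF, per-interval document listing
and range-minimum LCP scans. Property suites (PML soundness,
under-approximation, streak scoring, strategy agreement) run on dozens of
smaller random cases across all three repositioning strategies. The
end-to-end fixtures use the default 10 × 5 × 20 kb pangenome with hundreds
to a thousand 2 kb reads; these sizes keep the whole suite under a minute
on one CPU while the acceptance script's full recomputation takes well
under a minute as well.

# Limitations

* No external BWT construction: indexes are built in memory and target
  desk-scale references (tens of megabases), not multi-gigabase databases.
* No minimizer digestion, color-table compression beyond deduplication
  (meta-colors, spanning trees), or EM-based abundance estimation.
* Classification cannot be more specific than the document definition.
* Runtime claims of the move structure (constant-time steps via row
  splitting, cache layout) are out of scope; this implementation optimizes
  for verifiability.
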