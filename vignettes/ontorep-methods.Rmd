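---
title: "Methods: annotation and longitudinal lineage analysis of BCR repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotation and longitudinal lineage analysis of BCR repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ontorep` analyses bulk B-cell receptor (BCR) sequencing data with a focus
on a single question: given one or more known "seed" antibodies, which
transcripts in a longitudinal repertoire belong to the same clonal lineage,
and how did that lineage develop over time? This vignette documents the
models and procedures behind each stage, the tunable parameters and their
defaults, the numerical choices, and what the synthetic-data generator does
and does not emulate.

## Germline references and CDR3 anchors

Annotation is performed against a germline gene library
(`load_germline_library()`), one FASTA per segment (V, D, J, constant) with
either plain (`>IGHV3-30*18`) or IMGT-style pipe-delimited headers. Alleles
annotated ORF or pseudogene are excluded by default. Allele names are
truncated at `*` to gene names, and alleles with byte-identical sequences
are recorded in one duplicate group: such alleles (IGHV3-30\*18 and
IGHV3-30-5\*01 are the classic pair) cannot be distinguished by alignment,
which is one reason all downstream grouping works at the gene level. The
top allele is still reported per read.

CDR3 extraction needs two anchor positions on the references
(`annotate_anchors()`): on each V allele the codon of the second conserved
cysteine (IMGT position 104), found as the last in-frame `TGT`/`TGC` within
the final 12 codons; on each J allele the first codon of the conserved
W/F-G-X-G motif (IMGT 118). This motif heuristic replaces full IMGT gapped
numbering; it assumes frame-0 V references, which holds for IMGT V-REGION
sequences. Alleles without a detectable anchor are flagged and excluded
from CDR3 extraction but still participate in gene assignment.

## Alignment engine

All pairwise alignment is done by a native affine-gap dynamic-programming
engine (Gotoh three-state recursion, compiled) with three modes: local
(Smith–Waterman), global (Needleman–Wunsch with penalized end gaps), and
ends-free. Scoring defaults are BLASTN-like: match $+5$, mismatch $-4$, gap
opening $8$ and extension $2$ per column (a length-$L$ gap costs
$8 + 2L$); `N` scores 0 against everything. The original pipeline called
BLAST+ with "optimized parameters" it does not print, so these values are
package defaults, exposed in `align_params()`. Identity between two
sequences is always computed on the global alignment as matches divided by
total alignment columns, so gap columns — including end gaps — count
against identity; the source pipeline never defines its identity
arithmetic, and this is the strictest consistent choice. The engine is
validated in the test suite against `Biostrings::pairwiseAlignment` under
the identical scoring scheme.

## Annotation

`annotate_reads()` performs, per read: length filtering (default window
300–600 nt, inclusive; the variable region plus primers is ~350–470 nt);
V assignment by local alignment of both strands against all V alleles
(minus-strand hits reverse-complement the read for all downstream steps);
J assignment restricted to the read segment after the 3' end of the V
match; optional D (between V and J) and constant-region (after J)
assignment; CDR3 extraction; and a final status. Acceptance thresholds
default to a minimum V score of 250 with at least 50% reference coverage,
a minimum J score of 30, and a minimum D score of 25 (five consecutive
matches). The V threshold is set by the score distribution of unrelated
sequences: under this scoring, gapped chaining of chance matches between a
random 400-mer and a 296-nt reference reaches local scores of roughly
160–190, while genuine V hits stay above ~700 even at 25% divergence, so
250 separates the two regimes with a wide margin. Score ties are broken by fewer gaps, then lexicographic allele
name, which makes assignment deterministic; ties between
identically-sequenced alleles are resolved to the lexicographically first
name.

The CDR3 is the stretch strictly between the Cys-104 codon and the W/F-118
codon (IMGT 105–117). Anchors are mapped through the V and J alignments
into read coordinates. Because Smith–Waterman trims terminal mismatches, an
anchor can fall a few bases outside the aligned interval on a mutated read;
anchors within 15 nt of the interval are mapped by ungapped extrapolation
from the nearest aligned column, which is exact for substitution-only
differences, and extraction is reported absent beyond that.

Statuses follow the precedence `wrong_length` > `no_V` > `no_J` >
`no_CDR3` > `indel` > `stop` > `good`. A read is `indel` when the total gap
length in its V or its J alignment is not divisible by 3 (an optional
strict mode flags any gapped V alignment); `stop` when an in-frame stop
codon occurs anywhere on the V–J span, in the reading frame propagated from
the germline V (frame 0 of the reference mapped through the alignment) —
not from an ORF scan, since a frameshifted transcript should be reported
as `indel`, not rescued by a different frame.

## Dereplication

`dereplicate()` collapses redundant transcripts and suppresses
PCR/sequencing artifacts by greedy centroid clustering, in the UCLUST
style: exact duplicates are merged first (multiplicities summed), the
remaining sequences are ordered by decreasing abundance, then decreasing
length, then increasing id, and each sequence joins the first existing
centroid at or above the identity threshold or founds a new centroid. The
fixed ordering makes the procedure deterministic, unlike input-order-
dependent UCLUST. Defaults are 99% identity and a minimum retained cluster
size of 3; both are exposed, and a 97% threshold reproduces the
"non-redundant" accounting style used for repertoire summaries of
uncorrected pyrosequencing data.

## Identity–divergence analysis and islands

`calc_id_div()` computes, per read, (i) divergence: the mismatch
percentage over a global alignment of the read's V-matched region to the
matched region of its assigned germline allele — this is the SHM level —
and (ii) identity: the full-length global-alignment identity of the read
to each seed antibody. Lineage members appear as a high-identity "island"
separated from the bulk. `island()`/`get_island()` select reads inside a
closed rectangle on that plane; bounds are inclusive on all four sides.
Identity is computed over the full aligned span including primer-derived
termini, since trimming conventions vary by protocol and the package does
not guess them.

## Neighbor joining

`neighbor_joining()` is a classic Saitou–Nei implementation with two extra
guarantees. Q-matrix ties are broken by lexicographic taxon-pair order
(each cluster keyed by its smallest member label), so trees are
reproducible across platforms. Negative branch-length estimates are
clamped to zero with the deficit transferred to the sister branch,
preserving the path length between the joined pair. The final three
clusters join in an unrooted trifurcation with the closed-form lengths
$v_a = (d_{ab} + d_{ac} - d_{bc})/2$.

## Intradonor analysis

`intradonor_analysis()` iterates: shuffle the surviving reads (RNG stream
derived from the required `rng_seed`), split into chunks of at most
`group_size` (default 250; the source pipeline does not print its chunk
size), and for each chunk build a neighbor-joining tree of the reads, the
seed antibodies, and the germline V, rooted on the germline leaf. Reads in
the minimal rooted clade containing all seed leaves survive to the next
round. The analysis stops when at least `converge` (default 95%) of a
round's input survives that round, when nothing survives, or at
`max_iters` (warning). Chunk alignment is a reference-anchored star
alignment around the germline V: each sequence is ends-free-aligned to the
germline and projected onto germline coordinates, with insertions relative
to the reference discarded; distances are p-distances with gapped sites
deleted pairwise. This keeps the module self-contained where the original
shells out to a multiple aligner, at the cost of ignoring junction
insertions — acceptable here because intradonor discrimination rests on
shared V-region mutation patterns, and the CDR3-based methods cover the
junction signal.

A practical note reflected in the tests: the minimal clade spanning the
seeds is exactly that — if all seeds are drawn from one late time point,
their common ancestor is recent and the clade legitimately excludes early
lineage branches. Recovery of a whole lineage requires seeds that span it
(for example one isolated antibody per visit), and precision on real data
still requires manual curation; simulations here report recall and
precision against recorded truth.

## CDR3 lineage clustering

`cluster_cdr3_lineages()` implements unseeded (and optionally seeded)
lineage assignment: reads are grouped by assigned V and J gene — gene, not
allele — and within each group the CDR3 nucleotide sequences are greedily
clustered at 90% identity by default (the threshold is exposed; the source
prints no default). Each cluster is one lineage; seed antibodies can be
clustered along with the reads, and any lineage containing a seed is
flagged seeded.

## Longitudinal merging and birthdays

`merge_timepoints()` takes one FASTA per time point plus an ordered label
list (the supplied order *is* temporal order; labels are never parsed).
Sequences identical after uppercasing and degapping are collapsed into one
record whose `birthday` is the first label at which it was observed, with
all observations and copy counts retained. Collapsing uses exact equality;
a fuzzier rule would blur the birthday semantics that downstream coloring
depends on.

## Maximum-likelihood ontogeny trees

`build_ml_tree()` replaces the DNAML black box with a native
implementation. The model is HKY-style: empirical base frequencies,
transition/transversion ratio $\kappa$ (default 2.0), rate matrix scaled
to one expected substitution per unit branch length. Likelihoods come from
Felsenstein pruning over compressed site patterns (compiled hot path, with
a plain-R reference implementation kept for validation; the test suite
also checks log-likelihoods against `phangorn::pml` to ~1e-6). Gaps and
`N` are treated as missing data.

The search mirrors the "run three times on randomly ordered input"
protocol: for each of `n_orders` (default 3) random taxon orders, a
stepwise-addition starting tree is built (each insertion point scored by
optimizing the three edges around the new leaf), then refined by
nearest-neighbor interchange with per-edge Brent branch-length
optimization until no rearrangement improves the log-likelihood; the best
of the runs is kept. NNI candidates are screened with inherited branch
lengths and only the best few are re-optimized, which changes running time
but not the local-optimum property. The tree is rooted on the germline
outgroup, splitting that edge's length equally, which leaves the
likelihood unchanged under reversibility.

Ancestral sequences are marginal reconstructions: an up (pruning) pass and
a down pass give per-site posteriors at every internal node; the reported
base is the posterior argmax with ties resolved in the fixed order
A < C < G < T. On small trees the posteriors are verified in the tests
against brute-force enumeration over all internal-state assignments.
Heuristic search on hard instances can legitimately return a different
topology than an exhaustive scan when likelihoods tie; correctness is
asserted against exhaustive enumeration at small scale rather than against
DNAML concordance, whose defaults do not transfer to a native
implementation.

## Intermediates, collapsing, partitions

`pick_intermediates()` walks from the inferred unmutated common ancestor
(the child of the root opposite the germline leaf) to a target leaf,
accumulating amino-acid changes between consecutive node sequences
(codons containing stops are excluded from the comparison, with a
warning). "Approximately equally spaced" is resolved as: with `n`, pick
the path nodes nearest to $i \cdot \text{total}/(n+1)$, ties to the
earlier node; with `spacing_aa`, emit a node whenever that many changes
have accumulated since the last one. The UCA is always returned first.
`lineage_mrca()` reports the inferred sequence of the most recent common
ancestor of chosen leaves.

`collapse_minor_branches()` produces display-ready trees: in post-order, a
clade is collapsible when all its NGS leaves' CDR3s are within the
identity threshold of the clade's plurality CDR3 and it contains no
keep-listed leaf; maximal collapsible clades of at least `min_size` leaves
become one pseudo-leaf labelled `<representative>|size=<n>`, smaller ones
are pruned, and keep-listed leaves (known antibodies, the germline) always
survive. The summary table records each major branch's size, temporal span
of birthdays, and representative CDR3.

`partition_alignment()` emits the five column sets used for
evolutionary-rate analysis — full V(D)J, CDR union, framework union, codon
positions 1+2, and position 3 — and `write_nexus_sets()` serializes them
as a standard NEXUS `sets` block (with `a-b\3` stride notation for codon
partitions) that round-trips through `read_nexus_sets()`. Emitting
tool-specific XML configuration is out of scope; the computation is the
partitioning, and NEXUS charsets are the portable carrier.

## The synthetic repertoire generator

`simulate_repertoire()` exists so every stage is testable with recorded
ground truth. It emulates: V(D)J recombination (germline V/D/J draw,
exonuclease chewback up to `chewback_max` = 5 nt per junction side,
non-templated insertions up to `n_insert_max` = 8 nt, junctions kept
in frame and stop-free as naive productive receptors are); clonal
expansion over ordered time points, where the founder carries one round of
SHM shared by every clone member — the lineage signature an expanded clone
has acquired by the time it is first sampled — and further SHM accumulates
at `shm_rate`
(default 0.05 substitutions/site per step, putting a three-visit lineage
near the 10–15% divergence seen in chronic-infection lineages) with a 2×
hotspot multiplier on WRC/GYW motifs; exact carryover of some sequences
between visits (`carryover_prob` = 0.2), which is what gives the birthday
machinery something to collapse; unrelated background reads as singleton
lineages with uniform SHM up to `background_shm_max` = 0.05; and a
pyrosequencing-style error layer of substitutions plus single-nucleotide
indels. The truth table records lineage membership, the true alleles, each
read's own junction (post-SHM, pre-error), SHM counts, first-emergence
time point, and artifact indels. Everything is deterministic given
`rng_seed`, to the byte, including the FASTA output.

What it does not emulate — and therefore what green tests do not show
about real data: realistic gene-usage frequencies, primer and chimera
artifacts, quality-score structure, class switching, paired heavy/light
chains, position-specific mutability profiles beyond the simple hotspot
multiplier, or indels longer than 1 nt. Germline V alleles are random
296-mers with a planted cysteine context rather than real IMGT sequences,
so absolute alignment scores on real data will differ from the simulated
ones even though the logic is identical.

## Problem sizes and numerical choices

The test suite and the acceptance script run, by choice, at sizes where
exhaustive oracles are feasible: 200 random additive trees of 5–8 taxa
for neighbor joining; 50 alignments of 5 taxa × 600 sites for the ML
search against all 15 topologies; 2,000 simulated error-free reads for
annotation accuracy; 50 lineage reads among 450 same-V decoys for
intradonor recall; 500 reads for dereplication. Branch lengths are
optimized on $[0, 5]$ substitutions/site with Brent tolerance $10^{-7}$
and sweep tolerance $10^{-6}$; base frequencies get a $10^{-6}$
pseudocount so the HKY symmetrization is defined for degenerate
alignments; likelihood partials are rescaled per pattern when they drop
below $10^{-120}$. Distance matrices must be symmetric to $10^{-8}$.
Degenerate inputs (all-identical alignments, zero distances, empty
junctions) are exercised in the unit tests.

## Known limitations

Exact recombination-point calling and N/P-insertion inference are
deliberately out of scope, as is per-donor genotype inference; allele
calls are reported but not trusted. The intradonor star alignment ignores
insertions relative to the germline V. The ML machinery targets lineage
trees of tens of sequences; hundreds of leaves work but the stepwise
addition search grows quadratically, and no bootstrap support is
computed. Quality-based read preprocessing is expected to happen upstream.
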