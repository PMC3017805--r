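---
title: "Genome-free analysis of full-length cDNA collections: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-free analysis of full-length cDNA collections: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the methods behind each `flcdnakit` module —
the precise rules, thresholds, and formulas — so that results can be
interpreted and reproduced without reading the source.

## Pairwise alignment

Every identity-threshold rule in the package runs through one engine,
`align()`: an affine-gap Smith-Waterman with BLASTN-like scoring (match
+1, mismatch -2, a gap of length $L$ costs $5 + 2L$). Short pairs
(product of lengths up to 4e6) are solved by the exhaustive dynamic
programme; longer pairs are restricted to a diagonal band around exact
11-mer seed hits, widened by 31 diagonals. Because both routes share
one scoring scheme, the banded result can be validated against the
exact one, and the exact one against `Biostrings::pairwiseAlignment()`.
Identity is matches over alignment columns (gaps count as columns), and
`N` never matches anything. For splice-variant screening the engine is
re-parameterized with a flat gap cost (open 30, extension 0) so that
bridging a retained intron of any length always beats dropping a flank.

## Clustering and redundancy

`cluster_ests()` builds a graph with an edge between two sequences when
their local alignment contains a window of at least 80 columns at over
95% identity, then takes connected components (single linkage, via
igraph). `filter_redundant()` drops a sequence as redundant when it
aligns to a longer one at $\ge 99\%$ identity over $\ge 90\%$ of the
shorter sequence's length; the mapping of dropped to kept ids is
returned as an attribute.

## ORFs and composition

`find_longest_orf()` scans the three forward frames (FL-cDNA clones are
directional) for ATG-initiated ORFs ending at the first in-frame stop;
ORFs reaching the transcript end without a stop are kept and flagged
partial. Length is counted in codons excluding the stop; ties go to the
5'-most start. `composition_summary()` reports GC per region and GC at
each codon position over the annotated ORF (stop codon included).

## Microsatellites

`detect_ssrs()` finds perfect tandem arrays of period 1-6 using a
shift-by-period comparison and run-length encoding; an array qualifies
at period-specific minimum repeat counts (e.g. 10 for mononucleotides,
6 for dinucleotides, 5 for trinucleotides by default, see
`ssr_default_thresholds()`). Motifs are reported canonically (the
lexicographically smallest rotation), degenerate motifs (themselves a
repeat of a shorter motif) are suppressed, and arrays are truncated to
whole repeat units. `localize_ssrs()` assigns hits to 5' UTR / ORF /
3' UTR by interval midpoint and reports the signed distance to the
start codon.

## Alternative splicing without a genome

Within each cluster, `candidate_as_pairs()` aligns sequence pairs with
intron-tolerant gap costs and accepts a pair when both flanks around
internal gaps hold at least 100 columns at over 99% identity, and every
internal gap is at least 30 nt (the minimum credible intron).
`classify_as_event()` then slides each gap through every equivalent
placement permitted by the alignment and inspects the inserted segment:

- begins `GT` and ends `AG` in some placement: intron retention
  (`IntronR`), boundary `GT-AG`; a `GC..AG` placement is the minor
  `GC-AG` boundary;
- donor only (`GT`): alternative donor (`AltD`); acceptor only
  (`AG`): alternative acceptor (`AltA`); neither: exon skipping
  (`ExonS`);
- one intron-like insertion in *each* sequence at different positions:
  a single alternative-position (`AltP`) event;
- staggered overlap with no internal gap at all: exon overlap
  (`ExonO`).

`intron_size_summary()` averages inferred intron lengths over retained
introns.

## Natural antisense transcripts

`detect_nats()` screens all pairs with a shared-k-mer prefilter against
reverse complements, then finds the longest gap-free window between one
sequence and the reverse complement of the other containing at most one
mismatch. A pair qualifies when that window spans at least 50 nt; it is
reported once, with the window mapped onto each transcript's own
forward coordinates.

## Homology, orthology, and the shared/unique partition

Nucleotide-level homology requires over 75% identity covering over half
of the query; protein-level homology requires a window of 50 consecutive
aligned residues at over 60% identity between predicted peptides.
`pick_ortholog()` takes the best protein-level hit subject to a
reciprocal-best check and returns `NA` on ties (ambiguous paralogy);
`find_ortholog_groups()` keeps queries with a one-to-one ortholog in
every species. `partition_shared_unique()` classes each query by the
pattern of species in which it has a homolog.

## Ka/Ks and molecular-clock dating

`codon_align()` pairs coding sequences codon-by-codon via their
peptides (Needleman-Wunsch on amino acids), rejecting sequences that do
not start with ATG, are not a multiple of 3, or contain internal stops.
`estimate_ka_ks()` implements Nei-Gojobori pathway counting: each codon
contributes synonymous site counts averaged over the pair, multi-base
codon differences average over all orderings of single-base steps, and
the proportions $p_s, p_n$ are Jukes-Cantor corrected,
$d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$, with saturation at
$p \ge 0.75$ reported as `NA`. A divergence is dated as
$T = K_s / (2r)$ with $r = 6.5 \times 10^{-9}$ synonymous substitutions
per site per year by default, and `ks_window_filter()` restricts
ortholog pairs to $K_s < 0.75$, tabulating how many show
$K_a/K_s > 1$.

`duplication_analysis()` applies the same machinery inside EST
clusters: reads of one cluster are anchored to their full-length
reference, polymorphic columns supported by at least two reads split
the cluster into two haplotype consensuses, and when both consensuses
cover the full CDS their Ks dates the duplication; ages are binned into
a 5-My histogram.

## Phylogeny

`concat_alignment()` concatenates per-gene alignment blocks over a
common taxon set; `build_distance_matrix()` computes Jukes-Cantor
distances with pairwise deletion (requiring a minimum number of shared
ungapped columns per pair); `neighbor_joining()` wraps `ape::nj()`,
clamps negative branch lengths to zero (moving the deficit to the
sister edge), and roots on a requested outgroup;
`bootstrap_support()` resamples alignment columns with replacement
from a seeded RNG and reports per-clade support percentages.

## Synthetic data with known truth

`simulate_transcriptome()` generates transcripts whose UTR and codon
composition are calibrated to configurable GC/GC3 targets, and plants
splice variants of every class, antisense partners, SSRs, and
duplications at chosen Ks, recording every event in a truth table.
`simulate_ests()` adds 5'-biased, heavy-tail-depth reads with optional
error. `simulate_ortholog_panel()` evolves species copies to a target
Ks and Ka/Ks (UTRs mutated at the matching neutral rate) and adds
decoys. Every generator draws from an isolated, seeded RNG stream and
restores the caller's RNG state.

## A worked pipeline

```{r}
library(flcdnakit)
cfg <- pipeline_config(
  simulation = simulation_config(n_genes = 30, as_fraction = 0.3,
                                 nat_fraction = 0.1, seed = 1),
  panel_genes = 8, panel_species = 3)
res <- run_pipeline(cfg, "flcdna-report")
read.delim(file.path("flcdna-report", "summary.tsv"))
```
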