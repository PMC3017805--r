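# flcdnakit

Genome-free structural and evolutionary characterization of full-length
cDNA (FL-cDNA) collections and their 5'-EST companions.

## The science

Large FL-cDNA collections are often produced for species that do not yet
have a sequenced genome — fast-growing grasses such as Moso bamboo are a
classic case. Each clone captures one complete transcript: 5' UTR, open
reading frame and 3' UTR. Even without a genome, a surprising amount of
biology can be read directly off such a collection:

- **Redundancy and gene families.** Clustering clones and 5'-ESTs by
  sequence identity collapses the collection to non-redundant genes and
  exposes highly expressed or recently duplicated families.
- **Composition.** Grass genes have characteristically GC-rich coding
  regions with a strong GC gradient at the third codon position (GC3), a
  signature this package measures per region (5' UTR / ORF by codon
  position / 3' UTR).
- **Microsatellites (SSRs).** Tandem repeats with motif sizes 1-6 are
  detected and localized relative to the start codon; UTR-biased SSR
  placement is a well-known property of plant transcriptomes.
- **Alternative splicing without a genome.** When two clones of one gene
  differ by an internal insertion, the insertion is a candidate retained
  intron: if it begins with `GT` (or the minor `GC`) and ends with `AG`
  in some placement of the alignment gap, it is classified as intron
  retention; donor-only, acceptor-only, boundary-less and staggered
  cases map to alternative donor/acceptor sites, exon skipping, and exon
  overlap, and a pair carrying one intron-like insertion in *each*
  sequence at different positions is an alternative-position event.
- **Natural antisense transcripts (NATs).** Two clones whose sequences
  are reverse complements over at least 50 nt with at most one mismatch
  form a cis-NAT pair.
- **Homology and orthology.** Clones are partitioned by presence or
  absence of homologs in related species, and strict reciprocal-best
  one-to-one orthologs feed the evolutionary analyses.
- **Ka/Ks and molecular-clock dating.** Synonymous (Ks) and
  nonsynonymous (Ka) divergence is estimated by the Nei-Gojobori
  pathway-counting method with Jukes-Cantor correction; a divergence at
  synonymous rate *r* is dated as `T = Ks / (2 r)` with the grass rate
  6.5e-9 substitutions per synonymous site per year as default. The same
  machinery dates gene duplications discovered inside EST clusters (two
  haplotype consensuses in one cluster) and builds an age histogram.
- **Phylogeny.** Concatenated ortholog alignments give Jukes-Cantor
  distances, a neighbor-joining tree, and column-resampled bootstrap
  supports.

## The model

Because no public genome underlies the analyses, correctness is
established the other way around: `simulate_transcriptome()` generates a
transcriptome with *known* ground truth — gene lengths and UTR/ORF
composition calibrated to configurable GC and GC3 targets, planted
splice variants of every class, planted antisense partners, planted
duplications at a chosen Ks, and 5'-biased EST reads with a
heavy-tailed depth distribution — and every detector is asked to
recover what was planted. `simulate_ortholog_panel()` does the same for
cross-species analyses: ortholog copies are evolved to a target Ks and
Ka/Ks, and decoys are added, so homolog partitioning and ortholog-group
recovery can be scored exactly.

All randomness flows from explicit seeds; every function is
deterministic given its inputs.

## Worked example

```r
library(flcdnakit)

cfg <- simulation_config(n_genes = 12, as_fraction = 0.25,
                         nat_fraction = 0.15, ssr_rate_utr3 = 0.3,
                         seed = 42)
sim <- simulate_transcriptome(cfg)
data.frame(id = sim$transcripts$id[1:3],
           length = nchar(sim$transcripts$seq[1:3]))
#>         id length
#> 1 FLC00001    902
#> 2 FLC00002   1354
#> 3 FLC00003    653

ann <- annotate_orfs(sim$transcripts)
head(ann[, c("transcript_id", "orf_start", "orf_end", "aa_length",
             "partial")], 3)
#>   transcript_id orf_start orf_end aa_length partial
#> 1      FLC00001       143     667       174   FALSE
#> 2      FLC00002       595    1119       174   FALSE
#> 3      FLC00003        97     471       124   FALSE

round(composition_summary(sim$transcripts, ann)$summary, 3)
#>       n      gc gc_utr5 gc_utr3  gc_orf     gc1     gc2     gc3
#>  17.000   0.496   0.520   0.431   0.514   0.482   0.413   0.647

ev <- detect_as_events(cluster_ests(sim$transcripts), sim$transcripts)
ev[, c("transcript_a", "transcript_b", "as_type", "boundary",
       "inferred_intron_length")]
#>   transcript_a transcript_b as_type boundary inferred_intron_length
#> 1     FLC00001     FLC00002    AltA      -AG                    452
#> 2     FLC00003     FLC00004    AltA      -AG                    346
#> 3     FLC00005     FLC00006   ExonO                              NA

detect_nats(sim$transcripts)[, c("sense_id", "antisense_id",
                                 "overlap_length", "mismatches")]
#>   sense_id antisense_id overlap_length mismatches
#> 1 FLC00007     NATP0004            514          1
#> 2 FLC00009     NATP0005            323          1

# evolve a coding sequence to Ks = 0.2 and date the divergence
cds <- substr(sim$transcripts$seq[1], ann$orf_start[1], ann$orf_end[1])
div <- kaks_pair(cds, mutate_to_ks(cds, 0.2, seed = 7, ka_ks = 0.25))
div
#> NG86: S=102.67 N=419.33 Sd=18.00 Nd=21.00  Ks=0.1997 Ka=0.0518 Ka/Ks=0.260
round(date_divergence(div$Ks) / 1e6, 2)  # million years
#> [1] 15.36
```

`run_pipeline(pipeline_config(...), out_dir)` chains every stage —
simulation, clustering, redundancy filtering, ORF and composition
statistics, SSRs, splice variants, NATs, homolog partitioning, ortholog
groups, Ka/Ks with a Ks < 0.75 window, duplication dating, and a
bootstrapped NJ tree — and writes one TSV per stage plus `summary.tsv`.
A command-line entry point wrapping the same stages ships as
`system.file("scripts", "flcdnakit.R", package = "flcdnakit")`.

## License

MIT (see `LICENSE`).
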