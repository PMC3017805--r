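Package: flcdnakit
Title: Genome-Free Characterization of Full-Length cDNA Collections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for structural and evolutionary characterization of
    full-length cDNA (FL-cDNA) and 5'-EST collections without a reference
    genome. Provides EST clustering and redundancy filtering by identity
    thresholds, longest-ORF annotation with regional GC and codon-usage
    statistics, microsatellite (SSR) detection and UTR/ORF localization,
    genome-free alternative-splicing classification under the GT-AG rule,
    cis-natural-antisense transcript detection, homolog and one-to-one
    ortholog identification across species, Nei-Gojobori Ka/Ks estimation
    with Jukes-Cantor correction and molecular-clock dating of gene
    duplications from EST clusters, and neighbor-joining phylogeny with
    bootstrap support from concatenated ortholog alignments. A seeded
    synthetic-data generator produces FL-cDNA and EST sets with known
    ground truth so that every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    ape,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Collate: 
    'RcppExports.R'
    'alignment.R'
    'antisense.R'
    'clustering.R'
    'utils.R'
    'kaks.R'
    'dupdating.R'
    'homology.R'
    'orf.R'
    'phylogeny.R'
    'pipeline.R'
    'sequence_io.R'
    'simulate.R'
    'splice.R'
    'ssr.R'
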