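Package: emsHunter
Title: Candidate-Gene Identification from EMS Mutant Chromosome Sequencing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies candidate causal contigs from sequencing of multiple
    independent EMS-derived mutants mapped against a repeat-masked wild-type
    chromosome assembly. Calls near-fixed single-nucleotide variants per
    mutant line from samtools mpileup files, integrates call sets across
    mutants with a shared-position artifact filter, ranks contigs by the
    number of independently mutated lines, flags cultivar contaminants by
    SNV density and assembly artifacts by a wild-type self-check, and
    computes analytic false-positive probabilities under the canonical
    G/C-to-A/T EMS mutation spectrum. A complete synthetic-experiment
    simulator (reference assembly, mutant genomes, pileups, truth table)
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    data.table
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
biocViews: VariantDetection, Sequencing, GeneTarget, Software
RoxygenNote: 7.3.3
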