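Package: repeatscape
Title: Repetitive-Landscape Analysis of Large Plant Genomes
Version: 0.1.0
Authors@R:
    person("Repeatscape", "Developers", email = "repeatscape@example.org",
           role = c("aut", "cre"))
Description: Segment-based homology annotation of transposable elements (TEs)
    with explicit merge and gap-bridging rules, copy-number and chromosomal
    niche statistics, gene-space association analyses (gene clustering with a
    randomization null, TE-to-gene distances, orientation bias), TSS/TES
    anchored positional profiles, target-site nucleotide-composition matrices,
    and windowed bisulfite-methylation comparisons between genes with and
    without DNA transposons in their promoters. Ships a synthetic genome,
    TE-library and methylome generator with full ground truth so every stage
    of the pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
SystemRequirements: mafft (only for consensus construction)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
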