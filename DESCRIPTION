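Package: ventcomp
Title: Comparative Metagenomics of a Dominant Population Against a
    Finished Reference Genome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes the dominant population of a shotgun metagenome
    against a finished reference genome: fragment-recruitment profiling of
    reads by percent-identity bin, per-contig size/coverage/GC statistics,
    best-hit synteny anchoring with rearrangement-break and gene-fusion
    calls, prophage-insertion detection with direct-repeat logic, clone
    mate-pair linkage of transposase-bearing sequences, and a tiered
    homolog census over translated-search E-value thresholds.  Includes a
    self-contained seeded local aligner (nucleotide and translated modes,
    Karlin-Altschul statistics) and a synthetic genome-evolution and
    read-simulation module that plants rearrangements, fusions, a
    prophage with flanking direct repeats, and multi-copy transposases
    with a machine-readable truth ledger.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
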