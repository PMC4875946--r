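Package: domseln
Title: Evolutionary Contrasts Between Protein Domains and Unassigned
    Regions of Coding Sequences
Version: 0.1.0
Authors@R:
    person("Sam", "Roth", email = "sroth@example.org",
           role = c("aut", "cre"))
Description: Tools to compare the evolutionary pressures acting on
    Pfam-annotated domain regions versus the unassigned remainder of
    protein-coding sequences, using population variation and
    human-ancestor divergence. Implements SNP effect classification
    against spliced coding sequences, fractional synonymous and
    non-synonymous site counting, minor-allele-frequency
    stratification, Fisher-exact density contrasts, the Direction of
    Selection statistic, gamma distribution-of-fitness-effects
    inference from paired site-frequency spectra with per-class
    demographic nuisance terms, amino-acid composition and
    codon-usage-bias (effective number of codons) confounder controls,
    and a randomization null for domain families devoid of SNPs.
    Ships a synthetic-data generator with known ground truth so every
    stage is testable without genome-scale inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment,
    data.table,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
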