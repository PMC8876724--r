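Package: mitohap
Title: Mitochondrial Genome Haplotyping from Shotgun Whole-Genome
    Sequencing Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts high-quality mitochondrial genome (mitogenome)
    haplotypes from shotgun short-read whole-genome sequencing data.
    Implements circular-reference consensus mapping, low-frequency variant
    detection with neighbourhood quality filtering, forensic-nomenclature
    haplotype emission, and a deterministic rule engine that classifies
    mixed positions as authentic point heteroplasmies or artifacts of
    nuclear mitochondrial DNA segments (NUMTs).  Includes a paired-end read
    simulator with truth labels (point heteroplasmies, NUMT donor reads,
    contaminant mixtures, post-homopolymer sequencing error) for validation
    of the full pipeline, plus sample-level quality control and
    detection-threshold comparison reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
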