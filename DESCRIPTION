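Package: umivar
Title: UMI-Based Consensus Calling of Rare Variants in Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and quantifies rare variants (single-nucleotide variants,
    small indels, and large structural variants) from amplicon sequencing
    reads labeled with unique molecular identifiers (UMIs). Reads sharing a
    UMI are binned into groups, each representing one original DNA molecule;
    per-group consensus calling suppresses amplification and sequencing
    errors, enabling detection of alleles at frequencies down to 1e-4.
    Includes an error-tolerant structured-UMI extractor, a semi-global
    aligner with a two-piece gap cost that keeps multi-kilobase deletions as
    single events, structural-variant detection from CIGAR strings and
    split-segment realignment (inversions), population-level merging with
    variant-allele-fraction estimation, design calculators (detection power,
    polymerase error budget, somatic SNV load), and a synthetic-read
    simulator with molecule-level ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    parallel,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
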