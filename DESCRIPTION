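Package: ystrkit
Title: Forensic and Population-Genetic Analysis of Y-STR Haplotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for forensic Y-chromosomal short tandem repeat (Y-STR)
    haplotype data on the 27-locus Yfiler Plus panel. Provides haplotype-level
    forensic statistics by direct counting (haplotype diversity, match
    probability, discrimination capacity, unique-haplotype fraction), per-locus
    forensic parameters (gene diversity, random match probability, power of
    discrimination, polymorphism information content), two-level analysis of
    molecular variance on squared repeat-count differences with pairwise R_ST
    distance matrices, permutation significance tests and classical
    multidimensional scaling, and mutation-rate-weighted median-joining
    haplotype networks with cluster annotation. A stepwise-mutation-model
    simulator generates founder-effect tribal populations, including null
    alleles, duplications and microvariant alleles, so every analysis stage is
    testable on synthetic data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
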