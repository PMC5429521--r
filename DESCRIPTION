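Package: subgenomap
Title: Subgenome-Specific Locus Discrimination and Linkage Mapping in
    Allo-Octoploids
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for discriminating candidate subgenome-specific loci in
    allopolyploid selfed (S1) mapping populations. Provides an exact
    combinatorial model of disomic inheritance across four subgenomes with
    null alleles, a meiosis simulator for S1/F1 populations with known
    truth, chi-square based segregation classification of genotype
    matrices, de novo linkage-map construction (EM two-point recombination
    estimation, LOD grouping, seriation ordering, Haldane distances,
    co-segregation binning, imputation, orthology-based placement of
    dominant loci), and comparison of genetic maps against reference
    physical positions, ancestor-haplotype flags and probe read depths.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
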