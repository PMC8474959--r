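Package: popsweep
Title: Population-Genomic Diversity, Differentiation, and Selective-Sweep Scans from SNP Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream population-genomics analysis of multi-sample SNP
    genotype data with a two-level population hierarchy (populations nested
    in geographic groups). Reads biallelic SNP genotypes from VCF, applies
    minor-allele-frequency and call-rate (integrity) site filters, and
    computes per-population diversity summaries (nucleotide diversity,
    expected and observed heterozygosity, polymorphism information content),
    pairwise Weir-Cockerham F_ST, hierarchical distance-based AMOVA with
    permutation significance, and genotype-matrix PCA with Patterson
    normalization. Implements a windowed selective-sweep scan that joins
    per-window F_ST with the log2 ratio of per-group nucleotide diversity
    over non-overlapping 10-kb windows, calls joint empirical-tail outlier
    windows, overlaps them with gene annotations, and tests candidate gene
    sets for hypergeometric over-representation. A Balding-Nichols
    simulator generates structured genotype datasets with embedded sweep
    windows and ground truth for parameter-recovery and power testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
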