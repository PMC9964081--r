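Package: clonalpop
Title: Population Genomics and Clone Delimitation for Clonal Plants from ddRAD SNPs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for reduced-representation SNP data from
    clonal plant populations. Reads diploid genotypes from VCF, applies
    locus presence filtering, and computes per-population diversity
    (observed and expected heterozygosity, inbreeding coefficient,
    heterozygosity deficit), pairwise Weir-Cockerham F_ST with a Mantel
    test of isolation by distance, admixture-style ancestry estimation
    with cross-entropy selection of the number of ancestral clusters,
    discriminant analysis of principal components (DAPC), and clone
    delimitation by distance-threshold cutting of UPGMA trees with
    clonal-richness summaries. Includes a synthetic-data generator for
    structured, inbred, clonal SNP datasets with known truth, and a
    rule-based conservation genetic-value classification of populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    vcfR,
    vegan,
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    ape
Config/testthat/edition: 3
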