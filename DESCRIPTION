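Package: bogdiv
Title: Stage-Wise Domestication Genomics for Clonal Fruit Crop Diversity Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Population-genetic analysis of crop diversity panels that span
    successive domestication and breeding stages, motivated by the American
    cranberry (Vaccinium macrocarpon). Reads biallelic SNP genotypes from VCF,
    applies missingness and minor-allele-frequency marker filters, and computes
    per-subgroup diversity summaries (MAF spectra, joint-MAF contingency
    tables, polymorphic fractions, expected heterozygosity), per-locus
    Weir-Cockerham fixation-index scans with permutation significance
    thresholds, reduction-of-diversity (ROD) statistics across defined breeding
    steps, windowed linkage-disequilibrium decay curves, PCA / Ward clustering
    / sparse-NMF-style ancestry estimation with masked cross-entropy model
    selection, spatially adjusted genomic BLUPs, and EMMAX-style mixed-model
    association scans with Benjamini-Hochberg discovery control. Ships a
    coalescent-free domestication simulator with known ground truth for
    end-to-end validation, and a single-config pipeline orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    splines,
    vcfR,
    ape,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
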