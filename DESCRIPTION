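Package: vcfpopgen
Title: Diversity, Differentiation and Linkage Disequilibrium from
    Multi-Sample SNP Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for characterizing nucleotide diversity, population
    differentiation and linkage disequilibrium in whole-genome SNP data
    from multi-sample diploid VCFs. Implements GATK-style hard filtering
    together with a two-tier high-confidence / exclusion-cascade variant
    filter with a full accounting ledger; per-site and sliding-window
    nucleotide diversity, SNP density and Weir-Cockerham F_ST; genotype
    r-squared, distance-binned LD-decay curves and windowed LD; positional
    SNP classification against GFF3 gene models; per-base coverage
    summaries; and a founder-mosaic synthetic-data generator with
    Balding-Nichols population divergence and inversion-dependent
    recombination suppression for end-to-end testing of the whole chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    vcfR,
    ape,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
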