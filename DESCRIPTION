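Package: hapblocks
Title: Haplotype Blocks, Diversity and Haplotype-Based Association in
    Inbred Crop Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Linkage-disequilibrium haplotype-block construction by the
    solid-spine rule on genetic (cM) maps of homozygous inbred lines,
    with block haplotype enumeration and greedy tag-SNP selection;
    gene diversity, polymorphism information content and Nei's Gst for
    SNP alleles and block haplotypes, including three-block sliding
    window diversity profiles; Loiselle kinship, PCA structure
    covariates, multi-environment BLUP and heritability; mixed linear
    model (Q+K, P3D) association run per single SNP and per haplotype
    block with 1/n significance thresholds, ANOVA R-squared and
    favorable-allele calls; founder-reference allele painting; and a
    seeded generator of structured inbred panels with planted blocks,
    selection sweeps and block-resident QTL for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
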