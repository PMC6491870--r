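Package: delbin
Title: Deletion-Bin Mapping and Functional Markers for Wheat Peroxidase Genes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Physical mapping of PCR markers to wheat chromosome deletion
    bins from amplification patterns across aneuploid stocks
    (nullisomic-tetrasomic, ditelosomic and terminal-deletion lines),
    with a brute-force consistency oracle; assembly of overlapping
    amplicons into ATG-anchored gene models (UTR/ORF partition,
    translation, GC content, molecular weight); pairwise-alignment
    SNP/InDel calling between allele sequences with protein-level
    consequences; in-silico allele-specific PCR and dominant STS marker
    genotyping; and marker-trait association by replicate CV quality
    control, one-way ANOVA and Fisher's LSD. Includes generators for
    synthetic deletion panels, allele pairs, PCR templates and variety
    phenotype panels with recorded ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
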