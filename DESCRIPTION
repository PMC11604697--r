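Package: capcv2g
Title: Variant-to-Gene Mapping from Promoter-Focused Capture-C and ATAC-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates promoter-focused Capture-C contact maps, replicate
    ATAC-seq peaks, gene models, GWAS sentinel variants with their linkage
    disequilibrium proxies, expression tables, chromatin-state segmentations
    and transcription-factor binding motifs into a variant-to-gene (V2G)
    mapping pipeline for implicating effector genes at disease association
    loci. Provides in silico restriction digestion and fragment binning,
    consensus open-chromatin calling from replicates, promoter-interacting
    region derivation, allele-aware motif disruption scoring, enrichment
    statistics (rank-sum, chromatin-state fold enrichment, hypergeometric
    gene-set overlap, delta-delta-Ct, paired t), and a seeded synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
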