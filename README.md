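# capcv2g

Variant-to-gene (V2G) mapping from promoter-focused Capture-C and ATAC-seq.

Most GWAS risk variants for complex metabolic disease lie in non-coding
DNA, and the gene each variant regulates — its effector gene — is often
not the nearest one. `capcv2g` implicates effector genes by chaining
physical and biochemical evidence: a sentinel variant is expanded to its
linkage-disequilibrium proxies (strictly r² > 0.8), proxies are kept only
if they fall in a consensus open chromatin region (an ATAC peak
reproducible in ≥ 2 replicates), and an open proxy implicates gene *G*
when its OCR either overlaps *G*'s promoter window (−1500/+500 bp around
the TSS, strand-aware) or overlaps the non-bait end — the
promoter-interacting region (PIR) — of a significant Capture-C contact
(score ≥ 5, at single-fragment and 4-fragment-bin resolution) baited at
*G*'s promoter.

The package is aimed at regulatory genomicists who have pre-called
contacts and peaks and want a tested, reproducible implication pipeline.
It provides:

- a restriction-fragment genome model: in silico GATC digestion, fragment
  binning, promoter windows, nearest-gene lookup (`digest_sequence()`,
  `bin_fragments()`, `promoter_windows()`, `nearest_gene()`);
- contact-map handling: score filtering, bait annotation (including
  bait-to-bait accounting), PIR derivation, distance summaries;
- a consensus OCR atlas with promoter/PIR classification and Jaccard
  similarity between cell-type annotations;
- the V2G core: proxy expansion, gene implication, sentinel
  classification, cross-cell-type summaries, cRE BED export
  (`expand_proxies()`, `implicate_genes()`, `cross_celltype_summary()`,
  `export_cre_annotation()`);
- enrichment statistics: Mann-Whitney rank-sum (exact or corrected normal
  approximation), chromatin-state log2 fold enrichment against a
  genome-fraction null, one-sided hypergeometric gene-set overlap, ΔΔCt
  normalisation, paired t tests;
- allele-aware motif disruption scoring: best-window log-odds scores for
  reference and alternative alleles over both strands, with
  TF-expression filtering of the summary (`scan_variant()`,
  `summarize_tf_disruption()`);
- a seeded synthetic-data generator with planted proxy → OCR → PIR → gene
  chains and a truth audit (`sim_config()`, `generate_bundle()`,
  `audit_truth()`).

## Worked example

Generate a small noise-free bundle, run the pipeline, and audit the
planted truth:

```r
library(capcv2g)

cfg <- sim_config(seed = 42, chrom_lengths = c(chr1 = 6e5), n_genes = 25,
                  n_background_peaks = 80, n_contacts = 200, n_sentinels = 12,
                  n_planted_chains = 6, dropout = 0, distance_meanlog = log(4e4))
generate_bundle(cfg, "demo_bundle")
bundle <- load_bundle("demo_bundle")
res <- run_bundle_pipeline(bundle)
res$v2g[, c("sentinel_id", "r2", "cell_type", "mechanism", "resolution", "gene_id")]
#>   sentinel_id    r2 cell_type        mechanism  resolution gene_id
#> 1       rs001 0.865     cellA      pir_contact 1frag,4frag    G017
#> 2       rs003 0.862     cellA      pir_contact 1frag,4frag    G009
#> 3       rs005 0.973     cellA      pir_contact 1frag,4frag    G020
#> 4       rs002 0.954     cellB promoter_overlap        <NA>    G005
#> 5       rs004 0.872     cellB promoter_overlap        <NA>    G024
#> 6       rs006 0.937     cellB promoter_overlap        <NA>    G025
```

Each row is one implicated (sentinel, gene) pair: `mechanism` says whether
the open proxy sat in the gene's promoter OCR or in a PIR contacting it,
and `resolution` lists the contact resolutions supporting a PIR route.
The OCR atlas behind it is classified into the three primary classes:

```r
S4Vectors::metadata(res$per_cell$cellA$ocrs)$class_counts
#> promoterOCR     PIR-OCR  nonPIR-OCR
#>           9          27          46

audit_truth(bundle)[c("sensitivity", "precision")]
#> $sensitivity [1] 1
#> $precision   [1] 1
```

`audit_truth()` replays every planted chain through the real operations:
on this noise-free bundle all 6 planted chains are recovered and nothing
else is implicated. The expression comparison behind the map's usual
validation figure (promoter-connected genes are expressed higher) on a
simulated table with a 1 log2-unit planted shift:

```r
set.seed(7)
sim <- simulate_expression(100, 100, delta = 1)
cmp <- expression_contact_comparison(sim$expr, sim$connected)
#> connected median 3.56 vs 2.01 log2(TPM+1), two-sided p = 3.82e-08
```

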