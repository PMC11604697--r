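---
title: "Promoter Capture-C variant-to-gene mapping: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter Capture-C variant-to-gene mapping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capcv2g)
```

## The problem

Most disease-associated variants found by genome-wide association studies
(GWAS) fall in non-coding DNA, and the gene a risk variant regulates — its
*effector gene* — is usually not obvious: it need not be the nearest gene,
and the regulatory contact may act over hundreds of kilobases. Promoter-
focused Capture-C measures, at restriction-fragment resolution, which
distal regions physically contact gene promoters; ATAC-seq marks which
regions are in open chromatin and therefore plausibly regulatory. `capcv2g`
integrates these two assays with gene models, GWAS sentinel variants and
their linkage-disequilibrium (LD) proxies, expression tables,
chromatin-state segmentations and transcription-factor binding motifs into
a variant-to-gene (V2G) mapping pipeline, together with the enrichment
statistics used to validate such maps and a fully seeded synthetic-data
generator with planted ground truth.

## The mapping procedure

The chain of evidence for implicating a gene `G` from a sentinel variant
`s` is:

1. **Proxy expansion.** Every variant in high LD with the sentinel
   (strictly `r² > 0.8`) is a candidate causal variant; the sentinel is
   always included as its own proxy (`expand_proxies()`). The threshold is
   strict because that is how LD proxy lists are conventionally cut; a
   proxy at exactly 0.8 is excluded.
2. **Open chromatin.** Only proxies falling inside a consensus open
   chromatin region (OCR) are carried forward. OCRs are ATAC peaks
   reproducible in at least `min_support = 2` of the replicates
   (`consensus_ocrs()` clusters peaks across replicates by single-linkage
   at ≥ 1 bp overlap and emits the cluster's union interval).
3. **Gene implication** (`implicate_genes()`), by either route:
   - *promoter overlap*: the OCR overlaps the promoter window of `G`. The
     promoter window spans −1500/+500 bp around the transcription start
     site in transcription direction, mirrored for minus-strand genes.
   - *PIR contact*: the OCR overlaps the non-bait end (the
     promoter-interacting region, PIR) of a significant Capture-C contact
     whose bait is `G`'s promoter. Contacts are pre-called interactions
     filtered at score ≥ 5 (inclusive), at single-fragment (1frag) and
     4-fragment-bin (4frag) resolution; implications from both resolutions
     are unioned with the supporting resolutions recorded per record.

Records are deduplicated per (sentinel, gene, cell type, mechanism).
Downstream summaries classify sentinels by whether they implicate the
nearest gene (`classify_sentinels()`), count genes exclusive to or shared
between cell types (`cross_celltype_summary()`), and export the merged
promoter-OCR + PIR-OCR annotation as BED for external
partitioned-heritability tooling (`export_cre_annotation()`).

## Geometry conventions

- In memory, all intervals are `GRanges` (1-based, closed) — the native
  convention of the R/Bioconductor interval stack the package is built on.
  BED carriers are 0-based half-open on disk and converted at the I/O
  boundary; ibed-like contact files and the gene/variant tables carry
  1-based positions on disk, as the upstream tools emit them.
- In silico digestion (`digest_sequence()`) cuts at the first base of
  every GATC occurrence (the `^GATC` convention). Any consistent cut
  convention preserves all downstream invariants, since contacts, peaks
  and proxies are all located on the same fragment map.
- 4-fragment bins are tiled from each chromosome's first fragment: tiling
  is deterministic and keeps every fragment in exactly one bin. Anchoring
  bins on baited fragments instead would be equally defensible; tiling was
  chosen for its simpler invariant.
- Nearest-gene ties (equidistant TSSs) break to the lexicographically
  smallest gene id, for reproducibility. The nearest gene is measured from
  the sentinel position, not from a locus interval.
- Contact distances are midpoint-to-midpoint, which is robust across the
  1frag/4frag resolutions; trans-chromosomal contacts are excluded from
  distance summaries and counted separately. Distance summaries are
  reported per resolution and pooled.
- OCR classification gives promoter precedence: an OCR overlapping both a
  promoter window and a PIR is a promoterOCR with a secondary PIR flag, so
  the three classes partition the atlas.
- The Jaccard similarity between cell-type annotations is computed on
  nucleotide sets after merging; by default the compared sets are the
  promoter-connected annotation (promoter OCRs ∪ PIR-OCRs, via
  `jaccard_matrix()` on whatever sets the caller supplies), since either
  reading of "loops between promoter and OCR" can be reproduced by passing
  the corresponding set.

## Statistics

- `rank_sum_test()` computes the Mann-Whitney U for the first sample and
  uses exact enumeration if `n1 + n2 ≤ 10` with no ties, otherwise the
  normal approximation with tie and continuity corrections. The package's
  tests check the exact path against an independent enumeration over all
  group labellings and check the two paths against each other at
  `n1 = n2 = 10`.
- `expression_contact_comparison()` compares `log2(TPM + 1)` between genes
  whose promoters contact at least one PIR-OCR and all other genes; the
  two-sided p value is reported together with the one-sided
  (connected-higher) p value and the median direction, so either reading
  of a one- vs two-sided comparison is available.
- `chromhmm_enrichment()` uses a genome-fraction null: the fold enrichment
  of state `s` is the fraction of query bp in `s` divided by `|s| /
  genome_size`, reported as log2. The closed-form null was chosen over
  coordinate shuffling for determinism; a shuffle-based empirical null can
  be layered on top by the caller if desired. States with zero overlap
  report `-Inf`.
- `geneset_overlap_test()` is the upper-tail hypergeometric (one-sided
  Fisher) test with the 2×2 table returned.
- `qpcr_ddct()` implements ΔΔCt relative quantification
  (`2^−ΔΔCt`, reference sample ≡ 1); `paired_t_test()` reports t on the
  paired differences plus the percent change of means, flagging
  zero-variance difference vectors as degenerate instead of producing NaN.

## The synthetic-data generator

`sim_config()` + `generate_bundle()` produce a complete, internally
consistent input bundle: genome FASTA with GATC sites placed to match a
configured expected fragment length, gene table, per-replicate narrowPeak
files, ibed contacts at both resolutions, a sentinel/proxy variant table,
an expression table, a chromatin-state BED and JASPAR motifs — plus
`truth.json` recording every planted proxy → OCR → (PIR | promoter) → gene
chain, planted motif disruption and expression shift.

Default conditions (chosen once, at desk scale, to mirror the qualitative
structure of real promoter Capture-C studies):

| parameter | default | rationale |
|---|---|---|
| chromosomes | 2 × 2 Mb | large enough for 100 kb-scale contacts |
| expected fragment length | 400 bp | typical 4-cutter (DpnII) spacing |
| replicates / support | 3 / ≥ 2 | the standard reproducibility rule |
| peak edge jitter, dropout | 25 bp, 0.1 | replicate-to-replicate noise |
| contact distances | log-normal, meanlog log(8e4), sdlog 0.8 (mean ≈ 110 kb) | in the range of reported per-cell-type means |
| contact score | 30% below 5; retained scores 5 + Exp(5) | exercises the ≥ 5 filter |
| bait-to-bait fraction | 0.15 | middle of the reported 10–29% range |
| proxies | r² ∈ [0.5, 0.99], strict 0.8 threshold downstream | boundary exercised by low-r² controls |
| expression baseline | log2(TPM+1) ~ Gamma(2, 1.2) | positive, continuous, right-skewed |
| connected-gene shift δ | 1 log2 unit | a clearly detectable but not extreme effect |
| motifs | 5 PWMs, length 10–12, 91/3/3/3 columns | sharp motifs giving clean score separation |

Planted chains are placed in *reserved* genomic space (reserved at
4-fragment-bin granularity) and background contacts, peaks and variants
avoid it, so that on noise-free settings (`dropout = 0`) the pipeline
recovers exactly the planted (sentinel, gene) pairs — sensitivity and
precision 1 — which is what `audit_truth()` verifies by replaying every
chain through the real pipeline operations. Negative controls are
generated alongside: contacts below score 5, proxies with r² ≤ 0.8 inside
planted OCRs, and high-r² proxies in closed chromatin.

What the generator does *not* emulate: realistic sequence composition
beyond GATC placement, read-level noise (no FASTQ), peak-summit structure,
distance-dependent contact score decay, LD block structure beyond a
uniform proxy window, and trans-chromosomal contacts (background
bait-to-bait contacts may be trans, but planted chains are always cis).
Passing recovery tests therefore demonstrates the correctness of the
mapping logic, not the calibration of any statistical model against real
sequencing noise.

Motif planting writes the PWM consensus into the FASTA centred on the
proxy, with the alternative allele chosen as the worst base of the variant
column; consensus sequences are generated GATC-free and kept clear of
fragment boundaries (any junction-induced GATC is repaired outside the
motif) so digestion is unaffected. The allele-score delta is
`score_ref − score_alt`: positive delta means the alternative allele
destabilises the motif ("decreasing" stability), and hits are retained
when the better allele reaches 80% of the matrix's maximum achievable
log-odds score (both the fraction and the pseudocount, 0.25 on a uniform
background, are exposed as arguments).

## Problem sizes used in tests

The shipped test-suite and acceptance script use these sizes, chosen as a
compromise between statistical resolution and desk-scale runtime:
recovery runs 20 independent bundles (1 × 600 kb chromosome, 25 genes,
200 background contacts, 6 planted chains, dropout 0); null calibration
uses 200 simulated expression tables of 100 + 100 genes (and 100 tables at
δ = 1 for power); oracle equivalence uses 1,000 random interval fixtures,
all rank-sum group sizes with `n1 + n2 ≤ 8`, and a 10,000-resample
permutation check of the hypergeometric test.

## Known limitations

- Interaction calling (CHiCAGO-style scoring) and peak calling are out of
  scope: contacts and peaks arrive pre-called, and the score threshold is
  applied as given.
- Variants are restricted to single-nucleotide substitutions; the
  allele-delta motif score is not defined for indels, which readers
  reject.
- The LD table is an input; no LD is computed from genotypes.
- The partitioned-heritability regression itself is external; the package
  only exports the merged cRE annotation it consumes.
- Whether genes implicated by several sentinels should be deduplicated
  before cross-cell-type counting is a reporting choice;
  `cross_celltype_summary()` counts unique genes per cell type and unique
  genes in the union, and the per-gene membership table is returned so
  either convention can be derived.
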