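toy_variants <- function() {
  data.frame(
    variant_id = c("rs1", "rs2", "p80", "p81", "p95"),
    chrom = "chr1", pos = c(100L, 50000L, 200L, 300L, 400L),
    ref = "A", alt = "G",
    role = c("sentinel", "sentinel", "proxy", "proxy", "proxy"),
    sentinel_id = c("rs1", "rs2", "rs1", "rs1", "rs1"),
    r2 = c(1, 1, 0.80, 0.81, 0.95), stringsAsFactors = FALSE
  )
}

test_that("proxy expansion is strict at r2 > 0.8 and adds self-proxies", {
  px <- expand_proxies(toy_variants(), 0.8)
  expect_false("p80" %in% px$variant_id)     # boundary excluded
  expect_true(all(c("p81", "p95") %in% px$variant_id))
  # both sentinels appear as their own proxy with r2 = 1 (rs2 has no proxies)
  self <- px[px$role == "sentinel", ]
  expect_setequal(self$variant_id, c("rs1", "rs2"))
  expect_true(all(self$r2 == 1))

  bad <- toy_variants()
  bad$sentinel_id[3] <- "rs99"
  expect_error(expand_proxies(bad), "unknown sentinel")
})

v2g_fixture <- function() {
  # genes gG (tss 5000) and gH (tss 40000); proxy chain pieces around 20 kb
  sizes <- c(chr1 = 100000)
  genes <- data.frame(gene_id = c("gG", "gH"), chrom = "chr1",
                      tss = c(5000, 40000), strand = "+")
  prom <- promoter_windows(genes, sizes)
  list(sizes = sizes, genes = genes, prom = prom)
}

test_that("gene implication follows the open-proxy -> OCR -> promoter/PIR routes", {
  fx <- v2g_fixture()
  ocr_pir <- granges_from_bed("chr1", 20000, 20300)       # inside a contact other end
  ocr_closed <- granges_from_bed("chr1", 70000, 70200)    # no contact, no promoter
  ocrs <- classify_ocrs(suppressWarnings(c(ocr_pir, ocr_closed)), fx$prom,
                        granges_from_bed("chr1", 19900, 20500))
  contacts <- pc_row("gG", c(3501, 5500), c(19901, 20500), res = "1frag")
  proxies <- data.frame(variant_id = c("pA", "pB"), chrom = "chr1",
                        pos = c(20100L, 70100L), ref = "A", alt = "G",
                        role = "proxy", sentinel_id = c("rsA", "rsB"),
                        r2 = c(0.95, 0.95), stringsAsFactors = FALSE)
  v2g <- implicate_genes(proxies, ocrs, contacts, fx$prom, cell_type = "cellA")
  # planted chain: exactly one pir_contact record for gG; closed proxy yields none
  expect_equal(nrow(v2g), 1L)
  expect_equal(v2g$gene_id, "gG")
  expect_equal(v2g$mechanism, "pir_contact")
  expect_equal(v2g$resolution, "1frag")
  expect_equal(v2g$sentinel_id, "rsA")

  # proxy inside gG's promoter OCR that also contacts gH's promoter:
  # records for gG (promoter_overlap) and gH (pir_contact)
  ocr_prom <- classify_ocrs(granges_from_bed("chr1", 4800, 5200), fx$prom,
                            GenomicRanges::GRanges())
  b2b <- pc_row("gH", c(38501, 40500), c(4501, 5500), res = "1frag", b2b = TRUE)
  prox2 <- data.frame(variant_id = "pC", chrom = "chr1", pos = 5000L,
                      ref = "A", alt = "G", role = "proxy", sentinel_id = "rsC",
                      r2 = 0.9, stringsAsFactors = FALSE)
  v2 <- implicate_genes(prox2, ocr_prom, b2b, fx$prom, cell_type = "cellA")
  expect_setequal(v2$gene_id, c("gG", "gH"))
  expect_equal(v2$mechanism[v2$gene_id == "gG"], "promoter_overlap")
  expect_equal(v2$mechanism[v2$gene_id == "gH"], "pir_contact")

  # resolutions union into one deduplicated record
  both_res <- rbind(contacts, pc_row("gG", c(3501, 6000), c(19001, 21000), res = "4frag"))
  v3 <- implicate_genes(proxies[1, ], ocrs, both_res, fx$prom, cell_type = "cellA")
  expect_equal(nrow(v3), 1L)
  expect_equal(v3$resolution, "1frag,4frag")
})

test_that("sentinel classification partitions by relation to the nearest gene", {
  genes <- data.frame(gene_id = c("gN", "gF"), chrom = "chr1",
                      tss = c(1000, 90000), strand = "+")
  sentinels <- data.frame(variant_id = c("s1", "s2", "s3"), chrom = "chr1",
                          pos = c(1500L, 1600L, 1700L), stringsAsFactors = FALSE)
  v2g <- data.frame(
    sentinel_id = c("s1", "s2", "s2", "s3"),
    cell_type = "cellA",
    gene_id = c("gN", "gN", "gF", "gF"), stringsAsFactors = FALSE
  )
  cl <- classify_sentinels(v2g, genes, sentinels)
  expect_equal(cl$category[cl$sentinel_id == "s1"], "nearest_only")
  expect_equal(cl$category[cl$sentinel_id == "s2"], "multiple_including_nearest")
  expect_equal(cl$category[cl$sentinel_id == "s3"], "not_nearest")
  expect_equal(sort(unique(cl$category)),
               sort(c("nearest_only", "multiple_including_nearest", "not_nearest")))
  # counts invariant to record order
  cl2 <- classify_sentinels(v2g[rev(seq_len(nrow(v2g))), ], genes, sentinels)
  expect_equal(table(cl2$category), table(cl$category))
})

test_that("cross-cell-type summary counts exclusive and shared genes", {
  sets <- list(A = c("g1", "g2", "g5"), B = c("g3", "g5"), C = c("g4", "g5", "g3"))
  s <- cross_celltype_summary(sets)
  expect_equal(s$union_size, 5L)
  expect_equal(unname(s$exclusive), c(2, 0, 1))
  expect_equal(s$n_shared_two_plus, 2L)   # g3 (B,C) and g5 (all)
  expect_equal(s$n_shared_all, 1L)
  expect_equal(s$n_one_cell + s$n_shared_two_plus, s$union_size)
  expect_equal(s$pct_one_cell + s$pct_shared_two_plus, 100, tolerance = 0.1)
  expect_error(cross_celltype_summary(list(A = "g1")), "at least two")
})

test_that("cRE annotation export merges promoter OCRs and PIR-OCRs", {
  tmp <- withr::local_tempfile(fileext = ".bed")
  ocrs <- granges_from_bed("chr1", c(0, 50, 400), c(100, 200, 500))
  ocrs$class <- c("promoterOCR", "PIR-OCR", "nonPIR-OCR")
  merged <- export_cre_annotation(ocrs, tmp)
  expect_equal(c(bed_starts(merged), bed_ends(merged)), c(0, 200))
  back <- read_regions(tmp, "BED3")
  expect_equal(bed_starts(back), bed_starts(merged))
  expect_equal(bed_ends(back), bed_ends(merged))

  only_non <- ocrs[3]
  m2 <- export_cre_annotation(only_non, tmp)
  expect_length(m2, 0)
  expect_length(read_regions(tmp, "BED3"), 0)   # header comment only
})
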