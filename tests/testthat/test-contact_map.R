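make_contact <- function(bait0, oe0, score, chrom = "chr1", res = "1frag") {
  data.frame(bait_chr = chrom, bait_start = bait0[1] + 1L, bait_end = bait0[2],
             bait_name = ".", oe_chr = chrom, oe_start = oe0[1] + 1L, oe_end = oe0[2],
             oe_name = ".", N_reads = 10L, score = score, resolution = res,
             cell_type = "cellA", stringsAsFactors = FALSE)
}

test_that("score filtering is inclusive at the threshold, idempotent, monotone", {
  tab <- rbind(make_contact(c(0, 100), c(900, 1000), 4.9),
               make_contact(c(0, 100), c(1900, 2000), 5.0),
               make_contact(c(0, 100), c(2900, 3000), 7.2))
  expect_equal(nrow(filter_contacts(tab, 5)), 2L)
  expect_equal(filter_contacts(tab, 0)$score, tab$score)
  expect_equal(nrow(filter_contacts(tab[0, ], 5)), 0L)
  once <- filter_contacts(tab, 5)
  expect_equal(filter_contacts(once, 5)$score, once$score)
  thresholds <- c(0, 3, 5, 6, 8)
  sizes <- vapply(thresholds, function(t) nrow(filter_contacts(tab, t)), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("bait annotation attributes contacts to promoters and flags bait-to-bait", {
  # 10 fragments of 1000 bp; genes A and B with promoters in fragments 1 and 5
  fr <- tile_fragments("chr1", cumsum(rep(1000, 10)))
  sizes <- c(chr1 = 10000)
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                      tss = c(500, 4500), strand = "+")
  prom <- promoter_windows(genes, sizes)

  # promoter fragment <-> intergenic fragment: single record, not bait-to-bait
  c1 <- make_contact(c(0, 1000), c(8000, 9000), 10)
  r1 <- annotate_baits(c1, prom, fr)
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$gene_id, "gA")
  expect_false(r1$is_bait_to_bait)

  # promoter fragment <-> promoter fragment: records for both genes, flagged
  c2 <- make_contact(c(0, 1000), c(4000, 5000), 10)
  r2 <- annotate_baits(c2, prom, fr)
  expect_setequal(r2$gene_id, c("gA", "gB"))
  expect_true(all(r2$is_bait_to_bait))
  # the gB record sees gA's fragment as its interacting end
  expect_equal(r2$oe_start[r2$gene_id == "gB"], 1L)

  # 10 contacts of which 3 both-bait: fraction 0.3
  b2b <- do.call(rbind, replicate(3, c2, simplify = FALSE))
  # other ends on fragments clear of both promoter windows ([0,1000) for gA,
  # [3000,5000) for gB)
  plain <- do.call(rbind, lapply(c(2, 3, 6:10), function(k) {
    make_contact(c(0, 1000), c(k * 1000 - 1000, k * 1000), 10)
  }))
  r3 <- annotate_baits(rbind(b2b, plain), prom, fr)
  expect_equal(attr(r3, "bait_to_bait_fraction"), 0.3)
})

test_that("PIR derivation merges other ends, including both bait-to-bait ends", {
  # abutting other-ends merge into a single PIR
  pc <- rbind(pc_row("gA", c(1, 100), c(1, 4)),
              pc_row("gA", c(1, 100), c(5, 8)))
  pir <- derive_pirs(pc)
  expect_equal(length(pir), 1L)
  expect_equal(c(GenomicRanges::start(pir), GenomicRanges::end(pir)), c(1, 8))

  one <- pc_row("gA", c(1, 100), c(900, 1100))
  p1 <- derive_pirs(one)
  expect_equal(c(GenomicRanges::start(p1), GenomicRanges::end(p1)), c(900, 1100))
  expect_length(derive_pirs(pc[0, ]), 0)

  # merged PIR set equals the per-nucleotide union oracle
  set.seed(5)
  for (i in 1:20) {
    oes <- random_interval_set(sample(2:6, 1))
    pc2 <- do.call(rbind, lapply(seq_along(oes), function(j) {
      pc_row("gA", c(1, 10), c(GenomicRanges::start(oes)[j], GenomicRanges::end(oes)[j]),
             chrom = "chrT")
    }))
    got <- derive_pirs(pc2)
    expect_setequal(covered_positions(got), covered_positions(oes))
    expect_true(all(diff(GenomicRanges::start(got)) > 0))
  }
})

test_that("contact distances are midpoint based, cis only", {
  tab <- make_contact(c(0, 100), c(900, 1100), 10)
  st <- contact_distance_stats(tab)
  expect_equal(st$distances, 950)

  same <- make_contact(c(0, 100), c(0, 100), 10)
  expect_equal(contact_distance_stats(same)$distances, 0)

  two <- rbind(make_contact(c(0, 100), c(100, 200), 10),   # distance 100
               make_contact(c(0, 100), c(300, 400), 10))   # distance 300
  st2 <- contact_distance_stats(two)
  expect_equal(st2$mean, 200)
  expect_equal(st2$cdf(100), 0.5)
  expect_equal(st2$n_cis, 2L)

  trans <- make_contact(c(0, 100), c(900, 1100), 10)
  trans$oe_chr <- "chr2"
  st3 <- contact_distance_stats(rbind(two, trans))
  expect_equal(length(st3$distances), st3$n_cis)
  expect_equal(st3$n_trans, 1L)
})
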