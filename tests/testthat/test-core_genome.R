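test_that("digestion cuts at motif starts and tiles the chromosome", {
  # no cut site: single fragment
  fr <- digest_sequence("AAAAAAAA", "chr1")
  expect_equal(length(fr), 1L)
  expect_equal(c(bed_starts(fr), bed_ends(fr)), c(0, 8))

  # one occurrence at index 2 (N never matches)
  fr <- digest_sequence("NNGATCNN", "chr1")
  expect_equal(bed_starts(fr), c(0, 2))
  expect_equal(bed_ends(fr), c(2, 8))

  # occurrence at index 0 produces no empty leading fragment
  fr <- digest_sequence("GATCGATC", "chr1")
  expect_equal(bed_starts(fr), c(0, 4))
  expect_equal(bed_ends(fr), c(4, 8))

  # lower case matches; motif longer than sequence is one fragment
  expect_equal(length(digest_sequence("aagatcaa", "chr1")), 2L)
  expect_equal(length(digest_sequence("AAA", "chr1")), 1L)
  expect_error(digest_sequence("", "chr1"), "non-empty")
})

test_that("digestion partitions random sequences exactly", {
  set.seed(101)
  for (i in 1:10) {
    n <- sample(50:500, 1)
    seq <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    fr <- digest_sequence(seq, "chrX")
    expect_equal(sum(GenomicRanges::width(fr)), n)
    s <- GenomicRanges::start(fr); e <- GenomicRanges::end(fr)
    expect_equal(s[1], 1L)
    expect_equal(e[length(e)], n)
    if (length(fr) > 1) expect_equal(s[-1], e[-length(e)] + 1L)
    # every cut coincides with a GATC occurrence
    occ <- gregexpr("GATC", seq, fixed = TRUE)[[1]]
    if (length(fr) > 1) expect_true(all((s[-1]) %in% occ))
  }
})

test_that("fragment binning tiles groups of k and conserves fragments", {
  fr8 <- tile_fragments("chr1", cumsum(rep(10, 8)))
  b <- bin_fragments(fr8, 4)
  expect_equal(length(b), 2L)
  expect_equal(unname(vapply(b$member_ids, length, integer(1))), c(4L, 4L))

  fr9 <- tile_fragments("chr1", cumsum(rep(10, 9)))
  b <- bin_fragments(fr9, 4)
  expect_equal(unname(vapply(b$member_ids, length, integer(1))), c(4L, 4L, 1L))

  fr1 <- tile_fragments("chr1", 10)
  b <- bin_fragments(fr1, 4)
  expect_equal(length(b), 1L)
  expect_equal(GenomicRanges::width(b), GenomicRanges::width(fr1))

  # conservation and chromosome confinement on a two-chromosome genome
  fr2 <- suppressWarnings(c(tile_fragments("chr1", cumsum(rep(7, 11))),
                            tile_fragments("chr2", cumsum(rep(9, 6)))))
  b2 <- bin_fragments(fr2, 4)
  expect_equal(sum(lengths(b2$member_ids)), length(fr2))
  expect_true(all(table(as.character(GenomicRanges::seqnames(b2))) == c(3, 2)))
  # bin interval equals the union of member intervals
  expect_equal(sum(GenomicRanges::width(b2)), sum(GenomicRanges::width(fr2)))

  # unsorted input is rejected
  bad <- fr8[c(2, 1, 3:8)]
  expect_error(bin_fragments(bad, 4), "sorted")
})

test_that("promoter windows follow the -1500/+500 convention on both strands", {
  sizes <- c(chr1 = 50000)
  gp <- data.frame(gene_id = "gP", chrom = "chr1", tss = 10000, strand = "+")
  gm <- data.frame(gene_id = "gM", chrom = "chr1", tss = 10000, strand = "-")
  wp <- promoter_windows(gp, sizes)
  wm <- promoter_windows(gm, sizes)
  expect_equal(c(bed_starts(wp), bed_ends(wp)), c(8500, 10500))
  expect_equal(c(bed_starts(wm), bed_ends(wm)), c(9501, 11501))
  expect_equal(GenomicRanges::width(wp), 2000L)
  expect_equal(GenomicRanges::width(wm), 2000L)

  # clamped at the chromosome start
  ge <- data.frame(gene_id = "gE", chrom = "chr1", tss = 100, strand = "+")
  we <- promoter_windows(ge, sizes)
  expect_equal(c(bed_starts(we), bed_ends(we)), c(0, 600))

  expect_error(promoter_windows(
    data.frame(gene_id = "gX", chrom = "chr1", tss = 60000, strand = "+"), sizes
  ), "bounds")
})

test_that("nearest gene minimises TSS distance with lexicographic ties", {
  genes <- data.frame(gene_id = c("gB", "gA", "gC"), chrom = c("chr1", "chr1", "chr2"),
                      tss = c(4000, 7000, 100), strand = "+")
  expect_equal(nearest_gene("chr1", 5000, genes), "gB")
  genes2 <- data.frame(gene_id = c("gB", "gA"), chrom = "chr1",
                       tss = c(4000, 6000), strand = "+")
  expect_equal(nearest_gene("chr1", 5000, genes2), "gA")  # tie at 1000 bp
  expect_equal(nearest_gene("chr1", 7000, genes), "gA")   # identity, distance 0
  expect_error(nearest_gene("chr9", 5000, genes), "unmappable")
})

test_that("interval-to-unit assignment matches per-nucleotide membership", {
  fr <- tile_fragments("chr1", c(2, 8))
  expect_equal(assign_to_units(granges_from_bed("chr1", 2, 8), fr), 2L)
  expect_equal(assign_to_units(granges_from_bed("chr1", 1, 3), fr), c(1L, 2L))
  expect_length(assign_to_units(granges_from_bed("chr1", 8, 9), fr), 0L)
  expect_length(assign_to_units(granges_from_bed("chr9", 0, 5), fr), 0L)

  set.seed(7)
  units <- tile_fragments("chrR", cumsum(sample(3:20, 25, replace = TRUE)))
  total <- max(GenomicRanges::end(units))
  for (i in 1:50) {
    s <- sample.int(total - 1L, 1)
    e <- min(total, s + sample.int(40L, 1))
    q <- granges_from_bed("chrR", s, e)
    got <- assign_to_units(q, units)
    # oracle: a unit is hit iff any of its nucleotides lies in [s, e)
    pos <- s:(e - 1)
    want <- which(vapply(seq_along(units), function(u) {
      any(pos %in% covered_positions(units[u]))
    }, logical(1)))
    expect_equal(got, units$fragment_id[want])
  }
})
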