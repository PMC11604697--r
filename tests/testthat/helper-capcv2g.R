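# Shared fixtures and independent oracles.

# BED-style (0-based half-open) views of a GRanges
bed_starts <- function(gr) GenomicRanges::start(gr) - 1L
bed_ends <- function(gr) GenomicRanges::end(gr)

# tiling fragment GRanges from 0-based boundaries, e.g. ends0 = c(2, 8)
# gives fragments [0,2), [2,8)
tile_fragments <- function(chrom, ends0, chrom_len = max(ends0)) {
  starts0 <- c(0, head(ends0, -1))
  gr <- granges_from_bed(rep(chrom, length(ends0)), starts0, ends0,
                         fragment_id = seq_along(ends0))
  GenomeInfoDb::seqlengths(gr) <- stats::setNames(chrom_len, chrom)
  gr
}

# per-nucleotide membership oracle: the set of 0-based positions covered
covered_positions <- function(gr) {
  if (length(gr) == 0) return(integer(0))
  unique(unlist(lapply(seq_along(gr), function(i) {
    seq(GenomicRanges::start(gr)[i] - 1L, GenomicRanges::end(gr)[i] - 1L)
  })))
}

# random interval set on one chromosome within [0, span)
random_interval_set <- function(n, span = 400, chrom = "chrT") {
  s <- sample.int(span - 2L, n, replace = TRUE)
  w <- sample.int(60L, n, replace = TRUE)
  granges_from_bed(rep(chrom, n), s, pmin(s + w, span))
}

# exact rank-sum two-sided p by enumeration of all C(n, n1) group labellings
# (independent of wilcox.test); assumes no ties
ranksum_enum_oracle <- function(x, y) {
  n1 <- length(x)
  vals <- c(x, y)
  n <- length(vals)
  u_of <- function(idx) sum(outer(vals[idx], vals[-idx], ">"))
  u_obs <- u_of(seq_len(n1))
  combs <- utils::combn(n, n1)
  us <- apply(combs, 2, u_of)
  mu <- n1 * (n - n1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# small, noise-free simulation used for recovery tests
small_recovery_config <- function(seed) {
  sim_config(seed = seed, chrom_lengths = c(chr1 = 6e5), n_genes = 25,
             n_background_peaks = 80, n_contacts = 200, n_sentinels = 12,
             n_planted_chains = 6, dropout = 0, distance_meanlog = log(4e4))
}

# minimal promoter-contact data.frame (1-based inclusive coordinates)
pc_row <- function(gene, bait, oe, score = 10, res = "1frag", ct = "cellA",
                   b2b = FALSE, chrom = "chr1") {
  data.frame(gene_id = gene, bait_chr = chrom, bait_start = bait[1], bait_end = bait[2],
             oe_chr = chrom, oe_start = oe[1], oe_end = oe[2], score = score,
             resolution = res, cell_type = ct, is_bait_to_bait = b2b,
             stringsAsFactors = FALSE)
}
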