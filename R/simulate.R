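# Seeded synthetic-data generator: produces a complete, internally
# consistent input bundle (genome FASTA, gene table, replicate ATAC peaks,
# ibed contacts at both resolutions, sentinel/proxy variants, expression,
# chromatin-state segmentation, PWMs) with planted proxy -> OCR -> PIR ->
# gene chains recorded in a truth table, so every pipeline stage is
# testable without external downloads.

#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic bundle. Defaults
#' are desk-scale study conditions: two 2 Mb chromosomes digested at an
#' expected 400 bp fragment length, three ATAC replicates per cell type
#' with a two-replicate reproducibility requirement, log-normal contact
#' distances with mean around 110 kb, strict r2 > 0.8 proxy expansion, and
#' a 1 log2-unit expression shift for promoter-connected genes.
#'
#' @param seed integer seed fixing the entire bundle
#' @param chrom_lengths named vector of target chromosome lengths (bp);
#'   realised lengths may differ slightly because fragments are whole
#' @param frag_len expected restriction fragment length (bp)
#' @param frag_len_max upper cap on sampled fragment lengths (bp)
#' @param n_genes number of genes (TSSs at least 10 kb apart)
#' @param cell_types character vector of cell-type labels
#' @param n_replicates ATAC replicates per cell type
#' @param n_background_peaks background peak locations per cell type
#' @param peak_width min/max background peak width (bp)
#' @param rep_jitter per-replicate peak edge jitter (bp)
#' @param dropout probability a background peak is missing from a replicate
#' @param n_contacts background called contacts per cell type
#' @param frac_below_threshold fraction of contacts drawn below score 5
#' @param frac_bait_to_bait fraction of contacts joining two promoters
#' @param distance_meanlog,distance_sdlog log-normal contact distance
#'   parameters
#' @param n_sentinels total sentinel variants (includes planted chains)
#' @param proxies_per_sentinel proxies per background sentinel
#' @param ld_window maximum proxy distance from its sentinel (bp)
#' @param n_planted_chains planted proxy->OCR->gene chains (alternating
#'   pir_contact / promoter_overlap mechanisms across cell types)
#' @param planted_motif_fraction fraction of planted chains whose proxy
#'   also disrupts a planted TF motif
#' @param delta log2(TPM+1) shift added to promoter-connected genes
#' @param expr_shape,expr_scale Gamma parameters of baseline log2(TPM+1)
#' @param chromhmm_states named vector of genome coverage fractions per
#'   chromatin state (must sum to 1)
#' @param segment_len expected chromatin-state segment length (bp)
#' @param n_pwms number of generated motifs
#' @param pwm_len min/max motif length (bp)
#' @return a validated config list of class `capc_sim_config`
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chr1 = 2e6, chr2 = 2e6),
                       frag_len = 400, frag_len_max = 1200,
                       n_genes = 80,
                       cell_types = c("cellA", "cellB"),
                       n_replicates = 3,
                       n_background_peaks = 300,
                       peak_width = c(200, 500),
                       rep_jitter = 25, dropout = 0.1,
                       n_contacts = 1000,
                       frac_below_threshold = 0.3,
                       frac_bait_to_bait = 0.15,
                       distance_meanlog = log(8e4), distance_sdlog = 0.8,
                       n_sentinels = 30, proxies_per_sentinel = 5,
                       ld_window = 5e4,
                       n_planted_chains = 10,
                       planted_motif_fraction = 0.5,
                       delta = 1, expr_shape = 2, expr_scale = 1.2,
                       chromhmm_states = c(TssA = 0.03, TssBiv = 0.02, Enh = 0.10,
                                           Tx = 0.25, ReprPC = 0.10, Quies = 0.50),
                       segment_len = 2000,
                       n_pwms = 5, pwm_len = c(10, 12)) {
  cfg <- as.list(environment())
  probs <- c(cfg$dropout, cfg$frac_below_threshold, cfg$frac_bait_to_bait,
             cfg$planted_motif_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]")
  if (abs(sum(chromhmm_states) - 1) > 1e-6) stop("chromhmm_states must sum to 1")
  counts <- c(cfg$n_genes, cfg$n_contacts, cfg$n_sentinels, cfg$n_planted_chains,
              cfg$n_background_peaks, cfg$n_pwms, cfg$n_replicates)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (cfg$n_planted_chains > cfg$n_contacts) {
    stop("infeasible config: more planted chains than contacts")
  }
  if (cfg$n_planted_chains > cfg$n_sentinels) {
    stop("infeasible config: more planted chains than sentinels")
  }
  if (cfg$n_planted_chains > cfg$n_genes) {
    stop("infeasible config: more planted chains than genes")
  }
  if (is.null(names(chrom_lengths))) stop("chrom_lengths must be named")
  class(cfg) <- "capc_sim_config"
  cfg
}

random_bases <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

strip_gatc <- function(s) {
  while (grepl("GATC", s, fixed = TRUE)) s <- gsub("GATC", "GAAC", s, fixed = TRUE)
  s
}

#' Simulate an expression table with a planted connected-gene shift
#'
#' Baseline log2(TPM + 1) values are Gamma(shape, scale) distributed
#' (positive, continuous, right-skewed); connected genes receive an
#' additive shift of `delta` log2 units. With `delta = 0` the two groups
#' are exchangeable.
#'
#' @param n_connected,n_unconnected group sizes
#' @param delta log2 shift for the connected group
#' @param shape,scale Gamma parameters of the baseline
#' @return a list with `expr` (data.frame `gene_id`, `tpm`) and
#'   `connected` (character vector of connected gene ids)
#' @export
simulate_expression <- function(n_connected, n_unconnected, delta = 1,
                                shape = 2, scale = 1.2) {
  n <- n_connected + n_unconnected
  ids <- sprintf("G%05d", seq_len(n))
  connected <- ids[seq_len(n_connected)]
  x <- stats::rgamma(n, shape = shape, scale = scale)
  x[seq_len(n_connected)] <- x[seq_len(n_connected)] + delta
  list(expr = data.frame(gene_id = ids, tpm = 2^x - 1, stringsAsFactors = FALSE),
       connected = connected)
}

# ---- internal generator helpers --------------------------------------------

# sample one chromosome as GATC-separated fragments; returns list(seq, starts)
build_chromosome <- function(target_len, frag_len, frag_len_max) {
  lens <- integer(0)
  total <- 0
  while (total < target_len) {
    l <- min(frag_len_max, max(40L, round(stats::rexp(1, 1 / frag_len))))
    lens <- c(lens, l)
    total <- total + l
  }
  pieces <- character(length(lens))
  for (i in seq_along(lens)) {
    if (i == 1) {
      pieces[i] <- strip_gatc(random_bases(lens[i]))
    } else {
      pieces[i] <- paste0("GATC", strip_gatc(random_bases(lens[i] - 4L)))
    }
  }
  list(seq = paste(pieces, collapse = ""),
       starts1 = cumsum(c(1L, lens[-length(lens)])),
       lens = lens)
}

# mutate `genome_env$seq[[chrom]]`, replacing [start1, start1+nchar(repl)-1]
mutate_seq <- function(genome_env, chrom, start1, repl) {
  s <- genome_env$seq[[chrom]]
  substr(s, start1, start1 + nchar(repl) - 1L) <- repl
  genome_env$seq[[chrom]] <- s
}

# remove GATC occurrences introduced around an inserted motif without
# touching the motif itself; positions are 1-based on the chromosome
fix_gatc_around <- function(genome_env, chrom, motif_start, motif_end) {
  for (pass in 1:10) {
    s <- genome_env$seq[[chrom]]
    lo <- max(1L, motif_start - 3L)
    hi <- min(nchar(s), motif_end + 3L)
    window <- substr(s, lo, hi)
    m <- gregexpr("GATC", window, fixed = TRUE)[[1]]
    if (m[1] == -1) return(invisible(TRUE))
    occ <- lo + m[1] - 1L          # chromosome position of the occurrence
    cand <- occ:(occ + 3L)
    cand <- cand[cand < motif_start | cand > motif_end]
    if (length(cand) == 0) stop("internal: spurious GATC inside planted motif")
    pos <- cand[1]
    cur <- substr(s, pos, pos)
    repl <- setdiff(c("C", "G", "T", "A"), cur)[1]
    mutate_seq(genome_env, chrom, pos, repl)
  }
  stop("internal: could not clear spurious GATC around planted motif")
}

gr_point <- function(chrom, pos1) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(pos1, pos1))
}

overlaps_any <- function(gr, registry) {
  length(registry) > 0 && GenomicRanges::countOverlaps(gr, registry) > 0
}

# O(log n) point-in-tiling lookup tables (fragments tile each chromosome)
make_point_index <- function(gr) {
  ch <- as.character(GenomicRanges::seqnames(gr))
  idx <- split(seq_along(gr), ch)
  lapply(idx, function(ii) {
    list(idx = ii, starts = GenomicRanges::start(gr)[ii],
         ends = GenomicRanges::end(gr)[ii])
  })
}

point_to_unit <- function(index, ch, pos) {
  tab <- index[[ch]]
  if (is.null(tab)) return(NA_integer_)
  j <- findInterval(pos, tab$starts)
  if (j == 0 || pos > tab$ends[j]) return(NA_integer_)
  tab$idx[j]
}

# point-in-interval-set test against a reduced (disjoint, sorted) GRanges;
# seqinfo is dropped so buffered intervals may poke past chromosome ends
make_blocklist <- function(gr) {
  bare <- GenomicRanges::GRanges(as.character(GenomicRanges::seqnames(gr)),
                                 IRanges::IRanges(pmax(1L, GenomicRanges::start(gr)),
                                                  GenomicRanges::end(gr)))
  make_point_index(GenomicRanges::reduce(bare))
}

point_blocked <- function(blocklist, ch, pos) {
  tab <- blocklist[[ch]]
  if (is.null(tab)) return(FALSE)
  j <- findInterval(pos, tab$starts)
  j > 0 && pos <= tab$ends[j]
}

interval_blocked <- function(blocklist, ch, s, e) {
  tab <- blocklist[[ch]]
  if (is.null(tab)) return(FALSE)
  j <- findInterval(e, tab$starts)
  j > 0 && tab$ends[j] >= s
}

# span of the 4-fragment bins overlapping an interval
bin_span <- function(gr, bins) {
  hits <- GenomicRanges::findOverlaps(gr, bins)
  if (length(hits) == 0) return(gr)
  sub <- bins[S4Vectors::subjectHits(hits)]
  GenomicRanges::reduce(GenomicRanges::granges(sub), min.gapwidth = 1e9)
}
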