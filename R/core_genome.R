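# Restriction-fragment model of a genome: in silico digestion, fragment
# binning, promoter windows and nearest-gene geometry.

#' In silico restriction digestion of one chromosome
#'
#' Cuts a nucleotide sequence at the first base of every occurrence of the
#' recognition motif (the `^GATC` convention for DpnII) and returns the
#' resulting fragments. Fragments tile the chromosome exactly: the first
#' starts at position 1, adjacent fragments abut, and the last ends at the
#' chromosome length. A motif occurrence at the very start of the sequence
#' does not produce an empty leading fragment. Ambiguous bases (N) never
#' match the motif; matching is case-insensitive.
#'
#' @param seq a character string or `Biostrings::DNAString` with the
#'   chromosome sequence
#' @param chrom chromosome name
#' @param motif recognition sequence (default `"GATC"`, DpnII)
#' @return a `GRanges` of fragments with metadata column `fragment_id`
#'   (1-based ordinal along the chromosome) and `seqlengths` set
#' @export
digest_sequence <- function(seq, chrom, motif = "GATC") {
  if (is.character(seq)) {
    if (length(seq) != 1 || nchar(seq) == 0) stop("seq must be a single non-empty sequence")
    seq <- Biostrings::DNAString(toupper(seq))
  }
  n <- length(seq)
  if (n == 0) stop("seq must be non-empty")
  if (nchar(motif) == 0) stop("motif must be non-empty")
  # fixed = TRUE: IUPAC ambiguity codes in the subject (e.g. N) never match
  hits <- Biostrings::matchPattern(toupper(motif), seq, fixed = TRUE)
  cuts <- BiocGenerics::start(hits)          # 1-based first base of each site
  cuts <- cuts[cuts > 1L]                    # cut at position 1 => no empty fragment
  starts <- c(1L, cuts)
  ends <- c(cuts - 1L, n)
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = starts, end = ends),
    fragment_id = seq_along(starts)
  )
  GenomeInfoDb::seqlengths(gr) <- stats::setNames(n, chrom)
  gr
}

#' Digest every chromosome of a genome
#'
#' @param genome a named `DNAStringSet` (or named character vector) of
#'   chromosome sequences
#' @inheritParams digest_sequence
#' @return a `GRanges` of fragments across all chromosomes; `fragment_id`
#'   restarts at 1 on each chromosome
#' @export
digest_genome <- function(genome, motif = "GATC") {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (is.null(names(genome)) || any(!nzchar(names(genome)))) {
    stop("genome sequences must be named by chromosome")
  }
  frags <- lapply(names(genome), function(ch) digest_sequence(genome[[ch]], ch, motif))
  out <- suppressWarnings(do.call(c, frags))
  GenomeInfoDb::seqlengths(out) <-
    stats::setNames(Biostrings::width(genome), names(genome))
  out
}

check_fragment_tiling <- function(fragments) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(fragments)),
    start = GenomicRanges::start(fragments),
    end = GenomicRanges::end(fragments)
  )
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, ]
    if (is.unsorted(d$start)) stop("fragments must be sorted within chromosome")
    if (d$start[1] != 1L) stop("first fragment must start at the chromosome origin")
    if (nrow(d) > 1 && any(d$start[-1] != d$end[-nrow(d)] + 1L)) {
      stop("fragments must abut exactly (no gaps or overlaps)")
    }
  }
  invisible(TRUE)
}

#' Bin consecutive restriction fragments
#'
#' Groups each chromosome's fragments into non-overlapping tiles of `k`
#' consecutive fragments, anchored at the first fragment; the final bin may
#' hold fewer than `k`. Every fragment belongs to exactly one bin and each
#' bin's interval is the union of its members.
#'
#' @param fragments fragment `GRanges` from [digest_sequence()] /
#'   [digest_genome()]
#' @param k bin size in fragments (default 4, the "4frag" resolution)
#' @return a `GRanges` of bins with metadata columns `bin_id` (per
#'   chromosome) and `member_ids` (an `IntegerList` of member fragment ids)
#' @export
bin_fragments <- function(fragments, k = 4L) {
  if (k < 1) stop("k must be >= 1")
  check_fragment_tiling(fragments)
  ch <- as.character(GenomicRanges::seqnames(fragments))
  pieces <- lapply(unique(ch), function(cc) {
    fr <- fragments[ch == cc]
    n <- length(fr)
    grp <- (seq_len(n) - 1L) %/% as.integer(k) + 1L
    starts <- tapply(GenomicRanges::start(fr), grp, min)
    ends <- tapply(GenomicRanges::end(fr), grp, max)
    members <- IRanges::IntegerList(split(fr$fragment_id, grp))
    GenomicRanges::GRanges(
      cc, IRanges::IRanges(start = as.integer(starts), end = as.integer(ends)),
      bin_id = seq_along(starts), member_ids = members
    )
  })
  out <- suppressWarnings(do.call(c, pieces))
  sl <- GenomeInfoDb::seqlengths(fragments)
  if (!all(is.na(sl))) {
    GenomeInfoDb::seqlengths(out) <- sl[GenomeInfoDb::seqlevels(out)]
  }
  out
}

validate_genes <- function(genes) {
  stop_if_missing_cols(genes, c("gene_id", "chrom", "tss", "strand"), "gene table")
  if (!all(genes$strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  if (anyDuplicated(genes$gene_id)) stop("gene_id values must be unique")
  invisible(genes)
}

#' Promoter windows around transcription start sites
#'
#' Builds the promoter window covering 1500 bp transcriptionally upstream and
#' 500 bp downstream of each TSS (the \eqn{-1500/+500} convention), mirrored
#' for minus-strand genes and truncated at chromosome bounds. Windows are
#' exactly 2000 bp except when clamped at a chromosome end.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `tss` (0-based
#'   position of the first transcribed base) and `strand` (`+`/`-`)
#' @param chrom_sizes named integer vector of chromosome lengths (bp)
#' @param upstream,downstream window extent in transcription direction (bp)
#' @return a `GRanges` of promoter windows with metadata column `gene_id`
#' @export
promoter_windows <- function(genes, chrom_sizes, upstream = 1500L, downstream = 500L) {
  validate_genes(genes)
  if (is.null(names(chrom_sizes))) stop("chrom_sizes must be a named vector")
  miss <- setdiff(unique(genes$chrom), names(chrom_sizes))
  if (length(miss) > 0) stop("unknown chromosome(s) in gene table: ", paste(miss, collapse = ", "))
  len <- unname(chrom_sizes[genes$chrom])
  if (any(genes$tss < 0 | genes$tss >= len)) stop("TSS outside chromosome bounds")
  plus <- genes$strand == "+"
  # 0-based half-open window, then clamped
  s0 <- ifelse(plus, genes$tss - upstream, genes$tss - (downstream - 1L))
  e0 <- ifelse(plus, genes$tss + downstream, genes$tss + upstream + 1L)
  s0 <- pmax(s0, 0L)
  e0 <- pmin(e0, len)
  gr <- granges_from_bed(genes$chrom, s0, e0, gene_id = genes$gene_id)
  GenomicRanges::strand(gr) <- genes$strand
  GenomeInfoDb::seqlengths(gr) <-
    chrom_sizes[GenomeInfoDb::seqlevels(gr)]
  gr
}

#' Nearest gene to a genomic position
#'
#' Returns the gene whose TSS lies at minimum absolute distance from the
#' query position; ties are broken by lexicographically smallest `gene_id`
#' for reproducibility.
#'
#' @param chrom chromosome of the query position
#' @param pos 0-based position (vectorised)
#' @param genes gene table as in [promoter_windows()]
#' @return character vector of gene ids
#' @export
nearest_gene <- function(chrom, pos, genes) {
  validate_genes(genes)
  if (length(chrom) == 1 && length(pos) > 1) chrom <- rep(chrom, length(pos))
  vapply(seq_along(pos), function(i) {
    g <- genes[genes$chrom == chrom[i], , drop = FALSE]
    if (nrow(g) == 0) stop("no gene on chromosome '", chrom[i], "': unmappable position")
    d <- abs(g$tss - pos[i])
    cand <- g$gene_id[d == min(d)]
    sort(cand)[1]
  }, character(1))
}

#' Map an interval onto tiling units (fragments or bins)
#'
#' Returns the ids of all units overlapping the query by at least one base
#' pair, in genomic order. A query chromosome absent from the units yields
#' an empty result.
#'
#' @param query a `GRanges` of length 1 (or BED-style `chrom`,`start0`,`end0`
#'   via [granges_from_bed()])
#' @param units fragment or bin `GRanges` with an id metadata column
#' @param id_col name of the unit id column (default auto-detects
#'   `fragment_id` or `bin_id`)
#' @return integer vector of unit ids
#' @export
assign_to_units <- function(query, units, id_col = NULL) {
  if (is.null(id_col)) {
    id_col <- intersect(c("fragment_id", "bin_id"), names(S4Vectors::mcols(units)))[1]
    if (is.na(id_col)) stop("units must carry a fragment_id or bin_id column")
  }
  # a query chromosome absent from the units is a valid empty result
  hits <- suppressWarnings(GenomicRanges::findOverlaps(query, units, minoverlap = 1L))
  idx <- sort(S4Vectors::subjectHits(hits))
  S4Vectors::mcols(units)[[id_col]][idx]
}
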