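# Score-filtering of called contacts, bait annotation, promoter-interacting
# region (PIR) derivation and contact-distance summaries.

#' Filter called contacts on interaction score
#'
#' Keeps rows with `score >= min_score` (the conventional significance
#' threshold for Capture-C interaction scores is 5, applied inclusively).
#' Idempotent and monotone in `min_score`.
#'
#' @param contacts contact data.frame (see [read_contacts_ibed()])
#' @param min_score minimum retained score (default 5)
#' @return the filtered contact table; counts of retained rows per
#'   resolution attached as attribute `retained_by_resolution`
#' @export
filter_contacts <- function(contacts, min_score = 5) {
  stop_if_missing_cols(contacts, "score", "contact table")
  out <- contacts[contacts$score >= min_score, , drop = FALSE]
  rownames(out) <- NULL
  if ("resolution" %in% names(out)) {
    attr(out, "retained_by_resolution") <- table(out$resolution)
  }
  out
}

#' Annotate contact ends against baited promoter units
#'
#' Labels each contact end bait/non-bait by overlap with a promoter-containing
#' unit (restriction fragment or bin), and emits one promoter-contact record
#' per implicated bait gene. Contacts whose two ends are both baited are
#' flagged `is_bait_to_bait` and attributed to both promoters' contact lists
#' (each promoter sees the other end as its interacting region). Contacts
#' whose designated bait does not map to any promoter are dropped (their
#' count is attached as attribute `n_unbaited`).
#'
#' @param contacts filtered contact data.frame
#' @param promoters promoter window `GRanges` from [promoter_windows()]
#' @param units fragment or bin `GRanges` tiling the genome
#' @return data.frame of promoter contacts: one row per (contact, bait gene)
#'   with columns `gene_id`, bait and other-end coordinates (1-based
#'   inclusive), `score`, `resolution`, `cell_type`, `is_bait_to_bait`
#' @export
annotate_baits <- function(contacts, promoters, units) {
  stop_if_missing_cols(contacts, contact_cols, "contact table")
  if (nrow(contacts) == 0) {
    return(empty_promoter_contacts())
  }
  bait_gr <- GenomicRanges::GRanges(contacts$bait_chr,
                                    IRanges::IRanges(contacts$bait_start, contacts$bait_end))
  oe_gr <- GenomicRanges::GRanges(contacts$oe_chr,
                                  IRanges::IRanges(contacts$oe_start, contacts$oe_end))
  if (any(GenomicRanges::countOverlaps(bait_gr, units) == 0) ||
      any(GenomicRanges::countOverlaps(oe_gr, units) == 0)) {
    stop("contact end not mappable to any unit")
  }
  # genes reachable from an end: promoters overlapping any unit that the end overlaps
  genes_for <- function(end_gr) {
    uo <- GenomicRanges::findOverlaps(end_gr, units)
    pu <- GenomicRanges::findOverlaps(units, promoters)
    # end i -> units -> promoters
    m <- merge(
      data.frame(row = S4Vectors::queryHits(uo), unit = S4Vectors::subjectHits(uo)),
      data.frame(unit = S4Vectors::queryHits(pu), prom = S4Vectors::subjectHits(pu)),
      by = "unit"
    )
    m$gene_id <- promoters$gene_id[m$prom]
    unique(m[, c("row", "gene_id")])
  }
  bait_genes <- genes_for(bait_gr)
  oe_genes <- genes_for(oe_gr)
  b2b_rows <- intersect(unique(bait_genes$row), unique(oe_genes$row))

  rec <- function(rows_genes, bait_side) {
    if (nrow(rows_genes) == 0) return(NULL)
    i <- rows_genes$row
    if (bait_side == "bait") {
      data.frame(
        gene_id = rows_genes$gene_id,
        bait_chr = contacts$bait_chr[i], bait_start = contacts$bait_start[i],
        bait_end = contacts$bait_end[i],
        oe_chr = contacts$oe_chr[i], oe_start = contacts$oe_start[i],
        oe_end = contacts$oe_end[i],
        score = contacts$score[i], resolution = contacts$resolution[i],
        cell_type = contacts$cell_type[i],
        is_bait_to_bait = i %in% b2b_rows,
        stringsAsFactors = FALSE
      )
    } else {
      # the other-end promoter's record: ends swapped
      data.frame(
        gene_id = rows_genes$gene_id,
        bait_chr = contacts$oe_chr[i], bait_start = contacts$oe_start[i],
        bait_end = contacts$oe_end[i],
        oe_chr = contacts$bait_chr[i], oe_start = contacts$bait_start[i],
        oe_end = contacts$bait_end[i],
        score = contacts$score[i], resolution = contacts$resolution[i],
        cell_type = contacts$cell_type[i],
        is_bait_to_bait = TRUE,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- rbind(rec(bait_genes, "bait"),
               rec(oe_genes[oe_genes$row %in% b2b_rows, , drop = FALSE], "oe"))
  if (is.null(out)) out <- empty_promoter_contacts()
  out <- unique(out)
  rownames(out) <- NULL
  attr(out, "n_unbaited") <- sum(!seq_len(nrow(contacts)) %in% unique(bait_genes$row))
  attr(out, "bait_to_bait_fraction") <- length(b2b_rows) / nrow(contacts)
  out
}

empty_promoter_contacts <- function() {
  data.frame(gene_id = character(), bait_chr = character(), bait_start = integer(),
             bait_end = integer(), oe_chr = character(), oe_start = integer(),
             oe_end = integer(), score = numeric(), resolution = character(),
             cell_type = character(), is_bait_to_bait = logical(),
             stringsAsFactors = FALSE)
}

#' Derive promoter-interacting regions (PIRs)
#'
#' Merges the other-end intervals of annotated promoter contacts into a
#' sorted, non-overlapping interval set. Bait-to-bait contacts contribute
#' both ends, since each promoter is the other promoter's interacting
#' region (this falls out of the per-gene records of [annotate_baits()]).
#'
#' @param promoter_contacts data.frame from [annotate_baits()]
#' @return a reduced `GRanges` of PIRs
#' @export
derive_pirs <- function(promoter_contacts) {
  if (nrow(promoter_contacts) == 0) return(GenomicRanges::GRanges())
  gr <- GenomicRanges::GRanges(
    promoter_contacts$oe_chr,
    IRanges::IRanges(promoter_contacts$oe_start, promoter_contacts$oe_end)
  )
  GenomicRanges::reduce(BiocGenerics::sort(gr))
}

#' Contact distance summaries
#'
#' Midpoint-to-midpoint distances between the two ends of each cis contact
#' (midpoints are robust to the 1-fragment vs 4-fragment resolutions).
#' Trans-chromosomal contacts are excluded from the distances and counted
#' separately.
#'
#' @param contacts contact data.frame (raw or annotated; needs bait/oe
#'   coordinate columns)
#' @return a list with `distances`, `mean`, the empirical `cdf` function,
#'   `n_cis`, `n_trans`, and a per-resolution breakdown `by_resolution`
#'   when a resolution column is present
#' @export
contact_distance_stats <- function(contacts) {
  stop_if_missing_cols(contacts,
                       c("bait_chr", "bait_start", "bait_end", "oe_chr", "oe_start", "oe_end"),
                       "contact table")
  cis <- contacts$bait_chr == contacts$oe_chr
  d <- abs(interval_midpoint(contacts$bait_start[cis], contacts$bait_end[cis]) -
             interval_midpoint(contacts$oe_start[cis], contacts$oe_end[cis]))
  out <- list(
    distances = d,
    mean = if (length(d) > 0) mean(d) else NA_real_,
    cdf = if (length(d) > 0) stats::ecdf(d) else NULL,
    n_cis = sum(cis), n_trans = sum(!cis)
  )
  if ("resolution" %in% names(contacts) && length(d) > 0) {
    out$by_resolution <- tapply(d, contacts$resolution[cis], function(v) {
      list(n = length(v), mean = mean(v))
    })
  }
  out
}
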