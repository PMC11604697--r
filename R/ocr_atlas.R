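# Consensus open-chromatin region (OCR) calling from replicate ATAC peak
# sets, classification against promoters and PIRs, and Jaccard similarity
# between cell-type annotations.

#' Consensus OCRs from replicate peak sets
#'
#' Clusters peaks across replicates by single-linkage (>= 1 bp overlap) and
#' emits the union interval of every cluster supported by at least
#' `min_support` distinct replicates. Reproducibility in at least two of
#' three replicates is the conventional criterion.
#'
#' @param replicate_peaks list of peak `GRanges`, one per replicate
#' @param min_support minimum number of distinct supporting replicates
#' @return a `GRanges` of OCRs with metadata column `support`
#' @export
consensus_ocrs <- function(replicate_peaks, min_support = 2L) {
  if (min_support > length(replicate_peaks)) {
    stop("min_support exceeds the number of replicates")
  }
  reps <- lapply(seq_along(replicate_peaks), function(i) {
    gr <- GenomicRanges::granges(replicate_peaks[[i]])
    gr$replicate <- rep(i, length(gr))
    gr
  })
  all_peaks <- suppressWarnings(do.call(c, reps))
  if (length(all_peaks) == 0) return(GenomicRanges::GRanges(support = integer()))
  # min.gapwidth = 0: merge only genuinely overlapping ranges (not abutting),
  # which is exactly single-linkage clustering by >= 1 bp overlap
  clusters <- GenomicRanges::reduce(all_peaks, min.gapwidth = 0L)
  hits <- GenomicRanges::findOverlaps(all_peaks, clusters, minoverlap = 1L)
  support <- tapply(all_peaks$replicate[S4Vectors::queryHits(hits)],
                    S4Vectors::subjectHits(hits),
                    function(r) length(unique(r)))
  supp <- integer(length(clusters))
  supp[as.integer(names(support))] <- as.integer(support)
  clusters$support <- supp
  BiocGenerics::sort(clusters[supp >= min_support])
}

#' Classify OCRs against promoter windows and PIRs
#'
#' Assigns each OCR exactly one primary class: `promoterOCR` if it overlaps
#' any promoter window (promoter takes precedence), else `PIR-OCR` if it
#' overlaps a promoter-interacting region, else `nonPIR-OCR`. A secondary
#' `pir_overlap` flag records PIR contact regardless of the primary class.
#'
#' @param ocrs OCR `GRanges` from [consensus_ocrs()]
#' @param promoters promoter window `GRanges`
#' @param pirs PIR `GRanges` from [derive_pirs()]
#' @return `ocrs` with metadata columns `class` and `pir_overlap`; per-class
#'   counts in `S4Vectors::metadata(.)$class_counts`
#' @export
classify_ocrs <- function(ocrs, promoters, pirs) {
  in_prom <- GenomicRanges::countOverlaps(ocrs, promoters, minoverlap = 1L) > 0
  in_pir <- GenomicRanges::countOverlaps(ocrs, pirs, minoverlap = 1L) > 0
  cls <- ifelse(in_prom, "promoterOCR", ifelse(in_pir, "PIR-OCR", "nonPIR-OCR"))
  ocrs$class <- cls
  ocrs$pir_overlap <- in_pir
  counts <- c(promoterOCR = sum(cls == "promoterOCR"),
              `PIR-OCR` = sum(cls == "PIR-OCR"),
              `nonPIR-OCR` = sum(cls == "nonPIR-OCR"))
  S4Vectors::metadata(ocrs)$class_counts <- counts
  ocrs
}

#' Jaccard index of two genomic interval sets
#'
#' Nucleotide-level intersection over union after merging each set to
#' non-overlapping intervals. An empty union yields 0 by definition.
#'
#' @param a,b `GRanges` interval sets
#' @return a number in \[0, 1\]
#' @export
jaccard_index <- function(a, b) {
  a <- GenomicRanges::reduce(GenomicRanges::granges(a))
  b <- GenomicRanges::reduce(GenomicRanges::granges(b))
  inter <- sum(as.numeric(GenomicRanges::width(GenomicRanges::intersect(a, b))))
  uni <- sum(as.numeric(GenomicRanges::width(GenomicRanges::union(a, b))))
  if (uni == 0) return(0)
  inter / uni
}

#' Pairwise Jaccard matrix across cell-type annotations
#'
#' @param sets named list of `GRanges` (one per cell type)
#' @return symmetric numeric matrix of Jaccard indices
#' @export
jaccard_matrix <- function(sets) {
  n <- length(sets)
  m <- matrix(1, n, n, dimnames = list(names(sets), names(sets)))
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- jaccard_index(sets[[i]], sets[[j]])
    }
  }
  m
}
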