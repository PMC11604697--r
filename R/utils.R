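#' @keywords internal
#' @importFrom stats ecdf median pt rexp rgamma rlnorm rnorm rpois runif
#'   sd setNames p.adjust phyper t.test wilcox.test
#' @importFrom utils read.delim write.table head tail
"_PACKAGE"

# Round half away from zero (commercial rounding); base round() is half-even.
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Build a GRanges from BED-style (0-based half-open) coordinates
#'
#' @param chrom character vector of chromosome names
#' @param start0 0-based inclusive starts
#' @param end0 exclusive ends
#' @param ... further metadata columns
#' @return a `GRanges` (1-based closed, the native R convention)
#' @export
granges_from_bed <- function(chrom, start0, end0, ...) {
  if (any(start0 < 0) || any(start0 >= end0)) {
    stop("invalid interval: require 0 <= start < end")
  }
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start0 + 1L, end = end0), ...)
}

# 0-based starts / exclusive ends of a GRanges (for BED-style output)
bed_start <- function(gr) GenomicRanges::start(gr) - 1L
bed_end <- function(gr) GenomicRanges::end(gr)

# midpoint on the 0-based continuous axis (robust to odd widths)
interval_midpoint <- function(start1, end1) {
  (start1 - 1 + end1) / 2
}

stop_if_missing_cols <- function(df, cols, what = "table") {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop(sprintf("%s is missing required column(s): %s", what, paste(miss, collapse = ", ")))
  }
  invisible(df)
}
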