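# Statistical comparisons: rank-sum expression enrichment, chromatin-state
# fold enrichment, hypergeometric gene-set overlap, delta-delta-Ct
# normalisation and paired t tests.

#' Mann-Whitney / Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test reporting the Mann-Whitney U statistic for the
#' first sample (number of (x, y) pairs with x > y, counting ties 1/2).
#' The p value is computed by exact enumeration when `n1 + n2 <= 10` and no
#' ties are present, and otherwise by the normal approximation with tie and
#' continuity corrections.
#'
#' @param x,y numeric samples (both non-empty)
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`
#' @return a list with `U`, `p`, `n1`, `n2`, `median_x`, `median_y`,
#'   `method` (`"exact"` or `"normal_approx"`)
#' @export
rank_sum_test <- function(x, y, alternative = "two.sided") {
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y) <= 10) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative,
                       exact = exact, correct = TRUE)
  )
  list(U = unname(wt$statistic), p = wt$p.value,
       n1 = length(x), n2 = length(y),
       median_x = stats::median(x), median_y = stats::median(y),
       method = if (exact) "exact" else "normal_approx")
}

#' Format a p value with the conventional floor
#'
#' Values below the floor print as `"< 2.2e-16"` (the conventional double
#' precision floor); the raw float is always available from the test
#' objects themselves.
#'
#' @param p p value(s)
#' @param floor smallest printed value
#' @return character vector
#' @export
format_pvalue <- function(p, floor = 2.2e-16) {
  vapply(p, function(pi) {
    if (pi < floor) paste0("< ", format(floor)) else format(signif(pi, 3))
  }, character(1))
}

#' Expression enrichment of promoter-connected genes
#'
#' Compares log2(TPM + 1) between genes whose promoter contacts at least one
#' PIR-OCR and the remaining genes, by rank-sum test. The two-sided p value
#' is reported together with the one-sided p for the connected group being
#' higher, and the direction of the median difference.
#'
#' @param expr expression data.frame with `gene_id` and a TPM column
#' @param connected_genes character vector of promoter-connected gene ids
#' @param tpm_col name of the TPM column (default the first non-`gene_id`
#'   column)
#' @return a list with the two-sided [rank_sum_test()] result, `p_greater`,
#'   `direction`, and the group sizes after dropping unknown genes
#' @export
expression_contact_comparison <- function(expr, connected_genes, tpm_col = NULL) {
  stop_if_missing_cols(expr, "gene_id", "expression table")
  if (is.null(tpm_col)) tpm_col <- setdiff(names(expr), "gene_id")[1]
  if (length(connected_genes) == 0) stop("connected gene set is empty")
  missing <- setdiff(connected_genes, expr$gene_id)
  if (length(missing) > 0) {
    warning(length(missing), " connected gene(s) absent from expression table; skipped")
    connected_genes <- setdiff(connected_genes, missing)
  }
  if (length(connected_genes) == 0) stop("no connected gene found in expression table")
  is_conn <- expr$gene_id %in% connected_genes
  if (all(is_conn)) stop("no unconnected genes to compare against")
  xc <- log2_tpm(expr[[tpm_col]][is_conn])
  xo <- log2_tpm(expr[[tpm_col]][!is_conn])
  two <- rank_sum_test(xc, xo, "two.sided")
  one <- rank_sum_test(xc, xo, "greater")
  list(test = two, p_two_sided = two$p, p_greater = one$p,
       direction = if (two$median_x > two$median_y) "connected_higher"
       else if (two$median_x < two$median_y) "connected_lower" else "equal_medians",
       n_connected = length(xc), n_unconnected = length(xo))
}

#' Chromatin-state fold enrichment of an interval set
#'
#' For every state s of a segmentation, computes the fold enrichment of a
#' query interval set as the fraction of query base pairs overlapping s
#' divided by the genome fraction covered by s, reported on the log2 scale.
#' States with zero overlap yield `-Inf`.
#'
#' @param query `GRanges` of query intervals (e.g. PIR-OCRs); must be
#'   non-empty
#' @param segmentation `GRanges` with a `state` metadata column
#' @param genome_size total genome size in bp
#' @return data.frame with `state`, `state_bp`, `overlap_bp`,
#'   `expected_frac`, `observed_frac`, `fold`, `log2_fold`
#' @export
chromhmm_enrichment <- function(query, segmentation, genome_size) {
  query <- GenomicRanges::reduce(GenomicRanges::granges(query))
  qbp <- sum(as.numeric(GenomicRanges::width(query)))
  if (qbp == 0) stop("query interval set is empty")
  states <- sort(unique(segmentation$state))
  rows <- lapply(states, function(s) {
    seg <- GenomicRanges::reduce(GenomicRanges::granges(segmentation[segmentation$state == s]))
    sbp <- sum(as.numeric(GenomicRanges::width(seg)))
    ov <- sum(as.numeric(GenomicRanges::width(GenomicRanges::intersect(query, seg))))
    expected <- sbp / genome_size
    fold <- (ov / qbp) / expected
    data.frame(state = s, state_bp = sbp, overlap_bp = ov,
               expected_frac = expected, observed_frac = ov / qbp,
               fold = fold, log2_fold = log2(fold), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-sided gene-set overlap test (hypergeometric / Fisher)
#'
#' Upper-tail hypergeometric probability of observing at least the realised
#' overlap between a hit set and a reference set drawn from a common
#' universe; equivalent to a one-sided Fisher's exact test on the 2x2
#' table, which is returned alongside.
#'
#' @param hits,reference,universe character vectors of gene ids; `hits` and
#'   `reference` must be subsets of `universe`
#' @return a list with `overlap`, `p`, and the 2x2 `table`
#' @export
geneset_overlap_test <- function(hits, reference, universe) {
  hits <- unique(hits); reference <- unique(reference); universe <- unique(universe)
  if (!all(hits %in% universe) || !all(reference %in% universe)) {
    stop("hits and reference must be subsets of the universe")
  }
  k <- length(intersect(hits, reference))
  p <- stats::phyper(k - 1, length(reference),
                     length(universe) - length(reference),
                     length(hits), lower.tail = FALSE)
  tab <- matrix(c(k, length(hits) - k,
                  length(reference) - k,
                  length(universe) - length(hits) - length(reference) + k),
                nrow = 2,
                dimnames = list(hit = c("yes", "no"), reference = c("yes", "no")))
  list(overlap = k, p = p, table = tab)
}

#' Relative expression by the delta-delta-Ct method
#'
#' Normalises qPCR target-gene Ct values to a control gene and a reference
#' sample: dCt = Ct_target - Ct_control, ddCt = dCt - dCt_reference,
#' relative expression = 2^(-ddCt). The reference sample maps to 1.
#'
#' @param ct data.frame with columns `sample`, `ct_target`, `ct_control`
#' @param reference_sample name of the reference sample
#' @return data.frame with `sample`, `dct`, `ddct`, `rel_expr`
#' @export
qpcr_ddct <- function(ct, reference_sample) {
  stop_if_missing_cols(ct, c("sample", "ct_target", "ct_control"), "Ct table")
  if (anyNA(ct$ct_control)) stop("missing control-gene Ct")
  if (!reference_sample %in% ct$sample) stop("reference sample not in table")
  dct <- ct$ct_target - ct$ct_control
  ddct <- dct - dct[match(reference_sample, ct$sample)]
  data.frame(sample = ct$sample, dct = dct, ddct = ddct,
             rel_expr = 2^(-ddct), stringsAsFactors = FALSE)
}

#' Paired two-sided t test with percent change
#'
#' t statistic on the paired differences (n - 1 degrees of freedom), with
#' the percent change of the second condition relative to the first
#' computed on the means. Zero variance of the differences is flagged
#' degenerate: p = 1 when all differences are zero, 0 otherwise.
#'
#' @param x,y paired numeric vectors of equal length (n >= 2)
#' @return a list with `t`, `p`, `df`, `mean_diff`, `percent_change`,
#'   `degenerate`
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  n <- length(x)
  if (n < 2) stop("need at least two pairs")
  d <- y - x
  pc <- 100 * (mean(y) - mean(x)) / mean(x)
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, p = 1, df = n - 1, mean_diff = 0,
                  percent_change = pc, degenerate = TRUE))
    }
    return(list(t = sign(mean(d)) * Inf, p = 0, df = n - 1, mean_diff = mean(d),
                percent_change = pc, degenerate = TRUE))
  }
  tt <- stats::t.test(y, x, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       mean_diff = mean(d), percent_change = pc, degenerate = FALSE)
}
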