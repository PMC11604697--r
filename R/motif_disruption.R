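# Allele-aware PWM scanning at proxy positions: reference-vs-alternative
# best-window scores, score delta and direction, and TF-expression
# filtering of the disrupted-motif summary.

BASES <- c("A", "C", "G", "T")

#' Convert a count PWM to a log-odds matrix (bits)
#'
#' Per column, probabilities are `(count + pseudocount) / (total + 4 *
#' pseudocount)` and entries are `log2(p / background)`.
#'
#' @param pwm PWM record (list with `counts`, see [read_pwm_jaspar()]) or a
#'   bare 4 x L count matrix with rownames A,C,G,T
#' @param background base composition (must sum to 1; default uniform)
#' @param pseudocount added to every count (default 0.25)
#' @return 4 x L numeric matrix of log2 odds
#' @export
pwm_logodds <- function(pwm, background = rep(0.25, 4), pseudocount = 0.25) {
  counts <- if (is.list(pwm)) pwm$counts else pwm
  if (!is.matrix(counts) || nrow(counts) != 4) stop("pwm counts must be a 4 x L matrix")
  if (abs(sum(background) - 1) > 1e-8) stop("background must sum to 1")
  tot <- colSums(counts)
  if (any(tot == 0) && pseudocount == 0) stop("all-zero column with zero pseudocount")
  p <- sweep(counts + pseudocount, 2, tot + 4 * pseudocount, "/")
  lo <- log2(p / background)
  rownames(lo) <- BASES
  lo
}

revcomp_chars <- function(chars) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rev(unname(comp[chars]))
}

score_window <- function(chars, lo) {
  idx <- match(chars, BASES)
  if (anyNA(idx)) return(-Inf)  # ambiguous base in window
  sum(lo[cbind(idx, seq_along(idx))])
}

#' Allele-aware best-window motif score at a variant
#'
#' Scans every window of motif length covering the variant position, on both
#' strands, scoring the window with the reference and the alternative
#' allele. The window maximising `max(score_ref, score_alt)` is selected
#' and retained only if that maximum reaches `min_score_frac` of the
#' highest score the matrix can achieve. The score delta is
#' `score_ref - score_alt`; a positive delta means the alternative allele
#' destabilises the motif (`direction = "decreasing"`), a negative delta
#' means it stabilises it (`"increasing"`).
#'
#' @param context sequence window around the variant (character or
#'   `DNAString`); must extend at least L - 1 bases on each side of the
#'   variant for a full scan
#' @param var_offset 1-based position of the variant within `context`
#' @param ref,alt reference and alternative alleles (single bases); `ref`
#'   must match the context
#' @param pwm PWM record (with `tf_name`) or 4 x L count matrix
#' @param min_score_frac retention threshold as a fraction of the maximum
#'   achievable score (default 0.8)
#' @param background,pseudocount passed to [pwm_logodds()]
#' @return a one-row data.frame (`tf_name`, `strand`, `window_start` within
#'   the context, `score_ref`, `score_alt`, `delta`, `direction`) or `NULL`
#'   when no window passes the threshold
#' @export
scan_variant <- function(context, var_offset, ref, alt, pwm,
                         min_score_frac = 0.8,
                         background = rep(0.25, 4), pseudocount = 0.25) {
  context <- toupper(as.character(context))
  chars <- strsplit(context, "")[[1]]
  if (var_offset < 1 || var_offset > length(chars)) stop("var_offset outside context")
  if (chars[var_offset] != toupper(ref)) {
    stop("reference allele does not match the sequence context ",
         "(coordinate/allele inconsistency)")
  }
  lo <- pwm_logodds(pwm, background, pseudocount)
  L <- ncol(lo)
  max_score <- sum(apply(lo, 2, max))
  tf <- if (is.list(pwm) && !is.null(pwm$tf_name)) pwm$tf_name else "PWM"

  best <- NULL
  for (ws in max(1L, var_offset - L + 1L):var_offset) {
    if (ws + L - 1L > length(chars)) next
    win_ref <- chars[ws:(ws + L - 1L)]
    win_alt <- win_ref
    win_alt[var_offset - ws + 1L] <- toupper(alt)
    for (str in c("+", "-")) {
      wr <- if (str == "+") win_ref else revcomp_chars(win_ref)
      wa <- if (str == "+") win_alt else revcomp_chars(win_alt)
      sr <- score_window(wr, lo)
      sa <- score_window(wa, lo)
      cand <- max(sr, sa)
      if (is.null(best) || cand > best$cand) {
        best <- list(cand = cand, strand = str, ws = ws, sr = sr, sa = sa)
      }
    }
  }
  if (is.null(best) || !is.finite(best$cand) || best$cand < min_score_frac * max_score) {
    return(NULL)
  }
  delta <- best$sr - best$sa
  data.frame(tf_name = tf, strand = best$strand, window_start = best$ws,
             score_ref = best$sr, score_alt = best$sa, delta = delta,
             direction = if (delta > 0) "decreasing"
             else if (delta < 0) "increasing" else "neutral",
             stringsAsFactors = FALSE)
}

#' Scan open proxies against a motif collection
#'
#' Convenience wrapper applying [scan_variant()] to every proxy that falls
#' inside an OCR (open proxies), against every PWM in a collection, pulling
#' the sequence context from the genome.
#'
#' @param genome named `DNAStringSet` (or character vector) of chromosomes
#' @param proxies proxy data.frame (1-based `pos`, `ref`, `alt`)
#' @param pwms list of PWM records
#' @param ocrs optional OCR `GRanges`; when given, only proxies inside an
#'   OCR are scanned
#' @param min_score_frac retention threshold (see [scan_variant()])
#' @return data.frame of motif hits, one row per retained proxy x TF, with
#'   `proxy_id`, `sentinel_id` and the [scan_variant()] columns
#' @export
scan_proxies <- function(genome, proxies, pwms, ocrs = NULL, min_score_frac = 0.8) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (!is.null(ocrs) && nrow(proxies) > 0) {
    pg <- GenomicRanges::GRanges(proxies$chrom, IRanges::IRanges(proxies$pos, proxies$pos))
    open <- GenomicRanges::countOverlaps(pg, ocrs) > 0
    proxies <- proxies[open, , drop = FALSE]
  }
  if (nrow(proxies) == 0) {
    return(data.frame(proxy_id = character(), sentinel_id = character(),
                      tf_name = character(), strand = character(),
                      window_start = integer(), score_ref = numeric(),
                      score_alt = numeric(), delta = numeric(),
                      direction = character(), stringsAsFactors = FALSE))
  }
  maxL <- max(vapply(pwms, function(p) ncol(p$counts), integer(1)))
  rows <- list()
  for (i in seq_len(nrow(proxies))) {
    ch <- proxies$chrom[i]
    if (!ch %in% names(genome)) stop("proxy chromosome absent from genome: ", ch)
    n <- length(genome[[ch]])
    lo_b <- max(1L, proxies$pos[i] - maxL + 1L)
    hi_b <- min(n, proxies$pos[i] + maxL - 1L)
    ctx <- as.character(Biostrings::subseq(genome[[ch]], lo_b, hi_b))
    off <- proxies$pos[i] - lo_b + 1L
    for (p in pwms) {
      hit <- scan_variant(ctx, off, proxies$ref[i], proxies$alt[i], p,
                          min_score_frac = min_score_frac)
      if (!is.null(hit)) {
        hit$proxy_id <- proxies$variant_id[i]
        hit$sentinel_id <- proxies$sentinel_id[i]
        rows[[length(rows) + 1L]] <- hit
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(proxy_id = character(), sentinel_id = character(),
                      tf_name = character(), strand = character(),
                      window_start = integer(), score_ref = numeric(),
                      score_alt = numeric(), delta = numeric(),
                      direction = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[, c("proxy_id", "sentinel_id", "tf_name", "strand", "window_start",
          "score_ref", "score_alt", "delta", "direction")]
}

#' Per-TF summary of predicted motif disruption with expression filters
#'
#' Summarises motif hits per transcription factor (number of disrupting
#' proxies, mean score delta) and checks each TF's expression against TPM
#' thresholds, reporting the global count and percentage of TFs passing
#' each threshold (percentage rounded half-up to one decimal).
#'
#' @param hits motif hit data.frame from [scan_proxies()] (or with at least
#'   `tf_name` and `delta` columns)
#' @param expr expression data.frame with `gene_id` and a TPM column (TF
#'   names are looked up as gene ids; absent TFs are flagged
#'   `expressed = NA`)
#' @param tpm_thresholds numeric thresholds (default c(1, 10))
#' @param tpm_col TPM column (default first non-`gene_id` column)
#' @return a list with `per_tf` (data.frame) and `global` (data.frame with
#'   one row per threshold: `threshold`, `n_tfs`, `n_passing`, `pct`)
#' @export
summarize_tf_disruption <- function(hits, expr, tpm_thresholds = c(1, 10),
                                    tpm_col = NULL) {
  if (nrow(hits) == 0) stop("no motif hits to summarise")
  if (is.null(tpm_col)) tpm_col <- setdiff(names(expr), "gene_id")[1]
  tfs <- sort(unique(hits$tf_name))
  tpm <- expr[[tpm_col]][match(tfs, expr$gene_id)]
  per_tf <- data.frame(
    tf_name = tfs,
    n_proxies = as.integer(table(factor(hits$tf_name, levels = tfs))),
    mean_delta = as.numeric(tapply(hits$delta, factor(hits$tf_name, levels = tfs), mean)),
    tpm = tpm, stringsAsFactors = FALSE
  )
  for (thr in tpm_thresholds) {
    per_tf[[sprintf("tpm_gt_%g", thr)]] <- tpm > thr
  }
  global <- do.call(rbind, lapply(tpm_thresholds, function(thr) {
    pass <- sum(tpm > thr, na.rm = TRUE)
    data.frame(threshold = thr, n_tfs = length(tfs), n_passing = pass,
               pct = round_half_up(100 * pass / length(tfs), 1))
  }))
  list(per_tf = per_tf, global = global)
}
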