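sharp_pwm <- function(consensus, tf = "TFtest") {
  cb <- strsplit(consensus, "")[[1]]
  counts <- matrix(3, 4, length(cb), dimnames = list(c("A", "C", "G", "T"), NULL))
  counts[cbind(match(cb, c("A", "C", "G", "T")), seq_along(cb))] <- 91
  list(matrix_id = "MAtest", tf_name = tf, counts = counts)
}

test_that("log-odds conversion follows the pseudocount formula", {
  unif <- matrix(25, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(pwm_logodds(unif), matrix(0, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL)))

  one <- matrix(c(100, 0, 0, 0), 4, 1, dimnames = list(c("A", "C", "G", "T"), NULL))
  lo <- pwm_logodds(one)
  expect_equal(unname(lo["A", 1]), log2((100.25 / 101) / 0.25), tolerance = 1e-9)
  expect_equal(unname(lo["A", 1]), 1.988, tolerance = 1e-3)

  zero <- matrix(0, 4, 1, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_error(pwm_logodds(zero, pseudocount = 0), "zero pseudocount")
  expect_error(pwm_logodds(one, background = c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
})

test_that("variant scanning finds the planted consensus and signs the delta", {
  pwm <- sharp_pwm("ACGTTACAGG")
  ctx <- paste0("TTTTT", "ACGTTACAGG", "TTTTT")
  off <- 5L + 6L                       # the consensus A at motif column 6
  hit <- scan_variant(ctx, off, "A", "G", pwm)
  expect_false(is.null(hit))
  expect_gt(hit$delta, 0)
  expect_equal(hit$direction, "decreasing")
  expect_equal(hit$delta, hit$score_ref - hit$score_alt)

  # allele swap negates the delta (antisymmetry)
  ctx_alt <- ctx
  substr(ctx_alt, off, off) <- "G"
  swap <- scan_variant(ctx_alt, off, "G", "A", pwm)
  expect_equal(swap$delta, -hit$delta, tolerance = 1e-9)
  expect_equal(swap$direction, "increasing")

  # strand symmetry: the reverse-complement context scores identically
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(ctx)))
  rc_off <- nchar(ctx) - off + 1L
  rc_hit <- scan_variant(rc, rc_off, "T", "C", pwm)   # complements of A/G
  expect_equal(rc_hit$score_ref, hit$score_ref, tolerance = 1e-9)
  expect_equal(rc_hit$score_alt, hit$score_alt, tolerance = 1e-9)

  # a context far from the consensus falls below the retention threshold
  weak <- scan_variant("TTTTTTTTTTTTTTTTTTTTT", 11L, "T", "A", pwm)
  expect_null(weak)

  expect_error(scan_variant(ctx, off, "C", "G", pwm), "does not match")
})

test_that("open-proxy scanning restricts to proxies inside OCRs", {
  pwm <- sharp_pwm("ACGTTACAGG")
  genome <- c(chrM = paste0(strrep("T", 50), "ACGTTACAGG", strrep("T", 50)))
  proxies <- data.frame(
    variant_id = c("pOpen", "pClosed"), chrom = "chrM", pos = c(56L, 56L),
    ref = "A", alt = "G", role = "proxy", sentinel_id = c("rs1", "rs2"),
    r2 = 0.9, stringsAsFactors = FALSE
  )
  ocr_at_motif <- granges_from_bed("chrM", 45, 70)
  hits <- scan_proxies(genome, proxies[1, ], list(pwm), ocrs = ocr_at_motif)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$proxy_id, "pOpen")

  far_ocr <- granges_from_bed("chrM", 90, 100)
  none <- scan_proxies(genome, proxies[2, ], list(pwm), ocrs = far_ocr)
  expect_equal(nrow(none), 0L)
})

test_that("TF disruption summary applies TPM thresholds with half-up rounding", {
  hits <- data.frame(tf_name = c("TF1", "TF1", "TF2", "TF3"),
                     delta = c(1, -1, 2, 0.5), stringsAsFactors = FALSE)
  expr <- data.frame(gene_id = c("TF1", "TF2"), tpm = c(5, 0.2))
  s <- summarize_tf_disruption(hits, expr)
  expect_equal(s$per_tf$mean_delta[s$per_tf$tf_name == "TF1"], 0)  # +1 and -1 cancel
  expect_equal(s$per_tf$n_proxies[s$per_tf$tf_name == "TF1"], 2L)
  expect_true(is.na(s$per_tf$tpm[s$per_tf$tf_name == "TF3"]))      # unknown expression
  g1 <- s$global[s$global$threshold == 1, ]
  expect_equal(g1$n_passing, 1L)
  expect_equal(g1$pct, round(100 / 3, 1), tolerance = 0.051)

  zero <- data.frame(gene_id = c("TF1", "TF2", "TF3"), tpm = 0)
  s0 <- summarize_tf_disruption(hits, zero)
  expect_equal(s0$global$n_passing, c(0L, 0L))
  expect_equal(s0$global$pct, c(0, 0))
})
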