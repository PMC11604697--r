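# Load a generated bundle from disk and replay the planted truth through
# the real pipeline operations.

#' Load a synthetic bundle from disk
#'
#' Reads every file listed in the bundle's `manifest.json` back through the
#' package's format readers and recomputes the genome geometry (digestion,
#' binning, promoter windows) from the FASTA.
#'
#' @param dir bundle directory written by [generate_bundle()]
#' @return a list with `genome`, `chrom_sizes`, `fragments`, `bins`,
#'   `genes`, `promoters`, `peaks` (per cell type, per replicate),
#'   `contacts` (per cell type), `variants`, `expr`, `chromhmm`, `pwms`,
#'   `truth`, `manifest`
#' @export
load_bundle <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  genome <- Biostrings::readDNAStringSet(file.path(dir, mf$files$genome))
  names(genome) <- sub("\\s.*", "", names(genome))
  chrom_sizes <- stats::setNames(Biostrings::width(genome), names(genome))
  fragments <- digest_genome(genome)
  bins <- bin_fragments(fragments, 4L)
  genes <- read_genes(file.path(dir, mf$files$genes))
  promoters <- promoter_windows(genes, chrom_sizes)
  cts <- mf$cell_types
  peaks <- stats::setNames(lapply(cts, function(ct) {
    lapply(unlist(mf$files$peaks[[ct]]), function(fp) {
      read_regions(file.path(dir, fp), "narrowPeak")
    })
  }), cts)
  contacts <- stats::setNames(lapply(cts, function(ct) {
    read_contacts_ibed(file.path(dir, mf$files$contacts[[ct]]))
  }), cts)
  truth <- jsonlite::read_json(file.path(dir, mf$files$truth), simplifyVector = TRUE)
  pwms_path <- file.path(dir, mf$files$pwms)
  list(genome = genome, chrom_sizes = chrom_sizes, fragments = fragments,
       bins = bins, genes = genes, promoters = promoters, peaks = peaks,
       contacts = contacts,
       variants = read_variants(file.path(dir, mf$files$variants), "TSV"),
       expr = read_expression(file.path(dir, mf$files$expression)),
       chromhmm = read_chromhmm(file.path(dir, mf$files$chromhmm)),
       pwms = if (file.exists(pwms_path)) read_pwm_jaspar(pwms_path) else list(),
       truth = truth, manifest = mf)
}

#' Run the variant-to-gene pipeline on a loaded bundle
#'
#' Per cell type: consensus OCR calling, score filtering, bait annotation
#' at both resolutions, PIR derivation, OCR classification and gene
#' implication from the expanded proxies.
#'
#' @param bundle list from [load_bundle()]
#' @param min_score contact score threshold (default 5)
#' @param r2_threshold strict proxy r2 threshold (default 0.8)
#' @param min_support OCR replicate support (default 2)
#' @return a list with `proxies`, `v2g` (all cell types), and `per_cell`
#'   (per cell type: `ocrs`, `pirs`, `promoter_contacts`, `v2g`)
#' @export
run_bundle_pipeline <- function(bundle, min_score = 5, r2_threshold = 0.8,
                                min_support = 2L) {
  proxies <- expand_proxies(bundle$variants, r2_threshold)
  sentinels <- bundle$variants[bundle$variants$role == "sentinel", , drop = FALSE]
  per_cell <- stats::setNames(lapply(names(bundle$peaks), function(ct) {
    ocrs <- consensus_ocrs(bundle$peaks[[ct]], min_support)
    kept <- filter_contacts(bundle$contacts[[ct]], min_score)
    ann <- rbind(
      annotate_baits(kept[kept$resolution == "1frag", , drop = FALSE],
                     bundle$promoters, bundle$fragments),
      annotate_baits(kept[kept$resolution == "4frag", , drop = FALSE],
                     bundle$promoters, bundle$bins)
    )
    pirs <- derive_pirs(ann)
    ocrs <- classify_ocrs(ocrs, bundle$promoters, pirs)
    v2g <- implicate_genes(proxies, ocrs, ann, bundle$promoters,
                           cell_type = ct, genes = bundle$genes,
                           sentinels = sentinels)
    list(ocrs = ocrs, pirs = pirs, promoter_contacts = ann, v2g = v2g)
  }), names(bundle$peaks))
  v2g <- do.call(rbind, lapply(per_cell, `[[`, "v2g"))
  rownames(v2g) <- NULL
  list(proxies = proxies, v2g = v2g, per_cell = per_cell)
}

#' Audit a bundle's planted truth through the pipeline
#'
#' Replays every planted chain (and planted motif disruption) through the
#' real pipeline operations and reports, per chain, whether it was
#' recovered. Sensitivity counts recovered planted (sentinel, gene, cell
#' type, mechanism) chains; precision asks whether every implicated
#' (sentinel, gene, cell type) pair was planted.
#'
#' @param dir bundle directory (or a list from [load_bundle()])
#' @param min_score_frac motif retention threshold (default 0.8)
#' @return a list with `chains` (truth plus `recovered` flag), `v2g`,
#'   `sensitivity`, `precision`, `motif_recall`, `motif_precision`,
#'   `all_pass`
#' @export
audit_truth <- function(dir, min_score_frac = 0.8) {
  bundle <- if (is.list(dir) && !is.null(dir$manifest)) dir else load_bundle(dir)
  res <- run_bundle_pipeline(bundle)
  chains <- as.data.frame(bundle$truth$chains, stringsAsFactors = FALSE)
  v2g <- res$v2g
  key <- function(df, cols) do.call(paste, c(df[cols], sep = "\r"))
  if (nrow(chains) > 0) {
    chains$recovered <- key(chains, c("sentinel_id", "gene_id", "cell_type", "mechanism")) %in%
      key(v2g, c("sentinel_id", "gene_id", "cell_type", "mechanism"))
    sens <- mean(chains$recovered)
    prec <- if (nrow(v2g) == 0) NA_real_ else {
      mean(key(unique(v2g[, c("sentinel_id", "gene_id", "cell_type")]),
               c("sentinel_id", "gene_id", "cell_type")) %in%
             key(chains, c("sentinel_id", "gene_id", "cell_type")))
    }
  } else {
    chains$recovered <- logical(0)
    sens <- NA_real_
    prec <- if (nrow(v2g) == 0) NA_real_ else 0
  }

  motifs <- as.data.frame(bundle$truth$motifs, stringsAsFactors = FALSE)
  motif_recall <- motif_precision <- NA_real_
  if (length(bundle$pwms) > 0) {
    all_ocrs <- suppressWarnings(do.call(c, unname(lapply(res$per_cell, function(x) {
      GenomicRanges::granges(x$ocrs)
    }))))
    hits <- scan_proxies(bundle$genome, res$proxies, bundle$pwms,
                         ocrs = all_ocrs, min_score_frac = min_score_frac)
    flagged <- unique(hits$proxy_id)
    if (nrow(motifs) > 0) {
      hk <- paste(hits$proxy_id, hits$tf_name, hits$direction, sep = "\r")
      mk <- paste(motifs$proxy_id, motifs$tf_name, motifs$expected_direction, sep = "\r")
      motif_recall <- mean(mk %in% hk)
    } else {
      motif_recall <- NA_real_
    }
    motif_precision <- if (length(flagged) == 0) NA_real_ else
      mean(flagged %in% motifs$proxy_id)
  }

  all_pass <- isTRUE(sens == 1) &&
    (is.na(prec) || isTRUE(prec == 1)) &&
    (is.na(motif_recall) || isTRUE(motif_recall == 1)) &&
    (is.na(motif_precision) || isTRUE(motif_precision == 1))
  list(chains = chains, v2g = v2g, sensitivity = sens, precision = prec,
       motif_recall = motif_recall, motif_precision = motif_precision,
       all_pass = all_pass)
}
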