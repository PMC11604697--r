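# generate_bundle(): realise a sim_config as an on-disk input bundle with a
# serialised truth table. Planted chain elements live in reserved genomic
# space (reserved at 4-fragment bin granularity) and background features
# avoid it, so that on noise-free settings the pipeline recovers exactly
# the planted (sentinel, gene) pairs. Negative controls (sub-threshold
# contacts, low-r2 proxies, closed-chromatin proxies) are generated
# alongside the positives.

#' Generate a synthetic input bundle with planted ground truth
#'
#' Writes a complete pipeline input set — genome FASTA, gene table,
#' per-replicate ATAC peaks, ibed contacts at 1-fragment and 4-fragment
#' resolution, sentinel/proxy variants, expression table, chromatin-state
#' segmentation BED and JASPAR motifs — plus `truth.json` recording every
#' planted proxy -> OCR -> gene chain, planted motif disruption and
#' expression shift, and `manifest.json` describing the layout. The same
#' config and seed reproduce the bundle byte for byte.
#'
#' @param config a [sim_config()] object
#' @param out_dir output directory (created if needed)
#' @param seed overrides `config$seed`
#' @return invisibly, a list with `dir`, `files`, `truth`, `genes`,
#'   `chrom_sizes`
#' @export
generate_bundle <- function(config, out_dir, seed = config$seed) {
  if (!inherits(config, "capc_sim_config")) stop("config must come from sim_config()")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "peaks"), showWarnings = FALSE)
  set.seed(as.integer(seed))
  cts <- config$cell_types
  jit <- config$rep_jitter

  ## genome ------------------------------------------------------------------
  genome_env <- new.env()
  genome_env$seq <- list()
  frag_list <- list()
  for (ch in names(config$chrom_lengths)) {
    b <- build_chromosome(config$chrom_lengths[[ch]], config$frag_len, config$frag_len_max)
    genome_env$seq[[ch]] <- b$seq
    frag_list[[ch]] <- GenomicRanges::GRanges(
      ch, IRanges::IRanges(start = b$starts1, end = b$starts1 + b$lens - 1L),
      fragment_id = seq_along(b$starts1)
    )
  }
  chrom_sizes <- vapply(genome_env$seq, nchar, numeric(1))
  fragments <- suppressWarnings(do.call(c, unname(frag_list)))
  GenomeInfoDb::seqlengths(fragments) <- chrom_sizes[GenomeInfoDb::seqlevels(fragments)]
  bins <- bin_fragments(fragments, 4L)
  frag_to_bin <- S4Vectors::subjectHits(
    GenomicRanges::findOverlaps(fragments, bins, type = "within")
  )
  frag_index <- make_point_index(fragments)

  ## genes (TSSs on a 10 kb grid => disjoint promoter windows) ---------------
  gene_count_by_chrom <- table(sample(names(chrom_sizes), config$n_genes,
                                      replace = TRUE, prob = chrom_sizes))
  gene_rows <- list()
  for (ch in names(gene_count_by_chrom)) {
    k <- gene_count_by_chrom[[ch]]
    grid <- seq(12000, chrom_sizes[[ch]] - 12000, by = 10000)
    if (k > length(grid)) stop("infeasible config: too many genes for chromosome ", ch)
    pos <- sort(sample(grid, k))
    gene_rows[[ch]] <- data.frame(chrom = ch, tss = pos,
                                  strand = sample(c("+", "-"), k, replace = TRUE),
                                  stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, gene_rows)
  genes <- genes[order(genes$chrom, genes$tss), ]
  genes$gene_id <- sprintf("G%03d", seq_len(nrow(genes)))
  genes$gene_name <- genes$gene_id
  genes <- genes[, c("gene_id", "gene_name", "chrom", "tss", "strand")]
  rownames(genes) <- NULL
  promoters <- promoter_windows(genes, chrom_sizes)
  p2f <- GenomicRanges::findOverlaps(promoters, fragments)
  bait_frags_by_gene <- split(S4Vectors::subjectHits(p2f),
                              promoters$gene_id[S4Vectors::queryHits(p2f)])
  tss_frag_idx <- S4Vectors::subjectHits(
    GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(genes$tss + 1L, genes$tss + 1L)),
      fragments
    )
  )

  ## motifs ------------------------------------------------------------------
  pwms <- vector("list", config$n_pwms)
  for (i in seq_len(config$n_pwms)) {
    L <- sample(config$pwm_len[1]:config$pwm_len[2], 1)
    repeat {
      cons <- random_bases(L)
      if (!grepl("GATC", cons, fixed = TRUE)) break
    }
    cb <- strsplit(cons, "")[[1]]
    counts <- matrix(3, 4, L, dimnames = list(BASES, NULL))
    counts[cbind(match(cb, BASES), seq_len(L))] <- 91
    pwms[[i]] <- list(matrix_id = sprintf("MA%04d.1", i),
                      tf_name = sprintf("TF%02d", i), counts = counts)
  }

  ## planted chains -----------------------------------------------------------
  reserved <- GenomicRanges::GRanges()
  planted_genes <- sample(genes$gene_id, nrow(genes))  # preference order
  used_genes <- character(0)
  chains <- list()
  motif_truth <- list()
  planted_peaks <- stats::setNames(vector("list", length(cts)), cts)
  planted_contacts <- list()
  gene_ptr <- 1L

  place_core <- function(lo, hi) {
    # centred core with 20 bp margins inside [lo, hi]; NULL if too narrow
    iw <- hi - lo + 1L - 40L
    if (iw < 110L) return(NULL)
    cw <- min(200L, iw)
    off <- (iw - cw) %/% 2L
    cs <- lo + 20L + off
    c(cs, cs + cw - 1L)
  }

  for (i in seq_len(config$n_planted_chains)) {
    ct <- cts[(i - 1L) %% length(cts) + 1L]
    mech <- if (i %% 2L == 1L) "pir_contact" else "promoter_overlap"
    placed <- FALSE
    while (!placed) {
      if (gene_ptr > length(planted_genes)) stop("infeasible config: could not place planted chains")
      g <- planted_genes[gene_ptr]
      gene_ptr <- gene_ptr + 1L
      gi <- match(g, genes$gene_id)
      ch <- genes$chrom[gi]

      if (mech == "pir_contact") {
        bait <- tss_frag_idx[gi]
        bait_mid <- interval_midpoint(GenomicRanges::start(fragments)[bait],
                                      GenomicRanges::end(fragments)[bait])
        oe <- NA_integer_
        for (try in 1:300) {
          d <- stats::rlnorm(1, config$distance_meanlog, config$distance_sdlog)
          target <- round(bait_mid + sample(c(-1, 1), 1) * d)
          if (target < 1 || target > chrom_sizes[[ch]]) next
          cand <- point_to_unit(frag_index, ch, target)
          if (is.na(cand) || cand == bait) next
          fr <- fragments[cand]
          if (GenomicRanges::width(fr) < 150L) next
          if (overlaps_any(fr, promoters)) next
          bsp <- bin_span(fr, bins)
          if (overlaps_any(bsp, promoters)) next
          if (overlaps_any(bsp, reserved)) next
          oe <- cand
          break
        }
        if (is.na(oe)) next  # try another gene
        core <- place_core(GenomicRanges::start(fragments)[oe],
                           GenomicRanges::end(fragments)[oe])
        if (is.null(core)) next
        score <- stats::runif(1, 6, 15)
        planted_contacts[[length(planted_contacts) + 1L]] <-
          data.frame(cell_type = ct, bait = bait, oe = oe, gene_id = g,
                     score = score, stringsAsFactors = FALSE)
        reserved <- suppressWarnings(c(reserved, bin_span(fragments[oe], bins)))
      } else {
        win <- promoters[promoters$gene_id == g]
        ov <- GenomicRanges::pintersect(
          rep(win, length(bait_frags_by_gene[[g]])),
          fragments[bait_frags_by_gene[[g]]]
        )
        widths <- GenomicRanges::width(ov)
        j <- which.max(widths)
        if (widths[j] < 150L) next
        fr_idx <- bait_frags_by_gene[[g]][j]
        bsp <- bin_span(fragments[fr_idx], bins)
        if (overlaps_any(bsp, reserved)) next
        core <- place_core(GenomicRanges::start(ov)[j], GenomicRanges::end(ov)[j])
        if (is.null(core)) next
        reserved <- suppressWarnings(c(reserved, bsp))
      }

      proxy_pos <- core[1] + (core[2] - core[1]) %/% 2L
      planted_peaks[[ct]] <- rbind(planted_peaks[[ct]],
                                   data.frame(chrom = ch, start = core[1], end = core[2],
                                              stringsAsFactors = FALSE))
      # deterministic quota: the realised motif share tracks the configured
      # fraction for any number of chains
      plant_motif <- config$n_pwms > 0 &&
        length(motif_truth) < config$planted_motif_fraction * i
      alt <- NA_character_
      if (plant_motif) {
        p <- pwms[[(i - 1L) %% config$n_pwms + 1L]]
        L <- ncol(p$counts)
        consb <- BASES[apply(p$counts, 2, which.max)]
        jcol <- as.integer(ceiling(L / 2))
        motif_start <- proxy_pos - jcol + 1L
        mutate_seq(genome_env, ch, motif_start, paste(consb, collapse = ""))
        fix_gatc_around(genome_env, ch, motif_start, motif_start + L - 1L)
        alt <- setdiff(BASES, consb[jcol])[1]
        motif_truth[[length(motif_truth) + 1L]] <-
          data.frame(proxy_id = sprintf("prx%03d", i), tf_name = p$tf_name,
                     expected_direction = "decreasing", stringsAsFactors = FALSE)
      }
      chains[[length(chains) + 1L]] <- data.frame(
        sentinel_id = sprintf("rs%03d", i), proxy_id = sprintf("prx%03d", i),
        gene_id = g, mechanism = mech, cell_type = ct, chrom = ch,
        ocr_start = core[1], ocr_end = core[2], proxy_pos = proxy_pos,
        alt = alt, stringsAsFactors = FALSE
      )
      used_genes <- c(used_genes, g)
      placed <- TRUE
    }
  }
  chains <- if (length(chains)) do.call(rbind, chains) else
    data.frame(sentinel_id = character(), proxy_id = character(), gene_id = character(),
               mechanism = character(), cell_type = character(), chrom = character(),
               ocr_start = integer(), ocr_end = integer(), proxy_pos = integer(),
               alt = character(), stringsAsFactors = FALSE)
  motif_truth <- if (length(motif_truth)) do.call(rbind, motif_truth) else
    data.frame(proxy_id = character(), tf_name = character(),
               expected_direction = character(), stringsAsFactors = FALSE)

  ## ATAC peaks ---------------------------------------------------------------
  peak_registry <- GenomicRanges::GRanges()   # all peak extents (closed-space sampling)
  rep_peaks <- stats::setNames(vector("list", length(cts)), cts)
  reserved_bl <- make_blocklist(
    if (length(reserved)) GenomicRanges::trim(suppressWarnings(reserved + (jit + 5L)))
    else reserved
  )
  for (ct in cts) {
    core_ch <- character(0); core_s <- integer(0); core_e <- integer(0)
    n_bg <- config$n_background_peaks
    tries <- 0
    while (length(core_s) < n_bg && tries < n_bg * 50) {
      tries <- tries + 1
      ch <- sample(names(chrom_sizes), 1, prob = chrom_sizes)
      w <- round(stats::runif(1, config$peak_width[1], config$peak_width[2]))
      s <- sample.int(as.integer(chrom_sizes[[ch]] - w - 1L), 1)
      if (interval_blocked(reserved_bl, ch, s, s + w - 1L)) next
      core_ch <- c(core_ch, ch); core_s <- c(core_s, s); core_e <- c(core_e, s + w - 1L)
    }
    bg_cores <- if (length(core_s)) {
      GenomicRanges::GRanges(core_ch, IRanges::IRanges(core_s, core_e))
    } else GenomicRanges::GRanges()
    pl <- planted_peaks[[ct]]
    pl_cores <- if (!is.null(pl)) GenomicRanges::GRanges(pl$chrom, IRanges::IRanges(pl$start, pl$end))
    else GenomicRanges::GRanges()
    peak_registry <- suppressWarnings(c(peak_registry, bg_cores + (jit + 2L), pl_cores + (jit + 2L)))

    rep_peaks[[ct]] <- lapply(seq_len(config$n_replicates), function(r) {
      keep <- stats::runif(length(bg_cores)) >= config$dropout
      sel <- suppressWarnings(c(pl_cores, bg_cores[keep]))
      if (length(sel) == 0) return(sel)
      s <- GenomicRanges::start(sel) + round(stats::runif(length(sel), -jit, jit))
      e <- GenomicRanges::end(sel) + round(stats::runif(length(sel), -jit, jit))
      s <- pmax(1L, as.integer(s))
      e <- pmax(s + 1L, as.integer(e))
      GenomicRanges::GRanges(GenomicRanges::seqnames(sel), IRanges::IRanges(s, e),
                             signalValue = round(stats::runif(length(sel), 2, 50), 2))
    })
  }

  ## contacts -----------------------------------------------------------------
  frag_start <- GenomicRanges::start(fragments)
  frag_end <- GenomicRanges::end(fragments)
  frag_chrom <- as.character(GenomicRanges::seqnames(fragments))
  # a fragment is blocked when its 4-fragment bin touches reserved space
  frag_blocked <- (GenomicRanges::countOverlaps(bins, reserved) > 0)[frag_to_bin]
  bait_ok <- function(idx) !frag_blocked[idx]

  contacts_by_ct <- stats::setNames(vector("list", length(cts)), cts)
  for (ct in cts) {
    rows <- list()
    n_made <- 0
    while (n_made < config$n_contacts) {
      g <- sample(genes$gene_id, 1)
      bait <- sample(c(bait_frags_by_gene[[g]], bait_frags_by_gene[[g]]), 1)  # safe sample
      if (!bait_ok(bait)) next
      oe <- NA_integer_
      if (stats::runif(1) < config$frac_bait_to_bait) {
        h <- sample(setdiff(genes$gene_id, g), 1)
        cand <- sample(c(bait_frags_by_gene[[h]], bait_frags_by_gene[[h]]), 1)
        if (cand != bait && bait_ok(cand)) oe <- cand
      }
      if (is.na(oe)) {
        ch <- frag_chrom[bait]
        bm <- interval_midpoint(frag_start[bait], frag_end[bait])
        for (try in 1:50) {
          d <- stats::rlnorm(1, config$distance_meanlog, config$distance_sdlog)
          target <- round(bm + sample(c(-1, 1), 1) * d)
          if (target < 1 || target > chrom_sizes[[ch]]) next
          cand <- point_to_unit(frag_index, ch, target)
          if (is.na(cand) || cand == bait) next
          if (!bait_ok(cand)) next
          oe <- cand
          break
        }
      }
      if (is.na(oe)) next
      score <- if (stats::runif(1) < config$frac_below_threshold) {
        stats::runif(1, 0.5, 4.99)
      } else {
        5 + stats::rexp(1, 1 / 5)
      }
      rows[[length(rows) + 1L]] <- data.frame(bait = bait, oe = oe, gene_id = g,
                                              score = score, stringsAsFactors = FALSE)
      n_made <- n_made + 1
    }
    bg <- do.call(rbind, rows)
    pl <- planted_contacts[vapply(planted_contacts, function(x) x$cell_type == ct, logical(1))]
    if (length(pl)) {
      bg <- rbind(bg, do.call(rbind, lapply(pl, function(x) {
        data.frame(bait = x$bait, oe = x$oe, gene_id = x$gene_id, score = x$score,
                   stringsAsFactors = FALSE)
      })))
    }
    one <- data.frame(
      bait_chr = frag_chrom[bg$bait], bait_start = frag_start[bg$bait],
      bait_end = frag_end[bg$bait], bait_name = bg$gene_id,
      oe_chr = frag_chrom[bg$oe], oe_start = frag_start[bg$oe],
      oe_end = frag_end[bg$oe], oe_name = ".",
      N_reads = 1L + stats::rpois(nrow(bg), pmax(1, round(bg$score * 3))),
      score = round(bg$score, 2), resolution = "1frag", cell_type = ct,
      stringsAsFactors = FALSE
    )
    bb <- frag_to_bin[bg$bait]
    ob <- frag_to_bin[bg$oe]
    key <- paste(bb, ob)
    ord <- order(key, -bg$score)
    keep <- ord[!duplicated(key[ord])]
    four <- data.frame(
      bait_chr = as.character(GenomicRanges::seqnames(bins))[bb[keep]],
      bait_start = GenomicRanges::start(bins)[bb[keep]],
      bait_end = GenomicRanges::end(bins)[bb[keep]],
      bait_name = bg$gene_id[keep],
      oe_chr = as.character(GenomicRanges::seqnames(bins))[ob[keep]],
      oe_start = GenomicRanges::start(bins)[ob[keep]],
      oe_end = GenomicRanges::end(bins)[ob[keep]], oe_name = ".",
      N_reads = 1L + stats::rpois(length(keep), pmax(1, round(bg$score[keep] * 3))),
      score = round(bg$score[keep], 2), resolution = "4frag", cell_type = ct,
      stringsAsFactors = FALSE
    )
    contacts_by_ct[[ct]] <- rbind(one, four)
  }

  ## variants -----------------------------------------------------------------
  blocklist <- make_blocklist(suppressWarnings(c(peak_registry, reserved)))
  closed_sample <- function(near_chrom = NULL, near_pos = NULL) {
    for (try in 1:500) {
      if (is.null(near_chrom)) {
        ch <- sample(names(chrom_sizes), 1, prob = chrom_sizes)
        pos <- sample.int(as.integer(chrom_sizes[[ch]] - 200L), 1) + 100L
      } else {
        ch <- near_chrom
        pos <- near_pos + round(stats::runif(1, -config$ld_window, config$ld_window))
        if (pos < 100 || pos > chrom_sizes[[ch]] - 100) next
      }
      if (point_blocked(blocklist, ch, pos)) next
      return(list(chrom = ch, pos = as.integer(pos)))
    }
    stop("could not sample a closed-chromatin position")
  }

  vrows <- list()
  for (i in seq_len(nrow(chains))) {
    sp <- closed_sample(chains$chrom[i], chains$proxy_pos[i])
    vrows[[length(vrows) + 1L]] <- data.frame(
      variant_id = chains$sentinel_id[i], chrom = sp$chrom, pos = sp$pos,
      role = "sentinel", sentinel_id = chains$sentinel_id[i], r2 = 1.0,
      stringsAsFactors = FALSE
    )
    vrows[[length(vrows) + 1L]] <- data.frame(
      variant_id = chains$proxy_id[i], chrom = chains$chrom[i],
      pos = chains$proxy_pos[i], role = "proxy",
      sentinel_id = chains$sentinel_id[i],
      r2 = round(stats::runif(1, 0.85, 0.99), 3), stringsAsFactors = FALSE
    )
    # low-r2 negative control inside the planted OCR (filtered at expansion)
    vrows[[length(vrows) + 1L]] <- data.frame(
      variant_id = paste0(chains$proxy_id[i], "lo"), chrom = chains$chrom[i],
      pos = chains$proxy_pos[i] + 31L, role = "proxy",
      sentinel_id = chains$sentinel_id[i],
      r2 = round(stats::runif(1, 0.4, 0.75), 3), stringsAsFactors = FALSE
    )
  }
  n_bg_sent <- max(0L, config$n_sentinels - nrow(chains))
  for (i in seq_len(n_bg_sent)) {
    sid <- sprintf("rs%03d", nrow(chains) + i)
    sp <- closed_sample()
    vrows[[length(vrows) + 1L]] <- data.frame(
      variant_id = sid, chrom = sp$chrom, pos = sp$pos, role = "sentinel",
      sentinel_id = sid, r2 = 1.0, stringsAsFactors = FALSE
    )
    for (j in seq_len(config$proxies_per_sentinel)) {
      pp <- closed_sample(sp$chrom, sp$pos)
      vrows[[length(vrows) + 1L]] <- data.frame(
        variant_id = sprintf("%sp%02d", sid, j), chrom = pp$chrom, pos = pp$pos,
        role = "proxy", sentinel_id = sid,
        r2 = round(stats::runif(1, 0.5, 0.95), 3), stringsAsFactors = FALSE
      )
    }
  }
  variants <- do.call(rbind, vrows)
  variants$ref <- vapply(seq_len(nrow(variants)), function(i) {
    substr(genome_env$seq[[variants$chrom[i]]], variants$pos[i], variants$pos[i])
  }, character(1))
  variants$alt <- vapply(seq_len(nrow(variants)), function(i) {
    ci <- match(variants$variant_id[i], chains$proxy_id)
    if (!is.na(ci) && !is.na(chains$alt[ci])) return(chains$alt[ci])
    sample(setdiff(BASES, variants$ref[i]), 1)
  }, character(1))
  variants <- variants[, c("variant_id", "chrom", "pos", "ref", "alt",
                           "role", "sentinel_id", "r2")]

  ## expression ---------------------------------------------------------------
  connected_by_ct <- stats::setNames(vector("list", length(cts)), cts)
  expr <- data.frame(gene_id = genes$gene_id, stringsAsFactors = FALSE)
  for (ct in cts) {
    ocrs <- consensus_ocrs(rep_peaks[[ct]], min_support = 2L)
    kept <- filter_contacts(contacts_by_ct[[ct]], 5)
    ann <- rbind(
      annotate_baits(kept[kept$resolution == "1frag", , drop = FALSE], promoters, fragments),
      annotate_baits(kept[kept$resolution == "4frag", , drop = FALSE], promoters, bins)
    )
    oe_gr <- GenomicRanges::GRanges(ann$oe_chr, IRanges::IRanges(ann$oe_start, ann$oe_end))
    conn <- unique(ann$gene_id[GenomicRanges::countOverlaps(oe_gr, ocrs) > 0])
    connected_by_ct[[ct]] <- conn
    x <- stats::rgamma(nrow(genes), shape = config$expr_shape, scale = config$expr_scale)
    x[genes$gene_id %in% conn] <- x[genes$gene_id %in% conn] + config$delta
    expr[[ct]] <- round(2^x - 1, 4)
  }
  if (config$n_pwms > 0) {
    tf_expr <- data.frame(gene_id = vapply(pwms, `[[`, character(1), "tf_name"),
                          stringsAsFactors = FALSE)
    for (ct in cts) {
      x <- stats::rgamma(nrow(tf_expr), shape = config$expr_shape, scale = config$expr_scale)
      tf_expr[[ct]] <- round(2^x - 1, 4)
    }
    expr <- rbind(expr, tf_expr)
  }

  ## chromatin-state segmentation ---------------------------------------------
  seg_rows <- list()
  for (ch in names(chrom_sizes)) {
    pos <- 1L
    while (pos <= chrom_sizes[[ch]]) {
      len <- max(200L, round(stats::rexp(1, 1 / config$segment_len)))
      end <- min(chrom_sizes[[ch]], pos + len - 1L)
      seg_rows[[length(seg_rows) + 1L]] <- data.frame(
        chrom = ch, start = pos, end = end,
        state = sample(names(config$chromhmm_states), 1,
                       prob = config$chromhmm_states),
        stringsAsFactors = FALSE
      )
      pos <- end + 1L
    }
  }
  seg <- do.call(rbind, seg_rows)

  ## write bundle --------------------------------------------------------------
  files <- list(genome = "genome.fa", genes = "genes.tsv", variants = "variants.tsv",
                expression = "expression.tsv", chromhmm = "chromhmm.bed",
                pwms = "pwms.jaspar", truth = "truth.json", manifest = "manifest.json")
  gss <- Biostrings::DNAStringSet(unlist(genome_env$seq))
  Biostrings::writeXStringSet(gss, file.path(out_dir, files$genome))
  write_genes(genes, file.path(out_dir, files$genes))
  write_variants(variants, file.path(out_dir, files$variants))
  write_expression(expr, file.path(out_dir, files$expression))
  seg_gr <- GenomicRanges::GRanges(seg$chrom, IRanges::IRanges(seg$start, seg$end),
                                   name = seg$state)
  write_regions(seg_gr, file.path(out_dir, files$chromhmm), "BED3")
  if (config$n_pwms > 0) write_pwm_jaspar(pwms, file.path(out_dir, files$pwms))
  files$peaks <- stats::setNames(lapply(cts, function(ct) {
    vapply(seq_len(config$n_replicates), function(r) {
      fp <- file.path("peaks", sprintf("%s_rep%d.narrowPeak", ct, r))
      gr <- rep_peaks[[ct]][[r]]
      gr$name <- sprintf("%s_r%d_p%05d", ct, r, seq_along(gr))
      gr$score <- 0
      gr$np_strand <- "."
      gr$pValue <- -1; gr$qValue <- -1; gr$peak <- -1
      write_regions(gr, file.path(out_dir, fp), "narrowPeak")
      fp
    }, character(1))
  }), cts)
  files$contacts <- stats::setNames(lapply(cts, function(ct) {
    fp <- sprintf("contacts_%s.ibed", ct)
    write_contacts_ibed(contacts_by_ct[[ct]], file.path(out_dir, fp))
    fp
  }), cts)

  truth <- list(seed = as.integer(seed), chains = chains, motifs = motif_truth,
                connected_genes = connected_by_ct)
  jsonlite::write_json(truth, file.path(out_dir, files$truth),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  manifest <- list(package = "capcv2g", seed = as.integer(seed),
                   chrom_sizes = as.list(chrom_sizes), cell_types = cts,
                   n_replicates = config$n_replicates, files = files)
  jsonlite::write_json(manifest, file.path(out_dir, files$manifest),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(dir = out_dir, files = files, truth = truth, genes = genes,
                 chrom_sizes = chrom_sizes))
}
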