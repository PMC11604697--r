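# Variant-to-gene (V2G) mapping: sentinel -> proxy expansion, OCR/PIR
# intersection, gene implication, sentinel classification, cross-cell-type
# summary and cRE annotation export.

#' Expand sentinels to their LD proxies
#'
#' Retains proxies in linkage disequilibrium with a sentinel at strictly
#' `r2 > r2_threshold` and adds every sentinel as its own proxy (r2 = 1),
#' so sentinels without tabulated proxies still enter the mapping.
#'
#' @param variants validated variant data.frame (sentinel and proxy rows,
#'   see [read_variants()])
#' @param r2_threshold strict lower bound on r2 (default 0.8)
#' @return data.frame of proxies (`role` preserved; self-proxies carry the
#'   sentinel's own id as `sentinel_id` and r2 = 1)
#' @export
expand_proxies <- function(variants, r2_threshold = 0.8) {
  variants <- validate_variants(variants)
  sent <- variants[variants$role == "sentinel", , drop = FALSE]
  prox <- variants[variants$role == "proxy", , drop = FALSE]
  unknown <- setdiff(prox$sentinel_id, sent$variant_id)
  if (length(unknown) > 0) {
    stop("proxy references unknown sentinel(s): ", paste(unknown, collapse = ", "))
  }
  selfp <- sent
  selfp$sentinel_id <- selfp$variant_id
  selfp$r2 <- 1.0
  out <- rbind(selfp, prox[prox$r2 > r2_threshold, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Implicate effector genes from open proxies
#'
#' For every proxy lying inside an OCR, emits a variant-to-gene record by
#' either route: (a) the OCR overlaps gene G's promoter window (mechanism
#' `promoter_overlap`); (b) the OCR overlaps the other end of a promoter
#' contact whose bait is gene G's promoter (mechanism `pir_contact`, with
#' the contact resolution recorded; implications from several resolutions
#' are unioned). Records are deduplicated per (sentinel, gene, cell type,
#' mechanism), keeping the highest-r2 proxy as representative and joining
#' the supporting resolutions. Proxies outside OCRs yield nothing.
#'
#' @param proxies expanded proxy data.frame from [expand_proxies()]
#' @param ocrs classified OCR `GRanges` from [classify_ocrs()]
#' @param promoter_contacts annotated contacts from [annotate_baits()]
#'   (any mix of resolutions)
#' @param promoters promoter window `GRanges`
#' @param cell_type cell-type label stored on the records
#' @param genes optional gene table; when given, `is_nearest_gene` is
#'   filled from [nearest_gene()] of each sentinel
#' @param sentinels optional sentinel data.frame (needed for
#'   `is_nearest_gene`; defaults to self-proxies present in `proxies`)
#' @return data.frame of V2G records
#' @export
implicate_genes <- function(proxies, ocrs, promoter_contacts, promoters,
                            cell_type = NA_character_, genes = NULL,
                            sentinels = NULL) {
  empty <- data.frame(sentinel_id = character(), proxy_id = character(), r2 = numeric(),
                      cell_type = character(), mechanism = character(),
                      ocr_chrom = character(), ocr_start = integer(), ocr_end = integer(),
                      resolution = character(), gene_id = character(),
                      is_nearest_gene = logical(), stringsAsFactors = FALSE)
  if (nrow(proxies) == 0 || length(ocrs) == 0) return(empty)
  pg <- GenomicRanges::GRanges(proxies$chrom, IRanges::IRanges(proxies$pos, proxies$pos))
  p2o <- GenomicRanges::findOverlaps(pg, ocrs)
  if (length(p2o) == 0) return(empty)

  rec_list <- list()
  # (a) promoter-overlap route
  o2p <- GenomicRanges::findOverlaps(ocrs, promoters)
  if (length(o2p) > 0) {
    m <- merge(
      data.frame(prx = S4Vectors::queryHits(p2o), ocr = S4Vectors::subjectHits(p2o)),
      data.frame(ocr = S4Vectors::queryHits(o2p),
                 gene_id = promoters$gene_id[S4Vectors::subjectHits(o2p)]),
      by = "ocr"
    )
    if (nrow(m) > 0) {
      rec_list$prom <- data.frame(
        sentinel_id = proxies$sentinel_id[m$prx], proxy_id = proxies$variant_id[m$prx],
        r2 = proxies$r2[m$prx], cell_type = cell_type,
        mechanism = "promoter_overlap",
        ocr_chrom = as.character(GenomicRanges::seqnames(ocrs))[m$ocr],
        ocr_start = GenomicRanges::start(ocrs)[m$ocr],
        ocr_end = GenomicRanges::end(ocrs)[m$ocr],
        resolution = NA_character_, gene_id = m$gene_id,
        stringsAsFactors = FALSE
      )
    }
  }
  # (b) PIR-contact route
  if (nrow(promoter_contacts) > 0) {
    oe_gr <- GenomicRanges::GRanges(
      promoter_contacts$oe_chr,
      IRanges::IRanges(promoter_contacts$oe_start, promoter_contacts$oe_end)
    )
    o2c <- GenomicRanges::findOverlaps(ocrs, oe_gr)
    if (length(o2c) > 0) {
      m <- merge(
        data.frame(prx = S4Vectors::queryHits(p2o), ocr = S4Vectors::subjectHits(p2o)),
        data.frame(ocr = S4Vectors::queryHits(o2c), ct = S4Vectors::subjectHits(o2c)),
        by = "ocr"
      )
      if (nrow(m) > 0) {
        rec_list$pir <- data.frame(
          sentinel_id = proxies$sentinel_id[m$prx], proxy_id = proxies$variant_id[m$prx],
          r2 = proxies$r2[m$prx], cell_type = cell_type,
          mechanism = "pir_contact",
          ocr_chrom = as.character(GenomicRanges::seqnames(ocrs))[m$ocr],
          ocr_start = GenomicRanges::start(ocrs)[m$ocr],
          ocr_end = GenomicRanges::end(ocrs)[m$ocr],
          resolution = promoter_contacts$resolution[m$ct],
          gene_id = promoter_contacts$gene_id[m$ct],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rec_list) == 0) return(empty)
  rec <- do.call(rbind, rec_list)

  # deduplicate per (sentinel, gene, cell type, mechanism): representative
  # proxy = highest r2 (ties by proxy_id), resolutions joined
  key <- paste(rec$sentinel_id, rec$gene_id, rec$cell_type, rec$mechanism, sep = "\r")
  ord <- order(key, -rec$r2, rec$proxy_id)
  rec <- rec[ord, , drop = FALSE]
  key <- key[ord]
  res_join <- tapply(rec$resolution, key, function(r) {
    r <- sort(unique(r[!is.na(r)]))
    if (length(r) == 0) NA_character_ else paste(r, collapse = ",")
  })
  first <- !duplicated(key)
  out <- rec[first, , drop = FALSE]
  out$resolution <- unname(res_join[key[first]])
  out <- out[order(out$sentinel_id, out$gene_id, out$mechanism), , drop = FALSE]
  rownames(out) <- NULL

  out$is_nearest_gene <- NA
  if (!is.null(genes)) {
    if (is.null(sentinels)) {
      sentinels <- proxies[proxies$role == "sentinel" &
                             proxies$variant_id == proxies$sentinel_id, , drop = FALSE]
    }
    idx <- match(out$sentinel_id, sentinels$variant_id)
    known <- !is.na(idx)
    if (any(known)) {
      ng <- nearest_gene(sentinels$chrom[idx[known]],
                         sentinels$pos[idx[known]] - 1L, genes)
      out$is_nearest_gene[known] <- out$gene_id[known] == ng
    }
  }
  out
}

#' Classify sentinels by their relation to the nearest gene
#'
#' Per sentinel (and cell type), the implicated gene set is compared with
#' the gene nearest to the sentinel position: `nearest_only` when the set is
#' exactly the nearest gene, `multiple_including_nearest` when it is larger
#' but contains it, `not_nearest` otherwise. Sentinels with no implicated
#' genes are absent from the result.
#'
#' @param v2g V2G data.frame from [implicate_genes()]
#' @param genes gene table
#' @param sentinels sentinel data.frame (columns `variant_id`, `chrom`,
#'   `pos`)
#' @return data.frame with `sentinel_id`, `cell_type`, `category`,
#'   `nearest_gene`, `genes` (comma-joined implicated set)
#' @export
classify_sentinels <- function(v2g, genes, sentinels) {
  if (nrow(v2g) == 0) {
    return(data.frame(sentinel_id = character(), cell_type = character(),
                      category = character(), nearest_gene = character(),
                      genes = character(), stringsAsFactors = FALSE))
  }
  idx <- match(v2g$sentinel_id, sentinels$variant_id)
  if (anyNA(idx)) stop("sentinel(s) in v2g absent from sentinel table")
  kk <- paste(v2g$sentinel_id, v2g$cell_type, sep = "\r")
  keys <- unique(v2g[, c("sentinel_id", "cell_type")])
  key_of <- paste(keys$sentinel_id, keys$cell_type, sep = "\r")
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sub <- v2g[kk == key_of[i], , drop = FALSE]
    gset <- sort(unique(sub$gene_id))
    si <- match(keys$sentinel_id[i], sentinels$variant_id)
    ng <- nearest_gene(sentinels$chrom[si], sentinels$pos[si] - 1L, genes)
    cat <- if (identical(gset, ng)) "nearest_only"
    else if (ng %in% gset) "multiple_including_nearest"
    else "not_nearest"
    data.frame(sentinel_id = keys$sentinel_id[i], cell_type = keys$cell_type[i],
               category = cat, nearest_gene = ng,
               genes = paste(gset, collapse = ","), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Cross-cell-type summary of implicated genes
#'
#' Upset-style summary over the union of implicated genes: per-cell-type
#' exclusive counts, genes shared in at least two cell types, genes shared
#' across all cell types, and the corresponding percentages of the union
#' (rounded half-up to one decimal).
#'
#' @param gene_sets named list of character vectors (implicated genes per
#'   cell type); at least two cell types
#' @return a list with `union_size`, `exclusive` (named counts),
#'   `n_one_cell`, `n_shared_two_plus`, `n_shared_all`, `pct_one_cell`,
#'   `pct_shared_two_plus`, `pct_shared_all` and the per-gene `membership`
#'   data.frame
#' @export
cross_celltype_summary <- function(gene_sets) {
  if (length(gene_sets) < 2) stop("need gene sets for at least two cell types")
  if (is.null(names(gene_sets)) || any(!nzchar(names(gene_sets)))) {
    stop("gene_sets must be named by cell type")
  }
  gene_sets <- lapply(gene_sets, unique)
  all_genes <- sort(unique(unlist(gene_sets)))
  memb <- vapply(gene_sets, function(s) all_genes %in% s,
                 logical(length(all_genes)))
  if (length(all_genes) == 1) memb <- matrix(memb, nrow = 1, dimnames = list(NULL, names(gene_sets)))
  n_types <- rowSums(memb)
  exclusive <- vapply(seq_along(gene_sets), function(j) {
    sum(memb[, j] & n_types == 1)
  }, numeric(1))
  names(exclusive) <- names(gene_sets)
  u <- length(all_genes)
  n_one <- sum(n_types == 1)
  n_two <- sum(n_types >= 2)
  n_all <- sum(n_types == length(gene_sets))
  list(
    union_size = u,
    exclusive = exclusive,
    n_one_cell = n_one,
    n_shared_two_plus = n_two,
    n_shared_all = n_all,
    pct_one_cell = round_half_up(100 * n_one / u, 1),
    pct_shared_two_plus = round_half_up(100 * n_two / u, 1),
    pct_shared_all = round_half_up(100 * n_all / u, 1),
    membership = data.frame(gene_id = all_genes, memb,
                            n_cell_types = n_types, stringsAsFactors = FALSE)
  )
}

#' Export the cRE annotation (promoter OCRs + PIR-OCRs) as BED
#'
#' Merges the classified promoter OCRs and PIR-OCRs into one sorted,
#' non-overlapping annotation suitable as input to partitioned-heritability
#' tooling. With no qualifying OCRs an empty BED with a header comment is
#' written.
#'
#' @param ocrs classified OCR `GRanges`
#' @param path output BED path
#' @return the merged `GRanges`, invisibly
#' @export
export_cre_annotation <- function(ocrs, path) {
  keep <- ocrs[ocrs$class %in% c("promoterOCR", "PIR-OCR")]
  merged <- GenomicRanges::reduce(BiocGenerics::sort(GenomicRanges::granges(keep)))
  if (length(merged) == 0) {
    writeLines("# cRE annotation: no promoter OCRs or PIR-OCRs", path)
  } else {
    write_regions(merged, path, "BED3")
  }
  invisible(merged)
}
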