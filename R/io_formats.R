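# Readers/writers for the external formats the pipeline touches. All readers
# validate coordinates and reject violations rather than silently clamping.
# BED carriers are 0-based half-open on disk; ibed-like contact files and the
# variant TSV/VCF-lite dialects carry 1-based positions on disk (as their
# upstream tools emit them). In memory, intervals are GRanges (1-based
# closed, the native R/Bioconductor convention).

read_tsv_checked <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             comment.char = "#", ...)
}

#' Read genomic regions from BED3 or narrowPeak files
#'
#' @param path file path (tab-separated, `#` comment lines ignored)
#' @param dialect `"BED3"` (chrom/start/end, optional name column kept) or
#'   `"narrowPeak"` (the ENCODE 10-column dialect; extra columns preserved
#'   as metadata)
#' @return a `GRanges`; empty files yield a zero-length `GRanges`
#' @export
read_regions <- function(path, dialect = c("BED3", "narrowPeak")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) return(GenomicRanges::GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nmin <- if (dialect == "narrowPeak") 10L else 3L
  bad <- which(vapply(fields, length, integer(1)) < nmin)
  if (length(bad) > 0) stop("malformed line ", bad[1], " in ", path)
  chrom <- vapply(fields, `[[`, character(1), 1)
  s0 <- as.numeric(vapply(fields, `[[`, character(1), 2))
  e0 <- as.numeric(vapply(fields, `[[`, character(1), 3))
  if (anyNA(s0) || anyNA(e0)) stop("non-numeric coordinates in ", path)
  if (any(s0 < 0 | s0 >= e0)) {
    stop("invalid interval (start >= end or negative) at line ",
         which(s0 < 0 | s0 >= e0)[1], " in ", path)
  }
  gr <- granges_from_bed(chrom, s0, e0)
  nfld <- vapply(fields, length, integer(1))
  if (dialect == "narrowPeak") {
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      name = vapply(fields, `[[`, character(1), 4),
      score = as.numeric(vapply(fields, `[[`, character(1), 5)),
      np_strand = vapply(fields, `[[`, character(1), 6),
      signalValue = as.numeric(vapply(fields, `[[`, character(1), 7)),
      pValue = as.numeric(vapply(fields, `[[`, character(1), 8)),
      qValue = as.numeric(vapply(fields, `[[`, character(1), 9)),
      peak = as.integer(vapply(fields, `[[`, character(1), 10))
    )
  } else if (all(nfld >= 4L)) {
    gr$name <- vapply(fields, `[[`, character(1), 4)
  }
  gr
}

#' Write genomic regions as BED3(+) or narrowPeak
#'
#' @param gr a `GRanges`; recognised metadata columns are emitted in the
#'   dialect's column order
#' @inheritParams read_regions
#' @param path output path
#' @return `path`, invisibly
#' @export
write_regions <- function(gr, path, dialect = c("BED3", "narrowPeak")) {
  dialect <- match.arg(dialect)
  base <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = bed_start(gr), end = bed_end(gr)
  )
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if (dialect == "narrowPeak") {
    base$name <- if ("name" %in% names(mc)) mc$name else "."
    base$score <- if ("score" %in% names(mc)) mc$score else 0
    base$strand <- if ("np_strand" %in% names(mc)) mc$np_strand else "."
    base$signalValue <- if ("signalValue" %in% names(mc)) mc$signalValue else 0
    base$pValue <- if ("pValue" %in% names(mc)) mc$pValue else -1
    base$qValue <- if ("qValue" %in% names(mc)) mc$qValue else -1
    base$peak <- if ("peak" %in% names(mc)) mc$peak else -1
  } else if ("name" %in% names(mc)) {
    base$name <- mc$name
  }
  write.table(base, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

contact_cols <- c("bait_chr", "bait_start", "bait_end", "bait_name",
                  "oe_chr", "oe_start", "oe_end", "oe_name",
                  "N_reads", "score")

#' Read called promoter contacts from an ibed-like table
#'
#' The carrier is the standard output dialect of Capture-C interaction
#' callers: one row per called contact with bait and other-end intervals
#' (1-based inclusive on disk), read support and an interaction score.
#' Optional `resolution` and `cell_type` columns are preserved; otherwise
#' they can be supplied as arguments.
#'
#' @param path file path (tab-separated with header)
#' @param resolution default resolution tag (`"1frag"`/`"4frag"`) for files
#'   without a resolution column
#' @param cell_type default cell-type label for files without one
#' @return a data.frame contact table
#' @export
read_contacts_ibed <- function(path, resolution = "1frag", cell_type = NA_character_) {
  df <- read_tsv_checked(path)
  stop_if_missing_cols(df, contact_cols, "contact table")
  if (nrow(df) > 0) {
    if (any(df$score < 0)) stop("negative interaction score in ", path)
    if (any(df$bait_start > df$bait_end) || any(df$oe_start > df$oe_end)) {
      stop("invalid interval (start > end) in ", path)
    }
    if (any(df$bait_start < 1) || any(df$oe_start < 1)) {
      stop("ibed coordinates are 1-based; start < 1 in ", path)
    }
  }
  if (!"resolution" %in% names(df)) df$resolution <- resolution
  if (!"cell_type" %in% names(df)) df$cell_type <- cell_type
  df
}

#' Write a contact table in the ibed-like dialect
#'
#' @param contacts contact data.frame from [read_contacts_ibed()] or built
#'   in code
#' @param path output path
#' @return `path`, invisibly
#' @export
write_contacts_ibed <- function(contacts, path) {
  stop_if_missing_cols(contacts, contact_cols, "contact table")
  keep <- c(contact_cols, intersect(c("resolution", "cell_type"), names(contacts)))
  write.table(contacts[, keep], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

variant_cols <- c("variant_id", "chrom", "pos", "ref", "alt", "role", "sentinel_id", "r2")

validate_variants <- function(df, where = "variant table") {
  stop_if_missing_cols(df, variant_cols, where)
  if (nrow(df) == 0) return(df)
  if (any(grepl(",", df$alt, fixed = TRUE))) {
    stop("multi-allelic ALT not supported (", where, ")")
  }
  if (any(nchar(df$ref) != 1 | nchar(df$alt) != 1)) {
    stop("only single-nucleotide variants are supported (", where, ")")
  }
  if (any(df$ref == df$alt)) stop("ref and alt alleles must differ (", where, ")")
  if (any(!df$role %in% c("sentinel", "proxy"))) {
    stop("variant role must be 'sentinel' or 'proxy' (", where, ")")
  }
  is_sent <- df$role == "sentinel"
  df$sentinel_id[is_sent & (is.na(df$sentinel_id) | df$sentinel_id == ".")] <-
    df$variant_id[is_sent & (is.na(df$sentinel_id) | df$sentinel_id == ".")]
  df$r2[is_sent & is.na(df$r2)] <- 1.0   # self-LD
  if (any(df$role == "proxy" & (is.na(df$sentinel_id) | df$sentinel_id == "."))) {
    stop("proxy without sentinel_id (", where, ")")
  }
  if (anyNA(df$r2) || any(df$r2 < 0 | df$r2 > 1)) stop("r2 must lie in [0,1] (", where, ")")
  df
}

#' Read sentinel/proxy variants
#'
#' Two dialects: a plain TSV with columns `variant_id chrom pos ref alt role
#' sentinel_id r2`, or a VCF-lite file (`#CHROM POS ID REF ALT ... INFO`
#' with `ROLE=`, `SENTINEL=`, `R2=` INFO keys). Positions are 1-based on
#' disk in both dialects. Sentinel rows without an `r2` default to 1 (self
#' linkage); multi-allelic or non-SNV records are rejected.
#'
#' @param path file path
#' @param dialect `"TSV"` or `"VCF"`
#' @return a validated variant data.frame (`pos` 1-based)
#' @export
read_variants <- function(path, dialect = c("TSV", "VCF")) {
  dialect <- match.arg(dialect)
  if (dialect == "TSV") {
    # force characters: a lone T/F allele must not become a logical
    df <- read_tsv_checked(path, colClasses = list(
      variant_id = "character", chrom = "character", ref = "character",
      alt = "character", role = "character", sentinel_id = "character"
    ))
    df <- validate_variants(df, path)
    return(df)
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(validate_variants(data.frame(variant_id = character(), chrom = character(),
                                        pos = integer(), ref = character(), alt = character(),
                                        role = character(), sentinel_id = character(),
                                        r2 = numeric())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(fields, length, integer(1)) < 8)) stop("malformed VCF-lite line in ", path)
  info <- vapply(fields, `[[`, character(1), 8)
  getk <- function(key) {
    vapply(info, function(s) {
      m <- regmatches(s, regexpr(paste0("(^|;)", key, "=[^;]*"), s))
      if (length(m) == 0) NA_character_ else sub(paste0("^.*?", key, "="), "", m)
    }, character(1), USE.NAMES = FALSE)
  }
  df <- data.frame(
    variant_id = vapply(fields, `[[`, character(1), 3),
    chrom = vapply(fields, `[[`, character(1), 1),
    pos = as.integer(vapply(fields, `[[`, character(1), 2)),
    ref = vapply(fields, `[[`, character(1), 4),
    alt = vapply(fields, `[[`, character(1), 5),
    role = getk("ROLE"), sentinel_id = getk("SENTINEL"),
    r2 = as.numeric(getk("R2")),
    stringsAsFactors = FALSE
  )
  df$role[is.na(df$role)] <- "sentinel"
  validate_variants(df, path)
}

#' Write variants as TSV
#'
#' @param variants validated variant data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_variants <- function(variants, path) {
  stop_if_missing_cols(variants, variant_cols, "variant table")
  write.table(variants[, variant_cols], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read position count matrices in JASPAR format
#'
#' Parses `>ID NAME` headers followed by `A [ ... ]`, `C [ ... ]`, `G [ ... ]`,
#' `T [ ... ]` count rows.
#'
#' @param path file path
#' @return a list of PWM records, each a list with `matrix_id`, `tf_name`
#'   and `counts` (a 4 x L matrix with rownames A,C,G,T)
#' @export
read_pwm_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0) stop("no JASPAR '>' header in ", path)
  out <- vector("list", length(heads))
  bounds <- c(heads, length(lines) + 1L)
  for (i in seq_along(heads)) {
    hdr <- sub("^>\\s*", "", lines[heads[i]])
    toks <- strsplit(hdr, "\\s+")[[1]]
    block <- lines[(heads[i] + 1L):(bounds[i + 1L] - 1L)]
    rows <- lapply(c("A", "C", "G", "T"), function(b) {
      ln <- block[grepl(paste0("^", b, "\\b"), block)]
      if (length(ln) != 1) stop("missing or duplicated ", b, " row for matrix ", toks[1])
      nums <- regmatches(ln, gregexpr("[0-9.]+", ln))[[1]]
      as.numeric(nums)
    })
    L <- unique(vapply(rows, length, integer(1)))
    if (length(L) != 1) stop("rows of unequal length for matrix ", toks[1])
    if (L < 1) stop("empty matrix ", toks[1])
    counts <- do.call(rbind, rows)
    rownames(counts) <- c("A", "C", "G", "T")
    if (any(counts < 0)) stop("negative counts in matrix ", toks[1])
    if (any(colSums(counts) == 0)) stop("all-zero column in matrix ", toks[1])
    out[[i]] <- list(matrix_id = toks[1],
                     tf_name = if (length(toks) > 1) toks[2] else toks[1],
                     counts = counts)
  }
  out
}

#' Write PWM records in JASPAR format
#'
#' @param pwms list of PWM records as returned by [read_pwm_jaspar()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_pwm_jaspar <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(sprintf(">%s %s", p$matrix_id, p$tf_name), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(format(p$counts[b, ], trim = TRUE), collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read a gene model table
#'
#' TSV with columns `gene_id`, `gene_name`, `chrom`, `tss`, `strand`. The
#' TSS is 1-based on disk (GTF-like convention) and converted to the
#' 0-based position of the first transcribed base in memory.
#'
#' @param path file path
#' @return validated gene data.frame (`tss` 0-based)
#' @export
read_genes <- function(path) {
  df <- read_tsv_checked(path)
  stop_if_missing_cols(df, c("gene_id", "chrom", "tss", "strand"), "gene table")
  if (any(df$tss < 1)) stop("gene TSS is 1-based on disk; tss < 1 in ", path)
  df$tss <- df$tss - 1L
  validate_genes(df)
  df
}

#' Write a gene model table
#'
#' @param genes gene data.frame (`tss` 0-based in memory; written 1-based)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_genes <- function(genes, path) {
  validate_genes(genes)
  out <- genes
  out$tss <- out$tss + 1L
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression table (TPM)
#'
#' Wide TSV: a `gene_id` column plus one TPM column per cell type.
#'
#' @param path file path
#' @return data.frame with `gene_id` and numeric TPM columns
#' @export
read_expression <- function(path) {
  df <- read_tsv_checked(path)
  stop_if_missing_cols(df, "gene_id", "expression table")
  num <- setdiff(names(df), "gene_id")
  if (length(num) == 0) stop("expression table has no TPM column")
  for (cc in num) {
    if (any(df[[cc]] < 0, na.rm = TRUE)) stop("negative TPM in ", path)
  }
  df
}

#' Write an expression table (TPM)
#'
#' @param expr expression data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_expression <- function(expr, path) {
  write.table(expr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' log2(TPM + 1) transform
#'
#' @param tpm numeric vector of TPM values
#' @return numeric vector
#' @export
log2_tpm <- function(tpm) log2(tpm + 1)

#' Read a chromatin-state segmentation (ChromHMM-style BED)
#'
#' BED with the state label in the name (4th) column.
#'
#' @param path file path
#' @return a `GRanges` with metadata column `state`
#' @export
read_chromhmm <- function(path) {
  gr <- read_regions(path, "BED3")
  if (length(gr) > 0) {
    if (!"name" %in% names(S4Vectors::mcols(gr))) {
      stop("segmentation BED needs a state label in column 4: ", path)
    }
    gr$state <- gr$name
    gr$name <- NULL
  }
  gr
}
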