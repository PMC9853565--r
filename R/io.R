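# Readers and writers for every tab-separated format the pipeline touches.
# Internal peak coordinates are 0-based half-open (BED convention); GWAS
# positions and sentinel-table outputs are 1-based. Conversion happens only at
# this I/O boundary.

#' Convert a 1-based inclusive position to the internal 0-based start
#' @param pos Integer vector of 1-based positions.
#' @return 0-based start coordinates.
#' @export
pos_to_0based <- function(pos) as.integer(pos) - 1L

#' Convert an internal 0-based start back to a 1-based inclusive position
#' @param start0 Integer vector of 0-based starts.
#' @return 1-based positions.
#' @export
pos_to_1based <- function(start0) as.integer(start0) + 1L

#' Read peaks from a BED or narrowPeak file
#'
#' BED coordinates are interpreted as 0-based half-open and kept that way
#' internally. For narrowPeak input the peak score is taken from column 7
#' (signalValue), per the ENCODE column order.
#'
#' @param path Path to a tab-separated BED3+/narrowPeak file (no header).
#' @param format Either "BED" or "narrowPeak".
#' @param source_set Optional label recorded in the `source_set` column.
#' @return A data.frame with columns chrom, start, end, name, score,
#'   source_set.
#' @export
read_peaks <- function(path, format = c("BED", "narrowPeak"), source_set = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  min_cols <- if (format == "narrowPeak") 10L else 3L
  bad <- which(nf < min_cols)
  if (length(bad)) {
    stop(sprintf("parse error at line %d of %s: expected >= %d tab-separated columns, got %d",
                 bad[1L], path, min_cols, nf[bad[1L]]))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    i <- which(is.na(start) | is.na(end))[1L]
    stop(sprintf("parse error at line %d of %s: non-integer coordinates", i, path))
  }
  name <- if (all(nf >= 4L)) vapply(fields, `[[`, "", 4L) else sprintf("peak_%06d", seq_along(fields))
  score <- if (format == "narrowPeak") {
    as.numeric(vapply(fields, `[[`, "", 7L))
  } else if (all(nf >= 5L)) {
    suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  } else {
    rep(NA_real_, length(fields))
  }
  peaks <- data.frame(chrom = chrom, start = start, end = end, name = name,
                      score = score, source_set = source_set,
                      stringsAsFactors = FALSE)
  validate_peaks(peaks)
  peaks
}

#' Write peaks as BED (0-based half-open, tab-separated, LF)
#'
#' @param peaks Peak data.frame (chrom, start, end, name, optional score).
#' @param path Output path.
#' @export
write_peaks <- function(peaks, path) {
  validate_peaks(peaks)
  name <- peaks$name %||% sprintf("peak_%06d", seq_len(nrow(peaks)))
  score <- peaks$score %||% rep(0, nrow(peaks))
  score[is.na(score)] <- 0
  out <- sprintf("%s\t%d\t%d\t%s\t%s", peaks$chrom, peaks$start, peaks$end, name,
                 format(score, trim = TRUE, scientific = FALSE))
  writeLines(out, path, sep = "\n")
  invisible(path)
}

#' Read GWAS summary statistics
#'
#' Requires a header with rsid, chrom, pos, pval, maf, is_coding,
#' ld_partner_count, dist_to_gene. MAF, LD-partner and distance columns are
#' required because the matched permutation test preserves them. Positions are
#' 1-based. Records are returned sorted by (chrom, pos).
#'
#' @param path Path to a tab-separated file with header.
#' @return A data.frame of SNP records.
#' @export
read_gwas <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("rsid", "chrom", "pos", "pval", "maf", "is_coding",
            "ld_partner_count", "dist_to_gene")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("GWAS table missing required column(s): ", paste(miss, collapse = ", "))
  df$is_coding <- as.logical(df$is_coding)
  validate_snps(df)
  df[order(df$chrom, df$pos), need, drop = FALSE]
}

# SnpRecord invariants: 0 < pval <= 1, 0 <= maf <= 0.5, ld_partner_count >= 0,
# unique rsid.
validate_snps <- function(snps) {
  if (anyDuplicated(snps$rsid)) {
    dup <- unique(snps$rsid[duplicated(snps$rsid)])
    stop("duplicate rsid(s): ", paste(utils::head(dup, 5L), collapse = ", "))
  }
  if (any(!is.finite(snps$pval)) || any(snps$pval <= 0 | snps$pval > 1)) {
    stop("validation error: pval must lie in (0, 1]")
  }
  if (any(snps$maf < 0 | snps$maf > 0.5)) stop("validation error: maf must lie in [0, 0.5]")
  if (any(snps$ld_partner_count < 0)) stop("validation error: ld_partner_count must be >= 0")
  invisible(snps)
}

#' Write GWAS summary statistics
#' @param snps SNP record data.frame.
#' @param path Output path.
#' @export
write_gwas <- function(snps, path) {
  utils::write.table(snps, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a peak-by-sample count matrix together with sample metadata
#'
#' The count matrix is a TSV whose first column is `peak_id` and whose
#' remaining columns are samples; the metadata TSV must have a `sample_id`
#' column matching those sample columns exactly. Metadata rows are reordered to
#' follow the matrix columns.
#'
#' @param path_counts Path to the count matrix TSV.
#' @param path_meta Path to the metadata TSV.
#' @return A list with `counts` (integer matrix, peaks x samples) and `meta`
#'   (data.frame).
#' @export
read_counts <- function(path_counts, path_meta) {
  cts <- utils::read.delim(path_counts, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(cts)[1L] != "peak_id") stop("count matrix must have 'peak_id' as its first column")
  meta <- utils::read.delim(path_meta, stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(meta$sample_id)) stop("metadata must have a 'sample_id' column")
  peak_ids <- cts$peak_id
  if (anyDuplicated(peak_ids)) stop("duplicate peak_id in count matrix")
  m <- as.matrix(cts[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- peak_ids
  only_counts <- setdiff(colnames(m), meta$sample_id)
  only_meta <- setdiff(meta$sample_id, colnames(m))
  if (length(only_counts) || length(only_meta)) {
    stop("sample id mismatch between counts and metadata; only in counts: {",
         paste(only_counts, collapse = ", "), "}; only in metadata: {",
         paste(only_meta, collapse = ", "), "}")
  }
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata")
  validate_counts(m)
  meta <- meta[match(colnames(m), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  if (!is.null(meta$cell_type)) meta$cell_type <- canonical_cell_type(meta$cell_type)
  list(counts = m, meta = meta)
}

validate_counts <- function(m) {
  if (anyNA(m)) stop("validation error: NA counts")
  if (any(m < 0)) stop("validation error: negative counts")
  invisible(m)
}

#' Write a count matrix and its metadata
#' @param counts Integer matrix with peak rownames.
#' @param meta Sample metadata data.frame.
#' @param path_counts,path_meta Output paths.
#' @export
write_counts <- function(counts, meta, path_counts, path_meta) {
  df <- data.frame(peak_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path_counts, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(meta, path_meta, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path_counts)
}

#' Read gene models (GTF-lite TSV)
#'
#' Columns: gene_id, chrom, strand, tss (1-based), tx_start, tx_end, and
#' optionally comma-separated exon_starts / exon_ends. The TSS must equal
#' tx_start on the + strand and tx_end on the - strand.
#'
#' @param path Path to the TSV.
#' @return A data.frame of gene models.
#' @export
read_gene_models <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_id", "chrom", "strand", "tss", "tx_start", "tx_end")
  miss <- setdiff(need, names(g))
  if (length(miss)) stop("gene model table missing column(s): ", paste(miss, collapse = ", "))
  validate_gene_models(g)
  g
}

validate_gene_models <- function(g) {
  if (any(!g$strand %in% c("+", "-"))) stop("validation error: strand must be + or -")
  if (any(g$tx_start >= g$tx_end)) stop("validation error: tx_start must be < tx_end")
  expected <- ifelse(g$strand == "+", g$tx_start, g$tx_end)
  if (any(g$tss != expected)) {
    stop("validation error: tss must equal tx_start (+) or tx_end (-)")
  }
  invisible(g)
}

#' Write gene models
#' @param genes Gene model data.frame.
#' @param path Output path.
#' @export
write_gene_models <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read marker gene sets (cluster, gene_id TSV) as a named list
#' @param path Path to a TSV with columns cluster, gene_id.
#' @return Named list of gene-id character vectors.
#' @export
read_marker_sets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("cluster", "gene_id") %in% names(df))) {
    stop("marker table must have columns cluster, gene_id")
  }
  split(df$gene_id, df$cluster)
}

#' Read an external differential-expression table (gene_id, log2fc, qval)
#' @param path Path to the TSV.
#' @return Data.frame with gene_id, log2fc, qval.
#' @export
read_de_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "qval")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("DE table missing column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(df$log2fc))) stop("validation error: non-finite log2fc")
  if (any(df$qval < 0 | df$qval > 1, na.rm = TRUE)) stop("validation error: qval outside [0, 1]")
  df
}

#' Read a qPCR Ct table (sample, gene, ct)
#' @param path Path to the TSV.
#' @return Data.frame with sample, gene, ct.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "gene", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("Ct table missing column(s): ", paste(miss, collapse = ", "))
  df
}
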