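# Peak-to-gene and SNP-to-peak annotation.
#
# Nearest-gene distance follows the HOMER convention: measured from the peak
# midpoint to the TSS, signed in gene orientation (negative upstream of the
# TSS, positive downstream). SNP-to-peak distances follow the sentinel-table
# convention and operate directly on 1-based printed coordinates.

#' Signed distance from a SNP to a peak (1-based coordinates)
#'
#' Returns 0 if the SNP lies inside the peak, `peak_start - pos` (positive)
#' when the SNP is before the peak, and `peak_end - pos` (negative) when it is
#' past the peak. All three inputs must be in the same 1-based coordinate
#' system; no conversion is applied because published sentinel tables print
#' values in that space.
#'
#' @param snp_pos,peak_start,peak_end Integer vectors (recycled).
#' @return Signed integer distances in bp.
#' @export
snp_peak_distance <- function(snp_pos, peak_start, peak_end) {
  stopifnot(all(peak_start <= peak_end)) # equality: a single-base peak

  ifelse(snp_pos < peak_start, peak_start - snp_pos,
         ifelse(snp_pos > peak_end, peak_end - snp_pos, 0L))
}

#' Annotate peaks to their nearest genes
#'
#' For each peak, the nearest gene is the one whose TSS is closest to the peak
#' midpoint; `dist_to_tss` is signed in gene orientation. Ties between
#' equidistant TSSs break to the lexicographically lower gene_id. Feature
#' classes are assigned against the nearest gene with precedence
#' promoter-TSS (within `promoter_window` of the TSS) > exon > intron >
#' TTS (within `promoter_window` of the transcript end) > intergenic.
#' Peaks on chromosomes absent from the gene models get `nearest_gene = NA`
#' and feature "intergenic", with a warning.
#'
#' @param peaks Peak data.frame (0-based half-open, with `name`).
#' @param genes Gene model data.frame (1-based tss / tx bounds).
#' @param promoter_window Promoter / TTS window in bp (default 1000).
#' @param tss_window Promoter-proximal threshold in bp (default 5000;
#'   `is_promoter_proximal` is `abs(dist_to_tss) < tss_window`).
#' @return Data.frame with peak_id, nearest_gene, dist_to_tss, feature,
#'   is_promoter_proximal.
#' @export
annotate_peaks <- function(peaks, genes, promoter_window = 1000L, tss_window = 5000L) {
  validate_peaks(peaks)
  if (nrow(genes) == 0L) stop("gene model list is empty")
  validate_gene_models(genes)
  name <- peaks$name %||% sprintf("peak_%06d", seq_len(nrow(peaks)))
  mid1 <- (peaks$start + peaks$end) %/% 2L + 1L # 1-based midpoint
  n <- nrow(peaks)
  nearest <- rep(NA_character_, n)
  dist <- rep(NA_integer_, n)
  feature <- rep("intergenic", n)
  missing_chroms <- character(0)
  exon_tab <- parse_exons(genes)
  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    gi <- which(genes$chrom == ch)
    if (!length(gi)) {
      missing_chroms <- c(missing_chroms, ch)
      next
    }
    g <- genes[gi, , drop = FALSE]
    # absolute genomic distance to every TSS on the chromosome; nearest by
    # |distance|, ties to the lower gene_id (genes pre-sorted by id)
    g <- g[order(g$gene_id), , drop = FALSE]
    d_abs <- abs(outer(mid1[pi], g$tss, `-`))
    best <- max.col(-d_abs, ties.method = "first")
    gene <- g[best, , drop = FALSE]
    draw <- mid1[pi] - gene$tss
    d_signed <- ifelse(gene$strand == "-", -draw, draw)
    nearest[pi] <- gene$gene_id
    dist[pi] <- as.integer(d_signed)
    tx_end3 <- ifelse(gene$strand == "+", gene$tx_end, gene$tx_start)
    in_tx <- mid1[pi] >= gene$tx_start & mid1[pi] <= gene$tx_end
    in_ex <- mapply(function(m, gid) in_exon(m, gid, exon_tab), mid1[pi], gene$gene_id)
    feature[pi] <- ifelse(
      abs(mid1[pi] - gene$tss) <= promoter_window, "promoter-TSS",
      ifelse(in_tx & in_ex, "exon",
             ifelse(in_tx, "intron",
                    ifelse(abs(mid1[pi] - tx_end3) <= promoter_window, "TTS",
                           "intergenic"))))
  }
  if (length(missing_chroms)) {
    warning("no gene models on chromosome(s) ", paste(missing_chroms, collapse = ", "),
            "; peaks there annotated intergenic with nearest_gene = NA")
  }
  data.frame(peak_id = name, nearest_gene = nearest, dist_to_tss = dist,
             feature = feature,
             is_promoter_proximal = !is.na(dist) & abs(dist) < tss_window,
             stringsAsFactors = FALSE)
}

# Exon intervals per gene (1-based inclusive), from optional comma-separated
# exon_starts/exon_ends columns.
parse_exons <- function(genes) {
  if (is.null(genes$exon_starts) || is.null(genes$exon_ends)) return(NULL)
  out <- lapply(seq_len(nrow(genes)), function(i) {
    s <- genes$exon_starts[i]
    e <- genes$exon_ends[i]
    if (is.na(s) || !nzchar(s)) return(NULL)
    cbind(as.integer(strsplit(s, ",")[[1L]]), as.integer(strsplit(e, ",")[[1L]]))
  })
  names(out) <- genes$gene_id
  out
}

in_exon <- function(mid1, gene_id, exon_tab) {
  if (is.null(exon_tab)) return(TRUE) # no exon structure: whole tx treated as exonic
  ex <- exon_tab[[gene_id]]
  if (is.null(ex)) return(TRUE)
  any(mid1 >= ex[, 1L] & mid1 <= ex[, 2L])
}

#' Nearest peak (by signed distance magnitude) for each SNP
#'
#' @param snps SNP record data.frame (1-based `pos`).
#' @param peaks Peak data.frame in internal 0-based half-open coordinates.
#' @return Data.frame with rsid, peak_id, peak_start, peak_end (1-based
#'   inclusive) and the signed `distance`; NA columns for SNPs on chromosomes
#'   without peaks.
#' @export
nearest_peak <- function(snps, peaks) {
  validate_peaks(peaks)
  name <- peaks$name %||% sprintf("peak_%06d", seq_len(nrow(peaks)))
  start1 <- peaks$start + 1L
  end1 <- peaks$end
  out <- data.frame(rsid = snps$rsid, peak_id = NA_character_,
                    peak_start = NA_integer_, peak_end = NA_integer_,
                    distance = NA_integer_, stringsAsFactors = FALSE)
  for (ch in unique(snps$chrom)) {
    si <- which(snps$chrom == ch)
    pi <- which(peaks$chrom == ch)
    if (!length(pi)) next
    for (k in si) {
      d <- snp_peak_distance(snps$pos[k], start1[pi], end1[pi])
      j <- which.min(abs(d))
      out$peak_id[k] <- name[pi[j]]
      out$peak_start[k] <- start1[pi[j]]
      out$peak_end[k] <- end1[pi[j]]
      out$distance[k] <- d[j]
    }
  }
  out
}

#' Annotate sentinel SNPs with their closest peak and cell-type specificity
#'
#' Reproduces the sentinel-SNP table logic: coding SNPs are dropped, each
#' remaining SNP is matched to its nearest consensus peak, rows whose absolute
#' distance is `>= max_dist` are dropped, and the three cell-type specificity
#' log2fc values are joined with significance flags (q < `q_max`).
#'
#' @param snps SNP record data.frame.
#' @param peaks Consensus peak data.frame (0-based internal coordinates).
#' @param diff_by_celltype Named list (NEUN/PU1/OEG) of differential result
#'   data.frames carrying peak_id, log2fc, qval.
#' @param max_dist Distance cutoff in bp (default 1000, strict).
#' @param q_max Significance threshold on q (default 0.05).
#' @return One row per retained SNP with distance, per-cell-type log2fc and
#'   significance flags.
#' @export
sentinel_annotation <- function(snps, peaks, diff_by_celltype, max_dist = 1000L,
                                q_max = 0.05) {
  stopifnot(all(names(diff_by_celltype) %in% .CELL_TYPES))
  keep <- !snps$is_coding
  snps <- snps[keep, , drop = FALSE]
  np <- nearest_peak(snps, peaks)
  ok <- !is.na(np$distance) & abs(np$distance) < max_dist
  snps <- snps[ok, , drop = FALSE]
  np <- np[ok, , drop = FALSE]
  out <- data.frame(rsid = snps$rsid, chrom = snps$chrom, pos = snps$pos,
                    pval = snps$pval, peak_id = np$peak_id,
                    peak_start = np$peak_start, peak_end = np$peak_end,
                    distance = np$distance, stringsAsFactors = FALSE)
  for (ct in names(diff_by_celltype)) {
    d <- diff_by_celltype[[ct]]
    m <- match(out$peak_id, d$peak_id)
    out[[paste0("log2fc_", ct)]] <- d$log2fc[m]
    out[[paste0("sig_", ct)]] <- !is.na(d$qval[m]) & d$qval[m] < q_max
  }
  out
}

#' Hypergeometric test for promoter-proximal enrichment
#'
#' Upper-tail `P(X >= k)` with population `N = |background|`, successes
#' `K` = proximal peaks in the background, draws `n = |foreground|` and
#' observed `k` = proximal peaks in the foreground;
#' `fold = (k/n) / (K/N)`.
#'
#' @param foreground,background Peak annotation data.frames (foreground must
#'   be a subset of background by peak_id) with `is_promoter_proximal`.
#' @return A list with k, n, K, N, fold and pval.
#' @export
promoter_enrichment_test <- function(foreground, background) {
  if (!all(foreground$peak_id %in% background$peak_id)) {
    stop("foreground must be a subset of background")
  }
  N <- nrow(background)
  K <- sum(background$is_promoter_proximal)
  n <- nrow(foreground)
  k <- sum(foreground$is_promoter_proximal)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  fold <- if (n == 0L || K == 0L) NA_real_ else (k / n) / (K / N)
  if (n > 0L && K == 0L && k == 0L) fold <- NA_real_
  list(k = k, n = n, K = K, N = N, fold = fold, pval = p)
}
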