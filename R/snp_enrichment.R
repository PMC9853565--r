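# Permutation-based colocalization test between GWAS SNPs and cell
# type-specific peak sets.
#
# Foreground SNPs (non-coding, p < 1e-3, LD-pruned at r^2 > 0.5) are compared
# against a null built by repeatedly replacing each foreground SNP with a
# catalog SNP matched on minor allele frequency, distance to gene and
# LD-partner count (GREGOR-style binned matching; exact matching on the
# continuous properties is impossible, so the binning is explicit and
# configurable).

#' Greedy LD pruning
#'
#' SNPs are visited in ascending p-value order; a SNP is kept iff its r^2 with
#' every already-kept SNP is at most `r2_max`.
#'
#' @param snps SNP record data.frame.
#' @param ld_pairs Data.frame with columns rsid_a, rsid_b, r2.
#' @param r2_max Pruning threshold (default 0.5).
#' @return The kept SNP records (original rows preserved).
#' @export
ld_prune <- function(snps, ld_pairs, r2_max = 0.5) {
  if (nrow(ld_pairs)) {
    known <- unique(c(ld_pairs$rsid_a, ld_pairs$rsid_b))
    unknown <- setdiff(known, snps$rsid)
    if (length(unknown)) stop("ld_pairs reference unknown rsid(s): ",
                              paste(utils::head(unknown, 5L), collapse = ", "))
  }
  strong <- ld_pairs[ld_pairs$r2 > r2_max, , drop = FALSE]
  # integer adjacency over the pairs that can block a SNP
  ia <- match(strong$rsid_a, snps$rsid)
  ib <- match(strong$rsid_b, snps$rsid)
  adj <- split(c(ib, ia), c(ia, ib))
  names_adj <- as.integer(names(adj))
  adj_of <- vector("list", nrow(snps))
  adj_of[names_adj] <- adj
  ord <- order(snps$pval)
  kept_flag <- logical(nrow(snps))
  for (i in ord) {
    partners <- adj_of[[i]]
    if (is.null(partners) || !any(kept_flag[partners])) kept_flag[i] <- TRUE
  }
  snps[kept_flag, , drop = FALSE]
}

#' Select the foreground SNP set
#'
#' Drops coding SNPs, then keeps SNPs with p-value strictly below `p_max`.
#' Warns when the result is empty.
#'
#' @param snps SNP record data.frame.
#' @param p_max Strict p-value cutoff (default 1e-3).
#' @return The selected SNP records.
#' @export
select_foreground <- function(snps, p_max = 1e-3) {
  out <- snps[!snps$is_coding & snps$pval < p_max, , drop = FALSE]
  if (nrow(out) == 0L) warning("foreground selection returned no SNPs")
  out
}

#' Assign matching bins over (MAF, distance to gene, LD-partner count)
#'
#' MAF is binned at fixed width; distance uses quantile edges over
#' `log10(1 + dist_to_gene)` computed on the catalog; LD-partner counts use
#' fixed integer edges ({0}, {1}, {2-5}, {6-20}, {>20} by default).
#'
#' @param catalog SNP record data.frame the bins partition.
#' @param maf_bin_width MAF bin width (default 0.05).
#' @param n_dist_bins Number of distance quantile bins (default 10).
#' @param ld_breaks Upper-inclusive integer edges for LD-partner bins.
#' @return Character vector of bin ids, one per catalog SNP.
#' @export
match_bins <- function(catalog, maf_bin_width = 0.05, n_dist_bins = 10L,
                       ld_breaks = c(0L, 1L, 5L, 20L)) {
  maf_bin <- floor(catalog$maf / maf_bin_width)
  ld <- log10(1 + catalog$dist_to_gene)
  edges <- unique(stats::quantile(ld, probs = seq(0, 1, length.out = n_dist_bins + 1L)))
  dist_bin <- findInterval(ld, edges, rightmost.closed = TRUE, all.inside = TRUE)
  ld_bin <- findInterval(catalog$ld_partner_count, ld_breaks + 1L)
  paste(maf_bin, dist_bin, ld_bin, sep = ":")
}

# TRUE for each 1-based position covered by >= 1 peak (0-based half-open
# peaks; overlap means pos in [start+1, end] inclusive). Handles overlapping
# peaks via a running-maximum end.
snp_in_peaks <- function(chrom, pos, peaks) {
  covered <- logical(length(pos))
  for (ch in unique(chrom)) {
    si <- which(chrom == ch)
    p <- peaks[peaks$chrom == ch, , drop = FALSE]
    if (!nrow(p)) next
    o <- order(p$start)
    starts1 <- p$start[o] + 1L
    cmax_end <- cummax(p$end[o])
    idx <- findInterval(pos[si], starts1)
    hit <- idx >= 1L
    hit[hit] <- pos[si][hit] <= cmax_end[idx[hit]]
    covered[si] <- hit
  }
  covered
}

#' Property-matched permutation enrichment of SNPs in peak annotations
#'
#' The observed statistic is the number of foreground SNPs falling inside at
#' least one peak of the annotation. Each permutation replaces every
#' foreground SNP with a uniform draw from the catalog SNPs sharing its
#' (MAF, distance, LD-count) bin, excluding the SNP itself; draws are with
#' replacement across permutations.
#' `log2_enrichment = log2((observed + 0.5) / (null_mean + 0.5))` and
#' `empirical_p = (1 + #\{null >= observed\}) / (1 + n_perm)` (one-sided);
#' BH correction across annotation labels.
#'
#' @param foreground SNP record data.frame (from `select_foreground` after
#'   `ld_prune`).
#' @param catalog Full SNP record data.frame the matched nulls are drawn from.
#' @param annotations Named list of peak data.frames (internal 0-based
#'   coordinates), e.g. one per cell-type-specific set.
#' @param bins Optional precomputed catalog bin ids (`match_bins`).
#' @param n_perm Number of permutations (default 1e5; published analyses used
#'   up to 1e6).
#' @param seed Integer seed for the permutation stream.
#' @return Data.frame with one row per annotation: n_foreground,
#'   observed_overlap, null_mean, null_sd, log2_enrichment, empirical_p, qval.
#' @export
matched_permutation_enrichment <- function(foreground, catalog, annotations,
                                           bins = NULL, n_perm = 100000L,
                                           seed = 1L) {
  stopifnot(is.list(annotations), !is.null(names(annotations)), nrow(foreground) >= 1L)
  if (is.null(bins)) bins <- match_bins(catalog)
  stopifnot(length(bins) == nrow(catalog))
  fg_in_cat <- match(foreground$rsid, catalog$rsid)
  fg_bins <- if (anyNA(fg_in_cat)) {
    # foreground SNPs not in the catalog are binned by their own properties
    match_bins(rbind(catalog, foreground))[nrow(catalog) + seq_len(nrow(foreground))]
  } else {
    bins[fg_in_cat]
  }
  bin_members <- split(seq_len(nrow(catalog)), bins)
  candidates <- lapply(seq_len(nrow(foreground)), function(i) {
    mem <- bin_members[[fg_bins[i]]]
    if (!is.na(fg_in_cat[i])) mem <- setdiff(mem, fg_in_cat[i])
    mem
  })
  short <- lengths(candidates) < 2L
  if (any(short)) {
    stop("under-populated matching bin for SNP(s) ",
         paste(utils::head(foreground$rsid[short], 5L), collapse = ", "),
         "; use coarser bins")
  }
  # overlap flags per annotation for the catalog and the foreground
  res <- vector("list", length(annotations))
  with_stage_seed(seed, "matched_permutation", {
    # one matched draw matrix (n_fg x n_perm) of catalog indices, shared
    # across annotations so labels are compared on the same null draws
    draw_idx <- vapply(candidates, function(mem) {
      mem[sample.int(length(mem), n_perm, replace = TRUE)]
    }, integer(n_perm))
    # draw_idx: n_perm x n_fg
    for (a in seq_along(annotations)) {
      peaks <- annotations[[a]]
      cat_flag <- snp_in_peaks(catalog$chrom, catalog$pos, peaks)
      obs <- sum(snp_in_peaks(foreground$chrom, foreground$pos, peaks))
      null_stat <- rowSums(matrix(cat_flag[draw_idx], nrow = n_perm))
      res[[a]] <- data.frame(
        annotation = names(annotations)[a],
        n_foreground = nrow(foreground),
        observed_overlap = obs,
        null_mean = mean(null_stat),
        null_sd = stats::sd(null_stat),
        log2_enrichment = log2((obs + 0.5) / (mean(null_stat) + 0.5)),
        empirical_p = (1 + sum(null_stat >= obs)) / (1 + n_perm),
        stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, res)
  out$qval <- stats::p.adjust(out$empirical_p, method = "BH")
  rownames(out) <- NULL
  out
}
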