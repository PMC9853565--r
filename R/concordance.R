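# Cross-modality concordance statistics and delta-delta-Ct qPCR
# quantification.

#' One-sided concordance t-test between DAR-annotated genes and external
#' differential expression
#'
#' Maps differentially acetylated regions to their nearest genes (optionally
#' promoter-proximal only), intersects with an external DE table, and runs a
#' one-sample one-sided t-test on the DE log2fc values (H0: mean = 0).
#'
#' @param dars Peak annotation data.frame for the DAR set (`annotate_peaks`
#'   output restricted to the DARs).
#' @param de DE table data.frame (gene_id, log2fc, qval).
#' @param direction "greater" or "less" (alternative on the mean log2fc).
#' @param proximal_only Restrict to |dist_to_tss| < 5 kb (default TRUE).
#' @return List with n_genes, mean_log2fc, t, pval and the gene ids used.
#' @export
concordance_ttest <- function(dars, de, direction = c("greater", "less"),
                              proximal_only = TRUE) {
  direction <- match.arg(direction)
  a <- dars
  if (proximal_only) a <- a[a$is_promoter_proximal, , drop = FALSE]
  genes <- unique(a$nearest_gene[!is.na(a$nearest_gene)])
  x <- de$log2fc[match(intersect(genes, de$gene_id), de$gene_id)]
  if (length(x) < 3L) stop("fewer than 3 mapped genes with DE values")
  tt <- stats::t.test(x, mu = 0, alternative = direction)
  list(n_genes = length(x), mean_log2fc = mean(x), t = unname(tt$statistic),
       pval = tt$p.value, genes = intersect(genes, de$gene_id))
}

#' Hypergeometric overlap test between two gene sets in a universe
#'
#' Upper tail `P(X >= k)` with `N = |universe|`, `K = |de_sig_genes|`,
#' `n = |dar_genes|`, `k = |intersection|`.
#'
#' @param dar_genes,de_sig_genes,universe Character vectors of gene ids; the
#'   first two must be subsets of the universe.
#' @return List with k, n, K, N and pval.
#' @export
overlap_hypergeom <- function(dar_genes, de_sig_genes, universe) {
  dar_genes <- unique(dar_genes)
  de_sig_genes <- unique(de_sig_genes)
  universe <- unique(universe)
  if (!all(dar_genes %in% universe) || !all(de_sig_genes %in% universe)) {
    stop("gene sets must be subsets of the universe")
  }
  N <- length(universe)
  K <- length(de_sig_genes)
  n <- length(dar_genes)
  k <- length(intersect(dar_genes, de_sig_genes))
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  list(k = k, n = n, K = K, N = N, pval = p)
}

#' Hedges' g standardised mean difference
#'
#' `g = J * (mean(x) - mean(y)) / s_pooled` with
#' `s_pooled = sqrt(((n1-1)s1^2 + (n2-1)s2^2) / (n1+n2-2))` and the
#' small-sample correction `J = 1 - 3 / (4(n1+n2) - 9)`. Returns NA with a
#' warning when the pooled sd is zero.
#'
#' @param x,y Numeric sample vectors.
#' @return A single numeric value.
#' @export
hedges_g <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  stopifnot(n1 >= 2L, n2 >= 2L)
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2))
  if (sp == 0) {
    warning("pooled standard deviation is zero; Hedges' g undefined")
    return(NA_real_)
  }
  J <- 1 - 3 / (4 * (n1 + n2) - 9)
  J * (mean(x) - mean(y)) / sp
}

#' Delta-delta-Ct qPCR quantification
#'
#' Per sample, the housekeeping reference is the geometric mean of the
#' housekeeping genes' Ct values (implemented literally as stated; an
#' arithmetic-mean variant is exposed via `hk_mean`). Then
#' `dCt_{s,g} = Ct_{s,g} - hk_s`,
#' `ddCt_g = mean(dCt over HIGH) - mean(dCt over REF)` and
#' `fold = 2^(-ddCt)`. Group membership comes from per-sample amyloid loads:
#' REF combines low (< `low_cut`) and mid (`low_cut`..`high_cut`) samples,
#' HIGH is load > `high_cut`. Per gene, a Welch t-test on the dCt values and
#' Hedges' g (HIGH minus REF on the dCt scale, so positive g means reduced
#' expression in HIGH) are reported with BH correction across genes. Samples
#' missing a housekeeping Ct are dropped with a warning.
#'
#' @param ct_table Long data.frame (sample, gene, ct).
#' @param housekeeping Housekeeping gene names (e.g. RPL13, CYC1, GAPDH).
#' @param loads Named numeric vector of amyloid loads (percent area) per
#'   sample.
#' @param high_cut,low_cut Group cutoffs on the load scale (defaults 7.71
#'   and 1).
#' @param hk_mean "geometric" (default) or "arithmetic" housekeeping mean.
#' @return Data.frame per target gene: n_high, n_ref, ddct, fold_change,
#'   hedges_g, pval, qval.
#' @export
ddct <- function(ct_table, housekeeping, loads, high_cut = 7.71, low_cut = 1,
                 hk_mean = c("geometric", "arithmetic")) {
  hk_mean <- match.arg(hk_mean)
  stopifnot(all(c("sample", "gene", "ct") %in% names(ct_table)))
  samples <- unique(ct_table$sample)
  if (!all(samples %in% names(loads))) {
    stop("missing amyloid load for sample(s): ",
         paste(utils::head(setdiff(samples, names(loads)), 5L), collapse = ", "))
  }
  hk_ref <- vapply(samples, function(s) {
    v <- ct_table$ct[ct_table$sample == s & ct_table$gene %in% housekeeping]
    if (length(v) < length(housekeeping) || anyNA(v)) return(NA_real_)
    if (hk_mean == "geometric") geomean(v) else mean(v)
  }, numeric(1L))
  dropped <- samples[is.na(hk_ref)]
  if (length(dropped)) {
    warning("dropping sample(s) without complete housekeeping Ct: ",
            paste(dropped, collapse = ", "))
    samples <- setdiff(samples, dropped)
  }
  grp <- ifelse(loads[samples] > high_cut, "HIGH", "REF")
  if (!all(c("HIGH", "REF") %in% grp)) stop("both HIGH and REF groups must be nonempty")
  targets <- setdiff(unique(ct_table$gene), housekeeping)
  rows <- lapply(targets, function(g) {
    ct_g <- ct_table[ct_table$gene == g & ct_table$sample %in% samples, , drop = FALSE]
    dct <- ct_g$ct - hk_ref[ct_g$sample]
    gg <- grp[ct_g$sample]
    hi <- dct[gg == "HIGH"]
    re <- dct[gg == "REF"]
    dd <- mean(hi) - mean(re)
    tt <- if (length(hi) >= 2L && length(re) >= 2L) {
      tryCatch(stats::t.test(hi, re), error = function(e) list(p.value = NA_real_))
    } else {
      list(p.value = NA_real_)
    }
    data.frame(gene = g, n_high = length(hi), n_ref = length(re), ddct = dd,
               fold_change = 2^(-dd),
               hedges_g = if (length(hi) >= 2L && length(re) >= 2L) hedges_g(hi, re) else NA_real_,
               pval = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$qval <- stats::p.adjust(out$pval, method = "BH")
  rownames(out) <- NULL
  out
}
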