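# Sorting validation against external marker-gene clusters.
#
# For every (snRNA-seq cluster, sorted population) pair the cell-type
# specificity log2fc values of peaks annotated to the cluster's marker genes
# are tested against the 0.5 threshold (~1.4-fold) with a one-sided one-sample
# t-test; BH correction is applied across all pairs in the run. Per-sample
# heatmap matrices use the stabilised counts.

#' Marker-set specificity t-tests
#'
#' For each (cluster, population): gathers the population's focal-vs-rest
#' log2fc at peaks whose nearest gene belongs to the cluster (optionally
#' restricted to promoter-proximal peaks, |dist_to_tss| < 5 kb), then tests
#' H1: mean log2fc > `threshold` with a one-sample t-test (sample sd, n-1).
#' BH correction across every test in the run (e.g. 45 for 15 clusters x 3
#' populations). Clusters mapping to no peaks give an NA row with a warning;
#' those with fewer than 3 peaks are flagged underpowered.
#'
#' @param diff Named list (population -> differential result data.frame with
#'   peak_id, log2fc), e.g. from `celltype_specific_peaks` per population.
#' @param annotations Peak annotation data.frame (`annotate_peaks`).
#' @param markers Named list of marker gene-id vectors per cluster.
#' @param threshold Null mean on the log2 scale (default 0.5).
#' @param proximal_only Restrict to promoter-proximal peaks.
#' @return Data.frame with cluster, population, n_peaks, mean_log2fc, t_stat,
#'   pval, qval, underpowered.
#' @export
marker_set_test <- function(diff, annotations, markers, threshold = 0.5,
                            proximal_only = FALSE) {
  stopifnot(is.list(diff), !is.null(names(diff)), is.list(markers))
  annot <- annotations
  if (proximal_only) annot <- annot[annot$is_promoter_proximal, , drop = FALSE]
  rows <- list()
  for (pop in names(diff)) {
    d <- diff[[pop]]
    for (cl in names(markers)) {
      genes <- unique(markers[[cl]])
      ids <- annot$peak_id[!is.na(annot$nearest_gene) & annot$nearest_gene %in% genes]
      x <- d$log2fc[match(ids, d$peak_id)]
      x <- x[is.finite(x)]
      n <- length(x)
      if (n == 0L) {
        warning("no annotated peaks for cluster ", cl, " (population ", pop, ")")
        rows[[length(rows) + 1L]] <- data.frame(
          cluster = cl, population = pop, n_peaks = 0L, mean_log2fc = NA_real_,
          t_stat = NA_real_, pval = NA_real_, underpowered = TRUE,
          stringsAsFactors = FALSE)
        next
      }
      if (n < 2L) {
        tt <- list(statistic = NA_real_, p.value = NA_real_)
      } else if (stats::sd(x) == 0) {
        # degenerate sample: all values equal; at the threshold the one-sided
        # test is exactly indifferent
        tt <- if (x[1L] == threshold) {
          list(statistic = 0, p.value = 0.5)
        } else {
          list(statistic = sign(x[1L] - threshold) * Inf,
               p.value = if (x[1L] > threshold) 0 else 1)
        }
      } else {
        tt <- stats::t.test(x, mu = threshold, alternative = "greater")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, population = pop, n_peaks = n, mean_log2fc = mean(x),
        t_stat = unname(tt$statistic), pval = tt$p.value, underpowered = n < 3L,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$qval <- NA_real_
  ok <- !is.na(out$pval)
  out$qval[ok] <- stats::p.adjust(out$pval[ok], method = "BH")
  rownames(out) <- NULL
  out
}

#' Per-tissue-sample specificity matrix
#'
#' For each tissue sample (subject x region) with all three sorted
#' populations present, and each marker cluster: the mean over the cluster's
#' peaks of `log2(stab_focal / mean(stab of the two non-focal populations))`,
#' where `stab` is the stabilised count. Samples missing a population get an
#' NA row with a warning.
#'
#' @param stabilized Real matrix from `stabilize` (peaks x samples).
#' @param meta Metadata with sample_id, subject_id, region, cell_type.
#' @param markers Named list of marker gene-id vectors per cluster.
#' @param annotations Peak annotation data.frame.
#' @param focal Focal population (default the cluster-cognate is up to the
#'   caller; this function computes the matrix for one focal population).
#' @return Matrix (tissue samples x clusters) of mean specificity values.
#' @export
per_sample_specificity <- function(stabilized, meta, markers, annotations, focal) {
  focal <- canonical_cell_type(focal)
  ct <- canonical_cell_type(meta$cell_type)
  tissue <- paste(meta$subject_id, meta$region, sep = "|")
  tissues <- unique(tissue)
  cluster_peaks <- lapply(markers, function(genes) {
    ids <- annotations$peak_id[!is.na(annotations$nearest_gene) &
                                 annotations$nearest_gene %in% unique(genes)]
    match(ids, rownames(stabilized))
  })
  out <- matrix(NA_real_, length(tissues), length(markers),
                dimnames = list(tissues, names(markers)))
  for (ts in tissues) {
    ix <- which(tissue == ts)
    present <- ct[ix]
    if (!all(.CELL_TYPES %in% present)) {
      warning("tissue sample ", ts, " is missing a sorted population; row set to NA")
      next
    }
    fcol <- ix[match(focal, present)]
    ocol <- ix[match(setdiff(.CELL_TYPES, focal), present)]
    for (cl in names(markers)) {
      rows <- cluster_peaks[[cl]]
      rows <- rows[!is.na(rows)]
      if (!length(rows)) next
      fv <- stabilized[rows, fcol]
      ov <- rowMeans(stabilized[rows, ocol, drop = FALSE])
      ratio <- log2(fv / ov)
      out[ts, cl] <- mean(ratio[is.finite(ratio)])
    }
  }
  out
}

#' Z-score a sample-by-cluster matrix (optionally group-averaged)
#'
#' Z-scores each cluster column across rows using the sample standard
#' deviation; constant columns map to zeros. If `grouping` is given (a factor
#' or character vector over rows, e.g. interaction of amyloid status, sex and
#' region), rows are first averaged within groups and the group means are
#' z-scored.
#'
#' @param values Numeric matrix (samples x clusters).
#' @param grouping Optional row grouping.
#' @return Z-scored matrix (per group when grouping is given).
#' @export
zscore_matrix <- function(values, grouping = NULL) {
  m <- values
  if (!is.null(grouping)) {
    grouping <- as.character(grouping)
    stopifnot(length(grouping) == nrow(values))
    groups <- unique(grouping)
    m <- t(vapply(groups, function(g) {
      colMeans(values[grouping == g, , drop = FALSE], na.rm = TRUE)
    }, numeric(ncol(values))))
    rownames(m) <- groups
  }
  z <- apply(m, 2L, function(col) {
    s <- stats::sd(col, na.rm = TRUE)
    if (!is.finite(s) || s == 0) return(rep(0, length(col)))
    (col - mean(col, na.rm = TRUE)) / s
  })
  if (is.null(dim(z))) z <- matrix(z, nrow = nrow(m), dimnames = dimnames(m))
  dimnames(z) <- dimnames(m)
  z
}
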