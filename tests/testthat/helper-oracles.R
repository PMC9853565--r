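# Independent oracles and small fixture builders shared across tests.

# Coverage-vector merge oracle: marks covered bases, fills uncovered runs
# strictly shorter than max_gap, and reads the covered runs back out.
# Deliberately unrelated to the sweep implementation in merge_with_gap.
oracle_merge <- function(peaks, max_gap) {
  out <- list()
  for (ch in sort(unique(peaks$chrom))) {
    p <- peaks[peaks$chrom == ch, , drop = FALSE]
    L <- max(p$end) + 1L
    cov <- logical(L)
    for (i in seq_len(nrow(p))) cov[(p$start[i] + 1L):p$end[i]] <- TRUE
    r <- rle(cov)
    inner <- seq_along(r$values)
    fill <- !r$values & r$lengths < max_gap &
      inner > 1L & inner < length(r$values)
    r$values[fill] <- TRUE
    r2 <- rle(inverse.rle(r))
    ends <- cumsum(r2$lengths)
    starts <- ends - r2$lengths + 1L
    runs <- which(r2$values)
    out[[ch]] <- data.frame(chrom = ch, start = starts[runs] - 1L,
                            end = ends[runs], stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

random_peakset <- function(n, chroms = c("chrA", "chrB"), span = 5000L) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(span, n, replace = TRUE)
  width <- sample.int(120L, n, replace = TRUE)
  data.frame(chrom = chrom, start = start, end = start + width,
             stringsAsFactors = FALSE)
}

# Cohort of one sorted population, 8 high-amyloid vs 8 control subjects.
cohort_8v8 <- function() {
  data.frame(subject_id = sprintf("S%02d", 1:16), region = "HIPP", sex = "F",
             abeta_status = rep(c("NONE", "HIGH"), each = 8L),
             stringsAsFactors = FALSE)
}

# Single-stratum config at the calibration scale (~2,000 peaks after
# placement, n = 8 vs 8, dispersion 0.1), with all planted effects off
# unless a DAR set is supplied.
calib_config <- function(seed, dar_sets = list()) {
  sim_config(seed = seed, n_peaks = 2500L, n_genes = 400L,
             peak_width = c(300L, 800L), prox_frac = 0.4,
             cohort = cohort_8v8(), cell_types = "OEG",
             planted_celltype_effect = 0, frac_extra_celltype = 0,
             planted_dar_sets = dar_sets, age_effect = NULL, dispersion = 0.1)
}
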