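# Bundled reference table.

#' Sentinel AD GWAS SNPs with their closest H3K27ac peak (hg19)
#'
#' Published table of lead SNPs at genome-wide significant late-onset
#' Alzheimer's disease loci (from two large GWAS meta-analyses), each with the
#' closest consensus H3K27ac peak from sorted brain cell populations, the
#' printed signed SNP-to-peak distance, and the three cell-type specificity
#' log2fc values (neuron, microglia, OEG vs the other two populations). All
#' coordinates are 1-based as printed; the distance column follows the
#' `snp_peak_distance` convention. Four rows (the ALPK2 row, both BIN1 rows
#' and the NYAP1 row) print distances inconsistent with the convention every
#' other row follows (the printed peak intervals cannot reproduce them; most
#' plausibly typos in the source); they are flagged via the `anomalous` column
#' rather than corrected.
#'
#' @return A data.frame with one row per (SNP, study) pair.
#' @export
sentinel_snp_table <- function() {
  path <- system.file("extdata", "ad_sentinel_snps.tsv", package = "acetylseq",
                      mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  df$anomalous <- df$rsid %in% c("rs76726049", "rs6733839", "rs4663105", "rs12539172")
  df
}
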