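# Nearest-gene annotation, signed SNP distances and the promoter test.

toy_genes <- function() {
  data.frame(gene_id = c("geneA", "geneB"),
             chrom = c("chr1", "chr1"), strand = c("+", "-"),
             tss = c(10000L, 80000L), tx_start = c(10000L, 60000L),
             tx_end = c(30000L, 80000L),
             exon_starts = c("10000,20000", "60000,75000"),
             exon_ends = c("11000,21000", "61000,80000"),
             stringsAsFactors = FALSE)
}

test_that("peak annotation: signed distance, feature precedence, proximal flag", {
  genes <- toy_genes()
  peaks <- data.frame(
    chrom = "chr1",
    start = c(9899L, 12399L, 20499L, 30399L, 44999L, 81999L),
    end = c(10099L, 12600L, 20700L, 30600L, 45200L, 82200L),
    name = paste0("p", 1:6), stringsAsFactors = FALSE)
  a <- annotate_peaks(peaks, genes)
  # midpoint exactly at the TSS
  expect_equal(a$dist_to_tss[1], 0L)
  expect_equal(a$feature[1], "promoter-TSS")
  # + strand, midpoint 12500, between exons -> intron, dist +2500
  expect_equal(a$dist_to_tss[2], 2500L)
  expect_equal(a$feature[2], "intron")
  # midpoint 20600 inside the second exon
  expect_equal(a$feature[3], "exon")
  # midpoint 30500, past the + strand tx end but within 1 kb of it -> TTS
  expect_equal(a$feature[4], "TTS")
  # midpoint 45100: nearer geneB TSS (80000? no - 35 kb) vs geneA (35.1 kb)
  expect_equal(a$nearest_gene[5], "geneB")
  expect_equal(a$feature[5], "intergenic")
  expect_false(a$is_promoter_proximal[5])
  # minus-strand gene: midpoint 82100 is 2100 bp past the TSS, i.e. upstream
  expect_equal(a$dist_to_tss[6], -2100L)
  expect_true(all(a$is_promoter_proximal == (abs(a$dist_to_tss) < 5000L)))
})

test_that("peaks on chromosomes without gene models get NA gene and a warning", {
  peaks <- data.frame(chrom = "chrZ", start = 0L, end = 200L, name = "p1")
  expect_warning(a <- annotate_peaks(peaks, toy_genes()), "chrZ")
  expect_true(is.na(a$nearest_gene))
  expect_equal(a$feature, "intergenic")
})

test_that("equidistant TSS ties break to the lexicographically lower gene id", {
  genes <- data.frame(gene_id = c("gB", "gA"), chrom = "chr1", strand = "+",
                      tss = c(900L, 1100L), tx_start = c(900L, 1100L),
                      tx_end = c(5000L, 6000L), stringsAsFactors = FALSE)
  peaks <- data.frame(chrom = "chr1", start = 899L, end = 1100L, name = "p") # mid 1000
  a <- annotate_peaks(peaks, genes)
  expect_equal(a$nearest_gene, "gA")
})

test_that("snp_peak_distance follows the inside/before/after convention", {
  expect_equal(snp_peak_distance(150L, 100L, 200L), 0L)
  expect_equal(snp_peak_distance(100L, 100L, 200L), 0L) # boundary inclusive
  expect_equal(snp_peak_distance(200L, 100L, 200L), 0L)
  expect_equal(snp_peak_distance(40L, 100L, 200L), 60L) # before: positive
  expect_equal(snp_peak_distance(260L, 100L, 200L), -60L) # after: negative
})

test_that("nearest_peak agrees with a brute-force scan on random instances", {
  set.seed(13)
  for (rep in 1:25) {
    peaks <- random_peakset(40, chroms = "chr1", span = 20000L)
    peaks <- merge_with_gap(peaks, 0L)
    peaks$name <- sprintf("pk%03d", seq_len(nrow(peaks)))
    snps <- data.frame(rsid = sprintf("rs%02d", 1:40), chrom = "chr1",
                       pos = sample.int(21000L, 40), stringsAsFactors = FALSE)
    got <- nearest_peak(snps, peaks)
    for (i in seq_len(nrow(snps))) {
      d_all <- snp_peak_distance(snps$pos[i], peaks$start + 1L, peaks$end)
      expect_equal(abs(got$distance[i]), min(abs(d_all)))
    }
  }
})

test_that("printed sentinel rows reproduce exactly except the flagged anomalies", {
  st <- sentinel_snp_table()
  ok <- !st$anomalous
  d <- snp_peak_distance(st$pos[ok], st$peak_start[ok], st$peak_end[ok])
  expect_identical(d, st$closest_peak_distance[ok])
  # the flagged rows genuinely fail the convention (documented inconsistency)
  bad <- st[st$anomalous, ]
  expect_true(all(snp_peak_distance(bad$pos, bad$peak_start, bad$peak_end) !=
                    bad$closest_peak_distance))
})

test_that("sentinel annotation drops coding and distant SNPs and joins specificity", {
  peaks <- data.frame(chrom = "chr1", start = c(999L, 5999L), end = c(2000L, 7000L),
                      name = c("pkA", "pkB"), stringsAsFactors = FALSE)
  snps <- data.frame(rsid = c("rs_in", "rs_coding", "rs_far", "rs_near"),
                     chrom = "chr1", pos = c(1500L, 1600L, 4000L, 6100L),
                     pval = 1e-9, maf = 0.2,
                     is_coding = c(FALSE, TRUE, FALSE, FALSE),
                     ld_partner_count = 1L, dist_to_gene = 0L,
                     stringsAsFactors = FALSE)
  diff <- list(
    PU1 = data.frame(peak_id = c("pkA", "pkB"), log2fc = c(1.61, -0.2),
                     qval = c(6.6e-81, 0.5)),
    NEUN = data.frame(peak_id = c("pkA", "pkB"), log2fc = c(-0.75, 0.1),
                      qval = c(1e-10, 0.9)))
  out <- sentinel_annotation(snps, peaks, diff, max_dist = 1000L)
  expect_equal(out$rsid, c("rs_in", "rs_near")) # coding and >=1 kb rows dropped
  expect_equal(out$distance, c(0L, 0L))
  expect_equal(out$log2fc_PU1, c(1.61, -0.2))
  expect_equal(out$sig_PU1, c(TRUE, FALSE))
  expect_equal(out$sig_NEUN, c(TRUE, FALSE))
})

test_that("promoter enrichment matches exact combinatorics and exhaustive enumeration", {
  bg <- data.frame(peak_id = paste0("p", 1:5),
                   is_promoter_proximal = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  fg <- bg[1:2, ]
  r <- promoter_enrichment_test(fg, bg)
  expect_equal(r$pval, 0.1) # C(2,2)C(3,0)/C(5,2)
  expect_equal(r$fold, 2.5)
  # foreground = background: k = K forced, p = 1
  r2 <- promoter_enrichment_test(bg, bg)
  expect_equal(r2$pval, 1)
  expect_equal(r2$fold, 1)
  # zero proximal foreground
  r3 <- promoter_enrichment_test(bg[3:4, ], bg)
  expect_equal(r3$fold, 0)
  expect_equal(r3$pval, 1)
  expect_error(promoter_enrichment_test(data.frame(peak_id = "zz",
                                                   is_promoter_proximal = TRUE), bg),
               "subset")
  # exhaustive enumeration for N <= 12: P(X >= k) over all C(N, n) draws
  set.seed(3)
  for (rep in 1:20) {
    N <- sample(4:12, 1L)
    K <- sample.int(N, 1L)
    n <- sample.int(N, 1L)
    ids <- paste0("p", seq_len(N))
    bgx <- data.frame(peak_id = ids, is_promoter_proximal = seq_len(N) <= K)
    draw <- sample(ids, n)
    k <- sum(match(draw, ids) <= K)
    combos <- utils::combn(N, n)
    exact <- mean(colSums(combos <= K) >= k)
    got <- promoter_enrichment_test(bgx[match(draw, ids), ], bgx)
    expect_equal(got$pval, exact, tolerance = 1e-12)
  }
})
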