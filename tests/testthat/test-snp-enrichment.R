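# LD pruning, foreground selection and the matched permutation test.

test_that("greedy LD pruning keeps the best SNP per correlated chain", {
  snps <- data.frame(rsid = c("a", "b", "c"), chrom = "chr1", pos = c(100L, 200L, 300L),
                     pval = c(1e-8, 1e-6, 1e-4), maf = 0.2, is_coding = FALSE,
                     ld_partner_count = 2L, dist_to_gene = 0L, stringsAsFactors = FALSE)
  pairs <- data.frame(rsid_a = c("a", "b", "a"), rsid_b = c("b", "c", "c"),
                      r2 = c(0.6, 0.6, 0.1))
  kept <- ld_prune(snps, pairs)
  expect_equal(sort(kept$rsid), c("a", "c")) # a blocks b; c only tied to b
  # no pairs above threshold: input unchanged
  expect_equal(ld_prune(snps, data.frame(rsid_a = "a", rsid_b = "b", r2 = 0.3)), snps)
  expect_error(ld_prune(snps, data.frame(rsid_a = "a", rsid_b = "zz", r2 = 0.9)),
               "unknown rsid")
})

test_that("pruning equals a brute-force reimplementation on small random instances", {
  brute <- function(snps, pairs, r2_max = 0.5) {
    strong <- pairs[pairs$r2 > r2_max, , drop = FALSE]
    kept <- character(0)
    for (id in snps$rsid[order(snps$pval)]) {
      partners <- c(strong$rsid_b[strong$rsid_a == id], strong$rsid_a[strong$rsid_b == id])
      if (!length(intersect(partners, kept))) kept <- c(kept, id)
    }
    sort(kept)
  }
  set.seed(17)
  for (rep in 1:40) {
    n <- sample(3:12, 1L)
    snps <- data.frame(rsid = paste0("s", 1:n), chrom = "chr1", pos = seq_len(n) * 10L,
                       pval = runif(n), maf = 0.2, is_coding = FALSE,
                       ld_partner_count = 0L, dist_to_gene = 0L, stringsAsFactors = FALSE)
    cmb <- utils::combn(n, 2L)
    idx <- which(runif(ncol(cmb)) < 0.4)
    pairs <- data.frame(rsid_a = sprintf("s%d", cmb[1, idx]),
                        rsid_b = sprintf("s%d", cmb[2, idx]),
                        r2 = runif(length(idx)), stringsAsFactors = FALSE)
    expect_equal(sort(ld_prune(snps, pairs)$rsid), brute(snps, pairs))
  }
})

test_that("foreground selection drops coding SNPs and uses a strict p cutoff", {
  snps <- data.frame(rsid = paste0("r", 1:4), chrom = "chr1", pos = 1:4,
                     pval = c(1e-4, 1e-3, 0.5, 1e-5), maf = 0.2,
                     is_coding = c(FALSE, FALSE, FALSE, TRUE),
                     ld_partner_count = 0L, dist_to_gene = 0L, stringsAsFactors = FALSE)
  fg <- select_foreground(snps)
  expect_equal(fg$rsid, "r1") # 1e-3 is excluded (strict <), coding excluded
  expect_warning(out <- select_foreground(transform(snps, is_coding = TRUE)), "no SNPs")
  expect_equal(nrow(out), 0L)
})

test_that("permutation enrichment: whole-genome annotation, p floor, determinism, monotonicity", {
  # one bin: identical matching properties
  catalog <- data.frame(rsid = sprintf("c%02d", 1:12), chrom = "chr1",
                        pos = c(150L, 160L, seq(5000L, 14000L, by = 1000L)),
                        pval = 0.5, maf = 0.2, is_coding = FALSE,
                        ld_partner_count = 2L, dist_to_gene = 100L,
                        stringsAsFactors = FALSE)
  fg <- catalog[1:2, ]
  peak <- data.frame(chrom = "chr1", start = 100L, end = 200L, name = "pk")
  whole <- data.frame(chrom = "chr1", start = 0L, end = 20000L, name = "all")
  bins <- rep("b", 12)
  # annotation covering everything: no enrichment, p = 1
  e_all <- matched_permutation_enrichment(fg, catalog, list(all = whole),
                                          bins = bins, n_perm = 50L, seed = 1L)
  expect_equal(e_all$observed_overlap, 2L)
  expect_equal(e_all$null_mean, 2)
  expect_equal(e_all$log2_enrichment, 0)
  expect_equal(e_all$empirical_p, 1)
  # observed beats every draw (both foreground SNPs' bin-mates lie outside
  # the peak): p sits exactly at the 1/(n_perm + 1) floor
  bins_floor <- c("A", "B", "A", "A", "B", "B", rep("C", 6))
  e <- matched_permutation_enrichment(fg, catalog, list(pk = peak),
                                      bins = bins_floor, n_perm = 10L, seed = 1L)
  expect_equal(e$observed_overlap, 2L)
  expect_equal(e$null_mean, 0)
  expect_equal(e$empirical_p, 1 / 11)
  # same seed is bit-identical
  e2 <- matched_permutation_enrichment(fg, catalog, list(pk = peak),
                                       bins = bins_floor, n_perm = 10L, seed = 1L)
  expect_identical(e, e2)
  # adding an in-annotation foreground SNP whose bin-mates are outside
  # never decreases the enrichment
  fg3 <- catalog[1:3, ]
  fg3$pos[3] <- 170L
  catalog3 <- catalog
  catalog3$pos[3] <- 170L
  e3 <- matched_permutation_enrichment(fg3, catalog3, list(pk = peak),
                                       bins = bins, n_perm = 200L, seed = 2L)
  e1 <- matched_permutation_enrichment(fg, catalog3, list(pk = peak),
                                       bins = bins, n_perm = 200L, seed = 2L)
  expect_gte(e3$log2_enrichment, e1$log2_enrichment)
  # under-populated bin errors with the offending SNP named
  expect_error(matched_permutation_enrichment(fg, catalog[1:2, ], list(pk = peak),
                                              bins = bins[1:2], n_perm = 10L),
               "under-populated")
})

test_that("match_bins partitions the catalog on the three preserved properties", {
  cfg <- sim_config(seed = 2)
  g <- gen_genome(cfg)
  sn <- gen_snp_catalog(cfg, g)
  b <- match_bins(sn$snps)
  expect_equal(length(b), nrow(sn$snps))
  # same bin means same MAF bin, same LD bin, same distance bin
  one <- which(b == b[1L])
  expect_true(diff(range(sn$snps$maf[one])) <= 0.05)
  sizes <- table(b)
  expect_gt(min(sizes), 0)
})

test_that("planted enrichment is detected in the designated cell type", {
  cfg <- sim_config(seed = 3,
                    snp = utils::modifyList(sim_config()$snp,
                                            list(fraction_causal_in_peaks = 0.5)))
  g <- gen_genome(cfg)
  pbc <- split(g$peaks, g$peaks$source_set)[c("NEUN", "PU1", "OEG")]
  sn <- gen_snp_catalog(cfg, g, pbc)
  fg <- select_foreground(ld_prune(sn$snps, sn$ld_pairs))
  bins <- match_bins(sn$snps, maf_bin_width = 0.1, n_dist_bins = 5L)
  e <- matched_permutation_enrichment(fg, sn$snps, pbc, bins = bins,
                                      n_perm = 2000L, seed = 3L)
  expect_equal(e$annotation[which.max(e$log2_enrichment)], "PU1")
  expect_lt(e$empirical_p[e$annotation == "PU1"], 0.01)
})
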