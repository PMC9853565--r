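# Normalisation and the NB Wald engine.

test_that("size factors follow median-of-ratios with unit geometric mean", {
  k <- matrix(rep(c(10L, 20L, 40L), 3), nrow = 3)
  expect_equal(unname(size_factors(k)), rep(1, 3)) # identical columns
  k2 <- cbind(a = c(10L, 20L, 40L), b = c(20L, 40L, 80L))
  expect_equal(unname(size_factors(k2)), c(1 / sqrt(2), sqrt(2)))
  zeros <- matrix(c(0L, 5L, 3L, 0L), nrow = 2)
  expect_error(size_factors(zeros), "pseudo_ref")
  expect_silent(size_factors(zeros, pseudo_ref = TRUE))
})

test_that("size factors cross-check against DESeq2 on a random matrix", {
  skip_if_not_installed("DESeq2")
  set.seed(21)
  k <- matrix(rnbinom(200 * 6, mu = 60, size = 10), nrow = 200,
              dimnames = list(paste0("p", 1:200), paste0("s", 1:6)))
  ours <- size_factors(k)
  ref <- DESeq2::estimateSizeFactorsForMatrix(k)
  ref <- ref / exp(mean(log(ref))) # DESeq2 does not rescale to unit geomean
  # DESeq2 takes the median in log space; with an even peak count the two
  # interpolate the middle pair differently, so agreement is close, not exact
  expect_equal(unname(ours), unname(ref), tolerance = 1e-5)
})

test_that("stabilize is log2(K/s + 1), monotone, with the doubling property", {
  k <- matrix(c(0L, 1L, 1024L, 2048L), nrow = 4, dimnames = list(NULL, "s"))
  v <- stabilize(k, factors = c(s = 1))
  expect_equal(v[1:2], c(0, 1))
  expect_lt(abs((v[4] - v[3]) - 1), 0.01) # doubling at large K shifts by ~1
})

test_that("null 2-group fit is calibrated and planted effects are recovered", {
  cfg <- calib_config(1)
  g <- gen_genome(cfg)
  co <- gen_cohort_counts(cfg, g)
  res <- nb_wald_fit(co$counts[seq_len(2000), ], co$meta,
                     design = ~abeta_status, contrast = "abeta_statusHIGH")
  rate <- mean(res$pval < 0.05, na.rm = TRUE)
  ci <- 2.58 * sqrt(0.05 * 0.95 / sum(!is.na(res$pval)))
  expect_gt(rate, 0.05 - ci)
  expect_lt(rate, 0.05 + ci)
  expect_true(all(sign(res$log2fc) == sign(res$stat), na.rm = TRUE))

  cfg2 <- calib_config(2, dar_sets = list(
    planted = list(cell_type = "OEG", region = "HIPP", sex = NULL,
                   direction = +1, effect = 1.0, n_peaks = 100L)))
  g2 <- gen_genome(cfg2)
  co2 <- gen_cohort_counts(cfg2, g2)
  res2 <- nb_wald_fit(co2$counts, co2$meta, design = ~abeta_status,
                      contrast = "abeta_statusHIGH")
  est <- res2$log2fc[match(co2$truth$peak_id, res2$peak_id)]
  expect_lt(abs(mean(est) - 1), 0.15)
})

test_that("rescaling one sample with its size factor is absorbed by the offset", {
  cfg <- calib_config(3)
  g <- gen_genome(cfg)
  co <- gen_cohort_counts(cfg, g)
  k <- co$counts[1:300, ]
  s <- size_factors(k)
  k2 <- k
  k2[, 1] <- k2[, 1] * 2L
  s2 <- s
  s2[1] <- s2[1] * 2
  # the normalisation layer is exactly invariant
  expect_equal(stabilize(k, s), stabilize(k2, s2), tolerance = 1e-12)
  expect_equal(acetylseq:::mom_dispersion(k, s), acetylseq:::mom_dispersion(k2, s2),
               tolerance = 1e-12)
  # the NB likelihood is not scale-free (IRLS weights mu/(1 + alpha*mu)
  # depend on the absolute count scale), so fitted log2fc moves slightly:
  # doubling one of 16 samples perturbs estimates by well under 0.1 log2 units
  res1 <- nb_wald_fit(k, co$meta, design = ~abeta_status,
                      contrast = "abeta_statusHIGH", factors = s)
  res2 <- nb_wald_fit(k2, co$meta, design = ~abeta_status,
                      contrast = "abeta_statusHIGH", factors = s2)
  d <- abs(res1$log2fc - res2$log2fc)
  expect_lt(max(d, na.rm = TRUE), 0.1)
  expect_lt(mean(d, na.rm = TRUE), 0.02)
})

test_that("with vanishing dispersion the fit reduces to the Poisson closed form", {
  set.seed(9)
  n <- 10L
  grp <- rep(c("NONE", "HIGH"), each = n / 2)
  k <- matrix(rpois(400 * n, lambda = rep(c(1000, 1600), each = n / 2)),
              ncol = n, byrow = TRUE,
              dimnames = list(paste0("p", 1:400), paste0("s", 1:n)))
  meta <- data.frame(abeta_status = grp)
  res <- nb_wald_fit(k, meta, design = ~abeta_status, contrast = "abeta_statusHIGH",
                     factors = setNames(rep(1, n), colnames(k)))
  closed <- log2(rowMeans(k[, grp == "HIGH"]) / rowMeans(k[, grp == "NONE"]))
  expect_equal(res$log2fc, unname(closed), tolerance = 1e-3)
})

test_that("all-zero peaks are excluded from testing with NA q-values", {
  cfg <- calib_config(4)
  g <- gen_genome(cfg)
  co <- gen_cohort_counts(cfg, g)
  k <- co$counts[1:50, ]
  k[1, ] <- 0L
  res <- nb_wald_fit(k, co$meta, design = ~abeta_status, contrast = "abeta_statusHIGH")
  expect_true(is.na(res$qval[1]))
  expect_false(res$converged[1])
})

test_that("cell-type specificity contrast recovers planted peaks symmetrically", {
  cfg <- sim_config(seed = 6, n_peaks = 1200L, n_genes = 300L,
                    peak_width = c(300L, 800L), prox_frac = 0.4,
                    planted_celltype_effect = 2.0, frac_extra_celltype = 0.6,
                    planted_dar_sets = list(), age_effect = NULL)
  g <- gen_genome(cfg)
  co <- gen_cohort_counts(cfg, g)
  sizes <- sapply(c("NEUN", "PU1", "OEG"), function(ct) {
    sp <- celltype_specific_peaks(co$counts, co$meta, ct)
    truth_ct <- co$truth$peak_id[co$truth$contrast == paste0("celltype_", ct)]
    recovered <- mean(truth_ct %in% sp$specific)
    expect_gt(recovered, 0.9)
    fdp <- mean(!(sp$specific %in% truth_ct))
    expect_lte(fdp, 0.1)
    length(sp$specific)
  })
  # symmetric construction: specific-set sizes within 2x of each other
  expect_lt(max(sizes) / min(sizes), 2)
  expect_error(celltype_specific_peaks(co$counts, co$meta[, setdiff(names(co$meta), "cell_type")], "NEUN"))
  m2 <- co$meta
  m2$cell_type <- "NEUN"
  expect_error(celltype_specific_peaks(co$counts, m2, "OEG"), "absent")
})

test_that("call_dars enforces stratum sizes and splits DARs by sign", {
  cfg <- calib_config(8, dar_sets = list(
    dn = list(cell_type = "OEG", region = "HIPP", sex = "F",
              direction = -1, effect = 2.0, n_peaks = 60L)))
  g <- gen_genome(cfg)
  co <- gen_cohort_counts(cfg, g)
  out <- call_dars(co$counts, co$meta, subset = "cell_type == 'OEG' & sex == 'F'")
  truth <- co$truth$peak_id
  # the planted hypoacetylation is recovered with the correct sign
  expect_gt(length(out$hypo), 0L)
  expect_gt(mean(out$hypo %in% truth), 0.9)
  expect_equal(length(out$hyper), 0L)
  est <- out$results$log2fc[match(truth, out$results$peak_id)]
  expect_lt(mean(est), -1.5) # estimates carry the planted direction and size
  # a stratum without enough samples errors before fitting
  expect_error(call_dars(co$counts, co$meta, subset = "sex == 'M'"), "2 samples")
})

test_that("the age model with covariates recovers a planted microglial trend", {
  cfg <- sim_config(seed = 77, n_peaks = 1500L, n_genes = 300L,
                    peak_width = c(300L, 900L), planted_celltype_effect = 0.5,
                    frac_extra_celltype = 0.3, planted_dar_sets = list(),
                    age_effect = list(cell_type = "PU1", fraction = 0.08, slope = 0.05))
  g <- gen_genome(cfg)
  co <- gen_cohort_counts(cfg, g)
  sel <- co$meta$cell_type == "PU1"
  res <- nb_wald_fit(co$counts[, sel], co$meta[sel, ],
                     design = ~ sex + abeta_status + region + age, contrast = "age")
  truth <- co$truth$peak_id[co$truth$contrast == "age_PU1"]
  est <- res$log2fc[match(truth, res$peak_id)]
  expect_lt(abs(mean(est, na.rm = TRUE) - 0.05), 0.01) # log2 units per year
  # peaks without a planted trend estimate ~0
  null_est <- res$log2fc[!res$peak_id %in% truth]
  expect_lt(abs(mean(null_est, na.rm = TRUE)), 0.005)
})

test_that("effect-size comparison reports correlation and sign concordance", {
  a <- data.frame(peak_id = paste0("p", 1:10), log2fc = seq(-1, 1, length.out = 10))
  expect_equal(compare_effect_sizes(a, a)$pearson_r, 1)
  b <- a
  b$log2fc <- -b$log2fc
  cmp <- compare_effect_sizes(a, b)
  expect_equal(cmp$pearson_r, -1)
  expect_equal(unname(cmp$concordance["concordant"]), 0L)
})

test_that("technical replicates collapse by summation", {
  k <- matrix(1:8, nrow = 2,
              dimnames = list(c("p1", "p2"), c("a1", "a2", "b1", "b2")))
  meta <- data.frame(sample_id = colnames(k),
                     subject_id = c("A", "A", "B", "B"),
                     region = "HIPP", cell_type = "OEG")
  cl <- collapse_replicates(k, meta)
  expect_equal(ncol(cl$counts), 2L)
  expect_equal(unname(colSums(cl$counts)), unname(tapply(colSums(k), meta$subject_id, sum)),
               ignore_attr = TRUE)
})
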