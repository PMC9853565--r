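# Seeded generators for every input the pipeline consumes, with the
# statistical structure the analysis assumes: a gene/peak "genome" with a
# controlled distance-to-TSS distribution, a sorted-cohort count matrix with
# planted cell-type, amyloid-DAR and age effects, an LD-structured SNP catalog
# with optional enrichment planted in one cell type's peaks, and a qPCR Ct
# table with planted fold changes.
#
# All generators are pure functions of the config: one root seed, with child
# streams derived per stage name, so adding a stage never perturbs another
# stage's draws.

#' Simulation configuration
#'
#' Defaults mirror the profiled cohort's shape — 26 tissue samples (10 dlPFC,
#' 16 hippocampus; 5 and 10 of them high-amyloid; 6M/4F and 6M/10F) times
#' three sorted populations — at a reduced genome scale (4,000 peaks, 400
#' genes on two chromosomes) chosen to keep full-pipeline runs fast while
#' leaving every stratum the analysis touches non-degenerate. Override any
#' field by name.
#'
#' @param seed Integer root seed.
#' @param ... Named overrides of the defaults (see the returned list).
#' @return A list of class "sim_config".
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_genes = 800L,
    n_peaks = 4000L,
    genome = data.frame(chrom = c("chr1", "chr2"),
                        length = c(60e6, 40e6), stringsAsFactors = FALSE),
    # cluster -> cognate sorted population (scaled-down stand-in for the 15
    # snRNA-seq clusters)
    marker_clusters = c(neuron_ex1 = "NEUN", neuron_ex2 = "NEUN",
                        microglia = "PU1", microglia_act = "PU1",
                        oligo_1 = "OEG", oligo_2 = "OEG"),
    genes_per_cluster = 15L,
    prox_frac = 0.6, # fraction of peaks within 5 kb of a TSS
    peak_width = c(1000L, 5000L),
    cohort = NULL, # data.frame(subject_id, region, sex, abeta_status); NULL = default 26
    cell_types = c("NEUN", "PU1", "OEG"),
    planted_celltype_effect = 1.0, # log2 units
    frac_extra_celltype = 0.95, # non-marker peaks given a random cell-type label
    planted_dar_sets = list(
      hipp_oeg_female_hypo = list(cell_type = "OEG", region = "HIPP", sex = "F",
                                  direction = -1, effect = 0.8, n_peaks = 150L),
      dlpfc_oeg_hyper = list(cell_type = "OEG", region = "DLPFC", sex = NULL,
                             direction = +1, effect = 0.8, n_peaks = 100L)
    ),
    age_effect = list(cell_type = "PU1", fraction = 0.05, slope = 0.03), # log2/yr
    dispersion = 0.1,
    baseline_mean = 50,
    baseline_spread = 1.0, # per-peak log2 sd of baseline abundance
    snp = list(n_snps = 8000L, n_ld_blocks = 800L, maf_range = c(0.01, 0.5),
               fraction_causal_in_peaks = 0.2, signal_strength = 5,
               n_signal = 400L, coding_fraction = 0.05,
               designated_celltype = "PU1"),
    qpcr = list(
      planted_fold = c(ADAMTS4 = 0.5, PICALM = 0.5, STMN4 = 0.5, MYRF = 0.5,
                       BIN1 = 1.0, APP = 1.0),
      housekeeping = c("RPL13", "CYC1", "GAPDH"),
      noise_sd = 0.2, n_high = 12L, n_ref = 12L)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$n_genes > 0, cfg$n_peaks > 0, cfg$dispersion > 0,
            all(is.finite(c(cfg$planted_celltype_effect, cfg$baseline_mean))))
  class(cfg) <- "sim_config"
  cfg
}

# Default cohort: tissue samples with the profiled composition.
default_cohort <- function() {
  mk <- function(region, sex, status, n, from) {
    data.frame(subject_id = sprintf("S%02d", from + seq_len(n) - 1L),
               region = region, sex = sex, abeta_status = status,
               stringsAsFactors = FALSE)
  }
  rbind(
    mk("DLPFC", "M", "HIGH", 3L, 1L), mk("DLPFC", "F", "HIGH", 2L, 4L),
    mk("DLPFC", "M", "NONE", 3L, 6L), mk("DLPFC", "F", "NONE", 2L, 9L),
    mk("HIPP", "M", "HIGH", 5L, 11L), mk("HIPP", "F", "HIGH", 5L, 16L),
    mk("HIPP", "M", "NONE", 1L, 21L), mk("HIPP", "F", "NONE", 5L, 22L)
  )
}

#' Generate the simulated gene/peak genome and marker sets
#'
#' Genes are placed uniformly; peaks are placed with a controlled
#' distance-to-TSS distribution (`prox_frac` within 5 kb of a TSS, the rest up
#' to 500 kb away) and must not overlap. Each marker cluster gets
#' `genes_per_cluster` disjoint genes; peaks proximal to a cluster's genes are
#' labelled with the cluster's cognate cell type in `source_set` (a further
#' `frac_extra_celltype` of peaks get a random cell-type label, the rest are
#' "shared"). Deterministic given the config seed.
#'
#' @param cfg A `sim_config`.
#' @return List with `genes`, `peaks`, `marker_sets` (cluster -> gene ids)
#'   and `annotations` (the `annotate_peaks` table used for labelling).
#' @export
gen_genome <- function(cfg) {
  n_clusters <- length(cfg$marker_clusters)
  if (cfg$n_peaks < 10L * n_clusters) {
    stop("need at least 10 peaks per marker cluster")
  }
  if (cfg$n_genes < n_clusters * cfg$genes_per_cluster) {
    stop("not enough genes for the marker clusters")
  }
  with_stage_seed(cfg$seed, "genome", {
    glen <- cfg$genome$length
    gchr <- cfg$genome$chrom
    # genes
    chrom <- sample(gchr, cfg$n_genes, replace = TRUE, prob = glen / sum(glen))
    tss <- vapply(chrom, function(ch) {
      L <- glen[match(ch, gchr)]
      as.integer(round(stats::runif(1, 1e6, L - 1e6)))
    }, integer(1L))
    strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
    txlen <- as.integer(round(stats::runif(cfg$n_genes, 5e3, 1e5)))
    tx_start <- ifelse(strand == "+", tss, tss - txlen)
    tx_end <- ifelse(strand == "+", tss + txlen, tss)
    genes <- data.frame(gene_id = sprintf("gene_%04d", seq_len(cfg$n_genes)),
                        chrom = chrom, strand = strand, tss = tss,
                        tx_start = as.integer(tx_start), tx_end = as.integer(tx_end),
                        stringsAsFactors = FALSE)
    genes <- cbind(genes, make_exons(genes))
    # marker clusters: disjoint gene sets
    pool <- sample(genes$gene_id)
    marker_sets <- list()
    for (i in seq_len(n_clusters)) {
      marker_sets[[names(cfg$marker_clusters)[i]]] <-
        sort(pool[(i - 1L) * cfg$genes_per_cluster + seq_len(cfg$genes_per_cluster)])
    }
    # peaks: proximal vs distal placement around random TSSs
    n <- cfg$n_peaks
    host <- sample.int(cfg$n_genes, n, replace = TRUE)
    prox <- stats::runif(n) < cfg$prox_frac
    off <- integer(n)
    off[prox] <- pmax(pmin(as.integer(round(stats::rnorm(sum(prox), 0, 2000))), 4800L), -4800L)
    off[!prox] <- as.integer(round(stats::runif(sum(!prox), 6e3, 5e5))) *
      sample(c(-1L, 1L), sum(!prox), replace = TRUE)
    width <- as.integer(round(stats::runif(n, cfg$peak_width[1L], cfg$peak_width[2L])))
    mid <- genes$tss[host] + off
    start <- pmax(mid - width %/% 2L, 0L)
    end <- start + width
    pchrom <- genes$chrom[host]
    Lp <- glen[match(pchrom, gchr)]
    keep0 <- end <= Lp & start >= 0L
    peaks <- data.frame(chrom = pchrom, start = as.integer(start),
                        end = as.integer(end), stringsAsFactors = FALSE)[keep0, ]
    # overlapping candidates coalesce into one peak (promoter zones are
    # broadly acetylated), keeping the set non-overlapping by construction
    peaks <- merge_with_gap(peaks, max_gap = 0L)
    if (nrow(peaks) < 0.5 * n) {
      stop("genome too small to place peaks without overlap")
    }
    peaks$name <- sprintf("peak_%06d", seq_len(nrow(peaks)))
    peaks$score <- NA_real_
    annot <- annotate_peaks(peaks, genes)
    # label peaks by planted cell-type specificity
    cluster_of_gene <- stats::setNames(
      rep(names(marker_sets), lengths(marker_sets)), unlist(marker_sets))
    src <- rep("shared", nrow(peaks))
    cl <- cluster_of_gene[annot$nearest_gene]
    # every peak annotated to a marker gene (promoter or distal regulatory
    # element) carries the cognate population's signal
    marker_peak <- !is.na(cl)
    src[marker_peak] <- cfg$marker_clusters[cl[marker_peak]]
    extra <- !marker_peak & stats::runif(nrow(peaks)) < cfg$frac_extra_celltype
    src[extra] <- sample(c("NEUN", "PU1", "OEG"), sum(extra), replace = TRUE)
    peaks$source_set <- src
    rownames(peaks) <- NULL
    list(genes = genes, peaks = peaks, marker_sets = marker_sets,
         annotations = annot)
  })
}

# Simple 1-4 exon structure inside each transcript.
make_exons <- function(genes) {
  n <- nrow(genes)
  starts <- character(n)
  ends <- character(n)
  for (i in seq_len(n)) {
    k <- sample.int(4L, 1L)
    cuts <- sort(as.integer(round(stats::runif(2L * k - 2L, genes$tx_start[i] + 1L,
                                               genes$tx_end[i] - 1L))))
    bounds <- unique(c(genes$tx_start[i], cuts, genes$tx_end[i]))
    if (length(bounds) %% 2L == 1L) bounds <- bounds[-length(bounds) + 0L]
    ex_s <- bounds[seq(1L, length(bounds) - 1L, by = 2L)]
    ex_e <- bounds[seq(2L, length(bounds), by = 2L)]
    starts[i] <- paste(ex_s, collapse = ",")
    ends[i] <- paste(ex_e, collapse = ",")
  }
  data.frame(exon_starts = starts, exon_ends = ends, stringsAsFactors = FALSE)
}

#' Generate the cohort count matrix with planted effects
#'
#' Counts are NB-distributed:
#' `K_ij ~ NB(mean = baseline_i * 2^(planted effects) * s_j, dispersion)`.
#' Planted structure: peaks labelled with a cell type in `source_set` are
#' up-shifted by `planted_celltype_effect` in that population's samples
#' (marker-cluster proximal peaks thereby carry their cognate population's
#' signal); each planted DAR set shifts `n_peaks` shared peaks only in its
#' (cell type, region, optional sex) stratum's high-amyloid samples; the age
#' effect adds `slope * (age - mean age)` to a random fraction of peaks in one
#' cell type. Size factors are drawn log-uniform in [0.5, 2]. The returned
#' truth table lists every planted (peak, contrast, log2fc).
#'
#' @param cfg A `sim_config`.
#' @param genome Output of `gen_genome(cfg)`.
#' @return List with `counts` (integer matrix), `meta` (sample metadata),
#'   `truth` (data.frame peak_id, contrast, log2fc) and `size_factors`.
#' @export
gen_cohort_counts <- function(cfg, genome) {
  peaks <- genome$peaks
  G <- nrow(peaks)
  cohort <- cfg$cohort %||% default_cohort()
  with_stage_seed(cfg$seed, "cohort", {
    # per-subject covariates
    subj <- unique(cohort$subject_id)
    age_s <- stats::setNames(pmin(pmax(stats::rnorm(length(subj), 88, 7.75), 75), 102), subj)
    pmi_s <- stats::setNames(pmin(pmax(stats::rnorm(length(subj), 9.5, 5.5), 1), 24), subj)
    educ_s <- stats::setNames(pmin(pmax(stats::rnorm(length(subj), 19, 2.5), 10), 28), subj)
    meta <- do.call(rbind, lapply(cfg$cell_types, function(ct) {
      m <- cohort
      m$cell_type <- ct
      m
    }))
    meta$sample_id <- paste(meta$subject_id, meta$region, meta$cell_type, sep = "_")
    meta$age <- unname(age_s[meta$subject_id])
    meta$pmi <- unname(pmi_s[meta$subject_id])
    meta$educ <- unname(educ_s[meta$subject_id])
    meta$abeta_load <- ifelse(meta$abeta_status == "HIGH",
                              pmin(pmax(stats::rnorm(nrow(meta), 7.3, 4.14), 2.3), 15.4), 0)
    meta$nsc <- stats::runif(nrow(meta), 1.02, 1.15)
    meta$rsc <- stats::runif(nrow(meta), 0.4, 1.5)
    rownames(meta) <- NULL
    n <- nrow(meta)
    s <- 2^stats::runif(n, -1, 1)
    base <- cfg$baseline_mean * 2^stats::rnorm(G, 0, cfg$baseline_spread)
    E <- matrix(0, G, n)
    truth <- list()
    # planted cell-type specificity
    for (ct in c("NEUN", "PU1", "OEG")) {
      rows <- which(peaks$source_set == ct)
      cols <- which(meta$cell_type == ct)
      if (length(rows) && length(cols) && cfg$planted_celltype_effect != 0) {
        E[rows, cols] <- E[rows, cols] + cfg$planted_celltype_effect
        truth[[length(truth) + 1L]] <- data.frame(
          peak_id = peaks$name[rows], contrast = paste0("celltype_", ct),
          log2fc = cfg$planted_celltype_effect, stringsAsFactors = FALSE)
      }
    }
    # planted amyloid DAR sets (drawn from shared peaks plus peaks specific to
    # the set's own cell type, mirroring the promoter-heavy OEG DAR sets)
    used_dar <- integer(0)
    for (nm in names(cfg$planted_dar_sets)) {
      d <- cfg$planted_dar_sets[[nm]]
      avail <- setdiff(which(peaks$source_set %in% c("shared", d$cell_type)), used_dar)
      in_stratum <- meta$cell_type == d$cell_type & meta$region == d$region &
        (is.null(d$sex) | meta$sex == (d$sex %||% ""))
      hi <- which(in_stratum & meta$abeta_status == "HIGH")
      lo <- which(in_stratum & meta$abeta_status == "NONE")
      if (length(hi) < 2L || length(lo) < 2L) {
        stop("planted DAR set '", nm, "' targets a stratum with < 2 samples per amyloid group")
      }
      if (length(avail) < d$n_peaks) stop("not enough eligible peaks for DAR set ", nm)
      pick <- sample(avail, d$n_peaks)
      used_dar <- c(used_dar, pick)
      eff <- d$direction * d$effect
      E[pick, hi] <- E[pick, hi] + eff
      truth[[length(truth) + 1L]] <- data.frame(
        peak_id = peaks$name[pick], contrast = nm, log2fc = eff,
        stringsAsFactors = FALSE)
    }
    # planted age trend
    ae <- cfg$age_effect
    if (!is.null(ae) && ae$fraction > 0 && ae$slope != 0) {
      rows <- sample(G, max(1L, round(ae$fraction * G)))
      cols <- which(meta$cell_type == ae$cell_type)
      if (length(cols)) {
        centered <- meta$age[cols] - mean(meta$age)
        E[rows, cols] <- E[rows, cols] + outer(rep(ae$slope, length(rows)), centered)
        truth[[length(truth) + 1L]] <- data.frame(
          peak_id = peaks$name[rows], contrast = paste0("age_", ae$cell_type),
          log2fc = ae$slope, stringsAsFactors = FALSE)
      }
    }
    mu <- (base * 2^E) %*% diag(s)
    counts <- matrix(stats::rnbinom(G * n, mu = mu, size = 1 / cfg$dispersion), G, n)
    storage.mode(counts) <- "integer"
    rownames(counts) <- peaks$name
    colnames(counts) <- meta$sample_id
    list(counts = counts, meta = meta,
         truth = do.call(rbind, truth) %||% data.frame(),
         size_factors = stats::setNames(s, meta$sample_id))
  })
}

#' Generate an LD-structured SNP catalog (and pairwise r-squared table)
#'
#' SNPs are grouped into LD blocks (`ld_partner_count` = block size - 1, with
#' consistent within-block pairwise r-squared values above 0.5 in `ld_pairs`),
#' MAF is uniform over `maf_range`, and p-values are uniform except for
#' `n_signal` low-p SNPs (`p = 10^-U(3, 3 + signal_strength)`). A configurable
#' fraction of the low-p SNPs is placed inside the designated cell type's
#' specific peaks; the rest sit at their block positions. A small fraction of
#' non-signal SNPs is flagged coding.
#'
#' @param cfg A `sim_config` (see `cfg$snp`).
#' @param genome Output of `gen_genome(cfg)`.
#' @param peaks_by_celltype Named list of peak data.frames; the designated
#'   cell type's entry receives the planted signal. Defaults to splitting the
#'   genome's peaks by `source_set` label.
#' @return List with `snps` (SNP records sorted by chrom, pos) and `ld_pairs`
#'   (rsid_a, rsid_b, r2).
#' @export
gen_snp_catalog <- function(cfg, genome, peaks_by_celltype = NULL) {
  sc <- cfg$snp
  if (is.null(peaks_by_celltype)) {
    peaks_by_celltype <- split(genome$peaks, genome$peaks$source_set)
    peaks_by_celltype <- peaks_by_celltype[intersect(names(peaks_by_celltype),
                                                     c("NEUN", "PU1", "OEG"))]
  }
  with_stage_seed(cfg$seed, "snps", {
    n <- sc$n_snps
    glen <- cfg$genome$length
    gchr <- cfg$genome$chrom
    # bounded block sizes (mean n/n_ld_blocks, jitter +-3, floor 4) so every
    # SNP has LD partners and no matching bin is left empty or near-empty
    nb <- sc$n_ld_blocks
    base <- n %/% nb
    if (base < 8L) stop("n_snps must be at least 8 * n_ld_blocks")
    sizes <- base + sample(rep(-3:3, length.out = nb))
    d <- n - sum(sizes)
    if (d != 0L) sizes <- sizes + sign(d) * tabulate(sample.int(nb, abs(d), replace = TRUE), nb)
    sizes <- pmax(sizes, 4L)
    sizes[1L] <- sizes[1L] + (n - sum(sizes))
    block <- rep(seq_len(nb), times = sizes)
    bchr <- sample(gchr, sc$n_ld_blocks, replace = TRUE, prob = glen / sum(glen))
    bcen <- vapply(bchr, function(ch) {
      stats::runif(1, 1e5, glen[match(ch, gchr)] - 1e5)
    }, numeric(1L))
    chrom <- bchr[block]
    pos <- as.integer(round(bcen[block] + stats::rnorm(n, 0, 2e4)))
    pos <- pmax(pos, 1L)
    pos <- pmin(pos, as.integer(glen[match(chrom, gchr)]))
    maf <- stats::runif(n, sc$maf_range[1L], sc$maf_range[2L])
    pval <- stats::runif(n)
    is_coding <- stats::runif(n) < sc$coding_fraction
    # planted signal
    sig <- sample.int(n, sc$n_signal)
    pval[sig] <- 10^(-stats::runif(sc$n_signal, 3, 3 + sc$signal_strength))
    is_coding[sig] <- FALSE
    n_causal <- round(sc$fraction_causal_in_peaks * sc$n_signal)
    if (n_causal > 0L) {
      target <- peaks_by_celltype[[sc$designated_celltype]]
      if (is.null(target) || !nrow(target)) stop("designated cell type has no peaks")
      causal <- sig[seq_len(n_causal)]
      pk <- target[sample.int(nrow(target), n_causal, replace = TRUE), , drop = FALSE]
      chrom[causal] <- pk$chrom
      pos[causal] <- pk$start + 1L +
        as.integer(floor(stats::runif(n_causal) * (pk$end - pk$start)))
    }
    # distance to nearest TSS
    dist_to_gene <- integer(n)
    for (ch in unique(chrom)) {
      si <- which(chrom == ch)
      tss <- sort(genome$genes$tss[genome$genes$chrom == ch])
      if (!length(tss)) {
        dist_to_gene[si] <- NA_integer_
        next
      }
      i1 <- findInterval(pos[si], tss)
      lo <- ifelse(i1 >= 1L, abs(pos[si] - tss[pmax(i1, 1L)]), .Machine$integer.max)
      hi <- ifelse(i1 < length(tss), abs(tss[pmin(i1 + 1L, length(tss))] - pos[si]),
                   .Machine$integer.max)
      dist_to_gene[si] <- as.integer(pmin(lo, hi))
    }
    snps <- data.frame(rsid = sprintf("rs%06d", seq_len(n)), chrom = chrom,
                       pos = pos, pval = pval, maf = maf, is_coding = is_coding,
                       ld_partner_count = as.integer(tabulate(block, sc$n_ld_blocks)[block] - 1L),
                       dist_to_gene = dist_to_gene, stringsAsFactors = FALSE)
    # within-block pairwise r2 above the pruning threshold
    pairs <- lapply(split(seq_len(n), block), function(ix) {
      if (length(ix) < 2L) return(NULL)
      cmb <- utils::combn(ix, 2L)
      data.frame(rsid_a = snps$rsid[cmb[1L, ]], rsid_b = snps$rsid[cmb[2L, ]],
                 r2 = stats::runif(ncol(cmb), 0.55, 1), stringsAsFactors = FALSE)
    })
    ld_pairs <- do.call(rbind, pairs)
    rownames(ld_pairs) <- NULL
    list(snps = snps[order(snps$chrom, snps$pos), , drop = FALSE],
         ld_pairs = ld_pairs %||% data.frame(rsid_a = character(),
                                             rsid_b = character(), r2 = numeric()))
  })
}

#' Generate a qPCR Ct table with planted fold changes
#'
#' `Ct = baseline_gene - log2(relative expression) + N(0, noise_sd)`; target
#' genes carry a planted HIGH/REF expression fold, housekeeping genes carry
#' none. Amyloid loads place `n_ref` samples in the reference group (half
#' low < 1, half mid 1-7.71) and `n_high` above 7.71.
#'
#' @param cfg A `sim_config` (see `cfg$qpcr`).
#' @return List with `ct` (long data.frame sample, gene, ct), `loads` (named
#'   vector) and `truth` (named planted fold-change vector).
#' @export
gen_qpcr <- function(cfg) {
  qc <- cfg$qpcr
  with_stage_seed(cfg$seed, "qpcr", {
    n_ref <- qc$n_ref
    n_high <- qc$n_high
    n_low <- n_ref %/% 2L
    loads <- c(stats::runif(n_low, 0, 0.9),
               stats::runif(n_ref - n_low, 1, 7.7),
               stats::runif(n_high, 8, 16))
    samples <- sprintf("q%02d", seq_along(loads))
    names(loads) <- samples
    high <- loads > 7.71
    genes <- c(names(qc$planted_fold), qc$housekeeping)
    baseline <- stats::setNames(stats::runif(length(genes), 18, 28), genes)
    rows <- list()
    for (g in genes) {
      fold <- if (g %in% names(qc$planted_fold)) qc$planted_fold[[g]] else 1
      expr <- ifelse(high, fold, 1)
      ct <- baseline[[g]] - log2(expr) + stats::rnorm(length(loads), 0, qc$noise_sd)
      rows[[g]] <- data.frame(sample = samples, gene = g, ct = ct,
                              stringsAsFactors = FALSE)
    }
    list(ct = do.call(rbind, rows), loads = loads, truth = qc$planted_fold)
  })
}

#' Write every simulated input to a directory as plain-text files
#'
#' Produces peaks.bed, genes.tsv, counts.tsv, meta.tsv, snps.tsv,
#' ld_pairs.tsv, qpcr.tsv, qpcr_loads.tsv and truth.tsv.
#'
#' @param cfg A `sim_config`.
#' @param outdir Output directory (created if needed).
#' @return The output directory, invisibly.
#' @export
write_sim <- function(cfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  genome <- gen_genome(cfg)
  cohort <- gen_cohort_counts(cfg, genome)
  snps <- gen_snp_catalog(cfg, genome)
  qpcr <- gen_qpcr(cfg)
  write_peaks(genome$peaks, file.path(outdir, "peaks.bed"))
  write_gene_models(genome$genes, file.path(outdir, "genes.tsv"))
  write_counts(cohort$counts, cohort$meta, file.path(outdir, "counts.tsv"),
               file.path(outdir, "meta.tsv"))
  write_gwas(snps$snps, file.path(outdir, "snps.tsv"))
  utils::write.table(snps$ld_pairs, file.path(outdir, "ld_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(qpcr$ct, file.path(outdir, "qpcr.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = names(qpcr$loads), abeta_load = qpcr$loads),
                     file.path(outdir, "qpcr_loads.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, file.path(outdir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  marker_df <- data.frame(
    cluster = rep(names(genome$marker_sets), lengths(genome$marker_sets)),
    gene_id = unlist(genome$marker_sets), stringsAsFactors = FALSE)
  utils::write.table(marker_df, file.path(outdir, "markers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}
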