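---
title: "Cell type-specific H3K27ac analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell type-specific H3K27ac analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acetylseq)
```

# Scope

`acetylseq` implements the downstream statistical pipeline for cell
type-resolved H3K27ac ChIP-seq of sorted brain nuclei — NeuN+ neurons, Pu.1+
microglia, and the NeuN-/Pu.1- oligodendrocyte-enriched glial population
(OEG) — profiled in two brain regions (dlPFC, hippocampus) across subjects
with and without amyloid-beta pathology. It starts from called peak sets and
read-count matrices: alignment, peak calling and ENCODE QC metrics (NSC, RSC,
FRiP) are upstream concerns, consumed here only as inputs and sample
covariates. Because the cohort data underlying analyses of this design are
typically restricted-access, the package ships seeded generators that emulate
the cohort's statistical structure, and every stage is tested against them.

# Interval conventions

All peak coordinates are held internally as 0-based half-open intervals (the
BED convention); GWAS positions and sentinel-table outputs are 1-based, with
conversion confined to the I/O boundary (`pos_to_0based`, `pos_to_1based`).

**Consensus merging.** Reproducible peak sets from the 12 (region x amyloid x
cell type) subsets are concatenated and merged, bridging gaps *strictly*
smaller than 200 bp — this absorbs local dips in acetylation signal over
broad regulatory elements. The strict reading means a gap of exactly 200 bp
does not merge; note that `bedtools merge -d` is inclusive, so the two
disagree at exactly the threshold. The merge is idempotent and
order-invariant, and the test suite checks it against an independent
coverage-vector oracle on a thousand random instances.

**Nearest-gene annotation.** Distance is measured from the peak midpoint to
the TSS and signed in gene orientation (negative upstream). Ties between
equidistant TSSs break deterministically to the lexicographically lower gene
id. Feature classes follow the precedence promoter-TSS (within 1 kb of the
TSS) > exon > intron > TTS (within 1 kb of the transcript end) > intergenic.
Gene models here carry no CDS boundaries, so 5'/3' UTR classes — which some
annotators report — cannot be assigned from these inputs and are omitted.
"Promoter-proximal" means |distance| < 5 kb throughout (configurable via
`tss_window`).

**SNP-to-peak distance.** The sentinel-table convention operates directly on
printed 1-based values: 0 inside the peak, `start - pos` (positive) before
it, `end - pos` (negative) past it. The bundled sentinel table
(`sentinel_snp_table()`) reproduces under this convention every printed row
except four that are internally inconsistent in the source (both BIN1 rows,
NYAP1, and ALPK2 — most plausibly typos in the printed peak bounds); those
are flagged `anomalous`, not silently corrected.

# The differential model

Counts at peak *i* in sample *j* are modelled as negative binomial with mean
$\mu_{ij} = s_j \exp(x_j^\top \beta_i)$ and dispersion $\alpha_i$, where
$s_j$ are median-of-ratios size factors rescaled to unit geometric mean.
The engine is intentionally simple and fully specified:

* **Dispersion** is estimated per peak by method of moments on normalised
  counts, $\hat\alpha_i = \max((v_i - m_i)/m_i^2,\ 10^{-8})$, with no
  empirical-Bayes shrinkage and no use of the design. The design-blindness
  matters: for peaks with a genuine group difference the between-group
  variance inflates $\hat\alpha_i$, so significance calls on strongly
  differential peaks are conservative, while log2 fold-change *estimates*
  are unaffected (the suite verifies |bias| <= 0.15 at a planted log2fc of
  1.0 with n = 8 vs 8). This is the main behavioural difference from
  shrinkage-based engines and the reason small strata (e.g. 5 vs 3) yield
  few significant calls at moderate effect sizes here.
* **Fitting** is IRLS with a log link and offset $\log s_j$, vectorised
  across peaks (shared design matrix, per-peak 2x2/3x3 normal equations).
  Linear predictors are clamped to [-30, 30]; peaks that do not converge
  within 50 iterations (e.g. complete separation of an all-zero group) are
  flagged, receive `pval = NA`, and are excluded from the BH denominator.
* **Inference** is a Wald test, $z_i = \hat\beta_{i,\text{contrast}} /
  \mathrm{SE}$, against the standard normal. A t reference with residual
  degrees of freedom was considered and rejected: under the generator's null
  (n = 8 vs 8, dispersion 0.1, 2,000 peaks) it is measurably conservative,
  while the standard normal keeps the per-test rate inside the binomial band
  the test suite checks — so the normal is used, as in the field's standard
  engines.
* **Multiplicity**: BH within each named contrast across the peaks passing
  an independent filter (mean normalised count >= 1 by default). A global
  correction across all contrasts can be emulated by pooling p-values
  before adjustment.
* **Sign conventions**: reference levels are no-amyloid, dlPFC, male, and
  "rest" (for focal-vs-rest cell-type contrasts), so positive log2fc always
  means higher acetylation in the named condition (high amyloid, the focal
  cell type, etc.).

Technical replicates are collapsed by summation per (subject, region, cell
type) before modelling. The RSC quality covariate can be added to any design
(`~ abeta_status + rsc`) for the post-hoc comparisons, and
`compare_effect_sizes` reports the Pearson correlation and sign concordance
between two fits over shared peaks.

# Sorting validation

For each (marker cluster, sorted population) pair, the population's
focal-vs-rest log2fc values at peaks annotated to the cluster's marker genes
are tested against a null mean of 0.5 (~1.4-fold) with a one-sided one-sample
t-test; sample standard deviation (n-1) is used, and BH correction spans all
pairs in the run. A degenerate sample with zero spread at exactly the
threshold returns t = 0, p = 0.5. The proximal-only variant (|distance| <
5 kb) is a separate run with its own BH family. Per-tissue-sample matrices
divide the focal population's stabilised count (`log2(K/s + 1)`) by the mean
of the two non-focal populations from the same tissue sample, log2-transform,
and average over each cluster's peaks; z-scoring is per cluster column with
sample sd (the axis is not dictated by the procedure itself, so it is fixed
here and documented), and a grouped variant averages rows within (amyloid,
sex, region) cells first.

# SNP colocalization by matched permutation

The foreground is built by LD pruning (greedy, ascending p-value, r^2 > 0.5
blocks), removing coding SNPs, and keeping p < 1e-3 (strict). Whether pruning
precedes or follows selection is ambiguous in the field's descriptions;
prune-then-select is the default and the other order is a one-line change at
the call site. The null preserves each SNP's minor allele frequency, distance
to gene, and LD-partner count by binned matching (fixed-width MAF bins,
quantile bins over log10(1 + distance), integer LD-count bins) — exact
matching on continuous properties is impossible, so the binning is explicit
and configurable. Each permutation redraws every foreground SNP uniformly
from its bin (excluding itself); the statistic is the number of foreground
SNPs inside the annotation, `log2_enrichment = log2((obs + 0.5)/(null_mean +
0.5))`, and the empirical p uses the +1 correction, so it is never zero and
is conservative at discrete atoms.

That discreteness shapes the calibration checks: with an annotation covering
only a few percent of SNP space the statistic's atoms are large and the
+1-corrected p is visibly super-uniform no matter how well matched the null
is. The uniformity check therefore runs against the union of the three
cell-type-specific sets (the natural "merged background" annotation, ~9% of
the simulated genome, expected overlap ~28), where the suite verifies KS
uniformity and a type-I rate inside the binomial band over 200 simulated
catalogs at 2,000 permutations each. The power check uses the three
per-cell-type sets: with
half the signal SNPs planted into microglial peaks, the microglial set ranks
first with empirical p at the permutation floor.

# Matched backgrounds for motif scans

Promoter-heavy DAR sets would make any motif scan return promoter motifs;
backgrounds are therefore sampled to match the foreground's distance-to-TSS
distribution within 100 bp per peak, on the *signed* distance by default
(preserving upstream/downstream structure; `match_abs` collapses it).
Sampling is greedy in foreground order without replacement within a set, and
a blocked state raises an error listing the unmatched peaks rather than
silently relaxing the tolerance (`widen = TRUE` doubles it exactly once,
recorded per pair). Ten sets with consecutive seeds give the replicate
backgrounds a motif tool needs.

# qPCR quantification

The housekeeping reference per sample is the geometric mean of the
housekeeping genes' Ct values — implemented literally as stated in the
protocols this emulates, although the arithmetic mean is the more common
convention; `hk_mean = "arithmetic"` exposes the alternative, and for
housekeeping genes within ~1 cycle of each other the difference is
negligible. Amyloid-load cutoffs 1 and 7.71 (percent area) define
low/mid/high; the reference group combines low and mid. Per gene the pipeline
reports ddCt, fold change `2^-ddCt`, a Welch t-test on dCt (the underlying
reports give q-values without naming the test; Welch is the robust default),
Hedges' g with the small-sample correction (computed HIGH minus REF on the
dCt scale, so positive g means reduced expression at high load), and BH
across the genes tested.

# The synthetic cohort

The generators are pure functions of one root seed; each stage derives its
own stream from the seed and a stage name, so adding a stage never perturbs
another's draws. Defaults were chosen once to mirror the emulated study's
relative scales:

* **Cohort**: 26 tissue samples (10 dlPFC: 5 high-amyloid, 6M/4F; 16
  hippocampus: 10 high-amyloid, 6M/10F) x 3 sorted populations = 78 count
  columns; ages ~ N(88, 7.75) truncated to [75, 102]; high-amyloid loads
  ~ N(7.3, 4.1) truncated to [2.3, 15.4]; size factors log-uniform in
  [0.5, 2].
* **Genome**: 800 genes on 100 Mb (one per 125 kb, the genome-wide density),
  ~4,000 placed peaks of 1-5 kb with 60% within 5 kb of a TSS; overlapping
  placements coalesce, leaving ~2,250 non-overlapping peaks covering ~9% of
  the genome (the real consensus covers 17.7%). About 95% of peaks carry a
  cell-type label — the study's three specific sets jointly exceed its
  consensus count — so each specific set covers ~3% of the genome (study:
  ~5-8%).
* **Effects**: cell-type specificity +1.0 log2 units in the cognate
  population; two planted amyloid DAR sets (hippocampus-female OEG down,
  dlPFC OEG up, 0.8 log2 units — the middle of the reported 0.4-1.2 range,
  which is a calibration choice, not ground truth); a microglial age trend
  of 0.03 log2/yr on 5% of peaks; NB dispersion 0.1; baseline mean 50 with
  1.0 log2 sd of per-peak abundance spread.
* **SNP catalog**: 8,000 SNPs in 800 LD blocks of bounded size (4 to ~17, so
  every matching bin is populated and every SNP has partners), MAF uniform
  on [0.01, 0.5], 400 planted low-p signal SNPs, 5% coding; pairwise r^2 for
  within-block pairs uniform on (0.55, 1]; a configurable fraction of signal
  SNPs is relocated into the designated cell type's peaks.
* **qPCR**: 12 high vs 12 reference samples, planted folds 0.5 for four
  target genes and 1.0 for two, Ct noise sd 0.2 cycles, housekeeping RPL13 /
  CYC1 / GAPDH.

What the generator does **not** emulate: read-level noise and mappability,
GC and width confounds, LD beyond block membership, subject-level random
effects shared across cell types, and cell-type composition impurity in the
sorted fractions. Tests passing on this cohort show the statistics are
implemented correctly and calibrated under the stated model — not that the
model captures every failure mode of real sorted-nuclei ChIP-seq.

Simulation sizes used by the test suite (2,000 peaks and n = 8 vs 8 for
calibration with 50 seeds; 200 catalogs at 2,000 permutations for the
permutation null; the 26-sample cohort for the specificity structure) were
fixed alongside these defaults.

# Known limitations

* No empirical-Bayes dispersion or LFC shrinkage: small strata are honest
  but low-powered; counts of significant DARs will undershoot
  shrinkage-based engines at the same FDR.
* The permutation p is conservative at its discrete atoms by construction.
* Nearest-gene annotation is midpoint-based and single-assignment; no
  many-to-many enhancer-gene mapping.
* `ld_prune` needs pairwise r^2 as input; `ld_partner_count` matching in the
  permutation test is a per-SNP integer and does not reconstruct LD
  structure.
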