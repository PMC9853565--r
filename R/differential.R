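# Count normalisation and negative-binomial Wald contrasts.
#
# This is a deliberately simple NB GLM engine: median-of-ratios size factors,
# per-peak method-of-moments dispersion (no empirical-Bayes shrinkage), IRLS
# with a log link and log size-factor offset, standard-normal Wald tests, and
# a mean-count independent filter before
# BH correction. Acceptance is judged by parameter recovery and calibration on
# simulated cohorts, not numerical equality with any external package.

#' Median-of-ratios size factors
#'
#' `s_j = median_i( K_ij / geomean_i )` over peaks whose geometric mean across
#' samples is positive, rescaled to unit geometric mean.
#'
#' @param counts Integer matrix (peaks x samples).
#' @param pseudo_ref If no peak has nonzero counts in every sample, setting
#'   this computes each peak's geometric mean over its positive entries only
#'   (pseudo-reference fallback) instead of erroring.
#' @return Named numeric vector of size factors (geometric mean 1).
#' @export
size_factors <- function(counts, pseudo_ref = FALSE) {
  validate_counts(counts)
  all_pos <- rowSums(counts == 0L) == 0L
  if (!any(all_pos)) {
    if (!pseudo_ref) {
      stop("no peak with nonzero counts in all samples; re-run with pseudo_ref = TRUE")
    }
    lg <- apply(counts, 1L, function(x) if (any(x > 0)) mean(log(x[x > 0])) else NA_real_)
    use <- which(!is.na(lg))
  } else {
    lg <- rep(NA_real_, nrow(counts))
    lg[all_pos] <- rowMeans(log(counts[all_pos, , drop = FALSE]))
    use <- which(all_pos)
  }
  ref <- exp(lg[use])
  s <- apply(counts[use, , drop = FALSE], 2L, function(col) {
    stats::median((col / ref)[col > 0 | !pseudo_ref])
  })
  s <- s / geomean(s)
  stats::setNames(s, colnames(counts))
}

#' Variance-stabilising transform of normalised counts
#'
#' `log2(K_ij / s_j + 1)`; monotone in the count for fixed size factor.
#'
#' @param counts Integer matrix (peaks x samples).
#' @param factors Size factors (defaults to `size_factors(counts)`).
#' @return Real matrix of the same dimensions.
#' @export
stabilize <- function(counts, factors = size_factors(counts)) {
  stopifnot(length(factors) == ncol(counts), all(factors > 0))
  log2(sweep(counts, 2L, factors, `/`) + 1)
}

# Per-peak method-of-moments NB dispersion on normalised counts, floored.
mom_dispersion <- function(counts, factors, alpha_min = 1e-8) {
  q <- sweep(counts, 2L, factors, `/`)
  m <- rowMeans(q)
  v <- apply(q, 1L, stats::var)
  a <- ifelse(m > 0, (v - m) / m^2, alpha_min)
  pmax(a, alpha_min)
}

# Vectorised IRLS for per-peak NB GLMs sharing one design matrix.
# Y: peaks x n counts; X: n x p design; off: length-n log size factors;
# alpha: per-peak dispersions. Returns Beta, SE (both peaks x p) and a
# converged flag per peak.
nb_irls <- function(Y, X, off, alpha, max_iter = 50L, tol = 1e-6) {
  G <- nrow(Y)
  n <- ncol(Y)
  p <- ncol(X)
  offm <- matrix(off, G, n, byrow = TRUE)
  # init: ordinary LS on log counts
  Z0 <- log(Y + 0.5) - offm
  Beta <- Z0 %*% X %*% solve(crossprod(X))
  pair_idx <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  Xpairs <- X[, pair_idx[, 1L], drop = FALSE] * X[, pair_idx[, 2L], drop = FALSE]
  conv <- rep(FALSE, G)
  A_rows <- matrix(NA_real_, G, nrow(pair_idx))
  for (it in seq_len(max_iter)) {
    Eta <- Beta %*% t(X) + offm
    Eta <- pmin(pmax(Eta, -30), 30)
    Mu <- exp(Eta)
    W <- Mu / (1 + alpha * Mu)
    Z <- (Eta - offm) + (Y - Mu) / Mu
    A_rows <- W %*% Xpairs # per-peak upper triangle of X'WX
    B_rows <- (W * Z) %*% X # per-peak X'Wz
    idx <- which(!conv)
    A <- matrix(0, p, p)
    for (g in idx) {
      A[cbind(pair_idx[, 1L], pair_idx[, 2L])] <- A_rows[g, ]
      A[cbind(pair_idx[, 2L], pair_idx[, 1L])] <- A_rows[g, ]
      bg <- tryCatch(solve(A, B_rows[g, ]), error = function(e) NULL)
      if (is.null(bg)) next
      if (max(abs(bg - Beta[g, ])) < tol * (1 + max(abs(Beta[g, ])))) conv[g] <- TRUE
      Beta[g, ] <- bg
    }
    if (all(conv)) break
  }
  # standard errors from the final Fisher information
  Eta <- pmin(pmax(Beta %*% t(X) + offm, -30), 30)
  Mu <- exp(Eta)
  W <- Mu / (1 + alpha * Mu)
  A_rows <- W %*% Xpairs
  SE <- matrix(NA_real_, G, p)
  A <- matrix(0, p, p)
  for (g in seq_len(G)) {
    A[cbind(pair_idx[, 1L], pair_idx[, 2L])] <- A_rows[g, ]
    A[cbind(pair_idx[, 2L], pair_idx[, 1L])] <- A_rows[g, ]
    Ainv <- tryCatch(solve(A), error = function(e) NULL)
    if (!is.null(Ainv)) {
      d <- diag(Ainv)
      if (all(d > 0)) SE[g, ] <- sqrt(d) else conv[g] <- FALSE
    } else {
      conv[g] <- FALSE
    }
  }
  list(beta = Beta, se = SE, converged = conv)
}

# Relevel metadata factors so log2fc signs follow the reporting convention:
# high-amyloid vs none, focal cell type vs rest, F vs M, HIPP vs DLPFC.
design_frame <- function(meta) {
  df <- as.data.frame(meta, stringsAsFactors = FALSE)
  relev <- list(abeta_status = "NONE", region = "DLPFC", sex = "M")
  for (nm in names(relev)) {
    if (!is.null(df[[nm]])) {
      f <- factor(df[[nm]])
      if (relev[[nm]] %in% levels(f)) f <- stats::relevel(f, ref = relev[[nm]])
      df[[nm]] <- f
    }
  }
  if (!is.null(df$cell_type)) df$cell_type <- factor(df$cell_type)
  df
}

#' Per-peak negative-binomial Wald contrasts
#'
#' Fits one NB GLM per peak (log link, log size-factor offset, per-peak
#' method-of-moments dispersion) and reports the Wald contrast for one model
#' coefficient: `stat = beta / SE`, two-sided p from the standard normal,
#' `log2fc = beta / ln 2`, and BH q-values across
#' the peaks passing the independent filter (mean normalised count >=
#' `min_mean`). Non-converged peaks are flagged, get `pval = NA`, and are
#' excluded from the BH denominator.
#'
#' @param counts Integer matrix (peaks x samples).
#' @param meta Sample metadata data.frame aligned with the columns of
#'   `counts`.
#' @param design Model formula over metadata columns (e.g.
#'   `~ abeta_status` or `~ sex + abeta_status + region + age`).
#' @param contrast Name of the model-matrix coefficient to test; defaults to
#'   the last coefficient.
#' @param factors Optional pre-computed size factors.
#' @param min_mean Independent-filter floor on the mean normalised count
#'   (default 1).
#' @param alpha_min Dispersion floor (default 1e-8).
#' @param max_iter IRLS iteration cap.
#' @return A data.frame of class "nb_diff" with peak_id, base_mean, log2fc,
#'   se, stat, pval, qval, converged; the tested contrast is kept in
#'   attributes.
#' @export
nb_wald_fit <- function(counts, meta, design = ~abeta_status, contrast = NULL,
                        factors = NULL, min_mean = 1, alpha_min = 1e-8,
                        max_iter = 50L) {
  validate_counts(counts)
  stopifnot(nrow(meta) == ncol(counts))
  df <- design_frame(meta)
  X <- stats::model.matrix(design, df)
  if (qr(X)$rank < ncol(X)) stop("design matrix is not full rank on this subset")
  if (is.null(contrast)) contrast <- colnames(X)[ncol(X)]
  if (!contrast %in% colnames(X)) {
    stop("contrast '", contrast, "' is not a model coefficient; available: ",
         paste(colnames(X), collapse = ", "))
  }
  if (is.null(factors)) factors <- size_factors(counts, pseudo_ref = TRUE)
  alpha <- mom_dispersion(counts, factors, alpha_min = alpha_min)
  base_mean <- rowMeans(sweep(counts, 2L, factors, `/`))
  nonzero <- rowSums(counts) > 0L
  G <- nrow(counts)
  beta <- se <- rep(NA_real_, G)
  conv <- rep(FALSE, G)
  if (any(nonzero)) {
    fit <- nb_irls(counts[nonzero, , drop = FALSE], X, log(factors),
                   alpha[nonzero], max_iter = max_iter)
    ci <- match(contrast, colnames(X))
    beta[nonzero] <- fit$beta[, ci]
    se[nonzero] <- fit$se[, ci]
    conv[nonzero] <- fit$converged
  }
  stat <- beta / se
  pval <- 2 * stats::pnorm(-abs(stat))
  pval[!conv] <- NA_real_
  tested <- conv & base_mean >= min_mean & !is.na(pval)
  qval <- rep(NA_real_, G)
  qval[tested] <- stats::p.adjust(pval[tested], method = "BH")
  out <- data.frame(
    peak_id = rownames(counts) %||% sprintf("peak_%06d", seq_len(G)),
    base_mean = base_mean,
    log2fc = beta / log(2),
    se = se / log(2),
    stat = stat,
    pval = pval,
    qval = qval,
    converged = conv,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "contrast") <- contrast
  attr(out, "design") <- deparse(design)
  attr(out, "n_samples") <- ncol(counts)
  class(out) <- c("nb_diff", "data.frame")
  out
}

#' @export
print.nb_diff <- function(x, ...) {
  cat("Negative-binomial Wald contrast\n")
  cat("  design:  ", attr(x, "design"), "\n", sep = "")
  cat("  contrast:", attr(x, "contrast"), "\n")
  cat("  samples: ", attr(x, "n_samples"), "; peaks: ", nrow(x),
      " (", sum(!is.na(x$qval)), " tested after filtering)\n", sep = "")
  nsig <- sum(x$qval < 0.05, na.rm = TRUE)
  cat("  q < 0.05:", nsig, sprintf("(%d up, %d down)\n",
      sum(x$qval < 0.05 & x$log2fc > 0, na.rm = TRUE),
      sum(x$qval < 0.05 & x$log2fc < 0, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.nb_diff <- function(object, q_max = 0.05, ...) {
  tested <- !is.na(object$qval)
  structure(list(
    contrast = attr(object, "contrast"),
    n_peaks = nrow(object),
    n_tested = sum(tested),
    n_sig = sum(object$qval < q_max, na.rm = TRUE),
    n_hyper = sum(object$qval < q_max & object$log2fc > 0, na.rm = TRUE),
    n_hypo = sum(object$qval < q_max & object$log2fc < 0, na.rm = TRUE),
    q_max = q_max
  ), class = "summary.nb_diff")
}

#' @export
print.summary.nb_diff <- function(x, ...) {
  cat(sprintf("contrast %s: %d/%d peaks tested, %d significant at q < %g (%d hyper / %d hypo)\n",
              x$contrast, x$n_tested, x$n_peaks, x$n_sig, x$q_max, x$n_hyper, x$n_hypo))
  invisible(x)
}

#' Cell-type specificity contrast (focal population vs the other two)
#'
#' Fits the focal-vs-rest two-level contrast over all samples; specific peaks
#' are those with positive log2fc at q < `q_max`. The full signed log2fc
#' vector is used downstream by sentinel annotation and sorting validation.
#'
#' @param counts Integer matrix (peaks x samples).
#' @param meta Metadata with a `cell_type` column (NEUN/PU1/OEG or aliases).
#' @param focal Focal cell type.
#' @param q_max Significance threshold (default 0.05).
#' @param ... Passed to `nb_wald_fit`.
#' @return A list with `results` (nb_diff) and `specific` (character vector of
#'   specific peak ids).
#' @export
celltype_specific_peaks <- function(counts, meta, focal, q_max = 0.05, ...) {
  ct <- canonical_cell_type(meta$cell_type)
  focal <- canonical_cell_type(focal)
  if (!focal %in% ct) stop("focal cell type ", focal, " absent from metadata")
  grp <- factor(ifelse(ct == focal, "focal", "rest"), levels = c("rest", "focal"))
  m <- data.frame(group = grp)
  res <- nb_wald_fit(counts, m, design = ~group, contrast = "groupfocal", ...)
  specific <- res$peak_id[!is.na(res$qval) & res$qval < q_max & res$log2fc > 0]
  list(results = res, specific = specific)
}

#' Call amyloid-associated differentially acetylated regions in a stratum
#'
#' Subsets the cohort (e.g. one region x sex x cell-type stratum), contrasts
#' high-amyloid against no-amyloid samples, and splits significant peaks by
#' sign of log2fc.
#'
#' @param counts Integer matrix (peaks x samples).
#' @param meta Metadata with `abeta_status` (and whatever `subset` needs).
#' @param subset Logical vector over samples, or a character predicate
#'   evaluated in the metadata (e.g. `"cell_type == 'OEG' & sex == 'F'"`).
#' @param design Model formula (default `~ abeta_status`; add covariates such
#'   as `~ abeta_status + rsc` for post-hoc checks).
#' @param contrast Coefficient to test (default the high-vs-none term).
#' @param q_max DAR threshold (default 0.05).
#' @param ... Passed to `nb_wald_fit`.
#' @return A list with `results` (nb_diff), `hyper` and `hypo` peak-id
#'   vectors.
#' @export
call_dars <- function(counts, meta, subset = NULL, design = ~abeta_status,
                      contrast = "abeta_statusHIGH", q_max = 0.05, ...) {
  keep <- if (is.null(subset)) {
    rep(TRUE, nrow(meta))
  } else if (is.character(subset)) {
    with(meta, eval(parse(text = subset)))
  } else {
    as.logical(subset)
  }
  m <- meta[keep, , drop = FALSE]
  k <- counts[, keep, drop = FALSE]
  tab <- table(m$abeta_status)
  if (length(tab) < 2L || any(tab < 2L)) {
    stop("stratum needs >= 2 samples in each amyloid group; got ",
         paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
  }
  res <- nb_wald_fit(k, m, design = design, contrast = contrast, ...)
  sig <- !is.na(res$qval) & res$qval < q_max
  list(results = res,
       hyper = res$peak_id[sig & res$log2fc > 0],
       hypo = res$peak_id[sig & res$log2fc < 0])
}

#' Compare effect sizes between two differential analyses
#'
#' Pearson correlation of log2fc over shared peaks plus sign-concordance
#' counts, as used for cross-region replication and covariate post-hoc
#' comparisons.
#'
#' @param res_a,res_b Differential result data.frames (peak_id, log2fc).
#' @param subset Optional peak ids to restrict to.
#' @return List with pearson_r, pval, n, and a `concordance` table
#'   (concordant / discordant counts).
#' @export
compare_effect_sizes <- function(res_a, res_b, subset = NULL) {
  ids <- intersect(res_a$peak_id, res_b$peak_id)
  if (!is.null(subset)) ids <- intersect(ids, subset)
  a <- res_a$log2fc[match(ids, res_a$peak_id)]
  b <- res_b$log2fc[match(ids, res_b$peak_id)]
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]
  b <- b[ok]
  ct <- stats::cor.test(a, b, method = "pearson")
  conc <- sum(sign(a) == sign(b) & a != 0)
  list(pearson_r = unname(ct$estimate), pval = ct$p.value, n = length(a),
       concordance = c(concordant = conc, discordant = length(a) - conc))
}

#' Collapse technical replicates by summation
#'
#' Sums counts over samples sharing (subject, region, cell type), mirroring
#' replicate collapsing before model fitting.
#'
#' @param counts Integer matrix (peaks x samples).
#' @param meta Metadata with the grouping columns.
#' @param by Grouping columns (default subject_id, region, cell_type).
#' @return List with collapsed `counts` and `meta` (first row per group).
#' @export
collapse_replicates <- function(counts, meta, by = c("subject_id", "region", "cell_type")) {
  key <- do.call(paste, c(meta[by], sep = "|"))
  groups <- split(seq_len(ncol(counts)), key)
  k <- vapply(groups, function(ix) rowSums(counts[, ix, drop = FALSE]),
              numeric(nrow(counts)))
  storage.mode(k) <- "integer"
  first <- vapply(groups, `[[`, integer(1L), 1L)
  m <- meta[first, , drop = FALSE]
  m$sample_id <- names(groups)
  colnames(k) <- names(groups)
  rownames(k) <- rownames(counts)
  rownames(m) <- NULL
  list(counts = k, meta = m)
}
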