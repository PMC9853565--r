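# Internal helpers: seed streams, validation, cell-type label canonicalisation.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a deterministic child seed for a named generator stage
#'
#' All synthetic-data generators draw from stage-specific streams derived from
#' one root seed, so adding a stage never perturbs another stage's draws.
#'
#' @param seed Integer root seed.
#' @param stage Character stage name.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647 # 2^31 - 1, Mersenne prime; keeps arithmetic exact in doubles
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% m
  s <- ((seed %% m) * 48271) %% m
  as.integer((s + h) %% (m - 1) + 1)
}

# Run code with a temporary RNG state seeded from (seed, stage); restores
# the caller's .Random.seed afterwards.
with_stage_seed <- function(seed, stage, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stage_seed(seed, stage))
  force(code)
}

# Canonical cell-type labels with aliases for the sorting-antibody strings.
.CELL_TYPES <- c("NEUN", "PU1", "OEG")
.CELL_TYPE_ALIASES <- c(
  "NEUN" = "NEUN", "NeuN+" = "NEUN", "NEUN+" = "NEUN",
  "PU1" = "PU1", "Pu.1+" = "PU1", "PU.1+" = "PU1",
  "OEG" = "OEG", "NeuN-/Pu.1-" = "OEG", "NEUN-/PU.1-" = "OEG"
)

#' Canonicalise cell-type labels
#'
#' Maps the sorting-antibody strings ("NeuN+", "Pu.1+", "NeuN-/Pu.1-") onto the
#' canonical enum NEUN / PU1 / OEG. Unknown labels raise an error.
#'
#' @param x Character vector of labels.
#' @return Character vector over NEUN, PU1, OEG.
#' @export
canonical_cell_type <- function(x) {
  out <- .CELL_TYPE_ALIASES[as.character(x)]
  if (anyNA(out)) {
    bad <- unique(as.character(x)[is.na(out)])
    stop("unknown cell-type label(s): ", paste(bad, collapse = ", "))
  }
  unname(out)
}

# Validate a peak data.frame against the interval invariants
# (start >= 0, end > start, 0-based half-open, unique names).
validate_peaks <- function(peaks, require_names = FALSE) {
  stopifnot(is.data.frame(peaks))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(peaks))
  if (length(miss)) stop("peak table missing column(s): ", paste(miss, collapse = ", "))
  if (any(peaks$start < 0)) stop("validation error: peak start < 0")
  if (any(peaks$end <= peaks$start)) {
    i <- which(peaks$end <= peaks$start)[1L]
    stop(sprintf("validation error: end <= start at row %d (%s:%d-%d)",
                 i, peaks$chrom[i], peaks$start[i], peaks$end[i]))
  }
  if (require_names) {
    if (is.null(peaks$name)) stop("peak names required")
    if (anyDuplicated(peaks$name)) stop("duplicate peak names")
  }
  invisible(peaks)
}

# Geometric mean (positive values).
geomean <- function(x) exp(mean(log(x)))
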