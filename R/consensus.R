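# Consensus peak construction and interval-overlap statistics.
#
# The merge rule bridges local "dips" in H3K27ac signal: peaks on the same
# chromosome merge iff the gap between them is strictly less than `max_gap`
# (the rule is stated as "less than 200 bp apart", so a gap of exactly 200 bp
# does NOT merge; note bedtools merge -d is inclusive).

#' Merge peaks, bridging gaps strictly smaller than `max_gap`
#'
#' Output is sorted by (chrom, start); any two output peaks on the same
#' chromosome are separated by at least `max_gap` bp, every input base is
#' covered, and merging is transitive (chains collapse). Idempotent.
#'
#' @param peaks Peak data.frame (chrom, start, end; 0-based half-open).
#' @param max_gap Non-negative gap threshold in bp (default 200).
#' @return Merged peak data.frame with columns chrom, start, end.
#' @export
merge_with_gap <- function(peaks, max_gap = 200L) {
  stopifnot(max_gap >= 0)
  validate_peaks(peaks)
  if (nrow(peaks) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  o <- order(peaks$chrom, peaks$start, peaks$end)
  chrom <- as.character(peaks$chrom[o])
  start <- as.integer(peaks$start[o])
  end <- as.integer(peaks$end[o])
  n <- length(chrom)
  # Running maximum end within each chromosome; a new merged peak starts where
  # the gap to everything before it is >= max_gap (strict-< merge rule).
  cme <- integer(n)
  brk <- logical(n)
  for (ix in split(seq_len(n), chrom)) {
    ce <- cummax(end[ix])
    cme[ix] <- ce
    k <- length(ix)
    brk[ix] <- c(TRUE, if (k > 1L) (start[ix][-1L] - ce[-k]) >= max_gap)
  }
  g <- cumsum(brk)
  last <- cumsum(tabulate(g)) # index of last element in each merged group
  data.frame(chrom = chrom[brk], start = start[brk], end = cme[last],
             stringsAsFactors = FALSE)
}

#' Build the consensus peak set from a collection of peak sets
#'
#' Equivalent to `merge_with_gap` applied to the concatenation of all sets
#' (the result is invariant to per-set pre-merging). Consensus peaks receive
#' sequential ids consensus_000001, consensus_000002, ...
#'
#' @param sets Named list of peak data.frames (e.g. the 12 region x amyloid x
#'   cell-type reproducible subsets).
#' @param max_gap Gap threshold in bp (default 200).
#' @return Peak data.frame with chrom, start, end, name.
#' @export
build_consensus <- function(sets, max_gap = 200L) {
  stopifnot(is.list(sets), length(sets) >= 1L)
  if (!is.null(names(sets)) && anyDuplicated(names(sets))) stop("duplicate set labels")
  all_peaks <- do.call(rbind, lapply(sets, function(s) {
    validate_peaks(s)
    s[, c("chrom", "start", "end"), drop = FALSE]
  }))
  merged <- merge_with_gap(all_peaks, max_gap = max_gap)
  merged$name <- sprintf("consensus_%06d", seq_len(nrow(merged)))
  merged
}

# Total bases covered by a peak set (after internal merge so overlaps are not
# double counted).
covered_bp <- function(peaks) {
  m <- merge_with_gap(peaks, max_gap = 0L)
  sum(as.numeric(m$end - m$start))
}

# Intersection in bp between two (merged) peak sets via a sweep over
# per-chromosome interval pairs.
intersect_bp <- function(a, b) {
  a <- merge_with_gap(a, max_gap = 0L)
  b <- merge_with_gap(b, max_gap = 0L)
  total <- 0
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ai <- a[a$chrom == ch, , drop = FALSE]
    bi <- b[b$chrom == ch, , drop = FALSE]
    i <- 1L
    j <- 1L
    while (i <= nrow(ai) && j <= nrow(bi)) {
      lo <- max(ai$start[i], bi$start[j])
      hi <- min(ai$end[i], bi$end[j])
      if (hi > lo) total <- total + (hi - lo)
      if (ai$end[i] < bi$end[j]) i <- i + 1L else j <- j + 1L
    }
  }
  total
}

#' Jaccard index between two peak sets
#'
#' `intersection_bp / (bp(a) + bp(b) - intersection_bp)`; symmetric, in
#' `[0, 1]`. Matches the bedtools jaccard statistic used to rank external
#' peak sets against cell-type-specific sets.
#'
#' @param a,b Peak data.frames.
#' @return A single numeric value.
#' @export
jaccard <- function(a, b) {
  inter <- intersect_bp(a, b)
  uni <- covered_bp(a) + covered_bp(b) - inter
  if (uni == 0) return(if (inter == 0) 0 else 1)
  inter / uni
}

#' Pairwise jaccard matrix over a collection of peak sets
#'
#' @param sets Named list of peak data.frames.
#' @return A list with `matrix` (symmetric, unit diagonal) and `ranking`
#'   (per-row data.frame of partners in descending jaccard order).
#' @export
pairwise_jaccard_matrix <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  labs <- names(sets)
  n <- length(labs)
  m <- diag(1, n)
  dimnames(m) <- list(labs, labs)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        v <- jaccard(sets[[i]], sets[[j]])
        m[i, j] <- v
        m[j, i] <- v
      }
    }
  }
  ranking <- do.call(rbind, lapply(labs, function(l) {
    others <- setdiff(labs, l)
    vals <- m[l, others]
    ord <- order(-vals)
    data.frame(query = l, partner = others[ord], jaccard = unname(vals[ord]),
               rank = seq_along(others), stringsAsFactors = FALSE)
  }))
  list(matrix = m, ranking = ranking)
}
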