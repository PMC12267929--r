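# Alignment- and genome-level diversity statistics and sliding-window
# tracks: variable/parsimony-informative sites, pairwise identity, GC,
# nucleotide diversity (pi), MDC density, and divergent-block scans.
# Gap handling is pairwise deletion throughout.

#' Number of variable sites in an alignment
#'
#' Columns with at least two distinct unambiguous bases; gaps and
#' ambiguity codes are ignored.
#' @param alignment a [dna_alignment].
#' @export
variable_sites <- function(alignment) {
  mat <- alignment$matrix
  if (nrow(mat) < 2) stop_ob("need >= 2 sequences")
  sum(apply(mat, 2, function(co) {
    b <- co[co %in% BASES]
    length(unique(b)) >= 2
  }))
}

#' Number of parsimony-informative sites
#'
#' Columns with at least two distinct unambiguous bases each carried by
#' at least two sequences.
#' @param alignment a [dna_alignment].
#' @export
parsimony_informative_sites <- function(alignment) {
  mat <- alignment$matrix
  if (nrow(mat) < 2) stop_ob("need >= 2 sequences")
  sum(apply(mat, 2, function(co) {
    tb <- table(co[co %in% BASES])
    sum(tb >= 2) >= 2
  }))
}

#' Mean pairwise identity of an alignment (percent)
#'
#' Mean over all unordered sample pairs of identical compared columns /
#' compared columns, where a column is compared when both samples carry
#' unambiguous bases.  Pairs with zero compared columns are dropped
#' from the mean with a warning.
#' @param alignment a [dna_alignment].
#' @export
pairwise_identity <- function(alignment) {
  pw <- pairwise_stats(alignment)
  ok <- pw$compared > 0
  if (!all(ok))
    warning(sprintf("%d pair(s) with no compared columns excluded",
                    sum(!ok)), call. = FALSE)
  if (!any(ok)) return(NA_real_)
  100 * mean((pw$compared[ok] - pw$diffs[ok]) / pw$compared[ok])
}

# per-pair difference and comparable-column counts (pairwise deletion)
pairwise_stats <- function(alignment) {
  mat <- alignment$matrix
  n <- nrow(mat)
  if (n < 2) stop_ob("need >= 2 sequences")
  isb <- matrix(mat %in% BASES, n)
  pairs <- utils::combn(n, 2)
  diffs <- integer(ncol(pairs)); comp <- integer(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    ok <- isb[i, ] & isb[j, ]
    comp[p] <- sum(ok)
    diffs[p] <- sum(ok & mat[i, ] != mat[j, ])
  }
  list(i = pairs[1, ], j = pairs[2, ], diffs = diffs, compared = comp)
}

#' GC content (percent)
#'
#' `(G + C) / (A + C + G + T) * 100`; gaps and ambiguity codes are
#' excluded from both numerator and denominator.
#' @param x a [dna_alignment], [genome_record], or character
#'   string/vector of sequence.
#' @export
gc_content <- function(x) {
  ch <- sequence_chars(x)
  n_gc <- sum(ch %in% c("G", "C"))
  n_acgt <- sum(ch %in% BASES)
  if (n_acgt == 0) return(NA_real_)
  100 * n_gc / n_acgt
}

sequence_chars <- function(x) {
  if (inherits(x, "dna_alignment")) as.vector(x$matrix)
  else if (inherits(x, "genome_record")) chars(x$sequence)
  else if (is.character(x) && length(x) == 1L && nchar(x) > 1L) chars(x)
  else as.character(x)
}

#' Nucleotide diversity (pi)
#'
#' Average over unordered sequence pairs of pairwise differences per
#' compared site, with pairwise deletion of gap/ambiguity columns.
#' @param alignment a [dna_alignment].
#' @export
pi_diversity <- function(alignment) {
  pw <- pairwise_stats(alignment)
  ok <- pw$compared > 0
  if (!any(ok)) return(NA_real_)
  mean(pw$diffs[ok] / pw$compared[ok])
}

# window start positions (0-based); empty when L < window
window_starts <- function(L, window, step) {
  if (L < window) return(integer(0))
  seq(0L, L - window, by = step)
}

new_window_track <- function(starts, window, values,
                             partial = rep(FALSE, length(starts)),
                             window_size = NA, step = NA) {
  df <- data.frame(start = starts, end = starts + window,
                   value = values, partial = partial)
  attr(df, "window") <- window_size
  attr(df, "step") <- step
  class(df) <- c("window_track", "data.frame")
  df
}

#' Sliding-window nucleotide diversity
#'
#' pi per window of alignment columns (default 600 bp windows sliding
#' by 100 bp, the classic circular-track parameterization).  Windows
#' with no compared sites in any pair get `NA`.
#'
#' @param alignment a [dna_alignment].
#' @param window window size in alignment columns.
#' @param step window shift.
#' @return a `window_track` data frame: `start` (0-based), `end`,
#'   `value`, `partial`.
#' @export
pi_windows <- function(alignment, window = 600, step = 100) {
  mat <- alignment$matrix
  n <- nrow(mat)
  if (n < 2) stop_ob("need >= 2 sequences")
  L <- ncol(mat)
  starts <- window_starts(L, window, step)
  if (!length(starts))
    return(new_window_track(integer(0), window, numeric(0),
                            window_size = window, step = step))
  isb <- matrix(mat %in% BASES, n)
  pairs <- utils::combn(n, 2)
  np <- ncol(pairs)
  # per-pair cumulative diff/comparable counts over columns
  cdiff <- matrix(0, np, L + 1L)
  ccomp <- matrix(0, np, L + 1L)
  for (p in seq_len(np)) {
    i <- pairs[1, p]; j <- pairs[2, p]
    ok <- isb[i, ] & isb[j, ]
    cdiff[p, ] <- c(0, cumsum(ok & mat[i, ] != mat[j, ]))
    ccomp[p, ] <- c(0, cumsum(ok))
  }
  vals <- vapply(starts, function(s) {
    d <- cdiff[, s + window + 1L] - cdiff[, s + 1L]
    co <- ccomp[, s + window + 1L] - ccomp[, s + 1L]
    ok <- co > 0
    if (!any(ok)) NA_real_ else mean(d[ok] / co[ok])
  }, numeric(1))
  new_window_track(starts, window, vals, window_size = window, step = step)
}

#' MDC density track
#'
#' Counts MDC sites in non-overlapping windows (step = window).  When
#' the length is not divisible by the window, the last partial window
#' is counted and flagged, so counts always sum to the number of sites.
#'
#' @param mdc_sites an `mdc_sites` data frame from [find_mdcs()] or a
#'   vector of 0-based site positions.
#' @param length total sequence/alignment length (bp).
#' @param window window size (bp).
#' @return a `window_track`.
#' @export
mdc_density <- function(mdc_sites, length, window = 1000) {
  pos <- if (is.data.frame(mdc_sites)) mdc_sites$column else mdc_sites
  if (any(pos < 0 | pos >= length)) stop_ob("site position out of bounds")
  starts <- seq(0L, max(0L, length - 1L), by = window)
  ends <- pmin(starts + window, length)
  counts <- vapply(seq_along(starts), function(w)
    sum(pos >= starts[w] & pos < ends[w]), numeric(1))
  tr <- new_window_track(starts, window, counts,
                         partial = ends - starts < window,
                         window_size = window, step = window)
  tr$end <- ends
  tr
}

#' GC content track over a genome
#'
#' GC percent in non-overlapping windows (default 100 bp tiles).
#' @param genome a [genome_record] or sequence string.
#' @param window window size (bp).
#' @param step window shift (defaults to `window`: tiling).
#' @return a `window_track`.
#' @export
gc_windows <- function(genome, window = 100, step = window) {
  s <- if (inherits(genome, "genome_record")) genome$sequence else genome
  ch <- chars(s)
  L <- length(ch)
  starts <- window_starts(L, window, step)
  cgc <- c(0, cumsum(ch %in% c("G", "C")))
  cac <- c(0, cumsum(ch %in% BASES))
  vals <- vapply(starts, function(st) {
    den <- cac[st + window + 1L] - cac[st + 1L]
    if (den == 0) NA_real_ else
      100 * (cgc[st + window + 1L] - cgc[st + 1L]) / den
  }, numeric(1))
  new_window_track(starts, window, vals, window_size = window, step = step)
}

#' Scan for divergent blocks of a focal sample
#'
#' Finds regions where the focal sample differs from the column
#' majority state in at least `min_frac` of columns, as a hypervariable
#' fragment in one sample would.  Windows of width `min_run` exceeding
#' the divergence fraction are merged into maximal intervals.
#'
#' @param alignment a [dna_alignment].
#' @param focal_sample sample id.
#' @param min_run minimum run length (columns).
#' @param min_frac minimum fraction of divergent columns within a run.
#' @return matrix of 0-based half-open column intervals.
#' @export
divergent_block_scan <- function(alignment, focal_sample, min_run = 100,
                                 min_frac = 0.3) {
  mat <- alignment$matrix
  if (!focal_sample %in% rownames(mat))
    stop_ob("sample '%s' not in alignment", focal_sample)
  L <- ncol(mat)
  maj <- apply(mat, 2, function(co) {
    b <- co[co %in% BASES]
    if (!length(b)) return(NA_character_)
    tb <- sort(table(b), decreasing = TRUE)
    nm <- names(tb)[tb == tb[1]]
    sort(nm)[1]  # alphabetical tie-break
  })
  f <- mat[focal_sample, ]
  div <- as.integer(f %in% BASES & !is.na(maj) & f != maj)
  starts <- window_starts(L, min_run, 1L)
  if (!length(starts)) return(cbind(start = integer(0), end = integer(0)))
  cs <- c(0, cumsum(div))
  frac <- (cs[starts + min_run + 1L] - cs[starts + 1L]) / min_run
  hot <- starts[frac >= min_frac]
  if (!length(hot)) return(cbind(start = integer(0), end = integer(0)))
  merge_intervals(cbind(hot, hot + min_run))
}
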