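# Seeded local-alignment homology scan: detects plastid-derived regions
# (MTPTs) in a mitogenome and repeated regions within a genome.
#
# Algorithm: exact k-mer seeds on both strands -> seeds collapsed into
# maximal runs per diagonal -> ungapped X-drop extension along the
# diagonal -> affine-gap local DP on a window around the ungapped HSP
# -> score/e-value filters -> per-diagonal collapse of redundant hits.

# Ungapped Karlin-Altschul K for common blastn-style reward/penalty
# pairs (uniform base composition).  lambda is always solved
# numerically from sum_ij p_i p_j exp(lambda * s_ij) = 1; the solved
# values agree with the tabulated ones to three decimals.
KARLIN_K_TABLE <- c("2/-3" = 0.408, "1/-2" = 0.46, "1/-3" = 0.711,
                    "1/-4" = 0.738)

#' Scoring scheme for the nucleotide homology scan
#'
#' Defaults mirror the classic blastn parameterization: match +2,
#' mismatch -3, gap open 5, gap extend 2 (a gap of length g costs
#' `open + g * extend`).  Karlin-Altschul lambda is solved numerically
#' for uniform base composition; K comes from a small precomputed table
#' for common reward/penalty pairs (ungapped values used as an
#' approximation for gapped scores) or must be supplied.
#'
#' @param match match reward (> 0).
#' @param mismatch mismatch score (< 0).
#' @param gap_open gap opening cost (>= 0).
#' @param gap_extend gap extension cost per residue (>= 0).
#' @param lambda,K optional Karlin-Altschul parameters overriding the
#'   computed/tabulated values.
#' @return an object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 2, mismatch = -3, gap_open = 5,
                           gap_extend = 2, lambda = NULL, K = NULL) {
  if (match <= 0 || mismatch >= 0)
    stop_ob("scoring scheme needs match > 0 and mismatch < 0")
  if (gap_open < 0 || gap_extend < 0)
    stop_ob("gap costs must be non-negative")
  # expected score per aligned pair must be negative for lambda to exist
  ex <- match / 4 + 3 * mismatch / 4
  if (ex >= 0)
    stop_ob("degenerate scoring: expected score per pair is %.3f >= 0", ex)
  if (is.null(lambda)) {
    f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
    lambda <- stats::uniroot(f, c(1e-6, 5), tol = 1e-12)$root
  }
  if (is.null(K)) {
    key <- sprintf("%g/%g", match, mismatch)
    if (!key %in% names(KARLIN_K_TABLE))
      stop_ob("no tabulated Karlin-Altschul K for scheme %s; supply K", key)
    K <- unname(KARLIN_K_TABLE[key])
  }
  if (lambda <= 0 || K <= 0) stop_ob("lambda and K must be positive")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K),
            class = "scoring_scheme")
}

#' Karlin-Altschul expectation of a raw alignment score
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of distinct
#' local alignments of raw score >= S between random sequences of
#' lengths `m` and `n`.
#'
#' @param raw_score raw alignment score(s).
#' @param m,n lengths (bp) of the two sequences searched.
#' @param scoring a [scoring_scheme].
#' @return numeric e-value(s).
#' @export
evalue <- function(raw_score, m, n, scoring = scoring_scheme()) {
  if (any(m <= 0) || any(n <= 0)) stop_ob("m and n must be positive")
  scoring$K * m * n * exp(-scoring$lambda * raw_score)
}

#' Bit score of a raw score under a scheme
#' @param raw_score raw alignment score(s).
#' @param scoring a [scoring_scheme].
#' @export
bit_score <- function(raw_score, scoring = scoring_scheme()) {
  (scoring$lambda * raw_score - log(scoring$K)) / log(2)
}

# -- k-mer machinery ---------------------------------------------------

# numeric codes of all k-mers of an integer-encoded sequence; windows
# containing a non-ACGT position get NA.  Codes are exact doubles for
# k <= 26.
kmer_codes <- function(s, k) {
  n <- length(s)
  if (n < k) return(numeric(0))
  m <- n - k + 1L
  code <- numeric(m)
  bad <- integer(m)
  for (j in 0:(k - 1L)) {
    sj <- s[(1L + j):(m + j)]
    code <- code + sj * 4^j
    bad <- bad + (sj == 0L)
  }
  code[bad > 0L] <- NA_real_
  code
}

# all (qpos, spos) seed pairs (1-based start positions) with equal k-mers
seed_pairs <- function(codesA, codesB) {
  ia <- which(!is.na(codesA))
  ib <- which(!is.na(codesB))
  dfa <- data.frame(code = codesA[ia], i = ia)
  dfb <- data.frame(code = codesB[ib], j = ib)
  keep <- dfa$code %in% dfb$code
  dfa <- dfa[keep, , drop = FALSE]
  keep <- dfb$code %in% dfa$code
  dfb <- dfb[keep, , drop = FALSE]
  if (nrow(dfa) == 0L)
    return(data.frame(i = integer(0), j = integer(0)))
  mg <- merge(dfa, dfb, by = "code")
  data.frame(i = mg$i, j = mg$j)
}

# collapse seed pairs on one diagonal into maximal runs; returns matrix
# with 1-based [start_i, end_i] spans (inclusive, in query coordinates)
seed_runs <- function(i_sorted, k) {
  brk <- which(diff(i_sorted) > k)
  starts <- i_sorted[c(1L, brk + 1L)]
  ends <- i_sorted[c(brk, length(i_sorted))] + k - 1L
  cbind(start = starts, end = ends)
}

# ungapped X-drop extension of a run on a diagonal; a, b integer-coded
# full sequences; run in 1-based inclusive query coords; d = i - j.
# Returns c(qs, qe) 1-based inclusive and the ungapped score.
xdrop_extend <- function(a, b, run_start, run_end, d, scoring, xdrop,
                         max_extend) {
  run_start <- unname(run_start); run_end <- unname(run_end)
  La <- length(a); Lb <- length(b)
  ilo <- max(1L, d + 1L, run_start - max_extend)
  ihi <- min(La, Lb + d, run_end + max_extend)
  idx <- ilo:ihi
  sc <- ifelse(a[idx] > 0L & a[idx] == b[idx - d],
               scoring$match, scoring$mismatch)
  rs <- run_start - ilo + 1L
  re <- run_end - ilo + 1L
  core <- sum(sc[rs:re])
  ext_best <- function(v) {
    if (!length(v)) return(c(0, 0L))
    cs <- cumsum(v)
    cm <- cummax(cs)
    stopi <- which(cm - cs > xdrop)
    lim <- if (length(stopi)) stopi[1] - 1L else length(v)
    if (lim == 0L) return(c(0, 0L))
    best <- which.max(cs[1:lim])
    if (cs[best] <= 0) c(0, 0L) else c(cs[best], best)
  }
  r <- ext_best(if (re < length(sc)) sc[(re + 1L):length(sc)] else numeric(0))
  l <- ext_best(rev(if (rs > 1L) sc[1:(rs - 1L)] else numeric(0)))
  c(qs = ilo + rs - 1L - l[2], qe = ilo + re - 1L + r[2],
    score = core + l[1] + r[1])
}

# vectorized affine-gap local DP (Gotoh) over two integer-coded
# windows; returns best score and its 1-based end cell (i, j).
sw_forward <- function(a, b, scoring) {
  n <- length(a); m <- length(b)
  oe <- scoring$gap_open + scoring$gap_extend
  e <- scoring$gap_extend
  js <- seq_len(m)
  Hprev <- numeric(m)
  Fprev <- rep(-Inf, m)
  best <- 0; bi <- 0L; bj <- 0L
  for (i in seq_len(n)) {
    sub <- ifelse(a[i] > 0L & a[i] == b, scoring$match, scoring$mismatch)
    diag <- c(0, Hprev[-m]) + sub
    Fv <- pmax(Hprev - oe, Fprev - e)
    tmp <- pmax(0, pmax(diag, Fv))
    # horizontal (gap-in-subject) moves via the cummax trick; gap-derived
    # cells can never improve the running max, so using tmp is exact
    pre <- cummax(tmp + js * e)
    M <- c(-Inf, pre[-m]) - oe - (js - 1) * e
    H <- pmax(tmp, M)
    rm <- which.max(H)
    if (H[rm] > best) { best <- H[rm]; bi <- i; bj <- rm }
    Hprev <- H
    Fprev <- Fv
  }
  c(score = best, i = bi, j = bj)
}

# full local alignment of two windows: score, query/subject intervals
# (1-based inclusive within windows), plus identity and aligned length
# from a global affine alignment of the delimited segments.
local_align_window <- function(a, b, scoring) {
  fw <- sw_forward(a, b, scoring)
  if (fw["score"] <= 0) return(NULL)
  ie <- fw["i"]; je <- fw["j"]
  rv <- sw_forward(rev(a[1:ie]), rev(b[1:je]), scoring)
  is <- ie - rv["i"] + 1L
  jstart <- je - rv["j"] + 1L
  qa <- Biostrings::DNAString(paste(decode_dna(a[is:ie]), collapse = ""))
  qb <- Biostrings::DNAString(paste(decode_dna(b[jstart:je]), collapse = ""))
  sm <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    qa, qb, type = "global", substitutionMatrix = sm,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  aln_len <- Biostrings::nchar(pa)
  matches <- Biostrings::nmatch(pa)
  list(score = unname(fw["score"]),
       qs = unname(is), qe = unname(ie), ss = unname(jstart), se = unname(je),
       identity = 100 * matches / aln_len, aln_len = aln_len)
}

# -- main scan ---------------------------------------------------------

#' Find local-alignment homology hits between two genomes
#'
#' Seeds every exact shared k-mer, collapses seeds into diagonal runs,
#' extends ungapped with an X-drop rule, then refines each candidate
#' with an affine-gap local alignment on a padded window.  Both strands
#' of `genomeB` are searched.  Circular molecules are linearized by
#' doubling; hits crossing the origin are reported split into two rows
#' sharing a `hit_id` with `origin_split = TRUE`.
#'
#' @param genomeA,genomeB [genome_record] objects (query and subject).
#' @param scoring a [scoring_scheme].
#' @param seed_len exact-seed length (>= 8).
#' @param min_raw_score minimum raw score kept (default 100, the classic
#'   "blast score > 100" cutoff interpreted as a raw score).
#' @param max_evalue maximum Karlin-Altschul e-value kept.
#' @param xdrop X-drop threshold for ungapped extension.
#' @param max_extend maximum ungapped extension beyond a seed run (bp).
#' @param pad window padding around the (chained) ungapped HSPs before
#'   the gapped refinement (also bounds how far a gapped alignment can
#'   grow beyond them).
#' @param chain_band,chain_gap ungapped HSPs whose diagonals differ by
#'   at most `chain_band` and whose query ranges lie within
#'   `chain_gap` bp of each other are chained into one gapped
#'   refinement, so indel-split segments are rejoined.
#' @param gap_trigger minimum ungapped score for a run to reach the
#'   gapped stage.
#' @param low_identity_pct hits below this percent identity are flagged
#'   for manual review (`low_identity` column), mirroring how ribosomal
#'   cross-matches of ~74% identity are best treated editorially.
#' @param self logical; set by [self_repeats()] to drop the trivial
#'   self-diagonal when a genome is scanned against itself.
#' @return a `data.frame` (class `homology_hits`) with columns
#'   `hit_id`, `query_start`, `query_end`, `subject_start`,
#'   `subject_end` (0-based half-open), `strand`, `raw_score`,
#'   `bit_score`, `evalue`, `pct_identity`, `aln_len`, `low_identity`,
#'   `origin_split`.
#' @export
find_hits <- function(genomeA, genomeB, scoring = scoring_scheme(),
                      seed_len = 11, min_raw_score = 100,
                      max_evalue = 1e-5, xdrop = 40, max_extend = 6000,
                      pad = 100, chain_band = 64, chain_gap = 200,
                      gap_trigger = 30,
                      low_identity_pct = 80, self = FALSE) {
  if (seed_len < 8) stop_ob("seed_len must be >= 8")
  if (genomeA$length == 0 || genomeB$length == 0)
    stop_ob("genomes must be non-empty")
  La0 <- genomeA$length; Lb0 <- genomeB$length
  aseq <- genomeA$sequence
  bseq <- genomeB$sequence
  circA <- isTRUE(genomeA$circular) && !self
  circB <- isTRUE(genomeB$circular) && !self
  if (circA) aseq <- paste0(aseq, aseq)
  if (circB) bseq <- paste0(bseq, bseq)
  a <- encode_dna(chars(aseq))
  codesA <- kmer_codes(a, seed_len)
  rows <- list()
  for (strand in c("+", "-")) {
    bs <- if (strand == "+") bseq else revcomp_chr(bseq)
    b <- encode_dna(chars(bs))
    codesB <- kmer_codes(b, seed_len)
    sp <- seed_pairs(codesA, codesB)
    if (self && strand == "+") sp <- sp[sp$i < sp$j, , drop = FALSE]
    if (nrow(sp) == 0L) next
    d <- sp$i - sp$j
    o <- order(d, sp$i)
    sp <- sp[o, ]; d <- d[o]
    cand <- list()
    for (dd in unique(d)) {
      ii <- sp$i[d == dd]
      runs <- seed_runs(ii, seed_len)
      for (r in seq_len(nrow(runs))) {
        ug <- xdrop_extend(a, b, runs[r, 1], runs[r, 2], dd, scoring,
                           xdrop, max_extend)
        if (ug["score"] >= gap_trigger)
          cand[[length(cand) + 1L]] <- c(ug, d = dd)
      }
    }
    if (!length(cand)) next
    cm <- do.call(rbind, cand)
    # drop ungapped HSPs nested in a better one on the same diagonal
    cm <- cm[order(-cm[, "score"]), , drop = FALSE]
    keep <- rep(TRUE, nrow(cm))
    for (i in seq_len(nrow(cm))) {
      if (!keep[i]) next
      if (i < nrow(cm)) {
        later <- (i + 1L):nrow(cm)
        ov <- cm[later, "d"] == cm[i, "d"] &
          cm[later, "qs"] <= cm[i, "qe"] & cm[later, "qe"] >= cm[i, "qs"]
        keep[later][ov] <- FALSE
      }
    }
    cm <- cm[keep, , drop = FALSE]
    # chain HSPs on nearby diagonals (indels shift the diagonal) so one
    # gapped refinement covers the whole homologous segment
    nc <- nrow(cm)
    par <- seq_len(nc)
    findp <- function(x) { while (par[x] != x) x <- par[x]; x }
    if (nc > 1) for (i in seq_len(nc - 1L)) for (j in (i + 1L):nc) {
      near <- abs(cm[i, "d"] - cm[j, "d"]) <= chain_band &&
        cm[j, "qs"] <= cm[i, "qe"] + chain_gap &&
        cm[i, "qs"] <= cm[j, "qe"] + chain_gap
      if (near) {
        ri <- findp(i); rj <- findp(j)
        if (ri != rj) par[rj] <- ri
      }
    }
    roots <- vapply(seq_len(nc), findp, integer(1))
    chains <- lapply(split(seq_len(nc), roots), function(idx) {
      c(qs = min(cm[idx, "qs"]), qe = max(cm[idx, "qe"]),
        dmin = min(cm[idx, "d"]), dmax = max(cm[idx, "d"]))
    })
    for (ch in chains) {
      wq1 <- max(1L, ch["qs"] - pad)
      wq2 <- min(length(a), ch["qe"] + pad)
      ws1 <- max(1L, wq1 - ch["dmax"] - pad)
      ws2 <- min(length(b), wq2 - ch["dmin"] + pad)
      la <- local_align_window(a[wq1:wq2], b[ws1:ws2], scoring)
      if (is.null(la)) next
      qs <- unname(wq1 + la$qs - 1L)   # 1-based inclusive
      qe <- unname(wq1 + la$qe - 1L)
      ss <- unname(ws1 + la$ss - 1L)
      se <- unname(ws1 + la$se - 1L)
      if (strand == "-") {
        Lb_s <- length(b)
        tmp <- ss; ss <- Lb_s - se + 1L; se <- Lb_s - tmp + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        query_start = qs - 1L, query_end = qe, subject_start = ss - 1L,
        subject_end = se, strand = strand, raw_score = la$score,
        pct_identity = la$identity, aln_len = la$aln_len)
    }
  }
  if (!length(rows)) return(empty_hits())
  h <- do.call(rbind, rows)
  h$bit_score <- bit_score(h$raw_score, scoring)
  h$evalue <- evalue(h$raw_score, La0, Lb0, scoring)
  h <- h[h$raw_score >= min_raw_score & h$evalue <= max_evalue, ,
         drop = FALSE]
  if (!nrow(h)) return(empty_hits())
  # collapse redundant hits: same strand, overlapping in both query and
  # subject -> keep the best-scoring
  h <- h[order(-h$raw_score, h$query_start, h$subject_start), ,
         drop = FALSE]
  keep <- rep(TRUE, nrow(h))
  for (i in seq_len(nrow(h))) {
    if (!keep[i]) next
    if (i < nrow(h)) {
      later <- (i + 1L):nrow(h)
      ov <- keep[later] & h$strand[later] == h$strand[i] &
        h$query_start[later] < h$query_end[i] &
        h$query_end[later] > h$query_start[i] &
        h$subject_start[later] < h$subject_end[i] &
        h$subject_end[later] > h$subject_start[i]
      keep[later][ov] <- FALSE
    }
  }
  h <- h[keep, , drop = FALSE]
  h$origin_split <- FALSE
  h$hit_id <- seq_len(nrow(h))
  if (circA) h <- unwrap_circular(h, La0, "query")
  if (circB) h <- unwrap_circular(h, Lb0, "subject")
  h$low_identity <- h$pct_identity < low_identity_pct
  h <- h[order(h$query_start, h$subject_start),
         c("hit_id", "query_start", "query_end", "subject_start",
           "subject_end", "strand", "raw_score", "bit_score", "evalue",
           "pct_identity", "aln_len", "low_identity", "origin_split"),
         drop = FALSE]
  rownames(h) <- NULL
  class(h) <- c("homology_hits", "data.frame")
  h
}

empty_hits <- function() {
  h <- data.frame(hit_id = integer(0), query_start = integer(0),
                  query_end = integer(0), subject_start = integer(0),
                  subject_end = integer(0), strand = character(0),
                  raw_score = numeric(0), bit_score = numeric(0),
                  evalue = numeric(0), pct_identity = numeric(0),
                  aln_len = integer(0), low_identity = logical(0),
                  origin_split = logical(0))
  class(h) <- c("homology_hits", "data.frame")
  h
}

# map hits found on a doubled circular sequence back to [0, L): drop
# copies starting in the second copy, split hits crossing the origin
unwrap_circular <- function(h, L, side) {
  s <- paste0(side, "_start"); e <- paste0(side, "_end")
  h <- h[h[[s]] < L, , drop = FALSE]
  cross <- which(h[[e]] > L)
  if (length(cross)) {
    extra <- h[cross, , drop = FALSE]
    h[[e]][cross] <- L
    h$origin_split[cross] <- TRUE
    extra[[s]] <- 0L
    extra[[e]] <- extra[[e]] - L
    extra$origin_split <- TRUE
    h <- rbind(h, extra)
  }
  h
}

#' Collapse duplicated homology hits into unique region pairs
#'
#' Hits whose query intervals or whose subject intervals reciprocally
#' overlap by at least `overlap_frac` are clustered (transitive
#' closure); each cluster yields one region pair with merged spans.
#' A plastid region transferred twice into the mitogenome therefore
#' collapses to a single region pair with two members.
#'
#' @param hits a `homology_hits` data frame from [find_hits()].
#' @param overlap_frac reciprocal overlap fraction in (0, 1].
#' @return data frame (class `region_pairs`) with one row per unique
#'   region: `region_id`, `n_members`, `member_ids`, `query_intervals`,
#'   `subject_intervals` (merged, formatted `start-end` 0-based
#'   half-open, comma-separated), `query_span_start`, `query_span_end`,
#'   `subject_span_start`, `subject_span_end`, `best_score`.
#' @export
dedupe_hits <- function(hits, overlap_frac = 0.5) {
  if (overlap_frac <= 0 || overlap_frac > 1)
    stop_ob("overlap_frac must be in (0, 1]")
  n <- nrow(hits)
  if (n == 0L)
    return(data.frame(region_id = integer(0), n_members = integer(0)))
  recip <- function(s1, e1, s2, e2) {
    ov <- pmin(e1, e2) - pmax(s1, s2)
    ov >= overlap_frac * (e1 - s1) & ov >= overlap_frac * (e2 - s2)
  }
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    link <- recip(hits$query_start[i], hits$query_end[i],
                  hits$query_start[j], hits$query_end[j]) ||
      recip(hits$subject_start[i], hits$subject_end[i],
            hits$subject_start[j], hits$subject_end[j])
    if (link) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), roots)
  fmt <- function(m) paste(sprintf("%d-%d", m[, 1], m[, 2]), collapse = ",")
  out <- lapply(seq_along(groups), function(g) {
    idx <- groups[[g]]
    qm <- merge_intervals(cbind(hits$query_start[idx], hits$query_end[idx]))
    sm <- merge_intervals(cbind(hits$subject_start[idx],
                                hits$subject_end[idx]))
    data.frame(region_id = g, n_members = length(idx),
               member_ids = paste(hits$hit_id[idx], collapse = ","),
               query_intervals = fmt(qm), subject_intervals = fmt(sm),
               query_span_start = min(qm[, 1]), query_span_end = max(qm[, 2]),
               subject_span_start = min(sm[, 1]),
               subject_span_end = max(sm[, 2]),
               best_score = max(hits$raw_score[idx]))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$query_span_start), , drop = FALSE]
  out$region_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("region_pairs", "data.frame")
  out
}

parse_intervals <- function(s) {
  parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], "-", fixed = TRUE)
  m <- do.call(rbind, lapply(parts, as.integer))
  colnames(m) <- c("start", "end")
  m
}

#' Classify gene content of homologous region pairs
#'
#' A gene is `complete` if its full annotated interval lies within one
#' merged subject interval of a region pair, `fragment` if it merely
#' overlaps one.
#'
#' @param pairs `region_pairs` from [dedupe_hits()].
#' @param features feature table (as in [genome_record]) in subject
#'   coordinates; only rows with `kind == "gene"` are classified unless
#'   `kinds` says otherwise.
#' @param kinds feature kinds to consider.
#' @return data frame `region_id`, `gene`, `completeness`.
#' @export
classify_gene_content <- function(pairs, features, kinds = "gene") {
  fe <- features[features$kind %in% kinds, , drop = FALSE]
  out <- list()
  for (r in seq_len(nrow(pairs))) {
    ints <- parse_intervals(pairs$subject_intervals[r])
    for (g in seq_len(nrow(fe))) {
      gs <- fe$start[g]; ge <- fe$end[g]
      contained <- any(ints[, 1] <= gs & ints[, 2] >= ge)
      overlaps <- any(ints[, 1] < ge & ints[, 2] > gs)
      if (contained || overlaps)
        out[[length(out) + 1L]] <- data.frame(
          region_id = pairs$region_id[r], gene = fe$name[g],
          completeness = if (contained) "complete" else "fragment")
    }
  }
  if (!length(out))
    return(data.frame(region_id = integer(0), gene = character(0),
                      completeness = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Detect repeated regions within a genome
#'
#' Scans the genome against itself (dropping the trivial
#' self-diagonal), keeps hits of at least `min_len` aligned columns and
#' `min_identity` percent identity, and returns the union of their
#' query and subject intervals as a sorted, merged mask.
#'
#' @param genome a [genome_record].
#' @param min_len minimum aligned length (bp) of a qualifying repeat.
#' @param min_identity minimum percent identity.
#' @param seed_len seed length passed to [find_hits()].
#' @param scoring a [scoring_scheme].
#' @param min_raw_score raw-score floor for candidate self-hits.
#' @return matrix of 0-based half-open intervals (columns `start`,
#'   `end`), sorted and non-overlapping.
#' @export
self_repeats <- function(genome, min_len = 100, min_identity = 90,
                         seed_len = 11, scoring = scoring_scheme(),
                         min_raw_score = 50) {
  if (min_len < seed_len) stop_ob("min_len must be >= seed_len")
  h <- find_hits(genome, genome, scoring = scoring, seed_len = seed_len,
                 min_raw_score = min_raw_score, max_evalue = Inf,
                 self = TRUE)
  h <- h[h$aln_len >= min_len & h$pct_identity >= min_identity, ,
         drop = FALSE]
  if (!nrow(h)) return(cbind(start = integer(0), end = integer(0)))
  ints <- rbind(cbind(h$query_start, h$query_end),
                cbind(h$subject_start, h$subject_end))
  merge_intervals(ints)
}
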