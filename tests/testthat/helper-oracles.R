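# Independent brute-force oracles and random fixture builders used
# across the suite.  The oracles re-derive each quantity from first
# principles with their own tables and loops, so agreement with the
# package implementations is a genuine cross-check.

BASES4 <- c("A", "C", "G", "T")

rand_seq <- function(n, gc = 0.5) {
  paste(sample(BASES4, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

rand_aln_matrix <- function(n_samples, L,
                            alphabet = c(BASES4, "-", "N", "R", "Y"),
                            prob = c(rep(0.22, 4), 0.06, 0.02, 0.02,
                                     0.02)) {
  m <- matrix(sample(alphabet, n_samples * L, replace = TRUE,
                     prob = prob),
              nrow = n_samples)
  rownames(m) <- paste0("s", seq_len(n_samples))
  m
}

# independent IUPAC expansion used only by the oracles
ORACLE_IUPAC <- list(A = "A", C = "C", G = "G", T = "T",
                     R = c("A", "G"), Y = c("C", "T"),
                     S = c("C", "G"), W = c("A", "T"),
                     K = c("G", "T"), M = c("A", "C"),
                     B = c("C", "G", "T"), D = c("A", "G", "T"),
                     H = c("A", "C", "T"), V = c("A", "C", "G"),
                     N = c("A", "C", "G", "T"))

# per-column MDC scan written as an explicit loop
brute_mdc_columns <- function(mat, q_ids, r_ids,
                              policy = "conservative") {
  out <- integer(0)
  for (col in seq_len(ncol(mat))) {
    qs <- mat[q_ids, col]
    if (any(!qs %in% BASES4)) next
    if (length(unique(qs)) != 1L) next
    b <- qs[1]
    rs <- mat[r_ids, col]
    if (policy == "conservative") {
      bad <- FALSE
      for (x in rs) {
        if (x == "-" || b %in% ORACLE_IUPAC[[x]]) { bad <- TRUE; break }
      }
      if (!bad) out <- c(out, col)
    } else {
      ra <- rs[rs %in% BASES4]
      if (length(ra) && !(b %in% ra)) out <- c(out, col)
    }
  }
  out
}

# transitive-closure clustering of hits by reciprocal overlap, done
# with an explicit adjacency matrix and breadth-first search
brute_cluster <- function(hits, frac) {
  n <- nrow(hits)
  adj <- matrix(FALSE, n, n)
  rec <- function(s1, e1, s2, e2) {
    ov <- min(e1, e2) - max(s1, s2)
    ov >= frac * (e1 - s1) && ov >= frac * (e2 - s2)
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- rec(hits$query_start[i], hits$query_end[i],
                     hits$query_start[j], hits$query_end[j]) ||
      rec(hits$subject_start[i], hits$subject_end[i],
          hits$subject_start[j], hits$subject_end[j])
  }
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    k <- k + 1L
    queue <- i
    while (length(queue)) {
      x <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[x])) next
      comp[x] <- k
      queue <- c(queue, which(adj[x, ] & is.na(comp)))
    }
  }
  comp
}

# optimal local alignment score under the blastn-like scheme
sw_score <- function(A, B, match = 2, mismatch = -3, gap_open = 5,
                     gap_extend = 2) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match, mismatch)
  Biostrings::score(Biostrings::pairwiseAlignment(
    Biostrings::DNAString(A), Biostrings::DNAString(B), type = "local",
    substitutionMatrix = sm, gapOpening = gap_open,
    gapExtension = gap_extend))
}

# plant a (possibly mutated) copy of subject[s_start..s_end] into a
# random query background at q_start; 1-based inclusive coordinates
plant_insert <- function(query_bg, subject, s_start, s_end, q_start,
                         divergence = 0) {
  seg <- strsplit(substr(subject, s_start, s_end), "")[[1]]
  if (divergence > 0) {
    nm <- rbinom(1, length(seg), divergence)
    if (nm > 0) {
      pos <- sample.int(length(seg), nm)
      for (p in pos) seg[p] <- sample(setdiff(BASES4, seg[p]), 1)
    }
  }
  paste0(substr(query_bg, 1, q_start - 1), paste(seg, collapse = ""),
         substr(query_bg, q_start + length(seg), nchar(query_bg)))
}
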