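# Codon-usage machinery: codon counting, RSCU, within-amino-acid
# Kruskal-Wallis tests with Dunn/Bonferroni post hocs, organelle
# contrasts, Pearson concordance, and the MILC codon-usage distance
# with its short-gene filter.

#' Synonymous family map of a genetic code
#'
#' @param genetic_code `"standard"` (plant organelles use the standard
#'   code) or a named character vector codon -> amino acid covering all
#'   64 codons (stops as `"*"`).
#' @param split_sixfold split the six-fold Leu/Ser/Arg families into
#'   their two-fold and four-fold halves (off by default: the common
#'   RSCU convention treats them as single r = 6 families).
#' @return data frame `codon`, `family`, `r` over the 61 sense codons.
#' @export
codon_families <- function(genetic_code = "standard",
                           split_sixfold = FALSE) {
  gc <- if (identical(genetic_code, "standard"))
    Biostrings::GENETIC_CODE else genetic_code
  sense <- names(gc)[gc != "*"]
  fam <- unname(gc[sense])
  if (split_sixfold) {
    two <- c(TTA = "Leu2", TTG = "Leu2", AGT = "Ser2", AGC = "Ser2",
             AGA = "Arg2", AGG = "Arg2")
    idx <- match(sense, names(two))
    fam[!is.na(idx)] <- two[idx[!is.na(idx)]]
  }
  r <- table(fam)[fam]
  data.frame(codon = sense, family = fam, r = as.integer(r))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Count codons in a set of coding sequences
#'
#' Sequences whose length is not a multiple of three lose their
#' trailing remainder with a warning.  Sequences shorter than
#' `min_len_aa` sense codons are excluded before counting (the hard
#' length filter used with MILC, default off here).
#'
#' @param cds_set character vector or `DNAStringSet` of CDS sequences
#'   (named; unnamed sequences get `gene1..N`).
#' @param min_len_aa exclude genes with fewer than this many sense
#'   codons.
#' @return object of class `codon_counts`: list with `per_gene`
#'   (gene x 61 sense-codon matrix), `counts` (pooled), `stops`
#'   (pooled stop-codon counts), `n_genes`, `excluded` (gene names
#'   dropped by the length filter).
#' @export
extract_codons <- function(cds_set, min_len_aa = 0) {
  nms <- names(cds_set)
  seqs <- toupper(as.character(cds_set))
  names(seqs) <- nms
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    names(seqs) <- paste0("gene", seq_along(seqs))
  fams <- codon_families()
  rem <- nchar(seqs) %% 3 != 0
  if (any(rem)) {
    warning(sprintf("%d sequence(s) not a multiple of 3; trailing bases dropped",
                    sum(rem)), call. = FALSE)
    seqs[rem] <- substr(seqs[rem], 1, nchar(seqs[rem]) %/% 3 * 3)
  }
  codon_list <- lapply(seqs, function(s) {
    n <- nchar(s) %/% 3
    if (n == 0) return(character(0))
    substring(s, 3 * seq_len(n) - 2, 3 * seq_len(n))
  })
  n_sense <- vapply(codon_list, function(cv)
    sum(cv %in% fams$codon), integer(1))
  keep <- n_sense >= min_len_aa
  excluded <- names(seqs)[!keep]
  if (!any(keep)) stop_ob("no sequence survives the length filter")
  codon_list <- codon_list[keep]
  per_gene <- t(vapply(codon_list, function(cv)
    table(factor(cv, levels = fams$codon)), integer(nrow(fams))))
  colnames(per_gene) <- fams$codon
  stops <- colSums(t(vapply(codon_list, function(cv)
    table(factor(cv, levels = STOP_CODONS)), integer(3))))
  structure(list(per_gene = per_gene, counts = colSums(per_gene),
                 stops = stops, n_genes = nrow(per_gene),
                 excluded = excluded),
            class = "codon_counts")
}

#' @export
print.codon_counts <- function(x, ...) {
  cat(sprintf("<codon_counts: %d genes, %d sense codons (%d excluded)>\n",
              x$n_genes, sum(x$counts), length(x$excluded)))
  invisible(x)
}

as_count_vector <- function(counts) {
  if (inherits(counts, "codon_counts")) counts$counts
  else {
    fams <- codon_families()
    v <- counts[fams$codon]
    v[is.na(v)] <- 0
    names(v) <- fams$codon
    v
  }
}

#' Relative synonymous codon usage
#'
#' `RSCU_c = r * observed_c / family_total`: 1 means no bias within
#' the synonymous family.  Families with zero total get `NA` for all
#' their codons.
#'
#' @param counts a `codon_counts` object or named count vector over the
#'   61 sense codons.
#' @param split_sixfold see [codon_families()].
#' @return named numeric vector of RSCU values over the sense codons.
#' @export
rscu <- function(counts, split_sixfold = FALSE) {
  v <- as_count_vector(counts)
  fams <- codon_families(split_sixfold = split_sixfold)
  out <- rep(NA_real_, nrow(fams))
  names(out) <- fams$codon
  for (f in unique(fams$family)) {
    idx <- fams$family == f
    tot <- sum(v[fams$codon[idx]])
    if (tot > 0) out[idx] <- fams$r[idx][1] * v[fams$codon[idx]] / tot
  }
  out
}

#' RSCU matrix over several species or genomes
#'
#' @param counts_list named list of `codon_counts` objects or count
#'   vectors (one per species/genome).
#' @inheritParams rscu
#' @return matrix rows = species, columns = sense codons (class
#'   `rscu_matrix`).
#' @export
rscu_matrix <- function(counts_list, split_sixfold = FALSE) {
  m <- t(vapply(counts_list, rscu, numeric(61),
                split_sixfold = split_sixfold))
  class(m) <- c("rscu_matrix", class(m))
  m
}

family_values <- function(mat, amino_acid, split_sixfold = FALSE) {
  fams <- codon_families(split_sixfold = split_sixfold)
  codons <- fams$codon[fams$family == amino_acid]
  if (!length(codons)) stop_ob("unknown amino-acid family '%s'", amino_acid)
  if (length(codons) < 2)
    stop_ob("family '%s' has degeneracy < 2", amino_acid)
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1)
  vals <- lapply(codons, function(cd) {
    v <- mat[, cd]
    v[!is.na(v)]
  })
  names(vals) <- codons
  vals
}

#' Kruskal-Wallis test of codon differences within an amino acid
#'
#' Tests whether RSCU differs among the synonymous codons of one amino
#' acid, using the rows of the matrix (species/genomes) as replicates.
#' Degenerate input (all values equal) returns p = 1.
#'
#' @param mat an `rscu_matrix` (rows = species).
#' @param amino_acid family label (e.g. `"L"`, `"A"`).
#' @param split_sixfold see [codon_families()].
#' @return the asymptotic chi-square p-value.
#' @export
kw_by_amino_acid <- function(mat, amino_acid, split_sixfold = FALSE) {
  vals <- family_values(mat, amino_acid, split_sixfold)
  if (any(vapply(vals, length, integer(1)) == 0)) return(NA_real_)
  allv <- unlist(vals)
  if (length(unique(allv)) == 1L) return(1)
  stats::kruskal.test(vals)$p.value
}

#' Dunn's post hoc test with Bonferroni correction
#'
#' Pairwise codon comparisons within one amino-acid family, using Dunn
#' z statistics from pooled mid-ranks with tie correction; p-values are
#' Bonferroni-corrected over the family's `choose(r, 2)` comparisons.
#'
#' @inheritParams kw_by_amino_acid
#' @param correction only `"bonferroni"` is implemented.
#' @param alpha significance level for the `significant` flag.
#' @return data frame `codon_i`, `codon_j`, `z`, `p`, `p_adj`,
#'   `significant`.
#' @export
dunn_posthoc <- function(mat, amino_acid, correction = "bonferroni",
                         alpha = 0.05, split_sixfold = FALSE) {
  stopifnot(identical(correction, "bonferroni"))
  vals <- family_values(mat, amino_acid, split_sixfold)
  g <- rep(names(vals), vapply(vals, length, integer(1)))
  x <- unlist(vals)
  N <- length(x)
  rk <- rank(x)
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  mr <- tapply(rk, g, mean)
  n <- tapply(rk, g, length)
  cods <- names(vals)
  cmb <- utils::combn(cods, 2)
  ncomp <- ncol(cmb)
  rows <- lapply(seq_len(ncomp), function(k) {
    ci <- cmb[1, k]; cj <- cmb[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[ci] + 1 / n[cj]))
    z <- if (se == 0) 0 else (mr[ci] - mr[cj]) / se
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(codon_i = ci, codon_j = cj, z = unname(z), p = unname(p),
               p_adj = min(1, unname(p) * ncomp))
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}

#' Per-codon contrast of codon usage between two organelles
#'
#' For each shared codon, a two-group rank test (Kruskal-Wallis between
#' the mitochondrial and plastid rows) with Bonferroni correction over
#' all tested codons; the direction is the sign of the median
#' difference (MT minus PT).
#'
#' @param mt,pt `rscu_matrix` objects (rows = species/genomes).
#' @param alpha significance level.
#' @return data frame `codon`, `p`, `p_adj`, `significant`,
#'   `direction` (-1, 0, 1).
#' @export
compare_organelles <- function(mt, pt, alpha = 0.05) {
  shared <- intersect(colnames(mt), colnames(pt))
  if (!length(shared)) stop_ob("no shared codon columns")
  rows <- lapply(shared, function(cd) {
    a <- mt[, cd]; a <- a[!is.na(a)]
    b <- pt[, cd]; b <- b[!is.na(b)]
    if (!length(a) || !length(b))
      return(data.frame(codon = cd, p = NA_real_, direction = 0))
    p <- if (length(unique(c(a, b))) == 1L) 1 else
      stats::kruskal.test(list(a, b))$p.value
    data.frame(codon = cd, p = p,
               direction = sign(stats::median(a) - stats::median(b)))
  })
  out <- do.call(rbind, rows)
  tested <- !is.na(out$p)
  out$p_adj <- NA_real_
  out$p_adj[tested] <- pmin(1, out$p[tested] * sum(tested))
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  out[, c("codon", "p", "p_adj", "significant", "direction")]
}

#' Pearson concordance of codon usage between organelles
#'
#' @param mt_counts,pt_counts `codon_counts` objects or named vectors
#'   over shared codons.
#' @return Pearson r, or `NA` when either vector has zero variance.
#' @export
pearson_concordance <- function(mt_counts, pt_counts) {
  to_vec <- function(v)
    if (inherits(v, "codon_counts")) v$counts else v
  x <- to_vec(mt_counts)
  y <- to_vec(pt_counts)
  if (!is.null(names(x)) && !is.null(names(y))) {
    shared <- intersect(names(x), names(y))
    x <- x[shared]; y <- y[shared]
  } else if (length(x) != length(y))
    stop_ob("unnamed vectors must have equal length")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' MILC codon-usage distance per gene
#'
#' MILC ("Measure Independent of Length and Composition") of each gene
#' against an expected codon-usage model:
#' `MILC = sum_a(M_a) / L - C` with
#' `M_a = 2 * sum_c o_c * ln(f_c / g_c)` over each synonymous family
#' (o observed counts, f observed within-family frequencies, g expected
#' within-family frequencies) and small-sample correction
#' `C = sum_a(r_a - 1) / L - 0.5` over the families present in the
#' gene.  Genes shorter than `min_len_aa` sense codons are excluded
#' (the hard filter; default 80 AA).
#'
#' @param gene_counts a `codon_counts` object (per-gene matrix used) or
#'   a gene x codon count matrix.
#' @param expected optional named expected codon frequencies over the
#'   sense codons (any normalization; only within-family proportions
#'   matter).  Defaults to the pooled usage of the input gene set.
#' @param min_len_aa length filter in sense codons.
#' @return named numeric vector of per-gene MILC values.
#' @export
milc <- function(gene_counts, expected = NULL, min_len_aa = 80) {
  pg <- if (inherits(gene_counts, "codon_counts")) gene_counts$per_gene
        else as.matrix(gene_counts)
  fams <- codon_families()
  pg <- pg[, fams$codon, drop = FALSE]
  if (is.null(expected)) expected <- colSums(pg)
  g_all <- expected[fams$codon]
  if (any(is.na(g_all))) stop_ob("expected model must cover all sense codons")
  lens <- rowSums(pg)
  keep <- lens >= min_len_aa
  if (!any(keep)) stop_ob("no gene passes the %d-codon length filter",
                          min_len_aa)
  pg <- pg[keep, , drop = FALSE]
  lens <- lens[keep]
  fam_split <- split(seq_len(nrow(fams)), fams$family)
  out <- vapply(seq_len(nrow(pg)), function(i) {
    o <- pg[i, ]
    Msum <- 0; corr_df <- 0
    for (idx in fam_split) {
      ofam <- o[idx]
      tot <- sum(ofam)
      if (tot == 0) next
      gfam <- g_all[idx]
      gtot <- sum(gfam)
      if (any(gfam == 0 & ofam > 0))
        stop_ob("expected frequency 0 for codon %s with observed count > 0",
                fams$codon[idx][which(gfam == 0 & ofam > 0)[1]])
      f <- ofam / tot
      gg <- gfam / gtot
      nz <- ofam > 0
      Msum <- Msum + 2 * sum(ofam[nz] * log(f[nz] / gg[nz]))
      corr_df <- corr_df + (length(idx) - 1)
    }
    Msum / lens[i] - (corr_df / lens[i] - 0.5)
  }, numeric(1))
  names(out) <- rownames(pg)
  out
}
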