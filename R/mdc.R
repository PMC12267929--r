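# Molecular diagnostic characters (MDCs): alignment columns at which
# every member of a query taxon carries the same unambiguous base and
# no reference-taxon member carries a state compatible with it.
# Query-polymorphic columns are excluded.

# COMPAT[code, base]: does IUPAC `code` possibly represent `base`?
build_compat <- function() {
  m <- matrix(FALSE, nrow = length(IUPAC_CODES), ncol = 4,
              dimnames = list(IUPAC_CODES, BASES))
  for (cd in IUPAC_CODES) m[cd, ] <- BASES %in% IUPAC_SETS[[cd]]
  m
}
IUPAC_COMPAT <- build_compat()

#' Find molecular diagnostic characters of a query taxon
#'
#' A column is an MDC iff (i) every query sample carries the same
#' unambiguous base, and (ii) no reference sample carries a state the
#' ambiguity policy deems compatible with that base.  Columns where any
#' query sample has a gap or ambiguity code are skipped under both
#' policies.
#'
#' Policies: `"conservative"` (default) disqualifies a column whenever
#' any reference sample carries a gap, an `N`, or an ambiguity code
#' whose base set contains the query base — it can only under-count.
#' `"strict_acgt"` ignores all non-ACGT reference characters and calls
#' an MDC when the query base is absent from the remaining reference
#' bases (at least one unambiguous reference base is required).
#'
#' @param alignment a [dna_alignment].
#' @param query_samples,reference_samples disjoint, non-empty character
#'   vectors of sample ids present in the alignment.
#' @param policy `"conservative"` or `"strict_acgt"`.
#' @return data frame (class `mdc_sites`): `fragment_id`, `column`
#'   (0-based), `query_state`, `ref_states`.
#' @export
find_mdcs <- function(alignment, query_samples, reference_samples,
                      policy = c("conservative", "strict_acgt")) {
  policy <- match.arg(policy)
  mat <- alignment$matrix
  if (length(query_samples) == 0L || length(reference_samples) == 0L)
    stop_ob("query and reference sample sets must be non-empty")
  if (length(intersect(query_samples, reference_samples)))
    stop_ob("query and reference sample sets overlap")
  missing <- setdiff(c(query_samples, reference_samples), rownames(mat))
  if (length(missing))
    stop_ob("sample '%s' not in alignment '%s'", missing[1],
            alignment$fragment_id)
  q <- mat[query_samples, , drop = FALSE]
  r <- mat[reference_samples, , drop = FALSE]
  L <- ncol(mat)
  qb <- q[1, ]
  fixed <- colSums(q == matrix(qb, nrow(q), L, byrow = TRUE)) == nrow(q) &
    qb %in% BASES
  is_mdc <- rep(FALSE, L)
  ridx <- matrix(match(r, IUPAC_CODES), nrow = nrow(r))
  gap_i <- match("-", IUPAC_CODES)
  for (b in BASES) {
    cols <- which(fixed & qb == b)
    if (!length(cols)) next
    rc <- ridx[, cols, drop = FALSE]
    if (policy == "conservative") {
      disq <- IUPAC_COMPAT[, b][rc] | rc == gap_i
      ok <- colSums(matrix(disq, nrow(r))) == 0L
    } else {
      rb <- r[, cols, drop = FALSE]
      acgt <- matrix(rb %in% BASES, nrow(r))
      has_b <- colSums(matrix(rb == b, nrow(r)) & acgt) > 0L
      ok <- !has_b & colSums(acgt) > 0L
    }
    is_mdc[cols[ok]] <- TRUE
  }
  cols <- which(is_mdc)
  ref_states <- vapply(cols, function(cc)
    paste(sort(unique(r[, cc])), collapse = ","), character(1))
  out <- data.frame(fragment_id = rep(alignment$fragment_id, length(cols)),
                    column = cols - 1L,
                    query_state = unname(qb[cols]),
                    ref_states = ref_states)
  class(out) <- c("mdc_sites", "data.frame")
  out
}

#' Count MDCs in both directions for a pair of taxa
#'
#' Asymmetric by construction: `countA` counts states fixed in taxon A
#' and absent from taxon B; `countB` the converse.
#'
#' @inheritParams find_mdcs
#' @param taxonA_samples,taxonB_samples disjoint sample id sets.
#' @return named integer vector `c(countA, countB)`.
#' @export
compare_taxa <- function(alignment, taxonA_samples, taxonB_samples,
                         policy = "conservative") {
  c(countA = nrow(find_mdcs(alignment, taxonA_samples, taxonB_samples,
                            policy)),
    countB = nrow(find_mdcs(alignment, taxonB_samples, taxonA_samples,
                            policy)))
}

#' Count variable nucleotides between two samples
#'
#' Columns where both samples carry unambiguous bases and the bases
#' differ; gap/ambiguity columns are skipped (pairwise deletion).
#'
#' @param alignment a [dna_alignment].
#' @param sampleA,sampleB sample ids.
#' @return integer count.
#' @export
count_pairwise_variants <- function(alignment, sampleA, sampleB) {
  mat <- alignment$matrix
  a <- mat[sampleA, ]; b <- mat[sampleB, ]
  ok <- a %in% BASES & b %in% BASES
  sum(ok & a != b)
}

#' Species-discrimination report over a fragment set
#'
#' For every taxon, MDCs are called against reference samples drawn
#' from the other species of the same genus (`scope = "genus"`, the
#' congeneric comparison) or from all other samples
#' (`scope = "panel"`).  A species is identified when it has at least
#' one MDC over the combined fragment set.  Under genus scope, species
#' that are the sole member of their genus cannot be evaluated and are
#' excluded from the efficiency denominator, which is reported
#' explicitly.
#'
#' @param alignments list of [dna_alignment] objects (one per
#'   fragment); samples may be missing from individual fragments.
#' @param panel a [species_panel].
#' @param scope `"genus"` or `"panel"`.
#' @param policy ambiguity policy passed to [find_mdcs()].
#' @param taxon_level `"species"` (subspecies merged, default) or
#'   `"subspecies"` (taxa split by the subspecies column when present).
#' @return an `mdc_report`: list with `per_fragment` (taxon x fragment
#'   MDC counts), `per_species` (combined counts, identified and
#'   evaluable flags), `per_fragment_efficiency`, `efficiency`
#'   (percent), `n_identified`, `denominator` and `scope`.
#' @export
discrimination <- function(alignments, panel,
                           scope = c("genus", "panel"),
                           policy = "conservative",
                           taxon_level = c("species", "subspecies")) {
  scope <- match.arg(scope)
  taxon_level <- match.arg(taxon_level)
  panel <- species_panel(as.data.frame(panel))
  taxon <- panel$species
  if (taxon_level == "subspecies") {
    has_ssp <- !is.na(panel$subspecies) & panel$subspecies != ""
    taxon[has_ssp] <- paste(panel$species[has_ssp],
                            panel$subspecies[has_ssp])
  }
  panel$taxon <- taxon
  taxa <- unique(panel$taxon)
  genus_of <- vapply(taxa, function(t)
    panel$genus[panel$taxon == t][1], character(1))
  if (any(table(panel$taxon[!duplicated(panel$sample_id)]) < 1))
    stop_ob("every taxon needs at least one sample")
  per_frag <- list()
  per_tax <- list()
  for (t in taxa) {
    qsam <- panel$sample_id[panel$taxon == t]
    rtaxa <- if (scope == "genus")
      taxa[taxa != t & genus_of[taxa] == genus_of[t]] else taxa[taxa != t]
    rsam <- panel$sample_id[panel$taxon %in% rtaxa]
    evaluable <- length(rsam) > 0L
    counts <- integer(length(alignments))
    for (i in seq_along(alignments)) {
      a <- alignments[[i]]
      qs <- intersect(qsam, aln_samples(a))
      rs <- intersect(rsam, aln_samples(a))
      counts[i] <- if (length(qs) && length(rs))
        nrow(find_mdcs(a, qs, rs, policy)) else 0L
      per_frag[[length(per_frag) + 1L]] <- data.frame(
        taxon = t, fragment_id = a$fragment_id, n_mdcs = counts[i])
    }
    per_tax[[length(per_tax) + 1L]] <- data.frame(
      taxon = t, genus = unname(genus_of[t]), total_mdcs = sum(counts),
      identified = evaluable && sum(counts) > 0L, evaluable = evaluable)
  }
  per_frag <- do.call(rbind, per_frag)
  per_tax <- do.call(rbind, per_tax)
  denom <- sum(per_tax$evaluable)
  n_id <- sum(per_tax$identified)
  eff <- if (denom > 0) 100 * n_id / denom else NA_real_
  pf_eff <- do.call(rbind, lapply(split(per_frag, per_frag$fragment_id),
    function(df) {
      ided <- df$taxon[df$n_mdcs > 0]
      ided <- ided[ided %in% per_tax$taxon[per_tax$evaluable]]
      data.frame(fragment_id = df$fragment_id[1],
                 n_species_identified = length(ided),
                 efficiency = if (denom > 0)
                   100 * length(ided) / denom else NA_real_)
    }))
  rownames(pf_eff) <- NULL
  structure(list(per_fragment = per_frag, per_species = per_tax,
                 per_fragment_efficiency = pf_eff, efficiency = eff,
                 n_identified = n_id, denominator = denom, scope = scope),
            class = "mdc_report")
}

#' @export
print.mdc_report <- function(x, ...) {
  cat(sprintf(
    "<mdc_report: %d/%d species identified (%.2f%%), scope = %s>\n",
    x$n_identified, x$denominator, x$efficiency, x$scope))
  invisible(x)
}
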