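# Barcode fragment selection: exclude MTPT and repeat masks from the
# reference mitogenome, keep sufficiently long intervals common to the
# species panel, and number the survivors c1..cN in genome order.

#' Select candidate barcode fragments of a reference genome
#'
#' Computes the complement of the union of all masks, drops intervals
#' shorter than `min_len`, then drops intervals present in fewer than
#' `min_presence_frac` of the species.  Presence is assessed per
#' species, not per sample, and is deliberately a soft criterion
#' (default 0.9): a fragment missing from a couple of taxa is still a
#' usable barcode.
#'
#' @param genome a [genome_record] (the reference mitogenome).
#' @param masks list of interval matrices/data frames (0-based
#'   half-open `start`, `end`), e.g. MTPT query intervals and repeat
#'   masks.
#' @param presence optional logical matrix, species x candidate
#'   interval (candidates = masked-complement intervals of at least
#'   `min_len`, in genome order); `TRUE` means the species has usable
#'   sequence for that interval.  `NULL` treats every interval as
#'   present in all species.  See [presence_from_alignments()].
#' @param min_len minimum fragment length (bp).
#' @param min_presence_frac minimum fraction of species in which a
#'   fragment must be present, in (0, 1].
#' @return data frame (class `barcode_fragments`): `fragment_id`
#'   (`c1`..`cN`), `start`, `end` (0-based half-open), `length`,
#'   `presence_frac`.
#' @export
select_fragments <- function(genome, masks = list(), presence = NULL,
                             min_len = 1000, min_presence_frac = 0.9) {
  if (min_presence_frac <= 0 || min_presence_frac > 1)
    stop_ob("min_presence_frac must be in (0, 1]")
  L <- genome$length
  allm <- if (length(masks))
    do.call(rbind, lapply(masks, function(m) as.matrix(m)[, 1:2,
                                                          drop = FALSE]))
  else matrix(numeric(0), ncol = 2)
  if (nrow(allm) && (any(allm[, 1] < 0) || any(allm[, 2] > L)))
    stop_ob("mask interval out of genome bounds")
  comp <- complement_intervals(allm, L)
  comp <- comp[comp[, 2] - comp[, 1] >= min_len, , drop = FALSE]
  if (nrow(comp) == 0L) {
    warning("no unmasked interval of sufficient length", call. = FALSE)
    return(empty_fragments())
  }
  pf <- rep(1, nrow(comp))
  if (!is.null(presence)) {
    if (ncol(presence) != nrow(comp))
      stop_ob("presence matrix must have one column per candidate (%d)",
              nrow(comp))
    pf <- colMeans(presence)
  }
  keep <- pf >= min_presence_frac
  comp <- comp[keep, , drop = FALSE]
  pf <- pf[keep]
  if (nrow(comp) == 0L) {
    warning("no fragment passes the presence criterion", call. = FALSE)
    return(empty_fragments())
  }
  out <- data.frame(fragment_id = paste0("c", seq_len(nrow(comp))),
                    start = comp[, 1], end = comp[, 2],
                    length = comp[, 2] - comp[, 1], presence_frac = pf)
  class(out) <- c("barcode_fragments", "data.frame")
  out
}

empty_fragments <- function() {
  out <- data.frame(fragment_id = character(0), start = integer(0),
                    end = integer(0), length = integer(0),
                    presence_frac = numeric(0))
  class(out) <- c("barcode_fragments", "data.frame")
  out
}

#' Species presence matrix from per-fragment alignments
#'
#' A species is present in a fragment when at least one of its samples
#' covers at least `min_cov` of the alignment columns with non-gap
#' characters.
#'
#' @param alignments named list of [dna_alignment] objects.
#' @param panel a [species_panel].
#' @param min_cov minimum non-gap coverage fraction.
#' @return logical matrix species x fragment.
#' @export
presence_from_alignments <- function(alignments, panel, min_cov = 0.5) {
  panel <- species_panel(as.data.frame(panel))
  sp <- unique(panel$species)
  out <- matrix(FALSE, length(sp), length(alignments),
                dimnames = list(sp, vapply(alignments,
                                           function(a) a$fragment_id,
                                           character(1))))
  for (i in seq_along(alignments)) {
    a <- alignments[[i]]
    cov <- rowMeans(a$matrix != "-")
    for (s in sp) {
      sam <- intersect(panel$sample_id[panel$species == s],
                       aln_samples(a))
      out[s, i] <- length(sam) > 0 && any(cov[sam] >= min_cov)
    }
  }
  out
}

#' Per-fragment effectiveness report
#'
#' One row per selected fragment with its reference length, alignment
#' length, GC content, mean pairwise identity, variable-site count and
#' (when a panel is given) the number of species the fragment alone
#' identifies by MDCs.
#'
#' @param fragments a `barcode_fragments` data frame.
#' @param alignments named list of [dna_alignment] objects keyed (or
#'   identified via their `fragment_id`) by fragment.
#' @param panel optional [species_panel] for the MDC columns.
#' @param scope discrimination scope, see [discrimination()].
#' @param policy ambiguity policy, see [find_mdcs()].
#' @return data frame with one row per fragment; fragments lacking an
#'   alignment get `NA` statistics with a warning.
#' @export
fragment_report <- function(fragments, alignments, panel = NULL,
                            scope = "genus", policy = "conservative") {
  fids <- vapply(alignments, function(a) a$fragment_id, character(1))
  names(alignments) <- fids
  disc <- NULL
  if (!is.null(panel))
    disc <- discrimination(alignments, panel, scope = scope,
                           policy = policy)
  rows <- lapply(seq_len(nrow(fragments)), function(i) {
    fid <- fragments$fragment_id[i]
    base <- data.frame(fragment_id = fid, ref_length = fragments$length[i],
                       aligned_length = NA_integer_, gc_pct = NA_real_,
                       pairwise_identity_pct = NA_real_,
                       variable_sites = NA_integer_,
                       pi = NA_real_,
                       n_species_identified = NA_integer_)
    if (!fid %in% fids) {
      warning(sprintf("no alignment for fragment %s", fid), call. = FALSE)
      return(base)
    }
    a <- alignments[[fid]]
    base$aligned_length <- aln_length(a)
    base$gc_pct <- gc_content(a)
    base$pairwise_identity_pct <- pairwise_identity(a)
    base$variable_sites <- variable_sites(a)
    base$pi <- pi_diversity(a)
    if (!is.null(disc)) {
      pe <- disc$per_fragment_efficiency
      base$n_species_identified <-
        pe$n_species_identified[match(fid, pe$fragment_id)]
    }
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
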