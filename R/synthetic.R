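# Synthetic data with exact ground truth for every pipeline stage:
# ultrametric species trees, multi-genus species panels with planted
# diagnostic sites, organelle genome pairs with planted plastid
# transfers (including duplicates) and repeats, and biased CDS sets.
#
# Diagnostic sites are planted post hoc at invariant columns rather
# than left to mutation, so recovery tests are exact (no homoplasy).

#' Simulate an ultrametric species tree
#'
#' Forward birth-death simulation conditioned on reaching `n_species`
#' extant lineages; extinct lineages are pruned.  After the split that
#' creates the n-th lineage the process runs for one further
#' exponential waiting time before sampling.  For a pure-birth tree
#' the expected crown height (root split to tips, the stem edge is not
#' part of the returned tree) is
#' `(1/b) * (sum_{k=2}^{n-1} 1/k + 1/n)`.
#'
#' @param n_species number of extant tips (>= 3).
#' @param seed RNG seed.
#' @param birth_rate,death_rate per-lineage rates (death defaults 0).
#' @param depth optional target height; branch lengths are rescaled so
#'   the root-to-tip depth equals `depth` (expected substitutions per
#'   site).
#' @return an ultrametric [ape::phylo] with tips `sp01..spNN`.
#' @export
sim_tree <- function(n_species, seed = 1, birth_rate = 1,
                     death_rate = 0, depth = NULL) {
  if (n_species < 3) stop_ob("need n_species >= 3")
  set.seed(seed)
  for (try in 1:100) {
    tr <- sim_bd_once(n_species, birth_rate, death_rate)
    if (!is.null(tr)) break
    tr <- NULL
  }
  if (is.null(tr)) stop_ob("birth-death simulation failed to reach %d tips",
                           n_species)
  tr$tip.label <- sprintf("sp%02d", seq_len(n_species))
  if (!is.null(depth)) {
    h <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length * depth / h
  }
  tr
}

sim_bd_once <- function(n, b, d) {
  # node bookkeeping: 1 is the root lineage
  parent <- c(NA_integer_)
  t_birth <- c(0)
  t_end <- c(NA_real_)
  children <- list(integer(0))
  alive <- 1L
  t <- 0
  while (length(alive) < n) {
    if (!length(alive)) return(NULL)
    k <- length(alive)
    t <- t + stats::rexp(1, k * (b + d))
    x <- alive[sample.int(k, 1)]
    if (stats::runif(1) < b / (b + d)) {
      for (j in 1:2) {
        parent <- c(parent, x)
        t_birth <- c(t_birth, t)
        t_end <- c(t_end, NA_real_)
        children <- c(children, list(integer(0)))
      }
      ids <- c(length(parent) - 1L, length(parent))
      children[[x]] <- ids
      t_end[x] <- t
      alive <- c(setdiff(alive, x), ids)
    } else {
      t_end[x] <- t
      alive <- setdiff(alive, x)
    }
  }
  T_final <- t + stats::rexp(1, length(alive) * (b + d))
  t_end[is.na(t_end)] <- T_final
  tips <- which(lengths(children) == 0)
  extinct <- setdiff(tips, alive)
  lab <- character(length(parent))
  lab[tips] <- paste0("n", tips)
  nwk <- function(x) {
    len <- t_end[x] - t_birth[x]
    if (!length(children[[x]]))
      sprintf("%s:%.10f", lab[x], len)
    else
      sprintf("(%s,%s):%.10f", nwk(children[[x]][1]),
              nwk(children[[x]][2]), len)
  }
  tr <- ape::read.tree(text = paste0(nwk(1L), ";"))
  if (length(extinct))
    tr <- ape::drop.tip(tr, paste0("n", extinct))
  if (is.null(tr) || ape::Ntip(tr) != length(alive)) return(NULL)
  tr
}

#' Default study-panel structure
#'
#' 33 species in six genera (18 + 5 x 3), two samples per species, one
#' hybrid whose haplotype is copied from its parental donor, 29
#' fragments, one of which is absent from two species.  Twenty-five
#' species carry planted diagnostic sites; the hybrid, its donor and
#' six further species carry none.
#' @return list of defaults consumed by [sim_panel()].
#' @export
panel_defaults <- function() {
  genera <- c(rep("Stipa", 18), rep("Achnatherum", 3), rep("Macrochloa", 3),
              rep("Nassella", 3), rep("Stipellula", 3), rep("Trikeraia", 3))
  species <- sprintf("%s_sp%02d", genera, 1:33)
  zero <- species[c(1, 2, 3, 4, 17, 18, 19, 25)]
  diagnostics <- stats::setNames(rep(0L, 33), species)
  planted <- setdiff(species, zero)
  diagnostics[planted] <- rep(c(1L, 2L, 3L, 5L, 8L), length.out =
                                length(planted))
  list(species = species, genera = genera,
       fragments = stats::setNames(round(seq(1000, 3000,
                                             length.out = 29)),
                                   paste0("c", 1:29)),
       diagnostics = diagnostics,
       hybrids = data.frame(hybrid = species[18], donor = species[17]),
       missing = data.frame(species = c(species[20], species[28]),
                            fragment = "c18"))
}

#' Simulate a multi-genus species panel with planted truth
#'
#' Species haplotypes are evolved along the tree under a Jukes-Cantor
#' process (`subst_rate = 0` gives an invariant backbone, the clean
#' null for exact recovery).  Per species, the requested number of
#' diagnostic sites is planted at columns invariant across the whole
#' panel, guaranteeing each is fixed within the species and absent
#' from all others at planting time.  Per-sample polymorphism is then
#' added, and finally each hybrid's samples are overwritten with its
#' donor species' haplotype (so hybrid and donor are expected to yield
#' zero MDCs).
#'
#' @param tree optional [ape::phylo] with tips matching `species`;
#'   simulated via [sim_tree()] when `NULL`.
#' @param species,genera character vectors defining the panel
#'   (defaults: the 33-species, six-genus study structure).
#' @param fragments named integer vector of fragment lengths.
#' @param subst_rate expected substitutions/site on the tree (0-0.1).
#' @param diagnostics named integer vector: planted diagnostic sites
#'   per species.  Alternatively `diagnostic_rate_per_species` draws
#'   counts binomially per species at that per-column rate.
#' @param diagnostic_rate_per_species per-column planting rate used
#'   when `diagnostics` is `NULL`.
#' @param polymorphism_rate per-column, per-sample polymorphism rate.
#' @param samples_per_species samples per species.
#' @param hybrids data frame with columns `hybrid`, `donor`.
#' @param missing data frame with columns `species`, `fragment`:
#'   fragments absent from given species (their samples are dropped
#'   from those alignments).
#' @param seed RNG seed.
#' @return list with `alignments` (named list of [dna_alignment]),
#'   `panel` (a [species_panel]) and `truth` (tree, planted
#'   diagnostics, polymorphisms, hybrids, missing table, and the
#'   vector `identifiable` of species expected to carry >= 1 MDC).
#' @export
sim_panel <- function(tree = NULL, species = NULL, genera = NULL,
                      fragments = NULL, subst_rate = 0,
                      diagnostics = NULL,
                      diagnostic_rate_per_species = NULL,
                      polymorphism_rate = 0, samples_per_species = 2,
                      hybrids = NULL, missing = NULL, seed = 1) {
  def <- panel_defaults()
  if (is.null(species)) { species <- def$species; genera <- def$genera }
  if (is.null(genera)) stop_ob("genera must accompany species")
  if (is.null(fragments)) fragments <- def$fragments
  if (is.null(names(fragments)))
    names(fragments) <- paste0("c", seq_along(fragments))
  if (is.null(diagnostics) && is.null(diagnostic_rate_per_species) &&
      identical(species, def$species))
    diagnostics <- def$diagnostics
  if (is.null(hybrids) && identical(species, def$species))
    hybrids <- def$hybrids
  if (is.null(missing) && identical(species, def$species))
    missing <- def$missing
  if (is.null(hybrids))
    hybrids <- data.frame(hybrid = character(0), donor = character(0))
  if (is.null(missing))
    missing <- data.frame(species = character(0), fragment = character(0))
  if (subst_rate < 0 || subst_rate > 0.1 ||
      polymorphism_rate < 0 || polymorphism_rate > 0.1)
    stop_ob("rates must lie in [0, 0.1]")
  ns <- length(species)
  set.seed(seed)
  if (is.null(tree)) tree <- sim_tree(ns, seed = seed, depth = 1)
  if (ape::Ntip(tree) != ns) stop_ob("tree has %d tips, need %d",
                                     ape::Ntip(tree), ns)
  if (!all(sort(tree$tip.label) == sort(species)))
    tree$tip.label <- species[seq_len(ns)]
  set.seed(seed + 1L)
  # species haplotypes per fragment
  haplo <- lapply(seq_along(fragments), function(i) {
    L <- fragments[i]
    if (subst_rate > 0) {
      sq <- phangorn::simSeq(tree, l = L, rate = subst_rate)
      m <- toupper(as.character(sq))
      m[species, , drop = FALSE]
    } else {
      root <- sample(BASES, L, replace = TRUE)
      matrix(root, nrow = ns, ncol = L, byrow = TRUE,
             dimnames = list(species, NULL))
    }
  })
  names(haplo) <- names(fragments)
  present <- matrix(TRUE, ns, length(fragments),
                    dimnames = list(species, names(fragments)))
  for (r in seq_len(nrow(missing)))
    present[missing$species[r], missing$fragment[r]] <- FALSE
  # planted diagnostic counts
  if (is.null(diagnostics)) {
    rate <- if (is.null(diagnostic_rate_per_species)) 0 else
      diagnostic_rate_per_species
    total_cols <- sum(fragments)
    diagnostics <- stats::setNames(
      stats::rbinom(ns, total_cols, rate), species)
  }
  diagnostics <- diagnostics[species]
  donors <- hybrids$donor
  if (any(diagnostics[c(hybrids$hybrid, donors)] > 0, na.rm = TRUE))
    warning("diagnostics planted for a hybrid or its donor will not be recoverable",
            call. = FALSE)
  # columns invariant across all species, per fragment, not yet used
  free_cols <- lapply(haplo, function(m)
    which(apply(m, 2, function(co) length(unique(co)) == 1L &&
                  co[1] %in% BASES)))
  diag_truth <- list()
  genus_of <- stats::setNames(genera, species)
  for (s in species) {
    k <- diagnostics[s]
    if (is.na(k) || k == 0) next
    # plant only on fragments carrying >= 3 members of the genus:
    # with exactly two, a site fixed in s would be reciprocally
    # diagnostic for the lone congener, breaking exact truth
    congeners_here <- vapply(names(fragments), function(f)
      sum(present[species[genus_of == genus_of[s]], f]), integer(1))
    frs <- names(fragments)[present[s, ] & congeners_here >= 3]
    for (q in seq_len(k)) {
      avail <- frs[vapply(frs, function(f) length(free_cols[[f]]) > 0,
                          logical(1))]
      if (!length(avail))
        stop_ob("not enough invariant columns to plant diagnostics; lower subst_rate or counts")
      f <- if (length(avail) == 1L) avail else sample(avail, 1)
      ci <- free_cols[[f]][sample.int(length(free_cols[[f]]), 1)]
      free_cols[[f]] <- setdiff(free_cols[[f]], ci)
      old <- haplo[[f]][s, ci]
      newb <- sample(setdiff(BASES, old), 1)
      haplo[[f]][s, ci] <- newb
      diag_truth[[length(diag_truth) + 1L]] <- data.frame(
        species = s, fragment_id = f, column = ci - 1L, state = newb)
    }
  }
  diag_truth <- if (length(diag_truth)) do.call(rbind, diag_truth) else
    data.frame(species = character(0), fragment_id = character(0),
               column = integer(0), state = character(0))
  # expand to samples, add polymorphism
  sample_ids <- as.vector(t(outer(species, seq_len(samples_per_species),
                                  function(s, i) paste0(s, "_s", i))))
  panel <- species_panel(data.frame(
    sample_id = sample_ids,
    species = rep(species, each = samples_per_species),
    genus = rep(genera, each = samples_per_species)))
  poly_truth <- list()
  alignments <- list()
  for (f in names(fragments)) {
    sp_here <- species[present[, f]]
    rows <- list()
    for (s in sp_here) {
      base <- haplo[[f]][s, ]
      src <- s
      hi <- match(s, hybrids$hybrid)
      if (!is.na(hi)) { src <- hybrids$donor[hi]; base <- haplo[[f]][src, ] }
      for (i in seq_len(samples_per_species)) {
        v <- base
        if (polymorphism_rate > 0) {
          nmut <- stats::rbinom(1, length(v), polymorphism_rate)
          if (nmut > 0) {
            pos <- sample.int(length(v), nmut)
            for (p in pos) {
              v[p] <- sample(setdiff(BASES, v[p]), 1)
              poly_truth[[length(poly_truth) + 1L]] <- data.frame(
                sample_id = paste0(s, "_s", i), fragment_id = f,
                column = p - 1L, state = v[p])
            }
          }
        }
        rows[[paste0(s, "_s", i)]] <- paste(v, collapse = "")
      }
    }
    alignments[[f]] <- dna_alignment(unlist(rows), fragment_id = f)
  }
  poly_truth <- if (length(poly_truth)) do.call(rbind, poly_truth) else
    data.frame(sample_id = character(0), fragment_id = character(0),
               column = integer(0), state = character(0))
  identifiable <- setdiff(names(diagnostics)[diagnostics > 0],
                          c(hybrids$hybrid, hybrids$donor))
  list(alignments = alignments, panel = panel,
       truth = list(tree = tree, diagnostics = diag_truth,
                    polymorphisms = poly_truth, hybrids = hybrids,
                    missing = missing, presence = present,
                    identifiable = identifiable))
}

# draw `n` non-overlapping intervals of given lengths within [0, L),
# avoiding `occupied` (matrix), with a minimum gap; NULL on failure
draw_intervals <- function(n, lens, L, occupied, gap = 30,
                           retries = 2000) {
  out <- matrix(integer(0), ncol = 2)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (r in seq_len(retries)) {
      s <- sample.int(L - lens[i], 1) - 1L
      e <- s + lens[i]
      all_ints <- rbind(occupied, out)
      clash <- nrow(all_ints) > 0 &&
        any(all_ints[, 1] < e + gap & all_ints[, 2] > s - gap)
      if (!clash) {
        out <- rbind(out, c(s, e))
        placed <- TRUE
        break
      }
    }
    if (!placed) return(NULL)
  }
  out
}

#' Simulate an organelle genome pair with planted transfers
#'
#' Builds a random plastome and mitogenome at the target GC content,
#' copies `n_mtpt - n_duplicates` distinct plastid source regions into
#' the mitogenome (each source of the first `n_duplicates` is inserted
#' twice, emulating duplicated transfers), mutates each insert at
#' `mtpt_divergence`, optionally reverse-complements it, and plants
#' exact repeats within the mitogenome.  Plastid gene annotations are
#' placed so that `n_full_gene_transfers` genes lie entirely inside
#' transferred regions and `n_partial_gene_transfers` straddle a
#' transfer boundary.
#'
#' @param mito_len,plastid_len genome lengths (bp).
#' @param n_mtpt total number of mitogenome insertions.
#' @param n_duplicates how many insertions are second copies of an
#'   already-used source region (`n_mtpt - n_duplicates` unique
#'   sources).
#' @param mtpt_len_range insert length range (bp).
#' @param mtpt_divergence per-site substitution probability applied to
#'   each insert, in [0, 0.2].
#' @param n_repeats number of planted exact repeat pairs.
#' @param repeat_len repeat length (bp).
#' @param n_full_gene_transfers plastid genes fully inside transferred
#'   regions.
#' @param n_partial_gene_transfers plastid genes overlapping a
#'   transfer boundary.
#' @param gc target GC fraction.
#' @param seed RNG seed.
#' @return list `mito` ([genome_record]), `plastid` ([genome_record]
#'   with gene features), `truth` (data frames `mtpt`, `repeats`,
#'   `genes`).
#' @export
sim_organelles <- function(mito_len = 80000, plastid_len = 40000,
                           n_mtpt = 30, n_duplicates = 10,
                           mtpt_len_range = c(200, 1500),
                           mtpt_divergence = 0.01, n_repeats = 2,
                           repeat_len = 1200,
                           n_full_gene_transfers = 5,
                           n_partial_gene_transfers = 4,
                           gc = 0.44, seed = 1) {
  if (mtpt_divergence < 0 || mtpt_divergence > 0.2)
    stop_ob("mtpt_divergence must lie in [0, 0.2]")
  if (n_duplicates >= n_mtpt) stop_ob("n_duplicates must be < n_mtpt")
  set.seed(seed)
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  pt <- sample(BASES, plastid_len, replace = TRUE, prob = prob)
  mt <- sample(BASES, mito_len, replace = TRUE, prob = prob)
  n_src <- n_mtpt - n_duplicates
  src_lens <- round(stats::runif(n_src, mtpt_len_range[1],
                                 mtpt_len_range[2]))
  src <- draw_intervals(n_src, src_lens, plastid_len,
                        matrix(integer(0), ncol = 2))
  if (is.null(src)) stop_ob("could not place source regions; lower n_mtpt")
  # one insertion per source + duplicates of the first n_duplicates
  src_of_insert <- c(seq_len(n_src), seq_len(n_duplicates))
  ins_lens <- src_lens[src_of_insert]
  if (sum(ins_lens) + n_repeats * 2 * repeat_len > 0.5 * mito_len)
    stop_ob("total planted length exceeds half the mitogenome")
  ins <- draw_intervals(n_mtpt, ins_lens, mito_len,
                        matrix(integer(0), ncol = 2))
  if (is.null(ins)) stop_ob("could not place inserts; enlarge mito_len")
  mtpt_rows <- list()
  for (i in seq_len(n_mtpt)) {
    si <- src_of_insert[i]
    seg <- pt[(src[si, 1] + 1):src[si, 2]]
    nmut <- stats::rbinom(1, length(seg), mtpt_divergence)
    if (nmut > 0) {
      pos <- sample.int(length(seg), nmut)
      for (p in pos) seg[p] <- sample(setdiff(BASES, seg[p]), 1)
    }
    strand <- sample(c("+", "-"), 1)
    if (strand == "-") seg <- chars(revcomp_chr(paste(seg, collapse = "")))
    mt[(ins[i, 1] + 1):ins[i, 2]] <- seg
    mtpt_rows[[i]] <- data.frame(
      insert_id = i, source_id = si, mito_start = ins[i, 1],
      mito_end = ins[i, 2], plastid_start = src[si, 1],
      plastid_end = src[si, 2], strand = strand,
      divergence = mtpt_divergence)
  }
  # exact repeats within the mitogenome
  rep_rows <- list()
  occupied <- ins
  for (r in seq_len(n_repeats)) {
    pair <- draw_intervals(2, rep(repeat_len, 2), mito_len, occupied)
    if (is.null(pair)) stop_ob("could not place repeats; enlarge mito_len")
    mt[(pair[2, 1] + 1):pair[2, 2]] <- mt[(pair[1, 1] + 1):pair[1, 2]]
    occupied <- rbind(occupied, pair)
    rep_rows[[r]] <- data.frame(repeat_id = r,
                                start1 = pair[1, 1], end1 = pair[1, 2],
                                start2 = pair[2, 1], end2 = pair[2, 2])
  }
  # plastid gene annotations: full transfers, partial transfers, and
  # two background genes untouched by any transfer
  genes <- list()
  full_src <- sample(seq_len(n_src), n_full_gene_transfers)
  for (j in seq_along(full_src)) {
    si <- full_src[j]
    sl <- src[si, 2] - src[si, 1]
    g_len <- max(30, round(sl * 0.5))
    g_s <- src[si, 1] + floor((sl - g_len) / 2)
    genes[[length(genes) + 1L]] <- data.frame(
      name = sprintf("fullgene%02d", j), start = g_s, end = g_s + g_len,
      strand = "+", kind = "gene", transfer = "complete")
  }
  part_src <- sample(setdiff(seq_len(n_src), full_src),
                     n_partial_gene_transfers)
  for (j in seq_along(part_src)) {
    si <- part_src[j]
    g_len <- 200L
    g_s <- src[si, 2] - 100L
    g_e <- min(plastid_len, g_s + g_len)
    genes[[length(genes) + 1L]] <- data.frame(
      name = sprintf("partgene%02d", j), start = g_s, end = g_e,
      strand = "+", kind = "gene", transfer = "partial")
  }
  bg <- draw_intervals(2, c(300L, 300L), plastid_len, src)
  if (!is.null(bg)) for (j in 1:2)
    genes[[length(genes) + 1L]] <- data.frame(
      name = sprintf("bggene%02d", j), start = bg[j, 1], end = bg[j, 2],
      strand = "+", kind = "gene", transfer = "none")
  genes <- do.call(rbind, genes)
  plastid <- genome_record("plastid_sim", paste(pt, collapse = ""),
                           features = genes[, c("name", "start", "end",
                                                "strand", "kind")])
  mito <- genome_record("mito_sim", paste(mt, collapse = ""))
  list(mito = mito, plastid = plastid,
       truth = list(mtpt = do.call(rbind, mtpt_rows),
                    repeats = if (length(rep_rows))
                      do.call(rbind, rep_rows) else NULL,
                    genes = genes))
}

#' Simulate coding sequences from a codon-usage profile
#'
#' Genes are drawn codon by codon (i.i.d.) from the profile, framed by
#' a start codon and a stop codon, so the profile is recoverable from
#' pooled counts.
#'
#' @param n_genes number of genes.
#' @param len_range_aa gene body length range in codons.
#' @param codon_bias_profile named non-negative weights over the 61
#'   sense codons; `NULL` means uniform.
#' @param seed RNG seed.
#' @return named character vector of CDS sequences.
#' @export
sim_cds <- function(n_genes = 40, len_range_aa = c(100, 400),
                    codon_bias_profile = NULL, seed = 1) {
  set.seed(seed)
  fams <- codon_families()
  w <- if (is.null(codon_bias_profile))
    stats::setNames(rep(1, nrow(fams)), fams$codon)
  else codon_bias_profile[fams$codon]
  if (any(is.na(w) | w < 0)) stop_ob("profile must cover all sense codons")
  lens <- sample(len_range_aa[1]:len_range_aa[2], n_genes, replace = TRUE)
  out <- vapply(seq_len(n_genes), function(i) {
    body <- sample(fams$codon, lens[i], replace = TRUE, prob = w)
    paste0("ATG", paste(body, collapse = ""), "TAA")
  }, character(1))
  names(out) <- sprintf("gene%03d", seq_len(n_genes))
  out
}
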