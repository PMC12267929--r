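# End-to-end orchestration: scan -> select -> mdc -> stats -> rscu ->
# treecmp on a configuration list, writing per-stage TSV/BED/JSON
# outputs stamped with a hash of the configuration.

default_config <- function() {
  list(min_score = 100, max_evalue = 1e-5, seed_len = 11,
       min_repeat_len = 100, min_repeat_identity = 90,
       min_len = 1000, min_presence = 0.9, policy = "conservative",
       scope = "genus", pi_window = 600, pi_step = 100,
       mdc_window = 1000, gc_window = 100, alpha = 0.05,
       support_threshold = 60, milc_min_len_aa = 80, seed = 1)
}

load_config_inputs <- function(config) {
  pathify <- function(field) {
    p <- config[[field]]
    if (!is.null(p) && is.character(p) && !file.exists(p))
      stop_ob("config field '%s': no such file: %s", field, p)
    p
  }
  for (f in c("mito_fasta", "mito_gff3", "plastid_fasta", "plastid_gff3",
              "panel_tsv", "alignment_dir", "tree_mt", "tree_pt"))
    pathify(f)
  if (is.null(config$mito) && !is.null(config$mito_fasta))
    config$mito <- read_genome(config$mito_fasta, config$mito_gff3)
  if (is.null(config$plastid) && !is.null(config$plastid_fasta))
    config$plastid <- read_genome(config$plastid_fasta,
                                  config$plastid_gff3)
  if (is.null(config$panel) && !is.null(config$panel_tsv))
    config$panel <- read_panel(config$panel_tsv)
  if (is.null(config$alignments) && !is.null(config$alignment_dir)) {
    files <- sort(list.files(config$alignment_dir,
                             pattern = "\\.(fa|fasta)$",
                             full.names = TRUE))
    config$alignments <- lapply(files, read_alignment)
  }
  config
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full super-barcode evaluation pipeline
#'
#' Executes every stage for which the configuration provides inputs:
#' the MTPT/repeat homology scans and fragment selection when a
#' mitogenome and plastome are given; MDC discrimination, per-fragment
#' statistics and window tracks when per-fragment alignments and a
#' sample panel are given; RSCU/MILC contrasts when CDS sets are
#' given; tree comparison when two trees are given.  All outputs are
#' written under `out_dir` and a `summary.json` carries the headline
#' numbers plus a hash of the configuration.  Deterministic given
#' config and seed.
#'
#' @param config list; recognized fields: `out_dir` (required),
#'   genomes as objects (`mito`, `plastid`) or paths (`mito_fasta`,
#'   `mito_gff3`, `plastid_fasta`, `plastid_gff3`), `alignments` (list
#'   of [dna_alignment]) or `alignment_dir`, `panel` or `panel_tsv`,
#'   `mt_cds`/`pt_cds` (named CDS character vectors), `tree_mt`,
#'   `tree_pt` (paths or `phylo`), and the thresholds of
#'   `orgbarcode:::default_config()`.
#' @return invisibly, the summary list.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$out_dir)) stop_ob("config field 'out_dir' is required")
  cfg <- utils::modifyList(default_config(), config)
  cfg <- load_config_inputs(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  hash_fields <- cfg[setdiff(names(cfg),
                             c("mito", "plastid", "panel", "alignments",
                               "mt_cds", "pt_cds"))]
  summary <- list(config_hash = object_hash(hash_fields))
  out <- function(...) file.path(cfg$out_dir, ...)

  if (!is.null(cfg$mito) && !is.null(cfg$plastid)) {
    hits <- find_hits(cfg$mito, cfg$plastid,
                      seed_len = cfg$seed_len,
                      min_raw_score = cfg$min_score,
                      max_evalue = cfg$max_evalue)
    write_tsv(as.data.frame(hits), out("mtpt_hits.tsv"))
    pairs <- dedupe_hits(hits)
    write_tsv(as.data.frame(pairs), out("mtpt_regions.tsv"))
    gene_tab <- classify_gene_content(pairs, cfg$plastid$features)
    write_tsv(gene_tab, out("mtpt_gene_content.tsv"))
    rep_mask <- self_repeats(cfg$mito, min_len = cfg$min_repeat_len,
                             min_identity = cfg$min_repeat_identity,
                             seed_len = cfg$seed_len)
    write_bed(rep_mask, cfg$mito$seq_id, out("repeats.bed"))
    mtpt_mask <- merge_intervals(cbind(hits$query_start, hits$query_end))
    write_bed(mtpt_mask, cfg$mito$seq_id, out("mtpt_mask.bed"))
    frags <- select_fragments(cfg$mito,
                              masks = list(mtpt_mask, rep_mask),
                              min_len = cfg$min_len,
                              min_presence_frac = cfg$min_presence)
    write_tsv(as.data.frame(frags), out("fragments.tsv"))
    write_bed(cbind(frags$start, frags$end), cfg$mito$seq_id,
              out("fragments.bed"))
    mtpt_bp <- sum(mtpt_mask[, 2] - mtpt_mask[, 1])
    summary$n_mtpt_hits <- nrow(hits)
    summary$n_mtpt_regions <- nrow(pairs)
    summary$n_complete_gene_transfers <-
      length(unique(gene_tab$gene[gene_tab$completeness == "complete"]))
    summary$mtpt_share_pct <- 100 * mtpt_bp / cfg$mito$length
    summary$n_fragments <- nrow(frags)
    gcw <- gc_windows(cfg$mito, window = cfg$gc_window)
    write_tsv(track_tsv(gcw), out("gc_windows.tsv"))
  }

  if (!is.null(cfg$alignments) && !is.null(cfg$panel)) {
    disc <- discrimination(cfg$alignments, cfg$panel, scope = cfg$scope,
                           policy = cfg$policy)
    write_tsv(disc$per_species, out("mdc_per_species.tsv"))
    write_tsv(disc$per_fragment, out("mdc_per_fragment.tsv"))
    summary$discrimination_pct <- disc$efficiency
    summary$discrimination_denominator <- disc$denominator
    summary$n_identified <- disc$n_identified
    summary$total_mdcs <- sum(disc$per_species$total_mdcs)
    stats_rows <- lapply(cfg$alignments, function(a)
      data.frame(fragment_id = a$fragment_id,
                 aligned_length = aln_length(a),
                 gc_pct = gc_content(a),
                 pairwise_identity_pct = pairwise_identity(a),
                 variable_sites = variable_sites(a),
                 parsimony_informative = parsimony_informative_sites(a),
                 pi = pi_diversity(a)))
    write_tsv(do.call(rbind, stats_rows), out("fragment_stats.tsv"))
    trk <- lapply(cfg$alignments, function(a) {
      tt <- pi_windows(a, window = cfg$pi_window, step = cfg$pi_step)
      if (nrow(tt)) cbind(fragment_id = a$fragment_id, track_tsv(tt))
    })
    trk <- do.call(rbind, trk)
    if (!is.null(trk)) write_tsv(trk, out("pi_windows.tsv"))
  }

  if (!is.null(cfg$mt_cds) && !is.null(cfg$pt_cds)) {
    mtc <- extract_codons(cfg$mt_cds)
    ptc <- extract_codons(cfg$pt_cds)
    rm_ <- rscu_matrix(list(MT = mtc, PT = ptc))
    write_tsv(data.frame(genome = rownames(rm_), rm_,
                         check.names = FALSE), out("rscu.tsv"))
    summary$pearson_concordance <- pearson_concordance(mtc, ptc)
    milc_mt <- milc(mtc, min_len_aa = cfg$milc_min_len_aa)
    milc_pt <- milc(ptc, min_len_aa = cfg$milc_min_len_aa)
    write_tsv(data.frame(genome = c(rep("MT", length(milc_mt)),
                                    rep("PT", length(milc_pt))),
                         gene = c(names(milc_mt), names(milc_pt)),
                         milc = c(milc_mt, milc_pt)),
              out("milc.tsv"))
    summary$milc_mt_median <- stats::median(milc_mt)
    summary$milc_pt_median <- stats::median(milc_pt)
  }

  if (!is.null(cfg$tree_mt) && !is.null(cfg$tree_pt)) {
    tmt <- if (inherits(cfg$tree_mt, "phylo")) cfg$tree_mt else
      read_tree(cfg$tree_mt)
    tpt <- if (inherits(cfg$tree_pt, "phylo")) cfg$tree_pt else
      read_tree(cfg$tree_pt)
    rf <- rf_distance(tmt, tpt)
    tg <- tanglegram(tmt, tpt)
    summary$rf <- rf$rf
    summary$rf_normalized <- rf$normalized
    summary$tanglegram_crossings <- tg$crossings
    summary$mt_tree <- tree_summary(tmt,
                                    support_threshold =
                                      cfg$support_threshold)
    summary$pt_tree <- tree_summary(tpt,
                                    support_threshold =
                                      cfg$support_threshold)
  }

  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Percentage share of a genome occupied by a feature class
#'
#' @param part summed feature length (bp).
#' @param total genome length (bp).
#' @return percent, `100 * part / total`.
#' @export
percent_share <- function(part, total) {
  if (any(total <= 0)) stop_ob("total must be positive")
  100 * part / total
}

#' Percentage by which one genome exceeds another in size
#'
#' @param larger,smaller lengths (bp); the excess is relative to
#'   `smaller`.
#' @return percent, `100 * (larger - smaller) / smaller`.
#' @export
percent_excess <- function(larger, smaller) {
  if (any(smaller <= 0)) stop_ob("smaller must be positive")
  100 * (larger - smaller) / smaller
}

track_tsv <- function(track) {
  data.frame(window_start = track$start + 1L, window_end = track$end,
             value = track$value)
}
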