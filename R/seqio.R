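# Readers/writers for the formats the pipeline touches and the core
# in-memory containers.  Internal coordinates are 0-based half-open
# everywhere; GFF3 (1-based inclusive) and BED (0-based half-open) are
# converted at the boundary.

#' Construct an alignment object
#'
#' An alignment is a character matrix of upper-case IUPAC nucleotide
#' codes (plus the gap `-`), one row per sample, with unique rownames.
#'
#' @param mat character matrix (rows = samples, columns = alignment
#'   columns) or a list/character vector of equal-length sequences
#'   named by sample id.
#' @param fragment_id identifier of the fragment this alignment covers.
#' @return an object of class `dna_alignment`.
#' @export
dna_alignment <- function(mat, fragment_id = "fragment") {
  if (!is.matrix(mat)) {
    seqs <- toupper(unlist(mat))
    if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_along(seqs))
    w <- nchar(seqs)
    if (length(unique(w)) > 1L) {
      bad <- names(seqs)[which(w != w[1])[1]]
      stop_ob("alignment is ragged: record '%s' has length %d, expected %d",
              bad, nchar(seqs[bad]), w[1])
    }
    mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    rownames(mat) <- names(seqs)
  }
  mat[] <- toupper(mat)
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat)))
    stop_ob("alignment rows must carry unique sample ids")
  bad <- which(!(mat %in% IUPAC_CODES))
  if (length(bad)) {
    r <- ((bad[1] - 1L) %% nrow(mat)) + 1L
    co <- ((bad[1] - 1L) %/% nrow(mat)) + 1L
    stop_ob("illegal character '%s' in record '%s' at column %d",
            mat[bad[1]], rownames(mat)[r], co)
  }
  structure(list(fragment_id = fragment_id, matrix = mat),
            class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat(sprintf("<dna_alignment '%s': %d samples x %d columns>\n",
              x$fragment_id, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' @export
dim.dna_alignment <- function(x) dim(x$matrix)

#' @export
#' @method as.matrix dna_alignment
as.matrix.dna_alignment <- function(x, ...) x$matrix

aln_samples <- function(aln) rownames(aln$matrix)
aln_length <- function(aln) ncol(aln$matrix)

#' Read an aligned multi-FASTA file
#'
#' @param path path to an aligned multi-FASTA file.
#' @param fragment_id fragment identifier; defaults to the file name
#'   without extension.
#' @return a [dna_alignment].
#' @export
read_alignment <- function(path, fragment_id = NULL) {
  if (!file.exists(path)) stop_ob("no such file: %s", path)
  if (is.null(fragment_id))
    fragment_id <- sub("\\.[^.]*$", "", basename(path))
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop_ob("no records in %s", path)
  w <- Biostrings::width(ss)
  if (length(unique(w)) > 1L)
    stop_ob("alignment is ragged: record '%s' has length %d, expected %d",
            names(ss)[which(w != w[1])[1]], w[which(w != w[1])[1]], w[1])
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  dna_alignment(seqs, fragment_id = fragment_id)
}

#' Write an alignment as multi-FASTA
#'
#' @param aln a [dna_alignment].
#' @param path output path.
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(aln$matrix, 1, paste, collapse = "")
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Construct a genome record
#'
#' Holds one (possibly circular) organellar genome sequence with
#' features in 0-based half-open coordinates.
#'
#' @param seq_id sequence identifier.
#' @param sequence nucleotide string (upper-cased on construction).
#' @param circular logical; is the molecule circular?
#' @param features `data.frame` with columns `name`, `start`, `end`
#'   (0-based half-open), `strand` (`+`/`-`), `kind`.
#' @return an object of class `genome_record`.
#' @export
genome_record <- function(seq_id, sequence, circular = FALSE,
                          features = NULL) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (is.null(features))
    features <- data.frame(name = character(0), start = integer(0),
                           end = integer(0), strand = character(0),
                           kind = character(0))
  stopifnot(all(c("name", "start", "end", "strand", "kind") %in%
                  names(features)))
  if (nrow(features)) {
    if (any(features$start < 0 | features$end > L |
              features$start >= features$end))
      stop_ob("feature out of range on sequence '%s' (length %d)", seq_id, L)
  }
  structure(list(seq_id = seq_id, sequence = sequence, length = L,
                 circular = circular, features = features),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record '%s': %d bp, %s, %d features>\n", x$seq_id,
              x$length, if (x$circular) "circular" else "linear",
              nrow(x$features)))
  invisible(x)
}

KNOWN_FEATURE_KINDS <- c("gene", "CDS", "tRNA", "rRNA", "orf")

#' Read a genome sequence with its GFF3 annotation
#'
#' GFF3 coordinates (1-based inclusive) are converted to the internal
#' 0-based half-open convention.  On a circular genome a feature whose
#' GFF3 `end` exceeds the sequence length is taken to span the origin
#' and is stored split into two intervals sharing the feature name.
#'
#' @param fasta_path FASTA file with a single record.
#' @param gff3_path GFF3 annotation file; its seqid must match the
#'   FASTA header.
#' @param circular logical flag for circular molecules.
#' @return a [genome_record].
#' @export
read_genome <- function(fasta_path, gff3_path = NULL, circular = FALSE) {
  ss <- Biostrings::readDNAStringSet(fasta_path)
  if (length(ss) != 1L)
    stop_ob("expected exactly one record in %s, found %d", fasta_path,
            length(ss))
  seq_id <- sub("\\s.*$", "", names(ss)[1])
  sequence <- as.character(ss[[1]])
  L <- nchar(sequence)
  feats <- NULL
  if (!is.null(gff3_path)) {
    gr <- rtracklayer::import(gff3_path, format = "gff3")
    if (length(gr)) {
      seqids <- as.character(GenomicRanges::seqnames(gr))
      if (!all(seqids == seq_id))
        stop_ob("GFF3 seqid '%s' does not match FASTA header '%s'",
                setdiff(seqids, seq_id)[1], seq_id)
      nm <- as.character(gr$Name)
      if (all(is.na(nm)) || is.null(gr$Name)) nm <- as.character(gr$ID)
      nm[is.na(nm)] <- paste0("feature", which(is.na(nm)))
      kind <- as.character(gr$type)
      unknown <- !(kind %in% KNOWN_FEATURE_KINDS)
      if (any(unknown)) {
        warning(sprintf("unknown feature kind(s) %s kept as 'other'",
                        paste(unique(kind[unknown]), collapse = ", ")),
                call. = FALSE)
        kind[unknown] <- "other"
      }
      st0 <- GenomicRanges::start(gr) - 1L   # to 0-based half-open
      en0 <- GenomicRanges::end(gr)
      strand <- as.character(GenomicRanges::strand(gr))
      strand[!strand %in% c("+", "-")] <- "+"
      rows <- vector("list", length(gr))
      for (i in seq_along(gr)) {
        if (en0[i] > L) {
          if (!circular || st0[i] >= L)
            stop_ob("feature '%s' [%d,%d) out of range on '%s' (length %d)",
                    nm[i], st0[i], en0[i], seq_id, L)
          # split across the origin of a circular molecule
          rows[[i]] <- data.frame(
            name = nm[i], start = c(st0[i], 0L), end = c(L, en0[i] - L),
            strand = strand[i], kind = kind[i])
        } else {
          rows[[i]] <- data.frame(name = nm[i], start = st0[i], end = en0[i],
                                  strand = strand[i], kind = kind[i])
        }
      }
      feats <- do.call(rbind, rows)
    }
  }
  genome_record(seq_id, sequence, circular = circular, features = feats)
}

#' Read the sample sheet mapping samples to species and genera
#'
#' @param path TSV file with header columns `sample_id`, `species`,
#'   `genus` and optionally `subspecies`.
#' @return a `data.frame` (class `species_panel`).
#' @export
read_panel <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  species_panel(df)
}

#' Construct a species panel
#'
#' @param df data frame with columns `sample_id`, `species`, `genus`
#'   and optionally `subspecies`.
#' @export
species_panel <- function(df) {
  need <- c("sample_id", "species", "genus")
  if (!all(need %in% names(df)))
    stop_ob("panel must have columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop_ob("duplicate sample_id in panel: %s",
            df$sample_id[duplicated(df$sample_id)][1])
  # species -> genus must be a function
  sg <- unique(df[, c("species", "genus")])
  if (anyDuplicated(sg$species))
    stop_ob("species '%s' maps to more than one genus",
            sg$species[duplicated(sg$species)][1])
  if (!"subspecies" %in% names(df)) df$subspecies <- NA_character_
  class(df) <- c("species_panel", "data.frame")
  df
}

#' Read a Newick tree
#'
#' Internal node labels are interpreted as bootstrap supports in
#' percent when numeric.
#'
#' @param path Newick file (or a Newick string via `text`).
#' @param text optional Newick string; overrides `path`.
#' @return an [ape::phylo] tree.
#' @export
read_tree <- function(path = NULL, text = NULL) {
  tr <- if (!is.null(text)) ape::read.tree(text = text) else
    ape::read.tree(path)
  if (is.null(tr)) stop_ob("could not parse Newick input")
  if (anyDuplicated(tr$tip.label))
    stop_ob("duplicate leaf label: %s",
            tr$tip.label[duplicated(tr$tip.label)][1])
  if (!is.null(tr$node.label)) {
    sup <- suppressWarnings(as.numeric(tr$node.label))
    if (any(!is.na(sup) & (sup < 0 | sup > 100)))
      stop_ob("support values must lie in [0, 100]")
  }
  tr
}

#' Write a tree as Newick
#' @param tree an [ape::phylo] tree.
#' @param path output path; if `NULL` the Newick string is returned.
#' @export
write_tree <- function(tree, path = NULL) {
  s <- ape::write.tree(tree, digits = 12)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(path)
}

#' Concatenate per-fragment alignments
#'
#' @param alignments list of [dna_alignment] objects.
#' @param panel optional [species_panel]; if supplied, sample ids are
#'   checked against it.
#' @param missing_policy `"fill_gaps"` pads samples absent from a
#'   fragment with `-`; `"drop_sample"` keeps only samples present in
#'   every fragment.
#' @return list with elements `alignment` (the concatenated
#'   [dna_alignment]) and `partition_map` (data frame `fragment_id`,
#'   `start`, `end` with 0-based half-open column intervals).
#' @export
concat_alignments <- function(alignments, panel = NULL,
                              missing_policy = c("fill_gaps",
                                                 "drop_sample")) {
  missing_policy <- match.arg(missing_policy)
  if (length(alignments) == 0L) stop_ob("no alignments to concatenate")
  ids <- lapply(alignments, aln_samples)
  universe <- Reduce(union, ids)
  if (!is.null(panel)) {
    unknown <- setdiff(universe, panel$sample_id)
    if (length(unknown))
      stop_ob("sample '%s' not in panel", unknown[1])
  }
  if (missing_policy == "drop_sample")
    universe <- Reduce(intersect, ids)
  if (length(universe) == 0L) stop_ob("no samples survive drop_sample")
  lens <- vapply(alignments, aln_length, integer(1))
  starts <- cumsum(c(0L, lens[-length(lens)]))
  pm <- data.frame(
    fragment_id = vapply(alignments, function(a) a$fragment_id,
                         character(1)),
    start = starts, end = starts + lens, row.names = NULL)
  big <- matrix("-", nrow = length(universe), ncol = sum(lens),
                dimnames = list(universe, NULL))
  for (i in seq_along(alignments)) {
    a <- alignments[[i]]
    keep <- intersect(universe, aln_samples(a))
    big[keep, (pm$start[i] + 1L):pm$end[i]] <- a$matrix[keep, , drop = FALSE]
  }
  list(alignment = dna_alignment(big, fragment_id = "concatenated"),
       partition_map = pm)
}

#' Write intervals as BED
#'
#' @param ints two-column matrix/data.frame of 0-based half-open
#'   intervals.
#' @param seq_id chromosome/sequence name.
#' @param path output path.
#' @export
write_bed <- function(ints, seq_id, path) {
  ints <- as.matrix(ints)
  df <- data.frame(chrom = seq_id,
                   start = as.integer(ints[, 1]),
                   end = as.integer(ints[, 2]))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file as an interval matrix
#' @param path BED path.
#' @return matrix with columns `start`, `end` (0-based half-open).
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  cbind(start = as.integer(df[[2]]), end = as.integer(df[[3]]))
}
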