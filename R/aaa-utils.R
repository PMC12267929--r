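# Shared internal helpers: IUPAC tables, interval algebra, small utilities.

# IUPAC nucleotide alphabet (upper case) plus the alignment gap.
IUPAC_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-")

# code -> set of unambiguous bases it may represent (gap maps to none)
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"), `-` = character(0)
)

BASES <- c("A", "C", "G", "T")

is_base <- function(x) x %in% BASES

#' @noRd
stop_ob <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Merge half-open intervals
#'
#' Sorts and merges a two-column matrix of 0-based half-open intervals.
#' @noRd
merge_intervals <- function(ints) {
  ints <- as.matrix(ints)
  if (nrow(ints) == 0L) return(matrix(numeric(0), ncol = 2))
  ir <- IRanges::reduce(IRanges::IRanges(start = ints[, 1] + 1L, end = ints[, 2]))
  cbind(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

#' Complement of intervals within [0, L)
#' @noRd
complement_intervals <- function(ints, L) {
  m <- merge_intervals(ints)
  if (nrow(m) == 0L) return(cbind(start = 0L, end = L))
  ir <- IRanges::IRanges(start = m[, 1] + 1L, end = m[, 2])
  gp <- IRanges::gaps(ir, start = 1L, end = L)
  out <- cbind(start = IRanges::start(gp) - 1L, end = IRanges::end(gp))
  out[out[, 2] > out[, 1], , drop = FALSE]
}

#' Reverse complement of a plain character string (IUPAC-aware)
#' @noRd
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# integer encoding A=1 C=2 G=3 T=4, anything else 0 (never matches a seed)
encode_dna <- function(chars) {
  code <- match(chars, BASES)
  code[is.na(code)] <- 0L
  code
}

decode_dna <- function(ints) {
  out <- rep("N", length(ints))
  ok <- ints >= 1L & ints <= 4L
  out[ok] <- BASES[ints[ok]]
  out
}

#' Split a string into single characters
#' @noRd
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Stable md5 hash of an R object (used for config hashes)
#' @noRd
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  # serialize version 2 for cross-version stability
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}
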