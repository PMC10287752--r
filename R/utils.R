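#' @useDynLib editaudit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# IUPAC nucleotide codes as base sets; used for PAM pattern matching.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# bitmask encoding A=1, C=2, G=4, T=8 for the C++ core
.iupac_mask <- function(code) {
  bases <- IUPAC_SETS[[toupper(code)]]
  if (is.null(bases)) stop("invalid IUPAC code: ", code, call. = FALSE)
  sum(c(A = 1L, C = 2L, G = 4L, T = 8L)[bases])
}

.base_index <- c(A = 0L, C = 1L, G = 2L, T = 3L)

#' Reverse complement of a DNA string
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA strings (A/C/G/T/N and IUPAC codes).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.assert_dna <- function(x, what = "sequence", allow_empty = FALSE) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single character string", call. = FALSE)
  if (!allow_empty && nchar(x) == 0L)
    stop(what, " must be non-empty", call. = FALSE)
  if (grepl("[^ACGT]", x))
    stop(what, " contains non-ACGT characters", call. = FALSE)
  invisible(x)
}

# Per-stage filter logging: every filter step reports counts in/out.
.log_counts <- function(stage, n_in, n_out, verbose = getOption("editaudit.verbose", TRUE)) {
  if (isTRUE(verbose))
    message(sprintf("[%s] %d -> %d records", stage, n_in, n_out))
  invisible(NULL)
}

# Coordinate convention crossing points (the only places 0- and 1-based mix):
# VCF positions are 1-based; BED-like intervals are 0-based half-open.
bed_to_pos1 <- function(start0) start0 + 1L
pos1_to_bed <- function(pos1) pos1 - 1L

# position 1-based `pos` falls in 0-based half-open [start, end)?
.in_interval0 <- function(pos, start0, end0) {
  p0 <- pos1_to_bed(pos)
  p0 >= start0 & p0 < end0
}
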