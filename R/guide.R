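#' Define a guide RNA for homology and editing analyses
#'
#' Bundles the 20-nt protospacer, its 3' PAM pattern (IUPAC), the seed
#' definition and the position-numbering frame used by every guide-relative
#' computation: protospacer bases are numbered 1..20 (5' to 3'), the PAM
#' occupies positions 21..23, and bases upstream of position 1 carry
#' negative indices (-1 is immediately 5' of position 1; there is no 0).
#'
#' @param protospacer 20-nt DNA string, 5' to 3'.
#' @param pam_pattern IUPAC pattern immediately 3' of the protospacer,
#'   e.g. "NGG" (SpCas9) or "NRN" (SpRY).
#' @param seed_length number of PAM-proximal protospacer bases treated as
#'   the seed region (default 12), i.e. positions
#'   `(20 - seed_length + 1)..20`.
#' @return object of class `guide_spec`.
#' @examples
#' gs <- guide_spec("GACTGACTGACTGACTGACT", "NRN")
#' @export
guide_spec <- function(protospacer, pam_pattern = "NRN", seed_length = 12L) {
  .assert_dna(protospacer, "protospacer")
  if (nchar(protospacer) != 20L)
    stop("protospacer must be exactly 20 nt", call. = FALSE)
  if (!is.character(pam_pattern) || length(pam_pattern) != 1L ||
      nchar(pam_pattern) < 1L)
    stop("pam_pattern must be a non-empty string", call. = FALSE)
  pam_pattern <- toupper(pam_pattern)
  if (!all(strsplit(pam_pattern, "")[[1]] %in% names(IUPAC_SETS)))
    stop("pam_pattern contains a non-IUPAC code", call. = FALSE)
  seed_length <- as.integer(seed_length)
  if (is.na(seed_length) || seed_length < 1L || seed_length > 20L)
    stop("seed_length must be in 1..20", call. = FALSE)
  structure(
    list(protospacer = toupper(protospacer),
         pam_pattern = pam_pattern,
         seed_length = seed_length),
    class = "guide_spec"
  )
}

#' @export
print.guide_spec <- function(x, ...) {
  cat("guide_spec\n")
  cat("  protospacer:", x$protospacer, "(positions 1-20)\n")
  cat("  PAM:         ", x$pam_pattern, " (positions 21-",
      20L + nchar(x$pam_pattern), ")\n", sep = "")
  cat("  seed:        positions ", 21L - x$seed_length, "-20\n", sep = "")
  invisible(x)
}

# protospacer positions belonging to the seed (PAM-proximal)
.seed_positions <- function(guide) {
  seq.int(20L - guide$seed_length + 1L, 20L)
}

#' Does a base match an IUPAC code?
#'
#' @param base single A/C/G/T character (vectorized).
#' @param code single IUPAC code character (vectorized).
#' @return logical vector.
#' @export
iupac_match <- function(base, code) {
  mapply(function(b, cd) {
    set <- IUPAC_SETS[[toupper(cd)]]
    if (is.null(set)) stop("invalid IUPAC code: ", cd, call. = FALSE)
    toupper(b) %in% set
  }, base, code, USE.NAMES = FALSE)
}
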