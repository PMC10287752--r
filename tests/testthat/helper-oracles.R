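# Independent oracles used to cross-check the implementation. Each one is
# a deliberately different route to the same quantity: enumeration where
# the implementation uses algebra, loops where it uses matrix ops.

options(editaudit.verbose = FALSE)

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# --- variant normalization: exhaustive enumeration of equivalent
# representations. A representation (p, r, a) is equivalent iff replacing
# r by a in the contig yields the same haplotype; the normalized form is
# the smallest-position representation whose alleles do not share a
# trailing base nor (beyond the indel anchor) a leading base.
oracle_normalize <- function(chrom, pos, ref, alt, reference) {
  contig <- reference[[chrom]]
  hap <- paste0(substr(contig, 1L, pos - 1L), alt,
                substr(contig, pos + nchar(ref), nchar(contig)))
  lo <- 1L
  hi <- min(nchar(contig), pos + 25L)
  best <- NULL
  for (p in lo:hi) {
    for (lr in 1:8) {
      if (p + lr - 1L > nchar(contig)) next
      r <- substr(contig, p, p + lr - 1L)
      suffix_len <- nchar(contig) - (p + lr - 1L)
      la <- nchar(hap) - suffix_len - (p - 1L)
      if (la < 1L) next
      a <- substr(hap, p, p + la - 1L)
      cand <- paste0(substr(contig, 1L, p - 1L), a,
                     substr(contig, p + lr, nchar(contig)))
      if (cand != hap) next
      if (substr(r, lr, lr) == substr(a, la, la)) next       # trailing shared
      if (lr > 1L && la > 1L &&
          substr(r, 1L, 1L) == substr(a, 1L, 1L)) next       # leading shared
      if (is.null(best) || p < best$pos)
        best <- list(chrom = chrom, pos = p, ref = r, alt = a)
    }
  }
  best
}

# --- guide homology: exhaustive DP over alignment moves (compiled oracle
# routine, algorithmically unrelated to the production scanner's
# gap-configuration enumeration)
oracle_min_edit <- function(window, guide, mode = "strict",
                            max_gap_len = 1L, max_gap_events = 2L) {
  pm <- vapply(strsplit(guide$pam_pattern, "")[[1]],
               editaudit:::.iupac_mask, integer(1))
  strict <- mode == "strict"
  d1 <- editaudit:::cpp_oracle_strand(toupper(window), guide$protospacer,
                                      pm, strict, max_gap_len,
                                      max_gap_events)
  d2 <- editaudit:::cpp_oracle_strand(revcomp(window), guide$protospacer,
                                      pm, strict, max_gap_len,
                                      max_gap_events)
  d <- c(d1, d2)
  d <- d[d >= 0]
  if (!length(d)) NA_integer_ else min(d)
}

# plant protospacer + instantiated PAM with k substitutions into a random
# background at a given 0-based offset; returns the window
plant_window <- function(guide, k, offset, total_len = 61L, strand = "+",
                         pam_bases = NULL) {
  proto <- strsplit(guide$protospacer, "")[[1]]
  if (k > 0L) {
    at <- sample(20L, k)
    for (j in at) proto[j] <- sample(setdiff(c("A", "C", "G", "T"),
                                             proto[j]), 1L)
  }
  if (is.null(pam_bases))
    pam_bases <- vapply(strsplit(guide$pam_pattern, "")[[1]], function(cd)
      sample(editaudit:::IUPAC_SETS[[cd]], 1L), character(1))
  cassette <- paste(c(proto, pam_bases), collapse = "")
  if (strand == "-") cassette <- revcomp(cassette)
  w <- rand_dna(total_len)
  substr(w, offset + 1L, offset + nchar(cassette)) <- cassette
  w
}

# --- splice classification: literal transcription of the published
# inequality block (unchanged band first, then the rescued clauses with
# their inclusive overshoot bounds, else mis-spliced)
oracle_classify_rescue <- function(o, e) {
  mapply(function(oo, ee) {
    if (abs(oo - ee) < 0.1) return("unchanged")
    rescued <-
      (oo > 0 && ((ee >= 0 && ee < oo) ||
                    (ee >= -0.2 && ee <= 0.2 && ee < oo))) ||
      (oo < 0 && ((ee <= 0 && ee > oo) ||
                    (ee >= -0.2 && ee <= 0.2 && ee > oo)))
    if (rescued) "rescued" else "mis-spliced"
  }, o, e, USE.NAMES = FALSE)
}

# mutually exclusive predicates for the partition property (no if/else
# precedence): each category as its own clause
rescue_predicates <- function(o, e) {
  unchanged <- abs(o - e) < 0.1
  rescued <- !unchanged &
    ((o > 0 & e >= -0.2 & e < o) | (o < 0 & e <= 0.2 & e > o))
  mis <- !unchanged &
    ((o > 0 & ((e >= 0 & e > o) | e < -0.2)) |
       (o < 0 & ((e <= 0 & e < o) | e > 0.2)))
  cbind(unchanged = unchanged, rescued = rescued, `mis-spliced` = mis)
}

# --- activity score: plain-loop mean of per-gene min-max rescaling
oracle_score_cells <- function(expression, gene_set) {
  x <- expression[gene_set, , drop = FALSE]
  out <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    vals <- numeric(0)
    for (g in seq_len(nrow(x))) {
      mn <- min(x[g, ]); mx <- max(x[g, ])
      if (mx > mn) vals <- c(vals, (x[g, j] - mn) / (mx - mn))
    }
    out[j] <- mean(vals)
  }
  names(out) <- colnames(x)
  out
}

# random variant-call table for round-trip properties
random_calls <- function(n, caller = "X") {
  pos <- sort(sample.int(10000L, n))
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b),
                                        1L), character(1))
  rd <- sample(c(NA, 0:60), n, replace = TRUE)
  ad <- ifelse(is.na(rd), NA, sample(0:40, n, replace = TRUE))
  af <- ifelse(!is.na(rd) & (rd + ad) > 0, ad / (rd + ad),
               ifelse(is.na(rd), sample(c(NA, 0.25), n, replace = TRUE),
                      NA))
  variant_calls(caller, "chr1", pos, ref, alt, rd, ad, af)
}
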