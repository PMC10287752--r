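#' Left-align and trim variant representations
#'
#' Re-implementation of the standard VCF normalization used to reconcile
#' call sets from different callers: shared trailing bases are trimmed
#' (extending left over the reference when an allele would become empty,
#' which shifts indels to their leftmost equivalent position), then shared
#' leading bases are trimmed while both alleles keep at least one base.
#' SNVs are fixed points; the operation is idempotent.
#'
#' @param calls `variant_calls` data.frame (or any data.frame with chrom,
#'   pos, ref, alt columns).
#' @param reference named character vector of contig sequences.
#' @return the input with pos/ref/alt replaced by the normalized
#'   representation.
#' @export
normalize_variants <- function(calls, reference) {
  stopifnot(is.data.frame(calls))
  if (!nrow(calls)) return(calls)
  for (i in seq_len(nrow(calls))) {
    nv <- .normalize_one(calls$chrom[i], calls$pos[i],
                         calls$ref[i], calls$alt[i], reference)
    calls$pos[i] <- nv$pos
    calls$ref[i] <- nv$ref
    calls$alt[i] <- nv$alt
  }
  calls
}

#' @rdname normalize_variants
#' @param chrom,pos,ref,alt a single variant.
#' @export
normalize_variant <- function(chrom, pos, ref, alt, reference) {
  .normalize_one(chrom, pos, ref, alt, reference)
}

.normalize_one <- function(chrom, pos, ref, alt, reference) {
  if (!chrom %in% names(reference))
    stop("contig not in reference: ", chrom, call. = FALSE)
  contig <- reference[[chrom]]
  pos <- as.integer(pos)
  if (substr(contig, pos, pos + nchar(ref) - 1L) != ref)
    stop("REF does not match reference at ", chrom, ":", pos, call. = FALSE)
  # trim shared trailing bases; left-extend when an allele would empty out
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    if (nr >= 1L && na >= 1L &&
        substr(ref, nr, nr) == substr(alt, na, na) &&
        (nr > 1L || na > 1L)) {
      if (nr == 1L || na == 1L) {
        if (pos == 1L)
          stop("cannot left-extend past contig start at ", chrom, ":1",
               call. = FALSE)
        pos <- pos - 1L
        b <- substr(contig, pos, pos)
        ref <- paste0(b, substr(ref, 1L, nr - 1L))
        alt <- paste0(b, substr(alt, 1L, na - 1L))
      } else {
        ref <- substr(ref, 1L, nr - 1L)
        alt <- substr(alt, 1L, na - 1L)
      }
    } else break
  }
  # trim shared leading bases (keep the 1-base indel anchor)
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(chrom = chrom, pos = pos, ref = ref, alt = alt)
}
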