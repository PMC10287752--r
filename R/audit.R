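#' Merge per-caller, per-tissue call sets into consensus variants
#'
#' Builds one consensus record per normalized variant key (chrom, pos, ref,
#' alt). Per tissue, the supporting callers are those reporting the key
#' with alternate-allele evidence (alt depth > 0 or AF > 0, or a bare call
#' without depth information), and depths/AF are taken from the
#' highest-priority caller that measured them — emulating the convention of
#' preferring one caller's allelic depths and falling back to the next.
#' Cohort-mode callers may report a key in a tissue with zero alternate
#' reads; such records contribute measured depths (AF = 0) without counting
#' as support.
#'
#' @param callsets nested list: `callsets[[tissue]][[caller]]` is a
#'   `variant_calls` data.frame of normalized calls.
#' @param priority ordered character vector of caller ids (highest first);
#'   every caller appearing in `callsets` must be listed.
#' @return `consensus_variants` data.frame: key columns plus, per tissue
#'   `T`, columns `callers_T`, `ref_depth_T`, `alt_depth_T`, `depth_T`,
#'   `af_T` (NA = unmeasured). Tissue order is kept in
#'   `attr(, "tissues")`.
#' @export
merge_callers <- function(callsets, priority) {
  tissues <- names(callsets)
  stopifnot(length(tissues) >= 1L, !is.null(tissues))
  seen <- unique(unlist(lapply(callsets, names)))
  unknown <- setdiff(seen, priority)
  if (length(unknown))
    stop("caller id(s) not in priority order: ",
         paste(unknown, collapse = ", "), call. = FALSE)

  # flatten to one long table
  long <- list()
  for (ti in tissues) {
    for (ca in names(callsets[[ti]])) {
      df <- callsets[[ti]][[ca]]
      if (!nrow(df)) next
      df$tissue <- ti
      df$caller_id <- ca
      long[[length(long) + 1L]] <- df
    }
  }
  if (!length(long)) {
    out <- .empty_consensus(tissues)
    return(out)
  }
  long <- do.call(rbind, long)
  long$key <- paste(long$chrom, long$pos, long$ref, long$alt, sep = ":")
  keys <- unique(long$key)
  idx <- split(seq_len(nrow(long)), long$key)[keys]

  n <- length(keys)
  first <- long[match(keys, long$key), c("chrom", "pos", "ref", "alt")]
  out <- data.frame(chrom = first$chrom, pos = first$pos, ref = first$ref,
                    alt = first$alt, key = keys, stringsAsFactors = FALSE)
  prio_rank <- stats::setNames(seq_along(priority), priority)
  for (ti in tissues) {
    cal <- character(n); rd <- integer(n); ad <- integer(n); af <- numeric(n)
    rd[] <- NA_integer_; ad[] <- NA_integer_; af[] <- NA_real_
    for (k in seq_len(n)) {
      sub <- long[idx[[k]], , drop = FALSE]
      sub <- sub[sub$tissue == ti, , drop = FALSE]
      if (!nrow(sub)) { cal[k] <- ""; next }
      has_evidence <- (!is.na(sub$alt_depth) & sub$alt_depth > 0L) |
        (!is.na(sub$allele_frequency) & sub$allele_frequency > 0) |
        (is.na(sub$alt_depth) & is.na(sub$allele_frequency))
      cal[k] <- paste(sort(unique(sub$caller_id[has_evidence])),
                      collapse = ",")
      sub <- sub[order(prio_rank[sub$caller_id]), , drop = FALSE]
      measured <- which(!is.na(sub$ref_depth) & !is.na(sub$alt_depth))
      if (length(measured)) {
        j <- measured[1L]
        rd[k] <- sub$ref_depth[j]; ad[k] <- sub$alt_depth[j]
        af[k] <- if (!is.na(sub$allele_frequency[j]))
          sub$allele_frequency[j]
        else if (rd[k] + ad[k] > 0L) ad[k] / (rd[k] + ad[k]) else 0
      } else {
        with_af <- which(!is.na(sub$allele_frequency))
        if (length(with_af)) af[k] <- sub$allele_frequency[with_af[1L]]
      }
    }
    out[[paste0("callers_", ti)]] <- cal
    out[[paste0("ref_depth_", ti)]] <- rd
    out[[paste0("alt_depth_", ti)]] <- ad
    out[[paste0("depth_", ti)]] <- rd + ad
    out[[paste0("af_", ti)]] <- af
  }
  out <- out[order(out$chrom, out$pos, out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tissues") <- tissues
  class(out) <- unique(c("consensus_variants", class(out)))
  out
}

.empty_consensus <- function(tissues) {
  out <- data.frame(chrom = character(0), pos = integer(0),
                    ref = character(0), alt = character(0),
                    key = character(0), stringsAsFactors = FALSE)
  for (ti in tissues) {
    out[[paste0("callers_", ti)]] <- character(0)
    out[[paste0("ref_depth_", ti)]] <- integer(0)
    out[[paste0("alt_depth_", ti)]] <- integer(0)
    out[[paste0("depth_", ti)]] <- integer(0)
    out[[paste0("af_", ti)]] <- numeric(0)
  }
  attr(out, "tissues") <- tissues
  class(out) <- unique(c("consensus_variants", class(out)))
  out
}

.tissues_of <- function(variants) {
  ti <- attr(variants, "tissues")
  if (is.null(ti))
    ti <- sub("^callers_", "", grep("^callers_", names(variants), value = TRUE))
  ti
}

.n_callers <- function(variants, tissue) {
  cal <- variants[[paste0("callers_", tissue)]]
  vapply(strsplit(cal, ",", fixed = TRUE),
         function(v) sum(nzchar(v)), integer(1))
}

#' Apply the multi-caller confidence filters
#'
#' A variant is retained iff (1) it is supported by at least `min_callers`
#' callers in at least one tissue, (2) its total read depth is at least
#' `min_depth_per_tissue` in every tissue, and (3) it has at least
#' `min_alt_total` alternate-allele reads summed over all tissues. A tissue
#' with unmeasured depth fails rule (2) unless
#' `unmeasured_depth_passes = TRUE` (for mixtures of cohort- and
#' single-sample callers where no depth source covers an absent tissue).
#'
#' @param variants `consensus_variants` data.frame.
#' @param min_callers minimum supporting callers in the best tissue
#'   (default 2).
#' @param min_depth_per_tissue minimum total depth per tissue (default 5).
#' @param min_alt_total minimum alternate reads across tissues (default 2).
#' @param unmeasured_depth_passes treat unmeasured tissue depth as passing
#'   rule (2).
#' @return the retained subset (counts in/out are logged).
#' @export
apply_confidence_filters <- function(variants, min_callers = 2L,
                                     min_depth_per_tissue = 5L,
                                     min_alt_total = 2L,
                                     unmeasured_depth_passes = FALSE) {
  tissues <- .tissues_of(variants)
  n <- nrow(variants)
  if (!n) return(variants)
  ncal <- sapply(tissues, function(ti) .n_callers(variants, ti))
  if (is.null(dim(ncal))) ncal <- matrix(ncal, nrow = n)
  rule1 <- apply(ncal, 1L, max) >= min_callers
  depth <- sapply(tissues, function(ti) variants[[paste0("depth_", ti)]])
  if (is.null(dim(depth))) depth <- matrix(depth, nrow = n)
  dok <- depth >= min_depth_per_tissue
  if (unmeasured_depth_passes) dok[is.na(dok)] <- TRUE else dok[is.na(dok)] <- FALSE
  rule2 <- apply(dok, 1L, all)
  altm <- sapply(tissues, function(ti) variants[[paste0("alt_depth_", ti)]])
  if (is.null(dim(altm))) altm <- matrix(altm, nrow = n)
  rule3 <- rowSums(altm, na.rm = TRUE) >= min_alt_total
  keep <- rule1 & rule2 & rule3
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tissues") <- tissues
  .log_counts("confidence_filters", n, nrow(out))
  out
}

#' Partition variants into known and novel
#'
#' A variant is known iff its normalized key matches an entry of any
#' supplied known-variant set (e.g. dbSNP or a strain variation catalogue).
#'
#' @param variants `consensus_variants` data.frame.
#' @param known_sets list of data.frames with chrom, pos, ref, alt
#'   (normalized representation).
#' @return list with elements `novel` and `known`; both carry a logical
#'   `known` column. The partition is exhaustive and disjoint.
#' @export
exclude_known <- function(variants, known_sets) {
  tissues <- .tissues_of(variants)
  if (!length(known_sets)) {
    kk <- rep(FALSE, nrow(variants))
  } else {
    keys <- unlist(lapply(known_sets, function(df) {
      if (!nrow(df)) character(0)
      else paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
    }))
    kk <- variants$key %in% keys
  }
  variants$known <- kk
  novel <- variants[!kk, , drop = FALSE]
  known <- variants[kk, , drop = FALSE]
  rownames(novel) <- rownames(known) <- NULL
  attr(novel, "tissues") <- attr(known, "tissues") <- tissues
  .log_counts("exclude_known", nrow(variants), nrow(novel))
  list(novel = novel, known = known)
}

#' Classify variants as common, tissue-specific or other
#'
#' Common variants have AF > 0 in every tissue and are identified on the
#' quality-filtered set before known-variant exclusion. Tissue-specific
#' variants are drawn from the novel pool (`known == FALSE`): AF > 0 in the
#' tissue in question while every other tissue has AF = 0 or an unmeasured
#' AF. Everything else is labeled `other`.
#'
#' @param variants `consensus_variants` with a logical `known` column (see
#'   [exclude_known()]).
#' @param tissues tissue names; defaults to the merge order.
#' @return input with a `specificity` column
#'   (`common`, `tissue-specific:<tissue>`, or `other`).
#' @export
classify_tissue_specificity <- function(variants, tissues = NULL) {
  if (is.null(tissues)) tissues <- .tissues_of(variants)
  if (!"known" %in% names(variants))
    stop("run exclude_known() first: `known` column required", call. = FALSE)
  n <- nrow(variants)
  af <- if (n) sapply(tissues, function(ti) variants[[paste0("af_", ti)]])
        else matrix(numeric(0), nrow = 0L, ncol = length(tissues))
  if (is.null(dim(af))) af <- matrix(af, nrow = n)
  spec <- rep("other", n)
  if (n) {
    pos_af <- !is.na(af) & af > 0
    zero_or_unmeasured <- is.na(af) | af == 0
    common <- apply(pos_af, 1L, all)
    spec[common] <- "common"
    for (j in seq_along(tissues)) {
      only_t <- pos_af[, j] & apply(zero_or_unmeasured[, -j, drop = FALSE],
                                    1L, all)
      sel <- only_t & !common & !variants$known
      spec[sel] <- paste0("tissue-specific:", tissues[j])
    }
  }
  variants$specificity <- spec
  attr(variants, "tissues") <- tissues
  variants
}

# the twelve ordered substitutions and their strand-collapsed pairs
CONVERSIONS_12 <- c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T",
                    "G>A", "G>C", "G>T", "T>A", "T>C", "T>G")
CONVERSIONS_6 <- c("A>G/T>C", "A>C/T>G", "A>T/T>A",
                   "C>T/G>A", "C>G/G>C", "C>A/G>T")
.collapse_map <- c("A>G" = "A>G/T>C", "T>C" = "A>G/T>C",
                   "A>C" = "A>C/T>G", "T>G" = "A>C/T>G",
                   "A>T" = "A>T/T>A", "T>A" = "A>T/T>A",
                   "C>T" = "C>T/G>A", "G>A" = "C>T/G>A",
                   "C>G" = "C>G/G>C", "G>C" = "C>G/G>C",
                   "C>A" = "C>A/G>T", "G>T" = "C>A/G>T")

#' Nucleotide conversion spectrum of SNVs
#'
#' Counts the 12 ordered single-nucleotide substitutions and collapses
#' complementary pairs into the 6 strand-symmetric classes (A>G/T>C etc.).
#' Indels are not admitted.
#'
#' @param variants data.frame with ref and alt columns; all records must be
#'   SNVs (single-base ref and alt).
#' @return list of class `conversion_spectrum` with `counts_12`,
#'   `counts_6`, `total`, and relative frequencies `rel_6` (empty spectrum:
#'   all-zero counts, total 0, NA frequencies).
#' @export
conversion_spectrum <- function(variants) {
  if (nrow(variants) &&
      any(nchar(variants$ref) != 1L | nchar(variants$alt) != 1L))
    stop("conversion_spectrum accepts SNVs only", call. = FALSE)
  conv <- if (nrow(variants)) paste0(variants$ref, ">", variants$alt)
          else character(0)
  c12 <- table(factor(conv, levels = CONVERSIONS_12))
  c12 <- stats::setNames(as.integer(c12), CONVERSIONS_12)
  c6 <- vapply(CONVERSIONS_6, function(cl)
    sum(c12[names(.collapse_map)[.collapse_map == cl]]), integer(1))
  total <- sum(c12)
  structure(list(counts_12 = c12, counts_6 = c6, total = total,
                 rel_6 = if (total > 0) c6 / total
                         else stats::setNames(rep(NA_real_, 6L),
                                              CONVERSIONS_6)),
            class = "conversion_spectrum")
}

#' Annotate variants with a genomic region class
#'
#' Assigns `exonic`, `UTR5`, `UTR3`, `intronic` or `other` by interval
#' overlap (precedence exonic > UTR5/UTR3 > intronic when intervals
#' overlap). Intervals are 0-based half-open; variant positions 1-based.
#' In RNA mode, variants falling in no annotated region are dropped,
#' mirroring the transcriptome-variant filter that keeps only exonic,
#' intronic, and UTR variants.
#'
#' @param variants `consensus_variants` data.frame.
#' @param annotation `region_annotation` data.frame.
#' @param rna_mode drop variants labeled `other`.
#' @return input with a `region_class` column (filtered in RNA mode).
#' @export
annotate_region <- function(variants, annotation, rna_mode = FALSE) {
  tissues <- .tissues_of(variants)
  prec <- c(exonic = 1L, UTR5 = 2L, UTR3 = 2L, intronic = 3L)
  n <- nrow(variants)
  cls <- rep("other", n)
  for (i in seq_len(n)) {
    hit <- annotation$chrom == variants$chrom[i] &
      .in_interval0(variants$pos[i], annotation$start, annotation$end)
    if (any(hit)) {
      classes <- annotation$class[hit]
      cls[i] <- classes[order(prec[classes])][1L]
    }
  }
  variants$region_class <- cls
  if (rna_mode) {
    keep <- cls != "other"
    out <- variants[keep, , drop = FALSE]
    rownames(out) <- NULL
    .log_counts("annotate_region[rna]", n, nrow(out))
    attr(out, "tissues") <- tissues
    return(out)
  }
  attr(variants, "tissues") <- tissues
  variants
}
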