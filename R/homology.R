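#' Extract the flanking window around a variant start site
#'
#' Returns the reference subsequence `[pos - flank, pos + flank]`, clipped
#' to the contig bounds; a full-length window has `2 * flank + 1` bases.
#'
#' @param reference named character vector of contig sequences.
#' @param chrom contig name.
#' @param pos 1-based variant start position (must lie on the contig).
#' @param flank bases to each side (default 30).
#' @return list with `seq`, `chrom`, `start`, `end` (1-based inclusive).
#' @export
extract_window <- function(reference, chrom, pos, flank = 30L) {
  if (!chrom %in% names(reference))
    stop("contig not in reference: ", chrom, call. = FALSE)
  contig <- reference[[chrom]]
  len <- nchar(contig)
  pos <- as.integer(pos)
  if (pos < 1L || pos > len)
    stop("position ", pos, " outside contig ", chrom, " (length ", len, ")",
         call. = FALSE)
  start <- max(1L, pos - flank)
  end <- min(len, pos + flank)
  list(seq = substr(contig, start, end), chrom = chrom,
       start = start, end = end)
}

#' Minimum constrained edit distance of a guide to a window
#'
#' Searches both strands and every placement of the protospacer + PAM
#' within the window for the best constrained alignment: substitutions are
#' allowed (and counted) anywhere in the protospacer; gap events are
#' limited to `max_gap_len` bases each with at most `max_gap_events` per
#' alignment; the PAM is aligned gaplessly under IUPAC semantics. In
#' `strict` mode a placement whose PAM carries any mismatch is
#' inadmissible; in `lenient` mode PAM mismatches are added to the
#' distance. The reported edit distance equals mismatches + gapped bases,
#' minimized over all admissible (strand, offset, alignment) triples; ties
#' are broken by fewest gaps, then smallest offset, then the + strand.
#' Edits falling in the PAM-proximal seed region are reported as a
#' sub-count, and `forbid_seed_gaps` disallows gap events (but not
#' substitutions) inside the seed.
#'
#' @param window DNA string (A/C/G/T), e.g. from [extract_window()].
#' @param guide [guide_spec()] object.
#' @param mode `"strict"` (default) or `"lenient"` PAM handling.
#' @param max_gap_len maximum bases per gap event (default 1).
#' @param max_gap_events maximum gap events per alignment (default 2).
#' @param forbid_seed_gaps disallow gap events inside the seed region.
#' @return list of class `homology_result` with `edit_distance`,
#'   `mismatches`, `gaps`, `seed_edits`, `best_strand`, `best_offset`
#'   (0-based start, in forward window coordinates, of the region the
#'   protospacer aligns to), `pam_offset`, `alignment` (paired gapped
#'   strings, protospacer then PAM positions marked `.`), `mode` and
#'   `alignable`. When no placement is admissible, `alignable` is FALSE
#'   and the distance is NA.
#' @export
min_edit_distance <- function(window, guide, mode = c("strict", "lenient"),
                              max_gap_len = 1L, max_gap_events = 2L,
                              forbid_seed_gaps = FALSE) {
  mode <- match.arg(mode)
  .assert_dna(window, "window")
  stopifnot(inherits(guide, "guide_spec"))
  window <- toupper(window)
  lp <- nchar(guide$pam_pattern)
  if (nchar(window) < lp)
    stop("window shorter than the PAM pattern", call. = FALSE)
  pam_mask <- vapply(strsplit(guide$pam_pattern, "")[[1]], .iupac_mask,
                     integer(1))
  seed_start <- 20L - guide$seed_length + 1L
  strict <- mode == "strict"
  n <- nchar(window)

  res_fwd <- cpp_scan_strand(window, guide$protospacer, pam_mask, strict,
                             as.integer(max_gap_len),
                             as.integer(max_gap_events),
                             isTRUE(forbid_seed_gaps), seed_start)
  res_rev <- cpp_scan_strand(revcomp(window), guide$protospacer, pam_mask,
                             strict, as.integer(max_gap_len),
                             as.integer(max_gap_events),
                             isTRUE(forbid_seed_gaps), seed_start)

  pack <- function(res, strand) {
    if (!isTRUE(res$valid)) return(NULL)
    offset <- if (strand == "+") res$proto_start else n - res$pam_start
    pam_offset <- if (strand == "+") res$pam_start
                  else n - res$pam_start - lp
    list(strand = strand, offset = offset, pam_offset = pam_offset,
         dist = res$dist, mismatches = res$mismatches, gaps = res$gaps,
         seed_edits = res$seed_edits,
         alignment = c(pattern = res$aln_pattern, window = res$aln_window))
  }
  cand <- Filter(Negate(is.null),
                 list(pack(res_fwd, "+"), pack(res_rev, "-")))
  if (!length(cand)) {
    return(structure(list(window = window, alignable = FALSE,
                          edit_distance = NA_integer_,
                          mismatches = NA_integer_, gaps = NA_integer_,
                          seed_edits = NA_integer_,
                          best_strand = NA_character_,
                          best_offset = NA_integer_,
                          pam_offset = NA_integer_,
                          alignment = NULL, mode = mode),
                     class = "homology_result"))
  }
  rank <- vapply(cand, function(x)
    x$dist * 1e9 + x$gaps * 1e6 + x$offset * 1e2 +
      (if (x$strand == "+") 0 else 1), numeric(1))
  best <- cand[[which.min(rank)]]
  structure(list(window = window, alignable = TRUE,
                 edit_distance = best$dist, mismatches = best$mismatches,
                 gaps = best$gaps, seed_edits = best$seed_edits,
                 best_strand = best$strand, best_offset = best$offset,
                 pam_offset = best$pam_offset, alignment = best$alignment,
                 mode = mode),
            class = "homology_result")
}

#' @export
print.homology_result <- function(x, ...) {
  cat("homology_result (mode ", x$mode, ")\n", sep = "")
  if (!x$alignable) {
    cat("  not alignable\n")
    return(invisible(x))
  }
  cat("  edit distance:", x$edit_distance,
      sprintf("(%d mismatches + %d gap bases; %d in seed)",
              x$mismatches, x$gaps, x$seed_edits), "\n")
  cat("  strand ", x$best_strand, ", protospacer offset ", x$best_offset,
      "\n", sep = "")
  cat("  ", x$alignment[["pattern"]], "\n  ", x$alignment[["window"]], "\n",
      sep = "")
  invisible(x)
}

#' Scan variant flanking windows for guide homology
#'
#' Applies [extract_window()] + [min_edit_distance()] to every variant of
#' an audited table.
#'
#' @param variants data.frame with chrom and pos columns (and optionally
#'   key).
#' @param reference named character vector of contig sequences.
#' @param guide [guide_spec()] object.
#' @param flank window half-width (default 30).
#' @param ... passed to [min_edit_distance()].
#' @return data.frame with one row per variant: key, window span, strand,
#'   offset, edit_distance, mismatches, gaps, seed_edits, alignable.
#' @export
scan_variant_homology <- function(variants, reference, guide, flank = 30L,
                                  ...) {
  n <- nrow(variants)
  out <- data.frame(
    key = if ("key" %in% names(variants)) variants$key
          else paste(variants$chrom, variants$pos, sep = ":"),
    chrom = variants$chrom, pos = variants$pos,
    window_start = integer(n), window_end = integer(n),
    strand = character(n), offset = integer(n),
    edit_distance = integer(n), mismatches = integer(n),
    gaps = integer(n), seed_edits = integer(n), alignable = logical(n),
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    w <- extract_window(reference, variants$chrom[i], variants$pos[i], flank)
    r <- min_edit_distance(w$seq, guide, ...)
    out$window_start[i] <- w$start
    out$window_end[i] <- w$end
    out$strand[i] <- if (r$alignable) r$best_strand else NA_character_
    out$offset[i] <- if (r$alignable) r$best_offset else NA_integer_
    out$edit_distance[i] <- r$edit_distance
    out$mismatches[i] <- r$mismatches
    out$gaps[i] <- r$gaps
    out$seed_edits[i] <- r$seed_edits
    out$alignable[i] <- r$alignable
  }
  out
}

#' Per-group summary of guide edit distances
#'
#' Mean, standard error of the mean and the full distance distribution per
#' group (e.g. tissue-specific vs. common variants). Empty groups are
#' flagged with a warning and omitted from the summary.
#'
#' @param results data.frame with an `edit_distance` column, e.g. from
#'   [scan_variant_homology()].
#' @param groups group label per row.
#' @return list with `summary` (group, n, mean, se) and `distribution`
#'   (group, edit_distance, count).
#' @export
summarize_mismatch_profile <- function(results, groups) {
  stopifnot(nrow(results) == length(groups))
  d <- results$edit_distance
  groups <- as.character(groups)
  lv <- unique(groups)
  rows <- list(); dist_rows <- list()
  for (g in lv) {
    x <- d[groups == g & !is.na(d)]
    if (!length(x)) {
      warning("group '", g, "' is empty; omitted from summary",
              call. = FALSE)
      next
    }
    rows[[g]] <- data.frame(
      group = g, n = length(x), mean = mean(x),
      se = if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0,
      stringsAsFactors = FALSE)
    tb <- table(x)
    dist_rows[[g]] <- data.frame(group = g,
                                 edit_distance = as.integer(names(tb)),
                                 count = as.integer(tb),
                                 stringsAsFactors = FALSE)
  }
  list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       distribution = do.call(rbind, c(dist_rows,
                                       list(make.row.names = FALSE))))
}
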