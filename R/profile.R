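#' Guide-frame position labels for an amplicon window
#'
#' Labels every window position in the guide numbering frame: protospacer
#' bases 1..20 (5' to 3'), PAM at 21..23, upstream bases negative (-1 is
#' immediately 5' of position 1; there is no 0), downstream of the PAM
#' continuing 24, 25, ... Labels are rendered `<refbase>_<index>` using
#' the guide-strand reference base.
#'
#' @param window amplicon window sequence. For a guide on the minus
#'   genomic strand, pass the window already oriented to the guide (the
#'   genomic-strand conversion belongs at I/O).
#' @param guide [guide_spec()] object.
#' @param proto_offset 0-based offset of the protospacer start within
#'   `window`.
#' @return data.frame with window_pos (1-based), guide_index, region
#'   (upstream/protospacer/PAM/downstream) and label.
#' @export
label_positions <- function(window, guide, proto_offset) {
  .assert_dna(window, "window")
  L <- nchar(window)
  lp <- nchar(guide$pam_pattern)
  proto_offset <- as.integer(proto_offset)
  if (is.na(proto_offset) || proto_offset < 0L ||
      proto_offset + 20L + lp > L)
    stop("guide not placeable in window at offset ", proto_offset,
         call. = FALSE)
  p <- seq_len(L)
  idx <- p - proto_offset
  idx[idx <= 0L] <- idx[idx <= 0L] - 1L  # no position 0
  region <- ifelse(idx < 0L, "upstream",
                   ifelse(idx <= 20L, "protospacer",
                          ifelse(idx <= 20L + lp, "PAM", "downstream")))
  bases <- strsplit(window, "")[[1]]
  data.frame(window_pos = p, guide_index = idx, region = region,
             label = paste0(bases, "_", idx), stringsAsFactors = FALSE)
}

# guide-frame index -> 1-based window position
.guide_index_to_window <- function(idx, proto_offset) {
  ifelse(idx >= 1L, proto_offset + idx, proto_offset + idx + 1L)
}

#' Per-position base counts and fractions from aligned amplicon reads
#'
#' Reads are pre-aligned to the window (equal length, `-` marking a
#' deleted base). Replicates are summed before fractions are taken; per
#' position, the fraction of each base is its count divided by the reads
#' covering that position.
#'
#' @param reads character vector of aligned reads, or a list of such
#'   vectors (one per replicate).
#' @param window reference window sequence (defines the expected read
#'   length).
#' @param guide,proto_offset optional; when supplied, guide-frame labels
#'   are attached (see [label_positions()]).
#' @return list of class `editing_pileup` with `counts` (5 x L matrix over
#'   A/C/G/T/del), `fractions`, `n_reads`, `window`, and `labels`.
#' @export
pileup_and_fractions <- function(reads, window, guide = NULL,
                                 proto_offset = NULL) {
  if (is.list(reads)) reads <- unlist(reads, use.names = FALSE)
  if (!length(reads)) stop("empty read set", call. = FALSE)
  L <- nchar(window)
  if (any(nchar(reads) != L))
    stop("read length inconsistent with window and no alignment given",
         call. = FALSE)
  mat <- do.call(rbind, strsplit(reads, ""))
  lev <- c("A", "C", "G", "T", "-")
  counts <- apply(mat, 2L, function(col) table(factor(col, levels = lev)))
  rownames(counts) <- c("A", "C", "G", "T", "del")
  covering <- colSums(counts)
  fractions <- sweep(counts, 2L, pmax(covering, 1L), "/")
  labels <- if (!is.null(guide) && !is.null(proto_offset))
    label_positions(window, guide, proto_offset) else NULL
  structure(list(counts = counts, fractions = fractions,
                 n_reads = length(reads), window = toupper(window),
                 labels = labels),
            class = "editing_pileup")
}

#' Fraction of reads that are exactly wild type
#'
#' The "repaired" metric: the fraction of reads whose sequence over the
#' quantification span is exactly the wild-type (post-repair) sequence.
#' Reads carrying any bystander edit, residual mutation, sequencing
#' mismatch or indel within the span are excluded from the numerator.
#'
#' @param reads character vector of aligned reads.
#' @param wt_window wild-type sequence over the window.
#' @param span optional integer vector `c(first, last)` of 1-based window
#'   positions to compare; defaults to the full window.
#' @return fraction in [0, 1].
#' @export
repaired_fraction <- function(reads, wt_window, span = NULL) {
  if (!length(reads)) return(NA_real_)
  if (is.null(span)) span <- c(1L, nchar(wt_window))
  a <- span[1L]; b <- span[2L]
  mean(substr(reads, a, b) == substr(wt_window, a, b))
}

#' Codon consequence of a substitution
#'
#' Standard genetic code translation of reference and alternative codons;
#' classification by amino-acid comparison.
#'
#' @param ref_codon,alt_codon 3-mers over A/C/G/T.
#' @return list with ref_aa, alt_aa and consequence
#'   (synonymous/missense/nonsense).
#' @export
codon_consequence <- function(ref_codon, alt_codon) {
  stopifnot(nchar(ref_codon) == 3L, nchar(alt_codon) == 3L)
  gc <- Biostrings::GENETIC_CODE
  ref_aa <- unname(gc[[toupper(ref_codon)]])
  alt_aa <- unname(gc[[toupper(alt_codon)]])
  if (is.null(ref_aa) || is.null(alt_aa))
    stop("invalid codon", call. = FALSE)
  consequence <- if (ref_aa == alt_aa) "synonymous"
                 else if (alt_aa == "*") "nonsense"
                 else "missense"
  list(ref_aa = ref_aa, alt_aa = alt_aa, consequence = consequence)
}

#' Bystander frequency conditional on the on-target edit
#'
#' Partitions reads by their on-target state and reports each bystander
#' position's edit frequency within each partition — the readout behind
#' the observation that bystander edits may occur only on reads that have
#' also received the correct edit.
#'
#' @param reads character vector of aligned reads.
#' @param target_pos 1-based window position of the on-target edit.
#' @param bystander_pos integer vector of 1-based window positions.
#' @param edit_to base installed by the editor (default "G").
#' @return data.frame with position, freq_repaired, freq_unrepaired
#'   (NA when a partition is empty, never 0), n_repaired, n_unrepaired.
#' @export
conditional_bystander <- function(reads, target_pos, bystander_pos,
                                  edit_to = "G") {
  L <- nchar(reads[1L])
  if (any(c(target_pos, bystander_pos) < 1L |
          c(target_pos, bystander_pos) > L))
    stop("position outside window", call. = FALSE)
  at <- function(p) substr(reads, p, p)
  repaired <- at(target_pos) == edit_to
  freq_in <- function(p, sel) {
    if (!sum(sel)) return(NA_real_)
    mean(at(p)[sel] == edit_to)
  }
  data.frame(
    position = bystander_pos,
    freq_repaired = vapply(bystander_pos, freq_in, numeric(1),
                           sel = repaired),
    freq_unrepaired = vapply(bystander_pos, freq_in, numeric(1),
                             sel = !repaired),
    n_repaired = sum(repaired), n_unrepaired = sum(!repaired))
}

#' Summarize editing outcomes over an amplicon window
#'
#' Computes the repaired fraction (exact wild-type reads), on-target edit
#' fraction, indel fraction, a bystander table in guide-frame labels with
#' codon consequences where a coding frame is supplied, and the
#' bystander-conditional-on-repair table.
#'
#' @param reads character vector of aligned reads.
#' @param window unedited (mutant) window sequence.
#' @param wt_window wild-type (post-repair) window sequence.
#' @param guide [guide_spec()] object.
#' @param proto_offset 0-based protospacer offset within the window.
#' @param target_position guide-frame index of the on-target edit.
#' @param edit_from,edit_to the conversion installed by the editor
#'   (default A to G).
#' @param span quantification span for the repaired metric (default full
#'   window).
#' @param codon_frame optional list(start = 1-based window position of a
#'   codon start in phase with the reading frame). Bystander consequences
#'   are computed against the wild-type sequence.
#' @param min_fraction report bystander positions with edit fraction above
#'   this floor (default 0, i.e. any observed edit).
#' @return list of class `editing_summary`.
#' @export
editing_summary <- function(reads, window, wt_window, guide, proto_offset,
                            target_position, edit_from = "A",
                            edit_to = "G", span = NULL, codon_frame = NULL,
                            min_fraction = 0) {
  if (!length(reads)) stop("empty read set", call. = FALSE)
  labels <- label_positions(window, guide, proto_offset)
  target_wp <- .guide_index_to_window(target_position, proto_offset)
  if (substr(window, target_wp, target_wp) != edit_from)
    stop("window does not carry '", edit_from, "' at the target position",
         call. = FALSE)
  at <- function(p) substr(reads, p, p)
  indel <- grepl("-", reads, fixed = TRUE)
  rep_frac <- repaired_fraction(reads, wt_window, span)
  on_target <- mean(at(target_wp) == edit_to)

  # candidate bystander positions: editable bases in the guide frame,
  # outside the PAM (positions 21..23) and excluding the target itself
  wbases <- strsplit(window, "")[[1]]
  cand <- which(wbases == edit_from & labels$region != "PAM" &
                  seq_along(wbases) != target_wp)
  byst <- lapply(cand, function(p) {
    f <- mean(at(p) == edit_to)
    if (f <= min_fraction) return(NULL)
    cons <- NA_character_; ref_aa <- NA_character_; alt_aa <- NA_character_
    if (!is.null(codon_frame)) {
      ph <- (p - codon_frame$start) %% 3L
      cs <- p - ph
      if (cs >= 1L && cs + 2L <= nchar(wt_window)) {
        ref_codon <- substr(wt_window, cs, cs + 2L)
        alt_codon <- ref_codon
        substr(alt_codon, ph + 1L, ph + 1L) <- edit_to
        cc <- codon_consequence(ref_codon, alt_codon)
        cons <- cc$consequence; ref_aa <- cc$ref_aa; alt_aa <- cc$alt_aa
      }
    }
    data.frame(label = labels$label[p], guide_index = labels$guide_index[p],
               window_pos = p, fraction = f, consequence = cons,
               ref_aa = ref_aa, alt_aa = alt_aa, stringsAsFactors = FALSE)
  })
  byst <- do.call(rbind, byst[!vapply(byst, is.null, logical(1))])
  cond <- conditional_bystander(reads, target_wp, cand, edit_to = edit_to)
  cond$label <- labels$label[cond$position]
  structure(list(repaired_fraction = rep_frac,
                 on_target_fraction = on_target,
                 indel_fraction = mean(indel),
                 bystander_table = byst,
                 conditional_bystander = cond,
                 n_reads = length(reads)),
            class = "editing_summary")
}

#' @export
print.editing_summary <- function(x, ...) {
  cat("editing_summary over", x$n_reads, "reads\n")
  cat(sprintf("  repaired (exact wild type): %.2f%%\n",
              100 * x$repaired_fraction))
  cat(sprintf("  on-target edited:           %.2f%%\n",
              100 * x$on_target_fraction))
  cat(sprintf("  indels:                     %.2f%%\n",
              100 * x$indel_fraction))
  if (!is.null(x$bystander_table) && nrow(x$bystander_table)) {
    cat("  bystanders:\n")
    for (i in seq_len(nrow(x$bystander_table)))
      cat(sprintf("    %s  %.2f%%  %s\n", x$bystander_table$label[i],
                  100 * x$bystander_table$fraction[i],
                  ifelse(is.na(x$bystander_table$consequence[i]), "",
                         x$bystander_table$consequence[i])))
  }
  invisible(x)
}
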