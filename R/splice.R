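#' Delta-PSI records from paired splicing comparisons
#'
#' Matches events across the (original vs WT) and (edited vs WT) rMATS
#' comparisons and computes group-mean PSI values and deltas relative to
#' wild type. Group means use the available (non-missing) replicates,
#' minimum one; events with all-missing WT PSI are excluded with a
#' warning. The sign convention is group mean minus WT mean, so a positive
#' delta means higher inclusion than wild type.
#'
#' @param original [read_rmats_jc()] table for the untreated-mutant vs WT
#'   comparison (group1 = mutant, group2 = WT).
#' @param edited optional matching table for the edited vs WT comparison.
#' @return data.frame with event_id, gene, event_type, fdr (from the
#'   original comparison), psi_wt, psi_original, psi_edited,
#'   delta_psi_original, delta_psi_edited, delta_delta_psi.
#' @export
compute_deltas <- function(original, edited = NULL) {
  mean_na <- function(col) vapply(col, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else mean(v)
  }, numeric(1))
  psi_orig <- mean_na(original$psi_group1)
  psi_wt <- mean_na(original$psi_group2)
  out <- data.frame(event_id = original$event_id, gene = original$gene,
                    event_type = original$event_type, fdr = original$fdr,
                    psi_wt = psi_wt, psi_original = psi_orig,
                    stringsAsFactors = FALSE)
  bad <- is.na(out$psi_wt)
  if (any(bad)) {
    warning(sum(bad), " event(s) excluded: no wild-type PSI", call. = FALSE)
    out <- out[!bad, , drop = FALSE]
  }
  out$psi_edited <- NA_real_
  if (!is.null(edited)) {
    j <- match(out$event_id, edited$event_id)
    pe <- mean_na(edited$psi_group1)
    out$psi_edited <- pe[j]
  }
  out$delta_psi_original <- out$psi_original - out$psi_wt
  out$delta_psi_edited <- out$psi_edited - out$psi_wt
  out$delta_delta_psi <- abs(out$delta_psi_original - out$delta_psi_edited)
  rownames(out) <- NULL
  out
}

#' Significance gate for splicing events
#'
#' An event is significant iff its FDR (consumed from the upstream caller,
#' never recomputed) is below `fdr_max` and the absolute delta PSI of the
#' original comparison exceeds `min_abs_delta`. Both comparisons are
#' strict, matching "FDR below 0.01" and "higher than 0.1 or smaller than
#' -0.1".
#'
#' @param records data.frame from [compute_deltas()].
#' @param fdr_max FDR ceiling (default 0.01).
#' @param min_abs_delta minimum |delta PSI| vs WT (default 0.1).
#' @return input with a logical `significant` column.
#' @export
significance_gate <- function(records, fdr_max = 0.01, min_abs_delta = 0.1) {
  records$significant <- !is.na(records$fdr) & records$fdr < fdr_max &
    !is.na(records$delta_psi_original) &
    abs(records$delta_psi_original) > min_abs_delta
  .log_counts("significance_gate", nrow(records), sum(records$significant))
  records
}

#' Classify a significant event as rescued, mis-spliced or unchanged
#'
#' With o = delta PSI of the untreated mutant and e = delta PSI of the
#' edited mutant (both relative to WT): the event is `unchanged` when
#' |o - e| < `unchanged_band`; otherwise, for o > 0 it is `rescued` iff
#' -`overshoot_band` <= e < o (the edited value moved toward WT, at most
#' overshooting to -0.2) and `mis-spliced` otherwise (moved further from
#' WT, or overshot beyond -0.2); symmetric for o < 0. The three categories
#' partition every significant event with |o| > `unchanged_band`.
#'
#' @param o,e numeric vectors of deltas (vectorized).
#' @param unchanged_band half-width of the unchanged band on |o - e|
#'   (default 0.1).
#' @param overshoot_band tolerated overshoot past WT (default 0.2).
#' @return character vector of categories (NA where e is missing).
#' @export
classify_rescue <- function(o, e, unchanged_band = 0.1,
                            overshoot_band = 0.2) {
  n <- max(length(o), length(e))
  o <- rep_len(o, n); e <- rep_len(e, n)
  out <- rep(NA_character_, n)
  known <- !is.na(o) & !is.na(e)
  if (any(!known & !is.na(o)))
    warning("missing edited delta: category unset for ",
            sum(!known & !is.na(o)), " event(s)", call. = FALSE)
  dd <- abs(o - e)
  unchanged <- known & dd < unchanged_band
  pos_rescued <- known & !unchanged & o > 0 & e >= -overshoot_band & e < o
  neg_rescued <- known & !unchanged & o < 0 & e <= overshoot_band & e > o
  out[unchanged] <- "unchanged"
  out[pos_rescued | neg_rescued] <- "rescued"
  out[known & !unchanged & !(pos_rescued | neg_rescued)] <- "mis-spliced"
  out
}

#' Classify all events of a paired comparison
#'
#' Runs the significance gate and the rescue classifier; non-significant
#' events are labeled `not-significant`.
#'
#' @param records data.frame from [compute_deltas()].
#' @param fdr_max,min_abs_delta see [significance_gate()].
#' @param unchanged_band,overshoot_band see [classify_rescue()].
#' @return input with `significant` and `category` columns.
#' @export
classify_events <- function(records, fdr_max = 0.01, min_abs_delta = 0.1,
                            unchanged_band = 0.1, overshoot_band = 0.2) {
  records <- significance_gate(records, fdr_max, min_abs_delta)
  records$category <- "not-significant"
  sig <- records$significant
  records$category[sig] <- classify_rescue(
    records$delta_psi_original[sig], records$delta_psi_edited[sig],
    unchanged_band, overshoot_band)
  records
}

#' Events significant in every comparison
#'
#' Intersects two or more labeled event sets on event identity, retaining
#' each comparison's delta. Multiple events per gene are preserved.
#'
#' @param ... two or more data.frames with event_id, significant and
#'   delta_psi_original columns (named arguments name the comparisons).
#' @return data.frame of events significant in all comparisons with one
#'   delta column per comparison.
#' @export
intersect_events <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]]) &&
      !is.data.frame(sets[[1L]])) sets <- sets[[1L]]
  if (length(sets) < 2L)
    stop("need at least two comparisons", call. = FALSE)
  nm <- names(sets)
  if (is.null(nm) || any(!nzchar(nm)))
    nm <- paste0("comparison", seq_along(sets))
  sig_ids <- lapply(sets, function(s) s$event_id[s$significant])
  common <- Reduce(intersect, sig_ids)
  out <- data.frame(event_id = common, stringsAsFactors = FALSE)
  first <- sets[[1L]]
  j <- match(common, first$event_id)
  for (col in intersect(c("gene", "event_type"), names(first)))
    out[[col]] <- first[[col]][j]
  for (i in seq_along(sets)) {
    ji <- match(common, sets[[i]]$event_id)
    out[[paste0("delta_", nm[i])]] <- sets[[i]]$delta_psi_original[ji]
  }
  out
}
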