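# All generators run under an isolated RNG scope: the caller's RNG state is
# left untouched and a fixed seed gives byte-identical output.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a reference with planted guide-homologous sites
#'
#' Generates uniform-random contigs and embeds, at each requested locus,
#' the protospacer + PAM carrying exactly the requested number of
#' protospacer substitutions; the PAM is instantiated to (and kept
#' matching) its IUPAC pattern. On the minus strand the reverse complement
#' of the cassette is embedded. Planted windows must not overlap.
#'
#' @param seed integer seed; the same seed reproduces the reference
#'   byte-for-byte.
#' @param contig_lengths named integer vector of contig lengths.
#' @param guide [guide_spec()] object.
#' @param plant_requests data.frame with columns contig, position (1-based
#'   start of the embedded cassette), strand (`+`/`-`) and edit_distance
#'   (0..6 protospacer substitutions).
#' @return list with `reference` (named character vector) and `truth`
#'   (list recording the seed and a `planted_sites` data.frame).
#' @export
make_reference <- function(seed, contig_lengths, guide,
                           plant_requests = NULL) {
  stopifnot(inherits(guide, "guide_spec"))
  .with_seed(seed, {
    reference <- vapply(contig_lengths, .random_dna, character(1))
    names(reference) <- names(contig_lengths)
    cassette_len <- 20L + nchar(guide$pam_pattern)
    planted <- NULL
    if (!is.null(plant_requests) && nrow(plant_requests)) {
      pr <- plant_requests
      if (any(pr$edit_distance < 0L | pr$edit_distance > 6L))
        stop("requested edit distance must be in 0..6", call. = FALSE)
      ends <- pr$position + cassette_len - 1L
      if (any(pr$position < 1L |
              ends > contig_lengths[pr$contig]))
        stop("planted window outside contig bounds", call. = FALSE)
      for (ct in unique(pr$contig)) {
        sub <- pr[pr$contig == ct, , drop = FALSE]
        o <- order(sub$position)
        if (any(sub$position[o][-1L] <=
                (sub$position[o] + cassette_len - 1L)[-nrow(sub)]))
          stop("planted windows overlap on contig ", ct, call. = FALSE)
      }
      for (i in seq_len(nrow(pr))) {
        pam <- vapply(strsplit(guide$pam_pattern, "")[[1]], function(cd)
          sample(IUPAC_SETS[[cd]], 1L), character(1))
        proto <- strsplit(guide$protospacer, "")[[1]]
        k <- pr$edit_distance[i]
        if (k > 0L) {
          at <- sample.int(20L, k)
          for (j in at)
            proto[j] <- sample(setdiff(c("A", "C", "G", "T"), proto[j]), 1L)
        }
        cassette <- paste(c(proto, pam), collapse = "")
        if (pr$strand[i] == "-") cassette <- revcomp(cassette)
        ct <- pr$contig[i]; p0 <- pr$position[i]
        substr(reference[[ct]], p0, p0 + cassette_len - 1L) <- cassette
      }
      planted <- pr
    }
    list(reference = reference,
         truth = list(seed = as.integer(seed),
                      contig_lengths = contig_lengths,
                      planted_sites = planted))
  })
}

#' Simulate ground-truth variants over a reference
#'
#' Plants germline (all tissues, also exported as the known-variant set),
#' common (all tissues, novel) and tissue-specific SNVs with substitution
#' classes drawn from a configurable strand-collapsed 6-class spectrum.
#'
#' @param reference named character vector of contigs.
#' @param tissues tissue names.
#' @param n_germline,n_common counts of germline / common variants.
#' @param n_specific named integer vector: tissue-specific variants per
#'   tissue.
#' @param spectrum named probabilities over the 6 collapsed conversion
#'   classes (default uniform).
#' @param af_range allele-frequency range of somatic (common and
#'   tissue-specific) variants.
#' @param seed integer seed.
#' @return data.frame of truth variants: chrom, pos, ref, alt, class
#'   (germline/common/specific:<tissue>), conversion, collapsed, and one
#'   `af_<tissue>` column per tissue.
#' @export
simulate_variant_truth <- function(reference, tissues, n_germline = 100L,
                                   n_common = 50L,
                                   n_specific = c(heart = 50L),
                                   spectrum = NULL,
                                   af_range = c(0.2, 0.5), seed = 1L) {
  if (is.null(spectrum))
    spectrum <- stats::setNames(rep(1 / 6, 6L), CONVERSIONS_6)
  stopifnot(setequal(names(spectrum), CONVERSIONS_6))
  spectrum <- spectrum[CONVERSIONS_6] / sum(spectrum)
  .with_seed(seed, {
    chars <- lapply(reference, function(s) strsplit(s, "")[[1]])
    lens <- vapply(chars, length, integer(1))
    classes <- c(rep("germline", n_germline), rep("common", n_common),
                 unlist(lapply(names(n_specific), function(ti)
                   rep(paste0("specific:", ti), n_specific[[ti]]))))
    n <- length(classes)
    used <- new.env(hash = TRUE)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      cl6 <- sample(CONVERSIONS_6, 1L, prob = spectrum)
      members <- names(.collapse_map)[.collapse_map == cl6]
      conv <- sample(members, 1L)
      from <- substr(conv, 1L, 1L); to <- substr(conv, 3L, 3L)
      repeat {
        ct <- sample(names(reference), 1L,
                     prob = lens / sum(lens))
        p <- sample.int(lens[[ct]], 1L)
        key <- paste0(ct, ":", p)
        if (chars[[ct]][p] == from &&
            !exists(key, envir = used, inherits = FALSE)) {
          assign(key, TRUE, envir = used)
          break
        }
      }
      af <- stats::setNames(rep(0, length(tissues)), tissues)
      if (classes[i] == "germline") {
        af[] <- sample(c(0.5, 1), 1L)
      } else if (classes[i] == "common") {
        af[] <- stats::runif(1L, af_range[1L], af_range[2L])
      } else {
        ti <- sub("^specific:", "", classes[i])
        af[ti] <- stats::runif(1L, af_range[1L], af_range[2L])
      }
      rows[[i]] <- data.frame(chrom = ct, pos = p, ref = from, alt = to,
                              class = classes[i], conversion = conv,
                              collapsed = cl6, t(af),
                              stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    names(out)[seq.int(ncol(out) - length(tissues) + 1L, ncol(out))] <-
      paste0("af_", tissues)
    out$key <- paste(out$chrom, out$pos, out$ref, out$alt, sep = ":")
    rownames(out) <- NULL
    out
  })
}

#' Default caller panels for simulated call sets
#'
#' Cohort-mode callers record allelic depths in every tissue (even where
#' the variant is absent, giving a measured AF of 0); single-sample
#' callers only report tissues where they detect the variant.
#'
#' @param which `"wgs"` (MU/HC cohort + LF single-sample) or `"rna"`
#'   (PL/HC cohort + ST single-sample).
#' @param sensitivity per-caller detection probability.
#' @param fp_per_mb false-positive calls per megabase per tissue.
#' @return data.frame with id, sensitivity, fp_per_mb, mode.
#' @export
caller_panel <- function(which = c("wgs", "rna"), sensitivity = 0.95,
                         fp_per_mb = 2) {
  which <- match.arg(which)
  ids <- if (which == "wgs") c("MU", "HC", "LF") else c("PL", "HC", "ST")
  data.frame(id = ids, sensitivity = sensitivity, fp_per_mb = fp_per_mb,
             mode = c("cohort", "cohort", "single"),
             stringsAsFactors = FALSE)
}

#' Simulate per-caller, per-tissue variant call sets
#'
#' Each true variant is detected by a caller with probability equal to the
#' caller's sensitivity (per variant for cohort-mode callers, per variant
#' and tissue for single-sample callers). Per tissue, read depth is
#' Poisson(`depth_mean`) and alternate reads Binomial(depth, true AF);
#' false positives are placed uniformly at the caller's per-megabase rate
#' with Beta(1, 20) allele frequencies. Germline variants are emitted in
#' all tissues and returned as the known-variant set.
#'
#' @param reference named character vector of contigs.
#' @param truth data.frame from [simulate_variant_truth()].
#' @param callers data.frame from [caller_panel()].
#' @param tissues tissue names (default: from the truth AF columns).
#' @param depth_mean mean sequencing depth.
#' @param seed integer seed.
#' @return list with `callsets` (nested `[[tissue]][[caller]]`
#'   `variant_calls`), `known` (data.frame of germline variant keys) and
#'   `truth`.
#' @export
simulate_caller_vcfs <- function(reference, truth, callers = caller_panel(),
                                 tissues = NULL, depth_mean = 40L,
                                 seed = 1L) {
  if (is.null(tissues))
    tissues <- sub("^af_", "", grep("^af_", names(truth), value = TRUE))
  stopifnot(all(callers$sensitivity >= 0 & callers$sensitivity <= 1))
  genome_mb <- sum(nchar(reference)) / 1e6
  .with_seed(seed, {
    callsets <- stats::setNames(vector("list", length(tissues)), tissues)
    for (ti in tissues) callsets[[ti]] <-
      stats::setNames(vector("list", nrow(callers)), callers$id)
    for (ci in seq_len(nrow(callers))) {
      ca <- callers$id[ci]
      sens <- callers$sensitivity[ci]
      cohort <- callers$mode[ci] == "cohort"
      detected_cohort <- stats::runif(nrow(truth)) < sens
      for (ti in tissues) {
        af_true <- truth[[paste0("af_", ti)]]
        keep <- if (cohort) detected_cohort
                else (af_true > 0) & (stats::runif(nrow(truth)) < sens)
        sub <- truth[keep, , drop = FALSE]
        af_sub <- af_true[keep]
        depth <- stats::rpois(nrow(sub), depth_mean)
        alt <- stats::rbinom(nrow(sub), depth, af_sub)
        rd <- depth - alt
        af_obs <- ifelse(depth > 0, alt / depth, NA_real_)
        # single-sample callers only report sites with alternate evidence
        if (!cohort) {
          ok <- alt > 0L
          sub <- sub[ok, , drop = FALSE]
          alt <- alt[ok]; rd <- rd[ok]; af_obs <- af_obs[ok]
        }
        calls <- if (nrow(sub))
          variant_calls(ca, sub$chrom, sub$pos, sub$ref, sub$alt,
                        rd, alt, af_obs)
        else .empty_variant_calls()
        # false positives: uniform placement, low-AF noise
        n_fp <- stats::rpois(1L, callers$fp_per_mb[ci] * genome_mb)
        if (n_fp > 0L) {
          ct <- sample(names(reference), n_fp, replace = TRUE,
                       prob = nchar(reference) / sum(nchar(reference)))
          p <- vapply(ct, function(cc)
            sample.int(nchar(reference[[cc]]), 1L), integer(1))
          refb <- substr(reference[ct], p, p)
          altb <- vapply(refb, function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
          fp_af <- stats::rbeta(n_fp, 1, 20)
          fdep <- stats::rpois(n_fp, depth_mean)
          falt <- pmax(1L, stats::rbinom(n_fp, fdep, fp_af))
          fp <- variant_calls(ca, ct, p, refb, altb,
                              pmax(fdep - falt, 0L), falt,
                              falt / pmax(fdep, falt))
          calls <- rbind(calls, fp)
        }
        callsets[[ti]][[ca]] <- calls
      }
    }
    known <- truth[truth$class == "germline",
                   c("chrom", "pos", "ref", "alt", "key"), drop = FALSE]
    list(callsets = callsets, known = known, truth = truth)
  })
}

#' Simulate amplicon reads over an editing window
#'
#' Draws reads from a mixture of repaired, unrepaired and 1-bp-deletion
#' (indel) reads. The on-target repair converts the mutant base at
#' `target_position` (guide frame) from `edit_from` to `edit_to`.
#' Bystander edits are applied per position at the given per-read
#' fractions — on repaired reads only when `conditional_on_repair` — and a
#' substitution-only sequencing error is overlaid. The latent per-read
#' classes are returned as truth.
#'
#' @param n_reads number of reads.
#' @param window mutant (pre-repair) window sequence; must carry
#'   `edit_from` at the target and at every bystander position.
#' @param guide [guide_spec()] object.
#' @param proto_offset 0-based protospacer offset within the window.
#' @param repair_fraction probability a read is repaired at the target.
#' @param bystander_spec named numeric: guide-frame position -> per-read
#'   bystander fraction.
#' @param conditional_on_repair restrict bystanders to repaired reads.
#' @param indel_fraction probability of a 1-bp deletion read
#'   (`repair_fraction + indel_fraction` must be at most 1).
#' @param error_rate per-base substitution error probability.
#' @param target_position guide-frame index of the on-target edit
#'   (default 6).
#' @param edit_from,edit_to conversion installed by the editor.
#' @param seed integer seed.
#' @return list with `reads`, `window`, `wt_window`, `proto_offset`,
#'   `target_position` and `truth` (parameters plus latent read classes).
#' @export
simulate_amplicon_reads <- function(n_reads, window, guide, proto_offset,
                                    repair_fraction,
                                    bystander_spec = numeric(0),
                                    conditional_on_repair = TRUE,
                                    indel_fraction = 0,
                                    error_rate = 0,
                                    target_position = 6L,
                                    edit_from = "A", edit_to = "G",
                                    seed = 1L) {
  .assert_dna(window, "window")
  stopifnot(repair_fraction >= 0, indel_fraction >= 0,
            repair_fraction + indel_fraction <= 1)
  L <- nchar(window)
  labels <- label_positions(window, guide, proto_offset)
  target_wp <- .guide_index_to_window(as.integer(target_position),
                                      proto_offset)
  byst_idx <- as.integer(names(bystander_spec))
  byst_wp <- .guide_index_to_window(byst_idx, proto_offset)
  if (any(c(target_wp, byst_wp) < 1L | c(target_wp, byst_wp) > L))
    stop("target/bystander position outside window", call. = FALSE)
  wbases <- strsplit(window, "")[[1]]
  if (any(wbases[c(target_wp, byst_wp)] != edit_from))
    stop("window must carry '", edit_from,
         "' at the target and bystander positions", call. = FALSE)
  wt_window <- window
  substr(wt_window, target_wp, target_wp) <- edit_to

  .with_seed(seed, {
    u <- stats::runif(n_reads)
    repaired <- u < repair_fraction
    indel <- u >= 1 - indel_fraction
    mat <- matrix(rep(wbases, each = n_reads), nrow = n_reads)
    mat[repaired, target_wp] <- edit_to
    byst_flag <- matrix(FALSE, n_reads, length(byst_wp))
    for (j in seq_along(byst_wp)) {
      eligible <- if (conditional_on_repair) repaired else !indel
      hit <- eligible & (stats::runif(n_reads) < bystander_spec[[j]])
      mat[hit, byst_wp[j]] <- edit_to
      byst_flag[, j] <- hit
    }
    proto_span <- which(labels$region == "protospacer")
    del_pos <- sample(proto_span, n_reads, replace = TRUE)
    mat[cbind(which(indel), del_pos[indel])] <- "-"
    if (error_rate > 0) {
      err <- matrix(stats::runif(n_reads * L) < error_rate, n_reads, L)
      err[mat == "-"] <- FALSE
      idx <- which(err, arr.ind = TRUE)
      if (nrow(idx)) {
        cur <- mat[idx]
        mat[idx] <- vapply(cur, function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
      }
    }
    reads <- apply(mat, 1L, paste, collapse = "")
    list(reads = reads, window = window, wt_window = wt_window,
         proto_offset = as.integer(proto_offset),
         target_position = as.integer(target_position),
         truth = list(seed = as.integer(seed),
                      repair_fraction = repair_fraction,
                      bystander_spec = bystander_spec,
                      conditional_on_repair = conditional_on_repair,
                      indel_fraction = indel_fraction,
                      error_rate = error_rate,
                      latent = data.frame(repaired = repaired,
                                          indel = indel,
                                          byst_flag)))
  })
}

#' Simulate a splicing comparison pair with known rescue categories
#'
#' Draws, per event, delta-PSI values (relative to WT) for the untreated
#' and edited mutant so that the intended category is the one assigned by
#' the classifier's inequality set, with safety margins around every
#' decision boundary; replicate PSI values are jittered with mean-centered
#' noise so group means are exact and the category is preserved.
#'
#' @param n_events number of events.
#' @param category_mix named probabilities over
#'   rescued/mis-spliced/unchanged/not-significant (must sum to 1).
#' @param n_replicates replicates per group (default 3).
#' @param na_rate probability that one replicate PSI is missing.
#' @param seed integer seed.
#' @return list with `original` and `edited` (rMATS-JC style data.frames,
#'   group1 = mutant, group2 = WT) and `truth` (event_id, category, o, e,
#'   fdr).
#' @export
simulate_splice_table <- function(n_events,
                                  category_mix = c(rescued = 0.4,
                                                   `mis-spliced` = 0.2,
                                                   unchanged = 0.2,
                                                   `not-significant` = 0.2),
                                  n_replicates = 3L, na_rate = 0.05,
                                  seed = 1L) {
  stopifnot(abs(sum(category_mix) - 1) < 1e-8)
  .with_seed(seed, {
    cats <- sample(names(category_mix), n_events, replace = TRUE,
                   prob = category_mix)
    o <- numeric(n_events); e <- numeric(n_events); fdr <- numeric(n_events)
    for (i in seq_len(n_events)) {
      sgn <- sample(c(-1, 1), 1L)
      oo <- sgn * stats::runif(1L, 0.15, 0.45)
      fdr[i] <- stats::runif(1L, 1e-5, 0.005)
      ee <- switch(cats[i],
        rescued = if (oo > 0) stats::runif(1L, -0.18, oo - 0.12)
                  else stats::runif(1L, oo + 0.12, 0.18),
        `mis-spliced` = if (sample(c(TRUE, FALSE), 1L)) {
          if (oo > 0) stats::runif(1L, oo + 0.12, oo + 0.3)
          else stats::runif(1L, oo - 0.3, oo - 0.12)
        } else {
          if (oo > 0) stats::runif(1L, -0.35, -0.22)
          else stats::runif(1L, 0.22, 0.35)
        },
        unchanged = oo + stats::runif(1L, -0.08, 0.08),
        `not-significant` = {
          fdr[i] <- stats::runif(1L, 0.02, 0.5)
          oo + stats::runif(1L, -0.08, 0.08)
        })
      o[i] <- oo; e[i] <- ee
    }
    margin <- 0.04
    lo <- pmax(margin, margin - pmin(0, o, e))
    hi <- pmin(1 - margin, 1 - margin - pmax(0, o, e))
    psi_wt <- lo + stats::runif(n_events) * (hi - lo)
    jitter_reps <- function(mean_val) {
      k <- n_replicates
      keep <- rep(TRUE, k)
      if (k > 1L && stats::runif(1L) < na_rate)
        keep[sample.int(k, 1L)] <- FALSE
      z <- stats::runif(sum(keep), -0.015, 0.015)
      z <- z - mean(z)
      out <- rep(NA_real_, k)
      out[keep] <- pmin(1, pmax(0, mean_val + z))
      out
    }
    ids <- sprintf("EV%04d", seq_len(n_events))
    types <- sample(c("SE", "A5SS", "A3SS", "MXE", "RI"), n_events,
                    replace = TRUE)
    wt1 <- lapply(psi_wt, jitter_reps)
    wt2 <- lapply(psi_wt, jitter_reps)
    original <- data.frame(event_id = ids,
                           gene = sprintf("gene%04d", seq_len(n_events)),
                           event_type = types, fdr = fdr,
                           stringsAsFactors = FALSE)
    original$psi_group1 <- lapply(psi_wt + o, jitter_reps)
    original$psi_group2 <- wt1
    edited <- original[, c("event_id", "gene", "event_type")]
    edited$fdr <- stats::runif(n_events, 1e-5, 0.5)
    edited$psi_group1 <- lapply(psi_wt + e, jitter_reps)
    edited$psi_group2 <- wt2
    truth <- data.frame(event_id = ids, category = cats, o = o, e = e,
                        fdr = fdr, stringsAsFactors = FALSE)
    list(original = original, edited = edited, truth = truth)
  })
}

#' Simulate a two-condition expression matrix with known markers
#'
#' Gene baselines are uniform on [0.5, 3] (truth genes on [2, 3] so the
#' downshift stays positive); cell values are Gaussian around the baseline
#' (sd `noise_sd`), floored at 0. In the second (mutant) condition the
#' designated up genes are shifted by `+effect` and down genes by
#' `-effect`.
#'
#' @param n_cells_per_condition cells per condition.
#' @param n_genes total genes.
#' @param n_up,n_down truth up-/downregulated gene counts
#'   (`n_up + n_down <= n_genes`).
#' @param effect shift in expression units (2 standard deviations when
#'   `effect = 2 * noise_sd`).
#' @param noise_sd per-cell Gaussian noise sd (default 0.5).
#' @param conditions two condition labels, reference first.
#' @param cluster cluster label stamped on all cells.
#' @param seed integer seed.
#' @return list with `cells` ([cell_matrix()]) and `truth` (up/down gene
#'   lists, effect, noise_sd).
#' @export
simulate_expression_matrix <- function(n_cells_per_condition, n_genes,
                                       n_up, n_down, effect,
                                       noise_sd = 0.5,
                                       conditions = c("WT", "MUT"),
                                       cluster = "VCM", seed = 1L) {
  stopifnot(n_up + n_down <= n_genes, length(conditions) == 2L)
  .with_seed(seed, {
    genes <- sprintf("gene%04d", seq_len(n_genes))
    up <- genes[seq_len(n_up)]
    down <- genes[seq.int(n_up + 1L, length.out = n_down)]
    mu <- stats::runif(n_genes, 0.5, 3)
    mu[seq_len(n_up + n_down)] <- stats::runif(n_up + n_down, 2, 3)
    n_cells <- 2L * n_cells_per_condition
    cond <- rep(conditions, each = n_cells_per_condition)
    shift <- matrix(0, n_genes, n_cells)
    mut <- cond == conditions[2L]
    shift[match(up, genes), mut] <- effect
    shift[match(down, genes), mut] <- -effect
    x <- matrix(stats::rnorm(n_genes * n_cells, mean = mu, sd = noise_sd),
                n_genes, n_cells) + shift
    x <- pmax(x, 0)
    rownames(x) <- genes
    colnames(x) <- sprintf("cell%05d", seq_len(n_cells))
    meta <- data.frame(cell_id = colnames(x), condition = cond,
                       cluster = cluster, stringsAsFactors = FALSE)
    list(cells = cell_matrix(x, meta),
         truth = list(up = up, down = down, effect = effect,
                      noise_sd = noise_sd, seed = as.integer(seed)))
  })
}
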