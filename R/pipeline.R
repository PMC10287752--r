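#' Read a pipeline configuration file
#'
#' YAML with nested keys naming inputs and thresholds; every threshold has
#' the audit's standard default so a minimal config only names the inputs:
#' `vcfs: {tissue: {caller: path}}`, `reference:`, `known: [paths]`,
#' `annotation:` (RNA mode), `guide: {protospacer, pam_pattern,
#' seed_length}`, `caller_priority: [ids]`, `thresholds: {min_callers,
#' min_depth, min_alt}`, `flank`, `homology_mode`, `seed`.
#'
#' @param path YAML config path.
#' @return config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

.cfg_default <- function(config, key, default) {
  v <- config[[key]]
  if (is.null(v)) default else v
}

.read_known_set <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (startsWith(first, "##") || startsWith(first, "#CHROM")) {
    df <- read_vcf(path, "known")
    df[, c("chrom", "pos", "ref", "alt")]
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(df)))
    df[, c("chrom", "pos", "ref", "alt")]
  }
}

.input_checksums <- function(paths) {
  paths <- unlist(paths, use.names = TRUE)
  paths <- paths[!is.na(paths) & nzchar(paths)]
  as.list(tools::md5sum(paths))
}

#' Run the whole-genome off-target audit end to end
#'
#' Stages, in order: read + normalize each per-(caller, tissue) call set,
#' merge across callers, apply the confidence filters, exclude known
#' variants, classify tissue specificity, compute conversion spectra per
#' specificity group, and scan each novel SNV's flanking window for guide
#' homology. All intermediate tables are written to `out_dir` together
#' with a run manifest (config snapshot, input checksums, per-stage record
#' counts); re-running an identical configuration reproduces identical
#' outputs.
#'
#' @param config list (see [read_config()]) or a YAML path. Required
#'   fields: `vcfs` (tissue -> caller -> path), `reference`, `guide`.
#' @param out_dir output directory (created); default `config$out_dir`.
#' @return list with `variants` (audited table), `spectra`, `homology`,
#'   `homology_summary` and `manifest`, invisibly written to `out_dir`.
#' @export
run_wgs_audit <- function(config, out_dir = NULL) {
  .run_audit(config, out_dir, rna_mode = FALSE)
}

#' Run the transcriptome variant audit end to end
#'
#' As [run_wgs_audit()] with the RNA defaults: caller priority PL, HC, ST
#' and the region filter switched on — variants outside exons, introns and
#' UTRs are dropped. A region `annotation` is required in the config.
#'
#' @inheritParams run_wgs_audit
#' @export
run_rna_audit <- function(config, out_dir = NULL) {
  .run_audit(config, out_dir, rna_mode = TRUE)
}

.run_audit <- function(config, out_dir, rna_mode) {
  if (is.character(config)) config <- read_config(config)
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) stop("out_dir required (config or argument)",
                             call. = FALSE)
  for (field in c("vcfs", "reference", "guide"))
    if (is.null(config[[field]]))
      stop("configuration error: missing field '", field, "'",
           call. = FALSE)
  if (rna_mode && is.null(config$annotation))
    stop("configuration error: missing field 'annotation' (RNA mode)",
         call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  thr <- .cfg_default(config, "thresholds", list())
  min_callers <- if (is.null(thr$min_callers)) 2L else thr$min_callers
  min_depth <- if (is.null(thr$min_depth)) 5L else thr$min_depth
  min_alt <- if (is.null(thr$min_alt)) 2L else thr$min_alt
  priority <- .cfg_default(config, "caller_priority",
                           if (rna_mode) c("PL", "HC", "ST")
                           else c("MU", "HC", "LF"))
  flank <- .cfg_default(config, "flank", 30L)
  mode <- .cfg_default(config, "homology_mode", "strict")

  reference <- read_fasta(config$reference)
  gcfg <- config$guide
  guide <- guide_spec(gcfg$protospacer,
                      if (is.null(gcfg$pam_pattern)) "NRN"
                      else gcfg$pam_pattern,
                      if (is.null(gcfg$seed_length)) 12L
                      else gcfg$seed_length)

  counts <- list()
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  callsets <- stage("read+normalize", {
    lapply(config$vcfs, function(by_caller)
      lapply(by_caller, function(entry) {
        # entry: a path, or a ready-made variant_calls table
        calls <- if (is.character(entry)) read_vcf(entry, "tmp") else entry
        normalize_variants(calls, reference)
      }))
  })
  for (ti in names(callsets))
    for (ca in names(callsets[[ti]]))
      callsets[[ti]][[ca]]$caller_id <-
        rep_len(ca, nrow(callsets[[ti]][[ca]]))
  counts$calls_in <- sum(vapply(callsets, function(x)
    sum(vapply(x, nrow, integer(1))), integer(1)))

  merged <- stage("merge", merge_callers(callsets, priority))
  counts$merged <- nrow(merged)
  filtered <- stage("filter", apply_confidence_filters(
    merged, min_callers, min_depth, min_alt))
  counts$filtered <- nrow(filtered)

  known_sets <- stage("exclude-known", lapply(
    .cfg_default(config, "known", list()), .read_known_set))
  parts <- exclude_known(filtered, known_sets)
  counts$novel <- nrow(parts$novel)
  flagged <- rbind(parts$known, parts$novel)
  attr(flagged, "tissues") <- .tissues_of(filtered)

  labeled <- stage("classify", classify_tissue_specificity(flagged))
  if (!is.null(config$annotation)) {
    ann <- read_region_bed(config$annotation)
    labeled <- stage("annotate", annotate_region(labeled, ann, rna_mode))
  }
  counts$labeled <- nrow(labeled)

  snv <- labeled[nchar(labeled$ref) == 1L & nchar(labeled$alt) == 1L, ,
                 drop = FALSE]
  groups <- unique(labeled$specificity)
  spectra <- lapply(stats::setNames(groups, groups), function(g)
    conversion_spectrum(snv[snv$specificity == g, , drop = FALSE]))

  novel_snv <- snv[!snv$known, , drop = FALSE]
  homology <- stage("homology", scan_variant_homology(
    novel_snv, reference, guide, flank = flank, mode = mode))
  hom_summary <- if (nrow(homology))
    summarize_mismatch_profile(homology,
                               novel_snv$specificity)$summary
  else NULL

  manifest <- list(
    tool = paste0("editaudit ",
                  as.character(utils::packageVersion("editaudit"))),
    mode = if (rna_mode) "rna" else "wgs",
    config = config,
    input_checksums = .input_checksums(c(
      unlist(config$vcfs), config$reference,
      unlist(.cfg_default(config, "known", list())), config$annotation)),
    stage_counts = counts)

  ord <- order(labeled$chrom, labeled$pos, labeled$ref, labeled$alt)
  labeled <- labeled[ord, , drop = FALSE]
  utils::write.table(labeled, file.path(out_dir, "audited_variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  spec_tab <- do.call(rbind, lapply(names(spectra), function(g)
    data.frame(group = g, class = CONVERSIONS_6,
               count = unname(spectra[[g]]$counts_6),
               fraction = unname(spectra[[g]]$rel_6))))
  if (is.null(spec_tab))
    spec_tab <- data.frame(group = character(0), class = character(0),
                           count = integer(0), fraction = numeric(0))
  utils::write.table(spec_tab, file.path(out_dir, "conversion_spectra.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(homology, file.path(out_dir, "homology.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(hom_summary))
    utils::write.table(hom_summary,
                       file.path(out_dir, "homology_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(variants = labeled, spectra = spectra,
                 homology = homology, homology_summary = hom_summary,
                 manifest = manifest))
}
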