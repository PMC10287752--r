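# build a small on-disk study: reference FASTA, per-(caller,tissue) VCFs,
# known-variant TSV, optional region annotation, YAML config
.build_study <- function(dir, seed = 101, with_annotation = FALSE,
                         empty = FALSE) {
  gs <- guide_spec("GACTGAACTGACTGACTACT", "NRN")
  mr <- make_reference(seed, c(chr1 = 60000L, chr2 = 40000L), gs)
  tissues <- c("heart", "liver", "tail")
  truth <- simulate_variant_truth(mr$reference, tissues, n_germline = 30,
                                  n_common = 15,
                                  n_specific = c(heart = 15),
                                  seed = seed + 1)
  sim <- simulate_caller_vcfs(mr$reference, truth,
                              caller_panel("wgs", 0.95, 2),
                              seed = seed + 2)
  fa <- file.path(dir, "ref.fa")
  write_fasta(mr$reference, fa)
  vcfs <- list()
  for (ti in tissues) {
    vcfs[[ti]] <- list()
    for (ca in names(sim$callsets[[ti]])) {
      p <- file.path(dir, paste0(ca, "_", ti, ".vcf"))
      calls <- sim$callsets[[ti]][[ca]]
      if (empty) calls <- calls[0, , drop = FALSE]
      write_vcf(calls, p, sort = TRUE)
      vcfs[[ti]][[ca]] <- p
    }
  }
  known_path <- file.path(dir, "known.tsv")
  utils::write.table(sim$known[, c("chrom", "pos", "ref", "alt")],
                     known_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg <- list(vcfs = vcfs, reference = fa, known = list(known_path),
              guide = list(protospacer = gs$protospacer,
                           pam_pattern = "NRN"),
              caller_priority = c("MU", "HC", "LF"))
  if (with_annotation) {
    ann_path <- file.path(dir, "regions.bed")
    writeLines(c("chr1\t0\t20000\texonic", "chr1\t20000\t40000\tintronic"),
               ann_path)
    cfg$annotation <- ann_path
  }
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  list(config = cfg_path, truth = truth, sim = sim, dir = dir)
}
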