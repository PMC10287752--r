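# small builder: one variant key seen by given callers/depths per tissue
.mk_callsets <- function(spec, tissues = c("heart", "liver", "tail")) {
  # spec: list(tissue = list(caller = c(ref, alt) or "bare"))
  out <- lapply(tissues, function(ti) {
    by_caller <- spec[[ti]]
    if (is.null(by_caller)) return(list())
    lapply(by_caller, function(ad) {
      if (identical(ad, "bare"))
        variant_calls("X", "chr1", 100L, "A", "G")
      else
        variant_calls("X", "chr1", 100L, "A", "G", ad[1], ad[2],
                      if (sum(ad) > 0) ad[2] / sum(ad) else NA)
    })
  })
  names(out) <- tissues
  out
}

test_that("merge takes depths from the priority caller, falling back", {
  cs <- .mk_callsets(list(heart = list(MU = c(10, 5), HC = c(12, 4))))
  m <- merge_callers(cs, c("MU", "HC", "LF"))
  expect_equal(nrow(m), 1L)
  expect_equal(m$ref_depth_heart, 10L)
  expect_equal(m$alt_depth_heart, 5L)
  expect_equal(m$af_heart, 5 / 15, tolerance = 1e-9)
  expect_equal(m$callers_heart, "HC,MU")
  # HC only -> HC depths used
  cs2 <- .mk_callsets(list(heart = list(HC = c(12, 4))))
  m2 <- merge_callers(cs2, c("MU", "HC", "LF"))
  expect_equal(m2$ref_depth_heart, 12L)
  # unreported tissue stays unmeasured
  expect_true(is.na(m2$af_liver))
})

test_that("merge rejects unknown callers and handles empty input", {
  cs <- .mk_callsets(list(heart = list(ZZ = c(1, 1))))
  expect_error(merge_callers(cs, c("MU", "HC")), "priority")
  empty <- merge_callers(list(heart = list(), liver = list(), tail = list()),
                         c("MU", "HC"))
  expect_equal(nrow(empty), 0L)
  expect_equal(attr(empty, "tissues"), c("heart", "liver", "tail"))
})

test_that("zero-alt cohort records measure AF without counting as support", {
  cs <- .mk_callsets(list(heart = list(MU = c(30, 10), HC = c(28, 12)),
                          liver = list(MU = c(40, 0)),
                          tail = list(MU = c(35, 0))))
  m <- merge_callers(cs, c("MU", "HC", "LF"))
  expect_equal(m$callers_heart, "HC,MU")
  expect_equal(m$callers_liver, "")
  expect_equal(m$af_liver, 0)
  expect_equal(m$af_tail, 0)
})

test_that("confidence filters implement the three published rules", {
  # {MU,HC} support; depths 10/6/7; alt total 3 -> retained
  cs <- .mk_callsets(list(heart = list(MU = c(7, 3), HC = c(8, 2)),
                          liver = list(MU = c(6, 0)),
                          tail = list(MU = c(7, 0))))
  m <- merge_callers(cs, c("MU", "HC", "LF"))
  expect_equal(nrow(apply_confidence_filters(m)), 1L)
  # single caller in one tissue -> removed
  cs1 <- .mk_callsets(list(heart = list(LF = c(7, 3)),
                           liver = list(MU = c(6, 0)),
                           tail = list(MU = c(7, 0))))
  m1 <- merge_callers(cs1, c("MU", "HC", "LF"))
  expect_equal(nrow(apply_confidence_filters(m1)), 0L)
  # heart depth 4 -> removed by the depth rule
  cs2 <- .mk_callsets(list(heart = list(MU = c(1, 3), HC = c(8, 2)),
                           liver = list(MU = c(6, 0)),
                           tail = list(MU = c(7, 0))))
  m2 <- merge_callers(cs2, c("MU", "HC", "LF"))
  expect_equal(nrow(apply_confidence_filters(m2)), 0L)
  # alt total 1 -> removed by the alternate-reads rule
  cs3 <- .mk_callsets(list(heart = list(MU = c(9, 1), HC = c(8, 1)),
                           liver = list(MU = c(6, 0)),
                           tail = list(MU = c(7, 0))))
  m3 <- merge_callers(cs3, c("MU", "HC", "LF"))
  expect_equal(nrow(apply_confidence_filters(m3)), 0L)
})

test_that("unmeasured tissue depth fails unless the config switch is set", {
  cs <- .mk_callsets(list(heart = list(MU = c(7, 3), HC = c(8, 2))))
  m <- merge_callers(cs, c("MU", "HC", "LF"))
  expect_equal(nrow(apply_confidence_filters(m)), 0L)
  expect_equal(nrow(apply_confidence_filters(m, unmeasured_depth_passes = TRUE)),
               1L)
})

test_that("raising any threshold never grows the retained set", {
  set.seed(77)
  gs <- guide_spec("GACTGAACTGACTGACTACT", "NRN")
  mr <- make_reference(21, c(chr1 = 50000L), gs)
  truth <- simulate_variant_truth(mr$reference, c("heart", "liver", "tail"),
                                  n_germline = 20, n_common = 20,
                                  n_specific = c(heart = 20), seed = 8)
  sim <- simulate_caller_vcfs(mr$reference, truth,
                              caller_panel("wgs", 0.8, 5), seed = 9)
  m <- merge_callers(sim$callsets, c("MU", "HC", "LF"))
  base_keys <- apply_confidence_filters(m)$key
  for (mc in 2:3) for (md in c(5, 20)) for (ma in c(2, 6)) {
    keys <- apply_confidence_filters(m, mc, md, ma)$key
    expect_true(all(keys %in% base_keys))
  }
})

test_that("known-variant exclusion partitions exactly on normalized keys", {
  cs <- .mk_callsets(list(heart = list(MU = c(7, 3), HC = c(8, 2)),
                          liver = list(MU = c(6, 2)),
                          tail = list(MU = c(7, 2))))
  m <- merge_callers(cs, c("MU", "HC", "LF"))
  known <- data.frame(chrom = "chr1", pos = 100L, ref = "A", alt = "G")
  parts <- exclude_known(m, list(known))
  expect_equal(nrow(parts$known), 1L)
  expect_equal(nrow(parts$novel), 0L)
  # empty known sets -> all novel
  parts2 <- exclude_known(m, list())
  expect_equal(nrow(parts2$novel), 1L)
  expect_false(any(parts2$novel$known))
  # same position, different allele is not known
  known3 <- data.frame(chrom = "chr1", pos = 100L, ref = "A", alt = "T")
  parts3 <- exclude_known(m, list(known3))
  expect_equal(nrow(parts3$novel), 1L)
})

test_that("tissue specificity follows the AF > 0 / AF = 0-or-unmeasured rule", {
  mk <- function(af_heart, af_liver, af_tail, known = FALSE) {
    v <- .empty_frame <- merge_callers(
      .mk_callsets(list(heart = list(MU = c(7, 3)))), c("MU", "HC"))
    v$af_heart <- af_heart; v$af_liver <- af_liver; v$af_tail <- af_tail
    v[["callers_liver"]] <- ""; v[["callers_tail"]] <- ""
    for (ti in c("liver", "tail")) {
      v[[paste0("ref_depth_", ti)]] <- NA_integer_
      v[[paste0("alt_depth_", ti)]] <- NA_integer_
      v[[paste0("depth_", ti)]] <- NA_integer_
    }
    v$known <- known
    attr(v, "tissues") <- c("heart", "liver", "tail")
    v
  }
  lab <- function(...) classify_tissue_specificity(mk(...))$specificity
  expect_equal(lab(0.3, 0, 0), "tissue-specific:heart")
  expect_equal(lab(0.3, 0.2, 0.1), "common")
  expect_equal(lab(0.3, NA, 0), "tissue-specific:heart")
  expect_equal(lab(0.3, 0.2, 0), "other")
  # known variants are never tissue-specific but can be common
  expect_equal(lab(0.3, 0, 0, known = TRUE), "other")
  expect_equal(lab(0.3, 0.2, 0.1, known = TRUE), "common")
})

test_that("conversion spectrum counts, collapses and rejects indels", {
  v <- data.frame(ref = c("A", "T", "C"), alt = c("G", "C", "T"))
  sp <- conversion_spectrum(v)
  expect_equal(sp$counts_6[["A>G/T>C"]], 2L)
  expect_equal(sp$counts_6[["C>T/G>A"]], 1L)
  expect_equal(sp$total, 3L)
  expect_equal(sum(sp$rel_6), 1)
  # empty spectrum
  sp0 <- conversion_spectrum(v[0, ])
  expect_equal(sp0$total, 0L)
  expect_true(all(is.na(sp0$rel_6)))
  # complementing every pair leaves the collapsed spectrum unchanged
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  v2 <- data.frame(ref = unname(comp[v$ref]), alt = unname(comp[v$alt]))
  expect_equal(conversion_spectrum(v2)$counts_6, sp$counts_6)
  expect_error(conversion_spectrum(data.frame(ref = "AT", alt = "A")),
               "SNVs only")
})

test_that("region annotation respects 0-based half-open intervals", {
  ann <- region_annotation(data.frame(
    chrom = "chr1", start = c(10L, 20L, 12L, 24L),
    end = c(20L, 30L, 18L, 28L),
    class = c("exonic", "intronic", "UTR5", "UTR3")))
  v <- merge_callers(.mk_callsets(list(heart = list(MU = c(7, 3)))),
                     c("MU", "HC"))
  at <- function(pos) {
    v$pos <- pos
    annotate_region(v, ann)$region_class
  }
  expect_equal(at(11L), "exonic")    # 0-based 10 inside [10,20)
  expect_equal(at(20L), "exonic")    # 0-based 19, last base of the exon
  expect_equal(at(21L), "intronic")  # 0-based 20: interval end is exclusive
  expect_equal(at(25L), "UTR3")      # UTR outranks intronic on overlap
  expect_equal(at(5L), "other")
  # exonic beats UTR on overlap
  expect_equal(at(15L), "exonic")
  # rna_mode drops unannotated positions
  v$pos <- 5L
  expect_equal(nrow(annotate_region(v, ann, rna_mode = TRUE)), 0L)
})
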