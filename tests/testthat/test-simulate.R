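gs <- guide_spec("GACTGAACTGACTGACTACT", "NRN")

test_that("references are seed-deterministic with verifiable plants", {
  req <- data.frame(contig = "chr1", position = c(100L, 300L),
                    strand = c("+", "-"), edit_distance = c(0L, 2L))
  mr1 <- make_reference(5, c(chr1 = 1000L), gs, req)
  mr2 <- make_reference(5, c(chr1 = 1000L), gs, req)
  expect_identical(mr1$reference, mr2$reference)
  # scanning the planted windows recovers the requested distances
  w0 <- substr(mr1$reference[["chr1"]], 90, 150)
  expect_equal(min_edit_distance(w0, gs)$edit_distance, 0L)
  w2 <- substr(mr1$reference[["chr1"]], 290, 350)
  r2 <- min_edit_distance(w2, gs)
  expect_equal(r2$edit_distance, 2L)
  expect_equal(r2$edit_distance, oracle_min_edit(w2, gs))
})

test_that("reference planting validates its preconditions", {
  req_overlap <- data.frame(contig = "chr1", position = c(100L, 110L),
                            strand = "+", edit_distance = 0L)
  expect_error(make_reference(1, c(chr1 = 1000L), gs, req_overlap),
               "overlap")
  req_far <- data.frame(contig = "chr1", position = 995L, strand = "+",
                        edit_distance = 0L)
  expect_error(make_reference(1, c(chr1 = 1000L), gs, req_far), "bounds")
  req_k <- data.frame(contig = "chr1", position = 100L, strand = "+",
                      edit_distance = 7L)
  expect_error(make_reference(1, c(chr1 = 1000L), gs, req_k), "0..6")
})

test_that("caller outputs honour sensitivity at the extremes", {
  mr <- make_reference(6, c(chr1 = 100000L), gs)
  truth <- simulate_variant_truth(mr$reference, c("heart", "liver"),
                                  n_germline = 30, n_common = 10,
                                  n_specific = c(heart = 10), seed = 7)
  # sensitivity 1, no false positives: every variant in every caller
  sim1 <- simulate_caller_vcfs(mr$reference, truth,
                               caller_panel("wgs", 1, 0), seed = 8)
  for (ca in c("MU", "HC"))
    expect_setequal(sim1$callsets$heart[[ca]]$pos, truth$pos)
  # single-sample caller only reports tissues with the variant
  lf_heart <- sim1$callsets$heart$LF
  expect_true(all(lf_heart$pos %in%
                    truth$pos[truth$af_heart > 0]))
  # sensitivity 0: only false positives remain
  sim0 <- simulate_caller_vcfs(mr$reference, truth,
                               caller_panel("wgs", 0, 50), seed = 9)
  expect_false(any(sim0$callsets$heart$MU$pos %in% truth$pos))
  # germline truth is exported as the known set
  expect_setequal(sim1$known$key, truth$key[truth$class == "germline"])
})

test_that("observed caller support tracks the sensitivity parameter", {
  mr <- make_reference(10, c(chr1 = 400000L), gs)
  truth <- simulate_variant_truth(mr$reference, c("heart", "liver"),
                                  n_germline = 500, n_common = 300,
                                  n_specific = c(heart = 200), seed = 11)
  sim <- simulate_caller_vcfs(mr$reference, truth,
                              caller_panel("wgs", 0.9, 0), seed = 12)
  support <- mean(truth$key %in%
                    paste(sim$callsets$heart$MU$chrom,
                          sim$callsets$heart$MU$pos,
                          sim$callsets$heart$MU$ref,
                          sim$callsets$heart$MU$alt, sep = ":"))
  expect_lt(abs(support - 0.9), 3 * sqrt(0.9 * 0.1 / 1000))
})

test_that("amplicon reads follow the mixture and its conditional mode", {
  proto <- "GACTGAACTGACTGACTACT"
  gsp <- guide_spec(proto, "NGG")
  window <- paste0("TTTTTTTTTT", proto, "TGGCCCCCCC")
  # repair 1, no bystanders, no error: every read is the repaired sequence
  sim <- simulate_amplicon_reads(200, window, gsp, 10L, 1, seed = 13)
  expect_true(all(sim$reads == sim$wt_window))
  # conditional mode: zero bystanders among unrepaired reads
  sim2 <- simulate_amplicon_reads(4000, window, gsp, 10L, 0.6,
                                  bystander_spec = c("2" = 0.3),
                                  conditional_on_repair = TRUE, seed = 14)
  cb <- conditional_bystander(sim2$reads,
                              editaudit:::.guide_index_to_window(6, 10L),
                              editaudit:::.guide_index_to_window(2, 10L))
  expect_equal(cb$freq_unrepaired, 0)
  expect_gt(cb$freq_repaired, 0.2)
  # independent mode: both partitions near the nominal rate
  sim3 <- simulate_amplicon_reads(8000, window, gsp, 10L, 0.5,
                                  bystander_spec = c("2" = 0.05),
                                  conditional_on_repair = FALSE, seed = 15)
  cb3 <- conditional_bystander(sim3$reads,
                               editaudit:::.guide_index_to_window(6, 10L),
                               editaudit:::.guide_index_to_window(2, 10L))
  tol <- 3 * sqrt(0.05 * 0.95 / 4000)
  expect_lt(abs(cb3$freq_repaired - 0.05), tol)
  expect_lt(abs(cb3$freq_unrepaired - 0.05), tol)
  # parameter errors
  expect_error(simulate_amplicon_reads(10, window, gsp, 10L, 0.5,
                                       bystander_spec = c("99" = 0.1)),
               "outside window")
  expect_error(simulate_amplicon_reads(10, window, gsp, 10L, 0.5,
                                       target_position = 1L),
               "must carry")
})

test_that("generators are byte-identical under a fixed seed", {
  proto <- "GACTGAACTGACTGACTACT"
  gsp <- guide_spec(proto, "NGG")
  window <- paste0("TTTTTTTTTT", proto, "TGGCCCCCCC")
  a <- simulate_amplicon_reads(100, window, gsp, 10L, 0.5,
                               bystander_spec = c("2" = 0.1),
                               indel_fraction = 0.05, error_rate = 0.01,
                               seed = 16)
  b <- simulate_amplicon_reads(100, window, gsp, 10L, 0.5,
                               bystander_spec = c("2" = 0.1),
                               indel_fraction = 0.05, error_rate = 0.01,
                               seed = 16)
  expect_identical(a$reads, b$reads)
  s1 <- simulate_splice_table(40, seed = 17)
  s2 <- simulate_splice_table(40, seed = 17)
  expect_identical(s1, s2)
  e1 <- simulate_expression_matrix(20, 30, 3, 3, 1, seed = 18)
  e2 <- simulate_expression_matrix(20, 30, 3, 3, 1, seed = 18)
  expect_identical(e1$cells$expression, e2$cells$expression)
  # generators do not disturb the caller's RNG stream
  set.seed(99); x1 <- runif(1)
  set.seed(99); invisible(simulate_splice_table(5, seed = 1)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("splice truth categories are consistent with their deltas", {
  sim <- simulate_splice_table(150, seed = 21)
  sig <- sim$truth$category != "not-significant"
  expect_equal(classify_rescue(sim$truth$o[sig], sim$truth$e[sig]),
               sim$truth$category[sig])
  expect_true(all(sim$truth$fdr[sig] < 0.01))
  expect_true(all(abs(sim$truth$o[sig]) > 0.1))
})

test_that("expression truth genes carry the requested shift", {
  sim <- simulate_expression_matrix(300, 50, 4, 4, effect = 1.5, seed = 22)
  x <- sim$cells$expression
  mut <- sim$cells$metadata$condition == "MUT"
  up_shift <- rowMeans(x[sim$truth$up, mut]) -
    rowMeans(x[sim$truth$up, !mut])
  expect_equal(mean(up_shift), 1.5, tolerance = 0.15)
  down_shift <- rowMeans(x[sim$truth$down, mut]) -
    rowMeans(x[sim$truth$down, !mut])
  expect_equal(mean(down_shift), -1.5, tolerance = 0.15)
})
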