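gs <- guide_spec("GACTGAACTGACTGACTACT", "NGG")

test_that("windows are extracted with clipping at contig ends", {
  ref <- c(chr1 = rand_dna(200))
  w <- extract_window(ref, "chr1", 100L, 30L)
  expect_equal(c(w$start, w$end), c(70L, 130L))
  expect_equal(nchar(w$seq), 61L)
  w2 <- extract_window(ref, "chr1", 10L, 30L)
  expect_equal(c(w2$start, w2$end), c(1L, 40L))
  w3 <- extract_window(ref, "chr1", 50L, 0L)
  expect_equal(nchar(w3$seq), 1L)
  expect_error(extract_window(ref, "chr1", 300L), "outside")
})

test_that("exact plants give distance 0 on either strand", {
  set.seed(11)
  w <- plant_window(gs, 0, 15)
  r <- min_edit_distance(w, gs)
  expect_equal(r$edit_distance, 0L)
  expect_equal(r$best_strand, "+")
  expect_equal(r$best_offset, 15L)
  expect_equal(r$gaps, 0L)
  rc <- min_edit_distance(revcomp(w), gs)
  expect_equal(rc$edit_distance, 0L)
  expect_equal(rc$best_strand, "-")
})

test_that("edit_distance decomposes as mismatches + gaps", {
  set.seed(12)
  for (k in 0:3) {
    w <- plant_window(gs, k, 12)
    r <- min_edit_distance(w, gs)
    expect_equal(r$edit_distance, r$mismatches + r$gaps)
    expect_lte(r$edit_distance, k)
  }
})

test_that("scanner equals the exhaustive DP oracle in both modes", {
  set.seed(13)
  for (i in 1:60) {
    n <- sample(23:61, 1)
    w <- if (i %% 3 == 0) rand_dna(n)
         else plant_window(gs, sample(0:4, 1), sample(0:(n - 23), 1),
                           total_len = n,
                           strand = sample(c("+", "-"), 1))
    for (mode in c("strict", "lenient")) {
      r <- min_edit_distance(w, gs, mode = mode)
      o <- oracle_min_edit(w, gs, mode = mode)
      expect_equal(r$edit_distance,
                   if (is.na(o)) NA_integer_ else as.integer(o),
                   info = sprintf("mode=%s w=%s", mode, w))
    }
  }
})

test_that("reverse-complementing the window flips strand, keeps distance", {
  set.seed(14)
  for (i in 1:20) {
    w <- plant_window(gs, sample(0:3, 1), sample(0:30, 1))
    r1 <- min_edit_distance(w, gs)
    r2 <- min_edit_distance(revcomp(w), gs)
    expect_equal(r2$edit_distance, r1$edit_distance)
  }
})

test_that("strict mode rejects placements without a matching PAM", {
  # a window with no G anywhere cannot satisfy NGG
  w <- paste(rep("A", 40), collapse = "")
  r <- min_edit_distance(w, gs, mode = "strict")
  expect_false(r$alignable)
  expect_true(is.na(r$edit_distance))
  # lenient mode scores the PAM mismatches instead
  rl <- min_edit_distance(w, gs, mode = "lenient")
  expect_true(rl$alignable)
  # whenever the strict placement is admissible under lenient scoring,
  # the lenient distance cannot exceed the strict one
  set.seed(15)
  for (i in 1:20) {
    w2 <- plant_window(gs, sample(0:3, 1), sample(0:30, 1))
    rs <- min_edit_distance(w2, gs, mode = "strict")
    rl2 <- min_edit_distance(w2, gs, mode = "lenient")
    if (rs$alignable) expect_lte(rl2$edit_distance, rs$edit_distance)
  }
})

test_that("windows shorter than the PAM pattern are rejected", {
  expect_error(min_edit_distance("AG", gs), "shorter")
})

test_that("gap events respect the 1-bp limit and are counted", {
  # plant a cassette with one protospacer base deleted: best alignment
  # needs one 1-bp gap
  set.seed(16)
  proto <- strsplit(gs$protospacer, "")[[1]]
  gapped <- paste(c(proto[-10], "T", "G", "G"), collapse = "")
  w <- rand_dna(50)
  substr(w, 11, 11 + nchar(gapped) - 1) <- gapped
  r <- min_edit_distance(w, gs)
  expect_equal(r$edit_distance, 1L)
  expect_equal(r$gaps, 1L)
  expect_equal(r$edit_distance, oracle_min_edit(w, gs))
})

test_that("seed-region edits are reported and optionally gap-forbidden", {
  set.seed(17)
  # substitution at protospacer position 15 (inside the 12-nt seed)
  proto <- strsplit(gs$protospacer, "")[[1]]
  proto[15] <- setdiff(c("A", "C", "G", "T"), proto[15])[1]
  w <- rand_dna(50)
  substr(w, 11, 33) <- paste(c(proto, "T", "G", "G"), collapse = "")
  r <- min_edit_distance(w, gs)
  expect_equal(r$edit_distance, 1L)
  expect_equal(r$seed_edits, 1L)
  # deletion inside the seed is suppressed by forbid_seed_gaps
  gapped <- paste(c(strsplit(gs$protospacer, "")[[1]][-15], "T", "G", "G"),
                  collapse = "")
  w2 <- rand_dna(50)
  substr(w2, 11, 11 + nchar(gapped) - 1) <- gapped
  r2 <- min_edit_distance(w2, gs)
  r2f <- min_edit_distance(w2, gs, forbid_seed_gaps = TRUE)
  expect_equal(r2$gaps, 1L)
  expect_gte(r2f$edit_distance, r2$edit_distance)
  expect_true(r2f$gaps == 0L || r2f$seed_edits == r2f$mismatches)
})

test_that("IUPAC PAM degeneracy is honoured", {
  gs_nrn <- guide_spec(gs$protospacer, "NRN")
  set.seed(18)
  w <- plant_window(gs_nrn, 0, 10, pam_bases = c("T", "A", "C"))
  expect_equal(min_edit_distance(w, gs_nrn)$edit_distance, 0L)
  expect_true(iupac_match("A", "R"))
  expect_false(iupac_match("C", "R"))
  expect_true(all(iupac_match(c("A", "C", "G", "T"), "N")))
})

test_that("mismatch profiles summarize per group with SEM", {
  res <- data.frame(edit_distance = c(3L, 3L, 3L, 5L, 7L))
  out <- summarize_mismatch_profile(res, c("a", "a", "a", "b", "b"))
  expect_equal(out$summary$mean[out$summary$group == "a"], 3)
  expect_equal(out$summary$se[out$summary$group == "a"], 0)
  expect_equal(out$summary$mean[out$summary$group == "b"], 6)
  expect_warning(
    summarize_mismatch_profile(data.frame(edit_distance = NA_integer_),
                               "empty"),
    "empty")
  # two identical groups summarize identically
  res2 <- data.frame(edit_distance = rep(c(2L, 4L), 2))
  out2 <- summarize_mismatch_profile(res2, rep(c("x", "y"), each = 2))
  expect_equal(out2$summary$mean[1], out2$summary$mean[2])
})
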