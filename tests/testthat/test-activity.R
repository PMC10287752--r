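test_that("marker selection caps lists at top_k and splits by direction", {
  sim <- simulate_expression_matrix(150, 120, n_up = 20, n_down = 8,
                                    effect = 2, seed = 31)
  mk <- select_markers(sim$cells, "VCM", "MUT", "WT")
  expect_length(mk$up, 15L)           # 20 truly up, capped at 15
  expect_true(all(mk$up %in% sim$truth$up))
  # every true down gene ranks ahead of any null false positive
  expect_true(all(sim$truth$down %in% mk$down))
  expect_lte(length(mk$down), 15L)
  # ranked by ascending p
  tab <- mk$table[match(mk$up, mk$table$gene), ]
  expect_true(all(diff(tab$p) >= 0))
})

test_that("a missing condition in the cluster is skipped with a warning", {
  sim <- simulate_expression_matrix(10, 20, 2, 2, effect = 1, seed = 32)
  expect_warning(mk <- select_markers(sim$cells, "VCM", "MUT", "ABSENT"),
                 "lacks")
  expect_length(mk$up, 0L)
})

test_that("under the null no genes pass, on average, beyond the 5% rate", {
  fp <- vapply(1:6, function(i) {
    sim <- simulate_expression_matrix(60, 100, 0, 0, effect = 0,
                                      seed = 400 + i)
    mk <- select_markers(sim$cells, "VCM", "MUT", "WT", top_k = Inf)
    (length(mk$up) + length(mk$down)) / 100
  }, numeric(1))
  expect_lte(mean(fp), 0.05 + 3 * sqrt(0.05 * 0.95 / 600))
})

test_that("scores are bounded, match the oracle, and ignore gene scaling", {
  sim <- simulate_expression_matrix(40, 60, 5, 5, effect = 1, seed = 33)
  set.seed(34)
  gene_set <- sample(rownames(sim$cells$expression), 50)
  sc <- score_cells(sim$cells, gene_set)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_equal(sc, oracle_score_cells(sim$cells$expression, gene_set),
               tolerance = 1e-12)
  # positive affine transform of one gene's vector leaves scores unchanged
  x2 <- sim$cells$expression
  x2[gene_set[1], ] <- 3.7 * x2[gene_set[1], ] + 11
  cells2 <- cell_matrix(x2, sim$cells$metadata)
  expect_equal(score_cells(cells2, gene_set), sc, tolerance = 1e-12)
})

test_that("extreme cells score exactly 0 and 1; constant genes drop", {
  x <- rbind(g1 = c(0, 2, 5), g2 = c(1, 4, 9), g3 = c(7, 7, 7))
  colnames(x) <- c("c1", "c2", "c3")
  meta <- data.frame(cell_id = colnames(x), condition = c("a", "a", "b"),
                     cluster = "k")
  cells <- cell_matrix(x, meta)
  expect_warning(sc <- score_cells(cells, c("g1", "g2", "g3")), "constant")
  expect_equal(unname(sc[c("c1", "c3")]), c(0, 1))
  expect_error(score_cells(cells, "g3"), "constant")
  expect_error(score_cells(cells, "nope"), "not in matrix")
})

test_that("threshold curves are survival functions, non-increasing in t", {
  set.seed(35)
  scores <- c(runif(300), rep(1, 3))
  cond <- rep(c("WT", "MUT"), length.out = 303)
  ts <- threshold_scan(scores, cond)
  for (cc in c("WT", "MUT")) {
    curve <- ts$percent_above[cc, ]
    expect_true(all(diff(curve) <= 0))
    s <- scores[cond == cc]
    expect_equal(curve, vapply(ts$grid, function(t) 100 * mean(s > t),
                               numeric(1)))
  }
  # all scores 1 -> 100% above every threshold below 1
  ts2 <- threshold_scan(rep(1, 10), rep(c("a", "b"), 5))
  expect_true(all(ts2$percent_above[, ts2$grid < 1] == 100))
  expect_error(threshold_scan(1:3 / 3, rep("only", 3)), "two")
})

test_that("the critical threshold is where the low condition drops below 50%", {
  scores <- c(rep(0.4, 10), rep(0.8, 10))
  cond <- rep(c("MUT", "WT"), each = 10)
  ts <- threshold_scan(scores, cond)
  ct <- critical_threshold(ts)
  expect_equal(ct$down_condition, "MUT")
  expect_equal(ct$critical_threshold, 0.40)
  expect_equal(unname(ct$percent_at_critical["WT"]), 100)
  expect_equal(unname(ct$percent_at_critical["MUT"]), 0)
  # a curve that never drops below 50% flags and unsets the threshold
  # (reachable when the scan is restricted to an interior grid)
  ts3 <- threshold_scan(rep(c(0.2, 0.9), 5), rep(c("lo", "hi"), 5))
  ts3$grid <- ts3$grid[ts3$grid < 0.9]
  ts3$percent_above <- ts3$percent_above[, seq_along(ts3$grid)]
  expect_warning(ct3 <- critical_threshold(ts3, "hi"), "50%")
  expect_true(is.na(ct3$critical_threshold))
})

test_that("a simulated activity shift separates conditions at the critical threshold", {
  set.seed(36)
  scores <- c(rnorm(500, 0.6, 0.05), rnorm(500, 0.4, 0.05))
  scores <- pmin(pmax(scores, 0), 1)
  cond <- rep(c("WT", "MUT"), each = 500)
  ct <- critical_threshold(threshold_scan(scores, cond))
  expect_equal(ct$down_condition, "MUT")
  expect_lt(ct$percent_at_critical["MUT"], 50)
  expect_gt(ct$percent_at_critical["WT"], 50)
})

test_that("PC distances reduce to plain Euclidean distance in 2-D", {
  # two genes whose principal axes are the coordinate axes
  set.seed(37)
  n <- 40
  x <- rbind(gA = c(rnorm(n, 20, 3), rnorm(n, 30, 3)),
             gB = rnorm(2 * n, 5, 0.2))
  colnames(x) <- sprintf("c%02d", seq_len(2 * n))
  meta <- data.frame(cell_id = colnames(x),
                     condition = rep(c("WT", "MUT"), each = n),
                     cluster = "k")
  cells <- cell_matrix(x, meta)
  pd <- pc_pairwise_distances(cells, "WT")
  direct <- as.numeric(sqrt(outer(x["gA", meta$condition == "MUT"],
                                  x["gA", meta$condition == "WT"], "-")^2 +
                            outer(x["gB", meta$condition == "MUT"],
                                  x["gB", meta$condition == "WT"], "-")^2))
  expect_equal(sort(pd$distances$MUT), sort(direct), tolerance = 1e-8)
  # identical cells are at distance zero
  x2 <- x; x2[, 1] <- x2[, n + 1]
  cells2 <- cell_matrix(x2, meta)
  pd2 <- pc_pairwise_distances(cells2, "WT")
  expect_true(any(pd2$distances$MUT < 1e-10))
  expect_error(pc_pairwise_distances(
    cell_matrix(x[, 1:2], meta[1:2, ]), "WT"), "fewer cells")
})

test_that("duplicating reference cells preserves the distance distribution", {
  sim <- simulate_expression_matrix(25, 30, 3, 3, effect = 1, seed = 38)
  pd <- pc_pairwise_distances(sim$cells, "WT")
  x <- sim$cells$expression
  wt <- sim$cells$metadata$condition == "WT"
  xd <- cbind(x, x[, wt])
  colnames(xd) <- c(colnames(x), paste0("dup", seq_len(sum(wt))))
  metad <- rbind(sim$cells$metadata,
                 data.frame(cell_id = paste0("dup", seq_len(sum(wt))),
                            condition = "WT", cluster = "VCM"))
  pdd <- pc_pairwise_distances(cell_matrix(xd, metad), "WT")
  expect_equal(length(pdd$distances$MUT), 2L * length(pd$distances$MUT))
})

test_that("marker recovery holds at a two-standard-deviation effect", {
  sim <- simulate_expression_matrix(150, 150, 12, 12, effect = 1,
                                    noise_sd = 0.5, seed = 39)
  mk <- select_markers(sim$cells, "VCM", "MUT", "WT")
  truth <- c(sim$truth$up, sim$truth$down)
  expect_gte(mean(truth %in% c(mk$up, mk$down)), 0.9)
})
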