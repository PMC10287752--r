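#' Select up/down marker genes between conditions within a cluster
#'
#' Per-gene Wilcoxon rank-sum test between two conditions within one
#' cluster; genes with p <= `p_max` are split by the direction of the mean
#' difference (condition_a minus condition_b) and up to `top_k` genes per
#' direction are retained, ranked by ascending p-value with ties broken by
#' absolute mean difference.
#'
#' @param cells [cell_matrix()] object.
#' @param cluster cluster label to test within.
#' @param condition_a,condition_b condition labels (a vs b; "up" means
#'   higher in `condition_a`).
#' @param p_max p-value ceiling (default 0.05).
#' @param top_k maximum genes per direction (default 15).
#' @return list with `up`, `down` (character vectors) and `table`
#'   (gene, p, mean_diff, direction for all tested genes).
#' @export
select_markers <- function(cells, cluster, condition_a, condition_b,
                           p_max = 0.05, top_k = 15L) {
  stopifnot(inherits(cells, "cell_matrix"))
  meta <- cells$metadata
  in_cl <- meta$cluster == cluster
  a <- in_cl & meta$condition == condition_a
  b <- in_cl & meta$condition == condition_b
  if (!any(a) || !any(b)) {
    warning("cluster '", cluster, "' lacks condition ",
            if (!any(a)) condition_a else condition_b, "; skipped",
            call. = FALSE)
    return(list(up = character(0), down = character(0), table = NULL))
  }
  xa <- cells$expression[, a, drop = FALSE]
  xb <- cells$expression[, b, drop = FALSE]
  genes <- rownames(cells$expression)
  p <- numeric(length(genes)); md <- numeric(length(genes))
  for (g in seq_along(genes)) {
    va <- xa[g, ]; vb <- xb[g, ]
    md[g] <- mean(va) - mean(vb)
    p[g] <- if (all(va == va[1L]) && all(vb == vb[1L]) && va[1L] == vb[1L])
      1 else suppressWarnings(stats::wilcox.test(va, vb)$p.value)
  }
  tab <- data.frame(gene = genes, p = p, mean_diff = md,
                    direction = ifelse(md > 0, "up",
                                       ifelse(md < 0, "down", "none")),
                    stringsAsFactors = FALSE)
  pick <- function(dir) {
    sel <- tab[tab$p <= p_max & tab$direction == dir, , drop = FALSE]
    sel <- sel[order(sel$p, -abs(sel$mean_diff)), , drop = FALSE]
    utils::head(sel$gene, top_k)
  }
  list(up = pick("up"), down = pick("down"), table = tab)
}

#' Per-cell gene-set activity score
#'
#' Each gene of the set is min-max rescaled across the scored cells so its
#' values lie in [0, 1] (1 = maximum activation, 0 = minimum/absent); the
#' cell's score is the mean of its rescaled values over the set. Constant
#' genes carry no information and are dropped with a warning.
#'
#' @param cells [cell_matrix()] object (the rescaling population is the
#'   cells in this object).
#' @param gene_set character vector of gene ids.
#' @return named numeric vector of per-cell scores in [0, 1].
#' @export
score_cells <- function(cells, gene_set) {
  stopifnot(inherits(cells, "cell_matrix"))
  if (!length(gene_set)) stop("empty gene set", call. = FALSE)
  miss <- setdiff(gene_set, rownames(cells$expression))
  if (length(miss))
    stop("gene(s) not in matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  x <- cells$expression[gene_set, , drop = FALSE]
  rng <- apply(x, 1L, range)
  constant <- rng[1L, ] == rng[2L, ]
  if (all(constant))
    stop("all genes in the set are constant across cells", call. = FALSE)
  if (any(constant)) {
    warning(sum(constant), " constant gene(s) dropped from the set",
            call. = FALSE)
    x <- x[!constant, , drop = FALSE]
    rng <- rng[, !constant, drop = FALSE]
  }
  scaled <- (x - rng[1L, ]) / (rng[2L, ] - rng[1L, ])
  colMeans(scaled)
}

#' Threshold scan of activity scores
#'
#' For each threshold t on a regular grid over [0, 1], the per-condition
#' percentage of cells with score strictly above t — an empirical survival
#' curve per condition, non-increasing in t.
#'
#' @param scores named per-cell scores from [score_cells()].
#' @param conditions condition label per cell.
#' @param grid_step grid spacing (default 0.01).
#' @return list of class `activity_result` with `grid`, `percent_above`
#'   (conditions x grid matrix, in percent), `scores`, `conditions`.
#' @export
threshold_scan <- function(scores, conditions, grid_step = 0.01) {
  stopifnot(length(scores) == length(conditions))
  if (length(unique(conditions)) < 2L)
    stop("need at least two conditions", call. = FALSE)
  grid <- seq(0, 1, by = grid_step)
  lv <- unique(conditions)
  pa <- t(vapply(lv, function(cond) {
    s <- scores[conditions == cond]
    vapply(grid, function(t) 100 * mean(s > t), numeric(1))
  }, numeric(length(grid))))
  rownames(pa) <- lv
  structure(list(grid = grid, percent_above = pa, scores = scores,
                 conditions = conditions),
            class = "activity_result")
}

#' Critical threshold of an activity scan
#'
#' The condition with downregulated activity (lowest mean score, or an
#' explicitly supplied one) defines the critical threshold: the smallest
#' grid value at which its percentage of active cells drops strictly below
#' 50%. All conditions' percentages at that threshold are reported.
#'
#' @param result `activity_result` from [threshold_scan()].
#' @param down_condition condition with downregulated activity; default =
#'   lowest mean score.
#' @return list with `critical_threshold` (NA, with a warning, when the
#'   curve never drops below 50%), `down_condition`, and
#'   `percent_at_critical` (named vector over conditions).
#' @export
critical_threshold <- function(result, down_condition = NULL) {
  stopifnot(inherits(result, "activity_result"))
  lv <- rownames(result$percent_above)
  if (is.null(down_condition)) {
    means <- vapply(lv, function(cond)
      mean(result$scores[result$conditions == cond]), numeric(1))
    down_condition <- lv[which.min(means)]
  }
  curve <- result$percent_above[down_condition, ]
  k <- which(curve < 50)[1L]
  if (is.na(k)) {
    warning("activity never drops below 50% for '", down_condition, "'",
            call. = FALSE)
    return(list(critical_threshold = NA_real_,
                down_condition = down_condition,
                percent_at_critical = NULL))
  }
  list(critical_threshold = result$grid[k],
       down_condition = down_condition,
       percent_at_critical = result$percent_above[, k])
}

#' Pairwise cell distances in principal-component space
#'
#' Principal components are computed on the pooled cell subset (centered,
#' not rescaled, matching upstream log-normalized expression; component
#' signs fixed so each component's largest loading is positive). For every
#' cell of each non-reference condition, Euclidean distances to all
#' reference-condition cells are measured in the plane of the first
#' `n_components` PCs.
#'
#' @param cells [cell_matrix()] object (already subset to the cluster of
#'   interest).
#' @param reference_condition reference condition (default "WT").
#' @param n_components number of leading PCs (default 2).
#' @param all_pairs also include reference-to-reference distances under
#'   the reference condition's own name.
#' @return list of class `pc_distances`: per non-reference condition, the
#'   numeric vector of its cell-to-reference distances; plus `pcs` (cells
#'   x components scores).
#' @export
pc_pairwise_distances <- function(cells, reference_condition = "WT",
                                  n_components = 2L, all_pairs = FALSE) {
  stopifnot(inherits(cells, "cell_matrix"))
  x <- t(cells$expression)  # cells x genes
  if (nrow(x) <= n_components)
    stop("fewer cells than components", call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  if (ncol(pc$x) < n_components)
    stop("fewer non-degenerate dimensions than components", call. = FALSE)
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  flip <- vapply(seq_len(n_components), function(j) {
    k <- which.max(abs(rot[, j]))
    if (rot[k, j] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(pc$x[, seq_len(n_components), drop = FALSE], 2L, flip, "*")
  cond <- cells$metadata$condition
  if (!reference_condition %in% cond)
    stop("reference condition absent: ", reference_condition, call. = FALSE)
  ref <- scores[cond == reference_condition, , drop = FALSE]
  others <- setdiff(unique(cond), reference_condition)
  if (all_pairs) others <- unique(cond)
  dists <- lapply(stats::setNames(others, others), function(cc) {
    q <- scores[cond == cc, , drop = FALSE]
    d2 <- outer(rowSums(q^2), rowSums(ref^2), "+") - 2 * tcrossprod(q, ref)
    as.numeric(sqrt(pmax(d2, 0)))
  })
  structure(list(distances = dists, pcs = scores,
                 reference = reference_condition),
            class = "pc_distances")
}
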