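test_that("path pseudotime starts at zero and orders a 1-d chain correctly", {
  # cells on a line in expression space, two clusters
  set.seed(2)
  n <- 80
  base <- seq(0, 8, length.out = n)
  s <- outer(base, c(1, 2, 3)) + matrix(rnorm(n * 3, sd = 0.05), n, 3)
  ds <- tivelo_dataset(pmax(s, 0), pmax(s / 2, 0), obs = tibble::tibble(
    cell = sprintf("c%d", 1:n),
    cluster = rep(c("start", "end"), each = n / 2)
  ))
  ds <- build_knn(ds, tivelo_config(k_neighbors = 8))
  pt <- path_pseudotime(ds, c("start", "end"), tivelo_config(k_neighbors = 8))
  root <- which(cluster_labels(ds) == "start")[1]
  expect_equal(pt$t[match(root, pt$cells)], 0, tolerance = 1e-9)
  # rank order matches the chain position (oracle: position along the line)
  expect_gt(cor(pt$t, base, method = "spearman"), 0.99)
  # rooting at the other chain end reverses the ranks; store the cells in
  # reverse order so the first stored "end" cell is the extreme one
  rev_idx <- rev(seq_len(n))
  ds_rev <- subset_dataset(ds, cells = rev_idx)
  ds_rev <- build_knn(ds_rev, tivelo_config(k_neighbors = 8))
  pt_rev <- path_pseudotime(ds_rev, c("end", "start"), tivelo_config(k_neighbors = 8))
  expect_lt(cor(pt_rev$t, base[rev_idx], method = "spearman"), -0.99)
  # strict ordering after tie-jitter
  expect_equal(anyDuplicated(pt$t), 0L)
})

test_that("series smoothing and normalization match hand computations", {
  expect_equal(tivelo:::series_smooth(c(0, 0, 1, 0, 0), 3),
               c(0, 1 / 3, 1 / 3, 1 / 3, 0))
  const <- rep(2, 10)
  expect_equal(tivelo:::series_smooth(const, 5), const)
  expect_equal(tivelo:::series_normalize(const, "sum"), rep(1 / 10, 10))
  y <- c(1, 4, 2, 0.5)
  expect_equal(sum(tivelo:::series_normalize(y, "sum")), 1)
  expect_equal(max(tivelo:::series_normalize(y, "max")), 1)
  # kernel longer than the series is clamped
  expect_length(tivelo:::series_smooth(c(1, 2, 3), 100), 3)
})

test_that("linear trees recover a single kink and respect the minimum interval", {
  cfg <- tivelo_config()
  # exact piecewise-linear series with a kink at index 40
  y <- c(seq(0, 2, length.out = 40), seq(2, 1, length.out = 61)[-1])
  tree <- fit_linear_tree(y, cfg)
  expect_equal(nrow(tree$segments), 2)
  expect_true(abs(tree$split_points[1] - 40) <= 1)
  expect_lt(sum(tree$segments$sse), 1e-10)
  expect_true(all(diff(tree$mse_path) <= 1e-15))

  # strictly linear series: no split, slope equals the closed form
  y2 <- 0.5 + 0.3 * (1:50)
  tree2 <- fit_linear_tree(y2, cfg)
  expect_equal(nrow(tree2$segments), 1)
  expect_equal(tree2$segments$slope, 0.3, tolerance = 1e-12)
  expect_equal(tree2$segments$slope,
               unname(coef(lm(y2 ~ x, data.frame(x = 1:50)))[2]),
               tolerance = 1e-10)

  # too short to split
  y3 <- rnorm(15)
  tree3 <- fit_linear_tree(y3, cfg)
  expect_equal(nrow(tree3$segments), 1)
  expect_true(all(tree3$segments$end - tree3$segments$start + 1 >= 1))

  # every segment respects the minimum interval
  set.seed(5)
  y4 <- cumsum(rnorm(200))
  tree4 <- fit_linear_tree(y4, cfg)
  expect_true(all(tree4$segments$end - tree4$segments$start + 1 >= cfg$tree_min_interval))

  # exhaustive oracle: the first split minimises total SSE over all
  # admissible positions
  y5 <- c(seq(0, 1, length.out = 30), seq(1, 0.2, length.out = 31)[-1])
  sse_at <- function(pos) {
    f <- function(a, b) {
      d <- data.frame(x = a:b, y = y5[a:b])
      sum(resid(lm(y ~ x, d))^2)
    }
    f(1, pos) + f(pos + 1, 60)
  }
  oracle <- which.min(vapply(10:50, sse_at, 0)) + 9
  tree5 <- fit_linear_tree(y5, cfg)
  expect_equal(tree5$split_points[1], oracle)
})

test_that("absolute-mode threshold of 100 never splits normalized series", {
  y <- tivelo:::series_normalize(c(seq(0, 1, length.out = 50), seq(1, 0, length.out = 50)), "sum")
  tree <- fit_linear_tree(y, tivelo_config(tree_mse_mode = "absolute"))
  expect_equal(nrow(tree$segments), 1)
})

test_that("the orientation score reproduces hand-computed section arithmetic", {
  # build two trees with known slopes via exactly linear pieces
  mk_tree <- function(slopes, lens) {
    start <- cumsum(c(1, lens[-length(lens)]))
    end <- cumsum(lens)
    structure(list(
      segments = tibble::tibble(
        start = as.integer(start), end = as.integer(end),
        slope = slopes, intercept = 0, sse = 0
      ),
      split_points = end[-length(end)], mse_path = 0, n = sum(lens)
    ), class = "tivelo_linear_tree")
  }
  # one rising section of length 4 with sum(d) = +0.02
  tu <- mk_tree(1, 4)
  ts <- mk_tree(0.5, 4)
  u <- rep(0.105, 4)  # d = 0.005 each, sum 0.02
  s <- rep(0.100, 4)
  expect_equal(orientation_score(tu, ts, u, s), 0.08, tolerance = 1e-12)

  # one falling section of length 5 with sum(d) = -0.03
  tu2 <- mk_tree(-1, 5)
  ts2 <- mk_tree(-0.5, 5)
  u2 <- rep(0.1, 5)
  s2 <- rep(0.106, 5)
  expect_equal(orientation_score(tu2, ts2, u2, s2), 0.15, tolerance = 1e-12)

  # identical series: d == 0 everywhere
  expect_equal(orientation_score(tu, ts, s, s), 0, tolerance = 1e-15)

  # mixed-sign section contributes nothing
  tu3 <- mk_tree(1, 6)
  ts3 <- mk_tree(-1, 6)
  expect_equal(orientation_score(tu3, ts3, rep(0.2, 6), rep(0.1, 6)), 0)

  # zero slope classifies as mixed
  tu4 <- mk_tree(0, 6)
  ts4 <- mk_tree(1, 6)
  expect_equal(orientation_score(tu4, ts4, rep(0.2, 6), rep(0.1, 6)), 0)

  # sections intersect the two segmentations
  tu5 <- mk_tree(c(1, -1), c(5, 5))
  ts5 <- mk_tree(c(1, -1), c(6, 4))  # overlap: [1,5]+, [6,6] mixed, [7,10]-
  u5 <- rep(0.12, 10)
  s5 <- rep(0.10, 10)
  # sections: [1,5] both rising (+1), [6,6] mixed (0), [7,10] both falling (-1)
  # score = (5 * 0.02) * 5 - (4 * 0.02) * 4 = 0.5 - 0.32
  expect_equal(orientation_score(tu5, ts5, u5, s5), 0.18, tolerance = 1e-12)
})

test_that("doubling a section's length doubles its contribution", {
  mk_tree <- function(slopes, lens) {
    start <- cumsum(c(1, lens[-length(lens)]))
    end <- cumsum(lens)
    structure(list(
      segments = tibble::tibble(
        start = as.integer(start), end = as.integer(end),
        slope = slopes, intercept = 0, sse = 0
      ),
      split_points = end[-length(end)], mse_path = 0, n = sum(lens)
    ), class = "tivelo_linear_tree")
  }
  d_per_cell <- 0.005
  s1 <- orientation_score(mk_tree(1, 4), mk_tree(1, 4),
                          rep(0.1 + d_per_cell, 4), rep(0.1, 4))
  s2 <- orientation_score(mk_tree(1, 8), mk_tree(1, 8),
                          rep(0.1 + d_per_cell, 8), rep(0.1, 8))
  expect_equal(s2, 4 * s1)  # sum(d) doubles and l doubles
})

test_that("a clean induction gene scores positive and reversal flips the sign", {
  k <- gene_kinetics(alpha = 4, beta = 2, gamma = 1)
  times <- seq(0.05, 3, length.out = 300)
  kv <- tivelo:::kinetics_evaluate(k, times)
  cfg <- tivelo_config()
  score_of <- function(u_raw, s_raw) {
    u <- tivelo:::series_normalize(tivelo:::series_smooth(u_raw, cfg$smoothing_kernel), "sum")
    s <- tivelo:::series_normalize(tivelo:::series_smooth(s_raw, cfg$smoothing_kernel), "sum")
    orientation_score(fit_linear_tree(u, cfg), fit_linear_tree(s, cfg), u, s)
  }
  fwd <- score_of(kv$u, kv$s)
  rev <- score_of(rev(kv$u), rev(kv$s))
  expect_gt(fwd, 0)
  expect_lt(rev, 0)
})

test_that("the velocity-gene filter applies all three thresholds", {
  set.seed(8)
  n <- 100
  s_base <- runif(n, 1, 5)
  s <- cbind(
    s_base,            # gene 1: u = 0.5 s exactly -> kept
    s_base,            # gene 2: u uncorrelated noise -> dropped (R2)
    s_base,            # gene 3: sd ratio 10 -> dropped
    rep(2, n)          # gene 4: zero variance in s -> excluded
  )
  u <- cbind(
    0.5 * s_base,
    pmax(rnorm(n, mean = 2, sd = 1), 0),
    10 * (s_base - mean(s_base)) + 20,
    runif(n, 1, 2)
  )
  ds <- tivelo_dataset(s, u)
  ds$layers$spliced_smooth <- s
  ds$layers$unspliced_smooth <- u
  keep <- velocity_gene_filter(ds, tivelo_config())
  expect_true(1 %in% keep)
  expect_false(2 %in% keep)
  expect_false(3 %in% keep)
  expect_false(4 %in% keep)
})

test_that("origin inference keeps, reverses, or follows a branch as scored", {
  ds <- small_preprocessed("linear")
  cfg <- tivelo_config()
  g <- build_cluster_graph(ds)
  g <- prune_graph(g, cfg)
  g <- score_terminal_states(ds, g)
  g <- select_origin(g, cfg)
  path <- select_main_path(g)
  out <- infer_orientation(ds, g, path, cfg)
  # case 1: a positive mean keeps the source end, a negative one flips it
  if (out$report$mean_score >= 0) {
    expect_equal(out$graph$origin, path$nodes[1])
    expect_equal(out$report$decision, "keep")
  } else {
    expect_equal(out$graph$origin, path$nodes[length(path$nodes)])
    expect_equal(out$report$decision, "reverse")
  }
  # regardless of starting endpoint, the inferred origin is the true root
  expect_equal(out$graph$origin, ds$uns$true_root)
})

test_that("a branch attached at the corrected source endpoint relocates the origin", {
  # start the path at the mid-chain cluster B of the linear lineage
  # A -> B -> C -> D -> E: the greedy path runs B -> C -> D -> E (heavier
  # side) and A remains as a branch attached at the source endpoint B; the
  # branch scores negative (true flow A -> B), so the origin moves to A
  res <- full_run("linear", fit_mode = "simple_fit")
  ds <- res$dataset
  cfg <- tivelo_config()
  # clean chain weights isolate the rule from connectivity noise
  g <- build_cluster_graph(ds, weights = chain_weights(c("A", "B", "C", "D", "E"), 0.8))
  g <- prune_graph(g, cfg)
  g$origin <- "B"
  path <- select_main_path(g)
  expect_equal(path$nodes, c("B", "C", "D", "E"))
  expect_equal(path$branches[[1]]$nodes, "A")
  out <- infer_orientation(ds, g, path, cfg)
  expect_gte(out$report$mean_score, 0)  # B -> E is the true direction
  expect_lt(mean(out$report$branch_scores$score, na.rm = TRUE), 0)
  expect_equal(out$graph$origin, "A")
})

test_that("no qualifying velocity genes raises an actionable error", {
  ds <- small_preprocessed("linear")
  cfg <- tivelo_config(velocity_gene_r2_min = 2)  # impossible threshold
  g <- build_cluster_graph(ds)
  g <- prune_graph(g, cfg)
  g <- score_terminal_states(ds, g)
  g <- select_origin(g, cfg)
  path <- select_main_path(g)
  expect_error(infer_orientation(ds, g, path, cfg), "relax")
})
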