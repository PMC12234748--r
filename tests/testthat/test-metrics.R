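# a small random instance shared by the metric oracle checks
metric_instance <- function(n = 50, g = 6, seed = 10) {
  cached(sprintf("metric_%d_%d_%d", n, g, seed), {
    set.seed(seed)
    s <- matrix(runif(n * g, 0, 5), n, g)
    u <- matrix(runif(n * g, 0, 2), n, g)
    v <- matrix(rnorm(n * g), n, g)
    knn <- t(vapply(seq_len(n), function(i) setdiff(sample(n), i)[1:7], integer(7)))
    labels <- sample(c("A", "B", "C"), n, replace = TRUE)
    ds <- tivelo_dataset(s, u, obs = tibble::tibble(
      cell = sprintf("c%d", 1:n), cluster = labels
    ))
    ds$layers$spliced_smooth <- s
    ds$knn <- knn
    ds$embedding <- prcomp(s, rank. = 2)$x
    list(ds = ds, v = v, labels = labels, knn = knn)
  })
}

test_that("CBDir matches its definition on constructed pairs and a dense oracle", {
  # single contributing pair with the velocity equal to the displacement
  s <- rbind(c(0, 0), c(1, 1), c(5, 5))
  ds <- tivelo_dataset(s, s)
  ds$layers$spliced_smooth <- s
  ds$knn <- rbind(c(2L, 3L), c(1L, 3L), c(1L, 2L))
  ds$obs$cluster <- c("A", "B", "B")
  v <- rbind(s[2, ] - s[1, ], c(0, 0), c(0, 0))
  vf <- tivelo:::new_velocity_field(v, v, "fit")
  edges <- cluster_edges("A", "B")
  got <- cbdir(ds, vf, edges, space = "gene")
  # cell 1 has both B cells as neighbours: mean of cos(1) and cos to cell 3
  expect_equal(got$per_edge$score[1], 1, tolerance = 1e-12)
  # reversed velocity gives -1
  vf2 <- tivelo:::new_velocity_field(-v, -v, "fit")
  expect_equal(cbdir(ds, vf2, edges, space = "gene")$mean, -1, tolerance = 1e-12)

  inst <- metric_instance()
  vf3 <- tivelo:::new_velocity_field(inst$v, inst$v, "fit")
  for (edge in list(c("A", "B"), c("B", "C"), c("C", "A"))) {
    got <- cbdir(inst$ds, vf3, cluster_edges(edge[1], edge[2]), space = "gene")
    want <- oracle_cbdir(inst$ds$layers$spliced_smooth, inst$v, inst$labels,
                         inst$knn, edge[1], edge[2])
    expect_equal(got$per_edge$score[1], want, tolerance = 1e-10)
  }
  # unknown cluster in the edge set
  expect_error(cbdir(inst$ds, vf3, cluster_edges("A", "nope")), "unknown")
})

test_that("TransCosine matches the brute-force pair mean and handles empty edges", {
  inst <- metric_instance()
  vf <- tivelo:::new_velocity_field(inst$v, inst$v, "fit")
  vg <- velocity_graph(inst$ds, vf, tivelo_config())
  pi_dense <- as.matrix(vg$pi)
  for (edge in list(c("A", "B"), c("C", "B"))) {
    got <- trans_cosine(vg, cluster_edges(edge[1], edge[2]), inst$labels)
    want <- oracle_trans_cosine(pi_dense, inst$labels, inst$knn, edge[1], edge[2])
    expect_equal(got$per_edge$score[1], want, tolerance = 1e-10)
  }
  # perfect transitions: all contributing cosines one
  s <- rbind(c(0, 0), c(1, 0), c(2, 0))
  ds <- tivelo_dataset(s, s)
  ds$layers$spliced_smooth <- s
  ds$knn <- rbind(c(2L, 3L), c(3L, 1L), c(2L, 1L))
  ds$obs$cluster <- c("A", "B", "B")
  v <- rbind(c(1, 0), c(1, 0), c(0, 0))
  vgp <- velocity_graph(ds, tivelo:::new_velocity_field(v, v, "fit"), tivelo_config())
  expect_equal(trans_cosine(vgp, cluster_edges("A", "B"), c("A", "B", "B"))$mean, 1,
               tolerance = 1e-12)
  # an edge whose source cells have no target-cluster neighbours is
  # undefined and excluded from the mean
  s4 <- matrix(runif(8), 4, 2)
  ds4 <- tivelo_dataset(s4, s4)
  ds4$layers$spliced_smooth <- s4
  ds4$obs$cluster <- c("A", "A", "B", "B")
  ds4$knn <- rbind(c(2L), c(1L), c(1L), c(3L))  # A cells only see A; cell 3 sees A
  v4 <- matrix(rnorm(8), 4, 2)
  vg4 <- velocity_graph(ds4, tivelo:::new_velocity_field(v4, v4, "fit"), tivelo_config())
  out4 <- trans_cosine(vg4, cluster_edges(c("A", "B"), c("B", "A")), ds4$obs$cluster)
  expect_true(is.na(out4$per_edge$score[1]))
  expect_false(is.na(out4$per_edge$score[2]))
  expect_equal(out4$mean, out4$per_edge$score[2])
})

test_that("VeloCoh matches the dense matrix-product oracle and its identities", {
  inst <- metric_instance()
  vf <- tivelo:::new_velocity_field(inst$v, inst$v, "fit")
  vg <- velocity_graph(inst$ds, vf, tivelo_config())
  got <- velo_coh(inst$ds, vf, vg)
  want <- oracle_velo_coh(inst$ds$layers$spliced_smooth, inst$v, as.matrix(vg$pi))
  expect_equal(got$per_cell, want, tolerance = 1e-10)
  # velocity equal to the predicted displacement scores one for that cell
  s <- inst$ds$layers$spliced_smooth
  pi_dense <- as.matrix(vg$pi)
  n0 <- which(rowSums(pi_dense) > 0)[1]
  disp <- colSums(pi_dense[n0, ] * s) / sum(pi_dense[n0, ]) - s[n0, ]
  vf_eq <- vf
  vf_eq$v_s[n0, ] <- disp
  expect_equal(velo_coh(inst$ds, vf_eq, vg)$per_cell[n0], 1, tolerance = 1e-12)
  # orthogonal velocity scores zero
  orth <- c(-disp[2], disp[1], rep(0, length(disp) - 2))
  vf_orth <- vf
  vf_orth$v_s[n0, ] <- orth
  expect_equal(velo_coh(inst$ds, vf_orth, vg)$per_cell[n0], 0, tolerance = 1e-10)
})

test_that("all cosine metrics are invariant to positive velocity rescaling", {
  inst <- metric_instance()
  vf <- tivelo:::new_velocity_field(inst$v, inst$v, "fit")
  vf_scaled <- tivelo:::new_velocity_field(inst$v * 3.7, inst$v * 3.7, "fit")
  edges <- cluster_edges("A", "B")
  expect_equal(cbdir(inst$ds, vf, edges, "gene")$mean,
               cbdir(inst$ds, vf_scaled, edges, "gene")$mean, tolerance = 1e-12)
  vg <- velocity_graph(inst$ds, vf, tivelo_config())
  vg_s <- velocity_graph(inst$ds, vf_scaled, tivelo_config())
  expect_equal(trans_cosine(vg, edges, inst$labels)$mean,
               trans_cosine(vg_s, edges, inst$labels)$mean, tolerance = 1e-12)
  expect_equal(velo_coh(inst$ds, vf, vg)$mean,
               velo_coh(inst$ds, vf_scaled, vg_s)$mean, tolerance = 1e-12)
})

test_that("sign accuracy scores exact, negated and random fields as expected", {
  set.seed(6)
  n_pos <- 10
  per <- 4
  g <- 50
  positions <- rep(seq_len(n_pos), each = per)
  s <- matrix(rnorm(n_pos * per * g), n_pos * per, g)
  ds <- tivelo_dataset(pmax(s + 5, 0), pmax(s + 5, 0))
  s_raw <- ds$spliced
  # per-position means and their forward differences
  s_bar <- t(vapply(seq_len(n_pos), function(p) colMeans(s_raw[positions == p, , drop = FALSE]),
                    numeric(g)))
  emp <- s_bar[-1, , drop = FALSE] - s_bar[-n_pos, , drop = FALSE]
  # inferred velocity exactly the empirical difference -> accuracy 1
  v_exact <- matrix(0, n_pos * per, g)
  for (p in seq_len(n_pos - 1)) v_exact[positions == p, ] <- rep(emp[p, ], each = per)
  out <- sign_accuracy(ds, v_exact, positions)
  expect_equal(out$mean, 1)
  expect_equal(nrow(out$per_position), n_pos - 1)
  # negated velocity: accuracy 0 (no zero components almost surely)
  expect_equal(sign_accuracy(ds, -v_exact, positions)$mean, 0)
  # random independent three-way signs agree about half the time here
  # (continuous values make the zero class empty, two equiprobable signs)
  set.seed(7)
  v_rand <- matrix(rnorm(n_pos * per * g), n_pos * per, g)
  acc <- sign_accuracy(ds, v_rand, positions)$mean
  expect_lt(abs(acc - 0.5), 0.15)
  expect_error(sign_accuracy(ds, v_exact, rep(1, n_pos * per)), "two cycle positions")
})

test_that("the difference reading of estimated velocity is available", {
  cyc <- make_fixture("cycle", seed = 0)
  truth <- cyc$layers$true_velocity
  a <- sign_accuracy(cyc, truth, cyc$obs$cycle_position, estimated = "mean")
  b <- sign_accuracy(cyc, truth, cyc$obs$cycle_position, estimated = "difference")
  expect_true(is.finite(a$mean) && is.finite(b$mean))
  expect_gte(a$mean, b$mean - 1)  # both defined on the same grid
})
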