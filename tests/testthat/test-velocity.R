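level_graph <- function(w, sizes, origin) {
  g <- graph_from_weights(w, sizes)
  g$origin <- origin
  g
}

test_that("level assignment walks the chain and respects thresholds", {
  w <- chain_weights(c("o", "a", "b"), 0.8)
  g <- assign_levels(level_graph(w, rep(10, 3), "o"), tivelo_config())
  expect_equal(unname(g$levels[c("o", "a", "b")]), c(0L, 1L, 2L))

  # shortcut suppression: w(o,b) weaker than z2 * w(o,a) * w(a,b)
  w2 <- named_matrix(c("o", "a", "b"),
    list("o", "a", 0.9), list("a", "b", 0.9), list("o", "b", 0.3)
  )
  g2 <- assign_levels(level_graph(w2, rep(10, 3), "o"), tivelo_config())
  expect_equal(unname(g2$levels["b"]), 2L)

  # an edge below z1 does not level the node from the origin
  w3 <- named_matrix(c("o", "x", "y"),
    list("o", "x", 0.05), list("o", "y", 0.5), list("y", "x", 0.6)
  )
  g3 <- assign_levels(level_graph(w3, rep(10, 3), "o"), tivelo_config())
  expect_equal(unname(g3$levels["x"]), 2L)  # reached through y, not o
})

test_that("unreachable nodes are attached below their strongest neighbour", {
  w <- named_matrix(c("o", "a", "iso"),
    list("o", "a", 0.9), list("a", "iso", 0.05)
  )
  expect_warning(
    g <- assign_levels(level_graph(w, rep(10, 3), "o"), tivelo_config()),
    "unreachable|isolated"
  )
  expect_equal(unname(g$levels["iso"]), unname(g$levels["a"]) + 1L)
})

test_that("child assignment enforces the single-parent rule", {
  w <- chain_weights(c("o", "a", "b"), 0.8)
  g <- assign_children(assign_levels(level_graph(w, rep(10, 3), "o"), tivelo_config()),
                       tivelo_config())
  expect_equal(g$children$o, "a")
  expect_equal(g$children$a, "b")
  expect_equal(nrow(g$dti_edges), 2)

  # two level-k parents compete: the stronger weight wins
  w2 <- named_matrix(c("o", "i1", "i2", "j"),
    list("o", "i1", 0.9), list("o", "i2", 0.9),
    list("i1", "j", 0.3), list("i2", "j", 0.7)
  )
  g2 <- assign_children(assign_levels(level_graph(w2, rep(10, 4), "o"), tivelo_config()),
                        tivelo_config())
  expect_equal(unname(g2$parent["j"]), "i2")
  expect_false("j" %in% g2$children$i1)

  # a node isolated by the z1 threshold attaches to its strongest neighbour
  w3 <- named_matrix(c("o", "a", "far"),
    list("o", "a", 0.9), list("a", "far", 0.05), list("o", "far", 0.02)
  )
  suppressWarnings({
    g3 <- assign_children(assign_levels(level_graph(w3, rep(10, 3), "o"), tivelo_config()),
                          tivelo_config())
  })
  expect_equal(unname(g3$parent["far"]), "a")
  # every non-origin node has exactly one parent
  expect_false(anyNA(g3$parent[c("a", "far")]))
})

test_that("directed neighbourhoods respect pseudotime and the cluster rules", {
  res <- full_run("linear", fit_mode = "simple_fit")
  ds <- res$dataset
  dnn <- res$dnn
  g <- res$graph
  labels <- cluster_labels(ds)
  for (n in sample(n_cells(ds), 200)) {
    members <- dnn$members[[n]]
    if (length(members) == 0) next
    expect_true(all(members %in% ds$knn[n, ]))
    expect_true(all(dnn$t_prime[members] > dnn$t_prime[n]))
    expect_true(all(labels[members] %in% c(labels[n], g$children[[labels[n]]])))
  }
  # a terminal cell whose neighbours are all earlier has an empty dnn
  terminal <- which.max(dnn$t_prime)
  expect_length(dnn$members[[terminal]], 0)
  # on noiseless data, mid-path neighbourhoods point downstream in
  # ground-truth latent time
  clean <- cached("dnn_noiseless", {
    d0 <- make_fixture("linear", n_cells = 800, n_genes = 60, noise = "none", seed = 1)
    st <- run_orientation_stage(d0)
    cfg <- tivelo_config()
    gg <- assign_children(assign_levels(st$graph, cfg), cfg)
    list(ds = st$dataset, dnn = build_dnn(st$dataset, gg, cfg))
  })
  lab0 <- cluster_labels(clean$ds)
  mid <- which(lab0 == "C")
  with_dnn <- mid[clean$dnn$sizes[mid] > 0]
  expect_gt(length(with_dnn), 0)
  frac_down <- mean(vapply(with_dnn, function(n) {
    mean(clean$ds$obs$latent_time[clean$dnn$members[[n]]] > clean$ds$obs$latent_time[n])
  }, 0))
  expect_gt(frac_down, 0.9)
})

test_that("simple_fit reproduces neighbourhood means and zeroes the objective", {
  # constructed instance: u_n = 2, dnn mean 5 -> velocity 3
  u <- matrix(c(2, 5, 5), 3, 1)
  s <- matrix(c(1, 4, 6), 3, 1)
  ds <- tivelo_dataset(s, u)
  ds$layers$spliced_smooth <- s
  ds$layers$unspliced_smooth <- u
  mask <- Matrix::sparseMatrix(i = c(1, 1), j = c(2, 3), x = 1, dims = c(3, 3))
  dnn <- structure(list(
    members = list(c(2L, 3L), integer(), integer()),
    mask = mask, sizes = c(2L, 0L, 0L), t_prime = c(0, 1, 2)
  ), class = "tivelo_dnn")
  vf <- simple_fit(ds, dnn)
  expect_equal(vf$v_u[1, 1], 3)
  expect_equal(vf$v_s[1, 1], 4)
  expect_equal(vf$v_u[2, 1], 0)  # empty dnn
  expect_equal(tivelo:::pointing_objective(vf, ds, dnn), 0)
})

test_that("the pointing objective vanishes at the simple fit on real fixtures", {
  res <- full_run("linear", fit_mode = "simple_fit")
  vf <- simple_fit(res$dataset, res$dnn)
  expect_equal(tivelo:::pointing_objective(vf, res$dataset, res$dnn), 0,
               tolerance = 1e-18)
})

test_that("the regularised fit degenerates to the simple fit at lambda_prime zero", {
  res <- full_run("linear", fit_mode = "simple_fit")
  vf0 <- fit_velocity(res$dataset, res$dnn, tivelo_config(lambda_prime = 0))
  vfs <- simple_fit(res$dataset, res$dnn)
  expect_equal(vf0$v_u, vfs$v_u)
  expect_equal(vf0$v_s, vfs$v_s)
})

test_that("consistency regularisation increases neighbour velocity agreement", {
  res <- full_run("linear", fit_mode = "simple_fit")
  ds <- res$dataset
  cfg <- tivelo_config(fit_iterations = 100)
  vfs <- simple_fit(ds, res$dnn)
  vfr <- fit_velocity(ds, res$dnn, cfg)
  labels <- cluster_labels(ds)
  mean_neighbour_cos <- function(vf) {
    v <- cbind(vf$v_u, vf$v_s)
    norms <- pmax(sqrt(rowSums(v^2)), 1e-12)
    u_mat <- v / norms
    vals <- c()
    for (n in seq_len(nrow(v))) {
      nb <- ds$knn[n, labels[ds$knn[n, ]] == labels[n]]
      if (length(nb) > 0) vals <- c(vals, u_mat[nb, , drop = FALSE] %*% u_mat[n, ])
    }
    mean(vals)
  }
  expect_gte(mean_neighbour_cos(vfr), mean_neighbour_cos(vfs) - 1e-9)
  # and the combined objective did not increase from the initial point
  expect_lte(vfr$trace[length(vfr$trace)], vfr$trace[1] + 1e-9)

  # determinism: same seed, same field
  vfr2 <- fit_velocity(ds, res$dnn, cfg)
  expect_identical(vfr$v_s, vfr2$v_s)
})

test_that("kinetic-rate velocities follow the rate equations and vary smoothly", {
  ds <- small_fixture("linear", n_cells = 300, n_genes = 15, noise = "none", seed = 2)
  ds <- suppressMessages(preprocess(ds, tivelo_config()))
  g <- build_cluster_graph(ds)
  g <- prune_graph(g, tivelo_config())
  g <- score_terminal_states(ds, g)
  g$origin <- "A"
  path <- select_main_path(g)
  g <- assign_children(assign_levels(g, tivelo_config()), tivelo_config())
  dnn <- build_dnn(ds, g, tivelo_config())
  cfg <- tivelo_config(kinetic_epochs = 50)
  vf <- fit_kinetic(ds, dnn, cfg)
  expect_true(all(vf$rates$alpha >= 0))
  expect_true(all(vf$rates$beta >= 0))
  expect_true(all(vf$rates$gamma >= 0))
  # velocities reproduce the kinetic relations exactly
  sm <- tivelo:::smoothed_layers(ds)
  expect_equal(vf$v_u, vf$rates$alpha - vf$rates$beta * sm$u, tolerance = 1e-12)
  expect_equal(vf$v_s, vf$rates$beta * sm$u - vf$rates$gamma * sm$s, tolerance = 1e-12)
  # continuity: the two most similar cells get near-identical rates
  d <- as.matrix(dist(cbind(sm$u, sm$s)))
  diag(d) <- Inf
  pair <- arrayInd(which.min(d), dim(d))
  gap_in <- d[pair]
  gap_rates <- max(abs(vf$rates$gamma[pair[1], ] - vf$rates$gamma[pair[2], ]))
  expect_lt(gap_rates, 0.05 + gap_in)
  # training is seeded and reproducible
  vf2 <- fit_kinetic(ds, dnn, cfg)
  expect_identical(vf$rates$gamma, vf2$rates$gamma)
  # loss decreases over training
  expect_lt(vf$trace[length(vf$trace)], vf$trace[1])
})

test_that("the velocity graph matches a dense cosine oracle and basic identities", {
  set.seed(3)
  n <- 40
  s <- matrix(runif(n * 5), n, 5)
  v <- matrix(rnorm(n * 5), n, 5)
  knn <- t(vapply(seq_len(n), function(i) {
    setdiff(sample(n), i)[1:6]
  }, integer(6)))
  ds <- tivelo_dataset(s, matrix(0, n, 5))
  ds$layers$spliced_smooth <- s
  ds$knn <- knn
  vf <- tivelo:::new_velocity_field(v, v, "fit")
  vg <- velocity_graph(ds, vf, tivelo_config())
  expect_equal(as.matrix(vg$pi), oracle_velocity_graph(s, v, knn),
               tolerance = 1e-12, ignore_attr = TRUE)
  # rows of the transition matrix sum to one over the support
  expect_equal(unname(Matrix::rowSums(vg$pi_tilde)), rep(1, n), tolerance = 1e-12)
  # exact parallel displacement gives cosine one
  i <- 1
  j <- knn[1, 1]
  vf2 <- vf
  vf2$v_s[i, ] <- s[j, ] - s[i, ]
  vg2 <- velocity_graph(ds, vf2, tivelo_config())
  expect_equal(vg2$pi[i, j], 1, tolerance = 1e-12)
  # positive rescaling of velocities leaves the graph unchanged
  vf3 <- vf
  vf3$v_s <- vf$v_s * 7.5
  vg3 <- velocity_graph(ds, vf3, tivelo_config())
  expect_equal(as.matrix(vg3$pi), as.matrix(vg$pi), tolerance = 1e-12)
  # zero-norm velocity: zero cosine row, uniform transition row
  vf4 <- vf
  vf4$v_s[2, ] <- 0
  vg4 <- velocity_graph(ds, vf4, tivelo_config())
  expect_equal(sum(abs(vg4$pi[2, ])), 0)
  expect_equal(unname(vg4$pi_tilde[2, knn[2, ]]), rep(1 / 6, 6), tolerance = 1e-12)
})

test_that("embedding velocities cancel under uniform transitions and follow a dominant target", {
  n <- 30
  set.seed(4)
  e <- matrix(rnorm(n * 2), n, 2)
  ds <- tivelo_dataset(matrix(1, n, 3), matrix(1, n, 3))
  ds$embedding <- e
  # uniform transitions over all pairs: exact cancellation
  pt_uniform <- Matrix::Matrix(matrix(1 / n, n, n), sparse = TRUE)
  vg <- structure(list(pi_tilde = pt_uniform, sigma = 1), class = "tivelo_velocity_graph")
  ve <- embedding_velocity(ds, vg)
  expect_equal(max(abs(ve)), 0, tolerance = 1e-10)
  # a single dominant target pulls the vector toward it
  pt <- matrix(0, n, n)
  pt[1, 2] <- 1
  vg2 <- structure(list(pi_tilde = Matrix::Matrix(pt, sparse = TRUE), sigma = 1),
                   class = "tivelo_velocity_graph")
  ve2 <- embedding_velocity(ds, vg2)
  delta <- (e[2, ] - e[1, ]) / sqrt(sum((e[2, ] - e[1, ])^2))
  expect_gt(sum(ve2[1, ] * delta) / sqrt(sum(ve2[1, ]^2)), 0.99)
})
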