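# Shared small fixtures and independent oracles. Fixtures are cached per
# session so expensive objects are built once.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small, quick version of a fixture for unit tests
small_fixture <- function(name, n_cells = 400, n_genes = 40, noise = NULL, seed = 0L) {
  cached(sprintf("small_%s_%d_%d_%s_%d", name, n_cells, n_genes,
                 noise %||% "default", seed), {
    make_fixture(name, n_cells = n_cells, n_genes = n_genes, noise = noise, seed = seed)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# preprocessed small fixture
small_preprocessed <- function(name, ...) {
  key <- sprintf("prep_%s_%s", name, paste(unlist(list(...)), collapse = "_"))
  cached(key, suppressMessages(preprocess(small_fixture(name, ...), tivelo_config())))
}

# two well-separated Gaussian blobs with raw-count-like values
blob_dataset <- function(n_per = 100, n_genes = 30, seed = 1) {
  set.seed(seed)
  centers <- rbind(rep(c(10, 0), length.out = n_genes),
                   rep(c(0, 10), length.out = n_genes))
  s <- rbind(
    matrix(rpois(n_per * n_genes, lambda = rep(centers[1, ] + 2, each = n_per)), n_per),
    matrix(rpois(n_per * n_genes, lambda = rep(centers[2, ] + 2, each = n_per)), n_per)
  )
  u <- matrix(rpois(2 * n_per * n_genes, lambda = 2), 2 * n_per)
  tivelo_dataset(s, u, obs = tibble::tibble(
    cell = sprintf("c%d", seq_len(2 * n_per)),
    truth = rep(c("a", "b"), each = n_per)
  ))
}

# ---- independent oracles ----------------------------------------------

# dense cosine between rows of two matrices
oracle_cos <- function(a, b) {
  sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
}

# brute-force CBDir: double loop over cells and neighbours
oracle_cbdir <- function(x, v, labels, knn, from, to) {
  vals <- c()
  for (n in which(labels == from)) {
    inner <- c()
    for (np in knn[n, ]) {
      if (labels[np] == to) inner <- c(inner, oracle_cos(v[n, ], x[np, ] - x[n, ]))
    }
    if (length(inner) > 0) vals <- c(vals, mean(inner))
  }
  if (length(vals) == 0) NA_real_ else mean(vals)
}

# brute-force velocity-graph cosine matrix (dense, zero off support)
oracle_velocity_graph <- function(s, v, knn) {
  n <- nrow(s)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in knn[i, ]) {
      d <- s[j, ] - s[i, ]
      den <- sqrt(sum(d^2)) * sqrt(sum(v[i, ]^2))
      out[i, j] <- if (den > 0) sum(d * v[i, ]) / den else 0
    }
  }
  out
}

# brute-force TransCosine for one edge
oracle_trans_cosine <- function(pi_dense, labels, knn, from, to) {
  vals <- c()
  for (n in which(labels == from)) {
    inner <- c()
    for (np in knn[n, ]) {
      if (labels[np] == to) inner <- c(inner, pi_dense[n, np])
    }
    if (length(inner) > 0) vals <- c(vals, mean(inner))
  }
  if (length(vals) == 0) NA_real_ else mean(vals)
}

# brute-force VeloCoh via dense matrix products
oracle_velo_coh <- function(s, v, pi_dense) {
  rs <- rowSums(pi_dense)
  out <- rep(NA_real_, nrow(s))
  for (n in seq_len(nrow(s))) {
    if (rs[n] <= 0) next
    pred <- colSums(pi_dense[n, ] * s) / rs[n]
    disp <- pred - s[n, ]
    den <- sqrt(sum(disp^2)) * sqrt(sum(v[n, ]^2))
    if (den > 0) out[n] <- sum(disp * v[n, ]) / den
  }
  out
}

# numerical ODE integration oracle for the splicing kinetics
oracle_integrate_kinetics <- function(k, times, dt = NULL) {
  t_max <- max(times)
  if (is.null(dt)) dt <- t_max / (length(times) * 10)
  alpha_at <- function(t) {
    a <- k$alpha
    if (isTRUE(k$is_murk) && is.finite(k$murk_time) && t >= k$murk_time) {
      a <- a * k$murk_factor
    }
    if (is.finite(k$switch_time) && t >= k$switch_time) a <- 0
    a
  }
  grid <- seq(0, t_max, by = dt)
  u <- s <- numeric(length(grid))
  for (i in seq_len(length(grid) - 1)) {
    # RK4 step
    f <- function(t, y) c(alpha_at(t) - k$beta * y[1], k$beta * y[1] - k$gamma * y[2])
    y <- c(u[i], s[i])
    t <- grid[i]
    k1 <- f(t, y)
    k2 <- f(t + dt / 2, y + dt / 2 * k1)
    k3 <- f(t + dt / 2, y + dt / 2 * k2)
    k4 <- f(t + dt, y + dt * k3)
    ynext <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    u[i + 1] <- ynext[1]
    s[i + 1] <- ynext[2]
  }
  idx <- vapply(times, function(t) which.min(abs(grid - t)), 0L)
  list(u = u[idx], s = s[idx])
}

# stages of the pipeline up to orientation, for direction-recovery checks
run_orientation_stage <- function(ds, cfg = tivelo_config()) {
  ds <- suppressMessages(preprocess(ds, cfg))
  g <- build_cluster_graph(ds)
  g <- prune_graph(g, cfg)
  g <- score_terminal_states(ds, g, sigma = cfg$sigma)
  g <- select_origin(g, cfg)
  path <- select_main_path(g)
  ori <- infer_orientation(ds, g, path, cfg)
  list(dataset = ds, graph = ori$graph, path = path, report = ori$report)
}

# cached full pipeline run on a standard-size fixture (shared across
# acceptance checks)
full_run <- function(name, seed = 0L, fit_mode = "fit") {
  cached(sprintf("run_%s_%d_%s", name, seed, fit_mode), {
    suppressMessages(suppressWarnings(
      tivelo_run(make_fixture(name, seed = seed), tivelo_config(fit_mode = fit_mode))
    ))
  })
}

# ---- explicit cluster-graph construction for unit tests ----------------

graph_from_weights <- function(w, sizes) {
  nodes <- rownames(w)
  structure(
    list(
      weights = w,
      nodes = tibble::tibble(node = nodes, n_cells = as.integer(sizes)),
      retained = nodes, dropped = character(),
      components = list(nodes), origin = NULL,
      origin_rule = NA_integer_, log = character()
    ),
    class = "tivelo_cluster_graph"
  )
}

named_matrix <- function(nodes, ...) {
  w <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (e in list(...)) {
    w[e[[1]], e[[2]]] <- w[e[[2]], e[[1]]] <- e[[3]]
  }
  w
}

chain_weights <- function(nodes, w = 0.8) {
  m <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (i in seq_len(length(nodes) - 1)) {
    m[nodes[i], nodes[i + 1]] <- m[nodes[i + 1], nodes[i]] <- w
  }
  m
}
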