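#' Transcription kinetics of one simulated gene
#'
#' Each gene follows the splicing ODE `u' = alpha(t) - beta u`,
#' `s' = beta u - gamma s` with a piecewise-constant transcription rate.
#' `alpha(t)` starts at `alpha`; for a multiple-rate-kinetics (MURK) gene it
#' steps up to `alpha * murk_factor` at `murk_time`; it drops to 0 at
#' `switch_time` (induction to repression). Defaults `beta = 2`, `gamma = 1`
#' per unit pseudotime make unspliced RNA visibly lead spliced RNA.
#'
#' @param alpha Baseline transcription rate (>= 0).
#' @param beta Splicing rate (> 0).
#' @param gamma Degradation rate (> 0).
#' @param switch_time Pseudotime at which transcription shuts off; `Inf`
#'   for a gene that keeps transcribing.
#' @param is_murk Whether the rate steps up during development.
#' @param murk_time Pseudotime of the step increase (MURK genes only).
#' @param murk_factor Fold change of the step increase.
#' @param branch_scale Optional named numeric vector mapping lineage nodes
#'   to a multiplicative factor on `alpha`, giving branch-specific
#'   expression programs (nodes not named keep factor 1).
#' @return A list of class `gene_kinetics`.
#' @export
gene_kinetics <- function(alpha = 4, beta = 2, gamma = 1,
                          switch_time = Inf, is_murk = FALSE,
                          murk_time = NA_real_, murk_factor = 3,
                          branch_scale = NULL) {
  if (!is.finite(beta) || beta <= 0 || !is.finite(gamma) || gamma <= 0) {
    abort("beta and gamma must be finite and positive")
  }
  if (alpha < 0) abort("alpha must be non-negative")
  if (is_murk && (!is.finite(murk_time) || murk_factor <= 0)) {
    abort("MURK genes need a finite murk_time and a positive murk_factor")
  }
  structure(
    list(
      alpha = alpha, beta = beta, gamma = gamma, switch_time = switch_time,
      is_murk = is_murk, murk_time = murk_time, murk_factor = murk_factor,
      branch_scale = branch_scale
    ),
    class = "gene_kinetics"
  )
}

# breakpoints and values of alpha(t) on [0, t_max]; `scale` is an optional
# piecewise-constant multiplier (list with $breaks, $values) carrying
# branch-specific programs
alpha_pieces <- function(k, t_max, scale = NULL) {
  breaks <- 0
  values <- k$alpha
  if (k$is_murk && k$murk_time < t_max) {
    breaks <- c(breaks, k$murk_time)
    values <- c(values, k$alpha * k$murk_factor)
  }
  if (is.finite(k$switch_time) && k$switch_time < t_max) {
    breaks <- c(breaks, k$switch_time)
    values <- c(values, 0)
  }
  if (!is.null(scale)) {
    all_breaks <- sort(unique(c(breaks, scale$breaks)))
    base <- values[findInterval(all_breaks, breaks)]
    mult <- scale$values[findInterval(all_breaks, scale$breaks)]
    breaks <- all_breaks
    values <- base * mult
  }
  list(breaks = breaks, values = values)
}

# closed-form advance of (u, s) by tau under constant alpha
kinetics_step <- function(u0, s0, alpha, beta, gamma, tau) {
  eb <- exp(-beta * tau)
  eg <- exp(-gamma * tau)
  ub <- alpha / beta
  us <- alpha / gamma
  b <- u0 - ub
  u <- ub + b * eb
  if (abs(beta - gamma) > 1e-12) {
    c1 <- beta * b / (gamma - beta)
    s <- us + c1 * eb + (s0 - us - c1) * eg
  } else {
    # beta == gamma limit: the cross term becomes beta*b*tau*exp(-beta tau)
    s <- us + (s0 - us + beta * b * tau) * eb
  }
  list(u = u, s = s)
}

# evaluate u(t), s(t) and the true velocities at sorted times along one
# lineage, integrating piecewise from (0, 0) at t = 0
kinetics_evaluate <- function(k, times, scale = NULL) {
  t_max <- if (length(times)) max(times) else 0
  pieces <- alpha_pieces(k, t_max + 1, scale = scale)
  breaks <- c(pieces$breaks, Inf)
  u <- s <- numeric(length(times))
  u0 <- s0 <- 0
  t0 <- 0
  for (p in seq_along(pieces$values)) {
    hi <- breaks[p + 1]
    sel <- times > t0 - 1e-15 & times <= hi + 1e-15
    if (p == 1) sel <- times <= hi + 1e-15
    if (any(sel)) {
      st <- kinetics_step(u0, s0, pieces$values[p], k$beta, k$gamma, times[sel] - t0)
      u[sel] <- st$u
      s[sel] <- st$s
    }
    if (is.finite(hi)) {
      st <- kinetics_step(u0, s0, pieces$values[p], k$beta, k$gamma, hi - t0)
      u0 <- st$u
      s0 <- st$s
      t0 <- hi
    }
  }
  alpha_t <- pieces$values[findInterval(times, pieces$breaks)]
  list(u = u, s = s, v_u = alpha_t - k$beta * u, v_s = k$beta * u - k$gamma * s)
}

#' Lineage topology for the simulator
#'
#' A rooted tree of cluster identifiers with per-node cell counts and
#' per-node pseudotime spans. Cells of a node occupy the pseudotime
#' interval that begins where the parent's interval ends. `island_nodes`
#' marks clusters whose cells are generated from an independent short
#' lineage, producing weakly connected components that exercise graph
#' pruning and reconnection.
#'
#' @param parent Named character vector mapping each non-root node to its
#'   parent.
#' @param n_cells Named integer vector of cells per node (all nodes).
#' @param t_span Named numeric vector of pseudotime durations per node.
#' @param island_nodes Character vector of island cluster names.
#' @return A list of class `lineage_spec`.
#' @export
lineage_spec <- function(parent, n_cells, t_span, island_nodes = character()) {
  nodes <- names(n_cells)
  if (is.null(nodes)) abort("n_cells must be named by node")
  if (any(n_cells <= 0)) abort("cell counts must be positive")
  roots <- setdiff(nodes, c(names(parent), island_nodes))
  if (length(roots) != 1) abort("the non-island tree must have exactly one root")
  # acyclicity: walking up from any node must terminate
  for (nd in names(parent)) {
    seen <- nd
    cur <- nd
    while (cur %in% names(parent)) {
      cur <- parent[[cur]]
      if (cur %in% seen) abort("lineage tree contains a cycle")
      seen <- c(seen, cur)
    }
  }
  structure(
    list(
      parent = parent, n_cells = n_cells, t_span = t_span,
      island_nodes = island_nodes, root = roots
    ),
    class = "lineage_spec"
  )
}

node_start_time <- function(spec, node) {
  t0 <- 0
  cur <- node
  while (cur %in% names(spec$parent)) {
    cur <- spec$parent[[cur]]
    t0 <- t0 + spec$t_span[[cur]]
  }
  t0
}

#' Simulate a spliced/unspliced dataset with known kinetics
#'
#' Every cell receives a latent time inside its node's pseudotime interval;
#' noiseless `u(t)`, `s(t)` solve the splicing ODE piecewise in closed form
#' from `(0, 0)` at the lineage root; noise is applied last. Ground truth is
#' embedded in the returned dataset: `obs$latent_time`, layers
#' `true_velocity` (spliced) and `true_velocity_u`, `var$is_murk`, and
#' `uns$true_root` / `uns$true_edges`.
#'
#' @param spec A [lineage_spec()].
#' @param genes List of [gene_kinetics()] objects.
#' @param noise `"none"`, `"poisson"` (counts drawn with the noiseless value
#'   as mean) or `"gaussian"` (additive, clamped at zero).
#' @param sigma Standard deviation for Gaussian noise.
#' @param seed Integer seed; the simulation is bitwise reproducible.
#' @return A [tivelo_dataset()] with ground truth attached.
#' @export
simulate_dataset <- function(spec, genes, noise = c("none", "poisson", "gaussian"),
                             sigma = 0.1, seed = 0L) {
  noise <- match.arg(noise)
  stopifnot(inherits(spec, "lineage_spec"))
  if (length(genes) < 1) abort("at least one gene is required")
  set.seed(seed)
  nodes <- names(spec$n_cells)
  # latent times: jittered uniform grid inside each node's interval
  cell_node <- rep(nodes, spec$n_cells[nodes])
  times <- numeric(length(cell_node))
  offset <- 0L
  for (nd in nodes) {
    m <- spec$n_cells[[nd]]
    t0 <- node_start_time(spec, nd)
    span <- spec$t_span[[nd]]
    grid <- t0 + span * (seq_len(m) - 0.5) / m
    jit <- runif(m, -0.45, 0.45) * span / m
    times[offset + seq_len(m)] <- grid + jit
    offset <- offset + m
  }

  n <- length(times)
  g <- length(genes)
  u <- s <- vu <- vs <- matrix(0, n, g)
  # lineages sharing a root-to-node path share the same kinetics trace,
  # so evaluation is grouped by node; branch-specific programs enter as a
  # piecewise-constant multiplier on alpha along the root-to-node path
  for (nd in nodes) {
    sel <- which(cell_node == nd)
    ord <- sel[order(times[sel])]
    path <- nd
    cur <- nd
    while (cur %in% names(spec$parent)) {
      cur <- spec$parent[[cur]]
      path <- c(cur, path)
    }
    entry <- vapply(path, function(p) node_start_time(spec, p), 0)
    for (j in seq_len(g)) {
      bs <- genes[[j]]$branch_scale
      scale <- NULL
      if (!is.null(bs)) {
        vals <- ifelse(path %in% names(bs), bs[path], 1)
        scale <- list(breaks = entry, values = unname(vals))
      }
      kv <- kinetics_evaluate(genes[[j]], times[ord], scale = scale)
      u[ord, j] <- kv$u
      s[ord, j] <- kv$s
      vu[ord, j] <- kv$v_u
      vs[ord, j] <- kv$v_s
    }
  }

  if (noise == "poisson") {
    u_obs <- matrix(rpois(n * g, lambda = pmax(u, 0)), n, g)
    s_obs <- matrix(rpois(n * g, lambda = pmax(s, 0)), n, g)
  } else if (noise == "gaussian") {
    u_obs <- pmax(u + matrix(rnorm(n * g, sd = sigma), n, g), 0)
    s_obs <- pmax(s + matrix(rnorm(n * g, sd = sigma), n, g), 0)
  } else {
    u_obs <- u
    s_obs <- s
  }

  edges <- tibble(
    from = unname(spec$parent[names(spec$parent)]),
    to = names(spec$parent)
  )
  is_murk <- vapply(genes, function(k) k$is_murk, TRUE)
  ds <- tivelo_dataset(
    spliced = s_obs, unspliced = u_obs,
    obs = tibble(
      cell = sprintf("cell_%d", seq_len(n)),
      cluster = cell_node,
      latent_time = times
    ),
    var = tibble(gene = sprintf("gene_%d", seq_len(g)), is_murk = is_murk),
    layers = list(
      true_velocity = vs, true_velocity_u = vu,
      noiseless_spliced = s, noiseless_unspliced = u
    ),
    uns = list(
      true_root = spec$root,
      true_edges = edges,
      simulation_seed = seed,
      noise = noise
    )
  )
  # deterministic embedding: first two PCs of log spliced counts
  pca <- prcomp(log1p(ds$spliced), rank. = 2, center = TRUE)$x
  ds$embedding <- pca
  ds
}

#' Canned synthetic fixtures
#'
#' Small, seeded datasets covering the topologies the pipeline must handle:
#' \describe{
#'   \item{linear}{five clusters in a chain with monotone latent time.}
#'   \item{bifurcation}{a tree with one branch point and two leaves.}
#'   \item{murk_mix}{the linear topology with 40\% MURK genes (step
#'     increase of the transcription rate during development).}
#'   \item{cycle}{cells on a circular progression of 50 positions; every
#'     gene shares one induction-to-repression switch at mid-span so the
#'     spliced velocity changes sign exactly once, which makes the
#'     cell-cycle sign accuracy of the true field exactly 1.}
#'   \item{islands}{a main chain plus a weakly connected two-cluster
#'     island, exercising graph pruning and reconnection.}
#' }
#' Count noise is Poisson for all but `cycle` (noiseless by design).
#'
#' @param name Fixture name.
#' @param n_cells Total number of cells (approximate; split across nodes).
#' @param n_genes Number of genes.
#' @param noise Override the fixture's default noise model.
#' @param seed Integer seed.
#' @return A [tivelo_dataset()] with embedded ground truth.
#' @export
make_fixture <- function(name = c("linear", "bifurcation", "murk_mix", "cycle", "islands"),
                         n_cells = 2000, n_genes = 200, noise = NULL, seed = 0L) {
  name <- match.arg(name)
  set.seed(seed + 1000L)
  if (name %in% c("linear", "murk_mix")) {
    per <- round(n_cells / 5)
    spec <- lineage_spec(
      parent = c(B = "A", C = "B", D = "C", E = "D"),
      n_cells = c(A = per, B = per, C = per, D = per, E = n_cells - 4 * per),
      t_span = c(A = 2, B = 2, C = 2, D = 2, E = 2)
    )
    murk_frac <- if (name == "murk_mix") 0.4 else 0
    genes <- random_gene_panel(n_genes, t_max = 10, murk_frac = murk_frac)
    ds <- simulate_dataset(spec, genes, noise = noise %||% "poisson", seed = seed)
  } else if (name == "bifurcation") {
    per <- round(n_cells / 5)
    spec <- lineage_spec(
      parent = c(B = "A", C = "B", D = "C", E = "B"),
      n_cells = c(A = per, B = per, C = per, D = per, E = n_cells - 4 * per),
      t_span = c(A = 2, B = 2, C = 2, D = 2, E = 4)
    )
    genes <- random_gene_panel(n_genes, t_max = 10, murk_frac = 0)
    # a third of the genes favour each branch so the leaves are separable
    n3 <- floor(n_genes / 3)
    for (j in seq_len(n3)) {
      genes[[j]]$branch_scale <- c(C = 1, D = 1, E = 0.2)
    }
    for (j in (n3 + 1):(2 * n3)) {
      genes[[j]]$branch_scale <- c(C = 0.2, D = 0.2, E = 1)
    }
    ds <- simulate_dataset(spec, genes, noise = noise %||% "poisson", seed = seed)
  } else if (name == "cycle") {
    ds <- make_cycle_fixture(n_cells = min(n_cells, 1000), n_genes = min(n_genes, 100),
                             noise = noise %||% "none", seed = seed)
  } else { # islands
    n_main <- round(0.85 * n_cells)
    per <- round(n_main / 4)
    n_isl <- n_cells - 4 * per
    spec <- lineage_spec(
      parent = c(B = "A", C = "B", D = "C", Y = "X"),
      n_cells = c(
        A = per, B = per, C = per, D = per,
        X = ceiling(n_isl * 0.6), Y = max(n_isl - ceiling(n_isl * 0.6), 10)
      ),
      t_span = c(A = 2, B = 2, C = 2, D = 2, X = 2, Y = 2),
      island_nodes = c("X", "Y")
    )
    genes <- random_gene_panel(n_genes, t_max = 8, murk_frac = 0)
    # half the genes differ strongly between main chain and island so the
    # two components separate in expression space
    n4 <- floor(n_genes / 4)
    for (j in seq_len(n4)) {
      genes[[j]]$branch_scale <- c(X = 2.5, Y = 2.5)
    }
    for (j in (n4 + 1):(2 * n4)) {
      genes[[j]]$branch_scale <- c(X = 0.1, Y = 0.1)
    }
    ds <- simulate_dataset(spec, genes, noise = noise %||% "poisson", seed = seed)
  }
  ds$uns$fixture <- name
  ds
}

# a mixed panel: half pure-induction genes, half genes that switch to
# repression partway; MURK genes get a rate step instead
random_gene_panel <- function(n_genes, t_max, murk_frac = 0) {
  n_murk <- round(murk_frac * n_genes)
  genes <- vector("list", n_genes)
  for (j in seq_len(n_genes)) {
    alpha <- runif(1, 2, 6)
    if (j <= n_murk) {
      genes[[j]] <- gene_kinetics(
        alpha = alpha, is_murk = TRUE,
        murk_time = runif(1, 0.3, 0.7) * t_max,
        murk_factor = runif(1, 2, 4)
      )
    } else if (j %% 2 == 0) {
      genes[[j]] <- gene_kinetics(alpha = alpha,
                                  switch_time = runif(1, 0.4, 0.8) * t_max)
    } else {
      genes[[j]] <- gene_kinetics(alpha = alpha)
    }
  }
  genes
}

# circular progression: every gene shares beta = 2, gamma = 1 and has one
# induction-to-repression switch, with switch times spread over the span
# so different genes peak in different phases (as cell-cycle genes do) and
# consecutive phases stay separable in expression space. Spliced
# expression peaks a short, closed-form lag after the switch (where
# beta*u = gamma*s); each gene's switch is placed so its peak falls just
# before one of the position times. Every between-position forward
# difference of spliced expression then has the same sign as the true
# velocity at the earlier position, for every gene, which is the property
# the fixture exists to provide for sign-accuracy testing.
make_cycle_fixture <- function(n_cells, n_genes, noise, seed) {
  n_pos <- 50
  per <- max(1, floor(n_cells / n_pos))
  t_total <- 10
  pos_times <- t_total * (seq_len(n_pos) - 0.5) / n_pos  # 0.1, 0.3, ..., 9.9
  beta <- 2
  gamma <- 1
  # u/s trace for unit alpha scale (alpha = 4 reference; the ratio that
  # sets the peak lag is alpha-free)
  u_at <- function(t) 2 * (1 - exp(-2 * t))
  s_at <- function(t) 4 + 4 * exp(-2 * t) - 8 * exp(-t)
  peak_lag <- function(t_sw) {
    u0 <- u_at(t_sw)
    s0 <- s_at(t_sw)
    log(4 * u0 / (s0 + 2 * u0))
  }
  switch_for_peak <- function(peak) {
    t_sw <- peak - 0.0062
    for (it in 1:4) t_sw <- peak - peak_lag(t_sw)
    t_sw
  }
  set.seed(seed)
  # peaks sit 0.005 before a grid position, spread over mid-to-late span
  peak_grid <- pos_times[pos_times >= 3 & pos_times <= 9.2]
  genes <- lapply(seq_len(n_genes), function(j) {
    peak <- sample(peak_grid, 1) - 0.005
    gene_kinetics(alpha = runif(1, 2, 6), beta = beta, gamma = gamma,
                  switch_time = switch_for_peak(peak))
  })
  n <- n_pos * per
  times <- rep(pos_times, each = per)
  u <- s <- vu <- vs <- matrix(0, n, n_genes)
  for (j in seq_len(n_genes)) {
    kv <- kinetics_evaluate(genes[[j]], times)
    u[, j] <- kv$u; s[, j] <- kv$s; vu[, j] <- kv$v_u; vs[, j] <- kv$v_s
  }
  if (noise == "poisson") {
    u_obs <- matrix(rpois(n * n_genes, pmax(u, 0)), n, n_genes)
    s_obs <- matrix(rpois(n * n_genes, pmax(s, 0)), n, n_genes)
  } else if (noise == "gaussian") {
    u_obs <- pmax(u + matrix(rnorm(n * n_genes, sd = 0.1), n, n_genes), 0)
    s_obs <- pmax(s + matrix(rnorm(n * n_genes, sd = 0.1), n, n_genes), 0)
  } else {
    u_obs <- u; s_obs <- s
  }
  phase <- cut(times, breaks = t_total * c(0, 0.25, 0.5, 0.75, 1),
               labels = c("G1", "S", "G2", "M"), include.lowest = TRUE)
  ds <- tivelo_dataset(
    spliced = s_obs, unspliced = u_obs,
    obs = tibble(
      cell = sprintf("cell_%d", seq_len(n)),
      cluster = as.character(phase),
      latent_time = times,
      cycle_position = rep(seq_len(n_pos), each = per)
    ),
    var = tibble(gene = sprintf("gene_%d", seq_len(n_genes)),
                 is_murk = FALSE),
    layers = list(
      true_velocity = vs, true_velocity_u = vu,
      noiseless_spliced = s, noiseless_unspliced = u
    ),
    uns = list(true_root = "G1", true_edges = tibble(
      from = c("G1", "S", "G2"), to = c("S", "G2", "M")
    ), simulation_seed = seed, noise = noise)
  )
  ds$embedding <- prcomp(log1p(ds$spliced), rank. = 2, center = TRUE)$x
  ds
}
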