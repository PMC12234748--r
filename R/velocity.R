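#' Assign levels to all cluster-graph nodes
#'
#' Breadth-first from the (post-orientation) origin on the full, unpruned
#' weight matrix: the origin has level 0; an unleveled node `i'` reachable
#' from a level-`k` node `i` receives level `k + 1` when the edge exceeds
#' `z1` and is not a suppressed shortcut, i.e. there is no third node `j`
#' with `w(i, i') < z2 * w(i, j) * w(j, i')`. Nodes still unleveled when
#' the search exhausts are attached at the level of their strongest
#' neighbour plus one, with a warning.
#'
#' @param g A `tivelo_cluster_graph` with origin set.
#' @param cfg A [tivelo_config()].
#' @return The graph with `levels` (named integer vector over all nodes).
#' @export
assign_levels <- function(g, cfg = tivelo_config()) {
  if (is.null(g$origin)) abort("origin not set")
  nodes <- g$nodes$node
  w <- g$weights[nodes, nodes, drop = FALSE]
  level <- setNames(rep(NA_integer_, length(nodes)), nodes)
  level[g$origin] <- 0L
  k <- 0L
  repeat {
    frontier <- names(level)[!is.na(level) & level == k]
    if (length(frontier) == 0) break
    for (i in frontier) {
      for (ip in nodes[is.na(level)]) {
        if (w[i, ip] <= cfg$z1) next
        others <- setdiff(nodes, c(i, ip))
        shortcut <- length(others) > 0 &&
          any(w[i, ip] < cfg$z2 * w[i, others] * w[others, ip])
        if (!shortcut) level[ip] <- k + 1L
      }
    }
    k <- k + 1L
  }
  while (anyNA(level)) {
    pending <- names(level)[is.na(level)]
    attached <- FALSE
    for (j in pending) {
      nb <- w[j, ]
      nb[j] <- 0
      leveled <- !is.na(level)
      if (any(nb[leveled] > 0)) {
        best <- names(which.max(nb * leveled))
        level[j] <- level[best] + 1L
        warn(sprintf(
          "cluster %s unreachable by the level rule; attached below its strongest neighbour %s",
          j, best
        ))
        attached <- TRUE
      }
    }
    if (!attached) {
      # fully isolated nodes: put them at level 1
      level[pending] <- 1L
      warn(sprintf(
        "isolated cluster(s) %s assigned level 1", paste(pending, collapse = ", ")
      ))
    }
  }
  g$levels <- level
  g
}

#' Assign child nodes and directed trajectory edges
#'
#' `i'` is a child of `i` when their edge exceeds `z1` and
#' `level(i') - level(i) = 1`. Every non-origin node must end up with
#' exactly one parent: a node with no parent is attached to its
#' strongest-weight neighbour; a node with several parents keeps only the
#' strongest. Directed parent-to-child edges are emitted as the directed
#' trajectory inference (DTI) result.
#'
#' @param g A `tivelo_cluster_graph` with `levels` assigned.
#' @param cfg A [tivelo_config()].
#' @return The graph with `parent` (named vector), `children` (named list)
#'   and `dti_edges` (tibble `from`, `to`).
#' @export
assign_children <- function(g, cfg = tivelo_config()) {
  if (is.null(g$levels)) abort("levels not assigned")
  nodes <- g$nodes$node
  w <- g$weights[nodes, nodes, drop = FALSE]
  level <- g$levels
  parent <- setNames(rep(NA_character_, length(nodes)), nodes)
  for (j in setdiff(nodes, g$origin)) {
    cand <- nodes[w[j, ] > cfg$z1 & level == level[j] - 1L & nodes != j]
    if (length(cand) == 0) {
      nb <- w[j, ]
      nb[j] <- 0
      nb[g$origin] <- nb[g$origin]  # origin may be the strongest neighbour
      parent[j] <- names(which.max(nb))
    } else if (length(cand) == 1) {
      parent[j] <- cand
    } else {
      parent[j] <- cand[which.max(w[j, cand])]
    }
  }
  children <- lapply(setNames(nodes, nodes), function(i) {
    unname(names(parent)[!is.na(parent) & parent == i])
  })
  g$parent <- parent
  g$children <- children
  g$dti_edges <- tibble(
    from = unname(parent[!is.na(parent)]),
    to = names(parent)[!is.na(parent)]
  )
  g
}

#' Build the directed nearest neighbourhood of every cell
#'
#' A global diffusion pseudotime is computed from the first stored cell of
#' the origin cluster. A neighbour `n'` of cell `n` belongs to `dnn(n)`
#' when it is later in pseudotime and its cluster is the cell's own or one
#' of its children — the neighbourhood is the cell's imputed near-future
#' state. Empty neighbourhoods are allowed (terminal cells).
#'
#' @param ds A preprocessed, clustered [tivelo_dataset()].
#' @param g A `tivelo_cluster_graph` with children assigned.
#' @param cfg A [tivelo_config()].
#' @return An object of class `tivelo_dnn`: `members` (list of integer
#'   vectors), `mask` (sparse membership matrix), `sizes`, and the global
#'   pseudotime `t_prime`.
#' @export
build_dnn <- function(ds, g, cfg = tivelo_config()) {
  if (is.null(g$children)) abort("children not assigned")
  if (is.null(ds$knn)) abort("knn graph missing")
  labels <- cluster_labels(ds)
  root <- which(labels == g$origin)[1]
  coords <- if (!is.null(ds$pca)) ds$pca else log1p(ds$spliced)
  t_prime <- diffusion_pseudotime(coords, root, k = min(cfg$k_neighbors, nrow(coords) - 1L))
  n <- n_cells(ds)
  k <- ncol(ds$knn)
  rows <- rep(seq_len(n), k)
  cols <- as.vector(ds$knn)
  clusters <- g$nodes$node
  allowed <- diag(length(clusters)) > 0
  dimnames(allowed) <- list(clusters, clusters)
  for (i in clusters) allowed[i, g$children[[i]]] <- TRUE
  keep <- allowed[cbind(labels[rows], labels[cols])] &
    (t_prime[cols] > t_prime[rows])
  mask <- Matrix::sparseMatrix(
    i = rows[keep], j = cols[keep], x = 1, dims = c(n, n)
  )
  sizes <- as.integer(Matrix::rowSums(mask))
  members <- split(cols[keep], factor(rows[keep], levels = seq_len(n)))
  structure(
    list(members = members, mask = mask, sizes = sizes, t_prime = t_prime),
    class = "tivelo_dnn"
  )
}

# mean expression over each cell's dnn (rows with empty dnn give zero)
dnn_mean <- function(dnn, m) {
  sizes <- dnn$sizes
  inv <- ifelse(sizes > 0, 1 / sizes, 0)
  as.matrix(Matrix::Diagonal(x = inv) %*% (dnn$mask %*% m))
}

new_velocity_field <- function(v_u, v_s, mode, rates = NULL, trace = NULL) {
  structure(
    list(v_u = v_u, v_s = v_s, mode = mode, rates = rates, trace = trace),
    class = "tivelo_velocity_field"
  )
}

#' Velocity by direct neighbourhood means (simple fit)
#'
#' The velocity of each cell is the difference between the mean expression
#' of its directed nearest neighbourhood and its own expression, for the
#' unspliced and spliced layers separately. This zeroes the pointing
#' objective exactly; cells with an empty neighbourhood get zero velocity.
#'
#' @param ds A preprocessed [tivelo_dataset()].
#' @param dnn A `tivelo_dnn`.
#' @return A `tivelo_velocity_field` with matrices `v_u` and `v_s`.
#' @export
simple_fit <- function(ds, dnn) {
  sm <- smoothed_layers(ds)
  has <- dnn$sizes > 0
  v_u <- dnn_mean(dnn, sm$u) - sm$u
  v_s <- dnn_mean(dnn, sm$s) - sm$s
  v_u[!has, ] <- 0
  v_s[!has, ] <- 0
  new_velocity_field(v_u, v_s, "simple_fit")
}

# value of the pointing objective sum_g L_g = L_u + lambda * L_s over
# cells with a non-empty dnn
pointing_objective <- function(vf, ds, dnn, lambda = 1) {
  sm <- smoothed_layers(ds)
  has <- dnn$sizes > 0
  ru <- (sm$u + vf$v_u - dnn_mean(dnn, sm$u))[has, , drop = FALSE]
  rs <- (sm$s + vf$v_s - dnn_mean(dnn, sm$s))[has, , drop = FALSE]
  sum(ru^2) + lambda * sum(rs^2)
}

#' Velocity with neighbour-consistency regularisation (fit)
#'
#' Minimizes the pointing objective plus a consistency term: the sum of
#' cosines between the concatenated (unspliced, spliced) velocity vectors
#' of each cell and its same-cluster neighbours, weighted by
#' `lambda_prime`. Because the cosine rewards agreement, the term enters
#' the minimized objective with a negative sign by default
#' (`consistency_sign = -1`). First-order gradient descent from the
#' simple-fit solution with a fixed iteration budget; cells with an empty
#' neighbourhood carry no data term and are shaped by consistency alone.
#' When `lambda_prime = 0` the output equals the simple fit exactly.
#'
#' @param ds A preprocessed [tivelo_dataset()].
#' @param dnn A `tivelo_dnn`.
#' @param cfg A [tivelo_config()].
#' @return A `tivelo_velocity_field` (mode `"fit"`) with the objective
#'   trace in `trace`.
#' @export
fit_velocity <- function(ds, dnn, cfg = tivelo_config()) {
  set.seed(cfg$random_seed)
  sm <- smoothed_layers(ds)
  lambda <- cfg$lambda
  lp <- cfg$lambda_prime
  sgn <- cfg$consistency_sign
  has <- dnn$sizes > 0
  tu <- dnn_mean(dnn, sm$u) - sm$u  # data-term targets
  ts <- dnn_mean(dnn, sm$s) - sm$s
  vu <- tu * has
  vs <- ts * has
  if (lp == 0) {
    return(new_velocity_field(vu, vs, "fit", trace = numeric()))
  }

  # same-cluster directed kNN pairs for the consistency term
  labels <- cluster_labels(ds)
  n <- n_cells(ds)
  k <- ncol(ds$knn)
  rows <- rep(seq_len(n), k)
  cols <- as.vector(ds$knn)
  same <- labels[rows] == labels[cols]
  a <- Matrix::sparseMatrix(i = rows[same], j = cols[same], x = 1, dims = c(n, n))
  a_sym <- a + Matrix::t(a)

  objective <- function(vu, vs) {
    v <- cbind(vu, vs)
    norms <- pmax(sqrt(rowSums(v * v)), 1e-12)
    u_mat <- v / norms
    lc <- sum(u_mat * (a %*% u_mat))
    data_term <- sum(((vu - tu)[has, ])^2) + lambda * sum(((vs - ts)[has, ])^2)
    data_term + sgn * lp * lc
  }

  best <- list(vu = vu, vs = vs, obj = objective(vu, vs))
  trace <- best$obj
  lr <- cfg$fit_learning_rate
  for (it in seq_len(cfg$fit_iterations)) {
    v <- cbind(vu, vs)
    norms <- pmax(sqrt(rowSums(v * v)), 1e-12)
    u_mat <- v / norms
    b <- as.matrix(a_sym %*% u_mat)
    cvec <- rowSums(u_mat * b)
    grad_c <- (b - cvec * u_mat) / norms
    g_all <- cbind(2 * (vu - tu) * has, 2 * lambda * (vs - ts) * has) + sgn * lp * grad_c
    vu <- vu - lr * g_all[, seq_len(ncol(vu)), drop = FALSE]
    vs <- vs - lr * g_all[, ncol(vu) + seq_len(ncol(vs)), drop = FALSE]
    obj <- objective(vu, vs)
    trace <- c(trace, obj)
    if (obj < best$obj) best <- list(vu = vu, vs = vs, obj = obj)
  }
  if (trace[length(trace)] > trace[1]) {
    warn("consistency fit did not improve the objective; returning the best iterate")
  }
  new_velocity_field(best$vu, best$vs, "fit", trace = trace)
}

#' Velocity through cell-specific kinetic rates
#'
#' A small fully connected network maps each cell's concatenated
#' (unspliced, spliced) expression (length 2G) through hidden widths
#' (256, 64) to per-cell transcription, splicing and degradation rates
#' (length 3G, kept non-negative by a softplus output). Velocities follow
#' the kinetic relations `v_u = alpha - beta * u`, `v_s = beta * u -
#' gamma * s`, and the network is trained to minimize the pointing
#' objective (mean over cells with a neighbourhood) for
#' `kinetic_epochs` epochs with Adam at `kinetic_learning_rate`, seeded.
#' Cells with similar expression receive similar rates by construction.
#'
#' @param ds A preprocessed [tivelo_dataset()].
#' @param dnn A `tivelo_dnn`.
#' @param cfg A [tivelo_config()].
#' @param hidden Hidden layer widths.
#' @return A `tivelo_velocity_field` (mode `"kinetic"`) with `rates`
#'   (list of matrices `alpha`, `beta`, `gamma`) and the loss trace.
#' @export
fit_kinetic <- function(ds, dnn, cfg = tivelo_config(), hidden = c(256, 64)) {
  set.seed(cfg$random_seed)
  sm <- smoothed_layers(ds)
  u <- sm$u
  s <- sm$s
  n <- nrow(u)
  G <- ncol(u)
  has <- dnn$sizes > 0
  n_eff <- max(sum(has), 1)
  mu <- dnn_mean(dnn, u)
  ms <- dnn_mean(dnn, s)
  lambda <- cfg$lambda

  x <- cbind(u, s)
  dims <- c(2 * G, hidden, 3 * G)
  params <- init_mlp(dims)
  adam <- init_adam(params)
  lr <- cfg$kinetic_learning_rate
  trace <- numeric(cfg$kinetic_epochs)
  for (ep in seq_len(cfg$kinetic_epochs)) {
    fwd <- mlp_forward(params, x)
    rates <- softplus(fwd$out)
    alpha <- rates[, seq_len(G), drop = FALSE]
    beta <- rates[, G + seq_len(G), drop = FALSE]
    gamma <- rates[, 2 * G + seq_len(G), drop = FALSE]
    vu <- alpha - beta * u
    vs <- beta * u - gamma * s
    ru <- (u + vu - mu) * has
    rs <- (s + vs - ms) * has
    loss <- (sum(ru^2) + lambda * sum(rs^2)) / n_eff
    trace[ep] <- loss
    if (!is.finite(loss)) {
      abort(sprintf("kinetic training diverged at epoch %d (loss %g)", ep, loss))
    }
    d_vu <- 2 * ru / n_eff
    d_vs <- 2 * lambda * rs / n_eff
    d_alpha <- d_vu
    d_beta <- (-d_vu + d_vs) * u
    d_gamma <- -d_vs * s
    d_rates <- cbind(d_alpha, d_beta, d_gamma) * sigmoid(fwd$out)
    grads <- mlp_backward(params, fwd, d_rates)
    upd <- adam_step(params, grads, adam, lr, ep)
    params <- upd$params
    adam <- upd$state
  }
  fwd <- mlp_forward(params, x)
  rates <- softplus(fwd$out)
  alpha <- rates[, seq_len(G), drop = FALSE]
  beta <- rates[, G + seq_len(G), drop = FALSE]
  gamma <- rates[, 2 * G + seq_len(G), drop = FALSE]
  new_velocity_field(
    v_u = alpha - beta * u,
    v_s = beta * u - gamma * s,
    mode = "kinetic",
    rates = list(alpha = alpha, beta = beta, gamma = gamma),
    trace = trace
  )
}

# ---- minimal dense network ---------------------------------------------

softplus <- function(z) ifelse(z > 30, z, log1p(exp(pmin(z, 30))))
sigmoid <- function(z) 1 / (1 + exp(-pmax(pmin(z, 30), -30)))
relu <- function(z) pmax(z, 0)

init_mlp <- function(dims) {
  params <- list()
  for (l in seq_len(length(dims) - 1)) {
    fan_in <- dims[l]
    params[[l]] <- list(
      w = matrix(rnorm(fan_in * dims[l + 1], sd = sqrt(2 / fan_in)), fan_in, dims[l + 1]),
      b = rep(0, dims[l + 1])
    )
  }
  params
}

mlp_forward <- function(params, x) {
  acts <- list(x)
  nl <- length(params)
  h <- x
  for (l in seq_len(nl)) {
    z <- sweep(h %*% params[[l]]$w, 2, params[[l]]$b, `+`)
    if (l < nl) {
      h <- relu(z)
      acts[[l + 1]] <- h
    } else {
      acts[[l + 1]] <- z
    }
  }
  list(acts = acts, out = acts[[nl + 1]])
}

mlp_backward <- function(params, fwd, d_out) {
  nl <- length(params)
  grads <- vector("list", nl)
  delta <- d_out
  for (l in rev(seq_len(nl))) {
    h_prev <- fwd$acts[[l]]
    grads[[l]] <- list(
      w = crossprod(h_prev, delta),
      b = colSums(delta)
    )
    if (l > 1) {
      delta <- (delta %*% t(params[[l]]$w)) * (fwd$acts[[l]] > 0)
    }
  }
  grads
}

init_adam <- function(params) {
  lapply(params, function(p) list(
    mw = p$w * 0, vw = p$w * 0, mb = p$b * 0, vb = p$b * 0
  ))
}

adam_step <- function(params, grads, state, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  for (l in seq_along(params)) {
    state[[l]]$mw <- b1 * state[[l]]$mw + (1 - b1) * grads[[l]]$w
    state[[l]]$vw <- b2 * state[[l]]$vw + (1 - b2) * grads[[l]]$w^2
    state[[l]]$mb <- b1 * state[[l]]$mb + (1 - b1) * grads[[l]]$b
    state[[l]]$vb <- b2 * state[[l]]$vb + (1 - b2) * grads[[l]]$b^2
    mw_hat <- state[[l]]$mw / (1 - b1^t)
    vw_hat <- state[[l]]$vw / (1 - b2^t)
    mb_hat <- state[[l]]$mb / (1 - b1^t)
    vb_hat <- state[[l]]$vb / (1 - b2^t)
    params[[l]]$w <- params[[l]]$w - lr * mw_hat / (sqrt(vw_hat) + eps)
    params[[l]]$b <- params[[l]]$b - lr * mb_hat / (sqrt(vb_hat) + eps)
  }
  list(params = params, state = state)
}

#' @export
print.tivelo_velocity_field <- function(x, ...) {
  cat(sprintf(
    "<tivelo_velocity_field> mode %s, %d cells x %d genes\n",
    x$mode, nrow(x$v_s), ncol(x$v_s)
  ))
  invisible(x)
}
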