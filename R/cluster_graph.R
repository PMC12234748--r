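#' Build the cluster-level connectivity graph
#'
#' Nodes are cell clusters; edge weights are a connectivity statistic in
#' \[0, 1\] per cluster pair. The default backend counts kNN edges between
#' each pair of clusters, divides by the count expected if edges were
#' placed at random proportionally to cluster sizes, and rescales by the
#' maximum (a PAGA-style statistic). A precomputed symmetric weight matrix
#' can be supplied instead through `weights`.
#'
#' @param ds A preprocessed, clustered [tivelo_dataset()].
#' @param weights Optional symmetric cluster-by-cluster weight matrix with
#'   dimnames naming the clusters (overrides the default backend).
#' @return An object of class `tivelo_cluster_graph` with fields `weights`
#'   (symmetric, zero diagonal, entries in \[0, 1\]), `nodes` (tibble with
#'   per-cluster cell counts), and slots filled by later stages.
#' @export
build_cluster_graph <- function(ds, weights = NULL) {
  labels <- cluster_labels(ds)
  if (is.null(labels)) abort("cluster labels missing: run cluster_cells() first")
  clusters <- sort(unique(labels))
  if (length(clusters) < 2) abort("cluster graph requires >= 2 clusters")
  sizes <- as.integer(table(factor(labels, levels = clusters)))
  if (is.null(weights)) {
    if (is.null(ds$knn)) abort("knn graph missing: run preprocess() first")
    weights <- knn_connectivity(labels, clusters, sizes, ds$knn)
  } else {
    weights <- as.matrix(weights)
    stopifnot(identical(rownames(weights), clusters))
  }
  structure(
    list(
      weights = weights,
      nodes = tibble(node = clusters, n_cells = sizes),
      retained = clusters,
      dropped = character(),
      components = list(clusters),
      origin = NULL,
      origin_rule = NA_integer_,
      log = character()
    ),
    class = "tivelo_cluster_graph"
  )
}

# observed inter-cluster knn edge count over its expectation under random
# placement proportional to cluster sizes, rescaled by the maximum
knn_connectivity <- function(labels, clusters, sizes, knn) {
  n <- length(labels)
  k <- ncol(knn)
  li <- factor(rep(labels, k), levels = clusters)
  lj <- factor(labels[as.vector(knn)], levels = clusters)
  counts <- table(li, lj)
  counts <- counts + t(counts)  # symmetrize directed kNN edges
  m <- n * k
  expected <- (2 * m) * outer(sizes, sizes) / n^2
  ratio <- as.matrix(counts) / expected
  diag(ratio) <- 0
  if (max(ratio) == 0) {
    dimnames(ratio) <- list(clusters, clusters)
    return(ratio)
  }
  w <- ratio / max(ratio)
  w <- pmin(pmax(w, 0), 1)
  dimnames(w) <- list(clusters, clusters)
  (w + t(w)) / 2
}

graph_components <- function(weights, nodes) {
  sub <- weights[nodes, nodes, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(sub > 0, mode = "undirected")
  comp <- igraph::components(g)
  split(nodes, comp$membership)
}

#' Prune small or isolated clusters from the graph
#'
#' Step 1 orders clusters by size and keeps the largest until they cover
#' `pruning_mass_fraction` of all cells and at least `pruning_min_clusters`
#' clusters are kept (all clusters when there are fewer); a dropped cluster
#' whose weight to a kept cluster exceeds `pruning_weight_factor` times its
#' best weight overall is added back. Step 2 reconnects disjoint
#' sub-graphs by re-adding, for each disjoint pair, the dropped cluster
#' with the largest product of its best weights into the two sides; when no
#' such cluster exists the components are reported separately (`run per
#' component`), never silently merged.
#'
#' @param g A `tivelo_cluster_graph`.
#' @param cfg A [tivelo_config()].
#' @return The graph with `retained`, `dropped` and `components` updated.
#' @export
prune_graph <- function(g, cfg = tivelo_config()) {
  sizes <- setNames(g$nodes$n_cells, g$nodes$node)
  total <- sum(sizes)
  ord <- names(sort(sizes, decreasing = TRUE))
  min_keep <- min(cfg$pruning_min_clusters, length(ord))
  kept <- character()
  for (nd in ord) {
    kept <- c(kept, nd)
    if (sum(sizes[kept]) > cfg$pruning_mass_fraction * total &&
        length(kept) >= min_keep) {
      break
    }
  }
  # re-add neighbours whose tie to the kept set is close to their best tie
  repeat {
    dropped <- setdiff(g$nodes$node, kept)
    added <- character()
    for (nd in dropped) {
      w_nd <- g$weights[nd, ]
      best <- max(w_nd[setdiff(names(w_nd), nd)])
      if (best <= 0) next
      if (max(w_nd[kept]) > cfg$pruning_weight_factor * best) {
        added <- c(added, nd)
      }
    }
    if (length(added) == 0) break
    kept <- c(kept, added)
  }

  # reconnect disjoint sub-graphs through the best dropped bridge cluster
  repeat {
    comps <- graph_components(g$weights, kept)
    if (length(comps) <= 1) break
    dropped <- setdiff(g$nodes$node, kept)
    best_bridge <- NULL
    best_score <- 0
    for (a in seq_along(comps)) {
      for (b in seq_along(comps)) {
        if (a >= b) next
        for (nd in dropped) {
          wa <- max(g$weights[nd, comps[[a]]])
          wb <- max(g$weights[nd, comps[[b]]])
          if (wa * wb > best_score) {
            best_score <- wa * wb
            best_bridge <- nd
          }
        }
      }
    }
    if (is.null(best_bridge)) break
    kept <- c(kept, best_bridge)
    g$log <- c(g$log, sprintf("reconnected components through cluster %s", best_bridge))
  }

  comps <- graph_components(g$weights, kept)
  if (length(comps) > 1) {
    g$log <- c(g$log, sprintf(
      "graph has %d disjoint components after pruning; run per component",
      length(comps)
    ))
  }
  g$retained <- g$nodes$node[g$nodes$node %in% kept]  # original order
  g$dropped <- setdiff(g$nodes$node, kept)
  g$components <- unname(comps)
  g
}

#' Score terminal states of the cluster graph
#'
#' A preliminary steady-state velocity field (residuals of the
#' through-origin regression of smoothed unspliced on smoothed spliced
#' expression) defines a cosine transition matrix over the kNN support.
#' End scores are the stationary distribution of the forward chain and root
#' scores that of the reversed chain, computed per connected component and
#' min-max scaled to \[0, 1\] over cells; per-cluster scores are means over
#' member cells.
#'
#' @param ds A preprocessed [tivelo_dataset()].
#' @param g A `tivelo_cluster_graph`.
#' @param sigma Transition-kernel width.
#' @return The graph with `root_score` and `end_score` columns in `nodes`,
#'   and per-cell scores stored in `g$cell_scores`.
#' @export
score_terminal_states <- function(ds, g, sigma = 1) {
  sm <- smoothed_layers(ds)
  gamma <- steady_state_gamma(sm$u, sm$s)
  v <- sm$u - sweep(sm$s, 2, gamma, `*`)
  tr <- cosine_triplets(sm$s, v, ds$knn)
  trans <- transition_from_triplets(tr, sigma = sigma)
  end_cell <- stationary_scores(trans)
  rev_trans <- row_normalize(Matrix::t(trans))
  root_cell <- stationary_scores(rev_trans)
  end_cell <- minmax(end_cell)
  root_cell <- minmax(root_cell)

  labels <- cluster_labels(ds)
  g$cell_scores <- tibble(cell = ds$obs$cell, root_score = root_cell, end_score = end_cell)
  agg <- tibble(node = labels, r = root_cell, e = end_cell) |>
    group_by(.data$node) |>
    summarise(root_score = mean(.data$r), end_score = mean(.data$e))
  g$nodes <- g$nodes |>
    select(!dplyr::any_of(c("root_score", "end_score"))) |>
    left_join(agg, by = "node")
  g
}

# per-gene through-origin regression slope of u on s
steady_state_gamma <- function(u, s) {
  num <- colSums(u * s)
  den <- colSums(s * s)
  ifelse(den > 0, num / den, 0)
}

minmax <- function(x) {
  r <- range(x)
  if (r[2] - r[1] < .Machine$double.eps) return(rep(0.5, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

# stationary distribution of a sparse row-stochastic chain, computed per
# connected component by damped power iteration
stationary_scores <- function(trans, teleport = 0.05, iter = 200, tol = 1e-10) {
  n <- nrow(trans)
  sym <- (trans + Matrix::t(trans)) > 0
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(sym, mode = "undirected")
  )$membership
  out <- numeric(n)
  tt <- Matrix::t(trans)
  for (cc in unique(comp)) {
    idx <- which(comp == cc)
    if (length(idx) == 1) {
      out[idx] <- 1
      next
    }
    sub <- tt[idx, idx, drop = FALSE]
    # renormalize columns (rows of the original chain) within the component
    cs <- Matrix::colSums(sub)
    cs[cs == 0] <- 1
    sub <- sub %*% Matrix::Diagonal(x = 1 / cs)
    x <- rep(1 / length(idx), length(idx))
    for (it in seq_len(iter)) {
      x_new <- (1 - teleport) * as.vector(sub %*% x) + teleport / length(idx)
      x_new <- x_new / sum(x_new)
      if (max(abs(x_new - x)) < tol) {
        x <- x_new
        break
      }
      x <- x_new
    }
    out[idx] <- x / max(x)
  }
  out
}

#' Select the initial origin node
#'
#' Clusters are ranked by mean root score and by mean end score. The origin
#' is (1) the best-ranked cluster with root score above `score_threshold`
#' and exceeding its end score; failing that, (2) the best-ranked cluster
#' with end score above the threshold and exceeding its root score;
#' failing that, (3) the cluster with the highest root score. Rank ties
#' break by ascending cluster id. The rule that fired is recorded.
#'
#' @param g A `tivelo_cluster_graph` with scored nodes.
#' @param cfg A [tivelo_config()].
#' @return The graph with `origin` and `origin_rule` set.
#' @export
select_origin <- function(g, cfg = tivelo_config()) {
  nodes <- g$nodes |> filter(.data$node %in% g$retained)
  if (!all(c("root_score", "end_score") %in% names(nodes))) {
    abort("terminal-state scores missing: run score_terminal_states() first")
  }
  thr <- cfg$score_threshold
  by_root <- nodes |> arrange(dplyr::desc(.data$root_score), .data$node)
  by_end <- nodes |> arrange(dplyr::desc(.data$end_score), .data$node)

  pick <- by_root |> filter(.data$root_score > thr, .data$end_score < .data$root_score)
  if (nrow(pick) > 0) {
    g$origin <- pick$node[1]
    g$origin_rule <- 1L
  } else {
    pick <- by_end |> filter(.data$end_score > thr, .data$root_score < .data$end_score)
    if (nrow(pick) > 0) {
      g$origin <- pick$node[1]
      g$origin_rule <- 2L
    } else {
      g$origin <- by_root$node[1]
      g$origin_rule <- 3L
    }
  }
  g$log <- c(g$log, sprintf(
    "origin node '%s' selected by rule %d", g$origin, g$origin_rule
  ))
  g
}

#' @export
print.tivelo_cluster_graph <- function(x, ...) {
  cat(sprintf(
    "<tivelo_cluster_graph> %d nodes (%d retained)\n",
    nrow(x$nodes), length(x$retained)
  ))
  if (!is.null(x$origin)) {
    cat(sprintf("  origin: %s (rule %d)\n", x$origin, x$origin_rule))
  }
  print(x$nodes)
  invisible(x)
}

#' Node table of a cluster graph
#'
#' @param x A `tivelo_cluster_graph`.
#' @param ... Unused.
#' @return A tibble with one row per cluster: cell count, retained flag,
#'   root/end scores and, when assigned, level and parent.
#' @method tidy tivelo_cluster_graph
#' @export
tidy.tivelo_cluster_graph <- function(x, ...) {
  out <- x$nodes |> mutate(retained = .data$node %in% x$retained)
  if (!is.null(x$levels)) {
    out <- out |> left_join(
      tibble(node = names(x$levels), level = unname(x$levels)),
      by = "node"
    )
  }
  if (!is.null(x$parent)) {
    out <- out |> left_join(
      tibble(node = names(x$parent), parent = unname(x$parent)),
      by = "node"
    )
  }
  out
}

#' Export a cluster graph to GraphML
#'
#' Writes the weighted graph over the retained clusters (node attributes:
#' cell count, root/end scores and level when present) for inspection in
#' external graph tools.
#'
#' @param g A `tivelo_cluster_graph`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(g, path) {
  nodes <- g$retained
  w <- g$weights[nodes, nodes, drop = FALSE]
  ig <- igraph::graph_from_adjacency_matrix(w, mode = "undirected", weighted = TRUE)
  tbl <- tidy(g)
  tbl <- tbl[match(nodes, tbl$node), ]
  igraph::V(ig)$n_cells <- tbl$n_cells
  if ("root_score" %in% names(tbl)) {
    igraph::V(ig)$root_score <- tbl$root_score
    igraph::V(ig)$end_score <- tbl$end_score
  }
  if ("level" %in% names(tbl)) igraph::V(ig)$level <- tbl$level
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}
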