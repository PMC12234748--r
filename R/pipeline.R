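#' Run the full velocity pipeline
#'
#' Chains every stage: preprocessing, clustering (skipped when annotations
#' exist), cluster-graph construction and pruning, terminal-state scoring
#' and origin selection, main-path selection, orientation inference (which
#' may reset the origin), level/child assignment, directed neighbourhoods,
#' velocity estimation in the configured mode, and the velocity graph with
#' its embedding projection. When pruning leaves several disconnected
#' components the pipeline runs once per component and returns a list of
#' results (class `tivelo_result_set`).
#'
#' @param ds A [tivelo_dataset()] (raw counts or already preprocessed).
#' @param cfg A [tivelo_config()].
#' @return A `tivelo_result`: the annotated dataset plus all intermediate
#'   objects (`graph`, `path`, `orientation`, `dnn`, `velocity`,
#'   `velocity_graph`, `embedding_velocity`), or a `tivelo_result_set`.
#' @export
tivelo_run <- function(ds, cfg = tivelo_config()) {
  ds <- preprocess(ds, cfg)
  ds <- cluster_cells(ds, cfg)
  g <- build_cluster_graph(ds)
  g <- prune_graph(g, cfg)
  if (length(g$components) > 1) {
    inform(sprintf(
      "cluster graph has %d disjoint components; running per component",
      length(g$components)
    ))
    labels <- cluster_labels(ds)
    results <- lapply(g$components, function(comp) {
      sub <- subset_dataset(ds, cells = which(labels %in% comp))
      sub$uns$preprocessed <- FALSE  # rebuild knn/smoothing on the subset
      sub$spliced <- expm1(sub$spliced)  # undo log for a clean re-run
      sub$unspliced <- expm1(sub$unspliced)
      tivelo_run(sub, cfg)
    })
    return(structure(list(results = results, components = g$components),
      class = "tivelo_result_set"
    ))
  }
  run_oriented(ds, g, cfg)
}

# pipeline stages downstream of pruning, on a connected graph
run_oriented <- function(ds, g, cfg) {
  g <- score_terminal_states(ds, g, sigma = cfg$sigma)
  g <- select_origin(g, cfg)
  path <- select_main_path(g)
  ori <- infer_orientation(ds, g, path, cfg)
  g <- ori$graph
  g <- assign_levels(g, cfg)
  g <- assign_children(g, cfg)
  dnn <- build_dnn(ds, g, cfg)
  vf <- switch(cfg$fit_mode,
    simple_fit = simple_fit(ds, dnn),
    fit = fit_velocity(ds, dnn, cfg),
    kinetic = fit_kinetic(ds, dnn, cfg)
  )
  vg <- velocity_graph(ds, vf, cfg)
  ve <- if (!is.null(ds$embedding)) embedding_velocity(ds, vg) else NULL

  labels <- cluster_labels(ds)
  ds$layers$velocity <- vf$v_s
  ds$layers$velocity_u <- vf$v_u
  ds$obs$pseudotime_global <- dnn$t_prime
  ds$obs$level <- unname(g$levels[labels])
  ds$uns$origin <- g$origin
  ds$uns$main_path <- path$nodes
  ds$uns$mean_orientation_score <- ori$report$mean_score
  structure(
    list(
      dataset = ds, graph = g, path = path, orientation = ori$report,
      dnn = dnn, velocity = vf, velocity_graph = vg,
      embedding_velocity = ve, config = cfg
    ),
    class = "tivelo_result"
  )
}

#' @export
print.tivelo_result <- function(x, ...) {
  cat("<tivelo_result>\n")
  cat(sprintf("  %d cells x %d genes\n", n_cells(x$dataset), n_genes(x$dataset)))
  cat(sprintf(
    "  main path: %s\n", paste(x$path$nodes, collapse = " -> ")
  ))
  cat(sprintf(
    "  mean orientation score: %.4f (%s); origin: %s\n",
    x$orientation$mean_score, x$orientation$decision, x$graph$origin
  ))
  cat(sprintf("  velocity mode: %s\n", x$velocity$mode))
  invisible(x)
}

#' One-row summary of a pipeline run
#' @param x A `tivelo_result`.
#' @param ... Unused.
#' @return A one-row tibble: cells, genes, origin, mean orientation score,
#'   decision, main-path length and velocity mode.
#' @method glance tivelo_result
#' @export
glance.tivelo_result <- function(x, ...) {
  tibble(
    n_cells = n_cells(x$dataset),
    n_genes = n_genes(x$dataset),
    origin = x$graph$origin,
    mean_orientation_score = x$orientation$mean_score,
    decision = x$orientation$decision,
    path_length = length(x$path$nodes),
    velocity_mode = x$velocity$mode
  )
}

#' Per-cell result table of a pipeline run
#' @param x A `tivelo_result`.
#' @param ... Unused.
#' @return A tibble with one row per cell: cluster, level, global
#'   pseudotime, directed-neighbourhood size and embedding velocity.
#' @method tidy tivelo_result
#' @export
tidy.tivelo_result <- function(x, ...) {
  out <- x$dataset$obs |> mutate(dnn_size = x$dnn$sizes)
  if (!is.null(x$embedding_velocity)) {
    out$ve_1 <- x$embedding_velocity[, 1]
    out$ve_2 <- x$embedding_velocity[, 2]
  }
  out
}

# ---- plotting ----------------------------------------------------------

#' Embedding stream-style plot of a pipeline result
#'
#' Cells on the 2-d embedding coloured by cluster with the projected
#' velocity drawn as arrows for a subsample of cells.
#'
#' @param object A `tivelo_result`.
#' @param arrow_cells Number of cells for which arrows are drawn.
#' @param arrow_scale Multiplier applied to embedding velocities.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tivelo_result
#' @export
autoplot.tivelo_result <- function(object, arrow_cells = 300, arrow_scale = 1, ...) {
  ds <- object$dataset
  if (is.null(ds$embedding)) abort("dataset has no embedding to plot")
  df <- tibble(
    x = ds$embedding[, 1], y = ds$embedding[, 2],
    cluster = cluster_labels(ds)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$cluster), size = 0.6, alpha = 0.7) +
    ggplot2::labs(x = "embedding 1", y = "embedding 2") +
    ggplot2::theme_minimal()
  if (!is.null(object$embedding_velocity)) {
    idx <- unique(round(seq(1, nrow(df), length.out = min(arrow_cells, nrow(df)))))
    adf <- df[idx, ]
    adf$dx <- object$embedding_velocity[idx, 1] * arrow_scale
    adf$dy <- object$embedding_velocity[idx, 2] * arrow_scale
    p <- p + ggplot2::geom_segment(
      data = adf,
      ggplot2::aes(xend = .data$x + .data$dx, yend = .data$y + .data$dy),
      arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm")),
      linewidth = 0.3, colour = "grey20"
    )
  }
  p
}

#' Distribution of per-gene orientation scores
#'
#' @param object A `tivelo_orientation` report.
#' @param ... Unused.
#' @return A ggplot histogram with the mean score marked.
#' @method autoplot tivelo_orientation
#' @export
autoplot.tivelo_orientation <- function(object, ...) {
  df <- object$per_gene |> filter(!is.na(.data$score))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$mean_score, colour = "red") +
    ggplot2::labs(
      x = "orientation score", y = "genes",
      title = sprintf("mean score %.3f: %s", object$mean_score, object$decision)
    ) +
    ggplot2::theme_minimal()
}

#' Series with its fitted piecewise-linear tree
#'
#' @param object A `tivelo_linear_tree`.
#' @param ... Unused.
#' @return A ggplot of the series and its fitted segments.
#' @method autoplot tivelo_linear_tree
#' @export
autoplot.tivelo_linear_tree <- function(object, ...) {
  df <- tibble(index = seq_len(object$n), value = object$y)
  seg <- object$segments |>
    mutate(
      y_start = .data$intercept + .data$slope * .data$start,
      y_end = .data$intercept + .data$slope * .data$end
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$value)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(
        x = .data$start, xend = .data$end,
        y = .data$y_start, yend = .data$y_end
      ),
      colour = "red", linewidth = 0.8
    ) +
    ggplot2::theme_minimal()
}
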