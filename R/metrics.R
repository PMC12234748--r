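#' Cluster edge set
#'
#' Ordered cluster pairs (A, B) encoding the expected development A -> B.
#'
#' @param from,to Character vectors of equal length.
#' @return A tibble with columns `from` and `to`.
#' @export
cluster_edges <- function(from, to) {
  stopifnot(length(from) == length(to))
  if (any(from == to)) abort("cluster edges must connect distinct clusters")
  tibble(from = as.character(from), to = as.character(to))
}

check_edges <- function(edges, labels) {
  known <- unique(labels)
  bad <- setdiff(unique(c(edges$from, edges$to)), known)
  if (length(bad) > 0) {
    abort(paste0("unknown cluster(s) in edge set: ", paste(bad, collapse = ", ")))
  }
}

# mean over contributing pairs (n in A, n' in knn(n) and B) of
# f(n, n') for one edge; NA when no pair contributes
edge_pair_mean <- function(labels, knn, edge, fun) {
  n_idx <- which(labels == edge$from)
  if (length(n_idx) == 0) return(NA_real_)
  vals <- c()
  for (n in n_idx) {
    nb <- knn[n, ]
    nb <- nb[labels[nb] == edge$to]
    if (length(nb) > 0) vals <- c(vals, fun(n, nb))
  }
  if (length(vals) == 0) NA_real_ else mean(vals)
}

row_cosine <- function(v, d) {
  # cosine of one vector v against the rows of d
  vn <- sqrt(sum(v * v))
  dn <- sqrt(rowSums(d * d))
  den <- vn * dn
  ifelse(den > 0, as.vector(d %*% v) / den, NA_real_)
}

#' Cross-boundary direction correctness (CBDir)
#'
#' For each expected cluster edge A -> B, the mean cosine between the
#' velocity of each cell in A and its displacement toward its kNN
#' neighbours in B — in the 2-d embedding (`space = "umap"`, using
#' embedding velocities) or in gene space (`space = "gene"`, using the
#' spliced velocity and the original — unsmoothed — spliced expression,
#' which distinguishes this metric from the transition cosine). Edges
#' without contributing pairs are reported as `NA` and excluded from the
#' mean.
#'
#' @param ds A preprocessed [tivelo_dataset()] with a kNN graph.
#' @param vf A `tivelo_velocity_field`.
#' @param edges A [cluster_edges()] tibble.
#' @param space `"gene"` or `"umap"`.
#' @param ve Optional precomputed embedding velocities (cells x 2); when
#'   missing in umap space they are derived via [velocity_graph()] and
#'   [embedding_velocity()].
#' @return A list with `per_edge` (tibble `from`, `to`, `score`) and
#'   `mean` over defined edges.
#' @export
cbdir <- function(ds, vf, edges, space = c("gene", "umap"), ve = NULL) {
  space <- match.arg(space)
  labels <- cluster_labels(ds)
  check_edges(edges, labels)
  if (space == "gene") {
    x <- ds$spliced
    v <- vf$v_s
  } else {
    if (is.null(ve)) {
      vg <- velocity_graph(ds, vf)
      ve <- embedding_velocity(ds, vg)
    }
    x <- ds$embedding
    v <- ve
  }
  scores <- vapply(seq_len(nrow(edges)), function(e) {
    edge_pair_mean(labels, ds$knn, edges[e, ], function(n, nb) {
      vals <- row_cosine(v[n, ], x[nb, , drop = FALSE] - rep(x[n, ], each = length(nb)))
      mean(vals, na.rm = TRUE)
    })
  }, 0)
  list(
    per_edge = edges |> mutate(score = scores),
    mean = mean(scores, na.rm = TRUE)
  )
}

#' Transition cosine similarity (TransCosine)
#'
#' For each expected cluster edge A -> B, the mean of the velocity-graph
#' cosines over pairs (n in A, n' in knn(n) and B).
#'
#' @param vg A `tivelo_velocity_graph`.
#' @param edges A [cluster_edges()] tibble.
#' @param labels Per-cell cluster labels.
#' @return A list with `per_edge` and `mean` (NA edges excluded).
#' @export
trans_cosine <- function(vg, edges, labels) {
  check_edges(edges, labels)
  scores <- vapply(seq_len(nrow(edges)), function(e) {
    edge_pair_mean(labels, vg$knn, edges[e, ], function(n, nb) {
      mean(vg$pi[n, nb])
    })
  }, 0)
  list(
    per_edge = edges |> mutate(score = scores),
    mean = mean(scores, na.rm = TRUE)
  )
}

#' Velocity coherence (VeloCoh)
#'
#' Per cell, the cosine between the predicted displacement — the
#' transition-weighted mean of spliced expression minus the cell's own —
#' and the inferred spliced velocity. The transition matrix here is the
#' velocity-graph cosine matrix divided by its row sums (the stated
#' simplification). Cells with a zero displacement, zero velocity, or a
#' non-positive cosine row sum are undefined and excluded from the mean.
#'
#' @param ds A preprocessed [tivelo_dataset()].
#' @param vf A `tivelo_velocity_field`.
#' @param vg A `tivelo_velocity_graph`.
#' @return A list with `per_cell` (numeric, NA where undefined) and `mean`.
#' @export
velo_coh <- function(ds, vf, vg) {
  s <- smoothed_layers(ds)$s
  rs <- Matrix::rowSums(vg$pi)
  ok_row <- rs > 0
  pt <- vg$pi
  pt <- Matrix::Diagonal(x = ifelse(ok_row, 1 / rs, 0)) %*% pt
  disp <- as.matrix(pt %*% s) - s
  v <- vf$v_s
  num <- rowSums(disp * v)
  den <- sqrt(rowSums(disp^2)) * sqrt(rowSums(v^2))
  per_cell <- ifelse(ok_row & den > 0, num / den, NA_real_)
  list(per_cell = per_cell, mean = mean(per_cell, na.rm = TRUE))
}

three_way_sign <- function(x, eps) {
  out <- sign(x)
  out[abs(x) < eps] <- 0
  out
}

#' Velocity sign accuracy along a cyclic progression
#'
#' Cells carry an ordered cycle position. Per position the empirical
#' velocity is proportional to the forward difference of mean spliced
#' expression; the estimated velocity is the per-position mean of the
#' inferred velocities (`estimated = "mean"`, default) or the forward
#' difference of those means (`"difference"`). Accuracy at a position is
#' the fraction of gene components whose three-way signs (+/-/0, zero
#' below `eps`) agree; the last position has no successor and is skipped.
#'
#' @param ds A [tivelo_dataset()].
#' @param vf A `tivelo_velocity_field` (or a matrix of spliced
#'   velocities).
#' @param positions Integer/numeric per-cell positions with at least two
#'   distinct values.
#' @param estimated `"mean"` or `"difference"`.
#' @param eps Zero-sign threshold.
#' @param layer Expression layer for the empirical difference
#'   (`"spliced"` raw counts by default).
#' @return A list with `per_position` (tibble `position`, `accuracy`) and
#'   `mean`.
#' @export
sign_accuracy <- function(ds, vf, positions, estimated = c("mean", "difference"),
                          eps = 1e-8, layer = "spliced") {
  estimated <- match.arg(estimated)
  v <- if (is.matrix(vf)) vf else vf$v_s
  uniq <- sort(unique(positions))
  if (length(uniq) < 2) abort("sign accuracy needs at least two cycle positions")
  s <- get_layer(ds, layer)
  s_bar <- t(vapply(uniq, function(p) colMeans(s[positions == p, , drop = FALSE]), numeric(ncol(s))))
  v_bar <- t(vapply(uniq, function(p) colMeans(v[positions == p, , drop = FALSE]), numeric(ncol(v))))
  np <- length(uniq)
  acc <- numeric(np - 1)
  for (i in seq_len(np - 1)) {
    emp <- s_bar[i + 1, ] - s_bar[i, ]
    est <- if (estimated == "mean") v_bar[i, ] else v_bar[i + 1, ] - v_bar[i, ]
    acc[i] <- mean(three_way_sign(emp, eps) == three_way_sign(est, eps))
  }
  list(
    per_position = tibble(position = uniq[-np], accuracy = acc),
    mean = mean(acc)
  )
}

#' Evaluate a velocity field against expected cluster edges
#'
#' Convenience wrapper computing CBDir (gene space, and UMAP space when an
#' embedding is present), TransCosine and VeloCoh in one call.
#'
#' @param ds A preprocessed [tivelo_dataset()].
#' @param vf A `tivelo_velocity_field`.
#' @param edges A [cluster_edges()] tibble.
#' @param cfg A [tivelo_config()].
#' @return A tibble with one row per metric (`metric`, `mean`).
#' @export
evaluate_velocity <- function(ds, vf, edges, cfg = tivelo_config()) {
  labels <- cluster_labels(ds)
  vg <- velocity_graph(ds, vf, cfg)
  out <- tibble(
    metric = c("cbdir_gene", "trans_cosine", "velo_coh"),
    mean = c(
      cbdir(ds, vf, edges, space = "gene")$mean,
      trans_cosine(vg, edges, labels)$mean,
      velo_coh(ds, vf, vg)$mean
    )
  )
  if (!is.null(ds$embedding)) {
    ve <- embedding_velocity(ds, vg)
    out <- bind_rows(out, tibble(
      metric = "cbdir_umap",
      mean = cbdir(ds, vf, edges, space = "umap", ve = ve)$mean
    ))
  }
  out
}
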