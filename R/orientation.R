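#' Diffusion pseudotime for the cells of a path
#'
#' The root cell is the first stored cell belonging to the root cluster
#' (lowest index). Pseudotime is the diffusion-map distance from that root
#' on the symmetrized kNN transition matrix of the path cells: with
#' eigenpairs `(lambda_i, psi_i)` of the transition operator, the distance
#' is `sqrt(sum_i (lambda_i / (1 - lambda_i))^2 (psi_i(root) - psi_i(n))^2)`
#' over the non-trivial eigenvectors. Ties are broken by adding a jitter
#' far below the data scale so the ordering is strict.
#'
#' @param ds A preprocessed [tivelo_dataset()].
#' @param path_nodes Character vector of clusters defining the path; the
#'   first element is the root cluster.
#' @param cfg A [tivelo_config()].
#' @param n_comps Number of diffusion components.
#' @return A list with `cells` (dataset row indices of path cells, in
#'   stored order) and `t` (their pseudotime; the root cell has `t = 0`).
#' @export
path_pseudotime <- function(ds, path_nodes, cfg = tivelo_config(), n_comps = 15) {
  labels <- cluster_labels(ds)
  cells <- which(labels %in% path_nodes)
  if (length(cells) == 0) abort("no cells on the requested path")
  root_candidates <- which(labels == path_nodes[1])
  if (length(root_candidates) == 0) {
    abort("internal error: path must start at a non-empty cluster")
  }
  root <- root_candidates[1]
  root_local <- match(root, cells)
  coords <- if (!is.null(ds$pca)) ds$pca[cells, , drop = FALSE] else log1p(ds$spliced[cells, , drop = FALSE])
  t <- diffusion_pseudotime(coords, root_local,
    k = min(cfg$k_neighbors, length(cells) - 1L), n_comps = n_comps
  )
  # strict ordering: break exact ties by stored cell order
  eps <- max(t[is.finite(t)], 1) * 1e-12
  t <- t + eps * (rank(t, ties.method = "first") - rank(t, ties.method = "average"))
  list(cells = cells, t = t)
}

# diffusion-map distance from a root cell on a kNN graph built over
# `coords`; the backend contract is deterministic given the inputs
diffusion_pseudotime <- function(coords, root_local, k = 30, n_comps = 15) {
  n <- nrow(coords)
  if (n == 1) return(0)
  k <- max(1L, min(k, n - 1L))
  nn <- knn_index(coords, k)
  a <- Matrix::sparseMatrix(
    i = rep(seq_len(n), k), j = as.vector(nn), x = 1, dims = c(n, n)
  )
  a <- (a + Matrix::t(a))
  a@x <- pmin(a@x, 1)
  deg <- Matrix::rowSums(a)
  deg[deg == 0] <- 1
  d_inv_sqrt <- 1 / sqrt(deg)
  sym <- Matrix::Diagonal(x = d_inv_sqrt) %*% a %*% Matrix::Diagonal(x = d_inv_sqrt)
  m <- min(n_comps + 1L, n - 1L)
  eig <- RSpectra::eigs_sym(sym, k = m, which = "LA")
  lambda <- eig$values
  psi <- Matrix::Diagonal(x = d_inv_sqrt) %*% eig$vectors
  psi <- as.matrix(psi)
  # drop the trivial stationary component(s); clamp near-unit eigenvalues
  keep <- lambda < 1 - 1e-9
  lambda <- pmin(lambda[keep], 1 - 1e-9)
  psi <- psi[, keep, drop = FALSE]
  if (ncol(psi) == 0) return(numeric(n))
  scale <- lambda / (1 - lambda)
  diffs <- sweep(psi, 2, psi[root_local, ], `-`)
  sqrt(rowSums(sweep(diffs, 2, scale, `*`)^2))
}

#' Extract the smoothed, normalized time series of one gene
#'
#' The gene's unspliced and spliced values (smoothed layers when present)
#' are reordered by pseudotime, smoothed with a length-`K` uniform 1-d
#' convolution (`K = min(smoothing_kernel, N)`, same-length output with
#' edge-replication padding), and normalized per `normalization_mode`
#' (sum-to-one by default, max-scaling as the alternative).
#'
#' @param ds A [tivelo_dataset()].
#' @param pt Result of [path_pseudotime()].
#' @param gene Gene name or column index.
#' @param cfg A [tivelo_config()].
#' @return A list of class `tivelo_series` with `u`, `s` (normalized
#'   series), `order` (dataset row indices in pseudotime order), and
#'   `excluded` (TRUE when a series was all zero).
#' @export
extract_series <- function(ds, pt, gene, cfg = tivelo_config()) {
  if (is.character(gene)) gene <- match(gene, ds$var$gene)
  sm <- smoothed_layers(ds)
  ord <- pt$cells[order(pt$t)]
  u <- series_smooth(sm$u[ord, gene], cfg$smoothing_kernel)
  s <- series_smooth(sm$s[ord, gene], cfg$smoothing_kernel)
  excluded <- sum(u) == 0 || sum(s) == 0
  structure(
    list(
      u = series_normalize(u, cfg$normalization_mode),
      s = series_normalize(s, cfg$normalization_mode),
      order = ord, excluded = excluded, gene = ds$var$gene[gene]
    ),
    class = "tivelo_series"
  )
}

# uniform moving average of width K with edge-replication padding,
# same-length output
series_smooth <- function(y, K) {
  n <- length(y)
  K <- max(1L, min(as.integer(K), n))
  if (K == 1) return(y)
  left <- ceiling((K - 1) / 2)
  right <- K - 1 - left
  padded <- c(rep(y[1], left), y, rep(y[n], right))
  cs <- cumsum(c(0, padded))
  (cs[(K + 1):(n + K)] - cs[1:n]) / K
}

series_normalize <- function(y, mode) {
  if (mode == "sum") {
    tot <- sum(y)
    if (tot > 0) y / tot else y
  } else {
    m <- max(y)
    if (m > 0) y / m else y
  }
}

#' Fit a piecewise-linear tree to a series
#'
#' Recursive binary splitting: each iteration finds, within every current
#' segment, the split minimizing the total sum of squared errors of
#' least-squares lines on both sides (grid search over admissible splits;
#' each resulting segment must have at least `tree_min_interval` points).
#' All segment-best splits are applied at once; iteration stops when the
#' drop of the total mean squared error falls below the threshold —
#' absolute (`tree_mse_mode = "absolute"`) or relative to the current MSE
#' (`"relative"`, the default, since sum-to-one normalized series make an
#' absolute scale meaningless) — or when no admissible split remains.
#'
#' @param y Numeric series (values at indices `1..N`).
#' @param cfg A [tivelo_config()].
#' @return An object of class `tivelo_linear_tree`: `segments` tibble
#'   (`start`, `end`, `slope`, `intercept`, `sse`), `split_points`, and the
#'   non-increasing `mse_path`.
#' @export
fit_linear_tree <- function(y, cfg = tivelo_config()) {
  n <- length(y)
  min_int <- cfg$tree_min_interval
  # each leaf carries its own sse and precomputed best split so unchanged
  # segments cost nothing across iterations
  make_leaf <- function(a, b, sse = NULL) {
    if (is.null(sse)) sse <- segment_fit(y, a, b)$sse
    list(a = a, b = b, sse = sse, split = best_split(y, a, b, min_int))
  }
  segs <- list(make_leaf(1L, n))
  mse_path <- segs[[1]]$sse / n
  repeat {
    splittable <- vapply(segs, function(l) !is.null(l$split), TRUE)
    if (!any(splittable)) break
    new_sse <- sum(vapply(segs, function(l) {
      if (is.null(l$split)) l$sse else l$split$sse_l + l$split$sse_r
    }, 0))
    new_mse <- new_sse / n
    cur <- mse_path[length(mse_path)]
    drop <- cur - new_mse
    stop_now <- if (cfg$tree_mse_mode == "absolute") {
      drop < cfg$tree_mse_drop_threshold
    } else {
      cur <= 0 || drop / cur < cfg$tree_mse_drop_threshold
    }
    if (stop_now) break
    proposal <- list()
    for (l in segs) {
      if (is.null(l$split)) {
        proposal[[length(proposal) + 1]] <- l
      } else {
        proposal[[length(proposal) + 1]] <- make_leaf(l$a, l$split$pos, l$split$sse_l)
        proposal[[length(proposal) + 1]] <- make_leaf(l$split$pos + 1L, l$b, l$split$sse_r)
      }
    }
    segs <- proposal
    mse_path <- c(mse_path, new_mse)
  }
  fits <- lapply(segs, function(l) {
    f <- segment_fit(y, l$a, l$b)
    c(l$a, l$b, f$slope, f$intercept, f$sse)
  })
  fm <- do.call(rbind, fits)
  fm <- fm[order(fm[, 1]), , drop = FALSE]
  seg_tbl <- tibble(
    start = as.integer(fm[, 1]), end = as.integer(fm[, 2]),
    slope = fm[, 3], intercept = fm[, 4], sse = fm[, 5]
  )
  structure(
    list(
      segments = seg_tbl,
      split_points = seg_tbl$end[-nrow(seg_tbl)],
      mse_path = mse_path,
      n = n,
      y = y
    ),
    class = "tivelo_linear_tree"
  )
}

# least-squares line on y[a..b] against index a..b
segment_fit <- function(y, a, b) {
  x <- as.numeric(a:b)
  yy <- y[a:b]
  n <- length(x)
  if (n == 1) {
    return(list(slope = 0, intercept = yy, sse = 0))
  }
  mx <- mean(x)
  my <- mean(yy)
  sxx <- sum((x - mx)^2)
  sxy <- sum((x - mx) * (yy - my))
  slope <- sxy / sxx
  sse <- sum((yy - my)^2) - slope * sxy
  list(slope = slope, intercept = my - slope * mx, sse = max(sse, 0))
}

# best admissible split of y[a..b]; NULL when the segment is too short or
# no split reduces the error
best_split <- function(y, a, b, min_int) {
  len <- b - a + 1L
  if (len < 2L * min_int) return(NULL)
  x <- as.numeric(a:b)
  yy <- y[a:b]
  cx <- cumsum(x)
  cy <- cumsum(yy)
  cxx <- cumsum(x * x)
  cxy <- cumsum(x * yy)
  cyy <- cumsum(yy * yy)
  tx <- cx[len]; ty <- cy[len]; txx <- cxx[len]; txy <- cxy[len]; tyy <- cyy[len]
  m <- min_int:(len - min_int)  # left part sizes
  sse_part <- function(n_, sx, sy, sxx, sxy, syy) {
    vx <- sxx - sx^2 / n_
    vy <- syy - sy^2 / n_
    vxy <- sxy - sx * sy / n_
    out <- vy - vxy^2 / pmax(vx, .Machine$double.eps)
    out[out < 0] <- 0
    out
  }
  sse_l <- sse_part(m, cx[m], cy[m], cxx[m], cxy[m], cyy[m])
  nr <- len - m
  sse_r <- sse_part(nr, tx - cx[m], ty - cy[m], txx - cxx[m], txy - cxy[m], tyy - cyy[m])
  total <- sse_l + sse_r
  best <- which.min(total)
  base <- segment_fit(y, a, b)$sse
  if (total[best] >= base) return(NULL)
  list(pos = a + as.integer(m[best]) - 1L, sse_l = sse_l[best], sse_r = sse_r[best])
}

#' Orientation score of one gene (rising/falling section statistic)
#'
#' The two linear trees over the same index range are intersected: every
#' maximal interval on which both trees keep a single segment becomes a
#' section, classified by the pair of slopes. Sections where both series
#' rise (slopes > 0) contribute `+ sum(d) * l`, sections where both fall
#' contribute `- sum(d) * l`, with `d = u - s` (normalized series) and `l`
#' the section length; mixed-sign or zero-slope sections contribute 0. A
#' positive score supports the current direction of pseudotime, a negative
#' score indicates it should be reversed.
#'
#' @param tree_u,tree_s Linear trees fitted to the unspliced and spliced
#'   series.
#' @param u,s The normalized series the trees were fitted to.
#' @return The scalar score.
#' @export
orientation_score <- function(tree_u, tree_s, u, s) {
  stopifnot(tree_u$n == tree_s$n, length(u) == tree_u$n, length(s) == tree_u$n)
  n <- tree_u$n
  ku <- rep(tree_u$segments$slope, tree_u$segments$end - tree_u$segments$start + 1L)
  ks <- rep(tree_s$segments$slope, tree_s$segments$end - tree_s$segments$start + 1L)
  # sections: maximal runs where both trees keep a single segment
  bounds <- sort(unique(c(tree_u$segments$end, tree_s$segments$end)))
  sec_id <- rep(seq_along(bounds), diff(c(0L, bounds)))
  sign_vec <- (ku > 0 & ks > 0) - (ku < 0 & ks < 0)  # constant within a section
  d_sum <- rowsum(u - s, sec_id)[, 1]
  len <- tabulate(sec_id)
  sec_sign <- sign_vec[c(1L, bounds[-length(bounds)] + 1L)]
  sum(sec_sign * d_sum * len)
}

#' Select velocity genes for orientation scoring
#'
#' A gene qualifies when the through-origin regression of unspliced on
#' spliced expression (smoothed layers) has slope above
#' `velocity_gene_gamma_min`, a coefficient of determination above
#' `velocity_gene_r2_min`, and a standard-deviation ratio sd(u)/sd(s)
#' inside `sigma_ratio_bounds`. Zero-variance genes are excluded. With
#' `extreme_quantile` set, the regression uses only cells in the extreme
#' quantiles of combined expression, mimicking steady-state fits.
#'
#' @param ds A preprocessed [tivelo_dataset()].
#' @param cfg A [tivelo_config()].
#' @param extreme_quantile Optional fraction (e.g. 0.05) selecting extreme
#'   cells for the regression; `NULL` uses all cells.
#' @return Integer vector of qualifying gene column indices.
#' @export
velocity_gene_filter <- function(ds, cfg = tivelo_config(), extreme_quantile = NULL) {
  sm <- smoothed_layers(ds)
  u <- sm$u
  s <- sm$s
  if (!is.null(extreme_quantile)) {
    q <- extreme_quantile
    keep_rows <- lapply(seq_len(ncol(s)), function(j) {
      tot <- u[, j] + s[, j]
      lo <- quantile(tot, q)
      hi <- quantile(tot, 1 - q)
      which(tot <= lo | tot >= hi)
    })
  } else {
    keep_rows <- NULL
  }
  stats <- vapply(seq_len(ncol(s)), function(j) {
    uj <- u[, j]
    sj <- s[, j]
    if (!is.null(keep_rows)) {
      uj <- uj[keep_rows[[j]]]
      sj <- sj[keep_rows[[j]]]
    }
    sdu <- sd(uj)
    sds <- sd(sj)
    if (!is.finite(sdu) || !is.finite(sds) || sdu == 0 || sds == 0) {
      return(c(NA_real_, NA_real_, NA_real_))
    }
    den <- sum(sj^2)
    gamma <- if (den > 0) sum(uj * sj) / den else 0
    ss_tot <- sum((uj - mean(uj))^2)
    r2 <- if (ss_tot > 0) 1 - sum((uj - gamma * sj)^2) / ss_tot else 0
    c(gamma, r2, sdu / sds)
  }, numeric(3))
  which(
    stats[1, ] > cfg$velocity_gene_gamma_min &
      stats[2, ] > cfg$velocity_gene_r2_min &
      stats[3, ] > cfg$sigma_ratio_bounds[1] &
      stats[3, ] < cfg$sigma_ratio_bounds[2]
  )
}

# orientation scores for a set of genes along ordered path cells
score_genes <- function(ds, pt, genes, cfg) {
  scores <- rep(NA_real_, length(genes))
  for (k in seq_along(genes)) {
    ser <- extract_series(ds, pt, genes[k], cfg)
    if (ser$excluded) next
    tu <- fit_linear_tree(ser$u, cfg)
    ts <- fit_linear_tree(ser$s, cfg)
    scores[k] <- orientation_score(tu, ts, ser$u, ser$s)
  }
  tibble(gene = ds$var$gene[genes], score = scores)
}

#' Infer the direction of the main path and reset the origin
#'
#' Orientation scores of all velocity genes are computed along the main
#' path. When no branch touches the corrected source endpoint of the main
#' path, a negative mean score flips the origin to the far end and a
#' non-negative mean keeps it (case 1). When a branch attaches at the
#' corrected source endpoint `i`, the branch is scored the same way
#' (pseudotime from `i` outward): a negative branch score means the flow
#' enters the path through the branch, so the origin moves to the far
#' branch endpoint `j`; otherwise `i` is a bifurcation source and stays
#' the origin (case 2). With several branches at `i` the one carrying most
#' cells decides.
#'
#' @param ds A preprocessed [tivelo_dataset()].
#' @param g A `tivelo_cluster_graph` with origin set.
#' @param path A `tivelo_main_path`.
#' @param cfg A [tivelo_config()].
#' @return A list with `graph` (origin updated) and `report` (class
#'   `tivelo_orientation`: per-gene scores, mean score, decision, branch
#'   scores when computed, origin before/after, and the path pseudotime).
#' @export
infer_orientation <- function(ds, g, path, cfg = tivelo_config()) {
  genes <- velocity_gene_filter(ds, cfg)
  if (length(genes) == 0) {
    abort(paste(
      "no velocity genes pass the filter;",
      "relax velocity_gene_gamma_min / velocity_gene_r2_min / sigma_ratio_bounds"
    ))
  }
  pt <- path_pseudotime(ds, path$nodes, cfg)
  per_gene <- score_genes(ds, pt, genes, cfg)
  mean_score <- mean(per_gene$score, na.rm = TRUE)
  reverse <- mean_score < 0
  origin_before <- g$origin
  source_end <- if (reverse) path$nodes[length(path$nodes)] else path$nodes[1]

  branch_scores <- NULL
  branch_used <- NULL
  attached <- Filter(function(b) identical(b$attach, source_end), path$branches)
  if (length(attached) > 0) {
    sizes <- setNames(g$nodes$n_cells, g$nodes$node)
    mass <- vapply(attached, function(b) sum(sizes[b$nodes]), 0)
    branch <- attached[[which.max(mass)]]
    branch_used <- branch
    bpt <- path_pseudotime(ds, c(source_end, branch$nodes), cfg)
    branch_tbl <- score_genes(ds, bpt, genes, cfg)
    branch_scores <- branch_tbl
    branch_mean <- mean(branch_tbl$score, na.rm = TRUE)
    if (branch_mean < 0) {
      new_origin <- branch$nodes[length(branch$nodes)]
      decision_note <- sprintf(
        "branch score %.4f < 0: flow enters through branch, origin -> %s",
        branch_mean, new_origin
      )
    } else {
      new_origin <- source_end
      decision_note <- sprintf(
        "branch score %.4f >= 0: bifurcation at %s", branch_mean, source_end
      )
    }
  } else {
    new_origin <- source_end
    decision_note <- if (reverse) "main path reversed" else "main path kept"
  }

  g$origin <- new_origin
  g$log <- c(g$log, sprintf(
    "orientation: mean score %.4f over %d velocity genes; %s; origin %s -> %s",
    mean_score, sum(!is.na(per_gene$score)), decision_note, origin_before, new_origin
  ))
  report <- structure(
    list(
      per_gene = per_gene,
      mean_score = mean_score,
      decision = if (reverse) "reverse" else "keep",
      branch_scores = branch_scores,
      branch = branch_used,
      origin_before = origin_before,
      new_origin = new_origin,
      pseudotime = pt,
      n_velocity_genes = length(genes),
      velocity_genes = genes
    ),
    class = "tivelo_orientation"
  )
  list(graph = g, report = report)
}

#' @rdname infer_orientation
#' @param report A `tivelo_orientation` report.
#' @export
infer_new_origin <- function(g, path, report) {
  g$origin <- report$new_origin
  g
}

#' @export
print.tivelo_orientation <- function(x, ...) {
  cat(sprintf(
    "<tivelo_orientation> mean score %.4f over %d velocity genes -> %s\n",
    x$mean_score, x$n_velocity_genes, x$decision
  ))
  cat(sprintf("  origin: %s -> %s\n", x$origin_before, x$new_origin))
  invisible(x)
}

#' Per-gene orientation scores as a tibble
#' @param x A `tivelo_orientation` report.
#' @param ... Unused.
#' @return A tibble with `gene` and `score`.
#' @method tidy tivelo_orientation
#' @export
tidy.tivelo_orientation <- function(x, ...) x$per_gene

#' One-row summary of an orientation report
#' @param x A `tivelo_orientation` report.
#' @param ... Unused.
#' @return A one-row tibble: mean score, decision, origin before/after.
#' @method glance tivelo_orientation
#' @export
glance.tivelo_orientation <- function(x, ...) {
  tibble(
    mean_score = x$mean_score,
    decision = x$decision,
    n_velocity_genes = x$n_velocity_genes,
    origin_before = x$origin_before,
    new_origin = x$new_origin
  )
}

#' Segment table of a linear tree
#' @param x A `tivelo_linear_tree`.
#' @param ... Unused.
#' @return The `segments` tibble.
#' @method tidy tivelo_linear_tree
#' @export
tidy.tivelo_linear_tree <- function(x, ...) x$segments

#' Export an orientation report
#'
#' Writes the per-gene scores as CSV and the run summary (mean score,
#' decision, origin before/after) as JSON.
#'
#' @param report A `tivelo_orientation` report.
#' @param dir Output directory (created when missing).
#' @return The two file paths, invisibly.
#' @export
write_orientation_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, "orientation_scores.csv")
  json <- file.path(dir, "orientation_summary.json")
  utils::write.csv(report$per_gene, csv, row.names = FALSE)
  jsonlite::write_json(
    list(
      mean_score = report$mean_score,
      decision = report$decision,
      n_velocity_genes = report$n_velocity_genes,
      origin_before = report$origin_before,
      new_origin = report$new_origin
    ),
    json, auto_unbox = TRUE, digits = NA
  )
  invisible(c(csv, json))
}
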