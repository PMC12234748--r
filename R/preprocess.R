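#' Build the cell kNN graph on a PCA of log spliced counts
#'
#' Principal components are computed on the log1p-transformed spliced layer
#' and each cell's `k` nearest neighbours (excluding itself) are found by a
#' kd-tree search. The index matrix and the PCA coordinates are stored on
#' the dataset.
#'
#' @param ds A [tivelo_dataset()].
#' @param cfg A [tivelo_config()]; `k_neighbors` and `n_pcs` are used.
#' @return `ds` with `knn` (cells x k integer matrix) and `pca` filled.
#' @export
build_knn <- function(ds, cfg = tivelo_config()) {
  x <- log1p(ds$spliced)
  n_pcs <- min(cfg$n_pcs, nrow(x) - 1L, ncol(x))
  pca <- prcomp(x, rank. = n_pcs, center = TRUE, scale. = FALSE)$x
  k <- min(cfg$k_neighbors, nrow(x) - 1L)
  ds$knn <- knn_index(pca, k)
  ds$pca <- pca
  ds
}

# k nearest neighbours by index, never including the query cell itself
# (duplicated coordinates can make the kd-tree return the query)
knn_index <- function(coords, k) {
  n <- nrow(coords)
  k <- max(1L, min(k, n - 1L))
  nn <- FNN::get.knn(coords, k = min(k + 1L, n - 1L))$nn.index
  self <- nn == seq_len(n)
  if (any(self)) {
    for (i in which(rowSums(self) > 0)) {
      row <- nn[i, ]
      others <- row[row != i]
      if (length(others) < k) {
        others <- c(others, setdiff(seq_len(n), c(i, others)))
      }
      nn[i, seq_len(k)] <- others[seq_len(k)]
    }
  }
  nn[, seq_len(k), drop = FALSE]
}

# mean over the cell's own value and its k neighbours (k+1 values),
# matching first-order-moment conventions
smooth_layer <- function(m, knn) {
  n <- nrow(m)
  k <- ncol(knn)
  a <- Matrix::sparseMatrix(
    i = c(seq_len(n), rep(seq_len(n), k)),
    j = c(seq_len(n), as.vector(knn)),
    x = 1, dims = c(n, n)
  )
  out <- as.matrix(a %*% m) / (k + 1)
  dimnames(out) <- dimnames(m)
  out
}

#' Preprocess raw spliced/unspliced counts
#'
#' Standard filtering and normalisation for velocity work: genes detected
#' (non-zero in both layers) in fewer than `min_shared_counts` cells are
#' removed; the top `n_top_genes` highly variable genes are retained (via
#' the mean-variance trend of \pkg{scran}); values are log1p-transformed;
#' the kNN graph is built on a PCA of the log counts; and smoothed layers
#' (`spliced_smooth`, `unspliced_smooth`) are computed as the mean over each
#' cell and its `k_neighbors` nearest neighbours. Applying `preprocess()` to
#' its own output changes nothing.
#'
#' @param ds A [tivelo_dataset()] with raw counts.
#' @param cfg A [tivelo_config()].
#' @return A preprocessed `tivelo_dataset`.
#' @export
preprocess <- function(ds, cfg = tivelo_config()) {
  if (isTRUE(ds$uns$preprocessed)) return(ds)
  shared <- colSums(ds$spliced > 0 & ds$unspliced > 0)
  keep <- shared >= cfg$min_shared_counts
  if (!any(keep)) abort("no genes pass the shared-count filter")
  ds <- subset_dataset(ds, genes = which(keep))

  if (n_genes(ds) > cfg$n_top_genes) {
    hvg <- rank_hvg(log1p(ds$spliced))
    ds <- subset_dataset(ds, genes = sort(hvg[seq_len(cfg$n_top_genes)]))
  } else if (n_genes(ds) < cfg$n_top_genes) {
    inform(sprintf(
      "only %d genes after filtering (requested %d highly variable genes); keeping all",
      n_genes(ds), cfg$n_top_genes
    ))
  }

  ds$spliced <- log1p(ds$spliced)
  ds$unspliced <- log1p(ds$unspliced)
  ds <- build_knn(ds, cfg)
  ds$layers$spliced_smooth <- smooth_layer(ds$spliced, ds$knn)
  ds$layers$unspliced_smooth <- smooth_layer(ds$unspliced, ds$knn)
  ds$uns$preprocessed <- TRUE
  validate_dataset(ds)
  ds
}

# gene indices ordered from most to least variable
rank_hvg <- function(log_counts) {
  fit <- scran::modelGeneVar(t(log_counts))
  order(fit$bio, decreasing = TRUE)
}

#' Cluster cells by modularity community detection
#'
#' A no-op when a `cluster` column is already present in `ds$obs` (existing
#' annotations take precedence). Otherwise Leiden community detection is
#' run on the undirected kNN graph at `cfg$leiden_resolution`, seeded by
#' `cfg$random_seed`, and labels `"0"`, `"1"`, ... are assigned.
#'
#' @param ds A preprocessed [tivelo_dataset()] (needs `knn`).
#' @param cfg A [tivelo_config()].
#' @return `ds` with a `cluster` column in `obs`.
#' @export
cluster_cells <- function(ds, cfg = tivelo_config()) {
  if (!is.null(cluster_labels(ds))) return(ds)
  if (is.null(ds$knn)) {
    abort("knn graph missing: run preprocess() (or build_knn()) first")
  }
  g <- knn_igraph(ds$knn)
  set.seed(cfg$random_seed)
  comm <- igraph::cluster_leiden(
    g,
    objective_function = "modularity",
    resolution = cfg$leiden_resolution,
    n_iterations = 5
  )
  ds$obs$cluster <- as.character(igraph::membership(comm) - 1L)
  ds
}

# undirected simple graph from the kNN index matrix
knn_igraph <- function(knn) {
  n <- nrow(knn)
  edges <- rbind(rep(seq_len(n), ncol(knn)), as.vector(knn))
  g <- igraph::graph_from_edgelist(t(edges), directed = FALSE)
  igraph::simplify(g)
}
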