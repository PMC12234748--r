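#' Expression dataset container
#'
#' A cells-by-genes container holding spliced and unspliced count layers,
#' optional neighbour-smoothed layers, per-cell metadata (`obs`), per-gene
#' metadata (`var`), a 2-d embedding, a kNN index matrix and arbitrary
#' unstructured results (`uns`). Layers are stored as dense base matrices
#' with cells in rows; gene and cell order is preserved by every operation.
#'
#' @param spliced,unspliced Numeric cells-by-genes matrices of identical
#'   shape with non-negative entries.
#' @param obs Optional data frame of per-cell annotations (one row per
#'   cell); a `cluster` column is used as the cell-type / cluster label.
#' @param var Optional data frame of per-gene annotations.
#' @param embedding Optional cells-by-2 coordinate matrix.
#' @param layers Optional named list of additional cells-by-genes matrices
#'   (for example smoothed values or velocities).
#' @param uns Named list of unstructured results.
#' @param cell_names,gene_names Character vectors; default to the matrix
#'   dimnames or generated identifiers.
#'
#' @return An object of class `tivelo_dataset`.
#' @export
#' @examples
#' s <- matrix(rpois(50, 4), 10, 5)
#' u <- matrix(rpois(50, 2), 10, 5)
#' ds <- tivelo_dataset(s, u)
#' dim(ds)
tivelo_dataset <- function(spliced, unspliced, obs = NULL, var = NULL,
                           embedding = NULL, layers = list(), uns = list(),
                           cell_names = NULL, gene_names = NULL) {
  spliced <- as.matrix(spliced)
  unspliced <- as.matrix(unspliced)
  if (!identical(dim(spliced), dim(unspliced))) {
    abort(sprintf(
      "shape mismatch between layers: spliced is %d x %d, unspliced is %d x %d",
      nrow(spliced), ncol(spliced), nrow(unspliced), ncol(unspliced)
    ))
  }
  n <- nrow(spliced)
  g <- ncol(spliced)
  if (is.null(cell_names)) {
    cell_names <- rownames(spliced) %||% sprintf("cell_%d", seq_len(n))
  }
  if (is.null(gene_names)) {
    gene_names <- colnames(spliced) %||% sprintf("gene_%d", seq_len(g))
  }
  dimnames(spliced) <- dimnames(unspliced) <- list(cell_names, gene_names)
  if (is.null(obs)) obs <- tibble(cell = cell_names)
  obs <- as_tibble(obs)
  if (!"cell" %in% names(obs)) obs$cell <- cell_names
  if (is.null(var)) var <- tibble(gene = gene_names)
  var <- as_tibble(var)
  if (!"gene" %in% names(var)) var$gene <- gene_names
  if (nrow(obs) != n) abort("obs must have one row per cell")
  if (nrow(var) != g) abort("var must have one row per gene")
  if (!is.null(embedding)) {
    embedding <- as.matrix(embedding)
    if (nrow(embedding) != n || ncol(embedding) != 2) {
      abort("embedding must be a cells x 2 matrix")
    }
  }
  for (nm in names(layers)) {
    layers[[nm]] <- as.matrix(layers[[nm]])
    if (!identical(dim(layers[[nm]]), c(n, g))) {
      abort(sprintf("layer '%s' does not match the dataset shape", nm))
    }
    dimnames(layers[[nm]]) <- list(cell_names, gene_names)
  }
  ds <- structure(
    list(
      spliced = spliced, unspliced = unspliced, layers = layers,
      obs = obs, var = var, embedding = embedding, knn = NULL, pca = NULL,
      uns = uns
    ),
    class = "tivelo_dataset"
  )
  validate_dataset(ds)
  ds
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a dataset container
#'
#' Checks the structural invariants: aligned layer shapes, non-negative
#' counts, kNN lists of exactly k entries never containing the cell itself,
#' and one cluster label per cell when labels are present.
#'
#' @param ds A `tivelo_dataset`.
#' @return `ds`, invisibly; errors describe the violated invariant.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "tivelo_dataset"))
  if (min(ds$spliced) < 0 || min(ds$unspliced) < 0) {
    abort("count layers must be non-negative")
  }
  if (!is.null(ds$knn)) {
    n <- nrow(ds$spliced)
    if (nrow(ds$knn) != n) abort("knn must have one row per cell")
    if (any(ds$knn == seq_len(n))) abort("knn lists must not contain the cell itself")
  }
  if ("cluster" %in% names(ds$obs) && anyNA(ds$obs$cluster)) {
    abort("every cell must have exactly one cluster label")
  }
  invisible(ds)
}

#' @export
dim.tivelo_dataset <- function(x) dim(x$spliced)

#' Number of cells / genes in a dataset
#' @param ds A `tivelo_dataset`.
#' @return Integer count.
#' @export
n_cells <- function(ds) nrow(ds$spliced)

#' @rdname n_cells
#' @export
n_genes <- function(ds) ncol(ds$spliced)

#' Cluster labels of a dataset
#' @param ds A `tivelo_dataset`.
#' @return Character vector of per-cell labels, or `NULL` when absent.
#' @export
cluster_labels <- function(ds) {
  if ("cluster" %in% names(ds$obs)) as.character(ds$obs$cluster) else NULL
}

#' Retrieve a layer by name
#'
#' `"spliced"` and `"unspliced"` address the core layers; any other name is
#' looked up in `ds$layers`. `"spliced_smooth"`/`"unspliced_smooth"` are the
#' neighbour-averaged layers written by [preprocess()].
#'
#' @param ds A `tivelo_dataset`.
#' @param name Layer name.
#' @return A cells-by-genes matrix.
#' @export
get_layer <- function(ds, name) {
  if (name == "spliced") return(ds$spliced)
  if (name == "unspliced") return(ds$unspliced)
  if (!name %in% names(ds$layers)) {
    abort(sprintf(
      "layer not found: '%s' (available: %s)", name,
      paste(c("spliced", "unspliced", names(ds$layers)), collapse = ", ")
    ))
  }
  ds$layers[[name]]
}

# smoothed layers with fallback to the raw ones
smoothed_layers <- function(ds) {
  list(
    u = if ("unspliced_smooth" %in% names(ds$layers)) ds$layers$unspliced_smooth else ds$unspliced,
    s = if ("spliced_smooth" %in% names(ds$layers)) ds$layers$spliced_smooth else ds$spliced
  )
}

#' @export
print.tivelo_dataset <- function(x, ...) {
  cat(sprintf(
    "<tivelo_dataset> %d cells x %d genes\n", n_cells(x), n_genes(x)
  ))
  cat("  layers:", paste(c("spliced", "unspliced", names(x$layers)), collapse = ", "), "\n")
  cat("  obs:   ", paste(names(x$obs), collapse = ", "), "\n")
  if (!is.null(x$knn)) cat(sprintf("  knn:    k = %d\n", ncol(x$knn)))
  if (!is.null(x$embedding)) cat("  embedding: present\n")
  if (length(x$uns) > 0) cat("  uns:   ", paste(names(x$uns), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a dataset to a set of cells and/or genes
#'
#' Positional alignment of every layer, obs/var table, embedding and kNN
#' structure is preserved; the kNN matrix is dropped (indices would be
#' stale) and must be rebuilt by [preprocess()] or [build_knn()].
#'
#' @param ds A `tivelo_dataset`.
#' @param cells,genes Integer or logical index vectors; `NULL` keeps all.
#' @return A `tivelo_dataset`.
#' @export
subset_dataset <- function(ds, cells = NULL, genes = NULL) {
  if (is.null(cells)) cells <- seq_len(n_cells(ds))
  if (is.null(genes)) genes <- seq_len(n_genes(ds))
  layers <- lapply(ds$layers, function(m) m[cells, genes, drop = FALSE])
  tivelo_dataset(
    spliced = ds$spliced[cells, genes, drop = FALSE],
    unspliced = ds$unspliced[cells, genes, drop = FALSE],
    obs = ds$obs[cells, , drop = FALSE],
    var = ds$var[genes, , drop = FALSE],
    embedding = if (!is.null(ds$embedding)) ds$embedding[cells, , drop = FALSE],
    layers = layers,
    uns = ds$uns
  )
}
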