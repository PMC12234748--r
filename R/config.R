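#' Pipeline configuration
#'
#' Collects every tunable parameter of the pipeline in one validated list.
#' Defaults follow the standard spliced/unspliced preprocessing conventions
#' (30 neighbours, 2000 highly variable genes, minimum shared counts 20,
#' Leiden resolution 0.6) and the method's own thresholds: the graph-pruning
#' rules (retain clusters covering half the cells, at least five clusters,
#' re-add neighbours within 0.6 of their best weight), the level-assignment
#' thresholds `z1` and `z2`, the loss weights `lambda` and `lambda_prime`,
#' and the velocity-gene filter (slope > 0.01, R-squared > 0.01, standard
#' deviation ratio in (0.03, 3)).
#'
#' @param k_neighbors Number of nearest neighbours per cell (excluding the
#'   cell itself).
#' @param n_top_genes Number of highly variable genes to retain.
#' @param min_shared_counts Minimum number of cells in which a gene must have
#'   non-zero spliced and unspliced counts.
#' @param leiden_resolution Resolution for modularity community detection.
#' @param smoothing_kernel Length of the uniform 1-d convolution kernel used
#'   to smooth pseudotime-ordered series (clamped to the series length).
#' @param pruning_mass_fraction Fraction of all cells the retained clusters
#'   must cover.
#' @param pruning_min_clusters Minimum number of clusters retained.
#' @param pruning_weight_factor A dropped cluster is re-added when its weight
#'   to a retained cluster exceeds this factor times its best weight overall.
#' @param score_threshold Root/end score threshold in the origin rule chain.
#' @param z1,z2 Level-assignment thresholds: an edge must exceed `z1`, and is
#'   suppressed as a shortcut when weaker than `z2` times the best two-hop
#'   weight product.
#' @param lambda Weight of the spliced loss relative to the unspliced loss.
#' @param lambda_prime Weight of the neighbour-consistency regulariser.
#' @param consistency_sign `-1` (default) rewards neighbour cosine
#'   similarity; `+1` penalises it (kept for parity experiments).
#' @param tree_mse_drop_threshold Stop splitting when the per-iteration error
#'   drop falls below this value (`tree_mse_mode = "absolute"`) or below this
#'   fraction of the current error (`"relative"`).
#' @param tree_mse_mode `"relative"` (default) or `"absolute"`. Sum-to-one
#'   normalised series have squared errors of order 1/N^2, so an absolute
#'   threshold of 100 never splits; the relative criterion is scale-free.
#' @param tree_min_interval Minimum segment length in the linear tree.
#' @param velocity_gene_gamma_min Minimum through-origin slope of unspliced
#'   on spliced expression for a velocity gene.
#' @param velocity_gene_r2_min Minimum coefficient of determination.
#' @param sigma_ratio_bounds Bounds on sd(u)/sd(s) for a velocity gene.
#' @param normalization_mode `"sum"` rescales each series to sum to 1;
#'   `"max"` divides by the series maximum.
#' @param fit_mode Velocity estimator: `"fit"` (consistency-regularised,
#'   default), `"simple_fit"`, or `"kinetic"`.
#' @param fit_iterations,fit_learning_rate Gradient-descent budget and step
#'   for `fit_mode = "fit"`.
#' @param kinetic_epochs,kinetic_learning_rate Training budget and step for
#'   the kinetic-rate network.
#' @param sigma Kernel width of the velocity-graph transition matrix.
#' @param n_pcs Number of principal components for the kNN graph.
#' @param random_seed Seed used by every stochastic step.
#'
#' @return A list of class `tivelo_config`.
#' @export
#' @examples
#' cfg <- tivelo_config(leiden_resolution = 1)
#' cfg$k_neighbors
tivelo_config <- function(k_neighbors = 30,
                          n_top_genes = 2000,
                          min_shared_counts = 20,
                          leiden_resolution = 0.6,
                          smoothing_kernel = 100,
                          pruning_mass_fraction = 0.5,
                          pruning_min_clusters = 5,
                          pruning_weight_factor = 0.6,
                          score_threshold = 0.1,
                          z1 = 0.1,
                          z2 = 1.0,
                          lambda = 1.0,
                          lambda_prime = 0.1,
                          consistency_sign = -1,
                          tree_mse_drop_threshold = NULL,
                          tree_mse_mode = c("relative", "absolute"),
                          tree_min_interval = 10,
                          velocity_gene_gamma_min = 0.01,
                          velocity_gene_r2_min = 0.01,
                          sigma_ratio_bounds = c(0.03, 3),
                          normalization_mode = c("sum", "max"),
                          fit_mode = c("fit", "simple_fit", "kinetic"),
                          fit_iterations = 200,
                          fit_learning_rate = 0.01,
                          kinetic_epochs = 300,
                          kinetic_learning_rate = 0.001,
                          sigma = 1,
                          n_pcs = 30,
                          random_seed = 0L) {
  tree_mse_mode <- match.arg(tree_mse_mode)
  if (is.null(tree_mse_drop_threshold)) {
    tree_mse_drop_threshold <- if (tree_mse_mode == "absolute") 100 else 1e-3
  }
  cfg <- list(
    k_neighbors = as.integer(k_neighbors),
    n_top_genes = as.integer(n_top_genes),
    min_shared_counts = as.integer(min_shared_counts),
    leiden_resolution = leiden_resolution,
    smoothing_kernel = as.integer(smoothing_kernel),
    pruning_mass_fraction = pruning_mass_fraction,
    pruning_min_clusters = as.integer(pruning_min_clusters),
    pruning_weight_factor = pruning_weight_factor,
    score_threshold = score_threshold,
    z1 = z1,
    z2 = z2,
    lambda = lambda,
    lambda_prime = lambda_prime,
    consistency_sign = consistency_sign,
    tree_mse_drop_threshold = tree_mse_drop_threshold,
    tree_mse_mode = tree_mse_mode,
    tree_min_interval = as.integer(tree_min_interval),
    velocity_gene_gamma_min = velocity_gene_gamma_min,
    velocity_gene_r2_min = velocity_gene_r2_min,
    sigma_ratio_bounds = sigma_ratio_bounds,
    normalization_mode = match.arg(normalization_mode),
    fit_mode = match.arg(fit_mode),
    fit_iterations = as.integer(fit_iterations),
    fit_learning_rate = fit_learning_rate,
    kinetic_epochs = as.integer(kinetic_epochs),
    kinetic_learning_rate = kinetic_learning_rate,
    sigma = sigma,
    n_pcs = as.integer(n_pcs),
    random_seed = as.integer(random_seed)
  )
  positive <- c(
    "k_neighbors", "n_top_genes", "min_shared_counts", "leiden_resolution",
    "smoothing_kernel", "pruning_mass_fraction", "pruning_min_clusters",
    "pruning_weight_factor", "score_threshold", "z1", "z2", "lambda",
    "tree_mse_drop_threshold", "tree_min_interval", "sigma", "n_pcs"
  )
  for (nm in positive) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || cfg[[nm]] <= 0) {
      abort(sprintf("config field '%s' must be a positive scalar", nm))
    }
  }
  if (cfg$sigma_ratio_bounds[1] >= cfg$sigma_ratio_bounds[2]) {
    abort("sigma_ratio_bounds must satisfy lower < upper")
  }
  structure(cfg, class = "tivelo_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Fields in the file override the defaults of [tivelo_config()].
#'
#' @param path Path to a YAML file whose keys match [tivelo_config()]
#'   arguments.
#' @return A `tivelo_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(tivelo_config)))
  if (length(unknown) > 0) {
    warn(paste0("ignoring unknown config fields: ", paste(unknown, collapse = ", ")))
    vals <- vals[setdiff(names(vals), unknown)]
  }
  do.call(tivelo_config, vals)
}

#' @export
print.tivelo_config <- function(x, ...) {
  cat("<tivelo_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-24s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
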