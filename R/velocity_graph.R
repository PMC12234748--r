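# cosine between each cell's velocity and the displacement to each of its
# kNN neighbours, as triplets over the kNN support (zero-norm velocities
# give zero cosines); explicit zeros are kept so the support stays intact
cosine_triplets <- function(s, v, knn) {
  n <- nrow(s)
  k <- ncol(knn)
  vnorm <- sqrt(rowSums(v * v))
  vals <- numeric(n * k)
  for (j in seq_len(k)) {
    idx <- (j - 1L) * n + seq_len(n)
    delta <- s[knn[, j], , drop = FALSE] - s
    dnorm <- sqrt(rowSums(delta * delta))
    denom <- dnorm * vnorm
    vals[idx] <- ifelse(denom > 0, rowSums(delta * v) / denom, 0)
  }
  list(i = rep(seq_len(n), k), j = as.vector(knn), x = vals, n = n)
}

cosine_velocity_graph <- function(s, v, knn) {
  tr <- cosine_triplets(s, v, knn)
  Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x, dims = c(tr$n, tr$n))
}

# exponential kernel on the support triplets, rows normalized to sum to 1
transition_from_triplets <- function(tr, sigma = 1) {
  out <- Matrix::sparseMatrix(
    i = tr$i, j = tr$j, x = exp(tr$x / sigma^2), dims = c(tr$n, tr$n)
  )
  row_normalize(out)
}

transition_matrix <- function(pi_mat, sigma = 1, knn = NULL) {
  if (!is.null(knn)) {
    # rebuild the full support so exactly-zero cosines keep their slot
    n <- nrow(pi_mat)
    i <- rep(seq_len(n), ncol(knn))
    j <- as.vector(knn)
    x <- pi_mat[cbind(i, j)]
    return(transition_from_triplets(list(i = i, j = j, x = x, n = n), sigma))
  }
  tp <- methods::as(pi_mat, "TsparseMatrix")
  transition_from_triplets(
    list(i = tp@i + 1L, j = tp@j + 1L, x = tp@x, n = nrow(pi_mat)), sigma
  )
}

row_normalize <- function(m) {
  rs <- Matrix::rowSums(m)
  rs[rs == 0] <- 1
  Matrix::Diagonal(x = 1 / rs) %*% m
}

#' Build the cell-level velocity graph
#'
#' For every stored neighbour pair the velocity graph holds the cosine
#' between the cell's spliced velocity and the displacement of smoothed
#' spliced expression toward the neighbour; the transition matrix applies
#' an exponential kernel of width `sigma` and normalizes each row over its
#' stored entries. Cells with zero-norm velocity get a zero cosine row and
#' a uniform transition row.
#'
#' @param ds A preprocessed [tivelo_dataset()] with a kNN graph.
#' @param vf A `tivelo_velocity_field` (see [simple_fit()], [fit_velocity()]).
#' @param cfg A [tivelo_config()]; `sigma` sets the kernel width.
#' @return An object of class `tivelo_velocity_graph` with sparse fields
#'   `pi` (cosines in \[-1, 1\]) and `pi_tilde` (row-stochastic).
#' @export
velocity_graph <- function(ds, vf, cfg = tivelo_config()) {
  if (is.null(ds$knn)) abort("knn graph missing: run preprocess() first")
  sm <- smoothed_layers(ds)
  tr <- cosine_triplets(sm$s, vf$v_s, ds$knn)
  structure(
    list(
      pi = Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x, dims = c(tr$n, tr$n)),
      pi_tilde = transition_from_triplets(tr, sigma = cfg$sigma),
      knn = ds$knn,
      sigma = cfg$sigma
    ),
    class = "tivelo_velocity_graph"
  )
}

#' Project velocities onto a 2-d embedding
#'
#' Each cell's embedding velocity is the transition-weighted mean of unit
#' vectors toward every other cell, centred by the uniform weight `1/N`:
#' `v_e(n) = sum_{n' != n} (pi_tilde(n, n') - 1/N) * unit(e(n') - e(n))`.
#' Transition entries outside the stored support count as zero (the
#' `-1/N` term still applies to all pairs); pairs with duplicated
#' embedding coordinates are skipped.
#'
#' @param ds A [tivelo_dataset()] with an embedding.
#' @param vg A `tivelo_velocity_graph`.
#' @return A cells-by-2 matrix of embedding velocities.
#' @export
embedding_velocity <- function(ds, vg) {
  if (is.null(ds$embedding)) abort("dataset has no embedding")
  e <- ds$embedding
  n <- nrow(e)
  out <- matrix(0, n, 2)
  tp <- methods::as(methods::as(vg$pi_tilde, "generalMatrix"), "TsparseMatrix")
  # support term: sum over stored pairs of pi_tilde * unit displacement
  de <- e[tp@j + 1L, , drop = FALSE] - e[tp@i + 1L, , drop = FALSE]
  len <- sqrt(rowSums(de * de))
  ok <- len > 0
  wt <- tp@x[ok] / len[ok]
  out[, 1] <- as.vector(tapply(wt * de[ok, 1], factor(tp@i[ok] + 1L, levels = seq_len(n)), sum, default = 0))
  out[, 2] <- as.vector(tapply(wt * de[ok, 2], factor(tp@i[ok] + 1L, levels = seq_len(n)), sum, default = 0))
  # uniform term: (1/N) * sum over all pairs of unit displacement
  chunk <- 512L
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    dx <- outer(e[idx, 1], e[, 1], function(a, b) b - a)
    dy <- outer(e[idx, 2], e[, 2], function(a, b) b - a)
    len2 <- sqrt(dx^2 + dy^2)
    len2[len2 == 0] <- Inf  # self pairs and duplicated coordinates
    out[idx, 1] <- out[idx, 1] - rowSums(dx / len2) / n
    out[idx, 2] <- out[idx, 2] - rowSums(dy / len2) / n
  }
  out
}
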