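#' Read an expression dataset from disk
#'
#' Supports three on-disk dialects: `h5ad` (AnnData-style HDF5 with an `X`
#' matrix, `layers/`, `obs/`, `var/` and `obsm/`), `loom` (genes-by-cells
#' `matrix` plus `layers/`, `row_attrs/`, `col_attrs/`), and `mtx_dir` (a
#' directory with `spliced.mtx`, `unspliced.mtx`, `barcodes.tsv`,
#' `genes.tsv` and an optional `obs.tsv`). Spliced/unspliced layers are
#' located through a configurable alias map because producers name them
#' differently (`spliced`/`Ms`, `unspliced`/`Mu`).
#'
#' @param path File (h5ad, loom) or directory (mtx_dir) to read.
#' @param format One of `"h5ad"`, `"loom"`, `"mtx_dir"`; guessed from the
#'   file extension when missing.
#' @param aliases Named list with elements `spliced` and `unspliced`, each a
#'   character vector of acceptable layer names in priority order.
#' @return A [tivelo_dataset()]; gene and cell order as stored in the file.
#' @export
read_dataset <- function(path,
                         format = c("auto", "h5ad", "loom", "mtx_dir"),
                         aliases = default_layer_aliases()) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!file.exists(path)) abort(sprintf("path does not exist: %s", path))
  switch(format,
    h5ad = read_h5ad(path, aliases),
    loom = read_loom(path, aliases),
    mtx_dir = read_mtx_dir(path)
  )
}

#' @rdname read_dataset
#' @export
default_layer_aliases <- function() {
  list(
    spliced = c("spliced", "Ms", "X_spliced"),
    unspliced = c("unspliced", "Mu", "X_unspliced")
  )
}

guess_format <- function(path) {
  if (dir.exists(path)) return("mtx_dir")
  ext <- tolower(tools::file_ext(path))
  if (ext == "h5ad") return("h5ad")
  if (ext == "loom") return("loom")
  abort(sprintf("cannot guess format of '%s'; pass format=", path))
}

resolve_layer <- function(available, wanted, aliases) {
  hit <- intersect(aliases[[wanted]], available)
  if (length(hit) == 0) {
    abort(sprintf(
      "layer not found: no '%s' layer among available layers: %s",
      wanted, paste(available, collapse = ", ")
    ))
  }
  hit[1]
}

#' Write an expression dataset to disk
#'
#' The written file round-trips through [read_dataset()] with identical
#' counts, labels and layer names. Velocity and smoothed layers present in
#' `ds$layers` are written alongside the core layers.
#'
#' @param ds A [tivelo_dataset()].
#' @param path Destination file or directory.
#' @param format One of `"h5ad"`, `"loom"`, `"mtx_dir"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, format = c("auto", "h5ad", "loom", "mtx_dir")) {
  validate_dataset(ds)
  format <- match.arg(format)
  if (format == "auto") format <- guess_format_write(path)
  parent <- dirname(path)
  if (!dir.exists(parent)) abort(sprintf("directory does not exist: %s", parent))
  if (file.access(parent, 2) != 0) abort(sprintf("directory not writable: %s", parent))
  switch(format,
    h5ad = write_h5ad(ds, path),
    loom = write_loom(ds, path),
    mtx_dir = write_mtx_dir(ds, path)
  )
  invisible(path)
}

guess_format_write <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "h5ad") return("h5ad")
  if (ext == "loom") return("loom")
  if (ext == "") return("mtx_dir")
  abort(sprintf("cannot guess format of '%s'; pass format=", path))
}

# ---- h5ad --------------------------------------------------------------
# Layout mirrors AnnData: datasets are stored so that a row-major reader
# sees cells x genes; rhdf5 is column-major, hence the transposes.

read_h5ad <- function(path, aliases) {
  contents <- rhdf5::h5ls(path)
  layer_names <- contents$name[contents$group == "/layers"]
  s_name <- resolve_layer(layer_names, "spliced", aliases)
  u_name <- resolve_layer(layer_names, "unspliced", aliases)
  read_mat <- function(name) t(rhdf5::h5read(path, name))
  spliced <- read_mat(paste0("layers/", s_name))
  unspliced <- read_mat(paste0("layers/", u_name))
  if (!identical(dim(spliced), dim(unspliced))) {
    abort("shape mismatch between spliced and unspliced layers")
  }
  extra <- setdiff(layer_names, c(s_name, u_name))
  layers <- setNames(lapply(extra, function(nm) read_mat(paste0("layers/", nm))), extra)

  obs <- read_h5_frame(path, contents, "/obs", nrow(spliced), "cell")
  var <- read_h5_frame(path, contents, "/var", ncol(spliced), "gene")
  embedding <- NULL
  obsm <- contents$name[contents$group == "/obsm"]
  if (length(obsm) > 0) {
    embedding <- t(rhdf5::h5read(path, paste0("obsm/", obsm[1])))
    if (ncol(embedding) != 2 && nrow(embedding) == 2) embedding <- t(embedding)
  }
  uns <- list()
  if (any(contents$group == "/uns" | grepl("^/uns", contents$group))) {
    uns <- tryCatch(as.list(rhdf5::h5read(path, "uns")), error = function(e) list())
  }
  tivelo_dataset(spliced, unspliced,
    obs = obs, var = var, embedding = embedding,
    layers = layers, uns = uns,
    cell_names = obs$cell, gene_names = var$gene
  )
}

read_h5_frame <- function(path, contents, group, n, index_name) {
  cols <- contents$name[contents$group == group]
  if (length(cols) == 0) return(NULL)
  out <- list()
  for (nm in cols) {
    val <- rhdf5::h5read(path, paste(group, nm, sep = "/"))
    if (is.list(val) && all(c("categories", "codes") %in% names(val))) {
      val <- as.character(val$categories)[as.integer(val$codes) + 1L]
    }
    if (length(val) == n) out[[nm]] <- as.vector(val)
  }
  names(out)[names(out) == "_index"] <- index_name
  as_tibble(out)
}

write_h5ad <- function(ds, path) {
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  h5 <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(h5), add = TRUE)
  rhdf5::h5createGroup(h5, "layers")
  rhdf5::h5createGroup(h5, "obs")
  rhdf5::h5createGroup(h5, "var")
  rhdf5::h5createGroup(h5, "obsm")
  rhdf5::h5createGroup(h5, "uns")
  rhdf5::h5write(t(ds$spliced), h5, "X")
  rhdf5::h5write(t(ds$spliced), h5, "layers/spliced")
  rhdf5::h5write(t(ds$unspliced), h5, "layers/unspliced")
  for (nm in names(ds$layers)) {
    rhdf5::h5write(t(ds$layers[[nm]]), h5, paste0("layers/", nm))
  }
  write_h5_frame(h5, "obs", ds$obs, "cell")
  write_h5_frame(h5, "var", ds$var, "gene")
  if (!is.null(ds$embedding)) {
    rhdf5::h5write(t(ds$embedding), h5, "obsm/X_embedding")
  }
  for (nm in names(ds$uns)) {
    val <- ds$uns[[nm]]
    if (is.numeric(val) || is.character(val)) {
      rhdf5::h5write(val, h5, paste0("uns/", nm))
    }
  }
  invisible(path)
}

write_h5_frame <- function(h5, group, frame, index_name) {
  for (nm in names(frame)) {
    val <- frame[[nm]]
    if (is.factor(val)) val <- as.character(val)
    if (!is.numeric(val) && !is.character(val) && !is.logical(val)) next
    if (is.logical(val)) val <- as.integer(val)
    target <- if (nm == index_name) "_index" else nm
    rhdf5::h5write(val, h5, paste(group, target, sep = "/"))
  }
}

# ---- loom --------------------------------------------------------------
# loom stores genes in rows and cells in columns.

read_loom <- function(path, aliases) {
  contents <- rhdf5::h5ls(path)
  layer_names <- contents$name[contents$group == "/layers"]
  s_name <- resolve_layer(layer_names, "spliced", aliases)
  u_name <- resolve_layer(layer_names, "unspliced", aliases)
  # loom stores genes x cells in C order, which the column-major reader
  # already sees as cells x genes
  read_mat <- function(name) rhdf5::h5read(path, name)
  spliced <- read_mat(paste0("layers/", s_name))
  unspliced <- read_mat(paste0("layers/", u_name))
  extra <- setdiff(layer_names, c(s_name, u_name))
  layers <- setNames(lapply(extra, function(nm) read_mat(paste0("layers/", nm))), extra)
  col_attrs <- contents$name[contents$group == "/col_attrs"]
  obs <- list()
  for (nm in col_attrs) {
    obs[[nm]] <- as.vector(rhdf5::h5read(path, paste0("col_attrs/", nm)))
  }
  names(obs)[names(obs) == "CellID"] <- "cell"
  row_attrs <- contents$name[contents$group == "/row_attrs"]
  var <- list()
  for (nm in row_attrs) {
    var[[nm]] <- as.vector(rhdf5::h5read(path, paste0("row_attrs/", nm)))
  }
  names(var)[names(var) == "Gene"] <- "gene"
  obs <- as_tibble(obs)
  var <- as_tibble(var)
  tivelo_dataset(spliced, unspliced,
    obs = obs, var = var, layers = layers,
    cell_names = obs$cell, gene_names = var$gene
  )
}

write_loom <- function(ds, path) {
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  h5 <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(h5), add = TRUE)
  rhdf5::h5createGroup(h5, "layers")
  rhdf5::h5createGroup(h5, "row_attrs")
  rhdf5::h5createGroup(h5, "col_attrs")
  rhdf5::h5write(ds$spliced, h5, "matrix")  # stored genes x cells for a row-major reader
  rhdf5::h5write(ds$spliced, h5, "layers/spliced")
  rhdf5::h5write(ds$unspliced, h5, "layers/unspliced")
  for (nm in names(ds$layers)) rhdf5::h5write(ds$layers[[nm]], h5, paste0("layers/", nm))
  rhdf5::h5write(ds$var$gene, h5, "row_attrs/Gene")
  rhdf5::h5write(ds$obs$cell, h5, "col_attrs/CellID")
  for (nm in setdiff(names(ds$obs), "cell")) {
    val <- ds$obs[[nm]]
    if (is.factor(val)) val <- as.character(val)
    if (is.numeric(val) || is.character(val)) {
      rhdf5::h5write(val, h5, paste0("col_attrs/", nm))
    }
  }
  invisible(path)
}

# ---- mtx directory -----------------------------------------------------
# Matrices are written genes x cells (the common CellRanger orientation).

read_mtx_dir <- function(path) {
  need <- file.path(path, c("spliced.mtx", "unspliced.mtx", "barcodes.tsv", "genes.tsv"))
  missing <- need[!file.exists(need)]
  if (length(missing) > 0) {
    abort(paste0("mtx_dir is missing: ", paste(basename(missing), collapse = ", ")))
  }
  genes <- readLines(file.path(path, "genes.tsv"))
  cells <- readLines(file.path(path, "barcodes.tsv"))
  read_one <- function(f) {
    m <- t(as.matrix(Matrix::readMM(f)))  # -> cells x genes
    dimnames(m) <- list(cells, genes)
    m
  }
  spliced <- read_one(file.path(path, "spliced.mtx"))
  unspliced <- read_one(file.path(path, "unspliced.mtx"))
  extra_files <- setdiff(
    list.files(path, pattern = "\\.mtx$"),
    c("spliced.mtx", "unspliced.mtx")
  )
  layers <- setNames(
    lapply(file.path(path, extra_files), read_one),
    sub("\\.mtx$", "", extra_files)
  )
  obs <- NULL
  obs_file <- file.path(path, "obs.tsv")
  if (file.exists(obs_file)) {
    obs <- as_tibble(utils::read.delim(obs_file, stringsAsFactors = FALSE))
  }
  tivelo_dataset(spliced, unspliced,
    obs = obs, layers = layers,
    cell_names = cells, gene_names = genes
  )
}

write_mtx_dir <- function(ds, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  write_one <- function(m, f) {
    Matrix::writeMM(methods::as(Matrix::Matrix(t(m), sparse = TRUE), "generalMatrix"), f)
  }
  write_one(ds$spliced, file.path(path, "spliced.mtx"))
  write_one(ds$unspliced, file.path(path, "unspliced.mtx"))
  for (nm in names(ds$layers)) {
    write_one(ds$layers[[nm]], file.path(path, paste0(nm, ".mtx")))
  }
  writeLines(ds$obs$cell, file.path(path, "barcodes.tsv"))
  writeLines(ds$var$gene, file.path(path, "genes.tsv"))
  keep <- vapply(ds$obs, function(v) is.numeric(v) || is.character(v) || is.factor(v), TRUE)
  utils::write.table(ds$obs[keep], file.path(path, "obs.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
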