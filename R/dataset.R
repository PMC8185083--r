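#' Single-cell MS dataset container
#'
#' An `scms_dataset` bundles a protein x cell signal-to-noise matrix with the
#' per-protein and per-cell metadata produced by a multiplexed booster-channel
#' single-cell proteomics experiment. Quantitative layers share dimensions and
#' dimnames; every processing step appends to an immutable provenance log.
#'
#' @param raw_sn Numeric matrix, proteins in rows, cells in columns. Rownames
#'   are protein identifiers, colnames are cell identifiers. Values are
#'   reporter-ion signal-to-noise ratios; `NA` marks non-detection.
#' @param proteins Tibble of per-protein annotations with a `protein_id`
#'   column matching the rownames of `raw_sn`.
#' @param cells Tibble of per-cell records with a `cell_id` column matching
#'   the colnames of `raw_sn`; typically built by [assemble_cell_metadata()].
#'
#' @return An object of class `scms_dataset`: a list with elements `proteins`,
#'   `cells`, `layers` (named list of matrices) and `provenance` (tibble).
#' @export
scms_dataset <- function(raw_sn, proteins = NULL, cells = NULL) {
  if (!is.matrix(raw_sn) || !is.numeric(raw_sn)) {
    abort("`raw_sn` must be a numeric matrix (proteins x cells).")
  }
  if (is.null(rownames(raw_sn)) || is.null(colnames(raw_sn))) {
    abort("`raw_sn` must carry protein rownames and cell colnames.")
  }
  if (anyDuplicated(rownames(raw_sn))) {
    dups <- unique(rownames(raw_sn)[duplicated(rownames(raw_sn))])
    abort(paste0("Duplicate protein identifiers: ",
                 paste(head(dups, 5), collapse = ", ")))
  }
  if (any(raw_sn < 0, na.rm = TRUE)) {
    abort("raw signal-to-noise values must be >= 0 where present.")
  }
  if (is.null(proteins)) {
    proteins <- tibble(protein_id = rownames(raw_sn))
  }
  if (is.null(cells)) {
    cells <- tibble(cell_id = colnames(raw_sn))
  }
  proteins <- as_tibble(proteins)
  cells <- as_tibble(cells)
  stopifnot(identical(proteins$protein_id, rownames(raw_sn)),
            identical(cells$cell_id, colnames(raw_sn)))
  ds <- structure(
    list(
      proteins = proteins,
      cells = cells,
      layers = list(raw_sn = raw_sn),
      provenance = tibble(operation = character(), params = character(),
                          timestamp = character())
    ),
    class = "scms_dataset"
  )
  log_op(ds, "create", list(n_proteins = nrow(raw_sn), n_cells = ncol(raw_sn)))
}

#' @export
print.scms_dataset <- function(x, ...) {
  cat(sprintf("<scms_dataset> %d proteins x %d cells\n",
              nrow(x$layers[[1]]), ncol(x$layers[[1]])))
  cat("  layers: ", paste(names(x$layers), collapse = ", "), "\n", sep = "")
  if ("file_id" %in% names(x$cells)) {
    cat(sprintf("  files: %d  channels: %d\n",
                length(unique(x$cells$file_id)),
                length(unique(x$cells$channel))))
  }
  cat(sprintf("  provenance: %d operations\n", nrow(x$provenance)))
  invisible(x)
}

#' @export
dim.scms_dataset <- function(x) dim(x$layers[[1]])

# Append one entry to the provenance log; never rewrites earlier entries.
log_op <- function(ds, operation, params = list()) {
  entry <- tibble(
    operation = operation,
    params = as.character(jsonlite::toJSON(params, auto_unbox = TRUE)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  ds$provenance <- dplyr::bind_rows(ds$provenance, entry)
  ds
}

#' Extract a quantitative layer
#'
#' @param ds An [scms_dataset()].
#' @param layer Layer name, e.g. `"raw_sn"`, `"normalized"`, `"log2"`,
#'   `"imputed"`, `"scaled"`.
#' @return A protein x cell numeric matrix.
#' @export
get_layer <- function(ds, layer = "raw_sn") {
  if (!layer %in% names(ds$layers)) {
    abort(paste0("Layer '", layer, "' not present. Available: ",
                 paste(names(ds$layers), collapse = ", ")))
  }
  ds$layers[[layer]]
}

set_layer <- function(ds, layer, mat) {
  ref <- ds$layers[[1]]
  stopifnot(identical(dim(mat), dim(ref)),
            identical(rownames(mat), rownames(ref)),
            identical(colnames(mat), colnames(ref)))
  ds$layers[[layer]] <- mat
  ds
}

# Subset every layer and both metadata tables consistently.
subset_dataset <- function(ds, proteins = NULL, cells = NULL) {
  pidx <- proteins %||% seq_len(nrow(ds$layers[[1]]))
  cidx <- cells %||% seq_len(ncol(ds$layers[[1]]))
  ds$layers <- lapply(ds$layers, function(m) m[pidx, cidx, drop = FALSE])
  ds$proteins <- ds$proteins[pidx, , drop = FALSE]
  ds$cells <- ds$cells[cidx, , drop = FALSE]
  ds
}

#' Tidy a dataset layer into long form
#'
#' @param x An [scms_dataset()].
#' @param layer Which layer to tidy.
#' @param drop_missing Drop `NA` entries (default `TRUE`).
#' @param ... Unused.
#' @return A tibble with columns `protein_id`, `cell_id`, `value`.
#' @method tidy scms_dataset
#' @export
tidy.scms_dataset <- function(x, layer = "raw_sn", drop_missing = TRUE, ...) {
  m <- get_layer(x, layer)
  out <- tibble(
    protein_id = rep(rownames(m), times = ncol(m)),
    cell_id = rep(colnames(m), each = nrow(m)),
    value = as.vector(m)
  )
  if (drop_missing) out <- dplyr::filter(out, !is.na(.data$value))
  out
}

#' One-row summary of a dataset
#'
#' @param x An [scms_dataset()].
#' @param ... Unused.
#' @return A one-row tibble with dimensions, layer count, mean proteins per
#'   cell and overall completeness of the first layer.
#' @method glance scms_dataset
#' @export
glance.scms_dataset <- function(x, ...) {
  m <- x$layers[[1]]
  obs <- !is.na(m)
  tibble(
    n_proteins = nrow(m),
    n_cells = ncol(m),
    n_layers = length(x$layers),
    mean_proteins_per_cell = mean(colSums(obs)),
    completeness = mean(obs)
  )
}

DATASET_SCHEMA_VERSION <- 1L

# Full-precision text representation for doubles: %.17g round-trips IEEE754.
.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

.write_matrix_tsv <- function(mat, path) {
  df <- data.frame(protein_id = rownames(mat),
                   apply(mat, 2, .fmt_num),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' Save / load a dataset to a plain-text container
#'
#' The container is a directory holding one TSV per layer (doubles written at
#' full precision so they round-trip exactly), the metadata tables, and a JSON
#' manifest with schema version and the provenance log.
#'
#' @param ds An [scms_dataset()].
#' @param path Directory to create or read.
#' @return `save_dataset` returns `path` invisibly; `load_dataset` returns the
#'   reconstructed [scms_dataset()].
#' @export
save_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "scms_dataset"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(path, "layers"), showWarnings = FALSE)
  for (nm in names(ds$layers)) {
    .write_matrix_tsv(ds$layers[[nm]], file.path(path, "layers", paste0(nm, ".tsv")))
  }
  write.table(ds$proteins, file.path(path, "proteins.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ds$cells, file.path(path, "cells.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    schema_version = DATASET_SCHEMA_VERSION,
    layers = names(ds$layers),
    dim = dim(ds$layers[[1]]),
    provenance = ds$provenance
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) {
    abort("Not a dataset container: manifest.json missing.")
  }
  manifest <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  if (is.null(manifest$schema_version) ||
      manifest$schema_version != DATASET_SCHEMA_VERSION) {
    abort(sprintf("Container schema version mismatch: found %s, expected %d.",
                  manifest$schema_version %||% "none", DATASET_SCHEMA_VERSION))
  }
  layers <- list()
  for (nm in manifest$layers) {
    lp <- file.path(path, "layers", paste0(nm, ".tsv"))
    if (!file.exists(lp)) abort(paste0("Container truncated: missing layer ", nm))
    layers[[nm]] <- .read_matrix_tsv(lp)
  }
  proteins <- as_tibble(read.delim(file.path(path, "proteins.tsv"),
                                   check.names = FALSE))
  proteins$protein_id <- as.character(proteins$protein_id)
  cells <- as_tibble(read.delim(file.path(path, "cells.tsv"),
                                check.names = FALSE))
  cells$cell_id <- as.character(cells$cell_id)
  ds <- structure(
    list(proteins = proteins, cells = cells, layers = layers,
         provenance = as_tibble(manifest$provenance)),
    class = "scms_dataset"
  )
  ds
}

#' Export one layer as TSV
#'
#' @param ds An [scms_dataset()].
#' @param layer Layer name.
#' @param path Output file.
#' @export
export_layer <- function(ds, layer, path) {
  .write_matrix_tsv(get_layer(ds, layer), path)
  invisible(path)
}
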