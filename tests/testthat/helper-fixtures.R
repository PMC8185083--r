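# Shared fixtures, all generated in code at test time.

# A small dataset with injected structure, run through the full
# normalization / QC chain up to the log2 layer.
make_processed_dataset <- function(seed = 1, n_proteins = 200, n_cells = 140,
                                   ...) {
  cfg <- simulation_config(n_proteins = n_proteins, n_cells = n_cells,
                           seed = seed, ...)
  sim <- simulate_dataset(cfg)
  nm <- normalize_medians(sim$dataset)
  ds <- mask_noise_floor(nm$dataset)
  ds <- filter_cells(ds)$dataset
  ds <- filter_proteins_min_cells(ds)
  ds <- median_shift_and_log2(ds)
  list(ds = ds, truth = sim$truth, factors = nm$factors)
}

# A tiny dataset built by hand (no simulation) with all three layers set,
# for exact-arithmetic tests.
make_manual_dataset <- function(mat, files = NULL, channels = NULL) {
  n <- ncol(mat)
  cells <- tibble::tibble(
    cell_id = colnames(mat),
    file_id = files %||% rep("F01", n),
    channel = channels %||% paste0("ch", seq_len(n)),
    population = rep(c("A", "B"), length.out = n)
  )
  ds <- scms_dataset(mat, cells = cells)
  ds <- scmskit:::set_layer(ds, "normalized", mat)
  scmskit:::set_layer(ds, "log2", log2(mat))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One simulated experiment split into two batches by LC-MS file, the second
# batch given a global log2 shift: two datasets sharing populations whose
# only systematic difference is the shift.
make_split_batches <- function(seed = 7, n_proteins = 300, n_cells = 400,
                               shift = 2) {
  pops <- tibble::tibble(
    name = c("LSC", "Progenitor", "Blast"), weight = c(5, 5, 4) / 14,
    tau_center = c(0.08, 0.5, 0.92), tau_sd = c(0.04, 0.04, 0.04)
  )
  fx <- make_processed_dataset(seed, n_proteins, n_cells,
                               populations = pops, frac_trajectory = 0.25,
                               traj_effect_log2 = 2.5)
  ds <- fx$ds
  files <- unique(ds$cells$file_id)
  in_a <- ds$cells$file_id %in% files[seq_len(length(files) %/% 2)]
  split_one <- function(sel, delta, tag) {
    d <- scmskit:::subset_dataset(ds, cells = which(sel))
    d$layers$log2 <- d$layers$log2 + delta
    d$cells$cell_id <- paste0(tag, d$cells$cell_id)
    for (l in names(d$layers)) colnames(d$layers[[l]]) <- d$cells$cell_id
    coverage_filter(d, 0.4)
  }
  list(a = split_one(in_a, 0, "a_"), b = split_one(!in_a, shift, "b_"))
}

mean_sil <- function(coords, labels) {
  attr(silhouette_scores(coords, labels), "mean_silhouette")
}

# Independent brute-force kNN imputation: plain loops, no shared code with
# the implementation.
brute_impute <- function(mat, k) {
  n <- ncol(mat)
  d <- matrix(Inf, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    shared <- which(!is.na(mat[, i]) & !is.na(mat[, j]))
    if (length(shared)) {
      d[i, j] <- sqrt(sum((mat[shared, i] - mat[shared, j])^2) / length(shared))
    }
  }
  out <- mat
  for (ci in seq_len(n)) {
    nn <- order(d[, ci])[seq_len(k)]
    for (p in which(is.na(mat[, ci]))) {
      vals <- mat[p, nn]
      out[p, ci] <- if (any(!is.na(vals))) mean(vals, na.rm = TRUE) else
        mean(mat[p, ], na.rm = TRUE)
    }
  }
  out
}

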