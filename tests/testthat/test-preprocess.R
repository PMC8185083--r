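test_that("contaminant, failed-run and row removal behave as documented", {
  fx <- make_processed_dataset(seed = 1, n_proteins = 100, n_cells = 56)
  ds <- fx$ds
  n0 <- nrow(ds$proteins)
  ds$proteins$contaminant[1:2] <- TRUE
  out <- remove_contaminants_and_failed_runs(ds)
  expect_equal(nrow(out$proteins), n0 - 2L)
  # a file with no quantified proteins is dropped
  ds2 <- ds
  f1 <- ds2$cells$file_id == ds2$cells$file_id[1]
  ds2$layers$raw_sn[, f1] <- NA
  out2 <- remove_contaminants_and_failed_runs(ds2)
  expect_false(ds2$cells$file_id[1] %in% out2$cells$file_id)
  expect_error(remove_contaminants_and_failed_runs(
    ds2, run_min_proteins = 1e6), "every cell")
})

test_that("excluding plate rows removes exactly those wells' cells", {
  lay <- build_plate_layout(seed = 2)
  cells <- assemble_cell_metadata(lay)
  mat <- matrix(rlnorm(20 * nrow(cells), 2, 0.5), 20, nrow(cells),
                dimnames = list(sprintf("P%02d", 1:20), cells$cell_id))
  ds <- scms_dataset(mat, cells = cells)
  ds$proteins$contaminant <- FALSE
  out <- remove_contaminants_and_failed_runs(ds, exclude_rows = c("I", "J"))
  n_in_rows <- sum(cells$well_row %in% c("I", "J"))
  expect_equal(ncol(out$layers$raw_sn), nrow(cells) - n_in_rows)
  # on a full 384-well plate, rows I and J hold 2 x 24 wells
  expect_equal(sum(lay$well_row %in% c("I", "J")), 48L)
})

test_that("median normalization is a fixed point on already-equal medians", {
  mat <- matrix(rep(c(2, 4, 8), each = 4), 3, 4, byrow = TRUE,
                dimnames = list(paste0("P", 1:3), paste0("c", 1:4)))
  ds <- scms_dataset(mat,
                     cells = tibble::tibble(cell_id = colnames(mat),
                                            file_id = c("F1", "F1", "F2", "F2"),
                                            channel = c("A", "B", "A", "B")))
  out <- normalize_medians(ds)
  expect_equal(out$dataset$layers$normalized, mat)
  expect_equal(out$factors$iterations_used, 1L)
  expect_true(out$factors$converged)
})

test_that("injected file and channel factors are removed exactly (closed form)", {
  # constant true value 10; file2 x2, channel B x0.5 -> observed {10,5,20,10}
  true <- matrix(10, 2, 4, dimnames = list(c("P1", "P2"), paste0("c", 1:4)))
  files <- c("F1", "F1", "F2", "F2")
  channels <- c("A", "B", "A", "B")
  obs <- true *
    ifelse(files == "F2", 2, 1)[col(true)] *
    ifelse(channels == "B", 0.5, 1)[col(true)]
  ds <- scms_dataset(obs, cells = tibble::tibble(cell_id = colnames(obs),
                                                 file_id = files,
                                                 channel = channels))
  out <- normalize_medians(ds, convergence_threshold = 1e-8, max_iter = 100)
  norm <- out$dataset$layers$normalized
  # all entries equal up to one global scale
  expect_lt(diff(range(norm / norm[1, 1])), 1e-6)
})

test_that("iteration stops as soon as the max change is below threshold", {
  fx <- make_processed_dataset(seed = 3, n_proteins = 80, n_cells = 56)
  out <- normalize_medians(scms_dataset(get_layer(fx$ds, "raw_sn"),
                                        cells = fx$ds$cells))
  expect_true(out$factors$final_max_change < 1.1)
  # a tighter threshold takes at least as many iterations
  out2 <- suppressWarnings(
    normalize_medians(scms_dataset(get_layer(fx$ds, "raw_sn"),
                                   cells = fx$ds$cells),
                      convergence_threshold = 0.01))
  expect_gte(out2$factors$iterations_used, out$factors$iterations_used)
})

test_that("normalization warns instead of silently failing at max_iter", {
  fx <- make_processed_dataset(seed = 4, n_proteins = 60, n_cells = 56)
  expect_warning(
    out <- normalize_medians(scms_dataset(get_layer(fx$ds, "raw_sn"),
                                          cells = fx$ds$cells),
                             convergence_threshold = 1e-12, max_iter = 2),
    "did not converge")
  expect_false(out$factors$converged)
})

test_that("normalization is equivariant to a global rescaling", {
  cfg <- simulation_config(n_proteins = 60, n_cells = 56, seed = 5)
  sim <- simulate_dataset(cfg)
  m <- sim$dataset$layers$raw_sn
  ds1 <- scms_dataset(m, cells = sim$dataset$cells)
  ds2 <- scms_dataset(m * 7, cells = sim$dataset$cells)
  # scale the threshold too: the stopping rule is in absolute s/n units
  n1 <- suppressWarnings(
    normalize_medians(ds1, convergence_threshold = 1e-6, max_iter = 30))
  n2 <- suppressWarnings(
    normalize_medians(ds2, convergence_threshold = 7e-6, max_iter = 30))
  expect_equal(n2$dataset$layers$normalized,
               7 * n1$dataset$layers$normalized, tolerance = 1e-8)
})

test_that("noise-floor masking uses a strict inequality", {
  mat <- matrix(c(1.0, 1.1, 1.2, 5), 2, 2,
                dimnames = list(c("P1", "P2"), c("c1", "c2")))
  ds <- scms_dataset(mat)
  ds <- scmskit:::set_layer(ds, "normalized", mat)
  out <- mask_noise_floor(ds)
  expect_true(is.na(out$layers$normalized[1, 1]))   # 1.0 -> missing
  expect_equal(out$layers$normalized[2, 1], 1.1)    # boundary retained
  expect_equal(out$layers$normalized[1, 2], 1.2)
  # all-above-floor matrix unchanged
  ds2 <- scmskit:::set_layer(ds, "normalized", mat + 2)
  expect_equal(mask_noise_floor(ds2)$layers$normalized, mat + 2)
})

test_that("cell filtering applies MAD bounds and the protein-count cutoff", {
  # log2 totals {10, 10.2, 9.8, 10.1, 3}: only the 3 lies outside 3 MADs
  totals <- 2^c(10, 10.2, 9.8, 10.1, 3)
  mat <- rbind(totals / 2, totals / 2)
  dimnames(mat) <- list(c("P1", "P2"), paste0("c", 1:5))
  ds <- scms_dataset(mat)
  ds <- scmskit:::set_layer(ds, "normalized", mat)
  out <- filter_cells(ds, min_proteins_per_cell = 1)
  expect_equal(out$removed$cell_id, "c5")
  expect_match(out$removed$reason, "mad_low")
  # protein-count cutoff reports its own reason
  mat2 <- matrix(rlnorm(300, 4, 0.1), 30, 10,
                 dimnames = list(sprintf("P%02d", 1:30), paste0("c", 1:10)))
  mat2[4:30, 10] <- NA
  ds2 <- scms_dataset(matrix(1, 30, 10, dimnames = dimnames(mat2)))
  ds2 <- scmskit:::set_layer(ds2, "normalized", mat2)
  out2 <- filter_cells(ds2, mad_multiplier = 1e3, min_proteins_per_cell = 5)
  expect_equal(out2$removed$cell_id, "c10")
  expect_match(out2$removed$reason, "min_proteins")
})

test_that("simulated empty wells are removed with few true cells lost", {
  cfg <- simulation_config(n_proteins = 300, n_cells = 280, seed = 2,
                           empty_well_rate = 0.05)
  sim <- simulate_dataset(cfg)
  nm <- normalize_medians(sim$dataset)
  ds <- mask_noise_floor(nm$dataset)
  out <- filter_cells(ds)
  empt <- sim$truth$cells$cell_id[sim$truth$cells$is_empty]
  real <- setdiff(sim$truth$cells$cell_id, empt)
  expect_gte(mean(empt %in% out$removed$cell_id), 0.95)
  expect_lte(mean(real %in% out$removed$cell_id), 0.02)
})

test_that("protein min-cells filter is exclusive at the boundary", {
  mat <- matrix(rlnorm(40, 3, 0.3), 4, 10,
                dimnames = list(paste0("P", 1:4), paste0("c", 1:10)))
  mat[1, 3:10] <- NA  # P1 seen in 2 cells -> dropped
  mat[2, 4:10] <- NA  # P2 seen in exactly 3 -> kept
  ds <- scms_dataset(matrix(1, 4, 10, dimnames = dimnames(mat)))
  ds <- scmskit:::set_layer(ds, "normalized", mat)
  out <- filter_proteins_min_cells(ds, min_cells = 3)
  expect_setequal(out$proteins$protein_id, c("P2", "P3", "P4"))
})

test_that("median shift equalizes totals to machine precision, then log2", {
  mat <- matrix(c(40, 60, 150, 50, 100, 300), 3, 2,
                dimnames = list(paste0("P", 1:3), c("c1", "c2")))
  # totals 250 and 450 -> both shifted to median 350
  ds <- scms_dataset(mat)
  ds <- scmskit:::set_layer(ds, "normalized", mat)
  out <- median_shift_and_log2(ds)
  tot <- colSums(out$layers$normalized)
  expect_equal(unname(tot), c(350, 350), tolerance = 1e-12)
  expect_equal(out$layers$log2, log2(out$layers$normalized))
  # a value of 8 after shift maps to 3 in the log2 layer
  m8 <- matrix(c(8, 8), 1, 2, dimnames = list("P1", c("c1", "c2")))
  ds8 <- scmskit:::set_layer(scms_dataset(m8), "normalized", m8)
  expect_equal(unname(median_shift_and_log2(ds8)$layers$log2[1, ]), c(3, 3))
})

test_that("filters only remove, never alter, surviving values", {
  fx <- make_processed_dataset(seed = 6, n_proteins = 80, n_cells = 70)
  cfg <- simulation_config(n_proteins = 80, n_cells = 70, seed = 6)
  sim <- simulate_dataset(cfg)
  nm <- normalize_medians(sim$dataset)
  ds <- mask_noise_floor(nm$dataset)
  flt <- filter_cells(ds)$dataset
  keep <- colnames(ds$layers$normalized) %in% colnames(flt$layers$normalized)
  expect_identical(flt$layers$normalized,
                   ds$layers$normalized[, keep, drop = FALSE])
})

test_that("QC diagnostics flag an induced row batch and report confounding", {
  lay <- build_plate_layout(rows = 8, cols = 12,
                            channels = default_channels()[1:8, ] |>
                              dplyr::mutate(role = c("booster", "empty",
                                                     rep("single_cell", 6))),
                            populations = c("X", "Y"), seed = 3)
  cells <- assemble_cell_metadata(lay)
  set.seed(1)
  mat <- matrix(rlnorm(100 * nrow(cells), 4, 0.3), 100, nrow(cells),
                dimnames = list(sprintf("P%03d", 1:100), cells$cell_id))
  dep <- cells$well_row == "C"
  mat[, dep] <- mat[, dep] / 3
  ds <- scms_dataset(mat, cells = cells)
  ds <- scmskit:::set_layer(ds, "normalized", mat)
  rep_qc <- qc_factor_diagnostics(ds, factors = c("well_row", "channel"))
  flagged <- rep_qc$levels$level[rep_qc$levels$factor == "well_row" &
                                   rep_qc$levels$flagged]
  expect_true("C" %in% flagged)
  # batch-free factor shows no flags at alpha 0.01
  expect_false(any(rep_qc$levels$flagged[rep_qc$levels$factor == "channel"]))
  # population perfectly confounded with a factor -> Cramer's V = 1
  ds2 <- ds
  ds2$cells$population <- ifelse(ds2$cells$well_row %in% c("A", "B", "C"),
                                 "X", "Y")
  ds2$cells$confound <- ds2$cells$population
  qc2 <- qc_factor_diagnostics(ds2, factors = "confound")
  expect_equal(qc2$confounding$cramers_v, 1, tolerance = 1e-9)
  # single-level factors are skipped with a note
  ds$cells$const <- "one"
  expect_true("const" %in%
                qc_factor_diagnostics(ds, factors = "const")$skipped)
})
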