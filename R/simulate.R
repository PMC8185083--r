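#' Simulation configuration for synthetic multiplexed scMS data
#'
#' Defines a generative model that mirrors the structure of booster-channel
#' single-cell proteomics data: three cell populations positioned on a 1-D
#' differentiation axis tau in `[0, 1]`; per-protein log-normal abundance
#' programs with trajectory-linked effects; scalar multiplicative batch
#' factors per LC-MS file and per TMT channel; additive isotopic-impurity
#' bleed from the booster into its adjacent channels; injection-time-dependent
#' multiplicative log-normal measurement noise; logistic abundance-dependent
#' detection; empty wells carrying only background; doublets as pre-noise
#' sums of two cells; and index-FACS markers tied monotonically to tau.
#'
#' @param n_proteins Number of simulated proteins.
#' @param n_cells Number of cells when no `layout` is given; cells are packed
#'   into files of one well per single-cell channel.
#' @param layout Optional `plate_layout`; when supplied, files, channels and
#'   populations are taken from its sorted wells and `n_cells` is ignored.
#' @param populations Tibble with `name`, `weight`, `tau_center`, `tau_sd`.
#'   Weights must be positive and sum to 1.
#' @param tau_model `"populations"` (Gaussian around each population centre)
#'   or `"uniform"` (a continuum over `[0, 1]`).
#' @param baseline_log2_mean,baseline_log2_sd Per-protein baseline log2
#'   abundance distribution (s/n units).
#' @param frac_trajectory Fraction of proteins given a trajectory effect.
#' @param traj_effect_log2 Magnitude of the trajectory slope (log2 units over
#'   the full tau range); signs are random.
#' @param marker_slope Slope magnitude of the two dedicated marker proteins
#'   (CD34 decreasing, CD38 increasing along tau).
#' @param sigma_file,sigma_channel Log-scale SDs of the per-file and
#'   per-channel multiplicative batch factors (LogNormal(0, sigma)).
#' @param booster_bleed Additive leakage fraction lambda of the booster
#'   signal into `bleed_channels`; must lie in `[0, 1)`.
#' @param booster_cells Cell equivalents loaded in the booster channel.
#' @param bleed_channels Channels receiving booster bleed. The default is
#'   127C alone, the channel adjacent in reporter mass to the 126 booster
#'   and left empty for exactly this reason; widen it to model stronger
#'   impurity envelopes.
#' @param sigma_noise Log-scale SD of measurement noise at the reference
#'   injection time; actual SD scales as `sqrt(it_ref / it_ms)`.
#' @param it_ms,it_ref Nominal and reference injection times (ms). The true
#'   signal scales with `it_ms / it_ref` and the noise SD shrinks with
#'   longer injection times.
#' @param detect_a,detect_b Logistic detection model
#'   `P(observed) = plogis(detect_a + detect_b * log2(true s/n))`;
#'   `detect_b` must be positive.
#' @param empty_well_rate,doublet_rate Fractions of wells left empty or
#'   receiving two cells.
#' @param background_sn Mean ambient background s/n seen by empty wells.
#' @param sigma_cell_size Log-scale SD of the per-cell total protein
#'   content (cell size), independent of the differentiation axis.
#' @param facs_noise Log-scale SD of marker fluorescence noise.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_proteins = 500,
                              n_cells = 280,
                              layout = NULL,
                              populations = default_populations(),
                              tau_model = c("populations", "uniform"),
                              baseline_log2_mean = 4,
                              baseline_log2_sd = 1.5,
                              frac_trajectory = 0.1,
                              traj_effect_log2 = 1.5,
                              marker_slope = 2.5,
                              sigma_file = 0.3,
                              sigma_channel = 0.2,
                              booster_bleed = 0.002,
                              booster_cells = 200,
                              bleed_channels = "127C",
                              sigma_noise = 0.15,
                              it_ms = 500,
                              it_ref = 500,
                              detect_a = -2,
                              detect_b = 1.2,
                              empty_well_rate = 0,
                              doublet_rate = 0,
                              background_sn = 0.3,
                              sigma_cell_size = 0.15,
                              facs_noise = 0.1,
                              seed = 1L) {
  tau_model <- match.arg(tau_model)
  populations <- as_tibble(populations)
  stopifnot(all(c("name", "weight", "tau_center", "tau_sd") %in% names(populations)))
  if (any(populations$weight <= 0)) {
    abort("Populations with zero (or negative) mixing weight are not allowed.")
  }
  if (abs(sum(populations$weight) - 1) > 1e-8) {
    abort("Population weights must sum to 1.")
  }
  if (booster_bleed < 0 || booster_bleed >= 1) abort("`booster_bleed` must lie in [0, 1).")
  if (detect_b <= 0) abort("`detect_b` must be positive (detection rises with abundance).")
  if (any(c(sigma_file, sigma_channel, sigma_noise, facs_noise,
            sigma_cell_size) < 0)) {
    abort("Variance parameters must be >= 0.")
  }
  if (it_ms <= 0 || it_ref <= 0) abort("Injection times must be positive.")
  structure(list(
    n_proteins = n_proteins, n_cells = n_cells, layout = layout,
    populations = populations, tau_model = tau_model,
    baseline_log2_mean = baseline_log2_mean, baseline_log2_sd = baseline_log2_sd,
    frac_trajectory = frac_trajectory, traj_effect_log2 = traj_effect_log2,
    marker_slope = marker_slope, sigma_file = sigma_file,
    sigma_channel = sigma_channel, booster_bleed = booster_bleed,
    booster_cells = booster_cells, bleed_channels = bleed_channels,
    sigma_noise = sigma_noise, it_ms = it_ms, it_ref = it_ref,
    detect_a = detect_a, detect_b = detect_b,
    empty_well_rate = empty_well_rate, doublet_rate = doublet_rate,
    background_sn = background_sn, sigma_cell_size = sigma_cell_size,
    facs_noise = facs_noise,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Default three-population differentiation hierarchy
#'
#' Mixing weights follow the 5/5/4 channel split used when fourteen
#' single-cell channels are spread over LSC, progenitor and blast cells.
#'
#' @return Tibble with `name`, `weight`, `tau_center`, `tau_sd`.
#' @export
default_populations <- function() {
  tibble(
    name = c("LSC", "Progenitor", "Blast"),
    weight = c(5, 5, 4) / 14,
    tau_center = c(0.12, 0.5, 0.88),
    tau_sd = c(0.08, 0.1, 0.08)
  )
}

.sim_cells <- function(cfg) {
  sc_channels <- default_channels()$channel[default_channels()$role == "single_cell"]
  if (!is.null(cfg$layout)) {
    cells <- assemble_cell_metadata(cfg$layout)
    attr(cells, "n_facs_rows_ignored") <- NULL
  } else {
    n <- cfg$n_cells
    n_files <- ceiling(n / length(sc_channels))
    file_id <- sprintf("F%02d", rep(seq_len(n_files), each = length(sc_channels)))[seq_len(n)]
    channel <- rep(sc_channels, n_files)[seq_len(n)]
    cells <- tibble(
      cell_id = paste0(file_id, "_", channel),
      file_id = file_id, channel = channel,
      plate_id = "sim_plate",
      well = NA_character_, well_row = NA_character_, well_col = NA_integer_,
      population = sample(cfg$populations$name, n, replace = TRUE,
                          prob = cfg$populations$weight),
      is_empty_well = FALSE
    )
  }
  cells
}

#' Simulate a multiplexed scMS dataset with ground truth
#'
#' @param cfg A [simulation_config()].
#' @return A list with `dataset` (an [scms_dataset()] whose `raw_sn` layer
#'   holds the measured signal-to-noise) and `truth` (an `scms_ground_truth`
#'   carrying per-cell tau, flags, the true batch factors and the pre-noise
#'   true abundance matrix).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  cells <- .sim_cells(cfg)
  n_cells <- nrow(cells)
  n_prot <- cfg$n_proteins

  pop <- cfg$populations
  pidx <- match(cells$population, pop$name)
  tau <- if (cfg$tau_model == "uniform") {
    runif(n_cells)
  } else {
    pmin(1, pmax(0, rnorm(n_cells, pop$tau_center[pidx], pop$tau_sd[pidx])))
  }

  is_empty <- runif(n_cells) < cfg$empty_well_rate
  can_double <- !is_empty
  is_doublet <- runif(n_cells) < cfg$doublet_rate & can_double
  partner <- rep(NA_integer_, n_cells)
  if (any(is_doublet) && sum(can_double) > 1) {
    for (i in which(is_doublet)) {
      partner[i] <- sample(setdiff(which(can_double), i), 1)
    }
  }

  protein_id <- sprintf("P%04d", seq_len(n_prot))
  baseline <- rnorm(n_prot, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
  slope <- numeric(n_prot)
  n_traj <- max(2L, round(cfg$frac_trajectory * n_prot))
  traj_idx <- sample(n_prot, n_traj)
  slope[traj_idx] <- sample(c(-1, 1), n_traj, replace = TRUE) * cfg$traj_effect_log2
  marker <- rep(NA_character_, n_prot)
  marker[traj_idx[1]] <- "CD34"; slope[traj_idx[1]] <- -cfg$marker_slope
  marker[traj_idx[2]] <- "CD38"; slope[traj_idx[2]] <- cfg$marker_slope

  it_scale <- cfg$it_ms / cfg$it_ref
  true_log2 <- outer(baseline, rep(1, n_cells)) +
    outer(slope, tau - 0.5, `*`)
  true_sn <- 2^true_log2 * it_scale
  # Trajectory effects are compositional: differentiation remodels the
  # relative proteome, while total protein content per cell varies with cell
  # size independently of tau. Rescale each cell to a size-driven total.
  base_total <- median(colSums(true_sn))
  size_factor <- rlnorm(n_cells, 0, cfg$sigma_cell_size)
  true_sn <- sweep(true_sn, 2, base_total * size_factor / colSums(true_sn), `*`)
  for (i in which(is_doublet)) {
    true_sn[, i] <- true_sn[, i] + true_sn[, partner[i]]
  }
  true_sn[, is_empty] <- 0

  # Booster bleed: carrier pool mirrors the mean cell, loaded at many-cell
  # equivalents; a fraction lambda leaks into the adjacent channels.
  booster_sn <- cfg$booster_cells * rowMeans(true_sn[, !is_empty, drop = FALSE])
  bleed <- matrix(0, n_prot, n_cells)
  in_bleed <- cells$channel %in% cfg$bleed_channels
  if (any(in_bleed)) bleed[, in_bleed] <- cfg$booster_bleed * booster_sn
  background <- matrix(0, n_prot, n_cells)
  if (any(is_empty)) background[, is_empty] <- cfg$background_sn
  signal <- true_sn + bleed + background

  files <- unique(cells$file_id)
  channels <- unique(cells$channel)
  file_factor <- setNames(rlnorm(length(files), 0, cfg$sigma_file), files)
  channel_factor <- setNames(rlnorm(length(channels), 0, cfg$sigma_channel), channels)

  sigma_it <- cfg$sigma_noise * sqrt(cfg$it_ref / cfg$it_ms)
  noise <- matrix(rlnorm(n_prot * n_cells, 0, sigma_it), n_prot, n_cells)
  measured <- signal *
    rep(file_factor[cells$file_id], each = n_prot) *
    rep(channel_factor[cells$channel], each = n_prot) * noise

  p_obs <- plogis(cfg$detect_a + cfg$detect_b * log2(pmax(signal, 1e-6)))
  observed <- matrix(runif(n_prot * n_cells) < p_obs, n_prot, n_cells)
  measured[!observed] <- NA_real_
  dimnames(measured) <- list(protein_id, cells$cell_id)

  # Index-FACS markers: monotone transforms of tau with log-normal noise.
  facs_cd34 <- 800 * exp(-1.5 * tau) * rlnorm(n_cells, 0, cfg$facs_noise)
  facs_cd38 <- 200 * exp(1.5 * tau) * rlnorm(n_cells, 0, cfg$facs_noise)
  facs_cd34[is_empty] <- NA; facs_cd38[is_empty] <- NA
  cells$is_empty_well <- is_empty
  cells$facs_CD34 <- facs_cd34
  cells$facs_CD38 <- facs_cd38
  cells$facs_norm_CD34 <- normalize_facs_unit(facs_cd34)
  cells$facs_norm_CD38 <- normalize_facs_unit(facs_cd38)

  proteins <- tibble(protein_id = protein_id, gene_symbol = protein_id,
                     contaminant = FALSE)
  ds <- scms_dataset(measured, proteins = proteins, cells = cells)
  ds <- log_op(ds, "simulate", list(seed = cfg$seed, n_proteins = n_prot,
                                    n_cells = n_cells))

  dimnames(true_sn) <- dimnames(measured)
  truth <- structure(list(
    cells = tibble(cell_id = cells$cell_id, tau = tau,
                   population = cells$population, is_empty = is_empty,
                   is_doublet = is_doublet,
                   doublet_partner = cells$cell_id[partner]),
    file_factors = tibble(file_id = files, factor = unname(file_factor)),
    channel_factors = tibble(channel = channels, factor = unname(channel_factor)),
    proteins = tibble(protein_id = protein_id, baseline_log2 = baseline,
                      slope = slope, is_trajectory = slope != 0,
                      marker = marker),
    true_abundance = true_sn,
    config = cfg
  ), class = "scms_ground_truth")
  list(dataset = ds, truth = truth)
}

#' Simulate technical replicates of one pooled sample across IT settings
#'
#' Emulates injecting one pooled 14-cell TMT sample repeatedly at different
#' injection-time (IT) settings: all replicates share the same true protein
#' abundances; only the per-replicate loading factor, the IT-dependent
#' measurement noise (SD shrinking as `sqrt(it_ref / IT)`) and the detection
#' depth (signal grows with IT) differ.
#'
#' @param cfg A [simulation_config()]; its channel composition follows the
#'   5/5/4 population split over the 14 single-cell channels.
#' @param n_replicates Replicates per IT level (at least 2, or CVs are
#'   undefined).
#' @param it_levels Positive injection times in ms.
#' @param sigma_replicate Log-scale SD of the per-replicate loading factor.
#' @return An `scms_replicates` object: a list with `it_levels`,
#'   `replicates` (per IT level, a list of protein x channel matrices),
#'   `channel_populations` and `truth` (the shared true matrix).
#' @export
simulate_technical_replicates <- function(cfg, n_replicates = 3,
                                          it_levels = c(150, 300, 500),
                                          sigma_replicate = 0.15) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (n_replicates < 2) abort("Need at least 2 replicates; CV is undefined for one.")
  if (any(it_levels <= 0)) abort("`it_levels` must be positive.")
  set.seed(cfg$seed)
  sc_channels <- default_channels()$channel[default_channels()$role == "single_cell"]
  n_ch <- length(sc_channels)
  sizes <- .balanced_sizes(n_ch, nrow(cfg$populations))
  ch_pop <- rep(cfg$populations$name, sizes)
  pidx <- match(ch_pop, cfg$populations$name)
  tau <- pmin(1, pmax(0, rnorm(n_ch, cfg$populations$tau_center[pidx],
                               cfg$populations$tau_sd[pidx])))

  n_prot <- cfg$n_proteins
  protein_id <- sprintf("P%04d", seq_len(n_prot))
  baseline <- rnorm(n_prot, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
  slope <- numeric(n_prot)
  n_traj <- max(2L, round(cfg$frac_trajectory * n_prot))
  traj_idx <- sample(n_prot, n_traj)
  slope[traj_idx] <- sample(c(-1, 1), n_traj, replace = TRUE) * cfg$traj_effect_log2
  true_sn <- 2^(outer(baseline, rep(1, n_ch)) + outer(slope, tau - 0.5, `*`))
  dimnames(true_sn) <- list(protein_id, sc_channels)

  reps <- vector("list", length(it_levels))
  names(reps) <- make.unique(as.character(it_levels))
  for (li in seq_along(it_levels)) {
    it <- it_levels[li]
    scale <- it / cfg$it_ref
    sigma_it <- cfg$sigma_noise * sqrt(cfg$it_ref / it)
    p_obs <- plogis(cfg$detect_a + cfg$detect_b * log2(true_sn * scale))
    mats <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      load_factor <- rlnorm(1, 0, sigma_replicate)
      m <- true_sn * scale * load_factor *
        matrix(rlnorm(n_prot * n_ch, 0, sigma_it), n_prot, n_ch)
      m[matrix(runif(n_prot * n_ch), n_prot, n_ch) >= p_obs] <- NA_real_
      mats[[r]] <- m
    }
    reps[[li]] <- mats
  }
  structure(list(
    it_levels = it_levels,
    replicates = reps,
    channel_populations = tibble(channel = sc_channels, population = ch_pop,
                                 tau = tau),
    truth = true_sn,
    config = cfg
  ), class = "scms_replicates")
}

#' Write / read ground truth as TSV tables
#'
#' Emits `cells.tsv` (tau, population, flags), `factors.tsv` (one row per
#' file and per channel), `proteins.tsv` (baselines, slopes, markers) and
#' `true_abundance.tsv`; the round trip is lossless.
#'
#' @param gt An `scms_ground_truth`.
#' @param path Directory to write into.
#' @export
write_ground_truth <- function(gt, path) {
  stopifnot(inherits(gt, "scms_ground_truth"))
  if (nrow(gt$cells) == 0) abort("Ground truth is empty; nothing to write.")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, file) write.table(df, file.path(path, file), sep = "\t",
                                       quote = FALSE, row.names = FALSE)
  cells <- gt$cells
  cells$tau <- .fmt_num(cells$tau)
  wt(cells, "cells.tsv")
  factors <- dplyr::bind_rows(
    tibble(level_type = "file", level = gt$file_factors$file_id,
           factor = .fmt_num(gt$file_factors$factor)),
    tibble(level_type = "channel", level = gt$channel_factors$channel,
           factor = .fmt_num(gt$channel_factors$factor))
  )
  wt(factors, "factors.tsv")
  prot <- gt$proteins
  prot$baseline_log2 <- .fmt_num(prot$baseline_log2)
  prot$slope <- .fmt_num(prot$slope)
  wt(prot, "proteins.tsv")
  .write_matrix_tsv(gt$true_abundance, file.path(path, "true_abundance.tsv"))
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  rd <- function(file) as_tibble(read.delim(file.path(path, file),
                                            check.names = FALSE))
  cells <- rd("cells.tsv")
  cells$cell_id <- as.character(cells$cell_id)
  factors <- rd("factors.tsv")
  prot <- rd("proteins.tsv")
  prot$protein_id <- as.character(prot$protein_id)
  structure(list(
    cells = cells,
    file_factors = tibble(file_id = as.character(factors$level[factors$level_type == "file"]),
                          factor = factors$factor[factors$level_type == "file"]),
    channel_factors = tibble(channel = as.character(factors$level[factors$level_type == "channel"]),
                             factor = factors$factor[factors$level_type == "channel"]),
    proteins = prot,
    true_abundance = .read_matrix_tsv(file.path(path, "true_abundance.tsv")),
    config = NULL
  ), class = "scms_ground_truth")
}
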