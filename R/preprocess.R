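#' Remove contaminant proteins, failed runs and excluded plate rows
#'
#' Drops proteins flagged as potential contaminants, LC-MS files whose
#' identification count (proteins observed in at least one of the file's
#' cells) falls below a floor, and, optionally, whole plate rows. All
#' removals are appended to the provenance log.
#'
#' @param ds An [scms_dataset()] whose `proteins` table has a logical
#'   `contaminant` column.
#' @param run_min_proteins Files identifying fewer proteins are removed.
#' @param exclude_rows Optional character vector of plate row letters whose
#'   cells are removed (e.g. `c("I", "J")`).
#' @return The filtered dataset.
#' @export
remove_contaminants_and_failed_runs <- function(ds, run_min_proteins = 1,
                                                exclude_rows = NULL) {
  stopifnot(inherits(ds, "scms_dataset"))
  if (!"contaminant" %in% names(ds$proteins)) {
    abort("Protein annotations lack a `contaminant` flag column.")
  }
  keep_p <- !ds$proteins$contaminant
  X <- ds$layers[[1]][keep_p, , drop = FALSE]
  ids_per_file <- tapply(seq_len(ncol(X)), ds$cells$file_id, function(idx) {
    sum(rowSums(!is.na(X[, idx, drop = FALSE])) > 0)
  })
  failed <- names(ids_per_file)[ids_per_file < run_min_proteins]
  keep_c <- !(ds$cells$file_id %in% failed)
  if (!is.null(exclude_rows) && "well_row" %in% names(ds$cells)) {
    keep_c <- keep_c & !(ds$cells$well_row %in% exclude_rows)
  }
  if (!any(keep_c)) abort("Run/row exclusion would remove every cell.")
  out <- subset_dataset(ds, proteins = which(keep_p), cells = which(keep_c))
  log_op(out, "remove_contaminants_and_failed_runs",
         list(contaminants_removed = sum(!keep_p),
              failed_files = failed,
              excluded_rows = exclude_rows %||% character(),
              cells_removed = sum(!keep_c)))
}

# Per-protein medians within each level of a grouping vector; returns a
# proteins x levels matrix (NA where a protein is unseen in a level).
.group_row_medians <- function(X, groups, levels) {
  out <- matrix(NA_real_, nrow(X), length(levels),
                dimnames = list(rownames(X), levels))
  for (j in seq_along(levels)) {
    sub <- X[, groups == levels[j], drop = FALSE]
    out[, j] <- apply(sub, 1, median, na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  out
}

#' Iterative median equalization across files and channels
#'
#' The core batch-correction step: alternately, per protein, each LC-MS
#' file's median is pulled to that protein's grand median across files, then
#' each TMT channel's median to the grand median across channels, repeating
#' until the largest elementwise change between successive matrices (in s/n
#' units by default) drops below `convergence_threshold`. One multiplicative
#' correction factor per protein per file and one per protein per channel is
#' accumulated; missing values are ignored throughout, and proteins observed
#' in fewer than two levels of a factor are left untouched by that sweep.
#'
#' @param ds An [scms_dataset()] with a `raw_sn` layer containing only
#'   single-cell (and possibly empty-well) channels; booster and reference
#'   channels must have been excluded upstream.
#' @param convergence_threshold Stop once the maximum change is strictly
#'   below this (default 1.1 s/n, slightly above the reporter noise level).
#' @param max_iter Iteration cap; non-convergence warns and is flagged.
#' @param metric `"absolute"` (change in s/n units) or `"ratio"` (relative
#'   change), the former being the default reading of the noise-level rule.
#' @return A list: `dataset` (with a `normalized` layer appended) and
#'   `factors` (`scms_norm_factors`: per-protein-per-file and
#'   per-protein-per-channel factors, iterations used, final max change,
#'   convergence flag).
#' @export
normalize_medians <- function(ds, convergence_threshold = 1.1, max_iter = 50,
                              metric = c("absolute", "ratio")) {
  stopifnot(inherits(ds, "scms_dataset"))
  metric <- match.arg(metric)
  X <- get_layer(ds, "raw_sn")
  files <- ds$cells$file_id
  channels <- ds$cells$channel
  ufiles <- unique(files)
  uchannels <- unique(channels)
  n_prot <- nrow(X)

  file_factors <- matrix(1, n_prot, length(ufiles),
                         dimnames = list(rownames(X), ufiles))
  channel_factors <- matrix(1, n_prot, length(uchannels),
                            dimnames = list(rownames(X), uchannels))
  cur <- X
  iter <- 0L
  delta <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    prev <- cur

    med_f <- .group_row_medians(cur, files, ufiles)
    grand_f <- apply(med_f, 1, median, na.rm = TRUE)
    fac_f <- grand_f / med_f
    fac_f[!is.finite(fac_f)] <- 1
    # a protein seen in <2 files has its only median equal to the grand
    # median, so its factors are 1 and it is left untouched
    cur <- cur * fac_f[, match(files, ufiles), drop = FALSE]
    file_factors <- file_factors * fac_f

    med_c <- .group_row_medians(cur, channels, uchannels)
    grand_c <- apply(med_c, 1, median, na.rm = TRUE)
    fac_c <- grand_c / med_c
    fac_c[!is.finite(fac_c)] <- 1
    cur <- cur * fac_c[, match(channels, uchannels), drop = FALSE]
    channel_factors <- channel_factors * fac_c

    delta <- if (metric == "absolute") {
      max(abs(cur - prev), na.rm = TRUE)
    } else {
      max(abs(cur / prev - 1), na.rm = TRUE)
    }
    if (!is.finite(delta) || delta < convergence_threshold) break
  }
  converged <- is.finite(delta) && delta < convergence_threshold
  if (!converged) {
    warn(sprintf("Median normalization did not converge in %d iterations (last change %.3g).",
                 max_iter, delta))
  }
  factors <- structure(list(
    file_factors = file_factors, channel_factors = channel_factors,
    iterations_used = iter,
    final_max_change = if (is.finite(delta)) delta else 0,
    converged = converged
  ), class = "scms_norm_factors")
  out <- set_layer(ds, "normalized", cur)
  out <- log_op(out, "normalize_medians",
                list(convergence_threshold = convergence_threshold,
                     iterations = iter, converged = converged,
                     final_max_change = factors$final_max_change,
                     metric = metric))
  list(dataset = out, factors = factors)
}

#' Scalar batch factors implied by accumulated normalization factors
#'
#' Inverts the per-protein correction factors into one estimated injected
#' factor per file and per channel (median across proteins of the inverse
#' correction), rescaled to geometric mean 1 within each level type so the
#' estimates are comparable to injected factors up to global scale.
#'
#' @param factors An `scms_norm_factors` from [normalize_medians()].
#' @return Tibble with `level_type` (`file`/`channel`), `level`, `estimate`.
#' @export
estimated_level_factors <- function(factors) {
  one <- function(mat, type) {
    est <- apply(1 / mat, 2, median, na.rm = TRUE)
    est <- est / exp(mean(log(est)))
    tibble(level_type = type, level = colnames(mat), estimate = unname(est))
  }
  dplyr::bind_rows(one(factors$file_factors, "file"),
                   one(factors$channel_factors, "channel"))
}

#' Mask values below the noise floor
#'
#' Normalized signal-to-noise strictly below the floor is set missing: such
#' values sit below the reporter noise level and carry no quantitative
#' information. Values exactly at the floor are retained.
#'
#' @param ds Dataset with a `normalized` layer.
#' @param floor Noise floor in s/n units (default 1.1).
#' @return Dataset with masked `normalized` layer; the number of masked
#'   entries is logged in provenance.
#' @export
mask_noise_floor <- function(ds, floor = 1.1) {
  X <- get_layer(ds, "normalized")
  masked <- sum(X < floor, na.rm = TRUE)
  X[X < floor] <- NA_real_
  out <- set_layer(ds, "normalized", X)
  log_op(out, "mask_noise_floor", list(floor = floor, masked = masked))
}

#' Remove outlier cells by MAD bounds and a protein-count cutoff
#'
#' The total summed s/n per cell separates intact single cells from empty
#' wells, doublets and sample-loss wells. Cells whose log2 summed s/n falls
#' outside `median +/- mad_multiplier * MAD` (MAD scaled by 1.4826 for
#' normal consistency), or that observe fewer than `min_proteins_per_cell`
#' proteins, are removed.
#'
#' @param ds Dataset with a `normalized` layer.
#' @param mad_multiplier Bound width in robust SDs (default 3).
#' @param min_proteins_per_cell Minimum observed proteins per cell.
#' @return A list: `dataset` (filtered) and `removed` (tibble with
#'   `cell_id`, `log2_total`, `n_proteins`, `reason`).
#' @export
filter_cells <- function(ds, mad_multiplier = 3, min_proteins_per_cell = 10) {
  X <- get_layer(ds, "normalized")
  totals <- colSums(X, na.rm = TRUE)
  n_obs <- colSums(!is.na(X))
  log2_total <- log2(pmax(totals, .Machine$double.xmin))
  ctr <- median(log2_total)
  spread <- mad(log2_total)  # 1.4826 consistency constant is mad()'s default
  lo <- ctr - mad_multiplier * spread
  hi <- ctr + mad_multiplier * spread

  reason <- character(ncol(X))
  reason[log2_total < lo | totals == 0] <- "mad_low"
  reason[log2_total > hi] <- "mad_high"
  too_few <- n_obs < min_proteins_per_cell
  reason[too_few] <- ifelse(reason[too_few] == "", "min_proteins",
                            paste0(reason[too_few], ";min_proteins"))
  drop <- reason != ""
  if (all(drop)) abort("Cell filtering would remove every cell.")
  removed <- tibble(cell_id = colnames(X)[drop],
                    log2_total = log2_total[drop],
                    n_proteins = n_obs[drop],
                    reason = reason[drop])
  out <- subset_dataset(ds, cells = which(!drop))
  out <- log_op(out, "filter_cells",
                list(mad_multiplier = mad_multiplier,
                     min_proteins_per_cell = min_proteins_per_cell,
                     removed = sum(drop), bounds = c(lo, hi)))
  list(dataset = out, removed = removed)
}

#' Drop proteins quantified in too few cells
#'
#' @param ds Dataset with a `normalized` layer.
#' @param min_cells Proteins observed in fewer than this many cells are
#'   removed (strictly-less-than convention: a protein seen in exactly
#'   `min_cells` cells is kept).
#' @return The filtered dataset.
#' @export
filter_proteins_min_cells <- function(ds, min_cells = 3) {
  X <- get_layer(ds, "normalized")
  keep <- rowSums(!is.na(X)) >= min_cells
  out <- subset_dataset(ds, proteins = which(keep))
  log_op(out, "filter_proteins_min_cells",
         list(min_cells = min_cells, removed = sum(!keep)))
}

#' Median shift of per-cell totals, then log2 transform
#'
#' Rescales every cell so its total summed s/n equals the median pre-shift
#' total, normalizing for cell size and sampling depth, then appends a log2
#' layer. The (shifted) `normalized` layer is retained: fold changes are
#' computed from it, never from imputed or log values.
#'
#' @param ds Dataset with a filtered `normalized` layer.
#' @return Dataset with the shifted `normalized` layer and a new `log2`
#'   layer (missing values stay missing).
#' @export
median_shift_and_log2 <- function(ds) {
  X <- get_layer(ds, "normalized")
  totals <- colSums(X, na.rm = TRUE)
  if (any(totals == 0)) {
    abort("Cell(s) with zero total signal; run filter_cells() first.")
  }
  target <- median(totals)
  X <- sweep(X, 2, target / totals, `*`)
  out <- set_layer(ds, "normalized", X)
  out <- set_layer(out, "log2", log2(X))
  log_op(out, "median_shift_and_log2", list(target_total = target))
}

#' Technical-factor QC diagnostics
#'
#' Verifies that systematic technical biases were removed by comparing
#' cell-level summaries (summed intensity, proteins observed) across levels
#' of each technical factor (LC-MS file, TMT channel, plate row, ...). Each
#' factor gets a Kruskal-Wallis heterogeneity test; each level a rank test
#' against the remaining cells (BH-corrected within factor). Confounding
#' between every technical factor and the population label is reported as
#' Cramer's V, since a population sorted onto particular rows cannot be
#' separated from a row batch effect.
#'
#' @param ds Dataset with a `normalized` layer.
#' @param factors Cell-metadata columns to audit.
#' @param alpha Flagging threshold on the BH-adjusted per-level p-value.
#' @return An `scms_qc_report`: list of tibbles `levels`, `global`,
#'   `confounding`, plus `skipped` (single-level factors).
#' @export
qc_factor_diagnostics <- function(ds, factors = c("file_id", "channel", "well_row"),
                                  alpha = 0.01) {
  X <- get_layer(ds, "normalized")
  totals <- colSums(X, na.rm = TRUE)
  n_obs <- colSums(!is.na(X))
  levels_tbl <- list(); global_tbl <- list(); conf_tbl <- list()
  skipped <- character()
  for (f in factors) {
    if (!f %in% names(ds$cells)) { skipped <- c(skipped, f); next }
    g <- as.character(ds$cells[[f]])
    ok <- !is.na(g)
    if (length(unique(g[ok])) < 2) {
      skipped <- c(skipped, f)
      next
    }
    kw_tot <- kruskal.test(totals[ok], factor(g[ok]))$p.value
    kw_np <- kruskal.test(n_obs[ok], factor(g[ok]))$p.value
    lv <- sort(unique(g[ok]))
    p_lvl <- vapply(lv, function(l) {
      stats::wilcox.test(totals[ok][g[ok] == l], totals[ok][g[ok] != l],
                         exact = FALSE)$p.value
    }, numeric(1))
    q_lvl <- p.adjust(p_lvl, "BH")
    levels_tbl[[f]] <- tibble(
      factor = f, level = lv,
      n_cells = as.integer(table(factor(g[ok], levels = lv))),
      median_total = vapply(lv, function(l) median(totals[ok][g[ok] == l]), numeric(1)),
      median_n_proteins = vapply(lv, function(l) median(n_obs[ok][g[ok] == l]), numeric(1)),
      p_total = unname(p_lvl), q_total = unname(q_lvl),
      flagged = unname(q_lvl) < alpha
    )
    global_tbl[[f]] <- tibble(factor = f, kw_p_total = kw_tot,
                              kw_p_n_proteins = kw_np)
    if ("population" %in% names(ds$cells)) {
      pop <- ds$cells$population
      both <- ok & !is.na(pop)
      if (length(unique(pop[both])) >= 2 && length(unique(g[both])) >= 2) {
        conf_tbl[[f]] <- tibble(factor = f,
                                cramers_v = .cramers_v(g[both], pop[both]))
      }
    }
  }
  structure(list(
    levels = dplyr::bind_rows(levels_tbl),
    global = dplyr::bind_rows(global_tbl),
    confounding = dplyr::bind_rows(conf_tbl),
    skipped = skipped,
    alpha = alpha
  ), class = "scms_qc_report")
}

.cramers_v <- function(a, b) {
  tab <- table(a, b)
  chi2 <- suppressWarnings(chisq.test(tab, correct = FALSE)$statistic)
  as.numeric(sqrt(chi2 / (sum(tab) * (min(dim(tab)) - 1))))
}
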