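#' Equalize technical replicates per protein
#'
#' For each protein, every replicate injection is rescaled by one correction
#' factor so that its median s/n across the single-cell channels equals the
#' median of those per-replicate medians (the common target). Proteins
#' absent from any replicate are flagged and excluded from downstream CV
#' computation.
#'
#' @param mats List of >= 2 protein x channel matrices with identical
#'   dimnames (one per replicate injection).
#' @return An `scms_replicate_norm` list: `normalized` (list of matrices),
#'   `raw` (the input), `factors` (protein x replicate matrix) and
#'   `quantified_in_all` (logical per protein).
#' @export
replicate_normalize <- function(mats) {
  if (length(mats) < 2) abort("Need at least two replicates to normalize.")
  dn <- dimnames(mats[[1]])
  for (m in mats) stopifnot(identical(dimnames(m), dn))
  n_prot <- nrow(mats[[1]])
  meds <- matrix(vapply(mats, function(m) apply(m, 1, median, na.rm = TRUE),
                        numeric(n_prot)),
                 nrow = n_prot)
  meds[is.nan(meds)] <- NA_real_
  target <- apply(meds, 1, median, na.rm = TRUE)
  factors <- target / meds
  factors[!is.finite(factors)] <- 1
  normalized <- lapply(seq_along(mats), function(r) mats[[r]] * factors[, r])
  names(normalized) <- names(mats)
  structure(list(
    normalized = normalized,
    raw = mats,
    factors = factors,
    quantified_in_all = rowSums(!is.na(meds)) == length(mats)
  ), class = "scms_replicate_norm")
}

#' Per-protein per-channel CVs across technical replicates
#'
#' For each protein and each single-cell channel observed in all replicates,
#' the coefficient of variation is the sample standard deviation (ddof 1) of
#' the normalized s/n across replicates divided by the mean of the raw s/n
#' across replicates. Up to one CV per channel is obtained; the per-protein
#' mean CV and the percentage of proteins with mean CV below the threshold
#' summarise quantitative precision. Only proteins quantified in all
#' replicates enter the summary.
#'
#' @param rn An `scms_replicate_norm` from [replicate_normalize()].
#' @param threshold CV threshold for the summary fraction (default 0.20).
#' @return An `scms_cv_profile` list: `cv` (tibble protein_id, channel, cv),
#'   `per_protein` (tibble protein_id, mean_cv, n_cv, mean_log2_sn) and
#'   `pct_below_threshold` (percentage of proteins with mean CV below
#'   `threshold`).
#' @export
protein_cv_profile <- function(rn, threshold = 0.20) {
  stopifnot(inherits(rn, "scms_replicate_norm"))
  n_rep <- length(rn$raw)
  prot <- rownames(rn$raw[[1]])
  chans <- colnames(rn$raw[[1]])
  norm_arr <- simplify2array(rn$normalized)  # protein x channel x replicate
  raw_arr <- simplify2array(rn$raw)

  n_obs <- apply(!is.na(raw_arr), c(1, 2), sum)
  sd_norm <- apply(norm_arr, c(1, 2), sd, na.rm = TRUE)
  mean_raw <- apply(raw_arr, c(1, 2), mean, na.rm = TRUE)
  cv <- sd_norm / mean_raw
  cv[n_obs < n_rep] <- NA_real_  # a channel must be seen in every replicate

  cv_tbl <- tibble(
    protein_id = rep(prot, times = length(chans)),
    channel = rep(chans, each = length(prot)),
    cv = as.vector(cv)
  ) |> dplyr::filter(!is.na(.data$cv))

  mean_cv <- rowMeans(cv, na.rm = TRUE)
  n_cv <- rowSums(!is.na(cv))
  total_raw <- apply(raw_arr, 1, mean, na.rm = TRUE)
  per_protein <- tibble(
    protein_id = prot,
    mean_cv = ifelse(n_cv > 0, mean_cv, NA_real_),
    n_cv = n_cv,
    mean_log2_sn = log2(total_raw),
    quantified_in_all = rn$quantified_in_all
  )
  eligible <- per_protein$quantified_in_all & !is.na(per_protein$mean_cv)
  pct <- 100 * mean(per_protein$mean_cv[eligible] < threshold)
  structure(list(cv = cv_tbl, per_protein = per_protein,
                 pct_below_threshold = pct, threshold = threshold),
            class = "scms_cv_profile")
}

#' Fold-change agreement between single-cell and bulk data
#'
#' Pearson correlation of per-protein log2 fold changes measured in
#' single cells against a bulk reference, over a protein subset defined by
#' `selection`: `complete_case` (no missing values in any channel, requires
#' a logical `complete_case` column), `shared` (requires a logical `shared`
#' column marking proteins common to all compared methods), or
#' `top_n_coverage` (the `n` highest-coverage proteins, requires a
#' `coverage` column).
#'
#' @param sc_fc Tibble with `protein_id`, `log2fc` and any selection columns.
#' @param bulk_fc Tibble with `protein_id`, `log2fc`.
#' @param selection Subset rule.
#' @param n Proteins kept by `top_n_coverage`.
#' @return A list: `r` (Pearson), `n_proteins`, `table` (the joined scatter
#'   data).
#' @export
fold_change_agreement <- function(sc_fc, bulk_fc,
                                  selection = c("complete_case", "shared",
                                                "top_n_coverage"),
                                  n = 400) {
  selection <- match.arg(selection)
  sc_fc <- as_tibble(sc_fc)
  sel <- switch(selection,
    complete_case = {
      if (!"complete_case" %in% names(sc_fc)) {
        abort("`complete_case` selection needs a logical `complete_case` column.")
      }
      dplyr::filter(sc_fc, .data$complete_case)
    },
    shared = {
      if (!"shared" %in% names(sc_fc)) {
        abort("`shared` selection needs a logical `shared` column.")
      }
      dplyr::filter(sc_fc, .data$shared)
    },
    top_n_coverage = {
      if (!"coverage" %in% names(sc_fc)) {
        abort("`top_n_coverage` selection needs a numeric `coverage` column.")
      }
      dplyr::slice_max(sc_fc, .data$coverage, n = n, with_ties = FALSE)
    }
  )
  joined <- dplyr::inner_join(
    dplyr::select(sel, "protein_id", sc_log2fc = "log2fc"),
    dplyr::select(as_tibble(bulk_fc), "protein_id", bulk_log2fc = "log2fc"),
    by = "protein_id"
  ) |> dplyr::filter(is.finite(.data$sc_log2fc), is.finite(.data$bulk_log2fc))
  if (nrow(joined) < 3) abort("Fewer than 3 overlapping proteins with fold changes.")
  list(r = cor(joined$sc_log2fc, joined$bulk_log2fc),
       n_proteins = nrow(joined), table = joined)
}

#' Binned fold-change error against a bulk reference
#'
#' Restricts to proteins called significant in the bulk data (FDR and
#' absolute log2FC filters), splits them into equal-count bins of mean log2
#' s/n, and reports the median and quartiles of the absolute fold-change
#' difference per bin: fold-change accuracy as a function of signal.
#'
#' @param sc_fc Tibble `protein_id`, `log2fc`, `mean_log2_sn`.
#' @param bulk_fc Tibble `protein_id`, `log2fc`, `fdr`.
#' @param n_bins Number of equal-count bins (default 12).
#' @param bulk_fdr,bulk_min_lfc Bulk significance filters (default
#'   FDR < 0.05, |log2FC| > 0.5).
#' @return Tibble per bin: `bin`, `n`, `mean_log2_sn`, `median_abs_diff`,
#'   `q25`, `q75`.
#' @export
binned_fc_difference <- function(sc_fc, bulk_fc, n_bins = 12,
                                 bulk_fdr = 0.05, bulk_min_lfc = 0.5) {
  joined <- dplyr::inner_join(
    dplyr::select(as_tibble(sc_fc), "protein_id", sc_log2fc = "log2fc",
                  "mean_log2_sn"),
    dplyr::select(as_tibble(bulk_fc), "protein_id", bulk_log2fc = "log2fc",
                  "fdr"),
    by = "protein_id"
  ) |>
    dplyr::filter(.data$fdr < bulk_fdr, abs(.data$bulk_log2fc) > bulk_min_lfc,
                  is.finite(.data$sc_log2fc), is.finite(.data$mean_log2_sn))
  if (nrow(joined) < n_bins) {
    abort(sprintf("Only %d proteins pass the bulk filters; need >= %d bins.",
                  nrow(joined), n_bins))
  }
  joined |>
    dplyr::mutate(abs_diff = abs(.data$sc_log2fc - .data$bulk_log2fc),
                  bin = dplyr::ntile(.data$mean_log2_sn, n_bins)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_log2_sn = mean(.data$mean_log2_sn),
      median_abs_diff = median(.data$abs_diff),
      q25 = quantile(.data$abs_diff, 0.25),
      q75 = quantile(.data$abs_diff, 0.75),
      .groups = "drop"
    )
}

#' Silhouette of two populations in PC space
#'
#' The replicate-evaluation variant: complete-case protein selection (or an
#' explicit shared protein set), median shift of totals across samples, log2
#' transform, PCA, and silhouette coefficients of the two labelled groups on
#' the first `n_pcs` components.
#'
#' @param mat Protein x sample s/n matrix (may contain missing values).
#' @param labels Population label per sample (columns of `mat`); only the
#'   first two distinct labels are scored.
#' @param n_pcs Number of principal components (default 20).
#' @param proteins Optional explicit protein set (the shared variant);
#'   default is the per-matrix complete cases.
#' @return Silhouette tibble as from [silhouette_scores()].
#' @export
pc_space_silhouette <- function(mat, labels, n_pcs = 20, proteins = NULL) {
  if (is.null(proteins)) {
    keep <- rowSums(is.na(mat)) == 0
  } else {
    keep <- rownames(mat) %in% proteins
  }
  if (!any(keep)) abort("No complete-case proteins available.")
  X <- mat[keep, , drop = FALSE]
  totals <- colSums(X)
  X <- sweep(X, 2, median(totals) / totals, `*`)
  X <- log2(X)
  n_pcs <- min(n_pcs, ncol(X) - 1, nrow(X))
  pcs <- prcomp(t(X), rank. = n_pcs, center = TRUE)$x
  ulab <- unique(labels[!is.na(labels)])
  if (length(ulab) < 2) abort("Need two labelled groups.")
  silhouette_scores(pcs, labels, subset = ulab[1:2])
}
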