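#' Coverage filter before integration
#'
#' Retains proteins with at least `min_fraction` valid values across cells
#' (inclusive threshold). Balanced-design median equalization assumes the
#' same population mix in every file; across unbalanced datasets that
#' assumption fails, so integration instead restricts to well-covered
#' proteins and aligns datasets in embedding space.
#'
#' @param ds Dataset with a `normalized` layer.
#' @param min_fraction Minimum observed fraction per protein (default 0.40).
#' @return The filtered dataset.
#' @export
coverage_filter <- function(ds, min_fraction = 0.40) {
  X <- get_layer(ds, "normalized")
  keep <- rowMeans(!is.na(X)) >= min_fraction
  if (!any(keep)) abort("Coverage filter removed every protein.")
  out <- subset_dataset(ds, proteins = which(keep))
  log_op(out, "coverage_filter",
         list(min_fraction = min_fraction, removed = sum(!keep)))
}

# Mutual-nearest-neighbour pairs between two PC matrices. Each target cell
# keeps only its closest mutual partner, so a perfectly aligned cell pairs
# with its exact counterpart and receives a zero correction vector.
.mnn_pairs <- function(ref, target, k) {
  D <- as.matrix(stats::dist(rbind(ref, target)))
  nr <- nrow(ref)
  cross <- D[seq_len(nr), nr + seq_len(nrow(target)), drop = FALSE]
  k_r <- min(k, nrow(target)); k_t <- min(k, nr)
  nn_of_ref <- t(apply(cross, 1, function(d) order(d)[seq_len(k_r)]))
  nn_of_tgt <- t(apply(cross, 2, function(d) order(d)[seq_len(k_t)]))
  pairs <- list()
  for (r in seq_len(nr)) {
    for (t in nn_of_ref[r, ]) {
      if (r %in% nn_of_tgt[t, ]) {
        pairs[[length(pairs) + 1]] <- c(r, t, cross[r, t])
      }
    }
  }
  if (!length(pairs)) return(NULL)
  pairs <- do.call(rbind, pairs)
  pairs <- pairs[order(pairs[, 3]), , drop = FALSE]
  pairs[!duplicated(pairs[, 2]), , drop = FALSE]
}

# Median distance to the k-th within-batch neighbour: the scale on which
# genuine neighbourhoods live.
.median_knn_dist <- function(M, k) {
  D <- as.matrix(stats::dist(M))
  k <- min(k, nrow(M) - 1)
  median(apply(D, 1, function(r) sort(r)[k + 1]))
}

#' Integrate unbalanced datasets into one joint embedding
#'
#' Aligns two or more processed datasets that need not share the population
#' balance required by median equalization. The built-in `mnn_simple`
#' backend projects the shared-protein log2 matrices into a joint PC space,
#' detects mutual-nearest-neighbour (MNN) cell pairs between the reference
#' (largest) dataset and each other dataset, and shifts each non-reference
#' cell by a locally weighted average of its pair difference vectors. The
#' `panorama` backend delegates to an external panorama-stitching
#' implementation supplied via `backend_fn`. The integration contract,
#' backend-agnostic: dataset-of-origin structure should vanish from the
#' joint space (batch silhouette near 0) while population structure is
#' preserved.
#'
#' @param datasets List of processed [scms_dataset()]s with `log2` layers
#'   and (after [coverage_filter()]) a shared protein space; they must share
#'   at least one population, otherwise no mutual pairs exist.
#' @param backend `"mnn_simple"` (built in) or `"panorama"` (external).
#' @param n_pcs Joint PC dimensionality.
#' @param k Neighbours per direction for MNN detection.
#' @param knn_k Imputation neighbours for the per-dataset completion step.
#' @param seed Seed for the joint UMAP.
#' @param backend_fn For `backend = "panorama"`: a function taking the list
#'   of cell x PC matrices and returning corrected matrices.
#' @return An `scms_integration` list: `cells` (tibble cell_id, dataset,
#'   population), `corrected` (joint cell x PC matrix), `embedding` (UMAP
#'   coordinates), `n_pairs` (MNN pairs per dataset).
#' @export
integrate_unbalanced <- function(datasets, backend = c("mnn_simple", "panorama"),
                                 n_pcs = 20, k = 20, knn_k = 5, seed = 1,
                                 backend_fn = NULL) {
  backend <- match.arg(backend)
  stopifnot(length(datasets) >= 1)
  cells <- dplyr::bind_rows(lapply(seq_along(datasets), function(i) {
    ds <- datasets[[i]]
    tibble(cell_id = ds$cells$cell_id,
           dataset = names(datasets)[i] %||% paste0("dataset", i),
           population = ds$cells$population %||% NA_character_)
  }))

  shared <- Reduce(intersect, lapply(datasets, function(d) d$proteins$protein_id))
  if (!length(shared)) abort("Datasets share no proteins after filtering.")
  # impute and scale within each dataset: per-batch centering removes any
  # global dataset shift outright and keeps batch variance out of the
  # per-protein scale factors
  mats <- lapply(datasets, function(d) {
    m <- get_layer(d, "log2")[shared, , drop = FALSE]
    if (anyNA(m)) m <- impute_knn(m, k = min(knn_k, ncol(m) - 1))
    suppressWarnings(scale_features(m))
  })
  scaled <- do.call(cbind, mats)
  n_pcs <- min(n_pcs, nrow(scaled) - 1, ncol(scaled) - 1)
  pcs <- prcomp(t(scaled), rank. = n_pcs, center = TRUE)$x
  rownames(pcs) <- cells$cell_id

  sizes <- vapply(mats, ncol, integer(1))
  offsets <- cumsum(c(0, sizes))
  idx_of <- function(i) offsets[i] + seq_len(sizes[i])

  corrected <- pcs
  n_pairs <- integer(length(datasets))
  if (length(datasets) > 1) {
    if (backend == "panorama") {
      if (is.null(backend_fn)) {
        abort("backend 'panorama' delegates to an external implementation; supply `backend_fn`.")
      }
      split_pcs <- lapply(seq_along(datasets), function(i) pcs[idx_of(i), , drop = FALSE])
      out <- backend_fn(split_pcs)
      corrected <- do.call(rbind, out)
      rownames(corrected) <- cells$cell_id
    } else {
      ref_i <- which.max(sizes)
      ref <- pcs[idx_of(ref_i), , drop = FALSE]
      for (i in seq_along(datasets)) {
        if (i == ref_i) next
        tgt_rows <- idx_of(i)
        tgt <- pcs[tgt_rows, , drop = FALSE]
        pairs <- .mnn_pairs(ref, tgt, k)
        if (!is.null(pairs)) {
          # a cross-batch pair is credible only if it sits on the scale of
          # within-batch neighbourhoods; distant "nearest" cells indicate
          # populations with no counterpart
          thr <- 3 * max(.median_knn_dist(ref, k), .median_knn_dist(tgt, k))
          pairs <- pairs[pairs[, 3] <= thr, , drop = FALSE]
        }
        if (is.null(pairs) || nrow(pairs) == 0) {
          abort(paste0("No mutual-nearest-neighbour pairs between datasets ",
                       ref_i, " and ", i,
                       ": no shared populations detectable."))
        }
        n_pairs[i] <- nrow(pairs)
        vecs <- ref[pairs[, 1], , drop = FALSE] - tgt[pairs[, 2], , drop = FALSE]
        anchor <- tgt[pairs[, 2], , drop = FALSE]
        d_anchor <- as.matrix(stats::dist(rbind(tgt, anchor)))
        cross <- d_anchor[seq_len(nrow(tgt)), nrow(tgt) + seq_len(nrow(anchor)),
                          drop = FALSE]
        # wide bandwidth (median target-anchor distance): the correction
        # field varies slowly, so pair-matching noise averages out while a
        # genuinely local shift can still bend the field
        sigma <- median(cross) + 1e-12
        Wgt <- exp(-cross^2 / (2 * sigma^2))
        rs <- rowSums(Wgt)
        far <- rs == 0  # beyond kernel support: take the nearest anchor
        if (any(far)) {
          nearest <- apply(cross[far, , drop = FALSE], 1, which.min)
          Wgt[far, ] <- 0
          Wgt[cbind(which(far), nearest)] <- 1
          rs[far] <- 1
        }
        Wgt <- Wgt / rs
        corrected[tgt_rows, ] <- tgt + Wgt %*% vecs
      }
    }
  }

  set.seed(seed)
  um <- uwot::umap(corrected, n_neighbors = min(15, nrow(corrected) - 1),
                   min_dist = 0.5, n_threads = 1, n_sgd_threads = 0)
  rownames(um) <- cells$cell_id

  structure(list(cells = cells, corrected = corrected, embedding = um,
                 n_pairs = n_pairs, shared_proteins = shared,
                 backend = backend),
            class = "scms_integration")
}
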