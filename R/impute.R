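#' k-nearest-neighbour imputation
#'
#' Fills each missing entry (protein p, cell c) with the mean of p's observed
#' values among the k cells nearest to c. Cell-cell distance is Euclidean
#' over mutually observed proteins, rescaled by the shared-feature count
#' (root-mean-square difference), so cells with different coverage remain
#' comparable; cell pairs sharing no features sit at infinite distance. If
#' none of the k neighbours observes p, the fallback is p's global observed
#' mean. Observed entries are never altered.
#'
#' @param mat Protein x cell numeric matrix with `NA`s; every cell must have
#'   at least one observed value.
#' @param k Number of neighbours (default 5); must be `< ncol(mat)`.
#' @return A complete matrix of the same shape.
#' @export
impute_knn <- function(mat, k = 5) {
  stopifnot(is.matrix(mat))
  n_cells <- ncol(mat)
  if (k >= n_cells) abort("`k` must be smaller than the number of cells.")
  obs <- !is.na(mat)
  if (any(colSums(obs) == 0)) abort("Every cell needs at least one observed value.")
  if (!anyNA(mat)) return(mat)

  M <- obs * 1
  X0 <- mat
  X0[!obs] <- 0
  X2 <- X0^2
  # sum over mutually observed p of (x1 - x2)^2, via cross products; the
  # observation mask (not zero values) defines sharing, so observed zeros
  # are handled exactly
  cross <- crossprod(X0)
  sq1 <- crossprod(X2, M)
  d2 <- sq1 + t(sq1) - 2 * cross
  n_shared <- crossprod(M)
  d <- sqrt(pmax(d2, 0) / n_shared)
  d[n_shared == 0] <- Inf
  diag(d) <- Inf

  global_mean <- rowMeans(mat, na.rm = TRUE)
  out <- mat
  for (ci in seq_len(n_cells)) {
    miss_p <- which(!obs[, ci])
    if (!length(miss_p)) next
    nn <- order(d[, ci])[seq_len(k)]
    nn_vals <- mat[miss_p, nn, drop = FALSE]
    fill <- rowMeans(nn_vals, na.rm = TRUE)
    none <- !is.finite(fill)
    fill[none] <- global_mean[miss_p][none]
    out[miss_p, ci] <- fill
  }
  out
}

#' Scale proteins to zero mean and unit variance
#'
#' @param mat Complete protein x cell matrix.
#' @return Matrix with each protein at mean 0 and sample variance 1;
#'   zero-variance proteins become all zeros with a warning.
#' @export
scale_features <- function(mat) {
  stopifnot(!anyNA(mat))
  mu <- rowMeans(mat)
  s <- apply(mat, 1, sd)
  flat <- s == 0
  if (any(flat)) {
    warn(sprintf("%d zero-variance protein(s) scaled to all zeros.", sum(flat)))
    s[flat] <- 1
  }
  out <- (mat - mu) / s
  out[flat, ] <- 0
  out
}

#' Select the low-coverage protein threshold by label separation
#'
#' Sweeps a grid of per-protein coverage fractions between the extremes of
#' keeping every protein (threshold 0) and keeping only proteins with no
#' missing value (threshold 1). For each candidate the retained proteins are
#' imputed, scaled and embedded into 2-D UMAP space under a fixed seed, and
#' the mean silhouette of the provided labels is computed; the threshold with
#' the best separation wins, ties going to the lowest threshold (which keeps
#' the most proteins).
#'
#' @param ds Dataset with a `log2` layer.
#' @param labels Per-cell group labels; defaults to the `population` column.
#' @param grid Ascending coverage fractions to test.
#' @param knn_k Imputation neighbours.
#' @param n_neighbors,min_dist UMAP parameters.
#' @param seed Seed fixed across all candidates.
#' @return An `scms_coverage_selection`: list with `threshold` (chosen) and
#'   `table` (tibble: threshold, n_proteins, silhouette).
#' @export
select_coverage_threshold <- function(ds, labels = NULL,
                                      grid = seq(0, 1, by = 0.1),
                                      knn_k = 5, n_neighbors = 15,
                                      min_dist = 0.5, seed = 1) {
  labels <- labels %||% ds$cells$population
  labels <- as.character(labels)
  if (length(unique(labels[!is.na(labels)])) < 2) {
    abort("Need at least two labelled groups to score separation.")
  }
  X <- get_layer(ds, "log2")
  coverage <- rowMeans(!is.na(X))
  grid <- sort(grid)
  rows <- purrr::map(grid, function(t) {
    keep <- coverage >= t
    if (sum(keep) < 3) {
      return(tibble(threshold = t, n_proteins = sum(keep), silhouette = NA_real_))
    }
    sub <- X[keep, , drop = FALSE]
    imp <- impute_knn(sub, k = min(knn_k, ncol(sub) - 1))
    sc <- suppressWarnings(scale_features(imp))
    set.seed(seed)
    um <- uwot::umap(t(sc), n_neighbors = n_neighbors, min_dist = min_dist,
                     n_threads = 1, n_sgd_threads = 0)
    sil <- silhouette_scores(um, labels)
    tibble(threshold = t, n_proteins = sum(keep),
           silhouette = attr(sil, "mean_silhouette"))
  })
  tab <- dplyr::bind_rows(rows)
  ok <- which(!is.na(tab$silhouette))
  if (!length(ok)) abort("No grid threshold left enough proteins to embed.")
  best <- ok[which.max(tab$silhouette[ok])]
  structure(list(threshold = tab$threshold[best], table = tab),
            class = "scms_coverage_selection")
}
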