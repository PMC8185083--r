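#' Welch differential expression between two cell groups
#'
#' Per protein: a two-sided Welch's t-test (Satterthwaite degrees of freedom)
#' on the log2 layer, excluding missing values, never imputing. Proteins with
#' fewer than `min_per_group` observed values in either group are reported
#' untested. P-values are BH-corrected across the tested proteins. Log2 fold
#' changes come from the pre-log `normalized` layer (ratio of group means),
#' the two layers serving different purposes by design.
#'
#' @param ds Dataset with `log2` and `normalized` layers.
#' @param group_a,group_b Disjoint character vectors of cell ids (or logical
#'   masks over cells).
#' @param min_per_group Minimum observed values per group to test a protein.
#' @param fdr_alpha Significance cutoff on the BH-adjusted p-value.
#' @param lfc_floor Absolute log2 fold-change floor entering the
#'   `significant` flag (0 disables the effect-size filter).
#' @return An `scms_de` tibble: per protein, group means on the normalized
#'   scale, group sizes, `t`, `df`, `p`, `q`, `log2fc`, `tested`,
#'   `significant`.
#' @export
welch_de <- function(ds, group_a, group_b, min_per_group = 3,
                     fdr_alpha = 0.05, lfc_floor = 0) {
  ids <- ds$cells$cell_id
  a_idx <- .resolve_cells(group_a, ids)
  b_idx <- .resolve_cells(group_b, ids)
  if (length(intersect(a_idx, b_idx))) abort("Groups must be disjoint.")
  if (!length(a_idx) || !length(b_idx)) abort("Both groups must be non-empty.")

  L <- get_layer(ds, "log2")
  A <- L[, a_idx, drop = FALSE]
  B <- L[, b_idx, drop = FALSE]
  n1 <- rowSums(!is.na(A)); n2 <- rowSums(!is.na(B))
  m1 <- rowMeans(A, na.rm = TRUE); m2 <- rowMeans(B, na.rm = TRUE)
  v1 <- apply(A, 1, var, na.rm = TRUE); v2 <- apply(B, 1, var, na.rm = TRUE)

  tested <- n1 >= min_per_group & n2 >= min_per_group
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  zero_se <- tested & se2 == 0
  tstat[zero_se] <- 0
  p <- 2 * pt(-abs(tstat), df)
  p[zero_se] <- 1
  p[!tested] <- NA_real_
  tstat[!tested] <- NA_real_
  q <- rep(NA_real_, length(p))
  q[tested] <- p.adjust(p[tested], method = "BH")

  N <- get_layer(ds, "normalized")
  mean_a <- rowMeans(N[, a_idx, drop = FALSE], na.rm = TRUE)
  mean_b <- rowMeans(N[, b_idx, drop = FALSE], na.rm = TRUE)
  lfc <- log2(mean_a / mean_b)
  lfc[!is.finite(lfc)] <- NA_real_

  out <- tibble(
    protein_id = rownames(L),
    mean_a = unname(ifelse(is.nan(mean_a), NA_real_, mean_a)),
    mean_b = unname(ifelse(is.nan(mean_b), NA_real_, mean_b)),
    n_a = unname(n1), n_b = unname(n2),
    t = unname(tstat), df = unname(ifelse(tested, df, NA_real_)),
    p = unname(p), q = unname(q),
    log2fc = unname(lfc),
    tested = unname(tested),
    significant = unname(tested & !is.na(q) & q < fdr_alpha &
      !is.na(lfc) & abs(lfc) >= lfc_floor)
  )
  class(out) <- c("scms_de", class(out))
  attr(out, "fdr_alpha") <- fdr_alpha
  attr(out, "lfc_floor") <- lfc_floor
  out
}

.resolve_cells <- function(group, ids) {
  if (is.logical(group)) {
    stopifnot(length(group) == length(ids))
    return(which(group))
  }
  idx <- match(group, ids)
  if (anyNA(idx)) abort("Some requested cells are not in the dataset.")
  idx
}

#' @method glance scms_de
#' @export
glance.scms_de <- function(x, ...) {
  tibble(n_proteins = nrow(x), n_tested = sum(x$tested),
         n_significant = sum(x$significant),
         fdr_alpha = attr(x, "fdr_alpha"))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p P-values in `[0, 1]`.
#' @return Monotonized, capped adjusted values (q-values).
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric())
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("P-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Log2 fold change of group means on the pre-log normalized scale
#'
#' @param ds Dataset with a `normalized` layer.
#' @param group_a,group_b Cell id vectors (or logical masks).
#' @return Tibble (`protein_id`, `log2fc`); missing where either group mean
#'   is unavailable.
#' @export
log2_fold_change <- function(ds, group_a, group_b) {
  ids <- ds$cells$cell_id
  N <- get_layer(ds, "normalized")
  a <- rowMeans(N[, .resolve_cells(group_a, ids), drop = FALSE], na.rm = TRUE)
  b <- rowMeans(N[, .resolve_cells(group_b, ids), drop = FALSE], na.rm = TRUE)
  lfc <- log2(a / b)
  lfc[!is.finite(lfc)] <- NA_real_
  tibble(protein_id = rownames(N), log2fc = unname(lfc))
}

#' Hypergeometric over-representation of annotation terms
#'
#' For each term: with N background proteins of which K carry the term, and
#' a foreground of n proteins of which k carry it, the upper-tail
#' probability `P(X >= k)` under Hypergeometric(N, K, n); BH correction
#' across terms. Terms absent from the foreground get p = 1.
#'
#' @param foreground Character vector of proteins of interest; must be a
#'   subset of `background`.
#' @param background Character vector defining the universe.
#' @param annotations Tibble with columns `protein_id`, `term`.
#' @return An `scms_enrichment` tibble: `term`, `k`, `n`, `K`, `N`, `p`, `q`.
#' @export
hypergeom_enrichment <- function(foreground, background, annotations) {
  if (!all(foreground %in% background)) {
    abort("Foreground proteins must be a subset of the background.")
  }
  annotations <- dplyr::filter(as_tibble(annotations),
                               .data$protein_id %in% background)
  N <- length(unique(background))
  n <- length(unique(foreground))
  per_term <- annotations |>
    dplyr::distinct(.data$term, .data$protein_id) |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(K = dplyr::n(),
                     k = sum(.data$protein_id %in% foreground),
                     .groups = "drop")
  p <- phyper(per_term$k - 1, per_term$K, N - per_term$K, n,
              lower.tail = FALSE)
  out <- tibble(term = per_term$term, k = per_term$k, n = n,
                K = per_term$K, N = N, p = p, q = bh_adjust(p)) |>
    dplyr::arrange(.data$p)
  class(out) <- c("scms_enrichment", class(out))
  out
}

#' Select proteins changing along the trajectory
#'
#' Leiden community detection on the cell-neighbourhood graph, then a
#' one-vs-rest Welch test per community on the normalized, non-imputed data.
#' A protein is selected if, in any community, it is detected in at least
#' `min_cells` cells overall, moves by at least `min_lfc` in absolute log2
#' fold change, and clears the significance level `alpha`.
#'
#' @param ds Dataset with `log2` and `normalized` layers.
#' @param graph igraph cell-neighbourhood graph (e.g. from [embed_cells()]).
#' @param resolution Leiden resolution parameter.
#' @param min_cells,min_lfc,alpha Selection filters.
#' @param use_adjusted Apply `alpha` to BH-adjusted p-values (default) or raw.
#' @param seed Seed for the community detection.
#' @return A list: `proteins` (selected ids), `clusters` (tibble cell_id,
#'   cluster), `tests` (per-cluster `scms_de` results bound with a `cluster`
#'   column).
#' @export
trajectory_protein_selection <- function(ds, graph, resolution = 1,
                                         min_cells = 200, min_lfc = 0.15,
                                         alpha = 0.05, use_adjusted = TRUE,
                                         seed = 1) {
  set.seed(seed)
  cl <- igraph::cluster_leiden(graph, objective_function = "modularity",
                               resolution = resolution)
  membership <- igraph::membership(cl)
  clusters <- tibble(cell_id = ds$cells$cell_id,
                     cluster = as.integer(membership))
  n_detect <- rowSums(!is.na(get_layer(ds, "normalized")))

  if (length(unique(clusters$cluster)) < 2) {
    warn("Single community found; falling back to all-cells variance ranking.")
    v <- apply(get_layer(ds, "log2"), 1, var, na.rm = TRUE)
    sel <- names(sort(v, decreasing = TRUE))[seq_len(min(500, length(v)))]
    return(list(proteins = sel, clusters = clusters, tests = NULL,
                fallback = "variance_ranking"))
  }

  tests <- purrr::map(sort(unique(clusters$cluster)), function(cc) {
    in_cl <- clusters$cluster == cc
    de <- welch_de(ds, group_a = in_cl, group_b = !in_cl,
                   fdr_alpha = alpha, lfc_floor = min_lfc)
    de$cluster <- cc
    de
  })
  tests <- dplyr::bind_rows(tests)
  crit_p <- if (use_adjusted) tests$q else tests$p
  hits <- tests$tested & !is.na(crit_p) & crit_p < alpha &
    !is.na(tests$log2fc) & abs(tests$log2fc) >= min_lfc &
    n_detect[match(tests$protein_id, names(n_detect))] >= min_cells
  list(proteins = unique(tests$protein_id[hits]),
       clusters = clusters, tests = tests, fallback = NULL)
}

# Moving average along a vector with truncated (shrinking) edge windows.
.moving_average <- function(x, window) {
  if (window <= 1) return(x)
  n <- length(x)
  half_lo <- floor((window - 1) / 2)
  half_hi <- ceiling((window - 1) / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half_lo, 1)
  hi <- pmin(seq_len(n) + half_hi, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

.minmax01 <- function(x) {
  r <- range(x, finite = TRUE)
  if (diff(r) == 0) return(rep(0, length(x)))
  (x - r[1]) / diff(r)
}

#' Cluster trajectory proteins and build smoothed signatures
#'
#' Hierarchically clusters the selected proteins (correlation distance,
#' average linkage) into `n_clusters` groups, smooths each protein's imputed
#' expression over the pseudotime-ordered cells with a moving average
#' (truncated windows at the edges), min-max normalizes each protein to
#' `[0, 1]`, and aggregates each cluster into a signature (member mean,
#' again min-max normalized).
#'
#' @param mat Imputed protein x cell matrix restricted to selected proteins.
#' @param cell_order Integer or character ordering of cells by pseudotime.
#' @param n_clusters Number of protein clusters (default 5).
#' @param window Moving-average window in cells (default 50; 1 = identity).
#' @param method,linkage Distance (`"correlation"` or `"euclidean"`) and
#'   hclust linkage.
#' @return An `scms_signatures` list: `clusters` (tibble protein_id,
#'   cluster), `heatmap` (smoothed, 0-1 normalized matrix over ordered
#'   cells), `signatures` (cluster x cell matrix).
#' @export
protein_cluster_signatures <- function(mat, cell_order, n_clusters = 5,
                                       window = 50,
                                       method = c("correlation", "euclidean"),
                                       linkage = "average") {
  method <- match.arg(method)
  if (n_clusters > nrow(mat)) abort("More clusters requested than proteins.")
  if (is.character(cell_order)) cell_order <- match(cell_order, colnames(mat))
  ord <- mat[, cell_order, drop = FALSE]

  d <- if (method == "correlation") {
    cmat <- suppressWarnings(cor(t(ord)))
    cmat[!is.finite(cmat)] <- 0
    as.dist(1 - cmat)
  } else {
    stats::dist(ord)
  }
  hc <- hclust(d, method = linkage)
  clusters <- cutree(hc, k = n_clusters)

  smoothed <- t(apply(ord, 1, .moving_average, window = window))
  smoothed <- t(apply(smoothed, 1, .minmax01))
  dimnames(smoothed) <- dimnames(ord)

  signatures <- do.call(rbind, lapply(sort(unique(clusters)), function(cc) {
    .minmax01(colMeans(smoothed[clusters == cc, , drop = FALSE]))
  }))
  rownames(signatures) <- paste0("cluster_", sort(unique(clusters)))
  colnames(signatures) <- colnames(ord)

  structure(list(
    clusters = tibble(protein_id = rownames(mat), cluster = unname(clusters)),
    heatmap = smoothed,
    signatures = signatures
  ), class = "scms_signatures")
}
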