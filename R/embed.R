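#' Per-sample silhouette coefficients
#'
#' The standard definition: for sample i with mean within-cluster distance a
#' and smallest mean distance to another cluster b,
#' `s(i) = (b - a) / max(a, b)`, always in `[-1, 1]`. Supports restriction to
#' a subset of labels (e.g. scoring only two differentiation stages).
#'
#' @param coordinates Numeric matrix, one row per sample (any dimensionality:
#'   2-D embeddings or principal components).
#' @param labels Cluster/group label per row.
#' @param subset Optional label subset to restrict scoring to.
#' @return A tibble (`item`, `label`, `silhouette`) with the mean coefficient
#'   attached as attribute `mean_silhouette`. Every cluster must have at
#'   least two members.
#' @export
silhouette_scores <- function(coordinates, labels, subset = NULL) {
  coordinates <- as.matrix(coordinates)
  labels <- as.character(labels)
  stopifnot(nrow(coordinates) == length(labels))
  keep <- !is.na(labels)
  if (!is.null(subset)) keep <- keep & labels %in% subset
  coordinates <- coordinates[keep, , drop = FALSE]
  labels <- labels[keep]
  ulab <- unique(labels)
  if (length(ulab) < 2) abort("Silhouette needs at least two labelled groups.")
  counts <- table(labels)
  if (any(counts < 2)) {
    abort(paste0("Singleton cluster(s): ",
                 paste(names(counts)[counts < 2], collapse = ", ")))
  }
  D <- as.matrix(stats::dist(coordinates))
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- sum(D[i, own]) / (sum(own) - 1)
    b <- min(vapply(setdiff(ulab, labels[i]), function(l) {
      mean(D[i, labels == l])
    }, numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  out <- tibble(item = rownames(coordinates) %||% as.character(seq_len(n)),
                label = labels, silhouette = s)
  attr(out, "mean_silhouette") <- mean(s)
  out
}

# Gaussian kernel with local scaling on a mutual-union kNN structure.
.knn_kernel <- function(pc, n_neighbors) {
  D <- as.matrix(stats::dist(pc))
  n <- nrow(D)
  k <- min(n_neighbors, n - 1)
  sigma <- apply(D, 1, function(row) sort(row)[k + 1])  # dist to k-th neighbour
  sigma[sigma == 0] <- min(sigma[sigma > 0], 1e-8)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nn <- order(D[i, ])[2:(k + 1)]
    W[i, nn] <- exp(-D[i, nn]^2 / (sigma[i] * sigma[nn]))
  }
  pmax(W, t(W))  # symmetrize: union of neighbourhoods
}

#' Embed cells: PCA, neighbourhood graph, 2-D embeddings, diffusion map
#'
#' Runs principal component analysis on the scaled matrix, builds a weighted
#' k-nearest-neighbour graph in PC space, and derives the requested 2-D
#' embeddings (UMAP, force-directed drawing) plus diffusion components for
#' pseudotime. Deterministic for a fixed seed.
#'
#' @param scaled Complete, scaled protein x cell matrix.
#' @param n_pcs Number of principal components; must be smaller than both
#'   matrix dimensions.
#' @param n_neighbors Neighbourhood size for the graph and UMAP.
#' @param methods Subset of `c("umap", "force_directed", "diffusion_map")`.
#' @param min_dist UMAP `min_dist`.
#' @param n_dcs Number of diffusion components retained.
#' @param seed Random seed.
#' @return An `scms_embedding`: list with `cell_ids`, `pcs`, `graph`
#'   (igraph), `embeddings` (named list of cell x 2 matrices) and
#'   `diffusion` (eigenvalues + components).
#' @export
embed_cells <- function(scaled, n_pcs = 50, n_neighbors = 15,
                        methods = c("umap", "diffusion_map"),
                        min_dist = 0.5, n_dcs = 15, seed = 1) {
  stopifnot(is.matrix(scaled), !anyNA(scaled))
  methods <- match.arg(methods,
                       c("umap", "force_directed", "diffusion_map"),
                       several.ok = TRUE)
  n_cells <- ncol(scaled)
  if (n_pcs >= min(dim(scaled))) {
    abort("`n_pcs` must be smaller than both the protein and cell counts.")
  }
  set.seed(seed)
  pca <- prcomp(t(scaled), rank. = n_pcs, center = TRUE, scale. = FALSE)
  pcs <- pca$x
  rownames(pcs) <- colnames(scaled)

  W <- .knn_kernel(pcs, n_neighbors)
  graph <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                               weighted = TRUE)
  igraph::V(graph)$name <- colnames(scaled)

  embeddings <- list()
  if ("umap" %in% methods) {
    set.seed(seed)
    um <- uwot::umap(pcs, n_neighbors = min(n_neighbors, n_cells - 1),
                     min_dist = min_dist, n_threads = 1, n_sgd_threads = 0)
    rownames(um) <- colnames(scaled)
    embeddings$umap <- um
  }
  if ("force_directed" %in% methods) {
    set.seed(seed)
    fr <- igraph::layout_with_fr(graph, weights = igraph::E(graph)$weight)
    rownames(fr) <- colnames(scaled)
    embeddings$force_directed <- fr
  }

  # diffusion components are always computed: pseudotime needs them
  diffusion <- .diffusion_components(W, n_dcs = min(n_dcs, n_cells - 2))
  rownames(diffusion$components) <- colnames(scaled)
  if ("diffusion_map" %in% methods) {
    embeddings$diffusion_map <- diffusion$components[, 1:2, drop = FALSE]
  }

  structure(list(
    cell_ids = colnames(scaled),
    pcs = pcs,
    graph = graph,
    embeddings = embeddings,
    diffusion = diffusion,
    params = list(n_pcs = n_pcs, n_neighbors = n_neighbors, seed = seed,
                  min_dist = min_dist)
  ), class = "scms_embedding")
}

# Diffusion map of a symmetric kernel: density-normalized transition
# operator, symmetric eigendecomposition, trivial component dropped.
.diffusion_components <- function(W, n_dcs = 15) {
  q <- rowSums(W)
  q[q == 0] <- 1e-12
  W1 <- W / outer(q, q)
  d1 <- rowSums(W1)
  d1[d1 == 0] <- 1e-12
  S <- W1 / sqrt(outer(d1, d1))
  eig <- eigen(S, symmetric = TRUE)
  psi <- eig$vectors / sqrt(d1)
  # normalize each component; skip the constant first eigenvector
  idx <- seq(2, min(n_dcs + 1, ncol(psi)))
  comps <- psi[, idx, drop = FALSE]
  comps <- sweep(comps, 2, sqrt(colSums(comps^2)), `/`)
  list(values = eig$values[idx], components = comps)
}

#' Diffusion pseudotime from a root cell
#'
#' Distance to the root in diffusion space, each component weighted by
#' `lambda / (1 - lambda)`: cells progressing away from the root along the
#' dominant diffusion directions accrue pseudotime, which is rescaled to
#' `[0, 1]`. Cells in a graph component unreachable from the root get
#' missing pseudotime.
#'
#' @param embedding An `scms_embedding` from [embed_cells()].
#' @param root_cell Cell identifier (or index) of the root; its pseudotime
#'   is exactly 0. Defaults to the cell with the extremal first diffusion
#'   component.
#' @return Tibble (`cell_id`, `pseudotime`).
#' @export
diffusion_pseudotime <- function(embedding, root_cell = NULL) {
  stopifnot(inherits(embedding, "scms_embedding"))
  ids <- embedding$cell_ids
  if (is.null(root_cell)) {
    root <- which.max(abs(embedding$diffusion$components[, 1]))
  } else if (is.character(root_cell)) {
    root <- match(root_cell, ids)
    if (is.na(root)) abort(paste0("Root cell '", root_cell, "' not in dataset."))
  } else {
    root <- as.integer(root_cell)
    if (root < 1 || root > length(ids)) abort("Root cell index out of range.")
  }
  lam <- embedding$diffusion$values
  comps <- embedding$diffusion$components
  w <- lam / (1 - pmin(lam, 1 - 1e-10))
  diffs <- sweep(comps, 2, comps[root, ], `-`)
  dpt <- sqrt(rowSums(sweep(diffs, 2, w, `*`)^2))

  member <- igraph::components(embedding$graph)$membership
  reachable <- member == member[root]
  dpt[!reachable] <- NA_real_
  mx <- max(dpt, na.rm = TRUE)
  if (mx > 0) dpt <- dpt / mx
  tibble(cell_id = ids, pseudotime = unname(dpt))
}
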