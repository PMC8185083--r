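#' Pipeline configuration
#'
#' Collects every scalar tuning parameter of the processing chain in one
#' validated list. Defaults follow the published workflow where it states a
#' value (convergence and noise floor at 1.1 s/n, 5 imputation neighbours,
#' proteins kept when seen in at least 3 cells, 20 PCs for replicate
#' evaluation, trajectory filters of 200 cells / 0.15 log2FC / 0.05, 50-cell
#' smoothing window, five protein clusters, 40% coverage for integration);
#' the rest are documented package defaults.
#'
#' @param convergence_threshold Iterative median normalization stops once the
#'   largest elementwise change between successive matrices is below this, in
#'   s/n units.
#' @param noise_floor Normalized values strictly below this become missing.
#' @param mad_multiplier Width of the MAD outlier bounds on log2 summed s/n.
#' @param min_proteins_per_cell Cells observing fewer proteins are removed.
#' @param min_cells_per_protein Proteins seen in fewer cells are removed.
#' @param knn_k Neighbours for kNN imputation.
#' @param n_pcs_eval,n_pcs_embed Principal components for replicate
#'   evaluation and for the embedding neighbourhood graph.
#' @param n_neighbors Neighbourhood-graph size (also UMAP `n_neighbors`).
#' @param umap_min_dist UMAP `min_dist`.
#' @param coverage_grid Candidate per-protein coverage fractions for
#'   [select_coverage_threshold()]; must be sorted ascending.
#' @param de_min_per_group Minimum observed values per group for a protein to
#'   be tested.
#' @param fdr_alpha BH false-discovery cutoff.
#' @param traj_min_cells,traj_min_lfc Trajectory protein selection filters.
#' @param smooth_window Moving-average window (cells) for heatmap smoothing.
#' @param n_protein_clusters Protein clusters for the trajectory heatmap.
#' @param integrate_min_coverage Minimum valid-value fraction per protein
#'   before integrating unbalanced datasets.
#' @param random_seed Seed used by seeded steps unless overridden.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(convergence_threshold = 1.1,
                            noise_floor = 1.1,
                            mad_multiplier = 3,
                            min_proteins_per_cell = 10,
                            min_cells_per_protein = 3,
                            knn_k = 5,
                            n_pcs_eval = 20,
                            n_pcs_embed = 50,
                            n_neighbors = 15,
                            umap_min_dist = 0.5,
                            coverage_grid = seq(0, 1, by = 0.1),
                            de_min_per_group = 3,
                            fdr_alpha = 0.05,
                            traj_min_cells = 200,
                            traj_min_lfc = 0.15,
                            smooth_window = 50,
                            n_protein_clusters = 5,
                            integrate_min_coverage = 0.40,
                            random_seed = 1L) {
  cfg <- list(
    convergence_threshold = convergence_threshold, noise_floor = noise_floor,
    mad_multiplier = mad_multiplier,
    min_proteins_per_cell = min_proteins_per_cell,
    min_cells_per_protein = min_cells_per_protein, knn_k = knn_k,
    n_pcs_eval = n_pcs_eval, n_pcs_embed = n_pcs_embed,
    n_neighbors = n_neighbors, umap_min_dist = umap_min_dist,
    coverage_grid = coverage_grid, de_min_per_group = de_min_per_group,
    fdr_alpha = fdr_alpha, traj_min_cells = traj_min_cells,
    traj_min_lfc = traj_min_lfc, smooth_window = smooth_window,
    n_protein_clusters = n_protein_clusters,
    integrate_min_coverage = integrate_min_coverage,
    random_seed = as.integer(random_seed)
  )
  scalars <- c("convergence_threshold", "noise_floor", "mad_multiplier",
               "knn_k", "de_min_per_group", "traj_min_cells", "traj_min_lfc",
               "smooth_window", "n_protein_clusters")
  for (nm in scalars) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || cfg[[nm]] <= 0) {
      abort(paste0("`", nm, "` must be a positive scalar."))
    }
  }
  if (cfg$fdr_alpha <= 0 || cfg$fdr_alpha >= 1) abort("`fdr_alpha` must lie in (0, 1).")
  if (is.unsorted(cfg$coverage_grid)) abort("`coverage_grid` must be sorted ascending.")
  structure(cfg, class = "pipeline_config")
}
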