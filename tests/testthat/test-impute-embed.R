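test_that("kNN imputation matches exhaustive brute force on random instances", {
  set.seed(101)
  for (rep in 1:100) {
    mat <- matrix(rnorm(80, 5, 2), 8, 10,
                  dimnames = list(paste0("p", 1:8), paste0("c", 1:10)))
    n_missing <- sample.int(round(0.3 * 80), 1)
    mat[sample(80, n_missing)] <- NA
    # keep every cell with at least one observation
    empty_cells <- colSums(!is.na(mat)) == 0
    mat[1, empty_cells] <- rnorm(sum(empty_cells))
    k <- sample(2:5, 1)
    expect_equal(impute_knn(mat, k), brute_impute(mat, k), tolerance = 1e-12)
  }
})

test_that("imputation preserves observed entries and handles edge cases", {
  set.seed(7)
  mat <- matrix(rnorm(60), 6, 10,
                dimnames = list(paste0("p", 1:6), paste0("c", 1:10)))
  expect_identical(impute_knn(mat, 3), mat)  # complete matrix untouched
  mat[2, 4] <- NA
  out <- impute_knn(mat, 3)
  expect_identical(out[-2, ], mat[-2, ])
  expect_identical(out[2, -4], mat[2, -4])
  expect_false(is.na(out[2, 4]))
  expect_error(impute_knn(mat, 10), "smaller than the number of cells")
})

test_that("feature scaling yields mean zero, unit sample variance", {
  mat <- matrix(c(1, 2, 3, 5, 5, 5), 2, 3, byrow = TRUE,
                dimnames = list(c("p1", "p2"), c("c1", "c2", "c3")))
  expect_warning(out <- scale_features(mat), "zero-variance")
  expect_equal(unname(out[1, ]), c(-1, 0, 1))
  expect_equal(unname(out[2, ]), c(0, 0, 0))
  set.seed(1)
  big <- matrix(rnorm(3000, 4, 3), 30, 100)
  sc <- scale_features(big)
  expect_lt(max(abs(rowMeans(sc))), 1e-10)
  expect_equal(unname(apply(sc, 1, sd)), rep(1, 30))
})

test_that("coverage-threshold selection rejects noisy low-coverage proteins", {
  set.seed(20)
  n_cells <- 120
  labels <- rep(c("A", "B"), each = n_cells / 2)
  signal <- matrix(rnorm(15 * n_cells, 0, 1), 15, n_cells)
  signal[, labels == "B"] <- signal[, labels == "B"] + 1.2
  # low-coverage pure-noise proteins that drown the signal when imputed
  noise <- matrix(rnorm(85 * n_cells, 0, 4), 85, n_cells)
  noise[matrix(runif(85 * n_cells) < 0.7, 85, n_cells)] <- NA
  mat <- rbind(signal, noise)
  dimnames(mat) <- list(sprintf("p%03d", 1:100), sprintf("c%03d", 1:n_cells))
  ds <- scms_dataset(matrix(1, 100, n_cells, dimnames = dimnames(mat)),
                     cells = tibble::tibble(cell_id = colnames(mat),
                                            population = labels))
  ds <- scmskit:::set_layer(ds, "log2", mat)
  sel <- select_coverage_threshold(ds, grid = c(0, 0.5, 1), seed = 1)
  expect_gt(sel$threshold, 0)
  tab <- sel$table
  expect_equal(nrow(tab), 3L)
  expect_gte(tab$silhouette[tab$threshold == sel$threshold],
             tab$silhouette[tab$threshold == 0])
})

test_that("coverage selection tie rules favour the lowest threshold", {
  fx <- make_processed_dataset(seed = 12, n_proteins = 60, n_cells = 60)
  ds <- fx$ds
  full <- !anyNA(get_layer(ds, "log2"))
  ds$layers$log2[is.na(ds$layers$log2)] <- 0  # fully observed
  sel <- select_coverage_threshold(ds, grid = c(0.2, 0.6), seed = 1)
  expect_equal(sel$threshold, 0.2)  # identical protein sets -> lowest wins
  one <- select_coverage_threshold(ds, grid = 0.5, seed = 1)
  expect_equal(one$threshold, 0.5)
  expect_error(select_coverage_threshold(ds, labels = rep("A", ncol(ds$layers$log2))),
               "two labelled groups")
})

test_that("embedding is deterministic and PCA variance ordering holds", {
  set.seed(3)
  mat <- matrix(rnorm(50 * 80), 50, 80,
                dimnames = list(paste0("p", 1:50), paste0("c", 1:80)))
  sc <- scale_features(mat)
  e1 <- embed_cells(sc, n_pcs = 10, seed = 4)
  e2 <- embed_cells(sc, n_pcs = 10, seed = 4)
  expect_identical(e1$embeddings$umap, e2$embeddings$umap)
  vars <- apply(e1$pcs, 2, var)
  expect_true(all(diff(vars) <= 1e-8))
  expect_error(embed_cells(sc, n_pcs = 50), "n_pcs")
})

test_that("well-separated clouds separate cleanly in UMAP space", {
  set.seed(9)
  labels <- rep(c("A", "B"), each = 100)
  mat <- matrix(rnorm(50 * 200), 50, 200,
                dimnames = list(paste0("p", 1:50), paste0("c", 1:200)))
  mat[, labels == "B"] <- mat[, labels == "B"] + 6
  emb <- embed_cells(scale_features(mat), n_pcs = 10, seed = 1)
  expect_gt(mean_sil(emb$embeddings$umap, labels), 0.8)
})

test_that("pseudotime is zero at the root and monotone on a chain", {
  # cells along a 1-D chain in feature space
  n <- 60
  pos <- seq_len(n)
  set.seed(2)
  mat <- rbind(pos, pos, pos) + matrix(rnorm(3 * n, 0, 0.01), 3)
  mat <- rbind(mat, matrix(rnorm(5 * n, 0, 0.5), 5))
  dimnames(mat) <- list(paste0("p", 1:8), paste0("c", 1:n))
  emb <- embed_cells(mat, n_pcs = 3,
                     n_neighbors = 5, methods = "diffusion_map", seed = 1)
  pt <- diffusion_pseudotime(emb, root_cell = "c1")
  expect_equal(pt$pseudotime[1], 0)
  expect_gt(cor(pt$pseudotime, pos, method = "spearman"), 0.99)
  expect_error(diffusion_pseudotime(emb, "nope"), "not in dataset")
})

test_that("pseudotime is invariant to global scaling of the input", {
  set.seed(5)
  mat <- matrix(rnorm(20 * 50), 20, 50,
                dimnames = list(paste0("p", 1:20), paste0("c", 1:50)))
  e1 <- embed_cells(scale_features(mat), n_pcs = 5,
                    methods = "diffusion_map", seed = 2)
  e2 <- embed_cells(scale_features(mat * 100), n_pcs = 5,
                    methods = "diffusion_map", seed = 2)
  p1 <- diffusion_pseudotime(e1, "c1")$pseudotime
  p2 <- diffusion_pseudotime(e2, "c1")$pseudotime
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("silhouette coefficients match the definition on a worked case", {
  # 3 points: a = (0,0), b = (0,1) in cluster 1; c = (4,0) in cluster 2...
  # singleton clusters are rejected, so use 2+2:
  coords <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  labels <- c("g1", "g1", "g2", "g2")
  s <- silhouette_scores(coords, labels)
  # hand computation for point 1: a = 1, b = mean(10, sqrt(101)) -> s
  b1 <- mean(c(10, sqrt(101)))
  expect_equal(s$silhouette[1], (b1 - 1) / b1, tolerance = 1e-12)
  expect_true(all(s$silhouette > 0.8))
  expect_error(silhouette_scores(coords, c("a", "b", "b", "b")), "Singleton")
  expect_error(silhouette_scores(coords, rep("a", 4)), "two labelled")
})

test_that("silhouette agrees with the cluster package implementation", {
  set.seed(8)
  coords <- matrix(rnorm(40 * 3), 40, 3)
  labels <- sample(c("x", "y", "z"), 40, replace = TRUE)
  ours <- silhouette_scores(coords, labels)
  ref <- cluster::silhouette(as.integer(factor(labels)), stats::dist(coords))
  expect_equal(ours$silhouette, unname(ref[, "sil_width"]), tolerance = 1e-12)
})

test_that("random labels on one cloud give near-zero mean silhouette", {
  set.seed(13)
  coords <- matrix(rnorm(200 * 2), 200, 2)
  labels <- sample(c("A", "B"), 200, replace = TRUE)
  expect_lt(abs(mean_sil(coords, labels)), 0.1)
})
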