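test_that("Welch statistics match the textbook computation via t.test", {
  set.seed(30)
  mat <- matrix(2^rnorm(20 * 12, 4, 1), 20, 12,
                dimnames = list(sprintf("p%02d", 1:20), sprintf("c%02d", 1:12)))
  mat[sample(length(mat), 25)] <- NA
  ds <- make_manual_dataset(mat)
  a <- colnames(mat)[1:6]; b <- colnames(mat)[7:12]
  de <- welch_de(ds, a, b)
  for (i in seq_len(nrow(mat))) {
    x <- log2(mat[i, 1:6]); y <- log2(mat[i, 7:12])
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) >= 3 && length(y) >= 3) {
      ref <- t.test(x, y)
      expect_equal(de$t[i], unname(ref$statistic), tolerance = 1e-10)
      expect_equal(de$p[i], ref$p.value, tolerance = 1e-10)
      expect_equal(de$df[i], unname(ref$parameter), tolerance = 1e-10)
    } else {
      expect_false(de$tested[i])
    }
  }
})

test_that("groups {1,2,3,4} vs {2,3,4,5} reproduce the direct Welch formula", {
  mat <- rbind(p1 = 2^c(1, 2, 3, 4, 2, 3, 4, 5))
  colnames(mat) <- paste0("c", 1:8)
  ds <- make_manual_dataset(mat)
  de <- welch_de(ds, paste0("c", 1:4), paste0("c", 5:8))
  # direct arithmetic: means 2.5 vs 3.5, var 5/3 each, n = 4
  se <- sqrt(5 / 3 / 4 + 5 / 3 / 4)
  expect_equal(de$t, -1 / se, tolerance = 1e-12)
  expect_equal(de$df, 6, tolerance = 1e-12)
  expect_equal(de$p, 2 * pt(-abs(-1 / se), 6), tolerance = 1e-12)
})

test_that("identical groups give t = 0, p = 1; sparse proteins go untested", {
  mat <- rbind(p1 = rep(2^c(1, 2, 3), 2), p2 = 2^c(1, 2, NA, 3, 4, 5))
  colnames(mat) <- paste0("c", 1:6)
  ds <- make_manual_dataset(mat)
  de <- welch_de(ds, paste0("c", 1:3), paste0("c", 4:6))
  expect_equal(de$t[1], 0)
  expect_equal(de$p[1], 1)
  expect_false(de$tested[2])  # only 2 values in group A
  expect_error(welch_de(ds, paste0("c", 1:3), paste0("c", 3:6)), "disjoint")
})

test_that("BH adjustment matches the step-up hand computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_identical(bh_adjust(numeric()), numeric())
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205)
  expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("fold changes are antisymmetric and scale-invariant", {
  set.seed(31)
  mat <- matrix(2^rnorm(30 * 10, 3, 1), 30, 10,
                dimnames = list(sprintf("p%02d", 1:30), paste0("c", 1:10)))
  ds <- make_manual_dataset(mat)
  a <- paste0("c", 1:5); b <- paste0("c", 6:10)
  fc <- log2_fold_change(ds, a, b)
  fc_swapped <- log2_fold_change(ds, b, a)
  expect_equal(fc$log2fc, -fc_swapped$log2fc)
  ds2 <- scmskit:::set_layer(ds, "normalized", mat * 13)
  expect_equal(log2_fold_change(ds2, a, b)$log2fc, fc$log2fc,
               tolerance = 1e-12)
  # means 20 vs 10 -> exactly 1
  m <- rbind(p1 = c(20, 20, 10, 10)); colnames(m) <- paste0("c", 1:4)
  dm <- make_manual_dataset(m)
  expect_equal(log2_fold_change(dm, c("c1", "c2"), c("c3", "c4"))$log2fc, 1)
})

test_that("Welch + BH is calibrated under the global null", {
  fracs <- vapply(1:3, function(s) {
    set.seed(s)
    mat <- matrix(2^rnorm(1000 * 30, 4, 1), 1000, 30,
                  dimnames = list(sprintf("p%04d", 1:1000), paste0("c", 1:30)))
    ds <- make_manual_dataset(mat)
    de <- welch_de(ds, paste0("c", 1:15), paste0("c", 16:30))
    mean(de$p < 0.05, na.rm = TRUE)
  }, numeric(1))
  band <- 1.5 * sqrt(0.05 * 0.95 / 3000)
  expect_lt(abs(mean(fracs) - 0.05), band)
  # BH keeps false discoveries near zero under the null
  set.seed(4)
  mat <- matrix(2^rnorm(1000 * 20, 4, 1), 1000, 20,
                dimnames = list(sprintf("p%04d", 1:1000), paste0("c", 1:20)))
  ds <- make_manual_dataset(mat)
  de <- welch_de(ds, paste0("c", 1:10), paste0("c", 11:20))
  expect_lte(sum(de$q < 0.05, na.rm = TRUE), 1)
})

test_that("hypergeometric enrichment equals closed forms and exact sums", {
  ann <- tibble::tibble(protein_id = sprintf("P%02d", 1:10),
                        term = rep(c("T1", "T2"), each = 5))
  en <- hypergeom_enrichment(sprintf("P%02d", 1:5), sprintf("P%02d", 1:10), ann)
  expect_equal(en$p[en$term == "T1"], 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(en$p[en$term == "T2"], 1)  # k = 0 -> p = 1
  expect_error(hypergeom_enrichment("P99", sprintf("P%02d", 1:10), ann),
               "subset")
  # exact combinatorial sum oracle on all N <= 30 instances
  set.seed(44)
  for (rep in 1:50) {
    N <- sample(5:30, 1); K <- sample.int(N, 1); n <- sample.int(N, 1)
    bg <- sprintf("B%02d", seq_len(N))
    ann2 <- tibble::tibble(protein_id = bg[seq_len(K)], term = "T")
    fg <- sample(bg, n)
    k <- sum(fg %in% bg[seq_len(K)])
    exact <- sum(vapply(k:min(n, K), function(i) {
      choose(K, i) * choose(N - K, n - i) / choose(N, n)
    }, numeric(1)))
    en2 <- hypergeom_enrichment(fg, bg, ann2)
    expect_equal(en2$p, exact, tolerance = 1e-10)
  }
})

test_that("trajectory selection enforces detection, effect and significance", {
  fx <- make_processed_dataset(seed = 21, n_proteins = 120, n_cells = 280,
                               tau_model = "uniform")
  sc <- scale_features(impute_knn(get_layer(fx$ds, "log2"), k = 5))
  emb <- embed_cells(sc, n_pcs = 15, n_neighbors = 30, seed = 1)
  sel <- trajectory_protein_selection(fx$ds, emb$graph, min_cells = 200,
                                      seed = 1)
  n_detect <- rowSums(!is.na(get_layer(fx$ds, "normalized")))
  expect_true(all(n_detect[sel$proteins] >= 200))
  hits <- dplyr::filter(sel$tests, protein_id %in% sel$proteins)
  expect_true(all(tapply(abs(hits$log2fc) >= 0.15 & hits$q < 0.05,
                         hits$protein_id, any), na.rm = TRUE))
  # a protein detected in < 200 cells is excluded regardless of effect
  under <- names(n_detect)[n_detect < 200]
  expect_length(intersect(sel$proteins, under), 0)
})

test_that("protein clustering, smoothing and signatures behave at the edges", {
  set.seed(50)
  base <- sin(seq(0, pi / 2, length.out = 40))
  mat <- rbind(p1 = base, p2 = base * 2 + 1, p3 = rev(base), p4 = rev(base) + 3,
               p5 = rep(2, 40) + rnorm(40, 0, 1e-8))
  colnames(mat) <- paste0("c", 1:40)
  sig <- protein_cluster_signatures(mat, seq_len(40), n_clusters = 3,
                                    window = 5)
  expect_equal(sort(unique(sig$clusters$cluster)), 1:3)
  # proteins with identical shapes cluster together
  cl <- sig$clusters$cluster
  expect_equal(cl[1], cl[2])
  expect_equal(cl[3], cl[4])
  expect_true(all(sig$heatmap >= 0 & sig$heatmap <= 1))
  expect_true(all(sig$signatures >= 0 & sig$signatures <= 1))
  expect_error(protein_cluster_signatures(mat, 1:40, n_clusters = 9),
               "More clusters")
  # window = 1 is the identity smoother; constant proteins min-max to zero
  sig1 <- protein_cluster_signatures(mat, 1:40, n_clusters = 2, window = 1)
  expect_equal(unname(sig1$heatmap["p1", ]), unname(scmskit:::.minmax01(base)))
  const <- rbind(a = rep(3, 10), b = 1:10)
  colnames(const) <- paste0("c", 1:10)
  sigc <- protein_cluster_signatures(const, 1:10, n_clusters = 2, window = 1)
  expect_true(all(sigc$heatmap["a", ] == 0))
})

test_that("moving average uses truncated windows at the edges", {
  x <- c(1, 2, 3, 4, 5)
  sm <- scmskit:::.moving_average(x, 3)
  expect_equal(sm, c(mean(1:2), 2, 3, 4, mean(4:5)))
  expect_equal(scmskit:::.moving_average(x, 1), x)
})
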