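test_that("depth normalization maps proportional cells to identical profiles", {
  m <- matrix(c(1, 2, 3, 0,
                2, 4, 6, 0,
                5, 1, 0, 4), nrow = 4)
  ds <- toy_dataset(m)
  ds <- normalize_dataset(ds)
  ln <- as.matrix(ds$layers$lognorm)
  expect_equal(ln[, 1], ln[, 2])
  expect_false(isTRUE(all.equal(ln[, 1], ln[, 3])))
})

test_that("all-zero cells are dropped with a warning before scaling", {
  m <- cbind(c(1, 2, 3), c(0, 0, 0), c(2, 1, 1))
  ds <- toy_dataset(m)
  expect_warning(out <- normalize_dataset(ds), "all-zero")
  expect_equal(n_cells(out), 2)
})

test_that("scaled genes have mean 0 and unit variance; constant genes become zero", {
  sim <- small_sim()
  ds <- normalize_dataset(sim$datasets$speciesA)
  sc <- scale_genes(ds$layers$lognorm[1:100, ], clip = Inf)
  mu <- rowMeans(sc)
  v <- apply(sc, 1, function(x) mean(x^2) - mean(x)^2)
  expect_true(all(abs(mu) < 1e-8))
  nonconst <- apply(as.matrix(ds$layers$lognorm[1:100, ]), 1, var) > 0
  expect_true(all(abs(v[nonconst] - 1) < 1e-6))
  const <- matrix(5, 2, 10)
  expect_true(all(scale_genes(const) == 0))
})

test_that("HVG selection recovers planted variable genes and honours the batch rule", {
  # rare high-dispersion markers against a homogeneous background: 30
  # bimodal marker genes among 530, two batches
  set.seed(30)
  n_cells <- 200
  n_bg <- 500
  markers <- sprintf("MARK%02d", 1:30)
  # background genes span a wide mean range; markers are bimodal (off in
  # half the cells) so their dispersion stands out within their mean bin
  bg_mu <- runif(n_bg, 1, 40)
  mark_base <- runif(30, 5, 30)
  mark_mu <- outer(mark_base, rep(1, n_cells)) *
    matrix(ifelse(runif(30 * n_cells) < 0.5, 0.05, 1.95), 30, n_cells)
  m <- rbind(
    matrix(rpois(30 * n_cells, mark_mu), 30, n_cells,
           dimnames = list(markers, NULL)),
    matrix(rpois(n_bg * n_cells, bg_mu), n_bg, n_cells,
           dimnames = list(sprintf("BG%03d", 1:n_bg), NULL)))
  ds <- toy_dataset(m, batch = rep(c("b1", "b2"), n_cells / 2))
  ds <- normalize_dataset(ds)
  hvg <- suppressWarnings(select_hvg(ds, n_hvg = 10 * length(markers)))
  expect_gte(mean(markers %in% hvg), 0.95)
  # a zero-variance normalized gene can never be selected
  ds$layers$norm_spliced["BG001", ] <- 1
  hvg2 <- suppressWarnings(select_hvg(ds, n_hvg = nrow(m)))
  expect_false("BG001" %in% hvg2)
})

test_that("single-sample datasets relax the variable-in-two-samples rule with a warning", {
  sim <- small_sim()
  ds <- sim$datasets$speciesA
  ds$cells$batch <- "only_one"
  ds <- normalize_dataset(ds)
  expect_warning(hvg <- select_hvg(ds, n_hvg = 50), "relaxing")
  expect_length(hvg, 50)
})

test_that("PCA explained variance is non-increasing and both branches agree", {
  set.seed(4)
  x <- matrix(rnorm(200 * 30), 200, 30) %*% diag(seq(3, 0.1, length.out = 30))
  rownames(x) <- sprintf("c%03d", 1:200)
  p1 <- fatelink:::pca_fit(x, n_pcs = 10)             # genes <= cells
  p2 <- fatelink:::pca_fit(t(x)[, , drop = FALSE], n_pcs = 5)
  expect_true(all(diff(p1$var_explained) <= 1e-8))
  expect_true(all(diff(p2$var_explained) <= 1e-8))
  # scores reproduce centred data projections
  xc <- sweep(x, 2, colMeans(x))
  expect_equal(unname(p1$scores), unname(xc %*% p1$loadings),
               tolerance = 1e-8)
})

test_that("BBKNN graph equals the brute-force per-batch oracle", {
  set.seed(5)
  n <- 50
  pcs <- matrix(rnorm(n * 5), n, 5,
                dimnames = list(sprintf("c%03d", 1:n), NULL))
  batches <- sample(c("b1", "b2", "b3"), n, replace = TRUE)
  g <- build_bbknn_graph(pcs, batches, k = 3)
  got <- data.frame(from = match(g$edges$from, rownames(pcs)),
                    to = match(g$edges$to, rownames(pcs)))
  got <- got[order(got$from, got$to), ]
  want <- oracle_bbknn_edges(pcs, batches, k = 3)
  expect_equal(unname(as.matrix(got)), unname(as.matrix(want)))
  # no self edges; exactly k out-edges per (cell, large-enough batch)
  expect_false(any(g$edges$from == g$edges$to))
  per <- table(g$edges$from, g$edges$target_batch)
  big <- table(batches) >= 4
  expect_true(all(per[, names(big)[big]] == 3))
})

test_that("one batch reduces BBKNN to ordinary kNN", {
  set.seed(6)
  pcs <- matrix(rnorm(40 * 3), 40, 3,
                dimnames = list(sprintf("c%03d", 1:40), NULL))
  g1 <- build_bbknn_graph(pcs, rep("b", 40), k = 5)
  want <- oracle_bbknn_edges(pcs, rep("b", 40), k = 5)
  got <- data.frame(from = match(g1$edges$from, rownames(pcs)),
                    to = match(g1$edges$to, rownames(pcs)))
  got <- got[order(got$from, got$to), ]
  expect_equal(unname(as.matrix(got)), unname(as.matrix(want)))
})

test_that("small batches contribute all available cells with a warning", {
  pcs <- matrix(rnorm(10 * 2), 10, 2,
                dimnames = list(sprintf("c%02d", 1:10), NULL))
  batches <- c(rep("big", 8), "tiny", "tiny")
  expect_warning(g <- build_bbknn_graph(pcs, batches, k = 4), "tiny")
  tiny_edges <- g$edges[g$edges$target_batch == "tiny" &
                          !(g$edges$from %in% c("c09", "c10")), ]
  expect_true(all(table(tiny_edges$from) == 2))
})

test_that("merge_distance 0 keeps fine clusters and 2 collapses to one class", {
  sim <- small_sim()
  ds <- normalize_dataset(sim$datasets$speciesA)
  hvg <- suppressWarnings(select_hvg(ds, 200))
  pca <- run_pca(ds, hvg, n_pcs = 20)
  g <- build_bbknn_graph(pca, ds$cells$batch, k = 3)
  ca0 <- cluster_and_merge(g, ds, resolution = 5, merge_distance = 0,
                           seed = 1)
  expect_equal(length(unique(ca0$cells$class)),
               length(unique(ca0$cells$cluster)))
  ca2 <- cluster_and_merge(g, ds, resolution = 5, merge_distance = 2,
                           seed = 1)
  expect_equal(length(unique(ca2$cells$class)), 1)
  # dendrogram heights live in [0, 2] and are monotone non-decreasing
  expect_true(all(ca0$dendrogram$height >= -1e-12 &
                    ca0$dendrogram$height <= 2 + 1e-12))
  expect_true(all(diff(ca0$dendrogram$height) >= -1e-12))
})

test_that("clustering is reproducible under a fixed seed and respects class_map", {
  sim <- small_sim()
  ds <- normalize_dataset(sim$datasets$speciesA)
  hvg <- suppressWarnings(select_hvg(ds, 200))
  pca <- run_pca(ds, hvg, n_pcs = 20)
  g <- build_bbknn_graph(pca, ds$cells$batch, k = 3)
  ca1 <- cluster_and_merge(g, ds, resolution = 5, seed = 7)
  ca2 <- cluster_and_merge(g, ds, resolution = 5, seed = 7)
  expect_identical(ca1$cells, ca2$cells)
  map <- tibble::tibble(cluster = sort(unique(ca1$cells$cluster)))
  map$class <- rep(c("X", "Y"), length.out = nrow(map))
  ca3 <- cluster_and_merge(g, ds, resolution = 5, class_map = map, seed = 7)
  expect_setequal(unique(ca3$cells$class), c("X", "Y"))
})
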