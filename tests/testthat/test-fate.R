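# random small geometry for kernel tests
kernel_fixture <- function(n = 30, seed = 10) {
  set.seed(seed)
  pcs <- matrix(rnorm(n * 4), n, 4,
                dimnames = list(sprintf("c%03d", 1:n), NULL))
  batches <- sample(c("b1", "b2"), n, replace = TRUE)
  g <- build_bbknn_graph(pcs, batches, k = 3)
  genes <- sprintf("g%02d", 1:8)
  velocity <- matrix(rnorm(8 * n), 8, n,
                     dimnames = list(genes, rownames(pcs)))
  loadings <- matrix(rnorm(8 * 4), 8, 4,
                     dimnames = list(genes, paste0("PC", 1:4)))
  pca <- structure(list(scores = pcs, loadings = loadings, genes = genes),
                   class = "pca_embedding")
  colnames(pca$scores) <- paste0("PC", 1:4)
  field <- structure(list(velocity = velocity,
                          gamma = tibble::tibble(gene_id = genes,
                                                 gamma_hat = 1,
                                                 flagged = FALSE)),
                     class = "velocity_field")
  list(graph = g, field = field, pca = pca)
}

test_that("w = 1 returns the connectivity kernel exactly and rows are stochastic", {
  fx <- kernel_fixture()
  k1 <- build_kernels(fx$graph, fx$field, fx$pca, w = 1)
  expect_equal(as.matrix(k1$P), as.matrix(k1$connectivity),
               tolerance = 1e-14)
  k05 <- build_kernels(fx$graph, fx$field, fx$pca, w = 0.5)
  expect_true(all(abs(Matrix::rowSums(k05$P) - 1) < 1e-12))
  expect_true(all(k05$P@x >= 0))
  # support restricted to graph edges
  expect_true(all((k05$P != 0) * 1 <= fx$graph$symmetric))
})

test_that("the combined kernel converges entrywise to connectivity as w -> 1", {
  fx <- kernel_fixture()
  conn <- as.matrix(build_kernels(fx$graph, fx$field, fx$pca, 1)$P)
  dev <- sapply(c(0.5, 0.9, 0.99, 0.999), function(w)
    max(abs(as.matrix(build_kernels(fx$graph, fx$field, fx$pca, w)$P) -
              conn)))
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[4], 1e-2)
})

test_that("zero-velocity cells fall back to their connectivity row", {
  fx <- kernel_fixture()
  fx$field$velocity[, 1:5] <- 0
  expect_message(k <- build_kernels(fx$graph, fx$field, fx$pca, w = 0),
                 "zero velocity")
  expect_equal(as.matrix(k$P[1:5, ]), as.matrix(k$connectivity[1:5, ]),
               tolerance = 1e-12)
})

# manual kernel wrapper for absorption tests
manual_kernel <- function(P, ids = sprintf("s%02d", seq_len(nrow(P)))) {
  dimnames(P) <- list(ids, ids)
  list(P = methods::as(Matrix::Matrix(P, sparse = TRUE), "CsparseMatrix"),
       cell_ids = ids)
}

test_that("single-transient-state chain matches the geometric closed form exactly", {
  P <- rbind(c(0.5, 0.3, 0.2),
             c(0, 1, 0),
             c(0, 0, 1))
  k <- manual_kernel(P)
  labels <- setNames(c(NA, "A", "B"), k$cell_ids)
  res <- compute_absorption(k, labels)
  expect_equal(unname(res$absorption[1, "A"]), 0.6, tolerance = 1e-10)
  expect_equal(unname(res$absorption[1, "B"]), 0.4, tolerance = 1e-10)
})

test_that("a transient state wired to a single class absorbs there with probability 1", {
  P <- rbind(c(0, 1, 0),
             c(0, 1, 0),
             c(0, 0, 1))
  k <- manual_kernel(P)
  res <- compute_absorption(k, setNames(c(NA, "A", "B"), k$cell_ids))
  expect_equal(unname(res$absorption[1, ]), c(1, 0))
})

random_chain <- function(n_transient, classes, seed, p_abs = 0.15) {
  set.seed(seed)
  n_abs <- length(classes)
  n <- n_transient + n_abs
  P <- matrix(0, n, n)
  for (i in seq_len(n_transient)) {
    tr_mass <- runif(1, 0.5, 1 - p_abs)
    tr_targets <- sample(seq_len(n_transient), min(4, n_transient))
    w <- runif(length(tr_targets)); w <- w / sum(w) * tr_mass
    P[i, tr_targets] <- P[i, tr_targets] + w
    ab_targets <- n_transient + sample.int(n_abs, min(2, n_abs))
    w2 <- runif(length(ab_targets))
    w2 <- w2 / sum(w2) * (1 - tr_mass)
    P[i, ab_targets] <- P[i, ab_targets] + w2
  }
  for (j in seq_len(n_abs)) P[n_transient + j, n_transient + j] <- 1
  labels <- c(rep(NA_character_, n_transient), classes)
  list(P = P, labels = labels)
}

test_that("the sparse solver matches a Monte-Carlo random-walk oracle", {
  ch <- random_chain(12, c("A", "B", "C"), seed = 11)
  k <- manual_kernel(ch$P)
  labels <- setNames(ch$labels, k$cell_ids)
  res <- compute_absorption(k, labels)
  n_walks <- 50000
  mc <- mc_absorption(ch$P, ch$labels, n_walks = n_walks, seed = 12)
  se <- sqrt(mc * (1 - mc) / n_walks)
  expect_true(all(abs(res$absorption - mc) <= 3 * se + 1e-9))
  expect_true(all(abs(rowSums(res$absorption) - 1) < 1e-6))
})

test_that("states with no path to an absorbing class are flagged, not fatal", {
  P <- rbind(c(0, 1, 0, 0),
             c(1, 0, 0, 0),   # s1 <-> s2 closed loop
             c(0, 0, 0.5, 0.5),
             c(0, 0, 0, 1))
  k <- manual_kernel(P)
  labels <- setNames(c(NA, NA, NA, "A"), k$cell_ids)
  expect_warning(res <- compute_absorption(k, labels), "no path")
  expect_true(res$no_path[["s01"]])
  expect_true(res$no_path[["s02"]])
  expect_true(all(is.na(res$absorption["s01", ])))
  expect_equal(unname(res$absorption["s03", "A"]), 1, tolerance = 1e-10)
})

test_that("summarize_fates separates fully determined classes and caps per class", {
  n <- 60
  ids <- sprintf("c%03d", seq_len(n))
  A <- cbind(T1 = rep(c(1, 0), each = n / 2),
             T2 = rep(c(0, 1), each = n / 2))
  rownames(A) <- ids
  res <- structure(list(absorption = A,
                        no_path = setNames(rep(FALSE, n), ids),
                        terminal_classes = c("T1", "T2")),
                   class = "fate_result")
  cls <- tibble::tibble(cell_id = ids,
                        class = rep(c("X", "Y"), each = n / 2))
  s <- summarize_fates(res, cls, cap = 1000, top_n = 20, seed = 1)
  sk <- s$sankey
  expect_equal(sk$weight[sk$source_class == "X" & sk$target_class == "T1"], 20)
  expect_equal(sk$weight[sk$source_class == "Y" & sk$target_class == "T1"], 0)
  # column sums = min(top_n, candidates)
  sums <- tapply(sk$weight, sk$target_class, sum)
  expect_true(all(sums == 20))
  expect_equal(unname(s$mean_absorption["X", "T1"]), 1)
  # cap subsamples deterministically
  s2 <- summarize_fates(res, cls, cap = 25, top_n = 20, seed = 1)
  expect_true(all(s2$n_subsampled <= 25))
  expect_error(summarize_fates(res, cls, cap = 10, top_n = 20), "cap")
})

test_that("fate summaries are invariant to permuting cell order", {
  ch <- random_chain(20, c("A", "B"), seed = 13)
  k <- manual_kernel(ch$P)
  labels <- setNames(ch$labels, k$cell_ids)
  res <- compute_absorption(k, labels)
  cls <- tibble::tibble(cell_id = k$cell_ids[1:20],
                        class = rep(c("X", "Y"), 10))
  s1 <- summarize_fates(res, cls, cap = 1000, top_n = 10, seed = 3)
  perm <- sample(nrow(res$absorption))
  res2 <- res
  res2$absorption <- res$absorption[perm, ]
  res2$no_path <- res$no_path[perm]
  s2 <- summarize_fates(res2, cls, cap = 1000, top_n = 10, seed = 3)
  expect_equal(dplyr::arrange(s1$sankey, source_class, target_class),
               dplyr::arrange(s2$sankey, source_class, target_class))
  expect_equal(s1$mean_absorption, s2$mean_absorption)
})
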