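# two tiny normalized datasets over the same gene roles, species B genes
# renamed with the generator's "B." convention
xspecies_fixture <- function(seed = 20, n_cells = 40, shift_b = 0) {
  set.seed(seed)
  ng <- 60
  genes_a <- sprintf("G%02d", seq_len(ng))
  m_a <- matrix(rpois(ng * n_cells, 5), ng, n_cells)
  # two planted classes with disjoint marker blocks
  m_a[1:10, 1:(n_cells / 2)] <- m_a[1:10, 1:(n_cells / 2)] + 40
  m_a[11:20, (n_cells / 2 + 1):n_cells] <-
    m_a[11:20, (n_cells / 2 + 1):n_cells] + 40
  m_b <- matrix(rpois(ng * n_cells, 5), ng, n_cells) + shift_b
  m_b[1:10, 1:(n_cells / 2)] <- m_b[1:10, 1:(n_cells / 2)] + 40
  m_b[11:20, (n_cells / 2 + 1):n_cells] <-
    m_b[11:20, (n_cells / 2 + 1):n_cells] + 40
  mk <- function(m, genes, prefix, batches = 2) {
    cells <- tibble::tibble(
      cell_id = sprintf("%s%03d", prefix, seq_len(ncol(m))),
      batch = rep(sprintf("%s_b%d", prefix, seq_len(batches)),
                  length.out = ncol(m)))
    gt <- tibble::tibble(gene_id = genes, is_mito = FALSE, is_ribo = FALSE)
    dimnames(m) <- list(genes, cells$cell_id)
    normalize_dataset(expression_dataset(m, m, cells, gt))
  }
  ds_a <- mk(m_a, genes_a, "a")
  ds_b <- mk(m_b, paste0("B.", genes_a), "b")
  orth <- tibble::tibble(gene_a = genes_a, gene_b = paste0("B.", genes_a))
  cls <- function(prefix) tibble::tibble(
    cell_id = sprintf("%s%03d", prefix, seq_len(n_cells)),
    class = rep(c("K1", "K2"), each = n_cells / 2))
  list(ds_a = ds_a, ds_b = ds_b, orth = orth,
       hvg_a = genes_a, hvg_b = paste0("B.", genes_a),
       classes_a = cls("a"), classes_b = cls("b"))
}

test_that("merging identical datasets with the identity map stacks two equal blocks", {
  fx <- xspecies_fixture()
  # same counts for both species so the scaled blocks must be identical
  ds_b <- fx$ds_a
  ds_b$cells$cell_id <- sub("^a", "b", ds_b$cells$cell_id)
  colnames(ds_b$spliced) <- ds_b$cells$cell_id
  for (l in names(ds_b$layers)) colnames(ds_b$layers[[l]]) <- ds_b$cells$cell_id
  fx2_orth <- tibble::tibble(gene_a = fx$orth$gene_a,
                             gene_b = fx$orth$gene_a)
  merged <- suppressWarnings(
    merge_species(fx$ds_a, ds_b, fx2_orth, hvg_a = fx$hvg_a,
                  hvg_b = fx$hvg_a))
  n <- nrow(merged$x) / 2
  expect_equal(unname(merged$x[1:n, ]), unname(merged$x[(n + 1):(2 * n), ]))
})

test_that("a many-to-one orthologue map is rejected", {
  fx <- xspecies_fixture()
  orth_bad <- rbind(fx$orth, fx$orth[1, ])
  expect_error(merge_species(fx$ds_a, fx$ds_b, orth_bad), "one-to-one")
})

test_that("the shared gene space is the variable-in-both intersection of the map", {
  fx <- xspecies_fixture()
  # restrict the map to 25 pairs: merged dimension can be at most 25
  orth_sub <- fx$orth[1:25, ]
  merged <- suppressWarnings(
    merge_species(fx$ds_a, fx$ds_b, orth_sub, hvg_a = fx$hvg_a,
                  hvg_b = fx$hvg_b))
  expect_lte(ncol(merged$x), 25)
  expect_true(all(merged$shared_genes$gene_a %in% orth_sub$gene_a))
  # genes dropped from the map never appear
  expect_false(any(fx$orth$gene_a[26:60] %in% colnames(merged$x)))
})

test_that("MNN pairs equal the exhaustive brute-force oracle and are symmetric", {
  fx <- xspecies_fixture(n_cells = 30)
  merged <- suppressWarnings(
    merge_species(fx$ds_a, fx$ds_b, fx$orth, hvg_a = fx$hvg_a,
                  hvg_b = fx$hvg_b))
  pairs <- find_mnn_pairs(merged, k = 4, n_pcs = 10)
  pca <- attr(pairs, "pca")
  is_a <- merged$cells$.merge_species == "A"
  want <- oracle_mnn(pca$scores, is_a, k = 4)
  got <- cbind(match(pairs$cell_a, merged$cells$cell_id),
               match(pairs$cell_b, merged$cells$cell_id))
  got <- got[order(got[, 1], got[, 2]), , drop = FALSE]
  expect_equal(unname(got), unname(want))
  # mutuality is symmetric by construction: the pair set is unique
  expect_false(anyDuplicated(paste(pairs$cell_a, pairs$cell_b)) > 0)
})

test_that("two coincident cells with k = 1 form exactly one MNN pair", {
  # deterministic geometry: cells far apart except one coincident pair
  ng <- 10
  base <- diag(10, ng)[, c(1:4, 1:4)] * rep(c(1, 2, 4, 8), 2)
  m <- base + 1
  cells <- tibble::tibble(cell_id = sprintf("c%d", 1:8),
                          batch = "b1")
  genes <- tibble::tibble(gene_id = sprintf("g%d", seq_len(ng)),
                          is_mito = FALSE, is_ribo = FALSE)
  dimnames(m) <- list(genes$gene_id, cells$cell_id)
  ds <- suppressWarnings(normalize_dataset(
    expression_dataset(m, m, cells, genes)))
  merged <- structure(list(
    x = rbind(t(as.matrix(ds$layers$lognorm[, 1:4])),
              t(as.matrix(ds$layers$lognorm[, 5:8]))),
    cells = dplyr::mutate(ds$cells,
                          .merge_species = rep(c("A", "B"), each = 4)),
    shared_genes = tibble::tibble(gene_a = genes$gene_id,
                                  gene_b = genes$gene_id)),
    class = "merged_species")
  pairs <- find_mnn_pairs(merged, k = 1, n_pcs = 4)
  expect_equal(nrow(pairs), 4)  # each cell's twin is coincident
  expect_equal(sub("c", "", pairs$cell_a),
               as.character(as.integer(sub("c", "", pairs$cell_b)) - 4))
})

test_that("class homology counts MNN pairs per class pair and r = 1 for identical means", {
  fx <- xspecies_fixture()
  merged <- suppressWarnings(
    merge_species(fx$ds_a, fx$ds_b, fx$orth, hvg_a = fx$hvg_a,
                  hvg_b = fx$hvg_b))
  pairs <- find_mnn_pairs(merged, k = 5, n_pcs = 10)
  hom <- class_homology(pairs, fx$classes_a, fx$classes_b, merged)
  # total count preserved
  expect_equal(sum(hom$mnn_counts), nrow(pairs))
  # planted classes match across species
  expect_equal(unname(apply(hom$mnn_counts, 1, which.max)), c(1, 2))
  expect_equal(unname(apply(hom$correlation, 1, which.max)), c(1, 2))
  expect_true(all(hom$correlation >= -1 & hom$correlation <= 1))
})

test_that("homology is invariant to per-species affine rescaling of expression", {
  fx <- xspecies_fixture()
  merged1 <- suppressWarnings(
    merge_species(fx$ds_a, fx$ds_b, fx$orth, hvg_a = fx$hvg_a,
                  hvg_b = fx$hvg_b))
  # rescale species B counts by an affine-like scaling of the library
  fx2 <- xspecies_fixture(shift_b = 3)
  merged2 <- suppressWarnings(
    merge_species(fx2$ds_a, fx2$ds_b, fx2$orth, hvg_a = fx2$hvg_a,
                  hvg_b = fx2$hvg_b))
  p1 <- find_mnn_pairs(merged1, k = 5, n_pcs = 10)
  h1 <- class_homology(p1, fx$classes_a, fx$classes_b, merged1)
  p2 <- find_mnn_pairs(merged2, k = 5, n_pcs = 10)
  h2 <- class_homology(p2, fx2$classes_a, fx2$classes_b, merged2)
  # the class pairing conclusion is unchanged under the shift
  expect_equal(apply(h1$correlation, 1, which.max),
               apply(h2$correlation, 1, which.max))
})
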