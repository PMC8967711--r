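#' Merge two species into a shared orthologue space
#'
#' Restricts both datasets to one-to-one orthologue pairs whose genes are
#' highly variable in both species, standardizes expression within each
#' species (scaling before concatenation, so species-level location/scale
#' differences cancel), and stacks the cells. Gene identifiers of species A
#' name the shared space.
#'
#' @param ds_a,ds_b Normalized [expression_dataset()]s.
#' @param orthologues Two-column tibble (`gene_a`, `gene_b`); must be
#'   one-to-one (no gene in more than one pair).
#' @param hvg_a,hvg_b Highly variable gene lists per species (from
#'   [select_hvg()]); `NULL` computes them with defaults.
#' @param n_hvg Used when computing HVG lists internally.
#' @param clip Scaling clip bound.
#' @return A list of class `merged_species`: `x` (dense cells x shared
#'   genes, within-species scaled), `cells` tibble with `species`,
#'   `shared_genes` (tibble `gene_a`, `gene_b`).
#' @export
merge_species <- function(ds_a, ds_b, orthologues, hvg_a = NULL,
                          hvg_b = NULL, n_hvg = 12000, clip = 10) {
  orthologues <- as_tibble(orthologues)
  if (anyDuplicated(orthologues$gene_a) ||
      anyDuplicated(orthologues$gene_b)) {
    abort("orthologue map must be one-to-one: duplicated entries found.")
  }
  hvg_a <- hvg_a %||% select_hvg(ds_a, n_hvg = n_hvg)
  hvg_b <- hvg_b %||% select_hvg(ds_b, n_hvg = n_hvg)
  shared <- orthologues %>%
    filter(.data$gene_a %in% hvg_a, .data$gene_b %in% hvg_b)
  if (!nrow(shared)) {
    abort("no orthologue pair is variable in both species.")
  }
  ln_a <- ds_a$layers$lognorm %||%
    abort("`ds_a` must be normalized (missing `lognorm`).")
  ln_b <- ds_b$layers$lognorm %||%
    abort("`ds_b` must be normalized (missing `lognorm`).")
  xa <- t(scale_genes(ln_a[shared$gene_a, , drop = FALSE], clip = clip))
  xb <- t(scale_genes(ln_b[shared$gene_b, , drop = FALSE], clip = clip))
  colnames(xa) <- colnames(xb) <- shared$gene_a
  cells <- bind_rows(
    ds_a$cells %>% mutate(.merge_species = "A"),
    ds_b$cells %>% mutate(.merge_species = "B"))
  structure(list(x = rbind(xa, xb), cells = cells, shared_genes = shared),
            class = "merged_species")
}

#' @export
print.merged_species <- function(x, ...) {
  cat(sprintf("<merged_species> %d cells x %d shared variable orthologues\n",
              nrow(x$x), ncol(x$x)))
  invisible(x)
}

#' Cross-species mutual nearest neighbours
#'
#' Computes PCs of the merged matrix, then for every cell its `k` nearest
#' cross-species neighbours by Euclidean PC distance. A pair (a in A,
#' b in B) is a mutual nearest-neighbour (MNN) pair iff b is among a's k
#' nearest species-B cells AND a is among b's k nearest species-A cells.
#' Only cross-species candidates enter the mutuality test.
#'
#' @param merged A [merge_species()] result.
#' @param k Neighbours per direction (25 by default).
#' @param n_pcs Number of PCs of the merged space.
#' @return Tibble (`cell_a`, `cell_b`) of MNN pairs; the PC embedding is
#'   attached as attribute `"pca"`.
#' @export
find_mnn_pairs <- function(merged, k = 25, n_pcs = 100) {
  stopifnot(k >= 1)
  pca <- pca_fit(merged$x, n_pcs = n_pcs)
  pcs <- pca$scores
  is_a <- merged$cells$.merge_species == "A"
  ia <- which(is_a); ib <- which(!is_a)
  if (length(ia) < k || length(ib) < k) {
    warn("a species has fewer cells than k; using all of them.")
  }
  d2 <- cross_dist2(pcs[ia, , drop = FALSE], pcs[ib, , drop = FALSE])
  ka <- min(k, length(ib)); kb <- min(k, length(ia))
  nn_ab <- t(apply(d2, 1, function(r) rank(r, ties.method = "first") <= ka))
  nn_ba <- apply(d2, 2, function(r) rank(r, ties.method = "first") <= kb)
  mutual <- which(nn_ab & nn_ba, arr.ind = TRUE)
  out <- tibble(cell_a = merged$cells$cell_id[ia[mutual[, 1]]],
                cell_b = merged$cells$cell_id[ib[mutual[, 2]]]) %>%
    arrange(.data$cell_a, .data$cell_b)
  attr(out, "pca") <- pca
  out
}

cross_dist2 <- function(a, b) {
  outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
}

#' Class-level cross-species homology table
#'
#' Counts MNN pairs per (class A, class B) pair and computes the Pearson
#' correlation of class mean-expression vectors over the shared variable
#' orthologues of the merged, within-species-scaled data.
#'
#' @param pairs MNN pair tibble from [find_mnn_pairs()].
#' @param classes_a,classes_b Tibbles (`cell_id`, `class`) per species.
#' @param merged The [merge_species()] result the pairs came from.
#' @return A list of class `homology_table`: `mnn_counts` (A-classes x
#'   B-classes), `correlation` (same shape), `cell_counts_a`,
#'   `cell_counts_b`.
#' @export
class_homology <- function(pairs, classes_a, classes_b, merged) {
  classes_a <- as_tibble(classes_a)
  classes_b <- as_tibble(classes_b)
  cls_a <- sort(unique(classes_a$class))
  cls_b <- sort(unique(classes_b$class))
  pa <- classes_a$class[match(pairs$cell_a, classes_a$cell_id)]
  pb <- classes_b$class[match(pairs$cell_b, classes_b$cell_id)]
  if (anyNA(pa) || anyNA(pb)) abort("every paired cell needs a class.")
  mnn <- table(factor(pa, levels = cls_a), factor(pb, levels = cls_b))
  mnn <- matrix(as.integer(mnn), length(cls_a), length(cls_b),
                dimnames = list(cls_a, cls_b))

  mean_vec <- function(classes_tbl, cls) {
    idx <- match(classes_tbl$cell_id, merged$cells$cell_id)
    keep <- !is.na(idx)
    vapply(cls, function(k) {
      rows <- idx[keep][classes_tbl$class[keep] == k]
      if (!length(rows)) rep(0, ncol(merged$x))
      else colMeans(merged$x[rows, , drop = FALSE])
    }, numeric(ncol(merged$x)))
  }
  ma <- mean_vec(classes_a, cls_a)
  mb <- mean_vec(classes_b, cls_b)
  corr <- cor(ma, mb)
  empty_a <- cls_a[!(cls_a %in% classes_a$class)]
  structure(list(mnn_counts = mnn, correlation = corr,
                 cell_counts_a = table(classes_a$class),
                 cell_counts_b = table(classes_b$class)),
            class = "homology_table")
}

#' @export
print.homology_table <- function(x, ...) {
  cat(sprintf("<homology_table> %d x %d classes, %d MNN pairs total\n",
              nrow(x$mnn_counts), ncol(x$mnn_counts), sum(x$mnn_counts)))
  invisible(x)
}
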