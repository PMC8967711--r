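#' Depth-normalize and log-transform a dataset
#'
#' Per-cell depth normalization of the spliced counts to a fixed target sum
#' (the median of per-cell totals by default), followed by a natural
#' log(1 + x) transform. The result is stored as layer `lognorm`; the raw
#' counts are retained. A depth-normalized linear layer is also kept for
#' each of spliced and unspliced (`norm_spliced`, `norm_unspliced`), which
#' the velocity estimator consumes. All-zero cells are removed with a
#' warning before normalization.
#'
#' @param dataset An [expression_dataset()].
#' @param target_sum Target per-cell total; default median of totals.
#' @return The dataset with layers `lognorm`, `norm_spliced`,
#'   `norm_unspliced` added.
#' @export
normalize_dataset <- function(dataset, target_sum = NULL) {
  totals <- Matrix::colSums(dataset$spliced)
  if (any(totals == 0)) {
    warn(sprintf("removing %d all-zero cells before normalization.",
                 sum(totals == 0)))
    dataset <- subset_dataset(dataset, cells = which(totals > 0))
    totals <- totals[totals > 0]
  }
  target_sum <- target_sum %||% median(totals)
  norm_s <- dataset$spliced %*% Diagonal(x = target_sum / totals)
  u_tot <- pmax(Matrix::colSums(dataset$unspliced), 1)
  norm_u <- dataset$unspliced %*% Diagonal(x = target_sum / u_tot)
  dimnames(norm_s) <- dimnames(norm_u) <- dimnames(dataset$spliced)
  dataset$layers$norm_spliced <- as_dgc(norm_s)
  dataset$layers$norm_unspliced <- as_dgc(norm_u)
  lognorm <- norm_s
  lognorm@x <- log1p(lognorm@x)
  dataset$layers$lognorm <- as_dgc(lognorm)
  attr(dataset$layers$lognorm, "target_sum") <- target_sum
  dataset
}

#' Per-gene standardization with clipping
#'
#' Centers and scales each gene (row) to mean 0, variance 1 across cells,
#' clipping standardized values at `clip` to bound outlier leverage.
#' Constant genes are set to all-zero.
#'
#' @param mat Genes x cells matrix (dense or sparse); returns dense.
#' @param clip Symmetric clip bound on standardized values.
#' @return Dense standardized matrix, same dimnames.
#' @export
scale_genes <- function(mat, clip = 10) {
  m <- as.matrix(mat)
  mu <- rowMeans(m)
  # population-style variance matches the mean/var pair used for scaling
  v <- rowMeans(m^2) - mu^2
  v[v < 1e-12] <- Inf  # constant gene -> all zero after scaling
  m <- (m - mu) / sqrt(v)
  if (is.finite(clip)) m <- pmin(pmax(m, -clip), clip)
  m
}

#' Select highly variable genes by binned dispersion
#'
#' Implements Seurat-style dispersion selection per sequencing sample:
#' per-gene mean and dispersion (variance / mean) are computed on the
#' depth-normalized (linear) expression within each sample, genes are cut
#' into 20 equal-frequency bins by mean, and dispersions are z-scored
#' within bins. A gene is "variable in" a sample when its z-scored
#' dispersion exceeds `z_cutoff`. The final list is the top `n_hvg` genes
#' by mean z-scored dispersion among genes variable in at least
#' `min_samples` samples (relaxed, with a warning, when only one sample
#' exists).
#'
#' @param dataset A normalized [expression_dataset()].
#' @param n_hvg Number of genes to return (fewer, with a warning, when not
#'   enough genes qualify).
#' @param sample_col Cell metadata column defining sequencing samples.
#' @param z_cutoff Dispersion z-score above which a gene counts as
#'   variable within a sample.
#' @param min_samples Minimum number of samples a gene must be variable in.
#' @return Character vector of gene identifiers, ordered by decreasing
#'   aggregate dispersion; the per-gene table is attached as attribute
#'   `"hvg_table"`.
#' @export
select_hvg <- function(dataset, n_hvg = 12000, sample_col = "batch",
                       z_cutoff = 0.5, min_samples = 2) {
  norm <- dataset$layers$norm_spliced %||%
    abort("run `normalize_dataset()` first: missing `norm_spliced` layer.")
  samples <- dataset$cells[[sample_col]]
  uniq <- unique(samples)
  if (length(uniq) < min_samples) {
    warn(sprintf(
      "only %d sample(s); relaxing the variable-in->=%d-samples rule.",
      length(uniq), min_samples))
    min_samples <- length(uniq)
  }
  z_mat <- vapply(uniq, function(s) {
    sub <- norm[, samples == s, drop = FALSE]
    mu <- Matrix::rowMeans(sub)
    v <- Matrix::rowMeans(sub^2) - mu^2
    disp <- ifelse(mu > 0, v / mu, 0)
    bin_zscore(disp, mu, n_bins = 20)
  }, numeric(nrow(norm)))
  n_variable_in <- rowSums(z_mat > z_cutoff)
  agg <- rowMeans(z_mat)
  eligible <- which(n_variable_in >= min_samples)
  if (!length(eligible)) abort("no genes pass the variability rule.")
  if (length(eligible) < n_hvg) {
    warn(sprintf("only %d eligible genes (requested %d); returning all.",
                 length(eligible), n_hvg))
  }
  ord <- eligible[order(agg[eligible], decreasing = TRUE)]
  out <- rownames(norm)[head(ord, n_hvg)]
  attr(out, "hvg_table") <- tibble(
    gene_id = rownames(norm), dispersion_z = agg,
    n_samples_variable = n_variable_in,
    selected = rownames(norm) %in% out)
  out
}

bin_zscore <- function(disp, mu, n_bins = 20) {
  brk <- unique(quantile(mu, probs = seq(0, 1, length.out = n_bins + 1)))
  bins <- cut(mu, breaks = brk, include.lowest = TRUE)
  z <- disp
  for (b in levels(bins)) {
    i <- which(bins == b)
    s <- sd(disp[i])
    z[i] <- if (length(i) < 2 || !is.finite(s) || s == 0) 0 else
      (disp[i] - mean(disp[i])) / s
  }
  z
}

#' Principal components of the scaled expression matrix
#'
#' Exact PCA via the eigendecomposition of the smaller of the gene-gene or
#' cell-cell cross-product (deterministic; no randomized solver). PC signs
#' are fixed so the loading with the largest magnitude is positive.
#'
#' @param dataset A normalized [expression_dataset()].
#' @param genes Genes to use (typically the HVG list); default all.
#' @param n_pcs Number of components.
#' @param clip Clip bound passed to [scale_genes()].
#' @return A list of class `pca_embedding`: `scores` (cells x n_pcs),
#'   `loadings` (genes x n_pcs), `var_explained`, `genes`, `clip`.
#' @export
run_pca <- function(dataset, genes = NULL, n_pcs = 100, clip = 10) {
  lognorm <- dataset$layers$lognorm %||%
    abort("run `normalize_dataset()` first: missing `lognorm` layer.")
  genes <- genes %||% rownames(lognorm)
  x <- t(scale_genes(lognorm[genes, , drop = FALSE], clip = clip))
  pca_fit(x, n_pcs = n_pcs, genes = genes, clip = clip)
}

pca_fit <- function(x, n_pcs, genes = colnames(x), clip = NA) {
  n <- nrow(x)
  p <- ncol(x)
  n_pcs <- min(n_pcs, n - 1L, p)
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  if (p <= n) {
    ev <- eigen(crossprod(xc), symmetric = TRUE)
    rot <- ev$vectors[, seq_len(n_pcs), drop = FALSE]
    scores <- xc %*% rot
    lambda <- ev$values[seq_len(n_pcs)]
  } else {
    ev <- eigen(tcrossprod(xc), symmetric = TRUE)
    lambda <- ev$values[seq_len(n_pcs)]
    u <- ev$vectors[, seq_len(n_pcs), drop = FALSE]
    scores <- u %*% diag(sqrt(pmax(lambda, 0)), n_pcs)
    rot <- crossprod(xc, u) %*% diag(1 / sqrt(pmax(lambda, 1e-12)), n_pcs)
  }
  # deterministic sign: largest-|loading| entry positive
  for (j in seq_len(n_pcs)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- rownames(x)
  rownames(rot) <- genes
  colnames(scores) <- colnames(rot) <- paste0("PC", seq_len(n_pcs))
  structure(list(scores = scores, loadings = rot,
                 var_explained = pmax(lambda, 0) / max(n - 1L, 1L),
                 center = ctr, genes = genes, clip = clip),
            class = "pca_embedding")
}

#' Batch-balanced k-nearest-neighbour graph
#'
#' For every cell and every batch, the `k` nearest other cells of that
#' batch by Euclidean distance in PC space become out-neighbours; the
#' union over batches is the directed graph. A symmetrized copy is kept
#' for clustering and kernel construction. With a single batch this
#' reduces to ordinary kNN. Batches with fewer than `k + 1` cells
#' contribute all their cells, with a warning.
#'
#' @param pcs Cells x PCs coordinate matrix (rownames = cell ids), or a
#'   `pca_embedding`.
#' @param batches Per-cell batch labels.
#' @param k Neighbours per batch.
#' @return A list of class `neighbor_graph`: `edges` tibble (`from`, `to`,
#'   `dist`, `target_batch`), `adjacency` (directed sparse), `symmetric`
#'   (undirected sparse), `cell_ids`, `batches`, `k`.
#' @export
build_bbknn_graph <- function(pcs, batches, k = 3) {
  if (inherits(pcs, "pca_embedding")) pcs <- pcs$scores
  n <- nrow(pcs)
  stopifnot(length(batches) == n, k >= 1)
  cell_ids <- rownames(pcs) %||% as.character(seq_len(n))
  sq <- rowSums(pcs^2)
  edge_list <- list()
  for (b in unique(batches)) {
    tgt <- which(batches == b)
    if (length(tgt) < k + 1) {
      warn(sprintf("batch '%s' has %d cells (< k + 1 = %d); using all.",
                   b, length(tgt), k + 1))
    }
    # full squared-distance block, cells x batch members
    d2 <- outer(sq, sq[tgt], "+") - 2 * pcs %*% t(pcs[tgt, , drop = FALSE])
    d2[cbind(tgt, seq_along(tgt))] <- Inf  # no self-edges
    nn <- lapply(seq_len(n), function(i) {
      row <- d2[i, ]
      nf <- which(is.finite(row))
      nf[order(row[nf])[seq_len(min(k, length(nf)))]]
    })
    from <- rep(seq_len(n), lengths(nn))
    to_pos <- unlist(nn)
    dist <- sqrt(pmax(d2[cbind(from, to_pos)], 0))
    edge_list[[b]] <- tibble(
      from = cell_ids[from], to = cell_ids[tgt[to_pos]],
      dist = dist, target_batch = b)
  }
  edges <- bind_rows(edge_list) %>% arrange(.data$from, .data$to)
  adj <- sparseMatrix(i = match(edges$from, cell_ids),
                      j = match(edges$to, cell_ids),
                      x = 1, dims = c(n, n),
                      dimnames = list(cell_ids, cell_ids))
  sym <- ((adj + Matrix::t(adj)) > 0) * 1
  structure(list(edges = edges, adjacency = adj, symmetric = as_dgc(sym),
                 cell_ids = cell_ids, batches = batches, k = k),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("<neighbor_graph> %d cells, %d directed edges, k = %d per batch (%d batches)\n",
              length(x$cell_ids), nrow(x$edges), x$k,
              length(unique(x$batches))))
  invisible(x)
}

#' Leiden clustering and hierarchical merge into classes
#'
#' Fine Leiden clusters (modularity objective on the symmetrized BBKNN
#' graph, at the given resolution) are merged into classes by complete
#' linkage on the Pearson-correlation distance (1 - r) between cluster
#' mean log-normalized expression vectors. The dendrogram is cut at
#' `merge_distance`; `"auto"` cuts at the largest gap in merge heights
#' (an automatic stand-in for marker-guided manual merging), `0` keeps the
#' fine clusters, and an explicit cluster-to-class map overrides the cut.
#'
#' @param graph A [build_bbknn_graph()] result.
#' @param dataset The normalized dataset the graph was built from.
#' @param resolution Leiden resolution parameter.
#' @param merge_distance Dendrogram cut height in `[0, 2]`, or `"auto"`.
#' @param genes Genes used for cluster mean-expression vectors (default:
#'   the genes of the dataset's `lognorm` layer).
#' @param class_map Optional tibble (`cluster`, `class`) overriding the
#'   automatic merge (the supported manual path).
#' @param seed Seed for the Leiden refinement.
#' @return A list of class `class_assignment`: `cells` tibble (`cell_id`,
#'   `cluster`, `class`), `class_means` (genes x classes),
#'   `cluster_means`, `dendrogram` (an `hclust`), `merge_height`,
#'   `resolution`.
#' @export
cluster_and_merge <- function(graph, dataset, resolution = 10,
                              merge_distance = "auto", genes = NULL,
                              class_map = NULL, seed = 1L) {
  lognorm <- dataset$layers$lognorm %||%
    abort("run `normalize_dataset()` first: missing `lognorm` layer.")
  genes <- genes %||% rownames(lognorm)
  g <- igraph::graph_from_adjacency_matrix(graph$symmetric,
                                           mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  memb <- withr::with_seed(seed, {
    igraph::cluster_leiden(g, objective_function = "modularity",
                           resolution = resolution,
                           n_iterations = 3)$membership
  })
  clusters <- sprintf("C%03d", memb)
  expr <- lognorm[genes, match(graph$cell_ids, colnames(lognorm)),
                  drop = FALSE]
  cl_means <- group_means(expr, clusters)

  if (!is.null(class_map)) {
    class_map <- as_tibble(class_map)
    classes <- class_map$class[match(clusters, class_map$cluster)]
    if (anyNA(classes)) abort("`class_map` must cover every fine cluster.")
    hc <- NULL
    height <- NA_real_
  } else if (ncol(cl_means) == 1) {
    classes <- rep("K01", length(clusters))
    hc <- NULL
    height <- 0
  } else {
    d <- as.dist(1 - cor(cl_means))
    hc <- hclust(d, method = "complete")
    height <- if (identical(merge_distance, "auto")) {
      auto_cut_height(hc$height)
    } else {
      merge_distance
    }
    grp <- cutree(hc, h = height)
    classes <- sprintf("K%02d", grp[clusters])
  }
  cells <- tibble(cell_id = graph$cell_ids, cluster = clusters,
                  class = classes)
  k_means <- group_means(expr, classes)
  structure(list(cells = cells, cluster_means = cl_means,
                 class_means = k_means, dendrogram = hc,
                 merge_height = height, resolution = resolution),
            class = "class_assignment")
}

# Cut inside the largest *relative* gap between consecutive sorted merge
# heights (geometric midpoint). Within-class merges form a dense low run
# and between-class merges a sparse high run; the within/between boundary
# is the largest ratio of consecutive heights, whereas the largest absolute
# gap can fall between two between-class merges when those spread out.
auto_cut_height <- function(heights) {
  h <- sort(heights[heights > 0])
  if (length(h) <= 1) return(max(heights) / 2)
  ratios <- h[-1] / h[-length(h)]
  i <- which.max(ratios)
  sqrt(h[i] * h[i + 1])
}

group_means <- function(expr, groups) {
  uniq <- sort(unique(groups))
  out <- vapply(uniq, function(g)
    Matrix::rowMeans(expr[, groups == g, drop = FALSE]),
    numeric(nrow(expr)))
  out <- matrix(out, nrow = nrow(expr),
                dimnames = list(rownames(expr), uniq))
  out
}

#' @export
print.class_assignment <- function(x, ...) {
  cat(sprintf("<class_assignment> %d cells, %d fine clusters -> %d classes",
              nrow(x$cells), length(unique(x$cells$cluster)),
              length(unique(x$cells$class))),
      if (!is.na(x$merge_height)) sprintf(" (cut at %.3f)\n", x$merge_height)
      else "\n")
  invisible(x)
}
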