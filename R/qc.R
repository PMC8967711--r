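#' Droplet-level QC thresholds
#'
#' Cells are removed when fewer than `min_genes_detected` genes are
#' detected, or when more than `max_ribosomal_fraction` of reads are
#' ribosomal or more than `max_mitochondrial_fraction` mitochondrial
#' (strict inequalities, read literally). When the cell metadata carries a
#' `cell_probability` column from an upstream ambient-RNA model, droplets
#' with probability not exceeding `min_cell_probability` are removed too.
#'
#' @param min_genes_detected Minimum detected (nonzero spliced) genes.
#' @param max_ribosomal_fraction,max_mitochondrial_fraction Upper fraction
#'   bounds, in `[0, 1]`.
#' @param min_cell_probability Lower bound on the per-droplet cell
#'   probability (only applied when the column is present).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes_detected = 800,
                          max_ribosomal_fraction = 0.40,
                          max_mitochondrial_fraction = 0.15,
                          min_cell_probability = 0.99) {
  stopifnot(min_genes_detected >= 0,
            max_ribosomal_fraction >= 0, max_ribosomal_fraction <= 1,
            max_mitochondrial_fraction >= 0,
            max_mitochondrial_fraction <= 1,
            min_cell_probability >= 0, min_cell_probability <= 1)
  structure(list(min_genes_detected = min_genes_detected,
                 max_ribosomal_fraction = max_ribosomal_fraction,
                 max_mitochondrial_fraction = max_mitochondrial_fraction,
                 min_cell_probability = min_cell_probability),
            class = "qc_thresholds")
}

#' Filter cells on droplet-level QC thresholds
#'
#' Detected genes are counted on the spliced matrix; ribosomal and
#' mitochondrial fractions use total spliced counts per cell as the
#' denominator. A cell is retained iff detected >= `min_genes_detected`
#' AND ribo <= `max_ribosomal_fraction` AND mito <=
#' `max_mitochondrial_fraction` (and cell probability >
#' `min_cell_probability` when present). Removal reasons are recorded per
#' cell; a cell may fail several.
#'
#' @param dataset An [expression_dataset()] whose gene metadata carries
#'   logical `is_mito` and `is_ribo` columns.
#' @param thresholds A [qc_thresholds()].
#' @return A list of class `qc_result` with `dataset` (filtered; genes
#'   unchanged) and `report`, a per-cell tibble with the computed metrics,
#'   `pass`, and a comma-separated `reasons` string for removed cells.
#' @export
filter_cells <- function(dataset, thresholds = qc_thresholds()) {
  if (!all(c("is_mito", "is_ribo") %in% names(dataset$genes))) {
    abort(paste("gene metadata must contain logical `is_mito` and",
                "`is_ribo` columns to compute QC fractions."))
  }
  spl <- dataset$spliced
  detected <- Matrix::colSums(spl > 0)
  total <- Matrix::colSums(spl)
  denom <- pmax(total, 1)
  mito_frac <- Matrix::colSums(spl[dataset$genes$is_mito, , drop = FALSE]) /
    denom
  ribo_frac <- Matrix::colSums(spl[dataset$genes$is_ribo, , drop = FALSE]) /
    denom

  fails <- list(
    min_genes = detected < thresholds$min_genes_detected,
    max_ribo = ribo_frac > thresholds$max_ribosomal_fraction,
    max_mito = mito_frac > thresholds$max_mitochondrial_fraction
  )
  if ("cell_probability" %in% names(dataset$cells)) {
    fails$cell_probability <-
      dataset$cells$cell_probability <= thresholds$min_cell_probability
  }
  fail_mat <- do.call(cbind, fails)
  pass <- !apply(fail_mat, 1, any)
  reasons <- apply(fail_mat, 1, function(f)
    paste(names(fails)[f], collapse = ","))
  report <- tibble(
    cell_id = dataset$cells$cell_id,
    detected_genes = as.integer(unname(detected)),
    total_counts = as.numeric(unname(total)),
    mito_fraction = as.numeric(unname(mito_frac)),
    ribo_fraction = as.numeric(unname(ribo_frac)),
    pass = unname(pass),
    reasons = unname(ifelse(pass, "", reasons)))
  if (!any(pass)) warn("no cells pass the QC thresholds.")
  structure(list(dataset = subset_dataset(dataset, cells = which(pass)),
                 report = report, thresholds = thresholds),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("<qc_result> %d / %d cells retained\n",
              sum(x$report$pass), nrow(x$report)))
  rm <- x$report %>% filter(!.data$pass) %>%
    tidyr::separate_rows("reasons", sep = ",") %>% count(.data$reasons)
  if (nrow(rm)) {
    for (i in seq_len(nrow(rm))) {
      cat(sprintf("  failed %s: %d\n", rm$reasons[i], rm$n[i]))
    }
  }
  invisible(x)
}

#' Cluster-level inhibitory-neuron selection rule
#'
#' @param marker_genes Inhibitory marker genes (GAD/DLX family by default).
#' @param min_failing_genes_to_remove Remove a cluster when its mean
#'   normalized expression falls strictly below the dataset-wide mean for
#'   at least this many markers.
#' @param exempt_batches Batch labels exempt from removal (ganglionic
#'   eminence dissections in the original design).
#' @return A list of class `inhibitory_rule`.
#' @export
inhibitory_rule <- function(marker_genes = inhibitory_marker_genes(),
                            min_failing_genes_to_remove = 2,
                            exempt_batches = character()) {
  if (!length(marker_genes)) abort("`marker_genes` must be non-empty.")
  if (min_failing_genes_to_remove < 1) {
    abort("`min_failing_genes_to_remove` must be >= 1.")
  }
  structure(list(marker_genes = marker_genes,
                 min_failing_genes_to_remove = min_failing_genes_to_remove,
                 exempt_batches = exempt_batches),
            class = "inhibitory_rule")
}

#' Remove non-inhibitory clusters
#'
#' For each cluster (restricted to cells in non-exempt batches), compares
#' the cluster's mean normalized expression of each marker gene with the
#' dataset-wide mean of that gene over all cells; the cluster is removed
#' when it falls strictly below the global mean for
#' `min_failing_genes_to_remove` or more markers. The per-gene comparisons
#' and the kept/removed decision are returned for every cluster.
#'
#' @param dataset A normalized [expression_dataset()] (needs the `lognorm`
#'   layer from [normalize_dataset()]).
#' @param clusters A [class_assignment] from [cluster_and_merge()], or a
#'   tibble with `cell_id` and `cluster`.
#' @param rule An [inhibitory_rule()].
#' @return A list of class `inhibitory_selection` with the filtered
#'   `dataset`, a per-cluster `log` tibble (`cluster`, `n_failing`,
#'   `removed`, one logical `below_<gene>` column per marker), and the
#'   `rule`.
#' @export
select_inhibitory_clusters <- function(dataset, clusters,
                                       rule = inhibitory_rule()) {
  lognorm <- dataset$layers$lognorm %||%
    abort("run `normalize_dataset()` first: missing `lognorm` layer.")
  cl_tbl <- if (inherits(clusters, "class_assignment")) {
    clusters$cells
  } else {
    as_tibble(clusters)
  }
  missing <- setdiff(rule$marker_genes, rownames(lognorm))
  if (length(missing)) {
    abort(paste("marker genes absent from dataset:",
                paste(missing, collapse = ", ")))
  }
  cl <- cl_tbl$cluster[match(dataset$cells$cell_id, cl_tbl$cell_id)]
  if (anyNA(cl)) abort("every cell needs a cluster label.")
  marker_expr <- as.matrix(lognorm[rule$marker_genes, , drop = FALSE])
  global_mean <- rowMeans(marker_expr)
  exempt_cell <- dataset$cells$batch %in% rule$exempt_batches

  log <- lapply(sort(unique(cl)), function(k) {
    idx <- which(cl == k & !exempt_cell)
    if (!length(idx)) {
      below <- setNames(rep(FALSE, length(rule$marker_genes)),
                        rule$marker_genes)
    } else {
      cmean <- rowMeans(marker_expr[, idx, drop = FALSE])
      below <- cmean < global_mean
    }
    out <- tibble(cluster = k, n_failing = sum(below),
                  removed = sum(below) >= rule$min_failing_genes_to_remove)
    for (g in rule$marker_genes) out[[paste0("below_", g)]] <- below[[g]]
    out
  }) %>% bind_rows()

  removed_clusters <- log$cluster[log$removed]
  # removal applies to the non-exempt batches only; exempt cells stay
  keep <- !(cl %in% removed_clusters & !exempt_cell)
  structure(list(dataset = subset_dataset(dataset, cells = which(keep)),
                 log = log, rule = rule),
            class = "inhibitory_selection")
}
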