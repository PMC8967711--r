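#' Construct an expression dataset
#'
#' The universal carrier between pipeline stages: spliced and unspliced
#' cell x gene count matrices (stored genes-in-rows, cells-in-columns, as
#' sparse [Matrix::dgCMatrix-class]) together with per-cell and per-gene
#' metadata tibbles. Normalized layers are added by [normalize_dataset()].
#'
#' @param spliced,unspliced Sparse (or coercible) count matrices, genes in
#'   rows and cells in columns, identical dimensions and dimnames.
#' @param cells Tibble of per-cell metadata; must contain `cell_id` matching
#'   `colnames(spliced)`. Typical columns: `species`, `batch`, `region`,
#'   `age`, `role` ("developmental" or "terminal"), `terminal_class`.
#' @param genes Tibble of per-gene metadata; must contain `gene_id` matching
#'   `rownames(spliced)`. Columns `is_mito` and `is_ribo` (logical) are
#'   required by [filter_cells()].
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `spliced`, `unspliced`, `cells`, `genes` and `layers` (a named list of
#'   derived matrices such as `lognorm`).
#' @export
expression_dataset <- function(spliced, unspliced, cells, genes) {
  spliced <- as_dgc(spliced)
  unspliced <- as_dgc(unspliced)
  if (!identical(dim(spliced), dim(unspliced))) {
    abort("`spliced` and `unspliced` must have identical dimensions.")
  }
  cells <- as_tibble(cells)
  genes <- as_tibble(genes)
  if (!"cell_id" %in% names(cells)) abort("`cells` must contain `cell_id`.")
  if (!"gene_id" %in% names(genes)) abort("`genes` must contain `gene_id`.")
  if (anyDuplicated(cells$cell_id)) abort("duplicated `cell_id` values.")
  if (anyDuplicated(genes$gene_id)) abort("duplicated `gene_id` values.")
  if (is.null(colnames(spliced))) {
    colnames(spliced) <- colnames(unspliced) <- cells$cell_id
  }
  if (is.null(rownames(spliced))) {
    rownames(spliced) <- rownames(unspliced) <- genes$gene_id
  }
  if (!identical(colnames(spliced), cells$cell_id)) {
    abort("`colnames(spliced)` must equal `cells$cell_id` (same order).")
  }
  if (!identical(rownames(spliced), genes$gene_id)) {
    abort("`rownames(spliced)` must equal `genes$gene_id` (same order).")
  }
  structure(
    list(spliced = spliced, unspliced = unspliced,
         cells = cells, genes = genes, layers = list()),
    class = "expression_dataset"
  )
}

as_dgc <- function(x) {
  methods::as(methods::as(methods::as(Matrix(x, sparse = TRUE),
                                      "dMatrix"), "generalMatrix"), "CsparseMatrix")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d genes x %d cells\n",
              nrow(x$spliced), ncol(x$spliced)))
  cat("  layers:", if (length(x$layers)) paste(names(x$layers), collapse = ", ")
      else "(none)", "\n")
  extra <- setdiff(names(x$cells), "cell_id")
  if (length(extra)) cat("  cell metadata:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$spliced)

#' Number of cells / genes in a dataset
#' @param dataset An [expression_dataset()].
#' @return Integer count.
#' @export
n_cells <- function(dataset) ncol(dataset$spliced)

#' @rdname n_cells
#' @export
n_genes <- function(dataset) nrow(dataset$spliced)

#' Subset an expression dataset
#'
#' @param x An [expression_dataset()].
#' @param genes,cells Character identifiers, logical masks, or integer
#'   indices. Missing means keep all.
#' @param ... Ignored.
#' @return A subsetted `expression_dataset`; all layers are subsetted
#'   consistently.
#' @export
subset_dataset <- function(x, genes = NULL, cells = NULL, ...) {
  gi <- resolve_index(genes, rownames(x$spliced), "gene")
  ci <- resolve_index(cells, colnames(x$spliced), "cell")
  out <- x
  out$spliced <- x$spliced[gi, ci, drop = FALSE]
  out$unspliced <- x$unspliced[gi, ci, drop = FALSE]
  out$cells <- x$cells[ci, , drop = FALSE]
  out$genes <- x$genes[gi, , drop = FALSE]
  out$layers <- lapply(x$layers, function(m) m[gi, ci, drop = FALSE])
  out
}

resolve_index <- function(idx, nms, what) {
  if (is.null(idx)) return(seq_along(nms))
  if (is.character(idx)) {
    miss <- setdiff(idx, nms)
    if (length(miss)) {
      abort(sprintf("unknown %s identifiers: %s", what,
                    paste(head(miss, 5), collapse = ", ")))
    }
    return(match(idx, nms))
  }
  if (is.logical(idx)) return(which(idx))
  as.integer(idx)
}

#' Write / read an MTX bundle
#'
#' Serialises an [expression_dataset()] as plain-text MatrixMarket files
#' (`spliced.mtx`, `unspliced.mtx`) plus `genes.tsv`, `barcodes.tsv` and
#' `cell_metadata.tsv`, the interchange layout used throughout the pipeline.
#'
#' @param dataset An [expression_dataset()].
#' @param dir Directory to write into (created if needed).
#' @return `write_mtx_bundle()` returns `dir` invisibly; `read_mtx_bundle()`
#'   returns the reconstructed `expression_dataset`.
#' @export
write_mtx_bundle <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(dataset$spliced, file.path(dir, "spliced.mtx"))
  Matrix::writeMM(dataset$unspliced, file.path(dir, "unspliced.mtx"))
  readr::write_tsv(dataset$genes, file.path(dir, "genes.tsv"))
  readr::write_lines(dataset$cells$cell_id, file.path(dir, "barcodes.tsv"))
  readr::write_tsv(dataset$cells, file.path(dir, "cell_metadata.tsv"))
  invisible(dir)
}

#' @rdname write_mtx_bundle
#' @export
read_mtx_bundle <- function(dir) {
  spliced <- as_dgc(Matrix::readMM(file.path(dir, "spliced.mtx")))
  unspliced <- as_dgc(Matrix::readMM(file.path(dir, "unspliced.mtx")))
  genes <- readr::read_tsv(file.path(dir, "genes.tsv"),
                           show_col_types = FALSE)
  cells <- readr::read_tsv(file.path(dir, "cell_metadata.tsv"),
                           show_col_types = FALSE)
  dimnames(spliced) <- dimnames(unspliced) <-
    list(genes$gene_id, cells$cell_id)
  expression_dataset(spliced, unspliced, cells, genes)
}
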