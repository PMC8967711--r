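#' Combined connectivity + velocity transition kernel
#'
#' Builds the row-stochastic cell-to-cell transition matrix used for fate
#' mapping as the equally weighted (by default) mixture of two kernels on
#' the symmetrized neighbour graph:
#' * connectivity kernel: row-normalized adjacency;
#' * velocity kernel: for cell i, a softmax over its neighbours j of the
#'   cosine between the displacement `pcs[j] - pcs[i]` and cell i's
#'   velocity projected into PC space through the PCA loadings, with a
#'   self-tuning temperature (the row median of |cosine|).
#' Cells with zero projected velocity fall back to their connectivity row.
#'
#' @param graph A [build_bbknn_graph()] result.
#' @param field A [estimate_velocity()] result on the same cells.
#' @param pca The [run_pca()] embedding the graph was built from.
#' @param w Mixture weight on the connectivity kernel (`w = 1` gives the
#'   connectivity kernel exactly).
#' @return A list of class `transition_kernel`: `P` (sparse
#'   row-stochastic), `connectivity`, `velocity_kernel`, `w`, `cell_ids`.
#' @export
build_kernels <- function(graph, field, pca, w = 0.5) {
  stopifnot(w >= 0, w <= 1)
  adj <- graph$symmetric
  n <- nrow(adj)
  conn <- normalize_rows(adj)
  hvg <- intersect(pca$genes, rownames(field$velocity))
  v_pc <- t(field$velocity[hvg, graph$cell_ids, drop = FALSE]) %*%
    pca$loadings[hvg, , drop = FALSE]
  pcs <- pca$scores[graph$cell_ids, , drop = FALSE]

  adj_t <- methods::as(adj, "TsparseMatrix")
  # group neighbour lists once
  nbr <- split(adj_t@j + 1L, adj_t@i + 1L)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  zero_v <- numeric(0)
  for (i in seq_len(n)) {
    js <- nbr[[as.character(i)]]
    if (is.null(js)) next
    vi <- v_pc[i, ]
    nv <- sqrt(sum(vi^2))
    if (nv < 1e-12) {
      zero_v <- c(zero_v, i)
      p <- conn[i, js]
    } else {
      delta <- pcs[js, , drop = FALSE] -
        matrix(pcs[i, ], length(js), ncol(pcs), byrow = TRUE)
      dn <- sqrt(rowSums(delta^2))
      cosv <- as.numeric(delta %*% vi) / (pmax(dn, 1e-12) * nv)
      sigma <- max(median(abs(cosv)), 1e-8)
      e <- exp(cosv / sigma - max(cosv / sigma))
      p <- e / sum(e)
    }
    ii <- c(ii, rep(i, length(js))); jj <- c(jj, js); xx <- c(xx, p)
  }
  if (length(zero_v)) {
    inform(sprintf(
      "%d cells with zero velocity fall back to the connectivity kernel.",
      length(zero_v)))
  }
  vel <- sparseMatrix(i = ii, j = jj, x = xx, dims = dim(adj),
                      dimnames = dimnames(adj))
  P <- normalize_rows(w * conn + (1 - w) * vel)
  structure(list(P = as_dgc(P), connectivity = as_dgc(conn),
                 velocity_kernel = as_dgc(vel), w = w,
                 cell_ids = graph$cell_ids),
            class = "transition_kernel")
}

normalize_rows <- function(m) {
  rs <- Matrix::rowSums(m)
  Diagonal(x = ifelse(rs > 0, 1 / rs, 0)) %*% m
}

#' Absorption probabilities into terminal classes
#'
#' Terminal cells (those with a non-`NA` terminal label) become absorbing
#' states (their rows replaced by self-loops). With transient submatrix Q
#' and transient-to-absorbing block R, the per-cell class absorption
#' probabilities are the rows of `(I - Q)^-1 R`, aggregated by terminal
#' class, computed by sparse linear solves (one right-hand side per class,
#' never a dense inversion). Transient cells with no path to any absorbing
#' state are flagged (`no_path`) and carry all-`NA` probabilities rather
#' than aborting the run.
#'
#' @param kernel A [build_kernels()] result (or any row-stochastic sparse
#'   matrix wrapped in a list with `P` and `cell_ids`).
#' @param terminal_labels Named character vector over all cells; `NA` marks
#'   transient cells.
#' @return A list of class `fate_result`: `absorption` (transient cells x
#'   terminal classes), `no_path` (logical), `terminal_classes`,
#'   `terminal_labels`.
#' @export
compute_absorption <- function(kernel, terminal_labels) {
  P <- kernel$P
  ids <- kernel$cell_ids
  lab <- terminal_labels[ids]
  absorbing <- which(!is.na(lab))
  if (!length(absorbing)) abort("need at least one absorbing (terminal) cell.")
  transient <- which(is.na(lab))
  classes <- sort(unique(lab[absorbing]))

  Q <- P[transient, transient, drop = FALSE]
  R <- P[transient, absorbing, drop = FALSE]
  memb <- sparseMatrix(i = seq_along(absorbing),
                       j = match(lab[absorbing], classes),
                       x = 1,
                       dims = c(length(absorbing), length(classes)))
  Rc <- R %*% memb

  # reachability: transient cells that can reach an absorbing state
  supp <- igraph::graph_from_adjacency_matrix(drop0(P) != 0,
                                              mode = "directed")
  dist_to_abs <- igraph::distances(supp, v = igraph::V(supp)[absorbing],
                                   mode = "in")
  reachable_all <- apply(dist_to_abs, 2, function(x) any(is.finite(x)))
  ok <- reachable_all[transient]

  A <- matrix(NA_real_, length(transient), length(classes),
              dimnames = list(ids[transient], classes))
  if (any(ok)) {
    Qo <- Q[ok, ok, drop = FALSE]
    I <- Diagonal(nrow(Qo))
    sol <- Matrix::solve(I - Qo, Rc[ok, , drop = FALSE])
    A[ok, ] <- as.matrix(sol)
  }
  if (any(!ok)) {
    warn(sprintf("%d transient cells have no path to any absorbing state.",
                 sum(!ok)))
  }
  structure(list(absorption = A, no_path = setNames(!ok, ids[transient]),
                 terminal_classes = classes,
                 terminal_labels = setNames(lab, ids)),
            class = "fate_result")
}

#' @export
print.fate_result <- function(x, ...) {
  cat(sprintf("<fate_result> %d transient cells x %d terminal classes (%d without path)\n",
              nrow(x$absorption), ncol(x$absorption), sum(x$no_path)))
  invisible(x)
}

#' Sankey table and mean-absorption matrix
#'
#' Subsamples each initial class to at most `cap` cells (seeded, uniform —
#' absorption probabilities are biased by class sizes), then, for every
#' terminal class, ranks the subsampled transient cells by their
#' absorption probability into that class (ties broken by cell id for
#' determinism) and tabulates the initial-class identity of the top
#' `top_n` cells: the Sankey edge weights. Independently, the mean
#' absorption probability per (initial class, terminal class) pair is
#' computed over all subsampled cells.
#'
#' @param result A [compute_absorption()] result.
#' @param classes Initial classes of the transient cells: a
#'   [class_assignment] or tibble (`cell_id`, `class`).
#' @param cap Maximum cells per initial class after subsampling.
#' @param top_n Number of top absorbed cells reported per terminal class.
#' @param seed Subsampling seed.
#' @return A list of class `fate_summary`: `sankey` tibble
#'   (`source_class`, `target_class`, `weight`), `mean_absorption`
#'   (initial x terminal matrix), `n_subsampled` per class, `cap`,
#'   `top_n`, `seed`.
#' @export
summarize_fates <- function(result, classes, cap = 1000, top_n = 100,
                            seed = 1L) {
  if (cap < top_n) abort("`cap` must be >= `top_n`.")
  cl_tbl <- if (inherits(classes, "class_assignment")) classes$cells
    else as_tibble(classes)
  A <- result$absorption
  A <- A[!result$no_path[rownames(A)], , drop = FALSE]
  cls <- cl_tbl$class[match(rownames(A), cl_tbl$cell_id)]
  if (anyNA(cls)) abort("every transient cell needs an initial class.")

  keep <- withr::with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(A)), cls), function(idx) {
      if (length(idx) > cap) sort(sample(idx, cap)) else idx
    }), use.names = FALSE)
  })
  A <- A[keep, , drop = FALSE]
  cls <- cls[keep]

  init_classes <- sort(unique(cls))
  sankey <- list()
  for (tc in colnames(A)) {
    ord <- order(-A[, tc], rownames(A))
    nn <- min(top_n, nrow(A))
    if (nn < top_n) {
      inform(sprintf("terminal class '%s': only %d candidates.", tc, nn))
    }
    top <- cls[ord[seq_len(nn)]]
    cnt <- table(factor(top, levels = init_classes))
    sankey[[tc]] <- tibble(source_class = init_classes,
                           target_class = tc,
                           weight = as.integer(cnt))
  }
  sankey <- bind_rows(sankey)
  mean_abs <- t(vapply(init_classes, function(ic)
    colMeans(A[cls == ic, , drop = FALSE]), numeric(ncol(A))))
  structure(list(sankey = sankey, mean_absorption = mean_abs,
                 n_subsampled = table(cls), cap = cap, top_n = top_n,
                 seed = seed),
            class = "fate_summary")
}
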