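#' Steady-state RNA velocity estimate
#'
#' For each gene, the degradation-to-splicing ratio `gamma_hat` is fitted
#' as the zero-intercept slope of unspliced on spliced expression,
#' restricted to cells in the extreme spliced quantiles (bottom and top
#' `extreme_frac`), where the steady-state relation `u = (gamma/beta) s`
#' holds best. Velocity is the residual `v = u - gamma_hat * s`: positive
#' during induction, negative during repression. By default the
#' depth-normalized linear layers from [normalize_dataset()] are used;
#' `size_normalize = FALSE` fits on the raw layers (appropriate for
#' noise-free expected values, which carry no library-size variation).
#'
#' @param dataset An [expression_dataset()].
#' @param extreme_frac Fraction for each spliced tail used in the fit.
#' @param size_normalize Use the depth-normalized layers (default) rather
#'   than the raw spliced/unspliced matrices.
#' @return A list of class `velocity_field`: `gamma` tibble (`gene_id`,
#'   `gamma_hat`, `flagged`), `velocity` (dense genes x cells), and the
#'   matrices `u`, `s` the fit used.
#' @export
estimate_velocity <- function(dataset, extreme_frac = 0.05,
                              size_normalize = TRUE) {
  if (size_normalize) {
    s <- dataset$layers$norm_spliced %||%
      abort("run `normalize_dataset()` first: missing `norm_spliced` layer.")
    u <- dataset$layers$norm_unspliced
  } else {
    s <- dataset$spliced
    u <- dataset$unspliced
  }
  s <- as.matrix(s)
  u <- as.matrix(u)
  n <- ncol(s)
  n_tail <- max(1L, ceiling(extreme_frac * n))
  gamma_hat <- numeric(nrow(s))
  flagged <- logical(nrow(s))
  for (g in seq_len(nrow(s))) {
    sg <- s[g, ]
    ug <- u[g, ]
    if (all(ug == 0) || all(sg == 0)) {
      gamma_hat[g] <- 0
      flagged[g] <- TRUE
      next
    }
    ord <- order(sg)
    idx <- c(head(ord, n_tail), tail(ord, n_tail))
    denom <- sum(sg[idx]^2)
    gamma_hat[g] <- if (denom > 0) max(sum(ug[idx] * sg[idx]) / denom, 0)
      else 0
  }
  velocity <- u - gamma_hat * s
  structure(list(
    gamma = tibble(gene_id = rownames(s), gamma_hat = gamma_hat,
                   flagged = flagged),
    velocity = velocity, u = u, s = s),
    class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("<velocity_field> %d genes x %d cells; median gamma_hat %.3f\n",
              nrow(x$velocity), ncol(x$velocity),
              median(x$gamma$gamma_hat)))
  invisible(x)
}

#' Score progenitor-like cells for automatic root selection
#'
#' Mean log-normalized expression of the configured progenitor markers
#' (cycling/germinal-zone analogues); the top-scoring fraction of cells is
#' used as the root set when none is supplied to [compute_latent_time()].
#'
#' @param dataset A normalized [expression_dataset()].
#' @param markers Progenitor marker gene identifiers.
#' @param top_frac Fraction of cells to return as roots.
#' @return Character vector of root cell ids, highest score first.
#' @export
score_roots <- function(dataset, markers, top_frac = 0.02) {
  lognorm <- dataset$layers$lognorm %||%
    abort("run `normalize_dataset()` first: missing `lognorm` layer.")
  markers <- intersect(markers, rownames(lognorm))
  if (!length(markers)) abort("no progenitor markers found in the dataset.")
  score <- Matrix::colMeans(lognorm[markers, , drop = FALSE])
  n_root <- max(1L, ceiling(top_frac * length(score)))
  names(sort(score, decreasing = TRUE))[seq_len(n_root)]
}

#' Root-anchored latent time on the neighbour graph
#'
#' A per-cell pseudotemporal coordinate in [0, 1]: the geodesic
#' (shortest-path) distance from the root set along the symmetrized
#' neighbour graph, with edges weighted by Euclidean PC distance, min-max
#' rescaled. Root cells get time 0. Because the distances rescale
#' uniformly, the result is invariant to a global rescaling of the PC
#' coordinates.
#'
#' With explicit `roots`, cells in graph components containing no root are
#' unreachable and get time 1 with a warning. With automatic root scoring
#' (`dataset` + `root_markers`), roots are selected per connected
#' component — every branch carries its own progenitor-like cells — and
#' distances are min-max rescaled within each component.
#'
#' @param graph A [build_bbknn_graph()] result.
#' @param roots Character vector of root cell ids; if `NULL`, supply
#'   `dataset` and `root_markers` for automatic scoring via [score_roots()].
#' @param dataset,root_markers Used only for automatic root selection.
#' @param top_frac Fraction of top-scoring cells used as automatic roots.
#' @return Named numeric vector of latent times in `[0, 1]`.
#' @export
compute_latent_time <- function(graph, roots = NULL, dataset = NULL,
                                root_markers = NULL, top_frac = 0.02) {
  auto <- is.null(roots)
  if (auto && (is.null(dataset) || is.null(root_markers))) {
    abort(paste("empty root set: supply `roots`, or `dataset` +",
                "`root_markers` to enable automatic root scoring."))
  }
  w <- pmax(graph$edges$dist, 1e-12)
  g <- igraph::graph_from_data_frame(
    data.frame(from = graph$edges$from, to = graph$edges$to, weight = w),
    directed = FALSE, vertices = graph$cell_ids)
  g <- igraph::simplify(g, edge.attr.comb = "min")
  comp <- igraph::components(g)$membership[graph$cell_ids]

  if (auto) {
    lognorm <- dataset$layers$lognorm %||%
      abort("run `normalize_dataset()` first: missing `lognorm` layer.")
    markers <- intersect(root_markers, rownames(lognorm))
    if (!length(markers)) abort("no progenitor markers found in the dataset.")
    score <- Matrix::colMeans(lognorm[markers, graph$cell_ids,
                                      drop = FALSE])
    roots <- unlist(lapply(split(graph$cell_ids, comp), function(ids) {
      n_root <- max(1L, ceiling(top_frac * length(ids)))
      ids[order(score[ids], decreasing = TRUE)][seq_len(n_root)]
    }), use.names = FALSE)
  } else {
    roots <- intersect(roots, graph$cell_ids)
    if (!length(roots)) abort("none of the supplied roots are in the graph.")
  }

  d <- igraph::distances(g, v = roots, to = igraph::V(g))
  dmin <- apply(d, 2, min)
  unreachable <- !is.finite(dmin)
  if (any(unreachable)) {
    warn(sprintf("%d cells unreachable from the roots; latent time set to 1.",
                 sum(unreachable)))
  }
  lt <- rep(1, length(dmin))
  # min-max rescale within each component that contains a root
  for (k in unique(comp)) {
    idx <- which(comp == k & !unreachable)
    if (!length(idx)) next
    rng <- range(dmin[idx])
    lt[idx] <- if (diff(rng) > 0) (dmin[idx] - rng[1]) / diff(rng) else 0
  }
  setNames(lt, graph$cell_ids)
}

#' Classify new-born neurons by the class-wise latent-time median
#'
#' Within each class the threshold is the empirical 0.5 quantile of latent
#' time (linear-interpolation convention, `stats::quantile` type 7); a cell
#' is new-born iff its latent time lies strictly below the threshold.
#' Classes of size 1 are never flagged (with a warning). The flags depend
#' only on the within-class rank of latent time.
#'
#' @param times Named per-cell latent times.
#' @param classes A [class_assignment] or a tibble with `cell_id`, `class`.
#' @return Tibble (`cell_id`, `class`, `latent_time`, `threshold`,
#'   `newborn`).
#' @export
classify_newborn <- function(times, classes) {
  cl_tbl <- if (inherits(classes, "class_assignment")) classes$cells
    else as_tibble(classes)
  tbl <- tibble(cell_id = names(times), latent_time = as.numeric(times)) %>%
    left_join(cl_tbl %>% select("cell_id", "class"), by = "cell_id")
  if (anyNA(tbl$class)) abort("every cell needs a class label.")
  singletons <- tbl %>% count(.data$class) %>% filter(n == 1)
  if (nrow(singletons)) {
    warn(sprintf("%d singleton class(es) never flagged as new-born.",
                 nrow(singletons)))
  }
  tbl %>%
    group_by(.data$class) %>%
    mutate(threshold = quantile(.data$latent_time, 0.5, type = 7),
           newborn = n() > 1 & .data$latent_time < .data$threshold) %>%
    ungroup()
}
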