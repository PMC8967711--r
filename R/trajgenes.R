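#' Holm-Sidak step-down multiple-testing correction
#'
#' With the p-values sorted ascending, the i-th adjusted value is
#' `max over j <= i of 1 - (1 - p_(j))^(m - j + 1)`, clipped to 1 and
#' mapped back to the original order. Guarantees `q >= p` and
#' monotonicity along the sorted order.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed; returned
#'   as NA and excluded from the family size).
#' @return Vector of adjusted q-values, same order as `p`.
#' @export
holm_sidak <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].")
  }
  q <- rep(NA_real_, length(p))
  obs <- which(!is.na(p))
  m <- length(obs)
  if (!m) return(q)
  ord <- order(p[obs])
  ps <- p[obs][ord]
  adj <- 1 - (1 - ps)^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  q[obs[ord]] <- adj
  q
}

#' Trajectory gene screen: regression on latent time
#'
#' Per class and per gene, ordinary least squares of normalized (depth-
#' normalized, log1p; not z-scaled, so slopes stay interpretable)
#' expression on latent time. Two-tailed p-values come from the t
#' distribution with n - 2 degrees of freedom; constant genes get slope 0
#' and p = 1 by convention. q-values are Holm-Sidak-adjusted across all
#' genes within each class (set `family = "global"` to correct across all
#' classes jointly). Direction: `activated` if slope > 0 and q < alpha,
#' `inactivated` if slope < 0 and q < alpha, else `null`.
#'
#' @param dataset A normalized [expression_dataset()].
#' @param times Named per-cell latent times.
#' @param classes A [class_assignment] or tibble (`cell_id`, `class`).
#' @param alpha Significance threshold on q.
#' @param family `"class"` (default) or `"global"` correction family.
#' @param min_cells Classes with fewer cells are skipped with a warning;
#'   classes whose latent time has zero variance are skipped too.
#' @return A tibble of class `traj_gene_table`: `class`, `gene_id`,
#'   `slope`, `intercept`, `p_value`, `q_value`, `direction`, `n_cells`.
#' @export
regress_on_latent_time <- function(dataset, times, classes, alpha = 0.05,
                                   family = c("class", "global"),
                                   min_cells = 3) {
  family <- match.arg(family)
  lognorm <- dataset$layers$lognorm %||%
    abort("run `normalize_dataset()` first: missing `lognorm` layer.")
  cl_tbl <- if (inherits(classes, "class_assignment")) classes$cells
    else as_tibble(classes)
  cells <- intersect(names(times), colnames(lognorm))
  cls <- cl_tbl$class[match(cells, cl_tbl$cell_id)]

  res <- list()
  for (k in sort(unique(cls))) {
    ci <- cells[which(cls == k)]
    tt <- times[ci]
    if (length(ci) < min_cells) {
      warn(sprintf("class '%s' has < %d cells; skipped.", k, min_cells))
      next
    }
    if (var(tt) == 0) {
      warn(sprintf("class '%s' has zero latent-time variance; skipped.", k))
      next
    }
    fit <- ols_by_gene(as.matrix(lognorm[, ci, drop = FALSE]), tt)
    res[[k]] <- tibble(class = k, gene_id = rownames(lognorm),
                       slope = fit$slope, intercept = fit$intercept,
                       p_value = fit$p, n_cells = length(ci))
  }
  out <- bind_rows(res)
  if (!nrow(out)) abort("no class could be analysed.")
  if (family == "class") {
    out <- out %>% group_by(.data$class) %>%
      mutate(q_value = holm_sidak(.data$p_value)) %>% ungroup()
  } else {
    out$q_value <- holm_sidak(out$p_value)
  }
  out <- out %>%
    mutate(direction = dplyr::case_when(
      .data$q_value < alpha & .data$slope > 0 ~ "activated",
      .data$q_value < alpha & .data$slope < 0 ~ "inactivated",
      TRUE ~ "null")) %>%
    select("class", "gene_id", "slope", "intercept", "p_value",
           "q_value", "direction", "n_cells")
  class(out) <- c("traj_gene_table", class(out))
  attr(out, "alpha") <- alpha
  out
}

# vectorized per-gene simple OLS of rows of y (genes x cells) on x
ols_by_gene <- function(y, x) {
  n <- length(x)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  ym <- rowMeans(y)
  slope <- as.numeric(y %*% xc) / sxx
  intercept <- ym - slope * mean(x)
  fitted_ss <- slope^2 * sxx
  tot_ss <- rowSums(y^2) - n * ym^2
  rss <- pmax(tot_ss - fitted_ss, 0)
  df <- n - 2
  se <- sqrt(rss / df / sxx)
  tstat <- ifelse(se > 0, slope / se, 0)
  p <- 2 * pt(abs(tstat), df = df, lower.tail = FALSE)
  const <- tot_ss < 1e-12
  slope[const] <- 0
  p[const] <- 1
  # perfect fit, non-constant gene: p -> 0
  p[!const & se == 0] <- 0
  list(slope = unname(slope), intercept = unname(intercept),
       p = unname(p))
}

#' Jaccard index of two gene sets
#'
#' `|A intersect B| / |A union B|`; 0 when both sets are empty.
#'
#' @param set_a,set_b Character vectors (duplicates ignored).
#' @return A number in `[0, 1]`.
#' @export
jaccard_sets <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  u <- length(union(set_a, set_b))
  if (u == 0) return(0)
  length(intersect(set_a, set_b)) / u
}

#' Pairwise Jaccard matrices of trajectory gene sets
#'
#' For each direction (`activated`, `inactivated`), extracts the per-class
#' significant gene sets from a [regress_on_latent_time()] table and
#' computes the class x class Jaccard matrix.
#'
#' @param table A `traj_gene_table`.
#' @return Named list of two class x class matrices.
#' @export
trajectory_jaccard <- function(table) {
  cls <- sort(unique(table$class))
  out <- lapply(c(activated = "activated", inactivated = "inactivated"),
                function(dir) {
    sets <- lapply(cls, function(k)
      table$gene_id[table$class == k & table$direction == dir])
    names(sets) <- cls
    m <- outer(seq_along(cls), seq_along(cls),
               Vectorize(function(i, j) jaccard_sets(sets[[i]], sets[[j]])))
    dimnames(m) <- list(cls, cls)
    m
  })
  out
}
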