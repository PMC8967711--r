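#' Tidy a QC result
#'
#' @param x A `qc_result` from [filter_cells()].
#' @param ... Ignored.
#' @return The per-cell QC report tibble.
#' @method tidy qc_result
#' @export
tidy.qc_result <- function(x, ...) x$report

#' @rdname tidy.qc_result
#' @method glance qc_result
#' @export
glance.qc_result <- function(x, ...) {
  tibble(n_cells = nrow(x$report), n_pass = sum(x$report$pass),
         n_removed = sum(!x$report$pass),
         min_genes_detected = x$thresholds$min_genes_detected,
         max_ribosomal_fraction = x$thresholds$max_ribosomal_fraction,
         max_mitochondrial_fraction = x$thresholds$max_mitochondrial_fraction)
}

#' Tidy a class assignment
#'
#' @param x A `class_assignment` from [cluster_and_merge()].
#' @param ... Ignored.
#' @return Per-cell tibble (`cell_id`, `cluster`, `class`).
#' @method tidy class_assignment
#' @export
tidy.class_assignment <- function(x, ...) x$cells

#' @rdname tidy.class_assignment
#' @method glance class_assignment
#' @export
glance.class_assignment <- function(x, ...) {
  tibble(n_cells = nrow(x$cells),
         n_clusters = length(unique(x$cells$cluster)),
         n_classes = length(unique(x$cells$class)),
         merge_height = x$merge_height,
         resolution = x$resolution)
}

#' Tidy a velocity field
#'
#' @param x A `velocity_field` from [estimate_velocity()].
#' @param ... Ignored.
#' @return Per-gene tibble (`gene_id`, `gamma_hat`, `flagged`).
#' @method tidy velocity_field
#' @export
tidy.velocity_field <- function(x, ...) x$gamma

#' @rdname tidy.velocity_field
#' @method glance velocity_field
#' @export
glance.velocity_field <- function(x, ...) {
  tibble(n_genes = nrow(x$gamma), n_cells = ncol(x$velocity),
         n_flagged = sum(x$gamma$flagged),
         median_gamma = median(x$gamma$gamma_hat))
}

#' Tidy a fate result
#'
#' @param x A `fate_result` from [compute_absorption()].
#' @param ... Ignored.
#' @return Long tibble (`cell_id`, `terminal_class`, `probability`).
#' @method tidy fate_result
#' @export
tidy.fate_result <- function(x, ...) {
  as_tibble(x$absorption, rownames = "cell_id") %>%
    tidyr::pivot_longer(-"cell_id", names_to = "terminal_class",
                        values_to = "probability")
}

#' @rdname tidy.fate_result
#' @method glance fate_result
#' @export
glance.fate_result <- function(x, ...) {
  tibble(n_transient = nrow(x$absorption),
         n_terminal_classes = ncol(x$absorption),
         n_no_path = sum(x$no_path))
}

#' Tidy a fate summary
#'
#' @param x A `fate_summary` from [summarize_fates()].
#' @param ... Ignored.
#' @return The Sankey edge tibble.
#' @method tidy fate_summary
#' @export
tidy.fate_summary <- function(x, ...) x$sankey

#' Tidy a homology table
#'
#' @param x A `homology_table` from [class_homology()].
#' @param ... Ignored.
#' @return Long tibble (`class_a`, `class_b`, `mnn_count`, `correlation`).
#' @method tidy homology_table
#' @export
tidy.homology_table <- function(x, ...) {
  long <- as_tibble(x$mnn_counts, rownames = "class_a") %>%
    tidyr::pivot_longer(-"class_a", names_to = "class_b",
                        values_to = "mnn_count")
  corr <- as_tibble(x$correlation, rownames = "class_a") %>%
    tidyr::pivot_longer(-"class_a", names_to = "class_b",
                        values_to = "correlation")
  left_join(long, corr, by = c("class_a", "class_b"))
}

#' Heatmap of mean absorption probabilities
#'
#' @param object A `fate_summary`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot fate_summary
#' @export
autoplot.fate_summary <- function(object, ...) {
  df <- as_tibble(object$mean_absorption, rownames = "initial_class") %>%
    tidyr::pivot_longer(-"initial_class", names_to = "terminal_class",
                        values_to = "mean_absorption")
  ggplot(df, aes(.data$terminal_class, .data$initial_class,
                 fill = .data$mean_absorption)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "darkred") +
    labs(x = "terminal class", y = "initial class",
         fill = "mean\nabsorption") +
    theme_minimal()
}

#' Heatmaps of cross-species homology
#'
#' @param object A `homology_table`.
#' @param metric `"mnn"` or `"correlation"`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot homology_table
#' @export
autoplot.homology_table <- function(object,
                                    metric = c("mnn", "correlation"),
                                    ...) {
  metric <- match.arg(metric)
  df <- tidy.homology_table(object)
  if (metric == "mnn") {
    ggplot(df, aes(.data$class_b, .data$class_a, fill = .data$mnn_count)) +
      geom_tile() +
      scale_fill_gradient(low = "white", high = "steelblue") +
      labs(x = "species B class", y = "species A class",
           fill = "MNN pairs") +
      theme_minimal()
  } else {
    ggplot(df, aes(.data$class_b, .data$class_a,
                   fill = .data$correlation)) +
      geom_tile() +
      scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick",
                           midpoint = 0) +
      labs(x = "species B class", y = "species A class",
           fill = "Pearson r") +
      theme_minimal()
  }
}

#' Volcano-style plot of a trajectory gene screen
#'
#' @param object A `traj_gene_table`.
#' @param ... Ignored.
#' @return A ggplot object, faceted by class.
#' @method autoplot traj_gene_table
#' @export
autoplot.traj_gene_table <- function(object, ...) {
  df <- as_tibble(object) %>%
    mutate(neg_log_q = -log10(pmax(.data$q_value, 1e-300)))
  ggplot(df, aes(.data$slope, .data$neg_log_q,
                 colour = .data$direction)) +
    geom_point(size = 0.5) +
    facet_wrap(~class) +
    labs(x = "latent-time slope", y = "-log10 q") +
    theme_minimal()
}
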