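# Shared fixtures, memoised so expensive objects are built once per run.
.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# small two-species simulation: fast, no planted QC artifacts
small_sim <- function() {
  memo("small_sim", suppressWarnings(generate_dataset(
    trajectory_design(cells_per_branch = 60, terminal_cells_per_class = 0,
                      n_genes = 400, fraction_low_quality = 0, seed = 42))))
}

# the bundled study-scale simulation (default design) and full pipeline run
demo_run <- function() {
  memo("demo_run", suppressWarnings(
    run_pipeline(seed = 7, out_dir = file.path(tempdir(), "fatelink_demo"))))
}

# hand-built tiny dataset: `mat` genes x cells (dense ok)
toy_dataset <- function(spliced, unspliced = spliced, n_mito = 0,
                        n_ribo = 0, batch = NULL) {
  ng <- nrow(spliced)
  gene_id <- rownames(spliced) %||% sprintf("G%04d", seq_len(ng))
  if (n_mito > 0) gene_id[seq_len(n_mito)] <- sprintf("MT-%02d", seq_len(n_mito))
  if (n_ribo > 0) {
    gene_id[n_mito + seq_len(n_ribo)] <- sprintf("RPS%02d", seq_len(n_ribo))
  }
  cells <- tibble::tibble(
    cell_id = sprintf("c%03d", seq_len(ncol(spliced))),
    batch = batch %||% rep("b1", ncol(spliced)))
  genes <- tibble::tibble(gene_id = gene_id,
                          is_mito = seq_len(ng) <= n_mito,
                          is_ribo = seq_len(ng) > n_mito &
                            seq_len(ng) <= n_mito + n_ribo)
  dimnames(spliced) <- dimnames(unspliced) <- list(gene_id, cells$cell_id)
  expression_dataset(spliced, unspliced, cells, genes)
}

`%||%` <- rlang::`%||%`

# brute-force per-batch kNN oracle (independent of the implementation)
oracle_bbknn_edges <- function(pcs, batches, k) {
  n <- nrow(pcs)
  out <- list()
  for (i in seq_len(n)) {
    for (b in unique(batches)) {
      cand <- setdiff(which(batches == b), i)
      if (!length(cand)) next
      d <- sapply(cand, function(j) sqrt(sum((pcs[i, ] - pcs[j, ])^2)))
      ord <- cand[order(d)][seq_len(min(k, length(cand)))]
      out[[length(out) + 1]] <- data.frame(from = i, to = ord)
    }
  }
  ed <- do.call(rbind, out)
  ed[order(ed$from, ed$to), ]
}

# brute-force cross-species MNN oracle
oracle_mnn <- function(pcs, is_a, k) {
  ia <- which(is_a); ib <- which(!is_a)
  nn_of <- function(i, cand, kk) {
    d <- sapply(cand, function(j) sum((pcs[i, ] - pcs[j, ])^2))
    cand[order(d)][seq_len(min(kk, length(cand)))]
  }
  pairs <- list()
  for (a in ia) {
    for (b in nn_of(a, ib, k)) {
      if (a %in% nn_of(b, ia, k)) {
        pairs[[length(pairs) + 1]] <- c(a, b)
      }
    }
  }
  if (!length(pairs)) return(matrix(integer(0), 0, 2))
  m <- do.call(rbind, pairs)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# Monte-Carlo absorption oracle: group walks by state, step until absorbed
mc_absorption <- function(P, terminal_class, n_walks, seed,
                          max_steps = 10000, starts = NULL) {
  # terminal_class: character vector, NA for transient states
  set.seed(seed)
  n <- nrow(P)
  classes <- sort(unique(terminal_class[!is.na(terminal_class)]))
  transient <- starts %||% which(is.na(terminal_class))
  out <- matrix(0, length(transient), length(classes),
                dimnames = list(NULL, classes))
  P <- as.matrix(P)
  for (ti in seq_along(transient)) {
    cur <- rep(transient[ti], n_walks)
    absorbed <- rep(NA_integer_, n_walks)
    for (step in seq_len(max_steps)) {
      alive <- which(is.na(absorbed))
      if (!length(alive)) break
      tab <- split(alive, cur[alive])
      for (s in names(tab)) {
        idx <- tab[[s]]
        nxt <- sample.int(n, length(idx), replace = TRUE,
                          prob = P[as.integer(s), ])
        cur[idx] <- nxt
        done <- !is.na(terminal_class[nxt])
        absorbed[idx[done]] <- match(terminal_class[nxt[done]], classes)
      }
    }
    stopifnot(!anyNA(absorbed))
    out[ti, ] <- tabulate(absorbed, length(classes)) / n_walks
  }
  rownames(out) <- rownames(P)[transient]
  out
}

# brute-force Holm-Sidak step-down oracle, written independently:
# literal sequential rejection bookkeeping rather than the closed form
oracle_holm_sidak <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  running_max <- 0
  for (i in seq_len(m)) {
    adj <- 1 - (1 - p[ord[i]])^(m - i + 1)
    running_max <- max(running_max, adj)
    q[ord[i]] <- min(running_max, 1)
  }
  q
}
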