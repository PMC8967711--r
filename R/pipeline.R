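#' Default pipeline configuration
#'
#' Nested list mirroring the structured YAML config accepted by
#' [run_pipeline()]. Any subset of keys can be overridden; unknown keys
#' raise a configuration error naming the offending path.
#'
#' @return Named nested list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    design = list(),      # arguments to trajectory_design()
    kinetics = list(),    # arguments to kinetic_params()
    qc = list(min_genes_detected = 800, max_ribosomal_fraction = 0.40,
              max_mitochondrial_fraction = 0.15,
              min_cell_probability = 0.99),
    inhibitory = list(min_failing_genes_to_remove = 2,
                      exempt_batches = character()),
    cluster = list(n_hvg = 12000, n_pcs = 100, k_per_batch = 3,
                   resolution = 10, merge_distance = "auto",
                   scale_clip = 10),
    velocity = list(extreme_frac = 0.05, root_top_frac = 0.02),
    fate = list(weight = 0.5, cap = 1000, top_n = 100),
    xspecies = list(k = 25, n_pcs = 100),
    trajgenes = list(alpha = 0.05, family = "class")
  )
}

load_config <- function(config) {
  if (is.null(config)) return(default_config())
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- default_config()
  check_keys <- function(given, known, path = "") {
    bad <- setdiff(names(given), names(known))
    if (length(bad)) {
      abort(sprintf("unknown config key: %s%s", path, bad[1]))
    }
  }
  check_keys(config, defaults)
  for (k in intersect(names(config),
                      c("qc", "inhibitory", "cluster", "velocity",
                        "fate", "xspecies", "trajgenes"))) {
    check_keys(config[[k]], defaults[[k]], paste0(k, "/"))
  }
  modifyList(defaults, config)
}

pipeline_stages <- function() {
  c("simulate", "qc", "cluster", "velocity", "fate", "xspecies",
    "trajgenes")
}

# deterministic per-stage substreams derived from the root seed
stage_seed <- function(seed, stage) {
  (as.integer(seed) * 97L +
     match(stage, pipeline_stages()) * 1009L) %% 2147483562L
}

#' Run the full pipeline on a simulated experiment
#'
#' Executes the stages in order: `simulate` (synthetic two-species data),
#' `qc` (droplet filters per species), `cluster` (normalize, HVG, PCA,
#' BBKNN, Leiden, inhibitory-cluster selection, re-embedding and merge into
#' classes, per species), `velocity` (steady-state velocity, latent time,
#' new-born flags on species A), `fate` (developmental + terminal Markov
#' chain, absorption, Sankey and mean-absorption outputs), `xspecies`
#' (orthologue merge, MNN pairs, class homology) and `trajgenes`
#' (latent-time regression screen and Jaccard matrices). A subset of
#' stages can be selected; later stages recompute the prerequisites they
#' need from the held results. Failures halt with the failing stage named;
#' earlier outputs stay on disk.
#'
#' @param config `NULL` (defaults), a nested list, or a YAML file path.
#'   See [default_config()].
#' @param out_dir Output directory; one subdirectory per stage.
#' @param stages Stages to run (in pipeline order).
#' @param seed Root seed overriding `config$seed`. All stage seeds are
#'   derived from it as fixed substreams.
#' @return A list of class `pipeline_run` with the in-memory results per
#'   stage and `manifest` (config snapshot, seeds, outputs with checksums,
#'   wall-clock per stage). The manifest is written to
#'   `out_dir/manifest.yaml`.
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("fatelink_run_"),
                         stages = pipeline_stages(), seed = NULL) {
  cfg <- load_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  stages <- match.arg(stages, pipeline_stages(), several.ok = TRUE)
  stages <- pipeline_stages()[pipeline_stages() %in% stages]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- new.env(parent = emptyenv())
  manifest <- list(config = cfg, seeds = list(), stages = list())

  run_stage <- function(stage, fun) {
    t0 <- proc.time()[["elapsed"]]
    sdir <- file.path(out_dir, stage)
    dir.create(sdir, showWarnings = FALSE)
    manifest$seeds[[stage]] <<- stage_seed(cfg$seed, stage)
    res <- tryCatch(fun(sdir),
                    error = function(e) {
                      abort(sprintf("pipeline stage '%s' failed: %s",
                                    stage, conditionMessage(e)))
                    })
    outs <- list.files(sdir, recursive = TRUE, full.names = TRUE)
    rel <- file.path(stage, list.files(sdir, recursive = TRUE))
    manifest$stages[[stage]] <<- list(
      outputs = as.list(setNames(unname(tools::md5sum(outs)), rel)),
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 2))
    res
  }

  need_sim <- function() {
    if (is.null(state$sim)) {
      state$sim <- simulate_stage(cfg, NULL)
    }
    state$sim
  }
  need_qc <- function() {
    if (is.null(state$qc)) state$qc <- qc_stage(cfg, need_sim(), NULL)
    state$qc
  }
  need_cluster <- function() {
    if (is.null(state$cluster)) {
      state$cluster <- cluster_stage(cfg, need_qc(), NULL)
    }
    state$cluster
  }
  need_velocity <- function() {
    if (is.null(state$velocity)) {
      state$velocity <- velocity_stage(cfg, need_cluster(), NULL)
    }
    state$velocity
  }

  for (stage in stages) {
    switch(stage,
      simulate = {
        state$sim <- run_stage("simulate", function(d)
          simulate_stage(cfg, d))
      },
      qc = {
        need_sim()
        state$qc <- run_stage("qc", function(d) qc_stage(cfg, state$sim, d))
      },
      cluster = {
        need_qc()
        state$cluster <- run_stage("cluster", function(d)
          cluster_stage(cfg, state$qc, d))
      },
      velocity = {
        need_cluster()
        state$velocity <- run_stage("velocity", function(d)
          velocity_stage(cfg, state$cluster, d))
      },
      fate = {
        need_cluster()
        state$fate <- run_stage("fate", function(d)
          fate_stage(cfg, state$sim, state$qc, state$cluster, d))
      },
      xspecies = {
        need_cluster()
        state$xspecies <- run_stage("xspecies", function(d)
          xspecies_stage(cfg, state$sim, state$cluster, d))
      },
      trajgenes = {
        need_velocity()
        state$trajgenes <- run_stage("trajgenes", function(d)
          trajgenes_stage(cfg, state$cluster, state$velocity, d))
      })
  }
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  structure(list(simulate = state$sim, qc = state$qc,
                 cluster = state$cluster, velocity = state$velocity,
                 fate = state$fate, xspecies = state$xspecies,
                 trajgenes = state$trajgenes, manifest = manifest,
                 out_dir = out_dir),
            class = "pipeline_run")
}

simulate_stage <- function(cfg, dir) {
  design <- do.call(trajectory_design,
                    modifyList(cfg$design,
                               list(seed = stage_seed(cfg$seed,
                                                      "simulate"))))
  kinetics <- do.call(kinetic_params, cfg$kinetics)
  sim <- generate_dataset(design, kinetics)
  if (!is.null(dir)) write_simulation(sim, dir)
  sim$design <- design
  sim
}

qc_stage <- function(cfg, sim, dir) {
  thr <- do.call(qc_thresholds, cfg$qc)
  out <- lapply(sim$datasets, filter_cells, thresholds = thr)
  if (!is.null(dir)) {
    for (sp in names(out)) {
      readr::write_tsv(out[[sp]]$report,
                       file.path(dir, paste0(sp, "_qc_report.tsv")))
    }
  }
  out
}

# per-species: embed, fine-cluster, drop non-inhibitory clusters, re-embed,
# merge to classes (the paper's two-pass structure)
embed_and_classify <- function(ds, cfg, rule, seed) {
  ds <- normalize_dataset(ds)
  hvg <- select_hvg(ds, n_hvg = cfg$cluster$n_hvg)
  pca <- run_pca(ds, hvg, n_pcs = cfg$cluster$n_pcs,
                 clip = cfg$cluster$scale_clip)
  graph <- build_bbknn_graph(pca, ds$cells$batch,
                             k = cfg$cluster$k_per_batch)
  fine <- cluster_and_merge(graph, ds, resolution = cfg$cluster$resolution,
                            merge_distance = 0, seed = seed)
  sel <- select_inhibitory_clusters(ds, fine, rule)
  ds2 <- sel$dataset
  hvg2 <- select_hvg(ds2, n_hvg = cfg$cluster$n_hvg)
  pca2 <- run_pca(ds2, hvg2, n_pcs = cfg$cluster$n_pcs,
                  clip = cfg$cluster$scale_clip)
  graph2 <- build_bbknn_graph(pca2, ds2$cells$batch,
                              k = cfg$cluster$k_per_batch)
  classes <- cluster_and_merge(graph2, ds2,
                               resolution = cfg$cluster$resolution,
                               merge_distance = cfg$cluster$merge_distance,
                               seed = seed + 1L)
  list(dataset = ds2, hvg = hvg2, pca = pca2, graph = graph2,
       classes = classes, selection_log = sel$log)
}

cluster_stage <- function(cfg, qc, dir) {
  rule <- inhibitory_rule(
    min_failing_genes_to_remove = cfg$inhibitory$min_failing_genes_to_remove,
    exempt_batches = cfg$inhibitory$exempt_batches)
  seed <- stage_seed(cfg$seed, "cluster")
  out <- list()
  for (sp in names(qc)) {
    ds <- qc[[sp]]$dataset
    dev <- subset_dataset(ds, cells = ds$cells$role == "developmental")
    rule_sp <- rule
    if (sp != "speciesA") {
      rule_sp$marker_genes <- paste0("B.", rule$marker_genes)
    }
    out[[sp]] <- embed_and_classify(dev, cfg, rule_sp, seed)
    if (!is.null(dir)) {
      readr::write_tsv(out[[sp]]$classes$cells,
                       file.path(dir, paste0(sp, "_classes.tsv")))
      readr::write_tsv(out[[sp]]$selection_log,
                       file.path(dir, paste0(sp, "_inhibitory_log.tsv")))
      if (!is.null(out[[sp]]$classes$dendrogram) &&
          requireNamespace("ape", quietly = TRUE)) {
        ape::write.tree(ape::as.phylo(out[[sp]]$classes$dendrogram),
                        file.path(dir, paste0(sp, "_dendrogram.nwk")))
      }
    }
  }
  out
}

velocity_stage <- function(cfg, cluster, dir) {
  ca <- cluster$speciesA
  ds <- ca$dataset
  field <- estimate_velocity(ds, extreme_frac = cfg$velocity$extreme_frac)
  prog <- grep("^PROG", rownames(ds$spliced), value = TRUE)
  times <- compute_latent_time(ca$graph, dataset = ds, root_markers = prog,
                               top_frac = cfg$velocity$root_top_frac)
  newborn <- classify_newborn(times, ca$classes)
  if (!is.null(dir)) {
    readr::write_tsv(newborn, file.path(dir, "latent_time.tsv"))
    readr::write_tsv(field$gamma, file.path(dir, "gamma.tsv"))
  }
  list(field = field, times = times, newborn = newborn)
}

fate_stage <- function(cfg, sim, qc, cluster, dir) {
  ca <- cluster$speciesA
  qa <- qc$speciesA$dataset
  dev_ids <- ca$dataset$cells$cell_id
  term_ids <- qa$cells$cell_id[qa$cells$role == "terminal"]
  ds <- subset_dataset(qa, cells = qa$cells$cell_id %in%
                         c(dev_ids, term_ids))
  ds <- normalize_dataset(ds)
  hvg <- select_hvg(ds, n_hvg = cfg$cluster$n_hvg)
  pca <- run_pca(ds, hvg, n_pcs = cfg$cluster$n_pcs,
                 clip = cfg$cluster$scale_clip)
  graph <- build_bbknn_graph(pca, ds$cells$batch,
                             k = cfg$cluster$k_per_batch)
  field <- estimate_velocity(ds, extreme_frac = cfg$velocity$extreme_frac)
  kernel <- build_kernels(graph, field, pca, w = cfg$fate$weight)
  terminal_labels <- setNames(
    ifelse(ds$cells$role == "terminal", ds$cells$terminal_class,
           NA_character_),
    ds$cells$cell_id)
  res <- compute_absorption(kernel, terminal_labels)
  init <- ca$classes$cells
  summ <- summarize_fates(res, init, cap = cfg$fate$cap,
                          top_n = cfg$fate$top_n,
                          seed = stage_seed(cfg$seed, "fate"))
  if (!is.null(dir)) {
    readr::write_tsv(tidy.fate_result(res),
                     file.path(dir, "absorption.tsv"))
    readr::write_tsv(summ$sankey, file.path(dir, "sankey.tsv"))
    readr::write_tsv(as_tibble(summ$mean_absorption,
                               rownames = "initial_class"),
                     file.path(dir, "mean_absorption.tsv"))
  }
  list(kernel = kernel, result = res, summary = summ, graph = graph)
}

xspecies_stage <- function(cfg, sim, cluster, dir) {
  a <- cluster$speciesA
  b <- cluster$speciesB
  merged <- merge_species(a$dataset, b$dataset, sim$orthologues,
                          hvg_a = a$hvg, hvg_b = b$hvg)
  pairs <- find_mnn_pairs(merged, k = cfg$xspecies$k,
                          n_pcs = cfg$xspecies$n_pcs)
  hom <- class_homology(pairs, a$classes$cells, b$classes$cells, merged)
  if (!is.null(dir)) {
    readr::write_tsv(pairs, file.path(dir, "mnn_pairs.tsv"))
    readr::write_tsv(tidy.homology_table(hom),
                     file.path(dir, "homology.tsv"))
  }
  list(merged = merged, pairs = pairs, homology = hom)
}

trajgenes_stage <- function(cfg, cluster, velocity, dir) {
  ca <- cluster$speciesA
  tbl <- regress_on_latent_time(ca$dataset, velocity$times, ca$classes,
                                alpha = cfg$trajgenes$alpha,
                                family = cfg$trajgenes$family)
  jac <- trajectory_jaccard(tbl)
  if (!is.null(dir)) {
    readr::write_tsv(tbl, file.path(dir, "trajectory_genes.tsv"))
    for (nm in names(jac)) {
      readr::write_tsv(as_tibble(jac[[nm]], rownames = "class"),
                       file.path(dir, paste0("jaccard_", nm, ".tsv")))
    }
  }
  list(table = tbl, jaccard = jac)
}

#' @export
print.pipeline_run <- function(x, ...) {
  done <- names(Filter(Negate(is.null),
                       x[setdiff(names(x), c("manifest", "out_dir"))]))
  cat("<pipeline_run> stages held in memory:",
      paste(done, collapse = ", "), "\n")
  cat("  outputs under:", x$out_dir, "\n")
  invisible(x)
}
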