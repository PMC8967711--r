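#' Kinetic parameters for the two-state transcription model
#'
#' Each simulated gene follows the standard two-state kinetics used by RNA
#' velocity: transcription at rate `alpha` while the gene is "on" (a small
#' leak `leak * alpha` while off), splicing of unspliced into spliced
#' molecules at rate `beta`, and spliced degradation at rate `gamma`, all in
#' units of 1 / latent time. At steady state `u* = alpha/beta` and
#' `s* = alpha/gamma`, so the steady-state slope of unspliced on spliced is
#' `gamma/beta` — the quantity [estimate_velocity()] recovers.
#'
#' The per-role transcription rates set the relative expression budget of
#' the simulated library; they were chosen to give realistic mitochondrial
#' (~5%) and ribosomal (~20%) read fractions and >1,000 detected genes per
#' healthy cell.
#'
#' @param beta Splicing rate (shared across genes).
#' @param gamma_range Per-gene degradation rates are drawn uniformly from
#'   this range; kept away from `beta` so the ODE solution is non-degenerate.
#' @param leak Off-state transcription as a fraction of the on-state rate.
#' @param alpha_identity,alpha_activated,alpha_progenitor,alpha_marker,alpha_mito,alpha_ribo,alpha_hk_mean
#'   On-state transcription rates per gene role (housekeeping rates are drawn
#'   from a Gamma distribution with this mean).
#' @param nb_size Negative-binomial size (inverse overdispersion) for
#'   observed counts.
#' @param lib_mean,lib_sdlog Mean and log-sd of per-cell spliced library
#'   sizes (log-normal).
#' @param unspliced_ratio Unspliced library size as a fraction of spliced.
#'
#' @return A list of class `kinetic_params`.
#' @export
kinetic_params <- function(beta = 8,
                           gamma_range = c(5, 7.5),
                           leak = 0.02,
                           alpha_identity = 100,
                           alpha_activated = 60,
                           alpha_progenitor = 30,
                           alpha_marker = 50,
                           alpha_mito = 130,
                           alpha_ribo = 160,
                           alpha_hk_mean = 20,
                           nb_size = 10,
                           lib_mean = 8000,
                           lib_sdlog = 0.25,
                           unspliced_ratio = 0.25) {
  stopifnot(beta > 0, all(gamma_range > 0), leak >= 0, nb_size > 0,
            lib_mean > 0, unspliced_ratio > 0)
  structure(as.list(environment()), class = "kinetic_params")
}

#' Design of a synthetic two-species experiment
#'
#' Describes the branching differentiation experiment the generator
#' emulates: a set of inhibitory initial classes shared between two species,
#' one species-specific class that shares the transcriptional program of a
#' designated sister class plus a disjoint marker set (mirroring the
#' relationship between primate MGE_CRABP1/TAC3 and the ancestral
#' MGE_CRABP1/MAF class), one excitatory outgroup branch, and optional
#' terminal-class extensions used as absorbing states in fate mapping.
#'
#' @param shared_classes Inhibitory classes present in both species.
#' @param specific_class Species-A-only inhibitory class.
#' @param sister_class Shared class whose identity program the specific
#'   class co-expresses (must be in `shared_classes`).
#' @param excitatory_class Non-inhibitory outgroup branch (present in both
#'   species; GAD/DLX-analogue markers stay at leak level).
#' @param cells_per_branch Developmental cells simulated per branch per
#'   species.
#' @param terminal_cells_per_class Terminal ("adult") cells per inhibitory
#'   class appended to species A, with latent time near 1.
#' @param batches_per_species Number of developmental batches per species.
#' @param n_genes Total genes per species (filled up with housekeeping
#'   genes after the structured roles).
#' @param n_identity,n_activated,n_progenitor Genes per class-identity
#'   program, per class activated-along-trajectory set, and in the shared
#'   progenitor (inactivating) program.
#' @param orthologue_dropout Fraction of genes omitted from the generated
#'   one-to-one orthologue table.
#' @param fraction_low_quality Fraction of cells turned into planted
#'   low-quality cells by [plant_qc_artifacts()].
#' @param seed Integer seed; identical designs and seeds give byte-identical
#'   output.
#'
#' @return A list of class `trajectory_design`.
#' @export
trajectory_design <- function(shared_classes = c("MGE_CRABP1_MAF",
                                                 "LGE_MEIS2_PAX6",
                                                 "CGE_NR2F2",
                                                 "VMF_ZIC1"),
                              specific_class = "MGE_CRABP1_TAC3",
                              sister_class = "MGE_CRABP1_MAF",
                              excitatory_class = "Exc_EMX1",
                              cells_per_branch = 350,
                              terminal_cells_per_class = 250,
                              batches_per_species = 2,
                              n_genes = 1500,
                              n_identity = 30,
                              n_activated = 15,
                              n_progenitor = 20,
                              orthologue_dropout = 0.1,
                              fraction_low_quality = 0.08,
                              seed = 1L) {
  design <- structure(as.list(environment()), class = "trajectory_design")
  validate_design(design)
  design
}

validate_design <- function(design) {
  with(design, {
    if (length(shared_classes) < 1) {
      abort("invalid design: need at least one shared class.")
    }
    if (!is.null(specific_class) && !nzchar(specific_class)) {
      abort("invalid design: `specific_class` must be NULL or a class name.")
    }
    if (!is.null(specific_class) && !(sister_class %in% shared_classes)) {
      abort("invalid design: `sister_class` must be one of `shared_classes`.")
    }
    if (cells_per_branch < 2) {
      abort("invalid design: every branch needs at least 2 cells.")
    }
    if (fraction_low_quality < 0 || fraction_low_quality > 0.5) {
      abort("invalid design: `fraction_low_quality` must be in [0, 0.5].")
    }
    n_struct <- 6 + n_identity * (length(shared_classes) + 2 +
                                    (!is.null(specific_class))) +
      n_activated * (length(shared_classes) + 2) + n_progenitor + 13 + 40
    if (n_genes < n_struct) {
      abort(sprintf(
        "invalid design: `n_genes` (%d) smaller than structured genes (%d).",
        n_genes, n_struct))
    }
    invisible(NULL)
  })
}

## -- gene program table ------------------------------------------------------

#' @keywords internal
inhibitory_marker_genes <- function() {
  c("GAD1", "GAD2", "DLX1", "DLX2", "DLX5", "DLX6")
}

# One row per gene: role, owning class (NA for global roles), kinetic rates.
build_gene_table <- function(design, kinetics) {
  classes_a <- c(design$shared_classes, design$specific_class,
                 design$excitatory_class)
  inhib_a <- setdiff(classes_a, design$excitatory_class)

  rows <- list()
  rows$marker <- tibble(gene_id = inhibitory_marker_genes(),
                        role = "marker", class = NA_character_,
                        alpha = kinetics$alpha_marker)
  rows$identity <- tibble(
    gene_id = unlist(lapply(classes_a, function(cl)
      sprintf("%s_ID%02d", cl, seq_len(design$n_identity)))),
    role = "identity",
    class = rep(classes_a, each = design$n_identity),
    alpha = kinetics$alpha_identity)
  act_classes <- setdiff(classes_a, NULL)
  rows$activated <- tibble(
    gene_id = unlist(lapply(act_classes, function(cl)
      sprintf("%s_ACT%02d", cl, seq_len(design$n_activated)))),
    role = "activated",
    class = rep(act_classes, each = design$n_activated),
    alpha = kinetics$alpha_activated)
  rows$progenitor <- tibble(
    gene_id = sprintf("PROG%02d", seq_len(design$n_progenitor)),
    role = "progenitor", class = NA_character_,
    alpha = kinetics$alpha_progenitor)
  rows$mito <- tibble(gene_id = sprintf("MT-%02d", 1:13),
                      role = "mito", class = NA_character_,
                      alpha = kinetics$alpha_mito)
  rows$ribo <- tibble(gene_id = c(sprintf("RPS%02d", 1:20),
                                  sprintf("RPL%02d", 1:20)),
                      role = "ribo", class = NA_character_,
                      alpha = kinetics$alpha_ribo)
  genes <- bind_rows(rows)
  n_hk <- design$n_genes - nrow(genes)
  hk_alpha <- stats::rgamma(n_hk, shape = 2,
                            scale = kinetics$alpha_hk_mean / 2)
  genes <- bind_rows(genes, tibble(
    gene_id = sprintf("HK%04d", seq_len(n_hk)),
    role = "housekeeping", class = NA_character_,
    alpha = pmax(hk_alpha, 0.5)))
  genes$beta <- kinetics$beta
  genes$gamma <- runif(nrow(genes), kinetics$gamma_range[1],
                       kinetics$gamma_range[2])
  genes$is_mito <- genes$role == "mito"
  genes$is_ribo <- genes$role == "ribo"
  genes
}

# Per-branch schedule for one gene role: on-window and initial condition.
# init "on" means the gene was already on before t = 0 (starts at on-steady);
# init "leak" means it starts at the leak steady state.
gene_schedule <- function(genes, branch_class, design) {
  inhibitory <- branch_class != design$excitatory_class
  identity_on <- genes$role == "identity" &
    (genes$class %in% branch_class |
       (branch_class %in% (design$specific_class %||% character()) &
          genes$class %in% design$sister_class))
  on_all <- identity_on |
    genes$role %in% c("mito", "ribo", "housekeeping") |
    (genes$role == "marker" & inhibitory)
  t_on <- rep(0, nrow(genes))
  t_off <- rep(Inf, nrow(genes))
  init <- rep("leak", nrow(genes))
  init[on_all] <- "on"
  active <- on_all
  prog <- genes$role == "progenitor"
  t_off[prog] <- 0.15
  init[prog] <- "on"
  active[prog] <- TRUE
  act <- genes$role == "activated" & genes$class %in% branch_class
  t_on[act] <- 0.35
  active[act] <- TRUE
  # everything else: permanently off (leak only)
  t_on[!active] <- Inf
  list(t_on = t_on, t_off = t_off, init = init)
}

## -- two-state ODE solution --------------------------------------------------

# Propagate (u0, s0) for time tau under constant transcription rate alpha.
propagate_state <- function(u0, s0, alpha, beta, gamma, tau) {
  eb <- exp(-beta * tau)
  eg <- exp(-gamma * tau)
  u <- alpha / beta + (u0 - alpha / beta) * eb
  s <- s0 * eg + (alpha / gamma) * (1 - eg) +
    beta * (u0 - alpha / beta) * (eb - eg) / (gamma - beta)
  list(u = u, s = s)
}

#' Expected unspliced/spliced values under the two-state model
#'
#' Analytic solution of `u' = alpha(t) - beta u`, `s' = beta u - gamma s`
#' for a gene that is on during `[t_on, t_off)` (transcription `alpha`;
#' `leak * alpha` otherwise), evaluated at latent times `t`. Used by the
#' generator before noise is added and by tests as the noise-free oracle.
#'
#' @param t Vector of latent times in `[0, 1]`.
#' @param alpha,beta,gamma Kinetic rates.
#' @param t_on,t_off On-window (use `t_on = Inf` for a permanently off
#'   gene, `t_off = Inf` for no switch-off).
#' @param init `"on"` (gene at on-steady-state at `t = 0`; requires
#'   `t_on = 0`) or `"leak"` (leak steady state before `t_on`).
#' @param leak Off-state transcription fraction.
#' @return List with vectors `u` and `s`.
#' @export
expected_expression <- function(t, alpha, beta, gamma, t_on = 0,
                                t_off = Inf, init = "leak", leak = 0.02) {
  a_off <- leak * alpha
  u <- rep(a_off / beta, length(t))
  s <- rep(a_off / gamma, length(t))
  if (!is.finite(t_on) && init != "on") {
    return(list(u = u, s = s))
  }
  if (init == "on") t_on <- 0
  u0 <- if (init == "on") alpha / beta else a_off / beta
  s0 <- if (init == "on") alpha / gamma else a_off / gamma
  in_on <- t >= t_on & t < t_off
  if (any(in_on)) {
    st <- propagate_state(u0, s0, alpha, beta, gamma, t[in_on] - t_on)
    u[in_on] <- st$u
    s[in_on] <- st$s
  }
  past <- t >= t_off
  if (any(past)) {
    at_off <- propagate_state(u0, s0, alpha, beta, gamma, t_off - t_on)
    st <- propagate_state(at_off$u, at_off$s, a_off, beta, gamma,
                          t[past] - t_off)
    u[past] <- st$u
    s[past] <- st$s
  }
  list(u = u, s = s)
}

# Dense expected matrices (genes x cells) for one species.
expected_matrices <- function(genes, cell_class, cell_time, design,
                              kinetics) {
  n_g <- nrow(genes)
  n_c <- length(cell_time)
  U <- matrix(0, n_g, n_c)
  S <- matrix(0, n_g, n_c)
  for (cl in unique(cell_class)) {
    ci <- which(cell_class == cl)
    sched <- gene_schedule(genes, cl, design)
    for (g in seq_len(n_g)) {
      es <- expected_expression(cell_time[ci], genes$alpha[g],
                                genes$beta[g], genes$gamma[g],
                                sched$t_on[g], sched$t_off[g],
                                sched$init[g], kinetics$leak)
      U[g, ci] <- es$u
      S[g, ci] <- es$s
    }
  }
  dimnames(U) <- dimnames(S) <- list(genes$gene_id, NULL)
  list(U = U, S = S)
}

## -- sampling ----------------------------------------------------------------

sample_counts <- function(rel, lib_sizes, nb_size) {
  prop <- sweep(rel, 2, pmax(colSums(rel), 1e-12), "/")
  mu <- sweep(prop, 2, lib_sizes, "*")
  cnt <- matrix(rnbinom(length(mu), mu = mu, size = nb_size),
                nrow(mu), ncol(mu), dimnames = dimnames(mu))
  cnt
}

#' Generate a synthetic two-species dataset with known ground truth
#'
#' Simulates branching differentiation for every class branch of the
#' design: each cell gets a latent time drawn uniformly on its branch,
#' expected spliced/unspliced values follow the two-state transcription
#' ODE ([expected_expression()]), and observed counts are negative-binomial
#' draws around library-size-scaled expectations. Species A additionally
#' carries the species-specific class and terminal-class extension cells
#' (latent time in [0.92, 1]) that downstream fate mapping uses as
#' absorbing states. Low-quality cells are planted with
#' [plant_qc_artifacts()].
#'
#' @param design A [trajectory_design()].
#' @param kinetics A [kinetic_params()].
#' @param return_expected Also attach the noise-free expected matrices as
#'   layers `expected_spliced` / `expected_unspliced` (dense; intended for
#'   small designs and tests).
#'
#' @return A list with elements:
#'   * `datasets`: named list of [expression_dataset()] (speciesA, speciesB);
#'   * `truth`: per-cell tibble (`cell_id`, `species`, `batch`, `class`,
#'     `terminal_class`, `latent_time`, `role`, `quality`, `qc_mode`);
#'   * `gene_truth`: per-species per-class trajectory direction of every
#'     gene (`activated` / `inactivated` / `null`) plus kinetic rates;
#'   * `orthologues`: two-column one-to-one orthologue tibble
#'     (`gene_a`, `gene_b`);
#'   * `homology`: bijective class homology map over shared classes, with
#'     the species-specific class's designated sister recorded in
#'     `sister` attribute columns.
#' @export
generate_dataset <- function(design = trajectory_design(),
                             kinetics = kinetic_params(),
                             return_expected = FALSE) {
  validate_design(design)
  withr::with_seed(design$seed, {
    genes_a <- build_gene_table(design, kinetics)
    classes_a <- c(design$shared_classes, design$specific_class,
                   design$excitatory_class)
    classes_b <- c(design$shared_classes, design$excitatory_class)
    inhib_a <- setdiff(classes_a, design$excitatory_class)

    species_sim <- function(species, classes, terminal_classes, genes,
                            prefix) {
      n_dev <- design$cells_per_branch * length(classes)
      cls <- rep(classes, each = design$cells_per_branch)
      tt <- runif(n_dev)
      role <- rep("developmental", n_dev)
      if (length(terminal_classes) && design$terminal_cells_per_class > 0) {
        n_t <- design$terminal_cells_per_class
        cls <- c(cls, rep(terminal_classes, each = n_t))
        tt <- c(tt, runif(n_t * length(terminal_classes), 0.92, 1))
        role <- c(role, rep("terminal", n_t * length(terminal_classes)))
      }
      n_cells <- length(cls)
      batch <- ifelse(
        role == "developmental",
        sprintf("%s_b%d", prefix,
                sample.int(design$batches_per_species, n_cells,
                           replace = TRUE)),
        sprintf("%s_t%d", prefix, sample.int(2, n_cells, replace = TRUE)))
      cell_id <- sprintf("%s_c%05d", prefix, seq_len(n_cells))
      exp_mat <- expected_matrices(genes, cls, tt, design, kinetics)
      libs <- rlnorm(n_cells, log(kinetics$lib_mean), kinetics$lib_sdlog)
      spliced <- sample_counts(exp_mat$S, libs, kinetics$nb_size)
      unspliced <- sample_counts(exp_mat$U,
                                 libs * kinetics$unspliced_ratio,
                                 kinetics$nb_size)
      colnames(spliced) <- colnames(unspliced) <- cell_id
      region <- sub("_.*", "", cls)
      cells <- tibble(
        cell_id = cell_id, species = species, batch = batch,
        region = region, age = round(40 + 60 * tt), role = role,
        true_class = cls,
        terminal_class = ifelse(
          cls %in% design$excitatory_class, NA_character_,
          paste0("T_", cls)),
        latent_time = tt)
      ds <- expression_dataset(spliced, unspliced, cells, genes %>%
                                 select("gene_id", "role", "class",
                                        "is_mito", "is_ribo"))
      if (return_expected) {
        dn <- list(genes$gene_id, cell_id)
        dimnames(exp_mat$S) <- dimnames(exp_mat$U) <- dn
        ds$layers$expected_spliced <- exp_mat$S
        ds$layers$expected_unspliced <- exp_mat$U
      }
      ds
    }

    ds_a <- species_sim("speciesA", classes_a, inhib_a, genes_a, "A")
    genes_b <- genes_a
    genes_b$gene_id <- paste0("B.", genes_a$gene_id)
    ds_b <- species_sim("speciesB", classes_b, character(), genes_b, "B")

    ds_a <- plant_qc_artifacts(ds_a, design$fraction_low_quality,
                               seed = design$seed + 101L)
    ds_b <- plant_qc_artifacts(ds_b, design$fraction_low_quality,
                               seed = design$seed + 202L)

    truth <- bind_rows(ds_a$cells, ds_b$cells) %>%
      select("cell_id", "species", "batch", class = "true_class",
             "terminal_class", "latent_time", "role", "quality", "qc_mode")

    gene_truth <- bind_rows(lapply(
      list(speciesA = list(genes = genes_a, classes = classes_a),
           speciesB = list(genes = genes_b, classes = classes_b)),
      function(sp) {
        bind_rows(lapply(sp$classes, function(cl) {
          g <- sp$genes
          dir <- rep("null", nrow(g))
          dir[g$role == "activated" &
                sub("^B\\.", "", g$gene_id) %in%
                sprintf("%s_ACT%02d", cl, seq_len(design$n_activated))] <-
            "activated"
          dir[g$role == "progenitor"] <- "inactivated"
          tibble(class = cl, gene_id = g$gene_id, direction = dir,
                 role = g$role, alpha = g$alpha, beta = g$beta,
                 gamma = g$gamma)
        }))
      }), .id = "species")

    keep <- sort(sample.int(
      nrow(genes_a), size = round((1 - design$orthologue_dropout) *
                                    nrow(genes_a))))
    orthologues <- tibble(gene_a = genes_a$gene_id[keep],
                          gene_b = genes_b$gene_id[keep])

    homology <- tibble(class_a = design$shared_classes,
                       class_b = design$shared_classes)
    attr(homology, "specific_class") <- design$specific_class
    attr(homology, "sister_class") <- design$sister_class

    list(datasets = list(speciesA = ds_a, speciesB = ds_b),
         truth = truth, gene_truth = gene_truth,
         orthologues = orthologues, homology = homology)
  })
}

#' Plant low-quality cells into a dataset
#'
#' Flags a fraction of cells and corrupts their counts so that each flagged
#' cell decisively violates at least one droplet QC threshold: either most
#' genes are zeroed (detected genes far below 800), mitochondrial counts
#' are inflated to ~45% of reads, or ribosomal counts to ~65%. Flags are
#' recorded in `cells$quality` / `cells$qc_mode`.
#'
#' @param dataset An [expression_dataset()].
#' @param fraction Fraction of cells to corrupt, in `[0, 0.5]`.
#' @param seed Integer seed.
#' @return The modified dataset.
#' @export
plant_qc_artifacts <- function(dataset, fraction, seed = 1L) {
  if (fraction < 0 || fraction > 0.5) {
    abort("`fraction` must be in [0, 0.5].")
  }
  if (is.null(dataset$cells[["quality"]])) {
    dataset$cells$quality <- rep("good", n_cells(dataset))
  }
  if (is.null(dataset$cells[["qc_mode"]])) {
    dataset$cells$qc_mode <- rep(NA_character_, n_cells(dataset))
  }
  n_bad <- round(fraction * n_cells(dataset))
  if (n_bad == 0) return(dataset)
  withr::with_seed(seed, {
    bad <- sample.int(n_cells(dataset), n_bad)
    modes <- sample(c("min_genes", "max_mito", "max_ribo"), n_bad,
                    replace = TRUE)
    spl <- as.matrix(dataset$spliced[, bad, drop = FALSE])
    uns <- as.matrix(dataset$unspliced[, bad, drop = FALSE])
    mito <- dataset$genes$is_mito
    ribo <- dataset$genes$is_ribo
    for (j in seq_along(bad)) {
      if (modes[j] == "min_genes") {
        keep <- sample.int(nrow(spl), 250)
        spl[-keep, j] <- 0
        uns[-keep, j] <- 0
      } else if (modes[j] == "max_mito") {
        spl[, j] <- inflate_fraction(spl[, j], mito, 0.45)
      } else {
        spl[, j] <- inflate_fraction(spl[, j], ribo, 0.65)
      }
    }
    dataset$spliced[, bad] <- spl
    dataset$unspliced[, bad] <- uns
    dataset$spliced <- drop0(dataset$spliced)
    dataset$unspliced <- drop0(dataset$unspliced)
    dataset$cells$quality[bad] <- "low_quality"
    dataset$cells$qc_mode[bad] <- modes
  })
  dataset
}

# Scale counts in `mask` so they make up `target` of the cell's total.
inflate_fraction <- function(counts, mask, target) {
  in_sum <- sum(counts[mask])
  out_sum <- sum(counts[!mask])
  if (in_sum == 0) {
    counts[mask] <- ceiling(target / (1 - target) * out_sum /
                              max(sum(mask), 1))
    return(counts)
  }
  f <- target / (1 - target) * out_sum / in_sum
  counts[mask] <- ceiling(counts[mask] * f)
  counts
}

#' Write all generator outputs as a plain-text bundle
#'
#' Writes one MTX bundle per species plus `truth.tsv`, `gene_truth.tsv` and
#' `orthologues.tsv`.
#'
#' @param sim Result of [generate_dataset()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in names(sim$datasets)) {
    write_mtx_bundle(sim$datasets[[sp]], file.path(dir, sp))
  }
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  readr::write_tsv(sim$gene_truth, file.path(dir, "gene_truth.tsv"))
  readr::write_tsv(sim$orthologues, file.path(dir, "orthologues.tsv"))
  invisible(dir)
}
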