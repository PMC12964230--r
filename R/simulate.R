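#' Parameters for the synthetic cohort generators
#'
#' Describes a cohort with planted subtype structure: `K` disjoint blocks of
#' `module_size` genes, where block `s` is shifted upward by `delta` (log2
#' units) exactly in samples of subtype `s`.  Values are simulated directly
#' on a log2-like scale around a high baseline so that the matrix stays
#' nonnegative for NMF; any residual negative value is clipped at zero and
#' the clip count recorded.
#'
#' @param n_samples Number of samples (default 300).
#' @param n_genes Number of genes (default 1200, the desk-scale analogue of
#'   a ~1.2k-gene programmed-cell-death panel).
#' @param K Number of planted subtypes (>= 2).
#' @param module_size Genes per subtype-specific block; `module_size * K`
#'   must not exceed `n_genes`.
#' @param delta Log2 mean shift of a block within its own subtype.
#' @param noise_sd Gene-level Gaussian noise sd on the log2 scale (default
#'   0.5, typical within-group variability of normalized arrays).
#' @param baseline Mean baseline log2 expression (default 6).
#' @param gene_baseline_sd Sd of per-gene baseline expression around
#'   `baseline` (default 2, matching the wide spread of per-gene mean
#'   log2 expression on normalized arrays).  Baseline heterogeneity is what
#'   gives the signature exclusivity step its meaning: a generically
#'   high-expressed gene weighs heavily in every module and is removed,
#'   whereas subtype genes weigh heavily in one.
#' @param n_batches Number of batches (>= 1).
#' @param batch_shift_sd Sd of per-batch, per-gene additive offsets.
#' @param subtype_proportions Vector of length `K` summing to 1.
#' @param seed Integer seed; generators are deterministic given the seed.
#' @return A `simulation_params` list, validated.
#' @export
simulation_params <- function(n_samples = 300L, n_genes = 1200L, K = 3L,
                              module_size = 50L, delta = 1.2, noise_sd = 0.5,
                              baseline = 6, gene_baseline_sd = 2,
                              n_batches = 1L,
                              batch_shift_sd = 0.3,
                              subtype_proportions = rep(1 / K, K),
                              seed = 1L) {
  stopifnot_scalar_int(n_samples, "n_samples", 1L)
  stopifnot_scalar_int(n_genes, "n_genes", 1L)
  stopifnot_scalar_int(K, "K", 2L)
  stopifnot_scalar_int(module_size, "module_size", 1L)
  stopifnot_scalar_int(n_batches, "n_batches", 1L)
  if (module_size * K > n_genes) {
    stop("module_size * K exceeds n_genes: planted blocks cannot be disjoint")
  }
  if (noise_sd < 0 || batch_shift_sd < 0 || gene_baseline_sd < 0) {
    stop("sds must be >= 0")
  }
  if (length(subtype_proportions) != K || any(subtype_proportions < 0) ||
      abs(sum(subtype_proportions) - 1) > 1e-9) {
    stop("subtype_proportions must be length K, nonnegative, sum to 1")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes), K = as.integer(K),
                 module_size = as.integer(module_size), delta = delta,
                 noise_sd = noise_sd, baseline = baseline,
                 gene_baseline_sd = gene_baseline_sd,
                 n_batches = as.integer(n_batches),
                 batch_shift_sd = batch_shift_sd,
                 subtype_proportions = subtype_proportions,
                 seed = as.integer(seed)),
            class = "simulation_params")
}

# deterministic planted-block layout: block s = rows (s-1)*m+1 .. s*m
planted_modules <- function(params) {
  genes <- sprintf("g%04d", seq_len(params$n_genes))
  lapply(seq_len(params$K), function(s) {
    genes[((s - 1L) * params$module_size + 1L):(s * params$module_size)]
  })
}

#' Simulate a bulk expression cohort with planted subtypes
#'
#' @param params A [simulation_params()] object.
#' @return A list with components `matrix` (genes x samples, nonnegative
#'   log2 scale; attribute `n_clipped` counts values clipped at zero) and
#'   `truth` (a `synthetic_truth` list: `sample_labels`, `module_genes`,
#'   `batch_ids`).
#' @export
simulate_bulk_cohort <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  with_seed(params$seed, {
    genes <- sprintf("g%04d", seq_len(params$n_genes))
    samples <- sprintf("S%03d", seq_len(params$n_samples))
    labels <- sample.int(params$K, params$n_samples, replace = TRUE,
                         prob = params$subtype_proportions)
    batches <- sample.int(params$n_batches, params$n_samples, replace = TRUE)
    modules <- planted_modules(params)

    gene_baseline <- params$baseline +
      rnorm(params$n_genes, sd = params$gene_baseline_sd)
    m <- matrix(gene_baseline, params$n_genes, params$n_samples,
                dimnames = list(genes, samples))
    for (s in seq_len(params$K)) {
      rows <- match(modules[[s]], genes)
      m[rows, labels == s] <- m[rows, labels == s] + params$delta
    }
    if (params$n_batches > 1L && params$batch_shift_sd > 0) {
      offsets <- matrix(rnorm(params$n_genes * params$n_batches,
                              sd = params$batch_shift_sd),
                        params$n_genes, params$n_batches)
      m <- m + offsets[, batches, drop = FALSE]
    }
    if (params$noise_sd > 0) {
      m <- m + matrix(rnorm(length(m), sd = params$noise_sd),
                      nrow(m), ncol(m))
    }
    n_clipped <- sum(m < 0)
    m[m < 0] <- 0
    attr(m, "n_clipped") <- n_clipped
    truth <- structure(list(sample_labels = setNames(labels, samples),
                            module_genes = modules,
                            batch_ids = setNames(batches, samples)),
                       class = "synthetic_truth")
    list(matrix = m, truth = truth)
  })
}

#' Simulate an annotated single-cell cohort
#'
#' Every cell carries its sample's subtype block signal plus a cell-type
#' marker block, with cell types drawn per sample from the subtype's
#' composition vector.  Cell-type marker blocks are laid out after the
#' subtype blocks in the gene panel, so
#' `K * module_size + n_types * celltype_marker_size <= n_genes`.
#'
#' @param params A [simulation_params()] object (here `n_samples` is the
#'   number of donors/samples).
#' @param cells_per_sample Cells drawn per sample (>= 1).
#' @param composition K x n_types matrix of cell-type proportions per
#'   subtype; rows must sum to 1.  Columns may be named with cell types.
#'   The default plants a fibroblast excess in the last subtype, echoing a
#'   stroma-rich tumor subtype.
#' @param celltype_marker_size Genes per cell-type marker block.
#' @param celltype_effect Log2 shift of a cell type's marker block.
#' @return A list with `matrix` (genes x cells), `cells` (a
#'   `data.frame`: `cell_id`, `sample_id`, `cell_type`, `subtype`), and
#'   `truth` as in [simulate_bulk_cohort()].
#' @export
simulate_single_cell <- function(params, cells_per_sample = 300L,
                                 composition = NULL,
                                 celltype_marker_size = 20L,
                                 celltype_effect = 2) {
  stopifnot(inherits(params, "simulation_params"))
  stopifnot_scalar_int(cells_per_sample, "cells_per_sample", 1L)
  if (is.null(composition)) {
    base <- c(epithelial = 0.45, t_cell = 0.30, b_cell = 0.10,
              myeloid = 0.10, fibroblast = 0.05)
    composition <- matrix(base, params$K, length(base), byrow = TRUE,
                          dimnames = list(NULL, names(base)))
    composition[params$K, "fibroblast"] <- 0.30
    composition[params$K, "epithelial"] <- 0.20
  }
  if (!is.matrix(composition) || nrow(composition) != params$K) {
    stop("`composition` must be a K x n_types matrix")
  }
  if (any(abs(rowSums(composition) - 1) > 1e-9)) {
    stop("composition rows must sum to 1")
  }
  types <- colnames(composition)
  if (is.null(types)) types <- paste0("type", seq_len(ncol(composition)))
  needed <- params$K * params$module_size +
    length(types) * celltype_marker_size
  if (needed > params$n_genes) {
    stop("gene panel too small for subtype + cell-type marker blocks")
  }

  with_seed(params$seed, {
    genes <- sprintf("g%04d", seq_len(params$n_genes))
    samples <- sprintf("S%03d", seq_len(params$n_samples))
    labels <- sample.int(params$K, params$n_samples, replace = TRUE,
                         prob = params$subtype_proportions)
    modules <- planted_modules(params)
    marker_start <- params$K * params$module_size
    marker_rows <- lapply(seq_along(types), function(tt) {
      (marker_start + (tt - 1L) * celltype_marker_size + 1L):
        (marker_start + tt * celltype_marker_size)
    })

    counts <- vapply(seq_len(params$n_samples), function(j) {
      rmultinom(1L, cells_per_sample, composition[labels[j], ])[, 1L]
    }, integer(length(types)))          # n_types x n_samples
    total_cells <- params$n_samples * cells_per_sample

    cell_sample <- rep(seq_len(params$n_samples), each = cells_per_sample)
    cell_type <- unlist(lapply(seq_len(params$n_samples), function(j) {
      rep(seq_along(types), counts[, j])
    }), use.names = FALSE)
    cell_id <- sprintf("%s_c%04d", samples[cell_sample],
                       sequence(rep(cells_per_sample, params$n_samples)))

    gene_baseline <- params$baseline +
      rnorm(params$n_genes, sd = params$gene_baseline_sd)
    m <- matrix(gene_baseline, params$n_genes, total_cells,
                dimnames = list(genes, cell_id))
    for (s in seq_len(params$K)) {
      rows <- match(modules[[s]], genes)
      sel <- labels[cell_sample] == s
      m[rows, sel] <- m[rows, sel] + params$delta
    }
    for (tt in seq_along(types)) {
      sel <- cell_type == tt
      m[marker_rows[[tt]], sel] <- m[marker_rows[[tt]], sel] + celltype_effect
    }
    if (params$noise_sd > 0) {
      m <- m + matrix(rnorm(length(m), sd = params$noise_sd),
                      nrow(m), ncol(m))
    }
    n_clipped <- sum(m < 0)
    m[m < 0] <- 0
    attr(m, "n_clipped") <- n_clipped

    cells <- data.frame(cell_id = cell_id,
                        sample_id = samples[cell_sample],
                        cell_type = types[cell_type],
                        subtype = labels[cell_sample],
                        stringsAsFactors = FALSE)
    truth <- structure(list(sample_labels = setNames(labels, samples),
                            module_genes = modules,
                            batch_ids = setNames(rep(1L, params$n_samples),
                                                 samples)),
                       class = "synthetic_truth")
    list(matrix = m, cells = cells, truth = truth)
  })
}

#' Simulate relapse-free survival with subtype-specific hazards
#'
#' Event times are exponential with the sample subtype's hazard, multiplied
#' by the subtype's hazard ratio when the sample falls in the treated arm
#' (Bernoulli 1/2 per sample).  Censoring times are exponential with rate
#' `censor_rate` (`0` disables censoring); the observed time is the minimum
#' and the event flag indicates the event came first.
#'
#' @param truth A `synthetic_truth` object (for sample IDs and subtypes).
#' @param hazards Per-subtype baseline event rates (> 0), length K.
#' @param treatment_effect Per-subtype hazard ratio under treatment
#'   (default 1 = no effect).
#' @param censor_rate Exponential censoring rate (>= 0).
#' @param seed Integer seed.  Use a seed different from the one that
#'   generated `truth`: replaying the same stream that drew the subtype
#'   labels correlates the treatment assignment with subtype.
#' @return A `data.frame`: `sample_id`, `time` (months), `event` (0/1),
#'   `subtype`, `treatment` (0/1).
#' @export
simulate_survival <- function(truth, hazards, treatment_effect = NULL,
                              censor_rate = 0.02, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  K <- max(truth$sample_labels)
  if (length(hazards) < K || any(hazards <= 0)) {
    stop("`hazards` needs a positive rate for every planted subtype")
  }
  if (is.null(treatment_effect)) treatment_effect <- rep(1, length(hazards))
  if (length(treatment_effect) < K || any(treatment_effect <= 0)) {
    stop("`treatment_effect` needs a positive hazard ratio per subtype")
  }
  if (censor_rate < 0) stop("`censor_rate` must be >= 0")
  with_seed(seed, {
    n <- length(truth$sample_labels)
    subtype <- unname(truth$sample_labels)
    treatment <- rbinom(n, 1L, 0.5)
    rate <- hazards[subtype] * ifelse(treatment == 1L,
                                      treatment_effect[subtype], 1)
    t_event <- rexp(n, rate)
    t_cens <- if (censor_rate > 0) rexp(n, censor_rate) else rep(Inf, n)
    data.frame(sample_id = names(truth$sample_labels),
               time = pmin(t_event, t_cens),
               event = as.integer(t_event <= t_cens),
               subtype = subtype, treatment = treatment,
               stringsAsFactors = FALSE)
  })
}

#' Simulate multiplex-immunofluorescence cell-count tables
#'
#' Emulates a tissue-microarray readout: per sample, a total tumor-cell
#' count, the triple-positive (MDK+FAP+SDC2+) tumor-cell count, DAPI+ nuclei,
#' CD3+ T cells, and TIGIT+ T cells.  Counts are binomial with per-sample
#' rates drawn from tissue-class Beta distributions; the CD3 rate decreases
#' and the TIGIT rate increases with the sample's co-localization rate, so
#' that co-localization-high tumors are T-cell-excluded and
#' exhaustion-enriched.
#'
#' @param n_tumors Number of tumor samples.
#' @param n_adjacent Number of adjacent non-tumor samples.
#' @param coloc_means Named list with `tumor` and `adjacent` elements, each
#'   `c(alpha, beta)` of the Beta distribution of the co-localization rate.
#'   Defaults give means 0.10 (tumor) and 0.05 (adjacent).
#' @param cd3_coupling Linear decrease of the CD3 rate per unit
#'   co-localization rate (default 1).
#' @param tigit_coupling Linear increase of the TIGIT rate per unit
#'   co-localization rate (default 1.5).
#' @param mean_tumor_cells,mean_dapi Poisson means of the per-sample tumor
#'   cell and nucleus counts.
#' @param seed Integer seed.
#' @return A `data.frame`: `sample_id`, `tissue_class`, `tumor_cells`,
#'   `triple_positive`, `dapi`, `cd3`, `tigit`.
#' @export
simulate_mif_counts <- function(n_tumors = 94L, n_adjacent = 86L,
                                coloc_means = list(tumor = c(2, 18),
                                                   adjacent = c(1, 19)),
                                cd3_coupling = 1, tigit_coupling = 1.5,
                                mean_tumor_cells = 1500,
                                mean_dapi = 4000, seed = 1L) {
  stopifnot_scalar_int(n_tumors, "n_tumors", 1L)
  stopifnot_scalar_int(n_adjacent, "n_adjacent", 0L)
  for (cl in c("tumor", "adjacent")) {
    ab <- coloc_means[[cl]]
    if (is.null(ab) || length(ab) != 2L || ab[1L] < 0 || ab[2L] <= 0) {
      stop("`coloc_means$", cl, "` must be valid Beta parameters ",
           "(alpha >= 0 for a point mass at zero, beta > 0)")
    }
  }
  with_seed(seed, {
    n <- n_tumors + n_adjacent
    tissue <- rep(c("tumor", "adjacent"), c(n_tumors, n_adjacent))
    ab <- do.call(rbind, coloc_means[tissue])
    p_coloc <- ifelse(ab[, 1L] == 0, 0, rbeta(n, pmax(ab[, 1L], 1e-12), ab[, 2L]))
    tumor_cells <- rpois(n, mean_tumor_cells)
    triple <- rbinom(n, tumor_cells, p_coloc)
    dapi <- rpois(n, mean_dapi)
    p_cd3 <- pmin(pmax(rbeta(n, 4, 16) - cd3_coupling *
                         (p_coloc - mean(p_coloc)), 0.001), 0.999)
    cd3 <- rbinom(n, dapi, p_cd3)
    p_tigit <- pmin(pmax(rbeta(n, 3, 17) + tigit_coupling *
                           (p_coloc - mean(p_coloc)), 0.001), 0.999)
    tigit <- rbinom(n, cd3, p_tigit)
    data.frame(sample_id = sprintf("M%03d", seq_len(n)),
               tissue_class = tissue, tumor_cells = tumor_cells,
               triple_positive = triple, dapi = dapi, cd3 = cd3,
               tigit = tigit, stringsAsFactors = FALSE)
  })
}
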