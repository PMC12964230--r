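test_that("bulk generator is deterministic and honors the no-variation limit", {
  p0 <- simulation_params(n_samples = 20, n_genes = 60, K = 2,
                          module_size = 10, delta = 0, noise_sd = 0,
                          gene_baseline_sd = 0, n_batches = 1, seed = 3)
  sim <- simulate_bulk_cohort(p0)
  expect_true(all(sim$matrix == sim$matrix[1, 1]))

  p <- simulation_params(n_samples = 40, n_genes = 120, K = 3,
                         module_size = 20, seed = 9)
  a <- simulate_bulk_cohort(p)
  b <- simulate_bulk_cohort(p)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$truth$sample_labels, b$truth$sample_labels)
})

test_that("planted block contrast matches delta within Monte-Carlo error", {
  p <- simulation_params(n_samples = 150, n_genes = 600, K = 3,
                         module_size = 50, delta = 1.2, seed = 7)
  sim <- simulate_bulk_cohort(p)
  lab <- sim$truth$sample_labels
  for (s in 1:3) {
    block <- sim$truth$module_genes[[s]]
    inside <- mean(sim$matrix[block, lab == s])
    outside <- mean(sim$matrix[block, lab != s])
    n_in <- sum(lab == s) * length(block)
    sem <- p$noise_sd * sqrt(1 / n_in + 1 / (length(lab[lab != s]) * length(block)))
    expect_lt(abs((inside - outside) - 1.2), 3 * sem + 1e-6)
  }
})

test_that("invalid simulation parameters are rejected", {
  expect_error(simulation_params(n_genes = 100, K = 3, module_size = 40),
               "disjoint")
  expect_error(simulation_params(noise_sd = -1), "sds")
  expect_error(simulation_params(K = 3, subtype_proportions = c(0.5, 0.5)),
               "proportions")
})

test_that("single-cell generator respects composition, counts, and determinism", {
  p <- simulation_params(n_samples = 40, n_genes = 400, K = 3,
                         module_size = 40, seed = 5)
  comp <- matrix(c(0.65, 0.30, 0.05,
                   0.65, 0.30, 0.05,
                   0.40, 0.30, 0.30), 3, 3, byrow = TRUE,
                 dimnames = list(NULL, c("epithelial", "t_cell", "fibroblast")))
  sc <- simulate_single_cell(p, cells_per_sample = 100, composition = comp)
  counts <- table(sc$cells$sample_id)
  expect_true(all(counts == 100))

  # empirical fibroblast fraction in subtype-3 samples within binomial 99% CI
  s3 <- names(sc$truth$sample_labels)[sc$truth$sample_labels == 3]
  cells3 <- sc$cells[sc$cells$sample_id %in% s3, ]
  n3 <- nrow(cells3)
  phat <- mean(cells3$cell_type == "fibroblast")
  ci <- 2.576 * sqrt(0.30 * 0.70 / n3)
  expect_lt(abs(phat - 0.30), ci)

  sc2 <- simulate_single_cell(p, cells_per_sample = 100, composition = comp)
  expect_identical(sc$cells, sc2$cells)
  expect_identical(sc$matrix, sc2$matrix)
})

test_that("a one-cell-per-sample cohort pseudobulks to the cells themselves", {
  p <- simulation_params(n_samples = 6, n_genes = 300, K = 2,
                         module_size = 30, seed = 2)
  sc <- simulate_single_cell(p, cells_per_sample = 1)
  pb <- pseudobulk(sc$matrix, sc$cells)
  for (j in seq_len(ncol(pb))) {
    cell <- sc$cells$cell_id[sc$cells$sample_id == colnames(pb)[j]]
    expect_equal(unname(pb[, j]), unname(sc$matrix[, cell]))
  }
})

test_that("survival times follow the planted exponential model", {
  p <- simulation_params(n_samples = 400, n_genes = 60, K = 2,
                         module_size = 10, seed = 4,
                         subtype_proportions = c(1, 0))
  truth <- simulate_bulk_cohort(p)$truth
  lambda <- 0.05
  surv <- simulate_survival(truth, hazards = c(lambda, lambda),
                            censor_rate = 0, seed = 8)
  expect_true(all(surv$event == 1))
  sem <- (1 / lambda) / sqrt(nrow(surv))
  expect_lt(abs(mean(surv$time) - 1 / lambda), 3 * sem)
  expect_true(all(surv$time > 0))

  surv2 <- simulate_survival(truth, hazards = c(lambda, lambda),
                             censor_rate = 0, seed = 8)
  expect_identical(surv, surv2)
})

test_that("mIF generator respects planted rates, edge cases, and determinism", {
  mif <- simulate_mif_counts(n_tumors = 200, n_adjacent = 200, seed = 6)
  expect_true(all(mif$triple_positive <= mif$tumor_cells))
  expect_true(all(mif$cd3 <= mif$dapi))
  ratio <- mif$triple_positive / mif$tumor_cells
  tum <- ratio[mif$tissue_class == "tumor"]
  adj <- ratio[mif$tissue_class == "adjacent"]
  # Beta means 0.10 vs 0.05; group means separate within 3 SEM
  sem <- sqrt(var(tum) / length(tum) + var(adj) / length(adj))
  expect_gt(mean(tum) - mean(adj), 0.05 - 3 * sem)
  expect_lt(mean(tum) - mean(adj), 0.05 + 3 * sem)

  zero <- simulate_mif_counts(n_tumors = 10, n_adjacent = 10,
                              coloc_means = list(tumor = c(0, 10),
                                                 adjacent = c(0, 10)),
                              seed = 1)
  expect_true(all(zero$triple_positive == 0))

  expect_identical(simulate_mif_counts(seed = 3), simulate_mif_counts(seed = 3))
})
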