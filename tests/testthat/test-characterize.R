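test_that("Ro/e ratios follow contingency-table arithmetic and the printed bins", {
  tab <- matrix(c(10, 5, 0, 5), 2, 2,
                dimnames = list(c("T", "B"), c("S1", "S2")))
  roe <- roe_enrichment(cells_from_table(tab))
  r11 <- roe[roe$cell_type == "T" & roe$subtype == "S1", ]
  expect_equal(r11$expected, 7.5)
  expect_equal(r11$roe, 4 / 3)
  expect_equal(r11$symbol, "++")
  r12 <- roe[roe$cell_type == "T" & roe$subtype == "S2", ]
  expect_equal(r12$roe, 0)
  expect_equal(r12$symbol, "-")

  uni <- matrix(6, 3, 2, dimnames = list(c("a", "b", "c"), c("x", "y")))
  roe_u <- roe_enrichment(cells_from_table(uni))
  expect_true(all(roe_u$roe == 1))
  expect_true(all(roe_u$symbol == "+"))   # Ro/e = 1 belongs to "+"
})

test_that("Ro/e matches an independent expected-count computation on random tables", {
  set.seed(101)
  for (i in 1:20) {
    tab <- matrix(rpois(15, 20) + 1, 5, 3,
                  dimnames = list(paste0("ct", 1:5), paste0("S", 1:3)))
    roe <- roe_enrichment(cells_from_table(tab))
    exp_o <- roe_expected_oracle(tab)
    got <- matrix(roe$expected, 5, 3,
                  dimnames = list(sort(rownames(tab)), sort(colnames(tab))))
    expect_equal(got[rownames(tab), colnames(tab)], exp_o,
                 tolerance = 1e-12)
    # marginal conservation of expected counts
    expect_equal(rowSums(got), rowSums(tab)[rownames(got)], tolerance = 1e-12)
    expect_equal(colSums(got), colSums(tab)[colnames(got)], tolerance = 1e-12)
  }
})

test_that("pseudobulk sums cells within samples and is linear", {
  m <- matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3), c("c1", "c2")))
  ann <- data.frame(cell_id = c("c1", "c2"), sample_id = c("A", "A"))
  pb <- pseudobulk(m, ann)
  expect_equal(unname(pb[, "A"]), c(5, 7, 9))

  set.seed(102)
  m2 <- matrix(runif(30), 3, 10,
               dimnames = list(paste0("g", 1:3), paste0("c", 1:10)))
  ann2 <- data.frame(cell_id = colnames(m2),
                     sample_id = rep(c("A", "B"), each = 5))
  pb_all <- pseudobulk(m2, ann2)
  pb_a <- pseudobulk(m2[, 1:5], ann2[1:5, ])
  pb_b <- pseudobulk(m2[, 6:10], ann2[6:10, ])
  expect_equal(pb_all, cbind(pb_a, pb_b))

  ann3 <- rbind(ann2, data.frame(cell_id = "ghost", sample_id = "C"))
  expect_warning(pseudobulk(m2, ann3), "C")
})

test_that("log-rank statistic matches the first-principles computation", {
  surv <- data.frame(time = c(1, 2, 3, 4, 5, 6), event = 1,
                     subtype = rep(c("a", "b"), each = 3))
  res <- km_logrank(surv)
  expect_equal(res$chisq, logrank_oracle(surv$time, surv$event, surv$subtype),
               tolerance = 1e-9)

  set.seed(103)
  for (i in 1:15) {
    n <- 30
    st <- data.frame(time = rexp(n, 0.1) + 0.01,
                     event = rbinom(n, 1, 0.8),
                     subtype = sample(c("a", "b", "c"), n, TRUE))
    if (sum(st$event) == 0 || length(unique(st$subtype)) < 3) next
    res <- km_logrank(st)
    expect_equal(res$chisq,
                 logrank_oracle(st$time, st$event, st$subtype),
                 tolerance = 1e-9)
  }
})

test_that("identical groups give a null log-rank and uncensored KM is empirical", {
  base <- data.frame(time = c(2, 4, 6, 8), event = 1)
  surv <- rbind(cbind(base, subtype = "a"), cbind(base, subtype = "b"))
  res <- km_logrank(surv)
  expect_equal(res$chisq, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)

  # with no censoring the KM estimate equals the empirical survival function
  single <- data.frame(time = c(1, 2, 2, 3, 5), event = 1,
                       subtype = rep(c("a", "b"), c(2, 3)))
  res2 <- km_logrank(single)
  sf <- summary(res2$fit)
  emp <- vapply(seq_along(sf$time), function(i) {
    grp_times <- single$time[paste0("group=", single$subtype) == as.character(sf$strata[i])]
    mean(grp_times > sf$time[i])
  }, numeric(1))
  expect_equal(sf$surv, emp, tolerance = 1e-12)
})

test_that("treatment benefit reports O/E hazard ratios with arm symmetry", {
  set.seed(104)
  n <- 120
  st <- data.frame(time = rexp(n, 0.08), event = rbinom(n, 1, 0.9),
                   subtype = rep("S1", n),
                   treatment = rep(c(0, 1), each = n / 2))
  tb <- treatment_benefit(st)
  expect_equal(nrow(tb), 1L)
  swapped <- st
  swapped$treatment <- 1 - st$treatment
  tb2 <- treatment_benefit(swapped)
  expect_equal(tb2$hr, 1 / tb$hr, tolerance = 1e-9)
  expect_equal(tb2$p_value, tb$p_value, tolerance = 1e-12)

  st$treatment[st$subtype == "S1"] <- 0
  expect_error(suppressWarnings(treatment_benefit(st)), "no subtype")
})

test_that("Fisher p-values equal full enumeration for small tables", {
  tab <- matrix(c(8, 1, 2, 9), 2, 2)
  expect_equal(pcdsubtype:::fisher_exact_p(tab, "greater"),
               fisher_enum_oracle(tab, "greater"), tolerance = 1e-12)
  set.seed(105)
  for (i in 1:20) {
    t2 <- matrix(rpois(4, 6), 2, 2)
    if (any(rowSums(t2) == 0) || any(colSums(t2) == 0)) next
    for (alt in c("two.sided", "less", "greater")) {
      expect_equal(pcdsubtype:::fisher_exact_p(t2, alt),
                   fisher_enum_oracle(t2, alt), tolerance = 1e-9)
    }
  }
})

test_that("mIF statistics compute ratios, splits, and boundary rules", {
  mif <- simulate_mif_counts(n_tumors = 60, n_adjacent = 40, seed = 7)
  out <- mif_statistics(mif)
  expect_equal(out$per_sample$coloc_ratio,
               mif$triple_positive / mif$tumor_cells)
  tum <- out$per_sample[out$per_sample$tissue_class == "tumor", ]
  expect_true(all(tum$coloc_group[tum$coloc_ratio <= out$median_ratio] == "low"))
  expect_true(all(tum$coloc_group[tum$coloc_ratio > out$median_ratio] == "high"))
  expect_true(out$tumor_vs_adjacent_p >= 0 && out$tumor_vs_adjacent_p <= 1)
  expect_equal(sum(out$fisher_table), nrow(tum))

  # CD3 ratio exactly at the 20% cutoff goes to the high group
  mif2 <- data.frame(sample_id = c("a", "b"), tissue_class = "tumor",
                     tumor_cells = c(100, 100), triple_positive = c(10, 30),
                     dapi = c(100, 100), cd3 = c(20, 10), tigit = c(5, 2))
  out2 <- suppressWarnings(mif_statistics(mif2))
  expect_equal(out2$per_sample$cd3_group, c("high", "low"))

  # all-zero co-localization: ratios zero and the split is flagged degenerate
  mif3 <- simulate_mif_counts(n_tumors = 10, n_adjacent = 5,
                              coloc_means = list(tumor = c(0, 5),
                                                 adjacent = c(0, 5)),
                              seed = 2)
  expect_warning(out3 <- mif_statistics(mif3), "degenerate")
  expect_true(all(out3$per_sample$coloc_ratio == 0))
  expect_true(is.na(out3$fisher_p))
})
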