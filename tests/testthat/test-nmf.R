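random_v <- function(nr, nc, seed) {
  set.seed(seed)
  matrix(runif(nr * nc, 0.1, 5), nr, nc,
         dimnames = list(paste0("g", seq_len(nr)), paste0("s", seq_len(nc))))
}

test_that("an exact rank-1 matrix is reconstructed to negligible KL divergence", {
  set.seed(31)
  w <- runif(30, 0.5, 2)
  h <- runif(12, 0.5, 2)
  V <- outer(w, h)
  dimnames(V) <- list(paste0("g", 1:30), paste0("s", 1:12))
  fit <- nmf_factorize(V, 1, seed = 1, max_iter = 5000, tol = 1e-12)
  expect_lt(tail(fit$objective_trace, 1), 1e-6)
})

test_that("the KL objective trace is non-increasing at every iteration", {
  for (seed in 1:5) {
    V <- random_v(30, 20, seed)
    fit <- nmf_factorize(V, 3, seed = seed, max_iter = 300, tol = 0,
                         trace_every = 1)
    tr <- fit$objective_trace
    expect_true(all(diff(tr) <= 1e-8 * pmax(abs(tr[-length(tr)]), 1)))
  }
})

test_that("factorization is deterministic and validates its inputs", {
  V <- random_v(20, 10, 2)
  a <- nmf_factorize(V, 2, seed = 7, max_iter = 100)
  b <- nmf_factorize(V, 2, seed = 7, max_iter = 100)
  expect_identical(a$W, b$W)
  expect_identical(a$H, b$H)
  expect_true(all(a$W >= 0) && all(a$H >= 0))

  Vneg <- V; Vneg[1, 1] <- -1
  expect_error(nmf_factorize(Vneg, 2), "nonnegative")
  expect_error(nmf_factorize(V, 10), "min\\(dim")
  Vzero <- V; Vzero[3, ] <- 0
  expect_warning(nmf_factorize(Vzero, 2, max_iter = 20), "all-zero")
})

test_that("subtype assignment takes the largest coefficient with deterministic ties", {
  H <- cbind(s1 = c(0.1, 0.9, 0.2), s2 = c(0.5, 0.5, 0.1),
             s3 = c(0, 0, 0))
  rownames(H) <- paste0("module", 1:3)
  model <- structure(list(W = matrix(1, 2, 3,
                                     dimnames = list(c("a", "b"), rownames(H))),
                          H = H, k = 3L, objective_trace = 1,
                          iterations = 1L, seed = 1L),
                     class = "nmf_model")
  lab <- assign_subtypes(model)
  expect_equal(unname(lab[c("s1", "s2")]), c(2L, 1L))
  expect_true(is.na(lab["s3"]))
  expect_equal(attr(lab, "n_ties"), 1L)
  expect_equal(attr(lab, "unassignable"), "s3")
})

test_that("labels are equivariant under sample permutation of the coefficients", {
  set.seed(41)
  H <- matrix(runif(3 * 12), 3, 12,
              dimnames = list(paste0("module", 1:3), paste0("s", 1:12)))
  model <- structure(list(W = matrix(1, 2, 3), H = H, k = 3L,
                          objective_trace = 1, iterations = 1L, seed = 1L),
                     class = "nmf_model")
  perm <- sample(12)
  model_p <- model
  model_p$H <- H[, perm]
  expect_identical(as.vector(assign_subtypes(model_p)),
                   as.vector(assign_subtypes(model))[perm])
})

test_that("noise-free block data gives an exactly block-structured consensus", {
  blockV <- matrix(0.01, 40, 12)
  blockV[1:20, 1:6] <- 5
  blockV[21:40, 7:12] <- 5
  dimnames(blockV) <- list(paste0("g", 1:40), paste0("s", 1:12))
  cc <- consensus_cluster(blockV, 2, n_runs = 5, seed = 1, max_iter = 200)
  expect_true(all(cc$consensus %in% c(0, 1)))
  expect_equal(cc$cophenetic, 1)
  expect_true(all(diag(cc$consensus) == 1))
  expect_equal(cc$consensus, t(cc$consensus))
  expect_true(all(cc$consensus >= 0 & cc$consensus <= 1))
})

test_that("cophenetic correlation matches a hand-worked 3-sample dendrogram", {
  consensus <- matrix(c(1, 0.8, 0.2,
                        0.8, 1, 0.4,
                        0.2, 0.4, 1), 3, 3,
                      dimnames = list(paste0("s", 1:3), paste0("s", 1:3)))
  # dissimilarities d = (0.2, 0.8, 0.6); average linkage merges {1,2} at
  # 0.2, then joins 3 at mean(0.8, 0.6) = 0.7, so cophenetic distances are
  # (0.2, 0.7, 0.7); the statistic is their Pearson correlation with d.
  d <- c(0.2, 0.8, 0.6)
  cop <- c(0.2, 0.7, 0.7)
  expected <- sum((d - mean(d)) * (cop - mean(cop))) /
    sqrt(sum((d - mean(d))^2) * sum((cop - mean(cop))^2))
  st <- pcdsubtype:::consensus_stats(consensus, 2)
  expect_equal(st$cophenetic, expected, tolerance = 1e-12)
})

test_that("rank selection breaks cophenetic ties toward the smaller rank", {
  # two candidate ranks on data whose consensus is perfect for both ranks
  blockV <- matrix(0.01, 30, 9)
  blockV[1:10, 1:3] <- 6
  blockV[11:20, 4:6] <- 6
  blockV[21:30, 7:9] <- 6
  dimnames(blockV) <- list(paste0("g", 1:30), paste0("s", 1:9))
  rs <- select_rank(blockV, k_min = 3, k_max = 4, n_runs = 4, seed = 2,
                    max_iter = 300)
  if (rs$cophenetic[["3"]] == rs$cophenetic[["4"]]) {
    expect_equal(rs$selected_k, 3L)
  } else {
    expect_equal(rs$selected_k,
                 as.integer(names(which.max(rs$cophenetic))))
  }
})
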