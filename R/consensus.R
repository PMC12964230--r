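#' Consensus clustering over replicate NMF runs
#'
#' Runs `n_runs` factorizations at rank `k` from seeds derived from the
#' master seed, assigns each sample to its largest-coefficient module per
#' run, and averages the run-wise connectivity matrices (1 where two
#' samples share a module).  The cophenetic correlation is the Pearson
#' correlation between the consensus dissimilarities `1 - consensus` and
#' the cophenetic distances of their average-linkage dendrogram; the mean
#' silhouette width is computed on `1 - consensus` with the dendrogram's
#' k-cut labels.
#'
#' @param V Nonnegative genes-by-samples matrix.
#' @param k Rank (number of modules).
#' @param n_runs Number of replicate runs (>= 2; the discovery default is
#'   30).
#' @param seed Master seed; run `r` uses `seed + r - 1`.
#' @param max_iter Iteration cap per replicate run (default 1000; module
#'   membership stabilizes well before full objective convergence, so
#'   replicate runs are capped more tightly than a single discovery fit).
#' @param ... Passed to [nmf_factorize()] (e.g. `tol`).
#' @return A `consensus_result` list: `consensus` (samples x samples),
#'   `n_runs`, `k`, `cophenetic`, `silhouette`, `consensus_labels` (k-cut of
#'   the dendrogram), `best_model` (the run with the lowest final KL
#'   divergence), and `consensus_basis` — the per-run basis matrices
#'   averaged after aligning module order across runs (modules are matched
#'   to the first run by best-permutation correlation of coefficient
#'   rows).  Averaging over replicates cancels the run-to-run
#'   indeterminacy in how shared expression is allocated across modules,
#'   giving a more stable basis for signature extraction than any single
#'   run.
#' @export
consensus_cluster <- function(V, k, n_runs = 30L, seed = 1L,
                              max_iter = 1000L, ...) {
  stopifnot_scalar_int(n_runs, "n_runs", 2L)
  n <- ncol(V)
  if (n < 3L) stop("consensus clustering needs >= 3 samples")
  consensus <- matrix(0, n, n, dimnames = list(colnames(V), colnames(V)))
  best <- NULL
  best_obj <- Inf
  best_perm <- NULL
  W_sum <- NULL
  H_ref <- NULL
  perms <- all_permutations(k)
  for (r in seq_len(n_runs)) {
    model <- nmf_factorize(V, k, seed = seed + r - 1L,
                           max_iter = max_iter, ...)
    labels <- assign_subtypes(model)
    conn <- outer(labels, labels, `==`) * 1
    conn[is.na(conn)] <- 0            # unassignable samples join nothing
    consensus <- consensus + conn
    if (is.null(W_sum)) {
      H_ref <- model$H
      W_sum <- model$W
      p <- seq_len(k)
    } else {
      # match this run's modules to the reference run's
      cc <- cor(t(H_ref), t(model$H))
      cc[!is.finite(cc)] <- 0
      sums <- vapply(perms, function(p) sum(cc[cbind(seq_len(k), p)]),
                     numeric(1L))
      p <- perms[[which.max(sums)]]
      W_sum <- W_sum + model$W[, p, drop = FALSE]
    }
    obj <- model$objective_trace[length(model$objective_trace)]
    if (obj < best_obj) {
      best_obj <- obj
      best <- model
      best_perm <- p
    }
  }
  consensus <- consensus / n_runs
  consensus_basis <- W_sum / n_runs
  colnames(consensus_basis) <- paste0("module", seq_len(k))
  # put the best model in the reference module order so its labels index
  # the same modules as the consensus basis
  best$W <- best$W[, best_perm, drop = FALSE]
  best$H <- best$H[best_perm, , drop = FALSE]
  colnames(best$W) <- paste0("module", seq_len(k))
  rownames(best$H) <- paste0("module", seq_len(k))
  stats_ <- consensus_stats(consensus, k)
  structure(list(consensus = consensus, n_runs = as.integer(n_runs),
                 k = as.integer(k), cophenetic = stats_$cophenetic,
                 silhouette = stats_$silhouette,
                 consensus_labels = stats_$labels, best_model = best,
                 consensus_basis = consensus_basis),
            class = "consensus_result")
}

# cophenetic correlation, mean silhouette width, and k-cut labels of a
# consensus matrix; cophenetic defined as 1 when the dissimilarities (or
# dendrogram heights) are degenerate-constant
consensus_stats <- function(consensus, k) {
  d <- stats::as.dist(1 - consensus)
  hc <- hclust(d, method = "average")
  cop <- cophenetic(hc)
  dv <- as.numeric(d)
  cv <- as.numeric(cop)
  coph <- if (sd(dv) == 0 || sd(cv) == 0) 1 else cor(dv, cv)
  labels <- cutree(hc, k = k)
  sil <- mean(cluster::silhouette(labels, d)[, "sil_width"])
  list(cophenetic = coph, silhouette = sil, labels = labels)
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("Consensus over %d NMF runs at k = %d: cophenetic %.4f, mean silhouette %.4f\n",
              x$n_runs, x$k, x$cophenetic, x$silhouette))
  invisible(x)
}

#' Select the NMF rank by maximal cophenetic correlation
#'
#' Runs [consensus_cluster()] for each candidate rank and keeps the rank
#' with the largest cophenetic correlation coefficient; ties are broken
#' toward the smaller rank (parsimony).
#'
#' @param V Nonnegative genes-by-samples matrix.
#' @param k_min,k_max Candidate rank range (discovery default 3..7).
#' @param n_runs Replicate runs per rank.
#' @param seed Master seed, shared across ranks.
#' @param ... Passed to [consensus_cluster()] (e.g. `max_iter`).
#' @return A `rank_selection` list: `ranks`, `results` (one
#'   `consensus_result` per rank), `cophenetic` (named vector),
#'   `selected_k`.
#' @export
select_rank <- function(V, k_min = 3L, k_max = 7L, n_runs = 30L, seed = 1L,
                        ...) {
  stopifnot_scalar_int(k_min, "k_min", 2L)
  stopifnot_scalar_int(k_max, "k_max", k_min)
  if (k_max >= min(dim(V))) stop("k_max must be < min(dim(V))")
  ranks <- seq.int(k_min, k_max)
  results <- lapply(ranks, function(k) {
    consensus_cluster(V, k, n_runs = n_runs, seed = seed, ...)
  })
  coph <- setNames(vapply(results, `[[`, numeric(1L), "cophenetic"),
                   ranks)
  selected <- ranks[which.max(coph)]   # which.max takes the first maximum
  structure(list(ranks = ranks, results = setNames(results, ranks),
                 cophenetic = coph, selected_k = as.integer(selected)),
            class = "rank_selection")
}

#' @export
print.rank_selection <- function(x, ...) {
  cat("Cophenetic correlation by rank:\n")
  print(round(x$cophenetic, 4L))
  cat("Selected k =", x$selected_k, "\n")
  invisible(x)
}
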