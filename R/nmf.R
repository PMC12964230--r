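#' Factorize an expression matrix by KL-divergence NMF
#'
#' Multiplicative-update non-negative matrix factorization (Lee-Seung /
#' Brunet form) minimizing the generalized Kullback-Leibler divergence
#' between `V` and `W %*% H`.  `W` (genes x modules) holds the basis
#' weights used for signature extraction; `H` (modules x samples) holds the
#' sample coefficients used for subtype assignment.  Factors are
#' initialized i.i.d. uniform and scaled so the initial reconstruction
#' matches `mean(V)`; the objective trace is non-increasing by
#' construction.
#'
#' The diagonal scale indeterminacy of NMF (`W D` and `D^-1 H` reconstruct
#' identically) is resolved by balancing `W`'s columns to equal total
#' weight, with the inverse scaling applied to `H`'s rows.  This keeps
#' `W %*% H` and the objective unchanged and makes basis weights
#' comparable across modules, which the global signature cutoff requires.
#'
#' @param V Nonnegative genes-by-samples matrix with dimnames.  All-zero
#'   rows are dropped with a warning; all-zero columns are an error.
#' @param k Factorization rank, `1 <= k < min(dim(V))`.
#' @param seed Integer seed for the initialization.
#' @param max_iter Maximum update iterations (default 2000).
#' @param tol Relative objective change over a 10-iteration window below
#'   which iteration stops (default 1e-5).
#' @param trace_every Record the objective every this many iterations
#'   (default 10; use 1 for a per-iteration trace).  Must divide 10, the
#'   convergence window.
#' @return An `nmf_model` list: `W`, `H`, `k`, `objective_trace`,
#'   `trace_iterations` (iteration index of each trace entry),
#'   `iterations`, `seed`.
#' @export
nmf_factorize <- function(V, k, seed = 1L, max_iter = 2000L, tol = 1e-5,
                          trace_every = 10L) {
  stopifnot_matrix(V)
  if (any(V < 0)) stop("NMF input must be nonnegative")
  zero_rows <- rowSums(V) == 0
  if (any(zero_rows)) {
    warning(sum(zero_rows), " all-zero gene row(s) dropped before NMF")
    V <- V[!zero_rows, , drop = FALSE]
  }
  if (any(colSums(V) == 0)) stop("all-zero sample column(s) in NMF input")
  stopifnot_scalar_int(k, "k", 1L)
  if (k >= min(dim(V))) stop("rank k must be < min(dim(V))")

  init <- with_seed(seed, {
    scale <- 2 * sqrt(mean(V) / k)
    list(W = matrix(runif(nrow(V) * k), nrow(V), k) * scale,
         H = matrix(runif(k * ncol(V)), k, ncol(V)) * scale)
  })
  stopifnot_scalar_int(trace_every, "trace_every", 1L)
  if (10L %% trace_every != 0L) stop("`trace_every` must divide 10")
  fit <- .nmf_kl_cpp(V, init$W, init$H, as.integer(max_iter), tol, 10L,
                     as.integer(trace_every))
  cs <- colSums(fit$W)
  scale <- cs / mean(cs)
  W <- sweep(fit$W, 2L, scale, "/")
  H <- sweep(fit$H, 1L, scale, "*")
  dimnames(W) <- list(rownames(V), paste0("module", seq_len(k)))
  dimnames(H) <- list(paste0("module", seq_len(k)), colnames(V))
  structure(list(W = W, H = H, k = as.integer(k),
                 objective_trace = fit$objective_trace,
                 trace_iterations = fit$trace_iterations,
                 iterations = fit$iterations, seed = as.integer(seed)),
            class = "nmf_model")
}

#' @export
print.nmf_model <- function(x, ...) {
  cat(sprintf("NMF model: %d genes x %d samples, rank k = %d\n",
              nrow(x$W), ncol(x$H), x$k))
  cat(sprintf("  KL divergence %.4g after %d iterations (seed %d)\n",
              tail(x$objective_trace, 1L), x$iterations, x$seed))
  invisible(x)
}

#' Assign samples to NMF modules
#'
#' Each sample is labelled with the module of its largest coefficient in
#' `H`; ties go to the smallest module index and are counted.  Samples with
#' an all-zero coefficient column cannot be assigned and get `NA`.
#'
#' @param model An `nmf_model`.
#' @return Integer vector of module labels named by sample, with attributes
#'   `n_ties` and `unassignable` (sample IDs with all-zero columns).
#' @export
assign_subtypes <- function(model) {
  stopifnot(inherits(model, "nmf_model"))
  H <- model$H
  labels <- apply(H, 2L, which.max)
  maxes <- apply(H, 2L, max)
  ties <- colSums(H == rep(maxes, each = nrow(H))) > 1L
  zero <- colSums(H) == 0
  labels[zero] <- NA_integer_
  structure(setNames(as.integer(labels), colnames(H)),
            n_ties = sum(ties & !zero),
            unassignable = colnames(H)[zero])
}
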