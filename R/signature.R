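#' Global weight cutoff from the basis matrix
#'
#' The adaptive threshold for candidate signature genes: the `q`-th
#' quantile of *all* entries of `W` (default the 80th percentile), under
#' R's default linear-interpolation quantile (type 7).  This global-quantile
#' reading of "80% of all weights" is the default; see
#' [extract_signatures()] for the fraction-of-maximum alternative.
#'
#' @param W Nonnegative genes-by-modules basis matrix.
#' @param q Quantile in (0, 1), default 0.8.
#' @return The cutoff, a single number.
#' @export
global_weight_cutoff <- function(W, q = 0.8) {
  if (!is.numeric(W) || length(W) == 0L) stop("`W` must be a nonempty numeric matrix")
  if (any(W < 0)) stop("`W` must be nonnegative")
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1) {
    stop("`q` must be in (0, 1)")
  }
  unname(quantile(as.numeric(W), probs = q, type = 7L))
}

#' Extract mutually exclusive subtype signature genes
#'
#' The three-step procedure applied to the basis matrix `W`:
#' \enumerate{
#'   \item per module, candidate genes are those whose weight exceeds the
#'     global cutoff;
#'   \item a module with fewer than `min_genes` candidates falls back to
#'     its `min_genes` highest-weight genes (ties broken lexicographically
#'     by gene ID);
#'   \item genes appearing in more than one module's candidate list are
#'     removed from all of them.
#' }
#' Steps run in exactly this order, so modules may end up with fewer than
#' `min_genes` genes after the exclusivity step; no refilling is done.
#'
#' @param W Nonnegative genes-by-modules basis matrix with row names.
#' @param cutoff Global weight cutoff, typically from
#'   [global_weight_cutoff()].  With `cutoff_mode = "max-fraction"` the
#'   threshold used is `cutoff * max(W)` instead (an alternative reading of
#'   an "80% of all weights" rule; pass `cutoff = 0.8`).
#' @param min_genes Fallback module size (default 10).
#' @param cutoff_mode `"quantile"` (default; `cutoff` is an absolute
#'   threshold) or `"max-fraction"`.
#' @return A `subtype_signature` list: `modules` (named list of gene
#'   vectors ordered by decreasing weight), `cutoff`, `counts` (per-step
#'   per-module gene counts).
#' @export
extract_signatures <- function(W, cutoff, min_genes = 10L,
                               cutoff_mode = c("quantile", "max-fraction")) {
  cutoff_mode <- match.arg(cutoff_mode)
  if (!is.matrix(W) || is.null(rownames(W))) {
    stop("`W` must be a matrix with gene row names")
  }
  if (cutoff < 0) stop("`cutoff` must be >= 0")
  stopifnot_scalar_int(min_genes, "min_genes", 1L)
  if (nrow(W) < min_genes) stop("`W` has fewer than `min_genes` rows")
  if (any(colSums(W) == 0)) {
    stop("module with no weights (all-zero column): ",
         colnames(W)[colSums(W) == 0][1L])
  }
  thr <- if (cutoff_mode == "max-fraction") cutoff * max(W) else cutoff
  k <- ncol(W)
  mod_names <- colnames(W)
  if (is.null(mod_names)) mod_names <- paste0("module", seq_len(k))

  # Step 1: global threshold
  step1 <- lapply(seq_len(k), function(m) {
    w <- W[, m]
    genes <- rownames(W)[w > thr]
    genes[order(-w[match(genes, rownames(W))], genes)]
  })
  # Step 2: top-min_genes fallback for sparse modules
  step2 <- lapply(seq_len(k), function(m) {
    if (length(step1[[m]]) >= min_genes) return(step1[[m]])
    w <- W[, m]
    rownames(W)[order(-w, rownames(W))][seq_len(min_genes)]
  })
  # Step 3: enforce mutual exclusivity
  all_genes <- unlist(step2, use.names = FALSE)
  shared <- unique(all_genes[duplicated(all_genes)])
  final <- lapply(step2, function(g) setdiff(g, shared))
  names(final) <- mod_names

  counts <- data.frame(module = mod_names,
                       candidates = lengths(step1),
                       after_fallback = lengths(step2),
                       final = lengths(final),
                       stringsAsFactors = FALSE)
  structure(list(modules = final, cutoff = thr, counts = counts),
            class = "subtype_signature")
}

#' @export
print.subtype_signature <- function(x, ...) {
  cat(sprintf("Subtype signature: %d modules, %d genes total (cutoff %.4g)\n",
              length(x$modules), sum(lengths(x$modules)), x$cutoff))
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Write a subtype signature as a GMT gene-set file
#'
#' One line per module, named `PCDS1..PCDSk`; modules emptied by the
#' exclusivity step are omitted with a warning.  Round-trips through
#' [read_gmt()].
#'
#' @param signature A `subtype_signature`.
#' @param path Output GMT path.
#' @return `path`, invisibly.
#' @export
signature_to_gmt <- function(signature, path) {
  stopifnot(inherits(signature, "subtype_signature"))
  sets <- signature$modules
  names(sets) <- paste0("PCDS", seq_along(sets))
  empty <- lengths(sets) == 0L
  if (all(empty)) stop("signature has no genes in any module")
  if (any(empty)) {
    warning("omitting empty module(s): ",
            paste(names(sets)[empty], collapse = ", "))
    sets <- sets[!empty]
  }
  write_gmt(sets, path)
}
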