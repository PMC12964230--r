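#' Build binary templates from a subtype signature
#'
#' The template gene universe is the union of all signature genes found in
#' the matrix; each module's template is 1 on its own genes and 0
#' elsewhere.  Missing genes are dropped and reported; classification is
#' refused when the overlap falls below `min_overlap`, or when any module
#' loses all of its genes.
#'
#' @param signature A `subtype_signature`, or a named list of gene vectors
#'   (e.g. from [read_gmt()]).
#' @param matrix Expression matrix whose genes the templates must live in.
#' @param min_overlap Minimum fraction of signature genes that must be
#'   present (default 0.5).
#' @return A `template_set` list: `templates` (universe x modules binary
#'   matrix), `universe`, `missing_genes`.
#' @export
build_templates <- function(signature, matrix, min_overlap = 0.5) {
  sets <- if (inherits(signature, "subtype_signature")) {
    s <- signature$modules
    names(s) <- paste0("PCDS", seq_along(s))
    s
  } else {
    signature
  }
  if (!is.list(sets) || is.null(names(sets)) || length(sets) < 2L) {
    stop("`signature` must provide >= 2 named gene sets")
  }
  stopifnot_matrix(matrix)
  all_genes <- unique(unlist(sets, use.names = FALSE))
  present <- all_genes[all_genes %in% rownames(matrix)]
  frac <- length(present) / length(all_genes)
  if (frac < min_overlap) {
    stop(sprintf("only %.1f%% of signature genes present (< %.0f%% required)",
                 100 * frac, 100 * min_overlap))
  }
  kept <- lapply(sets, function(g) intersect(g, present))
  empty <- lengths(kept) == 0L
  if (any(empty)) {
    stop("module(s) with no genes in the matrix: ",
         paste(names(sets)[empty], collapse = ", "))
  }
  templates <- vapply(kept, function(g) as.numeric(present %in% g),
                      numeric(length(present)))
  rownames(templates) <- present
  structure(list(templates = templates, universe = present,
                 missing_genes = setdiff(all_genes, present)),
            class = "template_set")
}

# distinct cosine distances (in [0, 2]) of sample columns X (u x n) to
# binary templates T (u x k); zero-norm columns give NA rows
cosine_distances <- function(X, templ) {
  xn <- sqrt(colSums(X^2))
  tn <- sqrt(colSums(templ^2))
  D <- 1 - crossprod(X, templ) / (xn %o% tn)
  D[xn == 0, ] <- NA_real_
  D
}

#' Nearest-template prediction with permutation FDR
#'
#' Each sample is assigned the subtype whose binary template is nearest in
#' cosine distance, computed on gene-standardized expression restricted to
#' the template universe.  Significance comes from a gene-label resampling
#' null: for each sample, `n_perm` random gene subsets of the universe's
#' size are drawn from the whole matrix and the null minimum distance
#' recomputed; the add-one permutation p-value is
#' `(1 + #\{null <= observed\}) / (1 + n_perm)`, so p is never zero.
#' Benjamini-Hochberg adjustment runs across all samples of the cohort, and
#' calls with FDR below `fdr_threshold` are flagged confident.
#'
#' @param matrix Genes-by-samples expression matrix; gene standardization
#'   ([zscore_genes()]) is applied internally (idempotent if already done).
#' @param templates A `template_set` from [build_templates()].
#' @param n_perm Resampling iterations (default 1000; < 100 warns).
#' @param fdr_threshold Confidence threshold on BH FDR (default 0.05).
#' @param seed Integer seed for the resampling.
#' @param null `"permutation"` draws gene subsets without replacement (the
#'   default, the reference NTP null); `"bootstrap"` draws with
#'   replacement.
#' @return A `data.frame` (one row per sample): `sample_id`, `label`
#'   (template name, `NA` if unclassifiable), `dist` (minimum distance),
#'   one `dist.<template>` column per template, `p_value`, `fdr`,
#'   `confident`, `tie`.  Attribute `null` records the resampling mode.
#' @export
ntp_classify <- function(matrix, templates, n_perm = 1000L,
                         fdr_threshold = 0.05, seed = 1L,
                         null = c("permutation", "bootstrap")) {
  null <- match.arg(null)
  stopifnot(inherits(templates, "template_set"))
  stopifnot_scalar_int(n_perm, "n_perm", 2L)
  if (n_perm < 100L) warning("n_perm < 100 gives coarse p-values")
  Z <- zscore_genes(matrix)
  universe <- templates$universe
  if (!all(universe %in% rownames(Z))) {
    stop("matrix lacks template genes; rebuild templates against this matrix")
  }
  templ <- templates$templates
  X <- Z[universe, , drop = FALSE]
  D <- cosine_distances(X, templ)
  mins <- apply(D, 1L, function(d) if (anyNA(d)) NA_real_ else min(d))
  label_idx <- apply(D, 1L, function(d) {
    if (anyNA(d)) NA_integer_ else which.min(d)
  })
  tie <- apply(D, 1L, function(d) !anyNA(d) && sum(d == min(d)) > 1L)

  u <- length(universe)
  G <- nrow(Z)
  n <- ncol(Z)
  replace <- null == "bootstrap"
  p <- rep(NA_real_, n)
  with_seed(seed, {
    for (j in seq_len(n)) {
      if (is.na(mins[j])) next
      idx <- if (replace) {
        matrix(sample.int(G, u * n_perm, replace = TRUE), u, n_perm)
      } else {
        vapply(seq_len(n_perm), function(b) sample.int(G, u),
               integer(u))
      }
      M <- matrix(Z[, j][idx], u, n_perm)
      nd <- cosine_distances(M, templ)
      null_min <- apply(nd, 1L, min)
      null_min[is.na(null_min)] <- Inf   # degenerate draws never beat observed
      p[j] <- (1 + sum(null_min <= mins[j])) / (1 + n_perm)
    }
  })
  fdr <- p.adjust(p, method = "BH")
  out <- data.frame(sample_id = colnames(matrix),
                    label = colnames(templ)[label_idx],
                    dist = mins, stringsAsFactors = FALSE)
  dd <- as.data.frame(D)
  names(dd) <- paste0("dist.", colnames(templ))
  out <- cbind(out, dd)
  out$p_value <- p
  out$fdr <- fdr
  out$confident <- !is.na(fdr) & fdr < fdr_threshold
  out$tie <- tie
  rownames(out) <- NULL
  attr(out, "null") <- null
  attr(out, "n_perm") <- as.integer(n_perm)
  out
}

# all permutations of 1..n (n <= 8)
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  i <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      i <- i + 1L
      out[[i]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

#' Agreement between two labelings of the same samples
#'
#' Computes the adjusted Rand index and the raw agreement fraction under
#' the best one-to-one matching of label values (exhaustive assignment over
#' the confusion matrix; label sets of up to 8 classes).
#'
#' @param labels_a,labels_b Vectors of labels named by sample; the sample
#'   sets must intersect (comparison runs on the intersection).
#' @return A list: `ari`, `agreement`, `n` (samples compared), `mapping`
#'   (named vector mapping levels of `labels_a` to levels of `labels_b`).
#' @export
cohort_concordance <- function(labels_a, labels_b) {
  if (is.null(names(labels_a)) || is.null(names(labels_b))) {
    stop("labelings must be named by sample")
  }
  common <- intersect(names(labels_a), names(labels_b))
  if (length(common) == 0L) stop("label vectors share no samples")
  a <- as.character(labels_a[common])
  b <- as.character(labels_b[common])
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]
  b <- b[keep]
  ari <- mclust::adjustedRandIndex(a, b)
  tab <- table(a, b)
  la <- rownames(tab)
  lb <- colnames(tab)
  if (length(la) > 8L || length(lb) > 8L) {
    stop("best-matching agreement supports at most 8 classes")
  }
  # pad to square so permutation search covers unequal label sets
  k <- max(length(la), length(lb))
  sq <- matrix(0, k, k)
  sq[seq_along(la), seq_along(lb)] <- tab
  best <- -Inf
  best_perm <- NULL
  for (p in all_permutations(k)) {
    s <- sum(sq[cbind(seq_len(k), p)])
    if (s > best) {
      best <- s
      best_perm <- p
    }
  }
  mapping <- setNames(lb[best_perm[seq_along(la)]], la)
  list(ari = ari, agreement = best / length(a), n = length(a),
       mapping = mapping[!is.na(mapping)])
}
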