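#' Single-sample gene-set enrichment (ssGSEA) scores
#'
#' For each sample, genes are ranked by expression (descending; average
#' ranks for ties) and each set's score is the sum, along the ranked list,
#' of the difference between the weighted in-set empirical CDF (weights =
#' rank^alpha, ranks counted from the bottom so the top gene weighs most)
#' and the unweighted out-of-set empirical CDF.  Scores depend only on the
#' within-sample ranking, so they are invariant under any strictly
#' monotone transform of a sample's values.
#'
#' @param matrix Genes-by-samples expression matrix.
#' @param gene_sets Named list of gene vectors (e.g. from [read_gmt()]).
#' @param alpha Rank-weight exponent (default 0.25, the canonical ssGSEA
#'   weight).
#' @param min_overlap Minimum genes a set must share with the matrix
#'   (default 5); a smaller overlap is an error.
#' @param normalize If `TRUE`, scores are min-max rescaled by the range of
#'   all scores in the matrix (recorded in the `normalized` attribute).
#' @return Pathway-by-sample numeric matrix of enrichment scores.
#' @export
ssgsea_score <- function(matrix, gene_sets, alpha = 0.25, min_overlap = 5L,
                         normalize = FALSE) {
  stopifnot_matrix(matrix)
  if (!is.list(gene_sets) || is.null(names(gene_sets)) ||
      length(gene_sets) == 0L) {
    stop("`gene_sets` must be a non-empty named list")
  }
  genes <- rownames(matrix)
  idx_sets <- lapply(names(gene_sets), function(nm) {
    hit <- which(genes %in% gene_sets[[nm]])
    if (length(hit) < min_overlap) {
      stop(sprintf("gene set '%s' overlaps only %d matrix genes (< %d)",
                   nm, length(hit), min_overlap))
    }
    hit
  })
  names(idx_sets) <- names(gene_sets)
  N <- nrow(matrix)
  scores <- matrix(NA_real_, length(gene_sets), ncol(matrix),
                   dimnames = list(names(gene_sets), colnames(matrix)))
  for (j in seq_len(ncol(matrix))) {
    x <- matrix[, j]
    r <- rank(x, ties.method = "average")    # top gene gets rank N
    ord <- order(-x, genes)                  # deterministic descending order
    r_ord <- r[ord]
    for (s in seq_along(idx_sets)) {
      inset <- ord %in% idx_sets[[s]]
      w <- r_ord^alpha * inset
      p_in <- cumsum(w) / sum(w)
      p_out <- cumsum(!inset) / (N - sum(inset))
      scores[s, j] <- sum(p_in - p_out)
    }
  }
  if (normalize) {
    rng <- range(scores)
    if (diff(rng) > 0) scores <- scores / diff(rng)
  }
  attr(scores, "normalized") <- normalize
  attr(scores, "alpha") <- alpha
  scores
}

#' Subtype-specific differential expression
#'
#' Per-gene Welch two-sample t-test of the target subtype against all
#' other samples on log2-scale values, with Benjamini-Hochberg adjustment
#' across genes.  The fold change is `2^(mean log2 difference)`; a gene
#' passes when its adjusted p-value is below `alpha` and its fold change
#' exceeds `fc_threshold` (up-regulation in the target), the filter used to
#' call subtype-specific up-regulated genes.  This is a simple test, not a
#' moderated (shrunken-variance) linear-model fit; the choice is recorded
#' in the `method` attribute.
#'
#' @param matrix Genes-by-samples log2 expression matrix.
#' @param labels Subtype labels named by sample, covering all columns.
#' @param target_subtype The subtype to contrast against the rest.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param fc_threshold Fold-change threshold (default 1.5).
#' @return A `data.frame`: `gene`, `log2_fc`, `fold_change`, `p_value`,
#'   `adj_p`, `direction` (-1/0/1), `pass`.
#' @export
differential_expression <- function(matrix, labels, target_subtype,
                                    alpha = 0.05, fc_threshold = 1.5) {
  stopifnot_matrix(matrix)
  if (is.null(names(labels))) stop("`labels` must be named by sample")
  lab <- labels[colnames(matrix)]
  if (anyNA(lab)) stop("labels missing for some samples")
  in_target <- lab == target_subtype
  n1 <- sum(in_target)
  n2 <- sum(!in_target)
  if (n1 < 3L || n2 < 3L) {
    stop("target and complement each need >= 3 samples (got ",
         n1, " and ", n2, ")")
  }
  X1 <- matrix[, in_target, drop = FALSE]
  X2 <- matrix[, !in_target, drop = FALSE]
  m1 <- rowMeans(X1)
  m2 <- rowMeans(X2)
  v1 <- rowSums((X1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((X2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  diff <- m1 - m2
  tstat <- diff / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(diff[degenerate] == 0, 1, 0)
  adj <- p.adjust(p, method = "BH")
  fc <- 2^diff
  data.frame(gene = rownames(matrix), log2_fc = diff, fold_change = fc,
             p_value = p, adj_p = adj, direction = sign(diff),
             pass = adj < alpha & fc > fc_threshold,
             stringsAsFactors = FALSE, row.names = NULL) ->
    out
  attr(out, "method") <- "welch_t"
  out
}

#' Per-subtype mean pathway activity
#'
#' Summarizes a [ssgsea_score()] matrix by subtype: the mean score per
#' (pathway, subtype) cell plus a Kruskal-Wallis p-value across subtypes
#' per pathway.
#'
#' @param scores Pathway-by-sample score matrix.
#' @param labels Subtype labels named by sample, covering all scored
#'   samples; every subtype level must be non-empty.
#' @return A list: `means` (pathway x subtype matrix), `p_values` (named
#'   vector per pathway).
#' @export
pcd_activity_summary <- function(scores, labels) {
  if (is.null(names(labels))) stop("`labels` must be named by sample")
  lab <- labels[colnames(scores)]
  if (anyNA(lab)) stop("labels missing for some scored samples")
  lab <- factor(lab)
  if (any(table(lab) == 0L)) {
    stop("subtype with zero samples: ",
         paste(levels(lab)[table(lab) == 0L], collapse = ", "))
  }
  means <- t(apply(scores, 1L, function(x) tapply(x, lab, mean)))
  colnames(means) <- levels(lab)
  p <- apply(scores, 1L, function(x) {
    if (length(unique(x)) == 1L) return(1)
    kruskal.test(x, lab)$p.value
  })
  list(means = means, p_values = p)
}
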