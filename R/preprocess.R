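#' Collapse probeset-level rows to gene level
#'
#' When several probesets measure the same gene, the gene's expression is
#' taken as the arithmetic mean of its probeset rows.  Probesets absent from
#' the mapping are dropped; their count is recorded in the
#' `dropped_probesets` attribute of the result.
#'
#' @param matrix Probeset-by-sample numeric matrix with dimnames.
#' @param mapping A `data.frame` with columns `probeset` and `gene`, each
#'   probeset mapped to exactly one gene.
#' @return Gene-by-sample matrix; rows ordered by gene ID.
#' @export
collapse_probesets <- function(matrix, mapping) {
  stopifnot_matrix(matrix)
  if (!is.data.frame(mapping) || !all(c("probeset", "gene") %in% names(mapping))) {
    stop("`mapping` must be a data.frame with columns `probeset` and `gene`")
  }
  if (nrow(mapping) == 0L) stop("empty probeset-to-gene mapping")
  if (anyDuplicated(mapping$probeset)) {
    dup <- mapping$probeset[duplicated(mapping$probeset)][1L]
    stop("probeset mapped to more than one gene: ", dup)
  }
  keep <- rownames(matrix) %in% mapping$probeset
  dropped <- sum(!keep)
  sub <- matrix[keep, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no probeset in `matrix` is covered by `mapping`")
  genes <- mapping$gene[match(rownames(sub), mapping$probeset)]
  sums <- rowsum(sub, group = genes)
  counts <- as.vector(table(genes)[rownames(sums)])
  out <- sums / counts
  out <- out[order(rownames(out)), , drop = FALSE]
  attr(out, "dropped_probesets") <- dropped
  out
}

#' Standardize per-batch location and scale
#'
#' A simple surrogate for batch-effect removal: within each batch, every
#' gene is centered and rescaled to the pooled cross-batch mean and
#' (population) standard deviation.  Gene-batch combinations with zero
#' within-batch variance are centered only.  Because NMF requires
#' nonnegative input, the result is shifted by a recorded global constant so
#' its minimum is >= 0 (attribute `global_shift`); truncation is never used.
#'
#' An additive per-batch, per-gene offset is removed exactly: after
#' correction all batch means of a gene equal its pooled mean.
#'
#' @param matrix Gene-by-sample numeric matrix with dimnames.
#' @param annotation `data.frame` with columns `sample_id` and `batch`
#'   covering every column of `matrix`; every batch needs >= 2 samples.
#' @return Corrected matrix with attribute `global_shift`.
#' @export
batch_standardize <- function(matrix, annotation) {
  stopifnot_matrix(matrix)
  if (!is.data.frame(annotation) ||
      !all(c("sample_id", "batch") %in% names(annotation))) {
    stop("`annotation` must have columns `sample_id` and `batch`")
  }
  idx <- match(colnames(matrix), annotation$sample_id)
  if (anyNA(idx)) {
    stop("samples missing from annotation: ",
         paste(head(colnames(matrix)[is.na(idx)], 3L), collapse = ", "))
  }
  batch <- as.character(annotation$batch[idx])
  if (any(!nzchar(batch)) || anyNA(batch)) stop("empty batch labels")
  sizes <- table(batch)
  if (any(sizes < 2L)) {
    stop("singleton batch: ", names(sizes)[sizes < 2L][1L])
  }
  out <- matrix
  pooled_mean <- rowMeans(matrix)
  pooled_sd <- apply(matrix, 1L, pop_sd)
  for (b in unique(batch)) {
    cols <- which(batch == b)
    sub <- matrix[, cols, drop = FALSE]
    bm <- rowMeans(sub)
    bs <- apply(sub, 1L, pop_sd)
    scale <- ifelse(bs > 0, pooled_sd / bs, 1)   # center-only when flat
    out[, cols] <- (sub - bm) * scale + pooled_mean
  }
  shift <- max(0, -min(out))
  out <- out + shift
  attr(out, "global_shift") <- shift
  out
}

#' Row-standardize genes (z-score)
#'
#' Each gene row is centered to mean 0 and scaled to population standard
#' deviation 1.  Rows with zero variance are set to all zeros and their IDs
#' recorded in the `flat_genes` attribute.  Used upstream of
#' nearest-template distances and heatmaps; idempotent.
#'
#' @param matrix Gene-by-sample numeric matrix with >= 2 samples.
#' @return Row-standardized matrix with attribute `flat_genes`.
#' @export
zscore_genes <- function(matrix) {
  stopifnot_matrix(matrix)
  if (ncol(matrix) < 2L) stop("z-scoring needs >= 2 samples")
  mu <- rowMeans(matrix)
  sdv <- sqrt(rowMeans((matrix - mu)^2))
  flat <- sdv == 0
  sdv[flat] <- 1
  out <- (matrix - mu) / sdv
  out[flat, ] <- 0
  attr(out, "flat_genes") <- rownames(matrix)[flat]
  out
}
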