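#' Observed-over-expected (Ro/e) cell-type enrichment
#'
#' Builds the cell-type-by-subtype contingency table of cell counts,
#' derives expected counts from the chi-squared independence model
#' (`row_total * col_total / grand_total`), and reports the Ro/e ratio with
#' the conventional symbol bins: `+++` for Ro/e > 3, `++` for 1 < Ro/e <=
#' 3, `+` for 0.2 <= Ro/e <= 1 (so a cell type exactly at independence is
#' `+`), `+/-` for 0 < Ro/e < 0.2, and `-` for Ro/e = 0.
#'
#' @param cells `data.frame` with columns `cell_type` and `subtype` (one
#'   row per cell), e.g. from [simulate_single_cell()].  At least two cell
#'   types and two subtypes; zero marginals are an error.
#' @return A `data.frame`: `cell_type`, `subtype`, `observed`, `expected`,
#'   `roe`, `symbol`.
#' @export
roe_enrichment <- function(cells) {
  if (!is.data.frame(cells) ||
      !all(c("cell_type", "subtype") %in% names(cells))) {
    stop("`cells` must have columns `cell_type` and `subtype`")
  }
  tab <- table(cells$cell_type, cells$subtype)
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop("need >= 2 cell types and >= 2 subtypes")
  }
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs == 0)) stop("zero marginal for cell type: ",
                         names(rs)[rs == 0][1L])
  if (any(cs == 0)) stop("zero marginal for subtype: ",
                         names(cs)[cs == 0][1L])
  expected <- outer(rs, cs) / sum(tab)
  roe <- as.numeric(tab) / as.numeric(expected)
  # bins with the printed boundary ownership: Ro/e = 1 belongs to "+"
  symbol <- character(length(roe))
  symbol[roe == 0] <- "-"
  symbol[roe > 0 & roe < 0.2] <- "+/-"
  symbol[roe >= 0.2 & roe <= 1] <- "+"
  symbol[roe > 1 & roe <= 3] <- "++"
  symbol[roe > 3] <- "+++"
  data.frame(cell_type = rep(rownames(tab), ncol(tab)),
             subtype = rep(colnames(tab), each = nrow(tab)),
             observed = as.numeric(tab),
             expected = as.numeric(expected),
             roe = roe, symbol = symbol,
             stringsAsFactors = FALSE)
}

#' Pseudobulk expression by summing cells within samples
#'
#' Per sample, the pseudobulk gene vector is the sum of (normalized)
#' expression over all of the sample's cells, giving a sample-level matrix
#' consistent with the bulk subtyping framework.  Columns are ordered by
#' sample ID; annotated samples with zero cells are omitted with a warning.
#'
#' @param cell_matrix Genes-by-cells expression matrix.
#' @param cell_annotation `data.frame` with columns `cell_id` and
#'   `sample_id` covering every column of `cell_matrix`.
#' @return Genes-by-samples pseudobulk matrix.
#' @export
pseudobulk <- function(cell_matrix, cell_annotation) {
  stopifnot_matrix(cell_matrix)
  if (!is.data.frame(cell_annotation) ||
      !all(c("cell_id", "sample_id") %in% names(cell_annotation))) {
    stop("`cell_annotation` must have columns `cell_id` and `sample_id`")
  }
  idx <- match(colnames(cell_matrix), cell_annotation$cell_id)
  if (anyNA(idx)) {
    stop("cells missing from annotation: ",
         paste(head(colnames(cell_matrix)[is.na(idx)], 3L), collapse = ", "))
  }
  sample_of <- cell_annotation$sample_id[idx]
  empty <- setdiff(unique(cell_annotation$sample_id), sample_of)
  if (length(empty) > 0L) {
    warning("sample(s) with zero cells omitted: ",
            paste(empty, collapse = ", "))
  }
  out <- t(rowsum(t(cell_matrix), group = sample_of))
  out[, order(colnames(out)), drop = FALSE]
}

#' Kaplan-Meier curves and log-rank test across groups
#'
#' Right-censored Kaplan-Meier estimation per group with the standard
#' log-rank chi-squared statistic (observed-minus-expected form with
#' hypergeometric variance across event times) and a p-value on
#' `groups - 1` degrees of freedom.
#'
#' @param survival_table `data.frame` with columns `time`, `event` (0/1)
#'   and the grouping column.
#' @param group_field Name of the grouping column (default `"subtype"`).
#' @return A list: `fit` (a [survival::survfit] object), `chisq`, `df`,
#'   `p_value`, `n_groups`, and `obs`/`exp` per group.
#' @export
km_logrank <- function(survival_table, group_field = "subtype") {
  st <- survival_table
  if (!all(c("time", "event", group_field) %in% names(st))) {
    stop("survival table needs columns time, event, ", group_field)
  }
  if (any(st$time <= 0)) stop("times must be > 0")
  if (!all(st$event %in% c(0, 1))) stop("event must be 0/1")
  group <- factor(st[[group_field]])
  if (nlevels(group) < 2L) stop("need >= 2 groups")
  if (any(table(group) == 0L)) stop("group with zero samples")
  if (sum(st$event) == 0L) stop("no events observed")
  surv <- survival::Surv(st$time, st$event)
  fit <- survival::survfit(surv ~ group)
  sd_ <- survival::survdiff(surv ~ group)
  df <- nlevels(group) - 1L
  list(fit = fit, chisq = unname(sd_$chisq), df = df,
       p_value = pchisq(sd_$chisq, df, lower.tail = FALSE),
       n_groups = nlevels(group),
       obs = setNames(sd_$obs, levels(group)),
       exp = setNames(sd_$exp, levels(group)))
}

#' Treatment benefit within each subtype
#'
#' Within each subtype, compares treated against untreated samples with a
#' log-rank test and reports an (O/E)-ratio hazard-ratio approximation,
#' `HR = (O_treated / E_treated) / (O_control / E_control)`, with a normal
#' confidence interval on the log scale using `1/E_t + 1/E_c` as the
#' variance.  This is the standard log-rank-table approximation, not a
#' proportional-hazards model fit.  Subtypes with an empty arm are skipped
#' with a warning.
#'
#' @param survival_table `data.frame` with columns `time`, `event`, the
#'   label column, and the treatment column (0/1).
#' @param label_field Name of the subtype column (default `"subtype"`).
#' @param treatment_field Name of the treatment column (default
#'   `"treatment"`).
#' @param conf_level Confidence level for the HR interval (default 0.95).
#' @return A `data.frame` (one row per analyzable subtype): `subtype`,
#'   `n`, `n_treated`, `chisq`, `p_value`, `hr`, `hr_lower`, `hr_upper`.
#' @export
treatment_benefit <- function(survival_table, label_field = "subtype",
                              treatment_field = "treatment",
                              conf_level = 0.95) {
  st <- survival_table
  if (!all(c("time", "event", label_field, treatment_field) %in% names(st))) {
    stop("survival table needs columns time, event, ",
         label_field, ", ", treatment_field)
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  rows <- lapply(sort(unique(st[[label_field]])), function(s) {
    sub <- st[st[[label_field]] == s, ]
    arms <- table(factor(sub[[treatment_field]], levels = c(0, 1)))
    if (any(arms == 0L)) {
      warning("subtype ", s, " lacks a treatment arm; skipped")
      return(NULL)
    }
    if (sum(sub$event) == 0L) {
      warning("subtype ", s, " has no events; skipped")
      return(NULL)
    }
    grp <- factor(sub[[treatment_field]], levels = c(0, 1))
    sd_ <- survival::survdiff(survival::Surv(sub$time, sub$event) ~ grp)
    df <- 1L
    obs <- sd_$obs
    expd <- sd_$exp
    hr <- (obs[2L] / expd[2L]) / (obs[1L] / expd[1L])
    se <- sqrt(1 / expd[1L] + 1 / expd[2L])
    data.frame(subtype = s, n = nrow(sub), n_treated = sum(grp == 1),
               chisq = unname(sd_$chisq),
               p_value = pchisq(sd_$chisq, df, lower.tail = FALSE),
               hr = unname(hr),
               hr_lower = unname(hr * exp(-z * se)),
               hr_upper = unname(hr * exp(z * se)),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) stop("no subtype with both arms and events")
  do.call(rbind, rows)
}

# Wilcoxon rank-sum p-value: exact for small untied samples, otherwise the
# tie-corrected normal approximation with continuity correction
wilcox_rank_p <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) return(NA_real_)
  exact <- length(x) <= 25L && length(y) <= 25L &&
    !anyDuplicated(c(x, y))
  wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
}

# Fisher's exact test p-value for a 2x2 table (the association test used
# for co-localization-by-infiltration splits)
fisher_exact_p <- function(tab, alternative = "two.sided") {
  fisher.test(tab, alternative = alternative)$p.value
}

#' Multiplex-immunofluorescence co-localization statistics
#'
#' Quantifies the MDK+FAP+SDC2+ co-localization readout: the per-sample
#' co-localization ratio (triple-positive tumor cells / all tumor cells),
#' a Wilcoxon rank-sum comparison of tumor versus adjacent tissue ratios,
#' a median split of tumor samples into co-localization-high/low groups
#' (ties at the median go to the low group), the CD3+ infiltration ratio
#' (CD3+ / DAPI+) dichotomized at the `cd3_cutoff` (>= cutoff is high), a
#' Fisher's exact test of the co-localization-group-by-CD3-group 2x2
#' table, and a Wilcoxon comparison of the TIGIT+ fraction of CD3+ T cells
#' between co-localization groups.
#'
#' @param mif `data.frame` as produced by [simulate_mif_counts()]:
#'   `sample_id`, `tissue_class` ("tumor"/"adjacent"), `tumor_cells`,
#'   `triple_positive`, `dapi`, `cd3`, `tigit`.
#' @param cd3_cutoff High/low cutoff on the CD3 ratio (default 0.20).
#' @param fisher_alternative Sidedness of the Fisher test (default
#'   `"two.sided"`).
#' @return A list: `per_sample` (ratios and group assignments),
#'   `tumor_vs_adjacent_p`, `median_ratio`, `fisher_table`, `fisher_p`,
#'   `tigit_p`, `flagged` (samples with undefined ratios).
#' @export
mif_statistics <- function(mif, cd3_cutoff = 0.20,
                           fisher_alternative = "two.sided") {
  needed <- c("sample_id", "tissue_class", "tumor_cells", "triple_positive",
              "dapi", "cd3", "tigit")
  if (!is.data.frame(mif) || !all(needed %in% names(mif))) {
    stop("`mif` must have columns ", paste(needed, collapse = ", "))
  }
  if (any(mif$triple_positive > mif$tumor_cells)) {
    stop("triple_positive exceeds tumor_cells")
  }
  if (any(mif$cd3 > mif$dapi)) stop("cd3 exceeds dapi")
  flagged <- mif$sample_id[mif$tumor_cells == 0]
  ratio <- ifelse(mif$tumor_cells > 0,
                  mif$triple_positive / mif$tumor_cells, NA_real_)
  cd3_ratio <- ifelse(mif$dapi > 0, mif$cd3 / mif$dapi, NA_real_)
  tigit_ratio <- ifelse(mif$cd3 > 0, mif$tigit / mif$cd3, NA_real_)
  is_tumor <- mif$tissue_class == "tumor"

  tva_p <- wilcox_rank_p(ratio[is_tumor], ratio[!is_tumor])
  med <- median(ratio[is_tumor], na.rm = TRUE)
  coloc_group <- rep(NA_character_, nrow(mif))
  coloc_group[is_tumor] <- ifelse(ratio[is_tumor] > med, "high", "low")
  degenerate_split <- length(unique(stats::na.omit(coloc_group))) < 2L
  if (degenerate_split) {
    warning("median split degenerate: all tumor ratios on one side")
  }
  cd3_group <- ifelse(cd3_ratio >= cd3_cutoff, "high", "low")

  per_sample <- data.frame(sample_id = mif$sample_id,
                           tissue_class = mif$tissue_class,
                           coloc_ratio = ratio, coloc_group = coloc_group,
                           cd3_ratio = cd3_ratio, cd3_group = cd3_group,
                           tigit_ratio = tigit_ratio,
                           stringsAsFactors = FALSE)
  tum <- per_sample[is_tumor & !is.na(ratio), ]
  fisher_table <- table(factor(tum$coloc_group, levels = c("low", "high")),
                        factor(tum$cd3_group, levels = c("low", "high")),
                        dnn = c("coloc", "cd3"))
  fisher_p <- if (degenerate_split) NA_real_ else {
    fisher_exact_p(fisher_table, alternative = fisher_alternative)
  }
  tigit_p <- if (degenerate_split) NA_real_ else {
    wilcox_rank_p(tum$tigit_ratio[tum$coloc_group == "high"],
                  tum$tigit_ratio[tum$coloc_group == "low"])
  }
  list(per_sample = per_sample, tumor_vs_adjacent_p = tva_p,
       median_ratio = med, fisher_table = fisher_table,
       fisher_p = fisher_p, tigit_p = tigit_p, flagged = flagged)
}
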