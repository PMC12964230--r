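# pcdsubtype

Tumor cohorts can be stratified by the coordinated dysregulation of
programmed cell death (PCD) pathways — apoptosis, necroptosis, pyroptosis,
ferroptosis and related modalities.  `pcdsubtype` implements the full
workflow for building such a taxonomy (PCDS,
*programmed-cell-death-related subtype*) from bulk expression cohorts of
colon adenocarcinoma and carrying it across studies and modalities, for
computational biologists who want the machinery reusable and tested rather
than buried in a one-off analysis.

The core of the package:

* **Consensus NMF subtype discovery.**  The nonnegative log-scale
  expression matrix *V* (genes × samples) is factorized as *V ≈ WH* by
  multiplicative updates minimizing the generalized Kullback–Leibler
  divergence; 30 replicate runs are summarized into a consensus matrix,
  and the rank *k* is chosen by the maximal cophenetic correlation between
  consensus dissimilarities and their average-linkage dendrogram
  (`nmf_factorize()`, `consensus_cluster()`, `select_rank()`,
  `assign_subtypes()`).
* **Three-step signature extraction.**  From the basis matrix *W*:
  (1) genes whose weight exceeds the 80th percentile of all of *W*'s
  entries are a module's candidates; (2) modules with fewer than 10
  candidates fall back to their top-10 weights; (3) genes claimed by more
  than one module are removed, leaving mutually exclusive subtype
  signatures (`global_weight_cutoff()`, `extract_signatures()`).
* **Nearest-template prediction (NTP).**  New cohorts — bulk, or
  pseudobulk built by summing single-cell expression within samples — are
  classified by cosine distance to binary signature templates on
  gene-standardized expression, with a gene-resampling permutation null,
  add-one p-values, and Benjamini–Hochberg FDR (`build_templates()`,
  `ntp_classify()`, `pseudobulk()`).
* **Cohort characterization.**  ssGSEA pathway activity scores, subtype
  differential expression (adjusted p < 0.05 and fold change > 1.5),
  observed-over-expected (Ro/e) cell-type enrichment with the
  conventional `-`/`+/-`/`+`/`++`/`+++` bins, Kaplan–Meier / log-rank
  survival and per-subtype treatment-benefit comparison, and multiplex
  immunofluorescence co-localization statistics
  (`ssgsea_score()`, `differential_expression()`, `roe_enrichment()`,
  `km_logrank()`, `treatment_benefit()`, `mif_statistics()`).
* **Synthetic cohorts.**  Seeded generators plant known subtype blocks in
  bulk, single-cell, survival and mIF-count data so the whole pipeline is
  testable offline against ground truth (`simulate_bulk_cohort()`,
  `simulate_single_cell()`, `simulate_survival()`,
  `simulate_mif_counts()`).

See the vignette (`vignettes/pcds-methods.Rmd`) for the model details,
parameter rationale, and design decisions.

## Worked example

Discover three subtypes in a synthetic cohort, extract signatures, and
transfer the labels to an independent cohort:

```r
library(pcdsubtype)

params <- simulation_params(n_samples = 150, n_genes = 600, K = 3,
                            module_size = 50, delta = 1.2, seed = 1)
cohort <- simulate_bulk_cohort(params)

cons <- consensus_cluster(cohort$matrix, k = 3, n_runs = 30, seed = 1)
cons
#> Consensus over 30 NMF runs at k = 3: cophenetic 0.9998, mean silhouette 0.9920

sig <- extract_signatures(cons$consensus_basis,
                          global_weight_cutoff(cons$consensus_basis))
sig
#> Subtype signature: 3 modules, 134 genes total (cutoff 1.891)
#>   module candidates after_fallback final
#>  module1        124            124    49
#>  module2        115            115    41
#>  module3        121            121    44

validation <- simulate_bulk_cohort(
  simulation_params(n_samples = 150, n_genes = 600, K = 3,
                    module_size = 50, delta = 1.2, seed = 11))
templates <- build_templates(sig, validation$matrix)
pred <- ntp_classify(validation$matrix, templates, n_perm = 1000, seed = 11)
head(pred[, c("sample_id", "label", "dist", "p_value", "fdr", "confident")])
#>   sample_id label      dist     p_value         fdr confident
#> 1      S001 PCDS2 0.5895892 0.000999001 0.000999001      TRUE
#> 2      S002 PCDS2 0.4782425 0.000999001 0.000999001      TRUE
#> 3      S003 PCDS3 0.3957572 0.000999001 0.000999001      TRUE
#> 4      S004 PCDS2 0.4026324 0.000999001 0.000999001      TRUE
#> 5      S005 PCDS2 0.4630146 0.000999001 0.000999001      TRUE
#> 6      S006 PCDS1 0.3735312 0.000999001 0.000999001      TRUE

table(pred$label, validation$truth$sample_labels)
#>          1  2  3
#>   PCDS1 38  0  0
#>   PCDS2  0 61  0
#>   PCDS3  0  0 51
```

A cophenetic correlation near 1 says the 30 replicate runs partition the
cohort almost identically; the signature report shows the candidate counts
at each extraction step (134 mutually exclusive genes survive); each
validation sample's minimum template distance comes with a permutation
p-value (the floor `1/(n_perm + 1)` ≈ 0.001 here) and BH FDR, and every
confident call lands in its planted subtype.

A thin command-line wrapper over the same functions is installed at
`inst/cli/pcds.R` (subcommands `simulate`, `discover`, `signatures`,
`classify`, `score`, `roe`, `survival`, `mif`).

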