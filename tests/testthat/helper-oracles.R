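# Independent brute-force oracles used to cross-check package statistics.
# These deliberately share no code with the implementation paths they test.

# Benjamini-Hochberg step-up, written directly from the procedure:
# q_(i) = min over j >= i of p_(j) * m / j, capped at 1.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  scaled <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# log-rank chi-square from first principles: at each distinct event time,
# observed vs hypergeometric-expected events per group, variance from the
# multivariate hypergeometric; statistic = (O-E)' V^- (O-E) computed on the
# first g-1 groups.
logrank_oracle <- function(time, event, group) {
  group <- factor(group)
  g <- nlevels(group)
  times <- sort(unique(time[event == 1]))
  O <- numeric(g)
  E <- numeric(g)
  V <- matrix(0, g, g)
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    d <- sum(event == 1 & time == t)
    nj <- vapply(levels(group), function(l) sum(at_risk & group == l),
                 numeric(1))
    dj <- vapply(levels(group), function(l) {
      sum(event == 1 & time == t & group == l)
    }, numeric(1))
    O <- O + dj
    E <- E + d * nj / n
    if (n > 1) {
      for (a in seq_len(g)) for (b in seq_len(g)) {
        if (a == b) {
          V[a, b] <- V[a, b] + d * (nj[a] / n) * (1 - nj[a] / n) *
            (n - d) / (n - 1)
        } else {
          V[a, b] <- V[a, b] - d * (nj[a] / n) * (nj[b] / n) *
            (n - d) / (n - 1)
        }
      }
    }
  }
  idx <- seq_len(g - 1)
  dlt <- (O - E)[idx]
  drop(t(dlt) %*% solve(V[idx, idx, drop = FALSE]) %*% dlt)
}

# Fisher's exact p for a 2x2 table by full enumeration of tables with the
# same margins (hypergeometric probabilities).
fisher_enum_oracle <- function(tab, alternative = "two.sided") {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ])
  c1 <- sum(tab[, 1])
  n <- sum(tab)
  lo <- max(0, c1 - (n - r1))
  hi <- min(r1, c1)
  support <- lo:hi
  probs <- vapply(support, function(x) {
    choose(r1, x) * choose(n - r1, c1 - x) / choose(n, c1)
  }, numeric(1))
  p_obs <- probs[support == a]
  switch(alternative,
         less = sum(probs[support <= a]),
         greater = sum(probs[support >= a]),
         two.sided = sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# expected counts of an independence model, straight from the marginals
roe_expected_oracle <- function(tab) {
  outer(rowSums(tab), colSums(tab)) / sum(tab)
}

# ssGSEA score for one sample, evaluated step by step along the ranked list
ssgsea_oracle <- function(expr, genes, set, alpha = 0.25) {
  r <- rank(expr, ties.method = "average")
  ord <- order(-expr, genes)
  inset <- genes[ord] %in% set
  w <- r[ord]^alpha
  p_in <- cumsum(ifelse(inset, w, 0)) / sum(w[inset])
  p_out <- cumsum(!inset) / sum(!inset)
  sum(p_in - p_out)
}

# expand a cell-type x subtype count table into one row per cell
cells_from_table <- function(tab) {
  idx <- which(tab > 0, arr.ind = TRUE)
  df <- do.call(rbind, lapply(seq_len(nrow(idx)), function(i) {
    data.frame(cell_type = rownames(tab)[idx[i, 1]],
               subtype = colnames(tab)[idx[i, 2]],
               count = tab[idx[i, 1], idx[i, 2]])
  }))
  data.frame(cell_type = rep(df$cell_type, df$count),
             subtype = rep(df$subtype, df$count),
             stringsAsFactors = FALSE)
}

# default desk-scale discovery cohort used across tests
make_discovery_cohort <- function(seed = 1L, K = 3L, n_samples = 150L,
                                  delta = 1.2) {
  params <- simulation_params(n_samples = n_samples, n_genes = 600L, K = K,
                              module_size = 50L, delta = delta, seed = seed)
  simulate_bulk_cohort(params)
}

# map NMF module indices to planted subtypes via the confusion of labels
module_to_subtype <- function(labels, truth_labels) {
  tab <- table(labels, truth_labels[names(labels)])
  apply(tab, 1L, which.max)
}
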