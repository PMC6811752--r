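# Independent oracles and small data builders shared across tests.

# Exhaustive-enumeration oracle for the conditional exact test: the group
# sums are NB(n/phi) (Poisson at phi = 0) with an arbitrary common mean that
# cancels on conditioning; p sums the normalized products of the two pmfs
# over all splits at most as probable as the observed one.
oracle_exact_p <- function(s_a, s_b, n_a, n_b, phi, mu = 7) {
  total <- s_a + s_b
  if (total == 0) return(1)
  k <- 0:total
  if (phi == 0) {
    pk <- dpois(k, n_a * mu) * dpois(total - k, n_b * mu)
  } else {
    pk <- dnbinom(k, size = n_a / phi, mu = n_a * mu) *
      dnbinom(total - k, size = n_b / phi, mu = n_b * mu)
  }
  pk <- pk / sum(pk)
  min(1, sum(pk[pk <= pk[s_a + 1] * (1 + 1e-9)]))
}

# Brute-force over-representation oracle: the fraction of all size-k subsets
# of the universe whose overlap with the term reaches the observed overlap.
oracle_overrep_p <- function(n_universe, term_idx, sel_size, observed_overlap) {
  sets <- utils::combn(n_universe, sel_size)
  hits <- apply(sets, 2, function(s) sum(s %in% term_idx))
  mean(hits >= observed_overlap)
}

# Count matrix with exact CPM control: library size 1e6 so counts == CPM.
make_counts <- function(cpm_matrix, compartments = c("A", "A", "B", "B")) {
  xtalk_counts(round(cpm_matrix),
               factor(compartments, levels = unique(compartments)),
               lib_size = rep(1e6, ncol(cpm_matrix)))
}

# Hand-built DE result table with the attributes run_de() attaches.
make_de <- function(gene_id, log2fc, fdr = rep(1e-6, length(gene_id)),
                    significant = NULL, comps = c("A", "B")) {
  if (is.null(significant)) significant <- abs(log2fc) >= 1 & fdr <= 0.05
  de <- data.frame(gene_id = gene_id, log2fc = log2fc,
                   pvalue = fdr, fdr = fdr,
                   cpm_mean_a = NA_real_, cpm_mean_b = NA_real_,
                   significant = significant, stringsAsFactors = FALSE)
  attr(de, "compartments") <- comps
  de
}

# Noise-free planted scenario used by several end-to-end checks.
recovery_config <- function(seed, dispersion = 0, n_genes = 1000) {
  sim_config(n_genes = n_genes, dispersion = dispersion,
             mean_expression_range = c(500, 2000),
             n_planted_de = 50, planted_log2fc = 2, n_planted_pairs = 5,
             seed = seed)
}
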