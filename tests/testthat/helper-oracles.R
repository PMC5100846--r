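# Shared fixtures and independent oracles used across test files.

# Random coding sequence over the 61 sense codons (no stop appended).
random_cds <- function(n_codons, id = "g") {
  codons <- sample(sense_codons(), n_codons, replace = TRUE)
  coding_sequence(id, paste(codons, collapse = ""))
}

# Random codon usage table with strictly positive counts.
random_usage <- function() {
  counts <- setNames(sample(1:200, 61, replace = TRUE), sense_codons())
  relative_adaptiveness(counts, pseudo_count = 0)
}

# Brute-force CAI oracle: tabulate codon counts and take the count-weighted
# sum of log weights, independent of the per-codon streaming path.
cai_oracle <- function(cds, table) {
  excluded <- c("TAA", "TAG", "TGA", "ATG", "TGG")
  counts <- table(cds$codons)
  counts <- counts[!(names(counts) %in% excluded)]
  exp(sum(counts * log(table$w[names(counts)])) / sum(counts))
}

# Exhaustive best-subset oracle under the all-terms-significant rule:
# among all non-empty subsets of the screened candidates in which every
# term's p-value is below alpha, return the subset with the highest R^2.
best_subset_oracle <- function(table, candidates, alpha = 0.05) {
  best_terms <- NULL
  best_r2 <- -Inf
  for (m in seq_along(candidates)) {
    for (idx in utils::combn(length(candidates), m, simplify = FALSE)) {
      terms <- candidates[idx]
      fit <- tryCatch(fit_ols(table, terms), error = function(e) NULL)
      if (is.null(fit)) next
      p <- fit$p_values[setdiff(names(fit$p_values), "(Intercept)")]
      if (all(p < alpha) && fit$r_squared > best_r2) {
        best_r2 <- fit$r_squared
        best_terms <- terms
      }
    }
  }
  sort(best_terms)
}

# Small independent-predictor generator config for selection tests:
# five uncorrelated predictors, three with real effects, two pure noise.
selection_sim <- function(seed, n = 300L) {
  spec <- data.frame(
    name = paste0("p", 1:5),
    transform = "none",
    mean = 0, sd = 1
  )
  sim_predictor_table(
    n_genes = n, seed = seed, predictors = spec,
    beta = c(p1 = 0.020, p2 = 0.012, p3 = 0.009),
    intercept = 0.15, sigma = 0.025, target_r_squared = NULL
  )
}
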