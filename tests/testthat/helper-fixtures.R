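# Shared fixtures, all built in code.

# A small hand-written association table: 3 diseases, 6 genes.
tiny_table <- function() {
  as_association_table(tibble::tibble(
    disease_id = c("D1", "D1", "D1", "D2", "D2", "D2", "D3", "D3"),
    gene_symbol = c("g1", "g2", "g3", "g2", "g3", "g4", "g5", "g6"),
    association_type = "causal"
  ))
}

# Module-free synthetic background table.
null_table <- function(seed = 1, n_diseases = 100, n_genes = 500) {
  cfg <- synthetic_config(n_diseases = n_diseases, n_genes = n_genes,
                          max_degree = min(78L, n_diseases), seed = seed)
  filter_min_degree(generate_associations(cfg), "disease", 5)
}

# Background plus two disjoint planted 5-disease modules (pool 20, draw 10).
two_module_table <- function(seed = 1) {
  cfg <- synthetic_config(
    n_diseases = 100, n_genes = 500, max_degree = 78L, seed = seed,
    planted_modules = list(
      list(disease_ids = sprintf("PA%02d", 1:5),
           shared_gene_pool_size = 20, per_disease_draw = 10),
      list(disease_ids = sprintf("PB%02d", 1:5),
           shared_gene_pool_size = 20, per_disease_draw = 10)
    ))
  filter_min_degree(generate_associations(cfg), "disease", 5)
}

# Redundant-support fixture: one 10-disease module (pool 20, draw 10) on a
# smaller background, so removed module genes remain recoverable through
# sibling diseases.
module_cv_table <- function(seed = 11) {
  cfg <- synthetic_config(
    n_diseases = 60, n_genes = 300, max_degree = 40L, seed = seed,
    planted_modules = list(
      list(disease_ids = sprintf("PM%02d", 1:10),
           shared_gene_pool_size = 20, per_disease_draw = 10)
    ))
  filter_min_degree(generate_associations(cfg), "disease", 5)
}

# A module gene of `disease` that stays inside the >=5-link gene-comparison
# universe after one of its edges is deleted (degree >= 6), so re-prediction
# tests exercise the similarity machinery rather than the universe filter.
pick_removable_gene <- function(tab, disease) {
  deg <- gene_degrees(tab)
  cand <- grep("^M1_", entity_sets(tab)[[disease]], value = TRUE)
  cand <- cand[deg$degree[match(cand, deg$gene_symbol)] >= 6]
  stopifnot(length(cand) >= 1)
  cand[1]
}

# Independent textbook BH step-up (sort, p * n / i, cumulative min from the
# largest, cap at 1, back to input order).
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, cummin(rev(p[o] * n / seq_len(n)))[n:1])
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

# Independent term-by-term Poisson upper tail, summed upward from k = x in
# scaled space until terms become negligible.
poisson_tail_oracle <- function(x, lam) {
  if (x == 0) return(1)
  total <- 0
  k <- x
  repeat {
    term <- exp(k * log(lam) - lam - lgamma(k + 1))
    total <- total + term
    if ((term < total * 1e-18 && k > lam) || k > x + 10000) break
    k <- k + 1
  }
  total
}

# Exact Poisson-binomial upper tail by dynamic-programming convolution.
poisbinom_tail_oracle <- function(x, probs) {
  dp <- c(1, rep(0, length(probs)))
  for (p in probs) {
    dp <- dp * (1 - p) + c(0, dp[-length(dp)]) * p
  }
  sum(dp[(x + 1):length(dp)])
}
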