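# Independent reference computations used to certify the implementation.

# Fisher combination via numerical integration of the chi-square density.
fisher_numint <- function(p_values) {
  x <- -2 * sum(log(p_values))
  df <- 2 * length(p_values)
  stats::integrate(function(t) stats::dchisq(t, df), lower = x,
                   upper = Inf, rel.tol = 1e-12)$value
}

# Fisher combination via the even-df closed form e^(-x/2) sum_{j<k} (x/2)^j/j!
fisher_closed <- function(p_values) {
  x <- -2 * sum(log(p_values))
  k <- length(p_values)
  exp(-x / 2) * sum((x / 2)^(0:(k - 1)) / factorial(0:(k - 1)))
}

# Hypergeometric upper tail by exhaustive enumeration of all n-subsets.
hyper_brute <- function(N, K, n, k) {
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= K)   # successes are elements 1..K
  sum(hits >= k) / ncol(subsets)
}

# Minimal hand-built instances ------------------------------------------------

toy_records <- function(rows) {
  base <- data.frame(protein_a = character(0), domain_a = character(0),
                     protein_b = character(0), domain_b = character(0),
                     exons_a = character(0), exons_b = character(0),
                     transcripts_a = character(0),
                     transcripts_b = character(0), direction = character(0),
                     stringsAsFactors = FALSE)
  for (r in rows) {
    base <- rbind(base, data.frame(
      protein_a = r[[1]], domain_a = r[[2]], protein_b = r[[3]],
      domain_b = r[[4]],
      exons_a = if (length(r) >= 5) r[[5]] else "",
      exons_b = if (length(r) >= 6) r[[6]] else "",
      transcripts_a = "", transcripts_b = "",
      direction = if (length(r) >= 7) r[[7]] else "",
      stringsAsFactors = FALSE))
  }
  base
}

simple_tf_table <- function(tf, weight = 1, significant = TRUE) {
  out <- data.frame(tf = tf, n_targets = 10L, score = weight,
                    empirical_p = ifelse(significant, 0.001, 0.5),
                    significant = significant, weight = abs(weight),
                    stringsAsFactors = FALSE)
  class(out) <- c("tf_activity_table", "data.frame")
  out
}

simple_skips <- function(protein, domain, aggregated_p, mean_effect,
                         p_threshold = 0.05) {
  out <- data.frame(protein = protein, domain = domain,
                    aggregated_p = aggregated_p, mean_effect = mean_effect,
                    n_features = 1L,
                    skipped = aggregated_p <= p_threshold & mean_effect < 0,
                    stringsAsFactors = FALSE)
  class(out) <- c("domain_skip_table", "data.frame")
  out
}

# PERTURBATION -> A(a1) --DDI-- T(t1), T significant.
chain_instance <- function(w = 1, lambda = 0.01, alpha = 0.1,
                           mode = "hard", beta = NULL, skips = NULL) {
  recs <- toy_records(list(list("A", "a1", "T", "t1")))
  net <- build_network(recs)
  net <- attach_perturbation(net, roots = "A")
  build_ilp(net, simple_tf_table("T", weight = w), skips, mode = mode,
            lambda = lambda, alpha = alpha, beta = beta)
}

# A(a1,a2) -- two parallel DDIs -- T(t1): two equal-cost optima.
parallel_instance <- function() {
  recs <- toy_records(list(list("A", "a1", "T", "t1"),
                           list("A", "a2", "T", "t1")))
  net <- build_network(recs)
  net <- attach_perturbation(net, roots = "A")
  build_ilp(net, simple_tf_table("T"), NULL, mode = "hard")
}
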