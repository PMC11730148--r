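# Independent oracles, coded from first principles and kept separate from
# the package's implementation paths.

# Tajima's D recomputed directly from the defining formulas; per-site pi by
# explicit enumeration of chromosome pairs (mean pairwise difference).
oracle_constants <- function(n) {
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

oracle_pi_site <- function(alt_count, n_chrom) {
  alleles <- c(rep(1, alt_count), rep(0, n_chrom - alt_count))
  sum(stats::dist(alleles, method = "manhattan")) / choose(n_chrom, 2)
}

# Window D from per-site alt counts and per-site non-missing chromosome
# counts; n for the constants is the rounded median chromosome count.
oracle_window_d <- function(alt, nm) {
  poly <- alt > 0 & alt < nm
  s <- sum(poly)
  pi_sum <- sum(mapply(oracle_pi_site, alt, nm))
  n <- round(median(nm))
  if (s == 0 || n < 4) return(list(pi_sum = pi_sum, d = NA_real_))
  k <- oracle_constants(n)
  list(pi_sum = pi_sum,
       d = (pi_sum - s / k$a1) / sqrt(k$e1 * s + k$e2 * s * (s - 1)))
}

# Hardy-Weinberg exact test by enumeration over attainable heterozygote
# counts, with probabilities assembled from binomial coefficients (a code
# path distinct from the package's log-gamma implementation).
oracle_hwe <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  m <- min(2 * n_hom_ref + n_het, 2 * n_hom_alt + n_het)
  if (m == 0) return(1)
  h <- seq(m %% 2, min(m, 2 * n - m), by = 2)
  weight <- vapply(h, function(hh) {
    hom_rare <- (m - hh) / 2
    choose(n, hom_rare) * choose(n - hom_rare, hh) * 2^hh
  }, numeric(1))
  prob <- weight / sum(weight)
  p_obs <- prob[match(n_het, h)]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-9)]))
}

# One-sided exact MWU p for binary scores: with m score-1 genes among N,
# the count of score-1 genes inside a category of size k is hypergeometric,
# and U is monotone in it.
oracle_mwu_binary <- function(scores_in, scores_out) {
  k_obs <- sum(scores_in)
  m <- sum(scores_in) + sum(scores_out)
  n_tot <- length(scores_in) + length(scores_out)
  stats::phyper(k_obs - 1, m, n_tot - m, length(scores_in),
                lower.tail = FALSE)
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration of group
# assignments (small groups only).
oracle_wilcoxon_two_sided <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  subsets <- utils::combn(length(pooled), n1)
  u_all <- apply(subsets, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(y) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}
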