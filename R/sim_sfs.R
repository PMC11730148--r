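#' Site-frequency-spectrum weights for a selection regime
#'
#' Unnormalized sampling weights over derived-allele counts `1..n_chrom - 1`.
#' Neutral weights follow the standard `1/i` law; the sweep regime sharpens
#' it to `1/i^sweep_alpha`; the balancing regime mixes the (normalized)
#' neutral law with a Gaussian-shaped bump centred at `n_chrom / 2`, the
#' bump receiving `balancing_beta` times the weight of the neutral part.
#'
#' @param regime One of `"neutral"`, `"sweep"`, `"balancing"`.
#' @param n_chrom Number of sampled chromosomes (>= 4).
#' @param sweep_alpha,balancing_beta Distortion parameters, see
#'   [sim_config()].
#' @return Numeric vector of length `n_chrom - 1`, summing to 1.
#' @export
sfs_weights <- function(regime, n_chrom, sweep_alpha = 3, balancing_beta = 5) {
  if (length(regime) != 1 ||
      !regime %in% c("neutral", "sweep", "balancing")) {
    stop("unknown regime label: ", paste(regime, collapse = ", "),
         " (expected neutral, sweep or balancing)")
  }
  stopifnot(n_chrom >= 4)
  i <- seq_len(n_chrom - 1)
  w <- switch(regime,
    neutral = 1 / i,
    sweep = 1 / i^sweep_alpha,
    balancing = {
      neutral <- (1 / i) / sum(1 / i)
      bump <- exp(-0.5 * ((i - n_chrom / 2) / (n_chrom / 10))^2)
      bump <- bump / sum(bump)
      neutral + balancing_beta * bump
    }
  )
  w / sum(w)
}

#' Draw per-site derived-allele counts under a selection regime
#'
#' Counts are drawn independently per site from the regime's site frequency
#' spectrum (see [sfs_weights()]), so every count lies in
#' `[1, n_chrom - 1]` and every emitted site is polymorphic in the full
#' cohort.
#'
#' @inheritParams sfs_weights
#' @param n_sites Number of sites to draw (>= 0).
#' @param distortion Optional global exponent applied to the regime weights
#'   (`weights^distortion`, renormalized); 1 leaves them untouched.
#' @return Integer vector of derived-allele counts, length `n_sites`.
#' @examples
#' set.seed(1)
#' table(sample_site_frequencies("sweep", 20, 100, sweep_alpha = 3))
#' @export
sample_site_frequencies <- function(regime, n_chrom, n_sites,
                                    sweep_alpha = 3, balancing_beta = 5,
                                    distortion = 1) {
  stopifnot(n_chrom >= 4, n_sites >= 0)
  w <- sfs_weights(regime, n_chrom, sweep_alpha, balancing_beta)
  if (distortion != 1) {
    w <- w^distortion
    w <- w / sum(w)
  }
  if (n_sites == 0) return(integer(0))
  sample.int(n_chrom - 1L, size = n_sites, replace = TRUE, prob = w)
}

#' Expand derived-allele counts into diploid genotypes
#'
#' For each site the derived alleles are placed on chromosomes uniformly
#' without replacement, chromosomes are paired consecutively into diploid
#' individuals, and genotypes are then independently masked as missing with
#' probability `missing_rate`. With `missing_rate = 0` the per-site
#' derived-allele count of the returned matrix equals the input count
#' exactly.
#'
#' @param counts Integer vector of per-site derived-allele counts; each must
#'   lie in `[0, 2 * n_individuals - 1]`.
#' @param n_individuals Number of diploid individuals.
#' @param missing_rate Per-genotype missingness probability.
#' @return Integer matrix (sites x individuals) with entries 0/1/2 counting
#'   derived alleles and `NA` for missing genotypes.
#' @export
genotypes_from_frequencies <- function(counts, n_individuals,
                                       missing_rate = 0) {
  counts <- as.integer(counts)
  n2 <- 2L * as.integer(n_individuals)
  if (any(counts < 0L) || any(counts > n2 - 1L)) {
    stop("each derived-allele count must lie in [0, 2 * n_individuals - 1]")
  }
  stopifnot(missing_rate >= 0, missing_rate < 1)
  s <- length(counts)
  g <- matrix(0L, nrow = s, ncol = n_individuals)
  odd <- seq(1L, n2, by = 2L)
  for (j in seq_len(s)) {
    if (counts[j] == 0L) next
    alleles <- integer(n2)
    alleles[sample.int(n2, counts[j])] <- 1L
    g[j, ] <- alleles[odd] + alleles[odd + 1L]
  }
  if (missing_rate > 0 && s > 0) {
    mask <- matrix(runif(s * n_individuals) < missing_rate,
                   nrow = s, ncol = n_individuals)
    g[mask] <- NA_integer_
  }
  g
}
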