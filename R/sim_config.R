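#' Simulation configuration for two-condition larval cohorts
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults reproduce the study design the package targets: 16 control and
#' 10 heat-treated diploid larvae, scaffold-structured coordinates cut into
#' 5-kb windows, an average of 40 SNPs per window, and 5% of windows per
#' condition planted with a sweep-like site-frequency spectrum
#' (`sweep_alpha = 3`) plus 5% with a balancing-selection-like spectrum
#' (`balancing_beta = 5`).
#'
#' Selection regimes are phenomenological distortions of the neutral site
#' frequency spectrum (counts of the derived allele drawn independently per
#' site), not a genealogical model: sweep-like windows oversample rare
#' alleles (`weights ~ 1/i^sweep_alpha`), balancing windows mix the neutral
#' law with a bump of intermediate-frequency alleles weighted by
#' `balancing_beta`.
#'
#' @param n_control,n_heat Number of diploid individuals per condition.
#' @param n_scaffolds,windows_per_scaffold Genome layout; the total number of
#'   windows per condition is their product (default 25 x 20 = 500).
#' @param window_size Window length in bp (default 5000).
#' @param snps_per_window Mean of the Poisson number of SNPs per window.
#' @param sweep_alpha Exponent of the sweep-regime SFS distortion (> 1 skews
#'   towards rare alleles; larger is more sweep-like).
#' @param balancing_beta Weight of the intermediate-frequency bump in the
#'   balancing regime (0 recovers the neutral law).
#' @param frac_sweep,frac_balancing Fractions of windows per condition
#'   assigned each selected regime; their sum must be <= 1.
#' @param shared_fraction Fraction of each condition's selected windows that
#'   is common to both conditions.
#' @param missing_rate Per-genotype missingness probability in `[0, 0.25)`
#'   by default so sites survive the default calling-rate filter.
#' @param heat_sfs_distortion Global exponent applied to the heat condition's
#'   SFS weights (`weights^heat_sfs_distortion`); 1 (default) leaves the heat
#'   cohort undistorted. Values > 1 inject a genome-wide rare-allele excess
#'   into the heat group, used for robustness experiments that need a known
#'   global Tajima's D shift between conditions.
#' @param go_vocab_size Number of background GO terms in the vocabulary.
#' @param terms_per_gene Integer vector of possible background GO terms per
#'   gene (sampled uniformly).
#' @param designated_prob Probability that a gene in a selected window
#'   carries the designated GO term of its (condition, regime) pair.
#' @param background_term_prob Probability that any other gene carries a
#'   designated term.
#' @param frac_larva,frac_egg Probability that a gene is flagged as detected
#'   in the larval / egg proteome.
#' @param seed Integer seed; identical seeds give bitwise-identical outputs.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [simulate_cohort_data()], [simulate_cohorts()]
#' @export
sim_config <- function(n_control = 16, n_heat = 10,
                       n_scaffolds = 25, windows_per_scaffold = 20,
                       window_size = 5000, snps_per_window = 40,
                       sweep_alpha = 3, balancing_beta = 5,
                       frac_sweep = 0.05, frac_balancing = 0.05,
                       shared_fraction = 0.2, missing_rate = 0.05,
                       heat_sfs_distortion = 1,
                       go_vocab_size = 60, terms_per_gene = 1:3,
                       designated_prob = 0.8, background_term_prob = 0.02,
                       frac_larva = 0.85, frac_egg = 0.5,
                       seed = 1L) {
  cfg <- list(
    n_control = as.integer(n_control), n_heat = as.integer(n_heat),
    n_scaffolds = as.integer(n_scaffolds),
    windows_per_scaffold = as.integer(windows_per_scaffold),
    window_size = as.integer(window_size),
    snps_per_window = snps_per_window,
    sweep_alpha = sweep_alpha, balancing_beta = balancing_beta,
    frac_sweep = frac_sweep, frac_balancing = frac_balancing,
    shared_fraction = shared_fraction, missing_rate = missing_rate,
    heat_sfs_distortion = heat_sfs_distortion,
    go_vocab_size = as.integer(go_vocab_size),
    terms_per_gene = as.integer(terms_per_gene),
    designated_prob = designated_prob,
    background_term_prob = background_term_prob,
    frac_larva = frac_larva, frac_egg = frac_egg,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_control >= 2, cfg$n_heat >= 2,
    cfg$n_scaffolds >= 1, cfg$windows_per_scaffold >= 1,
    cfg$window_size > 0, cfg$snps_per_window >= 0,
    cfg$sweep_alpha > 0, cfg$balancing_beta >= 0,
    cfg$frac_sweep >= 0, cfg$frac_balancing >= 0,
    cfg$shared_fraction >= 0, cfg$shared_fraction <= 1,
    cfg$missing_rate >= 0, cfg$missing_rate < 1,
    cfg$heat_sfs_distortion > 0,
    cfg$go_vocab_size >= 4, all(cfg$terms_per_gene >= 0),
    cfg$designated_prob >= 0, cfg$designated_prob <= 1,
    cfg$background_term_prob >= 0, cfg$background_term_prob <= 1,
    cfg$frac_larva >= 0, cfg$frac_larva <= 1,
    cfg$frac_egg >= 0, cfg$frac_egg <= 1
  )
  if (cfg$frac_sweep + cfg$frac_balancing > 1) {
    stop("frac_sweep + frac_balancing must be <= 1")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  cohorts: %d control + %d heat diploids\n",
              x$n_control, x$n_heat))
  cat(sprintf("  genome: %d scaffolds x %d windows of %d bp (%d windows)\n",
              x$n_scaffolds, x$windows_per_scaffold, x$window_size,
              x$n_scaffolds * x$windows_per_scaffold))
  cat(sprintf("  SNPs/window ~ Poisson(%g), missing rate %g\n",
              x$snps_per_window, x$missing_rate))
  cat(sprintf("  regimes: %g%% sweep (alpha=%g), %g%% balancing (beta=%g), shared %g\n",
              100 * x$frac_sweep, x$sweep_alpha,
              100 * x$frac_balancing, x$balancing_beta, x$shared_fraction))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
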