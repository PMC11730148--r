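#' Site filter thresholds
#'
#' Defaults mirror the PLINK-style filtering used for the larval call set:
#' Hardy-Weinberg exact p >= 1e-6 (`--hwe 0.000001`), minor allele frequency
#' >= 0.01 (`--maf 0.01`) and at most 25% missing calls per site
#' (`--geno 0.25`).
#'
#' @param hwe_p_min Minimum Hardy-Weinberg exact-test p-value.
#' @param maf_min Minimum minor allele frequency (computed over non-missing
#'   calls).
#' @param max_missing_frac Maximum tolerated fraction of missing calls.
#' @return A `filter_thresholds` object.
#' @export
filter_thresholds <- function(hwe_p_min = 1e-6, maf_min = 0.01,
                              max_missing_frac = 0.25) {
  vals <- c(hwe_p_min = hwe_p_min, maf_min = maf_min,
            max_missing_frac = max_missing_frac)
  if (any(vals < 0) || any(vals > 1)) {
    stop("all filter thresholds must lie in [0, 1]")
  }
  structure(as.list(vals), class = "filter_thresholds")
}

#' Hardy-Weinberg exact test
#'
#' Two-sided conditional exact test of genotype proportions given allele
#' counts: conditional on the total `n` diploids and the minor-allele count
#' `m`, the heterozygote count `h` has probability
#' `P(h) = 2^h n! / (((m - h) / 2)! h! ((2n - m - h) / 2)!) / Z` over the
#' attainable `h` (same parity as `m`), and the returned p-value is the sum
#' of `P(h)` over all `h` whose probability does not exceed that of the
#' observed heterozygote count. A monomorphic site returns 1.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts (all >= 0, total >= 1).
#' @return The exact p-value, in (0, 1].
#' @examples
#' hwe_exact_test(1, 0, 1)  # 1/3
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n < 1) stop("at least one genotyped individual is required")
  m <- min(2L * n_hom_ref + n_het, 2L * n_hom_alt + n_het)  # minor alleles
  if (m == 0L) return(1)
  h <- seq.int(m %% 2L, min(m, 2L * n - m), by = 2L)
  hom_rare <- (m - h) / 2L
  hom_common <- n - h - hom_rare
  logp <- h * log(2) + lgamma(n + 1) -
    lgamma(hom_rare + 1) - lgamma(h + 1) - lgamma(hom_common + 1)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  p_obs <- prob[match(n_het, h)]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-9)]))
}

#' Apply the three site filters to a genotype matrix
#'
#' Sites are removed in a fixed order — missingness, then minor allele
#' frequency, then Hardy-Weinberg — so the per-filter exclusion counts are
#' deterministic and sum, with the survivors, to the input count. MAF and
#' the HWE test are computed over non-missing calls with both condition
#' groups pooled by default (the call set is filtered once before the
#' per-condition analyses), with a per-group HWE mode available.
#'
#' @param gm A [genotype_matrix()].
#' @param thresholds A [filter_thresholds()].
#' @param hwe_scope `"pooled"` (default) tests all samples together;
#'   `"per_group"` removes a site if the test fails in any group.
#' @return A list with elements `genotypes` (the filtered
#'   [genotype_matrix()]) and `report` (a `filter_report`: `n_input`,
#'   named `removed` counts, `n_surviving`).
#' @export
apply_filters <- function(gm, thresholds = filter_thresholds(),
                          hwe_scope = c("pooled", "per_group")) {
  stopifnot(inherits(gm, "genotype_matrix"), nrow(gm$sites) > 0)
  if (!inherits(thresholds, "filter_thresholds")) {
    thresholds <- do.call(filter_thresholds, as.list(thresholds))
  }
  hwe_scope <- match.arg(hwe_scope)
  calls <- gm$calls
  n_input <- nrow(calls)

  miss_frac <- rowMeans(is.na(calls))
  fail_miss <- miss_frac > thresholds$max_missing_frac

  nonmiss <- rowSums(!is.na(calls))
  alt <- rowSums(calls, na.rm = TRUE)
  freq <- ifelse(nonmiss > 0, alt / (2 * nonmiss), 0)
  maf <- pmin(freq, 1 - freq)
  fail_maf <- !fail_miss & maf < thresholds$maf_min

  candidate <- !fail_miss & !fail_maf
  fail_hwe <- rep(FALSE, n_input)
  hwe_p_site <- function(cl) {
    hwe_exact_test(sum(cl == 0L, na.rm = TRUE), sum(cl == 1L, na.rm = TRUE),
                   sum(cl == 2L, na.rm = TRUE))
  }
  for (i in which(candidate)) {
    p <- if (hwe_scope == "pooled") {
      hwe_p_site(calls[i, ])
    } else {
      min(vapply(unique(gm$samples$group), function(g) {
        hwe_p_site(calls[i, gm$samples$group == g])
      }, numeric(1)))
    }
    fail_hwe[i] <- p < thresholds$hwe_p_min
  }

  keep <- !fail_miss & !fail_maf & !fail_hwe
  report <- structure(list(
    n_input = n_input,
    removed = c(missingness = sum(fail_miss), maf = sum(fail_maf),
                hwe = sum(fail_hwe)),
    n_surviving = sum(keep),
    thresholds = thresholds, hwe_scope = hwe_scope
  ), class = "filter_report")

  filtered <- genotype_matrix(gm$sites[keep, , drop = FALSE],
                              calls[keep, , drop = FALSE], gm$samples)
  list(genotypes = filtered, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %d sites in, %d surviving\n",
              x$n_input, x$n_surviving))
  cat(sprintf("  removed: missingness %d, MAF %d, HWE %d (%s)\n",
              x$removed["missingness"], x$removed["maf"], x$removed["hwe"],
              x$hwe_scope))
  invisible(x)
}
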