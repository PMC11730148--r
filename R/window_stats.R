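#' Window specification
#'
#' Non-overlapping windows of `window_size` bp anchored at multiples of the
#' size from each scaffold origin, half-open
#' `[k * size, (k + 1) * size)` in 0-based coordinates. The default 5000 bp
#' matches the scan this package reproduces (chosen there for the small
#' scaffold sizes of the reference assembly).
#'
#' @param window_size Window length in bp (> 0).
#' @return A `window_spec` object.
#' @export
window_spec <- function(window_size = 5000) {
  stopifnot(window_size > 0)
  structure(list(window_size = as.integer(window_size)),
            class = "window_spec")
}

#' Constants of Tajima's D
#'
#' The standard normalizing constants for a sample of `n` chromosomes:
#' `a1 = sum(1/i)`, `a2 = sum(1/i^2)` for `i = 1..n-1`,
#' `b1 = (n+1)/(3(n-1))`, `b2 = 2(n^2+n+3)/(9n(n-1))`, `c1 = b1 - 1/a1`,
#' `c2 = b2 - (n+2)/(a1 n) + a2/a1^2`, `e1 = c1/a1`,
#' `e2 = c2/(a1^2 + a2)`.
#'
#' @param n Chromosome count (>= 2; the D denominator needs n >= 4).
#' @return Named list with `n`, `a1`, `a2`, `b1`, `b2`, `c1`, `c2`, `e1`,
#'   `e2`.
#' @export
watterson_constants <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(n = n, a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Per-site nucleotide diversity
#'
#' Mean pairwise difference at one site: `a (n - a) / choose(n, 2)` for
#' `a` alt alleles among `n` non-missing chromosomes. Vectorized.
#'
#' @param alt_count Alt (derived) allele count(s), `0 <= alt_count <= n`.
#' @param n_chrom Non-missing chromosome count(s) (>= 2).
#' @return Per-site pi value(s).
#' @examples
#' per_site_pi(2, 4)  # 4/6
#' @export
per_site_pi <- function(alt_count, n_chrom) {
  if (any(n_chrom < 2)) stop("per_site_pi needs >= 2 chromosomes")
  if (any(alt_count < 0) || any(alt_count > n_chrom)) {
    stop("alt_count must lie in [0, n_chrom]")
  }
  alt_count * (n_chrom - alt_count) / choose(n_chrom, 2)
}

#' Tajima's D from window summaries
#'
#' `D = (pi_sum - S / a1) / sqrt(e1 S + e2 S (S - 1))`, undefined (`NA`)
#' when `S = 0` or fewer than 4 chromosomes were sampled. For `S = 1` the
#' `e2` term vanishes and the formula remains defined.
#'
#' @param pi_sum Sum of per-site pi over the window (unscaled).
#' @param s Number of segregating sites.
#' @param n Chromosome count used for the constants.
#' @return Tajima's D, or `NA_real_` when undefined.
#' @export
tajima_d <- function(pi_sum, s, n) {
  if (s == 0 || n < 4) return(NA_real_)
  k <- watterson_constants(n)
  (pi_sum - s / k$a1) / sqrt(k$e1 * s + k$e2 * s * (s - 1))
}

#' Per-window pi and Tajima's D for one condition group
#'
#' Missing genotypes are excluded site-by-site: per-site pi uses the
#' non-missing chromosome count at that site, `S` counts the sites that are
#' polymorphic among the group's non-missing calls, and the chromosome
#' count behind the Watterson constants (`n_eff`) is, by default, the
#' rounded median of the per-site non-missing counts in the window
#' (`n_mode = "full"` instead uses twice the group size at every window).
#' Per-bp pi divides the per-window pi sum by the full window size.
#' Sites with fewer than 2 non-missing chromosomes contribute nothing and
#' are reported via the `n_dropped_sites` attribute. Windows without sites
#' (within the observed extent of each scaffold) are emitted with
#' `valid = FALSE`.
#'
#' @param gm A [genotype_matrix()].
#' @param spec A [window_spec()].
#' @param group Group label to analyze (must exist in `gm$samples$group`).
#' @param n_mode `"median"` (default) or `"full"`, see above.
#' @return Tibble with columns `scaffold`, `start` (0-based, multiple of
#'   the window size), `n_sites`, `n_snps` (S), `pi_sum`, `pi` (per-bp),
#'   `n_eff`, `tajima_d`, `valid`; window size kept as attribute
#'   `window_size`.
#' @export
window_statistics <- function(gm, spec = window_spec(), group,
                              n_mode = c("median", "full")) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(spec, "window_spec"))
  n_mode <- match.arg(n_mode)
  if (!group %in% gm$samples$group) {
    stop("group label not present in samples: ", group)
  }
  ws <- spec$window_size
  calls <- gm$calls[, gm$samples$group == group, drop = FALSE]
  nm_chrom <- 2L * rowSums(!is.na(calls))
  alt <- rowSums(calls, na.rm = TRUE)

  usable <- nm_chrom >= 2L
  n_dropped <- sum(!usable)

  site_tbl <- tibble::tibble(
    scaffold = gm$sites$scaffold,
    start = ((gm$sites$pos - 1L) %/% ws) * ws,
    nm_chrom = nm_chrom, alt = alt
  )[usable, , drop = FALSE]
  site_tbl$pi_site <- per_site_pi(site_tbl$alt, site_tbl$nm_chrom)
  site_tbl$poly <- site_tbl$alt > 0L & site_tbl$alt < site_tbl$nm_chrom

  agg <- site_tbl |>
    dplyr::group_by(.data$scaffold, .data$start) |>
    dplyr::summarise(
      n_sites = dplyr::n(),
      n_snps = sum(.data$poly),
      pi_sum = sum(.data$pi_site),
      n_eff = as.integer(round(median(.data$nm_chrom))),
      .groups = "drop"
    )

  # full window grid over the observed extent of each scaffold
  grid <- gm$sites |>
    dplyr::group_by(.data$scaffold) |>
    dplyr::summarise(max_start = ((max(.data$pos) - 1L) %/% ws) * ws,
                     .groups = "drop")
  grid <- dplyr::bind_rows(lapply(seq_len(nrow(grid)), function(i) {
    tibble::tibble(scaffold = grid$scaffold[i],
                   start = seq.int(0L, grid$max_start[i], by = ws))
  }))

  out <- dplyr::left_join(grid, agg, by = c("scaffold", "start"))
  out$n_sites[is.na(out$n_sites)] <- 0L
  out$n_snps[is.na(out$n_snps)] <- 0L
  out$pi_sum[is.na(out$pi_sum)] <- 0
  if (n_mode == "full") out$n_eff <- 2L * ncol(calls)
  out$pi <- out$pi_sum / ws
  out$tajima_d <- vapply(seq_len(nrow(out)), function(i) {
    if (is.na(out$n_eff[i])) return(NA_real_)
    tajima_d(out$pi_sum[i], out$n_snps[i], out$n_eff[i])
  }, numeric(1))
  out$valid <- out$n_sites > 0L
  out <- out[, c("scaffold", "start", "n_sites", "n_snps", "pi_sum", "pi",
                 "n_eff", "tajima_d", "valid")]
  attr(out, "window_size") <- ws
  attr(out, "n_dropped_sites") <- n_dropped
  attr(out, "group") <- group
  out
}

#' Pair window statistics of the two conditions
#'
#' Inner join on (scaffold, window start), keeping only windows valid in
#' both conditions — the windowed analogue of dropping non-called sites
#' before comparing the groups.
#'
#' @param stats_control,stats_heat Outputs of [window_statistics()] computed
#'   with the same [window_spec()].
#' @return Tibble with the shared window keys and suffixed statistic
#'   columns (`_control`, `_heat`); window size kept as attribute.
#' @export
merge_conditions <- function(stats_control, stats_heat) {
  ws_c <- attr(stats_control, "window_size")
  ws_h <- attr(stats_heat, "window_size")
  if (is.null(ws_c) || is.null(ws_h) || ws_c != ws_h) {
    stop("window specifications of the two conditions do not match")
  }
  a <- stats_control[stats_control$valid, , drop = FALSE]
  b <- stats_heat[stats_heat$valid, , drop = FALSE]
  out <- dplyr::inner_join(a, b, by = c("scaffold", "start"),
                           suffix = c("_control", "_heat"))
  attr(out, "window_size") <- ws_c
  out
}
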