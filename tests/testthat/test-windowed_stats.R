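test_that("per-site pi equals the pairwise enumeration oracle", {
  expect_equal(per_site_pi(2, 4), 4 / 6)
  expect_equal(per_site_pi(0, 10), 0)
  set.seed(21)
  for (i in 1:50) {
    n <- sample(2:12, 1)
    a <- sample(0:n, 1)
    expect_equal(per_site_pi(a, n), oracle_pi_site(a, n),
                 label = sprintf("a=%d n=%d", a, n))
  }
  # invariance under allele-label swap
  expect_equal(per_site_pi(3, 11), per_site_pi(8, 11))
  expect_error(per_site_pi(3, 1), ">= 2")
})

test_that("Tajima's D matches a direct-formula oracle and sign expectations", {
  # all-singleton window: n = 10 chromosomes, S = 5 -> pi_sum = 1, D < 0
  alt <- rep(1L, 5)
  nm <- rep(10L, 5)
  o <- oracle_window_d(alt, nm)
  expect_equal(o$pi_sum, 1.0)
  d <- tajima_d(o$pi_sum, 5, 10)
  expect_lt(d, 0)
  expect_equal(d, o$d, tolerance = 1e-12)

  # zero numerator gives exactly zero
  k <- watterson_constants(8)
  expect_equal(tajima_d(4 / k$a1, 4, 8), 0)

  # undefined cases
  expect_true(is.na(tajima_d(0, 0, 10)))
  expect_true(is.na(tajima_d(1, 3, 3)))

  # sign property: all-singleton negative, all-intermediate positive
  for (n in c(8, 12, 16)) {
    for (s in c(3, 10, 25)) {
      expect_lt(tajima_d(sum(per_site_pi(rep(1, s), n)), s, n), 0)
      expect_gt(tajima_d(sum(per_site_pi(rep(n / 2, s), n)), s, n), 0)
    }
  }
})

test_that("windowed statistics agree with the oracle on random windows", {
  set.seed(22)
  for (i in 1:200) {
    n_ind <- sample(4:16, 1)
    s <- sample(1:60, 1)
    nm <- 2L * n_ind
    alt <- sample.int(nm - 1L, s, replace = TRUE)
    g <- genotypes_from_frequencies(alt, n_ind, missing_rate = 0)
    gm <- toy_genotype_matrix(g)
    st <- window_statistics(gm, window_spec(5000), group = "control")
    o <- oracle_window_d(alt, rep(nm, s))
    expect_equal(st$pi_sum[1], o$pi_sum, tolerance = 1e-9)
    expect_equal(st$tajima_d[1], o$d, tolerance = 1e-9)
  }
})

test_that("missing genotypes are excluded site by site", {
  calls <- rbind(
    c(0L, 1L, NA, 2L),   # 3 called samples: 6 chrom, alt 3
    c(NA, NA, 1L, 1L),   # 2 called samples: 4 chrom, alt 2
    c(0L, 0L, 0L, 0L)    # monomorphic
  )
  gm <- toy_genotype_matrix(calls)
  st <- window_statistics(gm, window_spec(100), group = "control")
  expect_equal(st$n_snps, 2)
  expect_equal(st$pi_sum, per_site_pi(3, 6) + per_site_pi(2, 4))
  expect_equal(st$n_eff, as.integer(round(median(c(6, 4, 8)))))

  # a fully missing site contributes nothing and is counted as dropped
  calls2 <- rbind(calls, c(NA, NA, NA, NA))
  st2 <- window_statistics(toy_genotype_matrix(calls2), window_spec(100),
                           group = "control")
  expect_equal(st2$n_snps, st$n_snps)
  expect_equal(attr(st2, "n_dropped_sites"), 1)
})

test_that("windows are anchored at multiples of the window size", {
  gm <- genotype_matrix(
    sites = tibble::tibble(scaffold = "scf1", pos = c(4999L, 5000L, 5001L, 12000L),
                           ref = "A", alt = "T"),
    calls = matrix(c(0L, 1L), 4, 2, byrow = TRUE),
    samples = tibble::tibble(sample_id = c("a", "b"), group = "control")
  )
  st <- window_statistics(gm, window_spec(5000), group = "control")
  expect_equal(st$start, c(0L, 5000L, 10000L))
  expect_equal(st$n_sites, c(2L, 1L, 1L))  # pos 5000 is in [0, 5000)
  expect_true(all(st$start %% 5000 == 0))
})

test_that("empty windows are emitted invalid, with pi 0 and undefined D", {
  gm <- genotype_matrix(
    sites = tibble::tibble(scaffold = "scf1", pos = c(100L, 11000L),
                           ref = "A", alt = "T"),
    calls = matrix(1L, 2, 4),
    samples = tibble::tibble(sample_id = letters[1:4], group = "control")
  )
  st <- window_statistics(gm, window_spec(5000), group = "control")
  expect_equal(st$valid, c(TRUE, FALSE, TRUE))
  expect_equal(st$pi[2], 0)
  expect_true(is.na(st$tajima_d[2]))

  # covered window whose only site is monomorphic: valid, pi 0, D undefined
  gm2 <- genotype_matrix(
    sites = tibble::tibble(scaffold = "scf1", pos = 100L, ref = "A",
                           alt = "T"),
    calls = matrix(0L, 1, 4),
    samples = tibble::tibble(sample_id = letters[1:4], group = "control")
  )
  st2 <- window_statistics(gm2, window_spec(5000), group = "control")
  expect_true(st2$valid[1])
  expect_equal(st2$n_snps[1], 0)
  expect_equal(st2$pi[1], 0)
  expect_true(is.na(st2$tajima_d[1]))
})

test_that("merging conditions inner-joins valid windows only", {
  d <- simulate_cohort_data(small_config())
  sc <- window_statistics(d$genotypes, group = "control")
  sh <- window_statistics(d$genotypes, group = "heat")
  m <- merge_conditions(sc, sh)
  expect_lte(nrow(m), min(sum(sc$valid), sum(sh$valid)))
  # every truth window with sites in both conditions appears exactly once
  expect_equal(anyDuplicated(paste(m$scaffold, m$start)), 0)
  both <- dplyr::semi_join(sc[sc$valid, ], sh[sh$valid, ],
                           by = c("scaffold", "start"))
  expect_equal(nrow(m), nrow(both))

  # identical inputs join completely; disjoint scaffolds join empty
  mm <- merge_conditions(sc, sc)
  expect_equal(nrow(mm), sum(sc$valid))
  sh2 <- sh
  sh2$scaffold <- paste0("other_", sh2$scaffold)
  expect_equal(nrow(merge_conditions(sc, sh2)), 0)

  # mismatched window sizes are rejected
  attr(sh2, "window_size") <- 123L
  expect_error(merge_conditions(sc, sh2), "do not match")
})

test_that("full-n mode uses the group chromosome count everywhere", {
  d <- simulate_cohort_data(small_config(missing_rate = 0.1))
  st <- window_statistics(d$genotypes, group = "heat", n_mode = "full")
  expect_true(all(st$n_eff == 20L))
})
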