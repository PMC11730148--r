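fake_stats <- function(values, scaffold = "scf1") {
  n <- length(values)
  out <- tibble::tibble(
    scaffold = scaffold, start = (seq_len(n) - 1L) * 5000L,
    n_sites = 10L, n_snps = 5L, pi_sum = 1, pi = 1 / 5000,
    n_eff = 20L, tajima_d = values, valid = TRUE
  )
  attr(out, "window_size") <- 5000L
  out
}

test_that("percentile tails use interpolated cutoffs with closed membership", {
  ct <- classify_tails(fake_stats(as.numeric(1:100)))
  cuts <- attr(ct, "cutoffs")
  expect_equal(unname(cuts), c(5.95, 95.05))
  expect_equal(ct$start[ct$class == "positive-tail"] / 5000, 0:4)
  expect_equal(ct$start[ct$class == "balancing-tail"] / 5000, 95:99)
  expect_equal(sum(ct$class == "interior"), 90)

  # a window equal to the cutoff is inside the tail (closed membership)
  ct2 <- classify_tails(fake_stats(c(rep(0, 19), 5)), lower_q = 5,
                        upper_q = 95)
  expect_equal(sum(ct2$class == "balancing-tail"), 1)
})

test_that("constant statistics classify every window interior, with warning", {
  expect_warning(ct <- classify_tails(fake_stats(rep(1, 50))), "degenerate")
  expect_true(all(ct$class == "interior"))
})

test_that("few valid windows triggers a warning", {
  expect_warning(classify_tails(fake_stats(as.numeric(1:10))), "fewer than 20")
})

test_that("tail sizes approximate the nominal percentiles on continuous data", {
  set.seed(31)
  ct <- classify_tails(fake_stats(rnorm(1000)))
  expect_equal(sum(ct$class == "positive-tail"), 50, tolerance = 0.03)
  expect_equal(sum(ct$class == "balancing-tail"), 50, tolerance = 0.03)
})

test_that("condition contrast obeys set algebra exactly", {
  set.seed(32)
  for (i in 1:10) {
    cc <- classify_tails(fake_stats(rnorm(200)))
    ch <- classify_tails(fake_stats(c(rnorm(150), rnorm(50, 1))))
    out <- contrast_conditions(cc, ch)
    expect_equal(out$n_control + out$n_heat - out$n_shared, out$n_union)
    expect_equal(out$n_control - out$n_shared, out$n_unique_control)
    expect_equal(out$n_heat - out$n_shared, out$n_unique_heat)
  }

  cc <- classify_tails(fake_stats(as.numeric(1:100)))
  same <- contrast_conditions(cc, cc)
  expect_equal(same$n_shared, same$n_control)
  expect_equal(sum(same$n_unique_control), 0)

  ch <- classify_tails(fake_stats(as.numeric(1:100), scaffold = "scf2"))
  disj <- contrast_conditions(cc, ch)
  expect_true(all(disj$n_shared == 0))
})

test_that("shared truth windows appear in both conditions' tails", {
  cfg <- small_config(shared_fraction = 0.5, frac_sweep = 0.05,
                      frac_balancing = 0.05, seed = 33L)
  d <- simulate_cohort_data(cfg)
  cc <- classify_tails(window_statistics(d$genotypes, group = "control"))
  ch <- classify_tails(window_statistics(d$genotypes, group = "heat"))
  out <- contrast_conditions(cc, ch)
  truth <- d$truth
  shared_sweep_truth <- sum(truth$regime_control == "sweep" &
                              truth$regime_heat == "sweep")
  # half the selected windows are planted shared; the observed shared tail
  # count matches the truth within binomial noise (tails hold 5 slots here)
  row <- out[out$tail == "positive-tail", ]
  expect_gte(row$n_shared, shared_sweep_truth - 2)
  expect_lte(row$n_shared, row$n_control)
})

test_that("flank mapping links genes by half-open interval overlap", {
  calls <- tibble::tibble(scaffold = "scf1", start = 10000L,
                          class = "balancing-tail")
  link_at <- function(gene_start, gene_end) {
    ann <- tibble::tibble(gene_id = "g1", scaffold = "scf1",
                          start = gene_start, end = gene_end)
    nrow(map_windows_to_genes(calls, ann, flank = 1000, window_size = 5000L))
  }
  # window [10000, 15000) extended by the flank covers [9000, 16000)
  expect_equal(link_at(11000, 12000), 1)         # strictly inside the window
  expect_equal(link_at(12000, 13000), 1)
  expect_equal(link_at(15000 + 999, 17000), 1)   # begins 999 bp after window end
  expect_equal(link_at(15000 + 1000, 17000), 0)  # begins exactly flank away
  expect_equal(link_at(15000 + 1001, 17000), 0)
  expect_equal(link_at(8000, 9001), 1)   # overlaps the upstream flank by 1 bp
  expect_equal(link_at(8000, 9000), 0)   # ends exactly where the flank starts
})

test_that("mapping is stable under annotation shuffling and logs unknown scaffolds", {
  d <- simulate_cohort_data(small_config(seed = 34L))
  cc <- classify_tails(window_statistics(d$genotypes, group = "control"))
  ann <- d$annotation
  m1 <- map_windows_to_genes(cc, ann)
  set.seed(1)
  m2 <- map_windows_to_genes(cc, ann[sample(nrow(ann)), ])
  sorted <- function(m) m[order(m$scaffold, m$start, m$gene_id), ]
  expect_equal(sorted(m1), sorted(m2), ignore_attr = TRUE)

  ann_bad <- ann
  ann_bad$scaffold[1] <- "scaffold_unknown"
  expect_message(map_windows_to_genes(cc, ann_bad), "without called windows")
})

test_that("every called window links exactly its one planted CDS", {
  d <- simulate_cohort_data(small_config(seed = 35L))
  cc <- classify_tails(window_statistics(d$genotypes, group = "control"))
  m <- map_windows_to_genes(cc, d$annotation)
  called <- cc[cc$class != "interior", ]
  # CDS sits at [start + 1500, start + 3500) of its own 5-kb window, and
  # flanked windows reach 1000 bp into the neighbours, never touching a
  # neighbour's CDS (nearest CDS edge is 1500 bp beyond the window edge)
  expect_equal(nrow(m), nrow(called))
  expect_equal(m$gene_id, sprintf("gene_%s_%d", m$scaffold, m$start))
})

test_that("larva_only restricts links to proteome-detected genes", {
  calls <- tibble::tibble(scaffold = "scf1", start = 0L,
                          class = "positive-tail")
  ann <- tibble::tibble(gene_id = c("g1", "g2"), scaffold = "scf1",
                        start = c(100L, 2000L), end = c(900L, 2900L))
  prot <- tibble::tibble(gene_id = c("g1", "g2"), in_larva = c(1L, 0L))
  m <- map_windows_to_genes(calls, ann, window_size = 5000L,
                            proteome = prot, larva_only = TRUE)
  expect_equal(m$gene_id, "g1")
  expect_error(map_windows_to_genes(calls, ann, window_size = 5000L,
                                    larva_only = TRUE), "proteome")
})

test_that("gene score table flags mapped genes against the larval background", {
  mapping <- tibble::tibble(scaffold = "s", start = 0L,
                            class = "balancing-tail", gene_id = "g2")
  ann <- tibble::tibble(gene_id = c("g1", "g2", "g3"))
  prot <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                         in_larva = c(1L, 1L, 0L))
  tbl <- gene_score_table(mapping, ann, tail = "balancing-tail",
                          proteome = prot)
  expect_equal(tbl$score, c(0L, 1L, 0L))
  expect_equal(tbl$in_background, c(TRUE, TRUE, FALSE))
})
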