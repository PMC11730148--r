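test_that("small-sample MWU p comes from exact enumeration", {
  # 3 score-1 genes in the category vs 7 zeros outside: only 1 of C(10,3)
  # placements is as extreme
  res <- mann_whitney_u(c(1, 1, 1), rep(0, 7))
  expect_equal(res$method, "exact")
  expect_equal(res$p_value, 1 / 120)
  expect_equal(res$U, 21)  # maximal U = n1 * n2

  # identical all-zero groups
  expect_equal(mann_whitney_u(rep(0, 4), rep(0, 9))$p_value, 1)

  # binary exact p equals the hypergeometric tail oracle
  set.seed(51)
  for (i in 1:100) {
    n1 <- sample(2:8, 1)
    n2 <- sample(2:12, 1)
    x <- rbinom(n1, 1, 0.5)
    y <- rbinom(n2, 1, 0.3)
    expect_equal(mann_whitney_u(x, y)$p_value, oracle_mwu_binary(x, y),
                 tolerance = 1e-12,
                 label = sprintf("k=%d n1=%d m=%d N=%d", sum(x), n1,
                                 sum(c(x, y)), n1 + n2))
  }
})

test_that("normal approximation tracks exact enumeration on untied scores", {
  # on continuous (tie-free) scores the continuity-corrected normal p stays
  # within 0.02 of full enumeration; on heavily tied binary tables of this
  # size the U distribution is too lumpy for the normal approximation,
  # which is why the exact path handles them (see the methods vignette)
  set.seed(52)
  for (i in 1:40) {
    n1 <- sample(3:10, 1)
    n2 <- sample(3:(20 - n1), 1)
    x <- runif(n1)
    y <- runif(n2, 0.2, 1.2)
    p_exact <- mann_whitney_u(x, y)$p_value
    p_norm <- mann_whitney_u(x, y, exact_max_n = 0)$p_value
    expect_lt(abs(p_norm - p_exact), 0.02)
  }
})

test_that("MWU p is invariant to relabeling and input order", {
  set.seed(53)
  x <- rbinom(8, 1, 0.6)
  y <- rbinom(30, 1, 0.2)
  base <- mann_whitney_u(x, y)
  expect_equal(mann_whitney_u(sample(x), sample(y))$p_value, base$p_value)
  expect_error(mann_whitney_u(numeric(0), y), "nonempty")
})

test_that("enrichment ranks a fully separating term first", {
  genes <- sprintf("g%03d", 1:100)
  scores <- tibble::tibble(gene_id = genes,
                           score = c(rep(1L, 8), rep(0L, 92)))
  set.seed(54)
  go_map <- dplyr::bind_rows(
    tibble::tibble(gene_id = genes[1:8], go_id = "GO:HIT", namespace = "BP"),
    tibble::tibble(gene_id = sample(genes, 200, replace = TRUE),
                   go_id = sample(sprintf("GO:%04d", 1:20), 200,
                                  replace = TRUE),
                   namespace = "BP")
  )
  res <- run_enrichment(scores, go_map)
  expect_equal(res$go_id[1], "GO:HIT")
  expect_equal(res$n_scored[res$go_id == "GO:HIT"], 8)
  expect_equal(min(res$p_value), res$p_value[res$go_id == "GO:HIT"])
})

test_that("all-zero scores give p = 1 everywhere", {
  genes <- sprintf("g%03d", 1:60)
  scores <- tibble::tibble(gene_id = genes, score = 0L)
  set.seed(55)
  go_map <- tibble::tibble(
    gene_id = sample(genes, 150, replace = TRUE),
    go_id = sample(sprintf("GO:%04d", 1:10), 150, replace = TRUE),
    namespace = "MF"
  )
  res <- run_enrichment(scores, go_map)
  expect_true(all(res$p_value == 1))
  expect_true(all(res$p_adj == 1))
})

test_that("BH adjustment is monotone within namespace and bounds are enforced", {
  genes <- sprintf("g%03d", 1:200)
  set.seed(56)
  scores <- tibble::tibble(gene_id = genes, score = rbinom(200, 1, 0.2))
  go_map <- tibble::tibble(
    gene_id = sample(genes, 1000, replace = TRUE),
    go_id = sample(sprintf("GO:%04d", 1:40), 1000, replace = TRUE),
    namespace = sample(c("BP", "MF"), 1000, replace = TRUE)
  )
  res <- run_enrichment(scores, go_map, min_category = 5,
                        max_category_frac = 0.5)
  expect_true(all(res$n_category >= 5))
  expect_true(all(res$n_category <= 100))
  for (ns in unique(res$namespace)) {
    sub <- res[res$namespace == ns, ]
    ord <- order(sub$p_value)
    expect_true(all(diff(sub$p_adj[ord]) >= -1e-12))
  }
  # category size/scored-count bookkeeping: 0 <= k <= N
  expect_true(all(res$n_scored >= 0 & res$n_scored <= res$n_category))
})

test_that("raw p is near-uniform under a continuous-score null", {
  # background scale mirrors the study (6556 larval-protein CDS,
  # categories of 20-50 genes), keeping cross-category gene sharing low
  set.seed(1)
  genes <- sprintf("g%05d", 1:6556)
  scores <- tibble::tibble(gene_id = genes, score = runif(6556))
  go_map <- dplyr::bind_rows(lapply(1:200, function(i) {
    tibble::tibble(gene_id = sample(genes, sample(20:50, 1)),
                   go_id = sprintf("GO:N%03d", i), namespace = "BP")
  }))
  res <- run_enrichment(scores, go_map)
  expect_equal(nrow(res), 200)
  ks <- suppressWarnings(stats::ks.test(res$p_value, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("overlap summaries count shared and disjoint term sets", {
  r1 <- tibble::tibble(go_id = c("a", "b", "c"), p_value = c(0.01, 0.2, 0.6))
  r2 <- tibble::tibble(go_id = c("b", "c", "d"), p_value = c(0.03, 0.5, 0.9))
  ov <- overlap_summary(list(x = r1, y = r2))
  expect_equal(ov$pairwise["x", "y"], 2L)
  expect_equal(ov$n_common_all, 2L)

  same <- overlap_summary(list(x = r1, y = r1))
  expect_equal(same$n_common_all, 3L)

  r3 <- tibble::tibble(go_id = c("e", "f"), p_value = c(0.1, 0.2))
  expect_equal(overlap_summary(list(x = r1, y = r3))$n_common_all, 0L)

  # alpha restriction keeps sub-threshold terms only
  ov_a <- overlap_summary(list(x = r1, y = r2), alpha = 0.05)
  expect_equal(ov_a$sizes, c(x = 1L, y = 1L))
  expect_equal(ov_a$n_common_all, 0L)
})

test_that("condition-specific planted terms surface only in their own condition", {
  d <- simulate_cohort_data(small_config(seed = 58L, n_scaffolds = 10,
                                         designated_prob = 0.9))
  run_for <- function(group, tail) {
    ct <- classify_tails(window_statistics(d$genotypes, group = group))
    mp <- map_windows_to_genes(ct, d$annotation)
    sc <- gene_score_table(mp, d$annotation, tail = tail,
                           proteome = d$proteome)
    run_enrichment(sc, d$go_map)
  }
  res_cb <- run_for("control", "balancing-tail")
  res_hb <- run_for("heat", "balancing-tail")
  top <- function(r) r$go_id[r$p_value <= quantile(r$p_value, 0.1)]
  expect_true(d$designated_terms[["control_balancing"]] %in% top(res_cb))
  expect_true(d$designated_terms[["heat_balancing"]] %in% top(res_hb))
})
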