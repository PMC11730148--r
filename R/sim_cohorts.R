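#' Simulate a two-condition cohort in memory
#'
#' Generates the full synthetic study: a combined genotype matrix for the
#' control and heat cohorts, one CDS annotation per window, a gene-to-GO
#' map with designated terms concentrated in selected windows, a proteome
#' flag table, and the ground-truth regime table used by recovery tests.
#'
#' SNP positions are drawn once per window and shared by both conditions;
#' each condition then draws its own derived-allele counts from its
#' regime-specific site frequency spectrum, so the two cohorts are genotyped
#' at the same sites but under possibly different selection regimes.
#' Selected windows are assigned per condition according to `frac_sweep` /
#' `frac_balancing`, with `shared_fraction` of each regime's windows common
#' to both conditions and the remainder condition-specific and disjoint.
#'
#' @param config A [sim_config()].
#' @return A list with elements `genotypes` ([genotype_matrix()] over all
#'   samples), `annotation` (tibble: gene_id, scaffold, start, end; 0-based
#'   half-open CDS intervals, one per window, fully inside it), `go_map`
#'   (tibble: gene_id, go_id, namespace), `proteome` (tibble: gene_id,
#'   in_larva, in_egg), `truth` (tibble: scaffold, start, regime_control,
#'   regime_heat), `designated_terms` (named character vector keyed by
#'   `<condition>_<regime>`), and `config`.
#' @export
simulate_cohort_data <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ws <- config$window_size
  n_windows <- config$n_scaffolds * config$windows_per_scaffold

  windows <- tibble::tibble(
    scaffold = rep(sprintf("scaffold_%d", seq_len(config$n_scaffolds)),
                   each = config$windows_per_scaffold),
    start = rep((seq_len(config$windows_per_scaffold) - 1L) * ws,
                times = config$n_scaffolds)
  )

  truth <- assign_regimes(windows, config)

  # per-window SNP positions (1-based, unique within window), shared by both
  # conditions
  s_per_window <- rpois(n_windows, config$snps_per_window)
  s_per_window <- pmin(s_per_window, ws)

  site_list <- vector("list", n_windows)
  call_list <- vector("list", n_windows)
  n_ctrl_chrom <- 2L * config$n_control
  n_heat_chrom <- 2L * config$n_heat
  nt <- c("A", "C", "G", "T")

  for (w in seq_len(n_windows)) {
    s <- s_per_window[w]
    if (s == 0L) {
      site_list[[w]] <- NULL
      next
    }
    pos <- sort(sample.int(ws, s)) + windows$start[w]
    ref <- sample(nt, s, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1L), character(1))
    cnt_ctrl <- sample_site_frequencies(
      truth$regime_control[w], n_ctrl_chrom, s,
      sweep_alpha = config$sweep_alpha,
      balancing_beta = config$balancing_beta
    )
    cnt_heat <- sample_site_frequencies(
      truth$regime_heat[w], n_heat_chrom, s,
      sweep_alpha = config$sweep_alpha,
      balancing_beta = config$balancing_beta,
      distortion = config$heat_sfs_distortion
    )
    g_ctrl <- genotypes_from_frequencies(cnt_ctrl, config$n_control,
                                         config$missing_rate)
    g_heat <- genotypes_from_frequencies(cnt_heat, config$n_heat,
                                         config$missing_rate)
    site_list[[w]] <- tibble::tibble(
      scaffold = windows$scaffold[w], pos = pos, ref = ref, alt = unname(alt)
    )
    call_list[[w]] <- cbind(g_ctrl, g_heat)
  }

  keep <- !vapply(site_list, is.null, logical(1))
  sites <- dplyr::bind_rows(site_list[keep])
  calls <- do.call(rbind, call_list[keep])
  samples <- tibble::tibble(
    sample_id = c(sprintf("ctrl_%02d", seq_len(config$n_control)),
                  sprintf("heat_%02d", seq_len(config$n_heat))),
    group = rep(c("control", "heat"), c(config$n_control, config$n_heat))
  )
  gm <- genotype_matrix(sites, calls, samples)

  annotation <- tibble::tibble(
    gene_id = sprintf("gene_%s_%d", windows$scaffold, windows$start),
    scaffold = windows$scaffold,
    start = windows$start + as.integer(0.3 * ws),
    end = windows$start + as.integer(0.7 * ws)
  )

  designated <- c(
    control_sweep = "GO:9100001", control_balancing = "GO:9100002",
    heat_sweep = "GO:9100003", heat_balancing = "GO:9100004"
  )
  go_map <- build_go_map(annotation$gene_id, truth, designated, config)

  proteome <- tibble::tibble(
    gene_id = annotation$gene_id,
    in_larva = rbinom(n_windows, 1L, config$frac_larva),
    in_egg = rbinom(n_windows, 1L, config$frac_egg)
  )

  list(genotypes = gm, annotation = annotation, go_map = go_map,
       proteome = proteome, truth = truth,
       designated_terms = designated, config = config)
}

# Assign selection regimes to windows per condition. Counts are deterministic
# (round(frac * n)); shared windows first, remaining selected windows are
# condition-specific and disjoint across conditions and regimes.
assign_regimes <- function(windows, config) {
  n <- nrow(windows)
  n_sw <- round(config$frac_sweep * n)
  n_ba <- round(config$frac_balancing * n)
  sh_sw <- round(config$shared_fraction * n_sw)
  sh_ba <- round(config$shared_fraction * n_ba)
  need <- sh_sw + 2L * (n_sw - sh_sw) + sh_ba + 2L * (n_ba - sh_ba)
  if (need > n) stop("not enough windows for the requested regime fractions")

  idx <- sample.int(n, need)
  take <- function(k) {
    out <- idx[seq_len(k)]
    idx <<- idx[-seq_len(k)]
    out
  }
  shared_sweep <- take(sh_sw)
  ctrl_sweep <- c(shared_sweep, take(n_sw - sh_sw))
  heat_sweep <- c(shared_sweep, take(n_sw - sh_sw))
  shared_bal <- take(sh_ba)
  ctrl_bal <- c(shared_bal, take(n_ba - sh_ba))
  heat_bal <- c(shared_bal, take(n_ba - sh_ba))

  regime_control <- rep("neutral", n)
  regime_control[ctrl_sweep] <- "sweep"
  regime_control[ctrl_bal] <- "balancing"
  regime_heat <- rep("neutral", n)
  regime_heat[heat_sweep] <- "sweep"
  regime_heat[heat_bal] <- "balancing"

  tibble::tibble(
    scaffold = windows$scaffold, start = windows$start,
    regime_control = regime_control, regime_heat = regime_heat,
    sweep_alpha = config$sweep_alpha, balancing_beta = config$balancing_beta
  )
}

# Gene -> GO map: 1-3 background terms per gene plus designated terms
# concentrated in the selected windows of their (condition, regime) pair.
build_go_map <- function(gene_ids, truth, designated, config) {
  ns_cycle <- c("BP", "MF", "CC")
  vocab <- sprintf("GO:%07d", seq_len(config$go_vocab_size))
  vocab_ns <- ns_cycle[(seq_along(vocab) - 1L) %% 3L + 1L]
  n <- length(gene_ids)

  rows <- vector("list", n)
  for (g in seq_len(n)) {
    k <- if (length(config$terms_per_gene) == 1L) config$terms_per_gene else
      sample(config$terms_per_gene, 1L)
    pick <- if (k > 0L) sample.int(length(vocab), min(k, length(vocab))) else
      integer(0)
    ids <- vocab[pick]
    ns <- vocab_ns[pick]
    for (cond in c("control", "heat")) {
      regime <- truth[[paste0("regime_", cond)]][g]
      for (reg in c("sweep", "balancing")) {
        p <- if (regime == reg) config$designated_prob else
          config$background_term_prob
        if (runif(1) < p) {
          ids <- c(ids, designated[[paste0(cond, "_", reg)]])
          ns <- c(ns, "BP")
        }
      }
    }
    if (length(ids)) {
      rows[[g]] <- tibble::tibble(gene_id = gene_ids[g], go_id = ids,
                                  namespace = ns)
    }
  }
  dplyr::distinct(dplyr::bind_rows(rows))
}

#' Simulate a two-condition cohort and write it to disk
#'
#' Runs [simulate_cohort_data()] and writes the standard text outputs:
#' VCFv4.2 genotypes (one combined file plus a sample-to-group map by
#' default, or one VCF per condition), BED6 CDS intervals, the gene-to-GO
#' TSV, the proteome flag TSV and the truth table TSV. Identical
#' configurations (including the seed) produce byte-identical files.
#'
#' @inheritParams simulate_cohort_data
#' @param outdir Output directory (created if needed).
#' @param split If `TRUE`, write one VCF per condition instead of a combined
#'   VCF.
#' @return Invisibly, a list with the generated `data` (see
#'   [simulate_cohort_data()]) and a named character vector `files`.
#' @export
simulate_cohorts <- function(config = sim_config(), outdir, split = FALSE) {
  data <- simulate_cohort_data(config)
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", outdir)
  }
  scaffold_len <- config$windows_per_scaffold * config$window_size
  files <- c()
  if (split) {
    for (grp in c("control", "heat")) {
      f <- file.path(outdir, sprintf("genotypes_%s.vcf", grp))
      write_genotype_vcf(subset_samples(data$genotypes, group = grp), f,
                         scaffold_length = scaffold_len)
      files[paste0("vcf_", grp)] <- f
    }
  } else {
    f <- file.path(outdir, "genotypes.vcf")
    write_genotype_vcf(data$genotypes, f, scaffold_length = scaffold_len)
    files["vcf"] <- f
  }
  files["groups"] <- file.path(outdir, "groups.tsv")
  write_tsv_plain(data$genotypes$samples, files["groups"])
  files["cds_bed"] <- file.path(outdir, "cds.bed")
  bed <- data.frame(
    chrom = data$annotation$scaffold, chromStart = data$annotation$start,
    chromEnd = data$annotation$end, name = data$annotation$gene_id,
    score = 0L, strand = "+"
  )
  write.table(bed, files["cds_bed"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  files["go_map"] <- file.path(outdir, "go_map.tsv")
  write_tsv_plain(data$go_map, files["go_map"])
  files["proteome"] <- file.path(outdir, "proteome.tsv")
  write_tsv_plain(data$proteome, files["proteome"])
  files["truth"] <- file.path(outdir, "truth.tsv")
  write_tsv_plain(data$truth, files["truth"])
  invisible(list(data = data, files = files))
}

write_tsv_plain <- function(df, path) {
  write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
}

#' Simulate per-tank larval survival counts
#'
#' Emulates the tank design of the study: three replicate tanks of 200
#' larvae per condition followed daily for 21 days, with endpoint survival
#' near 70% (control) and 50% (heat). Survival is a per-day binomial
#' thinning with a tank-specific retention rate (small log-odds noise),
#' giving realistic monotone per-tank trajectories.
#'
#' @param n_tanks Tanks per condition.
#' @param n_days Number of days followed.
#' @param n_larvae Larvae per tank at day 0.
#' @param surv_control,surv_heat Target endpoint survival proportions.
#' @param tank_sd Standard deviation of the tank-level log-odds noise on the
#'   daily retention rate.
#' @param seed Integer seed.
#' @return Tibble with columns `condition`, `tank`, `day`, `alive`, `total`.
#' @export
simulate_survival <- function(n_tanks = 3, n_days = 21, n_larvae = 200,
                              surv_control = 0.70, surv_heat = 0.50,
                              tank_sd = 0.05, seed = 1L) {
  set.seed(seed)
  one_tank <- function(cond, tank, target) {
    r <- target^(1 / n_days)  # daily retention giving the target endpoint
    lo <- log(r / (1 - r)) + rnorm(1, 0, tank_sd)
    r_tank <- 1 / (1 + exp(-lo))
    alive <- integer(n_days + 1L)
    alive[1L] <- n_larvae
    for (d in seq_len(n_days)) {
      alive[d + 1L] <- rbinom(1L, alive[d], r_tank)
    }
    tibble::tibble(condition = cond, tank = sprintf("%s_tank%d", cond, tank),
                   day = 0:n_days, alive = alive, total = n_larvae)
  }
  dplyr::bind_rows(
    lapply(seq_len(n_tanks), function(t) one_tank("control", t, surv_control)),
    lapply(seq_len(n_tanks), function(t) one_tank("heat", t, surv_heat))
  )
}
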