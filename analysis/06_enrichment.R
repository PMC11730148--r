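#!/usr/bin/env Rscript
# Step 6 — rank-based GO enrichment: binary gene scores (1 = linked to an
# outlier window of the tail under analysis) against the larval-protein
# background, Mann-Whitney U per GO term, BH adjustment within namespace,
# and the cross-analysis overlap of term sets.

suppressMessages(library(larvascan))

outdir <- "results/enrichment"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

groups <- read.delim("results/simulation/groups.tsv")
gm <- read_vcf("results/filtering/genotypes_filtered.vcf", groups)
bed <- read.delim("results/simulation/cds.bed", header = FALSE,
                  col.names = c("scaffold", "start", "end", "gene_id",
                                "score", "strand"))
annotation <- tibble::tibble(gene_id = bed$gene_id, scaffold = bed$scaffold,
                             start = bed$start, end = bed$end)
proteome <- read.delim("results/simulation/proteome.tsv")
go_map <- read.delim("results/simulation/go_map.tsv")

results <- list()
for (grp in c("control", "heat")) {
  st <- window_statistics(gm, window_spec(5000), group = grp)
  ct <- classify_tails(st)
  mp <- map_windows_to_genes(ct, annotation, flank = 1000)
  for (tail in c("balancing-tail", "positive-tail")) {
    scores <- gene_score_table(mp, annotation, tail = tail,
                               proteome = proteome)
    res <- run_enrichment(scores, go_map)
    key <- sprintf("%s_%s", grp, sub("-tail", "", tail))
    results[[key]] <- res
    write.table(as.data.frame(res),
                file.path(outdir, sprintf("enrichment_%s.tsv", key)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    message(sprintf(
      "%s: %d terms tested; top term %s (raw p = %.2e, k/N = %d/%d)",
      key, nrow(res), res$go_id[1], res$p_value[1], res$n_scored[1],
      res$n_category[1]))
  }
}

ov <- overlap_summary(results, alpha = 0.05)
message("terms with raw p < 0.05 per analysis:")
print(ov$sizes)
message("pairwise overlaps:")
print(ov$pairwise)
write.table(ov$pairwise, file.path(outdir, "overlap_pairwise.tsv"),
            sep = "\t", quote = FALSE)
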