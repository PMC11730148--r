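#!/usr/bin/env Rscript
# Step 4 — percentile-tail outlier classification (5th/95th percentiles of
# Tajima's D per condition), cross-condition shared/unique set contrast,
# and mapping of outlier windows (+/- 1000 bp flanks) onto CDS annotations.

suppressMessages(library(larvascan))

outdir <- "results/outliers"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

groups <- read.delim("results/simulation/groups.tsv")
gm <- read_vcf("results/filtering/genotypes_filtered.vcf", groups)
bed <- read.delim("results/simulation/cds.bed", header = FALSE,
                  col.names = c("scaffold", "start", "end", "gene_id",
                                "score", "strand"))
annotation <- tibble::tibble(gene_id = bed$gene_id, scaffold = bed$scaffold,
                             start = bed$start, end = bed$end)
proteome <- read.delim("results/simulation/proteome.tsv")

calls <- list()
for (grp in c("control", "heat")) {
  st <- window_statistics(gm, window_spec(5000), group = grp)
  ct <- classify_tails(st, lower_q = 5, upper_q = 95)
  calls[[grp]] <- ct
  cuts <- attr(ct, "cutoffs")
  message(sprintf(
    "%s: %d positive-tail, %d balancing-tail windows (cutoffs %.3f / %.3f)",
    grp, sum(ct$class == "positive-tail"),
    sum(ct$class == "balancing-tail"), cuts["lower"], cuts["upper"]))
  out_bed <- ct[ct$class != "interior", ]
  write.table(
    data.frame(out_bed$scaffold, out_bed$start, out_bed$start + 5000L,
               as.character(out_bed$class)),
    file.path(outdir, sprintf("outliers_%s.bed", grp)),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
}

venn <- contrast_conditions(calls$control, calls$heat)
write.table(as.data.frame(venn), file.path(outdir, "contrast_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("shared windows per tail:")
print(as.data.frame(venn), row.names = FALSE)

for (grp in c("control", "heat")) {
  mp <- map_windows_to_genes(calls[[grp]], annotation, flank = 1000,
                             proteome = proteome, larva_only = TRUE)
  write.table(as.data.frame(mp),
              file.path(outdir, sprintf("window_genes_%s.tsv", grp)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("%s: %d outlier windows linked to larval-protein CDS",
                  grp, length(unique(paste(mp$scaffold, mp$start)))))
}
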