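#!/usr/bin/env Rscript
# Step 2 — read the simulated VCF back through the standard path and apply
# the PLINK-style site filters: missingness (--geno 0.25), minor allele
# frequency (--maf 0.01), Hardy-Weinberg exact test (--hwe 1e-6), in that
# fixed order, on the pooled call set.

suppressMessages(library(larvascan))

indir <- "results/simulation"
outdir <- "results/filtering"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

groups <- read.delim(file.path(indir, "groups.tsv"))
gm <- read_vcf(file.path(indir, "genotypes.vcf"), groups)
res <- apply_filters(gm, filter_thresholds())
print(res$report)

write_genotype_vcf(res$genotypes, file.path(outdir, "genotypes_filtered.vcf"))
rep_df <- data.frame(
  stage = c("input", names(res$report$removed), "surviving"),
  n_sites = c(res$report$n_input, unname(res$report$removed),
              res$report$n_surviving)
)
write.table(rep_df, file.path(outdir, "filter_report.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("retained %d of %d sites", res$report$n_surviving,
                res$report$n_input))
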