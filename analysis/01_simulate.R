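#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study: 16 control + 10 heat-treated
# diploid larvae genotyped over 500 five-kb windows, with 5% of windows per
# condition under a sweep-like regime and 5% under a balancing regime, plus
# matching CDS/GO/proteome annotations, the ground-truth regime table, and
# per-tank survival counts.

suppressMessages(library(larvascan))

outdir <- "results/simulation"
cfg <- sim_config(seed = 20260921L)
print(cfg)

sim <- simulate_cohorts(cfg, outdir)
surv <- simulate_survival(seed = cfg$seed)
write.table(as.data.frame(surv), file.path(outdir, "survival.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

truth <- sim$data$truth
message(sprintf("wrote %d files to %s", length(sim$files) + 1, outdir))
message(sprintf("sites simulated: %d across %d windows",
                nrow(sim$data$genotypes$sites), nrow(truth)))
message(sprintf("planted regimes (control): %s",
                paste(sprintf("%s=%d", names(table(truth$regime_control)),
                              table(truth$regime_control)), collapse = ", ")))
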