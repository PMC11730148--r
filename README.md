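# larvascan

Windowed selection scans on two-condition cohorts of individually
genotyped diploids, built around the contrast between control and
heat-stressed coral larvae: does thermal stress leave a different
selective footprint on the survivors' genomes even when overall genetic
diversity does not move?

The package is aimed at population geneticists and coral biologists who
want the full scan as a tested, reproducible pipeline: genotype
simulation with known selection regimes, PLINK-style site filtering,
windowed diversity statistics, percentile-tail outlier scans,
mixed-model group inference with subsampling, and rank-based GO
enrichment.

## The statistics at its core

For a 5-kb window with *S* segregating sites among *n* chromosomes,
nucleotide diversity and Watterson's estimator are

π̂ = Σ_sites aᵢ(nᵢ − aᵢ) / C(nᵢ, 2),  θ_W = S / a₁,  a₁ = Σᵢ₌₁ⁿ⁻¹ 1/i,

and Tajima's D is their studentized difference,

D = (π̂ − S/a₁) / √(e₁S + e₂S(S−1)).

Windows in the lowest 5% of D per condition are candidate targets of
positive selection (rare-allele excess), the highest 5% candidates for
balancing selection (intermediate-frequency excess). Outlier sets are
intersected across conditions, mapped (±1000 bp flanks) onto CDS
annotations, and the linked genes scored 0/1 for Mann–Whitney U GO
enrichment against a larval-proteome background. Group-level shifts in D
and π are tested with a likelihood-ratio contrast of linear mixed models
(`value ~ condition + (1 | window)` vs the same without condition, ML
fits via lme4), with a 100-iteration control-subsampling procedure to
equalize sample sizes.

Because the study's sequencing data is not required, a
site-frequency-spectrum simulator generates the cohorts: neutral windows
draw derived-allele counts ∝ 1/i, sweep-like windows ∝ 1/i^α, balancing
windows mix the neutral law with a bump at intermediate frequencies, and
a truth table records every planted regime. See the methods vignette
(`vignettes/selection-scan-methods.Rmd`) for assumptions and numerical
choices.

## Worked example

The `analysis/` directory holds the scan as numbered drivers
(`Rscript analysis/01_simulate.R`, then `02_filter.R` … `06_enrichment.R`),
writing tables under `results/`. The same steps in a session:

```r
library(larvascan)

cfg <- sim_config(seed = 20260921L)   # 16 + 10 diploids, 500 windows
d   <- simulate_cohort_data(cfg)

filt <- apply_filters(d$genotypes, filter_thresholds())
filt$report
#> <filter_report> 19925 sites in, 19920 surviving
#>   removed: missingness 3, MAF 2, HWE 0 (pooled)

sc <- window_statistics(filt$genotypes, window_spec(5000), "control")
sh <- window_statistics(filt$genotypes, window_spec(5000), "heat")
ct <- classify_tails(sc); ch <- classify_tails(sh)
contrast_conditions(ct, ch)
#>            tail n_control n_heat n_shared n_unique_control n_unique_heat n_union
#>   positive-tail        25     25        5               20            20      45
#>  balancing-tail        25     25        5               20            20      45

lmm_contrast(merge_conditions(sc, sh), "tajima_d")
#> <lmm_contrast> tajima_d: Chisq = 1.18, df = 1, P = 0.278 (n = 500 windows)
```

Each condition's 500 windows yield 25 windows per 5% tail; the five
shared windows per tail recover exactly the planted
`shared_fraction = 0.2` (20% of 25 selected windows). The Tajima's D
group contrast is null here because both conditions carry the *same
fractions* of selected windows — the selection signal is in which
windows are outliers, not in the genome-wide mean. Mapping and
enrichment then recover the planted condition-specific GO terms as top
hits, e.g. from `analysis/06_enrichment.R`:

```
control_positive: 64 terms tested; top term GO:9100001 (raw p = 9.19e-57, k/N = 19/26)
heat_positive:    64 terms tested; top term GO:9100003 (raw p = 1.70e-50, k/N = 15/20)
```

`k/N` is the scored-in-category fraction: 19 of the term's 26 background
genes sit in outlier windows. The subsampling summary
(`analysis/05_group_inference.R`) reports, over 100 redraws of 10 of the
16 control larvae, the fraction of significant contrasts and the
fraction agreeing in direction.

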