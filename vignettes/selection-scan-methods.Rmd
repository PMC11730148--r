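---
title: "Methods: windowed selection scans on two-condition larval cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed selection scans on two-condition larval cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`larvascan` re-implements, as a tested pipeline over simulated data, a
selection-scan contrast between two cohorts of individually genotyped coral
larvae: a control group reared at ambient temperature and a heat-stressed
group. The question the scan asks is whether the two rearing conditions
leave different selective footprints on the surviving larvae's genomes,
even when genome-wide diversity does not move.

## The statistics

For a window of `S` segregating sites among `n` sampled chromosomes, the
two classical estimators of the population mutation rate are the mean
pairwise diversity

$$\hat\pi = \sum_{\text{sites}} \frac{a_i (n_i - a_i)}{\binom{n_i}{2}},$$

with `a_i` the alternate-allele count among the `n_i` non-missing
chromosomes at site `i`, and Watterson's `S / a_1` with
`a_1 = sum(1/i), i = 1..n-1`. Tajima's D is their studentized difference,

$$D = \frac{\hat\pi - S/a_1}{\sqrt{e_1 S + e_2 S (S-1)}},$$

with the usual constants (`watterson_constants()`). An excess of rare
variants — the footprint of a selective sweep or purifying pressure —
pushes D negative; an excess of intermediate-frequency variants, as
maintained by balancing selection, pushes it positive. D is undefined for
`S = 0` or `n < 4`; for `S = 1` the `e_2` term vanishes and the formula is
used as-is.

Windows are non-overlapping 5-kb bins anchored at multiples of the window
size from each scaffold origin (half-open, 0-based); the final partial
window is retained. Per-bp π divides the per-window π sum by the full
window size, the convention of the standard windowed-π tools. Both choices
make window keys directly comparable across conditions.

### Missing genotypes

Missing calls are excluded site by site: per-site π uses the non-missing
chromosome count at that site, and `S` counts sites polymorphic among the
group's non-missing calls. The chromosome count behind the D constants is
not recoverable from varying per-site counts; `window_statistics()`
defaults to the rounded median per-site non-missing chromosome count of
the window (`n_mode = "median"`), a robust summary, with
`n_mode = "full"` (twice the group size) available as a sensitivity mode.
Sites with fewer than two non-missing chromosomes contribute nothing and
are counted in the `n_dropped_sites` attribute.

## Site filtering

`apply_filters()` applies the three PLINK-style filters with the defaults
used for the larval call set — calling rate (missing fraction ≤ 0.25),
minor allele frequency (≥ 0.01), and the classical two-sided conditional
exact test of Hardy-Weinberg equilibrium (p ≥ 1e-6; `hwe_exact_test()`,
no mid-p correction) — in that fixed order, so the per-filter exclusion
counts are deterministic and always sum to the input count. The filters
are computed on both condition groups pooled, matching a workflow that
filters one combined call set before splitting the per-condition analyses;
a per-group HWE mode is provided. A single PLINK invocation does not
define an order among its flags; the order here (missingness → MAF → HWE)
runs the cheap screens first and only attributes a site to the first
filter it fails.

## Outlier classification and gene mapping

Within each condition, windows at or below the 5th percentile of D are
called `positive-tail` and at or above the 95th percentile
`balancing-tail`. Cutoffs are linear-interpolation percentiles (R quantile
type 7, the dominant convention) over valid windows; membership is closed
(`<=` / `>=`). With constant D both cutoffs coincide; windows that would
fall in both tails are assigned interior with a warning. π-tails are
available behind the same interface, but D-tails drive the pipeline, as
they carry the selection interpretation.

Each 5-kb outlier window is treated as one region; adjacent outlier
windows are not merged (the merge rule of the original regions is not
recoverable, and unmerged windows keep the set algebra of the
cross-condition contrast exact). `contrast_conditions()` reports, per
tail, each condition's count, the shared windows, and the unique
remainders.

The original analysis BLASTed the 1000 bp flanking each outlier locus
against coding sequence; with a coordinate annotation in hand this is an
interval question, and `map_windows_to_genes()` links a gene to a window
when its CDS overlaps the window extended by 1000 bp on both sides
(half-open intervals; strand ignored). Restriction to genes with
larval-proteome evidence (`larva_only`) mirrors the focus on CDS encoding
larval proteins.

## Group inference

`lmm_contrast()` compares a window statistic between conditions with a
linear mixed model fitted by maximum likelihood in lme4:
`value ~ condition + (1 | window)` against the same model without the
condition effect, a likelihood-ratio test on one degree of freedom. The
reported headline form (Chisq, df = 1, p) follows the convention of the
study this reproduces; condition is a fixed effect with a random window
intercept, the only structure that yields a df = 1 group test. ML rather
than REML is required for likelihood ratios on fixed effects.

Two numerical choices. First, tiny negative ratio statistics (optimizer
noise) are clamped to zero. Second, each model's profiled deviance is also
evaluated at the other model's stopping point and the better value kept:
for regular fits this changes nothing, but when the window intercepts
explain the data exactly (e.g. a duplicated table) the residual variance
collapses, the profiled likelihood is unbounded in the variance ratio, and
the two optimizers stop at arbitrary points; the profiled deviances still
coincide at every ratio, so this evaluation pins the test statistic at
zero instead of an optimizer artifact.

### Subsampling robustness

`subsample_robustness()` redraws `k = 10` of the control individuals
without replacement, recomputes the control window statistics, and re-runs
both contrasts against the full heat group, 100 times; iteration `i` uses
seed `base_seed + i`, so any single iteration is independently
reproducible, and the summary reports the fraction of significant
iterations and the fraction agreeing in contrast direction. This mirrors
equalizing the control sample size to the heat group.

Sample size is not a nuisance here but a genuine confound: Tajima's D has
a small-sample bias that depends on the number of chromosomes, so two
*neutral* cohorts of 32 and 20 chromosomes differ in expected D by a few
hundredths — enough for the window-paired LMM, with hundreds of windows,
to reject reliably. For this reason the package's type-I calibration
experiment (see the acceptance tests) simulates *exchangeable* null
cohorts of 10 + 10 individuals, the subsampled size; the unequal-size
comparison is exercised by the subsampling procedure, which is the
appropriate instrument for it.

### Survival

`survival_compare()` treats survival as a per-tank proportion, smooths
each condition with loess (span 0.75 by default, recorded in the output),
and compares conditions with a two-sided Wilcoxon rank-sum test over tanks
— on final-day proportions by default (exact p when untied), or on all
tank-day proportions pooled (`mode = "per_day"`); both aggregations are
available because the original analysis does not state which daily
aggregate fed its rank test.

## Rank-based GO enrichment

Genes linked to outlier windows of the tail under analysis score 1, all
other background genes 0; the background is the set of genes with
larval-proteome evidence. `mann_whitney_u()` compares the scores of each
GO term's genes against the rest of the background with midrank ties, a
one-sided (enrichment) alternative, exact enumeration for combined sizes
up to 20, and a tie-corrected, continuity-corrected normal approximation
above. Raw p-values are BH-adjusted within each namespace (BP/MF/CC), and
both raw and adjusted values are always reported — with target sets of
tens of genes against thousands, raw-p rankings are informative where
adjusted values saturate. Terms smaller than 5 genes or larger than half
the background are skipped.

With binary scores and midranks the U statistic is a monotone function of
the number of score-1 genes in the category, so the exact enumeration
reduces to a hypergeometric tail — the tests exploit this as an
independent oracle. The normal approximation is accurate for untied
scores (within 0.02 of enumeration for group sizes ≥ 3) but *not* for
tiny tied binary tables, where the U distribution is too lumpy; that is
precisely why the exact path exists and why tie handling must be explicit
when rank machinery is applied to 0/1 scores.

`overlap_summary()` intersects the term sets of several analyses
(condition × tail), either all tested terms or those below a raw-p
threshold.

## The synthetic cohort generator

No sequencing data ships with the package; `simulate_cohort_data()`
generates cohorts in which every downstream claim can be checked against
a known truth table. Defaults reproduce the study design: 16 control + 10
heat diploids, 25 scaffolds × 20 windows of 5000 bp (500 windows per
condition), Poisson(40) SNPs per window, 5% per-genotype missingness
(safely under the 25% calling-rate filter), 5% of windows per condition
sweep-like and 5% balancing, with 20% of each regime's windows shared
between conditions (the original contrast found sharing of roughly this
order in the balancing tail and much less in the sweep tail).

Sites are drawn independently from a regime-specific site frequency
spectrum over derived-allele counts `1..n-1`: neutral `∝ 1/i`; sweep-like
`∝ 1/i^alpha` (default α = 3, concentrating mass on singletons); balancing
mixes the neutral law with a Gaussian-shaped bump at `n/2` carrying β = 5
times the neutral weight. Derived alleles are placed on chromosomes
uniformly without replacement and paired into diploids; genotypes are
masked missing independently. SNP positions are drawn once per window and
shared by both conditions, so the cohorts are genotyped at the same sites
(as a joint call set would be) while each condition follows its own
regime. A `heat_sfs_distortion` exponent can tilt the *entire* heat
cohort's SFS, providing a known genome-wide D shift for robustness
experiments.

Under these defaults the three regimes separate cleanly: mean window D is
about −2.4 (sweep), 0.0 (neutral), and +3.1 (balancing), with neutral
windows spread with a standard deviation near 0.35. Two consequences are
worth stating plainly. First, recovery of planted windows by the 5%
percentile tails is essentially complete. Second, because each tail has
exactly as many slots as there are planted windows (5% each), the planted
windows crowd neutral windows out of the tails almost entirely — nominal
5% tail occupancy by neutral windows is only observable in an all-neutral
simulation, not in the default run. The generator is phenomenological: it
controls the SFS, not a genealogy. It does not model pedigree structure
(the real larvae are sibling cohorts from eight mixed colonies), linkage
disequilibrium within windows, recombination, or demography — so passing
recovery tests demonstrate the pipeline's bookkeeping and statistical
machinery, not robustness to genealogical correlation, and D's sampling
variance under the independent-sites model is smaller than coalescent
theory would give for the same constants.

Annotations are built for unambiguous truth-based tests: one CDS per
window, fully inside it (occupying the central 40%), so each outlier
window maps to exactly one gene through the 1000-bp flanks; 1–3 background
GO terms per gene from a 60-term vocabulary plus four designated terms —
one per (condition, regime) pair — attached with probability 0.8 to genes
of matching selected windows and 0.02 otherwise; proteome flags mark 85%
of genes larva-detected (the real background is 6556 larval-protein CDS)
and 50% egg-detected. `simulate_survival()` emulates the tank design
(three tanks of 200 larvae per condition, 21 days) by daily binomial
thinning with tank-level noise, with endpoint survival near 70%
(control) and 50% (heat).

Identical configurations, including the seed, give byte-identical output
files.

## Problem sizes used by the checks

The test suite and the acceptance script run entirely on simulated data at
the study's own scale where that is what is being claimed (500 windows per
condition, 16 + 10 individuals), and at reduced scale where the claim is
statistical calibration rather than scale: 200 replicate null pairs of
10 + 10 individuals over 250 windows of Poisson(30) SNPs for the type-I
experiment; a single 250-window cohort pair with `heat_sfs_distortion =
1.5` and 100 subsample iterations for direction consistency; 50 replicate
200-window cohorts for GO-term recovery; 200 categories of 20–50 genes
from a 6556-gene background (the study's larval-protein CDS count) for
null uniformity of the enrichment p-values.

## Known limitations

- The simulator's independent-sites model understates window-level D
  variance relative to a coalescent genealogy; calibration statements are
  about the pipeline under this model.
- Because each condition draws its derived-allele counts conditioned on
  polymorphism *within its own cohort* (`1..n-1` of its chromosome count),
  the smaller cohort has a slightly higher expected per-site π — an
  ascertainment artifact of the generator, clearly visible as a highly
  significant π contrast in the default run. It is a property of the
  synthetic world, not of the pipeline, and disappears for cohorts of
  equal size.
- `n_eff` from the rounded median of per-site chromosome counts is one of
  several defensible conventions; results at 5% missingness are
  insensitive to the choice, which is why both modes ship.
- The enrichment normal approximation is crude for very small tied
  categories; the exact path covers combined sizes up to 20, and exact
  behavior beyond that (binary scores) is hypergeometric, available in
  closed form if needed.
- Percentile-tail scans control nothing beyond the marginal tail fraction;
  they are screens, not tests, and are interpreted here exactly as such.
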