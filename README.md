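# chronoDEG

Time-of-day differential expression analysis for NanoString nCounter panels.

## The problem

Digital expression panels (NanoString nCounter) report molecular counts for a
fixed gene set — here a ~770-gene neuroinflammation panel — one lane per
sample. When tissue from tumor-bearing and vehicle-injected animals is
collected at different circadian phases (mid-dark ZT19 vs mid-light ZT7), the
differentially expressed gene (DEG) lists obtained at the two phases can
overlap only slightly, so the time of day of sampling materially changes the
biological conclusions. chronoDEG is for researchers who want to quantify
that dependence: it implements the full chain from raw probe counts to
dark/light DEG overlap statistics, plus a synthetic-data generator that
emulates the whole study design with known ground truth, so every stage is
validated by parameter recovery.

## What it computes

Given a probes x lanes count matrix with probe classes (Endogenous /
Positive / Negative / Housekeeping) and lane factors (condition, phase,
region):

1. **Normalization** — negative background subtraction; positive-control and
   CodeSet content normalization by geometric-mean lane factors
   `f_j = gm(g_1..g_J)/g_j`; log2 transform; quantile normalization (per
   region by default).
2. **Per-gene testing** — for each region x phase, a two-sample t-test of
   tumor vs vehicle on log2 values (pooled variance; with two groups the
   ANOVA F equals t²), giving `log2FC`, `t`, `p`.
3. **Three DEG filters** — `p < 0.05` (strict, uncorrected);
   `|log2FC − μ| > 2σ` with μ, σ the mean and sample SD of the comparison
   group's fold changes; and their conjunction.
4. **Pooling & overlap** — per-region DEGs are unioned into whole-brain
   unique up/down lists per phase; dark and light lists are partitioned into
   dark-only / shared / light-only, the shared fraction
   `|shared| / |dark ∪ light|` is reported per filter x direction, and the
   min–max shared percentage across the six cells summarizes time-of-day
   independence. Immune cell-type marker DEGs are counted with sign.
5. **Enrichment (optional)** — hypergeometric over-representation of pooled
   lists against GMT gene sets with the panel as universe, and the
   dark-only / light-only / shared classification of significant sets.
6. **Endpoints** — tumor volume `(width² × length)/2` and two-way
   (condition x phase) ANOVA with Type II sums of squares.

File formats: RCC lane files (read/write), TSV count tables, CSV sample
sheets, GMT collections, JSON reports and ground truth.

## Worked example

```r
library(chronoDEG)

# a synthetic experiment in the emulated design: 770-gene panel, 5 lanes per
# condition, 3 brain regions x 2 phases x 2 conditions, with 20 dark-only,
# 20 light-only and 5 shared planted DEGs per direction (effect ±2 log2)
cfg <- simConfig(nDegDarkOnly = 20L, nDegLightOnly = 20L, nDegShared = 5L,
                 seed = 11)
report <- runPipeline(cfg)
report
#> RunReport
#>   comparisons: 6; DEG counts (p/fc/both) per comparison:
#>  region phase n_p n_fc n_both
#>     HYP  dark  81   51     51
#>     HPC  dark  85   50     49
#>      BS  dark  84   50     50
#>     HYP light  77   49     49
#>     HPC light  85   47     46
#>      BS light  82   50     49
#>   dark/light shared fractions:
#>  method direction n_dark n_light n_shared fraction_shared empty
#>       p        up     68      73       11      0.08461538 FALSE
#>       p      down     81      74       13      0.09154930 FALSE
#>      fc        up     25      25        5      0.11111111 FALSE
#>      fc      down     27      26        5      0.10416667 FALSE
#>    both        up     25      25        5      0.11111111 FALSE
#>    both      down     27      26        5      0.10416667 FALSE
#>   overlap range: 8.5% - 11.1%
```

Reading the output: each region x phase comparison flags ~80 genes at
p < 0.05 (the 45 planted DEGs per phase plus the expected ~5% false
positives of a 760-gene panel) and ~50 by the 2-SD fold-change cutoff. After
pooling, only 8.5–11.1% of DEGs are shared between dark and light lists —
close to the planted shared/union ratio 5/45 ≈ 0.111 — i.e. the pipeline
correctly reports that most tumor-driven expression changes it found are
specific to the sampling phase.

The stages are also available individually (`simulateExperiment`,
`normalizeCounts`, `runComparison`, `poolUniqueDegs`, `computeOverlap`,
`oraTest`, `twowayAnova`, …); see the methods vignette
(`vignettes/chronoDEG-methods.Rmd`) for the model, parameter meanings, and
design decisions.

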