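# gutrhythm

Tools for asking whether the *temporal structure* of the infant gut
microbiota — not just its composition — tracks the maturation of sleep in
the first months of life. The package targets densely sampled longitudinal
designs: a handful of stool samples per infant collected across a 48-h
window at each of several age assessments (2, 4 and 6 months), paired with
multi-day wearable actimetry, 15-minute parent diaries, and sleep
questionnaires.

It is written for microbiome researchers who have an ASV feature table,
taxonomy and rooted phylogeny on one side, and sleep phenotypes on the
other, and want the full chain from raw counts to mixed-model coefficients
to be reproducible and testable.

## What it computes

**Microbiota temporal structure**

- *Diurnal rhythmicity*: a fixed-period cosinor
  `y(t) = C + A·cos(2πt/24 + φ)` fit by OLS to each infant-age series
  (≥ 4 samples) of alpha diversity and genus relative abundance; the R² of
  the fit quantifies rhythmicity.
- *Temporal volatility*: for each beta-diversity metric, samples are
  embedded by PCoA (3 axes, Gower double-centering); an infant-age's
  volatility is the median Euclidean distance of its samples (≥ 2) to
  their centroid in that space.
- *Diversity*: rarefaction-bootstrapped (depth 3035, 100 replicates,
  means reported) observed features, Shannon entropy (bits), Pielou
  evenness and Faith PD; Bray–Curtis, binary Jaccard, unweighted and
  (non-normalized) weighted UniFrac. Filtering drops phylum-unassigned
  features, features with total frequency < 10, then samples below the
  rarefaction depth.

**Sleep phenotypes**

- *Sleep rhythmicity*: nonparametric circadian metrics on hourly-binned
  actimetry — interdaily stability (IS), intradaily variability (IV,
  clamped to [0, 2]), relative amplitude (RA = (M10 − L5)/(M10 + L5)) —
  composed into the Circadian Function Index
  `CFI = (IS + (2 − IV)/2 + RA) / 3 ∈ [0, 1]`, for infant-ages with ≥ 3
  continuous recording days.
- *Sleep quality*: the BabySQUID composite of four BISQ variables
  (nighttime sleep duration, onset latency, bedtime, awakenings):
  ≤ 2 missing variables are median-imputed, all are min-max scaled,
  all but duration reverse-coded, and the four averaged with equal
  weights.
- *History covariates* from diaries: time awake before each stool sample,
  duration of the last sleep, time since last feeding, time since the
  previous sample, and feeding rhythmicity (mean of day-level SDs of
  inter-feeding intervals).

**Association suite**: random-intercept linear mixed models (REML, Wald z)
per equation × metric — CFI against rhythmicity / diversity / volatility,
BabySQUID against diversity / volatility, stool melatonin and alpha
diversity against sleep/feeding history — with the protocol's aggregation
(median alpha per infant-age), covariate median imputation and the
melatonin > mean + 8 SD outlier rule.

A fully seeded **synthetic-cohort generator** emulates every input (counts
with planted diurnal genera, trees, metadata, actimetry, diaries,
questionnaires) plus a ground-truth record, so the entire pipeline is
testable without access to restricted cohort data.

## Worked example

```r
library(gutrhythm)

# cosinor fit of an alpha-diversity series over a 48-h window
t <- c(2, 9, 14, 20, 27, 33, 39, 46)          # hours since midnight, day 1
y <- c(21, 27, 24, 18, 22, 28, 23, 19)        # observed features
f <- fit_cosinor(t, y)
sprintf("amplitude = %.2f, peak hour = %.1f, mesor = %.2f, R2 = %.2f",
        f$amplitude, f$peak_hour, f$mesor, f$r_squared)
#> "amplitude = 4.59, peak hour = 9.3, mesor = 22.71, R2 = 0.98"
```

The series peaks around 09:20 with about ±4.6 features around a mean of
22.7, and the cosine explains 98% of its variance — a strongly diurnal
profile.

```r
# synthetic cohort end to end
cfg <- default_cohort_config(); cfg$n_infants <- 8
b <- generate_cohort(cfg, seed = 42)
filt <- filter_table(b$table, b$taxonomy)     # phylum -> freq<10 -> depth
#  retained: 120 samples x 74 features
a <- bootstrapped_alpha(filt$table, b$tree, depth = 3035, n_boot = 100,
                        seed = 1)
head(subset(a, metric == "shannon"), 3)
#>      sample_id  metric value
#> 121 I01_A2_S01 shannon 3.781
#> 122 I01_A2_S02 shannon 3.495
#> 123 I01_A2_S03 shannon 3.021

circ <- actigraphy_per_infant_age(b$actimetry)
head(circ$metrics[, c("infant_id", "age_group", "n_days", "is", "iv",
                      "ra", "cfi")], 3)
#>   infant_id age_group n_days   is   iv   ra  cfi
#> 1       I01         2     11 0.60 0.68 0.25 0.51
#> 2       I01         6      6 0.65 0.68 0.38 0.56
#> 3       I02         4      7 0.59 0.61 0.25 0.51

sq <- compute_babysquid(b$questionnaires)
head(sq$scores[, c("infant_id", "age_group", "babysquid", "n_imputed")], 3)
#>   infant_id age_group babysquid n_imputed
#> 1       I01         2     0.407         0
#> 2       I01         6     0.525         1
#> 3       I02         4     0.425         0
```

Shannon values are bootstrap means over 100 rarefactions; the CFI rows say,
e.g., that infant I01 at 2 months kept a fairly stable day-to-day pattern
(IS 0.60) with moderate fragmentation (IV 0.68) and a modest day–night
contrast (RA 0.25), giving a rest–activity maturity score of 0.51.

The whole chain — simulate, filter, diversity, rhythmicity, volatility,
actigraphy, sleep scores, mixed models — runs as one call:

```r
res <- run_pipeline(default_config(), out_dir = "out", seed = 1)
# out/ holds every stage table (TSV), model_fits.tsv, provenance.tsv,
# a resolved config snapshot and a run log; identical config + seed
# reproduce every file byte for byte.
```

or from the shell:

```sh
Rscript inst/cli/gutrhythm.R all --seed 1 --out-dir out
Rscript inst/cli/gutrhythm.R simulate --seed 7 --out-dir bundle
```

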