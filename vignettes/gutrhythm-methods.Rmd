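---
title: "gutrhythm: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gutrhythm: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its science: what each
statistic assumes, which conventions were chosen where the literature
offers several, what the synthetic cohort does and does not emulate, and
the numerical decisions a maintainer would otherwise have to reverse
engineer. It states no empirical result that the test suite does not
itself compute.

## The setting

Densely sampled infant cohorts collect a cluster of stool samples per
infant across a 48-h window at each age assessment (here 2, 4 and
6 months, age-days centered near 76, 128 and 190), alongside multi-day
ankle actimetry, 15-minute parent diaries and sleep questionnaires. Two
temporal scales matter: *diurnal* (does the community oscillate over the
day?) and *developmental* (do diversity, melatonin and sleep maturity
co-vary across months?). All person-level inference uses random-intercept
linear mixed models because infants contribute repeated, irregularly
spaced observations.

## Diurnal rhythmicity (cosinor)

The model is a cosine with the period fixed at 24 h,

$$y(t) = C + A\cos(2\pi t/24 + \varphi) + \varepsilon,$$

fit per infant-age to series of alpha diversity and genus relative
abundance with at least 4 samples. Because the model is linear in
$(C, a, b)$ with $a = A\cos\varphi$, $b = -A\sin\varphi$, the fit is
ordinary least squares on $(1, \cos\omega t, \sin\omega t)$ — exact and
deterministic, no nonlinear search. Rhythmicity is the plain $R^2$ of the
fit. Decisions:

- **Time origin** is midnight of the group's first sampling day. With the
  period fixed, $R^2$ is origin-invariant; the origin only standardizes
  the reported acrophase, which is also translated to a peak clock hour.
- **$R^2$ is not adjusted** for degrees of freedom. With $n = 4$ and
  3 parameters it is optimistic; `n_samples` is always reported alongside
  so downstream users can weight.
- Both days of the 48-h window fold into one 24-h phase (implied by the
  fixed period).
- Degenerate cases: $n < 4$ is refused; a zero-variance series yields a
  fit with missing $R^2$ and a `degenerate` flag; a design whose
  trigonometric columns are collinear (e.g. all times 12 h apart) is
  refused as rank-deficient. Rank is judged on singular values with a
  relative tolerance of 1e-10.

## Temporal volatility

Per beta metric, the cohort distance matrix is embedded by classical
PCoA: Gower double-centering of $-D^2/2$, symmetric eigendecomposition,
coordinates $v_k\sqrt{\lambda_k}$ for the three largest positive
eigenvalues. An infant-age's volatility is the median Euclidean distance
of its $\geq 2$ samples to their per-axis mean (centroid).

- **Embedding scope.** "The first three principal components of those
  samples" is ambiguous between a cohort-level and a group-level
  embedding. The default embeds the *whole cohort* once: a shared space
  makes volatilities comparable across infants, and a 2–3-sample group
  has no meaningful 3-axis embedding of its own. `embedding_scope =
  "group"` preserves the alternative reading, and outputs record which
  was used.
- **Negative eigenvalues** (from non-Euclidean dissimilarities) are not
  corrected (no Cailliez/Lingoes); they are simply not retained. If fewer
  than three positive eigenvalues exist, all positive axes are used and
  the count is recorded; a fully degenerate (all-coincident) cohort
  embeds in a zero-dimensional space with volatility 0.
- **Sign convention**: each axis is flipped so its largest-magnitude
  coordinate is positive, making outputs byte-reproducible.

## Diversity

Filtering runs phylum-unassigned removal, then the total-frequency < 10
feature filter, then the sample-depth filter (default 3035). The
protocol lists the steps without an explicit order; this order mimics the
upstream QIIME-style narrative and is config-overridable. Boundary
semantics are inclusive: a feature totalling exactly 10 and a sample at
exactly the depth are kept.

Alpha and beta metrics are computed on bootstrap rarefactions:
subsampling *without replacement* to exactly the depth, 100 independent
replicates, arithmetic mean reported (matching bootstrap-averaged
diversity plugins). Conventions that differ across implementations and
are therefore pinned here:

- Shannon entropy in **bits** (log base 2); Pielou uses the same base so
  evenness lies in [0, 1] and is undefined below 2 observed features.
- Faith PD **includes the root connection** (sum of branch lengths on
  the union of root-to-tip paths of observed features).
- Jaccard is the **binary** distance $1 - |A\cap B|/|A\cup B|$;
  Bray–Curtis is computed on counts.
- Weighted UniFrac is the **non-normalized** variant
  $\sum_b l_b |p_b(u) - p_b(v)|$ (a flag enables normalization);
  unweighted UniFrac is unshared over total branch length among branches
  leading to tips present in either sample.
- Per-sample rarefaction sub-seeds are derived by hashing
  `(seed, sample_id, replicate)`, so removing samples never perturbs the
  draws of the remaining ones — distance matrices on subsets stay
  consistent with full-cohort runs.
- A basal polytomy (star tree) is accepted and read as rooted at the hub.

Genus collapsing sums ASV counts by genus; ASVs without a genus label are
grouped under their finest resolved rank as `unclassified_<rank>`, and
`unclassified_*` groups are not eligible for the top-k list (the ranking
is meant to surface named dominant genera).

## Actimetry metrics

IS and IV are the standard nonparametric circadian statistics on hourly
bins ($p = 24$); the source protocol cites them without printing
formulas, so the definitions here are conventions, flagged as such:

$$\mathrm{IS} = \frac{n\sum_h(\bar x_h-\bar x)^2}{p\sum_i(x_i-\bar x)^2},
\qquad
\mathrm{IV} = \frac{n\sum_{i\ge2}(x_i-x_{i-1})^2}{(n-1)\sum_i(x_i-\bar x)^2}.$$

RA uses the average 24-h profile with **circular** M10/L5 windows (robust
to day-count imbalance). The Circadian Function Index is

$$\mathrm{CFI} = \tfrac13\left(\mathrm{IS} + \tfrac{2-\mathrm{IV}}2 +
\mathrm{RA}\right),$$

with IV clamped to [0, 2] beforehand — otherwise $(2-\mathrm{IV})/2$ goes
negative (IV reaches 4 for a strictly alternating series) and the index
would leave its stated [0, 1] range. The raw IV is reported alongside.

Binning rules: hourly means over wear epochs; an hour with < 50% wear is
invalid and imputed by the mean of the same clock hour on other days;
leading/trailing partial hours are dropped and the series trimmed to
whole days; fewer than 72 whole-day hours (the 3-continuous-day rule) is
a refusal. Zero-variance series leave IS/IV (hence CFI) missing with a
reason rather than erroring.

## Sleep quality (BabySQUID) and history covariates

The composite uses four questionnaire variables. Records with at most two
missing variables are kept, the gaps filled with the cohort median of
that variable; three or more missing excludes the record. Variables are
min-max scaled over all included infant-age records **pooled across
ages** — the score is compared across ages downstream, so per-age scaling
would remove exactly the contrast of interest (this scope is an open
choice; pooling is the default). Latency, bedtime and awakenings are
reverse-coded as $1 - \text{scaled}$; the composite is the equal-weight
mean. A constant variable scales to the uninformative midpoint 0.5 rather
than 0, to avoid biasing the composite direction.

Diary-derived covariates treat 15-minute entries as half-open intervals
(a sample on a boundary belongs to the later interval). For a sample
collected mid-sleep — a case the protocol does not define — prior awake
time is 0 and the last sleep duration is the *elapsed* time of the
ongoing bout. Feeding rhythmicity is the per-day sample SD (n−1) of
inter-feeding intervals, days bounded midnight-to-midnight, requiring at
least two intervals; day-level SDs aggregate by mean (median available).
Time since the last bowel movement is the gap to the infant's previous
sample within the same assessment.

## Association suite

One model per equation × metric: CFI on rhythmicity (per target), CFI on
diversity and volatility, BabySQUID on diversity and volatility,
melatonin on sample history, alpha diversity on sample history — all with
a per-infant random intercept. Protocol rules carried through: alpha
diversity per infant-age is the **median** of its samples; rows missing
outcome or exposure are dropped per model; missing covariates are
median-imputed (counts reported); melatonin values strictly above
mean + 8 SD are excluded (a value exactly at the cut is retained); no
multiplicity correction (the model count is reported instead).

Inference decisions, where the protocol names no software: REML
estimation with Wald z tests; covariates on raw scales (no
standardization), so coefficients are per day of age, per feature, etc.;
sex coded with female as reference; age enters as continuous age-days.
lme4 cannot fix a variance component at zero, so `random_intercept =
FALSE` provides the exact variance-zero model (plain OLS with the same
Wald machinery); singular REML fits also fall back to OLS with a flag,
and convergence warnings are captured into the fit's `converged` flag.
The two history equations put three history variables on the right-hand
side; the registry designates one headline exposure per model (time since
last bowel movement for melatonin; prior awake time for diversity) — the
others are treated as covariates, which places them under the
median-imputation rule rather than row exclusion.

## The synthetic cohort

The generator's defaults state a world mirroring the targeted design
wherever that design is quantified: 20 infants; 1/2/3 observed ages with
probabilities 0.2/0.55/0.25 (the realized pattern of the motivating
cohort); samples per infant-age log-normal with median 4 clipped to
[1, 11]; age-days normal around 76/128/190 (sd 5); actimetry durations
normal around 8 d (sd 2.71) clipped to [3, 11]; melatonin increasing at
0.638 pg/g per day of age; clock times uniform over the 48-h window at
2 months shifting to a morning-weighted mixture at 6 months; a
configurable fraction (5%) of phylum-unassigned ASVs and ten planted
features too rare to pass the frequency filter.

Where no value is stated, scales were chosen once for realism and frozen:
genus log-abundance baselines spanning the five dominant genera of the
young infant gut, diurnal amplitudes 0.3–0.6 (log scale) on those five
with acrophases spread over the day, infant random effects (sd 0.5) and
sample noise (sd 0.4, shrinking ~0.2%/day so volatility declines with
age), library sizes log-normal around 8000 floored at 4000 (above the
rarefaction depth), and a within-genus ASV weight dispersion giving
per-sample richness and Shannon values in the range reported for
breast-fed infants. Rest–activity series use a rectified-cosine profile
(activity positive for 16 h/day, so a relative amplitude of 1 produces a
≥ 5-h zero trough and realized RA = 1), white epoch noise, and a
two-state fragmentation process: quiet spells end at the fragmentation
rate, ~30-min episodes mirror activity within its clean range. The
episode rate — not a parity toggle — controls the flipped time fraction,
which is what makes realized IV increase monotonically with the
configured rate. Defaults give CFIs near 0.5–0.6, the range typical of
young infants.

Cross-couplings exist so downstream recovery is testable: each infant has
a latent "diversity propensity" that adds detectable ASVs and nudges the
true relative amplitude (so the diversity→CFI association is positive by
construction), and richness grows with age through late-onset ASVs whose
onset density is the configured features-per-day slope.

What the generator does **not** emulate: strain-level dynamics, realistic
phylogenetic signal in abundances (the tree is a random coalescent),
compositional interactions between genera beyond the shared multinomial,
raw 30 Hz accelerometry (epoch counts only), naps and irregular sleep
schedules (the diary is a discretized smooth profile), and cultural or
dietary covariates. A green test on synthetic data therefore establishes
that the *estimators and plumbing* behave as specified under the stated
world — not that the biological effect sizes of any real cohort are
reproduced.

## Numerical and reproducibility notes

- All sub-seeds are integer hashes of `(master seed, stage label, ...)`;
  repeated runs with the same config and seed are byte-identical (the run
  log carries no timestamps for this reason).
- TSV round-trips are exact for integers and ≤ 1e-12 relative for reals
  (15 significant digits); missing values are empty fields, `NA` accepted
  on read.
- PCoA eigenvalue positivity uses a relative tolerance of 1e-8 of the
  largest magnitude; bootstrap distance matrices are re-symmetrized
  (`(M + t(M))/2`) to keep symmetry exact after averaging.
- Datetimes are local wall-clock parsed in a fixed zone: the analyses
  need clock time, and single-site designs gain nothing from timezone
  arithmetic.
- Genus relative-abundance series for the cosinor use raw filtered
  counts, per-sample normalized (not rarefied counts); a config flag
  (`genus_abundance_source`) records the choice, which the protocol
  leaves unstated.

## Known limitations

- Wald z inference is mildly anticonservative at small cohort sizes;
  Satterthwaite-type denominators are not implemented (the registry
  reports n per model so users can judge).
- Twin pairs get no family-level random effect (not modeled upstream
  either).
- BIOM input requires the optional biomformat package; TSV is the
  first-class path.
- The BabySQUID equal-weight composite is a pragmatic index; learning
  data-driven weights is explicitly out of scope.
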