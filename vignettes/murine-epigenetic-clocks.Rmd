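---
title: "Building cross-strain murine epigenetic clocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building cross-strain murine epigenetic clocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(museclock)
```

## The problem

DNA methylation (DNAm) at CpG dinucleotides drifts with age in a
reproducible, site-specific way, which makes linear "epigenetic clocks"
the most accurate molecular age predictors available. Mouse work adds a
twist that human work mostly avoids: inbred strains such as C57BL/6 (B6)
and DBA/2J (DBA) differ in life expectancy (~2.42 vs ~1.87 years) *and*
in their baseline methylomes, so tens of thousands of CpGs separate the
strains regardless of age. A clock naively trained in one strain mixes
age signal with strain signal. `museclock` implements a construction
that confronts this: select CpGs by the *size* of their methylation
change over a normalized lifespan, do so independently per strain, and
build clocks only on the cross-strain intersection.

This vignette documents the model, its assumptions, the tunable
parameters, the synthetic data that exercises it, and the numerical
decisions — in that order.

## Age normalization and the selection statistic

Because the strains age on different time scales, chronological age is
first mapped to a common scale. The default is min–max scaling within
each (strain, sex) group: the youngest animal of a group gets `x = 0`,
the oldest `x = 1`. The alternative (`method = "lifespan"` in
`normalize_ages()`) divides age in weeks by the strain's life
expectancy. Min–max is the default for a concrete reason: with age on
[0, 1] and beta values naturally on [0, 1], the per-CpG selection
statistic

$$\mathrm{slope}_{CpG} \;=\; \frac{\sum_i (x_i - \bar x)(y_i - \bar y)}
       {\sum_i (x_i - \bar x)^2}$$

is the least-squares slope of beta on normalized age, and
$|\mathrm{slope}_{CpG}| > 0.3$ reads directly as "more than a 30%
absolute DNAm change over the observed lifespan". Selecting on the
slope rather than on the correlation coefficient favors CpGs with large
absolute changes — the sites that remain measurable by targeted assays
and robust to normalization differences — while in practice the
selected CpGs also carry high |r|.

Assumptions worth stating: the group's observed age range is treated as
representative of its lifespan (the min–max scale is only as meaningful
as the cohort's age coverage), and beta values are assumed already
normalized upstream (array background correction, dye-bias and
probe-type adjustment are out of scope; the package consumes processed
betas).

The selection threshold is strict (`|slope| > 0.3`, not `>=`), applied
per strain, and the clock-building set is the intersection of the
per-strain candidate sets. Note that CpGs with *opposite* trend
directions in the two strains still pass the intersection — selection
uses magnitude only — which mirrors the antagonistic age-associated
sites genuinely observed between strains.

## Quality control

`qc_filter()` applies, in a fixed order: (1) detection-p filtering
(any p > 0.01 drops the probe) when detection p-values are supplied —
processed beta exports usually lack them, so this step is skipped with
a message rather than an error; (2) probes with > 10% missing values;
(3) samples with > 10% missing values among surviving probes; (4)
optionally X/Y-chromosome probes. Probe filtering precedes sample
filtering so that systematically failing probes do not inflate sample
missingness and evict otherwise good samples. The X/Y flag is
deliberately per-analysis: clocks exclude the sex chromosomes, while
the all-sample correlation matrix conventionally keeps them.

## The two predictors

**Single-CpG ensemble.** Cohorts of a dozen animals cannot support a
multivariable model over a hundred CpGs, so each selected CpG is fitted
on its own: ordinary least squares of *normalized age on beta* (age is
the response; `calibration = "inverse"` exposes the
classical-calibration alternative of fitting beta on age and inverting
the line). A sample's prediction is the arithmetic mean of the per-CpG
age estimates, computed on the normalized scale and then mapped to
weeks via the training group's age range. Averaging before
denormalizing is equivalent to the reverse whenever all probes share
one group range, which is the only case that arises here. Predicting a
(strain, sex) group absent from training reuses the pooled training
range with a warning — this is exactly the situation of applying a
B6-trained clock to DBA samples, and it is the reason transferred
predictions can show a range offset while preserving r².

**Exhaustive 4-CpG model.** For targeted pyrosequencing data the
package enumerates every combination of 4 CpGs drawn from 4 *distinct*
amplicons (neighboring CpGs on one amplicon are nearly collinear),
fits `age ~ DNAm%` by OLS, and keeps the combination minimizing the
training MAD. Ties are broken by higher r², then by lexicographically
smallest label set, making the search deterministic; rank-deficient
designs are skipped. The published B6 model is shipped frozen in
`published_b6_clock()` with its four coefficients and intercept
(167.4533 weeks), inputs in percent DNAm, and no clamping of the
output.

**Metrics.** `evaluate_predictions()` follows the naming convention of
this clock family: MAE is the *median* absolute error and MAD the
*mean* absolute deviation (elsewhere these names are often used the
other way around); r² is the squared Pearson correlation of predicted
versus chronological age, so it is insensitive to scale and offset — a
transferred clock can have r² near 1 alongside a nonzero MAE. When
either vector is constant, r² is undefined and a classed error is
raised that still carries MAE/MAD on the condition object.

## Strain comparison

`differential_methylation()` runs a two-sided Wilcoxon rank-sum test
per CpG between two groups, Bonferroni-corrected. The p-value routing
deserves explicitness because group sizes of 4–12 sit at the
exact/approximate boundary:

* untied data, both groups below 50: the exact Wilcoxon distribution;
* tied data with a small assignment space (`choose(n, n1) <= 20000`,
  e.g. any 4-vs-4 or 8-vs-8 comparison): exact permutation enumeration
  over all group assignments of the midranks, two-sided by symmetric
  deviation from the null mean — ties make the classical exact
  distribution unavailable, and the enumeration is the honest small-
  sample answer;
* otherwise: normal approximation with continuity and tie correction.

The Bonferroni divisor defaults to the number of probes actually tested
after the X/Y/SNP/cross-reactive removal; a fixed divisor (e.g. a full
array size) is available via `bonferroni_m` for users who prefer
correcting against the chip. Significance is declared at adjusted
p < 0.01, strictly.

`sample_correlation_matrix()` uses pairwise-complete Pearson
correlation and refuses pairs sharing fewer than 3 probes.
`sex_effect_test()` is the same rank-sum machinery applied to
prediction errors by sex. `global_methylation_trend()` calls a CpG
methylated at beta > 0.5 by default — the calling threshold is not
standardized anywhere, so it is exposed as a parameter — and
correlates the per-sample methylated fraction with age.

## Homology mapping

Homology regions are *input* data (a TSV of ~121-nt alignment windows
pairing mouse probes with human intervals): genome alignment is
upstream, version-dependent work that this package does not redo. A
human array CpG on a chromosome carrying regions is `homolog` if it
falls inside a window (1-based, inclusive at both ends, matching the
`chr:start:end` coordinate convention of the field) and otherwise gets
the distance to the center of the nearest window, with
`center = floor((start + end) / 2)` — the floor fixes the undefined
center of even-length intervals — and ties broken toward the lower
start coordinate. Strand flips affect reporting orientation only, never
distances.

Human age association uses the correlation t-test,
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom, two-sided,
Bonferroni-corrected over the CpGs analyzed by default (a fixed divisor
for the full 450k array is again available). The conserved-candidate
report joins homolog assignments with both strains' slope tables and
the human associations, keeps human CpGs significant at adjusted
p < 0.01, and flags direction consistency: a conserved site must
hyper- or hypomethylate with age in B6, DBA *and* human.

## The synthetic cohort generator

`generate_mouse_cohort()` is first-class, tested code, not a fixture.
Its defaults are the study conditions the package is designed around:
12 female B6 mice spanning 11–117 weeks and 6 male + 6 female DBA mice
spanning 6–109 weeks (evenly spaced ages, emulating a designed cohort),
20,000 probes, 100 shared aging CpGs with an absolute beta change of
0.5 over the lifespan, 50/30 strain-private aging CpGs, 20 antagonistic
CpGs (opposite directions per strain), 500 strain-offset CpGs shifted
by 0.4 between strains, 200 X- and 50 Y-planted null probes, and
Gaussian measurement noise of sd 0.02 on the beta scale, clipped to
[0, 1]. Baselines are drawn per island context (islands low via
Beta(1.2, 8), open sea high via Beta(6, 2)); shared aging probes
hypomethylate with probability 0.65, reflecting the predominance of
age-associated methylation loss in blood; strain-private island probes
follow a per-strain direction bias (B6 islands tend to gain, DBA
islands to lose methylation). A truth table records every probe's
class, per-strain direction and effect size, and the whole cohort is a
deterministic function of the seed.

Noise is truncated-Gaussian-by-clipping rather than a beta-binomial
intensity model: the package consumes post-normalization betas, and
only the second-moment behavior of the noise matters to every statistic
tested. What the simulation therefore does *not* emulate: heteroscedastic
noise near the beta boundaries, probe-type chemistry differences,
batch effects, or correlated probes within islands. Passing the
recovery tests shows the cascade's statistics behave as designed under
the study's sample sizes and noise scale — it does not certify
performance on real arrays, where those unmodeled features live.

`generate_human_cohort()` mirrors a large human blood cohort (656
samples, 19–101 years by default). Conserved human homologs of the
shared mouse aging CpGs get sign-matched trends with a smaller effect
(0.3 by default — human blood effect sizes are modest relative to
within-strain mouse trends) and noisier betas (sd 0.05).
`generate_homology_table()` places 121-nt windows over the linked human
CpGs, with an attrition parameter displacing a fraction of windows off
any array CpG, emulating homolog regions without array representation.

## Pipeline and reproducibility

`run_pipeline()` wires the stages (simulate → qc → select →
train-ensemble → predict → evaluate → diffmeth → corr-matrix →
homology → report) over plain TSV/JSON files; `exec/museclock` is a
thin command-line wrapper. Every stage writes a provenance JSON with
input checksums, parameters, seed and package version, and
deliberately no timestamps, so identical configs produce byte-identical
outputs. Configuration is validated (e.g. `alpha` in (0, 1)) before any
stage runs.

## Problem sizes and numerical choices

The test suite exercises the full cascade at the default 20,000-probe,
24-sample scale and uses a 2,000-probe cohort of the same design for
module-level checks; rank-test null simulations use 1,000 probes at 12
vs 12 over 20 seeds. These sizes were chosen as the smallest that
exhibit every planted structure class at stable frequencies.

Numerical details fixed by design: strict inequalities at both the
slope threshold and the significance level; pairwise-complete handling
of missing betas everywhere (consistent with tolerating up to 10%
probe-level missingness); slope/correlation identities hold to 1e-10
and are tested against normal-equations oracles; the exhaustive search
compares MAD values exactly, relying on its deterministic tie-break
rather than an epsilon; JSON model serialization keeps full floating
precision (round-trips agree to the last bits for the frozen published
coefficients, and to 1e-12 for fitted models).

## Known limitations

* The min–max age scale depends on cohort age coverage; a cohort
  sampling only mid-life compresses the scale and inflates slopes.
* Ensemble transfer to an unseen strain reuses the training age range,
  so predictions can carry a constant offset even when r² is high.
* The ensemble weights all CpGs equally; no shrinkage or elastic-net
  selection is attempted (deliberately out of scope at these sample
  sizes).
* Clocks are blood-trained in concept; applying them to other tissues
  should be expected to show offsets.
* The homology step trusts the supplied alignment windows; it performs
  no alignment or liftover itself.
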