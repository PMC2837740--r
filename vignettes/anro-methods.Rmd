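---
title: "Methods: nuclear run-on time-course analysis with anro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nuclear run-on time-course analysis with anro}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anro)
```

## Scope and model

`anro` analyses paired nascent (nuclear run-on, NRO) and total-RNA microarray
time courses. The analysis chain is: detection filtering, per-array Z-score
normalization, Z-ratio differential expression per timepoint against the 0-hr
baseline, first-appearance wave assignment, PAGE gene-set enrichment across
the matrix of contrasts, cross-platform concordance, and intersection with
ChIP binding lists. The package assumes pre-summarized gene-level intensity
matrices on a positive raw scale; probe-level processing (RMA, BeadStudio) is
deliberately upstream of its scope.

## Normalization and the Z-ratio

Each array is standardized independently:
$z_{gi} = (\log_{10} x_{gi} - \bar{\ell}_i)/s_i$ with $\bar{\ell}_i$ and
$s_i$ the mean and sample SD (always $n-1$ denominators in this package) of
the array's log10 intensities. Standalone standardization makes arrays
comparable without cross-array fitting, at the cost of assuming the bulk of
genes is unchanged — reasonable here because even at 48 hr only a few percent
of genes respond.

For a contrast of timepoint $A$ against baseline $B$, the per-gene difference
of replicate-averaged z-scores $d_g = \bar z_{gA} - \bar z_{gB}$ is divided
by the sample SD of **all** $d_g$ in that comparison, giving the Z-ratio. Two
consequences shape the tests: the Z-ratio vector has sample SD exactly 1 by
construction, and the denominator is inflated when many genes truly respond,
which costs power at late timepoints if the regulated fraction is large (see
*Generator defaults* below). p-values are two-sided standard normal on the
Z-ratio; the statistic is already population-standardized, so no per-gene
variance estimate (and no t reference) is used. FDR control is
Benjamini–Hochberg — the procedure of choice where only "false discovery
rate" is specified, and the one with clean testable monotonicity properties.

Significance is the compound rule
$p \le 0.001 \wedge q \le 0.1 \wedge (\text{fold} \ge \pm 1.5 \vee |Z| \ge 3)$.
The fold/Z clause is a disjunction: the "either … or" reading. All bounds are
inclusive. Fold changes are ratios of raw-scale group means, not of
normalized values; log-ratios are reported in log2 (the community scale for
"fold change ±1.5"), while normalization operates in log10.

## Waves, transience and lead

A gene's first appearance is the earliest timepoint at which it passes the
compound filter with direction *up* (down-regulation is available behind the
`direction` argument but is not the default, matching how first-appearance
orderings are conventionally displayed). Classes on the default grid: early
$\le 1$ hr, delayed-early 3–6 hr, late = final timepoint; on custom grids the
boundaries generalize to $(1, 6]$ hr for delayed-early and $> 6$ hr for late,
so a first appearance between 6 and 48 hr falls to late. Transience requires
non-significance at the final timepoint specifically; a dropout at an
intermediate timepoint does not toggle the flag, because single-timepoint
misses are dominated by test noise rather than biology. The NRO lead for a
gene regulated in both channels is
$\mathrm{first\_up}_{total} - \mathrm{first\_up}_{NRO}$.

## PAGE / GSMA

For a gene set with $m$ members among the measured genes of a contrast,
$Z = (S_m - \mu)\sqrt{m}/\sigma$, where $S_m$ is the median of the members'
log-ratios and $\mu$, $\sigma$ the median and sample SD of all log-ratios in
the contrast. The background universe is **all measured genes** after
detection filtering (a `de`-restricted universe is available via the pipeline
option `gsma_universe = "de"`); the all-measured choice keeps $\sigma$
estimable and is the standard parametric-enrichment convention. The median of
an even-sized multiset is the midpoint of the two central values. Because the
statistic uses a median over $m$ draws but a global SD, its null SD is near
but not exactly 1 (the acceptance checks bound the null mean, not the SD).
Sets with no member among measured genes yield explicitly missing cells — an
`NA` can never be confused with "no enrichment" downstream. Set-level p/q
values (normal two-sided, BH within contrast) are a pragmatic add-on for
screening; the primary readout is the sorted Z matrix itself.

## Clustering

Heatmap ordering uses agglomerative complete linkage on
$1 - \text{uncentered Pearson}$ (the cosine similarity of raw profiles;
profiles are deliberately not centered, so a flat high profile and a flat low
profile are similar in shape but differ from a rising one). The
implementation is in-package rather than delegated because reproducible
output requires a documented tie-break: among pairs at the minimal merge
distance, the pair whose combined sorted leaf labels sort lexicographically
first merges first. Complete linkage guarantees non-decreasing merge heights.
The naive $O(n^3)$ Lance–Williams update is adequate for the few hundred to
few thousand significant genes this analysis clusters.

## Concordance and direct targets

Cross-platform joining uppercases and trims HUGO symbols, averages duplicate
symbols' log-ratios arithmetically (averaging happens on the log scale, where
replicate noise is approximately symmetric), then intersects. Filtering
precedes joining, so the common pool contains only genes detected on each
platform. Direct targets are the intersections bound ∩ up and bound ∩ down;
genes called both up and down across contrasts are excluded from both sets
and reported as conflicts rather than double-assigned.

## The synthetic generator

`simulate_experiment()` emulates the study design: timepoints 0, 0.25, 0.5,
1, 3, 6, 48 hr; 6 replicates per timepoint and 10 at 48 hr; paired NRO and
total channels over one gene universe. Baseline log10 intensities are
Normal(2.5, 0.5) truncated above 0.5 — spanning the dynamic range of
bead-array data. Regulated genes step up by `effect_log2` (default 1, i.e.
2-fold) from a wave-specific onset: early and transient-early onsets are
uniform over the grid points in (0, 1] hr, delayed-early over 3–6 hr, late at
48 hr only; transient-early genes return to baseline at the final timepoint;
the total-RNA onset is the NRO onset shifted `lag_steps` grid positions
(capped at the final timepoint — a transient gene whose shifted onset lands
there never rises in total RNA). Replicate noise is additive Gaussian and
homoscedastic on the log scale.

**Effect and noise share the log2 scale.** `effect_log2` and `noise_sd_log`
are both log2-scale quantities, converted internally to the generator's
log10 canonical scale. A shared scale is the only parameterization under
which "effect 1, noise 0.2" describes a well-powered design
(`effect / (noise * sqrt(2/6)) ≈ 8.7` z-units per contrast); mixing scales
would silently turn the same numbers into a ~2.6-z design with under 30%
power at $p \le 0.001$, which no array study would be sized to.

Generator defaults not pinned by the study design were fixed once:
`fraction_regulated = 0.05` and `fraction_background = 0.10` — a regulated
fraction in the few-percent range is typical of a single-factor induction,
and keeping it modest matters statistically because planted effects inflate
the Z-ratio denominator (at 5% regulated the inflation costs under one
z-unit; at 10% it approaches the significance boundary for late contrasts).
The wave mix (0.30 early, 0.30 delayed-early, 0.20 late, 0.20
transient-early) spreads onsets across the grid. Detection scores are 1 for
expressed genes and Uniform(0, 0.9) for background genes; the platform's
detection statistic is not modelled beyond its thresholding role.

What the generator does **not** emulate: intensity-dependent
(heteroscedastic) noise, probe- or exon-level structure, transcription/decay
kinetics between grid points, correlated replicates, or batch effects.
Recovery results on synthetic data therefore demonstrate the pipeline's
correctness under its own statistical assumptions, not performance on any
particular real platform.

## Numerical choices and degenerate inputs

Sample SDs use $n-1$ throughout. Zero within-array variance, zero variance of
z-differences, zero-variance correlation columns, all-zero cluster profiles
and empty set/universe intersections are explicit errors, never silent
results. Missing detection scores make the filter stage refuse (with advice
to skip it) rather than pass everything. Matrices round-trip as TSV with
genes in rows; gene sets as GMT; every pipeline artifact is recorded in an
MD5 manifest, and a rerun under the same configuration and seed is
hash-identical.

## Problem sizes used by the validation suite

The shipped tests and the acceptance script simulate 4,000-gene experiments
for wave/lead/enrichment recovery (200 regulated genes gives two-digit
precision on recovery rates), a 20,000-gene fully-null experiment for Z-test
calibration, 10,000 shared genes for the attenuation closed form
$\rho = v/(v+s^2)$, 1,000 random instances for the PAGE brute-force oracle
and 100 instances at $n \le 8$ for the exhaustive clustering oracle. These
sizes put Monte-Carlo error comfortably inside the asserted bounds while
keeping a full run in the tens of seconds.

## Known limitations

Variance moderation (limma-style) would beat the Z-ratio at very low
replicate counts; the Z-ratio is kept as the method this pipeline defines.
The wave classifier is threshold-based, not model-based: a gene hovering at
the significance boundary can be assigned a later wave than its true onset.
PAGE assumes an approximately normal null for the set median, which degrades
for very small sets ($m < 10$). Optimal leaf ordering of dendrograms is out
of scope; ordering is the deterministic merge-tree expansion.
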