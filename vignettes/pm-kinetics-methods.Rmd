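---
title: "Methods: phenotype microarray kinetic analysis in pmkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotype microarray kinetic analysis in pmkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmkin)
```

## The data and its model

A phenotype microarray run yields one kinetic curve per well: intensity
readings (arbitrary optical-density-derived instrument units) taken every
`cycle_min` minutes (15 by default) over a course of up to 72 hours, for
each well A01..H12 of each plate (PM01..PM20 in a standard bacterial
panel). pmkin's atomic object is therefore a `kinetic_curve` — strictly
increasing times in minutes paired with finite, non-negative intensities —
and every record carries its full metadata coordinate (project, species,
strain, phenotype, plate, well, replicate, temperature). Minutes are the
internal time unit throughout; an `Hour` column in an input file is
converted on read.

Record selection is conjunctive field filtering: a drill-down through
project → strain → phenotype → replicate → temperature is exactly a
composition of filters, and composing filters equals filtering with the
conjunction, so no fixed drill-down order is imposed. Temperature is part
of the replicate-group key — curves measured at different temperatures are
different experiments and are never averaged together. Species is carried
as metadata but is not a selection level.

## Shared curve mathematics

Every cross-curve computation first interpolates the curves onto a common
grid:

* the grid spans the **intersection** of the members' time ranges (largest
  minimum to smallest maximum) — no curve is ever extrapolated;
* the number of grid points equals the longest member's length, retaining
  maximal resolution;
* interpolation is **linear** between bracketing observations. Linear is
  the minimal monotonicity-preserving choice for 15-minute sampled growth
  data; anything smoother would invent curvature between readings. Grid
  points that coincide with observed times reproduce the observed values
  exactly.

Z-score scaling (used before clustering) subtracts the mean and divides by
the sample standard deviation (denominator n − 1, the R convention, stated
so tests can be exact). A flat curve cannot be scaled; it maps to all zeros
and carries a `degenerate` flag, and each analysis states what it does with
degenerate members.

Curves are reduced to scalars by `curve_summary`: the default is the
trapezoid **AUC** (intensity × minutes), with `max` and `endpoint` as
alternatives. AUC integrates the whole kinetic response and is robust to
single-reading noise, which is why it is also the default summary behind
the strain-comparison ratios; the choice is a package default, not a claim
about what any particular instrument software uses, and it is selectable
everywhere it matters.

## Quality control

**Outlier analysis.** Within each (strain, phenotype, plate) group, all
well × replicate members are resampled to the group grid and the pairwise
Pearson correlation matrix is computed. Each member's score is the median
of its correlations with every other member; members scoring below the
threshold (default 0.5, always user-settable) are flagged. The statistic is
per-member rather than a single per-group median because only a per-record
score can identify *which* record is aberrant; the group-level median of
all pairwise correlations is reported alongside for reference. Flat
(zero-variance) members have undefined correlation and are flagged as
degenerate — a flat replicate among growing ones is aberrant by definition.
Groups of size one are skipped with a warning. Note the symmetry limit:
with exactly two replicates, a corrupted member drags its partner's median
down equally, so both members of the pair flag and the well — not the
individual replicate — is the identifiable unit.

**Negative controls.** Control wells are resampled to their common grid
and, per quantile level (defaults 0.05, 0.25, 0.5, 0.75, 0.95, bracketing
the noise band), the empirical quantile across controls is computed at
every time point. Quantiles use linear interpolation between order
statistics (R's type 7 default). The per-level maximum over time is
reported as a candidate signal/noise threshold; following the guidance
framing of this analysis, no automatic boundary is chosen — the thresholds
are drawn on the plot and listed in the report. Controls are pooled across
plates; per-plate analysis is available by filtering first.

## Profile statistics

**Correlation matrix.** Pairwise Pearson r between all selected profiles on
the joint grid; zero-variance records yield undefined rows/columns (NA,
warned) rather than silently dropping.

**Profile search.** The target profile is piecewise linear through its
anchor points and is resampled like any curve; records are scored on the
record-set grid restricted to the pattern's time range. P-values use the
exact t-transform t = r·√((n−2)/(1−r²)) on n − 2 degrees of freedom,
two-sided, with |r| = 1 mapping to p = 0. Raw intensities are correlated by
default (consistent with the correlation matrix); z-scored comparison is an
option and leaves Pearson r unchanged. Grid points are serially dependent
within a growth curve, so these p-values order evidence rather than supply
calibrated error rates; they are reported raw, without multiplicity
correction.

**K-means.** Curves are resampled, z-score scaled, and partitioned by
`stats::kmeans` with `restarts` independent random starts (default 10),
keeping the run with the lowest within-cluster sum of squares; the RNG seed
(default 42) is part of the result, making runs bit-reproducible, and the
caller's RNG state is restored. We use the stock algorithm and its random
initialization rather than a hand-written seeding scheme: with a restart
budget the best-of-restarts objective is what matters, and on well-separated
shape families the optimum is found reliably (the test suite verifies the
exhaustive-partition optimum on small instances and exact recovery of
planted families). Each member's Pearson correlation to its cluster
centroid is reported; centroids are the means of their members' scaled
vectors. Zero-variance records are excluded with a warning. Assignment ties
are broken by the underlying implementation deterministically under the
fixed seed.

## Strain comparison

For each (test strain, plate, well): every replicate curve is reduced to
its scalar summary; the ratio is the mean of test summaries over the mean
of parent summaries (ratio of means, matching "average replicates, then
compare", not mean of ratios); the signed fold change is

FC = ratio (ratio ≥ 1), −1/ratio (ratio < 1),

so |FC| ≥ 1 always, the sign encodes direction, and ratio = 1 maps to +1
deterministically. Welch's unequal-variance t-test compares the replicate
summaries with Welch–Satterthwaite degrees of freedom; degenerate cases are
defined (both groups constant and equal → p = 1; constant and unequal →
p = 0 with a flag) rather than erroring mid-screen. The screening filter
retains p < 0.05 and |FC| ≥ 2 by default — the conventional two-fold
change screen — with both thresholds settable; p-values are raw by default,
and with ~2,000 wells per screen roughly 5% × wells false positives at
p < 0.05 are expected on null data (the two-fold FC requirement is what
keeps the joint screen quiet). Wells with non-positive parent mean summary
are incomputable and reported as such. Heat-map colour uses the symmetric
transform sign(FC)·log2|FC| — fold changes of +2 and −2 sit at equal
distances from no-change — but reported numbers are always FC itself.

At two replicates per strain, Welch's test is conservative (the
Satterthwaite degrees of freedom are estimated from two-point variances);
its null rejection rate at p < 0.05 sits below the nominal level, nearer
3–4% at three replicates. The calibration check in the acceptance script
measures this rate on 200 simulated null wells with three replicates per
strain and compares it with binomial bounds around the nominal level.

## The synthetic-data generator

`generate_experiment` emulates the standard study design: 2 strains (a
wild-type parent and a mutant) × 20 plates × 96 wells × 2 replicates,
readings every 15 minutes over 72 hours (289 points per curve). Each
(plate, well) gets a logistic growth model

v(t) = baseline + A/(1 + e^(−r(t − t_m))) + ε, ε ~ N(0, noise_sd²),

clipped at zero, with parameters shared across strains and replicates so
replicates correlate. Defaults: baseline 15 intensity units, amplitude A
uniform on [150, 250], rate r uniform on [0.005, 0.02] per minute (growth
spread over roughly 4–23 h), midpoint t_m uniform on [10, 30] h, and
noise_sd = 1% of A per reading — values chosen once to look like a healthy
bacterial PM run with growth completing well inside the course, and small
enough noise that zero-clipping is rare. Seeds are mandatory, recorded in
the truth table, and restore the caller's RNG state.

Planted features, each recorded in the returned ground-truth table:

* **outliers** — a chosen replicate's curve is replaced by the time-reversed
  mean curve (anti-correlated with its partners; note the reversal of an
  asymmetric logistic correlates near −0.7 to −1 with the original, well
  below any sensible flag threshold) or by a flat baseline (degenerate);
* **shape families** — designated wells decay sigmoidally instead of
  growing, giving cleanly separated cluster structure;
* **fold changes** — for designated wells, the mutant's entire noise-free
  curve is scaled by the planted ratio. Scaling the whole curve (rather
  than only the amplitude A) makes the planted AUC-summary ratio equal the
  nominal ratio exactly in the noise-free limit, so recovery error is
  attributable to noise alone; scaling A alone would confound recovery
  with the baseline's share of the AUC.

What the generator does **not** emulate — and hence what passing tests do
not certify about real data: dye chemistry and non-logistic kinetics
(diauxic shifts, lysis, inhibition rebounds), plate-edge and other spatial
effects, heteroscedastic or autocorrelated instrument noise, real Biolog
substrate panels (phenotype labels are synthetic), and replicate-to-
replicate biological drift beyond i.i.d. Gaussian noise. Recovery results
on this generator demonstrate correctness of the computations, not
robustness to every failure mode of real assays.

## Numerical and interface choices

* CSV is the report format (spreadsheet-openable, diff-able); numeric cells
  are written with enough digits that reading them back reproduces the
  double exactly, and a write–parse–write cycle is byte-identical.
* The kinetic-file dialect requires all 96 well columns by default, as
  instrument exports carry them; `partial = TRUE` accepts re-written
  subsets (the CLI's `filter` output).
* A degenerate/NA policy is stated per analysis instead of a global drop:
  QC flags degenerate members, the correlation matrix NAs them, clustering
  excludes them, comparison marks cells incomputable.
* Figures are multi-page vector documents (pdf default; postscript and svg
  selectable) drawn with base graphics; output is deterministic up to the
  device's embedded timestamps.
* Tests and the acceptance script run on deliberately scaled instances —
  full 2 × 20 × 96 × 2 geometry where the claim is about design arithmetic
  or the end-to-end workflow, and one-to-three-plate designs with shorter
  courses where the claim is statistical — keeping the whole suite in the
  low minutes on a single core.

## Known limitations

* No parametric growth-model fitting (lag/rate/asymptote estimation); the
  scalar summaries are non-parametric.
* Profile-search p-values are raw; the comparison screen is raw by default
  with any `p.adjust` method (e.g. Benjamini–Hochberg) selectable via
  `heatmap_compare(..., p_adjust = "BH")`.
* Spatial-bias QC across plate geometry is out of scope.
* The heat-map layout assumes the A01..H12 well naming; plates are free
  labels.
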