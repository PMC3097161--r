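# pmkin

Desk-scale analysis of phenotype microarray (PM) kinetic data in R.

Phenotype microarrays measure a microbe's response to hundreds of growth
conditions at once: each well of a 96-well plate holds a different substrate
(a carbon or nitrogen source, an antibiotic, a stressor) plus a redox dye,
and an incubating imager such as the OmniLog reads every well's optical
intensity every 15 minutes over hours to days. A standard bacterial run uses
20 plates (1,920 wells) per strain, and the instrument holds up to 50 plates
— 4,800 readings per 15-minute cycle. The result is one kinetic growth curve
per well, and the scientific questions are comparative: which replicates are
aberrant, where does signal leave the noise floor, which substrates separate
a mutant from its parent strain?

pmkin is for microbiologists and bioinformaticians who have such plate
exports (or want simulated ones) and need the standard PM analysis battery
without a database server:

* **Data model** — per-well `kinetic_curve` + metadata = `well_record`;
  ordered collections are `record_set`s supporting hierarchical filtering
  (project, strain, phenotype, plate, well, replicate, temperature) and
  replicate grouping.
* **I/O** — a documented plate-run CSV dialect (metadata header lines, a
  `Time(min)`/`Hour` column, 96 well columns A01..H12), with exact,
  byte-stable round trips; phenotype labels from a `plate,well,phenotype`
  sidecar map; all reports as spreadsheet-openable CSV.
* **Outlier analysis** — within each (strain, phenotype, plate) group,
  curves are interpolated to a common time grid and each well × replicate
  member is scored by the median of its pairwise Pearson correlations with
  the other members; records with median r below a chosen threshold
  (default 0.5) are flagged.
* **Negative-control analysis** — empirical quantile curves (default levels
  0.05, 0.25, 0.5, 0.75, 0.95) across control wells at every time point,
  with per-level maxima reported as candidate signal/noise thresholds.
* **Correlation matrix, profile search, k-means** — pairwise Pearson r
  between all selected profiles; correlation of each record against a
  user-drawn piecewise-linear target profile with two-sided p-values from
  t = r·√((n−2)/(1−r²)); k-means clustering of z-score-scaled curves with
  per-member correlation to the cluster centroid.
* **Strain comparison heat map** — replicate curves reduced to a scalar
  summary (AUC by default), per-well ratio of test to parent strain means,
  the signed fold change (FC = ratio if ≥ 1, −1/ratio otherwise), Welch's
  unequal-variance t-test with Welch–Satterthwaite degrees of freedom, and
  the conventional significance screen p < 0.05 with FC ≥ 2 or FC ≤ −2.
* **Synthetic experiments** — logistic growth curves
  v(t) = baseline + A/(1 + e^(−r(t−t_m))) + Gaussian noise, with planted
  outliers, shape families and fold changes recorded in a ground-truth
  table, so every analysis is testable end to end.
* **Figures** — multi-page vector output (pdf/ps/svg): bar plots, quantile
  curves, correlation intensity plots, profile overlays, cluster panels and
  the wells × plates fold-change heat map.

## Worked example

Simulate a two-strain, one-plate experiment with three replicates and two
planted effects — a four-fold growth gain in well A03 and a four-fold loss
in B07 of the mutant — then run QC and the strain comparison:

```r
library(pmkin)

plant <- data.frame(plate = "PM01", well = c("A03", "B07"),
                    ratio = c(4, 0.25))
exp <- generate_experiment(list(plates = "PM01", replicates = 3L,
                                planted_ratios = plant), seed = 42)
exp$records
#> <record_set> 576 records: 2 strain(s), 1 plate(s), 96 phenotype(s)

outlier_analysis(filter_records(exp$records, strain = "WT"),
                 threshold = 0.5)
#> Outlier analysis: 288 records in 96 groups, threshold 0.5
#>   flagged: 0 (0 degenerate)

heatmap_compare(exp$records, parent_strain = "WT")
#> Strain comparison vs parent 'WT' (auc summaries): 96 cells
#>   significant at p < 0.05, |FC| >= 2: 2
#>  test_strain parent_strain plate well     phenotype  ratio     fc     t    df
#>          MUT            WT  PM01  A03 phen_PM01_A03 3.9997  4.000  5493 3.787
#>          MUT            WT  PM01  B07 phen_PM01_B07 0.2502 -3.996 -1512 2.429
#>          p
#>  3.295e-14
#>  2.581e-08
```

Reading the output: no replicate fell below the median-correlation
threshold, so nothing is flagged in QC. The comparison screens all 96 wells
and recovers exactly the two planted effects — A03 with a signed fold change
of +4.0 (mutant grows more) and B07 with −4.0 (mutant inhibited), both far
below the p < 0.05 cutoff; every unplanted well stays near FC = ±1 and is
filtered out.

## Command line

A thin subcommand wrapper over the same functions ships in
`inst/cli/pmkin.R` (after installation:
`system.file("cli", "pmkin.R", package = "pmkin")`):

```sh
Rscript pmkin.R simulate --seed 1 --out-dir run/
Rscript pmkin.R outliers --in-dir run/ --threshold 0.5 --out outliers.csv
Rscript pmkin.R heatmap  --in-dir run/ --parent WT \
    --p-max 0.05 --fc-min 2 --out all.csv --filtered-out significant.csv
```

Subcommands: `simulate`, `parse`, `filter`, `outliers`, `negctrl`,
`barplot`, `corrmatrix`, `profilesearch`, `kmeans`, `heatmap`; every
threshold and seed is a flag (`--help` on any subcommand).

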