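# cytoscreen

Screening chromosome bands for prognostic value in copy-number-driven
tumors, with neuroblastoma as the motivating disease.

Neuroblastoma genomes carry few recurrent point mutations but frequent
gains and losses of whole chromosome bands (1p36 and 11q23 deletions, 17q
gain, MYCN amplification). Which of those recurrent events carry prognostic
information beyond the established clinical markers is the question this
package operationalizes, for analysts who have (a) segmental copy-number
profiles, (b) gene expression matrices with survival annotation, and (c) a
cytoband catalog with positional gene sets.

## The method

**1. Band-level copy number from segments.** For band *i* with length
*l<sub>i</sub>* and a sample's segments *j* with values *SCNV(j)* (log2
ratios) and band overlaps *l<sub>ij</sub>*:

```
CNV(i) = Σ_j (l_ij / l_i) · SCNV(j)
```

Basepairs untouched by segments contribute 0 (neutral). Bands are called
gained/lost by thresholding (default ±0.2), and bands whose gain or loss
frequency exceeds 15% of the cohort are the *frequent* bands; adjacent
same-direction frequent bands collapse to their most frequent
representative.

**2. Inferred copy number (iCNV) from expression.** For one sample and one
band, the band's genes form set B and all genes on any other band form set
A; on gene-wise centered (relative) expression the iCNV is the Welch
t-statistic

```
t = (x̄_B − x̄_A) / sqrt(s²_B/n_B + s²_A/n_A)
```

Positive t means relative gain. Bands with fewer than 10 genes are excluded
as unreliable.

**3. Survival screening.** Each band's iCNV enters a univariate Cox
proportional-hazards model of overall survival
(Benjamini–Hochberg-adjusted across bands, significance at adjusted
p < 0.05), then a covariate-adjusted model (iCNV + MYCN + age + gender +
stage, raw p < 0.05), with median-split Kaplan–Meier curves and
MYCN-stratified follow-up. Hazard ratios above 1 mean poorer survival per
unit iCNV.

A synthetic-cohort generator (`generate_cohort()`) draws band-structured
events, dosage-coupled expression and proportional-hazards survival with
full ground truth, so the whole pipeline is testable without any downloads.

## Worked example

```r
library(cytoscreen)

# a 300-sample cohort: chr1p3 gained in 30% of samples (log2-ratio 0.585),
# dosage-coupled expression, hazard doubling on the gain, MYCN HR 3
co <- generate_cohort(simulation_config(
  seed = 1, n_samples = 300, delta = 1,
  beta = c(chr1p3 = log(2) / 0.585)))

cnv <- map_segments_to_bands(co$segments, co$catalog,
                             samples = co$clinical$sample)
frequent <- select_frequent_bands(call_gain_loss(cnv), cutoff = 0.15)
frequent
#> frequent bands (freq > 0.15): 1 amplified, 0 deleted

icnv <- compute_icnv(normalize_expression(co$expression), co$gene_sets)
validate_icnv(icnv, co$truth$band_cnv)
#> iCNV validation over 300 samples: median own-band r = 0.944; 100% of bands with r > 0.8

uni <- univariate_screen(icnv, co$clinical)
head(as.data.frame(uni)[order(uni$p), c("band", "hr", "p", "p_adj")], 3)
#>      band        hr           p      p_adj
#> 3  chr1p3 1.0783035 0.000449418 0.01797672
#> 34 chr4p4 0.8629641 0.046333914 0.77038796
#> 11 chr2p1 0.8852882 0.074441025 0.77038796

multi <- multivariate_screen(icnv, co$clinical, bands = "chr1p3")
as.data.frame(multi)[, c("band", "hr", "ci_low", "ci_high", "p")]
#>     band       hr   ci_low  ci_high            p
#> 1 chr1p3 1.088334 1.041986 1.136743 0.0001376916

km_median_split(icnv$icnv["chr1p3", ], co$clinical)
#> Kaplan-Meier comparison (median split at -1.397): low = 150, high = 150; log-rank p = 0.0252
```

The gained band is the only frequent band, its iCNV tracks the true copy
state (r = 0.94), and it is the only band surviving multiple-testing
adjustment; its effect persists after adjustment for MYCN, age, gender and
stage, and the high-iCNV half of the cohort has visibly worse survival.

On real data the same flow is driven by the file-based pipeline:
`load_run_config()` (YAML), `run_frequency_stage()`, `run_survival_stage()`
and `run_report()`, or the thin command-line wrapper in
`inst/scripts/cytoscreen.R` (subcommands `simulate`, `frequency`,
`survive`, `report`). `reproduce_full_study()` reruns the published
analysis once the four study accessions (GEO GSE62564, GSE45478, ICGC
NBL-US, EBI E-MTAB-179) have been downloaded and converted to the package's
input formats.

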