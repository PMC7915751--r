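# mitopop

Detection and quantification of **MitoTracker-low monocyte subpopulations**
in confocal micrographs, from raw three-channel tiles to cohort-level
association statistics.

## The problem

Live staining of CD14+ monocytes with MitoTracker Orange CMTMRos — a dye
whose mitochondrial accumulation tracks the mitochondrial membrane
potential (MMP) — reveals two cell subpopulations: normally stained
(MitoTracker-high) cells and cells with strongly reduced staining
(MitoTracker-low; depolarized but viable mitochondria, still able to
metabolize 5-ALA into fluorescent PpIX). The per-subject proportion of
MitoTracker-low cells is a biomarker candidate: it associates with carotid
atherosclerotic plaque burden and with a blunted LPS-induced TNF response.

`mitopop` is for image-analysis and biostatistics practitioners who need
this pipeline as tested, reproducible code:

1. **Simulate** (`scene_spec`, `subject_spec`, `cohort_spec`,
   `render_tile`, `render_subject`, `generate_cohort`) — synthetic 16-bit
   three-channel tiles (MitoTracker / PpIX / transmitted light) and whole
   cohorts with complete ground truth.
2. **I/O** (`write_tile`, `read_tile`, `split_tilescan`,
   `write_data_table`) — pseudocolor RGB TIFF (red = MitoTracker,
   green = PpIX, blue = transmitted light) via a built-in 16-bit codec,
   plus the fixed-schema per-cell CSV table.
3. **Segment** (`pixel_classify`, `classify_objects`, `filter_singlets`)
   — deterministic edge-detection segmentation of the transmitted-light
   channel; objects classified by size into singlets / clumps / debris;
   retention requires singlet class, probability > 50%, and no border
   contact.
4. **Quantify** (`measure_cells`, `granularity_score`,
   `morphology_scatter`) — background-subtracted total and
   average-per-pixel fluorescence per cell; opening-spectrum granularity.
5. **Subpopulation** (`intensity_kde`, `find_valley`, `proportion_low`,
   `subpop_pipeline`) — per-subject Gaussian KDE of log10 per-cell
   MitoTracker intensity; the valley between the two heaviest modes
   dichotomizes cells; the proportion below the valley is the statistic.
6. **Cohort** (`normality_test`, `kmeans2`, `pearson_cor`, `ttest_ind`,
   `cohort_report`) — Shapiro–Wilk diagnostics, deterministic 1-D k-means
   (k = 2, exhaustive optimal split), Pearson correlations with TNF
   secretion, per-cluster mean ± SEM with pooled-variance t-tests.

The core statistic, per subject: with per-cell intensities
$x_1,\dots,x_n$, estimate the density $\hat f$ of $\log_{10} x$, find the
two dominant modes $m_1 < m_2$ of $\hat f$, set the threshold
$t = \arg\min_{m_1 < g < m_2} \hat f(g)$, and report
$\hat\pi_{\text{low}} = \frac{1}{n}\sum_i \mathbf 1\{\log_{10} x_i < t\}$.

## Worked example

```r
library(mitopop)

# one synthetic subject at protocol scale: 27 tiles of 225 x 225 um^2,
# true MitoTracker-low fraction 0.30
scene   <- scene_spec(seed = 7)
subject <- subject_spec("11", pi_low = 0.30, n_tiles = 27L)
cells   <- measure_subject(render_subject(scene, subject))
nrow(cells)
#> [1] 624
subpop_pipeline(cells)
#>   patient_id n_cells threshold_log10  prop_low bimodal fallback
#> 1         11     624        2.554227 0.3044872    TRUE    FALSE
```

624 retained single cells (protocol floor: 600), a bimodal per-cell
intensity distribution with the valley at 10^2.55 counts, and an estimated
MitoTracker-low proportion of 0.304 against a planted 0.30.

```r
# planted cohort statistics (5/7/23 donors; statistics stage shown on the
# true proportions)
cov <- generate_cohort(cohort_spec(seed = 1))$covariates
cov$prop_low <- cov$pi_low_true
rep <- cohort_report(cov)
rep$correlations
#>    variable           r         p  n
#> 1 tnf_basal -0.09687248 0.5798551 35
#> 2   tnf_lps -0.40657406 0.0153631 35
format_comparison(rep$comparison)[, c("variable","mean_1","mean_2","p")]
#>       variable  mean_1  mean_2       p
#> 1          imt    0.77    0.76 0.68500
#> 2 plaque_score    1.60    1.90 0.25300
#> 3    tnf_basal  855.00  739.00 0.40900
#> 4      tnf_lps 3187.00 2162.00 0.00176
#> 5 tnf_increase 2332.00 1423.00 0.01190
#> 6     tnf_fold    7.60    3.70 0.19600
table(rep$clusters$cluster)
#>  1  2
#> 21 14
```

The proportion of MitoTracker-low cells correlates negatively with
LPS-induced TNF secretion (r = −0.41, p = 0.015) but not with basal
secretion; k-means splits the cohort 21/14, and the high-proportion
cluster secretes markedly less LPS-induced TNF (2162 vs 3187 pg/mL,
p = 0.0018). The full image pipeline (`run_cohort_pipeline()`) reproduces
these directions from rendered pixels rather than planted truths.

## Command line

```sh
Rscript inst/cli/mitopop.R simulate --config cohort.json --out tiles/ --seed 5 --n-tiles 8
Rscript inst/cli/mitopop.R segment  --in tiles/ --out objects.csv
Rscript inst/cli/mitopop.R quantify --tiles tiles/ --out cells.csv
Rscript inst/cli/mitopop.R subpop   --cells cells.csv --out subjects.csv
Rscript inst/cli/mitopop.R cohort   --subjects subjects.csv --covariates tiles/covariates.csv --out report/
```

## Further reading

`vignettes/mitopop-methods.Rmd` documents the image-formation and cohort
models, every tunable parameter with units and defaults, the numerical
choices (valley persistence, edge-band compensation, noise sampling), and
what a green synthetic-data test does and does not establish.
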