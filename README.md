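# cellogram

Processing engine for **direct-infusion single-cell metabolomics (SCM)**
acquisitions in R.

In ambient SCM (e.g. nano-DESI in touch-down mode), a sampling probe parks
on one cell after another while the mass spectrometer acquires
continuously. The result is a *cellogram*: one long centroided MS1 run in
which every sampled cell appears as a *cellographic peak* on the extracted
ion chronogram (EIC) of an abundant endogenous marker. Without
chromatographic separation, the spectra contain thousands of m/z species,
most of them solvent, contaminant or artifact background. The analysis
problem is to (1) find the per-cell sampling events, (2) align the
high-resolution m/z values of each event into feature groups, and
(3) decide, species by species, what is endogenous and what is background.

`cellogram` implements that pipeline end to end:

- **spectra I/O** — centroided mzML read/write (via Bioconductor *mzR*),
  CSV peak-time and target/exclusion lists;
- **cell-event detection** — EIC extraction at ppm tolerance, robust noise
  estimation, threshold/refractory-period event finding with background,
  peak and extended windows per event, plus manual add/remove editing;
- **two-stage m/z alignment** — greedy grouping by dynamic ppm tolerance
  with intensity-weighted representative masses, first within each
  cellographic peak, then across peaks, then across experiment files;
- **statistical filter cascade** — fold change (FC), detection frequency
  (DF), ¹³C deisotoping, internal-standard/solvent-blank exclusion and
  mass-defect filtering, applied cumulatively with per-step retention
  accounting;
- **targeted workflow** — target matching, TIC / internal-standard
  normalisation, single-point IS quantification;
- **EIC profile classification** — deterministic 224×224 chronogram
  rendering and a trainable classifier (high S/N / low S/N / background,
  collapsed to endogenous vs background) with stratified validation,
  periodic checks and early stopping;
- **cellogram simulator** — fully seeded synthetic runs with ground truth
  (events, species classes, isotopologues, per-cell intensities), so every
  stage is testable without instrument data.

## The statistics at the core

For a species trace $x_s$ (scan $s$) in one cellographic peak with
background window $B$ (the 10 scans before the trigger) and peak window
$P$:

$$\mathrm{FC} = \frac{\max_{s \in P} x_s}{\tfrac{1}{|B|}\sum_{s \in B} x_s},$$

an S/N-like statistic (a zero background mean falls back to the EIC noise
floor). A feature *detects* in a cell when FC ≥ the threshold (default 3),
and survives the DF filter when it detects in at least a fraction
(default 33%) of cells. Detection triggers use the EIC signal-to-noise,
with noise estimated as the one-sided MAD of the sub-median trace,
$1.4826 \cdot \mathrm{med}(\mathrm{med}(x) - x_{x<\mathrm{med}})$.
M+1 isotopologues are removed when a partner sits $1.003355$ Th below a
feature (within 10 ppm) with a median intensity ratio consistent with
natural ¹³C abundance. The classifier judges each species' whole-run EIC
shape instead of its thresholded statistics, evaluated as binary
sensitivity = TP/(TP+FN) and specificity = TN/(TN+FP) against labels.

## Worked example

```r
library(cellogram)

# a 20-cell synthetic acquisition (3 cells/min, 2 Hz), written to mzML
sim <- simulate_run(sim_config(n_cells = 20, seed = 4))
write_mzml(sim$run, "run.mzML")

run <- read_mzml("run.mzML")
#> <sc_run> 881 MS1 scans, 44590 centroids, positive mode
#>   rt 0.000..7.333 min; m/z window [75.000, 1000.000]

# detect cell events on the PC 34:1 marker chronogram
eic    <- extract_eic(run, 760.586, ppm_tol = 5)
events <- detect_cell_events(eic, detection_params(760.586, sn_threshold = 25,
                                                   refractory_period = 0.15))
nrow(events)
#> [1] 20
head(as.data.frame(events), 3)
#>   cell_id trigger_scan trigger_time bg_start bg_end peak_start peak_end ext_start ext_end
#> 1       1           21    0.1666667       11     21         21       49        11      49
#> 2       2           59    0.4833333       49     59         59       93        49      93
#> 3       3          103    0.8500000       93    103        103      132        93     132

# two-stage alignment into a cells x features table, then the cascade
tab <- align_run(run, events, ppm_tol = 5, noise_floor = estimate_noise(eic))
tab
#> <cell_feature_table> 20 cells x 145 features (positive mode)
#>   m/z 113.0658 .. 984.7652; nonzero entries 57.6%

run_cascade(tab, filter_config())
#> <filter_result>
#>             step features_in features_out
#>               fc         145          136
#>               df         136           65
#>        deisotope          65           56
#>     is_exclusion          56           56
#>              mdf          56           56
#>  blank_exclusion          56           56

success_rate(nrow(events), nrow(sim$truth$events))
#> [1] 100
```

All 20 simulated cells are found (success rate 100%); the cascade then
cuts the 145 aligned features down to 56, dropping sporadic background
(DF) and ¹³C isotopologues while keeping the event-locked species. To
train and apply the profile classifier, render each species' EIC with
`render_eic_image()`, fit with `train_eic_classifier()` and predict with
`classify_eics()`; see the methods vignette
(`vignettes/cellogram-methods.Rmd`) for the full protocol.

A thin command-line front end over the same functions is included:

```sh
Rscript inst/cli/cellogram-cli.R simulate --out-dir demo --n-cells 20 --seed 4
Rscript inst/cli/cellogram-cli.R detect  --mzml demo/run.mzML --marker-mz 760.586 --out demo/events.csv
Rscript inst/cli/cellogram-cli.R process --mzml demo/run.mzML --events demo/events.csv --out demo/table.csv
Rscript inst/cli/cellogram-cli.R filter  --table demo/table.csv --report demo/report.csv
```

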