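---
title: "Methods: cellographic peak detection, m/z alignment, filtering and EIC classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cellographic peak detection, m/z alignment, filtering and EIC classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cellogram)
```

This vignette documents the models, conventions and design choices behind
the package: what each stage assumes, which tunables matter and why their
defaults are what they are, what the simulator does and does not emulate,
and the numerical edge cases. It states no empirical result beyond what
the test suite and `scripts/acceptance.R` compute themselves.

## The data model

A direct-infusion single-cell acquisition is one continuous centroided
MS1 run. `sc_run` stores it as an ordered list of per-scan `mz`/`intensity`
matrices with retention times in **minutes** (sampling rates and
refractory periods are naturally per-minute quantities; mzML's seconds are
converted on read). Scan indices are 1-based and all window ranges are
half-open `[start, end)`. Only centroided mzML is supported: vendor raw
formats carry per-peak noise and transient-domain extras, but those do not
survive conversion, so the package assumes they are absent and estimates
noise from the data instead.

## Cell-event detection

Detection runs on the EIC of a user-chosen marker — an abundant endogenous
species such as protonated PC 34:1 (m/z 760.586) or choline (m/z 104.107);
the right marker depends on the solvent system and polarity. The EIC value
of a scan is the sum of centroid intensities within ±`ppm_tol` of the
marker mass (binary search per scan; tolerances are relative, matching the
resolution behaviour of FTMS analyzers).

**Noise.** With the vendor noise channel lost, the baseline noise scale is
estimated as the one-sided MAD of sub-median EIC values,
`1.4826 * median(median(v) - v[v < median(v)])`. Using only deviations
*below* the median makes the estimate blind to the cell-event peaks riding
on the baseline; the Gaussian calibration factor makes it estimate the
baseline sigma. Degenerate traces fall back to the smallest positive value
observed (constant traces) or 1.0 (all-zero traces), so thresholding never
divides by zero.

**Triggering.** Scanning left to right, an event triggers at the first
scan whose S/N (or raw intensity, in intensity mode) meets the threshold
*inclusively*, provided at least one refractory period has elapsed since
the previous trigger (measured trigger-to-trigger; whether the clock
starts at the trigger or the peak end is a free choice, and the trigger is
the less ambiguous anchor). The threshold and the refractory period are
deliberately interdependent: a threshold low enough to catch weak cells
will re-trigger on the decaying tail of strong cells unless the refractory
period covers the tail — the classic peak-splitting failure, which the
tests pin down explicitly. Defaults (S/N 25, refractory 0.15 min,
10 background scans) suit a 3-cells-per-minute acquisition at 2 Hz;
real data sets need per-data-set tuning of both.

**Windows.** Each event gets: a background window (the `background_scans`
scans before the trigger, clipped at the run start, never borrowed from
the previous peak), an extended window running from its background start
to the next event's background start (the last event runs to the end of
the run), and a peak window from the trigger to the extended end — the
extended cellographic peak between consecutive backgrounds. With a
positive `pre_extension_scans` every extended window shifts its start
earlier by the same amount; ends follow the neighbouring (shifted) starts
so the extended windows always tile the run without overlap. Manual
editing (`edit_events()`) re-derives all windows with the same
construction, so curated and automatic events are indistinguishable
downstream.

## Two-stage m/z alignment

`group_mz()` sorts observations by m/z and grows groups greedily: a
candidate joins while it deviates from the group's running
intensity-weighted mean by at most `ppm_tol`, otherwise a new group
starts. Sorting first makes the partition deterministic and
order-invariant; the intensity weighting keeps representative masses
anchored at the well-measured (intense) centroids so low-intensity jitter
stragglers cannot drag a group away. On data whose true species are
separated by several tolerance widths this reproduces single-linkage
clustering exactly (oracle-checked); its tie behaviour on chained data —
split where the gap to the running mean exceeds the tolerance — is a
declared convention, not asserted to match any other implementation.
The default tolerance of 5 ppm is chosen for 240k-resolution FTMS spectra
with ~1–2 ppm scan-to-scan jitter and is exposed everywhere.

Alignment is split in two stages for tractability: first within each
event's extended window (background-window members grouped alongside but
flagged, so per-species background means are available), then across the
events' integrated representative masses. The per-cell feature intensity
is the sum over the event's **peak window** — the cell's material; the
background scans inform the fold change but are not added to the cell
signal. Within the peak windows, intensity is conserved: every centroid
lands in exactly one group, and the feature-table total equals the total
centroid intensity. A third grouping level (`align_across_files()`)
merges processed runs of equal polarity under file-qualified cell ids.

With per-scan jitter, a small fraction of centroids falls outside the
tolerance of their species' running mean and forms low-intensity
fragment features. This is inherent to tolerance-based grouping; the DF
filter removes such fragments, and species-level accounting (matching
features back to known masses) is the right way to score recovery —
which is how the acceptance checks do it.

## The filter cascade

Filters apply cumulatively, each on the survivors of the last, default
order FC → DF → deisotoping → IS exclusion → MDF → blank exclusion: the
statistical filters at low thresholds first, the one-shot deterministic
filters after, which minimises endogenous losses. All threshold
comparisons are inclusive (`>=`), pinned by boundary tests.

- **FC** (default 3): max in-peak intensity over the mean of the last 10
  background scans; zero background means fall back to the EIC noise
  floor so FC stays finite and comparable. Complex data sets may warrant
  FC 9 — that choice stays with the user.
- **DF** (default 1/3): fraction of cells in which the feature passed FC
  (not merely nonzero — sporadic species are dropped).
- **Deisotoping**: drop B if some A sits 1.003355 Th below (within 10 ppm
  of B's mass) and the median co-detected B/A ratio is ≤ 0.6. The ratio
  guard (0.6 covers natural ¹³C abundance up to roughly 50 carbons)
  protects distinct species one neutron apart; singly charged species are
  assumed, as appropriate for direct-infusion small molecules.
- **Exclusion lists**: representative mass within 5 ppm of a listed
  internal standard or solvent blank.
- **MDF**: fractional-mass windows, half-open, wrap-around allowed,
  overlaps merged with a warning. Ranges default to *empty*: useful
  windows are data-set specific and aggressive windows are the one filter
  that readily costs endogenous species.

Each filter is a pure function of its inputs, hence idempotent, and each
step can only shrink the feature set — both properties are tested on
randomized tables. When ground-truth labels are available the cascade
reports per-step endogenous/background retention relative to the input
pool.

## EIC profile classification

Thresholded statistics trade coverage against specificity; judging each
species' whole-run EIC shape avoids the threshold entirely. Three profile
classes are used: **high S/N** (sharp event-locked peaks, baseline orders
of magnitude below the apex), **low S/N** (event-locked but with elevated
background, possibly under one order of magnitude of separation) and
**background** (static, drifting, or spiking once or twice per run); the
binary mapping sends both endogenous classes to "endogenous".

**Rendering (version `v1`).** Deterministic, axis-free 224×224×3 raster:
the trace is resampled to one value per pixel column (max-pooled so
single-scan spikes survive; linearly interpolated when the run is shorter
than the image), scaled linearly from 0 to the trace maximum (1 if the
trace is all zero), and drawn as a 2-pixel vertical-stroke line on white.
Images depend only on profile *shape* — identical values give
byte-identical pixels and uniform scaling changes nothing. Because the
paper-style plot conventions (size, scale, line width) are genuinely
open choices, the renderer is versioned and every model records the
version it was trained with; prediction refuses mismatched renders.

**Model and protocol.** The reference classifier is a compact
feed-forward network: 28×28 block-averaged ink density in, one tanh
hidden layer (32 units), softmax out, trained by seeded mini-batch SGD
with momentum (batch 64). 30% of the training data is held out as a
stratified validation split; validation loss is evaluated every 30
iterations, training stops after 5 consecutive checks without strict
improvement, and the best-validation checkpoint (not the last) is
returned. The architecture is deliberately pluggable — any object with a
compatible `predict` and matching renderer version drops in, including
transfer-learned backbones; the contribution here is the
rendering/taxonomy/protocol pipeline, and this reference model trains on
one CPU in seconds at a few hundred images per class. Classes are
near-balanced in the intended training regime, so no reweighting happens
by default (optional class weights exist). Exact score ties break toward
background — conservative, since review can rescue a flagged species but
silent background pollutes every downstream analysis. Manual overrides
(`review_overrides()`) keep provenance and are idempotent.

**Augmentation.** `augment_by_event_count()` restricts an EIC to its
first n extended windows; rendered at fixed width, many events give
sharp centroid-like peaks and few events give broad Gaussian-like peaks.
Sweeping n from 10 to ~100 in steps of 5 multiplies a limited labelled
pool 19-fold.

## The simulator

`simulate_run()` emulates a touch-down direct-infusion acquisition: 100
cells at 3 cells/min (the typical design), 2 Hz scans over m/z 75–1000,
run length sized to the cell count plus 10%. Events have a 2-scan linear
rise and per-species exponential decay (2–3.5 scans), truncated at 2% of
apex — probe retraction ends extraction abruptly, which is what makes the
signal return to baseline between cells. Species: 25 high-S/N (baseline
10⁻³ of amplitude), 15 low-S/N (baseline 0.3 of amplitude), 10 static + 5
drifting + 5 spiking background species, 2 steadily infused internal
standards and 3 solvent blanks; 30% of endogenous species carry an M+1
isotopologue at 0.011 per carbon (5–40 carbons). Per-cell intensities get
log-normal heterogeneity (sdlog 0.5, presence probability 0.95/0.7 for
high/low S/N) — no distribution is established for biological
cell-to-cell variability, so log-normal is a configurable choice.
Per-scan multiplicative noise is sdlog 0.15 for cell-derived signal and
0.5 for background (solvent flicker is burstier), every centroid's m/z is
jittered by N(0, 2 ppm), and — critically — no centroid is emitted below
an instrument-style intensity floor (2×10³). That floor makes
near-threshold background *sparse*, which is exactly why real background
leaks through fold-change filtering: missing background scans shrink the
FC denominator. Without it the cascade looks unrealistically perfect.
The marker is a fixed high-amplitude species at m/z 760.586 present in
every cell. All randomness flows from one seed; identical configurations
produce byte-identical mzML.

What the simulator does **not** emulate: profile-mode peaks,
resolution-dependent peak widths, adducts, ion-suppression dynamics,
event-correlated background (matrix effects), calibration drift, and
real labelling ambiguity (a spiking background that happens to coincide
with cells is still labelled background). Tests passing on simulated data
therefore demonstrate the pipeline's correctness under these declared
conditions, not instrument-grade performance; published-scale metrics
require the original instrument data and are out of reach by design.

## Problem sizes and numerical notes

The test suite runs simulations at their design defaults (100 cells, ~60
species) for detection and pipeline checks, 10 and 5 seeds respectively,
and one labelled run with 300 species per profile class for the
classifier study — sizes chosen so the full suite completes in a few
minutes on one CPU while keeping every per-class sample count in the
hundreds. Degenerate inputs are handled explicitly: empty EICs error,
all-zero EICs render as a flat baseline and estimate noise 1.0, empty
event windows yield empty feature sets, zero denominators in
normalisation yield `NA` with a warning, and coincident simulated
centroids within a scan are merged by intensity summation. The
trade-off comparison in the acceptance tests gives both routes the same
deterministic one-shot filters (deisotoping and exclusion lists) and
varies only the statistical thresholds, since an M+1 isotopologue is
cell-derived material whose chronogram is indistinguishable from its
parent's — no profile classifier can remove it, and no threshold sweep
is needed to remove it either.
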