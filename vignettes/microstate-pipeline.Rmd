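---
title: "EEG microstates and EMG features: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG microstates and EMG features: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msrehab)
```

## The problem this package addresses

Resting-state EEG alternates between brief (tens of milliseconds) periods in
which the scalp potential topography stays quasi-stable before switching to
another configuration — *microstates*. In motor-rehabilitation studies these
dynamics, together with surface EMG amplitude features of the paretic arm,
are used to track how cortical network activity and muscle output change
under an intervention such as high-frequency rTMS over the affected primary
motor cortex. `msrehab` implements that analysis chain end to end:
conditioning raw EEG/EMG, segmenting EEG into microstates, extracting the
temporal microstate statistics and time-domain EMG features, and running the
pre/post and between-group statistics on the results.

Because clinical recordings of this kind are typically not redistributable,
the package also ships a seeded simulator that plants a known microstate
sequence in synthetic EEG and known amplitudes in synthetic EMG. Every stage
of the pipeline can therefore be validated against ground truth, and the
package's tests do exactly that.

## The microstate model

At each time point $t$, the global field power over $n$ electrodes is the
spatial standard deviation of the potential map $v(t)$:

$$\mathrm{GFP}(t) = \sqrt{\frac{1}{n}\sum_{i=1}^{n}\bigl(v_i(t) - \bar v(t)\bigr)^2}.$$

Topographies at local GFP maxima have the highest signal-to-noise ratio, so
the maps at GFP peaks are the input to clustering. `find_gfp_peaks()` takes
strict interior local maxima; a plateau of exactly equal values contributes
its midpoint (a tie-break that matters only on synthetic or quantised data).

**Modified K-means.** Microstate clustering is polarity invariant: a map and
its sign-flip are the same state. Each peak map is assigned to the cluster
centre maximising its *squared* spatial correlation (Pearson correlation
across channels), and each centre is updated as the dominant eigenvector of
the channel cross-product matrix of its assigned maps. Because the
eigenvector update maximises the GFP$^2$-weighted sum of squared
correlations within each cluster and the assignment step maximises it per
sample, the global explained variance

$$\mathrm{GEV} = \frac{\sum_t \mathrm{GFP}(t)^2\, r_t^2}{\sum_t \mathrm{GFP}(t)^2}$$

is non-decreasing over iterations (a property the test suite checks).
Iteration stops when the relative GEV improvement drops below `tol = 1e-6`
or after 500 iterations; 50 random restarts are run by default and the best
GEV retained. The returned clusters are ordered by their explained-variance
contribution and sign-canonicalised (largest-magnitude channel positive), so
the result is a deterministic function of the data and the seed.

**Two-level flow.** Subject-level models are clustered first (on each
subject's own GFP-peak maps); the subject template maps are then pooled and
re-clustered by `aggregate_group_model()` to give group templates. The
alternative — clustering all subjects' peak maps pooled — is also defensible;
clustering subject templates is used here because it weights subjects
equally regardless of recording length and is the common practice in
group-level microstate tooling.

**Class labels.** `label_classes()` matches model maps to reference
topographies by the injective assignment maximising summed absolute spatial
correlation, enumerated exhaustively ($K! \le 120$). The built-in references
are idealized Gaussian potential blobs at the canonical locations on the
16-channel motor montage (A right-frontal, B left-posterior, C left-frontal,
D midline-frontal, E central-parietal). They are *synthetic anchors* for
ordering and naming, not empirical templates; studies with their own
canonical maps should pass them instead.

**Backfitting and parameters.** `backfit()` labels *every* sample with the
class of highest absolute spatial correlation (ties to the lowest class
index; spatially flat samples get correlation 0). From the label sequence,
`microstate_parameters()` computes per class: mean duration (ms), time
coverage (%), and occurrence (1/s). Runs are confined within epochs, and
boundary-truncated runs are counted in all three statistics by default. That
policy makes the identity

$$\text{coverage} = \text{occurrence} \times \text{duration} / 10$$

(coverage in %, duration in ms) hold *exactly*, which the tests assert to
1e-9. A flag excludes boundary runs from the duration average only, since
some toolchains do; this intentionally breaks the identity for the affected
classes.

**Minimum-duration smoothing.** By default no temporal smoothing is applied
(`min_duration_ms = 0`): duration and occurrence then reflect the raw
argmax labelling. With noisy data, samples near the amplitude troughs of the
EEG oscillation carry almost no topographic signal, and their labels flicker
randomly for a few samples at a time; this leaves coverage nearly unbiased
but grossly inflates occurrence. `smooth_labels()` merges runs shorter than
a threshold into their longer neighbour, shortest first. For parameter
recovery on the package's simulated recordings we use 16 ms: noise flickers
at the envelope troughs last under ~10 ms at 500 Hz, while gamma-distributed
dwell times with an 80 ms mean are below 16 ms with probability under 7%, so
the two time scales separate cleanly. The threshold is an analysis choice of
the same kind as a filter order — pick it from the time scales of the data,
not per dataset.

## The synthetic-data generator

`simulate_eeg()` emulates eyes-closed resting EEG with planted ground truth:

* **Templates** (`make_templates()`): random zero-mean unit-norm maps with
  pairwise $|r| \le 0.6$ by rejection sampling. Zero-mean maps on $n$
  channels live in an $(n-1)$-dimensional space, hence the `n_channels >=
  K + 1` requirement (on 2 channels all zero-mean maps are collinear).
* **State path**: a semi-Markov chain. The next class is drawn with
  probability proportional to the class rates, excluding the current class
  (so a run belongs to one class by construction); dwell times are gamma
  with shape 2 — smooth, unimodal, strictly positive — scaled to the class's
  mean. Defaults: equal rates, 80 ms mean dwell, values in the typical range
  for resting microstates.
* **Amplitude envelope**: the active template is scaled by a rectified 10 Hz
  sinusoid, so GFP peaks arrive at ~20/s as in alpha-dominated resting EEG.
* **Noise**: spatially white Gaussian, scaled so that the ratio of mean
  squared signal GFP to expected squared noise GFP equals the requested SNR
  (in dB). `snr_db = Inf` is noise-free.

What the simulator deliberately does **not** model: volume conduction and
realistic source geometry, spatially correlated noise, eye/cardiac/muscle
artifacts, non-stationary alpha power, or inter-subject topography
variability. Passing the recovery tests therefore shows the *algorithms* are
correct under the stated generative model — not that any clinical effect
would be detected in real recordings.

`simulate_emg()` gives each channel a stationary sinusoid at an integer
frequency inside the 20–400 Hz surface-EMG band, so the analytic features
are exact over whole periods: PTP $= 2a$, RMS $= a/\sqrt 2$. It emulates
amplitude structure only, not burst timing, motor-unit statistics, or
spectral shape.

## Preprocessing choices

The conditioning chain mirrors standard resting-state practice: band-pass
(EEG 0.5–45 Hz, EMG 20–400 Hz), 50 Hz notch, downsampling to 500 Hz, common
average reference (EEG), 2-s epochs, and rejection of any epoch exceeding
±80 µV at any electrode and sample (strictly greater than the threshold;
exactly ±80 µV is retained). Filters are Hamming-window linear-phase FIRs
applied at zero phase via reflection padding and group-delay compensation;
orders are set from the transition bandwidth (≈ 3.3·fs/Δf), giving passband
gain within 1% and >20 dB notch attenuation with ±5 Hz neighbours within 5%.
Filtering is FFT-based (overlap-add), so the long low-edge filters stay
cheap. Interactive ICA-based artifact removal is out of scope; its place in
the chain is an explicit hook (`exclude_epochs()`) taking externally
determined epoch indices.

## Statistics

The comparison layer reports two-sided tests throughout:

* `paired_t()` / `independent_t()` (pooled by default, Welch optional), thin
  tidy wrappers over the standard tests with Cohen's effect sizes.
* `wilcoxon_signed_rank()`: zeros dropped; for $n \le 25$ the p-value is
  exact, from the signed-rank null distribution computed by a
  generating-function recursion over the (possibly tied, doubled) ranks —
  equivalent to enumerating all $2^n$ sign patterns, which is how the tests
  verify it; a tie-corrected normal approximation is used above.
* `mixed_anova()`: the classical univariate mixed design (one between-, one
  within-subject factor, one observation per cell), with the between effect
  tested against subjects-within-groups and the within/interaction effects
  against the class-by-subject stratum; partial $\eta^2 =
  SS_\text{effect}/(SS_\text{effect}+SS_\text{error})$. No sphericity
  correction is applied, matching common reporting in this literature;
  `simple_effects()` decomposes a significant interaction per within level.
* Normality gating: `compare_pre_post()` runs Shapiro–Wilk on the paired
  differences at α = 0.05 and reports *both* the t and the signed-rank test
  with a recommendation flag, rather than silently switching.
* `correlation_matrix()`: Pearson correlations of change scores
  (post − pre) for every microstate parameter against every muscle, adjusted
  over all cells (Benjamini–Hochberg by default, Bonferroni optional).
  Change scores are used on both sides because the scientific question is
  whether *improvements* co-vary; correlating pooled pre+post values would
  conflate between-subject level differences with treatment response.

## Worked example

```{r example, eval = FALSE}
set.seed(1)
templates <- make_templates(16, 5, seed = 1)
sim <- simulate_eeg(templates, class_rates = rep(1, 5),
                    mean_dwell_ms = rep(80, 5), snr_db = 10,
                    fs = 500, duration_s = 120, seed = 2)
ep <- epoch_recording(common_average_reference(sim$recording), 2)
model <- modified_kmeans(gfp_peak_maps(ep), K = 5, n_restarts = 20, seed = 3)
model <- label_classes(model, templates)
pars <- microstate_parameters(backfit(ep, model), min_duration_ms = 16)
pars
autoplot(model)
plot_parameters(pars)
```

The packaged clinical fixture reproduces its published summary exactly:

```{r clinical}
clinical_outcomes(clinical_scores())
```

## Problem sizes, tolerances, degenerate inputs

The validation suite simulates 120-s, 16-channel recordings at 500 Hz
(60,000 samples, ~11,000 GFP-peak maps) — long enough that planted coverage
is recovered within 3 percentage points and occurrence within 15% relative
error at 10 dB SNR, while a full run of tests plus the acceptance script
stays in the minutes range on a single core. Numerical tolerances: K-means
convergence at relative GEV 1e-6; the coverage identity asserted to 1e-9;
closed-form EMG features to 0.5%. Degenerate inputs are errors, not NaNs:
single-channel GFP, fewer peak maps than clusters, zero-variance paired
differences, all-zero Wilcoxon differences, empty epoch sets after
rejection. Spatially constant samples inside otherwise valid data are
labelled class 1 with fit correlation 0 rather than erroring, so a flat
segment cannot abort a whole recording.

## Known limitations

* The group-template step clusters subject templates, not pooled samples;
  with very unequal subject data quality the two differ.
* No microstate syntax (transition-probability) analysis and no criterion
  for choosing K; K defaults to 5 and is configurable.
* The built-in A–E references are idealized; automatic labelling of unusual
  montages requires user-supplied references.
* Recordings are read and written as CSV with a JSON sidecar; EDF files must
  be converted upstream.
* EMG units are carried symbolically (µV throughout); no calibration logic.
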