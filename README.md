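# msrehab

Analysis of synchronized resting-state EEG and surface EMG in
motor-rehabilitation studies: EEG **microstate** segmentation with a
polarity-invariant modified K-means, the temporal microstate statistics
(duration, coverage, occurrence), time-domain EMG features (peak-to-peak,
RMS), and the pre/post + between-group statistical layer used to relate
cortical dynamics to muscle recovery.

## Who it is for

Researchers analysing multichannel resting EEG (e.g. a 16-channel motor
montage) together with upper-limb surface EMG around an intervention such as
high-frequency rTMS over the affected primary motor cortex. Clinical
recordings of this kind are rarely shareable, so the package includes a
seeded simulator with planted ground truth and ships the clinical outcome
table of a 20-patient cohort as a plain-text fixture; the entire pipeline is
testable offline.

## The model in brief

* **Global field power** at time *t*:
  `GFP(t) = sqrt( sum_i (v_i(t) - vbar(t))^2 / n )` — the spatial SD of the
  potential map. Maps at GFP peaks are the clustering input.
* **Modified K-means** (polarity invariant): maps are assigned to the centre
  maximising squared spatial correlation; centres are updated as the
  dominant eigenvector of the assigned maps' cross-product matrix; the best
  of `n_restarts` seeded restarts by GFP²-weighted global explained variance
  (GEV) is kept.
* **Backfitting**: every sample is labelled with the template of highest
  |spatial correlation|; per class the pipeline reports mean duration (ms),
  coverage (%), and occurrence (1/s), satisfying
  `coverage = occurrence x duration / 10` exactly under the default
  run-counting policy.
* **EMG features**: `PTP = max(x) - min(x)`, `RMS = sqrt(mean(x^2))`, per
  2-s epoch, averaged.
* **Statistics**: paired/independent t, exact Wilcoxon signed-rank (n ≤ 25),
  mixed two-way ANOVA (group × class) with partial η² and simple effects,
  Bonferroni / Benjamini–Hochberg correction, and change-score Pearson
  correlation matrices (microstate parameter × muscle).

## Worked example

```r
library(msrehab)

# clinical outcomes of the embedded cohort
clinical_outcomes(clinical_scores())
#> # A tibble: 2 x 8
#>   outcome pre_mean pre_sd post_mean post_sd statistic    df  p_value
#> 1 fma_ue      31.5   22.0      33.6    21.9      4.36    19 0.000340
#> 2 arat        26.3   24.0      27.2    24.6      2.83    19 0.0108

# simulate EEG with a planted 5-class microstate sequence and recover it
tm  <- make_templates(16, 5, seed = 1)
sim <- simulate_eeg(tm, class_rates = rep(1, 5), mean_dwell_ms = rep(80, 5),
                    snr_db = 10, fs = 500, duration_s = 120, seed = 2)
ep    <- epoch_recording(common_average_reference(sim$recording), 2)
model <- label_classes(modified_kmeans(gfp_peak_maps(ep), K = 5,
                                       n_restarts = 20, seed = 3), tm)
microstate_parameters(backfit(ep, model), min_duration_ms = 16)
#> # A tibble: 5 x 5
#>   class mean_duration_ms coverage_pct occurrence_per_s n_runs
#> 1 A                 82.7         20.0             2.42    291
#> 2 B                 83.9         19.6             2.33    280
#> 3 C                 85.6         21.0             2.45    294
#> 4 D                 91.4         21.1             2.31    277
#> 5 E                 86.8         18.3             2.11    253
```

Here the five planted classes had equal rates and 80 ms mean dwells; the
realised (planted) path of this seed had coverages 18.4–21.1% and 2.2–2.6
runs/s per class, and the recovered parameters above match it to within a
fraction of a percentage point in coverage and a few percent in occurrence. `autoplot(model)`, `plot_parameters()`,
and `plot_correlation_matrix()` visualise templates, parameters and
change-score correlations; `cmd_simulate()` / `cmd_analyze()` run the whole
chain file-to-file from a validated `pipeline_config()`.

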