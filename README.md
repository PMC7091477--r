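# polyquant

Quantitative analysis of how fibrillar α-synuclein polymorphs bind, cluster,
diffuse and perturb network activity on cultured neurons.

Distinct fibrillar α-synuclein polymorphs (fibrils, ribbons, fibrils-91, …)
differ in how they decorate the neuronal plasma membrane, how their bound
molecules move, how they are endocytosed, and how they depress network
firing. Measuring those differences takes four quantitative pipelines that
are usually scattered across ad-hoc scripts. polyquant packages all four,
each with a synthetic-data generator carrying exact ground truth, so every
stage is testable end to end without access to raw microscopy or
electrophysiology recordings:

* **SMLM cluster analysis** — blink correction of localization tables,
  from-scratch DBSCAN at the *20 detections within 20 nm* density threshold,
  per-cluster convex-hull areas, field-level density / clustered-fraction
  metrics, and Gaussian rendering (10 nm kernel on a 10 nm grid).
* **Diffusive-state HMM for single-particle tracking** — a conjugate
  variational-Bayes hidden Markov model over displacement sequences
  (per-state emission `Δx, Δy ~ N(0, 2·D·dt)`, `dt = 20 ms`), priors
  centred on D = 0.1 µm²/s and a 50-frame (1000 ms) dwell, and model
  selection over K ∈ {1, 2, 3} by maximal evidence. Reports per-state D,
  dwell time `1000·dt/(1 − A_kk)` ms and occupancy.
* **Wavelet puncta quantification** — à-trous B3-spline segmentation,
  per-structure and per-field intensity/density/percent-area metrics,
  overlap-based colocalization, and surface-vs-internalized (endocytosis)
  classification of dual-labelled spots.
* **MEA network activity** — zero-phase 300 Hz high-pass filtering, ±6 SD
  spike detection with robust noise estimation, firing rates over 10-min
  sessions with the strict < 0.1 Hz channel discard, and control-normalised
  DIV14 → DIV21 network-rate change.

A config-driven runner (`run_pipeline()`), format readers/writers
(localization/trajectory CSV, 16/32-bit TIFF, int16 binary + JSON MEA
recordings) and a Mann-Whitney utility tie the stages together. Results are
tibbles with `tidy()` / `glance()` / `autoplot()` methods throughout.

## Worked example

Simulate a clustered localization field, blink-correct and cluster it, then
infer diffusive states from switching trajectories:

```r
library(polyquant)

sim  <- simulate_smlm_field(n_clusters = 8, detections_per_cluster_mean = 100,
                            cluster_radius_nm = 20, background_density_per_um2 = 1,
                            localization_sigma_nm = 10, seed = 7)
locs <- merge_consecutive_detections(sim$localizations)
cl   <- dbscan_cluster(locs, eps_nm = 20, min_pts = 20)
cl
#> <smlm_clusters> 656 localizations, 8 clusters, 159 noise (eps 20 nm, minPts 20)
glance(cl)
#> # A tibble: 1 × 6
#>   n_localizations n_clusters detections_per_um2 fraction_in_clusters ...
#> 1             656          8               6.56                0.758
```

All 8 simulated nanoclusters are recovered; 75.8% of detections fall inside
clusters (the rest are the simulated membrane background), at an overall
density of 6.56 detections/µm².

```r
A   <- matrix(0.01, 3, 3); diag(A) <- 0.98          # mean dwell 50 frames
spt <- simulate_trajectories(3000, 10, c(0.01, 0.1, 1.0), A,
                             dt_s = 0.02, seed = 7)
ds  <- displacements(spt$trajectories, dt_s = 0.02)
sel <- select_model(ds, seed = 7)                    # K chosen by evidence
sel
#> <hmm_selection> best K = 3
#> # A tibble: 3 × 3
#>       K evidence converged
#> 1     1   41283. TRUE
#> 2     2   67903. TRUE
#> 3     3   75811. TRUE
state_metrics(sel$best)
#> # A tibble: 3 × 6
#>   state D_um2_s dwell_time_ms dwell_infinite occupancy occupancy_stationary
#> 1     1 0.00989         1015. FALSE              0.340                0.326
#> 2     2 0.0990          1159. FALSE              0.324                0.352
#> 3     3 0.995           1061. FALSE              0.336                0.322
```

The evidence criterion picks three states, and the estimated diffusion
coefficients (0.0099, 0.099, 0.99 µm²/s), dwell times (~1000 ms) and
occupancies (~1/3 each) match the generating parameters.

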