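---
title: "Methods: models, estimators and design choices in polyquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in polyquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyquant)
```

polyquant reimplements, as reusable and tested functions, the four
quantitative readouts used to characterise how fibrillar alpha-synuclein
polymorphs behave on cultured neurons: nanoscale cluster analysis of
single-molecule localization (STORM-type) data, hidden-Markov inference of
diffusive states from single-particle trajectories, wavelet-based puncta
quantification of two-colour fluorescence images, and multielectrode-array
(MEA) network-activity analysis. Because no raw recordings accompany the
source study, every stage is paired with a synthetic-data generator with
exact ground truth; all empirical claims below are the ones the package's
own test suite and acceptance script compute.

## Single-molecule cluster analysis

A localization table is a tibble of `(frame, x, y)` detections in
nanometres. Two preprocessing conventions matter:

* **Blink correction.** A fluorophore that stays on across frames is
  detected repeatedly. `merge_consecutive_detections()` collapses chains of
  detections in consecutive frames (default `max_frame_gap = 1`, i.e.
  strictly consecutive) within `merge_radius_nm = 20` nm of the running
  chain centroid — twice the nominal 10 nm pointing accuracy — into a single
  localization at the chain centroid. Neither radius nor gap has a canonical
  value in the field; both are parameters, and the chaining pass iterates to
  a fixed point so the operation is idempotent. Detections in the same frame
  are simultaneous and never merged.
* **Clustering.** `dbscan_cluster()` is a from-scratch DBSCAN with the
  density threshold of a minimum of 20 detections within a radial distance
  of 20 nm. `min_pts` counts the point itself, the common DBSCAN
  formulation. Output is made deterministic by scanning points in
  `(frame, x, y)` order and assigning border points to the lowest-id
  reachable cluster; the test suite asserts exact partition equality with a
  brute-force O(n^2) oracle across 50 random fields and invariance to input
  row order. Neighbour search uses an eps-sized grid index, with the
  contract that results are identical to brute force.

Per-cluster area is the convex hull of member localizations (shoelace
formula). The hull is one of several defensible area estimators; it was
chosen because the downstream comparisons only need a consistent one.
Collinear clusters get area 0 and a degeneracy flag. Field-level metrics
(`cluster_metrics()`) are detections per square micrometre, the fraction of
detections inside clusters, and cluster-area summaries; the density
denominator is the full field area by default.

`render_storm()` renders localizations with unit-mass Gaussian kernels
(10 nm sd on a 10 nm grid by default), so total image mass equals the number
of localizations up to edge truncation.

The SMLM generator places a deterministic
`round(detections_per_cluster_mean / blink_repeat_mean)` emitters uniformly
in discs around uniform cluster centres (so the dense-cluster study
condition — on the order of 100 detections within a ~20 nm-radius cluster —
holds by construction), plus a Poisson background; each emitter blinks for a
geometric number (mean 2) of consecutive frames, and detections carry
isotropic Gaussian localization error (default sd 10 nm, matching the
nominal pointing accuracy; the true precision distribution of the original
acquisitions is unknown, so it is a parameter, not an assertion). The
recovery conditions used by the tests — 10 clusters of ~100 detections in
20 nm discs, 1 background emitter/um^2 — give exact cluster-count recovery
and >99% detection recall.

## Diffusive-state HMM for single-particle tracking

`displacements()` turns trajectories (20 ms frame interval, i.e. 50 Hz, by
default) into per-trajectory displacement sequences, splitting at frame gaps
and dropping trajectories shorter than two positions. Only displacement
vectors between successive time points enter the model.

The model: a hidden Markov chain with K in {1, 2, 3} diffusive states; given
state k, the x and y components of a displacement are independent
Gaussian(0, s_k) with s_k = 2 D_k dt. Inference is variational Bayes with
conjugate factors: inverse-gamma on each s_k, Dirichlet on each transition
row and on the initial distribution. The evidence lower bound is the scaled
forward-pass log-likelihood under the digamma-tilted parameters minus the KL
divergence of each factor from its prior — the standard conjugate VB-HMM
construction — and is provably non-decreasing across iterations, which the
tests assert for every fit. The source study used a modified external
VB-HMM tool whose exact update equations are not published; the package
derives the standard updates for this emission family, and its acceptance
surface is parameter and model-order recovery on simulations rather than
numeric equality to that tool.

Priors encode the study's stated values: prior D = 0.1 um^2/s and prior
dwell = 50 frames (1000 ms at 20 ms). The inverse-gamma prior carries one
pseudo-observation at `s0 = 2 * 0.1 * dt`; each Dirichlet row carries
`50 - 1` self-transition pseudocounts and a total off-diagonal pseudocount
of 1 split evenly. For K = 1 the chain has no free transition or initial
parameters, so those KL terms are exactly zero — the correct evidence for
the one-state model.

Numerical choices: responsibilities are initialised from a randomised
k-means split of log squared displacements; 10 restarts are run for ~25
iterations each and the best bound is continued to convergence
(tolerance 1e-6 nats per displacement, cap 500 iterations). States are
canonically ordered by D, making output invariant to restart permutation.
Degenerate all-zero data floors D at 1e-12 with a flag. Localization error
is excluded from the emission variance by default (the generator's
localization-noise option exists for robustness experiments).

`select_model()` fits each candidate K and keeps the largest evidence bound;
ties within 0.1 nat go to the smaller K (parsimony). Reported per-state
metrics are D, dwell time `1000 dt / (1 - A_kk)` ms, and occupancy. Whether
occupancy should be posterior probability mass over steps or the stationary
distribution of the fitted chain is ambiguous in the source description;
both are reported (`occupancy`, `occupancy_stationary`), with posterior mass
the default, and on simulated data they agree to within sampling error.

At the study-scale conditions (5000 trajectories of 10 steps, D = 0.01,
0.1, 1.0 um^2/s, dwell 50 frames) the acceptance tests recover every D
within 20%, occupancies within 0.05 and dwell times within 25% on each of 20
seeds, and the evidence criterion selects the generating K in at least 16/20
(three-state) and 18/20 (one-state) seeds. The one-state fit agrees with the
closed-form estimator `mean(|dr|^2) / (4 dt)` to within the prior-induced
shrinkage (~1e-5 relative at n = 1e5).

## Wavelet puncta quantification

`wavelet_segment()` implements the undecimated a-trous transform with the
B3-spline kernel `(1, 4, 6, 4, 1)/16` and mirror boundaries; the detection
plane is scale 2 (~4 px structures), thresholded at `k = 3` robust noise
standard deviations (median absolute deviation of the plane / 0.6745), with
8-connected components smaller than 4 px removed. The cited origin of the
method gives no parameter values; these are standard multiscale
spot-detection practice, all configurable, and the tests are recovery-based
rather than parameter-matching. Per-structure intensity sums the *original*
image under the mask (background-free mask, unsubtracted intensities), and
`structure_metrics()` reports mean intensity per cluster, clusters per um^2,
summed intensity and percent field area. Matrices use R's native 1-based
`(row, col)` indexing, origin top-left. `as_structure_mask()` ingests
pre-thresholded binary masks from other tools.

Colocalization follows the overlap definition: an A structure is colocalized
when it shares at least one pixel with a B structure (a 1-pixel criterion;
an opt-in apposition mode also accepts centroid distances <= 2 px).
`classify_endocytosed()` applies the surface-labelling logic: green
structures overlapping red (surface-restricted) structures are at the
membrane, green-only structures are endocytosed.

The image generator draws Gaussian puncta (sd 1.5 px) on Poisson background
with a controlled fraction of channel-A puncta sharing centres (within 1 px)
with channel-B puncta; non-paired centres are kept >= 5 psf sigma from the
other channel and >= 4 sigma within a channel so that true overlap is
unambiguous at these densities. At 100 puncta per 256x256 field with peak
SNR ~9.5 (amplitude 30 on background 10), segmentation detects >= 95% of
true puncta with <= 5 spurious structures and recovers the generator's
overlap fraction within 0.05.

What the generator does not emulate: spatially varying background (cell
autofluorescence), aggregate shape heterogeneity, chromatic misregistration,
and blur anisotropy. Passing recovery tests therefore demonstrates estimator
correctness under the stated point-source model, not robustness to every
real-image artefact; the threshold and scale parameters exist precisely
because real data need them tuned.

## MEA network activity

`highpass_filter()` is a 4th-order Butterworth high-pass (300 Hz default at
10 kHz sampling) applied forward and backward for zero phase; traces are
extended by odd reflection and cropped so startup transients stay out of the
data (a constant trace maps to zero at machine precision, a 1 Hz sinusoid is
attenuated below 1% RMS, a 1 kHz sinusoid passes within 5%). The filter core
is a small compiled direct-form-II kernel. `detect_spikes()` thresholds
|signal| at 6 noise standard deviations; the noise sd is robust
(median(|x|)/0.6745) by default because spikes inflate the plain standard
deviation — the original description says only "standard deviations", so the
plain estimator is available as a mode. Event time is the peak-|amplitude|
sample of each crossing, with a 1 ms dead time merging both lobes of one
biphasic waveform.

`channel_rates()` computes spike count / 600 s (10-min sessions); channels
below 0.1 Hz are flagged nonspiking and excluded from the network mean, with
the boundary kept strict (< 0.1 discarded, exactly 0.1 kept).
`normalized_change()` forms per-plate ratios `rate(DIV21) / rate(DIV14)`
normalised by the mean control-plate ratio, so control plates average 1 by
construction — the exact normalisation formula behind the published axis is
unstated, and this ratio-based, control-anchored choice is recorded in the
output.

The generator adds a biphasic template (peak 12 noise sd in the end-to-end
conditions) at homogeneous-Poisson times onto white Gaussian noise;
overlapping spikes superpose linearly and both remain in the ground truth.
White noise is a simplification — real extracellular noise is band-limited
and spike amplitudes vary per unit — so the detection-sensitivity results
bound performance under ideal noise only. Across 60 channels at rates
0.05-5 Hz for 10 minutes, detection sensitivity exceeds 95% with a
false-positive rate below 0.1 Hz per channel, noise-only channels yield at
most 2 detections (the Gaussian tail expectation at +/-6 sd is far below
one event per 10 minutes), and every channel with true rate < 0.1 Hz is
discarded.

## Orchestration, statistics and reproducibility

`run_pipeline()` executes a validated YAML/list config: unknown keys, stages
or parameters are rejected before any stage runs; stage i derives its seed
as `seed + i`; outputs are accompanied by the resolved config and a
provenance record; metric files carry no timestamps, so identical seed and
config reproduce them byte for byte. `mann_whitney()` wraps the two-sided
Wilcoxon rank-sum test (exact for min(n) <= 8 without ties, tie-corrected
normal approximation otherwise), matching the pairwise nonparametric
comparisons used throughout the source study; no multiple-comparison
correction is applied, mirroring that usage. Every simulator takes an
explicit seed and restores the session RNG state on exit.

Problem sizes in the test suite and acceptance script (50 oracle fields,
25-50 SMLM fields, 10-20 seeds per HMM grid, 10-20 image fields, 60 MEA
channels) were chosen as the smallest sizes at which the distributional
tolerances above (3 standard errors for distributional oracles, the stated
recovery bands otherwise) are meaningful.

## Known limitations

* Clustering and rendering are 2-D; no drift correction, Ripley-type
  statistics, or 3-D support.
* The HMM pools all trajectories into one model (no per-trajectory
  heterogeneity) and assumes pure Brownian states; anomalous diffusion is
  out of scope. Trajectory linking from raw localizations is not performed.
* Segmentation operates on single 2-D planes; no deconvolution and no
  synapse-marker semantics.
* MEA analysis stops at firing rates: no spike sorting, burst or synchrony
  metrics.
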