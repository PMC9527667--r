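---
title: "Methods: time-resolved seizure network analysis with ictalnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-resolved seizure network analysis with ictalnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question and the analysis model

Focal seizures share a localized cortical onset yet diverge sharply in
their evolution: some stay within one hemisphere, others generalize
across the corpus callosum into bilateral tonic-clonic activity, with far
worse clinical consequences. ictalnet implements a time-resolved
graph-theoretic analysis designed to ask whether functional brain
networks carry signatures of that divergence — both *before* onset (can
an impending seizure's propagation type be anticipated?) and *after*
(do the two types reorganize the network differently?).

The unit of analysis is a 25-min segment of multichannel intracranial
ECoG: 15 min pre-onset and 10 min post-onset at 500 Hz (for interictal
control segments a pseudo-onset is placed at the same 900-s mark).
Electrodes are network nodes; the edge weight between two channels in a
given time window is their Pearson correlation, negative values set to
zero, so edges measure instantaneous functional coupling on a 0-to-1
scale. Seven weighted graph statistics summarize each network, and the
scientific claims are statements about differences in their time courses
across seizure types, assessed by seizure-level resampling.

## Pipeline stages and the choices behind them

### Preprocessing

* **Band-pass 1–70 Hz + 60 Hz notch.** The filter family is a 4th-order
  Butterworth band-pass and a quality-factor-30 biquad notch, both
  applied zero-phase. Zero-phase application matters because the entire
  downstream analysis is built on inter-channel correlations, which
  phase-shifting filters would distort. Implementation note: the
  zero-phase (forward–backward) response |H(ω)|² is applied in the
  frequency domain with reflection padding; this is numerically
  equivalent to time-domain forward–backward filtering away from the
  segment edges (the suite verifies agreement with `signal::filtfilt`)
  and considerably faster on 750,000-sample channels.
* **AR(1) prewhitening.** Per channel over the full segment, φ is the
  lag-1 autocorrelation of the mean-removed signal (Yule–Walker at lag
  1) and the channel is replaced by its innovations x_t − φ x_{t−1}.
  This removes slow shared dynamics that would otherwise inflate every
  pairwise correlation. The first sample is dropped and the tail padded
  by repeating the final value so that all channels keep exactly
  750,000 samples and the window count below stays exact. Zero-variance
  channels get φ = 0 and a warning rather than an error.
* **Scope.** Prewhitening is applied after filtering and per segment,
  not globally; re-referencing is out of scope (inputs are assumed
  already common-referenced, as the synthetic data are by construction).

### Connectivity

Windows of 1 s advanced by 0.5 s give
`n_raw = floor((T − 1)/0.5) + 1 = 2999` correlation matrices for a
1500-s segment; element-wise averaging of 30-s spans advanced by 15 s
gives `n_smoothed = floor((2999 − 60)/30) + 1 = 98` networks. This
30/15-s smoothing geometry is the unique simple overlapping scheme that
yields exactly 98 windows, and the 15-s stride matches the 0.25-min
granularity at which significant intervals are reported. Each smoothed
window is stamped with its first raw window's start time;
onset-relative time is `start − 900 s`, and reported intervals are
`[first significant start, last significant start + 0.25 min]`.

Rectification (negative weights to zero) is applied after smoothing by
default, following the processing order the analysis was designed
around; a `rectify_stage = "raw"` switch rectifies before smoothing
instead. A channel with zero variance inside a window has its
correlations set to zero for that window and the event is counted in the
series' log field. Diagonals are forced to zero: self-loops are
meaningless for all seven statistics.

### Graph statistics

Definitions are in the README table. Non-obvious choices:

* **Path length** maps weights to lengths by l = 1/w (strong coupling =
  short distance) and averages over connected pairs only, reporting the
  number of excluded (disconnected) pairs as an attribute; an entirely
  disconnected network yields an `NA` marker rather than an error so
  degenerate windows propagate visibly through a metric series.
* **Clustering** uses the cube-root (Onnela) triangle intensity on raw
  weights without max-weight rescaling — weights are already bounded in
  [0, 1] by construction.
* **Assortativity** correlates endpoint *strengths* over edges, each
  undirected edge counted in both orientations; regular graphs (zero
  endpoint variance) give `NA`.
* **Modularity** is Newman's spectral method: leading eigenvector of
  B = A − γ k kᵀ/2m (weighted k and m), recursive bisection with a
  Kernighan–Lin-style single-node fine-tuning sweep, stopping when no
  split raises Q; γ = 1. Determinism is pinned down by two tie-break
  rules: eigenvector entries within 1e−12 of zero join the positive
  group, and the fine-tuning sweep visits nodes in index order. The
  returned Q is always evaluated with the closed-form modularity
  equation on the returned partition (the suite enforces
  equation-consistency and Q ≥ 0; the spectral method is a heuristic,
  so global optimality is not claimed).
* **Synchronizability** clamps the second-smallest Laplacian eigenvalue
  at zero before the ratio, absorbing eigen-solver roundoff on
  disconnected networks.

### Group statistics

For each metric and each of the 98 time points:

* **Bootstrap (B = 10000).** Whole segments (rows) are resampled with
  replacement independently within each condition; the difference of
  resampled condition means forms the difference distribution, with a
  2.5/97.5 percentile CI.
* **Permutation null (B = 10000).** Condition labels are shuffled over
  the pooled segments, preserving group sizes, and the group-mean
  difference recomputed per shuffle; nulls are centred at zero.
* **p-values.** Two one-tailed tests against zero, doubled, capped at 1
  and floored at 1/B (0.0001 at the default B — the resolution of the
  resampling scheme). Two estimates are computed: the wrong-side mass of
  the bootstrap difference distribution (`p_boot`) and the position of
  the observed mean difference in the permutation null (`p_null`); the
  null-based estimate is primary (`p`), the bootstrap-based one is
  reported alongside as a cross-check. The floor is applied after
  doubling so the reportable minimum is exactly 1/B.
* **No correction across time points.** Significance is per-time-point
  ("resampled p < 0.05"), as is conventional for this interval-style
  reporting; outputs say so explicitly. Interpret isolated significant
  windows with corresponding caution.
* **Effect sizes.** Cohen's d is computed on the bootstrapped
  distributions of condition means, d = (mean_A − mean_B)/s_pooled.
  Because those distributions have spread ≈ s/√n, this estimator scales
  like √n times the classical per-observation d — documented here and in
  the README; it is a within-analysis comparison device, not a
  population effect size. Within each maximal run of consecutive
  significant windows, d_min is the smallest |d|, with a percentile CI
  of the per-iteration d at that window (the only distribution available
  at that locus).
* **Windowed ANOVA.** Five-minute means (Preictal I–III, ictal,
  postictal; half-open bins, a window starting exactly at onset is
  ictal) feed a two-way repeated-measures ANOVA. Time window is the
  within-unit factor; seizure type is a between-unit grouping factor —
  each segment has exactly one type, so type cannot be within-subject at
  the segment level. Type-III sums of squares accommodate the unbalanced
  group sizes (49/18/67); sphericity-assumed univariate F tests are
  reported, and all-constant input (zero effect and error SS) reports
  F = 0 rather than 0/0. Post-hoc paired two-tailed t-tests compare
  window pairs within condition.

## The synthetic generator

Real intracranial recordings of this kind are not publicly depositable,
so the generator is a first-class module: it produces the three study
conditions at the study's geometry (49 focal / 18 bilateral / 67
interictal 25-min segments, 500 Hz, onset at 900 s) with a ground-truth
sidecar for every segment.

**Signal model.** Channels are partitioned into communities (default 4),
each confined to one hemisphere. Community k's shared signal is the
mixture `w_k(t)·f_k(t) + b(t)·g(t)` of a community latent f_k and a
global latent g — both band-limited 4–30 Hz Gaussian noise, inside the
1–70 Hz analysis band so preprocessing cannot remove the injected
structure — normalized pointwise to unit variance and scaled by a
synchrony amplitude A_k(t); each channel adds independent Gaussian noise
of amplitude σ (default 1, giving baseline same-community correlation
1/(1+σ²) = 0.5). A latent-factor model was chosen over biophysical
neural-mass models deliberately: the pipeline consumes only second-order
statistics, so controllable correlation structure is the requirement and
testability the payoff.

**Why mixing and amplitude are separate dials.** The mixing gains (w, b)
set the *pattern* of correlation — community structure versus global
coupling — at fixed overall correlation level; the amplitude sets the
*level*. An earlier design that normalized each channel's variance over
the whole segment let post-onset amplitude boosts leak backwards into
pre-onset correlation levels (segments with larger seizures were
globally downscaled), biasing pre-onset spectral radius downward for the
bilateral class even with no injected signature. Pointwise
normalization removes that artifact: with zero injection, pre-onset data
are identically distributed across conditions by construction, which the
type-I control in the acceptance suite verifies.

**Condition schedules** (piecewise linear, 2-s ramps):

* *interictal*: constant gains and amplitude — no event at all;
* *focal*: at onset, the onset community's amplitude rises by
  `post_sync_boost` (default 1.5×baseline increment); contralateral
  communities never change (hemisphere confinement, tested);
* *bilateral*: onset-hemisphere communities' amplitudes rise at onset,
  contralateral ones after `spread_delay` (default 30 s), and the
  between-mixing gain rises by `post_between_boost` — transcallosal
  hypersynchrony. This reproduces the post-onset phenomenology (higher
  density and clustering, shorter path length for the bilateral class)
  as emergent behaviour rather than direct injection;
* *pre-onset signature* (bilateral only, magnitude m): within-mixing
  ×(1+m), between-mixing ×(1−m) from segment start to onset, at
  unchanged amplitude — sharper segregation and weaker global coupling,
  i.e. higher modularity and lower spectral radius. The magnitude is a
  free simulation parameter: no quantitative raw-signal account of the
  pre-onset effect exists to calibrate against, so recovery tests check
  direction, not magnitude, and use m = 0.5 as "well above the noise
  floor".

**Reproducibility.** A cohort is a pure function of its spec: sub-seeds
are derived deterministically from (master seed, segment index), every
RNG use is seeded, and the previous RNG state is restored afterwards.
Fixed-seed reruns of the full pipeline are byte-identical, which the
suite checks at the file level.

**What the generator does not emulate** — and hence what passing tests
do and do not show: no seizure waveform morphology (spikes, DC shifts,
chirps), no volume conduction or shared-reference artifacts, no
electrode geometry or patient-level covariates, and stationary Gaussian
statistics within schedule phases. Recovery of injected signatures
demonstrates that the pipeline measures what it claims on data with
known ground truth; it is not evidence about patient physiology.

## Numerical choices and degenerate inputs

* FFT-based zero-phase filtering uses reflection padding (5000 samples)
  and highly composite FFT lengths; accuracy vs `filtfilt` is ~1e−8
  absolute on unit-variance signals, far below the channel noise floor.
* Sliding correlations use an exact block decomposition (per-block sums
  and cross-products) when the window is an integer multiple of the
  step, verified against per-window `cor()` to 1e−10.
* Zero-variance windows, empty networks, disconnected pairs and regular
  graphs all produce explicit `NA` markers or logged warnings, never
  silent drops; bootstrap means skip `NA` per column.
* Degenerate ANOVA input (all values identical) reports F = 0, p = 1.
* Eigen-solver roundoff: λ₂ clamped at 0; correlations clipped to
  [−1, 1] before the diagonal is zeroed.

## Problem sizes used by the test suite

Module tests run on short (2-min) segments and small panels chosen to
exercise every code path quickly. The acceptance checks use: one full
25-min, 500-Hz segment for the 2999/98 window-count identity; an
exhaustive oracle sweep over all weighted graphs on 2–4 nodes with
weights in {0, 0.3, 1} plus 2500-graph seeded subsamples at 5 and 6
nodes (full enumeration at 6 nodes would be 3^15 ≈ 14M graphs); 500
replicate no-effect cohorts at B = 1000 for type-I calibration; and a
full-scale 49/18/67 cohort at 8 channels — channel count is the one
dimension reduced, since the graph statistics are defined at any N —
for signature recovery with B = 10000.

## Known limitations

* The Cohen's d convention (on bootstrap mean distributions) is not
  comparable across sample sizes; see above.
* Per-time-point significance without multiplicity correction inflates
  the family-wise rate over 98 windows; the zero-injection control
  bounds the directional per-window rate, not the family-wise one.
* The spectral modularity heuristic can return locally optimal
  partitions; only equation-consistency of Q is guaranteed.
* EDF support covers the subset of EDF+C this package writes (16-bit,
  1-s records, one annotation channel), not arbitrary EDF files.
* Nodes are channels by default; `group_regions()` offers the averaged
  channel-to-region alternative but the pipeline driver does not expose
  a region map — apply it between the connectivity and metrics stages.
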