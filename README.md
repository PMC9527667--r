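# ictalnet

Time-resolved functional-connectivity network analysis of multichannel
intracranial recordings, built for studying how focal seizures that stay
within one hemisphere differ from focal seizures that spread bilaterally
(focal-to-bilateral tonic-clonic), before and after seizure onset. The
intended users are epilepsy researchers and methods developers who want a
tested, scriptable version of the sliding-window graph-theoretic workflow
— and, because clinical intracranial recordings are rarely shareable, the
package ships a seeded synthetic ECoG generator so every stage can be run,
tested and benchmarked without any patient data.

## What it computes

**Connectivity.** A 25-min segment (15 min pre-onset, 10 min post-onset,
500 Hz) is band-pass filtered 1–70 Hz with a 60 Hz notch (zero-phase),
prewhitened per channel with a first-order autoregressive model
(x_t ← x_t − φ x_{t−1}, φ the lag-1 autocorrelation), and cut into 1-s
windows overlapping by 0.5 s. Each window yields the matrix of pairwise
Pearson correlations A_ij; consecutive 30-s spans advanced by 15 s are
averaged, giving 98 smoothed networks per segment (2999 raw windows),
and negative weights are set to zero.

**Graph statistics.** Seven weighted measures per network A (N nodes,
strength k_i, total weight 2m):

| measure | definition |
|---|---|
| density | Σ_{i<j} A_ij / [N(N−1)/2] |
| clustering coefficient | mean_i Σ_{jh}(A_ij A_ih A_jh)^{1/3} / [k_i(k_i−1)], binary degree k |
| characteristic path length | mean shortest-path distance, edge length 1/A_ij |
| assortativity | Pearson correlation of endpoint strengths over edges |
| modularity Q | (1/2m) Σ_ij (A_ij − γ k_i k_j / 2m) δ(c_i,c_j), γ = 1, Newman leading-eigenvector partition |
| spectral radius | λ_max(A) |
| synchronizability | λ₂(L)/λ_max(L), L = D − A |

**Group statistics.** For each metric and time point, segments are
resampled with replacement at the seizure level (B = 10000) within each
condition; the difference of bootstrapped condition means gives a 95%
percentile CI and, against a shuffled-label permutation null, a doubled
one-tailed p-value floored at 1/B (0.0001). Runs of p < 0.05 are reported
as onset-relative intervals with Cohen's d per time point and the smallest
|d| (d_min) inside each significant run. Five-minute windowed averages
feed a two-way repeated-measures ANOVA (condition × window, type-III) with
paired post-hoc t-tests.

## Worked example

Simulate a small two-condition cohort with the pre-onset signature
injected into the bilateral class (sharper community structure, weaker
global coupling before onset), run the full pipeline, and look at the
bilateral-vs-focal contrasts:

```r
library(ictalnet)

spec <- cohort_spec(n_focal = 6, n_bilateral = 4, n_interictal = 0,
                    n_channels = 8, segment_length = 300, onset_offset = 180,
                    seed = 11)
sch  <- coupling_schedule(preictal_magnitude = 0.5)
cfg  <- run_config(spec, sch, boot_B = 2000, perm_B = 2000)
res  <- run_pipeline(cfg)

res$comparisons[["modularity_bilateral_vs_focal"]]
#> <group_comparison> bilateral vs focal | 18 time points | B = 2000
#>   significant (p < 0.05 ) intervals (min rel. onset):
#>     -3.00 to 0.00
#>     0.25 to 1.50
#>   Cohen's d_min = 17.21 at -1.00 min, 95% CI (14.85, 20.23)

res$comparisons[["spectral_radius_bilateral_vs_focal"]]
#> <group_comparison> bilateral vs focal | 18 time points | B = 2000
#>   significant (p < 0.05 ) intervals (min rel. onset):
#>     -3.00 to 1.50
#>   Cohen's d_min = 8.36 at 0.00 min, 95% CI (5.57, 11.06)
```

Reading this: modularity of the bilateral class is significantly *higher*
than the focal class across the pre-onset minutes (positive mean
difference, intervals in minutes relative to onset), and its spectral
radius significantly *lower* — the injected pre-onset signature recovered
by the pipeline. Cohen's d here is computed on the bootstrapped
distributions of condition means, so its magnitude grows with the number
of seizures (≈ √n times the per-seizure d); compare d values only across
time points of the same comparison. `run_pipeline()` also writes
`metrics.csv` (per-segment metric time series), `comparisons.json`,
windowed summaries with the ANOVA table, and optional figure PDFs to
`cfg$outdir`, each stamped with the config hash and seed.

At study scale the same call takes `cohort_spec()` defaults: 49 focal, 18
bilateral and 67 interictal 25-min segments at 500 Hz, 98 smoothed
networks each, with the three pairwise contrasts run for all seven
metrics.

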