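# cmetracks

Unsupervised analysis of clathrin-mediated endocytosis (CME) dynamics from
multi-channel fluorescence particle tracks.

## The problem

In live mammalian cells, CME sites are tracked as diffraction-limited spots
in up to three channels: AP2 (the coat), DNM2 (dynamin-2, whose fluorescence
maximum marks vesicle scission), and ARPC3 or N-WASP (branched actin).
Deciding *which* tracked spots are productive CME events, *when* each event
ends, and *whether and when* actin assembled at it — for thousands of events,
without hand-picking — is the analysis problem this package solves. It is
aimed at quantitative cell biologists working with single-particle tracking
output from TIRF movies of endogenously tagged cells.

The pipeline:

1. **Feature abstraction** — each event's AP2/DNM2 tracks become a fixed
   32-feature vector (brightness and positional dynamics), scaled
   per-feature by a rank-based quantile transform to N(0, 1):
   `z = Φ⁻¹((r − ½)/n)`.
2. **Clustering** — PCA (≥ 90% variance) followed by a full-covariance
   Gaussian mixture, K chosen by BIC over 2–8; events assigned by maximum
   posterior. The DNM2-positive population (detectable DNM2 throughout,
   long-lived, below visitor motility) is identified by a composite rank of
   per-cluster medians.
3. **Single-DNM2-peak selection** — burst counts are surveyed over grids of
   minimum peak height, width, and peak-to-peak distance; for each
   combination, single-peak lifetimes are fit to a Rayleigh distribution
   (MLE σ̂ = √(Σx²/2n)) and the combination minimizing the KS statistic is
   selected. The scission frame is the DNM2 argmax.
4. **Actin timing** — separately tracked third-channel tracks are linked to
   events (median separation ≤ 300 nm over ≥ 3 overlapping frames) and
   classified negative / early / late; a randomized-pairing control
   (events from one movie, actin tracks from another) measures the
   chance-overlap rate.
5. **Kinetics** — lifetimes (first AP2 frame → DNM2 peak), assembly
   durations, scission-aligned lifetime-cohort traces (error band = SD/4),
   inter-channel separations, lateral motility, straightness index
   (end-to-end / path length), Welch and Kolmogorov–Smirnov comparisons.

A first-class synthetic-data module (`simulateDataset()`) generates track
datasets with Rayleigh lifetimes, two-phase DNM2 recruitment, ~150 nm
laterally offset actin bursts, stalled-site AP2 plateaus, diffusing visitor
contaminants and stray actin tracks — with full ground truth, so every
stage has a parameter-recovery test.

## Worked example

```r
library(cmetracks)
res <- runPipeline(defaultConfig(seed = 1, nEvents = 400))

res$positiveFraction$fraction
#> 0.686  (95% CI 0.636–0.733, n = 341)

res$peakParams
#> PeakParams: minHeight 2 (noise_sd), minWidth 1 s, minDistance 3 s;
#>   Rayleigh sigma 24.33 s, KS gof 0.117

res$clusterSummaries
#>   cluster   n median_dnm2_sig_frac median_lifetime median_mean_step composite_rank
#> 1       1  58                0.222             6.5            127.8            3.0
#> 2       2 102                1.000            27.0             38.7            6.5
#> 3       3 240                1.000            39.0             37.7            8.5

print(res$cohorts)
#> CohortSummary: 4 cohort(s) over edges [ 10, 20, 40, 60, 120 ) s; 325 events
#>    cohort   n   percent
#>   [10,20)  52 16.000000
#>   [20,40) 186 57.230769
#>   [40,60)  76 23.384615
#>  [60,120)  11  3.384615

res$comparisons
#>                      comparison  statistic      p_value
#> 1     lifetime_pos_vs_neg_welch 7.92389428 1.548466e-13
#> 2 motility_before_pos_vs_neg_ks 0.08275421 6.960235e-01
```

Reading this output: the mixture resolved three clusters — one of
short-lived, highly motile visitor tracks (cluster 1, median DNM2
detectability 0.22) and two DNM2-positive CME clusters that differ in
lifetime (the stalled, actin-positive sub-population lives longer). About
69% of retained CME events are actin-positive, matching the generator's
conditions (70% of non-visitor events positive, minus linking losses).
Actin-positive events have significantly longer lifetimes (Welch
p ≈ 1.5e-13), the stalled-site signature. In the same run,
`res$separationVsMotility$fraction` is 0.996: virtually all actin-positive
events have scission-frame AP2–ARPC3 separations exceeding their own
frame-to-frame motility, so measured separations are not a motion artifact.

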