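---
title: "Unbiased kinetics of clathrin-mediated endocytosis from multi-channel particle tracks"
author: "cmetracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unbiased kinetics of clathrin-mediated endocytosis from multi-channel particle tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmetracks)
```

## The problem

Clathrin-mediated endocytosis (CME) internalizes membrane and cargo by
assembling a clathrin/adaptor coat (marked here by AP2), constricting and
severing the vesicle neck with dynamin-2 (DNM2), and — at a subset of sites —
recruiting the Arp2/3 complex (marked by ARPC3) to assemble a branched actin
network that supplies extra force. Live-cell TIRF imaging of endogenously
tagged cells yields thousands of tracked fluorescent spots per movie, but
most tracked objects are not productive CME events: transient clathrin
"visitor" structures diffuse through the evanescent field, nearby actin
structures overlap CME sites by chance, and some events contain multiple
DNM2 bursts. `cmetracks` implements an unbiased pipeline that (i) separates
bona-fide, DNM2-positive CME events from contaminants without manual
curation, (ii) retains only single-DNM2-peak events using a distributional
model-selection criterion, (iii) classifies branched-actin recruitment
timing with a randomization control, and (iv) computes the kinetic and
geometric statistics that distinguish stalled, actin-dependent sites from
unstalled ones.

The pipeline consumes per-event track tables (time, sub-pixel position,
fitted amplitude, and a per-frame detection-significance flag, per channel)
as produced by a spot-detection/tracking front end; tracking itself is out
of scope. A synthetic-data module emits the same table schema with full
ground truth, so every stage has a parameter-recovery test surface.

## Pipeline model and assumptions

**Feature abstraction.** Each event's AP2 and DNM2 traces are decomposed
into a fixed 32-feature vector covering brightness dynamics (per-channel
maximum and mean amplitude, time-fraction of the maximum, rise and decay
slopes, skewness, kurtosis, significant-frame fraction, local-maximum
count, plateau fraction, coefficient of variation), event timing (AP2
lifetime; DNM2-peak fraction in [0, 1]), AP2 positional dynamics (path
length, end-to-end distance, straightness, mean step, MSD log-log slope,
radius of gyration), the AP2–DNM2 amplitude correlation, and the post/pre
DNM2-maximum step ratio. The feature list is versioned
(`attr(features, "featureVersion")`) so runs are reproducible.

**Scaling.** Features live on wildly different scales (seconds, nanometres,
ratios), so each column is mapped through a rank-based quantile transform to
a standard normal (`qnorm((rank - 0.5) / n)`). This both normalizes scale
and bounds the influence of outliers: the most extreme value cannot map
beyond the (n − 0.5)/n normal quantile. The transform is monotone and is
stored, so held-out events can be scored against a trained run. A z-score
would preserve outlier leverage and is deliberately not used.

**Clustering.** Scaled features are projected by PCA, keeping the smallest
component set explaining ≥ 90% of variance (`varianceTarget`, tunable), and
clustered with a full-covariance Gaussian mixture. K is selected by BIC over
K = 2–8; the EM is initialized from model-based hierarchical agglomeration,
which is deterministic, so no random restarts are needed (the seed is still
recorded in the model). Events are assigned by maximum posterior, ties going
to the lowest component index. The DNM2-positive population is identified by
a composite rank over per-cluster medians — DNM2 significant-frame fraction
(high), lifetime (high), frame-to-frame step (low) — with a hard floor of
median DNM2 fraction ≥ 0.5. When the mixture resolves sub-populations of
bona-fide events (e.g. stalled vs unstalled sites differ in lifetime and
plateau shape), every cluster passing the floor is retained as DNM2-positive
(`dnm2Positive`); the composite rank still reports the single best cluster.
Composite-rank ties are resolved on the raw criteria, and only clusters
indistinguishable on all three stop the run for manual review.

**DNM2 peak selection.** Productive events end in a single DNM2 burst whose
maximum marks scission. Burst counting is governed by three parameters —
minimum height above the trace baseline (in units of the trace's robust
noise SD, so grids transfer across intensity scales), minimum full width at
half prominence, and minimum peak-to-peak distance. Traces are pre-smoothed
with a 3-frame centered moving average, which stabilizes width estimates at
1 s sampling. The parameter combination is not hand-picked: a grid survey
classifies every event as having 0, 1, or 2+ peaks, fits the single-peak
lifetime distribution to its expected form — a Rayleigh distribution, whose
scale has the closed-form MLE `sqrt(sum(x^2) / (2 n))` — and selects the
combination minimizing the one-sample Kolmogorov–Smirnov statistic.
Combinations yielding < 20 single-peak events are skipped; ties go to the
lexicographically smallest parameter tuple; the full survey table is
retained so the selection can be re-done under any other metric.

**Actin timing.** Third-channel (ARPC3 or N-WASP — same code path) tracks
are tracked separately and linked to events when ≥ 3 time-overlapping
frames have median separation ≤ 300 nm. The 300 nm default deliberately
exceeds the ~150 nm true lateral actin offset plus positional noise. Each
track links to at most one event (nearest median separation wins) and each
event keeps at most one track. The third-channel onset is the first frame
of ≥ 3 consecutive frames above 3 robust noise SDs; an event is `early`
when the onset falls in the first half of its lifetime *and* more than 20 s
before scission, `late` otherwise, and `negative` when nothing links, the
linked track has no sustained signal, or its onset falls at/after scission
(actin appearing only after completion is not assembly during vesicle
formation, and this keeps assembly durations non-negative by construction).

**Statistics.** Event lifetime runs from the first significant AP2 frame to
the presumed scission time (the DNM2 maximum); assembly duration from the
ARPC3 onset to scission. Cohort averages group events by AP2 lifetime
(default edges 10, 20, 40, 60, 120 s) and align all traces at scission
(time 0); the plotted band is SD/4. The straightness index is end-to-end
distance over path length — see Design choices. Lateral motility is the
mean frame-to-frame AP2 step over a 10-frame window on either side of
scission. Group comparisons use two-sided Welch's t and two-sample KS tests.

## The synthetic generator

`simulateDataset()` emulates the statistical structure the analysis
assumes, with these study conditions as defaults:

* **Lifetimes** are Rayleigh-distributed with scale `lifetimeSigma = 20 s`
  at a 1 s frame interval; only degenerate draws are re-sampled (at most
  `maxLifetimeRetries = 100` times), so the base sample is exactly Rayleigh.
* **AP2** rises linearly to its peak and decays exponentially after
  scission. For actin-positive (stalled) events the rise completes
  `stallPlateau = 10 s` early and the trace plateaus at peak until scission;
  the plateau extends the realized lifetime by the same amount, so stalled
  events are longer-lived — the stalled-site signature. Because of this the
  *mixed* lifetime distribution is Rayleigh-plus-shift for the positive
  class; the pure-Rayleigh property holds for the base draws (stored as
  `base_lifetime` in the ground truth) and for `stallPlateau = 0`
  configurations.
* **DNM2** is recruited in two phases: a constant early level
  (`dnm2EarlyFrac = 0.1` of the burst peak) plus a Gaussian terminal burst
  (FWHM `dnm2BurstWidth = 5 s`) peaking exactly at the scission frame.
  Optional second bursts (for peak-detection testing) are placed ≥ 10 s
  before scission, with the base lifetime drawn conditional on ≥ 18 s so
  the bursts are temporally resolvable at 1 s sampling — doubles are
  excluded from Rayleigh fits anyway, so the conditioning cannot bias the
  fitted scale.
* **ARPC3** bursts onset `arpc3OnsetLead = 15 s` before scission, displaced
  `arpc3Offset = 150 nm` from the coat in a random direction that is fixed
  within each event (the network stays on one side of the site).
* **Noise.** Amplitude noise is Gaussian with variance proportional to the
  mean (a shot-noise proxy, `ampNoiseScale = 1`); positional jitter is
  isotropic Gaussian with `positionNoiseSd = 20 nm` per frame, switching to
  a faster random walk after scission (released vesicles move).
* **Contaminants.** Visitors (default 15% of tracks) are short-lived
  (Rayleigh scale 5 s), highly motile (100 nm/frame random walk) tracks
  without a DNM2 burst and with flickering DNM2/AP2 detections. Stray
  ARPC3 tracks (0.5 per event) diffuse through the field independently of
  any event; an ARPC3-negative event that happens to receive an early stray
  transit is relabelled `random_overlap_early` in the ground truth. Random
  early overlap is therefore a property of track *density*, which is
  exactly why the randomized-pairing control (`randomizeChannelPairing()`,
  which pairs one dataset's events with another's ARPC3 tracks) collapses
  the late/positive fraction while approximately preserving the early
  fraction — the mechanism generating early overlaps is the same in matched
  and randomized data.
* `fracArpc3Positive = 0.7` is the fraction of *non-visitor* events with a
  true late actin burst, matching an actin-negative fraction of about 30%
  among completed events.

What the generator does **not** emulate: pixelated images or PSFs (tracks
are generated directly at the track-table level), clathrin plaques and
coat-splitting events, photobleaching, detection dropout correlated with
amplitude, class-dependent motility before scission, and dense fields where
linking must disambiguate overlapping events. Passing tests therefore
demonstrate correctness of the *analysis logic* under the stated
statistical structure, not robustness to every artifact of real microscopy
data.

## Numerical choices

* Robust per-frame noise SD of a trace: MAD-style estimate from residuals
  against the 3-frame moving average, rescaled by `sqrt(2/3)` (the variance
  fraction a 3-point mean leaves in the residual of white noise).
* Peak tie-breaks: when two peaks of equal height violate the minimum
  distance, the earlier peak is kept; grid ties are lexicographic in
  (height, width, distance).
* Degenerate features are imputed and logged: stationary trajectories get
  straightness 1 and MSD slope 0; constant feature columns pass through the
  scaler as zeros with a warning.
* Posterior rows sum to 1 within 1e-9; mixture weights likewise; covariance
  positive-definiteness is enforced by the class validity method.
* A single global seed fans out to per-stage seeds via a fixed affine map
  (`stageSeed`), keeping every derived seed below 2^31 and every stage
  independently reproducible.

## Design choices where the design was open

* **Straightness convention.** The verbal definition (sum of
  frame-to-frame distances to end-to-end distance) and the stated anchor
  (a perfectly straight trajectory has index 1, straighter is larger)
  coincide only for straight paths. The implementation uses end-to-end /
  path length, which honours both the anchor and the ordering; the literal
  path / end-to-end ratio is available via
  `straightnessIndex(..., convention = "path_over_net")`.
* **Peak height units.** The parameter is defined in amplitude units, but
  the survey expresses heights in robust-noise-SD units so one grid
  transfers across intensity scales; both are supported via `heightUnits`.
* **Early/late boundary** (first half of lifetime and > 20 s before
  scission), the 300 nm / 3-frame linking rule, the K = 2–8 BIC range, the
  90% variance target, the 0.5 DNM2-fraction floor, the 10-frame motility
  window, and the cohort edges are declared defaults — all configurable and
  recorded in every run's persisted configuration.
* **Single-link policy.** Whether multiple third-channel bursts may serve
  one event is unspecified upstream; linking keeps at most one track per
  event (nearest wins), a declared simplification.

## Problem sizes

The shipped tests exercise the pipeline at the sizes chosen for the
package's validation experiments: parameter-recovery runs use 300–1,000
events per dataset (5 seeds for the clustering-recovery property), 10,000
draws for Rayleigh scale recovery, 1,000 random traces for the brute-force
peak-count cross-check, and 400-event dataset pairs for the
randomized-pairing control. A default end-to-end `runPipeline()` on a few
hundred events completes in seconds on one core.

## Known limitations

* The feature catalogue is a reproducible, documented choice; upstream
  analyses describe "over thirty features" without an authoritative list,
  so correspondence beyond the explicitly named features is not claimed.
* Rayleigh goodness-of-fit is the default selection metric; the survey
  table retains enough information to re-select under any other criterion.
* The localization module computes 2-D (xy) centroid distances; 3-D STORM
  z-coordinates are carried through I/O but not used in the distance.
* Registration is translation-only; affine chromatic models are out of
  scope.

## A minimal run

```{r example, eval = FALSE}
res <- runPipeline(defaultConfig(seed = 1, nEvents = 400,
                                 outDir = "cme-run"))
res$positiveFraction$fraction     # fraction of actin-positive CME events
res$peakParams                    # selected peak-defining parameters
res$clusterSummaries              # per-cluster medians behind the selection
print(res$cohorts)                # lifetime cohorts aligned at scission
```
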