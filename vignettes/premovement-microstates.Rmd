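---
title: "Pre-movement EEG microstates: model, pipeline and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pre-movement EEG microstates: model, pipeline and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(premstates)
```

## The problem and the model

During the half second before a voluntary movement, the scalp electric
field passes through a short sequence of quasi-stable topographies —
EEG *microstates*. `premstates` asks whether the composition of that
pre-movement sequence carries graded information about the upcoming
motor demand (here: the load lifted in a biceps curl), and provides a
fully testable pipeline for answering it.

The microstate model treats the instantaneous scalp map
$\mathbf{v}_t \in \mathbb{R}^C$ (average-referenced across $C$
channels) as a scaled, polarity-ambiguous copy of one of $K$ template
maps $\mathbf{a}_1,\dots,\mathbf{a}_K$ plus noise. Three quantities
organize everything:

* **GFP** (global field power), the spatial standard deviation
  $\mathrm{GFP}_t = \sqrt{\tfrac1C\sum_i (v_{ti}-\bar v_t)^2}$. Its
  local maxima are the moments of highest topographic signal-to-noise,
  and only those samples enter clustering.
* **Spatial correlation**, the absolute Pearson correlation between two
  average-referenced maps. The absolute value makes every comparison
  polarity-invariant: a map and its negation denote the same state.
* **GEV** (global explained variance),
  $\mathrm{GEV} = \sum_t (\mathrm{GFP}_t\, c_t)^2 / \sum_t
  \mathrm{GFP}_t^2$, where $c_t$ is the correlation between
  $\mathbf{v}_t$ and its assigned template — the GFP-weighted fraction
  of topographic variance the segmentation explains.

### Modified k-means

`modifiedKmeans()` alternates (i) assignment of each map to the
template with the highest $|c|$, and (ii) template update as the
dominant eigenvector of $\sum_{t\in k}\mathbf{v}_t\mathbf{v}_t^\top$ —
the polarity-invariant centroid. Because the update maximizes the
cluster's Rayleigh quotient and the assignment maximizes each sample's
contribution, the iteration never decreases GEV (the package asserts
this per iteration via the returned `gevTrace`). The update uses power
iteration warm-started from the current template, which preserves that
monotonicity while avoiding a full eigendecomposition per cluster per
iteration. Ties in assignment break to the lower template index; an
emptied cluster is reseeded from the worst-fit map; the best of
`nRestarts` (default 20) random restarts by GEV is returned. We found
the GFP-weighted ascent reliable enough that a handful of restarts
reaches the same optimum on planted data; scripted analyses in this
package use 10.

### Choosing K: the meta-criterion

No single cluster-validity index is trustworthy across regimes, so
`validityCriteria()` computes seven of them on the polarity-invariant
distance $d = \sqrt{1-c^2}$ — Silhouette, Davies–Bouldin,
Calinski–Harabasz, Dunn, point-biserial, Krzanowski–Lai, and a
predictive-residual cross-validation criterion — records each one's
optimal $K$, and takes the **median** of the seven optima (ties broken
toward the smaller $K$). The battery is selectable by name so any
subset or replacement can be used.

### The two-level procedure

`withinSubjectTemplates()` pools each subject's GFP-peak maps across
all conditions, scans $K$ over `kRange` (default 2–10) and keeps the
meta-criterion solution. `acrossSubjectTemplates()` pools all subjects'
template maps as observations, clusters them again, and selects the
final group-level $K$ the same way. `backfit()` labels data by maximum
$|c|$ against a fixed template set, and `conditionStats()` accumulates,
per subject × condition × map, the **time frames** (number of assigned
GFP-peak samples) and the **GEV**, normalized within the cell.

Two definitions deserve emphasis because they are decisions, not
forced readings:

* *Time frames* are counted over GFP-peak samples only, consistent
  with the clustering input; `peaksOnly = FALSE` switches both
  backfitting and counting to every sample.
* GEV per condition is normalized within each subject × condition cell
  (not against pooled variance), so cells are comparable across
  conditions with different overall field strength.

### Statistics

Load effects on time frames and GEV are tested per map with the
Friedman rank test (`friedmanTest()`, mid-ranks with the standard tie
correction, $\chi^2$ approximation with $k-1$ df; a permutation option
enumerates all within-subject relabelings when $k!^n \le 10^5$ and
otherwise samples them), followed by Dunn's pairwise post-hoc
(`dunnPosthoc()`, $z = (\bar R_i - \bar R_j)\big/\sqrt{k(k+1)/(6n)}$)
with Bonferroni family-wise adjustment over all pairs by default; a
versus-baseline mode restricts the family. Associations between
microstate measures and behavior use `pearsonCor()` (two-sided
t-based p).

### Sources

The source stage deliberately trades anatomical realism for complete
testability. `buildLeadfield()` computes an analytic three-shell
concentric-sphere conductor (brain/skull/scalp, radii 80/85/92 mm,
conductivities 0.33/0.0042/0.33 S/m): the potential is expanded in
Legendre series and the per-degree transfer coefficient is obtained by
solving the interface boundary conditions exactly; with equal
conductivities the coefficients reduce to the closed-form homogeneous
value $(2n+1)/n$, which the tests verify, and the series itself is
checked against the direct infinite-medium dipole formula. The voxel
grid is origin-centred with 12 mm spacing inside a 60 mm radius
(~500 voxels) — small enough for a laptop, dense enough for every
algorithmic property to be exercised.

`sloretaInverse()` computes the regularized minimum-norm solution
$\mathbf{j} = G^\top (GG^\top + \alpha H)^{+}\mathbf{v}$ ($H$ the
average-reference operator; $\alpha$ defaults to $10^{-2}$ times the
mean eigenvalue of $GG^\top$) and standardizes each voxel's 3-vector by
its diagonal block of the resolution matrix $TG$. This standardization
is what gives sLORETA its defining property — zero localization error
for noiseless point sources on the grid — which the tests verify over
random voxels.

`snpmPairedContrast()` performs voxel-wise paired t-tests with the
family-wise null built from sign flips of the per-subject difference
images and the max-|t| statistic; when the requested 5,000 permutations
exceed $2^n$ (always true at $n = 10$, where $2^{10} = 1024$), the
complete enumeration is used instead, making the test exact.

## What the generator emulates — and what it does not

`defaultGroundTruth()` + `generateEpochs()` produce the study design
this package validates against: 10 subjects × 5 conditions (one
unloaded baseline, four graded loads) × 10 trials of 500 ms
pre-movement epochs at 250 Hz on a 32-channel 10-10 montage. Each epoch
is a chain of segments; segment identity is drawn from the
subject × condition prevalence, dwell lengths are geometric (mean 12
samples ≈ 48 ms, truncated at 1), and within a segment the planted map
is scaled by a smooth positive arch and a **random polarity sign**, so
any downstream code that fails to honor polarity invariance fails the
tests. Noise is spatially correlated 1/f noise (independent pink
channel noises mixed through a montage-distance kernel), scaled to
SNR 2 (template RMS / noise RMS). A per-segment topographic jitter
(SD 0.05 before renormalization) supplies mild inter-trial map
variability; the planted load effect is a linear decline of map 2's
prevalence from 0.25 to 0.05 across the load conditions, the remainder
shared equally by the other maps — a graded, monotone effect of the kind
a load-sensitive microstate would show.

These choices emulate structure, not physiology. The generator does
not model ocular or muscle artifacts, volume-conducted source mixing
(planted maps are orthogonalized, real microstate maps are not
orthogonal), serial correlation between segment identities, or
between-subject topographic variability beyond jitter. Passing tests
therefore demonstrate that the algorithms recover known structure under
realistic noise and polarity ambiguity — not that real recordings
contain eight maps or a load effect.

Behavioral data follow the same philosophy: reaction time gains a
per-condition shift on top of subject effects and noise; movement
duration has no condition effect; RMS EMG scales multiplicatively with
the per-condition `emgScale`. The EMG/kinematic generator produces
4,000 Hz band-limited EMG and 60 Hz trapezoidal flexion–extension
traces with known onsets, so `detectOnsets()` (10%-of-peak threshold on
a 50 ms-smoothed trace, sustained for ≥ 100 ms) can be validated
directly.

## Numerical choices and degenerate inputs

* Filtering is zero-phase forward–backward (4th-order Butterworth
  0.5–30 Hz), doubling the effective magnitude order but preserving
  pre-movement timing; downsampling low-passes at 80% of the target
  Nyquist before decimation and requires an integer rate ratio.
* The pre-movement window is half-open $[-500, 0)$ ms: the onset sample
  itself is excluded. Baseline correction subtracts the whole-epoch
  channel mean (the interval is a package decision; no other interval
  is implied). In the synthetic pipeline, filtering/decimation are
  exercised by their own tests while the epoch stage applies the
  average reference and baseline correction — the generator already
  emits band-limited epochs at the target rate.
* GFP-peak plateaus resolve to their first sample; series endpoints are
  never peaks.
* k-means convergence: labels stable or relative GEV change
  $< 10^{-6}$; restart winner chosen with a $10^{-12}$ relative margin
  so floating-point reordering (e.g. a channel permutation) cannot flip
  near-ties.
* Zero-variance maps are rejected rather than silently normalized;
  zero total GFP makes GEV undefined and errors.
* Bad-channel flagging z-scores log-variance against median/MAD (a
  plain z-score cannot flag an outlier among few channels because the
  outlier inflates its own denominator); interpolation uses
  inverse-distance weights over the 3 nearest montage neighbors and
  refuses a channel whose neighbors are all bad.
* At $\alpha = 0$ the inverse solver requires the gain Gram matrix to
  have full average-reference rank and otherwise errors with advice to
  regularize.

## Problem sizes used in the shipped analyses

The package's own test-suite and acceptance script run the full design
(10 × 5 × 10 trials; K searched 2–10; 10 restarts), 200-replicate power
and family-wise-error simulations at the design's size, a 5,000-replicate
null calibration of the Friedman test, and the ~500-voxel source grid.
The pipeline's reduced demonstration configurations (fewer subjects and
trials) exist only for quick interactive runs; every scientific claim
is exercised at the sizes above.

## Known limitations

* The spherical head model and unlabeled voxel grid support method
  validation, not anatomical inference; no atlas labels are produced.
* Template polarity is only reported up to sign (largest-|value|
  channel positive), as the model itself is polarity-blind.
* The meta-criterion inherits the biases of its seven constituents at
  very small sample counts (e.g. clustering a handful of pooled
  subject templates); degenerate fits are excluded with a note.
* EDF support is a minimal int16 reader/writer for data exchange, not a
  full EDF+ implementation (no annotations, one scaling per signal).
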