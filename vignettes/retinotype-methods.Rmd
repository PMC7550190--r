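---
title: "Methods: response typing and retina-to-tectum decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: response typing and retina-to-tectum decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its science: the models it
implements, the assumptions behind them, the parameters that matter, what
the synthetic-data generators do and do not emulate, and the places where
a design was genuinely open and a choice had to be made.

## Stimulus model and regressors

The visual battery is represented as an ordered, non-overlapping event
table: dark/bright luminance ramps (3 s) and flashes, a 5° dot moving at
90°/s forward (temporal-to-nasal) and backward at two elevations, a 30°
dot, a 5° high-frequency grating (negative control for small-dot
responses), and fast (~60°/s) and slow (~20°/s) looming discs that each
end in a sustained black screen. The battery maps onto **15 regressor
channels**: 4 small-dot (direction × elevation), 2 large-dot, 2 grating,
2 looming, 2 ramps, 2 flashes, and 1 sustained-dark channel. This 15-way
split is a convention of this package — it is the only decomposition of
the listed components that totals fifteen — and the channel identities are
exposed in `stim_channel_names()`.

Each channel's indicator (box for dots, gratings, flashes and dark
epochs; linearly rising for ramps and looming, whose drive grows with
angular size) is convolved with a GCaMP6 kernel
$(1 - e^{-t/\tau_r})\,e^{-t/\tau_d}$, normalized to unit peak. Published
time constants for the indicator variants are not precise enough to pin;
defaults are $\tau_r = 0.1$ s and $\tau_d = 1.8$ s (nuclear/cytoplasmic
GCaMP6s) or 0.5 s (GCaMP6f), all configurable — every downstream statistic
is kernel-agnostic. Regressor columns are rescaled to unit peak so a
regression slope reads directly in ΔF/F units.

**Response windows.** Because each stimulus variant recurs at several
separated times within a pass (and the sustained-dark epochs interleave
with the looming presentations), a single (start, end) pair cannot cover a
channel without swallowing other stimuli. Windows are therefore stored as
a per-channel list of merged intervals — each event epoch plus one decay
time constant — and scoring uses their union. Timing defaults (5 s
inter-stimulus gap, 2 Hz imaging rate, event durations) are configuration,
not science; the protocol object records them all.

## Scoring

Raw fluorescence is uniformly filtered over three frames (reflect
padding), the baseline $F_0$ is the 5th percentile of the filtered trace,
and ΔF/F $= (F - F_0)/F_0$. Synthetic traces that enter as ΔF/F directly
can request the same three-frame filter via
`score_population(presmooth = TRUE)`; the pipeline does, so simulated and
real data follow the same path.

For each regressor, ΔF/F is regressed on the regressor within its response
window by OLS **with a free intercept** (window-local baseline offsets
should not contaminate the slope). The slope is CR, R² is the squared
Pearson correlation of the fit, and the score is CR × R² — a
magnitude-times-reliability statistic. Consequences worth knowing:
scaling ΔF/F by $c$ scales CR and score by $c$ and leaves R² unchanged;
score is exactly 0 whenever R² is 0; and under trace noise R² shrinks
scores multiplicatively, more strongly for weak responses. Zero-variance
regressors inside a window yield score 0, R² 0, and a flag.

Trials are combined per regressor by the R²-weighted average
$(s_1 r_1 + s_2 r_2)/(r_1 + r_2)$ (0 if both R² are 0) — symmetric in the
trials. Scores are then normalized per fish to the 99th percentile of all
of that fish's score values. All percentiles use linear interpolation
(R's default type 7) for cross-implementation determinism.

## Clustering

Units with maximum normalized score below threshold are removed (0.2 for
tectal ROIs, 0.4 for RGC pixels; the boundary case is retained). Affinity
propagation — similarity = negative squared Euclidean distance, preference
= median off-diagonal similarity, damping 0.9, at most 1000 iterations —
compresses the retained units into exemplars; clusters with fewer than 5
members are dropped with their members. Exemplars are then merged by
average-linkage hierarchical clustering on correlation distance
($1 - r$), the tree is cut at a threshold, and final clusters carrying
fewer units than the minimum (20 cells, or 1% of pixels) are pruned.

The cut threshold is chosen by silhouette analysis **at the unit level**:
each unit inherits its exemplar's label, the mean silhouette width on the
units' correlation-distance matrix is computed for every distinct
partition of the tree (candidate cuts at midpoints between consecutive
merge heights), and the best silhouette wins, ties broken toward fewer
clusters. Exemplars alone are too few for a stable silhouette; units are
what the clustering is supposed to organize. Whether the original analyses
used correlation or Euclidean silhouettes is not documented; correlation
distance keeps the criterion consistent with the linkage.

Label transfer uses a plain k-NN vote (k = 10 for cells, 100 for pixels)
on Euclidean distance in score space, with vote ties resolved toward the
lowest class index and distance ties by reference order — deterministic by
construction. The shuffle control permutes each score column independently
across units (preserving marginals, destroying correlation) and compares
the explained-variance fraction of the top three principal components to
its mean over 1000 shuffles.

Affinity propagation is implemented in the package (no binding was
available); the degenerate all-identical-rows input short-circuits to a
single exemplar. With tight clusters and a median-similarity preference AP
deliberately over-fragments (that is its role here: local structure, noise
reduction); the hierarchical stage supplies the global structure.

## Non-negative L1 decomposition

Tectal score vectors are modeled as
$y = b + \sum_j w_j\,x_j$, $w_j \ge 0$, where $x_j$ are the 15-dimensional
average score vectors of the RGC clusters, by minimizing
$\sum_i (y_i - b - \sum_j w_j x_{ij})^2 + \lambda \sum_j w_j$. The bias is
free and unpenalized. On the positive orthant the stationarity conditions
reduce to non-negative least squares against the target
$X'y - \lambda/2$ (in centered Gram form), which the package solves
exactly with a Lawson–Hanson active-set iteration — inactive weights are
exact zeros, so `n_active` is well defined without a cutoff.

λ comes from a log-scale grid over $[10^{-5}, 10^{-1}]$ minimizing
cross-validated MSE. Two selection routes exist:

* `fit_unit()` alone runs a deterministic per-unit 5-fold CV over the 15
  score dimensions.
* `decompose_units()` — the pipeline path — selects **one population-level
  λ** by trial-split CV: for each candidate, every unit is fit on one
  trial's scores and evaluated on the other's, both directions averaged,
  and the population mean error minimized. Trial-splitting is the natural
  validation unit here (two acquisitions of the same protocol), and a
  shared penalty treats all units as draws from one model class.

Trace prediction is the dot product of the weights with the cluster-mean
ΔF/F traces plus the bias; `r_trace` is its Pearson correlation with the
measured trace (flagged undefined for zero-variance traces, e.g. an
all-zero fit). The random-weight null redraws each weight uniformly on
$[0, 2\max_j \hat w_j]$ (unit scale if the fit is empty) 1000 times; the
published analyses say only "random weights", so the scale is matched to
the fitted magnitudes and documented as configuration. Trial-split RMSE
re-estimates the intercept on the held-out trial: the intercept models a
trial-specific ΔF/F baseline, so a constant offset between acquisitions is
absorbed and the RMSE judges the weighted RGC component.

**Known limitation — support counts.** MSE-minimizing λ selection (any
fold structure) is prediction-optimal, not model-selection-consistent: it
tolerates small noise-driven activations, so the number of nonzero weights
per unit is biased upward at realistic noise levels even when the weight
*vectors* correlate strongly with the generative truth. Suppressing those
activations entirely would need a penalty several-fold above the CV
optimum. Users who need conservative support estimates should treat
`n_active` as an upper bound or stability-select across trials; the
package deliberately does not silently sparsify.

## Morphometry

The layer atlas is a stack of flat planes perpendicular to a depth axis
(eight named laminae, SM through SAC/SPV, with strictly increasing
boundary depths in µm). The original workflows segment curved laminae in
registered 3-D volumes; flat planes keep the computation exact and
testable, and the boundary logic is isolated so a curved atlas can be
plugged in later. Each SWC edge's 3-D cable length is split among layers
by clipping the edge at the boundary planes; cable outside the atlas goes
to an explicit `outside` bin (a convention of this package), and fractions
sum to 1 by construction. Arbor area per layer is the planar convex hull
of the layer's nodes — an approximation to manually outlined arbors,
reported as such; the deep/superficial ratio pools SFGS5/6–SAC/SPV over
SM–SFGS3/4.

Anterior–posterior cluster statistics use Gaussian KDEs (Scott's-rule
bandwidth) and a two-tailed two-sample t-test of the cluster's positions
**against the complement** (all other units). Figures in this literature
overlay a cluster on the all-units density, but testing a cluster against
a superset that contains it violates the independence the test assumes and
is miscalibrated under the null; the complement comparison is the version
whose null behavior is exact, and the all-units density is still returned
for display.

## Behavior

Bout segmentation realizes "change point on the tail-angle derivative" as
hysteresis thresholding of the Gaussian-smoothed (σ = 2 frames) absolute
derivative: epochs that exceed 300°/s, extended to the surrounding 150°/s
crossings, merged when separated by fewer than 10 frames, kept when at
least 20 frames long (defaults stated at 500 Hz). The low threshold sits
several-fold above the smoothed tracking-noise floor and several-fold
below the slowest bout's peak velocity; the 10-frame merge bridges the
mid-bout velocity dip of slow orienting turns.

The per-fish convergence threshold is the interior local minimum of the
convergence-angle KDE between its two largest modes, with an explicit
error on unimodal distributions (a fish that never hunted has no
threshold). Hunting fraction is the fraction of frames above threshold.
A bout is an initial J-turn iff the mean convergence over the 25 flanking
frames is below threshold before and above it after — flank averaging
buys robustness to single-frame jitter. DSI is
$(\#R - \#L)/\#\text{total}$ over J-turns, direction by the sign of the
bout integral (positive = rightward); zero J-turns give `NA` with a
warning rather than a silent 0. Group comparisons use the two-sided
Mann-Whitney U test on per-fish statistics.

## Synthetic data: what it emulates, and what it does not

The generators produce every input with known ground truth, at sizes
chosen to keep the full test suite in minutes on one CPU (300 RGC units,
200 tectal units, 60 s tracking sessions by default).

* **RGC archetypes.** Ten fixed 15-dimensional score profiles mimic the
  functional input classes: small-dot direction-selective (both
  directions), small-dot non-selective, large-dot, size-invariant,
  fast/slow looming, OFF/dimming, ON/brightening, grating. The matrix is
  built to be **mutually identifiable** — no archetype is close to a
  non-negative combination of the others (each carries a private channel
  signature). Without identifiability the generative weights of mixture
  units are not a well-defined recovery target; a first draft in which
  the size-invariant class was numerically a blend of the small- and
  large-dot classes made weight recovery ill-posed and was revised.
* **Populations.** RGC units are single archetypes plus i.i.d. Gaussian
  ΔF/F noise (default σ = 0.1; the reference populations for clustering
  use 0.05). Tectal units are sparse non-negative mixtures: support size
  1 + Geometric(0.3) (median 2, capped at 10), weights Exponential with
  mean 0.5, bias Uniform[0, 0.1], two independent-noise trials.
  A–P positions are Beta-skewed by the dominant input (large-dot anterior,
  small-dot posterior). The noise model is white in time; real imaging
  noise has slow components (hemodynamics-free but bleaching, motion
  residuals) that the generators do not emulate, so passing tests certify
  the analysis logic, not robustness to structured artifacts.
* **Behavior.** Tail angle is a sum of signed half-sine bout waveforms
  plus band-limited tracking noise (Gaussian-smoothed, σ = 2 frames, 0.2°)
  — tracker jitter is smooth, and white noise at 500 fps would carry
  derivative power no real tracker output has. Convergence switches
  between modes at 10° and 50° (SD 5°) mid-J-turn, so the ground-truth
  J-turn definition (unconverged before, converged after) holds exactly.
  Real bouts have oscillatory fine structure and variable envelopes that
  the half-sine omits.
* **Tracings.** A vertical shaft connects the mid-depths of the layers
  carrying mass; horizontal runs at each layer mid-depth supply the
  remaining cable, shrunk by exactly the shaft cable crossing that layer,
  so round-trip recovery of strictly positive profiles is exact up to
  floating point. Zero-mass layers crossed by the shaft receive at most
  their thickness in cable, bounding the worst-case profile error by
  (atlas depth span)/(total length) — under 2% at the 4000 µm default.

All generators are deterministic given a seed.

## Numerical and convention notes

* Percentiles: linear interpolation (type 7) throughout.
* Threshold boundaries: units exactly at a responsiveness threshold are
  retained.
* Correlation distance on a constant vector is undefined: constant
  exemplars raise an error rather than propagate NaN.
* k-NN ties: vote ties toward the lowest class index; distance ties by
  reference order.
* Silhouette tie between cuts: fewer clusters win.
* λ-grid CV ties: the larger (sparser) penalty wins.
* The FFT convolution clamps magnitudes below 1e-10 to zero (the true
  convolution of non-negative signals is non-negative).
* Final cluster labels are renumbered 1..K by decreasing unit count.

## Limitations

Beyond the support-count bias discussed above: the flat-plane atlas and
convex-hull areas are stated approximations; the regressor windows leak a
small amount of signal between temporally adjacent stimuli, so even
noiseless mixtures score with a small systematic residual; cluster counts
on real data depend on response prevalence and noise and are not expected
to reproduce any particular published count; and the behavior module
starts from extracted angle time series — pixel-level tracking is out of
scope.
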