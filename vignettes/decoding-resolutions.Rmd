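---
title: "Decoding multi-unit activity across spatiotemporal resolutions with NeuroPixelHD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding multi-unit activity across spatiotemporal resolutions with NeuroPixelHD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NeuroPixelHD)
```

# The question and the model

Spike trains can be decoded after averaging over time (wider count bins)
and over space (pooling neurons into populations, areas, regions, or the
whole brain). Averaging suppresses noise faster than signal up to a point,
and signal faster than noise beyond it, so some intermediate resolution
should maximize decoding accuracy. Measuring *which* resolution that is
requires a decoder whose own machinery performs no hidden averaging —
otherwise the classifier's biases masquerade as properties of the neural
code.

NeuroPixelHD is a hyperdimensional-computing (HDC) classifier designed for
exactly this measurement. All information is represented as dense vectors
in dimension `D` (default $10^4$). Independent random vectors in such
dimensions are nearly orthogonal (cosine $\sim 1/\sqrt D$), which gives the
two algebra operations their useful semantics:

* binding (`bindHV`, element-wise product) associates vectors, preserves
  pairwise similarity exactly, and is self-inverse on bipolar ($\pm 1$)
  inputs;
* bundling (`bundleHV`, element-wise sum) superimposes vectors while each
  constituent remains detectable: the cosine between a bundle of $k$
  orthogonal equal-norm vectors and any constituent is $1/\sqrt k$, not
  $0$ — bundling memorizes rather than averages.

## Encoding

Each *spatial unit* (a neuron, an E/I population, an area, or a region,
depending on the working spatial level) gets a spatial hypervector:

* **neuron level** — the neuron's 81-point Gabor receptive-field vector
  $F_i$ (mean full-trial spike count per grid location,
  `receptiveFieldMatrix`) is lifted to dimension $D$ by a
  random-Fourier-feature map $\cos(B^\top F_i + b) \otimes \sin(B^\top
  F_i)$ with $B$ an $81 \times D$ standard-normal matrix and $b$ uniform
  phases — similar receptive fields yield similar hypervectors (the RBF
  kernel trick) — and bound with a uniform-$[0,1)$ hypervector for the
  neuron's brain area;
* **population level** — one of two shared bipolar E/I hypervectors bound
  with the area hypervector;
* **area level** — the area hypervector itself;
* **region level** — a fresh independent hypervector per region;
* **whole-brain level** — no spatial hypervector; the trial encoding
  reduces to $V = \sum_t n(t)\,T(t)$.

Within a trial of $M$ bins, time is encoded by drawing binary $\{0,1\}$
endpoint hypervectors $T(0)$ and $T(M-1)$ and interpolating
$T(t) = (1 - t/M)\,T(0) + (t/M)\,T(M-1)$, so similarity between time
hypervectors decays with temporal distance. By default the endpoints are
drawn **independently for every trial** (`timeMode = "independent"`): with
shared time hypervectors, the similarity-preserving property of binding
would make every pair of trial hypervectors more alike and smuggle implicit
averaging into training. A `"shared"` mode is provided for comparison.

The trial hypervector polarizes presence versus absence of spikes with a
bipolar pair $H^- = -H^+$:

$$V \;=\; \sum_{t=1}^{M}\Big[\sum_{i:\,n_i(t)\neq 0} n_i(t)\, S_i \otimes H^+
\;+\; \sum_{i:\,n_i(t)=0} S_i \otimes H^-\Big] \otimes T(t).$$

No normalization by the number of units is applied (the formula is followed
literally); a `normalizeByUnits` switch exists, default off.

## Adaptive training

Class hypervectors start at zero and receive similarity-proportional
updates. Natural scenes ($m = 118$): a correct prediction adds
$\eta(1-\delta_\ell)V$ to the true class; an error moves both the true and
the predicted class by $\eta(\delta_{\ell'}-\delta_\ell)V$ in opposite
directions. Defaults $\eta = 0.01$, 3 epochs. Gabor locations ($m = 81$)
exploit grid proximity: the (up to 8) grid neighbors of the true (and, on
errors, predicted) class are co-updated with a smaller rate. Defaults
$\eta_{center} = 0.01$, $\eta_{neighbor} = 0.001$, 2 epochs. Samples are
shuffled once per epoch with a seeded generator (the presentation order is
otherwise unspecified); trial hypervectors are encoded once and reused
across epochs, which keeps epochs deterministic rather than re-drawing
per-trial time hypervectors each pass.

Prediction is the argmax of cosine similarity, ties to the lowest class
index. Cosine with a zero vector is defined as 0, which makes the first
training iteration (all-zero prototypes) well defined: an untrained class
is maximally uninformative.

# Tunable parameters

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `D` | 10000 | hyperdimension; $\gg$ 81 so random vectors are near-orthogonal ($\mathrm{sd}(\cos) = 1/\sqrt D = 0.01$) |
| `binSize` | 1–250 ms | temporal bin; divisors of 250 bin exactly, others via `overlap`/`crop` |
| `level` | five levels | spatial pooling from neuron to whole brain |
| `fanoBin` | 25 ms | bin for Fano factors; a sweepable hyperparameter (the clustering can depend on it) |
| `eta`, `etaCenter`, `etaNeighbor` | 0.01 / 0.01 / 0.001 | learning rates |
| `epochs` | 3 scenes / 2 gabor | training passes |
| `folds` | 5 | stratified cross-validation folds |
| `copies` | 4 | augmentation copies (5-fold total expansion) |
| `alpha` | 0.05 | joint-optimality level in `selectOptimalResolution` |
| `fmin`, `fmax` | 3, 50 Hz | oscillation search band; below 3 Hz the frequency resolution cannot establish a peak |
| `threshold` | 2 | peak threshold in robust residual spreads |

# Aggregation and selection machinery

**Temporal binning.** `exact` mode requires the bin to divide 250 ms and
conserves every spike. For the other bin widths two complementary schemes
are offered: `overlap` places $M=\lceil 250/w\rceil$ bins with starts
$\lfloor j(250-w)/(M-1)\rfloor$ so the last bin ends at 250 ms (bins may
overlap: over-counting), and `crop` drops the trailing remainder
(under-counting). Averaging results across the two bounds the bias of
either.

**E/I populations.** Per neuron, the Fano factor (variance/mean) of spike
counts in `fanoBin`-ms bins is pooled over all bins, Gabor positions and
trials (the pooled convention; computing per-bin Fano and averaging is a
noted alternative). Within each area the `ceiling(0.2 n)` highest-Fano
units are labeled putatively inhibitory — the nominal cortical 80/20 split;
elevated count dispersion is the functional proxy for fast-spiking
identity. Conventions the data do not fix: population (divide-by-$N$)
variance, silent units get Fano 0 (so they land in the excitatory pool),
boundary ties break by unit id, and a single-unit area gets one I unit by
the ceiling rule (logged as degenerate).

**Augmentation.** Within one class, trial indices are permuted
independently at every time bin but uniformly across neurons. Every
per-(neuron, time) count multiset is preserved; only the cross-time
combinations change. Four copies plus the original give the 5-fold
expansion. In cross-validation the package applies augmentation *within*
each (class, fold) cell, so a shuffled copy of a training trial can never
land in a test fold — stricter than splitting after augmenting, and both
behaviours are available through `augmentTrials` directly.

**Optimal-resolution selection.** The resolution with the lowest median
per-trial error is optimal; every resolution whose paired Wilcoxon
signed-rank test against it has $p \ge \alpha$ is *jointly* optimal, and
group-level histograms count each subject's whole optimal set. The test
delegates to `stats::wilcox.test(paired = TRUE)` (exact null for small
tie-free samples, normal approximation with zero-dropping otherwise). Both
the mean and the median error are reported per resolution.

**Correlation testing.** `pearsonRandomizationTest` computes Pearson $r$
and a two-sided permutation $p = (1 + \#\{|r_{perm}| \ge |r|\})/(1 +
n_{perm})$ with $10^4$ permutations by default.

# Oscillation analysis

`regionRate` pools a region's 1 ms-binned counts (mean across units) into
one contiguous stream across all Gabor trials; `welchPsd` computes an
averaged modified periodogram (Hann taper, 4 s windows, 50% overlap —
0.25 Hz resolution over the theta band; the integral of the density equals
the signal variance). `slowestPeak` is a deterministic, simplified spectral
parameterization: a robust line (`MASS::rlm`) in log power versus log
frequency over 3–50 Hz estimates the aperiodic 1/f component; the residual
is lightly smoothed (5-bin moving average, suppressing single-bin
periodogram spikes); local maxima exceeding twice the robust residual
spread qualify; the lowest-frequency qualifying peak at or above 3 Hz is
returned, and "no peak" is a value, not an error. Full spectral
parameterization toolchains fit multiple Gaussians with manually tuned
hyperparameters; the simplified fitter keeps the decision rule (slowest
peak ≥ 3 Hz, else none) while removing every manual step, at the cost of
cruder bandwidth estimates. Calibration (in the test suite): injected
4–8 Hz peaks are recovered within ±0.5 Hz whenever their power exceeds
about twice the local aperiodic level, and pure 1/f input yields no peak in
at least 18 of 20 seeds.

# The synthetic generator

`synthesizeDataset` emulates the structure of a passive-viewing session:
250 ms trials with no inter-stimulus gap, an 81-location Gabor task (45
repetitions per location by default) or a 118-image natural-scenes task (50
repetitions, preceded by a Gabor receptive-field mapping block, as real
sessions are), and units assigned to real area/region names. Per unit $i$
and class $c$ the rate is piecewise-constant over windows of the *signal
timescale* $\tau$:

$$\lambda_{i,c}(t) = \lambda_0 \max\{0,\; 1 + g\, s_{i,c}(\lfloor t/\tau
\rfloor)\},$$

with $s$ standard normal, Gaussian-smoothed over the 9×9 grid for Gabor
classes (`rf_smoothness`, default bandwidth 1.5 cells) so receptive fields
are spatially coherent. Excitatory units draw Poisson counts; inhibitory
units (20% per area) draw negative-binomial counts with variance inflated
by `inhib_dispersion` (default 3) — the minimal mechanism that separates
E/I Fano factors. A per-(area, trial, window) multiplicative log-normal
factor induces within-area shared noise (`noise_corr`, default 0.2). An
optional sinusoidal rate modulation running continuously across trials
(`osc_freq_hz`) supports the oscillation pipeline end to end.

Defaults were fixed once as the emulated study conditions: baseline rate
10 Hz (a typical cortical unit), gain 1, $\tau = 250$ ms, 4 areas × 10
units. What the generator does *not* emulate: biophysical spiking dynamics,
refractoriness, task-correlated running/arousal states, electrode drift and
sorting errors, or realistic pairwise correlation structure beyond the
single shared factor. Passing tests on this generator therefore
demonstrates that the *pipeline* recovers planted structure — not that real
recordings contain that structure.

## The two timescale regimes

The package's central in-silico result reproduces the resolution-recovery
phenomenon. With $\tau = 250$ ms (class signal constant over the trial) and
default rates, 1 ms bins decode at chance while 125/250 ms bins decode far
above it — at 1 ms nearly every bin of every unit is zero, so trial
hypervectors are dominated by the constant $H^-$ background.

The fast regime ($\tau = 10$ ms) is run at `base_rate_hz = 60`,
`signal_gain = 1.5`. This is a physical-regime requirement, not a tuning
choice: with independent per-trial time hypervectors, information crosses
trials through each unit's total count and its pattern of silent bins, and
a unit can only express a 10 ms temporal pattern through the spike/no-spike
polarization channel if its per-window occupancy is of order 1 — i.e.
rates of tens of hertz, as for fast-spiking interneurons or pooled
multi-unit activity. In that regime the ordering reverses: the
timescale-matched 10 ms bin decodes far above the 250 ms bin (whose
per-unit totals barely differ across classes because the 25 window values
average out).

# Numerical conventions and degenerate inputs

* Cosine with a zero-norm vector is 0 (untrained classes, silent trials).
* An all-zero receptive field encodes to the zero hypervector
  ($\sin 0 = 0$); such units contribute through the $H^-$ branch only —
  documented, not "fixed".
* Interpolated time hypervectors are used as real-valued vectors; nothing
  is re-quantized. At $t = M-1$ the printed interpolation gives weight
  $(M-1)/M$, i.e. the endpoint vector is approached, not reached.
* Spike times live in the half-open interval $[0, 250)$ ms and are floored
  into 1 ms bins; time 250.0 is rejected.
* Gabor label $\to$ grid map is row-major ($x = \ell \bmod 9$,
  $y = \lfloor \ell/9 \rfloor$) and configurable; Euclidean errors live on
  $\{0..8\}^2$ with maximum $\sqrt{128}$.
* F1 for a class absent from both truth and prediction is 0, not dropped.
* All randomness flows from one master seed through named substreams
  (`streamSeed`), so any component is reproducible in isolation and a
  pipeline rerun is bit-identical.

# Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen as
the package's own demonstration sizes: $D = 2000$ (resolution scans), 81
Gabor classes × 10 repetitions, 4 areas × 10 units, 60 s rate series for
spectral calibration. The full-scale defaults ($D = 10^4$, 45/50
repetitions) are the generator's and encoder's defaults and run the same
code paths.

# Known limitations

* With independent per-trial time hypervectors the binary $\{0,1\}$
  endpoints retain a mean-0.5 component, so even trials with identical
  counts encode to hypervectors with cosine ≈ 0.6 (not ≈ 0); this shared
  component is in fact the channel through which class evidence accumulates
  across trials. Mean-centered time hypervectors would change this
  geometry; the package follows the stated encoding.
* In the fast-timescale regime, bins finer than the signal timescale (5 ms
  against $\tau = 10$ ms) recover the right ordering against 250 ms but
  with a much smaller margin than the matched bin.
* The simplified peak parameterization reports a coarse half-height
  bandwidth and a single peak; multi-peak spectra return only the slowest.
* Baseline machine-learning comparisons (random forest, KNN, MLP, naive
  Bayes on flattened binned tensors) are deliberately out of scope; any
  external library can be applied to `binTemporal`/`aggregateSpatial`
  output directly.
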