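---
title: "Quantifying vestibular contributions to walking: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vestibular contributions to walking: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(vestigait)
```

## The scientific problem

During walking, the nervous system continuously transforms vestibular signals
of head motion into corrective muscle activity, and it does so in a
phase-dependent, muscle-specific way. A standard way to expose this pathway
is to deliver a continuous stochastic electrical vestibular stimulus (EVS)
at the mastoids while a participant walks on an instrumented treadmill, and
to measure how strongly the stimulus current is reflected in surface EMG and
in the mediolateral ground reaction force (GRF) at each phase of the stride
and at each frequency. A complementary question is how this coupling changes
when the stabilization demand of the task changes — walking with external
lateral support, with wide steps, or with narrow steps — and how it relates
to the *dynamic stability* of the gait pattern, summarized by the local
divergence exponent (LDE) of trunk motion.

`vestigait` implements that full analysis chain, together with a synthetic
walking-trial generator with *known, injected* vestibulo-motor coupling, so
every stage can be validated against ground truth.

## The stimulus

The stimulus is zero-mean Gaussian white noise, low-pass filtered at 25 Hz
with a zero-phase (forward–backward) 4th-order Butterworth filter,
mean-removed and scaled so its maximum absolute value is exactly the target
peak (5.0 mA by default, 8 minutes at 200 samples/s). Peak amplitude is
treated as the binding constraint; the RMS (~1.1–1.2 mA under the defaults)
is emergent, since only one of the two can be scaled to exactly. The stated
filter order refers to the designed single-pass filter; the bidirectional
pass doubles the effective roll-off.

```{r evs}
evs <- generate_evs(duration = 20, seed = 1)
evs
```

## Stride-synchronized wavelet coherence and gain

The coupling measures are time–frequency coherence and gain over the gait
cycle,

$$C(\tau, f) = \frac{|P_{xy}(\tau,f)|^2}{P_{xx}(\tau,f)\,P_{yy}(\tau,f)},
\qquad
G(\tau, f) = \left|\frac{P_{xy}(\tau,f)}{P_{xx}(\tau,f)}\right|,$$

where $P_{xx}$, $P_{yy}$ and $P_{xy}$ are stride-averaged auto- and
cross-spectra of the stimulus $x$ and a motor output $y$ (rectified EMG or
mediolateral GRF), obtained from a continuous analytic Morlet wavelet
decomposition of each stride segment. The processing chain follows the
standard design for this class of experiment:

* EMG is full-wave rectified first; every signal is low-pass filtered at
  100 Hz (zero-phase 6th-order Butterworth) and decimated to 200 samples/s.
  For the GRF the two belts' mediolateral forces are summed *before*
  filtering, because narrow-base walking puts both feet on both belts.
* Each stride is cut out aligned on one limb's heel strike and padded with
  half a stride of neighbouring data on each side. The pads protect the
  wavelet transform from edge distortion and are cropped again *after* the
  transform, before any averaging. We interpret the padding as half a stride
  per side (a symmetric choice; the alternative reading — 50% total — only
  narrows the protected band).
* Per stride, spectra are resampled along the stride-time axis onto the
  grand-average stride duration (duration normalization applies to the auto-
  and cross-spectra, never to the frequency axis), then averaged over
  strides. Left- and right-aligned coherence maps are averaged at the *map*
  level to pool the two legs.
* The Morlet centre parameter is $\omega_0 = 6$ with energy normalization
  (coherence is invariant to the normalization; gain units are recorded in
  the map metadata). The default frequency grid is 0.5–25 Hz in 0.25 Hz
  steps and the stride-phase grid has 101 points.

Under the hypothesis of no coupling, coherence estimated from $N$
independent strides exceeds

$$1 - \alpha^{1/(N-1)}$$

with probability $\alpha$; for $N = 256$ and $\alpha = 0.01$ this is 0.018,
the per-point significance level used throughout.

```{r threshold}
significance_threshold(256, 0.01)
```

### A localization caveat

Time–frequency cross-spectra localize *coupled energy* between the time the
stimulus occurred and the time the response appeared. If the physiological
response lags the stimulus by $\delta$, the coherence ridge appears earlier
than the response gate by roughly $\delta$ on the stride-phase axis. The
synthetic generator therefore uses a short-latency response kernel (~28 ms
group delay) so that injected gate phases are recovered within the tolerance
of the validation tests; with longer response latencies the recovered phase
must be interpreted as stimulus-referenced, not response-referenced.

## The synthetic walking trial

`simulate_trial()` emulates the instrumented streams of a real session —
per-belt 3-axis forces and moments at 200 samples/s, six EMG channels at
2000 samples/s, marker clusters (T6, pelvis, both heels) at 100 samples/s —
under metronome pacing (78 steps/min, stride time 1.538 s) with ~2%
stride-time jitter. Its purpose is validation: every quantity the analysis
estimates is known by construction and stored in `trial$truth`.

* **Coupling.** Each output channel is driven by
  `gain * gate(phase) * (kernel * EVS)(t - delay)`: a linear FIR response to
  the stimulus, multiplied by a raised-cosine stride-phase gate. This
  realizes the assumed linear, phase-gated stimulus–response relationship
  with exactly known gate centre, width and gain.
* **EMG.** Phasic baseline envelopes imitate the qualitative shapes seen in
  this muscle set (gastrocnemius peaking in late stance, gluteus medius
  after heel strike, erector spinae bimodal around both heel strikes),
  modulated multiplicatively by band-limited noise, plus the coupled
  component, half-wave floored at zero. Output noise is band-limited (50 Hz
  for EMG, 30 Hz for GRF) and scaled to the configured SD — noise that lives
  only above the 100 Hz anti-alias cutoff would vanish from the analysis and
  make any nonzero coupling look perfect.
* **Forces.** Vertical forces follow a double-bump stance profile with a
  sharp loading transient at contact; the mediolateral force carries the
  coupled EVS component (low-passed at 10 Hz) split across belts by load
  share. Plate moments encode a centre of pressure that travels
  heel-to-toe and backwards with the belt, so heel strikes mark local
  minima of the summed anterior CoP.
* **Step widths.** Each striking foot is placed at the drawn step width from
  the other foot's current position (weak recentring keeps the feet around
  the midline without altering widths), so the realized widths match the
  requested distribution exactly at the strikes.
* **Narrow-base cross-stepping.** With `cross_step = TRUE` each foot's load
  is split across both belts by its mediolateral position. Per-belt event
  detection then fails by construction and the analysis must fall back to
  the summed-plate CoP path, as in the corresponding experimental condition.
* **Trunk dynamics.** `simulate_t6_series()` integrates a planar limit
  cycle whose dynamical noise perturbs the *phase velocity* (stride-timing
  noise) plus a weakly noisy, contracting radial state. Phase perturbations
  are not corrected by the radial relaxation, so neighbouring trajectories
  separate at a rate proportional to the noise level while the attractor
  geometry stays fixed. This makes the LDE increase monotonically with
  `t6_noise_sd` — the property the stability pipeline must recover — and a
  noiseless run is exactly periodic (LDE numerically 0). A design with
  additive state noise does *not* have this property: there, both the
  nearest-neighbour distance and the divergence plateau scale with the
  noise level, and their ratio (hence the fitted slope) is flat or even
  decreasing in noise.

What the generator does **not** emulate: musculoskeletal dynamics, stimulus
artifacts bleeding into EMG, electrode noise spectra, marker dropout, arm
swing, or any nonlinearity in the stimulus–response pathway beyond the
half-wave floor. Passing validation on this generator therefore shows that
the *analysis chain* is correct and calibrated, not that real data meet its
assumptions.

## Gait events

Heel strikes and toe-offs are detected per belt as rising/falling crossings
of the vertical force through 5% of the median peak stance force, with a
0.2 s refractory period. When per-belt separation is unreliable (narrow-base
cross-stepping), the detector uses local minima of the summed-plate anterior
CoP — the onset of load transfer to the newly placed, forward foot — and
assigns feet from the mediolateral CoP once the new stance foot has taken up
load. Left/right strikes must interleave strictly; violations raise an error
rather than silently reordering. A constant standing load returns an
explicitly empty event set.

Stride times are same-foot first differences of heel-strike times; step
width is the absolute mediolateral distance between the two heel-cluster
centroids at each strike sample.

## Local dynamic stability

The LDE pipeline follows the standard single-trial recipe: three-point
differentiation of the T6 marker position (mediolateral axis by default; a
3-D speed option exists since the choice of components is a free parameter),
resampling so that the analysed strides contain exactly 100 samples each
(256 strides × 100 = 25,600 samples at full scale), delay embedding
(dimension 5, delay 10 samples — 0.1 stride — as in the gait-stability
literature), nearest neighbours under a half-stride Theiler window, and the
least-squares slope of the mean log divergence over 0–0.5 stride. Distances
are floored at 1e-12 so an exactly periodic series yields a flat, finite
curve. The estimator is invariant to amplitude scaling of the input. The
nearest-neighbour search is compiled (all-pairs, exact); the test suite
checks it against a brute-force pure-R oracle.

## Condition statistics

Gait parameters (stride time, step width, LDE) are compared across the four
conditions with one-way repeated-measures ANOVAs (`stats::aov`, subject
error stratum) plus planned, uncorrected paired t-tests of normal walking
against each modified condition. Both classical $\eta^2$
($SS_{cond}/SS_{total}$) and partial $\eta^2$ are reported, since either
convention is common.

Coherence maps are compared with cluster-based permutation tests: pointwise
paired t statistics, clusters formed at the two-sided $t$ critical value at
$\alpha = 0.05$ under 4-connectivity on the (stride-phase × frequency) grid,
signed cluster mass (sum of t) as the cluster statistic, and a
max-|mass| null built from random within-subject sign flips — the exact
exchangeability scheme for two paired conditions. Cluster p-values use the
add-one estimator $(1 + \#\{null \ge obs\})/(B + 1)$, so they are bounded
below by $1/(B+1)$ and the test is exact (slightly conservative). All grid
points enter the test; no pre-selection by per-point significance.

## Numerical choices and degenerate inputs

* All filtering is zero-phase (`signal::filtfilt`); stated orders are
  single-pass design orders.
* Segmentation indices are derived once from heel-strike times
  (`floor(t * rate) + 1`), so cropping pads and concatenating cores
  reproduces the original samples bit-exactly.
* Undefined grid points (zero auto-spectra, CoP below the force floor,
  marker dropout at a strike) propagate as `NA` flags, never as zeros.
* Degenerate inputs raise early: constant series for the LDE, fewer strides
  than requested, non-interleaving events, missing ANOVA cells (no
  imputation), permutation designs with fewer than two subjects.
* One global seed fans out to named substreams (per subject, condition and
  stream), so every stage is independently reproducible.

## Problem sizes used in validation

The packaged tests exercise the chain at the scales the analysis is designed
for where that is what is being claimed — 256 strides for the null
calibration, phase recovery and the resampling contract; 200 stimulus
realizations for the RMS; 100 null repetitions × 500 permutations for the
family-wise error check — and at reduced stride counts (16–66 strides) for
structural checks where stride count is immaterial. Monte-Carlo ladders
(gain, dynamical noise) use 20 seeds per level.

## Known limitations

* The significance bound assumes independent strides; the half-stride pads
  overlap neighbouring strides but are cropped before averaging, and the
  realized null exceedance is, if anything, slightly conservative at the
  lowest frequencies, where the wavelet support exceeds the padded segment.
* The LDE is a whole-trial mean; it says nothing about phase-dependent
  stability.
* Gain units depend on the wavelet normalization convention (energy
  normalization here, recorded in exported metadata); coherence does not.
* The simulator's condition presets encode plausible *directions* of change
  (e.g. external stabilization lowers both trunk-dynamics noise and coupling
  gains); the magnitudes of real between-condition effects are free
  parameters, not claims.
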