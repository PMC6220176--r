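---
title: "Modeling and measuring protrusion-coupled ERK pulses"
author: "pulsecoupler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and measuring protrusion-coupled ERK pulses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The system

In many adherent cell types, ERK (extracellular-signal-regulated kinase)
activates in discrete, stochastic pulses, and each pulse is preceded by a
localized protrusion of the cell edge enriched in active Ras and PI3K.
`pulsecoupler` implements both halves of the quantitative story behind
this observation:

1. a **mechanistic model** — a stochastic excitable activator–inhibitor
   network on the cell perimeter whose aggregate output drives a
   zero-order ultrasensitive ERK switch — that reproduces the two
   observed regimes (infrequent protrusions with discrete ERK pulses
   versus frequent protrusions with sustained ERK activation) and the
   response to sustained versus transient growth-factor stimulation; and
2. the **image-analysis pipeline** used to quantify the phenomenon in
   time-lapse microscopy: frame-difference (percent-change) processing,
   protrusion and interior-flash detection, perimeter kymographs,
   translocation-reporter quantification (C/N ratio), pulse calling, and
   cross-correlation lag analysis.

A ground-truthed synthetic-data generator ties the two together, so every
analysis stage is tested against planted truth without any external data.

## The excitable network

The cell perimeter is a periodic 1-D grid of `n_points = 300` points.
The activator \(X\) (Ras–PI3K–cytoskeleton activity) and inhibitor
\(Y\) obey

\[
\frac{\partial X}{\partial t} = D_X \nabla^2 X - a_1 X - a_2 (Y - R) X
  + \frac{a_3 X^2}{a_4^2 + X^2} + a_5 + U_N, \qquad
\frac{\partial Y}{\partial t} = D_Y \nabla^2 Y + \varepsilon (-Y + b_1 X).
\]

\(X\) is autocatalytic through the saturating (Hill) term and activates
its own slow inhibitor; \(R\) is the external stimulus and \(U_N\) a
zero-mean white-noise input on the activator only.  The Laplacian is the
central-difference operator with periodic wraparound; integration is
explicit Euler–Maruyama at `dt = 0.01` with the diffusive stability
bound `dt * max(D_X, D_Y) / dx^2 <= 0.5` enforced at construction.
Above a threshold perturbation the activator fires to the excited branch
of its fast dynamics (all-or-none response, `threshold_probe()`); the
slowly accumulating inhibitor terminates the excursion and leaves the
fired region refractory (`refractory_period()`).

### Parameter calibration

The shared constants are
`D_X = 30, D_Y = 2, a1 = 1, a2 = 1, a3 = 8, a4 = 2, a5 = 0.04,
epsilon = 0.3`, with `dx = 1` model length unit (no physical micrometre
claim).  They were calibrated, in this order, to make the network

* **monostable and excitable**: the resting state sits on the lower
  branch of the activator nullcline (`a5` small, `a3/a4` setting the
  firing threshold near 0.5 concentration units, roughly ten times the
  resting level), with a sharp all-or-none jump whose suprathreshold
  peaks agree to better than 25%;
* **terminating**: the inhibitor gain and time scale (`b1`, `epsilon`)
  quench an excursion after a few time units rather than freezing it
  into a stable spot (slow inhibitor diffusion, `D_Y = 2`, lets
  inhibitor accumulate locally, which is what ends the excursion);
* **spatially patchy**: fast activator diffusion (`D_X = 30`) lets a
  nucleated firing recruit a wave that covers roughly a fifth of the
  perimeter before being quenched, so single events move the spatial
  mean of \(Y\) well clear of its resting value.

The two presets modulate only the inhibitor gain and the noise level,
the two knobs that set the firing threshold and rate:

| preset | `b1` | `sigma_N` | phenotype |
|---|---|---|---|
| `high_threshold` | 1.2 | 0.30 | rare localized firings, discrete ERK pulses |
| `low_threshold` | 0.6 | 0.40 | frequent/persistent firings, sustained ERK |

### Noise model

Increments are Gaussian with Euler–Maruyama scaling
\(\sqrt{dt}\,\sigma_N\), applied to the activator only.  They carry a
spatial correlation length (`noise_corr_len = 10` grid points, Gaussian
kernel, unit marginal variance).  Spatially *independent* increments
were tried first and rejected: nucleating a coherent firing then
requires a per-point noise amplitude so large that the rectified
subthreshold fluctuations lift the mean inhibitor drive into the range
of genuine firing events, and no switch threshold can separate the two.
A finite correlation length is also the physically sensible reading of
receptor- and cytoskeleton-derived fluctuations, which are not
pixel-independent.  Setting `noise_corr_len = 0` recovers the fully
independent model.

### Time scale

The integration step is 0.01 model seconds while observed ERK pulses
live on a minutes scale, so display time is mapped through a single
factor: `time_scale = 0.5` displayed minutes per model time unit.  With
this choice the deterministic refractory period (13 model units = 6.5
min) and the inter-pulse intervals (roughly 10–30 min) land in the
experimentally reported range, and a "2-hour" run is 240 model units.

## The ERK switch

The global active-ERK state \(Z\) follows

\[
\frac{dZ}{dt} = c_1\!\left(\frac{U_E (c_2 - Z)}{c_3 + (c_2 - Z)}
  - \frac{c_4 Z}{c_3 + Z} - c_5 Z\right),
\]

a Goldbeter–Koshland covalent-modification cycle with an extra linear
loss `c5` that sharpens the decay of the state after the drive is
withdrawn.  The drive is the instantaneous spatial mean of the
inhibitor, \(U_E(t) = \overline{Y}(\cdot, t)\); no diffusion of \(Z\) is
modeled because the readout is cell-global.  Defaults:
`c1 = 30, c2 = 1, c3 = 0.01, c4 = 0.3, c5 = 0.05`.  `c3/c2 = 0.01` puts
the cycle deep in the zero-order regime (EC90/EC10 ≈ 1.2 versus the
Michaelian 81, `ultrasensitivity_ratio()`), and `c4` sits between the
resting drive (≈ 0.05) and the drive delivered by a single firing
(≈ 0.4), so single protrusive events flip the switch essentially fully —
the model's account of why protrusions covering a small fraction of the
perimeter produce full-scale ERK pulses.  `c1 = 30` makes the switch
fast relative to the excursion time scale so \(Z\) tracks events rather
than integrating them.

Integration is classical RK4 with the drive held piecewise-constant
between samples and substeps of at most `0.05 / c1`.  `[0, c2]` is an
invariant region of the exact flow; the integrator clips its own
micro-overshoot back into it, which also keeps it clear of the pole of
the rate law at \(Z = c_2 + c_3\).  A step-halving guard warns when the
median trajectory change exceeds 0.1% of the pool (the median, not the
maximum, because when the drive sits exactly at the switch point the
flip *time* is infinitely sensitive and pointwise differences there say
nothing about step quality).

## Stimulation protocols

Growth-factor input enters as the uniform stimulus \(R\), which offsets
the inhibition term.  The built-in EGF protocol (`stim_egf()`) is an
onset spike (amplitude 3 for 2 time units) followed by an adapted
plateau (0.7): receptor activation peaks on ligand addition and adapts
to a lower sustained level.  A constant step cannot reproduce the
observed phenomenology at any single amplitude — a weak step leaves the
resting state locally stable, so firing stays noise-nucleated and
patchy; a strong step parks the network in a stable excited state with
ERK locked on.  With the spike + plateau form the spike fires the whole
perimeter at once (a global first response and a large first ERK peak),
and the plateau removes the resting state while keeping the excited
state unstable, producing a relaxation oscillation: partially
synchronized secondary firings whose ERK peaks recur at roughly the
refractory period.  Ending the stimulus after the spike (the transient
protocol) leaves exactly one ERK peak of the same magnitude as the
sustained run's first peak.

## The frame difference method

For every pixel, the percent change between two `avg_window`-frame
temporal averages separated by `interval_minutes`:
`pct = 100 * (later - earlier) / earlier`, so +100 is exactly a twofold
increase.  Defaults follow the published analysis: a 6-min interval,
3-frame averaging (the midpoint of the stated 2–4 range), a 100%
threshold for boundary protrusions with a 5-min minimum duration and a
25-px minimum area, and a 10% threshold for interior flashes after
eroding 10 px off the boundary.  Denominators below an intensity floor
(1% of the stack maximum by default) are masked `NA`, never silently
zeroed.  Detected pixels are grouped by 8-neighborhood connectivity
within a frame and linked across consecutive frames by at least one
pixel of overlap, with no gap closing.  Each percent-change frame is
timestamped at the midpoint between its two window centers, which is
where a detected change actually happened; planted-event onsets are
recovered to within one frame under this convention.

Conventions: pixel coordinates are 1-based, row-major, origin top-left;
angles around the perimeter are measured counter-clockwise from the +x
axis at the cell centroid with y pointing up (decreasing row).
Kymograph bins take the maximum percent change over a 3-px band along
the boundary.

Cell segmentation (`segment_cell()`) is a deterministic stand-in for the
interactive tool used in practice: per-frame Otsu threshold, largest
connected component, hole filling, ordered boundary contour.

## Trace quantification

* `cn_ratio()`: mean cytoplasmic over mean nuclear reporter intensity,
  optionally divided by the same ratio of a volume marker to cancel
  shape-driven artifacts.
* `detect_pulses()`: after optional 3-frame smoothing, local minima are
  candidate baselines and subsequent maxima candidate peaks; a pulse is
  called when the fractional increase exceeds 20%.  An internal dip
  whose rise to the next peak stays at or below the calling threshold
  does not separate two events: the rises are merged into a single
  event flagged `fused` (pulses riding on one another's shoulders rather
  than returning to baseline), with ties between equal peaks resolved
  toward the earlier one.  Because the threshold is a ratio, the caller
  is invariant to rescaling the trace.
* `cross_correlation()`: Pearson correlation of overlapping segments at
  every integer-frame lag; positive best lag means the second trace
  follows the first.  Ties go to the smallest absolute lag, then the
  negative one; zero-variance overlaps are flagged and excluded.
* `half_max_lag()`: each ERK pulse is paired with the nearest preceding
  protrusion peak within a 15-min window (a documented stand-in for the
  narrative pairing used in practice), and the lag is measured between
  linearly interpolated half-maximum rising-edge crossings, reported as
  mean ± s.e.m. (sample s.d. / sqrt(n)).

## The synthetic generator

`synth_movie()` renders a disc cell (radius 40 px in a 120-px frame)
with a nucleus (radius 15 px) at 1 frame/min.  Scheduled protrusions are
boundary-attached patches whose intensity rises exponentially to
`amplitude_fold`-fold over the event duration, holds, and decays; the
exponential ramp keeps the percent change above the twofold threshold
for longer than the 5-min duration filter, as real accelerating
protrusions do.  The translocation reporter moves intensity from nucleus
to cytoplasm — total intensity conserved per frame, so C/N changes are
purely redistributive and volume normalization is testable — with a
configurable delay (default 5 min) and a fractional C/N increase equal
to `erk_gain * (amplitude_fold - 1)`.  Interior flashes perturb interior
intensity only.  Noise is additive Gaussian; the SNR-5 test condition is
`noise_sigma = 20` on a baseline of 100.  `synth_traces()` generates the
paired-trace analogue: Gaussian activity bumps with jittered onsets and
random amplitudes, plus a delayed, gain-scaled ERK copy.  Everything is
bitwise reproducible under a mandatory seed.

What the generator does *not* emulate: boundary deformation (the cell
shape is static; protrusions are intensity events, as seen by the
frame-difference method), photobleaching, uneven illumination, focus
drift, multiple cells, or Poisson shot noise (optional additive Gaussian
only).  Passing tests therefore demonstrate correctness of the analysis
logic and thresholds, not robustness to every real-microscopy artifact.

`render_from_model()` bridges simulation to imaging: the activator field
becomes boundary-band enrichment at matching angles and the ERK state a
global reporter redistribution, so the whole analysis stack can be run
on the model's output (the rendered perimeter kymograph correlates with
the underlying activator kymograph at r > 0.9).

## Problem sizes and numerical checks

Regime runs use 240 model units (a 2-hour-equivalent observation) at
`sample_every = 25`; stimulus runs 300 units.  Synthetic movies are
120 × 120 px over 120 min.  Convergence of the Euler–Maruyama scheme is
checked deterministically by step halving at `dt = 2.5e-4` through a
full firing excursion (relative change ≤ 1e-4); the ERK steady state is
verified against an interpolated 10^6-point dense-scan root; the
discrete Laplacian against its analytic cosine eigenvalues.  Degenerate
inputs fail loudly: non-finite states name the diverging step, empty
masks name the frame, missing TIFF sidecars are errors rather than
defaults, and the event trackers return empty, well-typed tables rather
than NULL.

## Known limitations

* The perimeter is 1-D with a static geometry; there is no
  mechanochemical boundary deformation and no 2-D membrane simulation.
* Model parameters are calibrated to reproduce the qualitative regime
  dichotomy and stimulus phenomenology, not fitted to any experimental
  movie; absolute concentrations and lengths are in model units.
* The refractory period depends on the probe amplitude (a
  near-threshold probe recovers later than a strong one); the default
  scan reports the 80%-recovery gap.
* Segmentation assumes one bright cell on a dark background.
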