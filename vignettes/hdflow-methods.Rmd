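---
title: "Methods: event-driven hyperdimensional classification of flowing microparticles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event-driven hyperdimensional classification of flowing microparticles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdflow)
```

## The measurement this package models

In label-free imaging flow cytometry, microparticles are pumped through a
microfluidic channel that is illuminated by a coherent source (a He–Ne
laser at 632.8 nm in the reference setup). Each particle crossing the
beam throws a diffraction/interference pattern onto a sensor; for a
roughly spherical particle the pattern is Airy-like, and its angular
scale is inversely proportional to the particle diameter, so particle
size is encoded in the ring geometry. Instead of a frame camera, an
event-based camera (dynamic vision sensor, DVS; 640 × 480 pixels,
10.56 µm pitch in the reference setup) watches the pattern: each pixel
independently emits an *event* whenever its log-brightness moves by more
than a contrast threshold, tagged +1 (brightening) or −1 (dimming).
A particle transit therefore yields a sparse cloud of timestamped,
polarity-tagged events rather than an image sequence.

Classification uses hyperdimensional computing (HDC). A transit is
reduced to a long binary feature vector; training *bundles* the vectors
of each class into one prototype hypervector by bitwise majority voting

$$P_l[j] = \mathrm{majority}\left(V_1^l[j], \ldots, V_{N_s}^l[j]\right),$$

and a query $V_q$ is assigned to the class whose prototype minimises the
Hamming distance

$$\mathrm{Ham}(A, B) = \sum_{j=1}^{D} A_j \oplus B_j, \qquad
  l^* = \arg\min_l \mathrm{Ham}(P_l, V_q).$$

Training is a single pass with no gradients; two properties of the
metric anchor the whole scheme: $\mathrm{Ham}(A,A) = 0$, and two
independent uniform binary vectors concentrate at distance $0.5\,D$, so
genuine structure stands far out of the background.

## From events to binary features

One recording (one transit) passes through this chain:

1. **Accumulation window.** Events in a window are counted per pixel and
   polarity (`accumulate_frame()`). The default window is the central
   30 % of the recording's time span (`central_window()`); see below for
   why.
2. **Binarization.** Counts become presence/absence bits: a map bit is 1
   iff at least one event (of that polarity) fell in the pixel
   (`binarize_frame()`). Each hypervector element thus encodes "events
   in this region or not".
3. **Down-sampling.** Each polarity map may be OR-pooled over
   non-overlapping blocks (`downsample_or()`): the coarse cell is 1 iff
   any of its pixels is 1. OR-pooling is the pooling consistent with
   region-presence semantics (a region saw an event iff some sub-region
   did), and it is applied per polarity map, before concatenation, so
   the split/merged factor of two holds at every resolution. A stride
   mode exists for comparison only.
4. **Polarity handling.** `split` concatenates the positive and
   negative maps (feature length $2 H' W'$); `merged` ORs them
   ($H' W'$), discarding polarity.

The encoder (`hdc_encoder()`) is the identity by default — the binary
pixel feature *is* the hypervector, which is exactly the "optical
scattering generates the code" idea; a `subsample` mode takes a frozen
seeded permutation prefix of the feature, providing a conventional
fixed dimension such as $D = 10{,}000$ when wanted. Neither mode is
claimed to be what any particular laboratory pipeline used; the mapping
from pixel counts to a round $D$ is generally left unstated in
experimental reports.

### Why the window is central, not the whole transit

With presence/absence encoding over a *complete* transit, the positive
and negative maps are close to copies of each other: every pixel whose
intensity rises as the pattern appears must fall back when it
disappears, so "ever brightened" and "ever dimmed" pick out nearly the
same pixel set, and keeping polarity cannot add information. Real
event-camera reconstructions of such patterns show clearly distinct
positive and negative components — because a short reconstruction
window mid-transit is dominated by *fringe motion*: a moving or
rescaling ring brightens pixels on one flank while dimming the other,
putting the two polarities on complementary, class-dependent pixel
sets. The package therefore accumulates features over the central 30 %
of each recording (`window_fraction = 0.3`). With this choice the
polarity ablation on synthetic data reproduces the experimentally
reported direction (split ≥ merged, strictly better when only polarity
discriminates); with `window_fraction = 1` the two modes become
statistically indistinguishable, for the structural reason above.
How single-particle samples are delimited in time is an
implementation decision in any such pipeline; `segment_transits()`
(rate-thresholded bins with gap bridging) is provided for recordings
containing several transits.

## Evaluation protocols and measurement bias

Acquisition conditions drift between measurement sessions: source
intensity fluctuates, beams walk, refractive indices creep. When each
class is recorded in its own session (classes acquired sequentially),
that drift is *class-correlated*: a classifier can exploit
session-specific artefacts as if they were class signal. The package
implements both protocols explicitly:

* `split_single_session()` — train and test drawn from the same
  session, per class (the optimistic protocol; default train fraction
  10/11, mirroring a 6,000/600 per-class sizing);
* `split_intertwined()` — whole sessions assigned to train or test,
  with disjointness asserted, so session drift cannot leak. The default
  intertwined figure is leave-one-session-out averaged over all
  holdouts (`loso_accuracy()`); the exact train/test session assignment
  used in any given experimental report is typically unstated, and
  LOSO is the symmetric, assignment-free choice.

`evaluate_model()` tallies the confusion matrix; `accuracy()` is
micro-averaged (trace over total), which on the class-balanced test
sets used here equals the per-class mean.

## The synthetic-data generator

No public recordings of this kind exist, so the package ships a
simulator whose role is to reproduce the *statistical structure* of the
experiment — not its photometry. `generate_dataset()` runs, per sample:

1. **`render_transit()`** — an Airy-type radial profile
   $(2 J_1(v)/v)^2$ with first-ring radius `ring_scale / diameter`
   pixels (Airy $1/d$ scaling; default `ring_scale = 720` px·µm puts
   the stock 9/12/16/20 µm beads at radii 80/60/45/36 px on the full
   sensor). Over the transit the pattern (i) fades in and out with a
   $\sin^2$ envelope that reaches zero at both ends, (ii) translates
   down the sensor by `travel_fraction` of its height (the channel is
   vertical), and (iii) its rings grow monotonically by `breathing`
   (20 % by default) as the particle crosses the beam waist. The
   per-session drift sample applies gain to the pattern over an
   un-gained background floor (a pure gain on *everything* would cancel
   in log-intensity differences and be invisible to the sensor), an
   additive background offset, and a beam-centre shift; per-particle
   lateral jitter and amplitude jitter model streamline spread.
2. **`apply_diffuser()`** — a ground-glass diffuser of grit 120/600/1500
   is modelled as a thin random-slope surface: every pixel's light is
   deflected by a frozen random displacement field, smooth at the
   `speckle_grain` scale (default 4 px) and with amplitude
   `envelope_sigma` that *decreases* with grit number (coarser glass
   deflects more; defaults 18/8/3 px), then modulated by a frozen
   speckle field — the interference grain, which stays sharp however
   wide the scattering cone is. Both fields come from one seeded
   realisation per physical diffuser, shared by all frames and
   samples. Deflection was chosen over an intensity-domain blur
   deliberately: a low-pass blur *erases* the class-specific ring
   structure and makes wider scattering strictly worse, whereas a
   ground glass physically redirects light, spreading the pattern
   while preserving its information — which is what lets a coarse
   diffuser help rather than hurt. Energy is redistributed, not
   absorbed (each frame is rescaled to its input total). Only the
   *ordering* of pattern widths across grits is asserted anywhere; the
   magnitudes are package defaults, and diffuser comparisons are run
   paired (same transits through each glass).
3. **`simulate_dvs()`** — the standard per-pixel contrast-threshold
   model: a pixel remembers a reference log-intensity and emits one
   event per threshold step crossed by the linearly interpolated
   log-intensity, ±1 by direction, with the closed form that a monotone
   ramp of size $\Delta$ yields $\lfloor \Delta/\theta \rfloor$ events
   per pixel. The default threshold is 0.15 with symmetric ON/OFF
   (asymmetric comparator bias is available via `off_threshold`). An
   $\varepsilon = 10^{-3}$ floor inside the logarithm avoids $-\infty$
   at dark pixels. Background noise events arrive uniformly at
   `noise_rate` events/pixel/s, and a per-pixel refractory time
   (default 10 µs) suppresses an event closer than that to the
   preceding event at the same pixel (implemented as a single pass over
   time-sorted per-pixel events).

Session drift is drawn once per (class, session) block when
`class_correlated = TRUE` — emulating sequential acquisition, the
source of measurement bias — or once per session shared across classes
otherwise. Every draw derives from `master_seed` through named child
seeds (`derive_seed()`), so a dataset is a pure function of its
configuration.

### What the simulator does and does not capture

It reproduces: the size ordering of pattern scales; polarity structure
concentrated on moving fringe flanks; grit-ordered envelope broadening
with a frozen speckle mask; class-correlated session drift and its
inflationary effect on single-session evaluation; event sparsity and
background noise. It does **not** attempt: rigorous Mie/Fraunhofer
scattering, coherent speckle statistics beyond a seeded multiplicative
field, fluidics (velocity profiles, rotation), multi-particle
coincidences, or sensor non-idealities beyond threshold/refractory/
noise. Notably, the *absolute* accuracy improvement that a coarse
diffuser produced experimentally over the no-diffuser condition is not
reproduced — in this simulator the diffuser's frozen mask mostly trades
information around — and so only within-diffuser orderings are ever
asserted. Passing the package's synthetic checks therefore says the
pipeline is correct and the directional phenomenology is right, not
that any particular accuracy is to be expected on real recordings.

## Study conditions used by tests and the acceptance script

The full-scale conditions (640 × 480 sensor, 6 sessions per class,
thousands of transits per class) are the `simulation_config()`
defaults. Routine verification runs on proportionally scaled-down
conditions chosen once and frozen in `demo_config()`: a 160 × 120
sensor with `ring_scale = 180` (stock diameters at radii 20/15/11.25/9
px), drift scaled to the smaller patterns (`gain_sd = 0.15`,
`offset_sd = 0.01`, `center_jitter_sd = 1.5` px), background rate 5
events/pixel/s, 6 sessions × 25 transits per class. The
feature-dimension sweep runs on the full 640 × 480 sensor with 12
transits per class and session, comparing full resolution against the
5 × 5-pooled 128 × 96 map. The measurement-bias experiment uses 10
freshly seeded repetitions at 4 sessions × 12 transits; the diffuser
comparison uses 5 seeded repetitions per grit at 3 sessions × 12
transits, with the per-grit deflection widths scaled by the same 1/4
factor as the sensor (`envelope_scale = 0.25`). These sizes are the package's choices for routine runs;
all of them scale up by changing the configuration only.

## Numerical and design notes

* Windows are half-open `[t_start, t_end)`; coordinates are 0-based
  with `x` the column and the origin top-left; on-disk polarity is
  `{0,1}` (0 ≡ −1), in-memory `{−1,+1}`.
* Majority ties (even class sizes) are broken by a tie-break
  hypervector drawn once from `tie_seed` — never re-drawn, so training
  is deterministic and order-free. Prediction ties go to the smallest
  class label.
* Binarization is presence at ≥ 1 event; a `min_count` extension exists
  but is off by default.
* The Airy profile is tabulated once on a fine grid (`u` step 0.005 up
  to 6 first-ring radii) and indexed by rounding — the pattern is
  smooth at the pixel scale, so interpolation error is far below the
  contrast threshold.
* Gaussian blurs use dense row-normalised separable operators, making
  the diffuser mass-preserving up to edge truncation, after which each
  frame is rescaled exactly.
* `floor(d/θ + 10⁻⁹)` guards threshold counts against floating-point
  representation of exact multiples.
* Model files store prototypes as hexadecimal-packed bits in JSON;
  event files are CSV (`t,x,y,p`) or Parquet with sensor dimensions in
  schema metadata.

## A worked run

```{r example, eval = FALSE}
cfg <- demo_config(master_seed = 1)
dir <- tempfile("hdflow")
manifest <- generate_dataset(cfg, dir) # 4 classes x 6 sessions x 25

fs <- build_features(manifest, cfg$optics$sensor, dir = dir,
                     block = c(2, 2))
loso_accuracy(fs)$accuracy # intertwined (leave-one-session-out)

split_intertwined(manifest, train_sessions = 1:5, test_sessions = 6)
```

The same pipeline is scriptable from a shell through the `hdflow`
command (see `inst/cli/hdflow`): `simulate`, `train`, `evaluate`,
`ablate-polarity`, `sweep-dims`, `compare-diffusers`.
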