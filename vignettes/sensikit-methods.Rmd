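---
title: "sensikit: models, thresholds, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sensikit: models, thresholds, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why: the
analysis conventions of each assay arm, the thresholds that matter, the
synthetic generators and what they do and do not emulate, and the design
choices made where more than one reading was defensible.

## 1. Calcium-imaging responder calling

### The model

A recording is a per-ROI raw fluorescence trace `F(t)` over four ordered
epochs: pre-compound baseline, drug application, wash, and a terminal
50 mM KCl depolarisation that serves as the viability positive control.
The fractional change is

```
dF/F(t) = (F(t) - B1) / B1
```

with `B1` the mean of `F` over the baseline window. Because every
criterion is a ratio of dF/F values to dF/F dispersions, the calls are
invariant under rescaling of the raw trace (`F -> c·F` for any `c > 0`) —
the pipeline is therefore detector-agnostic, and Fura-2 340/380 ratio
traces pass through as "raw F" without special handling. No absolute
calcium calibration is attempted.

Two baselines are kept. `B1` (raw units, with its SD) anchors dF/F; a
second baseline — mean `B2` and SD `s2` of dF/F over the wash window just
before KCl — anchors the live-cell criterion, because slow drift across a
long recording would otherwise distort a KCl threshold referenced to the
start of the experiment.

### The criteria and their parameters

All defaults live in `responder_params()`:

| parameter | default | meaning |
|---|---|---|
| `k_sd` | 3 | SD multiplier of both criteria |
| `live_min_frames` | 10 | KCl frames above `B2 + k·s2` for a live call |
| `responder_min_frames` | 80 | drug-epoch frames above the baseline threshold (about 2 min at the default 1.5 s frame period) |
| `onset_window_s` | 300 | maximum latency of the first suprathreshold frame after compound application |
| `min_amplitude` | 0.10 | minimum peak dF/F of a response |

Decisions taken where the convention is genuinely open, each exposed as a
parameter or documented here:

* **Which baseline feeds the responder predicate.** The responder
  threshold is evaluated against the *pre-compound* baseline in dF/F space
  (mean 0 by construction, SD estimated over the baseline frames). The
  wash baseline is the plausible alternative; `responder_params(responder_baseline
  = "baseline2")` switches to it. The pre-compound reading is the default
  because the predicate asks whether the *drug epoch* deviates from the
  state before the drug.
* **Cumulative, not consecutive frames.** The 80 suprathreshold frames are
  counted cumulatively within the drug epoch. Oscillatory responders dip
  below threshold between peaks; a consecutivity requirement would
  misclassify them.
* **Response timeframe.** The top-3-frame "max % response" and the
  amplitude check run from the onset frame (first suprathreshold drug
  frame) to the end of the drug epoch.
* **Amplitude floor.** "At least 10% above baseline" is read as
  `dF/F >= 0.10` at some frame of the response.
* **Windows are 1-based inclusive frame intervals**, the R indexing idiom;
  all boundary behaviour (80 vs 79 frames, 10 vs 9 frames, 299 s vs 301 s
  onset) is pinned by tests.

Negative calls carry a reason code (`dead`, `insufficient-frames`,
`late-onset`, `sub-amplitude`); a dead cell queried for responder status is
a non-responder with reason `dead`, never an error.

### Transient archetypes

`characterize_transient()` reports peak count, time to peak and post-peak
half-decay, and attaches one of four descriptive labels: `oscillatory`
(>= 3 peaks at >= 50% of the window maximum), else by half-decay —
`slow` (>= 40 s), `intermediate` (10–40 s), `rapid` (< 10 s) — or
`unclassified` when the trace never decays to half its peak. These cutoffs
are heuristics chosen to separate the generator's archetypes cleanly; the
label is descriptive only and never feeds classification.

## 2. Immunofluorescence purity

The chain is: maximum-intensity projection per channel, binarisation, DAPI
particle counting, and pairwise colocalization. Choices:

* **Otsu** is the default automatic threshold (a fixed threshold is
  available). Constant images raise a degenerate-threshold error rather
  than returning an arbitrary mask.
* **Connected components use 8-connectivity**, matching the usual particle
  analysis convention. The labelling runs a fast 4-connected pass and then
  merges diagonally adjacent labels through a graph components step.
* **Area-to-count rule** (all areas in µm², from the pixel size): below
  30 exclude (debris, dead-cell specks); above 130 count 2; above 200
  count 3. "Above" is strict — exactly 130 µm² is one nucleus, exactly
  200 µm² is two.
* **Colocalization is the pixelwise AND of the two marker masks**, with
  components counted under the same area rule. This replaces interactive
  colocalization thresholding with a deterministic, auditable equivalent
  for nuclear stains; intensity-correlation coefficients (Pearson,
  Manders) are out of scope.
* Purity = `100 · double_positive / DAPI`; a slide with zero DAPI nuclei
  is an explicit error, and a double-positive count exceeding the DAPI
  count is flagged, never clipped.

## 3. Current-clamp feature battery

* **AP detection**: an action potential is an upward crossing of
  dV/dt >= 10 mV/ms, with the derivative taken as the forward difference at
  the native sampling rate and no smoothing by default. Crossings within
  2 ms of an accepted onset merge into the same event — a spike's rendered
  upstroke can cross the threshold twice (biological rise, then the
  stereotyped apex), and the merge window absorbs that without ever
  splitting one spike into two. The event peak is the Vm maximum within
  5 ms of onset.
* **RMP** is the mean over the 200 ms immediately before the stimulus;
  shorter pre-stimulus segments raise a window error.
* **Rheobase** is the smallest step amplitude whose 200 ms window contains
  at least one detected AP; `NA` when nothing fires up to the protocol
  maximum, which feeds the exclusion rule.
* **Waveform features** are taken from the *first suprathreshold sweep* of
  the held-at-−75 mV protocol. Threshold = Vm at the first dV/dt crossing;
  amplitude = peak minus the reference level; half-width = interpolated
  duration at half amplitude; fAHP = Vm minimum between the first peak and
  the next event onset (or step end); mAHP = Vm minimum in a 200 ms window
  after step offset (the "after the stimulus" window had to be given a
  concrete length; 200 ms covers the medium AHP timescale without reaching
  the next sweep). The amplitude reference defaults to the *measured*
  pre-stimulus holding level (nominally −75 mV) rather than a hard-coded
  constant, which keeps amplitude and half-width invariant under the LJP
  shift; a fixed reference is available.
* **LJP**: corrected = recorded + (−14 mV) by default; the sign convention
  is configurable because conventions differ between rigs, and a state
  flag makes the correction idempotent (correcting twice is an error).
* **Firing pattern** is judged across all sweeps: `multiple` if any sweep
  holds >= 2 APs, `single` if the maximum is 1, `none` otherwise. Judging
  at rheobase or at a fixed multiple of rheobase are defensible
  alternatives; the all-sweeps rule is the least sensitive to where the
  amplitude grid happens to land relative to threshold.
* **Exclusions**: no AP up to the protocol maximum, or RMP above −40 mV.
* **Capacitance and input resistance** are accepted as metadata when an
  amplifier readout provides them; no estimator is implemented because no
  single measurement convention (test pulse, amplifier estimate) is
  assumed.

## 4. The synthetic generators

The generators exist so that every stage has inputs with machine-readable
ground truth. They emulate the *decision structure* of real data — epochs,
thresholds, margins, event counts — not its physics.

**Calcium cohorts.** Default frame period 1.5 s (so 80 frames span about
two minutes); default epoch layout 120 s baseline, 300 s drug, 120 s wash,
60 s KCl — the ordering is the experimental convention, the durations are
this package's defaults. Live cells carry a sustained KCl transient; true
responders carry an archetype transient (decay constants: slow 60 s,
intermediate 20 s, rapid 5 s; oscillation period 15 s — plausible values
chosen to make the ordering unambiguous) riding on a plateau built to clear
every criterion by the configured `response_margin` (frame counts scaled
up, the onset window scaled down, amplitudes scaled up). With margin
>= 1.5 and noise SD at most a tenth of the amplitude, label recovery is
exact by construction, and the tests hold the classifier to exactly that.

**Slides.** Disks on a 512² grid at 0.62 µm/px (a 20× objective scale);
nucleus radius 5 µm (area about 78.5 µm², comfortably inside the
one-nucleus band), merged pairs at 1.6 radii centre distance (union area
about 150 µm², inside the two-nucleus band), debris radii 1.2–2.4 µm
(always below the 30 µm² exclusion). Objects are placed by rejection
sampling so distinct objects never touch.

**Neurons.** An adaptive exponential integrate-and-fire (AdEx) model,

```
C dV/dt = -gL (V - EL) + gL·dT·exp((V - VT)/dT) - w + I
tau_w dw/dt = a (V - EL) - w
```

integrated with fixed-step Euler at 20 kHz, reset on a 0 mV cutoff with
`w += b`. AdEx was chosen over a conductance-based model because its reset
events are an unambiguous, cheap ground truth for spike counts and
rheobase. At each reset a stereotyped 2 ms triangular spike to +30 mV is
pasted onto the trace — a rendering convention that gives the dV/dt
detector a realistic upstroke; the fall lands on the value the underlying
simulation reached, so the rendered trace has no seam for the detector to
misread. Two default choices are deliberate simulator-design constraints:
capacitance (120 pF) is large enough that the passive charging slope of
the largest protocol step stays below the 10 mV/ms detection threshold,
and the reset potential (−65 mV) is deep enough that inter-spike intervals
stay above the detector's 2 ms merge window. Within those constraints,
detector counts and oracle reset counts agree exactly, which is what the
recovery tests assert. Membrane noise is white with a per-sqrt(ms) SD;
the default is 0 because the recovery guarantees are stated noise-free.

**What the generators do not emulate** — and hence what passing tests do
*not* show about real data: photobleaching, focus drift and motion;
indicator saturation and dye-loading variability; overlapping or
out-of-focus nuclei beyond simple merges; electrode access resistance,
capacitive artefacts and channel noise; biological variability in spike
shape. Exact label recovery on synthetic cohorts demonstrates that the
implementation applies its stated criteria correctly, not that those
criteria are optimal for any particular rig.

## 5. The statistical battery

* `auto_compare()` gates on Shapiro-Wilk at α = 0.05 per group (the gate
  test had to be fixed; Shapiro-Wilk is the standard default), then runs a
  two-tailed pooled-variance unpaired t test or a two-tailed Mann-Whitney
  test. The Mann-Whitney branch uses the exact U distribution for small
  samples without ties and the tie-corrected normal approximation
  otherwise. The suite checks the gate's composite type-I error on
  Gaussian nulls (2,000 simulations, n = 20 per group) stays within
  [0.035, 0.065] at α = 0.05.
* `fisher_exact_2x2()` implements the two-sided rule directly: the p value
  sums hypergeometric probabilities of all tables with the observed
  margins whose probability does not exceed the observed one (relative
  slack 1e-7 for floating-point ties). Tests cross-check it against a
  `choose()`-based enumeration and against `stats::fisher.test`.
* `bonferroni_ledger()` keeps the family bookkeeping honest: per-test
  threshold `alpha/m`, display value truncated to three decimals (0.05/14
  = 0.003571… displays as 0.003), significance flags always computed on
  the untruncated threshold.
* `literature_meta()` pools per-study control/inflamed RMP pairs and
  reports both a pooled Mann-Whitney and a paired t, side by side, because
  the two can disagree on the same table — which is exactly the point the
  synthesis makes. Absolute effects are binned negligible / moderate /
  large with contiguous edges [0, 1.5), [1.5, 10), [10, ∞) mV: published
  descriptions of such bins are often gapped ("0 to 1", "2 to 6", "10+"),
  and contiguous edges with the boundary at 1.5 mV classify every possible
  effect without holes. Mixed-effects (REML) modelling of f–I curves is
  deliberately not reimplemented; the long-format spike-count tables
  export cleanly to `lme4`/`lmerTest`.

## 6. Orchestration and reproducibility

`validate_config()` accepts YAML or JSON, rejects unknown keys by name
(misspellings fail loudly rather than silently using a default), fills
documented defaults, and checks that every referenced input file exists
before any stage runs. `run_pipeline()` executes the requested stages in
dependency order and writes a single `manifest.json` with the package
version, the normalized config and its checksum, and an MD5 per output
file. Environment variables never override config files — explicitness
over convenience. Two runs with the same config and seed produce
byte-identical analysis files; only manifest timestamps differ.

## 7. Problem sizes and numerical notes

The test suite and the acceptance script use: 500-trace cohorts for
responder recovery (with 1,000-trace random cohorts for the
oracle-agreement checks), 20 randomized neuron configurations for
electrophysiology recovery, 100-nucleus slides for purity, and 2,000
simulations for the type-I calibration — sizes chosen so the guarantees
are exercised at meaningful scale while the whole suite stays quick on a
laptop. Degenerate inputs are errors, not silent defaults: empty cohorts,
constant images under Otsu, zero-margin tables, zero DAPI counts,
sub-200 ms pre-stimulus windows, and double LJP correction all raise with
a message naming the problem. Half-width crossings are linearly
interpolated between samples; all other feature measurements are read at
native resolution.

## 8. Known limitations

* The archetype labels depend on invented decay cutoffs; they are for
  description and figure-making, not inference.
* Otsu is not a bit-for-bit reproduction of any particular interactive
  thresholding tool; purities from differently thresholded masks can
  differ near the threshold.
* The AdEx simulator is a decision-structure stand-in for recorded
  neurons, not a biophysical model of DRG neuron firing.
* The bundled literature table is synthetic (see its filename); pooled
  p values computed from it exercise the code and do not estimate any
  real literature effect.
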