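---
title: "Methods: simulated self-driving microscopy for protein aggregation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated self-driving microscopy for protein aggregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sdmscope)
```

## What this package models

Protein aggregation in cellular models of Huntington's disease (mutant
Httex1 with an expanded polyQ tract) is rapid and unpredictable: an
aggregate condenses from the soluble pool within minutes to tens of
minutes, at a moment that cannot be anticipated by eye. Brillouin
microscopy (BM) can measure the viscoelasticity of the aggregate as it
forms — the Brillouin shift $\nu_B$ rises with stiffness, the linewidth
$\Gamma$ with viscous damping — but BM is a slow, point-scanned modality,
so pointing it at the right cell at the right time is the hard part.

The package implements the full control-and-analysis chain of an
event-triggered ("self-driving") microscope at desk scale, with a
simulated instrument in place of hardware:

1. **`synthetic_scope`** — a generative virtual microscope: multi-plane
   fluorescence time lapses, brightfield images and per-pixel Brillouin
   spectra, all rendered from an explicit ground-truth world state.
2. **`classifiers`** — a training/evaluation harness for the
   aggregation-onset classifier (fluorescence input) and the
   aggregate-presence classifier (label-free brightfield input).
3. **`sdm_engine`** — the acquisition loop: an initial low-dose scan over
   a stage grid, real-time scoring, and event-triggered optimized
   multimodal scans, in two trigger modes, on a virtual clock.
4. **`brillouin_analysis`** — per-pixel Lorentzian fitting, instrumental
   deconvolution, Otsu segmentation and aggregate-vs-periphery statistics.

## The virtual sample and the pre-onset cue

Each field of view holds one cell with a fixed fate: EVENT cells carry a
finite onset time $t_0$ and an aggregate site; NON_EVENT cells never
aggregate. The published system demonstrates that a network can predict
aggregation from images of soluble protein, but the physical signature it
exploits is unknown (humans cannot see it). A simulator must make that
signature *explicit and controllable*, so the generator defines one:

- during the cue window $[t_0 - \texttt{cue\_lead\_time}, t_0]$ a
  proto-punctum of peak contrast `cue_contrast` (relative to the local
  cell intensity) grows at the aggregate site, together with a ~10%
  local variance increase;
- the cue grows as $1 - e^{-4u}$ over the window ($u$ the window
  fraction): nucleation is fast, then the proto-punctum persists. A
  linear ramp was tried first and makes early-window events carry almost
  no signal, which is a statement about the simulator, not about the
  method;
- after $t_0$ the soluble pool condenses into a tight punctum over
  `onset_duration_s` (default 300 s), conserving total fluorescence
  exactly (up to bleaching $e^{-\lambda t}$) — condensation moves
  photons, it does not create them;
- with `cue_contrast = 0` EVENT and NON_EVENT frames are
  distribution-identical before onset; the test suite verifies both this
  and that the training harness then finds *no* signal.

Noise is Poisson shot noise (expected peak photons `photon_budget`) plus
Gaussian read noise, z-planes share lateral structure under a defocus
blur growing with distance from focus, and every renderer is a pure
function of (configuration, seed).

Two presets exist. `sim_config()` records the instrument-faithful
geometry: 352 px crops at 111 nm back-projected pixel size (≈39 µm FOV)
and 8 simultaneous z-planes. `benchmark_config()` keeps that pixel size
on record but renders 128 px images at `photon_budget = 500`, so a full
train-and-evaluate cycle runs in about a CPU-minute; the cue calibration
(`cue_contrast = 0.6`, proto-punctum σ = 3.5 px, saturating growth) was
fixed once so the reference classifier reaches the published accuracy
bands, and is not a per-run tuning knob.

The default dataset composition is 71 events / 68 non-events. (The
source material states 68 non-events in one place and 69 in another; the
package follows the first.)

## Classifiers without a deep-learning framework

No neural-network framework is available in the target environment, so
the four architecture families are re-specified at desk scale around a
**frozen convolutional stem** and a **trainable head** with hand-derived
gradients:

- the stem applies per-image min–max normalization, a
  difference-of-Gaussians band-pass matched to punctum scale with a
  matched-filter re-smoothing, a local-variance map, and pooling of both
  response tails (fluorescent puncta are bright; brightfield aggregates
  are absorption dips). Multi-plane frames additionally pool the
  z-profile of the band-pass response and a focus-minus-defocus contrast
  map — the punctum is axially confined, the cytosolic texture is not,
  so the difference cancels the texture;
- heads: a one-hidden-layer MLP (`SINGLE_FRAME_CONV`), softmax attention
  pooling over patch tokens (`SINGLE_FRAME_ATTENTION`,
  `VIDEO_ATTENTION`), and a simple recurrence over per-frame features
  (`CONV_RECURRENT`). Gradients are verified against finite differences
  in the test suite.

Training follows the published protocol exactly: Adam at learning rate
$10^{-5}$, binary cross-entropy, 15% test split, 20% of the remainder
for validation, early stopping on the validation loss (patience 10),
and checkpointing of the best-validation parameters. Splits are
stratified and cell-disjoint (examples from one cell never straddle
splits), with floor rounding and the remainder going to train.

Two numerical choices matter at this learning rate and deserve
explanation. Adam's step size is $\approx$ lr per parameter per
update regardless of gradient magnitude, so across 200 epochs parameters
move by only a few hundredths: (i) the readout layer is
zero-initialized, otherwise the random initial logit could never be
unlearned; (ii) the trained head operates in a "signed vote" regime —
scores hover near 0.5 but their ordering is informative, and Adam
naturally suppresses features whose gradients flip sign between
minibatches. Hidden layers act as random projection features. Decision
threshold is 0.5, ties classified positive.

```{r}
cfg <- benchmark_config()
ds <- simulate_onset_dataset(cfg, n_events = 71, n_nonevents = 68,
                             T = 1, Z = 8, seed = 0)
sp <- split_dataset(ds, 0.15, 0.20, seed = 0)   # 96 / 23 / 20
model <- train_classifier(sp$train, sp$val,
                          arch_spec("SINGLE_FRAME_CONV", c(1, 8, 128, 128)),
                          train_config(seed = 0))
evaluate(model, sp$test)$metrics
```

## The acquisition loop

`run_session()` advances a virtual clock by the declared duration of
every action: per-FOV move overhead (0.5 s default), exposures, and
`dwell × n_points` for Brillouin maps. The sample evolves with the
clock, so a late trigger genuinely misses its event. `BATCH` mode scores
all FOVs first and then iterates the positive list in scan order;
`IMMEDIATE` mode interrupts the initial scan to run the optimized scan
at the triggering FOV, then resumes. A FOV triggers at most once per
session, Brillouin is excluded from the initial (exploration) scan, and
replays are bit-identical given the same seed and configuration.
`score_session()` counts a trigger as a true capture when its FOV hosts
an EVENT cell and the first optimized frame starts before
$t_0 + \texttt{onset\_duration}$.

## Brillouin quantification

Spectra span one free spectral range (15 GHz default — not stated by the
source; typical for a two-stage VIPA at 660 nm — over 512 bins) and
contain Rayleigh remnants at the axis ends plus the mirrored
Stokes/anti-Stokes doublet at $\nu_B$ and $\mathrm{FSR} - \nu_B$.
`fit_spectrum()` performs nonlinear least squares of a shared-width
mirrored-Lorentzian model with the linear parameters (Brillouin
amplitude, Rayleigh-tail amplitude, baseline) profiled out, optimizing
only $(\nu_B, \Gamma_{\mathrm{meas}})$; 0.5 GHz guard bands at the axis
ends are excluded from the window. Modeling the Rayleigh tails (as
fixed-width instrumental Lorentzians at 0 and FSR) is required for the
noiseless round trip to be exact to $10^{-3}$ GHz: with the tails left
out, the least-squares width is biased by several tens of MHz.

Because Lorentzian convolution adds full widths exactly, the
instrumental response (270 MHz) is removed by subtraction:
$\Gamma = \Gamma_{\mathrm{meas}} - \Gamma_{\mathrm{instr}}$, clamped to
zero and flagged invalid when non-positive (unresolved peak). At the
100 ms reference dwell the Monte-Carlo shift estimator has bias
< 5 MHz and SD ≈ 2 MHz, consistent with the ±0.04 GHz spreads printed
for real aggregates.

Maps follow the inclusive-endpoint convention (`floor(W/s) + 1` points
per axis: 35 µm at 1 µm → 36×36; 10 µm at 0.2 µm → 51×51).
Segmentation uses Otsu thresholds (maximum between-class variance over a
256-bin histogram, ties to the lowest threshold, foreground strictly
above threshold): the fluorescence image localizes the aggregate, each
Brillouin map's own Otsu foreground defines its signal support, and each
quantity's periphery is its signal support minus the aggregate. Per-map
peripheries (rather than one combined mask) avoid coupling noise between
the shift and linewidth maps; this choice is flagged as an open
interpretation question of the source protocol.

## What a green test establishes — and what it does not

The synthetic benchmark shows that the *pipeline* — generator,
protocol-faithful training, trigger logic, spectral quantification — is
internally correct and meets the published accuracy bands on a world
whose cue is learnable by construction. It does not certify the
published real-data numbers (91% / 97%): the real pre-onset signature,
its SNR, and biological variability are unknown and not claimed by the
simulator. Likewise the capture-rate properties hold for events whose
cue windows cover their visit times; real sessions miss events whose
windows close before the scan arrives.

## Known limitations

- No physical optics beyond Gaussian defocus; no stage drift, no
  registration errors (planes are emitted registered).
- The cue model is an explicit invention; only its controllability (not
  its realism) is load-bearing.
- Brillouin truths are piecewise-constant per region with a linear onset
  ramp; no sub-aggregate structure.
- Longitudinal-modulus conversion is out of scope (requires refractive
  index and density).
- The architectures are desk-scale analogs; no claim is made about
  VGG16/ViT weight-level behavior.
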