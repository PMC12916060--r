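---
title: "Trace learning of transform-invariant object representations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trace learning of transform-invariant object representations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`visnetr` simulates a rate-based, feedforward, unsupervised model of the
primate ventral visual stream: a hierarchy of four competitive networks
(Layers 1–4, corresponding roughly to V2, V4, posterior and anterior
inferior temporal cortex) on top of a Gabor-filtered model of V1. The
scientific question it addresses is how neurons at the top of the ventral
stream come to respond to *all* views of one object and to *no* views of
other objects, using only a local synaptic learning rule and the temporal
statistics of natural viewing — no error backpropagation, no labels, no
weight sharing.

The machinery, stage by stage:

**V1 front end.** A grayscale 256×256 image is convolved with a bank of
even-symmetric Gabor filters at 4 spatial frequencies (wavelength halving
per band) × 4 orientations, and each signed response is split into rectified
positive and negative channels, giving a 256×256×32 input volume of
non-negative "firing rates" in [0, 1].

**Architecture.** Each Layer is a 32×32 sheet of neurons (the `small-32`
preset; `large-256` scales the sheets to 256×256). A neuron receives
`n_connections` afferents (340 for Layer 1, 200 for Layers 2–4) sampled
without replacement from an isotropic 2-D Gaussian centred on its
retinotopic projection into the presynaptic sheet; the stated radius
(15 input pixels for Layer 1, 7 grid units for Layers 2–4) contains ≈67% of
the connections. The radii are chosen so that Layer-4 neurons are reachable
from the entire retina.

**Activation and competition.** A neuron's activation is the inner product
of its weight vector with its afferent rates. Within a Layer, competition is
implemented by a firing threshold: the threshold of the sigmoid
`y = 1 / (1 + exp(−2β(r − α)))` is set by search so that the population
sparseness `a = (Σy/n)² / (Σy²/n)` of the resulting rates matches a target
(default 0.01, i.e. ≈1% of neurons firing). Sub-threshold neurons fire at
exactly 0; the representation is sparse and graded, not winner-take-all.
An optional difference-of-Gaussians lateral-inhibition stage is provided
but disabled in the shipped presets, where the sparseness threshold carries
the competition.

**Trace learning.** During training all views of one object are presented
consecutively (in random order) before the next object. Each neuron keeps a
short-term memory trace `ȳ_τ = (1−η)·y_τ + η·ȳ_{τ−1}` (η = 0.8 by default).
Layers 2–4 use the trace as the postsynaptic term of the weight update, so
synapses active for the *current* view are strengthened on neurons that
fired for *recent* views — which, under object-blocked presentation, are
views of the same object. That is the entire invariance mechanism. By
default the postsynaptic term is the trace from the previous timestep only
(`use_previous_trace_only = TRUE`): the current view, which may never have
been seen before, contributes nothing to its own association. Layer 1 is
trained with the instantaneous rate instead of the trace (purely
associative), so that it first binds Gabor features into local feature
combinations before any invariance learning starts above it.

**Learning rules.** Three synaptic updates are implemented, sharing the
interface `w′ = f(w, x, y_post, α_learn)`:

* `hebb_normalized` — `δw = α·y_post·x` followed by rescaling the weight
  vector to unit length (the classical competitive-network normalisation);
* `competitive_standard` (default) — `δw = α·y_post·(x − w)`: Hebbian
  potentiation plus heterosynaptic depression proportional to the existing
  weight, which keeps neurons competing on an equal footing without any
  explicit normalisation and bounds weights in [0, 1];
* `oja` — `δw = α·y_post·(x − y_post·w)`, which normalises weight-vector
  length implicitly and reduces exactly to the competitive rule when rates
  are binary at 1.

Optionally the weights of a Layer are clipped at a ceiling (`max_weight`)
after every update, which spreads learning across many synapses instead of
letting a few grow large.

**Evaluation.** After training, the Layer-4 rates for all views of all
objects are correlated pairwise (Pearson). The object-selectivity statistic
is `S = W / (W_perfect + B)` with `W` the sum of within-object off-diagonal
correlations, `W_perfect = n_objects·n_views·(n_views−1)` its value for a
perfect representation, and `B` the sum of between-object correlations;
negative correlations are clipped at 0 first. `S` is 1 for perfect
view-invariant, object-exclusive coding and 0 for no within-object
correlation.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `sparseness` (a) | 0.01 | fraction of neurons firing per Layer per stimulus |
| `beta` (β) | 10 | sigmoid slope; ≥100 makes rates near-binary and excludes low-rate neurons from learning |
| `eta` (η) | 0.8 | trace proportion; 0 disables the memory trace |
| `learning_rate` | 0.1 | step size of all three rules |
| `max_weight` | 0.06 on Layers 1–3 (`small-32`) | synaptic ceiling; `NULL` disables clipping |
| `epochs_per_layer` | 50 | presentations of the full set per Layer |
| `view_step` | 40° | angular spacing of synthetic views |

The weight ceiling deserves emphasis. In this implementation, running the
competitive rule *without* any ceiling collapses the representation: a few
early-winning neurons develop large weights onto the few active afferents,
win the competition for every object, and the network converges to ~30
"hub" neurons shared across all objects regardless of training length. The
ceiling of 0.06 on Layers 1–3 (the standard setting for this model family;
Layer 4 is left unclipped) caps that positive feedback, recruits an order
of magnitude more neurons, and is applied from the start of training, so a
clipped run never retains initial weights above the ceiling. Clipping is
the single most consequential parameter in the small network.

The learning rate and epoch count are not printed in the main description
of the model family; 0.1 is standard competitive-network practice, and the
default of 50 epochs per layer is conservative — on the 9-object tutorial
problem the mean weight change per epoch plateaus by roughly epoch 10.

## The synthetic stimulus generator

`generate_synthetic_objects()` emulates a multi-view object library
(turntable-style photographs): each object is a distinct centred base shape
drawn from four families (star polygons, compound ellipse blobs, wobbled
annuli, disc-with-arms), rendered at `n_views` in-plane rotations spaced
`view_step` apart with mild per-view scale/shear jitter. Pixel correlation
between rotated views of a centred shape is carried by the
rotation-invariant image component, so each object gets an object-specific
*radial* shading profile, with profile frequency, phase and object size
spread across objects by low-discrepancy sequences; that guarantees the
within-object/between-object correlation block structure that the trainer
relies on, for sets from a handful up to hundreds of objects.

What the generator does **not** emulate: out-of-plane (3-D) rotation with
self-occlusion, lighting changes, backgrounds and clutter, scale changes
beyond a few percent, or the feature statistics of photographs. Passing
tests on synthetic sets therefore demonstrates the *mechanism* — trace
learning binds temporally adjacent, partially overlapping input patterns
into invariant representations, with the documented ordering of learning
rules and the benefits of clipping and high β — but absolute selectivity
values on real image libraries will differ. The directory loader
(`load_image_directory()`) accepts external multi-view image sets in the
same layout for exactly that purpose.

## Numerical choices

* **Sigmoid threshold search.** The threshold is placed on the sorted
  activations; the number of kept neurons is found by a galloping bracket
  plus bisection on the measured sparseness, with an exhaustive scan
  fallback if the bracket lands poorly (possible in principle because
  measured sparseness need not be exactly monotone in the kept count). Ties
  in activation are broken by neuron index. Sub-threshold neurons are set
  to exactly 0; the neuron at the threshold fires at 0.5.
* **Degenerate inputs.** If all activations are identical (e.g. an all-zero
  stimulus) the top-k neurons by index are selected with a warning.
* **Connectivity sampling.** Weighted sampling *without replacement* over
  presynaptic cells with Gaussian weights; this is always feasible (a
  corner neuron cannot stall resampling) and one synapse per (pre, post)
  pair is guaranteed. Because discrete without-replacement sampling
  depletes the centre cells and pushes connections outward, the Gaussian
  scale is calibrated numerically per layer so that ≈67% of a central
  neuron's *realised* connections fall within the stated radius; the
  continuous-Gaussian value σ = radius/1.5 is the calibration's upper
  bound and is used whenever it already meets the contract.
* **Gabor bank.** Envelope σ = 0.5·wavelength, even (cosine) phase, aspect
  ratio 1.5 along the bar; kernels are truncated at 2.5σ and made exactly
  zero-sum by subtracting a scaled envelope. Convolution is zero-padded
  FFT convolution (stimuli are centred on black backgrounds, so border
  effects are negligible); each channel is normalised once, at bank
  construction, by the kernel's peak response to a matched full-contrast
  grating, keeping filtering image-independent with responses in [0, 1].
* **Cached filtered inputs** are stored 8-bit quantised by default
  (resolution 1/255 on the [0, 1] rate scale, far below the variation that
  matters to the model); full double precision is available with
  `storage = "double"` and is the contract of `filter_image()` itself.
* **Two engines.** The per-layer training loop exists twice: a compiled
  kernel (the default) and a plain-R reference implementation. Both share
  one compiled dot-product primitive (so both accumulate activations in the
  same order — the dot product itself is checked against a loop-based
  oracle in the tests) and are asserted to produce the same trained weights
  on small problems. `options(visnetr.engine = "r")` switches globally.
* **Trace at object boundaries.** The trace is reset to zero when the
  presented object changes (`reset_trace_between_objects = TRUE`), so the
  last views of one object are not associated into the next; carrying the
  trace across boundaries is available as a flag since either behaviour is
  defensible.

## Problem sizes used by the shipped tests and script

Training runs in the test suite and the acceptance script use the
`small-32` preset with 10 epochs per layer (the plateau of the mean weight
change on these problems), 9×9 or 20×9 synthetic stimulus sets, 10 network
seeds per condition for replicate comparisons, and one seed per cell of the
capacity sweep (across seeds the selectivity SD in sweep conditions is on
the order of 10⁻³). These are the package's desk-scale working conditions;
all of them are plain configuration values that scale up directly.

## Known limitations

* The `large-256` preset is provided as configuration, but training a
  256×256×4-layer network with up to 10⁹ synapse visits per epoch is a
  batch-compute job, not something the test suite exercises.
* Selectivity values depend on the stimulus statistics; with the synthetic
  generator the reproduced results are the *orderings* and *directions* of
  effects (rule ranking, clipping benefit, β benefit, capacity growth with
  synapse count), with single-run selectivities in the same broad range as
  published small-net values rather than matched to them.
* No color pathway, no clutter/saliency handling, no recurrent or feedback
  connections, and no spiking dynamics: the model is a rate-based
  feedforward hierarchy by design.

## A worked example

```{r example}
library(visnetr)

cfg <- visnet_config(n_objects = 9, n_views = 9, epochs_per_layer = 10)
res <- run_visnet(cfg)          # generates, filters, builds, trains, tests
res$object_selectivity

plot_correlation_matrix(res$evaluation$corr, n_views = 9)
plot_weight_distribution(res$network, 3)

cr <- compare_rules(cfg, seeds = 1:10)
cr$summary
```
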