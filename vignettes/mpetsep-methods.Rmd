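---
title: "Kinetic model-informed separation of dual-tracer dynamic PET: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic model-informed separation of dual-tracer dynamic PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpetsep)
```

## The problem

Multiplexed PET injects two tracers — here [18F]FDG (half-life 109.8 min,
injected at 0 min) and [11C]MET (half-life 20.4 min, injected at 5 min) —
within a single dynamic scan. Every annihilation produces indistinguishable
511 keV photon pairs, so the reconstructed dynamic image is the *sum* of
the two single-tracer image sequences, and the separation must come from
the tracers' different temporal behaviour: kinetics, injection delay and
physical decay. This package simulates such dual-tracer brain acquisitions
end to end and implements four separation strategies on the reconstructed
images:

* **v-STCM / v-MTCM** — voxel-wise weighted least-squares fits of one- or
  two-tracer compartment models, with the arterial input functions (AIFs)
  assumed known;
* **IS-F4D** — an image-space alternating MLEM algorithm on a spectral
  kinetic model, needing no AIFs;
* an **unrolled deep network** that keeps the IS-F4D iteration structure
  but replaces the proximal step with trainable convolutional
  regularisers;
* a parameter-matched **convolutional encoder-decoder (CED)** as the pure
  data-driven baseline.

## The spectral kinetic model

A single-tracer voxel TAC is modelled as `f = H B c`: nonnegative
coefficients `c` over `N = 25` exponential temporal basis functions `B`
(decay rates 0 plus 24 log-spaced values in [0.001, 5] per minute, with the
isotope decay rate added and samples before the tracer's injection set to
zero), convolved with a single global generating function `h` shared by all
voxels. The AIF is one admissible `h`; the algorithm never needs to know
it. The dual-tracer model stacks the two tracer blocks and sums their
outputs, so the separated images always add up to the fitted dual model —
data consistency is structural, not imposed.

Two representation conventions needed a decision:

* **Where the injection delay lives.** The basis carries both the isotope
  decay and the injection delay. The generating function is therefore
  indexed by *lag since injection* and is initialised to ones without any
  pre-injection zeroing — putting the delay in both factors would delay the
  convolution twice (a MET model starting at 10 min instead of 5). With
  this convention the generating function that reproduces a compartment
  model TAC is the injection-aligned, decay-weighted AIF
  (`aligned_decayed_aif()`).
* **Where the data term lives.** The model is evaluated on a fine time
  grid (0.05 min by default) and integrated to the frame schedule; the KL
  data term compares frame-domain quantities, because the measurement is
  genuinely frame-sampled. Frame values are mean rates over the frame
  (frame-length-corrected), and the frame integration matrix uses exact
  trapezoid weights, so irregular schedules and fine grids that do not
  subdivide frames evenly are handled.

A property worth knowing: the compartmental *tissue* response of every
simulated tissue class is represented by the basis to better than 0.1%
relative L2 after nonnegative least squares. The *vascular* term
`VB * Cp(t)`, however, is a near-delta component that exponentials with
rates up to 5/min can only blur: with the canonical sharp Feng bolus the
full-TAC NNLS residual is 2-8% depending on region and tracer,
concentrated in the frames at each bolus peak. This is a genuine property
of the 25-function spectral model with realistic bolus inputs, not an
implementation artefact, and it is one driver of the residual bias of the
spectral methods on blood-rich regions.

## IS-F4D

IS-F4D minimises the generalized KL divergence between the measured dual
frames and the dual spectral model, alternating multiplicative MLEM
updates: 16 initial coefficient updates, then cycles of 4 coefficient
updates and 1 generating-function update, 1600 outer cycles at full scale.
Both updates are classic MLEM forms (ratio backprojection divided by
sensitivity); the coefficient update equals a proximal-gradient step with
step size `c / sens` and no regulariser — the identity the unrolled network
builds on, and one the test suite verifies to 1e-10. Because `h` is global,
its sensitivity and adjoint sum over all voxels; both are computed by
FFT-based causal correlations. The objective is bi-convex, so the KL trace
is monotone within each subproblem but the joint solution is non-unique
(only the product `H B c` is identified; tests therefore assert on fits
and residuals, never on `c` or `h` individually). Ratios are floored at
1e-12 to keep empty frames finite.

## Voxel-wise compartment fitting

The simulator uses the irreversible two-tissue model for FDG (`k4 = 0`)
and the reversible one for MET, each with a fractional blood volume and
physical decay referenced to that tracer's injection. Tissue responses are
closed-form bi-exponentials convolved with the AIF by an exact
piecewise-linear recursion (`exp_conv()`), validated against a Runge-Kutta
integration of the state equations to 1e-3 relative L2.

The fitting baselines minimise duration-weighted squared error with
bounded Levenberg-Marquardt: single init 0.01 for every parameter, lower
bound 1e-11, upper bounds `[VB, K1, k2, k3, k4] = [1, 5, 2, 1, 1]`,
relative tolerance 1e-8, at most 1600 iterations. Two numerical points
matter:

* the Jacobian is computed by central differences: the reversible model's
  `k4` sensitivity is so weak that one-sided differences strand the
  optimizer in flat valleys (0/10 noise-free recoveries in our
  experiments, against 20/20 with central differences);
* deliberately, there is no multi-start. The susceptibility of the joint
  dual-tracer fit to local minima is part of the method being studied;
  the single-tracer fit on noise-free data recovers all identifiable
  parameters to 1% in at least 95% of voxels, while noisy and very fast
  kinetics (`K1` near its bound) can legitimately end in local minima.

Parametric maps report the net influx rate `Ki = K1 k3 / (k2 + k3)`,
defined as 0 where `k2 + k3 = 0`.

## The unrolled network and the CED baseline

Each of the `K` blocks performs one coefficient MLEM step, pushes the
coefficient stack of each tracer through its own convolutional branch
(3 layers of 3x3 convolution + batch normalization + PReLU, then a 1x1
convolution and a ReLU that enforces nonnegativity), and finishes with one
generating-function MLEM step. With identity branches a forward pass *is*
`K` IS-F4D cycles — asserted exactly in the tests, which is the
"kinetic model-informed" claim in checkable form. At the full-scale
defaults (`K = 10`, width 50) the model has about 1.16 million trainable
parameters; the CED baseline auto-scales its channel width to match any
parameter budget within 10%.

Training minimises the summed per-tracer MSE between separated and label
images, end to end: gradients flow through the MLEM steps, the causal
convolutions and the frame integration. No R deep-learning backend
provides these operators, so the package carries a small reverse-mode
tape (`R/autodiff.R`) whose every operator's vector-Jacobian product is
checked against central finite differences in the test suite. Adam is the
optimizer (defaults: learning rate 1e-4, batch 8, early stopping on
validation loss); batch-norm uses batch statistics in training and running
statistics in evaluation. Weight initialisation is Xavier-uniform, seeded,
so runs are reproducible.

## The synthetic data generator

The generator emulates a multi-subject brain phantom study procedurally,
with no external data dependency:

* **Anatomy**: an elliptical head, a sinusoidally folded grey-matter
  ribbon standing in for cortex, white matter inside, and one circular
  tumour of diameter drawn uniformly in [12, 18] mm at a uniformly random
  admissible in-brain location. 20 synthetic "volumes" x 5 slices emulate
  the 100-slice study design. This preserves the WM/GM/tumour structure
  and scale the separation methods see, though not true cortical folding
  or partial-volume mixtures — conclusions about anatomical detail
  recovery do not transfer to real brains.
* **Kinetics**: regional parameters drawn per slice from Gaussians around
  literature means (CoV 0.1, absolute values), then modulated by a smooth
  within-region heterogeneity field (Gaussian-smoothed white noise, sigma
  2 voxels, +-10% multiplicative) — two interpretable knobs standing in
  for anatomical texture.
* **Input functions**: the Feng bolus model with canonical 1993 parameter
  values, rescaled to a configurable peak (the absolute scale is
  irrelevant because the acquisition sets count levels separately; the
  injected-dose ratio of the tracers is a knob, default 1:1, since no
  value is printed in the protocol literature). Per-example Feng
  parameters are jittered with CoV 0.1 to emulate population variation.
* **Acquisition**: a generic 2D parallel-beam system (180 angles x 192
  bins at full scale; bin width = voxel size) built as an explicit sparse
  matrix with 2x2 sub-voxel sampling; constant attenuation 0.0096/mm
  (water at 511 keV) over the head; a spatially uniform background equal
  to 20% of total expected counts standing in for scatter and randoms
  (treated as known in reconstruction, which isolates separation error
  from scatter estimation); one global scale setting the expected total
  counts (default 5e6 per slice, a knob because injected activities are
  not printed — all noise-level conclusions are trends, not absolute
  numbers); independent Poisson draws per bin; frame-by-frame MLEM (128
  iterations, uniform init, no post-smoothing), divided by frame duration.

## Problem sizes used by the tests

The test and acceptance suite runs everything at "desk" scale, chosen as
the smallest sizes at which each property is meaningful: 16x16 to 64x64
grids, the condensed 10-frame 50-min schedule (`desk_frame_schedule()`)
with a 0.25-min fine grid where the full 27-frame protocol is not itself
under test, 12-25 basis functions, IS-F4D runs of 150-200 outer cycles,
and network training with `K = 3`, width 8, 16 training examples of
32x32, 30 epochs and 3 seeds. The desk training runs use a larger Adam
step (2e-3) than the full-scale default, because 60 optimizer steps must
show the learning trend that full-scale training shows over thousands of
steps. Headline full-scale error statistics are deliberately not asserted
anywhere: they depend on absolute count levels and GPU-scale training
budgets that the protocol literature does not pin down, so the suite
asserts structure (identities, fixed points, monotonicity, recovery,
ordering trends) instead of reproducing figure values.

## Known limitations

* 2D only; the parallel-beam model has no detector blur, randoms/scatter
  physics beyond the uniform background, or time-of-flight.
* The spectral basis cannot represent sharp vascular spikes (see above);
  blood-rich voxels carry a structural bias in all spectral-model methods.
* The generating-function update assumes `h` is global across voxels.
* No metabolite correction, no plasma-to-blood conversion, no AIF
  estimation: the compartment baselines receive the true simulated AIFs.
* The bi-convex objective makes IS-F4D (and the unrolled network's
  initial state) sensitive to the `c`/`h` scale ambiguity; only products
  are identified.
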