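---
title: "Methods: magnitude least-squares shimming and its learned fast path"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: magnitude least-squares shimming and its learned fast path}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, numerical choices and design
decisions behind fastshim, in the order the pipeline uses them. No
empirical claims are made here beyond what the test suite and
`scripts/acceptance.R` compute.

## 1. The shimming problem

An `n`-channel transmit array produces, at every voxel `v` of a slice,
complex per-channel fields `A[v, c]`. Driving channel `c` with complex
weight `b[c]` yields the combined field `(A b)[v]`, and the flip angle
is proportional to its magnitude. The shim design problem is

$$ \min_b \; \sum_{v \in w} \big( |(Ab)_v| - m_v \big)^2 \;+\;
   \lambda \lVert b \rVert^2 , $$

with target magnitude `m` (unit by default), region-of-interest mask
`w`, and power regularization `lambda`. Only the magnitude enters, so
the objective is invariant under a global phase of `b` — the problem is
a phase-retrieval relative, non-convex with many local minima.

**Error metric.** Quality is reported as
`100 * sqrt(mean_w((|Ab| - m)^2)) / mean_w(m)`, the RMS excitation
error in percent of the target flip angle. The plain RMS form is not
dimensionless; dividing by the in-mask mean target makes it a
percentage and, with the default unit target, changes nothing
numerically. With a uniform target the mean- and peak-normalized
variants coincide, so the choice between them is moot here.

**Parameterization.** Optimization runs over the `2n` real parameters
`(Re b, Im b)`. The polar alternative (magnitude/phase) has a
coordinate singularity at zero magnitude where gradients are undefined;
the Cartesian form is smooth everywhere. At voxels where the combined
field is exactly zero the magnitude is non-differentiable; the
implementation uses the zero subgradient there (the phase factor is set
to 0), which in practice only matters at contrived starting points.

## 2. Multi-restart Adam (the reference arm)

`adam_shim()` runs `n_restarts` independent minimizations with the
Adam update rule (`beta1 = 0.9`, `beta2 = 0.999`, `eps = 1e-8`),
each started from a random weight vector with magnitudes uniform on
(0, 1] and phases uniform on [0, 360) degrees. Defaults: learning rate
0.05, at most 500 iterations per restart, stopping when the objective
changes by less than `1e-8` per step. The restart with the lowest
final objective wins; exact ties break to the lowest restart index, so
results are reproducible. Restarts that reach a non-finite objective
are discarded with a warning; only if all fail does the call error.

The default restart count is 300, the production setting for deriving
reference ("upper bound") weights; the desk-scale experiments in the
tests use 10–20 restarts, which on the synthetic slices already sits
within a few percent of the 300-restart objective.

Two deliberate additions beyond the bare algorithm:

* **Quadrature warm start.** One extra deterministic candidate — the
  CP mode scaled to the optimal real magnitude — is optimized alongside
  the random restarts, and its unoptimized form is also kept as a
  candidate. This guarantees the returned solution is never worse than
  the quadrature baseline, a property the batch comparisons rely on.
  It can be disabled (`include_quadrature_start = FALSE`), and is
  disabled in all oracle-agreement tests so the random-restart
  machinery is what is actually exercised.
* **Regularization default.** The two objective terms live on
  different scales: the error sum grows with the voxel count `N`, the
  power term with the channel count `n`. When `lambda` is not given it
  defaults to `1e-3 * N / n`, which keeps the power penalty three
  orders of magnitude below a unit-scale error sum regardless of grid
  resolution.

## 3. Variable exchange (the conventional arm)

`mls_variable_exchange()` implements the classic alternating scheme
for magnitude-only fitting: adopt the current combined field's
per-voxel phase onto the target, `z = m * exp(i arg(Ab))`, then solve
the regularized *linear* least squares `min_b ||Ab - z||^2 +
lambda ||b||^2` in closed form via the normal equations. Each step
cannot increase the MLS objective, and iteration stops when the
decrease falls below `1e-10` or after `max_outer = 50` rounds. With
`lambda = 0` and a rank-deficient `A` the normal matrix is solved by a
truncated SVD pseudo-inverse (with a warning). The starting point is
the scaled quadrature mode — the standard warm start in practice and
deterministic, which makes this solver a stable comparison arm.

Variable exchange is a local method: its fixed points are local minima
of the MLS objective, and on small adversarial fixtures the
quadrature start can land in a poor one. The exchanged variable is the
per-voxel *target phase*, so the natural multi-start is over that
variable: with `n_restarts > 1` additional runs begin from random
per-voxel target phases (one exchange step solves for the
corresponding weights), and the best fixed point wins. The default
remains the classic single start; the oracle-agreement tests use 30
phase restarts, which reliably reach the brute-force optimum on
two-channel fixtures.

## 4. The exhaustive oracle

For fixtures with one or two channels and a handful of voxels the MLS
problem can be solved by brute force: enumerate per-channel magnitudes
on a 0.01 grid up to 2 and phases on a 1-degree grid, with channel 1
pinned to phase 0 to remove the global-phase invariance.
`grid_search_shim()` (C++) shares no code with either optimizer and
serves as the independent reference: both iterative solvers must land
within the grid's own resolution of its optimum. The iterative
optimizers typically *beat* the grid slightly — the grid is quantized —
so agreement is asserted on the absolute relative gap.

## 5. The synthetic field generator

Real multi-channel B1+ maps come from electromagnetic solvers; no such
dataset is redistributable here, so the generator emulates the
*structure* of that data with a quasi-static model:

* Each channel is a circular current loop of effective radius `a`
  (default 20 voxels on the 101-grid scale) at distance `radius`
  (default 70) from the grid center, at azimuth `k * 45` degrees for 8
  channels. The magnitude follows the on-axis Biot–Savart law
  `a^2 / (a^2 + r^2)^{3/2}` evaluated at the 3-D distance `r` from the
  loop center — exact on the loop axis, a smooth monotone surrogate
  off-axis.
* A phase ramp `-2*pi*r / wavelength` (default wavelength 70 voxels,
  roughly the in-tissue RF wavelength at 298 MHz for a ~2 mm voxel)
  reproduces the propagation delay that makes the channels interfere;
  this is what gives the CP mode its center-bright, rim-dark pattern
  and makes shimming non-trivial.
* Channel `k` carries the CP drive phase `-k * 45` degrees. The sign
  convention (clockwise) is arbitrary but fixed; flipping it reflects
  all solutions and changes no error metric.
* The phantom is an ellipse (semi-axes 45 x 38 voxels on the reference
  grid) of uniform unit density; slices away from the center shrink
  head-like, and coils sit in planes offset axially by `slice_spacing`
  (3 voxels), so different slices see genuinely different fields.
  Masks are `density > 0.5 * density_inside`; surrounding air is
  excluded.
* A smooth random perturbation (three random-frequency sinusoids,
  relative amplitude `noise_level = 0.02` on magnitude and phase, per
  channel and slice) emulates subject-dependent field structure
  without destroying smoothness. Per-volume phantom scaling (±10 %)
  emulates a population of head sizes.
* Each slice is normalized so the CP-mode mean in-mask magnitude is 1,
  which makes the percent-of-target error comparable across slices and
  volumes.

Rotation augmentation rotates channel fields (bilinearly, on real and
imaginary parts separately), density (bilinearly) and mask
(nearest-neighbor, re-binarized) jointly about the grid center. The
default of 12 rotations (30-degree steps) reflects an augmentation
factor consistent with a 64-volume, 32-slice corpus expanded to about
25 thousand slices; it is configurable, and the reduced-scale
experiments use 4 rotations (90-degree steps).

What the generator does **not** emulate: dielectric resonance and
tissue-specific conductivity, coil-coil coupling, SAR, through-slice
effects, or measurement noise in B1+ mapping. Tests passing on this
generator demonstrate the *algorithms* behave as specified, not that
the learned models transfer to scanner data.

## 6. The shim-weight regressor

The network maps an encoded slice to the weight vector directly.

* **Encoding.** Default `realimag16`: the 8 real planes followed by
  the 8 imaginary planes (lossless, minimal). A 32-plane variant
  (`magphase32`: real, imaginary, magnitude, phase per channel) is
  provided for parity with a four-feature-per-channel input
  convention; magnitude and phase are redundant given real/imaginary,
  so the lean encoding is the default.
* **Architecture.** A residual regression network: 3x3 stem
  convolution, four stages of basic blocks (two 3x3 convolutions with
  batch normalization and ReLU, identity skip, stride-2 entry with 1x1
  projection from stage 2), global average pooling, and a linear head.
  Full-scale widths are 64/128/256/512 with two blocks per stage; the
  CPU-scale experiments use 8/16/32/64 with one block per stage, which
  trains in minutes while preserving the architecture family.
* **Head decoding.** Outputs pair as (real, imaginary) per channel; 8
  channels need 16 numbers. A 32-wide head is accepted for
  compatibility, with surplus entries ignored — 8 complex weights have
  only 16 real degrees of freedom, so any wider output is redundant by
  construction.
* **Head initialization.** The final-layer bias is set to the encoded
  CP-mode weights, so the untrained network already predicts the
  quadrature baseline and learning proceeds as a residual improvement
  on it. This removes the long initial phase in which an
  arbitrarily-initialized network predicts near-zero weights (RMSE
  near 100 %).
* **Physics-informed loss.** For each slice the predicted weights are
  pushed through the actual field matrix and the excitation RMSE is
  computed; the loss compares it with the stored reference RMSE. Two
  forms are implemented and tested: the plain mean of differences
  (`eq3_plain`, the default) and the mean of squared differences
  (`mse`). The plain form's gradient is simply the gradient of the
  predicted RMSE — training drives predicted error down regardless of
  the reference — while the squared form weights badly-missed slices
  more. Both are differentiable through the field combination; the
  gradient with respect to the head outputs is computed analytically
  and verified against finite differences in the suite.
* **Splitting.** Train/validation/test splits (default 8:1:1) operate
  on *source slices*, so all rotated copies of a slice land in the
  same subset; otherwise rotation augmentation would leak test
  information into training.
* **Schedule.** Adam, initial learning rate 1e-3 halved every 50
  epochs over 200 epochs at batch 16 (full-scale defaults). The
  reduced-scale runs train 30 epochs with the halving period shortened
  to 12 so the schedule still decays twice within the run. The best
  validation-RMSE epoch is checkpointed; a non-finite loss aborts with
  the last good checkpoint.
* **Reduced-scale study conditions.** The acceptance-level experiment
  trains on 512 slices (16 volumes x 8 slices x 4 rotations) at
  64 x 64 voxels with 16-restart Adam references. These sizes are the
  package's chosen desk-scale study conditions: large enough that the
  network must generalize across phantom sizes and rotations, small
  enough to train on a single CPU in minutes.

## 7. The non-uniformity detector

Aggregate RMSE can look acceptable while the field contains a local
void. The NFD is a small discriminator-style classifier over the
shimmed magnitude map: strided 4x4 convolutions doubling widths
(32→256 at full scale, 8→64 at desk scale), leaky-ReLU (slope 0.2),
batch normalization after all but the first convolution, and a single
sigmoid logit giving the confidence that a map is *uniform* (decision
threshold 0.5, configurable). Three design choices matter for small
voids:

* **Local-contrast input.** A shallow void of a few voxels barely
  moves the raw magnitude map — a matched filter on the raw map
  separates the classes poorly. The default input therefore carries a
  second plane: the map minus its 9x9 box-blurred version (scaled by
  `residual_gain = 5`, zero outside the map support), a high-pass
  representation in which local suppression stands out against the
  smooth shim landscape.
* **Flattened logit head.** The logit layer reads the flattened final
  feature grid rather than its global average: a void is a local
  event, and average pooling dilutes exactly the evidence the detector
  needs (the pooled head remains available as `head = "gap"`).
* **Flip augmentation and balanced checkpointing.** Training flips
  batches along rows/columns at random (labels are invariant) and
  checkpoints the epoch with the best *balanced* validation accuracy,
  so neither class can dominate model selection.

The desk-scale recipe is Adam at 2e-3 for 40 epochs at batch 16 with
widths 16/32/64/128.

Its training labels are generated programmatically rather than curated
by eye: the uniform class consists of well-shimmed maps (slice RMSE
below a configured cut), the non-uniform class of the same maps with
one or two smooth multiplicative voids injected,
`1 - depth * (1 - (d/radius)^2)^2` within radius `d < radius`. This
makes the ground truth objective and exactly reproducible, at the cost
of modeling only void-type artifacts. The input is the single
combined-magnitude plane, not the 8 per-channel maps: the detector
screens *output* fields, and a combined-map input keeps it independent
of channel count. Held-out evaluation uses slices from a separately
simulated volume, so no training slice (or rotation of one) is seen at
test time.

## 8. Degenerate inputs and numerical conventions

* Empty masks are rejected at every optimizer entry point; the batch
  driver (`shim_volume()`) converts per-slice failures into flagged
  rows instead of aborting the run.
* Rotation uses inverse mapping about the geometric grid center
  `((n+1)/2, (n+1)/2)`; out-of-grid samples fill with zero.
* Dataset containers are written uncompressed with a fixed
  serialization version, so write/read round trips are bit-exact and
  reruns of the pipeline produce byte-identical metric CSVs; the
  container carries a `layout_version` attribute checked on read.
* All randomness flows through R's RNG under explicitly derived
  per-stage seeds; the C++ kernels are deterministic and
  single-threaded.

## 9. Known limitations

* The simulator is quasi-static; it reproduces interference structure
  but not tissue-specific wave effects, so absolute RMSE levels are
  not comparable to electromagnetic-simulation or scanner values.
* Shimming is per-slice; joint multi-slice or volumetric shimming,
  pulse design and SAR constraints are out of scope.
* The NFD detects the void family it was trained on; other artifact
  types (e.g. ghosting, ringing) require retraining with suitable
  injectors.
* The network engine is deliberately minimal (CPU, double precision,
  no data parallelism); it is sized for the desk-scale experiments,
  not for the ~25k-slice full-scale corpus, although the architecture
  accepts it.
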