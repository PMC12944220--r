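---
title: "Methods: infrared-only fish volume estimation in aquavol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: infrared-only fish volume estimation in aquavol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

Top-view RGB-D rigs measure fish volume well but are expensive and fragile
in humid farm environments. `aquavol` implements an IR-only alternative:
a single-channel infrared camera above the tank is the only inference-time
sensor, and the missing modalities are synthesized. The pipeline is a
chain of five modules — IR-to-depth, IR-to-pseudo-RGB, multi-object
tracking, instance segmentation, and volume regression with a physics
correction — each independently trainable, with differentiable internals
so that gradients can in principle flow end to end.

This vignette explains the science implemented in each module, the
parameters that matter, what the bundled simulator does and does not
emulate, and the design decisions taken where the design was genuinely
open.

# The synthetic tank simulator

Every stage is trainable and testable without external data because the
simulator (`simulate_clip`) emits paired IR / RGB / depth frames plus
complete ground truth: per-fish masks, tight boxes, persistent ids, metric
depth, trajectories, and analytic volumes.

**Geometry.** A 1 m x 1 m x 0.5 m tank viewed from 1 m above the surface
by an ideal pinhole camera (principal point at the image center, no lens
distortion). The incidence angle of the ray through a pixel at radial
distance r from the principal point is `theta = atan(r / focal_px)`; under
the flat-surface approximation this is also the refraction incidence
angle.

**Fish bodies.** Each fish is a tube of elliptical cross-sections:
semi-axes `b(u) = b sqrt(1 - u^2)` (half-width) and `c(u) = c sqrt(1 - u^2)`
(half-height) strung along a spine of half-length `a`, which integrates to
exactly `(4/3) pi a b c`. Tail undulation displaces cross-sections
laterally without deforming them, so bending is volume-preserving by
construction — the analytic volume is exact ground truth in every frame
while the projected silhouette deforms. Morphology: body length 5–15 cm;
half-width `b/a ~ U(0.18, 0.25)` (slender carp-like bodies); half-height
`c/b ~ U(1.0, 1.2)` (goldfish are deeper than wide). The height ratio is
the one quantity the top view cannot observe; its spread sets an
irreducible floor on volume recovery of a few percent.

**Kinematics.** Constant speed (0.1–0.4 m/s) and turn rate, with smooth
wall avoidance: inside a 10 cm band along a wall the heading steers
inward at a bounded turn rate, so velocities change continuously (real
fish turn before walls; instantaneous reflections would be both
unrealistic and adversarial to any motion model). A `"crossing"` scenario
scripts two head-on pair crossings at different depths, producing brief
occlusions for tracking stress tests.

**Sensor models.** IR frames are emissivity-weighted projections
(per-fish emissivity `U(0.55, 0.95)`) over a darker background with
Gaussian sensor noise (sd 0.02); the acquisition hardware's IR image
formation is not documented in detail anywhere we could rely on, so this
contrast model is a deliberately simple stand-in. RGB frames color each
fish from a small goldfish palette and then apply Beer–Lambert
attenuation `exp(-kappa D)` (kappa = 0.05 m^-1). The returned depth stack
carries the refraction-distorted *apparent* depth
`d_app = d sqrt(n_w^2 - sin^2 theta) / n_w`, while the truth stack keeps
undistorted metric depth — so the volume module's correction can be
tested by exact recovery. Sinusoidal ripple warping (`ripple_warp`, the
A = 5 px, f = 0.05 regime) is provided as an augmentation operator;
simulated clips default to still water so that ground-truth masks align
pixel-exactly with the frames.

**What passing tests do not show.** The simulator has no turbidity
scattering, no caustics, no species-specific fin morphology, and its IR
contrast model is invented. Results on it demonstrate that the
implementation is correct and that the estimators recover known
parameters under the stated geometry — not that the pipeline reaches any
particular accuracy on real tanks.

# Depth estimation

A small U-Net-style encoder–decoder (widths 8/16/32 by default) maps the
IR frame, replicated to three channels, to a sigmoid output affinely
scaled to the metric range 0–5 m — predictions are in range by
architecture, trained or not. A contour branch computes the Sobel
gradient magnitude and refines it with three 3x3 convolutions
(16–32–1 channels) into a contour probability map `C`; per-scale gates
`A_s = sigmoid(conv1x1(C_s))` modulate all encoder scales as
`F' = F * A + F`, so non-negative features stay within `[F, 2F]`.

The loss is `mean |D - D_gt|` plus
`lambda * sum[(grad_x D - alpha grad_x I)^2 + (grad_y D - alpha grad_y I)^2]`
with lambda = 0.5 and alpha = 0.1: depth gradients are pulled toward
(scaled) IR intensity gradients, suppressing pseudo-surface artifacts.
The data term is a per-pixel mean while the smoothing term is written as
an un-normalized sum; as printed, their balance would depend on image
resolution, so the default divides the smoothing sum by the pixel count
(a `literal_sum` flag restores the printed form). Gradients are forward
differences with the last column/row excluded — the discretization had to
be fixed somewhere, and forward differences keep the zero point exact:
the term vanishes iff `grad D = alpha grad I` at every interior pixel.

# IR-to-RGB translation

A conditional U-Net generator with a texture-conditioning mechanism: a
small CNN pools 32x32 IR crops centered on fish boxes into a
128-dimensional embedding, which is tiled to the mid-decoder resolution,
concatenated channelwise, passed through LeakyReLU + 3x3 convolution, and
batch-normalized (per-channel normalization with learned gain/shift,
since the package trains with single-frame batches). Injection at a
single mid-decoder layer is the default; the layer index is
configurable.

The objective is `L_GAN + beta L_L1 + gamma * mean |R - I_IR e^(-kappa D)|`
with beta = 1, gamma = 0.3, kappa = 0.05 m^-1. The third term anchors the
generated color to the physically expected attenuated intensity and is
exactly zero on the simulator's own attenuated output, closing the loop
with the simulator's forward model. The discriminator is a conditional
patch classifier on the (IR, RGB) pair — three stride-2 and two stride-1
4x4 convolutions, giving the standard 70-pixel receptive field; the GAN
term is binary cross-entropy at patch level (the framework's classic
variant). A per-channel kappa vector (blue/green/red absorb differently)
is available but defaults to the scalar.

# Tracking

**Cross-modal features.** IR and pseudo-RGB appearance vectors (bilinear
16x8 crop resamples, L2-normalized) are fused by multi-head attention
with queries from IR and keys/values from RGB; per-head width d_k = 128
with 4 heads concatenated and projected back to 128. A brute-force
double-loop implementation serves as the oracle in the test suite.

**Filter.** The state is `[p_x, p_y, a, v_x, v_y, omega]` (metric
position, box aspect, velocity, angular rate). Prediction rotates the
velocity by `omega dt` and advances the position; behavior constraints
then clamp speed to at most 1 m/s and the turn rate so the radius
`speed/|omega|` stays above 5 cm. The covariance is propagated literally
as `P <- clip(P + Q_kal, P_min, P_max)` with eigenvalue clipping
(preserves symmetry and positive semidefiniteness; elementwise diagonal
clipping sits behind a flag). Under this propagation a diagonal Q would
never develop position–velocity cross-covariance, leaving velocity
unobservable from position measurements; Q_kal is therefore the standard
discretized white-acceleration block
`q [[dt^3/3, dt^2/2], [dt^2/2, dt]]` per planar axis (q = 0.5 m^2/s^3),
which restores observability while keeping the printed propagation.
Defaults `P_min = 1e-4`, `P_max = 10`. Measurement noise: 2 cm positional
(matching 2 px detector jitter at the nominal scale) and a deliberately
large aspect variance of 1 — on a 20x4 px fish a one-pixel height change
flips the aspect by 50 %, so treating the aspect as precise would blow
the gate whenever a fish turns.

**Association.** Gated Hungarian assignment on
`0.5 Mahalanobis^2 + 0.5 cosine` with the chi-square 0.95 gate at 3
degrees of freedom (7.815). Two pragmatic and consequential choices:
(1) cascade — confirmed tracks claim detections before tentative ones, so
a one-frame gate blip cannot seed a rival that steals the measurement
stream; (2) because the printed covariance propagation does not inflate
position uncertainty during coasting, the gate threshold is scaled by
`1 + misses` and the coasting velocity is damped by 0.8 per missed frame.
Track management is the usual confirm-after-3-hits /
delete-after-30-misses scheme; rows buffered while tentative are emitted
retroactively on confirmation, so confirmed tracks cover their full
lifetime.

# Segmentation

Per detection box, 14x14 ROI features are bilinearly resampled from small
convolutional stems over the IR frame and the depth map; fusion is a
positionwise two-layer perceptron on the channel concatenation with a
residual back onto the IR stream. The mask head is four 3x3 convolutions
plus one deconvolution (2x upsample + convolution) and a 1x1 sigmoid,
producing a 28x28 soft mask pasted back into frame coordinates; the
masked depth region is `DR = M * D` where the binarized mask is set and 0
elsewhere. Region proposals are out of scope: segmentation consumes
external boxes (tracker or oracle), which mirrors the pipeline's
dependency structure.

The loss adds a skeleton-topology penalty to pixelwise binary
cross-entropy (sum semantics as printed, probabilities clamped to
`[1e-7, 1 - 1e-7]`; a per-pixel-mean flag exists). Keypoints come from a
deterministic medial-axis operator replacing a learned keypoint network:
morphological thinning of the largest component, the longest geodesic
path across the skeleton (Dijkstra with sqrt(2) diagonal steps), and K = 5
points interpolated at equal arc-length fractions, head end chosen by the
larger projection on the mask's principal axis (sign fixed toward +x,
then +y — deterministic and translation-equivariant). The prior skeleton
is computed on the ground-truth mask; the penalty
`mu/K sum ||S_k - S_prior,k||^2` (mu = 0.2, coordinates normalized by
image size) is evaluated per step as a non-differentiable regularizer
while the cross-entropy term carries the gradients — a hard skeleton is
not differentiable, and the original learned predictor that would have
made it so is unspecified.

# Volume regression and refraction correction

Per tracked fish, trajectory rows `(p, v)` are lifted positionwise to the
model width and given sinusoidal positional encodings; a CNN pools the
masked-depth crop into a single depth token (one pooled token per clip is
the default reading; a per-frame variant is a config option). Each
transformer block cross-attends trajectory queries to the depth token
(softmax scaled by `sqrt(d_k)`, `d_k = d/heads`), applies residual +
layer normalization, then a feed-forward sublayer. The pooled output
passes through a perceptron head with softplus, so volumes are
non-negative; the head bias is initialized near a plausible fish volume
(25 cm^3) to start optimization on scale. Paper-scale defaults are
4 layers / 8 heads / width 256; the tiny CPU model is 2 layers / 4 heads
/ width 64.

The DR crop is a **fixed-size window** (48 px) around the centroid rather
than a box-normalized resize: normalizing by box size would destroy the
apparent-area information that, together with depth, determines physical
size. The apparent depth of a fish is the median of its DR pixels.

**Refraction.** The correction factor is the exact flat-interface form
`d_real/d_app = n_w / sqrt(n_w^2 - sin^2 theta)`, and volume scales by
its cube. The first-order expansion sometimes quoted for this factor
carries a spurious overall n_w (it does not equal 1 at normal incidence);
it is implemented verbatim behind `approx_as_printed = TRUE` for
comparison, but the exact form is the default on physical grounds. The
simulator's `apparent_depth` is the exact inverse, so the round trip is
an identity to floating-point precision — one of the acceptance
properties.

**Training.** Supervision is the L1 volume error (the temporal-smoothness
term `lambda mean (dV - dV_gt)^2`, lambda = 0.1, applies to per-frame
series; with one pooled volume per clip its training contribution
vanishes, and `volume_loss` computes it for evaluation). Adam with
initial rate 1.5e-3 decayed by 0.93 per epoch, 35 epochs — the plain rate
without decay left the L1 objective oscillating near its floor.

# Evaluation harness

`evaluate()` matches ground-truth fish to track hypotheses per frame with
previous-match stickiness (a fish keeps its hypothesis while it stays
within one body length) and greedy nearest-center matching for the
remainder — the CLEAR-MOT convention; an identity switch is a change of
matched hypothesis. Volume metrics (MAE, RMSE, MAPE, R^2, Pearson) are
computed over matched (fish, frame) pairs, mask metrics (IoU, precision,
recall, F1) over binarized masks at 0.5. Evaluating the truth against
itself returns the exact perfect-score vector, which the test suite
asserts. `split_dataset` implements stratified 70/15/15 splitting with
floor-then-distribute rounding (remainders go to the splits with the
largest fractional parts, ties to the earlier split).

# Problem sizes and numerical choices

The bundled studies are sized for a single CPU:

- Volume recovery: 400 fish-clip samples (50 clips x 8 fish) at
  224x224 px, focal 220 px, 90-frame clips; 300/100 train/held-out split;
  the off-axis comparison collects at least 30 fish with median incidence
  in [5, 10] degrees and compares corrected vs uncorrected MAPE *paired*
  (same preliminary volume, so the comparison isolates the correction).
- Training-improves-over-init: 48x48 px frames, 200 optimizer steps for
  depth, 300 for the generator and segmentation.
- Tracking: 10 fish, 192x192 px, 90 frames, 2 px detector jitter,
  detections dropped above 30 % occlusion.
- The smoke run uses 128x128 px with untrained tiny checkpoints; its
  contract is artifact completeness and byte-identical determinism, not
  accuracy.

Numerical details worth knowing: attention softmax subtracts row maxima;
binary cross-entropies clamp probabilities at 1e-7; layer/channel
normalizations use eps = 1e-5; covariance clipping eigendecomposes the
symmetrized matrix; the Hungarian solver treats infinite costs as
forbidden entries via a large sentinel; all simulator randomness flows
from the single config seed, and repeated runs are byte-identical.

# Known limitations

- The simulator's fish are smooth tubes with uncorrelated emissivity; no
  fins, no scale texture, no turbidity. Generator and segmentation
  results on it say little about photorealistic water.
- The volume regressor is calibrated to the camera geometry it was
  trained on (focal length, height); changing the rig requires
  retraining, as it would for the real system.
- The covariance propagation follows the printed regularized form rather
  than the full linearized propagation; the tracker compensates at the
  association level (age-scaled gates, coast damping). Both choices are
  documented above.
- End-to-end fine-tuning across all five stages is structurally possible
  (everything shares the autodiff engine) but only the volume/segmentation
  path is exercised; joint five-network training is out of scope.
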