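# aquavol

Estimating the body volume of individual fish in aquaculture tanks usually
requires an RGB-D camera rig or handling the animals. `aquavol` implements a
cheaper alternative for top-view monitoring: the only inference-time sensor
is a single-channel infrared (IR) camera, and everything else — metric
depth, color appearance, identities, masks, volumes — is reconstructed from
the IR stream. The package is aimed at quantitative aquaculture researchers
and computer-vision methodologists who want a fully inspectable, CPU-scale
reference implementation of this pipeline, together with a synthetic tank
simulator that provides complete ground truth for training and testing
every stage.

## The pipeline

Given an IR clip `I_IR` (90 frames, 3 s at 30 FPS), the stages run

```
D  = f_depth(I_IR)          metric depth from IR
R  = f_gen(I_IR)            pseudo-RGB from IR
T  = f_track(I_IR, R)       per-fish trajectories {(b_t, id)}
M  = f_seg(I_IR, D),  DR = M ⊙ D
V  = f_vol(T, DR)           per-fish volume, refraction-corrected
```

The scientifically load-bearing pieces are:

- **Contour-guided depth estimation.** A Sobel-seeded branch produces a
  contour probability map `C`; per-scale gates `A_s = σ(conv1×1(C_s))`
  modulate encoder features as `F' = F ⊙ A + F`. Training combines an L1
  data term with a gradient-alignment smoothing term
  `λ Σ (∇D − α ∇I)²` (λ = 0.5, α = 0.1).
- **Water-adaptive IR→RGB translation.** A conditional U-Net generator with
  a 128-dimensional texture embedding injected mid-decoder, a 70×70-field
  patch discriminator, and a Beer–Lambert anchor
  `γ ‖R − I_IR e^{−κD}‖₁` (γ = 0.3, κ = 0.05 m⁻¹).
- **Behavior-constrained tracking.** IR and pseudo-RGB appearance vectors
  are fused by multi-head cross-modal attention (d_k = 128, 4 heads); a
  Kalman filter over `[p_x, p_y, a, v_x, v_y, ω]` enforces speed ≤ 1 m/s
  and turn radius ≥ 5 cm, regularizes its covariance by
  `P ← clip(P + Q, P_min, P_max)`, and gates associations at the χ²(0.95, 3)
  Mahalanobis threshold before Hungarian assignment.
- **Deformation-aware segmentation.** Depth-guided ROI fusion
  (`ROI_fused = MLP(concat(ROI_IR, ROI_D)) + ROI_IR`) and a loss adding a
  skeleton-topology penalty `μ/K Σ‖S_k − S_prior,k‖²` (μ = 0.2, K = 5 spine
  keypoints from a deterministic medial-axis operator) to pixel
  cross-entropy.
- **Trajectory–depth transformer (TDT).** Trajectory tokens with sinusoidal
  positional encodings cross-attend to a pooled masked-depth embedding; the
  pooled output regresses a preliminary volume `V_pre`, corrected for
  flat-interface refraction by `V = V_pre · (n_w / √(n_w² − sin²θ))³` with
  n_w = 1.33 and θ the incidence angle of the camera ray.

All neural components run on a small reverse-mode autodiff engine included
in the package (no external deep-learning framework), with tiny default
architectures that train in minutes on one CPU.

## A worked example

```r
library(aquavol)

cfg  <- tank_config(n_fish = 10, image_size = c(192, 192), focal_px = 180,
                    clip_len = 90, seed = 1, scenario = "crossing")
clip <- simulate_clip(cfg)          # IR + RGB + depth + full ground truth

set.seed(1)
det <- oracle_detections(clip, jitter_sd = 2, occl_drop = 0.3)
ts  <- track_clip(det,
                  kf_config(m_per_px = (cfg$camera_height + 0.25) / cfg$focal_px),
                  make_fusion_weights())
length(unique(ts$id))
#> [1] 10

refraction_correct(V_pre = 30, theta = 10 * pi / 180)
#> $V        30.78396   (cm^3, corrected)
#> $factor    1.008634  (d_real / d_app)
#> $volume_factor 1.0261
```

Ten fish in, ten persistent identities out across both crossing events, and
a 10° off-axis fish gains the expected 2.6 % cubic refraction correction.
A full run (`run_pipeline`) adds depth, pseudo-RGB, masks and a per-frame
volume table, and `evaluate()` scores it against the simulator truth (MAE,
RMSE, MAPE, R², Pearson, IoU, precision/recall/F1, ID switches). On a
simulated 8-fish clip with a trained tiny TDT this reports R² ≈ 0.93 and
zero identity switches.

## Command line

A thin CLI wraps the simulator and the pipeline:

```sh
inst/exec/aquavol simulate --out clips/ --seed 1 --n-clips 4
inst/exec/aquavol run --out run1/ --seed 1
```

Clip directories contain numbered 8-bit IR/RGB PNGs, 16-bit depth PNGs in
millimeters, COCO-style RLE mask JSON, MOT Challenge CSV tracks, and a
`scene.yaml` echo of the configuration.
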