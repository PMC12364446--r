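---
title: "Single-shot fringe projection profilometry: models, simulator and training harness"
author: "EndoFPP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-shot fringe projection profilometry: models, simulator and training harness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Fringe projection profilometry (FPP) reconstructs a dense metric depth map
of a surface by projecting periodic light patterns onto it and decoding how
the fringes deform in a camera image taken from a slightly different
viewpoint. The classical route is precise but slow: it needs a *sequence*
of phase-shifted patterns at several frequencies, which rules out dynamic
scenes such as living tissue viewed through an endoscope. EndoFPP implements
the single-shot alternative: a two-path convolutional network (MaskNet for
sample/background segmentation, DepthNet for depth regression) that predicts
a depth map from *one* fringe image, trained against ground truth produced
by the classical multi-frequency pipeline or by a synthetic scene simulator.
The package contains all four layers of that programme — pattern generation,
an analytic simulator, the classical pipeline, and the learned predictor
with its training and evaluation harness — as testable R code.

## Fringe patterns

A pattern is a cosine profile across the projector width,
$I(u) = \mathrm{lo} + (\mathrm{hi}-\mathrm{lo})\,\bigl(1 + \cos(2\pi f u/W +
\delta)\bigr)/2$, with the *frequency* $f$ counted in cycles across the
full pattern width (the unit that structured-light work loosely calls Hz).
The binary pattern is the same cosine thresholded at its midpoint — a 50%
duty-cycle square wave; projector literature rarely states the duty cycle,
so it is a documented default rather than a derived fact. Phase-shift
sequences use the four quarter-cycle shifts $(0, \pi/2, \pi, 3\pi/2)$.
Fringes are vertical by default (phase varies along columns), pixel
coordinates are 0-based with `u` the column index and the origin at the
top-left.

## The scene simulator

`renderGeometry()` / `renderFrame()` replace a general-purpose renderer
with a small analytic ray-caster specialised to this measurement geometry:

* **Phantom.** A diamond (a square rotated 45°) of 4 cm side carrying a
  raised-cosine dome (default amplitude 10 mm) plus up to a few smooth
  low-order cosine modes (`randomPerturbation()`, amplitudes ≤ 2 mm) to
  diversify shapes. The envelope forces the height to zero at the diamond
  edge, so the silhouette stays crisp. Poses are drawn uniformly:
  translations ±10 mm, rotations ±15°, per-axis scale 0.85–1.15.
* **Geometry.** The world frame is the camera frame (camera at the origin
  looking along +z); depth is the z-coordinate of the hit point in mm, not
  the ray length. The camera focal length is `1.1 × image width` px so the
  phantom fits the field of view over the whole 70–140 mm working range;
  the projector (720-px pattern, focal 600 px) sits 25 mm to the side — an
  approximately coaxial arrangement — with its principal point chosen so
  the pattern is centred on the camera axis at the nominal 105 mm
  distance. With these numbers the fringe phase at 20 cycles moves by
  ≈ 0.24 rad per mm of depth, and the camera always looks at the interior
  of the projected pattern; the lowest ladder frequency (1 cycle) spans
  less than one period over the view, which makes temporal unwrapping
  unambiguous.
* **Shading.** Reflected intensity is `albedo × pattern`, the pattern
  sampled bilinearly at the projector-plane projection of the hit point;
  rays that project outside the pattern receive ambient 0. Sample albedo
  is 0.8, the background face (a large frontal plane at 140 mm) 0.025. The
  background reflectance is deliberately low: its fringe modulation
  variance on the 8-bit scale, (0.025·255/2)²/2 ≈ 5, plus its shot-noise
  variance ≈ 9, stays safely below the segmentation threshold γ = 30,
  which is what makes the variance mask meaningful.
* **Intersection.** Rays are marched in z (2 mm steps inside the
  phantom's bounding sphere — safe because the surface function is
  monotone along rays away from grazing silhouettes) and refined by
  bisection to 10⁻⁴ mm; a crossing of the base plane outside the diamond
  support is not a hit.
  Rays that miss both phantom and background raise an error rather than
  returning sentinel values.
* **Shot noise.** Every pixel is replaced by `Poisson(I·S)/S`, clipped to
  [0, 1]. The photon budget `S = 39.7` was calibrated once, by root-finding
  on simulated batches, so the mean PSNR between noisy and clean reference
  images is 27.56 dB; `calibratePhotonScale()` reproduces the calibration.

What the simulator does **not** model: diffuse shading and illumination
fall-off (intensity is independent of distance and surface normal), specular
reflection, lens distortion, motion blur, colour, and inter-reflections.
Passing the round-trip and training tests therefore demonstrates the
correctness of the algorithms under the stated image formation model, not
clinical performance on endoscopic video.

## The classical pipeline

* **Wrapped phase.** With images $I_k = a + b\cos(\phi + \theta_k)$ at the
  four shifts, $\phi = \mathrm{atan2}(I_4 - I_2,\; I_1 - I_3)$, exact for
  any offset $a$ and modulation $b > 0$; pixels with no modulation are
  flagged invalid rather than given a value.
* **Temporal unwrapping.** The ladder (1, 4, 16, 64 cycles) is resolved by
  the standard cascade $\Phi_{k+1} = \phi_{k+1} + 2\pi\,\mathrm{round}((r_k
  \Phi_k - \phi_{k+1})/2\pi)$, seeded by shifting the 1-cycle phase into
  $[0, 2\pi)$. Pixels whose cascade residual exceeds π at any rung are
  flagged unreliable.
* **Phase to depth.** The rational model $z = \frac{c_0 + c_1\phi + (c_2 +
  c_3\phi)u + (c_4 + c_5\phi)v}{d_0 + d_1\phi + (d_2 + d_3\phi)u + (d_4 +
  d_5\phi)v}$ with the gauge $d_0 = 1$. For a pinhole pair with a lateral
  baseline this model is *exact* (the phase is affine in $u$ and $1/z$),
  which is why the simulator round trip recovers depth to hundredths of a
  millimetre. `fitCalibration()` rearranges the model into a linear
  least-squares problem over ≥ 3 known-depth planes and reports rank
  deficiencies explicitly — two frontal planes genuinely underdetermine the
  11 free coefficients because each plane only spans five monomials.
  Pixels where the fitted denominator vanishes are marked invalid, never
  ±∞; validity travels as an explicit logical channel throughout.
* **Segmentation.** The mask is 1 where the *population* variance (divide
  by 16) of the sixteen phase-shifted intensities, on the 8-bit scale,
  reaches γ = 30, then cleaned by morphological opening followed by closing
  with a 5×5 square element (both sizes configurable). Whether the
  original rule uses population or sample variance is not documented; the
  population form was chosen and the threshold margin is wide enough that
  the distinction never flips a pixel class in the simulated scenes.

## The two-path network

Both paths are the same modified five-level U-Net: two 3×3 zero-padded
convolutions + ReLU per level, 2×2 max pooling down, 2×2 bicubic
(Catmull-Rom) upsampling with skip concatenation up, and — the modification
— a 1×1 convolution head at *every* decoder level. Head outputs are
bicubically upsampled to full resolution and summed **in logit space**,
then passed through one final activation (2-channel softmax for MaskNet,
sigmoid for DepthNet). Summing activations instead would break the simplex
normalisation, which is why logit-space summation was chosen where the
original description is ambiguous. Channel widths are a free design
choice; the package uses 32-64-128-256-512 ("paper" profile) and
8-16-32-64-128 ("tiny" profile). Weights are He-normal (convolutions) and
Xavier (heads) with a seed argument; biases start at zero.

DepthNet's sigmoid output `d` is mapped to millimetres by `150·d + 30`,
covering the 70–140 mm working range with margin. The final prediction is
the pixel-wise product of the rescaled depth and the binarised mask
(argmax; exact ties go to background), with masked-out pixels flagged
invalid.

The forward and reverse passes are implemented in the package's own
single-precision RcppArmadillo kernels (im2col convolutions, pooling with
stored argmax, fixed-weight bicubic resampling with exact adjoints); there
is no deep-learning framework underneath. The reverse pass is verified in
the test suite against directional finite differences at a point where
every ReLU is strictly active and no pooling window is tied — at generic
points the loss is only subdifferentiable and finite differences would
disagree for reasons unrelated to correctness.

## Losses and metrics

* **Depth loss** $L_d = \alpha\,\lVert \hat D \otimes M - D \otimes M
  \rVert_1 + (1-\alpha)\,(1 - \mathrm{SSIM}(\hat D \otimes M, D \otimes
  M))/2$ with α = 0.85. The L1 norm is averaged over all pixels of the
  masked, zero-filled maps (a per-valid-pixel alternative is a function
  argument). SSIM uses the standard 11×11 Gaussian window with σ = 1.5 and
  stabilisers $C_1 = (0.01 L)^2$, $C_2 = (0.03 L)^2$ with the dynamic range
  L = 150 mm, the span of the depth rescale; its analytic gradient is
  implemented alongside and checked against finite differences.
* **Dice loss** $L_m = 1 - \frac{1}{2}\sum_j \frac{2\sum_i M_{ij}\hat
  M_{ij} + \beta}{\sum_i M_{ij} + \sum_i \hat M_{ij} + \beta}$ over the two
  classes with β = 0.001.
* **Metrics** are computed over the valid set $V = \{M = 1\}$ of *ground
  truth* sample pixels: MAE, Abs Rel, and δ-accuracy with both δ = 1.1 and
  δ = 1.1² = 1.21 reported (benchmark tables in this field often quote the
  squared threshold). Abs Rel divides by the *prediction* — a deliberate,
  documented convention — with the conventional divide-by-truth form behind
  an argument. Valid pixels where the fused prediction is zero (MaskNet said
  background) are excluded from the ratio metrics and counted explicitly;
  they still penalise MAE. Segmentation quality is the sample-class Dice
  score and the mean IoU over both classes. Pattern comparisons use the
  standard two-tailed paired t-test.

## Training harness and scaled-down profiles

Acquired images are preprocessed by an 11×11 Gaussian (σ = 2, reflective
border) followed by bicubic downsampling to the network size. Training uses
Adam under a multistep schedule — rate 10⁻⁴ with 0.2 decays at epochs 20
and 60 over 150 epochs in the reference ("paper") profile. MaskNet and
DepthNet train separately, each with its own loss; the ground-truth mask
enters DepthNet's loss so background never drives the regression.

The **tiny profile** is the package's desk-scale study, dimensioned for a
single CPU: 512×512 renders downsampled to 64×64, 400 training / 100
validation / 100 test scenes, base width 8 (≈ 491k parameters per path),
batch 8, learning rate 10⁻³ with 0.2 decays at epochs 20 and 32, 34
DepthNet epochs and 20 MaskNet epochs (the Dice objective converges much
earlier than the regression). The render resolution matters because the
denoising filter is fixed at 11×11 with σ = 2: at 512 px the filter's
width-to-fringe-period ratio (0.087 at 20 cycles) approaches the reference
pipeline's 1024-px conditions (0.044), whereas a 256-px render would
remove nearly half the fringe amplitude before the network ever sees it.
The learning rate is ten times the reference value because the schedule is
compressed to ~1700 optimisation steps; these choices are the package's
own and claim no fidelity to the original training scale.
Ground-truth masks at network resolution are produced by applying the
5-mm-margin depth rule at render resolution and downsampling by block
majority vote — thresholding bicubically downsampled depth instead lets
edge ringing jitter the label boundary by about a pixel against the
visible phantom edge, an irreducible label noise that dominates the fused
model's error budget.

The ablation experiment retrains DepthNet with the loss unmasked (all-ones
mask), so the single path must also learn background depth, and evaluates
it without a segmentation path; this mirrors the design question the
two-path architecture answers — a single network's error budget is
dominated by the large background area. In the test suite this comparison
runs as its own paired experiment at a reduced scale (150 training / 40
test scenes, 12 epochs for both depth variants under identical schedules),
which keeps the comparison fair while staying small.

## Numerical and degenerate-case conventions

* Invalid pixels are carried as logical channels; no sentinel depths.
* `atan2(0, 0)` pixels (no modulation) are invalid; wrapped phases live in
  (−π, π] with the −π boundary folded to +π.
* Non-integer unwrapping ladder ratios warn; cascade outliers are flagged
  per pixel.
* Zero-variance paired t-tests and empty valid sets raise errors instead
  of returning NaN.
* Pool ties take the first maximum (column-major order); mask argmax ties
  go to background; both documented as contracts.
* Depth maps are stored on disk as 32-bit float TIFF in metres (values
  ≪ 1, which TIFF readers preserve exactly); the in-memory unit is mm.
  Images are 16-bit TIFF, masks 8-bit PNG, point clouds ASCII PLY.

## Known limitations

The renderer's image formation is deliberately idealised (no shading,
fall-off or specularity), so networks trained here exploit geometry-only
cues and transfer to real endoscopic imagery is untested. The tiny profile
underfits relative to the reference schedule; its error is dominated by
the phantom's sharp silhouette, where both depth and mask labels are
genuinely ambiguous at 64×64. The classical pipeline assumes the
projector is translated but not rotated relative to the camera; a strongly
toed-in projector would leave the rational calibration model only
approximate.
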