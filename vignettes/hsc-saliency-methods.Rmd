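---
title: "Hypercomplex spectral contrast: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hypercomplex spectral contrast: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hscsal)
```

## The model

Bottom-up (pre-attentive) visual saliency asks which image locations attract
attention before any task or recognition is involved. `hscsal` implements a
frequency-domain answer in which all colour channels — and for video, motion —
are processed *jointly* rather than as separate feature maps.

Each pixel of an image in HSV colour space is encoded as a pure quaternion

$$q(x,y) = H\,i + S\,j + V\,k,$$

so that hue, saturation and value travel together through one transform. A
quaternion image admits a *symplectic decomposition* $q = f_1 + f_2\,j$ with
$f_1 = w + x\,i$ and $f_2 = y + z\,i$ both lying in the complex subfield
spanned by $\{1, i\}$. The left-sided quaternion Fourier transform with
transform axis $i$ is then just two ordinary complex 2-D FFTs:

$$Q[u,v] = F_1[u,v] + F_2[u,v]\,j .$$

We use the unitary normalisation $1/\sqrt{MN}$ on both directions, making the
forward/inverse pair a true inverse pair and giving Parseval's identity
exactly — both properties are tested against a brute-force $O((MN)^2)$
quaternion DFT oracle.

Saliency is read off a **spectral contrast**. Blurring an image with a 2-D
Gaussian ($\sigma = 3$ px) averages its spectral energy; frequencies where the
original image carries much more energy than its blurred version are the
"unusual" ones. With the polar form $Q = \lVert Q \rVert \, e^{\nu \varphi}$
(amplitude times unit quaternion) the contrast spectrum is

$$CQ(u,v) = \ln\!\frac{\lVert Q_I(u,v)\rVert^2 + \varepsilon}
                      {\lVert Q_b(u,v)\rVert^2 + \varepsilon}\;
            \frac{Q_I(u,v)}{\lVert Q_I(u,v)\rVert},$$

i.e. the log energy ratio carried on the *original phase*, so both amplitude
(perceptual energy) and phase (structure) take part in the reconstruction.
The inverse transform gives a full quaternion image $cq = a + bi + cj + dk$,
and the single-scale map is the Gaussian-smoothed squared modulus
$S^l = G_{\sigma=3} * \lVert cq \rVert^2$ — non-negative by construction.

Scale matters: the map is computed at scales $l \in \{1, 0.5, 0.25\}$ of a
320 × 240 working resolution and averaged,

$$S_m = \frac{1}{L}\sum_l S^l,$$

then (optionally) divided by a logarithmic centre-bias weight
$1 + D_{\log}(x,y)$ and rescaled to $[0, 255]$.

For video, a five-frame motion cue on the intensity (HSV value) channel,

$$M_t = \tfrac{1}{8}\left(I_{t-2} - 4I_{t-1} - I_t + 4I_{t+1} - I_{t+2}\right),$$

fills the quaternion's scalar slot: $q_t = M_t + H_t i + S_t j + V_t k$. The
rest of the pipeline is unchanged, so spatial and temporal conspicuity compete
inside one spectrum instead of being fused by ad-hoc weights.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `scales` | 1, 0.5, 0.25 | – | pyramid levels averaged into $S_m$ |
| `blur_sigma` | 3 | px | energy-averaging blur and final map smoothing |
| `base_resolution` | 320 × 240 | px | working size for still images |
| `video_resolution` | 128 × 128 | px | working size for frames (keeps video cost low) |
| `log_epsilon` | 1e-12 | – | stabiliser inside the log ratio |
| `center_bias` | TRUE | – | divide by $1 + \ln(1 + r/r_{\text{half-diag}})$ |
| `motion_variant` | `"as_printed"` | – | five-tap weights; see below |
| `polar_axis` | `"eigen"` | – | reading of the polar phase factor; see below |

All of these live in one `hsc_config()` object.

## Design choices where the design was open

**DFT normalisation.** A symmetric prefactor on forward and inverse transform
is only self-inverse in the unitary convention, so $1/\sqrt{MN}$ is used on
both sides. Any fixed rescaling of the spectrum cancels in the contrast's log
*ratio*, so this choice does not change the saliency maps — it changes only
what the spectrum itself looks like, and it is the convention under which
round-trip and Parseval tests are exact.

**Polar phase factor.** The canonical per-frequency polar form
$Q = \lVert Q\rVert (Q/\lVert Q\rVert)$ (the *eigenaxis* form) is the default:
it loses nothing and reconstructs $Q$ exactly. A literal fixed-axis-$j$
reading, $\cos\varphi + j \sin\varphi$ with
$\varphi = \operatorname{atan2}(\lVert(x,y,z)\rVert, w)$, is available via
`polar_axis = "j"`; it coincides with the eigenaxis form when the spectrum
lies in the $\{1, j\}$ subfield and is lossy otherwise. It exists for
comparison, not for production use.

**Zero-amplitude frequencies.** The unit phase is undefined at
$\lVert Q\rVert = 0$; those frequencies get the identity quaternion, are
flagged, and receive a zero contrast coefficient — no 0/0 ever enters the
inverse transform.

**Pyramid semantics.** The point-wise spectral ratio requires the raw and
blurred spectra to live on the same frequency grid. Per scale $l$, the image
is bilinearly resized to $l \cdot$ `base_resolution`, *that* image is blurred
with $\sigma = 3$ (each level blurred independently), and the per-scale map is
resized back before averaging — so the multi-scale map is exactly the mean of
the per-scale maps, a property the tests assert with `identical()`.

**Blur boundary rule.** Gaussian filtering uses half-sample symmetric
(reflective) padding, implemented as banded convolution matrices. With a
symmetric kernel this rule preserves the channel mean *exactly* (tap pairs
$\pm d$ jointly conserve mass under reflection), which is why the tests can
demand mean preservation at 1e-6 and constants pass through untouched.

**Centre bias.** The log-distance weight is
$D_{\log} = \ln(1 + r / r_{\text{half-diag}})$ with
$r_{\text{half-diag}} = \tfrac{1}{2}\sqrt{(M-1)^2 + (N-1)^2}$ measured over
pixel centres. This makes the weight resolution-invariant, leaves the centre
pixel untouched and divides a corner pixel by exactly $1 + \ln 2$. Natural
logarithms are used throughout.

**The motion tap's central term.** The five-tap weights
$(1, -4, -1, 4, -1)/8$ sum to $-1/8$, so a perfectly static scene of
intensity $c$ yields a constant "motion" $-c/8$ rather than zero. That
constant mostly lands in the DC component and is largely cancelled by the
contrast ratio, but it is a real asymmetry. Both behaviours are shipped:
`motion_variant = "as_printed"` (default, faithful to the stated filter) and
`"zero_sum"`, which drops the central tap so any temporally constant sequence
gives exactly zero motion — the variant under which video saliency provably
reduces to static saliency on static scenes (tested to 1e-10). Frame indices
beyond the sequence ends are edge-replicated, so even a single-frame
"sequence" is well-defined.

**Evaluation conventions.** Foreground is `saliency > tau` (strict), so
`tau = 255` predicts nothing; precision over an empty prediction is defined
as 1, recall over an empty ground truth as 1. The ROC area is the trapezoid
over the 256-point sweep with the all-foreground anchor (1, 1) appended; ties
in FPR are ordered by TPR so the polyline is monotone. Connected components
are 8-connected (a diagonal touch joins components). The 30%-in-box detection
rule is evaluated with integer arithmetic (`10 * hits >= 3 * area`) so the
"at least 30%" boundary is exact.

## What the synthetic fixtures emulate — and what they do not

`make_popout_pattern()` renders the classic pre-attentive stimulus classes
(colour, orientation, curvature, intersection singletons, and a mixed pattern
with both a colour and an orientation deviant) as a regular grid of bars on a
black background, without anti-aliasing, so ground-truth boxes are
pixel-exact. `make_synthetic_video()` renders a 16 × 16 bright square
translating at 2 px/frame over either a *static texture* — a fixed-tint
luminance texture, since real static backgrounds (asphalt, sand, platforms)
vary in brightness far more than in hue — or *dynamic waves*, a drifting sum
of two sinusoidal gratings that defeats naive frame differencing. Default
sizes are 128 × 128 and 30 frames, matching the video working resolution.

Passing the behavioural tests on these fixtures shows that the model ranks a
feature singleton or a moving object above repetitive or quasi-periodic
surroundings under controlled conditions. It does *not* show performance on
natural photographs or surveillance footage: real scenes have textured,
hue-varying backgrounds, camera noise, illumination change and occlusion,
none of which the generators model. The evaluation module accepts any
user-supplied masks and boxes precisely so that real data can be scored with
the same protocols.

## Numerical notes and limitations

* Problem sizes: behavioural checks run at the standard operating points
  (320 × 240 stills, 128 × 128 × 30-frame videos, 100 pattern repetitions),
  which the package's test suite executes in a few minutes on one core.
* Bilinear resizing can produce values marginally outside `[0, 1]`; channels
  are clamped before HSV conversion, and maps are clamped at 0 after
  interpolation.
* Hue enters the quaternion as a plain coordinate in `[0, 1]`; its circular
  topology is not modelled, so two near-black pixels can differ strongly in
  hue. This follows the encoding's definition, but it means chromatic noise
  in dark regions is treated as genuine structure.
* The model is purely bottom-up: no object priors, no learning, no temporal
  smoothing of maps across frames. Camera motion is not compensated; on
  footage with global motion the motion cue fires everywhere.
* `saliency_threshold()` (3 × mean saliency) is the customary fixed rule of
  spectral saliency models for segmentation; scenes whose maps are not sparse
  call for a scene-specific threshold.
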