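---
title: "Recognising compound micro-expressions from magnified facial video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognising compound micro-expressions from magnified facial video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Micro-expressions (MEs) are involuntary facial movements lasting well under
a second, with muscle displacements that are often below one pixel in an
aligned face crop. Beyond the six basic emotion categories, people routinely
produce *compound* emotions — happily surprised, sadly fearful, and so on —
each formed by combining two basic emotions and expressed through a
characteristic union of FACS action units (AUs). `cmer` implements a
complete recognition pipeline for this setting:

1. **Eulerian video magnification (EVM)** makes the sub-visible motion
   visible;
2. **apex localisation** finds the frame of maximal expression via
   frequency-domain amplitude;
3. **TV-L1 optical flow** between the onset and apex frames summarises the
   motion as a dense displacement field, rendered as a colour-coded feature
   map;
4. a **shallow CNN** classifies the feature maps into 3 basic classes
   (Neg/Pos/Sur) or 7 compound classes (adding PS/NS/PN/NN), evaluated with
   leave-one-subject-out (LOSO) cross-validation.

A procedural face-video generator with AU-parameterised sub-pixel motion
makes every stage testable without access-restricted corpora.

## Stage models and their assumptions

### Eulerian video magnification

Each frame is decomposed into a Laplacian pyramid (Burt–Adelson, 5-tap
binomial kernel). At every detail level, each pixel's time series is
band-pass filtered with a Butterworth filter applied forward–backward
(zero phase), multiplied by the amplification factor $\alpha$ and added
back; the pyramid is collapsed and the result clipped to $[0,1]$. For a
motion of amplitude $a$ within the pass band, the first-order
(Taylor-linearised) model predicts an output amplitude of about
$(1+\alpha)a$; the approximation degrades once $\alpha a$ approaches the
spatial wavelength of the underlying texture, which is why large $\alpha$
visibly distorts fine structure.

Choices worth knowing:

* the low-pass residual is **not** amplified, so overall brightness is
  preserved; all detail levels share one $\alpha$ (no per-wavelength
  schedule);
* the default band is 0.1–0.4 Hz with a first-order filter: slow,
  sub-visible facial drift. The filter order and the reflect-padding length
  (`min(3 * order, T - 1)`) are exposed;
* clips shorter than one period of `f_lo` cannot resolve the band; the
  stage warns rather than refusing, since amplification of the in-clip
  spectrum is often still useful;
* RGB channels are processed independently (optionally attenuated above
  channel 1).

### Apex localisation by spectral amplitude

The apex is the frame deviating most from the clip's temporal baseline.
The detector removes the `dc_exclusion` lowest temporal-frequency planes of
the clip's temporal FFT (the default of 1 removes exactly the temporal
mean) and scores each frame by the total 3D-FFT amplitude of a Hann-tapered
`window`-frame block centred on it (clamped at the clip ends). Two details
matter and are deliberate:

* scoring the *residual* rather than the raw window is essential: the
  non-DC spectral energy of a raw window measures the local *rate* of
  change, which for a roughly triangular onset–apex–offset profile is
  constant on the ramps and *dips* at the apex — its argmax lands mid-ramp,
  not at the apex (we verified this numerically before settling the
  design);
* the Hann taper makes the score respond to the window centre. The
  magnitude spectrum is blind to circular shifts, so untapered clamped
  windows containing the same frames would tie exactly and the argmax
  would systematically undershoot isolated events.

Ties (within a relative $10^{-9}$) break toward the smallest frame index.

### TV-L1 optical flow

The flow field $U = (u, v)$ between onset $I_0$ and apex $I_1$ minimises an
L1 brightness-constancy data term weighted by $\lambda$ plus total-variation
regularisation of each flow component. The solver is the classical
duality-based scheme: coarse-to-fine over `n_scales` pyramid levels (factor
`eta`), with `n_warpings` relinearisations per level; each inner iteration
alternates (a) the pointwise closed-form threshold update producing the
auxiliary field $U'$ and (b) TV denoising of each component toward $U'$
with coupling $\theta$, realised as a Chambolle dual projection with step
$\tau$. Iterations stop when the mean absolute flow change drops below
$\varepsilon$. Defaults: $\tau = 0.25$, $\lambda = 0.05$, $\theta = 0.3$,
$\varepsilon = 0.01$, $\eta = 0.5$, 3 scales, 5 warpings.

Numerical choices:

* this $(\tau, \lambda, \theta)$ parameterisation is calibrated for 8-bit
  intensities; luminance is rescaled to 0–255 inside the solver so the
  data/regulariser balance matches the standard references (with inputs in
  $[0,1]$ the threshold steps shrink 255-fold and the stopping rule fires
  immediately);
* warping uses bilinear interpolation with border clamping; gradients are
  central differences; a 5-point (plus-shaped) median filter after each
  warp is on by default (`median_filter`);
* a dedicated instrumented entry point (`tvl1_energy_trace()`) runs the
  alternation with the TV proximal step iterated to near-convergence and
  reports the surrogate energy
  $TV(U) + \tfrac{1}{2\theta}\|U - U'\|^2 + \lambda|\rho(U')|$ per outer
  iteration, so block-coordinate descent can be asserted in tests.

The feature map encodes the flow with the Middlebury colour wheel — hue
from $\mathrm{atan2}(v, u)$, saturation $\propto |U| / \texttt{max\_mag}$
(95th percentile by default), value 1, zero flow white — and is resized to
$48 \times 48 \times 3$ for the classifier. The colour encoding is a
design choice; a raw $(u, v, |U|)$ encoding would be a straightforward
alternative but the wheel is the field's lingua franca for flow
visualisation and gives the network a locally smooth, bounded input.

### AU tables, compound recipes and compositing

The package ships two CSV-resourced AU tables: the prototypical AU sets of
the six basic micro-expressions (e.g. surprise = AU 1+2+5, disgust =
4+7+9+25+26), and the 18-emotion compound taxonomy in which each profile
lists prototypical AUs plus secondary AUs with observed usage proportions.
`resolve_aus()` builds a compound recipe: the compound's prototypical AUs
plus secondary AUs at or above `secondary_threshold` (default 0.5 —
"AUs most people use"). The *conflict rule* falls out of construction:
an AU of a source emotion absent from the compound's own profile is
dropped (disgust's jaw-drop AU 26 disappears in happily disgusted, whose
mouth is taken over by the AU 12 lip-corner puller of happiness).

Region sourcing is a fixed anatomical split: the head (dominant) emotion
of the compound name drives the upper face — brows, eyes, nose — and the
modifier drives the mouth. This matches the regional descriptions of
compound generation ("fear eye and sad mouth" for sadly fearful; surprised
brows with a happy mouth for happily surprised). We considered assigning
each region to whichever source contributes more of that region's resolved
AUs, but that rule mis-assigns the mouth of sadly fearful (fear contributes
AU 20/25 against sadness's none once low-proportion secondaries are
thresholded away), so the anatomical split is used.

`composite_faces()` takes each region's pixels from its assigned source and
blends across a box-filter feather band (default 7 px) at region
boundaries; the box kernel's compact support guarantees exact copies
beyond the band. `build_cmed()` assembles a compound dataset from
basic-emotion samples by pairing sources within subjects where possible
(across subjects otherwise, flagged) and compositing onset/apex/offset
triples.

### The classifier

The network follows the fixed shallow topology (input
$48 \times 48 \times 3$): a $1{\times}1{\times}12$ convolution (a cheap
non-linear channel mix), $5{\times}5{\times}12$, $3{\times}3$/stride-2 max
pool, $3{\times}3{\times}12$, pool, $5{\times}5{\times}24$, pool, two
1024-unit fully connected layers and a softmax output of 3 or 7 units.
Convolutions are zero-padded to preserve spatial size; pools are unpadded,
forcing the $48 \to 23 \to 11 \to 5$ chain. Batch normalisation follows
each convolution (before the ReLU); dropout follows each FC layer. The
loss is softmax cross-entropy with a max-shift.

Training is plain SGD: batch size 10, momentum 0.9, initial learning rate
0.01 stepped down tenfold every `decay_interval` epochs with a floor.
A literal reading of "ten-fold decay every 10 epochs" would underflow any
practical schedule by epoch 100, so the default interval is 100 epochs
with a floor of $10^{-5}$, both configurable. The default epoch budget is
500; dropout defaults to drop-probability 0.7. Everything — He
initialisation, shuffling, dropout masks — is driven by one Mersenne
Twister seed, so a seed fixes the loss curve exactly. The implementation
(forward, backward, BN, pooling) is hand-written in RcppArmadillo in
single precision; there is no deep-learning runtime among the
dependencies, and the network is small enough that an explicit
implementation is both transparent and fast.

LOSO evaluation trains one fold per subject and pools all folds'
predictions before computing accuracy, macro F1 and the confusion matrix
(macro averaging because class imbalance is the norm in this domain;
per-fold accuracies are also reported).

## The synthetic data generator

`render_face()` draws a schematic face — elliptical head with seeded,
smoothed skin texture, two brows, two eyes, nose, mouth — from a
continuous parametric geometry, so feature positions are real-valued and
sub-pixel displacements produce smooth intensity changes. Each supported
AU has one documented kinematic rule (AU 1/2 raise inner/outer brows, AU 4
lowers and knits them, AU 5 widens the eye aperture, AU 12 pulls mouth
corners up, AU 15 down, AU 20 stretches the mouth, AU 25/26 part the lips,
AU 9 shortens the nose, and so on), applied with displacement
`amplitude * phase` in pixels. Feature ink has compact support (hard
cutoff at ~4 sigma), so in noise-free mode the regions an emotion does not
activate are bit-identical across frames — a property the tests rely on.
Subject identity is a texture seed plus ±3% geometry jitter; motion
follows a triangular or Gaussian onset–apex–offset profile; optional
zero-mean Gaussian pixel noise is added per frame.

What the generator emulates: aligned face crops, frame rates and clip
lengths in the range of high-speed ME corpora, FACS-consistent regional
motion, sub-pixel amplitudes, inter-subject appearance variation. What it
does not: photorealistic appearance, head pose change, illumination
variation, idiosyncratic AU intensities, or the label noise of human FACS
coding. Passing the test suite therefore demonstrates that the pipeline's
machinery is correct and that the stages compose as designed — not that
real-data accuracies would reach any particular level.

## Demonstration conditions

`run_demo()` fixes the study conditions: 10 subjects × 7
class-representative emotions (happiness, disgust, surprise, happily
surprised, disgustedly surprised, happily disgusted, sadly angry), AU
amplitude 1.5 px, pixel noise sd 0.002, 35 frames at 30 fps, 96 × 96 px.
The demo pipeline magnifies with $\alpha = 2$ over 0.3–3 Hz — the band
containing the demo clips' onset–apex–offset timescale (roughly one cycle
per second); the canonical 0.1–0.4 Hz band targets much longer recordings
than a 1.2 s clip can resolve. The moderate $\alpha$ is deliberate: at the
demo's 1.5 px amplitude, stronger amplification saturates feature pixels
against the $[0,1]$ intensity bounds and, because zero-phase filtering is
non-causal, smears the motion bump's low-frequency energy across the
whole short clip; both effects corrupt the apex score, while at
$\alpha \le 2$ the detector recovers the true apex. Training uses 60
epochs with dropout 0.5: the folds have 63 training samples, so the
500-epoch/0.7-dropout defaults are unnecessarily heavy, and 60 epochs at
learning rate 0.01 converge on this data. Problem sizes throughout the
tests (64–96 px frames, tens of sequences) were chosen to keep the full
suite runnable on a laptop-class single core.

```{r demo}
library(cmer)
demo <- run_demo(seed = 1)
glance(demo$report)
autoplot(demo$report)
```

## Degenerate inputs, tolerances, tie-breaks

* `frame_sequence()` validates index ordering (onset ≤ apex ≤ offset) and
  channel counts; readers report the offending file on shape mismatches.
* The pyramid refuses depths the frame cannot support; collapse inverts
  build to float round-off by reusing the identical upsampling operator.
* `threshold_update()` is total: a zero warped gradient returns the flow
  unchanged.
* Apex ties break to the smallest index with a relative $10^{-9}$
  tolerance (FFT round-off makes exact ties astronomically unlikely
  otherwise).
* `f1_measure()` scores an unpredicted class 0 rather than NaN.
* Compositing demands masks disjoint beyond the feather band and errors
  otherwise.

## Known limitations

* The generator's schematic faces make class geometry more regular than
  real corpora; LOSO on synthetic data chiefly stresses the machinery, not
  the domain gap.
* Linear EVM saturates for $\alpha a$ beyond a fraction of the texture
  wavelength; the amplitude-gain tests deliberately use a band-limited
  texture to stay in regime.
* Flow feature maps are computed between exactly two frames (onset, apex);
  dense trajectories over the whole clip are out of scope.
* Video container input is not supported (no codec dependency); decode to
  frame directories first.
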