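---
title: "Mapping rod rhodopsin from autofluorescence bleaching movies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping rod rhodopsin from autofluorescence bleaching movies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhodomap)
```

## The measurement and its model

Rhodopsin, the visual pigment of rod photoreceptors, absorbs blue-green
light strongly until light exposure "bleaches" it into transparent
photoproducts. In 488 nm fundus autofluorescence imaging the detected
signal comes from lipofuscin in the retinal pigment epithelium *behind*
the rods, so a dark-adapted retina starts dim — the unbleached rhodopsin
absorbs roughly half of the double-pass light outside the fovea — and
brightens over the first minute of scanning as the rhodopsin bleaches.
The magnitude of that brightening, pixel by pixel, encodes the local
rhodopsin optical density. `rhodomap` turns a registered one-minute
autofluorescence movie into a spatial map of it.

By Beer–Lambert attenuation along the double light path
(excitation $\Lambda$ in, emission $\lambda$ out), with macular pigment
(optical density $D_{MP}$, concentrated in the fovea, time-invariant) and
rhodopsin (density $\varrho_{rh}$, bleaching away) as the absorbers in
front of the fluorophore, each pixel's intensity follows

$$AF(t) = \alpha\, e^{-\gamma e^{-\beta t}},$$

where

* $\alpha = I\Phi\, e^{-D_{MP}(460)(k_{MP}(\Lambda)+k_{MP}(\lambda))}$ is
  the fully bleached level: source power times fluorescence efficiency,
  attenuated by macular pigment (`compose_alpha()`);
* $\beta = I/L$ is the bleaching rate — illuminance over the reciprocal
  photosensitivity — in 1/s. It is a photochemical constant, spatially
  invariant across the field;
* $\gamma = \varrho_{rh}(0)(k_{rh}(\Lambda)+k_{rh}(\lambda))$ is the
  double-path rhodopsin optical density at the start. Since rhodopsin
  absorbance in the red emission band (590–600 nm) is negligible,
  $\gamma$ is effectively the rhodopsin absorbance at 488 nm. This is the
  map the pipeline produces.

The exponential bleaching law is the fast-illumination limit of the full
bleaching/regeneration balance
$dR/dt = -IR/L + (1-R)/K$, whose closed form
(`regeneration_fraction()`) decays from 1 to the steady state
$L/(KI+L)$. The visual-cycle time constant $K$ is 700–1000 s, far slower
than scanning-laser bleaching, so over a one-minute movie
$R(t) \approx e^{-\beta t}$ (`simplified_fraction()`); the package checks
the closed form against a Runge–Kutta integration of the balance
equation and the simplified law against the closed form in the relevant
regime.

## Macular pigment first

Because macular pigment sits in front of the rods, it both attenuates
$\alpha$ and must be known *before* fitting so the amplitude
initialization is spatially correct inside the macula. From a set of
$n \ge 2$ co-registered autofluorescence images at different
excitation/emission bands, with zero-sum weights $\omega_j$,

$$D_{MP}(460) = \frac{\sum_j \omega_j \ln\!\big(AF_p^{(j)}/AF_f^{(j)}\big)}
  {\sum_j \omega_j\big(k_{MP}(\Lambda_j)+k_{MP}(\lambda_j)\big)},$$

where $AF_p$ is a perifoveal reference (a circular average on a 6°
annulus, `perifoveal_reference()`). The zero-sum weights cancel the
band-dependent fluorescence-efficiency ratio, which is why the formula
needs no absolute calibration. Two bands with weights $(1,-1)$ recover
the classic two-wavelength estimate; more bands allow self-consistency
checks across weight choices (`mp_self_consistency()`), and the weight
set minimizing the total cross-set spread is reported. Nonpositive
pixels are masked, never clamped: clamping would bias a log-domain
estimate. Negative densities under noise are kept (an optional display
clip exists downstream).

The extinction templates $k_{MP}$ (normalized to 1 at 460 nm) and
$k_{rh}$ (normalized at 500 nm, zero at and beyond 590 nm) ship as
editable CSVs under `inst/extdata/` and are linearly interpolated; they
are smooth literature-style templates, user-overridable via
`read_coeff_table()` when calibrated curves are available.

## Fitting the brightening curve

Fitting $a e^{-c e^{-bt}}$ directly is awkward (double exponential), so
the fit minimizes the mean-square-log energy

$$E(p,b,c) = \sum_i \big|\ln f(t_i) - p + c\,e^{-b t_i}\big|^2 \Delta t_i,
\qquad p = \ln a,$$

a left-Riemann quadrature of the continuous objective on the timestamp
grid (uniform $\Delta t$ at a constant frame rate). Times are seconds
everywhere; frame indices are converted through the movie's timestamp
grid, which removes any per-frame/per-second ambiguity in the rate
parameter.

The minimizer comes from a semi-explicit gradient descent: the $p$ and
$c$ updates are implicit and solvable in closed form, the $b$ update is
explicit (`update_step()`). Within one sweep the $b$ and $c$ updates use
the current $p_n, b_n$ on their right-hand sides. For fixed $b > 0$ the
energy is *quadratic* in $(p, c)$ with constant Hessian

$$\partial_p^2 E = 2\textstyle\sum\Delta t,\quad
\partial_c^2 E = 2\sum e^{-2bt}\Delta t,\quad
\partial_p\partial_c E = -2\sum e^{-bt}\Delta t,$$

whose determinant is positive by Cauchy–Schwarz whenever $b > 0$ (it
degenerates only at $b = 0$, where $e^{-bt}$ and $1$ become linearly
dependent). The unique critical point is therefore the global minimum,
and the iteration converges to it from any start — the package verifies
this against brute-force grid search on noisy instances
(`energy_hessian()`, and the grid-search tests).

Numerical choices, made here because no reference values exist for them:

* step widths $\tau_p = \tau_c = 0.1$ (implicit updates are
  unconditionally stable, these just set speed), $\tau_b = 0.01$ (the
  explicit update's stability bound depends on $b$; during 3-parameter
  initialization fits a step that would drive $b \le 0$ is retried with
  a locally halved $\tau_b$);
* convergence when the largest parameter change falls below $10^{-7}$,
  capped at 5000 iterations; both exposed in `fit_config()`;
* pixels with any nonpositive sample after averaging are masked and
  handed to vessel detection as occlusion candidates.

**Initialization.** The movie is averaged over a perifoveal annulus
(5–8°, away from fovea, optic disc and major vessels) and one low-noise
3-parameter fit of that curve gives order-of-magnitude seeds. Then
3-parameter fits on a deterministic subsample of annulus pixels are
histogrammed (Freedman–Diaconis bins): the recovered rates concentrate
tightly around one value, which becomes $b_0$ — this is also the
evidence for holding $b$ spatially constant, which the production fit
does (`fix_b = TRUE`). If a macular pigment map is available, the
amplitude seed is modulated per pixel,
$p_0(x,y) = p_0 - D_{MP}(x,y)(k_{MP}(\Lambda)+k_{MP}(\lambda))$, which
matters twice: convergence inside the macula is faster, and — because
the iteration-count map is the vessel detector — a wrong foveal $p_0$
would otherwise masquerade as slow convergence and false vessel flags.

**Averaging.** Before fitting, every pixel of every frame is averaged
over its surrounding 8×8 window (sliding window, reflection borders,
`block_average()`): this is the noise suppression the fit relies on, at
the cost of ~4 px spatial smoothing; it also sets the contamination
radius used for mask dilation below.

## Vessels: detection from the fit itself

Retinal vessels block the excitation light; their pixels carry dark,
flow-modulated noise instead of the brightening signal. Rather than a
generic vessel segmenter, detection derives from the model fit:

* the iteration-count image $N(x,y)$ — the descent converges markedly
  slower where data and initialization disagree with the model
  (`detect_from_iterations()`, thresholded at a configurable percentile,
  default 95; non-converged and masked pixels are always included);
* the L1 residual $\Delta AF(x,y) = \sum_i |f(t_i) - \hat a
  e^{-\hat c e^{-\hat b t_i}}|$ (`detect_from_residual()`, percentile
  band, default 95–100; rank-based, hence invariant to global intensity
  scaling).

The final occlusion set is the union of both candidates, dilated by
half the averaging window (any pixel that close to a vessel has mixed
curves), with a smooth mask $\chi$ ramping linearly from 0 on the set to
1 at a configurable distance (default 3 px, Euclidean distance
transform). The ramp deliberately down-weights fidelity at vessel
borders, where eye-motion and registration jitter make the data
unreliable.

## Inpainting the occlusions

The preliminary $\hat c$ map is repaired by minimizing, per bit plane,
the modified wavelet Ginzburg–Landau energy

$$E_{WGL}(u) = w_f\!\int\!\chi\,|u-g|^2
 + \frac{1}{2\epsilon\mu}\!\int\!u^2(u-1)^2
 + \epsilon\mu\,|u|_B^2 ,$$

with $g$ the binary plane, the double-well driving $u$ to $\{0,1\}$, and
$|u|_B^2$ the Besov 1-2-2 seminorm. The seminorm is discretized as the
level-weighted detail energy of an orthonormal periodic wavelet
expansion (Daubechies-4 by default, 4 levels), weight $2^{2j}$ with
$j = 0$ at the coarsest detail level and growing toward fine scales —
the $H^1$-like convention; this discretization is the package's declared
convention. The map is quantized to 8 bits over a robust range (1st–99th
percentile, widened so that no fully-trusted pixel is clipped) and each
plane is processed separately, which contains gross artifacts to single
bit planes.

Minimization is plain gradient descent with backtracking (every accepted
step lowers the energy), starting from the data with holes filled by a
local 3×3-diffusion extension of the trusted surroundings — a local
start matters: a global-mean start lets the double-well lock entire
holes to the wrong phase. The result is thresholded at 1/2.
`fidelity_weight` defaults to 400, chosen so that trusted pixels
($\chi = 1$) are pinned against the seminorm's smoothing pressure in
every default variant; the descent controls (300 iterations, tolerance
5e-4 on the largest pixel change) are exposed in `wgl_config()`.

Following the two-step recipe, three variants with $(\epsilon,\mu)$
scaled by $\{0.5, 1, 2\}$ and mask transitions $\{2, 3, 4\}$ px are
averaged, and the average receives adaptive wavelet thresholding whose
threshold derives from the pointwise *disagreement between the
variants*, blended in only over the occlusion neighborhood. Where the
variants agree — in particular everywhere, when the mask is empty — the
threshold vanishes and the map passes through untouched up to
quantization.

Fidelity is reported as the maximum amplitude deviation (percent of the
robust dynamic range) and relative mean-square deviation between the
pre- and post-inpainting maps, assessed over the fully trusted region:
outside the occlusion set *and* beyond every variant's transition ring.
Inside the ring $\chi < 1$ by construction, so the energy deliberately
permits changes there and no preservation claim is made for it.

## The phantom: what it emulates, what it does not

`phantom_spec()`/`generate_movie()` simulate the whole acquisition with
known ground truth. Defaults are the standard study conditions: a
30° field at 256×256 (≈8.5 px/°), 8 frames/s for 60 s, bleaching rate
0.04 per frame (0.32 1/s — the one rate value reported for this
protocol), base amplitude 100 (8-bit-camera scale), additive Gaussian
noise of 2 % of the amplitude (scanning-laser autofluorescence is
low-SNR; no specific level is reported, so one realistic value was fixed
once), and a foveal macular pigment peak of $D_{MP} = 0.5$ with 1°
Gaussian width — a typical adult peak density.

The rhodopsin field follows human rod topology qualitatively:
$\gamma(r,\theta) = \gamma_{max}\,(1 - e^{-r/s(\theta)})$, zero at the
fovea center, $\gamma_{max} = 0.7$ (the ≈50 % double-pass attenuation of
a dark-adapted perifovea), with the rise scale smallest along the
superior vertical meridian and largest along the nasal horizontal
meridian, inferior retina in between. Vessels are a random tapering
tree entering from one edge, width 5 px (the ~0.5–0.7° arcade vessels
that actually occlude the signal), carrying 5 % residual intensity
modulated by a coherent 1.2 Hz pulsation of 30 % relative amplitude —
the flow modulation is what makes vessel pixels *violate* the monotone
brightening model, as real vessel pixels do; a noisy constant would be
fit perfectly by the model with $c \approx 0$ and would be undetectable
in principle.

Not emulated: eye motion and registration error (movies are perfectly
registered; the real pipeline assumes registration upstream), image
background (uncorrected background is why absolute amplitudes are not
claimed — the package maps the *distribution* of $\gamma$, in relative
units), wavelength-dependent lens absorption, and melanin. Passing
tests on phantoms therefore demonstrates correctness of the estimation
machinery under the stated model, not robustness to registration
artifacts or background structure.

## The five-step pipeline

`run_pipeline()` chains: macular pigment map (if an image set is given;
without one the amplitude seed is spatially constant — a documented
fallback that costs convergence speed and detector specificity in the
macula) → initialization → fixed-$b$ per-pixel fit → vessel detection →
inpainting, persisting every intermediate when asked. The run is
deterministic: the same inputs give bit-identical outputs, and each
stage validates its inputs and aborts with the stage name on failure.
Horizontal/vertical profiles through the fovea, averaged over small
stripes, summarize the final map (`radial_profiles()`).

Problem sizes used in the shipped tests were chosen to exercise every
code path at comfortable cost: most module tests run on 24–64 px
phantoms with 4 frames/s, 20 s movies; the end-to-end fidelity checks
run one full-scale 256×256, 480-frame phantom.

## Known limitations

* $\beta$ is assumed spatially constant; true spatial variation (e.g.
  local photosensitivity changes) would fold into $\hat c$.
* The iteration-count detector's contrast rests on the initialization
  being accurate *except* at vessels; where low-rhodopsin retina shares
  the vessels' parameter offset, its specificity drops and the residual
  detector and the union mask carry the detection.
* Bit-plane inpainting can flip single high bits near plane boundaries
  inside the transition ring; the variant averaging plus
  disagreement-driven thresholding suppresses but does not forbid this
  (it is confined to the down-weighted ring).
* Quantization to 8 bits bounds the inpainting's reconstruction
  resolution at 1/255 of the robust range.
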