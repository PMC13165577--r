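---
title: "Coflowing-stream viscometry and continuous RBC aggregation indexing: models, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coflowing-stream viscometry and continuous RBC aggregation indexing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coflowrheo)
```

## The measurement principle

The chip measures two hemorheological quantities at once while blood is
delivered continuously from a syringe:

1. **Viscosity**, from the lateral position of the interface that the test
   blood forms against a reference fluid (1x PBS) in a shared
   viscosity-sensing channel (width $w$ = 1 mm, depth $h$ = 0.05 mm).
2. **RBC aggregation**, from the intensity difference between a high-shear
   main chamber and a low-shear aggregation chamber fed by a small bleed of
   the same blood stream.

### The virtual-wall viscosity model

The coflow interface is treated as a rigid partition that splits the
channel into two parallel rectangular conduits, one carrying the reference
fluid at $Q_r$ and one carrying the blood at $Q_b - Q_{ac}$. Both conduits
share the same pressure drop, which after cancellation of the common
geometry factors gives

$$\mu_b = \mu_r \, \frac{\alpha_b}{1-\alpha_b}\,
  \frac{Q_r}{Q_b - Q_{ac}}\, C_f(\alpha_b),$$

where $\alpha_b = w_b / w$ is the blood-filled width fraction. The
virtual-wall idealization ignores the real, curved, stress-continuous
interface; the quartic correction factor

$$C_f(\alpha) = -12.038\,\alpha^4 + 26.171\,\alpha^3 - 20.770\,\alpha^2
  + 7.156\,\alpha + 0.014$$

absorbs that modeling error. It is an empirical calibration for this
channel cross-section (1 mm x 0.05 mm). Because it is a fit, the package
refuses to extrapolate: evaluation outside $\alpha_b \in [0.05, 0.95]$ is
an error, never a silent clamp. The practical remedy when the interface
drifts out of this window is the experimental one — retune $Q_r$ to bring
the interface back toward mid-channel.

The map $g(\alpha) = \frac{\alpha}{1-\alpha} C_f(\alpha)$ is strictly
increasing on the calibrated domain (asserted by dense sampling in the
tests), so the model can be inverted uniquely.
`interface_from_viscosity()` does this by bisection to a residual of
1e-10; a derivative-free method was chosen for robustness since the
function is cheap and the domain fixed. The synthetic renderer uses this
inverse as its forward model for placing the interface, which is what
makes closed-loop recovery tests meaningful: generation and analysis share
the physics but not the code path (generation inverts the model, analysis
evaluates it on measured images).

### Shear rates and auxiliary quantities

For a low-aspect rectangular channel the wall shear rate is
$\dot\gamma = 6Q/(wh^2)$; in the viscosity channel the blood stream
occupies only $\alpha_b w$, giving
$\dot\gamma = 6(Q_b - Q_{ac})/(\alpha_b w h^2)$. Hydraulic resistances use
the single-term aspect-corrected formula
$R = 12\mu L / (w h^3 (1 - 0.63\,h/w))$ — the truncation error of the full
series is far below 1 % at $h/w = 0.05$, and the resistance network is
only used to derive synthetic flow splits. Flow conservation
$Q_{vc} = Q_b - Q_{ac}$ is enforced structurally, not checked after the
fact.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `q_b` | 0.4 | mL/h | working blood flow rate; wall shear 266.7 1/s in the 1 mm channel, 2666.7 1/s in the 0.1 mm channel |
| `q_r` | per run | mL/h | retuned per fluid so the interface sits near mid-channel; the presets use 0.8–2.5 |
| `mu_r` | 1.0 | cP | PBS at room temperature; an assumption, configurable |
| `split` | 0.05 | – | measured fraction of blood entering the aggregation channel; glycerin-like fluids run nearer 0.073 (the `newtonian` preset uses that) |
| `window_px` | from pixel scale | px | the physical 67 µm interrogation window, 13 px at 5 µm/px |
| `overlap` | 0.5 | – | standard half-window overlap |
| `median_threshold`, `std_threshold` | 2, 3 | – | local-median and global-SD vector validation |
| `plateau_cv_threshold` | 0.05 | – | a run qualifies as "steady" when its rolling CV stays below 5 % |
| `smooth_window` | 11 | triggers | AI_max smoothing; suppresses single-trigger spikes |
| `sed_tau`, `stasis_kappa` | 600 s, 6 | | syringe sedimentation time constant and its acceleration while delivery is stopped |

## The micro-PIV correlator

Displacements in this chip are small: at $Q_b$ = 0.4 mL/h the main-chamber
plug velocity is about 2.2 mm/s, i.e. 0.44 px between burst frames at
5 µm/px and 1 ms; the aggregation chamber is twenty times slower still.
Two design decisions follow from prototyping at exactly these scales:

* **Integer stage by SSD, not correlation.** The integer displacement
  minimizes the sum of squared differences between the interrogation
  window and each offset window of the second frame (computed via one
  zero-padded FFT correlation plus summed-area tables). SSD is exactly
  zero for a pure translation and penalizes high-energy mismatches, which
  plain (or overlap-normalized) correlation does not: a bright particle
  just outside the window edge can otherwise drag the peak one pixel off.
  Offset windows come from the full frame, not the ROI, since matched
  content advects in from outside.
* **Subpixel stage on the matched windows.** The window and its
  integer-offset counterpart are zero-meaned and correlated
  (overlap-normalized, zero-padded FFT); a three-point log-Gaussian fit
  gives the residual. When the offset window is pixel-identical to the
  first window the integer vector is returned untouched — pure integer
  translations are recovered exactly, a property the unit tests assert to
  machine precision. Measured accuracy on rendered particle images is
  within about 0.01 px at half-pixel and 2.5 px shifts and a few percent
  of the displacement at 0.44 px.
* **ROI averaging as the magnitude of the mean vector.** Averaging
  per-vector magnitudes rectifies zero-mean estimation noise; at the
  aggregation-channel displacement (~0.02 px) under noise this inflates
  the speed roughly threefold and would bias the viscosity by >10 %.
  Component-wise averaging is unbiased for the uniform unidirectional
  chamber flows measured here; the per-vector-magnitude average remains
  available via `average = "magnitude"`.

A single-pass correlator suffices because the flows are uniform inside the
ROIs; no window deformation or multi-pass refinement is implemented. The
~20–25 % systematic velocimetry bias reported for real micrographs is
neither reproduced nor corrected at the PIV level: the plateau calibration
$Q_{mc} = U_{mc}/\langle U_{mc}\rangle \cdot Q_b$ cancels any
multiplicative bias by construction (a property the tests assert by
scaling all velocities by arbitrary constants).

## Intensity, interface, and AI conventions

* Coordinates are 0-based, row-major, origin top-left; ROIs are half-open
  rectangles; the interface is counted along image rows (across the
  channel).
* Otsu's threshold is computed on the vc ROI only, so chamber content
  cannot shift it; the implementation maximizes between-class variance
  over the 256-bin histogram with ties broken toward the lower threshold,
  and the tests compare it against an exhaustive 256-candidate scan on 200
  random images. Blood is assigned to the darker class by mean intensity,
  not by spatial side, so the chip may be mounted either way.
* **AI uses raw intensities by default.** $(I_{mc}-I_{ac})/I_{mc}$ is
  scale-sensitive: after background subtraction $I_{mc}$ can approach
  zero and the ratio explodes. The subtracted mode exists
  (`ai_mode = "subtracted"`, guarded against denominators below 10
  intensity units) because the background-subtraction convention of
  stopped-flow instruments is ambiguous; the default avoids the
  instability. Background subtraction itself keeps signed differences and
  defaults to the first trigger frame, the least-assuming reading of an
  "initial background image".
* The stopped-flow (stasis) AI is an endpoint-ratio variant:
  $(I(t_{stop}) - I(t_{stop}+120\,s))/I(t_{stop})$ with the start value
  averaged over the first five samples. The classical formula is cited in
  the stopped-flow literature without being restated in the source
  describing this chip, so the package documents its variant explicitly
  rather than guessing at another.
* Missing-value policy: any trigger with a failed PIV pair, an interface
  outside the $C_f$ domain, or a non-positive $I_{mc}$ produces `NA` in
  the outputs. Nothing is interpolated.

## What the synthetic generator emulates — and what it does not

The generator reproduces the features of real runs that drive the
analysis:

* **Syringe sedimentation.** Delivered hematocrit rises as
  $Hct(t) = Hct_0 (1 + a A (1 - e^{-s(t)/\tau}))$ where the sedimentation
  clock $s(t)$ accrues at rate 1 during delivery and rate $\kappa > 1$
  while the syringe is stopped. This reproduces the qualitative signatures
  of no-delivery waiting time and on–off schedules (faster viscosity rise,
  suppressed AI) without modeling the barrel hydrodynamics. Amplitude
  defaults are tuned for qualitative agreement only; the source data do
  not constrain them quantitatively.
* **Phantom viscosity** follows a Krieger–Dougherty-type law
  $\mu_b = \mu_{medium}(C_{dex})(1 - Hct/0.98)^{-2.5}$, monotone in both
  arguments; Newtonian calibration fluids override it with a fixed value.
* **Aggregation deficit**: the aggregation chamber is darkened by a factor
  $1 - d$ with $d = gain \cdot a \cdot f_{dex}(C_{dex})(1-Hct)\,g(\dot\gamma)$,
  $f_{dex}$ unimodal peaking at 15 mg/mL and $g$ decreasing in shear.
  Because the whole chamber content is scaled, the measured
  $(I_{mc}-I_{ac})/I_{mc}$ equals $d$ by construction, which is what makes
  $d$ a usable ground-truth AI target.
* **Paired chamber seeding.** Both chambers share one tracer layout per
  trigger (they have identical dimensions), advected at their own
  velocities. On control datasets the chambers are therefore
  pixel-identical in the first burst frame and the AI is exactly zero —
  seeding noise cannot masquerade as aggregation.
* **Interface placement** at row $\mathrm{round}(\alpha_b\,w_{px})$, so
  noiseless interface recovery is quantization-limited to half a pixel
  (0.0025 in $\alpha_b$ at 5 µm/px).
* **Plug rendering**: uniform velocity across each chamber ROI,
  consistent with treating PIV output as depth-averaged velocity in a
  channel whose depth is far below the correlation depth. Tracers are
  analytic Gaussians (sigma 1 px, amplitude 50) at a density of
  2400 mm^-2 (~10 per interrogation window).
* Dilute-tracer Newtonian fluids barely darken the coflow stream under
  the linear attenuation model, so the renderer accepts an explicit
  `vc_contrast` for the test stream; the `newtonian` preset sets 60
  intensity units.

Not emulated: optical point-spread and depth-of-correlation effects,
cell-scale image texture, the curved three-dimensional interface shape,
in-chip sedimentation, gravity, and entrance effects. Passing closed-loop
tests therefore demonstrates that the *analysis chain is a correct inverse
of the stated model at realistic signal levels and noise* — not that the
model captures every property of real micrographs. In particular the
renderer's noiseless interface is ruler-straight, so the measured
per-column dispersion of $w_b$ underestimates what a real coflow would
show.

## Validation design and problem sizes

The test suite runs closed loops at three scales, chosen to keep the whole
suite within a few minutes of one CPU:

* unit fixtures: 100–200 px particle images, exact-arithmetic oracles;
* closed-loop runs: full 1 mm channel width (200 px) with shortened
  0.3–0.6 mm ROIs, 24 triggers;
* the acceptance script: 0.9 mm^2 ROIs, 60 triggers per dataset.

Recovery bounds asserted over the grid $\mu_b/\mu_r \in \{1.5, 3, 6\}$,
noise $\sigma \in \{0, 3, 5\}$: viscosity within 5 % (noiseless) / 10 %
($\sigma = 5$) of ground truth at every trigger, AI within 0.02 / 0.05
absolute, interface within 1 / 2 px. The per-trigger maxima make these
bounds sensitive to ROI size (fewer interrogation windows, larger
realization scatter), which is why the grid uses the wider 0.6 mm ROI.

## Known limitations

* The correction factor is calibrated for one cross-section; other chip
  geometries need their own $C_f$.
* The inverse model requires the interface inside $[0.05, 0.95]$; runs
  whose viscosity ratio pushes it outside fail fast with advice to retune
  $Q_r$, mirroring experimental practice.
* The plateau selector assumes a steady delivery segment exists; strongly
  drifting velocity records need `plateau_override`.
* No non-Newtonian constitutive fitting and no inferential statistics
  (ANOVA, confidence intervals) are provided; the outputs are per-run
  time series and summary scalars.
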