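---
title: "Fourier ptychography at desk scale: model, algorithm and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fourier ptychography at desk scale: model, algorithm and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpmicro)
```

## Why Fourier ptychography

An objective lens is, in the coherent picture, a circular low-pass filter on
the sample's spatial-frequency spectrum with cutoff $2\pi\,\mathrm{NA}/\lambda$.
Low-NA objectives therefore give a large field of view and a large depth of
field but poor resolution; high-NA objectives give the opposite. For tasks
like scanning blood-smear slides for analyzable metaphase chromosomes, this
trade-off dominates the cost of the instrument and the scanning time.

Fourier ptychography microscopy (FPM) sidesteps the trade-off. An LED array
below the stage illuminates the sample from a grid of angles. Illuminating a
thin sample $s(x)$ with a tilted plane wave of transverse wave vector
$k_m$ shifts its spectrum: the objective now collects the disk of radius
$2\pi\,\mathrm{NA}_{\mathrm{obj}}/\lambda$ centred (in object-spectrum
coordinates) at $-k_m$. Recording one low-resolution intensity image per
LED samples many overlapping disks; stitching them computationally extends
the passband to $2\pi(\sin\theta_{\max} + \mathrm{NA}_{\mathrm{obj}})/\lambda$,
i.e. the system behaves like one of equivalent numerical aperture

$$\mathrm{NA}_{\mathrm{eq}} = \mathrm{NA}_{\mathrm{obj}} + \mathrm{NA}_{\mathrm{illum}}.$$

Because the camera records only intensities, the stitching is a phase
retrieval problem, and because real objectives are aberrated, the pupil
function must be estimated jointly with the object.

## The instrument emulated by the defaults

The package defaults describe a concrete LED-array microscope:

| parameter | default | unit | meaning |
|---|---|---|---|
| `wavelength_um` | 0.53 | um | green LED central wavelength |
| LED grid | 15 x 15 used (of 32 x 32) | – | centered illumination sub-grid |
| `pitch_mm` | 4 | mm | LED spacing |
| `stage_distance_mm` | 70 | mm | LED panel to sample |
| objective presets | 4x/0.1 NA, 10x/0.25 NA | – | raw acquisition lenses |
| `tube_focal_length_mm` | 150 | mm | platform tube lens |
| `reference_focal_length_mm` | 180 | mm | infinity-standard reference |

Two consequences of this geometry that the package computes rather than
assumes: the effective magnifications are $4 \times 150/180 \approx 3.33$
and $10 \times 150/180 \approx 8.33$, and the outermost axis-aligned LED
(28 mm off axis) gives $\sin\theta = 28/\sqrt{28^2+70^2} = 0.3714$.

`illumination_na()` reports this axis-aligned maximum by default and the
corner-LED (diagonal) maximum 0.4924 on request. The axis-aligned value is
the one that governs bar-target resolution (bars are resolved along one
axis), and it is the convention under which the instrument's nominal
illumination NA of 0.38 and equivalent NAs of 0.48 / 0.63 are quoted; the
geometry-exact sums are 0.4714 / 0.6214. The package reports both rather
than forcing agreement, since the stage distance of such instruments is
only known to a few per cent.

## Forward model

`simulate_acquisition()` implements, per LED $m$:

1. $S \leftarrow \mathcal{F}[s]$ on the high-resolution grid (pixel
   $p$ um, $n \times n$), with spectrum sampling
   $\Delta k = 2\pi/(np)$;
2. spectrum shift by $k_m$ rounded to an integer number of spectrum
   pixels (the rounding residual is recorded with the stack);
3. multiplication by the pupil $P(k)$ — a binary disk of radius
   $2\pi \mathrm{NA}/\lambda$, times the defocus phase
   $e^{i z k_z(k)}$, $k_z = \sqrt{(2\pi/\lambda)^2 - |k|^2}$ (air,
   $n = 1$) when the sample sits $z$ um from focus;
4. inverse transform, intensity $|\cdot|^2$, and reduction to the camera
   grid (factor `downsample_factor`);
5. optional Gaussian or Poisson noise under an explicit seed (default:
   none).

Exposure is normalized so a clear sample under on-axis illumination yields
mean intensity 1; all LEDs are assumed equally bright.

Two camera-reduction models are provided. `"box"` (the default) computes
the intensity on the high-resolution grid and box-averages it over camera
pixels — a physical model of pixel integration. `"sample"` extracts the
pupil-sized spectrum window directly and transforms it at the camera size,
i.e. it point-samples the band-limited field — exactly the measurement
model the reconstruction assumes. The two differ by a sinc-shaped
apodization of the intensity spectrum (about 14% at the band edge for the
default factor 4). Consistency experiments (object recovery error, pupil
recovery) use `"sample"` so that they measure the algorithm and not this
model mismatch; realism-oriented runs keep `"box"`. With `"box"` data the
recovery error floor is about 0.10 relative RMS instead of 0.04.

`brute_force_forward()` re-implements steps 1–4 for a single LED by
explicit DFT matrix products with its own pupil construction and no shared
spectral plumbing; the test suite requires the FFT path to match it to
1e-10 RMS. It refuses objects beyond 64 x 64 (quartic cost).

## Reconstruction with embedded pupil recovery

`fpm_reconstruct()` divides the high-resolution spectrum into one
subregion per LED (center $-\mathrm{round}(k_m/\Delta k)$ pixels) and
iterates full sweeps of three steps per subregion $m$:

1. **forward**: $\Psi_m = W_m P$, $\psi_m = \mathcal{F}^{-1}[\Psi_m]$,
   where $W_m$ is the pupil-sized window of the current spectrum;
2. **intensity constraint**: $\phi_m = \sqrt{I_m}\,\psi_m/|\psi_m|$ — the
   modelled magnitude is replaced by the measured one, the phase kept.
   Where $|\psi_m| = 0$ the phase factor is taken as 1, so
   $\phi_m = \sqrt{I_m}$ there;
3. **Gauss–Newton update**: with $\Delta\Psi = \mathcal{F}[\phi_m] - \Psi_m$,
   $$W_m \mathrel{+}= \frac{\bar P\,|P|}{\max|P|\,(|P|^2 + \delta_1)}\Delta\Psi,
   \qquad
   P \mathrel{+}= \frac{\bar W_m\,|W_m|}{\max|W_m|\,(|W_m|^2 + \delta_2)}\Delta\Psi,$$
   the embedded-pupil-recovery step form; the pupil is re-clipped to its
   ideal disk support after every update.

Numerical choices, all configurable through `reconstruction_options()`:

* **regularizers** $\delta_1 = \delta_2 = 10^{-8}\max|\cdot|^2$ of the
  respective divisor, recomputed per update — small enough to be inert
  away from zeros of $|P|$ or $|W|$;
* **ordering**: subregions are visited from the lowest $|k_m|$ outward
  ("spiral", bright field first), the convention that anchors the object
  estimate before dark-field updates arrive; raster order is available for
  ablation;
* **initialization**: the bilinearly upsampled square root of the on-axis
  image with zero phase. The interpolation treats the image as periodic,
  which makes the whole pipeline exactly equivariant under circular object
  shifts (a property the tests exercise at 1e-8);
* **stopping**: at most `max_iterations` sweeps (default 50) or a relative
  residual change below `tolerance` (default 1e-4) between consecutive
  sweeps, whichever comes first. The residual is
  $\sqrt{\sum_m\sum_r (|\psi_m| - \sqrt{I_m})^2 / \sum_m\sum_r I_m}$,
  accumulated as the sweep visits each subregion. No universal tolerance
  exists for this family of algorithms; these are engineering defaults,
  and on noiseless consistent data the residual decreases monotonically
  (tested to 1e-12 slack);
* **gauge**: a global phase is unobservable from intensities, so results
  are reported with the phase at the brightest amplitude pixel set to 0;
* **upsampling**: the reconstruction grid defaults to the acquisition's
  camera downsampling factor; initialization refuses configurations whose
  outermost subregion would not fit in the spectrum.

Pupil recovery is validated by planting a known 10 um defocus in the
simulated data and correlating the recovered pupil phase with the planted
one over the pupil support (masked Pearson; 0.96–0.998 in the shipped
experiments under the 4x/0.1 NA preset). Under the 10x/0.25 NA preset the
same defocus spans 6.1 rad of pupil phase, which wraps past $\pm\pi$ and
makes a Pearson comparison of wrapped angles meaningless — a limitation of
the comparison metric, not of the recovery.

## Phantoms: what they emulate and what they do not

`generate_usaf_phantom()` renders standard three-bar elements (length:width
5:1, both orientations) with exact USAF 1951 frequencies
$2^{g + (e-1)/6}$ lp/mm, antialiased by 4x supersampling and box
downsampling, on a clear background. Dark bars default to full amplitude
contrast and zero phase — the chrome-on-glass target carries no phase
structure — with an optional phase step for mixed targets. The element
layout is a shelf packing, not the historical target layout; the attached
index (rectangles, orientations, frequencies) is what the evaluation
functions consume.

`generate_chromosome_phantom()` renders elongated, slightly curved rods
with alternating dark/bright bands perpendicular to the centerline, both
absorbing and phase-retarding (Giemsa-stained chromatin is a partial phase
object; the phase is rendered proportional to absorption, peaking at 1 rad
by default). Band spatial frequencies default to 300–900 lp/mm — band
periods of 1.1–3.3 um, inside the sub-1000 lp/mm range where chromosome
banding lives and where FPM's contrast advantage matters. Dark-band
transmission (0.35) and the phase peak are rendering choices for visually
plausible contrast, not measured optical densities; no quantitative Giemsa
density data stands behind them. The generator does **not** emulate nuclei,
cytoplasm, debris, karyotype-accurate band catalogs, partial coherence,
vignetting, LED brightness variation or camera nonlinearity — so passing
tests demonstrate algorithmic correctness on idealized coherent data, not
clinical performance.

## Evaluating resolving power

`bar_contrast()` measures $C = (I_{\max} - I_{\min})/(I_{\max} + I_{\min})$
from the per-element profile obtained by averaging along the bar length
(trimmed 10% at each end, away from antialiased bar ends, and padded half a
period across the bars). $I_{\min}$ is the mean of the three deepest
valleys, $I_{\max}$ the mean of the two ridges between them; an element
counts as resolved only if those five extrema are detectable. Averaging
per extremum (rather than per profile) is a choice; the ratio form makes
the measure exposure-invariant.

`build_mtf()` collects one sample per element (orientations averaged) and
normalizes by the lowest-frequency element as the zero-frequency proxy.
`fit_mtf_curve()` isotonically regresses the samples (non-increasing) and
interpolates with a monotone Hyman-filtered cubic spline anchored at
$(0, 1)$; the cutoff is the first frequency at which the fitted curve
reaches 0.02 (configurable — fitted curves approach zero asymptotically, so
an exact zero crossing is ill-defined), and `frequency_at_contrast()`
inverts the curve. `smallest_resolved_element()` applies a 0.1 contrast
threshold on top of the extrema check.

One behaviour of ideal coherent simulations deserves emphasis: the
coherent transfer of a clean pupil is flat up to its edge, and finite
three-bar elements have spectral lobes of half-width about $f/3$, so
elements with fundamentals up to roughly $1.5\times$ the cutoff retain
measurable (low) contrast. The simulated 4x/0.1 NA raw image therefore
reads about one element past the 188.7 lp/mm edge, and its fitted cutoff
lands near 245 lp/mm — the same overshoot-beyond-theory that real coherent
instruments show. The package's tests assert these physically derived
brackets rather than the textbook Rayleigh number.

A second coherent-model caveat: depth-of-field comparisons between a
low-NA and a high-NA system at the *same* bar frequency are nearly a tie
at the raw-image level, because on-axis coherent defocus applies the same
phase error to the fundamental in both systems. The package's
depth-of-field experiment therefore compares the FPM *reconstruction* from
a defocused low-NA stack against the defocused conventional high-NA image,
where the advantage is real and large. An incoherent conventional-imaging
model (where the classical $\lambda/\mathrm{NA}^2$ depth of field would
emerge) is out of scope.

## Problem sizes and determinism

The shipped experiments run at deliberately modest sizes chosen to exercise
every code path: a 512 x 512 USAF scene (groups 7–9 at 0.2 um pixels, 225
LEDs, camera factor 4, 15 sweeps) for the resolution-gain experiment, and
128 x 128 chromosome scenes (40–50 sweeps) for the recovery and
pupil-recovery experiments. All randomness (phantom placement, noise draws)
flows through explicit seeds and restores the caller's RNG; noiseless
simulations are bit-deterministic, so repeated runs reproduce every
reported number exactly.

## Known limitations

* Single tile: no field-of-view tiling/stitching, no spatially varying
  aberrations across the field.
* No LED-position self-calibration, adaptive defocus search, or learned
  reconstruction.
* Illumination wave vectors are rounded to the spectrum grid (residuals
  recorded); sub-pixel spectrum placement is not implemented.
* The conventional-microscope comparison arm is coherent, which
  understates the depth-of-field contrast described above.
* Stack files store 32-bit samples scaled to a recorded full-scale value;
  quantization is $2^{-32}$ of full scale.
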