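---
title: "Methods: physics-augmented calibration transfer for infrared microscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: physics-augmented calibration transfer for infrared microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Quantitative FTIR calibrations (e.g. percent total lipid of microbial
biomass against gas-chromatography reference values) are normally built on
*macroscopic bulk* spectra: dried sample spots measured in transmission with
an effectively uniform optical path. Infrared *microscopy* produces a
hyperspectral cube — one spectrum per pixel of a few micrometres — whose
spectra are not directly compatible with that calibration, for two reasons:

1. **Mie scattering.** Structures of a few micrometres (lipid droplets, cell
   walls, hyphae) are comparable in size to mid-IR wavelengths. The light
   they scatter out of the collection aperture appears as absorbance,
   producing broad oscillatory baselines and derivative-shaped band
   distortions that move with particle size and refractive index.
2. **Domain shift.** Pixel spectra differ from bulk spectra in effective
   pathlength, lineshape and noise even without scattering.

`micral` implements a two-model pipeline: a **transfer model** maps a pixel
spectrum into the bulk-spectrum domain, then a **calibration model** trained
purely on bulk spectra predicts the analyte. Applied pixel-wise, this turns
a cube into a quantitative chemical map.

## Forward model of the scatter distortion

The scattering correction is anchored in electromagnetic theory rather than
empirical baselines.

**Lorenz–Mie series.** For a homogeneous sphere of radius $r$ and complex
relative refractive index $m = n_r + i\,n_i$ at size parameter
$x = 2\pi r \tilde\nu$ (with $r$ in cm and $\tilde\nu$ in cm$^{-1}$), the
scattering and extinction efficiencies are

$$Q_{sca} = \frac{2}{x^2}\sum_n (2n+1)(|a_n|^2 + |b_n|^2), \qquad
  Q_{ext} = \frac{2}{x^2}\sum_n (2n+1)\,\mathrm{Re}(a_n + b_n),$$

with coefficients $a_n, b_n$ computed by downward recursion of the
logarithmic derivative of the Riccati–Bessel function inside the sphere
(numerically stable for absorbing media) and upward recursion of the outer
Riccati–Bessel functions. The series is truncated at
$N = \lceil x + 4.05\,x^{1/3} + 2\rceil$. The implementation is vectorized
over wavenumber and validated against an independent arbitrary-precision
implementation, the Rayleigh limit, the extinction paradox
($Q_{ext} \to 2$) and the optical theorem (see the test suite).

**Finite collection aperture.** A microscope objective collects light
scattered into its numerical aperture, so only scattering *outside* the
half-angle $\theta_{NA}$ is lost. The aperture-restricted efficiency is the
angular integral

$$Q_{sca}^{NA} = \frac{1}{x^2}\int_{\theta_{NA}}^{\pi}
  \left(|S_1(\theta)|^2 + |S_2(\theta)|^2\right)\sin\theta\, d\theta,$$

evaluated by adaptive Gauss–Legendre quadrature; at $\theta_{NA} = 0$ it
reduces exactly to the series $Q_{sca}$ (an orthogonality identity of the
angular functions, also enforced by a test). The effective extinction seen
by the detector is $Q_{ext}^{NA} = c\,Q_{abs} + Q_{sca}^{NA}$ with a weight
$c$ for the absorption contribution.

**Kramers–Kronig consistency.** Absorption bands necessarily carry a
dispersive real-index partner, which is what couples chemistry into the
scattering ripple. The model builds
$n_i(\tilde\nu) \propto A_{clean}(\tilde\nu)$ and computes the fluctuating
part of $n_r$ as the Hilbert-transform partner of $n_i$ on a zero-padded
grid (FFT implementation, mean-centered; for a Lorentzian band it
reproduces the analytic dispersive Lorentzian to better than 2% over the
interior of the grid).

**Apparent absorbance.** With a fill factor $f$ (fraction of the
measurement aperture covered by the particle), transmission
$T = 1 - f\,Q_{ext}^{NA}$ gives the apparent absorbance

$$A_{app} = -\log_{10}\!\left(1 - f\,Q_{ext}^{NA}\right),$$

clipped (and flagged) when $f\,Q_{ext}^{NA} \ge 1$ saturates the pixel.
`distortSpectrum()` chains these steps: clean absorbance → $n_i$ →
Kramers–Kronig $n_r$ → Mie efficiencies → apparent absorbance.

Two notes on the domain of this relation. First, it is exactly the
two-component pixel transmission
$T = (1-f)\,T_{bg} + f\,(1 - Q_{ext}^{NA})$ with an *empty* background
($T_{bg} = 1$). A pixel inside a biomass structure has absorbing matrix,
not vacuum, in its non-particle fraction, so `distortSpectrum()` accepts an
optional `matrixAbsorbance` spectrum giving $T_{bg} = 10^{-A_{matrix}}$ —
the chemical absorption then passes through the pixel alongside the
scatter contribution, which is what measured spectra of intact biomass look
like. Second, the relation is only meaningful while $f\,Q < 1$; with
$Q_{ext}^{NA}$ reaching $\approx 4$ over the covered radius/index range,
fill factors are kept below $1/Q_{max} \approx 0.25$ so that saturation is
the exception rather than the rule.

## Synthetic data generator

Because real paired datasets (bulk spectra + reference chemistry +
registered cubes) are large and proprietary, the package ships a seeded
generator whose every object is a pure function of `(config, seed)`.

* **Chemistry.** Five components (saturated lipid, polyunsaturated lipid,
  protein, carbohydrate, chitin) with Lorentzian/Gaussian bands at textbook
  mid-IR positions (lipid ester carbonyl near 1745 cm$^{-1}$, amide I near
  1650 cm$^{-1}$, …), jittered per seed (±3 cm$^{-1}$ centers, ±15%
  heights/widths). Mixtures follow Beer–Lambert exactly; analytes are total
  lipid (% biomass), SFA/PFA (% of fatty acids) and glucosamine (% biomass).
* **Instruments.** The macroscopic instrument applies a 6 cm$^{-1}$
  Gaussian lineshape, a digital-spacing round trip, multiplicative gain,
  a weak polynomial baseline and white noise; the microscopic instrument is
  broader (8 cm$^{-1}$) and noisier.
* **Homogenized tiles.** Per-pixel Dirichlet composition jitter
  re-centered so that the mean composition of the normal pixels equals the
  bulk composition *exactly* (this is the premise that makes bulk spectra
  valid pixel targets), log-normal pathlength jitter, and a small fraction
  of labeled aberrant pixels (near-empty and lipid-cluster) to exercise
  quality control.
* **Intact scenes.** Lipid-rich droplets (disks) and lipid-poor hyphae
  (random-walk ribbons) on empty background, each structure carrying its
  own Mie distortion (radius tied to its pixel size, drawn refractive
  index), plus pathlength jitter and noise. Ground-truth analyte maps and
  structure labels are retained.

**Realism limits.** Pixels are independent (no optical cross-talk or
diffraction PSF); scattering is a single-sphere model per structure rather
than a full-wave simulation of the scene; band libraries are stylized; and
the composition-to-spectrum map is exactly linear. The generator is
intended for method validation and property-based testing, not for
training models meant to run on real instruments.

## Training-set construction

* **Transfer pairs** (`buildTransferPairs()`): QC-passing pixels of the
  homogenized tiles, paired with the replicate-averaged bulk spectrum of
  the same sample. Each selected pixel contributes (i) its *un-augmented*
  measured spectrum — the core supervised pair of the homogenized-biomass
  bridge — and (ii) augmented draws: with probability `forwardFraction` the
  pure forward-model apparent absorbance (what intact pixels look like),
  otherwise the clean spectrum plus a severity-scaled scattering
  contribution (`scatterAmplitude` drawn from `[0, 1]`), plus polynomial
  baseline and noise. The severity continuum matters: the model is applied
  both to nearly-clean homogenized pixels and to strongly distorted intact
  pixels, so its training inputs must span both ends. A fraction of
  noise-only inputs with zero targets teaches the null mapping for empty
  pixels.
* **Calibration pairs** (`buildCalibrationSet()`): replicate-averaged bulk
  spectra against reference values, plus zero anchors, plus
  nuisance-augmented copies (`nAugment`): multiplicative gain, smooth
  baseline and noise leave the *composition* unchanged, so these copies
  teach the calibration network invariance to exactly the residual modes
  that transferred pixel spectra still carry. Without them a network fit
  on a dozen clean spectra is unconstrained off its training manifold and
  per-pixel predictions are meaningless.

## Network and training

Both models share a 1-D convolutional backbone over the wavenumber axis
with a multi-head self-attention block (softmax attention over wavenumber
positions, shift-invariant row-wise stabilized), letting distant spectral
regions interact — e.g. the CH-stretch region informing the correction of
the carbonyl region. The transfer head is a 1×1 convolution over the
concatenated convolutional features, attention features and a standardized
skip copy of the input, followed by a *per-wavenumber affine output layer*.
The affine layer matters: inputs are standardized per wavenumber while
spectrum targets are scaled globally, so even an identity-like transfer
needs a position-dependent gain that a position-shared head cannot
represent. The calibration head mean-pools over wavenumber, applies a small
dense network, and adds a *direct linear readout* of the standardized input
spectrum: Beer–Lambert makes concentration-type targets linear in the
spectrum, so the hypothesis space should contain the linear chemometric
solution — without it, a pooled nonlinear head trained on a dozen
compositions is unstable and cannot extrapolate to out-of-range
compositions such as lipid droplets. Inputs are standardized per
wavenumber, transfer targets min-max scaled and calibration targets
z-scored, all statistics fitted on the training split only. Training is mini-batch RMSProp on mean squared error
with early stopping on a validation split; everything (initialization,
splits, shuffling) derives from one integer seed, and analytic gradients
are verified against finite differences in the test suite. The default
transfer network has a few thousand parameters — deliberately small, since
desk-scale training sets have a few hundred pairs.

## Pipeline, QC and evaluation

* `qcFilter()` removes pixels with weak amide-I signal (default max
  absorbance in 1600–1700 cm$^{-1}$ below 0.05 AU) and then pixels
  deviating from the recomputed image mean (1 − Pearson r > 0.2). QC only
  ever removes pixels.
* `microcalibrate()` = transfer → calibrate per pixel, with *empty-pixel
  zeroing*: pixels whose raw amide-I signal falls below the QC signal
  threshold are assigned zero analyte (a regression output on a no-biomass
  pixel is extrapolated noise, and percent-of-biomass analytes are zero
  where there is no biomass). `maskNegligibleBiomass()` additionally
  excludes such pixels from summaries; `summarizeMap()` gives image
  mean/sd/n.
* `evaluateTransfer()` quantifies the transfer on *held-out* pixels
  (disjoint from training pixels) as the ratio of median spectral RMSE to
  the bulk spectrum after vs before transfer.
* `looCrossValidate()` holds out one sample at a time, trains the
  calibration model on the others (the held-out sample's spectra, pixels
  and reference never enter that fold, audited by id), microcalibrates the
  held-out cube and pools image-mean predictions against reference values
  into an identity-line $R^2$ (`rSquared()`): residuals are taken to the
  identity line, the total sum of squares about the reference mean — a
  deliberately stricter convention than the correlation-based fit $R^2$,
  which is also reported.

## Numerical choices worth knowing

* Mie recursion: downward logarithmic derivative started
  15 orders above the truncation, stable for $x \le 500$ (guarded).
* Aperture integral: Gauss–Legendre with node doubling until relative
  change $< 10^{-6}$.
* Kramers–Kronig: power-of-two zero-padding to at least 4× the grid,
  centered placement; edge effects motivate the interior-only accuracy
  statement.
* Attention softmax: row-wise max shift applied only when scores exceed
  the overflow threshold — exact (softmax is shift-invariant per row) and
  free in the common case.
* All random draws flow through a single seed via a deterministic child
  seed derivation (a string-tagged hash below $2^{31}$), so any component
  can be reproduced in isolation.
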