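---
title: "K-space simulation and digital transformation of point-scanning OCT volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{K-space simulation and digital transformation of point-scanning OCT volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kspaceoct)
```

## The model

`kspaceoct` implements an angular-spectrum (K-space) description of image
formation in point-scanning optical coherence tomography under the single
ballistic-backscattering assumption (first Born approximation). Each spectral
component of the source, with wavenumber $k = k_n$, illuminates the tissue
through an aperture field $U_L(x, y; k)$ whose angular spectrum is

$$ g(k_x, k_y, k) = \iint U_L(x, y; k)\, e^{-i(k_x x + k_y y)}\, dx\, dy . $$

Propagation to depth $z$ multiplies every plane-wave component by the
unit-magnitude propagator $h = \exp\!\left(i\,(z - z_d)\sqrt{k^2 - k_x^2 -
k_y^2}\right)$ on the propagating domain $k_x^2 + k_y^2 \le k^2$ (evanescent
components are excluded); a paraxial variant
$\exp\!\left(i\,(z - z_d)\,(k - k_\perp^2/2k)\right)$ is available for
comparison with closed-form results. The field incident on a point scatterer
at $(x_s, y_s, z_s)$, for a beam axis scanned to $(x_0, y_0)$, is the
synthesis integral of $g\,h$ with the linear phase
$e^{i[k_x (x_s - x_0) + k_y (y_s - y_0)]}$. Because the illuminating and
backscattered waves traverse the same optics, the received amplitude from
scatterer $s$ is

$$ B_s(x_0, y_0; k) = K_s\, U_s^2(x_0, y_0; k), $$

valid for beams of arbitrary shape — the *double-pass* square is what makes
aberrations mix nonlinearly into the data. A-scans are assembled by the
wavenumber-to-depth transform of $\sum_s S(k_n) B_s$, where $S(k_n)$ is the
source envelope; the double-pass optical path gives the kernel
$e^{-2 i k_n z_q}$.

The key structural fact is the factorization of the scan-domain spectrum of
a single scatterer's signal:

$$ \hat B_s(k_x, k_y, k) = K_s\, e^{-i(k_x x_s + k_y y_s)}\,
   I(z_s; k, k_x, k_y), $$

where $I$ is the autoconvolution of $g\,h_{z_s}$ over the transverse
wavenumbers. Lateral position and scattering strength enter only through a
linear phase and a constant, so a *depth-indexed* spectral filter

$$ \mathrm{Filt}(z_q; k, k_x, k_y) =
   \frac{I^{(T)}(z_q)}{I(z_q) + \alpha \max_{k_x,k_y} |I(z_q)|} $$

transforms the volume acquired with one beam into the volume a *target* beam
$U_L^{(T)}$ would have produced, without knowing where the scatterers are.
With $\alpha = 0$ and target equal to initial the filter is identically one
on the kernel support. Both phase *and amplitude* are corrected — this is
what distinguishes the general transform from conventional phase-only
refocusing.

## Transforms built on the filter

* **Conventional refocusing** (`conventional_refocus()`, `refocus_one_step()`):
  for Gaussian beams the kernel is, up to a constant,
  $I(z_q; k_\perp) \propto e^{-k_\perp^2 W_0^2/8}\,
  e^{i k_\perp^2 (z_0 - z_q)/(4k)}$, and the ratio under the
  waist-conserving constraint $W_L'/z_0' = W_L/z_0$ collapses to the pure
  phase kernel $e^{-i (z_0 - z)\,k_\perp^2/(4k_0)}$ — the familiar one-step
  refocusing applied per depth slice. The package exposes the one-step
  kernel, the closed-form-filter path and a fully numeric kernel path; the
  first two agree to machine precision and the numeric path is the template
  for non-Gaussian work.
* **Fixed-aperture refocusing** (`refocus_fixed_aperture()`): keeping
  $W_L' = W_L$ makes the recovered waist depth-dependent,
  $W_0'(z) \approx \lambda z / (\pi W_L)$ — smaller above the physical
  focus, larger below.
* **Super-refocusing** (`super_refocus()`): choosing a constant target waist
  $W_{0T} = W_0 / M < W_0$ (equivalently a broader, flattened effective
  aperture) trades signal-to-noise for lateral resolution. The amplitude
  part of the filter amplifies the weak off-axis angular components, so the
  Tikhonov term $\alpha$ governs a resolution/noise compromise; with noisy
  data the useful range is of the order of the inverse amplitude SNR.
* **Beam conversion** (`convert_beam()`): numeric kernels for arbitrary
  initial/target pairs with the full non-paraxial propagator, e.g. a
  focused Lorentzian acquisition re-rendered as a non-diverging Bessel-beam
  image whose central lobe keeps its size with depth.
* **Aberration correction** (`correct_aberrations()`): a known aperture
  aberration $Q(x, y) = e^{-i A_0 Z_n^m(\rho,\varphi)}$ enters the kernel
  through the squared field; the kernel-ratio filter removes it *and*
  refocuses in one pass. Conjugate-phase corrections
  ($e^{-i\Phi}$ or $e^{-2i\Phi}$ at the aperture) provably cannot, because
  of the double-pass mixing; `naive_phase_correction()` demonstrates this
  and is not a supported transform.

## Reference conditions and tunable parameters

All demonstration configurations use a central wavelength of
$\lambda_0 = 0.85\ \mu m$, a typical OCT value.

| parameter | default | meaning |
|---|---|---|
| `WL` (focused config) | 35.9 um | aperture 1/e amplitude radius; waist $\approx$ 1.9 um at `z0` = 252 um |
| `W0` (weak-focus config) | 12.6 um | focal waist of the weakly focused beam |
| pair separation | 12 um | lateral two-point spacing probed by super-refocusing |
| chain span | 24–480 um | seven depths, middle one in focus |
| fractional bandwidth | ~2.6% | 32 lines; conjugate depth step 4 um at pad factor 4 |
| `alpha` | transform-specific | Tikhonov term, *relative* to the per-depth peak of $|I|$ |
| scan spacing `dx` | 0.75 um | below the focal radius (scan Nyquist condition) |

Numerical and design choices a user should know:

* **Grids** are even-sized and centered; the centered discrete transforms
  are exact inverses (round-trip error $<10^{-12}$), so all filter algebra
  is loss-free. Off-grid scatterer positions are handled exactly through
  spectral phase ramps — there is no interpolation anywhere in the forward
  model.
* **Windows**: the lateral window must hold both the out-of-focus beam and
  the aperture field; the focused reference uses a 192 um window (256
  samples), about 3x the largest beam diameter in the imaged range. A 96 um
  window truncates the 35.9 um aperture Gaussian and biases the focal width
  by more than 10%. `validate_scan_window()` warns on such configurations.
* **Propagator mode**: the focused reference configuration uses the
  *paraxial* propagator because its quoted beam parameters (waist 1.9 um
  from $W_0 = \lambda z_0 / \pi W_L$) and the one-step refocusing kernel are
  defined within the paraxial Gaussian model; at this beam's 1/e numerical
  aperture (~0.14) the rigorous propagator widens the focal image by 5–8%.
  Everywhere else — beam conversion, aberration work, generic
  `sim_config()` — the full non-paraxial propagator is the default.
* **alpha convention**: the regularization is relative to the per-depth peak
  kernel magnitude, so quoted values are comparable across kernel
  normalizations and the Tikhonov heuristic "alpha of the order of the
  inverse SNR" is meaningful on an absolute scale.
* **Narrowband vs full-chain filtering**: by default filters are applied at
  the central wavenumber only (`apply_filter_narrowband()`), which for a
  few-percent bandwidth agrees with the per-wavenumber chain
  (`apply_filter_full()`) to better than 1% RMS on refocusing tasks at a
  fraction of the cost. Two caveats found while validating the package are
  worth recording. First, for strongly structured kernels (large
  aberrations) the single-$k_0$ approximation leaves a residual of a few
  percent at depths far from focus, because the distorted kernel's
  across-band variation differs from the target's. Second, the full chain
  with a very small $\alpha$ is *not* automatically better on multi-scatterer
  scenes: the per-line inverse filter has large gain where the kernel at one
  depth is small, and in the full chain that gain multiplies full-strength
  spectral content belonging to scatterers at other depths before the axial
  phase cancellation can suppress it. The narrowband path, acting per depth
  slice, is immune to this leakage and is therefore the recommended default.
* **Degenerate depths**: a target "focused at depth 0" is treated as a waist
  at the aperture (curvature radius $\to \infty$).
* **Kernel support**: filters are zeroed where both kernels are below
  $10^{-12}$ of their peaks — outside the double-pass passband there is
  nothing to recover, only numerical noise to amplify.

## What the synthetic generator does and does not emulate

Scenes are collections of discrete point scatterers with constant complex
scattering coefficients; measurement noise is circular complex Gaussian,
calibrated as `20*log10(peak amplitude / RMS noise amplitude)`. This
reproduces the geometry-driven physics the transforms operate on —
depth-dependent defocus, double-pass PSF formation, aberration mixing,
noise amplification by inverse filtering — and supports scatterer densities
high enough to imitate cellular-scale tissue (a 192 x 192 x 512 um box at
matched density holds ~2.5e5 scatterers). It does **not** model multiple
scattering, attenuation, dispersion, wavenumber-dependent scattering
diagrams, polarization, or galvo scan distortion, so green tests here say
nothing about those effects in real data; they validate the transform
algebra and its noise behaviour under the stated model.

## Problem sizes used in the shipped experiments

The packaged experiments run at desk scale: the focused chain on a
256 x 256 x 128 grid (0.75 um lateral, 4 um axial sampling, 32 spectral
lines), the weak-focus pairs on 192 x 192 x 128, and the aberration
experiments on 128 x 128 x 128 with full-propagator numeric kernels. Each
simulation takes seconds on one core; the numeric kernel stacks for
aberration correction take a few seconds per volume.

## Known limitations

* Transform accuracy is bounded by the narrowband approximation discussed
  above (~1–3% on strongly aberrated deep images at 2.6% bandwidth).
* Super-refocusing is bounded by the diffraction limit, by the lateral
  window (which plays the role of the physical lens aperture — requests
  whose effective aperture exceeds the half-window are refused), and in
  practice by noise through $\alpha$.
* Aberration correction assumes $Q(x,y)$ is known; estimating it from data
  (computational adaptive optics) is out of scope.
* The regularization normalization in published comparisons of this family
  of methods is rarely stated; results that depend steeply on $\alpha$
  (amplitude loss at extreme $\alpha$, SNR cost near the optimum) should be
  read with the relative convention above in mind.
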