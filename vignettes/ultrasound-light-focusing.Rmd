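---
title: "Modeling ultrasound-shaped light focusing in turbid media"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling ultrasound-shaped light focusing in turbid media}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usfocus)
```

## The physical problem

Focusing light to a micrometric spot deep inside a scattering medium —
biological tissue, a milk emulsion, a composite — is limited by
scattering: ballistic photons decay as $e^{-\tau}$, where the optical
thickness $\tau = \mu_s d$ counts the expected scattering events over a
depth $d$ in a medium with scattering coefficient $\mu_s$.

One way around this is to make the medium itself act as a lens. A
cylindrical piezoelectric cavity driven on resonance sustains a radial
standing ultrasound wave. The pressure field modulates the density, and
hence the refractive index, of the fluid filling the cavity:

$$n(r, t) = n_0 + n_A\, J_0(k r)\, \cos(\omega t),$$

with $J_0$ the zeroth-order Bessel function, $k$ the acoustic
wavevector, $n_A \sim 10^{-5}$ the modulation amplitude, and $\omega$
the drive frequency. Near the axis $J_0(kr) \approx 1 - (kr)^2/4$, so
the channel is a gradient-index (GRIN) lens with gradient constant
$g = k\sqrt{n_A / (2 n_0)}$ and focal ("quarter-pitch") distance
$\pi/(2g)$. Because the index modulation co-exists with the scattering
medium, the lens is *embedded*: light is focused and guided along the
whole propagation path instead of being focused once from outside.
Laser pulses much shorter than the acoustic period interact with a
frozen snapshot of the modulation; the package defaults to the snapshot
phase of maximum on-axis index (`phase = 0`), the only phase that
produces the focusing behaviour the model is meant to study.

With the default parameters (water, $n_0 = 1.33$; 4 MHz drive,
$k = 15.8$ mm$^{-1}$; $n_A = 8\times 10^{-5}$) the quarter pitch is

```{r}
paraxial_grin(acoustic_cavity(nA = 8e-5))
```

about 18 mm — the focus of a collimated beam falls near the exit of a
2 cm cavity.

## The two propagation engines

**Wave optics (BPM).** `bpm_propagate()` implements the split-step
Fourier beam propagation method under the paraxial approximation: half
a diffraction step in the spatial-frequency domain, a thin phase screen
$\exp(i k_0 (n - n_0)\Delta z)$, half a diffraction step. A
supergaussian absorber over the outer 10 % of the transverse window
suppresses wrap-around; the axial step must keep the phase increment
$k_0 \max|n - n_0| \Delta z$ below 0.1 rad (the default 1 µm × 2048
window with $\Delta z = 5$ µm satisfies this for $n_A \le 10^{-4}$,
and halving both steps moves the focal width by under 2 %). A 300 µm
beam entering the modulated cavity collapses to a ~21 µm spot at 2 cm.
Because the beam extends past the first zero of $J_0$ (at
$2.405/k \approx 152$ µm), the outer rays feel a flattened potential
and focus later than the paraxial quarter pitch: the aberrated caustic
is an essential feature of the Bessel-profile lens, not an artifact.
For the same reason the "focus at the quarter pitch" rule only holds
for beams confined to the parabolic core (below roughly 100 µm width).

**Ray optics with scattering (Monte Carlo).** `run_mc_simulation()`
transports photon packets through a 2D $(x, z)$ slice — by default
2 cm × 500 µm at 4 µm cells, matching the geometry the wave simulation
uses — with four pieces of physics:

* free path lengths drawn as optical depth $-\ln \xi$ and consumed as
  $\int \mu_s\, \mathrm{d}s$ along the (bent) trajectory;
* continuous refraction by the index gradient, integrating the eikonal
  equation $\mathrm{d}(n\mathbf{u})/\mathrm{d}s = \nabla n$ in substeps
  of one cell;
* Henyey–Greenstein scattering with anisotropy $g = 0.94$: the polar
  cosine is drawn from the 3D inverse CDF and applied in-plane with a
  random sign, preserving $E[\cos\theta] = g$ exactly;
* Fresnel side walls: the chamber holding the fluid presents an index
  step to the surroundings, so photons hitting the lateral boundary are
  reflected with the unpolarised Fresnel coefficient — total internal
  reflection for most obliquely scattered light (exterior index 1 by
  default; a glass wall is equivalent by the Snell invariant). Open
  (absorbing) walls are available via `n_out = NA`, but they discard
  nearly all scattered light before it reaches the exit plane and with
  them the diffuse background that limits real focusing contrast never
  forms.

Uniform unmodulated regions are traversed analytically (straight
flight to the next event) rather than in substeps; this is exact for
piecewise-constant media. Packets are dropped at the entrance plane and
(if transmitted by the wall) the sides, and a safety cap kills paths
longer than ten region lengths. With a fixed seed results are
bit-identical.

### Source divergence: a contested parameter

The line source is 300 µm long, uniform, with a Gaussian angular
spread. The divergence deserves a note: the GRIN channel maps launch
angle $\theta$ to an exit-plane offset of roughly $\theta / g \approx
\theta \times 12$ mm, so the simulated spot size is essentially set by
the divergence once it exceeds a few times $10^{-4}$ rad. We default to
the physical diffraction divergence of the modeled beam,
$\sigma_\theta = \lambda / (2 \pi w_0) \approx 4.1 \times 10^{-4}$ rad
for a 300 µm FWHM beam at 660 nm (`beam_divergence_sigma()`). This
produces a ~15 µm ray-optics exit spot — tighter than the ~21 µm
wave-optics spot, as ray optics carries no diffraction limit — and a
~37 µm central lobe in the external-lens geometry. Divergences of
$10^{-3}$ rad and above inflate the embedded spot past 35 µm and wash
out the external-lens lobe entirely; the parameter is exposed on
`mc_source()` for exploration.

### The two focusing strategies

The comparison at the heart of the package is *embedded* ultrasound
focusing versus a conventional *external* lens:

* **Embedded**: the modulation fills the (possibly scattering) medium;
  `run_mc_simulation()` with a modulated `medium_grid()`.
* **External**: `run_external_lens_simulation()` propagates through a
  clear, weakly modulated 2 cm cavity ($n_A = 2\times 10^{-5}$) and
  then 2 cm into the sample, where any scattering is confined. The
  aberrated GRIN cavity bends rays so that they cross the axis right
  around the far plane, forming a Bessel-like profile: a narrow
  central caustic lobe over broad shoulders. We use
  $2\times 10^{-5}$ — the amplitude of the corresponding wave-optics
  scenario — because at $1\times 10^{-5}$ the paraxial crossing
  distance ($\approx 4.7$ cm past the cavity) lies beyond the 4 cm
  domain and no lobe can form there at all.

At $\tau = 2$ the embedded channel loses a modest fraction of its
focusing contrast (Eq. below) while the external lens loses about
half, and the loss ratio is the quantitative advantage of guiding.

## Metrics

`fwhm()` measures widths between interpolated half-maximum crossings
after subtracting the median of the outer 10 % of samples. The
focusing contrast applies the Michelson formula

$$C = \frac{I_{max} - I_{min}}{I_{max} + I_{min}}$$

with $I_{max}$ the profile peak and $I_{min}$ the mean beyond three
lobe radii of it (`focusing_contrast()`); relative losses are
`contrast_loss()` in percent. Phantom characterisation fits
$\ln I$ versus thickness by ordinary least squares
(`fit_scattering_coefficient()`), the plain collimated Beer–Lambert
reading of attenuation.

## Slanted-edge resolution pipeline

`mtf_slanted_edge()` chains the standard steps: locate the 50 %
crossing of the edge per scan line, fit the edge by total least
squares, project every pixel onto the edge normal, and average in bins
4× finer than the scan pitch (`extract_esf()`); differentiate centrally
to the line spread function, taper with a Tukey window (flat over the
central half-span, cosine to zero at the ends — the taper suppresses
differentiated noise in the tails without distorting the LSF core),
and area-normalise (`lsf_from_esf()`); Fourier-transform and normalise
at DC (`mtf_from_lsf()`); report the first downward crossing of
MTF = 0.1 and its inverse, the spatial resolution
(`resolution_from_mtf()`). A 10 % border margin is trimmed before
analysis since the simulated acquisition vignettes near the image
boundary, and sparsely populated projection bins (corner pixels) are
dropped. Edges steeper than 20° are rejected; below 0.5° the plain
per-line average is used. Reported cutoffs are capped at the scan
Nyquist frequency ($0.05$ µm$^{-1}$ at the default 10 µm step).

## The synthetic imaging model

Scanned-image data are generated, not downloaded. Targets are
anti-aliased reflectance maps: a knife edge with exact 50 % crossings
on the requested slant (`make_knife_edge()`, default 5°, a typical
slanted-edge choice) and USAF-1951 three-bar elements with the
standard geometry — bar width $w = 500/2^{g + (e-1)/6}$ µm, length
$5w$, gaps $w$ (`make_usaf_element()`).

`simulate_scan()` models point-by-point acquisition with a bucket
detector: the signal at each scan position is the PSF-weighted
integral of the reflectance. The PSF (`psf_gaussian()`,
`psf_from_profile()`) has three parts:

* a focused **core** (25 µm FWHM by default, the system's clear-medium
  response);
* a partially scattered **halo** pedestal (170 µm FWHM by default, the
  scale the resolution collapses to once the core is lost);
* a **diffuse background**, uniform over the field of view — the
  multiply scattered light whose extent (set by the transport mean
  free path, centimetres for $g = 0.94$) far exceeds the imaged
  region.

Noise is applied in that order: Poisson shot noise at a photon budget
of $10^4$ counts per point, Gaussian read noise of 1 % of full scale,
and a per-scan-line offset with 2 % standard deviation emulating
line-to-line intensity bias (removable by `remove_line_artifacts()`,
which subtracts each line's median excess; note this assumes the line
medians carry no signal, true for bar targets but not for a slanted
edge). Detector gain and absolute exposure are not modeled, so these
defaults are plausible rather than calibrated; all are configurable.

`psf_after_tau()` degrades a PSF parametrically: the core weight decays
as $e^{-\rho \tau}$ and the lost energy splits evenly between halo and
diffuse background. The degradation rate $\rho$ distinguishes the
strategies in `strategy_psf()`: the external lens loses its core at
the ballistic rate ($\rho = 1$), while the guided channel is assigned
$\rho = 0.1$, an order of magnitude slower, consistent with the
relative contrast losses of the transport simulations at $\tau = 2$.
Reflection-mode imaging traverses the sample twice, so
`reflection_mode_psf()` applies the transmission degradation for a
second $\tau$ — by construction the reflection response at $\tau$
equals the transmission response at $2\tau$, and the usable thickness
under any contrast floor halves.

`run_tau_sweep()` images a knife edge per $(\tau,$ strategy$)$ cell,
records the slanted-edge resolution and the Michelson contrast of the
near-edge plateaus (bands 30–120 µm on either side of the known edge
line, inside the halo's reach). Acquisitions are exposure-normalised
(attenuation divided out) — the Michelson contrast is scale-invariant
and a real detector integrates to full scale — so throughput loss
appears as background growth, not as signal starvation. Edges that
never cross MTF = 0.1 are recorded as censored rows. `run_imaging_demo()`
reconstructs a USAF element under both strategies in clear and turbid
media and reports the three-bar modulation, with 0.1 as the
"discernible" threshold.

## Problem sizes and reproducibility

The default study sizes keep every stage on a single CPU: BPM on a
2048-point window over 4000 steps (seconds); Monte Carlo runs of
$10^5$–$10^6$ packets (tens of seconds to ~2 minutes each at $10^6$);
scans of a 2–2.4 mm target at 10 µm pitch. Stochastic quantities in
the test-suite and the acceptance script average three seeds; all
random stages take explicit integer seeds and are bit-reproducible.

## What the synthetic data do and do not show

The generators emulate the *structure* of the experimental data —
point-scanned reflectance images with a focused core, scattered
background, shot/read noise and line bias — not their absolute
calibration. Passing tests demonstrate that the algorithms (transport,
metrics, slanted-edge chain, image formation) are internally correct
and mutually consistent; they do not certify detector-level
quantities (absolute SNR, gain) or 3D effects. Known limitations:

* the transport model is 2D; out-of-plane scattering and the
  cylindrical geometry of the real cavity are not represented, which
  overweights the retained scattered bed relative to a 3D medium;
* ray optics carries no diffraction, so clear-medium ray spots are
  sharper than the physical (wave) spots; the two engines should be
  read as complementary views, not interchangeable predictions;
* the eikonal integrator is first order with cell-sized steps —
  adequate because the index varies on the 1/k ≈ 63 µm scale, eight
  times the cell;
* the $\tau$-dependence of the imaging PSF is parametric
  (`strategy_psf()`), calibrated in rate to the transport simulations
  rather than derived per-$\tau$ from them;
* no polarisation, no time resolution, no acoustic pressure-to-$n_A$
  conversion.
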