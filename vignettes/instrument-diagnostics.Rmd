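---
title: "Characterizing a 100 keV cryo-microscope: models, estimators and synthetic data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing a 100 keV cryo-microscope: models, estimators and synthetic data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emdiag)
```

emdiag characterizes the optics and detector of a transmission electron
cryomicroscope, with an emphasis on the regime that matters for low-voltage
(around 100 keV) single-particle instruments: temporal coherence limited by
the source energy spread acting through the chromatic aberration of the
objective lens, and electron counting on a sparse hybrid-pixel detector.
This vignette is the package's own account of the models it implements, the
parameters that matter, the numerical choices made, and what the synthetic
data generator does and does not emulate.

## The contrast transfer function and its phase

A defocused, aberrated bright-field image transfers each spatial frequency
$q$ of the specimen's exit wave with the contrast transfer function

$$\mathrm{CTF}(q) = \sqrt{1 - W^2}\,\sin\chi(q) \; - \; W\cos\chi(q),
\qquad
\chi(q) = \pi\left[\tfrac12 C_s \lambda^3 q^4 + (\Delta z + \Delta f)\,\lambda q^2\right],$$

where $W$ is the amplitude contrast fraction (0.07 is a typical measured
value at 100 keV), $C_s$ the spherical aberration coefficient, $\lambda$ the
relativistic electron wavelength derived from the beam energy, $\Delta z$
the signed nominal defocus and $\Delta f$ any additional defocus offset.
This mixing has unit total amplitude, so $|\mathrm{CTF}| \le 1$ everywhere,
$\mathrm{CTF}(0) = -W$, and it is identically $\sin(\chi - \arcsin W)$ — an
identity the test suite asserts to $10^{-12}$. The defocus convention is
signed throughout, with underfocused imaging negative (e.g. $-2.5\,\mu$m
$= -25000$ Å); no underfocus-positive remapping is applied anywhere.
Internally all lengths are Angstrom (aberration coefficients are accepted
in mm at interfaces, 1 mm $= 10^7$ Å), energies eV, frequencies Å$^{-1}$
with $q = 1/d$ and no $2\pi$.

## Temporal coherence envelope

An electron with energy offset $\Delta E$ from the nominal beam energy $E$
is focused with an extra defocus

$$\Delta f = C_c\,\frac{\Delta E}{E},$$

so a source with finite energy spread images the specimen through a
distribution of defoci. `coherence_envelope()` computes the
energy-spread-weighted average CTF on a grid of offsets (by default $-1.8$
to $+1.8$ eV in 0.05 eV steps, a range of more than $\pm 3\sigma$ for the
spreads of interest) and extracts the amplitudes of the peaks and troughs
of the averaged curve. Because the monochromatic CTF has unit-amplitude
extrema under the convention above, those raw amplitudes *are* the temporal
coherence envelope $T(f)$; no normalization step is needed.

The source spectrum defaults to a Gaussian with the configured FWHM
(Schottky field-emission spreads are near-Gaussian at this level of
precision); a tabulated measured spectrum can be supplied instead. For the
Gaussian case a closed form exists,
$T(q) = \exp\!\big[-\tfrac12(\pi\lambda\delta q^2)^2\big]$ with defocus
spread $\delta = C_c \sigma_E / E$, and the numerical peak/trough
extraction is held to within 1% of it across $C_c \in \{1.0, 1.9, 3.0\}$ mm
and FWHM $\in \{0.3, 0.7, 1.2\}$ eV — a genuine dual-route check, since the
numerical path never evaluates the closed form.

For the instrument conditions of interest — $E = 100$ keV, $C_c = 1.9$ mm,
FWHM $0.7$ eV, $W = 0.07$, $\Delta z = -2.5\,\mu$m — the envelope at 3 Å
resolution ($q = 1/3$ Å$^{-1}$) is about 0.77, i.e. comfortably above 75%:

```{r}
p <- optical_params(100e3, cc_mm = 1.9, amplitude_contrast = 0.07,
                    defocus_a = -25000, energy_spread_fwhm_ev = 0.7)
env <- coherence_envelope(p)
envelope_at(env, 1 / 3)
```

Numerical choices. The frequency grid is 4096 points over $[0, 0.5]$
Å$^{-1}$; `averaged_ctf()` checks that at least 8 grid points fall within
one CTF oscillation at the top of the grid and flags the result (and warns)
otherwise. Extrema are located as 3-point local maxima of $|\overline{\mathrm{CTF}}|$
with ties broken toward lower frequency, then refined by parabolic
interpolation of both position and height. The envelope evaluator is a
monotonicity-preserving piecewise cubic (Fritsch–Carlson) through $(0, 1)$
and the extrema, clamped to $[0,1]$, and refuses to extrapolate beyond the
last extremum. Halving the energy-grid step changes the result by less than
0.2%.

The spherical aberration deserves a note: $C_s$ shifts the *positions* of
the CTF extrema but, at these parameters, has a negligible effect on their
*amplitudes*, which is all the envelope uses. The envelope workflow still
demands an explicit `cs_mm` in configuration files rather than defaulting
it silently, because the instrument's value is a deliberate input the user
should own. Only the temporal-coherence term is computed: spatial-coherence
(beam divergence) and detector-MTF envelopes are out of scope.

## Measuring the chromatic aberration coefficient

$C_c$ is measured from the dependence of defocus on accelerating voltage:
changing $V$ by $\Delta V$ around the nominal $V_0$ shifts the defocus by

$$\Delta z = C_c\,\frac{\Delta V}{V_0}.$$

The emulated protocol ramps $V$ from 100,000 V down to 99,960 V and back up
in 5 V steps with three micrographs per voltage (interior voltages are
visited twice, giving $(9 + 8) \times 3 = 51$ observations), and
`fit_cc()` regresses defocus on $\Delta V / V_0$ by ordinary least squares.
All observations enter jointly — replicates and ramp duplicates are not
pre-averaged — so replicate scatter propagates into the reported standard
error. No hysteresis term is modelled for the down/up ramp. The slope is
reported as a positive magnitude with its sign kept separately. With 50 Å
Gaussian defocus noise the protocol recovers a generating value of 1.9 mm
with a standard error near 0.006 mm, and repeated simulation shows the
$\pm 2\,$SE interval covers the truth at better than 90%.

```{r}
fit <- fit_cc(simulate_defocus_series(cc_true_mm = 1.9, noise_sd_a = 50, seed = 1))
generics::glance(fit)
```

`estimate_defocus_1d()` closes the loop from images: it cross-correlates the
background-subtracted squared radial amplitude spectrum with
$|\mathrm{CTF}(q; z)|^2$ over a defocus grid (400 trial values, parabolic
refinement of the best). It is deliberately a simplified one-dimensional
Thon-ring fit — astigmatism and 2D fitting belong to dedicated CTF
estimation programs. Its numerical guard rails: the baseline is a running
median over one tenth of the fitted band; the band's upper end is clipped
where one Thon-ring period would span fewer than three spectrum bins at the
mid-window defocus, so unresolvable rings do not dilute the correlation; a
correlation maximum at the window edge is an error (widen the window), and
a peak correlation below $\max(0.35,\ 3.5/\sqrt{n_{\mathrm{bins}}})$ — the
scale of pure-noise correlations — is reported as "no CTF modulation"
rather than a number, which is what a blank input produces.

## Spectral diagnostics of test specimens

The lattice-resolution diagnostic chain reproduces the classic
test-specimen analysis: crop a power-of-two square from the image centre,
taper the edges, Fourier transform, optionally noise-whiten, radially
average, and look for lattice reflections at their predicted spacings.

* `taper_edges()` blends a margin of the image toward its own mean with a
  raised-cosine profile (the exact profile is not critical; any smooth
  monotone blend removes the wrap-around discontinuity that otherwise
  streaks energy along the frequency axes). The interior is untouched and
  the mean is preserved.
* `fft_amplitude()` returns the centred 2D modulus and satisfies
  Parseval's identity to $10^{-9}$.
* `whiten()` divides by the radial amplitude of a blank (no-specimen)
  exposure, interpolated linearly in $q$ with constant extrapolation at the
  ends; a blank whitened by its own radial average is flat to within 5% in
  every well-populated bin.
* `radial_average()` uses equal-width annular bins up to the corner
  frequency $\sqrt2/(2\,\mathrm{pixel})$; bins beyond the physical-pixel
  Nyquist are kept and flagged `super_res`. The origin term (the image sum)
  is excluded, and empty bins are `NA`, never zero.
* `predict_reflections()` enumerates fcc spacings
  $d = a/\sqrt{h^2+k^2+l^2}$ with the all-even/all-odd selection rule, and
  2D hexagonal spacings $1/d^2 = \tfrac43 (h^2+hk+k^2)/a^2$ (monolayer, so
  $l = 0$ only). For gold ($a = 4.0782$ Å) this gives the familiar 2.35 Å
  ⟨111⟩, 2.04 Å ⟨200⟩ and 0.91 Å ⟨420⟩; for graphene ($a = 2.461$ Å) the
  2.13 Å ⟨100⟩ ring. Spacings display-round to two decimals above 1 Å and
  one below.
* `match_peaks()` subtracts an 11-bin running median, finds local maxima up
  to the sampling-grid axis Nyquist (bins beyond it have partial azimuthal
  coverage and unstable statistics), and reports each matched reflection
  with a z-score against the robust local scatter (31-bin window, centre
  excluded, global fallback when degenerate). An absent peak is a result,
  not an error.

```{r}
m <- make_micrograph(simulation_recipe(
  "gold_fcc", pixel_a = 1.6, size = 512, fluence = 50,
  params = optical_params(100e3, amplitude_contrast = 0.07, defocus_a = -75),
  super_res = TRUE, seed = 1))
res <- run_diagnose(m, lattice = "gold")
subset(res$peaks, matched & d > 1.9)
```

Both rings sit beyond the physical Nyquist $1/(2 \times 1.6)$ Å$^{-1}$ —
the super-resolution regime that subpixel electron counting makes
accessible.

## Electron-event counting

The detector model is a two-module hybrid-pixel counter: events arrive as
already-localized subpixel points (the real-time localization algorithm
itself is outside this package's scope), at a sparsity expressed as
"pixels per electron per frame" — 150 px/e at the 0.22 ms default frame
time is the reference operating point. `count_events()` implements the
post-processing needed to turn an event stream into a dose-fractionated
movie: static hot pixels are discarded; same-frame events whose 3×3 pixel
footprints overlap (centres within Chebyshev distance 2) are
coincidence-handled; surviving events accumulate on the physical grid or,
using the subpixel coordinates, a 2× super-resolution grid whose header
pixel is halved; module-gap rows are zero in every frame. The bookkeeping
is exact for every stream:
`events_in = counts_out + hot + gap + merge_losses (+ truncated frames)`.

Two coincidence policies are provided, since either is defensible: `merge`
(the default) replaces a cluster with one event at its centroid, losing
$k-1$ of $k$; `reject` drops the whole cluster. The analytic
pair-overlap model `coincidence_loss_approx()` —
$1 - (1-p)^{\,n-1}$ with $p = 25/\mathrm{live\ pixels}$, averaged over
Poisson frame occupancy — predicts the probability that an event *has* a
neighbour, i.e. the reject-mode loss; at 150 px/e on a 256² detector it
agrees with simulation to within Monte-Carlo error (the model ignores edge
truncation of the 5×5 kernel, a ~1% relative overestimate on small
detectors). Merge-mode loss is roughly half as large, as each pair costs
one event rather than two.

## What the synthetic data emulate — and what they do not

The generator exists so every stage runs and is testable without microscope
data; it reproduces the *features the diagnostics consume*, not the physics
of image formation:

* Lattice images are sums of cosines at the allowed reflection frequencies
  (deterministic golden-angle azimuths; components unrepresentable at the
  sampling Nyquist are skipped, with a warning if none survive) — not
  atomistic projections. Peak positions are right; structure-factor
  magnitudes are not modelled.
* Amorphous films are Gaussian random fields with $1/q$-weighted amplitude.
* The zero-mean contrast is multiplied by the CTF in Fourier space
  (weak-phase approximation; the mean is never scaled), then
  Poisson-sampled at the recipe fluence. No detector MTF, no radiation
  damage, no drift.
* Blanks are pure Poisson flat fields.
* `super_res = TRUE` samples the image on the half-pixel grid of a
  counting detector while recording the physical pixel, which is how a
  1.6 Å-pixel exposure can carry 2.04 Å information.

Default choices a scientist would recognise: lattice cosine amplitude 10%
of the mean intensity; amorphous RMS contrast 10%; lattice test recipes
image near focus (the worked examples use $-75$ Å, where $|\mathrm{CTF}|$
is close to 1 at the gold ring frequencies — exactly how an operator
focuses to see lattice fringes). All generators are bit-reproducible under
their seed.

Passing tests on these synthetics therefore demonstrate the correctness of
the *computations* — envelope extraction, least-squares calibration,
whitening, indexing, counting conservation — under controlled conditions.
They do not certify performance on real micrographs, where astigmatism,
drift, MTF, structured backgrounds and damage all intrude.

## Problem sizes, determinism and limitations

The test suite and examples use image sizes of 512–1024 pixels, 24–512
radial bins, 500-repetition calibration ensembles and event streams of a
few times $10^5$ electrons; these sizes were chosen so that every
Monte-Carlo assertion has comfortable statistical margin while the whole
suite runs in a couple of minutes on one core. All randomness flows through
explicit seeds, and seeded stages restore the caller's RNG state.

Known limitations, deliberate and otherwise: no astigmatism, beam tilt or
higher-order aberrations anywhere; the defocus estimator is 1D and can
mistake very weak Thon rings for a blank near its significance threshold;
the nominal imaging defocus and the stage height offset are treated as
independent configuration values (their relation on a physical column is
not modelled); and the detective quantum efficiency of a real detector
depends on the counting algorithm and sensor response, which this package
does not attempt to reproduce — the counting module models the
post-processing, not the detector physics.
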