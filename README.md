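# emdiag

Instrument-characterization toolkit for electron cryomicroscopes operated
at low accelerating voltage (around 100 keV), written for microscopists and
methods developers who need to quantify what their optics and detector
actually deliver: how much contrast the source energy spread leaves at a
given resolution, what the chromatic aberration coefficient of the column
is, whether test-specimen micrographs resolve the lattice spacings they
should (including beyond the physical Nyquist frequency of the detector),
and how electron-event streams turn into dose-fractionated movies.
Everything runs on synthetic data generated in-package, so the full
pipeline is testable without a microscope.

## The models at the core

**CTF and temporal coherence.** The contrast transfer function is
`CTF(q) = sqrt(1 - W^2) sin χ(q) - W cos χ(q)` with aberration phase
`χ(q) = π [ ½ Cs λ³ q⁴ + (Δz + Δf) λ q² ]`, where `W` is the amplitude
contrast, `Cs` the spherical aberration, `λ` the relativistic electron
wavelength, and `Δz` the signed nominal defocus. An electron with energy
offset `ΔE` is focused with an extra defocus `Δf = Cc ΔE / E`; averaging
the CTF over the source energy spectrum (Gaussian FWHM by default, grid
−1.8..+1.8 eV in 0.05 eV steps) and taking the amplitudes of the peaks and
troughs of the averaged curve yields the temporal coherence envelope
`T(f)`. For a Gaussian spread the numerical envelope is validated against
the closed form `exp(-½ (π λ δ q²)²)`, `δ = Cc σ_E / E`, to within 1%.

**Chromatic aberration calibration.** A voltage-ramp experiment
(`100,000 V → 99,960 V → 100,000 V` in 5 V steps, three exposures per
voltage) obeys `Δz = Cc ΔV / V₀`; `fit_cc()` recovers `Cc` and its standard
error by least squares, and `estimate_defocus_1d()` provides a simplified
1D Thon-ring defocus estimator so the loop closes from micrographs.

**Spectral diagnostics.** Edge tapering, 2D Fourier amplitudes, noise
whitening against a blank exposure, radial averaging (with super-resolution
bins flagged beyond the physical Nyquist `1/(2·pixel)`), lattice d-spacing
prediction (fcc selection rules; 2D hexagonal), and peak matching with
z-scores.

**Event counting.** Sparse hybrid-pixel event streams (`~150 pixels per
electron per 0.22 ms frame`) are counted into MRCS movies with hot-pixel
removal, coincidence handling of overlapping 3×3 footprints (merge or
reject), a two-module gap mask, physical or 2× super-resolution binning,
and exact count bookkeeping.

## A worked example

Temporal coherence of a 100 keV column with `Cc = 1.9 mm`, source FWHM
0.7 eV, `W = 0.07`, defocus −2.5 µm:

```r
library(emdiag)
p <- optical_params(100e3, cc_mm = 1.9, amplitude_contrast = 0.07,
                    defocus_a = -25000, energy_spread_fwhm_ev = 0.7)
env <- coherence_envelope(p)
envelope_at(env, 1 / 3)
#> [1] 0.766189
```

The envelope still transmits 77% of the contrast at 3 Å resolution — above
the 75% mark that makes such a column practical for high-resolution work.
Calibrating `Cc` from a simulated voltage ramp with 50 Å defocus noise:

```r
fit <- fit_cc(simulate_defocus_series(cc_true_mm = 1.9, noise_sd_a = 50, seed = 1))
generics::glance(fit)
#> # A tibble: 1 × 5
#>   cc_mm stderr_cc_mm r.squared sigma_a     n
#>   <dbl>        <dbl>     <dbl>   <dbl> <int>
#> 1  1.90      0.00472     1.000    41.5    51
```

And the super-resolution lattice test: a synthetic gold crystal imaged at a
1.6 Å *physical* pixel with 2× counting, tapered, whitened, radially
averaged, and matched against the predicted fcc reflections:

```r
m <- make_micrograph(simulation_recipe(
  "gold_fcc", pixel_a = 1.6, size = 512, fluence = 50,
  params = optical_params(100e3, amplitude_contrast = 0.07, defocus_a = -75),
  super_res = TRUE, seed = 1))
res <- run_diagnose(m, lattice = "gold")
subset(res$peaks, matched & d > 1.9)
#> # A tibble: 2 × 9
#>       h     k     l     d     q allowed q_measured     z matched
#> 1     1     1     1  2.35 0.425 TRUE         0.425  18.2 TRUE
#> 2     2     0     0  2.04 0.490 TRUE         0.494  17.3 TRUE
```

Both rings (2.35 Å ⟨111⟩ and 2.04 Å ⟨200⟩) are detected with z-scores near
18 at spatial frequencies beyond the physical Nyquist of 0.3125 Å⁻¹ —
information that only subpixel event counting can record.

A thin command-line wrapper with subcommands `envelope`, `ccfit`,
`diagnose`, `simulate`, `simulate-events` and `count` is installed at
`system.file("cli", "emdiag.R", package = "emdiag")`; see the package
vignette for the full methods account.

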