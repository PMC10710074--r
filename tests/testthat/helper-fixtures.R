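# Shared imaging conditions and lazily built synthetic fixtures.

# The 100 keV instrument conditions used for the envelope figure:
# Cc = 1.9 mm, W = 0.07, dz = -2.5 um, source FWHM 0.7 eV.
instrument_params <- function(cs_mm = 0) {
  optical_params(100e3, cs_mm = cs_mm, cc_mm = 1.9, amplitude_contrast = 0.07,
                 defocus_a = -25000, energy_spread_fwhm_ev = 0.7)
}

# Near-focus conditions for lattice test specimens: the defocus is chosen so
# |CTF| is close to 1 at the gold <111> and <200> frequencies, as an
# operator would when imaging lattice fringes.
lattice_params <- function() {
  optical_params(100e3, amplitude_contrast = 0.07, defocus_a = -75)
}

gold_superres_recipe <- function(seed = 1, fluence = 50, size = 512) {
  simulation_recipe("gold_fcc", pixel_a = 1.6, size = size, fluence = fluence,
                    params = lattice_params(), super_res = TRUE, seed = seed)
}

# One shared blank radial spectrum for whitening gold super-res images
# (a blank is measured once per imaging condition, not per exposure).
.fixture_cache <- new.env(parent = emptyenv())

gold_blank_radial <- function() {
  if (is.null(.fixture_cache$gold_blank)) {
    r <- simulation_recipe("blank", pixel_a = 1.6, size = 512, fluence = 50,
                           params = lattice_params(), super_res = TRUE,
                           seed = 4242)
    .fixture_cache$gold_blank <- make_blank_pair(r, n_bins = 128)$radial
  }
  .fixture_cache$gold_blank
}

# Full lattice diagnostics chain on a micrograph: taper, transform, whiten,
# radially average, match reflections.
diagnose_gold <- function(m, n_bins = 128) {
  fa <- whiten(fft_amplitude(taper_edges(m, 32)), gold_blank_radial())
  spectrum <- radial_average(fa, n_bins = n_bins)
  refl <- predict_reflections("cubic_fcc", 4.0782, 2)
  match_peaks(spectrum, refl[refl$allowed, ], tol = 0.02)
}
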