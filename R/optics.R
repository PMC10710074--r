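# Physical constants (CODATA 2018, exact where the SI defines them).
.const <- list(
  h  = 6.62607015e-34,    # Planck constant, J s
  m0 = 9.1093837015e-31,  # electron rest mass, kg
  e  = 1.602176634e-19,   # elementary charge, C
  c  = 2.99792458e8       # speed of light, m/s
)

#' Relativistic electron wavelength
#'
#' Computes the de Broglie wavelength of an electron accelerated through a
#' potential corresponding to `energy_ev`, with the relativistic correction
#' \eqn{\lambda = h / \sqrt{2 m_0 e V (1 + eV / (2 m_0 c^2))}}.
#'
#' @param energy_ev Primary beam energy in electron-volts (equivalently, the
#'   accelerating voltage in volts). Must be positive; vectorized.
#' @return Wavelength in Angstrom.
#' @examples
#' electron_wavelength(100e3) # ~0.0370 A
#' electron_wavelength(300e3) # ~0.0197 A
#' @export
electron_wavelength <- function(energy_ev) {
  if (!is.numeric(energy_ev) || any(!is.finite(energy_ev)) || any(energy_ev <= 0)) {
    stop_invalid("`energy_ev` must be a positive, finite beam energy in eV.")
  }
  with(.const, h / sqrt(2 * m0 * e * energy_ev * (1 + e * energy_ev / (2 * m0 * c^2)))) * 1e10
}

#' Imaging-condition parameter set
#'
#' Bundles the optical parameters of a defocused bright-field imaging system:
#' beam energy, spherical and chromatic aberration coefficients, amplitude
#' contrast, nominal defocus, magnified pixel size and source energy spread.
#' Lengths are stored internally in Angstrom (aberration coefficients are
#' accepted in mm at the interface, 1 mm = 1e7 A); the wavelength is derived
#' from the energy. The defocus is signed: the convention used throughout is
#' that the nominal defocus for imaging vitrified specimens is negative
#' (e.g. -2.5 um = -25000 A).
#'
#' @param energy_ev Primary beam energy E, eV (> 0).
#' @param cs_mm Spherical aberration coefficient Cs, mm (>= 0).
#' @param cc_mm Chromatic aberration coefficient Cc, mm (>= 0).
#' @param amplitude_contrast Amplitude contrast fraction W in `[0, 1)`.
#' @param defocus_a Nominal defocus, Angstrom (signed).
#' @param pixel_a Magnified pixel size, Angstrom (> 0).
#' @param energy_spread_fwhm_ev Full width at half maximum of the source
#'   energy spread, eV (>= 0).
#' @return An object of class `optical_params`.
#' @examples
#' optical_params(100e3, cc_mm = 1.9, amplitude_contrast = 0.07,
#'                defocus_a = -25000, energy_spread_fwhm_ev = 0.7)
#' @export
optical_params <- function(energy_ev,
                           cs_mm = 0,
                           cc_mm = 0,
                           amplitude_contrast = 0,
                           defocus_a = 0,
                           pixel_a = 1,
                           energy_spread_fwhm_ev = 0) {
  check_scalar <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop_invalid(sprintf("`%s` must be a single finite number.", nm))
    }
  }
  for (nm in c("energy_ev", "cs_mm", "cc_mm", "amplitude_contrast",
               "defocus_a", "pixel_a", "energy_spread_fwhm_ev")) {
    check_scalar(get(nm), nm)
  }
  if (energy_ev <= 0) stop_invalid("`energy_ev` must be > 0.")
  if (cs_mm < 0) stop_invalid("`cs_mm` must be >= 0.")
  if (cc_mm < 0) stop_invalid("`cc_mm` must be >= 0.")
  if (amplitude_contrast < 0 || amplitude_contrast >= 1) {
    stop_invalid("`amplitude_contrast` must lie in [0, 1).")
  }
  if (pixel_a <= 0) stop_invalid("`pixel_a` must be > 0.")
  if (energy_spread_fwhm_ev < 0) stop_invalid("`energy_spread_fwhm_ev` must be >= 0.")

  structure(
    list(
      energy_ev = energy_ev,
      lambda_a = electron_wavelength(energy_ev),
      cs_a = mm_to_angstrom(cs_mm),
      cc_a = mm_to_angstrom(cc_mm),
      amplitude_contrast = amplitude_contrast,
      defocus_a = defocus_a,
      pixel_a = pixel_a,
      energy_spread_fwhm_ev = energy_spread_fwhm_ev
    ),
    class = "optical_params"
  )
}

#' @export
print.optical_params <- function(x, ...) {
  cat("<optical_params>\n")
  cat(sprintf("  E        %g eV (lambda = %.5f A)\n", x$energy_ev, x$lambda_a))
  cat(sprintf("  Cs       %g mm   Cc %g mm\n",
              angstrom_to_mm(x$cs_a), angstrom_to_mm(x$cc_a)))
  cat(sprintf("  W        %g\n", x$amplitude_contrast))
  cat(sprintf("  defocus  %g A\n", x$defocus_a))
  cat(sprintf("  pixel    %g A\n", x$pixel_a))
  cat(sprintf("  dE FWHM  %g eV\n", x$energy_spread_fwhm_ev))
  invisible(x)
}

#' Unit conversions for aberration coefficients
#'
#' @param x Length in mm (`mm_to_angstrom`) or Angstrom (`angstrom_to_mm`).
#' @return Converted length (1 mm = 1e7 A).
#' @export
mm_to_angstrom <- function(x) x * 1e7

#' @rdname mm_to_angstrom
#' @export
angstrom_to_mm <- function(x) x / 1e7

#' Aberration phase function
#'
#' The wave-front phase error
#' \eqn{\chi(q) = \pi [ \tfrac12 C_s \lambda^3 q^4 + (\Delta z + \Delta f) \lambda q^2 ]},
#' combining the spherical-aberration and defocus terms. `df_extra_a` is an
#' additional defocus offset (e.g. the chromatic offset of an electron with
#' energy deviation dE) added to the nominal defocus of `params`.
#'
#' @param q Spatial frequency in 1/Angstrom; vectorized, must be >= 0.
#' @param params An [optical_params()] object.
#' @param df_extra_a Extra defocus offset in Angstrom (default 0).
#' @return Phase in radians, same shape as `q`.
#' @export
ctf_phase <- function(q, params, df_extra_a = 0) {
  stopifnot(inherits(params, "optical_params"))
  if (any(q < 0, na.rm = TRUE)) stop_invalid("`q` must be non-negative.")
  lam <- params$lambda_a
  dz <- params$defocus_a + df_extra_a
  pi * (0.5 * params$cs_a * lam^3 * q^4 + dz * lam * q^2)
}

#' Contrast transfer function
#'
#' Evaluates the phase/amplitude-contrast transfer function
#' \eqn{\mathrm{CTF}(q) = \sqrt{1 - W^2}\,\sin\chi(q) - W \cos\chi(q)}
#' with unit total amplitude, so that |CTF| <= 1 everywhere and
#' CTF(0) = -W. This is equivalent to \eqn{\sin(\chi - \arcsin W)}.
#'
#' @inheritParams ctf_phase
#' @return Transfer values in `[-1, 1]`, same shape as `q`.
#' @examples
#' p <- optical_params(100e3, amplitude_contrast = 0.07, defocus_a = -25000)
#' ctf(0, p) # -0.07
#' @export
ctf <- function(q, params, df_extra_a = 0) {
  stopifnot(inherits(params, "optical_params"))
  w <- params$amplitude_contrast
  chi <- ctf_phase(q, params, df_extra_a)
  sqrt(1 - w^2) * sin(chi) - w * cos(chi)
}

#' Read and write optical parameters as flat config files
#'
#' The on-disk format is a plain text `key = value` file with keys
#' `energy_ev`, `cs_mm`, `cc_mm`, `amplitude_contrast`, `defocus_a`,
#' `pixel_a`, `energy_spread_fwhm_ev`. Missing keys take the
#' [optical_params()] defaults; `energy_ev` is required. Lines starting with
#' `#` are comments.
#'
#' @param path File path.
#' @return `read_optical_params()` returns an [optical_params()] object;
#'   `write_optical_params()` returns `path` invisibly.
#' @export
read_optical_params <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("Config file not found: %s", path))
  kv <- parse_keyvalue(readLines(path, warn = FALSE))
  known <- c("energy_ev", "cs_mm", "cc_mm", "amplitude_contrast",
             "defocus_a", "pixel_a", "energy_spread_fwhm_ev")
  extra <- setdiff(names(kv), known)
  if (length(extra)) {
    stop_config(sprintf("Unknown key(s) in %s: %s", path, paste(extra, collapse = ", ")))
  }
  if (!"energy_ev" %in% names(kv)) stop_config("Config must set `energy_ev`.")
  args <- lapply(kv, as.numeric)
  if (any(is.na(unlist(args)))) stop_config("All config values must be numeric.")
  defaults <- list(cs_mm = 0, cc_mm = 0, amplitude_contrast = 0,
                   defocus_a = 0, pixel_a = 1, energy_spread_fwhm_ev = 0)
  args <- utils::modifyList(defaults, args)
  do.call(optical_params, args)
}

#' @rdname read_optical_params
#' @param params An [optical_params()] object to serialize.
#' @export
write_optical_params <- function(params, path) {
  stopifnot(inherits(params, "optical_params"))
  lines <- c(
    sprintf("energy_ev = %.10g", params$energy_ev),
    sprintf("cs_mm = %.10g", angstrom_to_mm(params$cs_a)),
    sprintf("cc_mm = %.10g", angstrom_to_mm(params$cc_a)),
    sprintf("amplitude_contrast = %.10g", params$amplitude_contrast),
    sprintf("defocus_a = %.10g", params$defocus_a),
    sprintf("pixel_a = %.10g", params$pixel_a),
    sprintf("energy_spread_fwhm_ev = %.10g", params$energy_spread_fwhm_ev)
  )
  writeLines(lines, path)
  invisible(path)
}

# Parse "key = value" lines into a named character list.
parse_keyvalue <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop_config(sprintf("Malformed config line: '%s'", lines[bad][1]))
  vals <- lapply(parts, function(p) trimws(p[2]))
  names(vals) <- vapply(parts, function(p) trimws(p[1]), character(1))
  vals
}
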