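# Provenance block written into every machine-readable result so reruns
# with an identical configuration are bit-identical and attributable.
provenance <- function(seed, config) {
  list(
    package = "emdiag",
    version = as.character(utils::packageVersion("emdiag")),
    seed = seed,
    config_hash = config_hash(config)
  )
}

resolve_params <- function(params, require_cs = FALSE) {
  if (inherits(params, "optical_params")) return(params)
  if (is.character(params) && length(params) == 1) {
    if (require_cs) {
      kv <- parse_keyvalue(readLines(params, warn = FALSE))
      if (!"cs_mm" %in% names(kv)) {
        stop_config("Config must state `cs_mm` explicitly (no silent default).")
      }
    }
    return(read_optical_params(params))
  }
  stop_config("`params` must be an optical_params object or a config file path.")
}

#' Compute and report the temporal coherence envelope
#'
#' End-to-end envelope stage: builds the Gaussian source spectrum on the
#' energy-offset grid, averages the CTF, extracts the envelope, optionally
#' writes it as CSV (`q_invA,T`) and writes a JSON summary reporting the
#' envelope at requested resolutions (default 3 Angstrom) together with a
#' provenance block.
#'
#' When `params` is a config file path, the file must state `cs_mm`
#' explicitly: the spherical aberration affects the averaged CTF and is a
#' deliberate input, not a defaultable one.
#'
#' @param params An [optical_params()] object or a config file path.
#' @param out_csv Optional path for the envelope CSV.
#' @param summary_json Optional path for the JSON summary.
#' @param report_resolution_a Resolutions (Angstrom) at which T is reported.
#' @param de_lo,de_hi,de_step Energy-offset grid, eV.
#' @param q_max,n_q Frequency grid for the averaging.
#' @return A list with `curve` (the `envelope_curve`) and `summary`
#'   (a tibble with columns `resolution_a`, `q`, `T`).
#' @export
run_envelope <- function(params, out_csv = NULL, summary_json = NULL,
                         report_resolution_a = 3,
                         de_lo = -1.8, de_hi = 1.8, de_step = 0.05,
                         q_max = 0.5, n_q = 4096) {
  p <- resolve_params(params, require_cs = TRUE)
  if (p$energy_spread_fwhm_ev > 0) {
    curve <- coherence_envelope(p, q_max = q_max, n_q = n_q,
                                de_lo = de_lo, de_hi = de_hi, de_step = de_step)
    at <- function(q) envelope_at(curve, q)
  } else {
    # monochromatic source: the envelope is identically 1
    curve <- NULL
    at <- function(q) rep(1, length(q))
  }
  qs <- 1 / report_resolution_a
  if (!is.null(curve) && any(qs > attr(curve, "q_max"))) {
    stop_config("Requested resolution lies beyond the computed envelope support.")
  }
  summary <- tibble::tibble(resolution_a = report_resolution_a, q = qs, T = at(qs))
  cfg <- list(params = unclass(p), de = c(de_lo, de_hi, de_step),
              q_max = q_max, n_q = n_q)
  if (!is.null(out_csv)) {
    qq <- if (is.null(curve)) seq(0, q_max, length.out = 512) else {
      seq(0, attr(curve, "q_max"), length.out = 512)
    }
    readr::write_csv(tibble::tibble(q_invA = qq, T = at(qq)), out_csv,
                     progress = FALSE)
  }
  if (!is.null(summary_json)) {
    jsonlite::write_json(
      list(envelope = summary, provenance = provenance(NA, cfg)),
      summary_json, auto_unbox = TRUE, digits = NA, na = "null"
    )
  }
  list(curve = curve, summary = summary)
}

#' Fit Cc from a defocus-series CSV
#'
#' Reads a `voltage_v,defocus_a,replicate` CSV (kV inputs normalized),
#' fits the chromatic aberration coefficient, and optionally writes a
#' one-line JSON result with provenance.
#'
#' @param series A data frame or a CSV path.
#' @param v0 Nominal accelerating voltage, V.
#' @param out_json Optional output JSON path.
#' @return A `cc_fit` object (see [fit_cc()]).
#' @export
run_ccfit <- function(series, v0 = 100000, out_json = NULL) {
  df <- if (is.character(series)) read_defocus_series(series) else series
  fit <- fit_cc(df, v0 = v0)
  if (!is.null(out_json)) {
    jsonlite::write_json(
      list(cc_mm = fit$cc_mm, cc_sign = fit$cc_sign,
           stderr_cc_mm = fit$stderr_cc_mm, intercept_a = fit$intercept_a,
           n_points = fit$n_points,
           provenance = provenance(NA, list(v0 = v0, n = nrow(df)))),
      out_json, auto_unbox = TRUE, digits = NA
    )
  }
  fit
}

#' Spectral diagnostics of a test-specimen micrograph
#'
#' The full image-analysis chain: central crop, edge taper, 2D Fourier
#' amplitude, optional noise whitening against a blank, radial averaging,
#' and matching of lattice reflections at their predicted d-spacings.
#'
#' @param image A [micrograph()] or an MRC path.
#' @param lattice `"gold"`, `"graphene"`, or a list with `family`, `a` and
#'   optionally `max_index`.
#' @param blank Optional blank for whitening: a `radial_spectrum`, a radial
#'   CSV path, or a blank MRC path.
#' @param crop Central crop (power of two); default largest available.
#' @param taper_width Edge taper width in pixels (default 32).
#' @param n_bins Radial bins.
#' @param tol Relative matching tolerance.
#' @param whiten_spectrum Whiten before radial averaging? Default: whiten
#'   when a blank is supplied. Requesting whitening without a blank is a
#'   configuration error.
#' @param out_spectrum_csv,out_peaks_csv Optional output CSV paths.
#' @return A list with `spectrum` (a `radial_spectrum`) and `peaks`
#'   (the [match_peaks()] table).
#' @export
run_diagnose <- function(image, lattice = "gold", blank = NULL, crop = NULL,
                         taper_width = 32, n_bins = 128, tol = 0.02,
                         whiten_spectrum = !is.null(blank),
                         out_spectrum_csv = NULL, out_peaks_csv = NULL) {
  m <- if (is.character(image)) read_mrc(image) else image
  if (!inherits(m, "micrograph")) stop_data("`image` must be a 2D micrograph.")
  if (whiten_spectrum && is.null(blank)) {
    stop_config("Whitening requested but no blank supplied.")
  }
  lat <- if (is.list(lattice)) {
    list(family = lattice$family, a = lattice$a,
         max_index = if (is.null(lattice$max_index)) 4 else lattice$max_index)
  } else {
    switch(lattice,
      gold = list(family = "cubic_fcc", a = 4.0782, max_index = 4),
      graphene = list(family = "hexagonal_2d", a = 2.461, max_index = 2),
      stop_config(sprintf("Unknown lattice '%s'.", lattice))
    )
  }
  fa <- fft_amplitude(taper_edges(m, taper_width), crop = crop)
  if (whiten_spectrum) {
    blank_radial <- if (inherits(blank, "radial_spectrum")) {
      blank
    } else if (is.character(blank) && grepl("\\.csv$", blank)) {
      read_radial_spectrum(blank)
    } else if (is.character(blank)) {
      bm <- read_mrc(blank)
      radial_average(fft_amplitude(taper_edges(bm, taper_width), crop = crop),
                     n_bins = n_bins)
    } else {
      stop_config("`blank` must be a radial_spectrum, a CSV path or an MRC path.")
    }
    fa <- whiten(fa, blank_radial)
  }
  spectrum <- radial_average(fa, n_bins = n_bins)
  predicted <- predict_reflections(lat$family, lat$a, lat$max_index)
  peaks <- match_peaks(spectrum, predicted[predicted$allowed, ], tol = tol)
  if (!is.null(out_spectrum_csv)) write_radial_spectrum(spectrum, out_spectrum_csv)
  if (!is.null(out_peaks_csv)) readr::write_csv(peaks, out_peaks_csv, progress = FALSE)
  list(spectrum = spectrum, peaks = peaks)
}
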