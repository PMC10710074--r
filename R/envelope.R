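#' Source energy spectrum on a discrete offset grid
#'
#' Builds the weight table used for energy-spread-weighted CTF averaging:
#' a grid of energy offsets dE (relative to the nominal beam energy) and
#' normalized non-negative weights. The default grid runs from -1.8 to
#' +1.8 eV in 0.05 eV steps. For `shape = "gaussian"` the weights follow
#' \eqn{w(\Delta E) \propto \exp(-\Delta E^2 / 2\sigma^2)} with
#' \eqn{\sigma = \mathrm{FWHM} / (2\sqrt{2 \ln 2})}; `shape = "tabulated"`
#' interpolates a user-supplied (offset, weight) table onto the grid, for
#' sources whose measured spread is not Gaussian.
#'
#' @param fwhm_ev Energy spread FWHM in eV (> 0 for the Gaussian shape).
#' @param lo,hi,step Offset grid limits and spacing in eV.
#' @param shape `"gaussian"` or `"tabulated"`.
#' @param table For `shape = "tabulated"`, a data frame with columns
#'   `offset_ev` and `weight`.
#' @return A tibble of class `energy_spectrum` with columns `offset_ev`
#'   and `weight` (weights sum to 1).
#' @examples
#' spec <- energy_spectrum(0.7)
#' nrow(spec) # 73
#' @export
energy_spectrum <- function(fwhm_ev, lo = -1.8, hi = 1.8, step = 0.05,
                            shape = c("gaussian", "tabulated"), table = NULL) {
  shape <- match.arg(shape)
  if (!(lo < hi)) stop_invalid("`lo` must be < `hi`.")
  if (step <= 0) stop_invalid("`step` must be > 0.")
  offsets <- seq(lo, hi, by = step)
  if (shape == "gaussian") {
    if (fwhm_ev <= 0) stop_invalid("`fwhm_ev` must be > 0 for a Gaussian spectrum.")
    sigma <- fwhm_ev / (2 * sqrt(2 * log(2)))
    w <- exp(-offsets^2 / (2 * sigma^2))
  } else {
    if (is.null(table)) stop_data("`shape = \"tabulated\"` requires a `table` of (offset_ev, weight).")
    if (!all(c("offset_ev", "weight") %in% names(table))) {
      stop_data("`table` must have columns `offset_ev` and `weight`.")
    }
    if (any(table$weight < 0)) stop_invalid("Tabulated weights must be non-negative.")
    w <- stats::approx(table$offset_ev, table$weight, xout = offsets,
                       rule = 1)$y
    w[is.na(w)] <- 0
    if (all(w == 0)) stop_data("Tabulated spectrum does not cover the offset grid.")
  }
  tibble::new_tibble(
    tibble::tibble(offset_ev = offsets, weight = w / sum(w)),
    class = "energy_spectrum"
  )
}

#' Chromatic defocus offset for an energy deviation
#'
#' An electron with energy offset dE from the nominal beam energy E is
#' focused with an additional defocus \eqn{\Delta f = C_c \, \Delta E / E}.
#'
#' @param de_ev Energy offset in eV; vectorized.
#' @param params An [optical_params()] object (uses its Cc and E).
#' @return Defocus offset in Angstrom.
#' @examples
#' p <- optical_params(100e3, cc_mm = 1.9)
#' defocus_offset(0.7, p) # 133 A
#' @export
defocus_offset <- function(de_ev, params) {
  stopifnot(inherits(params, "optical_params"))
  params$cc_a * de_ev / params$energy_ev
}

#' Energy-spread-weighted average CTF
#'
#' Averages the CTF over the energy spectrum of the source: each energy
#' offset contributes the CTF at a chromatically shifted defocus, weighted by
#' the spectral weight. With a single zero offset this reduces exactly to the
#' monochromatic [ctf()].
#'
#' The frequency grid must sample the fastest CTF oscillation adequately;
#' if fewer than 8 grid points fall within one oscillation at the highest
#' frequency, a warning is issued and the result carries
#' `attr(, "undersampled") = TRUE`.
#'
#' @param q Numeric vector of spatial frequencies (1/Angstrom), increasing.
#' @param params An [optical_params()] object.
#' @param spectrum An [energy_spectrum()] table.
#' @return A tibble with columns `q` and `ctf` (the weighted mean transfer
#'   value), with attribute `undersampled`.
#' @export
averaged_ctf <- function(q, params, spectrum) {
  stopifnot(inherits(params, "optical_params"))
  if (!all(c("offset_ev", "weight") %in% names(spectrum))) {
    stop_invalid("`spectrum` must have columns `offset_ev` and `weight`.")
  }
  offs <- defocus_offset(spectrum$offset_ev, params)
  acc <- numeric(length(q))
  for (i in seq_along(offs)) {
    acc <- acc + spectrum$weight[i] * ctf(q, params, df_extra_a = offs[i])
  }
  undersampled <- FALSE
  if (length(q) > 1) {
    qmax <- max(q)
    dq <- max(diff(q))
    # steepest local phase slope over the offset range
    dz_max <- max(abs(params$defocus_a + offs))
    dchi <- pi * (2 * params$cs_a * params$lambda_a^3 * qmax^3 +
                    2 * dz_max * params$lambda_a * qmax)
    if (dchi > 0) {
      samples_per_osc <- (2 * pi / dchi) / dq
      if (samples_per_osc < 8) {
        undersampled <- TRUE
        warning("Frequency grid undersamples the CTF oscillations (fewer than ",
                "8 samples per period at max q); refine the grid.",
                call. = FALSE)
      }
    }
  }
  out <- tibble::tibble(q = q, ctf = acc)
  attr(out, "undersampled") <- undersampled
  out
}

#' Extract the temporal coherence envelope from an averaged CTF
#'
#' Locates the peaks and troughs of the averaged CTF (3-point local maxima of
#' |CTF| with parabolic refinement; ties broken toward lower frequency) and
#' takes their amplitudes as samples of the temporal coherence envelope T(f).
#' A monotonicity-preserving piecewise-cubic interpolant is fitted through
#' (0, 1) and the extrema. Because the monochromatic CTF has unit-amplitude
#' extrema, the raw extremum amplitudes are the envelope directly and no
#' normalization is applied.
#'
#' @param avg A tibble from [averaged_ctf()] (columns `q`, `ctf`).
#' @return An object of class `envelope_curve`: a tibble with columns `q`
#'   (extremum frequencies, strictly increasing) and `amplitude` in `[0, 1]`,
#'   carrying the interpolant as an attribute. Evaluate it with
#'   [envelope_at()].
#' @export
extract_envelope <- function(avg) {
  if (!all(c("q", "ctf") %in% names(avg))) {
    stop_invalid("`avg` must have columns `q` and `ctf` (see averaged_ctf()).")
  }
  q <- avg$q
  a <- abs(avg$ctf)
  n <- length(a)
  if (n < 3) stop_data("Averaged CTF has too few samples to locate extrema.")
  # strict rise then non-strict fall: ties resolve to the lower-q sample
  idx <- which(a[2:(n - 1)] > a[1:(n - 2)] & a[2:(n - 1)] >= a[3:n]) + 1L
  if (length(idx) < 2) {
    stop_data("Fewer than 2 CTF extrema in range; extend the frequency grid.")
  }
  # parabolic refinement of both position and height
  refine <- function(i) {
    y0 <- a[i - 1]; y1 <- a[i]; y2 <- a[i + 1]
    denom <- y0 - 2 * y1 + y2
    if (denom >= 0) return(c(q[i], y1))        # degenerate: keep the sample
    delta <- 0.5 * (y0 - y2) / denom
    delta <- max(min(delta, 0.5), -0.5)
    qq <- q[i] + delta * (q[i + 1] - q[i])
    yy <- y1 - 0.25 * (y0 - y2) * delta
    c(qq, yy)
  }
  ref <- vapply(idx, refine, numeric(2))
  freqs <- ref[1, ]
  amps <- pmin(pmax(ref[2, ], 0), 1)
  keep <- !duplicated(freqs)
  freqs <- freqs[keep]; amps <- amps[keep]
  ord <- order(freqs)
  freqs <- freqs[ord]; amps <- amps[ord]

  knots_q <- c(0, freqs)
  knots_a <- c(1, amps)
  interp <- stats::splinefun(knots_q, knots_a, method = "monoH.FC")
  out <- tibble::new_tibble(
    tibble::tibble(q = freqs, amplitude = amps),
    class = "envelope_curve"
  )
  attr(out, "interpolant") <- interp
  attr(out, "q_max") <- max(freqs)
  out
}

#' Evaluate an envelope curve
#'
#' @param curve An `envelope_curve` from [extract_envelope()] or
#'   [coherence_envelope()].
#' @param q Spatial frequencies in `[0, max(curve$q)]` (1/Angstrom).
#' @return Envelope amplitudes in `[0, 1]`.
#' @export
envelope_at <- function(curve, q) {
  stopifnot(inherits(curve, "envelope_curve"))
  if (any(q < 0) || any(q > attr(curve, "q_max") + 1e-12)) {
    stop_data(sprintf(
      "`q` outside the envelope support [0, %.4g]; extrapolation is not supported.",
      attr(curve, "q_max")
    ))
  }
  pmin(pmax(attr(curve, "interpolant")(q), 0), 1)
}

#' Temporal coherence envelope of an imaging system
#'
#' One-call wrapper around the full calculation: build the source energy
#' spectrum (Gaussian with the FWHM stored in `params`, unless `spectrum`
#' is supplied), average the CTF over the chromatic defocus offsets on a
#' dense frequency grid, and extract the envelope from the peak/trough
#' amplitudes.
#'
#' @param params An [optical_params()] object; `energy_spread_fwhm_ev` must
#'   be > 0 unless `spectrum` is given.
#' @param spectrum Optional [energy_spectrum()]; overrides the Gaussian
#'   default.
#' @param q_max Upper end of the frequency grid, 1/Angstrom.
#' @param n_q Number of grid points (default 4096 over `[0, q_max]`).
#' @param de_lo,de_hi,de_step Offset grid passed to [energy_spectrum()].
#' @return An `envelope_curve` (see [extract_envelope()]).
#' @examples
#' p <- optical_params(100e3, cc_mm = 1.9, amplitude_contrast = 0.07,
#'                     defocus_a = -25000, energy_spread_fwhm_ev = 0.7)
#' env <- coherence_envelope(p)
#' envelope_at(env, 1 / 3) # > 0.75
#' @export
coherence_envelope <- function(params, spectrum = NULL, q_max = 0.5, n_q = 4096,
                               de_lo = -1.8, de_hi = 1.8, de_step = 0.05) {
  stopifnot(inherits(params, "optical_params"))
  if (is.null(spectrum)) {
    if (params$energy_spread_fwhm_ev <= 0) {
      stop_config("Energy spread FWHM is 0 and no `spectrum` was given; nothing to average.")
    }
    spectrum <- energy_spectrum(params$energy_spread_fwhm_ev,
                                lo = de_lo, hi = de_hi, step = de_step)
  }
  q <- seq(0, q_max, length.out = n_q)
  avg <- averaged_ctf(q, params, spectrum)
  extract_envelope(avg)
}

#' Closed-form Gaussian temporal coherence envelope
#'
#' For a Gaussian energy spread of standard deviation `sigma_ev`, averaging
#' the CTF over the chromatic defocus distribution has the analytic envelope
#' \eqn{T(q) = \exp(-\tfrac12 (\pi \lambda \delta q^2)^2)} with defocus
#' spread \eqn{\delta = C_c \sigma_E / E}. Useful as an independent check of
#' the numerical peak/trough extraction.
#'
#' @param q Spatial frequency, 1/Angstrom; vectorized.
#' @param params An [optical_params()] object (uses lambda, Cc, E).
#' @param sigma_ev Gaussian energy spread standard deviation, eV. Defaults
#'   to the FWHM stored in `params` converted to a standard deviation.
#' @return Envelope values in `(0, 1]`.
#' @export
gaussian_envelope <- function(q, params, sigma_ev = NULL) {
  stopifnot(inherits(params, "optical_params"))
  if (is.null(sigma_ev)) {
    sigma_ev <- params$energy_spread_fwhm_ev / (2 * sqrt(2 * log(2)))
  }
  delta <- params$cc_a * sigma_ev / params$energy_ev
  exp(-0.5 * (pi * params$lambda_a * delta * q^2)^2)
}

#' Plot an envelope curve
#'
#' @param object An `envelope_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.envelope_curve <- function(object, ...) {
  qq <- seq(0, attr(object, "q_max"), length.out = 400)
  dense <- tibble::tibble(q = qq, amplitude = envelope_at(object, qq))
  ggplot2::ggplot(dense, ggplot2::aes(x = .data$q, y = .data$amplitude)) +
    ggplot2::geom_line(colour = "purple") +
    ggplot2::geom_point(data = as.data.frame(object), size = 0.4, alpha = 0.4) +
    ggplot2::labs(x = expression(q ~ (ring(A)^-1)), y = "T(f)",
                  title = "Temporal coherence envelope") +
    ggplot2::ylim(0, 1)
}
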