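#' Simulate a defocus-versus-voltage measurement series
#'
#' Emulates the chromatic-aberration measurement protocol: the accelerating
#' voltage is ramped down from `v0` by `v_span` volts in steps of `v_step`
#' and back up again (interior voltages therefore appear twice), with
#' `replicates` micrographs per voltage. The defocus of each micrograph is
#' \eqn{z = z_0 + C_c \, \Delta V / V_0} (with \eqn{\Delta V = V_0 - V})
#' plus Gaussian measurement noise.
#'
#' @param cc_true_mm Generating chromatic aberration coefficient, mm.
#' @param v0 Nominal accelerating voltage, V (default 100,000 V).
#' @param v_step Ramp step, V (default 5 V).
#' @param v_span Total ramp depth, V (default 40 V; must be a positive
#'   multiple of `v_step`).
#' @param replicates Micrographs per voltage (default 3).
#' @param noise_sd_a Gaussian defocus measurement noise, Angstrom.
#' @param base_defocus_a Base defocus z0 at `v0`, Angstrom.
#' @param seed Integer seed; the same seed reproduces the series exactly.
#' @return A tibble with columns `voltage_v`, `defocus_a`, `replicate`.
#' @examples
#' s <- simulate_defocus_series(1.9, seed = 1)
#' nrow(s) # 51 = (9 down + 8 up) x 3 replicates
#' @export
simulate_defocus_series <- function(cc_true_mm,
                                    v0 = 100000,
                                    v_step = 5,
                                    v_span = 40,
                                    replicates = 3,
                                    noise_sd_a = 50,
                                    base_defocus_a = -10000,
                                    seed = 1) {
  if (v_step <= 0) stop_invalid("`v_step` must be > 0.")
  if (v_span <= 0 || abs(v_span / v_step - round(v_span / v_step)) > 1e-9) {
    stop_invalid("`v_span` must be a positive multiple of `v_step`.")
  }
  if (replicates < 1) stop_invalid("`replicates` must be >= 1.")
  down <- seq(v0, v0 - v_span, by = -v_step)
  up <- seq(v0 - v_span + v_step, v0, by = v_step)
  voltages <- c(down, up)
  cc_a <- mm_to_angstrom(cc_true_mm)
  with_seed(seed, {
    # acquisition order: ramp is the outer loop, replicates inner
    rows <- tibble::tibble(
      voltage_v = rep(voltages, each = replicates),
      replicate = rep(seq_len(replicates), times = length(voltages))
    )
    dv <- v0 - rows$voltage_v
    rows$defocus_a <- base_defocus_a + cc_a * dv / v0 +
      stats::rnorm(nrow(rows), mean = 0, sd = noise_sd_a)
    rows[, c("voltage_v", "defocus_a", "replicate")]
  })
}

#' Fit the chromatic aberration coefficient from a defocus series
#'
#' Ordinary least squares of measured defocus against the relative voltage
#' offset \eqn{\Delta V / V_0} (with \eqn{\Delta V = V_0 - V}): the slope is
#' the chromatic aberration coefficient Cc and the intercept estimates the
#' base defocus. All observations (replicates, ramp duplicates) enter the fit
#' jointly so replicate scatter propagates into the slope standard error.
#' Cc is reported as a positive magnitude with the slope sign kept separately.
#'
#' @param series A data frame with columns `voltage_v` and `defocus_a`
#'   (a `replicate` column is allowed and ignored by the fit).
#' @param v0 Nominal accelerating voltage V0, V.
#' @return An object of class `cc_fit` with elements `cc_mm`, `cc_sign`,
#'   `intercept_a`, `stderr_cc_mm`, `n_points` and the underlying `lm` fit.
#'   Supports [generics::tidy()] and [generics::glance()].
#' @examples
#' s <- simulate_defocus_series(1.9, noise_sd_a = 0)
#' fit_cc(s)$cc_mm # 1.9
#' @export
fit_cc <- function(series, v0 = 100000) {
  if (!all(c("voltage_v", "defocus_a") %in% names(series))) {
    stop_data("`series` must have columns `voltage_v` and `defocus_a`.")
  }
  if (nrow(series) < 2) stop_data("Need at least 2 observations to fit Cc.")
  if (any(series$voltage_v > v0 + 1e-9)) {
    stop_data("All voltages must be <= the nominal voltage `v0`.")
  }
  if (length(unique(series$voltage_v)) < 2) {
    stop_data("Degenerate design: all voltages identical; cannot fit a slope.")
  }
  x <- (v0 - series$voltage_v) / v0
  fit <- stats::lm(series$defocus_a ~ x)
  # noiseless series fit perfectly; the stock lm note about that is expected
  co <- suppressWarnings(summary(fit))$coefficients
  slope_a <- co["x", "Estimate"]
  se_a <- co["x", "Std. Error"]
  structure(
    list(
      cc_mm = angstrom_to_mm(abs(slope_a)),
      cc_sign = sign(slope_a),
      intercept_a = unname(co["(Intercept)", "Estimate"]),
      stderr_cc_mm = angstrom_to_mm(se_a),
      n_points = nrow(series),
      v0 = v0,
      fit = fit
    ),
    class = "cc_fit"
  )
}

#' @export
print.cc_fit <- function(x, ...) {
  cat("<cc_fit>\n")
  cat(sprintf("  Cc       %.4f mm (slope sign %+d)\n", x$cc_mm, x$cc_sign))
  cat(sprintf("  std.err  %.4f mm\n", x$stderr_cc_mm))
  cat(sprintf("  z0       %.1f A\n", x$intercept_a))
  cat(sprintf("  n        %d observations\n", x$n_points))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.cc_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))
  tibble::tibble(
    term = c("cc_mm", "base_defocus_a"),
    estimate = c(x$cc_mm * x$cc_sign, x$intercept_a),
    std.error = c(x$stderr_cc_mm, s$coefficients["(Intercept)", "Std. Error"])
  )
}

#' @export
glance.cc_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))
  tibble::tibble(
    cc_mm = x$cc_mm,
    stderr_cc_mm = x$stderr_cc_mm,
    r.squared = s$r.squared,
    sigma_a = s$sigma,
    n = x$n_points
  )
}

#' Read and write defocus-series CSV files
#'
#' CSV dialect: header `voltage_v,defocus_a,replicate`. Voltages supplied in
#' kV (all values below 1000) are normalized to volts on read.
#'
#' @param path File path.
#' @return `read_defocus_series()` returns a tibble; `write_defocus_series()`
#'   returns `path` invisibly.
#' @export
read_defocus_series <- function(path) {
  if (!file.exists(path)) stop_data(sprintf("Series file not found: %s", path))
  df <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) stop_data(sprintf("Cannot parse %s: %s", path, conditionMessage(e)))
  )
  need <- c("voltage_v", "defocus_a")
  if (!all(need %in% names(df))) {
    stop_data(sprintf("%s must have columns %s.", path, paste(need, collapse = ", ")))
  }
  bad <- which(!is.finite(df$voltage_v) | !is.finite(df$defocus_a))
  if (length(bad)) {
    stop_data(sprintf("Non-numeric value in %s at line %d.", path, bad[1] + 1L))
  }
  if (max(df$voltage_v) < 1000) df$voltage_v <- df$voltage_v * 1000  # kV -> V
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  tibble::as_tibble(df[, c("voltage_v", "defocus_a", "replicate")])
}

#' @rdname read_defocus_series
#' @param series Tibble with columns `voltage_v`, `defocus_a`, `replicate`.
#' @export
write_defocus_series <- function(series, path) {
  readr::write_csv(series[, c("voltage_v", "defocus_a", "replicate")], path,
                   progress = FALSE)
  invisible(path)
}

#' Estimate defocus from a 1D radial power spectrum
#'
#' A simplified one-dimensional Thon-ring fit: the squared radial amplitude
#' spectrum, after subtraction of a smooth running-median baseline, is
#' cross-correlated with |CTF(q; z)|^2 (baseline-subtracted the same way)
#' over a grid of trial defoci, and the best normalized correlation is
#' refined parabolically. Intended as a pipeline stand-in for full 2D
#' astigmatic CTF estimation, not a replacement for it.
#'
#' @param spectrum A `radial_spectrum` tibble (see [radial_average()]) of the
#'   micrograph's Fourier amplitudes.
#' @param params An [optical_params()] object; its `defocus_a` is ignored.
#' @param search_lo,search_hi Signed defocus search window, Angstrom
#'   (`search_lo < search_hi`).
#' @param n_grid Number of trial defoci across the window.
#' @param q_range Frequency band used for the fit, 1/Angstrom. By default
#'   the band runs from 0.04 up to the smaller of 0.95x the axis Nyquist and
#'   the frequency at which one Thon-ring period (which shrinks as
#'   `1/(2 |z| lambda q)`) still spans three spectrum bins at the mid-window
#'   defocus, so unresolvable high-frequency rings do not dilute the
#'   correlation.
#' @return Estimated defocus in Angstrom, with attributes `ncc` (peak
#'   normalized correlation) and `n_osc` (Thon-ring oscillations in band).
#' @export
estimate_defocus_1d <- function(spectrum, params, search_lo, search_hi,
                                n_grid = 400, q_range = NULL) {
  stopifnot(inherits(params, "optical_params"))
  if (!(search_lo < search_hi)) stop_invalid("`search_lo` must be < `search_hi`.")
  if (!all(c("q", "amplitude") %in% names(spectrum))) {
    stop_data("`spectrum` must have columns `q` and `amplitude`.")
  }
  nyq <- attr(spectrum, "nyquist")
  if (is.null(nyq)) nyq <- max(spectrum$q) / sqrt(2)
  if (is.null(q_range)) {
    bw <- stats::median(diff(spectrum$q))
    dz_mid <- abs((search_lo + search_hi) / 2)
    q_resolve <- 1 / (6 * dz_mid * params$lambda_a * bw)
    q_range <- c(0.04, max(min(0.95 * nyq, q_resolve), 0.04 + 40 * bw))
  }
  keep <- is.finite(spectrum$amplitude) &
    spectrum$q >= q_range[1] & spectrum$q <= q_range[2]
  q <- spectrum$q[keep]
  if (length(q) < 32) stop_data("Too few usable spectrum bins in the fit band.")
  pw <- spectrum$amplitude[keep]^2

  win <- max(3L, 2L * floor(length(q) / 20) + 1L)  # ~1/10 of range, odd
  bg <- stats::runmed(pw, win)
  sig <- pw - bg

  # precondition: the window must put >= 3 Thon-ring oscillations in band
  n_osc_at <- function(dz) {
    abs(ctf_phase(max(q), repar(params, dz)) - ctf_phase(min(q), repar(params, dz))) / pi
  }
  if (max(n_osc_at(search_lo), n_osc_at(search_hi)) < 3) {
    stop_data("Fewer than 3 CTF oscillations in the fit band for this search window.")
  }

  grid <- seq(search_lo, search_hi, length.out = n_grid)
  score <- vapply(grid, function(dz) {
    model <- ctf(q, repar(params, dz))^2
    model <- model - stats::runmed(model, win)
    suppressWarnings(stats::cor(sig, model))
  }, numeric(1))
  score[!is.finite(score)] <- -1
  best <- which.max(score)
  # blank guard: with n independent bins, noise correlations scale like
  # 1/sqrt(n); require the peak to clear that scale decisively
  if (score[best] < max(0.35, 3.5 / sqrt(length(q)))) {
    stop_data("No significant CTF modulation found (flat correlation); is the input a blank?")
  }
  if (best == 1L || best == n_grid) {
    stop_data("Correlation maximum at the edge of the search window; widen it.")
  }
  # parabolic refinement
  y0 <- score[best - 1]; y1 <- score[best]; y2 <- score[best + 1]
  denom <- y0 - 2 * y1 + y2
  delta <- if (denom < 0) max(min(0.5 * (y0 - y2) / denom, 0.5), -0.5) else 0
  dz_hat <- grid[best] + delta * (grid[2] - grid[1])
  structure(dz_hat, ncc = y1, n_osc = n_osc_at(dz_hat))
}

# replace the nominal defocus of a parameter set
repar <- function(params, defocus_a) {
  params$defocus_a <- defocus_a
  params
}
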