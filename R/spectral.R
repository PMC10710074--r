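#' Micrograph container
#'
#' A real-valued 2D image with its magnified pixel size. Stored as a matrix
#' indexed `[x, y]` (x fastest, matching MRC layout) of class `micrograph`.
#' When an image was acquired with super-resolution counting, the attribute
#' `physical_pixel_a` records the physical detector pixel (twice the
#' sampling pixel).
#'
#' @param data Numeric matrix of intensities; both dimensions >= 64, all
#'   values finite.
#' @param pixel_a Sampling pixel size, Angstrom (> 0).
#' @param physical_pixel_a Optional physical detector pixel size, Angstrom.
#' @return A `micrograph` object.
#' @export
micrograph <- function(data, pixel_a, physical_pixel_a = NULL) {
  if (!is.matrix(data) || !is.numeric(data)) stop_invalid("`data` must be a numeric matrix.")
  if (any(dim(data) < 64)) stop_invalid("Micrograph dimensions must both be >= 64.")
  if (!all(is.finite(data))) stop_data("Micrograph contains non-finite values.")
  if (!is.numeric(pixel_a) || length(pixel_a) != 1 || pixel_a <= 0) {
    stop_invalid("`pixel_a` must be a single positive number.")
  }
  structure(data, class = "micrograph", pixel_a = pixel_a,
            physical_pixel_a = physical_pixel_a)
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("<micrograph> %d x %d px, %.4g A/px\n",
              nrow(x), ncol(x), attr(x, "pixel_a")))
  invisible(x)
}

#' Taper micrograph edges
#'
#' Blends the image toward its own mean within a margin of `width` pixels at
#' every edge using a raised-cosine profile, removing the wrap-around
#' discontinuities that otherwise streak the Fourier transform along the
#' axes. The interior is unchanged and the image mean is preserved to well
#' within 0.5%.
#'
#' @param m A [micrograph()].
#' @param width Margin width in pixels; must be < min(dim)/4. `width = 0`
#'   is the identity.
#' @return A tapered `micrograph`.
#' @export
taper_edges <- function(m, width) {
  stopifnot(inherits(m, "micrograph"))
  if (width == 0) return(m)
  if (width < 0 || width >= min(dim(m)) / 4) {
    stop_invalid("`width` must be in [0, min(dim)/4).")
  }
  ramp <- function(n) {
    w <- rep(1, n)
    i <- seq_len(width)
    edge <- 0.5 * (1 - cos(pi * (i - 0.5) / width))
    w[i] <- edge
    w[n + 1 - i] <- edge
    w
  }
  wx <- ramp(nrow(m)); wy <- ramp(ncol(m))
  w2 <- outer(wx, wy)
  mu <- mean(m)
  out <- mu + w2 * (unclass(m) - mu)
  micrograph(out, attr(m, "pixel_a"), attr(m, "physical_pixel_a"))
}

#' 2D Fourier amplitude of a central crop
#'
#' Crops a `crop` x `crop` square (a power of two) from the image centre,
#' Fourier transforms it and returns the modulus with the zero-frequency
#' term shifted to the array centre (index `crop/2 + 1`). Satisfies
#' Parseval's identity: `sum(|F|^2) / crop^2 == sum(crop_region^2)`.
#'
#' @param m A [micrograph()].
#' @param crop Side length of the central square, a power of two
#'   <= min(dim); default the largest such power of two.
#' @return An object of class `fourier_amplitude`: list with elements
#'   `amplitude` (matrix, DC at centre), `pixel_a`, `crop`, and the
#'   frequency step `dq`.
#' @export
fft_amplitude <- function(m, crop = NULL) {
  stopifnot(inherits(m, "micrograph"))
  d <- dim(m)
  if (is.null(crop)) crop <- 2^floor(log2(min(d)))
  if (crop > min(d)) stop_invalid("`crop` exceeds the image dimensions.")
  if (crop < 2 || bitwAnd(crop, crop - 1L) != 0) {
    stop_invalid("`crop` must be a power of two.")
  }
  x0 <- floor((d[1] - crop) / 2)
  y0 <- floor((d[2] - crop) / 2)
  sub <- unclass(m)[x0 + seq_len(crop), y0 + seq_len(crop)]
  fa <- Mod(stats::fft(sub))
  sh <- c((crop / 2 + 1):crop, 1:(crop / 2))
  fa <- fa[sh, sh]
  structure(
    list(amplitude = fa, pixel_a = attr(m, "pixel_a"), crop = crop,
         dq = 1 / (crop * attr(m, "pixel_a")),
         physical_pixel_a = attr(m, "physical_pixel_a")),
    class = "fourier_amplitude"
  )
}

# |q| for every element of a centred Fourier array
freq_grid <- function(fa) {
  n <- fa$crop
  f1 <- (seq_len(n) - (n / 2 + 1)) * fa$dq
  sqrt(outer(f1^2, f1^2, "+"))
}

#' Noise-whiten a Fourier amplitude array
#'
#' Divides every element of a 2D Fourier amplitude by the radial amplitude
#' of a blank (no-specimen) image interpolated at the element's |q|,
#' flattening the noise spectrum so that lattice peaks stand against a
#' uniform background. Interpolation is linear in q between blank bin
#' centres with constant extrapolation at the ends.
#'
#' @param fa A `fourier_amplitude` from [fft_amplitude()].
#' @param blank_radial A `radial_spectrum` of the blank (see
#'   [radial_average()]); must cover the frequency range and be positive.
#' @return A `fourier_amplitude` with whitened `amplitude`.
#' @export
whiten <- function(fa, blank_radial) {
  stopifnot(inherits(fa, "fourier_amplitude"))
  if (!all(c("q", "amplitude") %in% names(blank_radial))) {
    stop_data("`blank_radial` must have columns `q` and `amplitude`.")
  }
  bq <- blank_radial$q
  ba <- blank_radial$amplitude
  ok <- is.finite(ba)
  bq <- bq[ok]; ba <- ba[ok]
  qmax_needed <- sqrt(2) / (2 * fa$pixel_a)
  if (max(bq) < 0.95 * qmax_needed) {
    stop_data("Blank radial spectrum does not cover the image frequency range.")
  }
  if (any(ba <= 0)) {
    stop_data("Blank radial amplitude is <= 0 in a needed bin; cannot divide.")
  }
  qq <- freq_grid(fa)
  denom <- stats::approx(bq, ba, xout = as.vector(qq), rule = 2)$y
  fa$amplitude <- fa$amplitude / matrix(denom, nrow = fa$crop)
  fa
}

#' Radially averaged amplitude spectrum
#'
#' Azimuthally averages a 2D Fourier amplitude into equal-width annular bins
#' of |q| from 0 up to the corner frequency `sqrt(2)/(2 pixel)`. Bins beyond
#' the axis Nyquist frequency are retained and flagged `super_res` (they
#' carry signal only in super-resolution imaging). Empty bins are recorded
#' as `NA`, not zero.
#'
#' @param fa A `fourier_amplitude` from [fft_amplitude()].
#' @param n_bins Number of annular bins (>= 16).
#' @param nyquist Frequency above which bins are flagged super-resolution;
#'   defaults to the axis Nyquist of the *physical* pixel when the source
#'   micrograph recorded one, else of the sampling pixel.
#' @return A tibble of class `radial_spectrum` with columns `q` (bin
#'   centres, 1/Angstrom), `amplitude` (mean modulus), `n` (elements per
#'   bin) and `super_res`; attributes `pixel_a` and `nyquist`.
#' @export
radial_average <- function(fa, n_bins = 128, nyquist = NULL) {
  stopifnot(inherits(fa, "fourier_amplitude"))
  if (n_bins < 16) stop_invalid("`n_bins` must be >= 16.")
  if (is.null(nyquist)) {
    ref_pixel <- if (!is.null(fa$physical_pixel_a)) fa$physical_pixel_a else fa$pixel_a
    nyquist <- 1 / (2 * ref_pixel)
  }
  qmax <- sqrt(2) / (2 * fa$pixel_a)
  qq <- as.vector(freq_grid(fa))
  amp <- as.vector(fa$amplitude)
  # the origin is the image sum, not a noise amplitude: leave it out
  keep <- qq > 0
  qq <- qq[keep]; amp <- amp[keep]
  bin <- pmin(pmax(ceiling(qq / (qmax / n_bins)), 1L), n_bins)
  sums <- tapply(amp, bin, sum)
  cnts <- tapply(amp, bin, length)
  amps <- rep(NA_real_, n_bins)
  npb <- integer(n_bins)
  idx <- as.integer(names(sums))
  amps[idx] <- sums / cnts
  npb[idx] <- cnts
  centres <- (seq_len(n_bins) - 0.5) * qmax / n_bins
  out <- tibble::new_tibble(
    tibble::tibble(q = centres, amplitude = amps, n = npb,
                   super_res = centres > nyquist),
    class = "radial_spectrum"
  )
  attr(out, "pixel_a") <- fa$pixel_a
  attr(out, "nyquist") <- nyquist
  out
}

#' Read and write radial spectra as CSV
#'
#' CSV dialect: header `q_invA,amplitude,n`.
#'
#' @param spectrum A `radial_spectrum` tibble.
#' @param path File path.
#' @return `write_radial_spectrum()` returns `path` invisibly;
#'   `read_radial_spectrum()` returns a `radial_spectrum` tibble.
#' @export
write_radial_spectrum <- function(spectrum, path) {
  out <- tibble::tibble(q_invA = spectrum$q, amplitude = spectrum$amplitude,
                        n = spectrum$n)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_radial_spectrum
#' @export
read_radial_spectrum <- function(path) {
  if (!file.exists(path)) stop_data(sprintf("Spectrum file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("q_invA", "amplitude") %in% names(df))) {
    stop_data("Radial spectrum CSV must have columns `q_invA` and `amplitude`.")
  }
  if (!"n" %in% names(df)) df$n <- NA_integer_
  out <- tibble::new_tibble(
    tibble::tibble(q = df$q_invA, amplitude = df$amplitude, n = df$n,
                   super_res = FALSE),
    class = "radial_spectrum"
  )
  out
}

#' Predict lattice reflections and d-spacings
#'
#' Enumerates reflections of a cubic face-centred (fcc) lattice or a 2D
#' hexagonal lattice up to `max_index`. For the cubic family,
#' `d = a / sqrt(h^2 + k^2 + l^2)` with the fcc structure-factor selection
#' rule (h, k, l all even or all odd) marking `allowed`; for the hexagonal
#' 2D family, `1/d^2 = (4/3)(h^2 + hk + k^2)/a^2` with all reflections
#' allowed and `l = 0`. Reflections with equal d are deduplicated and the
#' result is sorted by decreasing d.
#'
#' @param family `"cubic_fcc"` or `"hexagonal_2d"`.
#' @param a Lattice constant, Angstrom.
#' @param max_index Maximum Miller index (>= 1).
#' @return A tibble with columns `h`, `k`, `l`, `d` (Angstrom), `q` (= 1/d,
#'   1/Angstrom) and `allowed`.
#' @examples
#' gold <- predict_reflections("cubic_fcc", a = 4.0782, max_index = 4)
#' round(gold$d[gold$allowed][1:2], 2) # 2.35 (<111>), 2.04 (<200>)
#' @export
predict_reflections <- function(family = c("cubic_fcc", "hexagonal_2d"),
                                a, max_index = 4) {
  family <- match.arg(family)
  if (a <= 0) stop_invalid("`a` must be > 0.")
  if (max_index < 1) stop_invalid("`max_index` must be >= 1.")
  idx <- 0:max_index
  if (family == "cubic_fcc") {
    g <- tidyr::expand_grid(h = idx, k = idx, l = idx) |>
      dplyr::filter(!(.data$h == 0 & .data$k == 0 & .data$l == 0)) |>
      dplyr::mutate(
        s = .data$h^2 + .data$k^2 + .data$l^2,
        allowed = (.data$h %% 2 == 0 & .data$k %% 2 == 0 & .data$l %% 2 == 0) |
          (.data$h %% 2 == 1 & .data$k %% 2 == 1 & .data$l %% 2 == 1)
      )
  } else {
    g <- tidyr::expand_grid(h = idx, k = idx) |>
      dplyr::filter(!(.data$h == 0 & .data$k == 0)) |>
      dplyr::mutate(
        l = 0L,
        s = (4 / 3) * (.data$h^2 + .data$h * .data$k + .data$k^2),
        allowed = TRUE
      )
  }
  g |>
    dplyr::arrange(.data$s, dplyr::desc(.data$allowed),
                   dplyr::desc(.data$h), dplyr::desc(.data$k), dplyr::desc(.data$l)) |>
    dplyr::group_by(.data$s) |>
    dplyr::summarise(
      h = dplyr::first(.data$h), k = dplyr::first(.data$k), l = dplyr::first(.data$l),
      allowed = any(.data$allowed), .groups = "drop"
    ) |>
    dplyr::mutate(d = a / sqrt(.data$s), q = 1 / .data$d) |>
    dplyr::arrange(dplyr::desc(.data$d)) |>
    dplyr::select("h", "k", "l", "d", "q", "allowed")
}

#' Match radial-spectrum peaks to predicted reflections
#'
#' Subtracts a running-median background (11 bins) from the radial
#' amplitudes, locates local maxima, and matches them to the predicted
#' reflection frequencies within a relative tolerance. Each candidate match
#' reports a z-score of the background-subtracted peak height against the
#' robust local scatter; unmatched predictions are returned with missing
#' measurements (absence of a peak is a result, not an error).
#'
#' @param spectrum A `radial_spectrum` tibble.
#' @param predicted Reflection table from [predict_reflections()].
#' Peak search is restricted to frequencies up to the axis Nyquist of the
#' sampling grid (when the spectrum records its pixel size): annular bins
#' beyond it have only partial azimuthal coverage and unstable statistics.
#'
#' @param tol Relative frequency tolerance in (0, 0.1].
#' @param bg_window Running-median window in bins (odd; default 11).
#' @return `predicted` with added columns `q_measured`, `z` and `matched`.
#' @export
match_peaks <- function(spectrum, predicted, tol = 0.02, bg_window = 11) {
  if (tol <= 0 || tol > 0.1) stop_invalid("`tol` must be in (0, 0.1].")
  px <- attr(spectrum, "pixel_a")
  q_limit <- if (!is.null(px)) 1 / (2 * px) else Inf
  q <- spectrum$q
  amp <- spectrum$amplitude
  ok <- is.finite(amp)
  # interpolate over missing bins so the running median is well defined
  if (any(!ok)) amp[!ok] <- stats::approx(q[ok], amp[ok], xout = q[!ok], rule = 2)$y
  bg <- stats::runmed(amp, bg_window)
  resid <- amp - bg
  n <- length(resid)
  peaks <- which(resid[2:(n - 1)] > resid[1:(n - 2)] &
                   resid[2:(n - 1)] >= resid[3:n]) + 1L
  # robust local scatter in a 31-bin window around each peak, centre excluded;
  # fall back to the global scatter when the neighbourhood is degenerate
  half <- 15L
  s_global <- stats::sd(resid)
  zscore <- function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    nb <- setdiff(lo:hi, (i - 1L):(i + 1L))
    s <- stats::mad(resid[nb], center = 0)
    if (!is.finite(s) || s <= 0) s <- stats::sd(resid[nb])
    if (!is.finite(s) || s <= 0) s <- s_global
    if (!is.finite(s) || s <= 0) return(0)
    resid[i] / s
  }
  peaks <- peaks[q[peaks] <= q_limit]
  pk_q <- q[peaks]
  pk_z <- vapply(peaks, zscore, numeric(1))

  res <- predicted
  res$q_measured <- NA_real_
  res$z <- NA_real_
  for (j in seq_len(nrow(res))) {
    cand <- which(abs(pk_q - res$q[j]) / res$q[j] <= tol)
    if (length(cand)) {
      best <- cand[which.max(pk_z[cand])]
      res$q_measured[j] <- pk_q[best]
      res$z[j] <- pk_z[best]
    }
  }
  res$matched <- !is.na(res$q_measured)
  res
}

#' Plot a radial amplitude spectrum
#'
#' @param object A `radial_spectrum`.
#' @param ... Unused.
#' @return A ggplot; the physical Nyquist frequency is marked with a dashed
#'   line and super-resolution bins drawn in a different colour.
#' @export
autoplot.radial_spectrum <- function(object, ...) {
  df <- as.data.frame(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$q, y = .data$amplitude,
                                   colour = .data$super_res)) +
    ggplot2::geom_line(ggplot2::aes(group = 1), na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = attr(object, "nyquist"), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "goldenrod"),
                                 name = "super-res") +
    ggplot2::labs(x = expression(q ~ (ring(A)^-1)), y = "mean |F(q)|")
}
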