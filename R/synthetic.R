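#' Recipe for a synthetic test micrograph
#'
#' Describes a simulated test-specimen exposure: a crystalline lattice
#' (fcc gold or monolayer graphene), an amorphous film, or a blank
#' flat-field, imaged with a given optical parameter set and Poisson shot
#' noise at a stated fluence. When `super_res = TRUE` the image is sampled
#' on the 2x super-resolution grid of a counting detector: the data grid
#' pixel is `pixel_a / 2` while `pixel_a` remains the physical pixel.
#'
#' @param kind `"gold_fcc"`, `"graphene"`, `"amorphous"` or `"blank"`.
#' @param pixel_a Physical pixel size, Angstrom.
#' @param size Image side in pixels; a power of two >= 256.
#' @param fluence Mean electrons per pixel of the sampling grid.
#' @param params An [optical_params()] object.
#' @param lattice Optional list with `family`, `a`, `max_index` overriding
#'   the built-in lattice constants (gold a = 4.0782 A, graphene
#'   a = 2.461 A).
#' @param orientation_deg In-plane rotation of the lattice, degrees.
#' @param lattice_contrast Amplitude of each lattice cosine component as a
#'   fraction of the mean intensity (default 0.1).
#' @param amorphous_contrast RMS contrast of the amorphous phase signal
#'   (default 0.1).
#' @param super_res Sample at half the physical pixel (2x grid)?
#' @param seed Integer seed for the shot noise and random film.
#' @return A `simulation_recipe` object.
#' @export
simulation_recipe <- function(kind = c("gold_fcc", "graphene", "amorphous", "blank"),
                              pixel_a, size = 512, fluence = 100,
                              params = optical_params(100e3),
                              lattice = NULL, orientation_deg = 0,
                              lattice_contrast = 0.1,
                              amorphous_contrast = 0.1,
                              super_res = FALSE, seed = 1) {
  kind <- match.arg(kind)
  if (fluence <= 0) stop_invalid("`fluence` must be > 0.")
  if (size < 256 || bitwAnd(as.integer(size), as.integer(size) - 1L) != 0) {
    stop_invalid("`size` must be a power of two >= 256.")
  }
  stopifnot(inherits(params, "optical_params"))
  if (is.null(lattice)) {
    lattice <- switch(kind,
      gold_fcc = list(family = "cubic_fcc", a = 4.0782, max_index = 4),
      graphene = list(family = "hexagonal_2d", a = 2.461, max_index = 2),
      NULL
    )
  }
  structure(
    list(kind = kind, pixel_a = pixel_a, size = as.integer(size),
         fluence = fluence, params = params, lattice = lattice,
         orientation_deg = orientation_deg,
         lattice_contrast = lattice_contrast,
         amorphous_contrast = amorphous_contrast,
         super_res = isTRUE(super_res), seed = as.integer(seed)),
    class = "simulation_recipe"
  )
}

#' Generate a synthetic micrograph from a recipe
#'
#' Lattice kinds are built as sums of 2D cosine components at the allowed
#' reflection frequencies (one component per distinct d-spacing, at
#' deterministic azimuths spread from `orientation_deg`; components whose
#' frequency vector cannot be represented at the sampling Nyquist are
#' skipped). The amorphous kind is a Gaussian random film with 1/q-weighted
#' amplitude. The zero-mean contrast field is multiplied in Fourier space by
#' the CTF of the recipe's optical parameters (weak-phase approximation),
#' scaled onto a mean intensity of `fluence`, and Poisson-sampled. Blanks
#' are a pure Poisson flat field. Output is bit-reproducible under the
#' recipe seed.
#'
#' @param recipe A [simulation_recipe()].
#' @return A [micrograph()]; for `super_res = TRUE` recipes its sampling
#'   `pixel_a` is half the physical pixel, which is recorded as
#'   `physical_pixel_a`.
#' @export
make_micrograph <- function(recipe) {
  stopifnot(inherits(recipe, "simulation_recipe"))
  ps <- if (recipe$super_res) recipe$pixel_a / 2 else recipe$pixel_a
  n <- recipe$size
  with_seed(recipe$seed, {
    if (recipe$kind == "blank") {
      counts <- matrix(stats::rpois(n * n, recipe$fluence), n, n)
      return(micrograph(counts, ps,
                        physical_pixel_a = if (recipe$super_res) recipe$pixel_a else NULL))
    }
    contrast <- if (recipe$kind == "amorphous") {
      amorphous_field(n, ps, recipe$amorphous_contrast)
    } else {
      lattice_field(n, ps, recipe$lattice, recipe$orientation_deg,
                    recipe$lattice_contrast)
    }
    # CTF applied multiplicatively to the zero-mean contrast spectrum
    modulated <- apply_ctf(contrast, ps, recipe$params)
    intensity <- recipe$fluence * pmax(1 + modulated, 0)
    counts <- matrix(stats::rpois(n * n, intensity), n, n)
    micrograph(counts, ps,
               physical_pixel_a = if (recipe$super_res) recipe$pixel_a else NULL)
  })
}

# sum of cosine components at allowed reflection frequencies
lattice_field <- function(n, ps, lattice, orientation_deg, amp) {
  refl <- predict_reflections(lattice$family, lattice$a, lattice$max_index)
  refl <- refl[refl$allowed, ]
  nyq <- 1 / (2 * ps)
  coords <- (0:(n - 1)) * ps
  field <- matrix(0, n, n)
  golden <- 137.50776405
  n_used <- 0L
  for (i in seq_len(nrow(refl))) {
    theta <- (orientation_deg + golden * (i - 1)) * pi / 180
    fx <- refl$q[i] * cos(theta)
    fy <- refl$q[i] * sin(theta)
    if (abs(fx) >= nyq || abs(fy) >= nyq) {
      # try the 45-degree-rotated azimuth before giving up on this ring
      theta <- theta + pi / 4
      fx <- refl$q[i] * cos(theta)
      fy <- refl$q[i] * sin(theta)
      if (abs(fx) >= nyq || abs(fy) >= nyq) next
    }
    field <- field + amp * Re(exp(2i * pi * fx * coords) %o% exp(2i * pi * fy * coords))
    n_used <- n_used + 1L
  }
  if (n_used == 0L) {
    warning("All lattice reflections lie beyond the sampling Nyquist; ",
            "image carries no lattice signal.", call. = FALSE)
  }
  field
}

# Gaussian random film with 1/q amplitude weighting, unit RMS target
amorphous_field <- function(n, ps, rms) {
  white <- matrix(stats::rnorm(n * n), n, n)
  ft <- stats::fft(white)
  f1 <- c(0:(n / 2), -(n / 2 - 1):-1) / (n * ps)   # unshifted FFT frequencies
  qq <- sqrt(outer(f1^2, f1^2, "+"))
  wgt <- 1 / pmax(qq, f1[2])
  wgt[1, 1] <- 0                                    # zero-mean field
  filt <- Re(stats::fft(ft * wgt, inverse = TRUE)) / (n * n)
  filt * (rms / stats::sd(filt))
}

# multiply the zero-mean spectrum by CTF(|q|)
apply_ctf <- function(field, ps, params) {
  n <- nrow(field)
  f1 <- c(0:(n / 2), -(n / 2 - 1):-1) / (n * ps)
  qq <- sqrt(outer(f1^2, f1^2, "+"))
  h <- ctf(qq, params)
  h[1, 1] <- 0                                      # never scale the mean
  ft <- stats::fft(field) * h
  Re(stats::fft(ft, inverse = TRUE)) / (n * n)
}

#' Generate a blank image together with its radial amplitude
#'
#' Convenience for the whitening workflow: simulates a no-specimen
#' flat-field exposure and returns both the image and its radially averaged
#' Fourier amplitude, ready to pass to [whiten()].
#'
#' @param recipe A [simulation_recipe()] with `kind = "blank"`.
#' @param n_bins Radial bins for the returned spectrum.
#' @param taper_width Edge taper applied before the transform (pixels).
#' @return A list with elements `micrograph` and `radial`.
#' @export
make_blank_pair <- function(recipe, n_bins = 128, taper_width = 0) {
  stopifnot(inherits(recipe, "simulation_recipe"))
  if (recipe$kind != "blank") stop_invalid("`recipe` must have kind = \"blank\".")
  m <- make_micrograph(recipe)
  mt <- if (taper_width > 0) taper_edges(m, taper_width) else m
  fa <- fft_amplitude(mt)
  list(micrograph = m, radial = radial_average(fa, n_bins = n_bins))
}
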