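# build a fourier_amplitude object directly (for radial-average unit tests)
fake_fa <- function(amplitude, pixel_a) {
  n <- nrow(amplitude)
  structure(list(amplitude = amplitude, pixel_a = pixel_a, crop = n,
                 dq = 1 / (n * pixel_a), physical_pixel_a = NULL),
            class = "fourier_amplitude")
}

test_that("edge taper leaves constant images and the interior untouched", {
  m <- micrograph(matrix(5, 128, 128), pixel_a = 1)
  expect_equal(unclass(taper_edges(m, 16)), unclass(m), tolerance = 1e-12)
  set.seed(1)
  m2 <- micrograph(matrix(rnorm(128^2, 100, 10), 128, 128), pixel_a = 1)
  expect_identical(taper_edges(m2, 0), m2)
  t2 <- taper_edges(m2, 16)
  expect_equal(unclass(t2)[17:112, 17:112], unclass(m2)[17:112, 17:112])
  expect_lt(abs(mean(t2) / mean(m2) - 1), 0.005)
  expect_error(taper_edges(m2, 40), class = "emdiag_invalid_parameter")
})

test_that("tapering suppresses the axis-aligned streak of a sharp-edged image", {
  # a wrap-around ramp discontinuity streaks energy along one frequency axis
  n <- 256
  ramp <- micrograph(matrix(rep(seq(0, 100, length.out = n), n), n, n),
                     pixel_a = 1)
  axis_energy <- function(m) {
    fa <- fft_amplitude(m)
    a <- fa$amplitude
    c0 <- n / 2 + 1
    f <- (seq_len(n) - c0) * fa$dq
    hi <- abs(f) > 0.05          # the streak, not the ramp's own low-f content
    sum(a[hi, c0]^2) + sum(a[c0, hi]^2)
  }
  expect_gt(axis_energy(ramp) / axis_energy(taper_edges(ramp, 32)), 10)
})

test_that("Fourier amplitude places cosine peaks correctly and obeys Parseval", {
  n <- 128
  px <- 2
  x <- matrix(rep(cos(2 * pi * (0:(n - 1)) / 8), n), n, n)  # period 8 px
  fa <- fft_amplitude(micrograph(x, pixel_a = px))
  c0 <- n / 2 + 1
  peak_idx <- which(fa$amplitude > 0.4 * max(fa$amplitude), arr.ind = TRUE)
  expect_equal(nrow(peak_idx), 2)
  q_peaks <- (peak_idx[, 1] - c0) * fa$dq
  expect_equal(sort(q_peaks), c(-1, 1) / (8 * px), tolerance = 1e-12)
  expect_true(all(peak_idx[, 2] == c0))
  # constant image: single central term
  fc <- fft_amplitude(micrograph(matrix(3, n, n), pixel_a = 1))
  expect_equal(fc$amplitude[c0, c0], 3 * n^2)
  expect_equal(max(fc$amplitude[-((c0 - 1) * n + c0)]), 0)
  # Parseval on a random image
  set.seed(2)
  mr <- matrix(rnorm(n^2), n, n)
  fr <- fft_amplitude(micrograph(mr, pixel_a = 1))
  expect_equal(sum(fr$amplitude^2) / n^2, sum(mr^2), tolerance = 1e-9)
  expect_error(fft_amplitude(micrograph(mr, 1), crop = 100),
               class = "emdiag_invalid_parameter")
})

test_that("radial averaging reproduces rotationally symmetric inputs", {
  n <- 256
  px <- 1.5
  dq <- 1 / (n * px)
  c0 <- n / 2 + 1
  f1 <- ((1:n) - c0) * dq
  qq <- sqrt(outer(f1^2, f1^2, "+"))
  g <- function(q) 10 * exp(-50 * q)
  sp <- radial_average(fake_fa(g(qq), px), n_bins = 64)
  ok <- !is.na(sp$amplitude) & sp$n > 50
  expect_lt(max(abs(sp$amplitude[ok] - g(sp$q[ok])) / g(sp$q[ok])), 0.1)
  expect_true(all(diff(sp$q) > 0))
  expect_equal(max(sp$q), sqrt(2) / (2 * px), tolerance = 0.01)
  expect_equal(sp$super_res, sp$q > 1 / (2 * px))
})

test_that("a pure cosine lands in a single non-background bin", {
  n <- 256
  x <- matrix(rep(cos(2 * pi * (0:(n - 1)) / 16), n), n, n)
  sp <- radial_average(fft_amplitude(micrograph(x, pixel_a = 1)), n_bins = 64)
  bg <- stats::median(sp$amplitude, na.rm = TRUE)
  hot <- which(sp$amplitude > bg + 0.1 * max(sp$amplitude, na.rm = TRUE))
  hot <- setdiff(hot, 1L)   # ignore the DC bin
  expect_equal(length(hot), 1)
  expect_lt(abs(sp$q[hot] - 1 / 16), diff(sp$q)[1])
})

test_that("whitening flattens a blank against its own radial average", {
  r <- simulation_recipe("blank", pixel_a = 1.2, size = 256, fluence = 100,
                         params = optical_params(100e3), seed = 21)
  pair <- make_blank_pair(r, n_bins = 48)
  fa <- fft_amplitude(pair$micrograph)
  wh <- whiten(fa, pair$radial)
  spw <- radial_average(wh, n_bins = 48)
  ok <- !is.na(spw$amplitude) & spw$n > 30
  expect_true(all(abs(spw$amplitude[ok] - 1) < 0.05))
  # flat blank spectrum of value c just divides by c
  n <- 256
  flat <- tibble::tibble(q = seq(0.001, 0.6, length.out = 50), amplitude = 4,
                         n = 1L, super_res = FALSE)
  wh2 <- whiten(fa, flat)
  expect_equal(wh2$amplitude, fa$amplitude / 4, tolerance = 1e-12)
  bad <- flat; bad$amplitude[10] <- 0
  expect_error(whiten(fa, bad), class = "emdiag_data_error")
})

test_that("whitening raises the z-score of a lattice peak over noise", {
  r <- gold_superres_recipe(seed = 31, fluence = 50)
  m <- make_micrograph(r)
  fa <- fft_amplitude(taper_edges(m, 32))
  refl <- predict_reflections("cubic_fcc", 4.0782, 2)
  refl <- refl[refl$allowed, ][1:2, ]
  raw_z <- match_peaks(radial_average(fa, n_bins = 128), refl)$z
  wh_z <- match_peaks(radial_average(whiten(fa, gold_blank_radial()),
                                     n_bins = 128), refl)$z
  expect_true(all(wh_z > raw_z | wh_z > 5))
})

test_that("whiten-then-average is invariant to joint image and blank rescaling", {
  set.seed(5)
  n <- 256
  img <- matrix(rpois(n^2, 50), n, n)
  mk_sp <- function(scale) {
    m <- micrograph(img * scale, pixel_a = 1)
    fa <- fft_amplitude(m)
    blank <- radial_average(fa, n_bins = 48)   # self as blank, scaled identically
    radial_average(whiten(fa, blank), n_bins = 48)
  }
  s1 <- mk_sp(1); s3 <- mk_sp(3)
  ok <- !is.na(s1$amplitude)
  expect_equal(s1$amplitude[ok], s3$amplitude[ok], tolerance = 1e-10)
})

test_that("predicted d-spacings match the gold and graphene lattices", {
  gold <- predict_reflections("cubic_fcc", a = 4.0782, max_index = 4)
  d_of <- function(h, k, l) gold$d[gold$h == h & gold$k == k & gold$l == l]
  expect_equal(round(d_of(2, 0, 0), 2), 2.04)
  expect_equal(round(d_of(1, 1, 1), 2), 2.35)
  expect_equal(round(d_of(4, 2, 0), 1), 0.9)
  expect_true(gold$allowed[gold$h == 2 & gold$k == 0 & gold$l == 0])
  expect_false(gold$allowed[gold$h == 1 & gold$k == 0 & gold$l == 0])
  expect_true(all(abs(gold$d * gold$q - 1) < 1e-12))
  expect_true(all(diff(gold$d) < 0))
  graphene <- predict_reflections("hexagonal_2d", a = 2.461, max_index = 2)
  expect_equal(round(graphene$d[1], 1), 2.1)   # <100>
  expect_true(all(graphene$l == 0))
})

test_that("reflection enumeration agrees exactly with brute force", {
  # independent oracle: flat enumeration with base R, dedupe by spacing
  brute_fcc <- function(a, mi) {
    g <- expand.grid(h = 0:mi, k = 0:mi, l = 0:mi)
    g <- g[g$h + g$k + g$l > 0, ]
    s <- g$h^2 + g$k^2 + g$l^2
    allowed <- tapply((g$h %% 2 == g$k %% 2) & (g$k %% 2 == g$l %% 2), s, any)
    s_u <- sort(unique(s))
    data.frame(d = a / sqrt(s_u), allowed = unname(allowed[as.character(s_u)]))
  }
  brute_hex <- function(a, mi) {
    g <- expand.grid(h = 0:mi, k = 0:mi)
    g <- g[g$h + g$k > 0, ]
    s <- sort(unique((4 / 3) * (g$h^2 + g$h * g$k + g$k^2)))
    data.frame(d = a / sqrt(s), allowed = TRUE)
  }
  for (mi in c(2, 4, 6)) {
    mine <- predict_reflections("cubic_fcc", 4.0782, mi)
    oracle <- brute_fcc(4.0782, mi)
    expect_equal(sort(mine$d, decreasing = TRUE),
                 sort(oracle$d, decreasing = TRUE), tolerance = 1e-12)
    expect_identical(mine$allowed[order(-mine$d)], oracle$allowed[order(-oracle$d)])
    mh <- predict_reflections("hexagonal_2d", 2.461, mi)
    oh <- brute_hex(2.461, mi)
    expect_equal(sort(mh$d, decreasing = TRUE),
                 sort(oh$d, decreasing = TRUE), tolerance = 1e-12)
  }
})

test_that("peak matching finds constructed peaks and reports absences", {
  q <- seq(0.005, 0.6, by = 0.005)
  amp <- rep(1, length(q))
  amp[which.min(abs(q - 1 / 2.04))] <- 5
  sp <- tibble::new_tibble(
    tibble::tibble(q = q, amplitude = amp, n = 100L, super_res = FALSE),
    class = "radial_spectrum")
  refl <- predict_reflections("cubic_fcc", 4.0782, 2)
  refl <- refl[refl$allowed, ]
  res <- match_peaks(sp, refl, tol = 0.02)
  r200 <- res[res$h == 2 & res$k == 0, ]
  expect_true(r200$matched)
  expect_lt(abs(r200$q_measured - 1 / 2.04), 0.005)
  # featureless spectrum: nothing matches, no error
  flat <- sp; flat$amplitude <- rep(1, length(q))
  res2 <- match_peaks(flat, refl)
  expect_false(any(res2$matched))
  expect_error(match_peaks(sp, refl, tol = 0.5), class = "emdiag_invalid_parameter")
})
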