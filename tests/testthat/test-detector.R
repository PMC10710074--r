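test_that("event simulation matches the stated sparsity and respects geometry", {
  geom <- detector_geometry(256, 256)
  ev <- simulate_events(geom, mean_px_per_electron = 150, n_frames = 1000, seed = 1)
  per_frame <- tabulate(ev$frame + 1L, nbins = 1000)
  mu <- 256^2 / 150   # ~436.9 electrons per frame
  se <- sqrt(mu / 1000)
  expect_lt(abs(mean(per_frame) - mu), 3 * se)
  # determinism under the seed
  expect_identical(
    as.data.frame(simulate_events(geom, 150, 3, seed = 9)),
    as.data.frame(simulate_events(geom, 150, 3, seed = 9))
  )
  # gap rows receive no events
  geom_gap <- detector_geometry(64, 64, gap_rows = 30:33)
  evg <- simulate_events(geom_gap, 50, 20, seed = 2)
  expect_false(any(floor(evg$y) %in% 30:33))
  # a one-pixel intensity map concentrates all events there
  map <- matrix(0, 64, 64); map[11, 21] <- 1
  evm <- simulate_events(detector_geometry(64, 64), 50, 10, seed = 3,
                         intensity = map)
  expect_true(all(floor(evm$x) == 10 & floor(evm$y) == 20))
  expect_error(simulate_events(geom, 0.5, 1, seed = 1),
               class = "emdiag_invalid_parameter")
})

test_that("counting merges overlapping footprints and conserves every event", {
  geom <- detector_geometry(64, 64)
  mk_ev <- function(df) {
    out <- tibble::new_tibble(df, class = "event_list")
    attr(out, "geometry") <- geom
    out
  }
  # far apart: both survive
  far <- mk_ev(tibble::tibble(frame = c(0L, 0L), x = c(10.5, 20.5), y = c(10.5, 10.5)))
  expect_equal(sum(count_events(far)), 2)
  # same pixel: merged to one count at the centroid
  near <- mk_ev(tibble::tibble(frame = c(0L, 0L), x = c(10.2, 10.8), y = c(10.3, 10.7)))
  mv <- count_events(near)
  expect_equal(sum(mv), 1)
  expect_equal(mv[11, 11, 1], 1L)   # centroid (10.5, 10.5) -> pixel (10, 10)
  # same positions in different frames never merge
  sep <- mk_ev(tibble::tibble(frame = c(0L, 1L), x = c(10.2, 10.8), y = c(10.3, 10.7)))
  expect_equal(sum(count_events(sep)), 2)
  # chebyshev distance 2 merges, 3 does not
  d2 <- mk_ev(tibble::tibble(frame = c(0L, 0L), x = c(10.5, 12.5), y = c(10.5, 10.5)))
  expect_equal(sum(count_events(d2)), 1)
  d3 <- mk_ev(tibble::tibble(frame = c(0L, 0L), x = c(10.5, 13.5), y = c(10.5, 10.5)))
  expect_equal(sum(count_events(d3)), 2)
  # reject mode drops the whole cluster
  expect_equal(sum(count_events(d2, overlap = "reject")), 0)
})

test_that("count bookkeeping is exact for seeded streams with hot pixels and a gap", {
  geom <- detector_geometry(128, 128, gap_rows = 62:65,
                            hot_pixels = tibble::tibble(x = c(5L, 100L), y = c(7L, 90L)))
  ev <- simulate_events(geom, mean_px_per_electron = 40, n_frames = 12, seed = 11)
  # push some events onto the hot pixels to exercise the discard path
  hot_ev <- tibble::tibble(frame = rep(0:11, 2),
                           x = rep(c(5.5, 100.5), each = 12),
                           y = rep(c(7.5, 90.5), each = 12))
  all_ev <- tibble::new_tibble(rbind(as.data.frame(ev), hot_ev), class = "event_list")
  attr(all_ev, "geometry") <- geom
  # injected hot events plus whatever the stream put there by chance
  n_hot <- 24 + sum((floor(ev$x) == 5 & floor(ev$y) == 7) |
                      (floor(ev$x) == 100 & floor(ev$y) == 90))
  for (mode in c("merge", "reject")) {
    mov <- count_events(all_ev, fractions = 4, overlap = mode)
    t <- attr(mov, "tally")
    expect_equal(t$events_in,
                 t$counts_out + t$hot_discards + t$gap_discards +
                   t$merge_losses + t$truncated)
    expect_equal(t$counts_out, sum(mov))
    expect_equal(t$hot_discards, n_hot)
  }
  # gap rows are identically zero in every fraction
  mov <- count_events(all_ev, fractions = 4)
  expect_true(all(mov[, 63:66, ] == 0))
  expect_error(count_events(ev, fractions = 100),
               class = "emdiag_invalid_parameter")
})

test_that("sparse streams are counted without loss", {
  geom <- detector_geometry(512, 512)
  ev <- simulate_events(geom, mean_px_per_electron = 5000, n_frames = 5, seed = 4)
  mov <- count_events(ev, fractions = 5)
  t <- attr(mov, "tally")
  expect_equal(t$hot_discards + t$gap_discards, 0)
  expect_lt(t$merge_losses / t$events_in, 0.02)
  expect_equal(t$events_in, sum(mov) + t$merge_losses)
})

test_that("coincidence loss grows with flux and matches the pair-overlap model", {
  geom <- detector_geometry(256, 256)
  losses <- vapply(c(1000, 300, 150, 50), function(sp) {
    coincidence_loss_fraction(geom, sp, n_frames = 10, seed = 5)
  }, numeric(1))
  expect_true(all(diff(losses) > 0))
  # reject-mode loss vs analytic Poisson-averaged neighbour probability
  sim <- coincidence_loss_fraction(geom, 150, n_frames = 30, seed = 6,
                                   overlap = "reject")
  ana <- coincidence_loss_approx(geom, 150)
  expect_lt(abs(sim - ana), 0.012)
  # vanishing flux: loss tends to zero
  expect_lt(coincidence_loss_fraction(geom, 2e4, n_frames = 5, seed = 7), 0.01)
})

test_that("per-pixel counts at uniform flux are Poisson", {
  geom <- detector_geometry(64, 64)
  ev <- simulate_events(geom, mean_px_per_electron = 1000, n_frames = 1500, seed = 8)
  mov <- count_events(ev, fractions = 1)
  counts <- as.vector(mov[, , 1])
  expect_gt(var(counts) / mean(counts), 0.9)
  expect_lt(var(counts) / mean(counts), 1.1)
})

test_that("super-resolution binning localizes a point source below one pixel", {
  geom <- detector_geometry(64, 64)
  # point source just inside the lower-left quadrant of pixel (10, 20)
  set.seed(13)
  n <- 400
  ev <- tibble::new_tibble(
    tibble::tibble(frame = rep(0L, n),
                   x = pmin(pmax(10.22 + rnorm(n, 0, 0.02), 10), 10.49),
                   y = pmin(pmax(20.22 + rnorm(n, 0, 0.02), 20), 20.49)),
    class = "event_list")
  attr(ev, "geometry") <- geom
  centroid <- function(mov, scale) {
    w <- mov[, , 1]
    ix <- (seq_len(nrow(w)) - 0.5) / scale
    c(sum(ix * rowSums(w)), sum(ix * colSums(w))) / sum(w)
  }
  phys <- centroid(count_events(ev, binning = "physical"), 1)
  sup <- centroid(count_events(ev, binning = "super2x"), 2)
  truth <- c(10.22, 20.22)
  err_phys <- max(abs(phys - truth))
  err_sup <- max(abs(sup - truth))
  expect_lt(err_sup, 0.15)          # within half a physical pixel with margin
  expect_gt(err_phys, err_sup)      # physical binning cannot do better
  # super2x doubles the grid
  expect_equal(dim(count_events(ev, binning = "super2x")), c(128, 128, 1))
})

test_that("hot pixels are detectable from their outlier rates", {
  geom <- detector_geometry(64, 64)
  ev <- simulate_events(geom, 500, 200, seed = 14)
  hot_ev <- tibble::tibble(frame = rep(0:199, each = 2),
                           x = 33.5, y = 44.5)
  all_ev <- tibble::new_tibble(rbind(as.data.frame(ev), hot_ev), class = "event_list")
  attr(all_ev, "geometry") <- geom
  found <- detect_hot_pixels(all_ev, threshold_sd = 6)
  expect_true(any(found$x == 33 & found$y == 44))
  expect_lte(nrow(found), 3)
})

test_that("counted movies and event lists round-trip through disk", {
  geom <- detector_geometry(64, 64, gap_rows = 31:32)
  ev <- simulate_events(geom, 100, 4, seed = 15)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_event_list(ev, csv)
  ev2 <- read_event_list(csv, geom)
  expect_equal(as.data.frame(ev2), as.data.frame(ev), tolerance = 1e-9)

  mov <- count_events(ev, binning = "physical", fractions = 2)
  path <- withr::local_tempfile(fileext = ".mrcs")
  write_movie(mov, path, pixel_a = 1.6, mode = 1)
  back <- read_mrc(path)
  expect_equal(array(as.integer(back), dim = dim(back)),
               array(unclass(mov), dim = dim(mov)))
  expect_equal(attr(back, "pixel_a"), 1.6, tolerance = 1e-6)
  expect_true(all(back[, 32:33, ] == 0))
  # super-resolution stacks double the array and halve the header pixel
  sup <- count_events(ev, binning = "super2x", fractions = 2)
  write_movie(sup, path, pixel_a = 1.6, mode = 1)
  back2 <- read_mrc(path)
  expect_equal(dim(back2), c(128, 128, 2))
  expect_equal(attr(back2, "pixel_a"), 0.8, tolerance = 1e-6)
})
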