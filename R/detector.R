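#' Hybrid-pixel detector geometry
#'
#' Describes the counting detector: pixel dimensions, the rows belonging to
#' the physical gap between the two sensor modules (recorded as zero in
#' every output frame), a static list of hot pixels, and the frame time of
#' the real-time counting electronics (default 0.22 ms).
#'
#' Pixel coordinates are zero-based: an event at `(x, y)` with
#' `0 <= x < width`, `0 <= y < height` falls in pixel
#' `(floor(x), floor(y))`.
#'
#' @param width,height Detector size in pixels (>= 32).
#' @param gap_rows Integer row (y) indices of the inter-module gap.
#' @param hot_pixels Data frame with integer columns `x`, `y`.
#' @param frame_time_ms Frame time, ms (> 0).
#' @return A `detector_geometry` object.
#' @export
detector_geometry <- function(width, height, gap_rows = integer(),
                              hot_pixels = NULL, frame_time_ms = 0.22) {
  if (width < 32 || height < 32) stop_invalid("Detector must be at least 32 x 32 px.")
  if (frame_time_ms <= 0) stop_invalid("`frame_time_ms` must be > 0.")
  gap_rows <- as.integer(gap_rows)
  if (length(gap_rows) && (any(gap_rows < 0) || any(gap_rows >= height))) {
    stop_invalid("`gap_rows` must lie within [0, height).")
  }
  if (is.null(hot_pixels)) hot_pixels <- tibble::tibble(x = integer(), y = integer())
  if (!all(c("x", "y") %in% names(hot_pixels))) {
    stop_invalid("`hot_pixels` must have columns `x` and `y`.")
  }
  structure(
    list(width = as.integer(width), height = as.integer(height),
         gap_rows = gap_rows,
         hot_pixels = tibble::as_tibble(hot_pixels[, c("x", "y")]),
         frame_time_ms = frame_time_ms),
    class = "detector_geometry"
  )
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat(sprintf("<detector_geometry> %d x %d px, %d gap row(s), %d hot pixel(s), %.3g ms/frame\n",
              x$width, x$height, length(x$gap_rows), nrow(x$hot_pixels),
              x$frame_time_ms))
  invisible(x)
}

#' Simulate a sparse electron-event stream
#'
#' Generates per-frame electron arrivals for a counting detector. The number
#' of electrons in each frame is Poisson with mean
#' `width * height / mean_px_per_electron` (the sparsity idiom "N pixels per
#' electron per frame"); positions are uniform over the live (non-gap) area,
#' or proportional to an `intensity` rate map, with uniform subpixel jitter.
#'
#' @param geom A [detector_geometry()].
#' @param mean_px_per_electron Sparsity: detector pixels per electron per
#'   frame (> 1); 150 is a typical counting flux.
#' @param n_frames Number of raw frames (>= 1).
#' @param seed Integer seed; the same seed reproduces the stream exactly.
#' @param intensity Optional non-negative `width x height` matrix of
#'   relative arrival rates (gap rows are forced to zero).
#' @return An `event_list` tibble with columns `frame` (0-based), `x`, `y`
#'   (subpixel coordinates) and the geometry attached as attribute
#'   `geometry`.
#' @export
simulate_events <- function(geom, mean_px_per_electron = 150, n_frames = 1,
                            seed = 1, intensity = NULL) {
  stopifnot(inherits(geom, "detector_geometry"))
  if (mean_px_per_electron <= 1) stop_invalid("`mean_px_per_electron` must be > 1.")
  if (n_frames < 1) stop_invalid("`n_frames` must be >= 1.")
  w <- geom$width; h <- geom$height
  live_rows <- setdiff(0:(h - 1L), geom$gap_rows)
  mean_per_frame <- w * h / mean_px_per_electron

  use_map <- !is.null(intensity)
  if (use_map) {
    if (!is.matrix(intensity) || !all(dim(intensity) == c(w, h))) {
      stop_invalid("`intensity` must be a width x height matrix.")
    }
    if (any(intensity < 0)) stop_invalid("`intensity` must be non-negative.")
    map <- intensity
    if (length(geom$gap_rows)) map[, geom$gap_rows + 1L] <- 0
    if (sum(map) <= 0) stop_data("`intensity` map has no live flux.")
    prob <- as.vector(map) / sum(map)
  }

  with_seed(seed, {
    counts <- stats::rpois(n_frames, mean_per_frame)
    total <- sum(counts)
    if (use_map) {
      cell <- sample.int(w * h, total, replace = TRUE, prob = prob)
      px <- (cell - 1L) %% w
      py <- (cell - 1L) %/% w
      x <- px + stats::runif(total)
      y <- py + stats::runif(total)
    } else {
      x <- stats::runif(total, 0, w)
      y <- live_rows[sample.int(length(live_rows), total, replace = TRUE)] +
        stats::runif(total)
    }
    out <- tibble::new_tibble(
      tibble::tibble(frame = rep.int(seq_len(n_frames) - 1L, counts), x = x, y = y),
      class = "event_list"
    )
    attr(out, "geometry") <- geom
    out
  })
}

#' Count electron events into a dose-fractionated movie
#'
#' Post-processes a localized event stream the way raw detector frames are
#' converted to movies: events on hot pixels are discarded; events in the
#' same raw frame whose 3x3 pixel footprints overlap (pixel centres within
#' a Chebyshev distance of 2) are coincidence-handled, either merged into a
#' single event at their centroid (`overlap = "merge"`, the default loss
#' model) or discarded entirely (`overlap = "reject"`); surviving events
#' are accumulated into `fractions` movie frames on the physical pixel grid
#' or, using the subpixel coordinates, on a 2x super-resolution grid. Gap
#' rows are zero in every output frame. Counts are conserved exactly:
#' `events_in = counts_out + hot_discards + gap_discards + merge_losses`.
#'
#' @param events An `event_list` (see [simulate_events()]), or any data
#'   frame with `frame`, `x`, `y` plus a `geometry` attribute.
#' @param binning `"physical"` or `"super2x"`.
#' @param fractions Number of movie fractions; raw frames are split evenly
#'   and any remainder truncated. Must not exceed the raw frame count.
#' @param overlap `"merge"` or `"reject"`.
#' @return A `counted_movie`: integer array `[x, y, fraction]` with
#'   attributes `pixel_a` (NA unless known), `binning` and `tally`
#'   (named list of the count bookkeeping).
#' @export
count_events <- function(events, binning = c("physical", "super2x"),
                         fractions = 1, overlap = c("merge", "reject")) {
  binning <- match.arg(binning)
  overlap <- match.arg(overlap)
  geom <- attr(events, "geometry")
  if (is.null(geom)) stop_data("`events` must carry a `geometry` attribute.")
  if (!all(c("frame", "x", "y") %in% names(events))) {
    stop_data("`events` must have columns `frame`, `x`, `y`.")
  }
  n_raw <- if (nrow(events)) max(events$frame) + 1L else 0L
  if (fractions < 1) stop_invalid("`fractions` must be >= 1.")
  if (fractions > max(n_raw, 1L)) {
    stop_invalid("`fractions` exceeds the number of raw frames.")
  }

  w <- geom$width; h <- geom$height
  events_in <- nrow(events)

  px <- floor(events$x); py <- floor(events$y)
  hot <- logical(events_in)
  if (nrow(geom$hot_pixels)) {
    hotkey <- geom$hot_pixels$y * w + geom$hot_pixels$x
    hot <- (py * w + px) %in% hotkey
  }
  gap <- py %in% geom$gap_rows
  keep <- !hot & !gap
  hot_discards <- sum(hot)
  gap_discards <- sum(gap & !hot)

  ev <- tibble::tibble(frame = events$frame[keep], x = events$x[keep],
                       y = events$y[keep], px = px[keep], py = py[keep])

  merge_losses <- 0L
  if (nrow(ev)) {
    pieces <- split(ev, ev$frame)
    pieces <- lapply(pieces, function(fr) {
      cl <- cluster_events(fr$px, fr$py)
      sizes <- tabulate(cl)
      if (all(sizes <= 1L)) return(fr[, c("frame", "x", "y")])
      if (overlap == "merge") {
        out <- tibble::tibble(
          frame = fr$frame[1],
          x = as.vector(tapply(fr$x, cl, mean)),
          y = as.vector(tapply(fr$y, cl, mean))
        )
      } else {
        solo <- sizes[cl] == 1L
        out <- fr[solo, c("frame", "x", "y")]
      }
      out
    })
    counted <- dplyr::bind_rows(pieces)
    merge_losses <- nrow(ev) - nrow(counted)
  } else {
    counted <- ev[, c("frame", "x", "y")]
  }

  scale <- if (binning == "super2x") 2L else 1L
  ww <- w * scale; hh <- h * scale
  frames_per_frac <- max(n_raw %/% fractions, 1L)
  arr <- array(0L, dim = c(ww, hh, fractions))
  if (nrow(counted)) {
    frac <- counted$frame %/% frames_per_frac
    inside <- frac < fractions
    cx <- pmin(floor(counted$x * scale), ww - 1L)
    cy <- pmin(floor(counted$y * scale), hh - 1L)
    idx <- (frac * hh + cy) * ww + cx + 1L
    idx <- idx[inside]
    tab <- tabulate(idx, nbins = ww * hh * fractions)
    arr <- array(as.integer(tab), dim = c(ww, hh, fractions))
    truncated <- sum(!inside)
  } else {
    truncated <- 0L
  }
  # enforce the gap mask on the output grid
  if (length(geom$gap_rows)) {
    gap_out <- as.vector(outer(seq_len(scale) - 1L, geom$gap_rows * scale, "+")) + 1L
    arr[, gap_out, ] <- 0L
  }

  structure(
    arr,
    class = "counted_movie",
    binning = binning,
    geometry = geom,
    tally = list(events_in = events_in, hot_discards = hot_discards,
                 gap_discards = gap_discards, merge_losses = merge_losses,
                 truncated = truncated, counts_out = sum(arr))
  )
}

# Single-linkage clustering of events whose pixel centres are within
# Chebyshev distance 2 (overlapping 3x3 footprints). Union-find over a
# sweep sorted by x.
cluster_events <- function(px, py) {
  n <- length(px)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ord <- order(px, py)
  for (a in seq_len(n - 1L)) {
    i <- ord[a]
    for (b in (a + 1L):n) {
      j <- ord[b]
      if (px[j] - px[i] > 2L) break
      if (abs(py[j] - py[i]) <= 2L) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Coincidence-loss fraction of the counting pipeline
#'
#' Runs a seeded simulate-then-count round trip at uniform flux and returns
#' the fraction of incoming events lost to footprint overlap,
#' `(events_in - counts_out) / events_in`. With `overlap = "reject"` this
#' estimates the probability that an event has at least one same-frame
#' neighbour, which [coincidence_loss_approx()] predicts analytically.
#'
#' @inheritParams simulate_events
#' @param overlap Passed to [count_events()].
#' @return Loss fraction in `[0, 1]`.
#' @export
coincidence_loss_fraction <- function(geom, mean_px_per_electron = 150,
                                      n_frames = 10, seed = 1,
                                      overlap = c("reject", "merge")) {
  overlap <- match.arg(overlap)
  ev <- simulate_events(geom, mean_px_per_electron, n_frames, seed)
  mov <- count_events(ev, binning = "physical", fractions = 1, overlap = overlap)
  tally <- attr(mov, "tally")
  if (tally$events_in == 0) return(0)
  (tally$events_in - tally$counts_out) / tally$events_in
}

#' Analytic pair-overlap approximation to the coincidence loss
#'
#' For n events per frame uniform over the live pixels, the probability that
#' a given event has at least one neighbour within the 5x5 overlap kernel is
#' `1 - (1 - p)^(n-1)` with `p = 25 / live_pixels`; averaging over Poisson n
#' gives the expected rejected fraction at a given sparsity. Edge truncation
#' of the kernel is ignored (a ~1% relative overestimate on small
#' detectors).
#'
#' @param geom A [detector_geometry()].
#' @param mean_px_per_electron Sparsity (pixels per electron per frame).
#' @return Expected loss fraction in `[0, 1]` under reject-mode counting.
#' @export
coincidence_loss_approx <- function(geom, mean_px_per_electron = 150) {
  stopifnot(inherits(geom, "detector_geometry"))
  live <- geom$width * (geom$height - length(geom$gap_rows))
  p <- 25 / live
  mu <- geom$width * geom$height / mean_px_per_electron
  nmax <- max(10, ceiling(mu + 10 * sqrt(mu)))
  n <- 0:nmax
  pmf <- stats::dpois(n, mu)
  # event-weighted: a frame with n events contributes n events each with
  # neighbour probability 1 - (1-p)^(n-1)
  ev_w <- n * pmf / mu
  sum(ev_w * (1 - (1 - p)^pmax(n - 1, 0)))
}

#' Flag hot pixels from an event stream
#'
#' Helper for building the static hot-pixel list: counts events per pixel
#' over the whole stream and flags pixels whose totals exceed the mean by
#' more than `threshold_sd` standard deviations (Poisson scale,
#' `sqrt(mean)`).
#'
#' @param events An `event_list`.
#' @param threshold_sd Detection threshold in standard deviations (default 6).
#' @return A tibble with columns `x`, `y`, `count`.
#' @export
detect_hot_pixels <- function(events, threshold_sd = 6) {
  geom <- attr(events, "geometry")
  if (is.null(geom)) stop_data("`events` must carry a `geometry` attribute.")
  w <- geom$width; h <- geom$height
  px <- floor(events$x); py <- floor(events$y)
  idx <- py * w + px + 1
  tab <- tabulate(idx, nbins = w * h)
  live <- rep(TRUE, w * h)
  if (length(geom$gap_rows)) {
    live[as.vector(outer(seq_len(w), geom$gap_rows * w, "+"))] <- FALSE
  }
  mu <- mean(tab[live])
  thr <- mu + threshold_sd * sqrt(max(mu, 1e-12))
  hotidx <- which(tab > thr & live)
  tibble::tibble(
    x = (hotidx - 1L) %% w,
    y = (hotidx - 1L) %/% w,
    count = tab[hotidx]
  )
}

#' Write a counted movie as an MRCS stack
#'
#' @param movie A `counted_movie` from [count_events()].
#' @param path Output `.mrcs` path.
#' @param pixel_a Physical pixel size in Angstrom; halved automatically in
#'   the header for super-resolution movies.
#' @param mode MRC mode, 1 (int16, default) or 2 (float32).
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path, pixel_a = 1, mode = 1) {
  stopifnot(inherits(movie, "counted_movie"))
  px <- if (attr(movie, "binning") == "super2x") pixel_a / 2 else pixel_a
  write_mrc(unclass(movie), path, pixel_a = px, mode = mode)
}

#' Read and write event-list CSV files
#'
#' CSV dialect: header `frame,x,y`.
#'
#' @param path File path.
#' @param geom A [detector_geometry()] to attach on read.
#' @return `read_event_list()` returns an `event_list` tibble.
#' @export
read_event_list <- function(path, geom) {
  if (!file.exists(path)) stop_data(sprintf("Event file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("frame", "x", "y") %in% names(df))) {
    stop_data("Event CSV must have columns `frame`, `x`, `y`.")
  }
  if (any(df$x < 0 | df$x >= geom$width | df$y < 0 | df$y >= geom$height)) {
    stop_data("Event coordinates outside the detector.")
  }
  out <- tibble::new_tibble(tibble::as_tibble(df[, c("frame", "x", "y")]),
                            class = "event_list")
  attr(out, "geometry") <- geom
  out
}

#' @rdname read_event_list
#' @param events An `event_list` tibble.
#' @export
write_event_list <- function(events, path) {
  readr::write_csv(tibble::as_tibble(events)[, c("frame", "x", "y")], path,
                   progress = FALSE)
  invisible(path)
}
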