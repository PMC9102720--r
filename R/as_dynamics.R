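#' Start of the standard amnioserosa analysis window
#'
#' The AS measurement window begins when the dorsal gap is `gap_width` um
#' wide (50 um by default) and lasts `window_min` minutes (15 by default).
#'
#' @param hole A [hole_series()].
#' @param gap_width Gap width defining the window start (um).
#' @param window_min Window length (min).
#' @param require_full_window Error if the series ends before
#'   `start + window_min`?
#' @return 1-based frame index of the first frame with `W <= gap_width`.
#' @export
window_start <- function(hole, gap_width = 50, window_min = 15,
                         require_full_window = TRUE) {
  stopifnot(inherits(hole, "hole_series"), gap_width > 0)
  i <- which(hole$W <= gap_width)
  if (!length(i))
    stop("closure insufficient: hole width never reaches ", gap_width, " um")
  i <- i[1L]
  if (require_full_window && hole$t[i] + window_min > hole$t[length(hole$t)])
    stop("movie ends before the ", window_min,
         " min analysis window is complete")
  i
}

#' Select the most central amnioserosa cells
#'
#' Returns the `k` tracks whose centroids, at the given frame, lie nearest
#' the hole centroid (ties broken by smaller track id) -- the "six most
#' central AS cells" convention.
#'
#' @param tracks A [link_tracks()] result.
#' @param center Hole centroid as `c(x, y)` in um, or a [hole_series()]
#'   whose contour centroid at `frame` is used.
#' @param k Number of cells to select.
#' @param frame 1-based frame index at which centroids are evaluated
#'   (default: first frame).
#' @return A `cell_tracks` object with `k` tracks.
#' @export
select_central_cells <- function(tracks, center = c(0, 0), k = 6L, frame = 1L) {
  stopifnot(inherits(tracks, "cell_tracks"), k >= 0L)
  if (inherits(center, "hole_series")) {
    ct <- center$contours[[frame]]
    center <- if (is.null(ct)) c(0, 0) else polygon_centroid(ct)
  }
  alive <- Filter(function(tr) frame %in% tr$frames, tracks)
  if (length(alive) < k)
    stop("only ", length(alive), " tracks alive at frame ", frame,
         "; need ", k)
  if (k == 0L) {
    return(structure(list(), px_size = attr(tracks, "px_size"),
                     dt = attr(tracks, "dt"),
                     t0_frame = attr(tracks, "t0_frame"),
                     class = "cell_tracks"))
  }
  d <- vapply(alive, function(tr) {
    cen <- tr$centroid[match(frame, tr$frames), ]
    sqrt(sum((cen - center)^2))
  }, numeric(1L))
  ids <- vapply(alive, `[[`, integer(1L), "track_id")
  sel <- alive[order(d, ids)[seq_len(k)]]
  structure(sel, px_size = attr(tracks, "px_size"), dt = attr(tracks, "dt"),
            t0_frame = attr(tracks, "t0_frame"), class = "cell_tracks")
}

#' Normalized relative apical-area trace
#'
#' Normalizes an apical-area series over the analysis window to a zero-mean
#' relative change: `n(t) = A(t) / mean(A) - 1`.  This makes pulsation
#' amplitudes dimensionless and comparable across cells of different sizes,
#' and is the single place to swap in an alternative normalization.
#'
#' @param area Apical-area series (um^2) over the window; all positive.
#' @return Numeric vector `n(t)` with `mean(n) == 0`.
#' @export
normalize_trace <- function(area) {
  if (length(area) < 2L) stop("need at least 2 samples to normalize")
  if (any(!is.finite(area)) || any(area <= 0))
    stop("areas must be positive and finite")
  area / mean(area) - 1
}

#' Detect apical-area pulses in a normalized trace
#'
#' Finds local maxima with topographic prominence at least `prominence` and
#' reports the pulse count and mean pulse height in the window.  By default
#' a pulse height is peak-to-trough: the peak value minus the preceding
#' inter-pulse trough (a first peak with no interior trough before it uses
#' the trough that follows it, so a clean sinusoid of relative amplitude `a`
#' yields heights close to `2a`).  `mode = "peak-to-baseline"` instead
#' measures each peak against the zero mean of the normalized trace.
#' Extremum values are refined by three-point parabolic interpolation, which
#' removes most of the amplitude attenuation caused by sampling a smooth
#' pulse away from its true peak (up to 8% at 30-s sampling of a 230-s
#' pulse).
#'
#' @param n Normalized trace (uniform sampling assumed).
#' @param times Optional sample times (s); defaults to `0, 1, 2, ...`.
#' @param prominence Minimum topographic prominence for an accepted peak
#'   (default 0.02, i.e. 20% of the control pulse amplitude).
#' @param mode Pulse-height convention; see Details.
#' @return A `pulse_trace` object: list with `times`, `n`, `peaks` (indices),
#'   `prominences`, `heights`, `count`, `amplitude_mean` (0, flagged, when
#'   no pulse is found) and `no_pulse` flag.
#' @export
detect_pulses <- function(n, times = NULL, prominence = 0.02,
                          mode = c("peak-to-trough", "peak-to-baseline")) {
  mode <- match.arg(mode)
  if (length(n) < 3L) stop("need at least 3 samples to detect pulses")
  if (is.null(times)) times <- seq_along(n) - 1
  peaks <- .local_maxima(n)
  prom <- numeric(0)
  if (length(peaks)) {
    prom <- vapply(peaks, function(p) .prominence(n, p), numeric(1L))
    keep <- prom >= prominence
    peaks <- peaks[keep]
    prom <- prom[keep]
  }
  if (!length(peaks)) {
    out <- list(times = times, n = n, peaks = integer(0),
                prominences = numeric(0), heights = numeric(0), count = 0L,
                amplitude_mean = 0, no_pulse = TRUE, mode = mode)
    class(out) <- "pulse_trace"
    return(out)
  }
  peak_val <- vapply(peaks, function(p) .refine_extremum(n, p), numeric(1L))
  heights <- if (mode == "peak-to-baseline") {
    peak_val
  } else {
    trough_val <- function(from, to) {
      j <- from - 1L + which.min(n[from:to])
      .refine_extremum(n, j)
    }
    vapply(seq_along(peaks), function(i) {
      p <- peaks[i]
      trough <- if (i > 1L) {
        trough_val(peaks[i - 1L], p)
      } else {
        pre <- n[1L:p]
        has_interior_min <- p > 2L &&
          any(diff(sign(diff(pre))) > 0)   # a local minimum before the peak
        if (has_interior_min) {
          trough_val(1L, p)
        } else if (length(peaks) > 1L) {
          trough_val(p, peaks[2L])
        } else {
          min(pre)
        }
      }
      peak_val[i] - trough
    }, numeric(1L))
  }
  out <- list(times = times, n = n, peaks = peaks, prominences = prom,
              heights = heights, count = length(peaks),
              amplitude_mean = mean(heights), no_pulse = FALSE, mode = mode)
  class(out) <- "pulse_trace"
  out
}

# strict-left, non-strict-right interior local maxima
.local_maxima <- function(n) {
  k <- length(n)
  if (k < 3L) return(integer(0))
  which(n[2:(k - 1)] > n[1:(k - 2)] & n[2:(k - 1)] >= n[3:k]) + 1L
}

# parabolic (three-point) refinement of a sampled extremum's value,
# countering the attenuation of sampling a smooth pulse off-peak
.refine_extremum <- function(n, j) {
  if (j <= 1L || j >= length(n)) return(n[j])
  denom <- n[j - 1L] - 2 * n[j] + n[j + 1L]
  if (abs(denom) < 1e-12) return(n[j])
  delta <- 0.5 * (n[j - 1L] - n[j + 1L]) / denom
  if (abs(delta) > 1) return(n[j])
  n[j] - 0.25 * (n[j - 1L] - n[j + 1L]) * delta
}

# topographic prominence of peak p (window edges act as bases)
.prominence <- function(n, p) {
  left <- n[1L:p]
  higher <- which(left > n[p])
  lmin <- if (length(higher)) min(left[max(higher):p]) else min(left)
  right <- n[p:length(n)]
  higher <- which(right > n[p])
  rmin <- if (length(higher)) min(right[1L:min(higher)]) else min(right)
  n[p] - max(lmin, rmin)
}

#' @export
print.pulse_trace <- function(x, ...) {
  cat(sprintf("Pulse trace: %d samples, %d pulse(s), mean height %.4f%s\n",
              length(x$n), x$count, x$amplitude_mean,
              if (x$no_pulse) " (no pulse detected)" else ""))
  invisible(x)
}

#' @export
plot.pulse_trace <- function(x, ...) {
  graphics::plot(x$times, x$n, type = "l", xlab = "time (s)",
                 ylab = "normalized relative area", ...)
  if (length(x$peaks))
    graphics::points(x$times[x$peaks], x$n[x$peaks], pch = 19, col = "firebrick")
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Convex-hull shape index of a cell polygon
#'
#' `N = area(polygon) / area(convex hull(polygon))`, a dimensionless measure
#' of boundary convolution: `N = 1` for convex outlines, `N < 1` for wavy
#' ones.  Scale- and rotation-invariant; the hull is computed on the polygon
#' vertices, not on a raster.
#'
#' @param poly Two-column vertex matrix of a simple polygon.
#' @return The shape index, in `(0, 1]`.
#' @export
shape_index <- function(poly) {
  if (!is.matrix(poly) || nrow(poly) < 3L)
    stop("polygon must have at least 3 vertices")
  a <- polygon_area(poly)
  if (a <= 0) stop("degenerate polygon with zero area")
  h <- grDevices::chull(poly)
  hull_a <- polygon_area(poly[h, , drop = FALSE])
  min(a / hull_a, 1)
}

#' Amnioserosa cell area and perimeter at the window-start gap width
#'
#' Reports the polygon (shoelace) area and perimeter of each tracked cell at
#' the frame where the dorsal gap first reaches `gap_width` um.
#'
#' @param tracks A [link_tracks()] result (typically the selected central
#'   cells).
#' @param hole Optional [hole_series()] used to locate the window start;
#'   alternatively give `frame` directly.
#' @param gap_width Gap width (um) defining the measurement frame.
#' @param frame Optional explicit 1-based frame index, overriding `hole`.
#' @return A data.frame with `track_id`, `area` (um^2), `perimeter` (um).
#' @export
cell_area_at_gap <- function(tracks, hole = NULL, gap_width = 50, frame = NULL) {
  stopifnot(inherits(tracks, "cell_tracks"))
  if (is.null(frame)) {
    if (is.null(hole)) stop("give either a hole series or a frame index")
    frame <- window_start(hole, gap_width, require_full_window = FALSE)
  }
  rows <- lapply(tracks, function(tr) {
    k <- match(frame, tr$frames)
    if (is.na(k)) return(NULL)
    data.frame(track_id = tr$track_id, area = tr$area[k],
               perimeter = tr$perimeter[k])
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(track_id = integer(0), area = numeric(0),
                      perimeter = numeric(0))
  rownames(out) <- NULL
  out
}

#' Quantify amnioserosa pulsation for the central cells of a sheet movie
#'
#' End-to-end AS dynamics stage: extracts polygons, links tracks, selects
#' the `k` most central cells, normalizes each cell's apical-area series
#' over the window, and detects pulses.
#'
#' @param movie A [label_movie()] covering the 15-min analysis window.
#' @param center Hole/sheet centroid in um (default: image center).
#' @param k Number of central cells to analyze.
#' @param prominence Pulse-prominence threshold, see [detect_pulses()].
#' @param mode Pulse-height convention, see [detect_pulses()].
#' @return A list with `traces` (per-cell `pulse_trace`), `cells` (the
#'   selected `cell_tracks`), and `summary` (data.frame: `track_id`, `area`,
#'   `perimeter`, `shape_index` at window start, `amplitude`, `count`).
#' @export
quantify_pulsation <- function(movie, center = NULL, k = 6L,
                               prominence = 0.02,
                               mode = c("peak-to-trough", "peak-to-baseline")) {
  mode <- match.arg(mode)
  stopifnot(inherits(movie, "label_movie"))
  if (is.null(center)) {
    d <- dim(movie$frames[[1L]])
    center <- c((d[2L] - 1) / 2, (d[1L] - 1) / 2) * movie$px_size
  }
  tracks <- link_tracks(movie)
  full <- Filter(function(tr) length(tr$frames) == length(movie$frames), tracks)
  full <- structure(full, px_size = attr(tracks, "px_size"),
                    dt = attr(tracks, "dt"),
                    t0_frame = attr(tracks, "t0_frame"),
                    class = "cell_tracks")
  cells <- select_central_cells(full, center = center, k = k, frame = 1L)
  dt <- attr(cells, "dt")
  traces <- lapply(cells, function(tr) {
    n <- normalize_trace(tr$area)
    detect_pulses(n, times = (tr$frames - 1) * dt, prominence = prominence,
                  mode = mode)
  })
  summary <- do.call(rbind, lapply(seq_along(cells), function(i) {
    tr <- cells[[i]]
    data.frame(track_id = tr$track_id,
               area = tr$area[1L],
               perimeter = tr$perimeter[1L],
               shape_index = shape_index(tr$polygons[[1L]]),
               amplitude = traces[[i]]$amplitude_mean,
               count = traces[[i]]$count)
  }))
  list(traces = traces, cells = cells, summary = summary)
}
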