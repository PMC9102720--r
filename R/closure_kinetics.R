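#' Width and length of a dorsal-hole contour
#'
#' The hole length `L` is its extent along the anterior-posterior (AP) axis
#' and the width `W` its maximal extent perpendicular to it.  The AP axis is
#' the image x-axis by default; supply `ap_angle` (radians) when metadata
#' gives the embryo axis.
#'
#' @param contour Two-column vertex matrix (um), or `NULL`/empty for a
#'   closed hole.
#' @param ap_angle AP-axis angle relative to the x-axis (radians).
#' @return Named numeric `c(W, L)` in um; `c(0, 0)` for an empty contour.
#' @export
hole_dimensions <- function(contour, ap_angle = 0) {
  if (is.null(contour) || !length(contour)) return(c(W = 0, L = 0))
  stopifnot(is.matrix(contour), ncol(contour) == 2L)
  if (nrow(contour) >= 3L && .self_intersects(contour))
    stop("self-intersecting hole contour")
  if (ap_angle != 0) {
    R <- matrix(c(cos(-ap_angle), -sin(-ap_angle),
                  sin(-ap_angle), cos(-ap_angle)), 2L, 2L, byrow = TRUE)
    contour <- contour %*% t(R)
  }
  c(W = diff(range(contour[, 2L])), L = diff(range(contour[, 1L])))
}

# O(n^2) segment-crossing check; contours here are short (~100 vertices)
.self_intersects <- function(poly) {
  n <- nrow(poly)
  p <- rbind(poly, poly[1L, ])
  cross <- function(o, a, b) {
    (a[1L] - o[1L]) * (b[2L] - o[2L]) - (a[2L] - o[2L]) * (b[1L] - o[1L])
  }
  seg_int <- function(a1, a2, b1, b2) {
    d1 <- cross(b1, b2, a1); d2 <- cross(b1, b2, a2)
    d3 <- cross(a1, a2, b1); d4 <- cross(a1, a2, b2)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next   # closing edge shares a vertex with edge 1
      if (seg_int(p[i, ], p[i + 1L, ], p[j, ], p[j + 1L, ])) return(TRUE)
    }
  }
  FALSE
}

#' Leading-edge convergence speed
#'
#' Forward finite difference of the hole-width series,
#' `v(t_x) = (W(t_x) - W(t_x+1)) / dt`, smoothed with a 3-frame centered
#' moving average so that a "maximum convergence speed" is well defined on
#' discretized data.  The first and last difference, where the centered
#' window is undefined, are left unsmoothed.
#'
#' @param W Hole-width series (um).
#' @param dt Frame interval (min).
#' @param smooth Apply the 3-frame moving average?
#' @return Speed series (um/min) of length `length(W) - 1`, aligned with the
#'   left edge of each frame interval.
#' @export
convergence_speed <- function(W, dt, smooth = TRUE) {
  if (length(W) < 2L) stop("need at least 2 frames")
  stopifnot(dt > 0)
  raw <- -diff(W) / dt
  if (!smooth || length(raw) < 3L) return(raw)
  sm <- as.numeric(stats::filter(raw, rep(1 / 3, 3L), sides = 2L))
  sm[1L] <- raw[1L]
  sm[length(sm)] <- raw[length(raw)]
  sm
}

#' Zipping speed
#'
#' Exact per-frame finite difference of the hole-length series,
#' `v(t_x) = (length(t_x) - length(t_x+1)) / dt`; no smoothing by default.
#'
#' @param L Hole-length series (um).
#' @param dt Frame interval (min).
#' @return Speed series (um/min) of length `length(L) - 1`.
#' @export
zipping_speed <- function(L, dt) {
  if (length(L) < 2L) stop("need at least 2 frames")
  stopifnot(dt > 0)
  -diff(L) / dt
}

#' Duration of dorsal closure
#'
#' Time from timepoint zero (frame right after germ-band retraction) to the
#' first frame whose hole width is at or below the closure threshold.
#'
#' @param W Hole-width series (um).
#' @param dt Frame interval (min).
#' @param t0_frame 1-based index of timepoint zero.
#' @param closed_thresh Width at/below which the hole counts as closed (um);
#'   0 for exact synthetic geometry, a small positive value (e.g. 2) for
#'   pixelated input.
#' @return Closure duration (min).
#' @export
closure_duration <- function(W, dt, t0_frame = 1L, closed_thresh = 0) {
  stopifnot(dt > 0, t0_frame >= 1L, t0_frame <= length(W))
  i <- which(W <= closed_thresh + sqrt(.Machine$double.eps))
  if (!length(i))
    stop("hole never closes (final width ", signif(W[length(W)], 4), " um)")
  (i[1L] - t0_frame) * dt
}

#' Length-to-width ratio at a reference gap width
#'
#' `L/W` evaluated where the hole width first crosses `width` um (30 by
#' default), with `W` and `L` interpolated linearly between the bracketing
#' frames to reduce frame-interval quantization.
#'
#' @param W,L Hole width and length series (um).
#' @param width Reference width (um).
#' @return Dimensionless length-to-width ratio at the crossing.
#' @export
lw_ratio_at <- function(W, L, width = 30) {
  stopifnot(length(W) == length(L), width > 0)
  i <- which(W <= width)
  if (!length(i)) stop("hole width never reaches ", width, " um")
  i <- i[1L]
  if (i == 1L) return(L[1L] / W[1L])
  # linear interpolation on the bracketing interval
  f <- (W[i - 1L] - width) / (W[i - 1L] - W[i])
  Ls <- L[i - 1L] + f * (L[i] - L[i - 1L])
  Ls / width
}

#' Average kinetic curves across embryos
#'
#' Pointwise mean and sample standard deviation over embryos at each aligned
#' timepoint (curves aligned at timepoint zero).  Shorter curves are treated
#' as missing beyond their end, so each timepoint averages the embryos still
#' observed there.
#'
#' @param curves List of numeric vectors, one per embryo, aligned at index 1.
#' @return A list with `mean`, `sd` (sample sd; 0 where only one embryo
#'   contributes) and `n_curves` per timepoint.
#' @export
average_curves <- function(curves) {
  if (!length(curves)) stop("no curves to average")
  len <- max(vapply(curves, length, integer(1L)))
  m <- matrix(NA_real_, length(curves), len)
  for (i in seq_along(curves)) m[i, seq_along(curves[[i]])] <- curves[[i]]
  n_at <- colSums(!is.na(m))
  mu <- colMeans(m, na.rm = TRUE)
  sd <- apply(m, 2L, stats::sd, na.rm = TRUE)
  sd[n_at <= 1L] <- 0
  list(mean = mu, sd = sd, n_curves = n_at)
}

#' Closure-kinetics summary of one embryo
#'
#' Runs the full kinetic stage on a hole series: convergence and zipping
#' speed curves, closure duration, length-to-width ratio at 30 um, mean
#' zipping speed over the first 84 min (the most dynamic zipping phase) and
#' first-phase maximum zipping speed.
#'
#' @param hole A [hole_series()].
#' @param closed_thresh Closure threshold (um), see [closure_duration()].
#' @param lw_width Reference width (um) for the length-to-width ratio.
#' @param zip_mean_upto Upper limit (min) of the early-phase zipping mean.
#' @param first_phase_upto Upper limit (min) for the first-phase maximum
#'   zipping speed.
#' @return A `kinetic_summary` object: list with `t` (speed-curve times),
#'   `v_conv`, `v_zip` (um/min), `duration` (min), `lw_ratio_at_30`,
#'   `mean_zip_0_84`, `max_conv`, `conv_t0`, `zip_t0`, `max_zip_first_phase`.
#' @export
kinetic_summary <- function(hole, closed_thresh = 0, lw_width = 30,
                            zip_mean_upto = 84, first_phase_upto = 150) {
  stopifnot(inherits(hole, "hole_series"))
  v_conv <- convergence_speed(hole$W, hole$dt)
  v_zip <- zipping_speed(hole$L, hole$dt)
  tv <- hole$t[-length(hole$t)] - hole$t[hole$t0_frame]
  early <- tv >= 0 & tv <= zip_mean_upto
  first <- tv >= 0 & tv <= first_phase_upto
  out <- list(
    t = tv, v_conv = v_conv, v_zip = v_zip,
    duration = closure_duration(hole$W, hole$dt, hole$t0_frame, closed_thresh),
    lw_ratio_at_30 = lw_ratio_at(hole$W, hole$L, lw_width),
    mean_zip_0_84 = mean(v_zip[early]),
    max_conv = max(v_conv[tv >= 0]),
    conv_t0 = v_conv[which(tv == 0)],
    zip_t0 = v_zip[which(tv == 0)],
    max_zip_first_phase = max(v_zip[first])
  )
  class(out) <- "kinetic_summary"
  out
}

#' @export
print.kinetic_summary <- function(x, ...) {
  cat("Dorsal-closure kinetics\n")
  cat(sprintf("  duration:                %.1f min\n", x$duration))
  cat(sprintf("  convergence speed:       %.3f um/min at t0, max %.3f um/min\n",
              x$conv_t0, x$max_conv))
  cat(sprintf("  zipping speed:           %.3f um/min at t0, first-phase max %.3f um/min\n",
              x$zip_t0, x$max_zip_first_phase))
  cat(sprintf("  mean zipping (0-84 min): %.3f um/min\n", x$mean_zip_0_84))
  cat(sprintf("  length/width at 30 um:   %.2f\n", x$lw_ratio_at_30))
  invisible(x)
}

#' @export
plot.kinetic_summary <- function(x, ...) {
  graphics::matplot(x$t, cbind(x$v_conv, x$v_zip), type = "l", lty = 1,
                    col = c("firebrick", "steelblue"),
                    xlab = "time (min)", ylab = "speed (um/min)", ...)
  graphics::legend("topleft", c("LE convergence", "zipping"),
                   col = c("firebrick", "steelblue"), lty = 1, bty = "n")
  invisible(x)
}

#' Hole series from per-frame contours
#'
#' Measures `W(t)` and `L(t)` with [hole_dimensions()] on each stored
#' contour, producing a [hole_series()] from contour data alone (e.g. traced
#' outlines read from file).
#'
#' @param contours List of per-frame contour matrices (um) or `NULL`.
#' @param dt Frame interval (min).
#' @param t0_frame 1-based index of timepoint zero.
#' @param ap_angle AP-axis angle (radians), see [hole_dimensions()].
#' @return A [hole_series()].
#' @export
hole_series_from_contours <- function(contours, dt, t0_frame = 1L,
                                      ap_angle = 0) {
  wl <- vapply(contours, hole_dimensions, numeric(2L), ap_angle = ap_angle)
  hole_series(t = (seq_along(contours) - 1L) * dt, W = wl[1L, ], L = wl[2L, ],
              contours = contours, dt = dt, t0_frame = t0_frame)
}
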