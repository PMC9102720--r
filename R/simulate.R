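#' Simulate dorsal-hole closure geometry
#'
#' Renders the noise-free (or vertex-jittered) outline of the eye-shaped
#' dorsal hole over time for a genotype preset.  The hole width follows
#' `W(t) = W0 - integral of v_conv` and the length `L(t) = L0 - integral of
#' v_zip`, both clipped at zero, sampled every `dt_closure` minutes from
#' timepoint zero (end of germ-band retraction) until one frame past closure.
#' The contour at each frame is two symmetric arcs meeting at the canthi at
#' `(+-L/2, 0)`, with dorsoventral width `W` at the midline.
#'
#' @param preset An [make_preset()] object.
#' @param seed Integer seed controlling vertex jitter (only used when
#'   `noise = TRUE`).
#' @param noise Add Gaussian vertex jitter with sd `noise_sd * px_size`?
#' @param n_arc Number of contour vertices per arc.
#' @return A `hole_series` object: list with `t` (min), `W`, `L` (um),
#'   `contours` (list of two-column vertex matrices in um, origin at the hole
#'   centroid; `NULL` once closed), `dt` (min) and `t0_frame` (1-based index
#'   of timepoint zero).
#' @examples
#' hs <- simulate_closure(make_preset("WT"))
#' hs$W[1]  # initial width, 98.2 um
#' @export
simulate_closure <- function(preset, seed = 1L, noise = FALSE, n_arc = 60L) {
  validate_preset(preset)
  dt <- preset$dt_closure
  n_frames <- ceiling(preset$duration / dt) + 1L
  t <- (seq_len(n_frames) - 1L) * dt
  W <- preset$W0 - profile_integral(preset$conv_knots, t)
  L <- preset$L0 - profile_integral(preset$zip_knots, t)
  eps <- 1e-9
  W <- ifelse(W < eps, 0, W)
  L <- ifelse(L < eps, 0, L)
  set.seed(seed)
  contours <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    if (W[i] <= 0 || L[i] <= 0) next
    poly <- .eye_contour(W[i], L[i], n_arc)
    if (noise) {
      poly <- poly + matrix(stats::rnorm(length(poly), 0,
                                         preset$noise_sd * preset$px_size),
                            ncol = 2L)
    }
    contours[[i]] <- poly
  }
  hole_series(t = t, W = W, L = L, contours = contours, dt = dt, t0_frame = 1L)
}

# eye-shaped contour: cosine arcs meeting at the canthi, CCW orientation
.eye_contour <- function(W, L, n_arc) {
  xs <- seq(-L / 2, L / 2, length.out = n_arc + 1L)
  y <- (W / 2) * cos(pi * xs / L)
  upper <- cbind(rev(xs), rev(y))      # right canthus -> left canthus
  lower <- cbind(xs[-c(1L, n_arc + 1L)], -y[-c(1L, n_arc + 1L)])
  rbind(lower, upper)[, , drop = FALSE]
}

#' Construct a dorsal-hole time series
#'
#' Container for the per-frame hole contour and its width/length series.
#'
#' @param t Frame times (min).
#' @param W Dorsoventral hole width per frame (um).
#' @param L Anterior-posterior hole length per frame (um).
#' @param contours List of per-frame contour polygons (two-column matrices,
#'   um) or `NULL` for closed/absent frames.
#' @param dt Frame interval (min).
#' @param t0_frame 1-based index of timepoint zero.
#' @return A `hole_series` object.
#' @export
hole_series <- function(t, W, L, contours = NULL, dt = NULL, t0_frame = 1L) {
  if (is.null(dt)) dt <- if (length(t) > 1L) t[2L] - t[1L] else 1
  stopifnot(length(W) == length(t), length(L) == length(t),
            dt > 0, t0_frame >= 1L, t0_frame <= length(t))
  if (is.null(contours)) contours <- vector("list", length(t))
  structure(list(t = t, W = W, L = L, contours = contours,
                 dt = dt, t0_frame = as.integer(t0_frame)),
            class = "hole_series")
}

#' @export
print.hole_series <- function(x, ...) {
  cat(sprintf("Dorsal-hole series: %d frames every %g min, W0 = %.1f um, L0 = %.1f um\n",
              length(x$t), x$dt, x$W[1L], x$L[1L]))
  closed <- which(x$W <= 0)
  if (length(closed))
    cat(sprintf("  closed from t = %g min (frame %d)\n",
                x$t[closed[1L]], closed[1L]))
  invisible(x)
}

#' @export
plot.hole_series <- function(x, ...) {
  graphics::matplot(x$t, cbind(x$W, x$L), type = "l", lty = 1,
                    col = c("firebrick", "steelblue"),
                    xlab = "time (min)", ylab = "extent (um)", ...)
  graphics::legend("topright", c("width W", "length L"),
                   col = c("firebrick", "steelblue"), lty = 1, bty = "n")
  invisible(x)
}

#' Simulate a pulsating amnioserosa cell sheet
#'
#' Renders a label-image movie of a polygonal AS cell sheet over the
#' standard 15-minute analysis window.  Cells are laid out as a centroidal
#' (hexagonal) tessellation clipped to an elliptical patch; cell `i`'s
#' polygon is scaled about its centroid so its apical area follows
#' `A_i(t) = A0_i * (1 + a * sin(2*pi*t*freq_mult/T + phi_i))` with phases
#' `phi_i` drawn uniformly from `[0, 2*pi)`.  A sinusoidal radial boundary
#' perturbation of relative amplitude `waviness` makes the noise-free cell
#' outlines wavy (non-convex), as seen in control embryos.
#'
#' @param preset An [make_preset()] object.
#' @param seed Integer seed for phases, waviness phases and jitter.
#' @param noise Add Gaussian vertex jitter (sd `noise_sd * px_size`) before
#'   rasterization?
#' @param window_min Length of the rendered window (min); frames are sampled
#'   every `dt_as` seconds from 0 to `window_min * 60` inclusive.
#' @return A list with components:
#'   \describe{
#'     \item{movie}{a [label_movie()] (frames, `px_size`, `dt = dt_as`).}
#'     \item{truth}{ground truth: `centers` (um), `A0` (um^2), `phase`,
#'       `area` (cells x frames matrix of true areas), `amplitude` (true
#'       normalized peak-to-trough pulse amplitude, `2 * pulse_amp`),
#'       `count` (true number of area maxima interior to the window,
#'       per cell).}
#'   }
#' @export
simulate_as_sheet <- function(preset, seed = 1L, noise = FALSE, window_min = 15) {
  validate_preset(preset)
  set.seed(seed)
  d <- 20                               # cell center spacing, um
  apothem <- d / 2
  centers <- .hex_centers(preset$n_cells, d, aspect = 1.3)
  n <- nrow(centers)
  a <- preset$pulse_amp
  w <- preset$waviness
  # damp the boundary perturbation until the largest possible radial
  # excursion stays inside the cell's lattice tile (no polygon overlap)
  circum <- apothem * 2 / sqrt(3)
  while (0.70 * circum * (1 + w) * sqrt(1 + a) >= 0.99 * apothem) {
    w <- 0.7 * w
    warning("cell boundary perturbation would overlap neighbours; ",
            "damping waviness to ", signif(w, 3))
  }
  theta <- 2 * pi * (seq_len(72L) - 1L) / 72L
  r_hex <- apothem / cos(((theta + pi / 6) %% (pi / 3)) - pi / 6)
  phase <- stats::runif(n, 0, 2 * pi)
  wphase <- stats::runif(n, 0, 2 * pi)
  base_r <- lapply(seq_len(n), function(i)
    0.70 * r_hex * (1 + w * sin(5 * theta + wphase[i])))
  A0 <- vapply(seq_len(n), function(i)
    polygon_area(cbind(centers[i, 1L] + base_r[[i]] * cos(theta),
                       centers[i, 2L] + base_r[[i]] * sin(theta))),
    numeric(1L))

  t_s <- seq(0, window_min * 60, by = preset$dt_as)
  omega <- 2 * pi * preset$freq_mult / preset$pulse_period
  px <- preset$px_size
  ext <- apply(abs(centers), 2L, max) + circum + 4 * px
  nc <- 2L * ceiling(ext[1L] / px) + 4L
  nr <- 2L * ceiling(ext[2L] / px) + 4L
  xs <- (seq_len(nc) - (nc + 1) / 2) * px   # pixel-center x (um)
  ys <- (seq_len(nr) - (nr + 1) / 2) * px

  frames <- vector("list", length(t_s))
  area_true <- matrix(NA_real_, n, length(t_s))
  for (k in seq_along(t_s)) {
    img <- matrix(0L, nr, nc)
    f <- sqrt(1 + a * sin(omega * t_s[k] + phase))
    for (i in seq_len(n)) {
      vx <- centers[i, 1L] + f[i] * base_r[[i]] * cos(theta)
      vy <- centers[i, 2L] + f[i] * base_r[[i]] * sin(theta)
      if (noise) {
        vx <- vx + stats::rnorm(length(vx), 0, preset$noise_sd * px)
        vy <- vy + stats::rnorm(length(vy), 0, preset$noise_sd * px)
      }
      ci <- range(findInterval(range(vx), xs + px / 2) + c(0L, 1L))
      ri <- range(findInterval(range(vy), ys + px / 2) + c(0L, 1L))
      ci <- pmin(pmax(ci, 1L), nc)
      ri <- pmin(pmax(ri, 1L), nr)
      grid <- expand.grid(x = xs[ci[1L]:ci[2L]], y = ys[ri[1L]:ri[2L]])
      inside <- mgcv::in.out(cbind(c(vx, vx[1L]), c(vy, vy[1L])),
                             as.matrix(grid))
      if (any(inside)) {
        rows <- rep(ri[1L]:ri[2L], each = ci[2L] - ci[1L] + 1L)
        cols <- rep(ci[1L]:ci[2L], times = ri[2L] - ri[1L] + 1L)
        idx <- cbind(rows, cols)[inside, , drop = FALSE]
        img[idx] <- i
      }
      area_true[i, k] <- A0[i] * (1 + a * sin(omega * t_s[k] + phase[i]))
    }
    frames[[k]] <- img
  }
  count_true <- vapply(phase, function(ph)
    .sin_maxima_count(omega, ph, max(t_s)), integer(1L))
  movie <- label_movie(frames, px_size = px, dt = preset$dt_as, t0_frame = 1L)
  truth <- list(centers = centers, A0 = A0, phase = phase,
                times = t_s, area = area_true,
                amplitude = 2 * a, count = count_true)
  list(movie = movie, truth = truth)
}

# hexagonal lattice centers, the n nearest to the origin in elliptical metric
.hex_centers <- function(n, d, aspect = 1.3) {
  m <- ceiling(sqrt(n)) + 3L
  ij <- expand.grid(i = -m:m, j = -m:m)
  x <- d * (ij$i + ij$j / 2)
  y <- d * sqrt(3) / 2 * ij$j
  r <- sqrt((x / aspect)^2 + y^2)
  ord <- order(r, x, y)
  cbind(x = x[ord[seq_len(n)]], y = y[ord[seq_len(n)]])
}

# number of strict interior maxima of sin(omega*t + phase) on [0, t_max]
.sin_maxima_count <- function(omega, phase, t_max) {
  # maxima where omega*t + phase = pi/2 + 2*pi*k
  k <- seq(ceiling((omega * 0 + phase - pi / 2) / (2 * pi)),
           floor((omega * t_max + phase - pi / 2) / (2 * pi)))
  tm <- (pi / 2 + 2 * pi * k - phase) / omega
  sum(tm > 0 & tm < t_max)
}

#' Simulate filopodia annotations for six engrailed stripes
#'
#' Generates per-stripe filopodium polylines the way they would be traced
#' manually with a line tool: counts per stripe are Poisson, total lengths
#' are Gamma distributed, and each filopodium is a short polyline anchored in
#' its stripe and pointing roughly toward the opposing leading edge.
#'
#' @param preset An [make_preset()] object (used only for its name).
#' @param seed Integer seed.
#' @param lambda Mean filopodia count per stripe.
#' @param shape,mean_len Gamma shape and mean (um) of filopodium length.
#' @return A list with `stripes` (list of 6; each a list of two-column
#'   polyline matrices in um) and `truth` (`counts` per stripe, `lengths`
#'   vector of generated lengths in um).
#' @export
simulate_filopodia <- function(preset, seed = 1L, lambda = 8, shape = 4,
                               mean_len = 3) {
  set.seed(seed)
  counts <- stats::rpois(6L, lambda)
  stripe_w <- 10                         # um per en stripe
  stripes <- vector("list", 6L)
  lengths <- numeric(0)
  for (s in seq_len(6L)) {
    polys <- vector("list", counts[s])
    if (counts[s] > 0L) {
      len <- stats::rgamma(counts[s], shape = shape, rate = shape / mean_len)
      lengths <- c(lengths, len)
      for (f in seq_len(counts[s])) {
        base <- c(stats::runif(1, (s - 1) * stripe_w, s * stripe_w),
                  stats::runif(1, 0, 2))
        ang <- pi / 2 + stats::rnorm(3L, 0, 0.25)
        seg <- len[f] * c(0.4, 0.35, 0.25)
        pts <- rbind(base,
                     base + seg[1L] * c(cos(ang[1L]), sin(ang[1L])))
        pts <- rbind(pts, pts[2L, ] + seg[2L] * c(cos(ang[2L]), sin(ang[2L])))
        pts <- rbind(pts, pts[3L, ] + seg[3L] * c(cos(ang[3L]), sin(ang[3L])))
        # rescale so the traced polyline length equals the drawn length
        pl <- sum(sqrt(rowSums(diff(pts)^2)))
        pts <- sweep(sweep(pts, 2L, pts[1L, ]) * (len[f] / pl),
                     2L, pts[1L, ], "+")
        polys[[f]] <- unname(pts)
      }
    }
    stripes[[s]] <- polys
  }
  list(stripes = stripes, truth = list(counts = counts, lengths = lengths))
}

#' Shoelace area of a simple polygon
#'
#' Signed-area magnitude of a polygon given as an ordered vertex matrix
#' (closing edge implied).
#'
#' @param poly Two-column matrix of vertices.
#' @return Area in squared input units.
#' @export
polygon_area <- function(poly) {
  abs(.signed_area(poly))
}

.signed_area <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  sum(x * y2 - x2 * y) / 2
}

#' Perimeter of a polygon
#'
#' @param poly Two-column matrix of vertices (closing edge implied).
#' @return Perimeter in input units.
#' @export
polygon_perimeter <- function(poly) {
  d <- diff(rbind(poly, poly[1L, , drop = FALSE]))
  sum(sqrt(rowSums(d^2)))
}

polygon_centroid <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  cr <- x * y2 - x2 * y
  A <- sum(cr) / 2
  if (abs(A) < 1e-12) return(colMeans(poly))
  c(sum((x + x2) * cr), sum((y + y2) * cr)) / (6 * A)
}
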