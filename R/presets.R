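#' Genotype presets for the synthetic-embryo generator
#'
#' An `embryo_preset` bundles every parameter needed to render a synthetic
#' dorsal-closure movie for one genotype: piecewise-linear speed profiles for
#' leading-edge (LE) convergence and zipping, the amnioserosa (AS) sheet
#' geometry and pulsation parameters, and the imaging calibration.
#'
#' Speed profiles are given as knot tables `(time min, speed um/min)` and
#' interpolated linearly between knots.  The initial hole width `W0` and
#' length `L0` are not stored: they are derived as the trapezoid integral of
#' the respective speed profile over `[0, duration]`, so that the hole closes
#' exactly at the last knot time in the noise-free case.
#'
#' @section Available genotypes:
#' `WT` (control), and the formin mutants `DAAM`, `frl`, `form3`, `dia`.
#' Their knot tables encode the published closure durations (174, 219, 204,
#' 245 and 274 min), initial and maximal LE convergence speeds, and zipping
#' speed profiles; mutant pulsation amplitude is reduced to 45% of the
#' control value.
#'
#' @param name Genotype label, one of `"WT"`, `"DAAM"`, `"frl"`, `"form3"`,
#'   `"dia"`.
#' @return An object of class `embryo_preset`: a list with fields `name`,
#'   `conv_knots`, `zip_knots` (two-column matrices, minutes and um/min),
#'   `duration` (min), `n_cells`, `pulse_amp`, `pulse_period` (s),
#'   `freq_mult`, `waviness`, `noise_sd`, `px_size` (um/px), `dt_closure`
#'   (min), `dt_as` (s), and derived `W0`, `L0` (um).
#' @examples
#' p <- make_preset("WT")
#' p$duration   # 174 min
#' p$W0         # 98.2 um, the integral of the convergence-speed profile
#' @export
make_preset <- function(name) {
  if (!is.character(name) || length(name) != 1L || !name %in% names(.preset_table)) {
    stop("unknown preset '", paste(name, collapse = ","),
         "'; valid names: ", paste(names(.preset_table), collapse = ", "))
  }
  p <- .preset_table[[name]]
  p$name <- name
  p$conv_knots <- .knots(p$conv_knots)
  p$zip_knots <- .knots(p$zip_knots)
  p$duration <- unname(p$conv_knots[nrow(p$conv_knots), 1L])
  p$W0 <- unname(profile_integral(p$conv_knots, p$duration))
  p$L0 <- unname(profile_integral(p$zip_knots, p$duration))
  class(p) <- "embryo_preset"
  validate_preset(p)
  p
}

# knot tables: columns t (min), v (um/min)
.knots <- function(x) {
  m <- matrix(unlist(x), ncol = 2L, byrow = TRUE,
              dimnames = list(NULL, c("t", "v")))
  m
}

.preset_table <- list(
  WT = list(
    conv_knots = list(c(0, 0.55), c(40, 1.12), c(100, 0.30), c(174, 0.30)),
    zip_knots  = list(c(0, 0.7), c(84, 1.5), c(90, 1.7), c(150, 1.7), c(174, 2.5)),
    n_cells = 12L, pulse_amp = 0.10, pulse_period = 230, freq_mult = 1.0,
    waviness = 0.15, noise_sd = 0.5, px_size = 0.4, dt_closure = 4, dt_as = 30
  ),
  frl = list(
    conv_knots = list(c(0, 0.45), c(60, 0.71), c(120, 0.71), c(204, 0.0)),
    zip_knots  = list(c(0, 0.4), c(84, 0.4), c(158, 1.1), c(204, 1.3)),
    n_cells = 12L, pulse_amp = 0.045, pulse_period = 230, freq_mult = 0.9,
    waviness = 0.15, noise_sd = 0.5, px_size = 0.4, dt_closure = 4, dt_as = 30
  ),
  DAAM = list(
    conv_knots = list(c(0, 0.50), c(40, 0.95), c(100, 0.25), c(219, 0.05)),
    zip_knots  = list(c(0, 0.3), c(84, 1.1), c(90, 1.2), c(150, 0.9), c(219, 1.5)),
    n_cells = 12L, pulse_amp = 0.045, pulse_period = 230, freq_mult = 0.9,
    waviness = 0.03, noise_sd = 0.5, px_size = 0.4, dt_closure = 4, dt_as = 30
  ),
  form3 = list(
    conv_knots = list(c(0, 0.28), c(40, 0.85), c(120, 0.20), c(245, 0.10)),
    zip_knots  = list(c(0, 0.3), c(84, 1.1), c(90, 1.1), c(160, 0.9), c(215, 0.9), c(245, 1.5)),
    n_cells = 12L, pulse_amp = 0.045, pulse_period = 230, freq_mult = 1.1,
    waviness = 0.03, noise_sd = 0.5, px_size = 0.4, dt_closure = 4, dt_as = 30
  ),
  dia = list(
    conv_knots = list(c(0, 0.27), c(52, 0.80), c(140, 0.20), c(274, 0.10)),
    zip_knots  = list(c(0, 0.6), c(84, 0.4), c(138, 1.1), c(274, 1.3)),
    n_cells = 12L, pulse_amp = 0.045, pulse_period = 230, freq_mult = 1.1,
    waviness = 0.03, noise_sd = 0.5, px_size = 0.4, dt_closure = 4, dt_as = 30
  )
)

#' Validate an embryo preset
#'
#' Checks the structural invariants of an [make_preset()] object: knot times
#' strictly increasing and starting at 0, non-negative speeds, pulsation
#' amplitude in `[0, 0.5)`, positive period and calibration, at least six AS
#' cells, and positive derived initial hole dimensions.
#'
#' @param p An `embryo_preset`.
#' @return `p`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_preset <- function(p) {
  stopifnot(inherits(p, "embryo_preset"))
  for (k in list(p$conv_knots, p$zip_knots)) {
    if (k[1L, "t"] != 0) stop("first knot time must be 0")
    if (any(diff(k[, "t"]) <= 0)) stop("knot times must be strictly increasing")
    if (any(k[, "v"] < 0)) stop("speeds must be non-negative")
  }
  if (p$zip_knots[nrow(p$zip_knots), "t"] != p$duration)
    stop("zip profile must end at the closure duration")
  if (p$pulse_amp < 0 || p$pulse_amp >= 0.5) stop("pulse_amp must lie in [0, 0.5)")
  if (p$pulse_period <= 0) stop("pulse_period must be positive")
  if (p$n_cells < 6L) stop("n_cells must be at least 6")
  if (p$px_size <= 0 || p$dt_closure <= 0 || p$dt_as <= 0)
    stop("calibration (px_size, dt_closure, dt_as) must be positive")
  if (p$W0 <= 0 || p$L0 <= 0) stop("derived W0/L0 must be positive")
  invisible(p)
}

#' @export
print.embryo_preset <- function(x, ...) {
  cat("Synthetic embryo preset '", x$name, "'\n", sep = "")
  cat(sprintf("  closure duration: %g min   W0 = %.1f um   L0 = %.1f um\n",
              x$duration, x$W0, x$L0))
  cat(sprintf("  AS sheet: %d cells, pulse amplitude %.3f, period %g s (x%.2f)\n",
              x$n_cells, x$pulse_amp, x$pulse_period, x$freq_mult))
  cat(sprintf("  sampling: closure every %g min, AS every %g s, %g um/px\n",
              x$dt_closure, x$dt_as, x$px_size))
  invisible(x)
}

#' Evaluate a piecewise-linear speed profile
#'
#' @param knots Two-column matrix `(t, v)` with strictly increasing times.
#' @param t Times (min) at which to evaluate; values beyond the last knot
#'   give speed 0 (the hole is closed).
#' @return Speeds (um/min) at `t`.
#' @export
profile_speed <- function(knots, t) {
  v <- stats::approx(knots[, 1L], knots[, 2L], xout = t, rule = 2L)$y
  v[t > knots[nrow(knots), 1L]] <- 0
  v
}

#' Integrate a piecewise-linear speed profile
#'
#' Trapezoid integration of the profile from 0 to `t` (exact for a
#' piecewise-linear integrand).  Used to derive the initial hole width/length
#' from a speed profile and to compute noise-free `W(t)`, `L(t)`.
#'
#' @inheritParams profile_speed
#' @param t Upper limits (min); may be a vector.
#' @return Integral values (um) at each `t`.
#' @export
profile_integral <- function(knots, t) {
  tk <- knots[, 1L]
  vk <- knots[, 2L]
  # cumulative integral at each knot
  ck <- c(0, cumsum(diff(tk) * (vk[-length(vk)] + vk[-1L]) / 2))
  vapply(t, function(ti) {
    if (ti >= tk[length(tk)]) return(ck[length(ck)])
    i <- findInterval(ti, tk)
    vi <- vk[i] + (vk[i + 1L] - vk[i]) * (ti - tk[i]) / (tk[i + 1L] - tk[i])
    ck[i] + (ti - tk[i]) * (vk[i] + vi) / 2
  }, numeric(1L))
}

#' Write a preset to YAML
#'
#' @param p An `embryo_preset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_preset_yaml <- function(p, path) {
  stopifnot(inherits(p, "embryo_preset"))
  out <- unclass(p)
  out$conv_knots <- apply(p$conv_knots, 1L, as.list)
  out$zip_knots <- apply(p$zip_knots, 1L, as.list)
  yaml::write_yaml(out, path)
  invisible(path)
}
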