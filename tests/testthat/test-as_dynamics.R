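test_that("the analysis window opens at the 50-um gap", {
  p <- make_preset("WT")
  hs <- simulate_closure(p)
  ws <- window_start(hs)
  # oracle: dense scan of the piecewise-linear width
  tt <- seq(0, p$duration, by = 0.001)
  Wt <- p$W0 - profile_integral(p$conv_knots, tt)
  t_cross <- tt[which(Wt <= 50)[1]]
  expect_equal(ws, which(hs$t >= t_cross)[1])
  expect_lte(hs$W[ws], 50)
  expect_gt(hs$W[ws - 1], 50)

  # boundary: W(0) = 50 um gives frame 1
  h0 <- hole_series(t = c(0, 4), W = c(50, 40), L = c(100, 90), dt = 4)
  expect_equal(window_start(h0, require_full_window = FALSE), 1L)
  # movie ending before start + 15 min
  expect_error(window_start(h0), "window")
  # hole never small enough
  h1 <- hole_series(t = c(0, 4), W = c(90, 80), L = c(100, 90), dt = 4)
  expect_error(window_start(h1), "closure insufficient")
})

test_that("central-cell selection picks the k nearest centroids, ties by id", {
  centers <- rbind(c(0, 1), c(1, 0), c(-1, 0), c(0, -1), c(2, 2), c(-2, -2),
                   c(40, 40))  # one far peripheral cell
  tr <- fake_tracks(centers)
  sel <- select_central_cells(tr, center = c(0, 0), k = 6L)
  expect_setequal(vapply(sel, `[[`, integer(1), "track_id"), 1:6)
  # exactly k tracks: all returned
  sel6 <- select_central_cells(fake_tracks(centers[1:6, ]), k = 6L)
  expect_length(sel6, 6L)
  # ties broken by smaller track id
  tied <- fake_tracks(rbind(c(1, 0), c(0, 1), c(-1, 0)))
  s1 <- select_central_cells(tied, center = c(0, 0), k = 2L)
  expect_equal(vapply(s1, `[[`, integer(1), "track_id"), c(1L, 2L))
  expect_length(select_central_cells(tr, k = 0L), 0L)
  expect_error(select_central_cells(fake_tracks(centers[1:4, ]), k = 6L),
               "4 tracks")
})

test_that("normalization gives a zero-mean relative area change", {
  expect_equal(normalize_trace(rep(7, 10)), rep(0, 10))
  # sinusoid sampled evenly over whole periods recovers itself to 1e-6
  tt <- (0:22) * 10   # one full 230-s period at 10-s sampling
  A <- 100 * (1 + 0.1 * sin(2 * pi * tt / 230))
  expect_equal(normalize_trace(A), 0.1 * sin(2 * pi * tt / 230),
               tolerance = 1e-6)
  expect_equal(mean(normalize_trace(runif(20, 50, 150))), 0, tolerance = 1e-12)
  expect_error(normalize_trace(100), "2 samples")
  expect_error(normalize_trace(c(10, -1)), "positive")
})

test_that("pulse detection recovers a sinusoid's count and peak-to-trough height", {
  t <- seq(0, 900, by = 30)
  n <- 0.1 * sin(2 * pi * t / 230)
  pt <- detect_pulses(n, times = t)
  expect_equal(pt$count, 4L)
  expect_lt(abs(pt$amplitude_mean - 0.2), 0.01)
  expect_true(all(pt$times[pt$peaks] > 0 & pt$times[pt$peaks] < 900))

  flat <- detect_pulses(rep(0, 31))
  expect_equal(flat$count, 0L)
  expect_equal(flat$amplitude_mean, 0)
  expect_true(flat$no_pulse)
  expect_error(detect_pulses(c(0, 1)), "3 samples")

  # peak-to-baseline mode measures each peak against the zero mean
  pb <- detect_pulses(n, times = t, mode = "peak-to-baseline")
  expect_lt(abs(pb$amplitude_mean - 0.1), 0.005)
})

test_that("peak prominences match the independent signal-processing oracle", {
  fx <- pulse_fixture()
  pt <- detect_pulses(fx$trace, prominence = 0.02)
  expect_equal(pt$peaks, fx$peaks)
  expect_equal(pt$prominences, fx$prominences, tolerance = 1e-6)
  # raising the threshold drops the weakest peak
  pt2 <- detect_pulses(fx$trace, prominence = 0.05)
  expect_equal(pt2$peaks, fx$peaks[-1])
})

test_that("the shape index is the polygon/convex-hull area ratio", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(shape_index(sq), 1.0)
  star <- rbind(c(2, 0), c(0.5, 0.5), c(0, 2), c(-0.5, 0.5), c(-2, 0),
                c(-0.5, -0.5), c(0, -2), c(0.5, -0.5))
  expect_equal(polygon_area(star), 4)
  expect_equal(shape_index(star), 0.5)
  expect_error(shape_index(star[1:2, ]), "3 vertices")
  expect_error(shape_index(cbind(c(0, 1, 2), c(0, 0, 0))), "zero area")
})

test_that("the shape index is scale- and rotation-invariant and 1 iff convex", {
  set.seed(99)
  for (rep in 1:20) {
    poly <- random_star_polygon()
    N <- shape_index(poly)
    expect_gt(N, 0)
    expect_lte(N, 1)
    # invariance
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
    expect_equal(shape_index(3.7 * poly %*% R), N, tolerance = 1e-9)
    # the hull of any polygon is convex, so its index is 1
    hull <- poly[grDevices::chull(poly), ]
    expect_equal(shape_index(hull), 1.0, tolerance = 1e-12)
  }
})

test_that("cell area and perimeter are reported at the window-start frame", {
  expect_equal(polygon_area(cbind(c(0, 4, 0), c(0, 0, 3))), 6.0)
  expect_equal(polygon_perimeter(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))), 4.0)
  tr <- fake_tracks(rbind(c(0, 0), c(3, 0)), areas = c(4, 9))
  out <- cell_area_at_gap(tr, frame = 1L)
  expect_equal(out$area, c(4, 9))
  expect_equal(out$perimeter, c(8, 12))
  expect_error(cell_area_at_gap(tr), "hole series or a frame")
})

test_that("pulsation parameters are recovered from a rendered control sheet", {
  p <- make_preset("WT")
  sh <- simulate_as_sheet(p, seed = 1L)
  q <- quantify_pulsation(sh$movie)
  expect_equal(nrow(q$summary), 6L)
  # amplitude = 2a within 5% for every analyzed cell
  expect_true(all(abs(q$summary$amplitude - 2 * p$pulse_amp) <=
                    0.05 * 2 * p$pulse_amp))
  # count within floor/ceil of the window-frequency product
  expected <- 900 * p$freq_mult / p$pulse_period
  expect_true(all(q$summary$count %in% c(floor(expected), ceiling(expected))))
  # wavy control cells are non-convex but valid
  expect_true(all(q$summary$shape_index > 0 & q$summary$shape_index < 1))
  # areas within 2% of generator truth at the window start
  d <- dim(sh$movie$frames[[1]])
  off <- c((d[2] - 1) / 2, (d[1] - 1) / 2) * sh$movie$px_size
  for (cell in q$cells) {
    cen <- cell$centroid[1, ] - off
    i <- which.min(colSums((t(sh$truth$centers) - cen)^2))
    expect_lt(abs(cell$area[1] - sh$truth$area[i, 1]) / sh$truth$area[i, 1],
              0.02)
  }
})

test_that("halving the generative amplitude halves the recovered amplitude", {
  p <- make_preset("WT")
  q1 <- quantify_pulsation(simulate_as_sheet(p, seed = 2L)$movie)
  p2 <- p
  p2$pulse_amp <- p$pulse_amp / 2
  q2 <- quantify_pulsation(simulate_as_sheet(p2, seed = 2L)$movie)
  ratio <- mean(q2$summary$amplitude) / mean(q1$summary$amplitude)
  expect_equal(ratio, 0.5, tolerance = 0.05)
})
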