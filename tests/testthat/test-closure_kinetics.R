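test_that("hole dimensions are AP-axis extents, invariant to supplied rotation", {
  th <- seq(0, 2 * pi, length.out = 200)[-200]
  ell <- cbind(50 * cos(th), 20 * sin(th))   # 100 long x 40 wide
  wl <- hole_dimensions(ell)
  expect_equal(unname(wl["W"]), 40, tolerance = 0.1)
  expect_equal(unname(wl["L"]), 100, tolerance = 0.1)

  expect_equal(hole_dimensions(NULL), c(W = 0, L = 0))
  expect_equal(hole_dimensions(matrix(numeric(0), 0, 2)), c(W = 0, L = 0))

  a <- pi / 7
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  wl_rot <- hole_dimensions(ell %*% t(R), ap_angle = a)
  expect_equal(wl_rot, wl, tolerance = 1e-9)

  bowtie <- rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2))
  expect_error(hole_dimensions(bowtie), "self-intersecting")
})

test_that("convergence speed is the smoothed width decrement rate", {
  expect_equal(convergence_speed(c(98.2, 94.2), dt = 4), 1.0)
  expect_equal(convergence_speed(rep(60, 10), dt = 4), rep(0, 9))
  expect_error(convergence_speed(60, dt = 4), "2 frames")
  # interior values are 3-frame averages of the raw differences
  W <- c(100, 95, 92, 88, 81, 80)
  raw <- -diff(W) / 2
  sm <- convergence_speed(W, dt = 2)
  expect_equal(sm[2], mean(raw[1:3]))
  expect_equal(sm[3], mean(raw[2:4]))
  expect_equal(sm[c(1, 5)], raw[c(1, 5)])
})

test_that("zipping speed is exactly the per-frame finite difference", {
  expect_equal(zipping_speed(c(100, 96), dt = 4), 1.0)
  expect_equal(zipping_speed(c(120, 112, 108), dt = 4), c(2.0, 1.0))
  expect_error(zipping_speed(100, dt = 4), "2 frames")
  # loop-free independent recomputation on random series
  set.seed(3)
  for (rep in 1:10) {
    L <- cumsum(rnorm(50, 0, 2)) + 200
    dt <- runif(1, 0.5, 5)
    v <- zipping_speed(L, dt)
    oracle <- vapply(seq_len(49), function(x) (L[x] - L[x + 1]) / dt,
                     numeric(1))
    expect_equal(v, oracle, tolerance = 1e-12)
  }
})

test_that("closure duration counts frames from timepoint zero to the closed frame", {
  W <- seq(60, 0, by = -4)   # 1 um/min at dt = 4
  expect_equal(closure_duration(W, dt = 4), 60)
  expect_equal(closure_duration(W, dt = 4, t0_frame = 6L), 60 - 5 * 4)
  expect_error(closure_duration(c(60, 50, 40), dt = 4), "never closes")
  # configurable closure threshold for pixelated input
  expect_equal(closure_duration(c(10, 5, 1.5, 0.5), dt = 4,
                                closed_thresh = 2), 8)
})

test_that("the length-to-width ratio interpolates at the 30-um crossing", {
  expect_equal(lw_ratio_at(c(40, 20), c(90, 60)), 2.5)
  W <- c(50, 30, 10)
  expect_equal(lw_ratio_at(W, W * 1.7), 1.7, tolerance = 1e-9)
  expect_error(lw_ratio_at(c(40, 50, 60), c(90, 95, 99)), "never reaches")
})

test_that("curve averaging is the pointwise mean with sample sd over embryos", {
  one <- average_curves(list(c(2, 4, 6)))
  expect_equal(one$mean, c(2, 4, 6))
  expect_equal(one$sd, c(0, 0, 0))
  same <- average_curves(list(c(1, 2), c(1, 2)))
  expect_equal(same$mean, c(1, 2))
  expect_equal(same$sd, c(0, 0))
  two <- average_curves(list(c(1, 1), c(3, 3)))
  expect_equal(two$mean, c(2, 2))
  expect_equal(two$sd, c(sqrt(2), sqrt(2)))
  # shorter curves are padded as missing
  mix <- average_curves(list(c(1, 1, 1), c(3, 3)))
  expect_equal(mix$mean, c(2, 2, 1))
  expect_equal(mix$n_curves, c(2L, 2L, 1L))
  expect_error(average_curves(list()), "no curves")
})

test_that("recovered speed curves track the generating profiles at the knots", {
  for (nm in c("WT", "form3")) {
    p <- make_preset(nm)
    hs <- simulate_closure(p)
    k <- kinetic_summary(hs)
    # discretization error at most one frame interval in time and the
    # corresponding speed change in value
    for (j in seq_len(nrow(p$conv_knots) - 1L)) {
      tk <- p$conv_knots[j, "t"]
      vk <- p$conv_knots[j, "v"]
      near <- abs(k$t - tk) <= p$dt_closure
      expect_lt(min(abs(k$v_conv[near] - vk)), 0.06)
    }
    # integral conservation: recovered speed curve re-integrates to W0
    expect_equal(sum(k$v_conv) * p$dt_closure, p$W0,
                 tolerance = 0.01 * p$W0)
    expect_equal(sum(k$v_zip) * p$dt_closure, p$L0, tolerance = 1e-9)
    # duration within one frame interval of the preset
    expect_lte(abs(k$duration - p$duration), p$dt_closure)
  }
})

test_that("contour-only input reproduces the width/length series", {
  p <- make_preset("WT")
  hs <- simulate_closure(p)
  hs2 <- hole_series_from_contours(hs$contours, dt = hs$dt)
  open <- hs$W > 0 & hs$L > 0
  expect_equal(hs2$W[open], hs$W[open], tolerance = 1e-9)
  expect_equal(hs2$L[open], hs$L[open], tolerance = 1e-9)
})
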