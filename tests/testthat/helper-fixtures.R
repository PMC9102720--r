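# Shared fixtures and independent oracle helpers.

# Fixed samples for the statistics oracle tests (reproducible under the
# default Mersenne-Twister RNG).
stat_fixtures <- function() {
  set.seed(42)
  x_norm <- round(rnorm(40, 10, 2), 6)
  x_exp <- round(rexp(40, 1), 6)
  set.seed(7)
  g <- list(WT = round(rnorm(10, 10, 1.5), 6),
            DAAM = round(rnorm(8, 11.2, 1.5), 6),
            frl = round(rnorm(9, 9.1, 1.5), 6),
            form3 = round(rnorm(7, 12.0, 1.5), 6))
  g$WT[1:2] <- 10
  g$frl[1:2] <- 10
  list(x_norm = x_norm, x_exp = x_exp, groups = g,
       counts = matrix(c(50, 3, 10, 32), 2, 2, byrow = TRUE))
}

# Reference values computed with an independent implementation
# (scipy.stats 1.17: normaltest, kruskal, dunnett, f_oneway,
# chi2_contingency(correction=False); Dunn z from rankdata + the
# tie-corrected normal formula) on the stat_fixtures() data, frozen.
stat_oracle <- list(
  normaltest_norm = list(k2 = 0.671681641342163, p = 0.7147368680965321),
  normaltest_exp = list(k2 = 48.56810401482952, p = 2.8416475736243944e-11),
  kruskal = list(H = 14.809710350858047, p = 0.0019867010731353814),
  dunn = list(
    DAAM = list(z = 2.997880744275654, p_unadj = 0.0027186403296633396,
                p_adj = 0.008155920988990019),
    frl = list(z = 0.26975785237276056, p_unadj = 0.7873465499934921,
               p_adj = 1.0),
    form3 = list(z = 2.718049332282655, p_unadj = 0.006566804635573409,
                 p_adj = 0.019700413906720227)),
  dunnett = list(stat = c(3.6697251409666007, -0.12217958989854684,
                          2.6081245413896066),
                 p = c(0.002637941620409978, 0.9987717220923175,
                       0.03790750998142578)),
  anova = list(F = 7.01733489272184, p = 0.0010318424920656326),
  chisq = list(stat = 50.09316305138408, p = 1.4661695105625408e-12)
)

# Noisy pulsation trace with reference peaks/prominences frozen from
# scipy.signal.find_peaks(prominence = 0.02).
pulse_fixture <- function() {
  set.seed(11)
  trace <- round(0.08 * sin(2 * pi * (0:30) * 30 / 230 + 0.7) +
                   0.015 * rnorm(31), 6)
  list(trace = trace,
       peaks = c(2L, 9L, 18L, 25L),
       prominences = c(0.037622, 0.159170, 0.172541, 0.164018))
}

# Independent convex hull (Jarvis march / gift wrapping), used as the
# brute-force oracle for the shape index.
jarvis_hull <- function(pts) {
  n <- nrow(pts)
  start <- which.min(pts[, 1L] + 1e-9 * pts[, 2L])
  hull <- integer(0)
  cur <- start
  repeat {
    hull <- c(hull, cur)
    cand <- setdiff(seq_len(n), cur)
    nxt <- cand[1L]
    for (j in cand[-1L]) {
      cr <- (pts[nxt, 1L] - pts[cur, 1L]) * (pts[j, 2L] - pts[cur, 2L]) -
        (pts[nxt, 2L] - pts[cur, 2L]) * (pts[j, 1L] - pts[cur, 1L])
      d_nxt <- sum((pts[nxt, ] - pts[cur, ])^2)
      d_j <- sum((pts[j, ] - pts[cur, ])^2)
      if (cr < 0 || (abs(cr) < 1e-12 && d_j > d_nxt)) nxt <- j
    }
    cur <- nxt
    if (cur == start) break
  }
  pts[hull, , drop = FALSE]
}

shoelace <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

# random star-shaped polygon around the origin (simple by construction)
random_star_polygon <- function(n_vertices = 24L, wavy = TRUE) {
  theta <- sort(runif(n_vertices, 0, 2 * pi))
  r <- if (wavy) runif(n_vertices, 0.5, 1.5) else rep(1, n_vertices)
  cbind(r * cos(theta), r * sin(theta))
}

# label frame with a filled axis-aligned rectangle
rect_frame <- function(nr, nc, r0, r1, c0, c1, label = 1L) {
  f <- matrix(0L, nr, nc)
  f[r0:r1, c0:c1] <- label
  f
}

# hand-built cell_tracks object for unit tests that don't need a movie
fake_tracks <- function(centers, areas = NULL, px_size = 1, dt = 30) {
  n <- nrow(centers)
  if (is.null(areas)) areas <- rep(1, n)
  trks <- lapply(seq_len(n), function(i) {
    sq <- cbind(c(-0.5, 0.5, 0.5, -0.5), c(-0.5, -0.5, 0.5, 0.5)) *
      sqrt(areas[i])
    poly <- sweep(sq, 2L, centers[i, ], "+")
    list(track_id = i, frames = 1L, labels = i, polygons = list(poly),
         area = shoelace(poly), perimeter = 4 * sqrt(areas[i]),
         centroid = matrix(centers[i, ], 1L))
  })
  structure(trks, px_size = px_size, dt = dt, t0_frame = 1L,
            class = "cell_tracks")
}
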