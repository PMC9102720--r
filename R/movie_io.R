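#' Calibrated label-image movies
#'
#' A `label_movie` holds a segmented time-lapse movie as a list of 2-D
#' non-negative integer matrices (label 0 = background) together with its
#' spatial and temporal calibration.  Pixel `[r, c]` has its center at
#' `((c - 1) * px_size, (r - 1) * px_size)` um.
#'
#' @param frames List of integer matrices, all the same shape.
#' @param px_size Pixel size (um/px), positive.
#' @param dt Frame interval (s), positive.
#' @param t0_frame 1-based index of timepoint zero (frame right after
#'   germ-band retraction).
#' @return A `label_movie` object.
#' @export
label_movie <- function(frames, px_size, dt, t0_frame = 1L) {
  if (!length(frames)) stop("movie must contain at least one frame")
  dims <- vapply(frames, dim, integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    stop("all frames must have the same shape")
  for (f in frames) {
    if (any(f < 0)) stop("labels must be non-negative")
    if (max(abs(f - round(f))) > 1e-9) stop("pixels must be integer labels")
  }
  if (!is.numeric(px_size) || px_size <= 0) stop("px_size must be positive")
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive")
  t0_frame <- as.integer(t0_frame)
  if (t0_frame < 1L || t0_frame > length(frames))
    stop("t0_frame out of range")
  structure(list(frames = lapply(frames, function(f) {
    storage.mode(f) <- "integer"; f
  }), px_size = px_size, dt = dt, t0_frame = t0_frame),
  class = "label_movie")
}

#' @export
print.label_movie <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf("Label movie: %d frames of %d x %d px, %g um/px, every %g s\n",
              length(x$frames), d[1L], d[2L], x$px_size, x$dt))
  invisible(x)
}

#' Read a multi-page TIFF label movie
#'
#' @param path Path to a multi-page TIFF with integer pixel type.
#' @inheritParams label_movie
#' @return A [label_movie()].
#' @export
read_label_movie <- function(path, px_size, dt, t0_frame = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  for (p in pages) {
    if (max(abs(p - round(p))) > 1e-9)
      stop("non-integer pixel type: label movies must be integer-valued")
    if (any(p < 0))
      stop("non-integer or unsupported pixel type: ",
           "negative values after decoding")
  }
  label_movie(lapply(pages, round), px_size = px_size, dt = dt,
              t0_frame = t0_frame)
}

#' Write a label movie as a 16-bit multi-page TIFF
#'
#' @param movie A [label_movie()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_movie <- function(movie, path) {
  stopifnot(inherits(movie, "label_movie"))
  mx <- max(vapply(movie$frames, max, numeric(1L)))
  if (mx > 65535) stop("labels exceed 16-bit range")
  tiff::writeTIFF(lapply(movie$frames, function(f) f / 65535), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' Extract one boundary polygon per label
#'
#' Traces the outer boundary of every labeled region with sub-pixel
#' (marching-squares) contour extraction at the 0.5 level between region and
#' background, in the movie's um coordinate frame.  The polygon area agrees
#' with the pixel-count area to within ~1.5 px^2 for 4-connected regions.
#'
#' @param frame Integer label matrix.
#' @param px_size Pixel size (um/px).
#' @return Named list mapping label to a CCW-oriented two-column vertex
#'   matrix (um).  Background-only frames give an empty list.  A label whose
#'   pixels fall into several connected components keeps only the largest
#'   boundary ring, with a warning.
#' @export
polygons_from_labels <- function(frame, px_size) {
  stopifnot(px_size > 0)
  labs <- sort(setdiff(unique(as.vector(frame)), 0L))
  out <- vector("list", length(labs))
  names(out) <- as.character(labs)
  for (i in seq_along(labs)) {
    lb <- labs[i]
    idx <- which(frame == lb, arr.ind = TRUE)
    r0 <- max(min(idx[, 1L]) - 1L, 0L); r1 <- min(max(idx[, 1L]) + 1L, nrow(frame) + 1L)
    c0 <- max(min(idx[, 2L]) - 1L, 0L); c1 <- min(max(idx[, 2L]) + 1L, ncol(frame) + 1L)
    # padded indicator crop so boundary contours always close
    nr <- r1 - r0 + 1L; nc <- c1 - c0 + 1L
    ind <- matrix(0, nr, nc)
    rr <- idx[, 1L] - r0 + 1L; cc <- idx[, 2L] - c0 + 1L
    ind[cbind(rr, cc)] <- 1
    xs <- (c0:c1 - 1) * px_size       # x runs along columns
    ys <- (r0:r1 - 1) * px_size
    cl <- grDevices::contourLines(x = ys, y = xs, z = ind, levels = 0.5)
    if (!length(cl)) next
    polys <- lapply(cl, function(ct) cbind(ct$y, ct$x))  # -> (x, y)
    areas <- vapply(polys, polygon_area, numeric(1L))
    if (length(polys) > 1L) {
      warning("label ", lb, " has ", length(polys),
              " boundary components; keeping the largest")
    }
    poly <- polys[[which.max(areas)]]
    # drop duplicated closing vertex if present
    if (all(abs(poly[1L, ] - poly[nrow(poly), ]) < 1e-12))
      poly <- poly[-nrow(poly), , drop = FALSE]
    if (.signed_area(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), ]
    out[[i]] <- poly
  }
  out[!vapply(out, is.null, logical(1L))]
}

#' Link labels across frames into cell tracks
#'
#' Greedy bipartite matching between consecutive frames by descending
#' intersection-over-union (IoU) of the labeled pixel sets.  A match is
#' accepted iff IoU >= `iou_min`; ties are broken by larger IoU, then by
#' smaller incoming label.  Unmatched labels start or terminate tracks.  AS
#' cells move far less than their diameter per 30-s frame, so greedy
#' matching is sufficient (and replaceable).
#'
#' @param movie A [label_movie()] with at least two frames.
#' @param iou_min Minimum IoU to accept a link.
#' @return An object of class `cell_tracks`: a list of tracks, each a list
#'   with `track_id`, `frames` (contiguous 1-based indices), `polygons`
#'   (per-frame vertex matrices, um), `area`, `perimeter` (um^2, um) and
#'   `centroid` (two-column matrix), plus attributes `px_size`, `dt`,
#'   `t0_frame`.
#' @export
link_tracks <- function(movie, iou_min = 0.5) {
  stopifnot(inherits(movie, "label_movie"))
  nF <- length(movie$frames)
  if (nF < 2L) stop("need at least 2 frames to link tracks")
  polys <- lapply(movie$frames, polygons_from_labels, px_size = movie$px_size)

  tracks <- list()
  next_id <- 1L
  open_track <- function(frame, label) {
    id <- next_id; next_id <<- next_id + 1L
    tracks[[id]] <<- list(track_id = id, frames = integer(0),
                          labels = integer(0), polygons = list())
    id
  }
  # active: map current-frame label -> track id
  active <- integer(0)
  lab1 <- as.integer(names(polys[[1L]]))
  active <- stats::setNames(vapply(lab1, function(l) open_track(1L, l),
                                   integer(1L)), lab1)
  append_obs <- function(id, frame, label) {
    tr <- tracks[[id]]
    tr$frames <- c(tr$frames, frame)
    tr$labels <- c(tr$labels, label)
    tr$polygons <- c(tr$polygons, polys[[frame]][as.character(label)])
    tracks[[id]] <<- tr
  }
  for (l in lab1) append_obs(active[[as.character(l)]], 1L, l)

  for (f in 2L:nF) {
    m <- .iou_pairs(movie$frames[[f - 1L]], movie$frames[[f]])
    m <- m[m[, "iou"] >= iou_min, , drop = FALSE]
    m <- m[order(-m[, "iou"], m[, "to"]), , drop = FALSE]
    used_from <- character(0); used_to <- character(0)
    new_active <- integer(0)
    if (nrow(m)) for (k in seq_len(nrow(m))) {
      from <- as.character(m[k, "from"]); to <- as.character(m[k, "to"])
      if (from %in% used_from || to %in% used_to) next
      if (!from %in% names(active)) next
      used_from <- c(used_from, from); used_to <- c(used_to, to)
      id <- active[[from]]
      new_active[to] <- id
      append_obs(id, f, as.integer(to))
    }
    for (l in setdiff(names(polys[[f]]), used_to)) {
      id <- open_track(f, as.integer(l))
      new_active[l] <- id
      append_obs(id, f, as.integer(l))
    }
    active <- new_active
  }
  tracks <- lapply(tracks, function(tr) {
    tr$polygons <- unname(tr$polygons)
    tr$area <- vapply(tr$polygons, polygon_area, numeric(1L))
    tr$perimeter <- vapply(tr$polygons, polygon_perimeter, numeric(1L))
    tr$centroid <- t(vapply(tr$polygons, polygon_centroid, numeric(2L)))
    tr
  })
  structure(tracks, px_size = movie$px_size, dt = movie$dt,
            t0_frame = movie$t0_frame, class = "cell_tracks")
}

# IoU for every overlapping label pair between two label frames
.iou_pairs <- function(f1, f2) {
  n1 <- tabulate(f1[f1 > 0L])
  n2 <- tabulate(f2[f2 > 0L])
  both <- f1 > 0L & f2 > 0L
  if (!any(both)) {
    return(matrix(numeric(0), 0L, 3L,
                  dimnames = list(NULL, c("from", "to", "iou"))))
  }
  key <- (as.numeric(f1[both]) - 1) * (max(f2) + 1) + as.numeric(f2[both])
  tab <- table(key)
  keys <- as.numeric(names(tab))
  from <- floor(keys / (max(f2) + 1)) + 1
  to <- keys - (from - 1) * (max(f2) + 1)
  inter <- as.numeric(tab)
  iou <- inter / (n1[from] + n2[to] - inter)
  cbind(from = from, to = to, iou = iou)
}

#' @export
print.cell_tracks <- function(x, ...) {
  spans <- vapply(x, function(tr) length(tr$frames), integer(1L))
  cat(sprintf("%d cell tracks (span %d-%d frames), %g um/px, dt = %g s\n",
              length(x), min(spans), max(spans),
              attr(x, "px_size"), attr(x, "dt")))
  invisible(x)
}

#' Write cell tracks to a long-format CSV
#'
#' One row per track, frame and vertex: `track_id, frame, vertex, x, y,
#' area, perimeter`.
#'
#' @param tracks A [link_tracks()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  rows <- do.call(rbind, lapply(tracks, function(tr) {
    do.call(rbind, lapply(seq_along(tr$frames), function(k) {
      p <- tr$polygons[[k]]
      data.frame(track_id = tr$track_id, frame = tr$frames[k],
                 vertex = seq_len(nrow(p)), x = p[, 1L], y = p[, 2L],
                 area = tr$area[k], perimeter = tr$perimeter[k])
    }))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
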