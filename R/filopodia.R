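#' Frames inside the leading-edge separation window
#'
#' Filopodia are scored when the two leading edges are between `lo` and `hi`
#' um apart (closed interval, 30-50 um by default).
#'
#' @param W Hole-width series (um).
#' @param lo,hi Separation bounds (um).
#' @return Integer vector of 1-based frame indices with `lo <= W <= hi`.
#' @export
in_measurement_window <- function(W, lo = 30, hi = 50) {
  stopifnot(lo <= hi)
  idx <- which(W >= lo & W <= hi)
  if (!length(idx))
    stop("no frames in separation window [", lo, ", ", hi, "] um")
  idx
}

#' Polyline length
#'
#' Sum of Euclidean segment lengths of a traced filopodium.
#'
#' @param pts Two-column matrix of polyline vertices (um).
#' @return Length in um.
#' @export
polyline_length <- function(pts) {
  stopifnot(is.matrix(pts), ncol(pts) == 2L, nrow(pts) >= 2L)
  sum(sqrt(rowSums(diff(pts)^2)))
}

#' Filopodia counts and lengths per engrailed stripe
#'
#' Summarizes filopodium polyline annotations over the six en-Gal4 stripes
#' of one embryo.  The per-embryo statistics used for genotype comparisons
#' are the mean count across the six stripes and the mean filopodium length.
#' An empty stripe contributes a zero count and no lengths.
#'
#' @param stripes List of exactly six stripes, each a list of two-column
#'   polyline matrices (um).  A filopodium crossing stripes is annotated in
#'   the stripe containing its base.
#' @return A list with `count` (per-stripe counts), `lengths` (all lengths,
#'   um), `mean_count` (per-embryo mean count per stripe) and `mean_length`
#'   (um; `NA` if no filopodium was annotated).
#' @export
filopodia_stats <- function(stripes) {
  if (!is.list(stripes) || length(stripes) != 6L)
    stop("expected exactly 6 stripes, got ", length(stripes))
  count <- vapply(stripes, length, integer(1L))
  lengths <- unlist(lapply(stripes, function(s)
    vapply(s, polyline_length, numeric(1L))))
  if (is.null(lengths)) lengths <- numeric(0)
  list(count = count, lengths = lengths, mean_count = mean(count),
       mean_length = if (length(lengths)) mean(lengths) else NA_real_)
}

#' Write filopodia annotations to CSV
#'
#' Long format: `embryo, stripe, filopodium_id, vertex, x, y`.
#'
#' @param stripes List of six stripes of polylines (see [filopodia_stats()]).
#' @param path Output CSV path.
#' @param embryo Embryo identifier recorded in the file.
#' @return `path`, invisibly.
#' @export
write_filopodia_csv <- function(stripes, path, embryo = 1L) {
  rows <- do.call(rbind, lapply(seq_along(stripes), function(s) {
    do.call(rbind, lapply(seq_along(stripes[[s]]), function(f) {
      p <- stripes[[s]][[f]]
      data.frame(embryo = embryo, stripe = s, filopodium_id = f,
                 vertex = seq_len(nrow(p)), x = p[, 1L], y = p[, 2L])
    }))
  }))
  if (is.null(rows))
    rows <- data.frame(embryo = integer(0), stripe = integer(0),
                       filopodium_id = integer(0), vertex = integer(0),
                       x = numeric(0), y = numeric(0))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read filopodia annotations from CSV
#'
#' Inverse of [write_filopodia_csv()].
#'
#' @param path CSV path.
#' @return List of six stripes of polyline matrices.
#' @export
read_filopodia_csv <- function(path) {
  d <- utils::read.csv(path)
  stripes <- lapply(1:6, function(s) {
    ds <- d[d$stripe == s, , drop = FALSE]
    lapply(split(ds, ds$filopodium_id), function(df) {
      df <- df[order(df$vertex), , drop = FALSE]
      unname(cbind(df$x, df$y))
    })
  })
  lapply(stripes, unname)
}
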