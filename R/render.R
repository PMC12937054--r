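#' Render an EIC profile as a standardized image
#'
#' Draws the chronogram as an axis-free line plot on a white background and
#' rasterises it to a fixed 224 x 224 x 3 array in [0, 1] — the input
#' representation for profile classification. Rendering convention
#' (version `"v1"`): the trace is resampled to one value per pixel column
#' (max-pooling when several scans map to a column, so narrow spikes
#' survive; linear interpolation when the run has fewer scans than
#' columns), the y axis is linear from 0 to the trace maximum (1 when the
#' trace is all zero), and consecutive column points are joined by vertical
#' strokes of fixed 2-pixel width. The renderer is deterministic —
#' identical values give byte-identical pixels — and scale-invariant:
#' images depend only on the profile's shape, never its absolute
#' intensity.
#'
#' @param eic an `sc_eic`.
#' @param size image side in pixels (default 224).
#' @return `eic_image`: numeric array `size x size x 3` with attributes
#'   `renderer_version` and `mz_center`.
#' @export
render_eic_image <- function(eic, size = 224L) {
  v <- eic$values
  if (!length(v)) stop("empty EIC")
  size <- as.integer(size)
  n <- length(v)
  if (n >= size) {
    # max-pool scans into pixel columns
    col_of <- pmin(size, floor((seq_len(n) - 1L) / n * size) + 1L)
    prof <- numeric(size)
    mx <- tapply(v, col_of, max)
    prof[as.integer(names(mx))] <- mx
  } else {
    prof <- stats::approx(seq_len(n), v, xout = seq(1, n, length.out = size))$y
  }
  top <- max(prof)
  if (top <= 0) top <- 1
  yn <- prof / top
  # row 1 = top of image; baseline (0) sits on the bottom row
  yr <- size - pmin(size - 1L, pmax(0L, as.integer(round(yn * (size - 1L)))))
  img <- matrix(1, size, size)
  for (j in seq_len(size)) {
    y0 <- if (j == 1L) yr[j] else yr[j - 1L]
    rows <- seq.int(min(y0, yr[j]), max(y0, yr[j]))
    img[rows, j] <- 0
    rows2 <- pmax(1L, rows - 1L)          # fixed 2-px stroke, upward
    img[rows2, j] <- 0
  }
  out <- array(img, dim = c(size, size, 3L))
  attr(out, "renderer_version") <- "v1"
  attr(out, "mz_center") <- eic$mz_center
  class(out) <- "eic_image"
  out
}

#' Restrict an EIC to its first n cell events (training augmentation)
#'
#' Magnification-style augmentation of chronogram profiles: the EIC is cut
#' down to the concatenation of the first `n_events` extended event
#' windows. Rendered at fixed width, many events give sharp, centroid-like
#' peaks while few events give broader, Gaussian-like peaks, diversifying
#' a limited pool of labelled species. Sweeping n over 10..100 in steps of
#' 5 is the standard recipe.
#'
#' @param eic an `sc_eic` covering the run.
#' @param events a `cell_events` data.frame for the same run.
#' @param n_events how many leading events to keep (>= 5, at most the
#'   number available).
#' @return an `sc_eic` over the selected scans.
#' @export
augment_by_event_count <- function(eic, events, n_events) {
  if (n_events > nrow(events))
    stop("n_events (", n_events, ") exceeds available events (", nrow(events), ")")
  if (n_events < 5L) stop("n_events must be at least 5")
  sel <- events[seq_len(n_events), , drop = FALSE]
  scans <- unlist(lapply(seq_len(nrow(sel)), function(i)
    seq.int(sel$ext_start[i], sel$ext_end[i] - 1L)), use.names = FALSE)
  scans <- scans[scans >= 1L & scans <= length(eic$values)]
  structure(list(mz_center = eic$mz_center, ppm_tol = eic$ppm_tol,
                 times = eic$times[scans], values = eic$values[scans]),
            class = "sc_eic")
}
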