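#' Extract an ion chronogram
#'
#' Sums, for every scan, the centroid intensities within `ppm_tol` of
#' `mz_center`; scans with no matching centroid contribute 0. This per-scan
#' trace of one species across a direct-infusion run is the basic object on
#' which cell events are detected and chronogram profiles are classified.
#'
#' @param run an [sc_run].
#' @param mz_center species m/z (Th), inside the run's acquisition window.
#' @param ppm_tol half-width of the extraction window in ppm.
#' @return An `sc_eic`: list with `mz_center`, `ppm_tol`, `times` (minutes)
#'   and `values` (one non-negative intensity per scan).
#' @export
extract_eic <- function(run, mz_center, ppm_tol) {
  stopifnot(inherits(run, "sc_run"), ppm_tol > 0)
  if (mz_center < run$mz_range[1L] || mz_center > run$mz_range[2L])
    stop(sprintf("mz_center %.4f outside run m/z window [%.3f, %.3f]",
                 mz_center, run$mz_range[1L], run$mz_range[2L]))
  half <- mz_center * ppm_tol * 1e-6
  lo <- mz_center - half; hi <- mz_center + half
  values <- vapply(run$peaks, function(p) {
    if (!nrow(p)) return(0)
    i0 <- findInterval(lo, p[, 1L], left.open = TRUE) + 1L
    i1 <- findInterval(hi, p[, 1L])
    if (i1 < i0) 0 else sum(p[i0:i1, 2L])
  }, double(1))
  structure(list(mz_center = mz_center, ppm_tol = ppm_tol,
                 times = run$rt, values = values),
            class = "sc_eic")
}

#' Extract many ion chronograms at once
#'
#' Batched counterpart of [extract_eic()] built on one sorted centroid
#' table, for workflows (simulation benchmarking, classifier input) that
#' need hundreds of species traces from the same run.
#'
#' @inheritParams extract_eic
#' @param mz_centers numeric vector of species m/z values.
#' @return list of `sc_eic`, one per centre, in input order.
#' @export
extract_eic_matrix <- function(run, mz_centers, ppm_tol) {
  stopifnot(inherits(run, "sc_run"), ppm_tol > 0)
  bad <- mz_centers < run$mz_range[1L] | mz_centers > run$mz_range[2L]
  if (any(bad)) stop("mz_center outside run m/z window: ", mz_centers[bad][1L])
  tab <- run_centroid_table(run)
  ns <- n_scans(run)
  lapply(mz_centers, function(mc) {
    half <- mc * ppm_tol * 1e-6
    i0 <- findInterval(mc - half, tab$mz, left.open = TRUE) + 1L
    i1 <- findInterval(mc + half, tab$mz)
    values <- numeric(ns)
    if (i1 >= i0) {
      idx <- i0:i1
      agg <- rowsum(tab$intensity[idx], tab$scan[idx])
      values[as.integer(rownames(agg))] <- agg[, 1L]
    }
    structure(list(mz_center = mc, ppm_tol = ppm_tol,
                   times = run$rt, values = values),
              class = "sc_eic")
  })
}

#' @export
print.sc_eic <- function(x, ...) {
  cat(sprintf("<sc_eic> m/z %.4f (±%g ppm), %d scans, max %.3g\n",
              x$mz_center, x$ppm_tol, length(x$values),
              if (length(x$values)) max(x$values) else NA_real_))
  invisible(x)
}

#' @export
plot.sc_eic <- function(x, ...) {
  plot(x$times, x$values, type = "l",
       xlab = "time (min)", ylab = "intensity",
       main = sprintf("EIC m/z %.4f", x$mz_center), ...)
  invisible(x)
}

#' Robust noise level of a chronogram
#'
#' Estimates the baseline noise scale of an EIC as the one-sided median
#' absolute deviation of the values lying below the EIC median,
#' Gaussian-calibrated: `1.4826 * median(median(v) - v[v < median(v)])`.
#' Using only the sub-median half makes the estimate insensitive to the
#' cell-event peaks riding on the baseline. When that estimate is zero
#' (e.g. a constant trace) the smallest positive value observed is used,
#' and 1.0 when the trace is all-zero. Conversion to mzML discards the
#' vendor per-peak noise channel, so this data-driven estimate is what S/N
#' thresholding runs on.
#'
#' @param eic an `sc_eic` from [extract_eic()].
#' @return scalar noise level in intensity units, always positive.
#' @export
estimate_noise <- function(eic) {
  v <- eic$values
  if (!length(v)) stop("empty EIC")
  med <- stats::median(v)
  below <- v[v < med]
  est <- if (length(below)) 1.4826 * stats::median(med - below) else 0
  if (est > 0) return(est)
  pos <- v[v > 0]
  if (length(pos)) min(pos) else 1.0
}
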