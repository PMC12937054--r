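#' Construct a centroided MS run
#'
#' An `sc_run` holds an ordered set of centroided MS1 scans: one retention
#' time (minutes) and one two-column `mz`/`intensity` matrix per scan. It is
#' the substrate every other stage of the package consumes — the "cellogram"
#' is simply the intensity of one or more species across these scans.
#'
#' @param peaks list of numeric matrices, one per scan, with columns
#'   `mz` (strictly ascending within a scan) and `intensity` (non-negative).
#' @param rt numeric vector of retention times in minutes, non-decreasing,
#'   one per scan.
#' @param polarity `"positive"` or `"negative"`.
#' @param mz_range length-2 numeric, the acquisition m/z window (Th).
#'   Defaults to the observed range padded by 1 Th.
#' @param noise optional list of per-peak noise vectors matching `peaks`
#'   (lost by most mzML converters; kept for completeness).
#' @param source_path provenance string.
#' @return An object of class `sc_run`.
#' @seealso [read_mzml()], [write_mzml()], [extract_eic()]
#' @export
sc_run <- function(peaks, rt, polarity = "positive", mz_range = NULL,
                   noise = NULL, source_path = NA_character_) {
  stopifnot(is.list(peaks), length(peaks) == length(rt))
  polarity <- match.arg(polarity, c("positive", "negative"))
  peaks <- lapply(peaks, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2L) stop("each peaks matrix needs two columns (mz, intensity)")
    storage.mode(p) <- "double"
    colnames(p) <- c("mz", "intensity")
    p
  })
  if (is.null(mz_range)) {
    mzs <- unlist(lapply(peaks, function(p) p[, 1L]), use.names = FALSE)
    mz_range <- if (length(mzs)) c(min(mzs) - 1, max(mzs) + 1) else c(0, 0)
  }
  run <- structure(
    list(peaks = peaks, rt = as.numeric(rt), polarity = polarity,
         mz_range = as.numeric(mz_range), noise = noise,
         source_path = source_path),
    class = "sc_run")
  validate_run(run)
  run
}

#' Validate an sc_run's invariants
#'
#' Checks that m/z values are strictly ascending within each scan,
#' intensities are non-negative, retention times are non-decreasing, and all
#' m/z values lie inside the run's acquisition window.
#'
#' @param run an [sc_run].
#' @return `run`, invisibly; errors describe the first violated invariant.
#' @export
validate_run <- function(run) {
  stopifnot(inherits(run, "sc_run"))
  if (is.unsorted(run$rt)) stop("retention times must be non-decreasing")
  for (i in seq_along(run$peaks)) {
    p <- run$peaks[[i]]
    if (nrow(p) > 1L && any(diff(p[, 1L]) <= 0))
      stop("m/z not strictly ascending in scan ", i)
    if (any(p[, 2L] < 0)) stop("negative intensity in scan ", i)
    if (nrow(p) && (min(p[, 1L]) < run$mz_range[1L] ||
                    max(p[, 1L]) > run$mz_range[2L]))
      stop("m/z outside mz_range in scan ", i)
  }
  invisible(run)
}

#' @export
print.sc_run <- function(x, ...) {
  n <- length(x$peaks)
  npk <- sum(vapply(x$peaks, nrow, integer(1)))
  cat(sprintf("<sc_run> %d MS1 scans, %d centroids, %s mode\n",
              n, npk, x$polarity))
  if (n) cat(sprintf("  rt %.3f..%.3f min; m/z window [%.3f, %.3f]\n",
                     x$rt[1L], x$rt[n], x$mz_range[1L], x$mz_range[2L]))
  invisible(x)
}

#' Number of scans in a run
#' @param run an [sc_run].
#' @return integer scan count.
#' @export
n_scans <- function(run) length(run$peaks)

# Long-format centroid table (scan, mz, intensity) sorted by mz; cached on
# the run object by callers that need repeated windowed m/z lookups.
run_centroid_table <- function(run) {
  nper <- vapply(run$peaks, nrow, integer(1))
  scan <- rep.int(seq_along(run$peaks), nper)
  mz <- unlist(lapply(run$peaks, function(p) p[, 1L]), use.names = FALSE)
  intensity <- unlist(lapply(run$peaks, function(p) p[, 2L]), use.names = FALSE)
  o <- order(mz)
  list(scan = scan[o], mz = mz[o], intensity = intensity[o])
}
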