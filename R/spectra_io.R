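#' Read a centroided mzML file
#'
#' Imports all MS1 scans of a centroided mzML acquisition in scan order.
#' Retention times are normalised to minutes regardless of the unit the
#' source file used (mzML stores seconds; the package works in minutes
#' because sampling rates and refractory periods are naturally quoted per
#' minute). MSn scans are skipped. Per-peak noise channels do not survive
#' mzML conversion, so `noise` is always `NULL` for files read here;
#' downstream S/N estimation falls back to [estimate_noise()].
#'
#' @param path path to an mzML file with centroided MS1 spectra.
#' @return An [sc_run].
#' @section Errors: a missing file, a file with zero MS1 scans, or a scan
#'   recorded as profile mode (named in the message) all raise errors.
#' @export
read_mzml <- function(path) {
  if (!file.exists(path)) stop("mzML file not found: ", path)
  fh <- mzR::openMSfile(path, backend = "pwiz")
  on.exit(mzR::close(fh), add = TRUE)
  hdr <- mzR::header(fh)
  if (!nrow(hdr)) stop("empty run: no spectra in ", path)
  prof <- which(hdr$msLevel == 1L & !is.na(hdr$centroided) & !hdr$centroided)
  if (length(prof))
    stop("profile-mode spectrum not supported: scan ", hdr$acquisitionNum[prof[1L]])
  keep <- which(hdr$msLevel == 1L)
  if (!length(keep)) stop("empty run: no MS1 scans in ", path)
  pk <- mzR::peaks(fh, keep)
  if (is.matrix(pk)) pk <- list(pk)
  pk <- lapply(pk, function(p) {
    p <- matrix(as.numeric(p), ncol = 2L,
                dimnames = list(NULL, c("mz", "intensity")))
    if (nrow(p) > 1L && is.unsorted(p[, 1L])) p <- p[order(p[, 1L]), , drop = FALSE]
    p
  })
  rt_min <- hdr$retentionTime[keep] / 60
  pol <- if (all(hdr$polarity[keep] == 0L)) "negative" else "positive"
  lo <- suppressWarnings(min(hdr$scanWindowLowerLimit[keep], na.rm = TRUE))
  hi <- suppressWarnings(max(hdr$scanWindowUpperLimit[keep], na.rm = TRUE))
  rng <- if (is.finite(lo) && is.finite(hi) && hi > lo) c(lo, hi) else NULL
  sc_run(pk, rt_min, polarity = pol, mz_range = rng, source_path = path)
}

#' Write a run to mzML
#'
#' Emits a standard-conformant centroided mzML file (zlib-compressed 64-bit
#' arrays, via proteowizard). Reading the file back with [read_mzml()]
#' reproduces every m/z and intensity within floating-point round-trip
#' tolerance, and the output is byte-deterministic for a given run.
#'
#' @param run an [sc_run].
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  validate_run(run)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("cannot write mzML: no such directory ", dir)
  n <- n_scans(run)
  cnt <- vapply(run$peaks, nrow, integer(1))
  bp_i <- vapply(run$peaks, function(p) if (nrow(p)) max(p[, 2L]) else 0, double(1))
  bp_mz <- vapply(run$peaks, function(p)
    if (nrow(p)) p[which.max(p[, 2L]), 1L] else 0, double(1))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = rep(1L, n),
    polarity = rep(if (run$polarity == "positive") 1L else 0L, n),
    peaksCount = cnt,
    totIonCurrent = vapply(run$peaks, function(p) sum(p[, 2L]), double(1)),
    retentionTime = run$rt * 60,
    basePeakMZ = bp_mz, basePeakIntensity = bp_i,
    collisionEnergy = rep(0, n), ionisationEnergy = rep(0, n),
    lowMZ = vapply(run$peaks, function(p) if (nrow(p)) p[1L, 1L] else 0, double(1)),
    highMZ = vapply(run$peaks, function(p) if (nrow(p)) p[nrow(p), 1L] else 0, double(1)),
    precursorScanNum = rep(0L, n), precursorMZ = rep(0, n),
    precursorCharge = rep(0L, n), precursorIntensity = rep(0, n),
    mergedScan = rep(0L, n), mergedResultScanNum = rep(0L, n),
    mergedResultStartScanNum = rep(0L, n), mergedResultEndScanNum = rep(0L, n),
    injectionTime = rep(0, n), filterString = rep(NA_character_, n),
    spectrumId = paste0("scan=", seq_len(n)),
    centroided = rep(TRUE, n), ionMobilityDriftTime = rep(NA_real_, n),
    isolationWindowTargetMZ = rep(NA_real_, n),
    isolationWindowLowerOffset = rep(NA_real_, n),
    isolationWindowUpperOffset = rep(NA_real_, n),
    scanWindowLowerLimit = rep(run$mz_range[1L], n),
    scanWindowUpperLimit = rep(run$mz_range[2L], n),
    stringsAsFactors = FALSE)
  mzR::writeMSData(unname(run$peaks), path, header = hdr, outformat = "mzml")
  invisible(path)
}

# Auto-detect a header row: first field of the first line non-numeric.
.read_csv_auto <- function(path, ncol_min) {
  first <- readLines(path, n = 1L)
  if (!length(first) || !nzchar(trimws(first)))
    return(data.frame())
  f1 <- strsplit(first, ",", fixed = TRUE)[[1L]][1L]
  has_header <- is.na(suppressWarnings(as.numeric(trimws(f1))))
  d <- utils::read.csv(path, header = has_header, stringsAsFactors = FALSE,
                       strip.white = TRUE)
  if (ncol(d) < ncol_min)
    stop("expected at least ", ncol_min, " column(s) in ", path)
  d
}

#' Read a manual peak-time list
#'
#' Parses a two-column CSV of start/end times (minutes) delimiting extended
#' cellographic peaks, as used for manual event selection. A header row is
#' auto-detected. Rows are returned sorted by start time.
#'
#' @param path CSV path.
#' @return data.frame with columns `start_time`, `end_time` (minutes).
#' @section Errors: any row with `end <= start`, and any pair of
#'   overlapping intervals, raises a validation error naming the row.
#' @export
read_peak_list_csv <- function(path) {
  if (!file.exists(path)) stop("peak list not found: ", path)
  d <- .read_csv_auto(path, 2L)
  if (!nrow(d))
    return(data.frame(start_time = numeric(0), end_time = numeric(0)))
  out <- data.frame(start_time = as.numeric(d[[1L]]),
                    end_time = as.numeric(d[[2L]]))
  bad <- which(!is.finite(out$start_time) | !is.finite(out$end_time))
  if (length(bad)) stop("non-numeric time in row ", bad[1L])
  rev_ <- which(out$end_time <= out$start_time)
  if (length(rev_)) stop("end_time <= start_time in row ", rev_[1L])
  o <- order(out$start_time)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) > 1L) {
    ov <- which(out$start_time[-1L] < out$end_time[-nrow(out)])
    if (length(ov))
      stop("overlapping intervals in rows ", ov[1L], " and ", ov[1L] + 1L,
           " (after sorting by start time)")
  }
  out
}

#' Read a target / exclusion m/z list
#'
#' Parses a CSV with columns m/z, name, class. Only the m/z column is
#' required; missing names are blank and a missing class defaults to
#' `"target"`. Recognised classes are `target`, `internal_standard` and
#' `solvent_blank`.
#'
#' @param path CSV path.
#' @return data.frame with columns `mz`, `name`, `class`.
#' @export
read_mz_list_csv <- function(path) {
  if (!file.exists(path)) stop("m/z list not found: ", path)
  empty <- data.frame(mz = numeric(0), name = character(0),
                      class = character(0), stringsAsFactors = FALSE)
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) return(empty)
  d <- .read_csv_auto(path, 1L)
  if (!nrow(d)) return(empty)
  mz <- suppressWarnings(as.numeric(d[[1L]]))
  bad <- which(!is.finite(mz))
  if (length(bad)) stop("non-numeric m/z in row ", bad[1L])
  nm <- if (ncol(d) >= 2L) as.character(d[[2L]]) else rep("", length(mz))
  cls <- if (ncol(d) >= 3L) as.character(d[[3L]]) else rep("target", length(mz))
  cls[is.na(cls) | !nzchar(cls)] <- "target"
  ok <- cls %in% c("target", "internal_standard", "solvent_blank")
  if (any(!ok)) stop("unknown class '", cls[!ok][1L], "' in row ", which(!ok)[1L])
  data.frame(mz = mz, name = nm, class = cls, stringsAsFactors = FALSE)
}
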