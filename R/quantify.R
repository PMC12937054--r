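#' Match a target list against a feature table
#'
#' Matches each target m/z to the nearest feature within `ppm_tol`,
#' one-to-one: when two targets claim the same feature, the closer one (in
#' ppm) wins and the other is left unmatched. The targeted workflow
#' typically runs on a table produced at low filter thresholds.
#'
#' @param table a `cell_feature_table`.
#' @param targets data.frame from [read_mz_list_csv()] (columns `mz`,
#'   `name`, `class`), or any data.frame with those columns.
#' @param ppm_tol matching tolerance (ppm).
#' @return data.frame of class `target_matches`: `name`, `target_mz`,
#'   `matched` (logical), `feature_id`, `feature_mz`, `ppm_error`
#'   (signed, feature relative to target).
#' @export
match_targets <- function(table, targets, ppm_tol = 5) {
  stopifnot(ppm_tol > 0, all(c("mz", "name") %in% names(targets)))
  fmz <- table$features$rep_mz
  n <- nrow(targets)
  out <- data.frame(name = targets$name, target_mz = targets$mz,
                    matched = rep(FALSE, n), feature_id = rep(NA_integer_, n),
                    feature_mz = rep(NA_real_, n), ppm_error = rep(NA_real_, n),
                    stringsAsFactors = FALSE)
  if (!length(fmz) || !n) { class(out) <- c("target_matches", "data.frame"); return(out) }
  # candidate pairs within tolerance, assigned best-first so the closer
  # target wins a contested feature
  cand <- do.call(rbind, lapply(seq_len(n), function(i) {
    err <- (fmz - targets$mz[i]) / targets$mz[i] * 1e6
    j <- which(abs(err) <= ppm_tol)
    if (!length(j)) return(NULL)
    data.frame(target = i, feature = j, ppm_error = err[j])
  }))
  if (!is.null(cand) && nrow(cand)) {
    cand <- cand[order(abs(cand$ppm_error)), , drop = FALSE]
    used_f <- logical(length(fmz)); used_t <- logical(n)
    for (r in seq_len(nrow(cand))) {
      i <- cand$target[r]; j <- cand$feature[r]
      if (used_t[i] || used_f[j]) next
      used_t[i] <- TRUE; used_f[j] <- TRUE
      out$matched[i] <- TRUE
      out$feature_id[i] <- table$features$feature_id[j]
      out$feature_mz[i] <- fmz[j]
      out$ppm_error[i] <- cand$ppm_error[r]
    }
  }
  class(out) <- c("target_matches", "data.frame")
  out
}

#' Quantify a matched target against an internal standard
#'
#' Single-point quantification with an assumed response factor of 1:
#' `quantity[cell] = intensity_target[cell] / intensity_IS[cell] *
#' is_concentration * response_factor`. Cells where the internal standard
#' was not detected get `NA`.
#'
#' @param table the `cell_feature_table` the matches refer to.
#' @param match one row of [match_targets()] output for the analyte.
#' @param is_match one row for the paired internal standard.
#' @param is_concentration spiked IS concentration (output units follow it).
#' @param response_factor relative response of analyte vs IS (default 1).
#' @return named numeric vector of per-cell quantities.
#' @export
quantify_target <- function(table, match, is_match, is_concentration,
                            response_factor = 1) {
  if (!isTRUE(match$matched[1L]) || !isTRUE(is_match$matched[1L]))
    stop("both the target and the internal standard must be matched")
  stopifnot(is_concentration > 0, response_factor > 0)
  ti <- which(table$features$feature_id == match$feature_id[1L])
  si <- which(table$features$feature_id == is_match$feature_id[1L])
  it <- table$intensity[, ti]
  is_ <- table$intensity[, si]
  q <- ifelse(is_ > 0, it / is_ * is_concentration * response_factor, NA_real_)
  names(q) <- table$cell_ids
  q
}

#' Normalise a feature table per cell
#'
#' `"is_ratio"` divides each cell's row by that cell's internal-standard
#' intensity; `"tic"` divides by the cell's total summed intensity. Zeros
#' propagate as zeros; a cell with a zero denominator gets `NA` across all
#' features with a warning.
#'
#' @param table a `cell_feature_table`.
#' @param mode `"is_ratio"` or `"tic"`.
#' @param is_feature_id feature id of the internal standard (required for
#'   `"is_ratio"`).
#' @return a `cell_feature_table` with normalised intensities.
#' @export
normalize_table <- function(table, mode = c("tic", "is_ratio"),
                            is_feature_id = NULL) {
  mode <- match.arg(mode)
  denom <- switch(mode,
    tic = rowSums(table$intensity),
    is_ratio = {
      if (is.null(is_feature_id)) stop("is_ratio mode needs is_feature_id")
      si <- which(table$features$feature_id == is_feature_id)
      if (!length(si)) stop("internal-standard feature not in table")
      table$intensity[, si]
    })
  zero <- denom == 0
  if (any(zero))
    warning(sum(zero), " cell(s) with zero denominator set to NA")
  denom[zero] <- NA_real_
  out <- table
  out$intensity <- table$intensity / denom
  out$intensity[is.na(out$intensity)] <- NA_real_
  out
}
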