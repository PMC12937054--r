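#' Configuration for the statistical filter cascade
#'
#' Collects the tunables of the cumulative background-removal cascade.
#' Defaults follow the standard settings: fold change 3 (an S/N-like
#' filter), detection frequency one third of cells (sporadically found
#' species are dropped), ten background scans for the FC average. The
#' carbon-13 spacing is 1.003355 Th; a putative M+1 must also be small
#' relative to its parent (`isotope_max_ratio`, default 0.6, covering
#' natural abundance of up to roughly 50 carbons) so that genuinely
#' distinct species one neutron apart are not discarded. Mass-defect
#' ranges are opt-in (data-set specific). Higher FC (e.g. 9) suits very
#' complex data sets; that choice stays with the user.
#'
#' @param fc_threshold fold-change threshold (>= 1), inclusive.
#' @param df_threshold detection-frequency threshold, fraction of cells
#'   (0, 1], inclusive.
#' @param background_scans scans averaged for the fold change.
#' @param isotope_delta 13C-12C mass difference (Th).
#' @param isotope_ppm_tol tolerance for matching the isotope spacing (ppm).
#' @param isotope_max_ratio maximum median M+1/M intensity ratio for a
#'   feature to be called an isotopologue.
#' @param exclusion_ppm_tol tolerance for exclusion-list matching (ppm).
#' @param mdf_ranges list of length-2 vectors, half-open fractional-mass
#'   intervals `[low, high)` within [0, 1); an interval with low > high
#'   wraps through 1.
#' @param is_list,blank_list numeric m/z vectors: internal standards and
#'   known solvent blanks to exclude.
#' @return classed list `filter_config`.
#' @export
filter_config <- function(fc_threshold = 3, df_threshold = 1 / 3,
                          background_scans = 10L,
                          isotope_delta = 1.003355, isotope_ppm_tol = 10,
                          isotope_max_ratio = 0.6, exclusion_ppm_tol = 5,
                          mdf_ranges = list(), is_list = numeric(0),
                          blank_list = numeric(0)) {
  stopifnot(fc_threshold >= 1, df_threshold > 0, df_threshold <= 1,
            background_scans >= 1L, isotope_delta > 0, isotope_ppm_tol > 0,
            isotope_max_ratio > 0, exclusion_ppm_tol > 0)
  for (r in mdf_ranges)
    if (length(r) != 2L || any(r < 0) || any(r >= 1))
      stop("mdf_ranges must be length-2 vectors within [0, 1)")
  structure(list(fc_threshold = fc_threshold, df_threshold = df_threshold,
                 background_scans = as.integer(background_scans),
                 isotope_delta = isotope_delta,
                 isotope_ppm_tol = isotope_ppm_tol,
                 isotope_max_ratio = isotope_max_ratio,
                 exclusion_ppm_tol = exclusion_ppm_tol,
                 mdf_ranges = mdf_ranges,
                 is_list = as.numeric(is_list),
                 blank_list = as.numeric(blank_list)),
            class = "filter_config")
}

# scalar FC with the zero-background fallback
fold_change_value <- function(peak_max, bg_mean, noise_floor = 1.0) {
  if (bg_mean > 0) peak_max / bg_mean else peak_max / noise_floor
}

#' Fold change of a species over one cellographic peak
#'
#' Highest signal intensity within the peak divided by the averaged
#' intensity over the last `n_background` background scans before the
#' peak. A zero background mean is replaced by the supplied noise floor so
#' that species absent from the background still get a finite, comparable
#' FC.
#'
#' @param peak_trace per-scan intensities inside the peak window
#'   (non-empty).
#' @param background_trace per-scan intensities of the background window
#'   (absent scans as 0).
#' @param n_background how many trailing background scans to average; when
#'   the trace is shorter, all of it is used.
#' @param noise_floor positive fallback denominator.
#' @return scalar fold change.
#' @export
fold_change <- function(peak_trace, background_trace, n_background = 10L,
                        noise_floor = 1.0) {
  if (!length(peak_trace)) stop("empty peak trace")
  bg <- utils::tail(background_trace, n_background)
  bg_mean <- if (length(bg)) mean(bg) else 0
  fold_change_value(max(peak_trace), bg_mean, noise_floor)
}

#' Fold-change filter
#'
#' Marks each (cell, feature) entry as a detection when its fold change
#' meets the threshold (inclusive), and drops features detected in no cell.
#'
#' @param table a `cell_feature_table` carrying per-cell fold changes.
#' @param cfg a [filter_config()].
#' @return list: `table` (features with >= 1 passing cell), `mask` (logical
#'   cells-by-features detection matrix for the retained features),
#'   `retained` (indices into the input feature set).
#' @export
fc_filter <- function(table, cfg) {
  mask <- table$fold_change >= cfg$fc_threshold
  keep <- which(colSums(mask) > 0L)
  list(table = subset_features(table, keep),
       mask = mask[, keep, drop = FALSE], retained = keep)
}

#' Detection-frequency filter
#'
#' Keeps features whose fraction of FC-passing cells meets the threshold
#' (inclusive). DF counts cells that passed the fold-change filter, not
#' mere nonzero detections.
#'
#' @param mask logical cells-by-features detection matrix from
#'   [fc_filter()].
#' @param cfg a [filter_config()].
#' @return integer vector of retained feature column indices.
#' @export
df_filter <- function(mask, cfg) {
  which(colMeans(mask) >= cfg$df_threshold)
}

#' Carbon-13 deisotoping
#'
#' Drops feature B when some feature A sits one 13C spacing below it
#' (|rep_mz(B) - rep_mz(A) - 1.003355| within `isotope_ppm_tol` of B's
#' mass) and the median over co-detected cells of intensity(B)/intensity(A)
#' does not exceed `isotope_max_ratio`. The ratio guard keeps distinct
#' species that happen to sit a neutron apart. Singly charged species are
#' assumed (direct-infusion small molecules).
#'
#' @param table a `cell_feature_table` (features ascending in m/z).
#' @param cfg a [filter_config()].
#' @return integer vector of retained feature indices.
#' @export
deisotope <- function(table, cfg) {
  mz <- table$features$rep_mz
  nf <- length(mz)
  drop <- logical(nf)
  for (b in seq_len(nf)) {
    tol <- cfg$isotope_ppm_tol * 1e-6 * mz[b]
    cand <- which(abs(mz[b] - mz - cfg$isotope_delta) <= tol)
    for (a in cand) {
      both <- table$intensity[, a] > 0 & table$intensity[, b] > 0
      if (!any(both)) next
      ratio <- stats::median(table$intensity[both, b] / table$intensity[both, a])
      if (ratio <= cfg$isotope_max_ratio) { drop[b] <- TRUE; break }
    }
  }
  which(!drop)
}

#' Exclusion-list filter
#'
#' Drops features whose representative m/z matches any listed mass
#' (internal standards or known solvent blanks) within `ppm_tol`.
#'
#' @param table a `cell_feature_table`.
#' @param mz_list numeric vector of masses to exclude.
#' @param ppm_tol matching tolerance (ppm).
#' @return integer vector of retained feature indices.
#' @export
exclusion_filter <- function(table, mz_list, ppm_tol = 5) {
  mz <- table$features$rep_mz
  if (!length(mz_list)) return(seq_along(mz))
  hit <- vapply(mz, function(m)
    any(abs(m - mz_list) / m * 1e6 <= ppm_tol), logical(1))
  which(!hit)
}

# normalise mdf ranges: split wrapped intervals, merge overlaps
.normalize_mdf_ranges <- function(ranges) {
  if (!length(ranges)) return(list())
  flat <- list()
  for (r in ranges) {
    if (r[1L] < r[2L]) flat[[length(flat) + 1L]] <- r
    else if (r[1L] > r[2L]) {           # wraps through 1
      flat[[length(flat) + 1L]] <- c(r[1L], 1)
      if (r[2L] > 0) flat[[length(flat) + 1L]] <- c(0, r[2L])
    }                                    # zero-length ranges dropped
  }
  if (!length(flat)) return(list())
  o <- order(vapply(flat, `[`, double(1), 1L))
  flat <- flat[o]
  merged <- list(flat[[1L]])
  overlapped <- FALSE
  for (r in flat[-1L]) {
    last <- merged[[length(merged)]]
    if (r[1L] < last[2L]) {
      overlapped <- TRUE
      merged[[length(merged)]] <- c(last[1L], max(last[2L], r[2L]))
    } else merged[[length(merged) + 1L]] <- r
  }
  if (overlapped) warning("overlapping mass-defect ranges merged")
  merged
}

#' Mass-defect filter
#'
#' Drops features whose fractional mass (rep_mz - floor(rep_mz)) lies in
#' any of the half-open exclusion ranges. Useful against solvent peaks,
#' salt clusters and multiply charged species, but its windows are
#' data-set specific — ranges default to none.
#'
#' @param table a `cell_feature_table`.
#' @param mdf_ranges list of `[low, high)` fractional-mass intervals;
#'   `low > high` wraps through 1. Overlaps are merged with a warning.
#' @return integer vector of retained feature indices.
#' @export
mass_defect_filter <- function(table, mdf_ranges) {
  mz <- table$features$rep_mz
  ranges <- .normalize_mdf_ranges(mdf_ranges)
  if (!length(ranges)) return(seq_along(mz))
  frac <- mz - floor(mz)
  hit <- vapply(frac, function(f)
    any(vapply(ranges, function(r) f >= r[1L] && f < r[2L], logical(1))),
    logical(1))
  which(!hit)
}

#' Apply the cumulative filter cascade
#'
#' Runs the selected filters in order, each on the survivors of the
#' previous one, and reports per-step feature counts. The default order —
#' FC, DF, deisotoping, IS exclusion, MDF, blank exclusion — starts with
#' the low statistical thresholds and applies the one-shot filters after,
#' minimising endogenous losses. When ground-truth labels are supplied the
#' report also tracks percent retention of endogenous and background
#' features relative to the input table at every step.
#'
#' @param table a `cell_feature_table`.
#' @param cfg a [filter_config()].
#' @param order character vector, subset of
#'   `c("fc","df","deisotope","is_exclusion","mdf","blank_exclusion")`.
#' @param truth optional character vector over the input features with
#'   values `"endogenous"` or `"background"`.
#' @return list of class `filter_result`: `table` (filtered), `report`
#'   (data.frame: step, features_in, features_out, and retention columns
#'   when truth is given), `retained` (indices into the input features),
#'   `mask` (detection mask of the retained features, when FC ran).
#' @export
run_cascade <- function(table, cfg,
                        order = c("fc", "df", "deisotope", "is_exclusion",
                                  "mdf", "blank_exclusion"),
                        truth = NULL) {
  known <- c("fc", "df", "deisotope", "is_exclusion", "mdf", "blank_exclusion")
  bad <- setdiff(order, known)
  if (length(bad)) stop("unknown cascade step: ", bad[1L])
  if (!is.null(truth) && length(truth) != nrow(table$features))
    stop("truth labels must cover all features")
  n_endo0 <- if (!is.null(truth)) sum(truth == "endogenous") else NA_integer_
  n_bg0 <- if (!is.null(truth)) sum(truth == "background") else NA_integer_
  cur <- table
  cur_idx <- seq_len(nrow(table$features))   # indices into the input table
  mask <- NULL
  steps <- list()
  for (st in order) {
    n_in <- nrow(cur$features)
    if (st == "fc") {
      res <- fc_filter(cur, cfg)
      keep <- res$retained
      mask <- res$mask
      cur <- res$table
    } else {
      keep <- switch(st,
        df = {
          if (is.null(mask))
            mask <- cur$fold_change >= cfg$fc_threshold
          df_filter(mask, cfg)
        },
        deisotope = deisotope(cur, cfg),
        is_exclusion = exclusion_filter(cur, cfg$is_list, cfg$exclusion_ppm_tol),
        mdf = mass_defect_filter(cur, cfg$mdf_ranges),
        blank_exclusion = exclusion_filter(cur, cfg$blank_list,
                                           cfg$exclusion_ppm_tol))
      keep <- sort(keep)
      cur <- subset_features(cur, keep)
      if (!is.null(mask)) mask <- mask[, keep, drop = FALSE]
    }
    cur_idx <- cur_idx[sort(keep)]
    row <- data.frame(step = st, features_in = n_in,
                      features_out = nrow(cur$features))
    if (!is.null(truth)) {
      row$retained_endogenous_pct <- if (n_endo0 > 0)
        100 * sum(truth[cur_idx] == "endogenous") / n_endo0 else NA_real_
      row$retained_background_pct <- if (n_bg0 > 0)
        100 * sum(truth[cur_idx] == "background") / n_bg0 else NA_real_
    }
    steps[[length(steps) + 1L]] <- row
  }
  report <- if (length(steps)) do.call(rbind, steps) else
    data.frame(step = character(0), features_in = integer(0),
               features_out = integer(0))
  structure(list(table = cur, report = report, retained = cur_idx,
                 mask = mask),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat("<filter_result>\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' Binary classification metrics against ground truth
#'
#' Sensitivity is retained endogenous species (true positives) over true
#' positives plus lost endogenous species (false negatives); specificity
#' is removed background (true negatives) over true negatives plus
#' retained background (false positives); accuracy is (TP+TN)/total.
#' An empty truth class leaves its metric `NA`.
#'
#' @param predicted_endogenous logical vector over features: predicted
#'   (retained) as endogenous.
#' @param truth character vector, `"endogenous"` or `"background"`, same
#'   length.
#' @return list: `sensitivity`, `specificity`, `accuracy`, `tp`, `fn`,
#'   `tn`, `fp`.
#' @export
binary_metrics <- function(predicted_endogenous, truth) {
  stopifnot(length(predicted_endogenous) == length(truth),
            all(truth %in% c("endogenous", "background")))
  pos <- truth == "endogenous"
  tp <- sum(predicted_endogenous & pos)
  fn <- sum(!predicted_endogenous & pos)
  tn <- sum(!predicted_endogenous & !pos)
  fp <- sum(predicted_endogenous & !pos)
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       accuracy = if (length(truth)) (tp + tn) / length(truth) else NA_real_,
       tp = tp, fn = fn, tn = tn, fp = fp)
}
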