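#' Group m/z observations into feature groups within a ppm tolerance
#'
#' The high-resolution alignment primitive. Observations are sorted by m/z
#' and grouped greedily left to right: a candidate joins the current group
#' while it deviates from the group's running intensity-weighted mean by at
#' most `ppm_tol`, otherwise it starts a new group. Dynamic (relative)
#' tolerance, rather than static binning, is what preserves the resolution
#' of FTMS data across the m/z range. Sorting first makes the partition
#' deterministic and independent of input order.
#'
#' @param obs data.frame with columns `id` (scan or cell identifier), `mz`
#'   (positive, Th) and `intensity` (non-negative).
#' @param ppm_tol grouping tolerance (ppm), > 0.
#' @param weighted use intensity-weighted running means and representative
#'   masses (default); `FALSE` falls back to unweighted means.
#' @return list of class `mz_groups` with
#'   \describe{
#'     \item{groups}{data.frame `group`, `rep_mz` (weighted mean of member
#'       m/z, sorted ascending), `n_members`, `total_intensity`.}
#'     \item{members}{`obs` sorted by m/z with a `group` column.}
#'   }
#' @export
group_mz <- function(obs, ppm_tol, weighted = TRUE) {
  stopifnot(is.data.frame(obs), all(c("id", "mz", "intensity") %in% names(obs)),
            ppm_tol > 0)
  if (!nrow(obs)) stop("no observations to group")
  if (any(obs$mz <= 0)) stop("non-positive m/z in observations")
  o <- order(obs$mz)
  obs <- obs[o, , drop = FALSE]
  mz <- obs$mz
  w <- if (weighted) obs$intensity else rep(1, length(mz))
  n <- length(mz)
  grp <- integer(n)
  g <- 1L
  # running weighted mean of the open group; zero-weight members count as
  # unweighted so a group of all-zero intensities still has a mean
  cm <- mz[1L]; cw <- w[1L]; cn <- 1L; csum <- mz[1L] * w[1L]; cunw <- mz[1L]
  grp[1L] <- 1L
  for (i in seq_len(n)[-1L]) {
    if (abs(mz[i] - cm) / cm * 1e6 <= ppm_tol) {
      grp[i] <- g
      cw <- cw + w[i]; csum <- csum + mz[i] * w[i]
      cn <- cn + 1L; cunw <- cunw + mz[i]
      cm <- if (cw > 0) csum / cw else cunw / cn
    } else {
      g <- g + 1L
      grp[i] <- g
      cw <- w[i]; csum <- mz[i] * w[i]; cn <- 1L; cunw <- mz[i]
      cm <- if (cw > 0) csum / cw else mz[i]
    }
  }
  tw <- rowsum(w, grp)[, 1L]
  rep_mz <- ifelse(tw > 0,
                   rowsum(mz * w, grp)[, 1L] / tw,
                   rowsum(mz, grp)[, 1L] / tabulate(grp))
  groups <- data.frame(group = seq_len(g), rep_mz = rep_mz,
                       n_members = tabulate(grp),
                       total_intensity = rowsum(obs$intensity, grp)[, 1L])
  obs$group <- grp
  structure(list(groups = groups, members = obs), class = "mz_groups")
}

#' Align m/z values within one cellographic peak
#'
#' First alignment stage: all centroids inside one event's extended window
#' (which spans the event's background scans and its extended peak) are
#' grouped with [group_mz()]. For every feature group the summed intensity
#' over the peak window (the cell's signal), the in-peak maximum, and the
#' mean over the background window are recorded, so the fold change —
#' highest in-peak signal over the averaged pre-peak background — is
#' available per species. Background-window members are flagged in the
#' member table.
#'
#' @param run an [sc_run].
#' @param event one row of a `cell_events` data.frame.
#' @param ppm_tol grouping tolerance (ppm).
#' @param n_background number of background scans averaged for the fold
#'   change (default 10); at most the background window length is used.
#' @param noise_floor positive fallback denominator used when a species has
#'   zero background mean, keeping FC finite and comparable (typically the
#'   marker EIC noise level).
#' @return data.frame of class `event_features`: `rep_mz`, `intensity`
#'   (peak-window sum), `peak_max`, `bg_mean`, `fold_change`, `n_members`;
#'   attribute `members` holds the flagged member table.
#' @export
align_within_event <- function(run, event, ppm_tol = 5, n_background = 10L,
                               noise_floor = 1.0) {
  stopifnot(inherits(run, "sc_run"))
  scans <- seq.int(event$ext_start, event$ext_end - 1L)
  empty <- data.frame(rep_mz = numeric(0), intensity = numeric(0),
                      peak_max = numeric(0), bg_mean = numeric(0),
                      fold_change = numeric(0), n_members = integer(0))
  class(empty) <- c("event_features", "data.frame")
  if (!length(scans)) return(empty)
  pk <- run$peaks[scans]
  nper <- vapply(pk, nrow, integer(1))
  if (!sum(nper)) return(empty)
  obs <- data.frame(
    id = rep.int(scans, nper),
    mz = unlist(lapply(pk, function(p) p[, 1L]), use.names = FALSE),
    intensity = unlist(lapply(pk, function(p) p[, 2L]), use.names = FALSE))
  gr <- group_mz(obs, ppm_tol)
  mem <- gr$members
  mem$background <- mem$id >= event$bg_start & mem$id < event$bg_end
  in_peak <- mem$id >= event$peak_start & mem$id < event$peak_end
  ng <- nrow(gr$groups)
  peak_sum <- peak_max <- numeric(ng)
  if (any(in_peak)) {
    ps <- rowsum(mem$intensity[in_peak], mem$group[in_peak])
    gi <- as.integer(rownames(ps))
    peak_sum[gi] <- ps[, 1L]
    # per-scan trace maximum: within one group a scan can hold two centroids
    pm <- tapply(mem$intensity[in_peak],
                 list(mem$group[in_peak], mem$id[in_peak]), sum)
    peak_max[as.integer(rownames(pm))] <- apply(pm, 1L, max, na.rm = TRUE)
  }
  # background mean over the last n_background scans of the window,
  # counting scans where the species is absent as zero
  nbg_window <- event$bg_end - event$bg_start
  nbg <- min(as.integer(n_background), nbg_window)
  bg_mean <- numeric(ng)
  if (nbg > 0) {
    bg_lo <- event$bg_end - nbg
    in_bg <- mem$id >= bg_lo & mem$id < event$bg_end
    if (any(in_bg)) {
      bs <- rowsum(mem$intensity[in_bg], mem$group[in_bg])
      bg_mean[as.integer(rownames(bs))] <- bs[, 1L] / nbg
    }
  }
  fc <- vapply(seq_len(ng), function(i)
    fold_change_value(peak_max[i], bg_mean[i], noise_floor), double(1))
  out <- data.frame(rep_mz = gr$groups$rep_mz, intensity = peak_sum,
                    peak_max = peak_max, bg_mean = bg_mean,
                    fold_change = fc, n_members = gr$groups$n_members)
  attr(out, "members") <- mem
  class(out) <- c("event_features", "data.frame")
  out
}

#' Align integrated m/z values across cellographic peaks
#'
#' Second alignment stage: the representative masses of every event's
#' feature groups are themselves grouped with [group_mz()], producing the
#' experiment-level feature set and the cells-by-features matrices of
#' summed intensity and fold change. Absent combinations are zero-filled.
#'
#' @param per_event named list: one `event_features` (from
#'   [align_within_event()]) per cell; names are the cell ids.
#' @param ppm_tol grouping tolerance (ppm).
#' @return A `cell_feature_table`: list with `cell_ids`, `features`
#'   (data.frame `feature_id`, `rep_mz` ascending, `n_members`,
#'   `ppm_spread`), `intensity` and `fold_change` matrices (cells in rows),
#'   and `polarity`.
#' @export
align_across_events <- function(per_event, ppm_tol = 5, polarity = "positive") {
  stopifnot(length(per_event) >= 1L)
  ids <- names(per_event)
  if (is.null(ids)) ids <- as.character(seq_along(per_event))
  if (anyDuplicated(ids)) stop("duplicate cell ids")
  nfeat <- vapply(per_event, nrow, integer(1))
  keep <- nfeat > 0L
  obs <- data.frame(
    id = rep.int(ids[keep], nfeat[keep]),
    mz = unlist(lapply(per_event[keep], `[[`, "rep_mz"), use.names = FALSE),
    intensity = unlist(lapply(per_event[keep], `[[`, "intensity"),
                       use.names = FALSE))
  obs$fold_change <- unlist(lapply(per_event[keep], `[[`, "fold_change"),
                            use.names = FALSE)
  if (!nrow(obs)) stop("no features in any event")
  gr <- group_mz(obs, ppm_tol)
  mem <- gr$members
  nf <- nrow(gr$groups)
  nc <- length(ids)
  intensity <- matrix(0, nc, nf, dimnames = list(ids, NULL))
  fold_change <- matrix(0, nc, nf, dimnames = list(ids, NULL))
  ci <- match(mem$id, ids)
  for (r in seq_len(nrow(mem))) {
    intensity[ci[r], mem$group[r]] <- intensity[ci[r], mem$group[r]] + mem$intensity[r]
    fold_change[ci[r], mem$group[r]] <- max(fold_change[ci[r], mem$group[r]],
                                            mem$fold_change[r])
  }
  spread <- vapply(seq_len(nf), function(g) {
    m <- mem$mz[mem$group == g]
    (max(m) - min(m)) / gr$groups$rep_mz[g] * 1e6
  }, double(1))
  features <- data.frame(feature_id = seq_len(nf),
                         rep_mz = gr$groups$rep_mz,
                         n_members = gr$groups$n_members,
                         ppm_spread = spread)
  new_cell_feature_table(ids, features, intensity, fold_change, polarity)
}

new_cell_feature_table <- function(cell_ids, features, intensity,
                                   fold_change, polarity = "positive") {
  stopifnot(nrow(intensity) == length(cell_ids),
            ncol(intensity) == nrow(features),
            all(dim(intensity) == dim(fold_change)),
            !is.unsorted(features$rep_mz, strictly = TRUE),
            all(intensity >= 0))
  structure(list(cell_ids = cell_ids, features = features,
                 intensity = intensity, fold_change = fold_change,
                 polarity = polarity),
            class = "cell_feature_table")
}

#' @export
print.cell_feature_table <- function(x, ...) {
  cat(sprintf("<cell_feature_table> %d cells x %d features (%s mode)\n",
              length(x$cell_ids), nrow(x$features), x$polarity))
  if (nrow(x$features))
    cat(sprintf("  m/z %.4f .. %.4f; nonzero entries %.1f%%\n",
                min(x$features$rep_mz), max(x$features$rep_mz),
                100 * mean(x$intensity > 0)))
  invisible(x)
}

#' @export
summary.cell_feature_table <- function(object, ...) {
  cat(sprintf("cells: %d, features: %d\n",
              length(object$cell_ids), nrow(object$features)))
  cat("features per cell (nonzero):\n")
  print(summary(rowSums(object$intensity > 0)))
  invisible(object)
}

# subset a table to a set of feature indices (order preserved)
subset_features <- function(table, keep_idx) {
  keep_idx <- sort(keep_idx)
  features <- table$features[keep_idx, , drop = FALSE]
  rownames(features) <- NULL
  new_cell_feature_table(table$cell_ids, features,
                         table$intensity[, keep_idx, drop = FALSE],
                         table$fold_change[, keep_idx, drop = FALSE],
                         table$polarity)
}

#' Run the two-stage alignment over a detected run
#'
#' Convenience wrapper: [align_within_event()] for every detected event,
#' then [align_across_events()].
#'
#' @param run an [sc_run].
#' @param events `cell_events` from [detect_cell_events()].
#' @param ppm_tol grouping tolerance (ppm).
#' @param n_background scans averaged for the fold change.
#' @param noise_floor FC fallback denominator, see [align_within_event()].
#' @return a `cell_feature_table`.
#' @export
align_run <- function(run, events, ppm_tol = 5, n_background = 10L,
                      noise_floor = 1.0) {
  stopifnot(nrow(events) >= 1L)
  per_event <- lapply(seq_len(nrow(events)), function(i)
    align_within_event(run, events[i, ], ppm_tol, n_background, noise_floor))
  names(per_event) <- as.character(events$cell_id)
  align_across_events(per_event, ppm_tol, polarity = run$polarity)
}

#' Align feature tables across experiment files
#'
#' Groups the feature masses of several processed runs with [group_mz()]
#' and concatenates their cells under file-qualified ids, zero-filling
#' features a file did not observe.
#'
#' @param tables list of `cell_feature_table`s (>= 2, same polarity),
#'   optionally named; names qualify the cell ids.
#' @param ppm_tol grouping tolerance (ppm).
#' @return merged `cell_feature_table`; a `file` attribute records each
#'   cell's source.
#' @export
align_across_files <- function(tables, ppm_tol = 5) {
  stopifnot(length(tables) >= 2L)
  pol <- unique(vapply(tables, `[[`, character(1), "polarity"))
  if (length(pol) > 1L) stop("cannot align tables of mixed polarity")
  fids <- names(tables)
  if (is.null(fids)) fids <- paste0("file", seq_along(tables))
  nf <- vapply(tables, function(t) nrow(t$features), integer(1))
  obs <- data.frame(
    id = rep.int(fids, nf),
    mz = unlist(lapply(tables, function(t) t$features$rep_mz), use.names = FALSE),
    intensity = unlist(lapply(tables, function(t) colSums(t$intensity)),
                       use.names = FALSE))
  obs$local <- unlist(lapply(nf, seq_len), use.names = FALSE)
  gr <- group_mz(obs, ppm_tol)
  mem <- gr$members
  ng <- nrow(gr$groups)
  cell_ids <- unlist(lapply(seq_along(tables), function(i)
    paste(fids[i], tables[[i]]$cell_ids, sep = ":")), use.names = FALSE)
  file_of <- rep.int(fids, vapply(tables, function(t) length(t$cell_ids), integer(1)))
  intensity <- matrix(0, length(cell_ids), ng, dimnames = list(cell_ids, NULL))
  fold_change <- matrix(0, length(cell_ids), ng)
  row_off <- c(0L, cumsum(vapply(tables, function(t) length(t$cell_ids), integer(1))))
  for (r in seq_len(nrow(mem))) {
    fi <- match(mem$id[r], fids)
    rows <- row_off[fi] + seq_len(length(tables[[fi]]$cell_ids))
    g <- mem$group[r]; lc <- mem$local[r]
    intensity[rows, g] <- intensity[rows, g] + tables[[fi]]$intensity[, lc]
    fold_change[rows, g] <- pmax(fold_change[rows, g], tables[[fi]]$fold_change[, lc])
  }
  features <- data.frame(feature_id = seq_len(ng), rep_mz = gr$groups$rep_mz,
                         n_members = gr$groups$n_members,
                         ppm_spread = vapply(seq_len(ng), function(g) {
                           m <- mem$mz[mem$group == g]
                           (max(m) - min(m)) / gr$groups$rep_mz[g] * 1e6
                         }, double(1)))
  out <- new_cell_feature_table(cell_ids, features, intensity, fold_change, pol)
  attr(out, "file") <- file_of
  out
}

#' Write a feature table to CSV
#'
#' Writes the intensity matrix with `cell_id` as the first column and one
#' column per feature named by its representative m/z to 4 decimals, plus
#' companions `*_features.csv` (per-feature metadata) and `*_fc.csv` (the
#' per-cell fold-change matrix, same layout).
#'
#' @param table a `cell_feature_table`.
#' @param path destination CSV for the matrix.
#' @return `path`, invisibly.
#' @export
write_feature_table_csv <- function(table, path) {
  write_m <- function(mat, p) {
    m <- as.data.frame(mat)
    names(m) <- sprintf("%.4f", table$features$rep_mz)
    utils::write.csv(cbind(cell_id = table$cell_ids, m), p, row.names = FALSE)
  }
  write_m(table$intensity, path)
  companion <- function(suffix) {
    fp <- sub("\\.csv$", paste0(suffix, ".csv"), path)
    if (identical(fp, path)) paste0(path, suffix, ".csv") else fp
  }
  utils::write.csv(table$features, companion("_features"), row.names = FALSE)
  write_m(table$fold_change, companion("_fc"))
  invisible(path)
}

#' Read a feature table written by [write_feature_table_csv()]
#'
#' @param path the intensity-matrix CSV; the `*_features.csv` and
#'   `*_fc.csv` companions are picked up when present.
#' @param polarity ionisation mode to record.
#' @return a `cell_feature_table`.
#' @export
read_feature_table_csv <- function(path, polarity = "positive") {
  d <- utils::read.csv(path, check.names = FALSE)
  intensity <- as.matrix(d[, -1L, drop = FALSE])
  mz <- as.numeric(colnames(intensity))
  fpath <- sub("\\.csv$", "_features.csv", path)
  feats <- if (file.exists(fpath)) utils::read.csv(fpath) else
    data.frame(feature_id = seq_along(mz), rep_mz = mz,
               n_members = 1L, ppm_spread = 0)
  fcpath <- sub("\\.csv$", "_fc.csv", path)
  fc <- if (file.exists(fcpath)) {
    as.matrix(utils::read.csv(fcpath, check.names = FALSE)[, -1L, drop = FALSE])
  } else intensity * 0 + Inf
  new_cell_feature_table(as.character(d[[1L]]), feats, intensity, fc, polarity)
}
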