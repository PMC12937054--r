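#' Detection parameters for automatic cell-event identification
#'
#' Bundles the tunables of the automatic cellographic-peak finder. The
#' marker m/z is an abundant endogenous species (e.g. protonated PC 34:1 at
#' m/z 760.586, or choline at 104.107 — the right marker is data-set
#' dependent); detection runs on its EIC. Thresholding is either on S/N
#' (EIC value over the [estimate_noise()] level) or on absolute intensity.
#' The refractory period is the minimum time after a trigger during which
#' no new cell may be registered; too low an S/N threshold splits peaks and
#' is compensated by a longer refractory period, so the two interact.
#'
#' @param marker_mz marker species m/z (Th).
#' @param ppm_tol EIC extraction tolerance (ppm).
#' @param sn_threshold trigger threshold: S/N units, or intensity units
#'   when `mode = "intensity"`. Crossing is inclusive (`>=`).
#' @param refractory_period minimum trigger-to-trigger separation, minutes.
#' @param background_scans number of scans immediately before a trigger
#'   used as that cell's background window (default 10, matching the
#'   fold-change filter's default background average).
#' @param pre_extension_scans extra scans prepended to each extended
#'   window, for events whose onset precedes the S/N crossing (default 0).
#' @param mode `"sn"` or `"intensity"`.
#' @return classed list `detection_params`.
#' @export
detection_params <- function(marker_mz, ppm_tol = 5, sn_threshold = 25,
                             refractory_period = 0.15, background_scans = 10L,
                             pre_extension_scans = 0L, mode = c("sn", "intensity")) {
  mode <- match.arg(mode)
  stopifnot(sn_threshold > 0, refractory_period > 0, background_scans >= 1L,
            pre_extension_scans >= 0L, ppm_tol > 0)
  structure(list(marker_mz = marker_mz, ppm_tol = ppm_tol,
                 sn_threshold = sn_threshold,
                 refractory_period = refractory_period,
                 background_scans = as.integer(background_scans),
                 pre_extension_scans = as.integer(pre_extension_scans),
                 mode = mode),
            class = "detection_params")
}

# Shared window construction: given sorted trigger scans, build background,
# peak and extended windows. All windows are half-open [start, end) in
# 1-based scan indices. Event k's extended window runs from its background
# start (minus any pre-extension) to event k+1's (equally pre-extended)
# background start; the last event extends to the run end. The peak window
# runs from the trigger to the extended end, i.e. the extended cellographic
# peak between consecutive backgrounds.
.build_event_windows <- function(trigger_scans, trigger_times, ns,
                                 background_scans, pre_extension_scans) {
  k <- length(trigger_scans)
  if (!k)
    return(data.frame(cell_id = integer(0), trigger_scan = integer(0),
                      trigger_time = numeric(0), bg_start = integer(0),
                      bg_end = integer(0), peak_start = integer(0),
                      peak_end = integer(0), ext_start = integer(0),
                      ext_end = integer(0)))
  bg_start <- pmax(1L, trigger_scans - background_scans)
  bg_end <- trigger_scans                      # exclusive
  ext_start <- pmax(1L, bg_start - pre_extension_scans)
  ext_end <- c(ext_start[-1L], ns + 1L)        # exclusive
  data.frame(cell_id = seq_len(k),
             trigger_scan = trigger_scans, trigger_time = trigger_times,
             bg_start = bg_start, bg_end = bg_end,
             peak_start = trigger_scans, peak_end = ext_end,
             ext_start = ext_start, ext_end = ext_end)
}

#' Detect cellographic peaks on a marker EIC
#'
#' Scans the chronogram left to right. A new cell event triggers at the
#' first scan whose value meets the threshold (S/N relative to
#' [estimate_noise()], or raw intensity) and which is at least the
#' refractory period after the previous trigger. Each event gets a
#' background window (the `background_scans` scans before the trigger,
#' clipped at the run start), an extended window reaching to the next
#' event's background, and a peak window from the trigger to the extended
#' end. Windows are half-open `[start, end)` scan ranges, 1-based.
#'
#' @param eic marker `sc_eic` from [extract_eic()].
#' @param params a [detection_params()].
#' @return `cell_events` data.frame: `cell_id`, `trigger_scan`,
#'   `trigger_time` (min), `bg_start`, `bg_end`, `peak_start`, `peak_end`,
#'   `ext_start`, `ext_end`.
#' @export
detect_cell_events <- function(eic, params) {
  stopifnot(inherits(eic, "sc_eic"), inherits(params, "detection_params"))
  v <- eic$values
  ns <- length(v)
  duration <- if (ns > 1L) eic$times[ns] - eic$times[1L] else 0
  if (params$refractory_period > duration)
    warning("refractory period exceeds run duration; at most one event can trigger")
  level <- if (params$mode == "sn") estimate_noise(eic) else 1.0
  cand <- which(v / level >= params$sn_threshold)
  triggers <- integer(0)
  last_t <- -Inf
  for (s in cand) {
    if (eic$times[s] - last_t >= params$refractory_period) {
      triggers <- c(triggers, s)
      last_t <- eic$times[s]
    }
  }
  ev <- .build_event_windows(triggers, eic$times[triggers], ns,
                             params$background_scans,
                             params$pre_extension_scans)
  class(ev) <- c("cell_events", "data.frame")
  attr(ev, "n_scans") <- ns
  ev
}

#' Manually add or delete cell events
#'
#' Reproduces the manual curation step: events named in `remove` are
#' dropped, triggers are added at the scans nearest the times in `add`, and
#' the whole set is re-windowed and renumbered 1..n in time order with the
#' same window construction as [detect_cell_events()]. An added trigger
#' falling within the refractory period of an existing (kept) trigger is
#' rejected with a warning, consistent with the automatic rule.
#'
#' @param events a `cell_events` data.frame.
#' @param eic the marker `sc_eic` the events were detected on.
#' @param params the [detection_params()] used.
#' @param add numeric vector of trigger times (minutes) to insert.
#' @param remove integer vector of `cell_id`s to delete.
#' @return re-windowed `cell_events`.
#' @export
edit_events <- function(events, eic, params, add = numeric(0),
                        remove = integer(0)) {
  stopifnot(inherits(events, "cell_events"), inherits(eic, "sc_eic"),
            inherits(params, "detection_params"))
  if (length(remove)) {
    unknown <- setdiff(remove, events$cell_id)
    if (length(unknown)) stop("unknown cell_id: ", unknown[1L])
    events <- events[!events$cell_id %in% remove, , drop = FALSE]
  }
  trig <- events$trigger_scan
  ns <- length(eic$values)
  for (t in add) {
    if (t < eic$times[1L] || t > eic$times[ns])
      stop("added trigger time ", t, " outside run duration")
    s <- which.min(abs(eic$times - t))
    gaps <- abs(eic$times[s] - eic$times[trig])
    if (length(trig) && any(gaps < params$refractory_period)) {
      warning(sprintf(
        "trigger at %.3f min rejected: within refractory period of an existing event", t))
      next
    }
    trig <- c(trig, s)
  }
  trig <- sort(unique(trig))
  ev <- .build_event_windows(trig, eic$times[trig], ns,
                             params$background_scans,
                             params$pre_extension_scans)
  class(ev) <- c("cell_events", "data.frame")
  attr(ev, "n_scans") <- ns
  ev
}

#' Success rate of automatic cell identification
#'
#' Percentage of correctly identified cellographic peaks out of the known
#' number of cells deposited in the experiment, rounded to the nearest
#' integer percent — the figure of merit quoted per data set for the
#' automatic identification.
#'
#' @param identified number of correctly identified cellographic peaks.
#' @param known_total known number of individual cells (> 0).
#' @return integer percent.
#' @examples
#' success_rate(84, 93)  # 90
#' success_rate(98, 99)  # 99
#' @export
success_rate <- function(identified, known_total) {
  if (known_total <= 0) stop("known_total must be positive")
  stopifnot(identified >= 0, identified <= known_total)
  as.integer(floor(100 * identified / known_total + 0.5))
}

#' Write detected events to CSV
#'
#' @param events a `cell_events` data.frame.
#' @param path destination CSV.
#' @return `path`, invisibly. Scan indices are 1-based, window ends
#'   exclusive.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}
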