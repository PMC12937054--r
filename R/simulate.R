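#' Simulation settings for a synthetic cellogram
#'
#' Describes a direct-infusion single-cell acquisition to simulate: a
#' typical run holds 100 cells sampled in touch-down mode at 3 cells per
#' minute, scanning at 2 Hz over m/z 75–1000, with the run length sized
#' to the cell count plus a 10% margin. Species fall into the three
#' chronogram classes — high-S/N endogenous (sharp event-locked peaks over
#' a baseline three orders of magnitude lower), low-S/N endogenous
#' (event-locked peaks under an order of magnitude above an elevated
#' background), and background (static, slowly drifting, or spiking once
#' or twice per run) — plus steadily infused internal standards and
#' solvent blanks. Endogenous species may carry a 13C M+1 isotopologue at
#' natural abundance (0.011 per carbon). Every centroid's m/z is jittered
#' per scan (Gaussian, ppm scale) to exercise the dynamic alignment.
#' All randomness flows from the single `seed`.
#'
#' @param n_cells number of cells in the run.
#' @param cell_rate sampling rate, cells per minute.
#' @param scan_hz scans per second.
#' @param mz_range acquisition window (Th).
#' @param n_high_sn,n_low_sn,n_background_static,n_background_drift,n_background_spike
#'   species counts per chronogram class.
#' @param n_internal_standard,n_blank counts of IS and solvent-blank
#'   species (background-like, with known m/z reported in the truth).
#' @param marker_mz m/z of the designated cell marker (first high-S/N
#'   species, present in every cell).
#' @param marker_intensity marker peak amplitude.
#' @param rise_scans scans of linear rise at event onset.
#' @param decay_scans range of per-species exponential decay constants
#'   (scans), emulating exhaustive extraction of the metabolome.
#' @param high_sn_meanlog,high_sn_sdlog log-normal peak-amplitude
#'   distribution of high-S/N species.
#' @param high_sn_baseline_frac baseline level as a fraction of amplitude
#'   for high-S/N species.
#' @param low_sn_meanlog,low_sn_sdlog,low_sn_baseline_frac same for
#'   low-S/N species (elevated baseline).
#' @param bg_meanlog,bg_sdlog log-normal level distribution of background
#'   (and blank) species.
#' @param detect_prob_high,detect_prob_low per-cell presence probability
#'   of an endogenous species.
#' @param cell_sdlog log-normal sd of per-cell intensity factors
#'   (biological heterogeneity).
#' @param noise_sdlog_endo,noise_sdlog_bg multiplicative per-scan
#'   intensity noise (log sd) for endogenous vs background/blank species;
#'   background solvent flicker is burstier than cell-derived signal.
#' @param mass_jitter_ppm per-scan m/z jitter sd (ppm).
#' @param isotopologue_fraction fraction of endogenous species carrying an
#'   M+1.
#' @param carbon_range carbon-count range for isotopologue abundance.
#' @param time_jitter_min sd of cell-arrival jitter (minutes).
#' @param min_separation_ppm minimum spacing enforced between distinct
#'   species (and their M+1 slots).
#' @param intensity_floor instrument centroiding threshold: no centroid is
#'   emitted below this intensity, so weak species appear sparsely — the
#'   reason near-threshold background leaks through fold-change filtering
#'   on real centroided data.
#' @param seed RNG seed; fixes the complete output.
#' @return classed list `sim_config`.
#' @export
sim_config <- function(n_cells = 100L, cell_rate = 3, scan_hz = 2,
                       mz_range = c(75, 1000),
                       n_high_sn = 25L, n_low_sn = 15L,
                       n_background_static = 10L, n_background_drift = 5L,
                       n_background_spike = 5L,
                       n_internal_standard = 2L, n_blank = 3L,
                       marker_mz = 760.586, marker_intensity = 1e7,
                       rise_scans = 2L, decay_scans = c(2, 3.5),
                       high_sn_meanlog = log(1e6), high_sn_sdlog = 0.7,
                       high_sn_baseline_frac = 1e-3,
                       low_sn_meanlog = log(3e4), low_sn_sdlog = 0.5,
                       low_sn_baseline_frac = 0.3,
                       bg_meanlog = log(1e4), bg_sdlog = 1,
                       detect_prob_high = 0.95, detect_prob_low = 0.7,
                       cell_sdlog = 0.5,
                       noise_sdlog_endo = 0.15, noise_sdlog_bg = 0.5,
                       mass_jitter_ppm = 2,
                       isotopologue_fraction = 0.3,
                       carbon_range = c(5L, 40L),
                       time_jitter_min = 0.02,
                       min_separation_ppm = 50, intensity_floor = 2e3,
                       seed = 1L) {
  stopifnot(n_cells >= 1L, cell_rate > 0, scan_hz > 0,
            isotopologue_fraction >= 0, isotopologue_fraction <= 1,
            mass_jitter_ppm >= 0, n_high_sn >= 1L)
  run_minutes <- n_cells / cell_rate * 1.1
  if (n_cells / cell_rate > run_minutes)
    stop("infeasible config: cells x rate exceed the run length")
  structure(as.list(environment()), class = "sim_config")
}

# event shape kernel: linear rise then exponential decay, truncated where
# it falls below 2% of the apex (probe retraction ends extraction abruptly)
.event_kernel <- function(rise_scans, decay) {
  len <- rise_scans + ceiling(decay * log(50))
  k <- numeric(len)
  k[seq_len(rise_scans)] <- seq_len(rise_scans) / rise_scans
  tail_idx <- (rise_scans + 1L):len
  k[tail_idx] <- exp(-(tail_idx - rise_scans) / decay)
  k
}

# add per-cell copies of kernel*amp into a length-ns trace
.add_events <- function(trace, onsets, amps, kernel) {
  L <- length(kernel)
  idx <- rep(onsets, each = L) + rep(seq_len(L) - 1L, times = length(onsets))
  val <- rep(amps, each = L) * rep(kernel, times = length(onsets))
  ok <- idx <= length(trace)
  agg <- rowsum(val[ok], idx[ok])
  at <- as.integer(rownames(agg))
  trace[at] <- trace[at] + agg[, 1L]
  trace
}

#' Simulate a single-cell direct-infusion run with ground truth
#'
#' Generates a complete centroided cellogram per [sim_config()]: cells
#' placed at the configured rate with arrival jitter, species traces per
#' chronogram class, natural-abundance M+1 isotopologues, steadily infused
#' internal standards, solvent blanks, multiplicative scan noise and
#' per-scan ppm mass jitter, assembled into ordered centroided spectra.
#' The paired ground truth records the true events (windowed exactly as
#' [detect_cell_events()] windows its detections, background of 10 scans),
#' every species' true m/z, class, carbon count and parent link, and each
#' species' per-cell summed intensity over the true peak windows.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sc_simulation`: `run` (an [sc_run]) and `truth`
#'   (list: `events` as a `cell_events` data.frame, `species` data.frame,
#'   `cell_intensity` species-by-cells matrix, `marker_mz`, `config`).
#' @export
simulate_run <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(cfg$seed)

  ns <- ceiling(cfg$run_minutes * 60 * cfg$scan_hz)
  times <- (seq_len(ns) - 1L) / (cfg$scan_hz * 60)   # minutes

  # --- cell arrival times -------------------------------------------------
  base <- (seq_len(cfg$n_cells) - 0.5) / cfg$cell_rate
  tt <- sort(base + stats::rnorm(cfg$n_cells, 0, cfg$time_jitter_min))
  tt <- pmin(pmax(tt, times[1L]), times[ns])
  onsets <- pmin(ns, floor(tt * 60 * cfg$scan_hz) + 1L)

  # --- species table ------------------------------------------------------
  classes <- c(rep("high_sn", cfg$n_high_sn), rep("low_sn", cfg$n_low_sn),
               rep("background_static", cfg$n_background_static),
               rep("background_drift", cfg$n_background_drift),
               rep("background_spike", cfg$n_background_spike),
               rep("internal_standard", cfg$n_internal_standard),
               rep("solvent_blank", cfg$n_blank))
  n_sp <- length(classes)
  lo <- cfg$mz_range[1L] + 5; hi <- cfg$mz_range[2L] - 5
  # marker first; keep every species (and its potential M+1 slot) separated
  iso_d <- 1.003355
  cand_ok <- function(m, pool) {
    slots <- c(pool, pool + iso_d)
    all(abs(m - slots) / m * 1e6 > cfg$min_separation_ppm &
        abs(m + iso_d - slots) / m * 1e6 > cfg$min_separation_ppm)
  }
  mz <- cfg$marker_mz
  while (length(mz) < n_sp) {
    m <- stats::runif(1, lo, hi)
    if (cand_ok(m, mz)) mz <- c(mz, m)
  }
  species <- data.frame(species_id = seq_len(n_sp), mz = mz, class = classes,
                        carbons = NA_integer_, parent_id = NA_integer_,
                        stringsAsFactors = FALSE)

  # --- clean trace per species -------------------------------------------
  S <- matrix(0, n_sp, ns)
  present <- matrix(FALSE, n_sp, cfg$n_cells)
  t_frac <- times / times[ns]
  for (i in seq_len(n_sp)) {
    cl <- classes[i]
    if (cl %in% c("high_sn", "low_sn")) {
      amp <- if (i == 1L) cfg$marker_intensity else
        stats::rlnorm(1, if (cl == "high_sn") cfg$high_sn_meanlog else cfg$low_sn_meanlog,
                      if (cl == "high_sn") cfg$high_sn_sdlog else cfg$low_sn_sdlog)
      bl_frac <- if (cl == "high_sn") cfg$high_sn_baseline_frac else cfg$low_sn_baseline_frac
      p_det <- if (i == 1L) 1 else
        if (cl == "high_sn") cfg$detect_prob_high else cfg$detect_prob_low
      pres <- stats::runif(cfg$n_cells) < p_det
      present[i, ] <- pres
      cellfac <- stats::rlnorm(cfg$n_cells, 0, cfg$cell_sdlog)
      kernel <- .event_kernel(cfg$rise_scans,
                              stats::runif(1, cfg$decay_scans[1L], cfg$decay_scans[2L]))
      tr <- rep(amp * bl_frac, ns)
      if (any(pres))
        tr <- .add_events(tr, onsets[pres], amp * cellfac[pres], kernel)
      S[i, ] <- tr
    } else if (cl == "background_static") {
      S[i, ] <- stats::rlnorm(1, cfg$bg_meanlog, cfg$bg_sdlog)
    } else if (cl == "background_drift") {
      lvl <- stats::rlnorm(1, cfg$bg_meanlog, cfg$bg_sdlog)
      a <- stats::runif(1, 0.3, 0.8)
      f <- stats::runif(1, 0.5, 2)
      ph <- stats::runif(1, 0, 2 * pi)
      S[i, ] <- lvl * (1 + a * sin(2 * pi * f * t_frac + ph))
    } else if (cl == "background_spike") {
      lvl <- stats::rlnorm(1, cfg$bg_meanlog - 1, cfg$bg_sdlog)
      tr <- rep(lvl, ns)
      nsp_ev <- sample(1:2, 1)
      at <- sample(ns - 40L, nsp_ev)
      kernel <- .event_kernel(cfg$rise_scans,
                              stats::runif(1, cfg$decay_scans[1L], cfg$decay_scans[2L]))
      tr <- .add_events(tr, at, lvl * stats::runif(nsp_ev, 20, 100), kernel)
      S[i, ] <- tr
    } else if (cl == "internal_standard") {
      S[i, ] <- stats::rlnorm(1, log(1e5), 0.3)
    } else {                                  # solvent_blank
      S[i, ] <- stats::rlnorm(1, cfg$bg_meanlog, cfg$bg_sdlog)
    }
  }

  # --- isotopologues ------------------------------------------------------
  endo <- which(classes %in% c("high_sn", "low_sn"))
  iso_parents <- endo[stats::runif(length(endo)) < cfg$isotopologue_fraction]
  if (length(iso_parents)) {
    carbons <- sample(cfg$carbon_range[1L]:cfg$carbon_range[2L],
                      length(iso_parents), replace = TRUE)
    iso_rows <- data.frame(species_id = n_sp + seq_along(iso_parents),
                           mz = species$mz[iso_parents] + iso_d,
                           class = "isotopologue", carbons = carbons,
                           parent_id = iso_parents, stringsAsFactors = FALSE)
    species <- rbind(species, iso_rows)
    S <- rbind(S, S[iso_parents, , drop = FALSE] * (0.011 * carbons))
    present <- rbind(present, present[iso_parents, , drop = FALSE])
    n_sp <- nrow(species)
  }

  # --- noise and mass jitter ---------------------------------------------
  sd_by_class <- ifelse(species$class %in%
                          c("high_sn", "low_sn", "isotopologue", "internal_standard"),
                        cfg$noise_sdlog_endo, cfg$noise_sdlog_bg)
  noise <- matrix(stats::rlnorm(n_sp * ns, 0, rep(sd_by_class, ns)), n_sp, ns)
  I <- S * noise
  I[I < cfg$intensity_floor] <- 0            # below the centroiding threshold
  MZ <- species$mz * (1 + matrix(stats::rnorm(n_sp * ns, 0, cfg$mass_jitter_ppm * 1e-6),
                                 n_sp, ns))

  # --- truth events and per-cell intensities ------------------------------
  events <- .build_event_windows(onsets, times[onsets], ns,
                                 background_scans = 10L,
                                 pre_extension_scans = 0L)
  class(events) <- c("cell_events", "data.frame")
  attr(events, "n_scans") <- ns
  cell_intensity <- matrix(0, n_sp, cfg$n_cells,
                           dimnames = list(NULL, as.character(events$cell_id)))
  for (k in seq_len(cfg$n_cells)) {
    sc <- seq.int(events$peak_start[k], events$peak_end[k] - 1L)
    cell_intensity[, k] <- rowSums(I[, sc, drop = FALSE])
  }

  # --- assemble centroided spectra ---------------------------------------
  peaks <- vector("list", ns)
  for (j in seq_len(ns)) {
    emit <- which(I[, j] > 0)
    o <- emit[order(MZ[emit, j])]
    m <- MZ[o, j]; v <- I[o, j]
    dup <- which(diff(m) <= 0)
    while (length(dup)) {                     # merge coincident centroids
      v[dup] <- v[dup] + v[dup + 1L]
      m <- m[-(dup + 1L)]; v <- v[-(dup + 1L)]
      dup <- which(diff(m) <= 0)
    }
    peaks[[j]] <- cbind(mz = m, intensity = v)
  }
  run <- sc_run(peaks, times, polarity = "positive", mz_range = cfg$mz_range,
                source_path = sprintf("simulated(seed=%d)", cfg$seed))

  truth <- list(events = events, species = species,
                cell_intensity = cell_intensity, present = present,
                marker_mz = cfg$marker_mz, config = cfg)
  structure(list(run = run, truth = truth), class = "sc_simulation")
}

#' @export
print.sc_simulation <- function(x, ...) {
  cat(sprintf("<sc_simulation> %d cells, %d species (%d isotopologues), seed %d\n",
              nrow(x$truth$events), nrow(x$truth$species),
              sum(x$truth$species$class == "isotopologue"),
              x$truth$config$seed))
  print(x$run)
  invisible(x)
}

#' Binary ground-truth label of each simulated species
#'
#' Endogenous means a monoisotopic high- or low-S/N cell-derived species;
#' isotopologues, internal standards, blanks and all background classes
#' count as background (they are what the filters and the classifier
#' should remove).
#'
#' @param species the `species` data.frame of a simulation truth.
#' @return character vector, `"endogenous"` / `"background"`.
#' @export
truth_binary_labels <- function(species) {
  ifelse(species$class %in% c("high_sn", "low_sn"), "endogenous", "background")
}

#' Three-class chronogram label of each simulated species
#'
#' Maps the simulator's species classes onto the classifier taxonomy:
#' background subtypes, internal standards, and solvent blanks are all
#' `background` profiles; an isotopologue inherits its parent's profile
#' class (its trace is a scaled copy of the parent's).
#'
#' @param species the `species` data.frame of a simulation truth.
#' @return character vector over `c("high_sn", "low_sn", "background")`.
#' @export
truth_profile_labels <- function(species) {
  cls <- species$class
  out <- ifelse(cls %in% c("high_sn", "low_sn"), cls, "background")
  iso <- which(cls == "isotopologue")
  if (length(iso)) out[iso] <- species$class[species$parent_id[iso]]
  out
}

#' Export simulation ground truth to CSV
#'
#' Writes `events.csv` (the true cell events, in the exact column layout
#' of [write_events_csv()]), `species.csv` (true m/z, class, carbon count,
#' parent link) and `cell_intensity.csv` (per-cell true summed intensity,
#' species in rows).
#'
#' @param truth the `truth` element of an `sc_simulation`.
#' @param dir output directory (created if needed).
#' @return character vector of the three paths, invisibly.
#' @export
export_truth <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "events.csv")
  write_events_csv(truth$events, p1)
  p2 <- file.path(dir, "species.csv")
  utils::write.csv(truth$species, p2, row.names = FALSE)
  p3 <- file.path(dir, "cell_intensity.csv")
  ci <- data.frame(species_id = truth$species$species_id,
                   mz = truth$species$mz, truth$cell_intensity,
                   check.names = FALSE)
  utils::write.csv(ci, p3, row.names = FALSE)
  invisible(c(p1, p2, p3))
}
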