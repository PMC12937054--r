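# Shared fixtures, built in code and memoised for the session.

.fx <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fx)) assign(key, builder(), envir = .fx)
  get(key, envir = .fx)
}

# hand-built EIC (no run needed)
make_eic <- function(values, scan_hz = 2, mz_center = 500, ppm_tol = 5) {
  structure(list(mz_center = mz_center, ppm_tol = ppm_tol,
                 times = (seq_along(values) - 1) / (scan_hz * 60),
                 values = as.numeric(values)),
            class = "sc_eic")
}

# tiny deterministic run: 3 scans, incl. an empty one
make_toy_run <- function() {
  sc_run(list(cbind(mz = c(100, 200.0005, 300), intensity = c(10, 20, 30)),
              cbind(mz = c(150.5, 200.0008), intensity = c(5, 6)),
              cbind(mz = numeric(0), intensity = numeric(0))),
         rt = c(0, 0.5, 1.0), mz_range = c(75, 1000))
}

# random run for brute-force EIC oracles
make_random_run <- function(seed, n_scans = 50, n_peaks = 30) {
  set.seed(seed)
  peaks <- lapply(seq_len(n_scans), function(i) {
    mz <- sort(runif(n_peaks, 80, 990))
    while (any(diff(mz) <= 0)) mz <- sort(runif(n_peaks, 80, 990))
    cbind(mz = mz, intensity = rexp(n_peaks, 1e-4))
  })
  sc_run(peaks, rt = (seq_len(n_scans) - 1) / 120, mz_range = c(75, 1000))
}

# random feature table for filter property tests
make_random_table <- function(seed, n_cells = 20, n_features = 30,
                              sparsity = 0.3) {
  set.seed(seed)
  mz <- sort(runif(n_features, 80, 990))
  while (any(diff(mz) / mz[-n_features] * 1e6 < 20))
    mz <- sort(runif(n_features, 80, 990))
  intensity <- matrix(rexp(n_cells * n_features, 1e-4), n_cells, n_features)
  intensity[matrix(runif(n_cells * n_features) < sparsity,
                   n_cells, n_features)] <- 0
  fc <- matrix(rexp(n_cells * n_features, 1 / 4), n_cells, n_features)
  fc[intensity == 0] <- 0
  features <- data.frame(feature_id = seq_len(n_features), rep_mz = mz,
                         n_members = 1L, ppm_spread = 0)
  cellogram:::new_cell_feature_table(paste0("c", seq_len(n_cells)),
                                     features, intensity, fc)
}

# 1-D single-linkage oracle: connected components of the "within ppm_tol"
# graph, i.e. split the sorted masses where a consecutive gap exceeds tol
single_linkage_groups <- function(mz, ppm_tol) {
  o <- order(mz)
  m <- mz[o]
  gap <- diff(m) / m[-length(m)] * 1e6
  grp_sorted <- cumsum(c(1L, as.integer(gap > ppm_tol)))
  grp <- integer(length(mz))
  grp[o] <- grp_sorted
  grp
}

# default simulated run + marker detection, memoised per seed
get_sim <- function(seed, ...) {
  memo(paste0("sim_", seed, "_", paste(c(...), collapse = "_")), function() {
    simulate_run(sim_config(seed = seed, ...))
  })
}

detect_marker <- function(sim, sn_threshold = 25, refractory = 0.15) {
  eic <- extract_eic(sim$run, sim$truth$marker_mz, 5)
  list(eic = eic,
       events = detect_cell_events(
         eic, detection_params(sim$truth$marker_mz, sn_threshold = sn_threshold,
                               refractory_period = refractory)))
}

# classifier study fixture: labeled simulated run with 300 species per
# chronogram class, rendered images, trained model and held-out split
get_classifier_fixture <- function() {
  memo("clf_fixture", function() {
    sim <- simulate_run(sim_config(
      n_high_sn = 300, n_low_sn = 300, n_background_static = 120,
      n_background_drift = 90, n_background_spike = 90, seed = 101))
    sp <- sim$truth$species
    labels <- truth_profile_labels(sp)
    eics <- extract_eic_matrix(sim$run, sp$mz, 5)
    images <- lapply(eics, render_eic_image)
    set.seed(202)
    test_idx <- sort(unlist(lapply(unique(labels), function(k) {
      i <- which(labels == k)
      sample(i, floor(0.3 * length(i)))
    })))
    train_idx <- setdiff(seq_along(images), test_idx)
    model <- train_eic_classifier(images[train_idx], labels[train_idx],
                                  train_config(seed = 7))
    pred <- classify_eics(model, images[test_idx], feature_ids = test_idx)
    metrics <- binary_metrics(pred$binary == "endogenous",
                              ifelse(labels[test_idx] %in% c("high_sn", "low_sn"),
                                     "endogenous", "background"))
    list(sim = sim, species = sp, labels = labels, eics = eics,
         images = images, model = model, test_idx = test_idx,
         train_idx = train_idx, pred = pred, metrics = metrics)
  })
}

# three synthetic, perfectly separable profile families
separable_images <- function(n_per_class, seed) {
  set.seed(seed)
  mk <- function(cls, i) {
    v <- switch(cls,
      flat = rep(1, 400) + runif(400, 0, 0.01),
      spikes = { x <- rep(0, 400); x[seq(10, 400, by = 20)] <- 1 + runif(1); x },
      noise = runif(400))
    render_eic_image(make_eic(v))
  }
  classes <- c(flat = "high_sn", spikes = "low_sn", noise = "background")
  imgs <- list(); labs <- character(0)
  for (cls in names(classes)) for (i in seq_len(n_per_class)) {
    imgs[[length(imgs) + 1L]] <- mk(cls, i)
    labs <- c(labs, classes[[cls]])
  }
  list(images = imgs, labels = labs)
}
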