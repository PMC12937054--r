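test_that("extract_eic matches a brute-force linear scan", {
  run <- make_random_run(42)
  set.seed(43)
  centers <- runif(20, 100, 950)
  for (mc in centers) {
    eic <- extract_eic(run, mc, ppm_tol = 200)   # wide tol to catch peaks
    brute <- vapply(run$peaks, function(p) {
      sum(p[abs(p[, 1] - mc) / mc * 1e6 <= 200, 2])
    }, double(1))
    expect_equal(eic$values, brute, tolerance = 1e-12)
  }
  # batched extraction agrees with the scalar path
  eics <- extract_eic_matrix(run, centers[1:5], ppm_tol = 200)
  for (i in 1:5)
    expect_equal(eics[[i]]$values, extract_eic(run, centers[i], 200)$values)
})

test_that("extract_eic sums co-eluting centroids and checks the window", {
  run <- sc_run(list(cbind(mz = c(200.0000, 200.0008), intensity = c(5, 7))),
                rt = 0, mz_range = c(75, 1000))
  expect_equal(extract_eic(run, 200.0004, 5)$values, 12)
  expect_error(extract_eic(run, 1500, 5), "outside")
})

test_that("estimate_noise recovers a Gaussian baseline scale and floors", {
  # constant trace: MAD degenerate, smallest positive value convention
  expect_equal(estimate_noise(make_eic(rep(100, 50))), 100)
  expect_equal(estimate_noise(make_eic(rep(0, 50))), 1.0)
  # Monte-Carlo: baseline N(100, 10), n = 1000
  set.seed(7)
  v <- rnorm(1000, 100, 10)
  expect_lt(abs(estimate_noise(make_eic(v)) - 10) / 10, 0.2)
  # peaks on the baseline do not inflate the estimate
  v2 <- v
  v2[seq(1, 1000, by = 20)] <- 5000
  expect_lt(abs(estimate_noise(make_eic(v2)) - 10) / 10, 0.35)
})

test_that("threshold crossings trigger events at pulse leading edges", {
  params <- detection_params(500, sn_threshold = 20, refractory_period = 0.1)
  expect_identical(nrow(detect_cell_events(make_eic(rep(0, 100)), params)), 0L)

  # two rectangular pulses at S/N ~50, separated by 3x the refractory
  set.seed(1)
  v <- abs(rnorm(200, 10, 1))
  noise_ref <- estimate_noise(make_eic(v))
  v[60:70] <- 50 * noise_ref
  v[130:140] <- 50 * noise_ref
  eic <- make_eic(v)   # 2 Hz: scans 60 and 130 are 0.58 min apart
  ev <- detect_cell_events(eic, params)
  expect_identical(ev$trigger_scan, c(60L, 130L))
  expect_identical(ev$cell_id, 1:2)
  # background windows sit immediately before the triggers
  expect_identical(ev$bg_start, c(50L, 120L))
  expect_identical(ev$bg_end, c(60L, 130L))
  # extended windows tile the run from the first background to the end
  expect_identical(ev$ext_end[1], ev$bg_start[2])
  expect_identical(ev$ext_end[2], 201L)
})

test_that("refractory period controls peak splitting on slow decays", {
  # a decaying peak drops below threshold, then a tail bump re-crosses it
  v <- rep(1, 300)
  v[100:110] <- 1000 * exp(-(0:10))
  v[118:119] <- 30
  eic <- make_eic(v)
  base <- detection_params(500, sn_threshold = 20, refractory_period = 0.2,
                           mode = "intensity")
  short <- detection_params(500, sn_threshold = 20, refractory_period = 0.05,
                            mode = "intensity")
  expect_identical(nrow(detect_cell_events(eic, base)), 1L)    # no split
  expect_identical(nrow(detect_cell_events(eic, short)), 2L)   # split
})

test_that("detection invariants hold on simulated cellograms", {
  sim <- get_sim(5, n_cells = 25)
  det <- detect_marker(sim)
  ev <- det$events
  # consecutive triggers at least one refractory period apart
  expect_true(all(diff(ev$trigger_time) >= 0.15 - 1e-12))
  # extended windows tile [first bg start, run end] without gaps/overlap
  expect_identical(ev$ext_start[-1], ev$ext_end[-nrow(ev)])
  expect_identical(ev$ext_end[nrow(ev)], n_scans(sim$run) + 1L)
  # S/N-mode detection is invariant to uniform intensity scaling
  sc <- det$eic
  sc$values <- sc$values * 37.5
  ev2 <- detect_cell_events(sc, detection_params(sim$truth$marker_mz,
                                                 sn_threshold = 25,
                                                 refractory_period = 0.15))
  expect_identical(ev$trigger_scan, ev2$trigger_scan)
})

test_that("manual event editing re-windows and renumbers consistently", {
  sim <- get_sim(5, n_cells = 25)
  det <- detect_marker(sim)
  params <- detection_params(sim$truth$marker_mz, sn_threshold = 25,
                             refractory_period = 0.15)
  ev <- det$events
  # removing an event renumbers and extends the neighbour's window
  ev2 <- edit_events(ev, det$eic, params, remove = 2L)
  expect_identical(ev2$cell_id, seq_len(nrow(ev) - 1L))
  expect_identical(ev2$trigger_scan, ev$trigger_scan[-2])
  expect_identical(ev2$ext_end[1], ev$ext_start[3])
  # adding back the removed trigger restores the original windows
  ev3 <- edit_events(ev2, det$eic, params, add = ev$trigger_time[2])
  expect_equal(ev3$trigger_scan, ev$trigger_scan)
  expect_equal(ev3$ext_start, ev$ext_start)
  # adding inside a refractory span is rejected with a warning
  expect_warning(
    ev4 <- edit_events(ev, det$eic, params, add = ev$trigger_time[3] + 0.02),
    "refractory")
  expect_identical(nrow(ev4), nrow(ev))
  expect_error(edit_events(ev, det$eic, params, remove = 999L), "unknown")
})

test_that("success rate rounds to the nearest integer percent", {
  expect_identical(success_rate(0, 10), 0L)
  expect_identical(success_rate(10, 10), 100L)
  expect_identical(success_rate(1, 3), 33L)
  expect_identical(success_rate(2, 3), 67L)
  expect_error(success_rate(1, 0), "positive")
})
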