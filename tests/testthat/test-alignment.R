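obs_df <- function(mz, intensity = rep(1, length(mz)),
                   id = seq_along(mz)) {
  data.frame(id = id, mz = mz, intensity = intensity)
}

test_that("group_mz honours the ppm tolerance boundary", {
  g1 <- group_mz(obs_df(c(200.0000, 200.0008)), ppm_tol = 5)   # 4 ppm apart
  expect_identical(nrow(g1$groups), 1L)
  g2 <- group_mz(obs_df(c(200.0000, 200.0030)), ppm_tol = 5)   # 15 ppm apart
  expect_identical(nrow(g2$groups), 2L)
  expect_error(group_mz(obs_df(c(-1, 200)), 5), "positive")
})

test_that("group_mz partitions input, ignores order, matches single-linkage", {
  for (seed in 1:10) {
    set.seed(seed)
    centers <- 200 * (1 + cumsum(runif(10, 100e-6, 300e-6))) # >=100 ppm apart
    # jitter sd = tol/4, truncated at 2 sd so a cluster spans at most one
    # tolerance width (the regime where greedy and single-linkage agree)
    jit <- pmin(pmax(rnorm(100, 0, 1.25), -2.5), 2.5) * 1e-6
    mz <- rep(centers, each = 10) * (1 + jit)
    o <- obs_df(mz, intensity = rexp(100))
    gr <- group_mz(o, ppm_tol = 5)
    # partition: every observation in exactly one group
    expect_identical(nrow(gr$members), 100L)
    expect_false(anyNA(gr$members$group))
    expect_identical(sum(gr$groups$n_members), 100L)
    # matches the 1-D single-linkage oracle on separated centers
    oracle <- single_linkage_groups(gr$members$mz, 5)
    expect_identical(nrow(gr$groups), length(unique(oracle)))
    expect_identical(nrow(gr$groups), 10L)
    split_ours <- split(seq_len(100), gr$members$group)
    split_oracle <- split(seq_len(100), oracle)
    expect_true(all(vapply(split_ours, function(s)
      any(vapply(split_oracle, identical, logical(1), y = s)), logical(1))))
    # permutation invariance
    perm <- sample(nrow(o))
    gr2 <- group_mz(o[perm, ], ppm_tol = 5)
    expect_equal(gr2$groups$rep_mz, gr$groups$rep_mz)
  }
})

test_that("group representative mass is the intensity-weighted mean", {
  o <- obs_df(c(200.0000, 200.0008), intensity = c(3, 1))
  gr <- group_mz(o, 5)
  expect_equal(gr$groups$rep_mz, (3 * 200.0000 + 1 * 200.0008) / 4)
  expect_true(gr$groups$rep_mz >= min(o$mz) && gr$groups$rep_mz <= max(o$mz))
  # unweighted alternative
  gru <- group_mz(o, 5, weighted = FALSE)
  expect_equal(gru$groups$rep_mz, mean(o$mz))
})

test_that("within-event alignment integrates species and flags background", {
  # two species, constant m/z, across a hand-built event
  peaks <- lapply(1:20, function(i)
    cbind(mz = c(200.0, 300.0), intensity = c(10 * i, 5)))
  run <- sc_run(peaks, rt = (0:19) / 120, mz_range = c(75, 1000))
  event <- data.frame(cell_id = 1L, trigger_scan = 11L, trigger_time = 10 / 120,
                      bg_start = 1L, bg_end = 11L, peak_start = 11L,
                      peak_end = 21L, ext_start = 1L, ext_end = 21L)
  ef <- align_within_event(run, event, ppm_tol = 5)
  expect_identical(nrow(ef), 2L)
  expect_equal(ef$intensity[1], sum(10 * (11:20)))    # peak-window sum
  expect_equal(ef$peak_max[1], 200)
  expect_equal(ef$bg_mean[1], mean(10 * (1:10)))
  expect_equal(ef$fold_change[1], 200 / 55)
  expect_equal(ef$fold_change[2], 1)                  # flat species
  mem <- attr(ef, "members")
  expect_identical(sum(mem$background), 20L)          # 10 scans x 2 species
})

test_that("scan-level ppm jitter within tolerance stays one group", {
  set.seed(8)
  mz <- 500 * (1 + runif(40, -2e-6, 2e-6))           # +-2 ppm jitter
  peaks <- lapply(seq_along(mz), function(i)
    cbind(mz = mz[i], intensity = 100))
  run <- sc_run(peaks, rt = (seq_along(mz) - 1) / 120, mz_range = c(75, 1000))
  event <- data.frame(cell_id = 1L, trigger_scan = 11L, trigger_time = 10 / 120,
                      bg_start = 1L, bg_end = 11L, peak_start = 11L,
                      peak_end = 41L, ext_start = 1L, ext_end = 41L)
  ef <- align_within_event(run, event, ppm_tol = 5)
  expect_identical(nrow(ef), 1L)
})

test_that("across-event alignment builds the cells-by-features matrix", {
  ef <- function(mz, int, fc = 10) {
    structure(data.frame(rep_mz = mz, intensity = int, peak_max = int,
                         bg_mean = 1, fold_change = fc,
                         n_members = 1L),
              class = c("event_features", "data.frame"))
  }
  tab <- align_across_events(list(`1` = ef(c(200.0, 300.0), c(5, 7)),
                                  `2` = ef(200.0004, 11)), ppm_tol = 5)
  expect_identical(nrow(tab$features), 2L)
  expect_equal(tab$intensity[, 1], c(`1` = 5, `2` = 11))   # shared species
  expect_equal(tab$intensity[, 2], c(`1` = 7, `2` = 0))    # zero-filled
  expect_true(!is.unsorted(tab$features$rep_mz, strictly = TRUE))
  expect_error(align_across_events(list(`1` = ef(200, 1), `1` = ef(200, 1))),
               "duplicate")
})

test_that("simulated run: two-step alignment recovers species and conserves intensity", {
  sim <- get_sim(21, n_cells = 12, n_high_sn = 8, n_low_sn = 4,
                 n_background_static = 3, n_background_drift = 0,
                 n_background_spike = 0, isotopologue_fraction = 0,
                 mass_jitter_ppm = 0.5)
  ev <- sim$truth$events                       # exact truth windows
  tab <- align_run(sim$run, ev, ppm_tol = 5)
  sp <- sim$truth$species
  # every species recovered as a feature within tolerance
  hits <- vapply(sp$mz, function(m)
    any(abs(tab$features$rep_mz - m) / m * 1e6 <= 5), logical(1))
  expect_true(all(hits))
  # conservation: matrix total equals all peak-window centroid intensity
  total <- sum(vapply(seq_len(nrow(ev)), function(k) {
    sum(vapply(seq.int(ev$peak_start[k], ev$peak_end[k] - 1L), function(s)
      sum(sim$run$peaks[[s]][, 2]), double(1)))
  }, double(1)))
  expect_equal(sum(tab$intensity), total, tolerance = 1e-9)
  # two-step result matches one-step grouping over all raw peak centroids
  allobs <- do.call(rbind, lapply(seq_len(nrow(ev)), function(k) {
    scans <- seq.int(ev$peak_start[k], ev$peak_end[k] - 1L)
    do.call(rbind, lapply(scans, function(s) {
      p <- sim$run$peaks[[s]]
      if (!nrow(p)) return(NULL)
      data.frame(id = s, mz = p[, 1], intensity = p[, 2])
    }))
  }))
  one <- group_mz(allobs, 5)
  expect_identical(nrow(tab$features), nrow(one$groups))
  # representative masses agree to well under the grouping tolerance
  expect_true(all(abs(tab$features$rep_mz - one$groups$rep_mz) /
                    one$groups$rep_mz * 1e6 < 1))
})

test_that("cross-file alignment merges features and keeps provenance", {
  mk <- function(mz, ids, val) {
    nf <- length(mz)
    cellogram:::new_cell_feature_table(
      ids, data.frame(feature_id = seq_len(nf), rep_mz = mz,
                      n_members = 1L, ppm_spread = 0),
      matrix(val, length(ids), nf), matrix(10, length(ids), nf))
  }
  a <- mk(500.0000, c("c1", "c2"), 5)
  b <- mk(500.0015, c("c1", "c2"), 7)          # 3 ppm away: merged
  m <- align_across_files(list(runA = a, runB = b), ppm_tol = 5)
  expect_identical(nrow(m$features), 1L)
  expect_identical(length(m$cell_ids), 4L)
  expect_true(all(c("runA:c1", "runB:c2") %in% m$cell_ids))
  expect_equal(unname(m$intensity[, 1]), c(5, 5, 7, 7))
  # partially overlapping species sets: union recovered
  c3 <- mk(c(400.0, 500.0), c("x"), c(1, 2))
  m2 <- align_across_files(list(a = a, c = c3), ppm_tol = 5)
  expect_identical(nrow(m2$features), 2L)
  neg <- mk(600, "n1", 1); neg$polarity <- "negative"
  expect_error(align_across_files(list(a = a, n = neg)), "polarity")
})

test_that("feature tables round-trip through their CSV layout", {
  tab <- make_random_table(33, n_cells = 5, n_features = 8)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "table.csv")
  write_feature_table_csv(tab, p)
  expect_true(all(file.exists(file.path(dir, c("table.csv",
                                               "table_features.csv",
                                               "table_fc.csv")))))
  back <- read_feature_table_csv(p)
  expect_equal(unname(back$intensity), unname(tab$intensity), tolerance = 1e-12)
  expect_equal(unname(back$fold_change), unname(tab$fold_change),
               tolerance = 1e-12)
  expect_equal(back$features$rep_mz, tab$features$rep_mz)
  expect_identical(back$cell_ids, tab$cell_ids)
})
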