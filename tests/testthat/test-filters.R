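test_that("fold change follows the max-over-background-mean definition", {
  expect_equal(fold_change(c(100, 300, 250), rep(100, 10)), 3.0)
  # zero background: noise-floor fallback keeps FC finite
  expect_equal(fold_change(c(500), rep(0, 10), noise_floor = 1), 500)
  # only the trailing n_background scans enter the average
  expect_equal(fold_change(200, c(rep(1e6, 5), rep(10, 10)), n_background = 10),
               20)
  # random traces vs direct recomputation
  set.seed(12)
  for (i in 1:25) {
    pk <- rexp(sample(5:30, 1), 1e-3)
    bg <- rexp(sample(1:15, 1), 1e-2)
    nb <- sample(1:12, 1)
    want <- max(pk) / mean(utils::tail(bg, nb))
    expect_equal(fold_change(pk, bg, nb), want)
  }
})

test_that("FC filter is inclusive at the threshold and drops dead features", {
  tab <- make_random_table(1)
  cfg <- filter_config(fc_threshold = 3)
  tab$fold_change[, 1] <- 3                      # exactly at threshold
  tab$fold_change[, 2] <- 2.999
  res <- fc_filter(tab, cfg)
  expect_true(1L %in% res$retained)
  expect_false(2L %in% res$retained)
  expect_true(all(res$mask[, match(1L, res$retained)]))
  # brute force over a random table
  want <- which(apply(tab$fold_change >= 3, 2, any))
  expect_identical(res$retained, want)
})

test_that("DF filter keeps features passing FC in enough cells", {
  cfg <- filter_config(df_threshold = 0.33)
  mask <- matrix(FALSE, 100, 3)
  mask[1:40, 1] <- TRUE                          # 40% -> kept
  mask[1:32, 2] <- TRUE                          # 32% -> dropped
  mask[1:33, 3] <- TRUE                          # 33% -> kept (inclusive)
  expect_identical(df_filter(mask, cfg), c(1L, 3L))
  # counting oracle on random masks
  set.seed(3)
  for (i in 1:20) {
    m <- matrix(runif(200) < 0.4, 20, 10)
    want <- which(colSums(m) / 20 >= 1 / 3)
    expect_identical(df_filter(m, filter_config(df_threshold = 1 / 3)), want)
  }
})

test_that("deisotoping drops natural-abundance M+1 but spares lookalikes", {
  mk <- function(mzB, ratio) {
    intensity <- cbind(A = rep(1000, 10), B = rep(1000 * ratio, 10))
    cellogram:::new_cell_feature_table(
      paste0("c", 1:10),
      data.frame(feature_id = 1:2, rep_mz = c(104.1070, mzB),
                 n_members = 1L, ppm_spread = 0),
      intensity, intensity * 0 + 10)
  }
  cfg <- filter_config()
  # choline M+1: 5 carbons -> expected ratio ~ 5 x 0.011
  expect_identical(deisotope(mk(104.1070 + 1.00336, 0.055), cfg), 1L)
  # spacing off by 7 mTh: outside tolerance, retained
  expect_identical(deisotope(mk(104.1070 + 1.0100, 0.055), cfg), c(1L, 2L))
  # ratio too large for an isotopologue: a distinct species, retained
  expect_identical(deisotope(mk(104.1070 + 1.00336, 1.2), cfg), c(1L, 2L))
})

test_that("exclusion lists remove matching masses within tolerance", {
  tab <- make_random_table(4)
  expect_identical(exclusion_filter(tab, numeric(0), 5),
                   seq_len(nrow(tab$features)))
  # the PC 34:1 example: 760.5850 vs listed 760.586 is ~1.3 ppm
  tab$features$rep_mz[5] <- 760.5850
  kept <- exclusion_filter(tab, 760.586, 5)
  expect_false(5L %in% kept)
  # brute force on random lists
  set.seed(9)
  for (i in 1:10) {
    lst <- runif(4, 80, 990)
    want <- which(!vapply(tab$features$rep_mz, function(m)
      any(abs(m - lst) / m * 1e6 <= 5), logical(1)))
    expect_identical(exclusion_filter(tab, lst, 5), want)
  }
})

test_that("mass-defect filtering excludes fractional-mass windows", {
  tab <- make_random_table(5)
  tab$features$rep_mz[1] <- 760.586
  tab$features$rep_mz[2] <- 445.120
  expect_true(1L %in% mass_defect_filter(tab, list(c(0.90, 0.9999))))
  expect_false(2L %in% mass_defect_filter(tab, list(c(0.10, 0.15))))
  # wrapped range [0.95, 0.05)
  tab$features$rep_mz[3] <- 500.97
  expect_false(3L %in% mass_defect_filter(tab, list(c(0.95, 0.05))))
  expect_warning(mass_defect_filter(tab, list(c(0.1, 0.3), c(0.2, 0.4))),
                 "merged")
  # brute force on random ranges
  set.seed(10)
  for (i in 1:10) {
    lo <- runif(2, 0, 0.8); rng <- list(c(lo[1], lo[1] + 0.1),
                                        c(lo[2], lo[2] + 0.05))
    frac <- tab$features$rep_mz %% 1
    want <- which(!vapply(frac, function(f)
      any(vapply(rng, function(r) f >= r[1] && f < r[2], logical(1))),
      logical(1)))
    got <- suppressWarnings(mass_defect_filter(tab, rng))
    expect_identical(got, want)
  }
})

test_that("cascade is cumulative, monotone and idempotent", {
  cfg <- filter_config(is_list = c(200.5), blank_list = c(300.5),
                       mdf_ranges = list(c(0.4, 0.45)))
  expect_error(run_cascade(make_random_table(6), cfg, order = "bogus"),
               "unknown")
  r0 <- run_cascade(make_random_table(6), cfg, order = character(0))
  expect_identical(nrow(r0$report), 0L)
  expect_identical(nrow(r0$table$features), 30L)
  for (seed in 1:50) {
    tab <- make_random_table(seed, n_cells = 10, n_features = 15)
    res <- run_cascade(tab, cfg)
    expect_true(all(res$report$features_out <= res$report$features_in))
    expect_true(all(diff(c(nrow(tab$features),
                           res$report$features_out)) <= 0))
    # applying the cascade to its own output changes nothing except FC's
    # zero-cell pruning, which has already happened: idempotence
    res2 <- run_cascade(res$table, cfg)
    expect_identical(res2$table$features$rep_mz, res$table$features$rep_mz)
  }
})

test_that("cascade retention accounting matches an independent recomputation", {
  tab <- make_random_table(77, n_cells = 15, n_features = 40)
  set.seed(78)
  truth <- sample(c("endogenous", "background"), 40, replace = TRUE)
  cfg <- filter_config()
  res <- run_cascade(tab, cfg, truth = truth)
  # recompute the final retention from the retained index set
  keep <- res$retained
  want_endo <- 100 * sum(truth[keep] == "endogenous") / sum(truth == "endogenous")
  want_bg <- 100 * sum(truth[keep] == "background") / sum(truth == "background")
  n <- nrow(res$report)
  expect_equal(res$report$retained_endogenous_pct[n], want_endo)
  expect_equal(res$report$retained_background_pct[n], want_bg)
  expect_error(run_cascade(tab, cfg, truth = truth[-1]), "cover")
})

test_that("binary metrics implement the confusion-matrix definitions", {
  pred <- c(rep(TRUE, 95), rep(FALSE, 5), rep(FALSE, 98), rep(TRUE, 2))
  truth <- c(rep("endogenous", 100), rep("background", 100))
  m <- binary_metrics(pred, truth)
  expect_equal(m$sensitivity, 0.95)
  expect_equal(m$specificity, 0.98)
  expect_equal(m$accuracy, 0.965)
  perf <- binary_metrics(truth == "endogenous", truth)
  expect_equal(c(perf$sensitivity, perf$specificity, perf$accuracy), c(1, 1, 1))
  # random predictions vs a hand-coded confusion matrix
  set.seed(13)
  for (i in 1:10) {
    tr <- sample(c("endogenous", "background"), 50, replace = TRUE)
    pr <- runif(50) < 0.5
    m <- binary_metrics(pr, tr)
    tp <- sum(pr & tr == "endogenous"); fn <- sum(!pr & tr == "endogenous")
    tn <- sum(!pr & tr == "background"); fp <- sum(pr & tr == "background")
    expect_identical(c(m$tp, m$fn, m$tn, m$fp), c(tp, fn, tn, fp))
    expect_equal(m$sensitivity, tp / (tp + fn))
    expect_equal(m$specificity, tn / (tn + fp))
  }
  # an empty truth class leaves its metric undefined
  m <- binary_metrics(c(TRUE, FALSE), c("endogenous", "endogenous"))
  expect_true(is.na(m$specificity))
})
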