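test_that("moving median matches hand-computed values with replicated edges", {
  rec <- swRecording(matrix(c(1, 9, 1, 9, 1), 1), fs = 1)
  out <- applyFilter(rec, filterSpec("moving_median", window_s = 3))
  expect_equal(samples(out)[1, ], c(1, 1, 9, 1, 1))
})

test_that("zero-phase Butterworth low-pass has unit DC gain", {
  rec <- swRecording(matrix(7.5, 1, 400), fs = 20)
  out <- applyFilter(rec, filterSpec("butterworth", band = "low",
                                     cutoff_hz = 2, order = 3))
  expect_lt(max(abs(samples(out)[1, ] - 7.5)), 1e-8)
  expect_error(applyFilter(rec, filterSpec("butterworth", cutoff_hz = 15)),
               "inside \\(0, fs/2\\)")
})

test_that("Savitzky-Golay smoothing keeps the slow component, drops the fast", {
  fs <- 50
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  slow <- sin(2 * pi * 0.05 * t)
  rec <- swRecording(matrix(slow + sin(2 * pi * 10 * t), 1), fs = fs)
  out <- applyFilter(rec, filterSpec("savitzky_golay", window_s = 2,
                                     poly_order = 2))
  expect_gt(stats::cor(samples(out)[1, ], slow), 0.99)
})

test_that("wavelet filter reconstructs perfectly when every band is kept", {
  set.seed(41)
  x <- rnorm(777)
  rec <- swRecording(matrix(x, 1), fs = 10)
  out <- applyFilter(rec, filterSpec("wavelet", wavelet_name = "db4",
                                     decomposition_level = 4,
                                     kept_bands = "approx,d4,d3,d2,d1"))
  expect_lt(max(abs(samples(out)[1, ] - x)), 1e-9)
  ## dropping all detail bands is a smoother: variance shrinks
  lp <- applyFilter(rec, filterSpec("wavelet", decomposition_level = 4,
                                    kept_bands = "approx"))
  expect_lt(stats::var(samples(lp)[1, ]), stats::var(x))
  expect_error(applyFilter(rec, filterSpec("wavelet", wavelet_name = "haar9")),
               "unknown wavelet")
})

test_that("moving-median baseline subtraction removes slow drift", {
  fs <- 10
  drift <- (0:(100 * fs - 1)) / fs * 1.0          # 1 uV/s ramp, 100 uV total
  rec <- swRecording(matrix(drift, 1), fs = fs)
  out <- removeBaseline(rec, "moving_median_subtract", 20)
  interior <- samples(out)[1, (20 * fs):(80 * fs)]
  expect_lt(max(abs(interior)), 0.05 * 100)
  ## zero in, zero out
  z <- removeBaseline(swRecording(matrix(0, 1, 500), fs = fs),
                      "moving_median_subtract", 20)
  expect_equal(samples(z)[1, ], rep(0, 500))
  expect_warning(removeBaseline(rec, "moving_median_subtract", 20,
                                dominant_period_s = 20),
                 "below 5x")
})

test_that("baseline wander removal preserves event peak-to-trough", {
  sc <- clean_scenario(duration = 120, seed = 2)
  clean <- generateRecording(sc)
  wander <- generateRecording(slowWaveScenario(
    duration = 120, white_sd_uv = 0, wander_amp_uv = 300, wander_hz = 0.002,
    wander_walk_uv = 0, seed = 2))
  f_clean <- removeBaseline(clean$recording, "moving_median_subtract", 20)
  f_wander <- removeBaseline(wander$recording, "moving_median_subtract", 20)
  ch <- 1L
  t1 <- clean$truth$marks$time[clean$truth$marks$channel == "ch1"][2]
  win <- round((t1 + c(-1, 1)) * 32) + 1L
  pp <- function(r) diff(range(samples(r)[ch, win[1]:win[2]]))
  expect_lt(abs(pp(f_wander) - pp(f_clean)) / pp(f_clean), 0.10)
})

test_that("filters never shift a clean event's steepest descent", {
  sc <- clean_scenario(duration = 60, seed = 3)
  gen <- generateRecording(sc)
  fs <- 32
  steepest <- function(r, ch) {
    x <- samples(r)[ch, ]
    which.min(diff(x))
  }
  ref <- steepest(gen$recording, 5)
  for (spec in list(filterSpec("moving_median", window_s = 0.5),
                    filterSpec("savitzky_golay", window_s = 1, poly_order = 2),
                    filterSpec("butterworth", band = "low", cutoff_hz = 4,
                               order = 3))) {
    out <- applyFilter(gen$recording, spec)
    expect_lt(abs(steepest(out, 5) - ref), 2)  # < 1 sample of lag
  }
})

test_that("filtering preserves shape, rate and channel order", {
  set.seed(42)
  rec <- swRecording(matrix(rnorm(5 * 200), 5, 200), fs = 25,
                     channelIds = paste0("e", 1:5))
  out <- applyFilter(rec, filterSpec("savitzky_golay", window_s = 0.5))
  expect_identical(dim(samples(out)), dim(samples(rec)))
  expect_identical(samplingRate(out), samplingRate(rec))
  expect_identical(channelIds(out), channelIds(rec))
  expect_error(applyFilter(rec, filterSpec("moving_median", window_s = 60)),
               "longer than signal")
})

test_that("channel exclusion is honoured, reversible and passthrough", {
  sc <- clean_scenario(duration = 60, seed = 4)
  gen <- generateRecording(sc)
  rec <- setChannelStatus(gen$recording, "ch3", "excluded")
  out <- applyFilter(rec, filterSpec("savitzky_golay", window_s = 1))
  expect_identical(samples(out)[3, ], samples(rec)[3, ])   # untouched
  expect_false(identical(samples(out)[1, ], samples(rec)[1, ]))
  mk <- fevtDetect(preprocessDefault(rec))
  expect_false("ch3" %in% marksTable(mk)$channel)
  expect_equal(length(unique(marksTable(mk)$channel)), 63L)
  ## re-inclusion restores the never-excluded result
  back <- setChannelStatus(rec, "ch3", "ok")
  mk2 <- fevtDetect(preprocessDefault(back))
  mk_ref <- fevtDetect(preprocessDefault(gen$recording))
  expect_identical(marksTable(mk2), marksTable(mk_ref))
  expect_error(setChannelStatus(rec, "nope", "excluded"), "unknown channel")
})

test_that("excluding a noise-only channel removes its false positives", {
  sc <- slowWaveScenario(duration = 120, dead_channels = 17L, seed = 5)
  gen <- generateRecording(sc)
  rec <- preprocessDefault(gen$recording)
  mk_all <- fevtDetect(rec)
  fp_dead <- sum(marksTable(mk_all)$channel == "ch17")
  mk_excl <- fevtDetect(setChannelStatus(rec, "ch17", "excluded"))
  expect_equal(sum(marksTable(mk_excl)$channel == "ch17"), 0L)
  expect_equal(nrow(marksTable(mk_all)) - nrow(marksTable(mk_excl)), fp_dead)
})
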