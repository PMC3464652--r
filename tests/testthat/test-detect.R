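test_that("falling-edge transform is zero on rising edges, exact on ramps", {
  fs <- 8
  up <- seq(0, 10, length.out = 81)
  expect_equal(fallingEdgeTransform(up, fs, smooth_s = 0), rep(0, 81))
  ## slope -1 uV/sample -> derivative -fs uV/s -> D = fs^2 at p = 2
  down <- -(1:50)
  D <- fallingEdgeTransform(down, fs, power_p = 2, smooth_s = 0)
  expect_equal(D[2:49], rep(fs^2, 48))
  expect_error(fallingEdgeTransform(c(1, NA, 3), fs), "non-finite")
})

test_that("transform peaks at the steepest descent of a biphasic event", {
  fs <- 32
  tmpl <- waveformTemplate("biphasic", 400, 2, fs)
  x <- c(rep(0, 100), tmpl$samples, rep(0, 100))
  D <- fallingEdgeTransform(x, fs)
  truth <- which.min(diff(x))                 # brute-force steepest descent
  expect_lte(abs(which.max(D) - truth), 2)
})

test_that("variable threshold tracks the moving median with a positive floor", {
  fs <- 10
  theta <- variableThreshold(rep(1, 200), fs, window_s = 3, eta = 5)
  expect_equal(theta, rep(5, 200))
  th0 <- variableThreshold(rep(0, 200), fs, window_s = 3, eta = 5)
  expect_true(all(th0 > 0))
  expect_equal(length(unique(th0)), 1L)
  expect_error(variableThreshold(rep(1, 10), fs = 1, window_s = 1), "3 samples")
  expect_error(variableThreshold(rep(1, 10), fs = 1, window_s = 5, eta = 0),
               "eta")
})

test_that("sparse spikes do not inflate the median threshold", {
  fs <- 10
  D <- rep(0, 2000)
  spikes <- seq(100, 1900, by = 200)
  D[spikes] <- 100                             # duty cycle far below 50%
  theta <- variableThreshold(D, fs, window_s = 15, eta = 5)
  floor_val <- min(theta)
  expect_equal(max(theta), floor_val)          # zero inflation anywhere
  ## brute-force check at one spike
  k <- 151                                     # 15 s at 10 Hz, odd
  i <- spikes[5]
  expect_equal(stats::median(D[(i - 75):(i + 75)]), 0)
})

test_that("detection on a clean multi-wave recording recovers every event", {
  sc <- clean_scenario(duration = 120, seed = 6)   # 5+ planar waves
  gen <- generateRecording(sc)
  mk <- fevtDetect(preprocessDefault(gen$recording))
  tr <- gen$truth$marks
  per_ch <- table(marksTable(mk)$channel)
  expect_true(all(per_ch == table(tr$channel)))
  expect_lte(max_mark_error(mk, tr), 1 / 32)       # within one sample
})

test_that("a flat recording yields zero marks, not an error", {
  rec <- swRecording(matrix(0, 4, 600), fs = 30)
  mk <- fevtDetect(rec)
  expect_equal(nMarks(mk), 0L)
})

test_that("mark times are invariant to channel rescaling", {
  sc <- slowWaveScenario(duration = 120, seed = 7)
  gen <- generateRecording(sc)
  rec <- preprocessDefault(gen$recording)
  m1 <- marksTable(fevtDetect(rec))
  scaled <- rec
  scaled@samples <- scaled@samples * 3.7
  m2 <- marksTable(fevtDetect(scaled))
  expect_equal(m1$channel, m2$channel)
  expect_equal(m1$time, m2$time)
})

test_that("marks shift with the recording (interior time equivariance)", {
  sc <- clean_scenario(duration = 90, seed = 8)
  gen <- generateRecording(sc)
  rec <- preprocessDefault(gen$recording)
  fs <- samplingRate(rec)
  shift_n <- 4 * fs                              # 4 s of leading zeros
  shifted <- swRecording(cbind(matrix(0, nChannels(rec), shift_n),
                               samples(rec)), fs = fs,
                         channelIds = channelIds(rec))
  m1 <- marksTable(fevtDetect(rec))
  m2 <- marksTable(fevtDetect(shifted))
  keep1 <- m1$time > 8 & m1$time < 80
  match2 <- m2[m2$time - 4 > 8 & m2$time - 4 < 80, ]
  expect_equal(match2$time - 4, m1$time[keep1], tolerance = 1e-9)
})

test_that("sensitivity is monotone non-increasing in eta", {
  sc <- slowWaveScenario(duration = 120, seed = 9)
  gen <- generateRecording(sc)
  rec <- preprocessDefault(gen$recording)
  counts <- vapply(c(5, 15, 25, 60, 120), function(eta)
    nMarks(fevtDetect(rec, params = parameterSet(fevt.eta = eta))),
    integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("identical input and parameters give identical marks", {
  sc <- slowWaveScenario(duration = 60, seed = 10)
  gen <- generateRecording(sc)
  rec <- preprocessDefault(gen$recording)
  expect_identical(marksTable(fevtDetect(rec)), marksTable(fevtDetect(rec)))
})

test_that("manual mark editing adds, snaps, deletes and guards refractory", {
  sc <- clean_scenario(duration = 60, seed = 11)
  gen <- generateRecording(sc)
  rec <- preprocessDefault(gen$recording)
  mk <- fevtDetect(rec)
  m <- marksTable(mk)
  tr <- gen$truth$marks

  ## delete the only mark on a channel -> none left
  one <- eventMarks("ch1", 10)
  none <- editMarks(one, "delete", "ch1", 10.1)
  expect_equal(nMarks(none), 0L)

  ## add then delete at the same spot restores the original table
  t_free <- max(m$time[m$channel == "ch1"]) + 10
  added <- editMarks(mk, "add", "ch1", t_free)
  expect_equal(nMarks(added), nMarks(mk) + 1L)
  restored <- editMarks(added, "delete", "ch1", t_free)
  expect_identical(marksTable(restored), marksTable(mk))

  ## snapped add lands on the true steepest descent
  truth1 <- tr$time[tr$channel == "ch2"][2]
  del <- editMarks(mk, "delete", "ch2", truth1)
  snapped <- editMarks(del, "add", "ch2", truth1 + 0.3, recording = rec)
  got <- marksTable(snapped)
  expect_lte(min(abs(got$time[got$channel == "ch2"] - truth1)), 1 / 32)

  ## refractory conflict names the existing mark
  t_busy <- m$time[m$channel == "ch3"][1]
  expect_error(editMarks(mk, "add", "ch3", t_busy + 0.6),
               "refractory conflict")
  expect_error(editMarks(mk, "delete", "ch3", t_busy + 50), "no mark within")
})
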