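## small helper: marks + assignment for one planar wave on an 8x8 grid,
## delay `step_s` per column
planar_wave <- function(step_s = 1, n_rows = 8, n_cols = 8, t0 = 0) {
  ch <- paste0("ch", seq_len(n_rows * n_cols))
  cols <- (seq_len(n_rows * n_cols) - 1L) %% n_cols
  mk <- eventMarks(ch, t0 + cols * step_s)
  asg <- new("CycleAssignment",
             cycle = rep(1L, length(ch)), nCycles = 1L)
  list(marks = mk, assignment = asg)
}

test_that("activation maps place each member mark at its grid site", {
  lay <- gridLayout(8, 8, 4)
  w <- planar_wave()
  amap <- buildActivationMap(w$assignment, w$marks, lay, 1)
  expect_equal(sum(siteFlags(amap) == "measured"), 64L)
  expect_equal(sum(siteFlags(amap) == "missing"), 0L)
  expect_equal(activationTimes(amap)[3, 5], 4)     # col index 4 -> 4 s

  single <- eventMarks("ch10", 2.5)
  asg1 <- new("CycleAssignment", cycle = 1L, nCycles = 1L)
  m1 <- buildActivationMap(asg1, single, lay, 1)
  expect_equal(sum(siteFlags(m1) == "measured"), 1L)
  expect_equal(sum(siteFlags(m1) == "missing"), 63L)
  expect_error(buildActivationMap(asg1, single, lay, 2), "out of range")
})

test_that("noise-free maps equal the generator's arrival times exactly", {
  gen <- generateRecording(clean_scenario(duration = 90, seed = 61))
  mt <- marks_from_truth(gen$truth)
  amap <- buildActivationMap(mt$assignment, mt$marks, gen$layout, 2)
  tr <- gen$truth$marks[gen$truth$marks$cycle == 2, ]
  for (i in seq_len(nrow(tr)))
    expect_identical(activationTimes(amap)[tr$row[i] + 1, tr$col[i] + 1],
                     tr$time[i])
})

test_that("SIV fills by neighbour median, respects thresholds, two stages", {
  lay <- gridLayout(3, 3, 4)
  ch <- paste0("ch", c(1:4, 6:9))                 # centre (ch5) missing
  mk <- eventMarks(ch, c(1, 2, 3, 4, 5, 6, 7, 8))
  asg <- new("CycleAssignment", cycle = rep(1L, 8), nCycles = 1L)
  amap <- buildActivationMap(asg, mk, lay, 1)
  out <- sivInterpolate(amap, K1 = 5, K2 = 5)
  expect_equal(activationTimes(out)[2, 2], 4.5)
  expect_equal(siteFlags(out)[2, 2], "interpolated")

  ## a corner with only 3 neighbours stays missing at K = 5
  corner <- eventMarks(paste0("ch", c(2, 4, 5)), c(1, 2, 3))
  asg3 <- new("CycleAssignment", cycle = rep(1L, 3), nCycles = 1L)
  cm <- sivInterpolate(buildActivationMap(asg3, corner, lay, 1),
                       K1 = 5, K2 = 5)
  expect_equal(siteFlags(cm)[1, 1], "missing")

  ## measured values are never altered; a fully missing map is unchanged
  expect_identical(activationTimes(out)[siteFlags(amap) == "measured"],
                   activationTimes(amap)[siteFlags(amap) == "measured"])
  empty <- new("ActivationMap", times = matrix(NA_real_, 3, 3),
               flags = matrix("missing", 3, 3), cycle = 1L, spacingMm = 4)
  expect_identical(siteFlags(sivInterpolate(empty, 5, 3)),
                   siteFlags(empty))
})

test_that("SIV recovers seeded deletions of a planar map within one step", {
  lay <- gridLayout(8, 8, 4)
  w <- planar_wave(step_s = 1)
  full <- buildActivationMap(w$assignment, w$marks, lay, 1)
  set.seed(62)
  holes <- sample(64, 10)
  tm <- activationTimes(full); fl <- siteFlags(full)
  tm[holes] <- NA; fl[holes] <- "missing"
  holed <- new("ActivationMap", times = tm, flags = fl, cycle = 1L,
               spacingMm = 4)
  fixed <- sivInterpolate(holed, K1 = 5, K2 = 3)
  interior <- matrix(FALSE, 8, 8); interior[2:7, 2:7] <- TRUE
  for (h in holes[interior[holes]]) {
    expect_true(siteFlags(fixed)[h] != "missing")
    expect_lte(abs(activationTimes(fixed)[h] - activationTimes(full)[h]), 1)
  }
})

test_that("planar-wave velocity matches the closed form to 1e-9", {
  lay <- gridLayout(8, 8, 4)
  w <- planar_wave(step_s = 1)                    # 1 s per 4 mm electrode
  amap <- buildActivationMap(w$assignment, w$marks, lay, 1)
  vf <- computeVelocityField(amap)
  def <- vf@flags == "defined"
  expect_true(all(def))
  expect_lt(max(abs(speedGrid(vf)[def] - 4)), 1e-9)
  expect_lt(max(abs(velocityComponents(vf)$vx[def] - 4)), 1e-9)
  expect_lt(max(abs(velocityComponents(vf)$vy[def])), 1e-9)
})

test_that("simultaneous activation yields an all-undefined field", {
  lay <- gridLayout(5, 5, 4)
  ch <- paste0("ch", 1:25)
  asg <- new("CycleAssignment", cycle = rep(1L, 25), nCycles = 1L)
  amap <- buildActivationMap(asg, eventMarks(ch, rep(3, 25)), lay, 1)
  vf <- computeVelocityField(amap)
  expect_true(all(vf@flags == "undefined"))
  empty <- new("ActivationMap", times = matrix(NA_real_, 3, 3),
               flags = matrix("missing", 3, 3), cycle = 1L, spacingMm = 4)
  expect_error(computeVelocityField(empty), "no usable sites")
})

test_that("radial waves give near-true speed and radial directions", {
  gen <- generateRecording(clean_scenario(
    pattern = list(type = "radial", origin_row = 3, origin_col = 3,
                   speed_mm_s = 6), duration = 90, seed = 63))
  mt <- marks_from_truth(gen$truth)
  amap <- buildActivationMap(mt$assignment, mt$marks, gen$layout, 2)
  vf <- computeVelocityField(amap)
  interior <- matrix(FALSE, 8, 8); interior[3:7, 3:7] <- TRUE
  near_origin <- matrix(FALSE, 8, 8); near_origin[3:5, 3:5] <- TRUE
  use <- vf@flags == "defined" & interior & !near_origin
  expect_gt(sum(use), 10)
  sp <- speedGrid(vf)[use]
  expect_lt(abs(stats::median(sp) - 6) / 6, 0.10)
  ## direction against the true outward radial unit vector
  idx <- which(use, arr.ind = TRUE)
  ang_err <- vapply(seq_len(nrow(idx)), function(i) {
    r <- idx[i, 1]; c <- idx[i, 2]
    truth <- c(c - 1 - 3, r - 1 - 3)              # (dx, dy) from origin
    v <- c(vf@vx[r, c], vf@vy[r, c])
    cosang <- sum(truth * v) / sqrt(sum(truth^2) * sum(v^2))
    acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  }, numeric(1))
  expect_lt(stats::median(ang_err), 15)
})

test_that("zero-crossing amplitude matches clean closed forms", {
  fs <- 32
  tmpl <- waveformTemplate("biphasic", 400, 2, fs)
  x <- c(rep(0, 3 * fs), tmpl$samples, rep(0, 3 * fs))
  t_mark <- (3 * fs + tmpl$activation_index - 1) / fs
  est <- estimateAmplitude(x, fs, t_mark)
  expect_equal(est$amplitude_uv, 400, tolerance = 0.02)
  expect_equal(est$confidence, "high")

  ## pure sine, 100 uV amplitude, 1 s period, mark on a descending zero
  t <- seq(0, 10, by = 1 / fs)
  sine <- 100 * sin(2 * pi * t)
  est2 <- estimateAmplitude(sine, fs, t_mark = 5.5)
  expect_equal(est2$amplitude_uv, 200, tolerance = 0.02)

  ## offset invariance
  est3 <- estimateAmplitude(x + 1234.5, fs, t_mark)
  expect_equal(est3$amplitude_uv, est$amplitude_uv)
  expect_error(estimateAmplitude(x, fs, t_mark = 99), "outside the recording")
})

test_that("amplitude estimation beats raw peak-trough under noise", {
  fs <- 32
  tmpl <- waveformTemplate("biphasic", 400, 2, fs)
  n <- 10 * fs
  base <- numeric(n)
  c0 <- 5 * fs - tmpl$activation_index + 1
  base[c0:(c0 + length(tmpl$samples) - 1)] <- tmpl$samples
  t_mark <- (5 * fs - 1) / fs
  set.seed(64)
  est <- numeric(200); raw <- numeric(200)
  half <- round(0.75 * fs)
  for (i in 1:200) {
    x <- base + rnorm(n, sd = 20)
    est[i] <- estimateAmplitude(x, fs, t_mark)$amplitude_uv
    seg <- x[(5 * fs - half):(5 * fs + half)]
    raw[i] <- max(seg) - min(seg)
  }
  expect_lt(abs(mean(est) - 400) / 400, 0.10)
  expect_lte(abs(mean(est) - 400), abs(mean(raw) - 400))
})

test_that("interval maps report uniform periods with zero spread", {
  lay <- gridLayout(4, 4, 4)
  ch <- rep(paste0("ch", 1:16), times = 3)
  tt <- rep(c(0, 20, 40), each = 16)
  mk <- eventMarks(ch, tt)
  m <- marksTable(mk)
  asg <- new("CycleAssignment",
             cycle = as.integer(m$time %/% 20 + 1), nCycles = 3L)
  ivs <- computeIntervals(asg, mk, lay)
  expect_length(ivs, 2L)
  expect_true(all(intervalGrid(ivs[[1]]) == 20))
  expect_equal(unname(intervalSummary(ivs[[1]])["mean_s"]), 20)
  expect_equal(unname(intervalSummary(ivs[[1]])["sd_s"]), 0)
  expect_true(all(ivs[[1]]@freqCpm == 3))
  expect_true(all(siteClasses(ivs[[1]]) == "normal"))
  expect_error(computeIntervals(new("CycleAssignment",
                                    cycle = rep(1L, 16), nCycles = 1L),
                                mk, lay), "at least 2 cycles")
})

test_that("sites missing a measured mark in either cycle stay undefined", {
  lay <- gridLayout(3, 3, 4)
  ch1 <- paste0("ch", 1:9)
  ch2 <- paste0("ch", 1:8)                        # ch9 absent in cycle 2
  mk <- eventMarks(c(ch1, ch2), c(rep(0, 9) + (0:8) * 0.1,
                                  20 + (0:7) * 0.1))
  m <- marksTable(mk)
  asg <- new("CycleAssignment",
             cycle = as.integer(ifelse(m$time < 10, 1L, 2L)), nCycles = 2L)
  ivs <- computeIntervals(asg, mk, lay)
  expect_equal(sum(!is.na(intervalGrid(ivs[[1]]))), 8L)
  expect_equal(siteClasses(ivs[[1]])[3, 3], "undefined")
})

test_that("a seeded tachygastric patch is classified exactly", {
  gen <- generateRecording(clean_scenario(
    pattern = list(type = "tachy_patch", direction_deg = 0, speed_mm_s = 6,
                   patch_rows = 2:4, patch_cols = 2:4, patch_period_s = 10),
    duration = 120, seed = 65))
  mt <- marks_from_truth(gen$truth)
  ivs <- computeIntervals(mt$assignment, mt$marks, gen$layout,
                          bounds_cpm = c(2, 4))
  cl <- siteClasses(ivs[[1]])
  patch <- matrix(FALSE, 8, 8); patch[2:4 + 1, 2:4 + 1] <- TRUE
  expect_equal(sum(cl == "tachy"), 9L)
  expect_true(all(cl[patch] == "tachy"))
  expect_true(all(cl[!patch] %in% c("normal", "undefined")))
})

test_that("intervals are invariant under time reversal of the recording", {
  lay <- gridLayout(3, 3, 4)
  ch <- rep(paste0("ch", 1:9), 3)
  tt <- rep(c(0, 18, 36), each = 9) + rep((0:8) * 0.2, 3)
  mk <- eventMarks(ch, tt)
  m <- marksTable(mk)
  asg <- new("CycleAssignment", cycle = as.integer(m$time %/% 18 + 1),
             nCycles = 3L)
  fwd <- computeIntervals(asg, mk, lay)
  T_max <- 40
  mk_rev <- eventMarks(ch, T_max - tt)
  mr <- marksTable(mk_rev)
  asg_rev <- new("CycleAssignment",
                 cycle = as.integer(mr$time %/% 18 + 1), nCycles = 3L)
  rev_ <- computeIntervals(asg_rev, mk_rev, lay)
  expect_equal(sort(intervalGrid(fwd[[1]])), sort(intervalGrid(rev_[[2]])))
  expect_equal(sort(intervalGrid(fwd[[2]])), sort(intervalGrid(rev_[[1]])))
})
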