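test_that("the quadratic surface fit recovers exact generating polynomials", {
  g <- expand.grid(x = 0:2, y = 0:2)
  lin <- fitActivationSurface(data.frame(x = g$x, y = g$y,
                                         t = 2 + 0.5 * g$x))
  expect_equal(lin@coefficients, c(2, 0.5, 0, 0, 0, 0), tolerance = 1e-9)
  expect_lt(lin@residRms, 1e-10)

  g4 <- expand.grid(x = 0:3, y = 0:3)
  quad <- fitActivationSurface(data.frame(
    x = g4$x, y = g4$y, t = 1 + g4$x^2 - 0.3 * g4$x * g4$y))
  expect_equal(quad@coefficients, c(1, 0, 0, 1, -0.3, 0), tolerance = 1e-9)
  expect_lt(quad@residRms, 1e-9)
  expect_equal(predictSurface(quad, 2, 3), 1 + 4 - 0.3 * 6, tolerance = 1e-9)

  expect_error(fitActivationSurface(data.frame(x = 1:5, y = 1:5, t = 1:5)),
               "at least 6")
  collinear <- data.frame(x = 1:7, y = 1:7, t = rnorm(7))
  expect_error(fitActivationSurface(collinear), "degenerate configuration")
})

test_that("noisy surface fits agree with lm and stay within theory error", {
  set.seed(51)
  g <- expand.grid(x = 0:7, y = 0:7)
  beta <- c(5, 0.8, -0.4, 0.05, 0.02, -0.03)
  X <- cbind(1, g$x, g$y, g$x^2, g$x * g$y, g$y^2)
  sigma <- 0.1
  se <- sigma * sqrt(diag(solve(crossprod(X))))   # closed-form LS errors
  err <- matrix(0, 50, 6)
  for (r in 1:50) {
    t_obs <- as.vector(X %*% beta) + rnorm(64, sd = sigma)
    fit <- fitActivationSurface(data.frame(x = g$x, y = g$y, t = t_obs))
    ## independent oracle: lm on the same design
    ref <- unname(coef(lm(t_obs ~ x + y + I(x^2) + I(x * y) + I(y^2),
                          data = g)))
    expect_equal(fit@coefficients, ref, tolerance = 1e-8)
    err[r, ] <- fit@coefficients - beta
  }
  rmse <- sqrt(colMeans(err^2))
  expect_true(all(rmse < 3 * se))
})

test_that("two clean planar waves cluster into two full cycles", {
  lay <- gridLayout(8, 8, 4)
  ch <- c(); tt <- c(); wave <- c()
  for (w in 0:1) for (r in 0:7) for (c in 0:7) {
    ch <- c(ch, paste0("ch", r * 8 + c + 1))
    tt <- c(tt, w * 20 + c)
    wave <- c(wave, w + 1)
  }
  mk <- eventMarks(ch, tt)
  asg <- regroupsCluster(mk, lay)
  expect_equal(nCycles(asg), 2L)
  expect_equal(orphanCount(asg), 0L)
  expect_equal(as.vector(table(cycleOf(asg))), c(64L, 64L))
  ## brute-force oracle: bisection at the 10 s time gap
  m <- marksTable(mk)
  oracle <- ifelse(m$time < 10, 1L, 2L)
  expect_equal(cycleOf(asg), oracle)
})

test_that("a single mark forms a cycle, or an orphan when cycles need size", {
  lay <- gridLayout(8, 8, 4)
  one <- eventMarks("ch1", 5)
  asg <- regroupsCluster(one, lay)
  expect_equal(nCycles(asg), 1L)
  expect_equal(orphanCount(asg), 0L)
  asg2 <- regroupsCluster(one, lay,
                          parameterSet(regroups.min_cycle_size = 2))
  expect_equal(nCycles(asg2), 0L)
  expect_equal(orphanCount(asg2), 1L)
  expect_error(regroupsCluster(eventMarks(), lay), "no marks")
})

test_that("spurious marks far from any wavefront become orphans", {
  lay <- gridLayout(8, 8, 4)
  ch <- c(); tt <- c()
  for (w in 0:1) for (r in 0:7) for (c in 0:7) {
    ch <- c(ch, paste0("ch", r * 8 + c + 1)); tt <- c(tt, w * 20 + c)
  }
  base <- eventMarks(ch, tt)
  base_asg <- regroupsCluster(base, lay)
  spur_ch <- paste0("ch", c(5, 20, 35, 50, 60))
  spur_t <- c(12, 13, 11.5, 12.5, 13.5)       # >= 8 s off either wavefront
  mk <- eventMarks(c(ch, spur_ch), c(tt, spur_t))
  asg <- regroupsCluster(mk, lay)
  expect_equal(nCycles(asg), 2L)
  expect_equal(orphanCount(asg), 5L)
  m <- marksTable(mk)
  expect_setequal(m$time[is.na(cycleOf(asg))], spur_t)
  ## wave memberships unchanged relative to the spurious-free run
  clean_m <- marksTable(base)
  for (k in 1:2) {
    got <- m[cycleMembers(asg, k), c("channel", "time")]
    ref <- clean_m[cycleMembers(base_asg, k), c("channel", "time")]
    expect_equal(got[order(got$channel), ], ref[order(ref$channel), ],
                 ignore_attr = TRUE)
  }
})

test_that("clean planar, radial and retrograde waves are recovered exactly", {
  for (pat in list(list(type = "planar", direction_deg = 0, speed_mm_s = 6),
                   list(type = "radial", origin_row = 3, origin_col = 3,
                        speed_mm_s = 6),
                   list(type = "retrograde", speed_mm_s = 6))) {
    gen <- generateRecording(clean_scenario(pattern = pat, seed = 52))
    mk <- fevtDetect(preprocessDefault(gen$recording))
    asg <- regroupsCluster(mk, gen$layout)
    expect_equal(orphanCount(asg), 0L)
    tc <- true_cycle_of(mk, gen$truth$marks)
    for (k in seq_len(nCycles(asg)))
      expect_equal(length(unique(tc[cycleMembers(asg, k)])), 1L)
    expect_equal(nCycles(asg), max(gen$truth$marks$cycle))
  }
})

test_that("retrograde arrival order is the exact reverse of antegrade", {
  ante <- waveArrivalTimes(clean_scenario(seed = 1))
  retro <- waveArrivalTimes(clean_scenario(
    pattern = list(type = "retrograde", speed_mm_s = 6), seed = 1))
  a1 <- ante$marks[ante$marks$cycle == 1, ]
  r1 <- retro$marks[retro$marks$cycle == 1, ]
  a_col <- tapply(a1$time, a1$col, mean)
  r_col <- tapply(r1$time, r1$col, mean)
  expect_true(all(diff(a_col) > 0))               # antegrade: left to right
  expect_true(all(diff(r_col) < 0))               # retrograde: right to left
  expect_equal(unname(a_col - min(a_col)),
               unname(rev(r_col - min(r_col))), tolerance = 1 / 32)
})

test_that("manual regrouping conserves marks and handles conflicts", {
  lay <- gridLayout(4, 4, 4)
  ch <- paste0("ch", 1:16)
  mk <- eventMarks(c(ch, "ch1"), c((0:15) %% 4, 30))
  asg <- regroupsCluster(mk, lay)
  n_total <- nMarks(mk)
  expect_equal(sum(!is.na(cycleOf(asg))) + orphanCount(asg), n_total)

  orphan_idx <- which(is.na(cycleOf(asg)))
  if (!length(orphan_idx)) {
    ## ensure an orphan exists for the move test
    asg <- editCluster(asg, mk, nMarks(mk), "orphan")
    orphan_idx <- which(is.na(cycleOf(asg)))
  }
  ## moving the orphan onto an occupied channel errors
  expect_error(editCluster(asg, mk, orphan_idx[1], 1), "channel conflict")
  ## orphan -> new cycle, then back to orphan, is an involution
  moved <- editCluster(asg, mk, orphan_idx[1], "new")
  expect_equal(orphanCount(moved), orphanCount(asg) - 1L)
  back <- editCluster(moved, mk, orphan_idx[1], "orphan")
  expect_identical(cycleOf(back), cycleOf(asg))
  expect_equal(sum(!is.na(cycleOf(moved))) + orphanCount(moved), n_total)
})

test_that("cycle renumbering is idempotent and ordered by mean time", {
  lay <- gridLayout(2, 2, 4)
  mk <- eventMarks(rep(paste0("ch", 1:4), 2),
                   c(20, 21, 20.5, 21.5, 0, 1, 0.5, 1.5))
  asg <- regroupsCluster(mk, lay)
  expect_equal(nCycles(asg), 2L)
  m <- marksTable(mk)
  expect_lt(mean(m$time[cycleMembers(asg, 1)]),
            mean(m$time[cycleMembers(asg, 2)]))
  ## a no-op edit leaves numbering untouched
  same <- editCluster(asg, mk, cycleMembers(asg, 1)[1], 1)
  expect_identical(cycleOf(same), cycleOf(asg))
})
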