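## Shared builders for synthetic fixtures; everything is generated in code.

## noise-free scenario, short by default so unit tests stay fast
clean_scenario <- function(pattern = list(type = "planar", direction_deg = 0,
                                          speed_mm_s = 6),
                           duration = 120, seed = 1, ...) {
  slowWaveScenario(duration = duration, pattern = pattern,
                   white_sd_uv = 0, wander_amp_uv = 0, wander_walk_uv = 0,
                   seed = seed, ...)
}

## greedy per-channel matching of detected marks to ground truth
match_marks <- function(marks, truth, tol = 0.5) {
  m <- marksTable(marks)
  tp <- 0L; fp <- 0L
  for (ch in unique(truth$channel)) {
    tt <- truth$time[truth$channel == ch]
    used <- rep(FALSE, length(tt))
    for (d in m$time[m$channel == ch]) {
      j <- which(!used & abs(tt - d) <= tol)
      if (length(j)) { used[j[1L]] <- TRUE; tp <- tp + 1L } else fp <- fp + 1L
    }
  }
  list(tp = tp, fp = fp, fn = nrow(truth) - tp,
       sensitivity = tp / nrow(truth),
       fp_rate = if (tp + fp > 0) fp / (tp + fp) else 0)
}

## ground-truth cycle label of each detected mark (nearest truth event)
true_cycle_of <- function(marks, truth) {
  m <- marksTable(marks)
  vapply(seq_len(nrow(m)), function(i) {
    tt <- truth[truth$channel == m$channel[i], ]
    tt$cycle[which.min(abs(tt$time - m$time[i]))]
  }, numeric(1))
}

## EventMarks + CycleAssignment straight from a generator truth table
marks_from_truth <- function(truth) {
  tr <- truth$marks
  ord <- order(tr$channel, tr$time)
  mk <- eventMarks(tr$channel[ord], tr$time[ord])
  asg <- new("CycleAssignment", cycle = as.integer(tr$cycle[ord]),
             nCycles = max(tr$cycle))
  list(marks = mk, assignment = asg)
}

## max per-mark distance to the nearest truth event on its channel (s)
max_mark_error <- function(marks, truth) {
  m <- marksTable(marks)
  max(vapply(seq_len(nrow(m)), function(i)
    min(abs(truth$time[truth$channel == m$channel[i]] - m$time[i])),
    numeric(1)))
}
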