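## REGROUPS: region-growing assignment of activation marks to wavefront
## cycles, stabilised by a continuously refit second-order polynomial
## activation-time surface T(x, y).

#' Second-order activation-time surface
#'
#' Least-squares fit of `T(x, y) = a0 + a1 x + a2 y + a3 x^2 + a4 x y +
#' a5 y^2` with `x`/`y` in electrode-index units and `T` in seconds.
#'
#' @slot coefficients numeric vector `a0..a5`.
#' @slot residRms root-mean-square fit residual (s).
#' @export
setClass("PolySurface",
  representation(coefficients = "numeric", residRms = "numeric"))

.quad_design <- function(x, y) cbind(1, x, y, x^2, x * y, y^2)

#' Fit the quadratic activation-time surface
#'
#' Exact interpolation when the points are generated by a quadratic;
#' otherwise ordinary least squares. Requires at least six points whose
#' quadratic design matrix has full rank.
#'
#' @param points data.frame with columns `x`, `y` (electrode indices) and
#'   `t` (seconds).
#' @return a [PolySurface-class].
#' @seealso [predictSurface()], [regroupsCluster()]
#' @export
fitActivationSurface <- function(points) {
  if (nrow(points) < 6L)
    stop("need at least 6 points to fit a quadratic surface")
  X <- .quad_design(points$x, points$y)
  qr_ <- qr(X)
  if (qr_$rank < 6L)
    stop("degenerate configuration: quadratic design matrix is rank deficient")
  beta <- qr.coef(qr_, points$t)
  resid <- points$t - as.vector(X %*% beta)
  new("PolySurface", coefficients = as.numeric(beta),
      residRms = sqrt(mean(resid^2)))
}

#' @rdname fitActivationSurface
#' @param surface a [PolySurface-class].
#' @param x,y electrode-index coordinates.
#' @return `predictSurface`: predicted activation times (s).
#' @export
predictSurface <- function(surface, x, y)
  as.vector(.quad_design(x, y) %*% surface@coefficients)

setMethod("show", "PolySurface", function(object) {
  cat(sprintf("PolySurface: T = %.3g + %.3g x + %.3g y + %.3g x^2 + %.3g xy + %.3g y^2 (RMS %.3g s)\n",
              object@coefficients[1], object@coefficients[2],
              object@coefficients[3], object@coefficients[4],
              object@coefficients[5], object@coefficients[6],
              object@residRms))
})

## order cycles by mean member time and relabel 1..K
.renumber_cycles <- function(cycle, times) {
  ids <- unique(cycle[!is.na(cycle)])
  if (!length(ids)) return(list(cycle = cycle, n = 0L))
  mt <- vapply(ids, function(k) mean(times[!is.na(cycle) & cycle == k]),
               numeric(1))
  remap <- integer(max(ids))
  remap[ids[order(mt)]] <- seq_along(ids)
  out <- cycle
  out[!is.na(cycle)] <- remap[cycle[!is.na(cycle)]]
  list(cycle = as.integer(out), n = length(ids))
}

#' Cluster activation marks into wavefront cycles (REGROUPS)
#'
#' Region growing with polynomial-surface stabilisation. A cycle is seeded
#' at the earliest unassigned mark on the channel with the most
#' 8-connected neighbours holding unassigned marks within
#' `regroups.seed_window_s` (ties to the smallest channel); the frontier
#' then grows over 8-neighbours, accepting on each the unassigned mark
#' nearest the predicted time when within `regroups.tau_s`. Predictions
#' use the mean of assigned neighbour times while the group has fewer than
#' six members, then a continuously refit quadratic surface
#' ([fitActivationSurface()]). After every `regroups.n_batch` acceptances
#' the surface is refit and members whose residual exceeds
#' `max(regroups.resid_factor * fitRMS, tau)` are ejected back to the
#' unassigned pool (they may be adopted by a later cycle). When no
#' seedable mark remains, leftovers become orphans. Cycles are numbered
#' 1-based in order of mean member time.
#'
#' Isolated marks with no temporal neighbour support cannot seed a cycle
#' once at least one cycle exists, so spurious detections far from any
#' wavefront end in the orphan pool; on degenerate inputs where nothing
#' has support (for example a single mark) the earliest mark seeds anyway.
#'
#' @param marks an [EventMarks-class].
#' @param layout an [ElectrodeLayout-class] covering every marked channel.
#' @param params a [ParameterSet-class]; the `regroups.*` keys apply.
#' @return a [CycleAssignment-class].
#' @export
regroupsCluster <- function(marks, layout, params = defaultParameters()) {
  m <- marks@marks
  if (!nrow(m)) stop("no marks to cluster")
  pos <- .layout_pos(layout, m$channel)
  if (anyNA(pos$row))
    stop("layout does not place channel(s): ",
         paste(unique(m$channel[is.na(pos$row)]), collapse = ", "))
  tau <- param(params, "regroups.tau_s")
  dt_seed <- param(params, "regroups.seed_window_s")
  n_batch <- param(params, "regroups.n_batch")
  min_size <- param(params, "regroups.min_cycle_size")
  rfac <- param(params, "regroups.resid_factor")
  n <- nrow(m)
  state <- rep("free", n)              # free | member | orphan | done
  cycle <- rep(NA_integer_, n)
  chan_of <- m$channel
  t_of <- m$time
  channels <- unique(chan_of)
  ch_pos <- .layout_pos(layout, channels)
  rownames(ch_pos) <- channels
  ## neighbour channel labels per channel
  site_of <- paste(ch_pos$row, ch_pos$col)
  nb_list <- lapply(seq_along(channels), function(i) {
    nb <- .neighbours8(ch_pos$row[i], ch_pos$col[i], layout@gridShape)
    channels[match(paste(nb$row, nb$col), site_of, nomatch = 0L)]
  })
  names(nb_list) <- channels
  free_on <- function(ch) which(state == "free" & chan_of == ch)
  next_cycle <- 0L
  any_cycle <- FALSE
  repeat {
    free_idx <- which(state == "free")
    if (!length(free_idx)) break
    ## ---- seed selection ----
    cand_ch <- unique(chan_of[free_idx])
    seed_mark <- NA_integer_; best <- -1L
    for (ch in sort(cand_ch)) {
      fo <- free_on(ch)
      mk <- fo[which.min(t_of[fo])]
      supp <- 0L
      for (nb in nb_list[[ch]]) {
        fn <- free_on(nb)
        if (length(fn) && any(abs(t_of[fn] - t_of[mk]) <= dt_seed))
          supp <- supp + 1L
      }
      if (supp > best) { best <- supp; seed_mark <- mk }
    }
    if (best < 1L) {
      if (any_cycle) {                 # no supported seed left -> orphans
        state[state == "free"] <- "orphan"
        break
      }
      ## degenerate input: nothing has support; seed the earliest mark
      seed_mark <- free_idx[which.min(t_of[free_idx])]
    }
    ## ---- grow one cycle ----
    next_cycle <- next_cycle + 1L
    members <- seed_mark
    state[seed_mark] <- "member"
    ejected_ch <- character()
    surface <- NULL
    n_accept <- 0L
    frontier <- setdiff(nb_list[[chan_of[seed_mark]]], chan_of[members])
    tried <- character()
    guard <- 0L; guard_max <- 50L * n + 100L
    while (length(frontier) && guard < guard_max) {
      guard <- guard + 1L
      ch <- frontier[1L]; frontier <- frontier[-1L]
      if (ch %in% tried || ch %in% ejected_ch || ch %in% chan_of[members])
        next
      tried <- c(tried, ch)
      fo <- free_on(ch)
      if (!length(fo)) next
      ## prediction
      if (length(members) >= 6L && !is.null(surface)) {
        t_pred <- predictSurface(surface, ch_pos[ch, "col"], ch_pos[ch, "row"])
      } else {
        nbm <- members[chan_of[members] %in% nb_list[[ch]]]
        if (!length(nbm)) next
        t_pred <- mean(t_of[nbm])
      }
      cand <- fo[which.min(abs(t_of[fo] - t_pred))]
      if (abs(t_of[cand] - t_pred) > tau) next
      ## accept
      members <- c(members, cand)
      state[cand] <- "member"
      n_accept <- n_accept + 1L
      frontier <- c(frontier,
                    setdiff(nb_list[[ch]],
                            c(chan_of[members], tried, ejected_ch)))
      ## stabilise: refit + eject
      if (n_accept %% n_batch == 0L && length(members) >= 6L) {
        pts <- data.frame(x = ch_pos[chan_of[members], "col"],
                          y = ch_pos[chan_of[members], "row"],
                          t = t_of[members])
        surface <- tryCatch(fitActivationSurface(pts),
                            error = function(e) NULL)
        if (!is.null(surface)) {
          pred <- predictSurface(surface, pts$x, pts$y)
          thr <- max(rfac * surface@residRms, tau)
          out <- which(abs(pts$t - pred) > thr)
          if (length(out)) {
            ej <- members[out]
            ejected_ch <- c(ejected_ch, chan_of[ej])
            state[ej] <- "free"
            members <- members[-out]
            tried <- character()       # fresh attempts under the new fit
            frontier <- unique(c(frontier, unlist(nb_list[chan_of[members]])))
            frontier <- setdiff(frontier, c(chan_of[members], ejected_ch))
          }
        }
      }
    }
    ## ---- close the cycle ----
    if (length(members) >= min_size) {
      cycle[members] <- next_cycle
      state[members] <- "done"
      any_cycle <- TRUE
    } else {
      state[members] <- "orphan"
      next_cycle <- next_cycle - 1L
    }
  }
  state[state == "free"] <- "orphan"
  rn <- .renumber_cycles(cycle, t_of)
  new("CycleAssignment", cycle = rn$cycle, nCycles = rn$n)
}

#' Manually move a mark between cycles and the orphan pool
#'
#' @param assignment a [CycleAssignment-class].
#' @param marks the matching [EventMarks-class].
#' @param mark row index of the mark in [marksTable()].
#' @param target `"orphan"`, `"new"`, or an existing cycle index.
#' @return the updated, renumbered [CycleAssignment-class].
#' @export
editCluster <- function(assignment, marks, mark, target) {
  cy <- assignment@cycle
  m <- marks@marks
  if (mark < 1L || mark > length(cy)) stop("no such mark: ", mark)
  if (identical(target, "orphan")) {
    cy[mark] <- NA_integer_
  } else if (identical(target, "new")) {
    cy[mark] <- max(c(0L, cy), na.rm = TRUE) + 1L
  } else {
    k <- as.integer(target)
    if (is.na(k) || k < 1L || k > assignment@nCycles)
      stop("no such cycle: ", target)
    occupied <- which(!is.na(cy) & cy == k &
                        m$channel == m$channel[mark] &
                        seq_along(cy) != mark)
    if (length(occupied))
      stop(sprintf(
        "channel conflict: cycle %d already holds mark %d on channel %s at t = %.3f s",
        k, occupied[1L], m$channel[occupied[1L]], m$time[occupied[1L]]))
    cy[mark] <- k
  }
  rn <- .renumber_cycles(cy, m$time)
  new("CycleAssignment", cycle = rn$cycle, nCycles = rn$n)
}
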