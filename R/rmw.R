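#' Range modulator wheel steps and wheels
#'
#' An RMW step is an angular sector of the bimaterial staircase wheel:
#' `pullback` is the water-equivalent range reduction (cm) relative to the
#' thinnest step (index 0), and a `blocked` step models the brass wedge that
#' stops the beam completely. A wheel is an ordered list of steps with
#' pairwise disjoint angular sectors, rotating at `rpm` (default 600).
#'
#' @param index Integer step index from 0 (thinnest step, zero pullback).
#' @param angle_start Sector start angle in degrees, in `[0, 360)`.
#' @param angle_width Sector width in degrees (> 0).
#' @param pullback Water-equivalent range pullback in cm (>= 0; 0 for step 0).
#' @param blocked Logical; `TRUE` for the beam-stopping wedge.
#' @return `rmw_step()`: a list of class `"rmw_step"`; `rmw()`: a list of
#'   class `"rmw"`.
#' @export
rmw_step <- function(index, angle_start, angle_width, pullback,
                     blocked = FALSE) {
  if (angle_start < 0 || angle_start >= 360)
    stop("'angle_start' must be in [0, 360)")
  if (angle_width <= 0) stop("'angle_width' must be positive")
  if (pullback < 0) stop("'pullback' must be non-negative")
  structure(list(index = as.integer(index), angle_start = angle_start,
                 angle_width = angle_width, pullback = pullback,
                 blocked = isTRUE(blocked)),
            class = "rmw_step")
}

#' @param steps List of `rmw_step` objects, ordered by index.
#' @param rpm Rotation speed in rotations per minute (> 0).
#' @rdname rmw_step
#' @export
rmw <- function(steps, rpm = 600) {
  if (!length(steps) || !all(vapply(steps, inherits, logical(1), "rmw_step")))
    stop("'steps' must be a non-empty list of rmw_step objects")
  if (rpm <= 0) stop("'rpm' must be positive")
  idx <- vapply(steps, `[[`, integer(1), "index")
  steps <- steps[order(idx)]
  pull <- vapply(steps, `[[`, numeric(1), "pullback")
  if (abs(pull[1]) > 1e-12)
    stop("step 0 must have zero pullback")
  if (any(diff(pull) < -1e-12))
    stop("pullback must be non-decreasing in step index")
  if (sum(vapply(steps, `[[`, numeric(1), "angle_width")) > 360 + 1e-9)
    stop("step angular widths exceed 360 degrees")
  ivs <- do.call(rbind, lapply(steps, function(s)
    split_circular(s$angle_start, s$angle_width)))
  o <- order(ivs[, 1])
  if (any(ivs[o, 1][-1] < ivs[o, 2][-nrow(ivs)] - 1e-9))
    stop("step angular sectors overlap")
  structure(list(steps = steps, rpm = rpm), class = "rmw")
}

# split a circular arc [start, start+width) into 1-2 linear intervals in
# [0, 360)
split_circular <- function(start, width) {
  end <- start + width
  if (end <= 360 + 1e-12) {
    matrix(c(start, min(end, 360)), ncol = 2)
  } else {
    rbind(c(start, 360), c(0, end - 360))
  }
}

overlap_len <- function(a, b) {
  # total overlap of two sets of linear intervals (rows lo, hi)
  tot <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    lo <- max(a[i, 1], b[j, 1]); hi <- min(a[i, 2], b[j, 2])
    if (hi > lo) tot <- tot + (hi - lo)
  }
  tot
}

#' Default staircase wheel for a beam configuration
#'
#' Builds a wheel whose uniform pullback increments span the requested
#' modulation width. The pullback spacing defaults to about 1.5 times the
#' distal smearing width of the deepest peak (rounded to 0.05 cm, floor
#' 0.2 cm), so that adjacent pulled-back peaks overlap enough for a flat
#' plateau; a brass-wedge blocked sector occupies the last `blocked_deg`
#' degrees and the unblocked steps share the rest of the circle uniformly.
#'
#' @param range_d90 Deepest-peak range in cm.
#' @param modulation Modulation width to span in cm (<= `range_d90`).
#' @param spacing Pullback per step in cm; default derives from the range as
#'   described above.
#' @param blocked_deg Angular width of the beam-stopping wedge in degrees.
#' @param rpm Rotation speed.
#' @return An `"rmw"` object.
#' @export
default_rmw <- function(range_d90, modulation, spacing = NULL,
                        blocked_deg = 30, rpm = 600) {
  if (modulation > range_d90) stop("'modulation' must not exceed 'range_d90'")
  if (is.null(spacing)) {
    sigma0 <- max(0.012 * range_d90^0.935, 0.15)
    spacing <- max(0.2, round(1.5 * sigma0 / 0.05) * 0.05)
  }
  pull <- seq(0, by = spacing, length.out = ceiling(modulation / spacing) + 2L)
  pull <- pull[pull < range_d90 - 0.4 * spacing - 1e-9]
  n <- length(pull)
  open_deg <- 360 - blocked_deg
  width <- open_deg / n
  steps <- lapply(seq_len(n), function(i)
    rmw_step(index = i - 1L, angle_start = (i - 1) * width,
             angle_width = width, pullback = pull[i]))
  if (blocked_deg > 0)
    steps[[n + 1L]] <- rmw_step(index = n, angle_start = open_deg,
                                angle_width = blocked_deg,
                                pullback = pull[n], blocked = TRUE)
  rmw(steps, rpm = rpm)
}

#' Pulsed beam striking the rotating wheel
#'
#' A pulse train fires at a fixed period; pulse `k` strikes the wheel at
#' angle `(phase + 360 * (rpm/60) * k * period) mod 360`. A pulse has a
#' finite angular footprint `pulse_angular_width` (uniform intensity); the
#' default period of 0.002 s yields 50 pulses per rotation at 600 rpm, and
#' the default footprint of 7.2 degrees makes consecutive pulses tile the
#' circle, so pulses striking a step boundary split their fluence (the
#' "partial shining" case).
#'
#' @param period Seconds between pulses (> 0).
#' @param phase Wheel angle at pulse 0, degrees in `[0, 360)`.
#' @param pulse_angular_width Angular footprint of one pulse in degrees
#'   (>= 0; 0 means a point pulse).
#' @return A list of class `"pulse_train"`.
#' @export
pulse_train <- function(period = 0.002, phase = 0,
                        pulse_angular_width = 7.2) {
  if (period <= 0) stop("'period' must be positive")
  if (phase < 0 || phase >= 360) stop("'phase' must be in [0, 360)")
  if (pulse_angular_width < 0)
    stop("'pulse_angular_width' must be non-negative")
  structure(list(period = period, phase = phase,
                 pulse_angular_width = pulse_angular_width),
            class = "pulse_train")
}

#' Map beam pulses onto wheel steps
#'
#' Determines the timing and landing sector of every pulse over `rotations`
#' full wheel rotations. A point pulse is assigned wholly to the step
#' containing its angle; a finite-width pulse overlapping a step boundary is
#' split proportionally to angular overlap. Pulses (or pulse portions) on
#' blocked steps contribute zero fluence. An error is raised if any pulse
#' reaches an angle not covered by any step.
#'
#' @param wheel An `"rmw"` object.
#' @param train A `"pulse_train"` object.
#' @param rotations Integer number of full rotations (>= 1).
#' @return A list of class `"step_fluence_map"` with `assignments` (data
#'   frame: pulse, step, fraction), `totals` (named per-step fluence in pulse
#'   units, unblocked steps), `n_pulses`, and `pulses_per_rotation`.
#' @export
map_pulses_to_steps <- function(wheel, train, rotations = 1L) {
  stopifnot(inherits(wheel, "rmw"), inherits(train, "pulse_train"))
  if (rotations < 1) stop("'rotations' must be >= 1")
  t_total <- rotations * 60 / wheel$rpm
  n_pulses <- floor(t_total / train$period + 1e-9)
  if (n_pulses < 1) stop("pulse period exceeds total rotation time")
  k <- seq_len(n_pulses) - 1L
  t_k <- k * train$period
  keep <- t_k < t_total - 1e-12
  k <- k[keep]; t_k <- t_k[keep]
  angles <- (train$phase + 360 * (wheel$rpm / 60) * t_k) %% 360
  pw <- train$pulse_angular_width
  step_iv <- lapply(wheel$steps, function(s)
    split_circular(s$angle_start, s$angle_width))
  blocked <- vapply(wheel$steps, `[[`, logical(1), "blocked")
  sidx <- vapply(wheel$steps, `[[`, integer(1), "index")
  rows <- vector("list", length(k))
  for (i in seq_along(k)) {
    a <- angles[i]
    if (pw == 0) {
      hit <- which(vapply(seq_along(step_iv), function(j) {
        iv <- step_iv[[j]]
        any(a >= iv[, 1] - 1e-12 & a < iv[, 2] - 1e-12)
      }, logical(1)))
      if (!length(hit))
        stop(sprintf("pulse %d at angle %.3f deg falls in an angular gap not covered by any step",
                     k[i], a))
      j <- hit[1]
      if (!blocked[j])
        rows[[i]] <- data.frame(pulse = k[i], step = sidx[j], fraction = 1)
    } else {
      piv <- split_circular((a - pw / 2) %% 360, pw)
      ol <- vapply(step_iv, overlap_len, numeric(1), a = piv)
      if (abs(sum(ol) - pw) > 1e-6 * pw)
        stop(sprintf("pulse %d footprint [%.3f +- %.3f deg] overlaps an angular gap not covered by any step",
                     k[i], a, pw / 2))
      use <- which(ol > 1e-12 & !blocked)
      if (length(use))
        rows[[i]] <- data.frame(pulse = k[i], step = sidx[use],
                                fraction = ol[use] / pw)
    }
  }
  assignments <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(assignments))
    assignments <- data.frame(pulse = integer(), step = integer(),
                              fraction = numeric())
  unblocked_idx <- sidx[!blocked]
  totals <- vapply(unblocked_idx, function(s)
    sum(assignments$fraction[assignments$step == s]), numeric(1))
  names(totals) <- unblocked_idx
  structure(list(assignments = assignments, totals = totals,
                 n_pulses = length(k),
                 pulses_per_rotation = length(k) / rotations,
                 angles = angles),
            class = "step_fluence_map")
}

#' Equalize per-step proton fluence across pulses
#'
#' Computes per-pulse fluence multipliers so that every step the beam passes
#' through receives the same number of protons (`protons_per_step`,
#' nominally 3e6), regardless of how many pulses land on it. When every
#' pulse lands wholly on one step the solution is exact
#' (`weight = protons_per_step / step total`); when pulses straddle step
#' boundaries the weights solve the corresponding non-negative least-squares
#' system and residual imbalance is reported. Steps hit by no pulse are
#' flagged in `excluded`, with a warning, not silently skipped.
#'
#' @param map A `"step_fluence_map"`.
#' @param protons_per_step Protons each hit step must receive.
#' @return A list with `pulse_weights` (named by pulse index),
#'   `step_totals` (recomputed weighted per-step protons), `excluded`
#'   (step indices hit by no pulse) and `max_relative_imbalance`.
#' @export
equalize_step_fluence <- function(map, protons_per_step = 3e6) {
  stopifnot(inherits(map, "step_fluence_map"))
  asg <- map$assignments
  hit <- names(map$totals)[map$totals > 1e-12]
  excluded <- as.integer(names(map$totals)[map$totals <= 1e-12])
  if (length(excluded))
    warning(sprintf("steps with zero pulse fluence excluded: %s",
                    paste(excluded, collapse = ", ")))
  pulses <- sort(unique(asg$pulse))
  straddle <- any(table(asg$pulse) > 1L)
  if (!straddle) {
    w <- vapply(pulses, function(p) {
      s <- asg$step[asg$pulse == p]
      protons_per_step / map$totals[as.character(s)]
    }, numeric(1))
  } else {
    A <- matrix(0, nrow = length(hit), ncol = length(pulses),
                dimnames = list(hit, pulses))
    for (r in seq_len(nrow(asg))) {
      s <- as.character(asg$step[r])
      if (s %in% hit)
        A[s, as.character(asg$pulse[r])] <-
          A[s, as.character(asg$pulse[r])] + asg$fraction[r]
    }
    w <- pracma::lsqnonneg(A, rep(protons_per_step, length(hit)))$x
  }
  names(w) <- pulses
  step_totals <- vapply(hit, function(s) {
    rows <- asg$step == as.integer(s)
    sum(asg$fraction[rows] * w[as.character(asg$pulse[rows])])
  }, numeric(1))
  names(step_totals) <- hit
  imb <- if (length(step_totals))
    max(abs(step_totals - protons_per_step)) / protons_per_step else 0
  list(pulse_weights = w, step_totals = step_totals,
       excluded = excluded, max_relative_imbalance = imb)
}

#' Per-step pristine peak library for a wheel
#'
#' Generates one pristine Bragg peak per unblocked wheel step, with range
#' `base$range_d90 - pullback[i]` (each calibrated to its own distal 90%
#' within the generator tolerance). Shallower peaks may optionally be
#' broadened linearly with pullback (`sigma_growth`, cm of extra smearing
#' per cm of pullback), emulating the additional energy spread picked up in
#' thicker wheel steps.
#'
#' @param wheel An `"rmw"` object.
#' @param base A [pristine_peak_params()] for the thinnest step (step 0).
#' @param grid Common depth grid for all peaks.
#' @param sigma_growth Extra smearing per cm of pullback (default 0.02).
#' @return A list of class `"pristine_peak_set"`: `peaks` (list of
#'   depth-dose curves), `pullbacks`, `step_index`, `grid`.
#' @export
build_step_peak_library <- function(wheel, base, grid, sigma_growth = 0.02) {
  stopifnot(inherits(wheel, "rmw"), inherits(base, "pristine_peak_params"))
  steps <- Filter(function(s) !s$blocked, wheel$steps)
  pull <- vapply(steps, `[[`, numeric(1), "pullback")
  if (any(pull >= base$range_d90))
    stop("step pullback meets or exceeds the base range")
  peaks <- lapply(seq_along(steps), function(i) {
    p <- pristine_peak_params(
      range_d90 = base$range_d90 - pull[i],
      distal_spread_sigma = base$distal_spread_sigma + sigma_growth * pull[i],
      entrance_fraction = base$entrance_fraction,
      background_fraction = base$background_fraction,
      fluence = base$fluence)
    generate_pristine_peak(p, grid)
  })
  structure(list(peaks = peaks, pullbacks = pull,
                 step_index = vapply(steps, `[[`, integer(1), "index"),
                 grid = grid),
            class = "pristine_peak_set")
}

#' @export
print.pristine_peak_set <- function(x, ...) {
  cat(sprintf("<pristine_peak_set> %d peaks, pullback 0..%.2f cm, grid %.1f..%.1f cm\n",
              length(x$peaks), max(x$pullbacks), x$grid[1],
              x$grid[length(x$grid)]))
  invisible(x)
}

# dose matrix (depth x peak) for a peak set
peak_matrix <- function(peaks) {
  do.call(cbind, lapply(peaks$peaks, `[[`, "dose"))
}

#' Read and write wheel and pulse-train definitions (JSON)
#'
#' Wheels serialize as
#' `{"steps": [{"index", "angle_start", "angle_width", "pullback_cm",
#' "blocked"}], "rpm"}`; trains as `{"period_s", "phase_deg",
#' "pulse_angular_width_deg"}`.
#'
#' @param path File path.
#' @param wheel,train Objects to write.
#' @return Readers return the parsed object; writers return the path,
#'   invisibly.
#' @export
read_rmw <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  steps <- lapply(seq_len(nrow(j$steps)), function(i)
    rmw_step(j$steps$index[i], j$steps$angle_start[i], j$steps$angle_width[i],
             j$steps$pullback_cm[i], isTRUE(j$steps$blocked[i])))
  rmw(steps, rpm = j$rpm)
}

#' @rdname read_rmw
#' @export
write_rmw <- function(wheel, path) {
  steps <- data.frame(
    index = vapply(wheel$steps, `[[`, integer(1), "index"),
    angle_start = vapply(wheel$steps, `[[`, numeric(1), "angle_start"),
    angle_width = vapply(wheel$steps, `[[`, numeric(1), "angle_width"),
    pullback_cm = vapply(wheel$steps, `[[`, numeric(1), "pullback"),
    blocked = vapply(wheel$steps, `[[`, logical(1), "blocked"))
  jsonlite::write_json(list(steps = steps, rpm = wheel$rpm), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname read_rmw
#' @export
read_pulse_train <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  pulse_train(period = j$period_s, phase = j$phase_deg,
              pulse_angular_width = j$pulse_angular_width_deg)
}

#' @rdname read_rmw
#' @export
write_pulse_train <- function(train, path) {
  jsonlite::write_json(list(period_s = train$period,
                            phase_deg = train$phase,
                            pulse_angular_width_deg = train$pulse_angular_width),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
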