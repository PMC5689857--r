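#' Compose a spread-out Bragg peak from weighted pristine peaks
#'
#' Pointwise weighted sum `D(d) = sum_i w_i p_i(d)` over the peaks of a
#' library; linear in the weights and grid-preserving.
#'
#' @param peaks A `"pristine_peak_set"` whose peaks share one depth grid.
#' @param weights Non-negative numeric vector, one weight per peak.
#' @return A `"depth_dose_curve"` (un-normalized).
#' @export
compose_sobp <- function(peaks, weights) {
  stopifnot(inherits(peaks, "pristine_peak_set"))
  if (inherits(weights, "fit_result")) weights <- weights$weights
  if (length(weights) != length(peaks$peaks))
    stop("need one weight per peak")
  if (any(weights < 0)) stop("weights must be non-negative")
  grids <- vapply(peaks$peaks, function(p) length(p$depths), integer(1))
  if (length(unique(grids)) != 1L ||
      max(vapply(peaks$peaks, function(p)
        max(abs(p$depths - peaks$grid)), numeric(1))) > 1e-9)
    stop("all peaks must share one depth grid")
  dose <- as.numeric(peak_matrix(peaks) %*% weights)
  dose_curve(peaks$grid, dose,
             meta = list(role = "simulated", kind = "sobp",
                         normalized = FALSE))
}

#' Idealized flat SOBP target
#'
#' Constant `plateau_dose` on `[range_d90 - modulation, range_d90]`. The
#' distal edge either rolls off over a cosine taper of length
#' `distal_taper` (default 0.3 cm), or, when `distal_edge` supplies a
#' pristine peak, follows that peak's own falloff beyond its crest scaled
#' to the plateau (anchoring the target's distal 90% at the peak's D90,
#' which a physical peak library can reproduce exactly). Proximal of the
#' plateau the target is flat at `proximal_level` (default 0).
#'
#' @param range_d90 Plateau distal edge in cm.
#' @param modulation Plateau extent in cm (<= `range_d90`).
#' @param plateau_dose Plateau level (default 100).
#' @param grid Depth grid.
#' @param distal_taper Cosine roll-off length in cm.
#' @param proximal_level Sub-plateau dose level (fraction of plateau dose it
#'   is NOT; absolute dose units).
#' @param distal_edge Optional `"depth_dose_curve"` (typically the deepest
#'   peak of the library being fit) shaping the distal edge.
#' @return A `"depth_dose_curve"` with `meta$plateau_start`,
#'   `meta$plateau_end` recorded.
#' @export
flat_target <- function(range_d90, modulation, plateau_dose = 100, grid,
                        distal_taper = 0.3, proximal_level = 0,
                        distal_edge = NULL) {
  if (modulation > range_d90)
    stop("'modulation' must not exceed 'range_d90'")
  check_grid(grid, "grid")
  p0 <- range_d90 - modulation
  if (is.null(distal_edge)) {
    dose <- ifelse(grid >= p0 & grid <= range_d90, plateau_dose,
            ifelse(grid > range_d90 & grid <= range_d90 + distal_taper,
                   plateau_dose / 2 *
                     (1 + cos(pi * (grid - range_d90) / distal_taper)),
                   proximal_level))
    dose[grid > range_d90 + distal_taper] <- 0
  } else {
    stopifnot(inherits(distal_edge, "depth_dose_curve"))
    edge <- stats::approx(distal_edge$depths, distal_edge$dose,
                          xout = grid, rule = 2)$y
    crest <- grid[which.max(edge)]
    dose <- ifelse(grid <= crest, plateau_dose,
                   edge / max(edge) * plateau_dose)
    dose[grid < p0] <- proximal_level
  }
  dose[dose < 0] <- 0
  dose_curve(grid, dose,
             meta = list(role = "target", kind = "flat_target",
                         plateau_start = p0, plateau_end = range_d90,
                         normalized = FALSE))
}

#' Fit SOBP weights by constrained least squares
#'
#' Finds the non-negative per-peak weights minimizing the sum of squared
#' differences between the target and the weighted peak sum, evaluated on a
#' 0.1 cm depth lattice over the fit window. The problem is convex with
#' non-negativity constraints (solved by non-negative least squares), so the
#' result is deterministic. The default window runs from 0.5 cm (excluding
#' surface artifacts) to the depth where the target first falls below 1% of
#' its maximum beyond the peak; a target built by [flat_target()] instead
#' starts the window at its recorded plateau start, since proximal of the
#' plateau an idealized target carries no dose for the physical entrance
#' region to match.
#'
#' @param peaks A `"pristine_peak_set"`.
#' @param target A `"depth_dose_curve"`; linearly resampled to the lattice.
#' @param window `"auto"` or numeric `c(d1, d2)` in cm.
#' @return A list of class `"fit_result"`: `weights`, `sse`, `fit_window`,
#'   `n_points`.
#' @export
fit_weights <- function(peaks, target, window = "auto") {
  stopifnot(inherits(peaks, "pristine_peak_set"),
            inherits(target, "depth_dose_curve"))
  if (identical(window, "auto")) {
    d1 <- if (!is.null(target$meta$plateau_start))
      max(target$meta$plateau_start, target$depths[1]) else
      max(0.5, target$depths[1])
    ipk <- which.max(target$dose)
    beyond <- which(seq_along(target$dose) > ipk &
                    target$dose < 0.01 * max(target$dose))
    d2 <- if (length(beyond)) target$depths[min(beyond)]
          else target$depths[length(target$depths)]
  } else {
    if (length(window) != 2L || window[1] >= window[2])
      stop("'window' must be c(d1, d2) with d1 < d2")
    d1 <- window[1]; d2 <- window[2]
  }
  gl <- range(peaks$grid)
  if (d1 < gl[1] - 1e-9 || d2 > gl[2] + 1e-9)
    stop("fit window extends beyond the peak grid")
  lattice <- seq(d1, d2, by = 0.1)
  if (length(lattice) < length(peaks$peaks))
    stop("fewer lattice points than peaks; enlarge the fit window")
  A <- apply(peak_matrix(peaks), 2, function(col)
    stats::approx(peaks$grid, col, xout = lattice, rule = 2)$y)
  b <- stats::approx(target$depths, target$dose, xout = lattice, rule = 2)$y
  if (max(b) <= 0) {
    w <- rep(0, length(peaks$peaks)); sse <- 0
  } else {
    w <- pracma::lsqnonneg(A, b)$x
    sse <- sum((b - as.numeric(A %*% w))^2)
  }
  structure(list(weights = as.numeric(w), sse = sse,
                 fit_window = c(d1, d2), n_points = length(lattice)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %d weights, window [%.2f, %.2f] cm (%d points), SSE %.4g\n",
              length(x$weights), x$fit_window[1], x$fit_window[2],
              x$n_points, x$sse))
  invisible(x)
}

# SOBP width (prox95 -> d90) of a composed weight vector; NA when undefined
composed_width <- function(peaks, weights) {
  dose <- as.numeric(peak_matrix(peaks) %*% weights)
  if (max(dose) <= 0) return(NA_real_)
  y <- dose / max(dose) * 100
  x <- peaks$grid
  d90 <- crossing_depth(x, y, 90, "distal")
  if (is.na(d90)) return(NA_real_)
  p95 <- crossing_depth(x, y, 95, "proximal")
  if (is.na(p95)) p95 <- if (y[1] >= 95) x[1] else return(NA_real_)
  d90 - p95
}

#' Synthesize a flat SOBP of requested range and modulation
#'
#' Two-stage pipeline mirroring how a passively scattered machine sets up a
#' beam: (1) non-negative least-squares fit of the per-step weights against
#' a flat target whose distal edge follows the deepest peak of the library
#' (so D90 lands at the requested range), over the plateau window; (2) the
#' modulation width is then trimmed to the requested value by removing the
#' shallowest steps' weights one at a time and scaling the weight at the
#' boundary step by a fraction found by bisection on the recomputed
#' proximal-95/distal-90 width -- the weight-space analogue of stop-pulse
#' beam-current modulation. A full-modulation request whose plateau reaches
#' the surface is left untrimmed.
#'
#' @param peaks A `"pristine_peak_set"` spanning at least the requested
#'   modulation.
#' @param range_d90 Requested beam range in cm (D90 of the deepest peak).
#' @param modulation Requested SOBP width in cm.
#' @return A list of class `"sobp_fit"`: `weights`, `curve` (composed,
#'   un-normalized), `fit` (the stage-1 `"fit_result"`), `achieved_width`,
#'   `requested` and `metrics` (a `"pdd_metrics"`).
#' @export
synthesize_sobp <- function(peaks, range_d90, modulation) {
  stopifnot(inherits(peaks, "pristine_peak_set"))
  if (modulation > range_d90)
    stop("'modulation' must not exceed 'range_d90'")
  deepest <- peaks$peaks[[which.min(peaks$pullbacks)]]
  target <- flat_target(range_d90, modulation, 100, peaks$grid,
                        distal_edge = deepest)
  support <- which(target$dose > 0.5)
  fit <- fit_weights(peaks, target,
                     window = c(max(peaks$grid[1], range_d90 - modulation),
                                peaks$grid[max(support)]))
  w <- fit$weights
  ord <- order(peaks$pullbacks, decreasing = TRUE)
  k <- 0L
  while (k < length(ord) - 1L) {
    cand <- w; cand[ord[k + 1L]] <- 0
    wd <- composed_width(peaks, cand)
    if (is.na(wd) || wd < modulation) break
    w <- cand; k <- k + 1L
  }
  boundary <- ord[k + 1L]
  if (!is.na(composed_width(peaks, w)) &&
      composed_width(peaks, w) > modulation) {
    lo <- 0; hi <- 1
    for (i in seq_len(40L)) {
      f <- (lo + hi) / 2
      cand <- w; cand[boundary] <- w[boundary] * f
      wd <- composed_width(peaks, cand)
      if (is.na(wd) || wd < modulation) lo <- f else hi <- f
    }
    w[boundary] <- w[boundary] * hi
  }
  curve <- compose_sobp(peaks, w)
  met <- pdd_metrics(curve)
  structure(list(weights = w, curve = curve, fit = fit,
                 achieved_width = met$sobp_width,
                 requested = c(range_d90 = range_d90,
                               modulation = modulation),
                 metrics = met),
            class = "sobp_fit")
}

#' @export
print.sobp_fit <- function(x, ...) {
  cat(sprintf("<sobp_fit> requested range %.2f / modulation %.2f cm -> achieved width %.2f cm, D90 %.2f cm, plateau flatness %.2f%%\n",
              x$requested["range_d90"], x$requested["modulation"],
              x$achieved_width, x$metrics$d90, x$metrics$plateau_flatness))
  invisible(x)
}

# landing step of each pulse (step receiving the largest fraction) and the
# stop-pulse removal order: shallowest-peak pulses first (landing-step
# pullback descending), ties broken by pulse index descending
stop_pulse_order <- function(peaks, pulse_map) {
  asg <- pulse_map$assignments
  pulses <- sort(unique(asg$pulse))
  landing <- vapply(pulses, function(p) {
    rows <- asg[asg$pulse == p, ]
    rows$step[which.max(rows$fraction)]
  }, numeric(1))
  pb <- peaks$pullbacks[match(landing, peaks$step_index)]
  pulses[order(-pb, -pulses)]
}

# per-step weights implied by per-pulse weights through the fluence map
step_weights_from_pulses <- function(peaks, pulse_map, pulse_weights) {
  asg <- pulse_map$assignments
  w <- numeric(length(peaks$peaks))
  uw <- pulse_weights[as.character(asg$pulse)]
  uw[is.na(uw)] <- 0
  contrib <- asg$fraction * uw
  for (i in seq_along(peaks$step_index)) {
    sel <- asg$step == peaks$step_index[i]
    w[i] <- sum(contrib[sel])
  }
  w
}

#' Translate fitted step weights into per-pulse weights
#'
#' Finds non-negative per-pulse beam-current multipliers whose delivered
#' per-step fluences reproduce the fitted per-step weights, by non-negative
#' least squares on the pulse-to-step fluence-fraction system. A pulse
#' cannot be split physically, so when pulses straddle step boundaries the
#' reproduction is a least-squares compromise (the partial-shining
#' limitation of a pulsed beam); the residual per-step error is available
#' by recomposing with [compose_sobp()].
#'
#' @param peaks A `"pristine_peak_set"`.
#' @param pulse_map A `"step_fluence_map"`.
#' @param step_weights Fitted per-peak weights.
#' @param equalized Optional result of [equalize_step_fluence()]; when
#'   supplied, its per-pulse weights seed the scale of the solution (the
#'   solve itself already accounts for unequal pulse counts per step).
#' @return Named numeric vector of per-pulse weights.
#' @export
pulse_weights_for_steps <- function(peaks, pulse_map, step_weights,
                                    equalized = NULL) {
  asg <- pulse_map$assignments
  pulses <- sort(unique(asg$pulse))
  Fm <- matrix(0, nrow = length(peaks$step_index), ncol = length(pulses),
               dimnames = list(peaks$step_index, pulses))
  for (r in seq_len(nrow(asg))) {
    si <- match(asg$step[r], peaks$step_index)
    if (!is.na(si))
      Fm[si, as.character(asg$pulse[r])] <-
        Fm[si, as.character(asg$pulse[r])] + asg$fraction[r]
  }
  u <- pracma::lsqnonneg(Fm, as.numeric(step_weights))$x
  names(u) <- pulses
  u
}

#' Stop-pulse curve: SOBP width versus removed pulses
#'
#' Starting from the fully modulated beam, pulses are removed one at a time
#' in a fixed order (pulses landing on the shallowest steps first, ties by
#' pulse index descending) and the SOBP width of each truncated composition
#' is recorded. The resulting lookup curve is the basis for modulation
#' width adjustment. Entry 0 is the fully modulated width; the curve stops
#' when the width becomes undefined (the plateau vanishes).
#'
#' @param peaks A `"pristine_peak_set"`.
#' @param pulse_map A `"step_fluence_map"` for the wheel the library was
#'   built from.
#' @param pulse_weights Named per-pulse weights of the fully modulated beam
#'   (see [pulse_weights_for_steps()]).
#' @return A list of class `"stop_pulse_curve"`: `entries` (data frame
#'   `stop_pulse`, `sobp_width`), `removal_order`, `pulse_weights`.
#' @export
stop_pulse_curve <- function(peaks, pulse_map, pulse_weights) {
  stopifnot(inherits(peaks, "pristine_peak_set"),
            inherits(pulse_map, "step_fluence_map"))
  ord <- stop_pulse_order(peaks, pulse_map)
  u <- pulse_weights
  widths <- numeric(0)
  for (kk in 0:length(ord)) {
    if (kk > 0) u[as.character(ord[kk])] <- 0
    w <- step_weights_from_pulses(peaks, pulse_map, u)
    wd <- composed_width(peaks, w)
    if (is.na(wd)) break
    widths <- c(widths, wd)
  }
  if (length(widths) < 2L)
    stop("stop-pulse curve degenerate: fewer than two defined widths")
  structure(list(entries = data.frame(stop_pulse = seq_along(widths) - 1L,
                                      sobp_width = widths),
                 removal_order = ord,
                 pulse_weights = pulse_weights),
            class = "stop_pulse_curve")
}

#' @export
print.stop_pulse_curve <- function(x, ...) {
  e <- x$entries
  cat(sprintf("<stop_pulse_curve> %d entries, width %.2f -> %.2f cm\n",
              nrow(e), e$sobp_width[1], e$sobp_width[nrow(e)]))
  invisible(x)
}

#' Adjust modulation width via a fractional stop pulse
#'
#' Looks up the bracketing integer stop pulses `(k, k+1)` on the stop-pulse
#' curve, linearly interpolates the fraction of the last pulse to apply,
#' scales that pulse's fluence by `1 - fraction` (pulses removed before it
#' are zeroed), and recomposes the per-step weights. The achieved width is
#' recomputed from the composition with the width metric.
#'
#' @param curve A `"stop_pulse_curve"`.
#' @param desired_width Requested SOBP width in cm; must lie within the
#'   curve's width range.
#' @param peaks,pulse_map The library and fluence map the curve was built
#'   from.
#' @param refine When `TRUE` (default) and the linearly interpolated
#'   fraction leaves the recomputed width more than 0.02 cm from the
#'   request, the fraction is polished by bisection (the width is monotone
#'   in the applied fraction), recovering the 0.1 cm width granularity on
#'   libraries whose width-versus-pulse curve is locally nonlinear.
#'   `refine = FALSE` applies the plain interpolated fraction.
#' @return A list of class `"adjusted_weights"`: `weights` (per-step),
#'   `pulse_weights`, `fractional_stop_pulse`, `achieved_width`.
#' @export
adjust_modulation <- function(curve, desired_width, peaks, pulse_map,
                              refine = TRUE) {
  stopifnot(inherits(curve, "stop_pulse_curve"))
  e <- curve$entries
  wmax <- max(e$sobp_width); wmin <- min(e$sobp_width)
  if (desired_width > wmax + 1e-9 || desired_width < wmin - 1e-9)
    stop(sprintf("desired width %.2f cm outside achievable interval [%.2f, %.2f] cm",
                 desired_width, wmin, wmax))
  # deepest k with width_k >= desired (widths non-increasing in k)
  k <- max(which(e$sobp_width >= desired_width - 1e-12)) - 1L
  wk <- e$sobp_width[k + 1L]
  if (abs(wk - desired_width) < 1e-12 || k + 2L > nrow(e)) {
    frac <- 0
  } else {
    wk1 <- e$sobp_width[k + 2L]
    frac <- if (wk - wk1 < 1e-12) 0 else (wk - desired_width) / (wk - wk1)
  }
  ord <- curve$removal_order
  apply_frac <- function(f) {
    u <- curve$pulse_weights
    if (k > 0) u[as.character(ord[seq_len(k)])] <- 0
    if (f > 0)
      u[as.character(ord[k + 1L])] <- u[as.character(ord[k + 1L])] * (1 - f)
    u
  }
  u <- apply_frac(frac)
  w <- step_weights_from_pulses(peaks, pulse_map, u)
  achieved <- composed_width(peaks, w)
  if (isTRUE(refine) && frac > 0 && !is.na(achieved) &&
      abs(achieved - desired_width) > 0.02) {
    lo <- 0; hi <- 1
    for (i in seq_len(30L)) {
      f <- (lo + hi) / 2
      wf <- composed_width(peaks,
                           step_weights_from_pulses(peaks, pulse_map,
                                                    apply_frac(f)))
      if (is.na(wf) || wf < desired_width) hi <- f else lo <- f
    }
    frac <- (lo + hi) / 2
    u <- apply_frac(frac)
    w <- step_weights_from_pulses(peaks, pulse_map, u)
    achieved <- composed_width(peaks, w)
  }
  structure(list(weights = w, pulse_weights = u,
                 fractional_stop_pulse = k + frac,
                 achieved_width = achieved),
            class = "adjusted_weights")
}

#' @export
print.adjusted_weights <- function(x, ...) {
  cat(sprintf("<adjusted_weights> fractional stop pulse %.2f -> achieved width %.2f cm\n",
              x$fractional_stop_pulse, x$achieved_width))
  invisible(x)
}

#' Read and write weight vectors (JSON)
#'
#' Serialized as `{"step_weights": [...], "fractional_stop_pulse": x}`;
#' the fractional stop pulse is optional.
#'
#' @param path File path.
#' @param weights Numeric weights or an `"adjusted_weights"` object.
#' @param fractional_stop_pulse Optional fractional stop pulse to record.
#' @return `read_weights()`: list with `step_weights` and
#'   `fractional_stop_pulse` (NULL if absent).
#' @export
write_weights <- function(weights, path, fractional_stop_pulse = NULL) {
  if (inherits(weights, "adjusted_weights")) {
    fractional_stop_pulse <- weights$fractional_stop_pulse
    weights <- weights$weights
  }
  if (inherits(weights, "fit_result")) weights <- weights$weights
  obj <- list(step_weights = as.numeric(weights))
  if (!is.null(fractional_stop_pulse))
    obj$fractional_stop_pulse <- fractional_stop_pulse
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(step_weights = as.numeric(j$step_weights),
       fractional_stop_pulse = j$fractional_stop_pulse)
}

#' Write a stop-pulse curve as CSV
#'
#' Two columns `stop_pulse,width_cm`.
#'
#' @param curve A `"stop_pulse_curve"`.
#' @param path File path.
#' @export
write_stop_pulse_curve <- function(curve, path) {
  df <- data.frame(stop_pulse = curve$entries$stop_pulse,
                   width_cm = curve$entries$sobp_width)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
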