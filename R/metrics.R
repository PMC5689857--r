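#' Normalize a curve for metric extraction
#'
#' Depth-dose curves are scaled so the maximum dose is 100 (`mode = "max"`,
#' the default) or so the mean plateau dose is 100 (`mode = "plateau"`,
#' plateau taken as the middle 80% of the proximal-95/distal-90 span).
#' Lateral profiles are scaled so the dose at the field center (midpoint of
#' the two 50% crossings) is 100; with an off-center global maximum the
#' maximum may then exceed 100. Normalization is recorded in `meta`.
#'
#' @param curve A `"depth_dose_curve"` or `"lateral_profile"`.
#' @param mode Normalization convention for depth curves.
#' @return A curve of the same class with `meta$normalized = TRUE`.
#' @export
normalize_curve <- function(curve, mode = c("max", "plateau")) {
  stopifnot(inherits(curve, "beam_curve"))
  mode <- match.arg(mode)
  if (max(curve$dose) <= 0) stop("cannot normalize an all-zero curve")
  out <- curve
  if (inherits(curve, "lateral_profile")) {
    tmp <- curve$dose / max(curve$dose) * 100
    ed <- profile_edges(curve$positions, tmp)
    centre <- (ed[1] + ed[2]) / 2
    cval <- stats::approx(curve$positions, curve$dose, xout = centre)$y
    out$dose <- curve$dose / cval * 100
    out$meta$field_center <- centre
  } else if (mode == "max") {
    out$dose <- curve$dose / max(curve$dose) * 100
  } else {
    tmp <- curve$dose / max(curve$dose) * 100
    d90 <- crossing_depth(curve$depths, tmp, 90, "distal")
    p95 <- crossing_depth(curve$depths, tmp, 95, "proximal")
    if (is.na(p95)) p95 <- curve$depths[1]
    if (is.na(d90)) stop("plateau normalization requires a distal 90% crossing")
    w <- d90 - p95
    sel <- curve$depths >= p95 + 0.1 * w & curve$depths <= d90 - 0.1 * w
    if (!any(sel)) stop("plateau region empty; cannot plateau-normalize")
    out$dose <- curve$dose / mean(curve$dose[sel]) * 100
  }
  out$meta$normalized <- TRUE
  out$meta$normalization <- if (inherits(curve, "lateral_profile"))
    "center" else mode
  out
}

# crossing search on a uniform grid. distal: deepest interval where the
# (percent) dose crosses from >= level to < level; proximal: shallowest
# interval crossing from < level to >= level. Linear interpolation inside
# the interval; NA when no crossing exists.
crossing_depth <- function(x, y, level, side) {
  n <- length(y)
  if (side == "distal") {
    i <- which(y[-n] >= level & y[-1] < level)
    if (!length(i)) return(NA_real_)
    j <- max(i)
    x[j] + (x[j + 1] - x[j]) * (y[j] - level) / (y[j] - y[j + 1])
  } else {
    i <- which(y[-n] < level & y[-1] >= level)
    if (!length(i)) return(NA_real_)
    j <- min(i)
    x[j] + (x[j + 1] - x[j]) * (level - y[j]) / (y[j + 1] - y[j])
  }
}

#' Depth of a given dose level
#'
#' Finds the depth where the normalized dose crosses `level` percent.
#' `side = "distal"` returns the deepest crossing from at-or-above to below
#' the level; `side = "proximal"` the shallowest crossing from below to
#' at-or-above. Positions are linearly interpolated within the grid
#' interval. Curves not yet normalized are normalized (max = 100)
#' internally.
#'
#' @param curve A `"depth_dose_curve"`.
#' @param level Dose level in percent, in (0, 100).
#' @param side `"distal"` or `"proximal"`.
#' @return Depth in cm, or `NA` if the curve never crosses the level.
#' @export
depth_at_level <- function(curve, level, side = c("distal", "proximal")) {
  stopifnot(inherits(curve, "depth_dose_curve"))
  side <- match.arg(side)
  if (level <= 0 || level >= 100) stop("'level' must be in (0, 100)")
  y <- if (isTRUE(curve$meta$normalized)) curve$dose
       else curve$dose / max(curve$dose) * 100
  crossing_depth(curve$depths, y, level, side)
}

#' Depth-dose metrics
#'
#' Extracts the scalar percent-depth-dose metrics used in commissioning
#' comparisons: beam range D90 (distal 90% depth), distal 20% depth, the
#' proximal 95% depth, PDD(0.5) (normalized dose at 0.5 cm, linearly
#' interpolated), the SOBP width (D90 minus proximal 95%), peak depth, and
#' an in-plateau flatness evaluated over the middle 80% of the
#' proximal-95/distal-90 span. When the curve is still at or above 95% at
#' the first grid point (full modulation reaching the surface) the proximal
#' 95% depth is taken as the first grid depth.
#'
#' @param curve A `"depth_dose_curve"`; normalized internally (max = 100)
#'   if not already.
#' @return A list of class `"pdd_metrics"`: `d90`, `d20`, `prox95`,
#'   `pdd05`, `sobp_width`, `peak_depth`, `plateau_flatness`.
#' @export
pdd_metrics <- function(curve) {
  stopifnot(inherits(curve, "depth_dose_curve"))
  y <- if (isTRUE(curve$meta$normalized)) curve$dose
       else curve$dose / max(curve$dose) * 100
  x <- curve$depths
  d90 <- crossing_depth(x, y, 90, "distal")
  if (is.na(d90)) stop("no distal 90% crossing; cannot compute range")
  d20 <- crossing_depth(x, y, 20, "distal")
  prox95 <- crossing_depth(x, y, 95, "proximal")
  if (is.na(prox95) && y[1] >= 95) prox95 <- x[1]
  pdd05 <- stats::approx(x, y, xout = 0.5, rule = 1)$y
  width <- if (is.na(prox95)) NA_real_ else d90 - prox95
  flat <- NA_real_
  if (!is.na(width) && width > 0) {
    sel <- x >= prox95 + 0.1 * width & x <= d90 - 0.1 * width
    if (sum(sel) >= 2) {
      dmax <- max(y[sel]); dmin <- min(y[sel])
      flat <- abs(dmax - dmin) / (dmax + dmin) * 100
    }
  }
  structure(list(d90 = d90, d20 = d20, prox95 = prox95, pdd05 = pdd05,
                 sobp_width = width, peak_depth = x[which.max(y)],
                 plateau_flatness = flat),
            class = "pdd_metrics")
}

#' @export
print.pdd_metrics <- function(x, ...) {
  cat(sprintf("<pdd_metrics> D90 %.2f cm | D20 %.2f cm | prox95 %s cm | width %s cm | PDD(0.5) %.1f%%\n",
              x$d90, x$d20,
              ifelse(is.na(x$prox95), "NA", sprintf("%.2f", x$prox95)),
              ifelse(is.na(x$sobp_width), "NA", sprintf("%.2f", x$sobp_width)),
              x$pdd05))
  invisible(x)
}

# 50% field edges of a percent-scale profile: shallowest rising and deepest
# falling crossing. Errors unless both exist.
profile_edges <- function(x, y) {
  left <- crossing_depth(x, y, 50, "proximal")
  right <- crossing_depth(x, y, 50, "distal")
  if (is.na(left) || is.na(right) || right <= left)
    stop("profile must have two 50% crossings")
  c(left, right)
}

# trapezoidal integral of interpolated curve between a and b, using grid
# points inside plus interpolated endpoints
trapz_between <- function(x, y, a, b) {
  inner <- x[x > a & x < b]
  xs <- c(a, inner, b)
  ys <- stats::approx(x, y, xout = xs)$y
  sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
}

#' Lateral profile metrics
#'
#' Field edges are the 50% crossings (linear interpolation) of the
#' center-normalized profile; FWHM is their distance and the field center
#' their midpoint. Flatness is `|Dmax - Dmin| / (Dmax + Dmin) * 100` over
#' the middle 80% of the field (field size taken as the FWHM); symmetry is
#' `|DL - DR| / (DL + DR) * 100` with `DL`, `DR` the trapezoidal integral
#' doses of the left and right halves of that middle-80% region. Both are
#' reported as absolute values. The per-side penumbra is the 80%-20%
#' crossing distance on that side.
#'
#' @param profile A `"lateral_profile"`; normalized internally if needed.
#' @return A list of class `"profile_metrics"`: `penumbra_left`,
#'   `penumbra_right`, `penumbra_mean`, `fwhm`, `field_center`, `flatness`,
#'   `symmetry`, `dmin`, `dmax`, `dl`, `dr`.
#' @export
profile_metrics <- function(profile) {
  stopifnot(inherits(profile, "lateral_profile"))
  prof <- if (isTRUE(profile$meta$normalized)) profile
          else normalize_curve(profile)
  x <- prof$positions; y <- prof$dose
  ed <- profile_edges(x, y)
  fwhm <- ed[2] - ed[1]
  centre <- (ed[1] + ed[2]) / 2
  lo <- centre - 0.4 * fwhm; hi <- centre + 0.4 * fwhm
  sel_x <- c(lo, x[x > lo & x < hi], hi)
  sel_y <- stats::approx(x, y, xout = sel_x)$y
  dmax <- max(sel_y); dmin <- min(sel_y)
  flatness <- abs(dmax - dmin) / (dmax + dmin) * 100
  dl <- trapz_between(x, y, lo, centre)
  dr <- trapz_between(x, y, centre, hi)
  symmetry <- abs(dl - dr) / (dl + dr) * 100
  p20l <- crossing_depth(x, y, 20, "proximal")
  p80l <- crossing_depth(x, y, 80, "proximal")
  p80r <- crossing_depth(x, y, 80, "distal")
  p20r <- crossing_depth(x, y, 20, "distal")
  pen_l <- p80l - p20l
  pen_r <- p20r - p80r
  structure(list(penumbra_left = pen_l, penumbra_right = pen_r,
                 penumbra_mean = (pen_l + pen_r) / 2,
                 fwhm = fwhm, field_center = centre,
                 flatness = flatness, symmetry = symmetry,
                 dmin = dmin, dmax = dmax, dl = dl, dr = dr),
            class = "profile_metrics")
}

#' @export
print.profile_metrics <- function(x, ...) {
  cat(sprintf("<profile_metrics> FWHM %.2f cm | penumbra L/R %.3f/%.3f cm | flatness %.2f%% | symmetry %.2f%%\n",
              x$fwhm, x$penumbra_left, x$penumbra_right, x$flatness,
              x$symmetry))
  invisible(x)
}
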