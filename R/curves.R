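#' Depth-dose curves and lateral profiles
#'
#' `dose_curve()` builds a depth-dose curve (dose versus depth in water,
#' uniform ascending grid); `lateral_profile()` builds a lateral dose profile
#' (dose versus off-axis position at a fixed depth). Both are plain lists of
#' class `"depth_dose_curve"` / `"lateral_profile"` (and common parent
#' `"beam_curve"`) with fields `depths` (or `positions`), `dose` and a
#' free-form `meta` list (configuration id, role, scan depth, normalization
#' state, ...).
#'
#' Invariants enforced at construction: the grid is strictly increasing with
#' constant spacing (within 1e-9 cm), `dose` matches the grid in length and is
#' non-negative everywhere; a curve whose `meta$normalized` is `TRUE` must
#' have maximum dose 100 (within 1e-6) for depth curves, or dose 100 at the
#' field center for profiles.
#'
#' @param depths,positions Numeric grid in cm, strictly increasing, uniformly
#'   spaced.
#' @param dose Non-negative dose values (arbitrary units, or percent once
#'   normalized), same length as the grid.
#' @param meta Named list of free-form metadata tags.
#' @return An object of class `"depth_dose_curve"` or `"lateral_profile"`.
#' @seealso [generate_pristine_peak()], [generate_lateral_profile()],
#'   [normalize_curve()]
#' @export
dose_curve <- function(depths, dose, meta = list()) {
  check_grid(depths, "depths")
  check_dose(dose, depths, "dose")
  obj <- structure(list(depths = as.numeric(depths), dose = as.numeric(dose),
                        meta = meta),
                   class = c("depth_dose_curve", "beam_curve"))
  if (isTRUE(meta$normalized) && abs(max(obj$dose) - 100) > 1e-6)
    stop("curve flagged normalized but max(dose) != 100")
  obj
}

#' @rdname dose_curve
#' @export
lateral_profile <- function(positions, dose, meta = list()) {
  check_grid(positions, "positions")
  check_dose(dose, positions, "dose")
  structure(list(positions = as.numeric(positions), dose = as.numeric(dose),
                 meta = meta),
            class = c("lateral_profile", "beam_curve"))
}

# shared axis accessor: depths for depth curves, positions for profiles
curve_axis <- function(curve) {
  if (inherits(curve, "lateral_profile")) curve$positions else curve$depths
}

curve_spacing <- function(curve) {
  ax <- curve_axis(curve)
  ax[2] - ax[1]
}

check_grid <- function(x, what) {
  if (!is.numeric(x) || length(x) < 2L)
    stop(sprintf("'%s' must be a numeric grid of length >= 2", what))
  d <- diff(x)
  if (any(d <= 0))
    stop(sprintf("'%s' must be strictly increasing", what))
  if (max(d) - min(d) > 1e-9)
    stop(sprintf("'%s' must be uniformly spaced (within 1e-9 cm)", what))
  invisible(x)
}

check_dose <- function(dose, grid, what) {
  if (length(dose) != length(grid))
    stop(sprintf("'%s' must match the grid in length", what))
  if (anyNA(dose) || any(dose < 0))
    stop(sprintf("'%s' must be non-negative and free of NA", what))
  invisible(dose)
}

#' @export
print.depth_dose_curve <- function(x, ...) {
  cat(sprintf("<depth_dose_curve> %d points, depth %.2f..%.2f cm, max dose %.4g\n",
              length(x$depths), x$depths[1], x$depths[length(x$depths)],
              max(x$dose)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.lateral_profile <- function(x, ...) {
  cat(sprintf("<lateral_profile> %d points, position %.2f..%.2f cm, max dose %.4g\n",
              length(x$positions), x$positions[1],
              x$positions[length(x$positions)], max(x$dose)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.depth_dose_curve <- function(x, ...) {
  data.frame(depth_cm = x$depths, dose = x$dose)
}

#' @export
as.data.frame.lateral_profile <- function(x, ...) {
  data.frame(position_cm = x$positions, dose = x$dose)
}

#' Uniform grids for curve generation
#'
#' `depth_grid()` returns a uniform depth grid (default spacing 0.1 cm);
#' `position_grid()` returns a symmetric off-axis grid centered at 0.
#'
#' @param to,from Depth extent in cm.
#' @param by Grid spacing in cm.
#' @param halfwidth Half-extent of the position grid in cm.
#' @return Numeric vector.
#' @export
depth_grid <- function(to, from = 0, by = 0.1) {
  if (to <= from) stop("'to' must exceed 'from'")
  seq(from, to, by = by)
}

#' @rdname depth_grid
#' @export
position_grid <- function(halfwidth, by = 0.1) {
  if (halfwidth <= 0) stop("'halfwidth' must be positive")
  seq(-halfwidth, halfwidth, by = by)
}

# linear interpolation of a curve at arbitrary axis values (NA outside grid)
interp_curve <- function(curve, at) {
  stats::approx(curve_axis(curve), curve$dose, xout = at, rule = 1)$y
}
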