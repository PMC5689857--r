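#' Parameters for synthetic pristine Bragg peaks
#'
#' The synthetic pristine peak is a Bragg-Kleeman stopping-power shape,
#' `D0(d) ~ (R - d)^(1/p - 1)` with `p = 1.77` for `d < R`, plus a linear
#' nuclear-background term and a near-flat entrance pedestal, convolved with a
#' Gaussian kernel in depth whose width `distal_spread_sigma` is the proxy for
#' beam energy spread. Increasing `distal_spread_sigma` raises the normalized
#' entrance dose and lengthens the distal falloff, the behavior commissioning
#' tuning relies on. The generator internally shifts `R` so that the distal
#' 90% crossing of the finished curve equals `range_d90` within 0.02 cm.
#'
#' @param range_d90 Target distal 90% depth (beam range) in cm; must be > 0.
#' @param distal_spread_sigma Gaussian smearing width in cm (> 0). Default
#'   `NULL` picks `max(0.012 * range_d90^0.935, 0.15)`: a Bortfeld-style
#'   range-straggling estimate with a 0.15 cm floor standing in for the
#'   machine energy spread that dominates shallow-range configurations.
#' @param entrance_fraction Unitless entrance-pedestal amplitude relative to
#'   the peak maximum, shaping the PDD(0.5)/peak ratio; in `[0, 1)`.
#' @param background_fraction Amplitude of the linear nuclear background
#'   `background_fraction * (1 - d/R)`, relative to the peak maximum; in
#'   `[0, 0.2)`.
#' @param fluence Protons delivered for this peak (nominal 3e6 per wheel
#'   step); scales the output dose linearly.
#' @return A list of class `"pristine_peak_params"`.
#' @export
pristine_peak_params <- function(range_d90,
                                 distal_spread_sigma = NULL,
                                 entrance_fraction = 0.05,
                                 background_fraction = 0.02,
                                 fluence = 3e6) {
  if (!is.numeric(range_d90) || range_d90 <= 0)
    stop("'range_d90' must be positive")
  if (is.null(distal_spread_sigma))
    distal_spread_sigma <- max(0.012 * range_d90^0.935, 0.15)
  if (distal_spread_sigma <= 0)
    stop("'distal_spread_sigma' must be positive")
  if (entrance_fraction < 0 || entrance_fraction >= 1)
    stop("'entrance_fraction' must be in [0, 1)")
  if (background_fraction < 0 || background_fraction >= 0.2)
    stop("'background_fraction' must be in [0, 0.2)")
  if (fluence <= 0) stop("'fluence' must be positive")
  structure(list(range_d90 = range_d90,
                 distal_spread_sigma = distal_spread_sigma,
                 entrance_fraction = entrance_fraction,
                 background_fraction = background_fraction,
                 fluence = fluence),
            class = "pristine_peak_params")
}

#' Parameters for synthetic lateral profiles
#'
#' Flat-topped field of full width `field_width` with Gaussian-blurred edges
#' (error-function penumbra of width `penumbra_sigma`) and an optional
#' in-field cosine ripple. The ripple completes one full period across the
#' middle 80% of the field, so its amplitude maps directly onto the flatness
#' statistic.
#'
#' @param field_width Flat-top full width L in cm (> 0).
#' @param penumbra_sigma Gaussian edge width in cm (> 0); the per-side 80-20
#'   penumbra of the ideal profile is `1.6832 * penumbra_sigma`.
#' @param ripple_amplitude In-field cosine ripple amplitude in percent,
#'   in `[0, 5]`.
#' @return A list of class `"profile_params"`.
#' @export
profile_params <- function(field_width, penumbra_sigma,
                           ripple_amplitude = 0) {
  if (field_width <= 0) stop("'field_width' must be positive")
  if (penumbra_sigma <= 0) stop("'penumbra_sigma' must be positive")
  if (ripple_amplitude < 0 || ripple_amplitude > 5)
    stop("'ripple_amplitude' must be in [0, 5]")
  structure(list(field_width = field_width,
                 penumbra_sigma = penumbra_sigma,
                 ripple_amplitude = ripple_amplitude),
            class = "profile_params")
}

# exact cell average of the Bragg-Kleeman term (R - d)^(a - 1), a = 1/p,
# over [lo, hi] clipped to [0, R]; integrable singularity handled in closed
# form, avoiding divergence at d -> R
bk_cell_average <- function(d, R, h, p = 1.77) {
  a <- 1 / p
  lo <- pmin(pmax(d - h / 2, 0), R)
  hi <- pmin(pmax(d + h / 2, 0), R)
  out <- numeric(length(d))
  ok <- hi > lo
  out[ok] <- ((R - lo[ok])^a - (R - hi[ok])^a) / (a * h)
  out
}

# Gaussian smearing on the internal supersampled grid; dose reflected at the
# surface (d = 0) and zero-padded distally
smear_gaussian <- function(f, sigma, h) {
  half <- max(ceiling(6 * sigma / h), 1L)
  kx <- (-half:half) * h
  kern <- stats::dnorm(kx, 0, sigma)
  kern <- kern / sum(kern)
  n <- length(f)
  pad_lo <- rev(f[seq(2L, half + 1L)])
  fp <- c(pad_lo, f, rep(0, half))
  as.numeric(stats::filter(fp, kern, sides = 2L))[(half + 1L):(half + n)]
}

# distal crossing at `level` percent of max on an arbitrary uniform grid;
# deepest crossing, linear interpolation; NA when absent
distal_crossing <- function(x, y, level) {
  m <- max(y)
  yy <- y / m * 100
  ipk <- which.max(yy)
  i <- which(yy[-length(yy)] >= level & yy[-1] < level)
  i <- i[i >= ipk]
  if (!length(i)) return(NA_real_)
  j <- max(i)
  x[j] + (x[j + 1] - x[j]) * (yy[j] - level) / (yy[j] - yy[j + 1])
}

#' Generate a synthetic pristine Bragg peak
#'
#' Builds the depth-dose curve of a single pristine Bragg peak on the
#' requested grid. The shape is computed on an internal 0.01 cm supersampled
#' grid (exact cell averages of the Bragg-Kleeman term, so the integrable
#' singularity at the range is handled analytically), convolved with the
#' Gaussian energy-spread kernel, calibrated so the distal 90% crossing
#' equals `params$range_d90` within 0.02 cm, then linearly resampled to
#' `grid`. Dose is scaled so that the peak maximum is
#' `100 * fluence / 3e6` (dose per nominal step fluence); the curve is not
#' flagged normalized.
#'
#' @param params A [pristine_peak_params()] object.
#' @param grid Depth grid in cm (see [depth_grid()]); must cover the distal
#'   falloff: generation fails if the dose at the last grid point exceeds 1%
#'   of the peak maximum.
#' @return A `"depth_dose_curve"`.
#' @examples
#' pk <- generate_pristine_peak(pristine_peak_params(25), depth_grid(27))
#' depth_at_level(normalize_curve(pk), 90, "distal")  # 25.00 +- 0.02
#' @export
generate_pristine_peak <- function(params, grid) {
  stopifnot(inherits(params, "pristine_peak_params"))
  check_grid(grid, "grid")
  if (grid[1] > 1e-9) stop("depth grid must start at 0")
  R_target <- params$range_d90
  sigma <- params$distal_spread_sigma
  if (max(grid) < R_target)
    stop("grid too short: does not reach the requested range")
  h <- 0.01
  fine <- seq(0, max(grid) + 6 * sigma + 0.5, by = h)
  Rint <- R_target
  dose_fine <- NULL
  for (it in seq_len(25L)) {
    bk <- bk_cell_average(fine, Rint, h)
    core <- smear_gaussian(bk, sigma, h)
    m0 <- max(core)
    ramp <- ifelse(fine < Rint, 1 - fine / Rint, 0)
    pede <- ifelse(fine < Rint, 1 - (fine / Rint)^2, 0)
    dose_fine <- core +
      m0 * params$background_fraction * smear_gaussian(ramp, sigma, h) +
      m0 * params$entrance_fraction * smear_gaussian(pede, sigma, h)
    # calibrate against the crossing measured on the requested output grid,
    # so the returned curve itself meets the range contract
    dose_out <- stats::approx(fine, dose_fine, xout = grid, rule = 2)$y
    d90 <- distal_crossing(grid, dose_out, 90)
    if (is.na(d90))
      stop("grid too short to contain the distal falloff (no distal 90% crossing)")
    err <- R_target - d90
    if (abs(err) < 0.002) break
    Rint <- max(Rint + err, h)
  }
  scale <- params$fluence / 3e6 * 100 / max(dose_fine)
  dose <- stats::approx(fine, dose_fine * scale, xout = grid, rule = 2)$y
  dose[dose < 0] <- 0
  if (dose[length(dose)] > 0.01 * max(dose))
    stop("grid too short to contain the distal falloff (dose at last depth > 1% of max)")
  dose_curve(grid, dose,
             meta = list(role = "simulated", kind = "pristine",
                         range_d90 = R_target,
                         distal_spread_sigma = sigma,
                         fluence = params$fluence,
                         normalized = FALSE))
}

#' Generate a synthetic lateral beam profile
#'
#' `P(x) = [Phi((x + L/2)/sigma) - Phi((x - L/2)/sigma)] * (1 + ripple)`,
#' with `Phi` the standard normal CDF and the ripple a cosine of amplitude
#' `ripple_amplitude` percent completing one period across the middle 80% of
#' the field. The profile is symmetric about 0 (the ripple is even in x) and
#' scaled to 100 at its center value.
#'
#' @param params A [profile_params()] object.
#' @param grid Position grid in cm (see [position_grid()]); must span at
#'   least `field_width + 8 * penumbra_sigma`.
#' @return A `"lateral_profile"`.
#' @export
generate_lateral_profile <- function(params, grid) {
  stopifnot(inherits(params, "profile_params"))
  check_grid(grid, "grid")
  L <- params$field_width
  sp <- params$penumbra_sigma
  if (max(grid) - min(grid) < L + 8 * sp)
    stop("position grid narrower than field_width + 8 * penumbra_sigma")
  env <- stats::pnorm((grid + L / 2) / sp) - stats::pnorm((grid - L / 2) / sp)
  rip <- 1 + params$ripple_amplitude / 100 * cos(2 * pi * grid / (0.8 * L))
  dose <- env * rip
  dose <- dose / stats::approx(grid, dose, xout = 0, rule = 2)$y * 100
  dose[dose < 0] <- 0
  lateral_profile(grid, dose,
                  meta = list(role = "simulated", kind = "profile",
                              field_width = L, penumbra_sigma = sp,
                              ripple_amplitude = params$ripple_amplitude,
                              normalized = FALSE))
}

#' Add multiplicative measurement noise to a curve
#'
#' Emulates point-by-point detector noise in commissioning scans:
#' each dose value is multiplied by an independent Gaussian factor
#' `N(1, relative_sd)` and clipped at zero. The RNG state of the session is
#' left untouched; identical `(curve, relative_sd, seed)` give identical
#' output, and `relative_sd = 0` returns the input unchanged.
#'
#' @param curve A `"depth_dose_curve"` or `"lateral_profile"`.
#' @param relative_sd Relative standard deviation of the noise (>= 0).
#' @param seed Integer seed for reproducibility.
#' @return A curve of the same class, with `meta$role = "measured"` and the
#'   seed and noise level recorded in `meta`.
#' @export
add_measurement_noise <- function(curve, relative_sd, seed) {
  stopifnot(inherits(curve, "beam_curve"))
  if (!is.numeric(relative_sd) || relative_sd < 0)
    stop("'relative_sd' must be non-negative")
  if (relative_sd == 0) return(curve)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  factors <- stats::rnorm(length(curve$dose), mean = 1, sd = relative_sd)
  noisy <- pmax(curve$dose * factors, 0)
  out <- curve
  out$dose <- noisy
  out$meta$role <- "measured"
  out$meta$noise_relative_sd <- relative_sd
  out$meta$noise_seed <- as.integer(seed)
  out
}
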