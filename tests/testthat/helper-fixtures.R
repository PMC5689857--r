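# Shared fixtures, built once per test run and cached.
fixture_cache <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (!exists(name, envir = fixture_cache))
    assign(name, builder(), envir = fixture_cache)
  get(name, envir = fixture_cache)
}

# 14-step wheel with uniform 0.7 cm pullback steps, narrow fixed-sigma
# peaks (pullback spacing >= 3 sigma so weights are identifiable)
library_14step <- function() {
  get_fixture("lib14", function() {
    width <- 330 / 14
    steps <- lapply(0:13, function(i)
      rmw_step(i, i * width, width, i * 0.7))
    steps[[15]] <- rmw_step(14L, 330, 30, 13 * 0.7, blocked = TRUE)
    build_step_peak_library(
      rmw(steps),
      pristine_peak_params(20, distal_spread_sigma = 0.2),
      depth_grid(22), sigma_growth = 0)
  })
}

# compact default library + pulse machinery for stop-pulse tests
pulse_fixture <- function() {
  get_fixture("pulse_fix", function() {
    wheel <- default_rmw(15, 10)
    peaks <- build_step_peak_library(wheel, pristine_peak_params(15),
                                     depth_grid(17))
    map <- map_pulses_to_steps(wheel, pulse_train())
    fit <- synthesize_sobp(peaks, 15, 10)
    u <- pulse_weights_for_steps(peaks, map, fit$weights)
    list(wheel = wheel, peaks = peaks, map = map, fit = fit, u = u,
         curve = stop_pulse_curve(peaks, map, u))
  })
}

# brute-force level crossing on a 0.001 cm linearly interpolated grid
brute_crossing <- function(curve, level, side) {
  x <- if (inherits(curve, "lateral_profile")) curve$positions else curve$depths
  y <- curve$dose / max(curve$dose) * 100
  fx <- seq(x[1], x[length(x)], by = 0.001)
  fy <- approx(x, y, xout = fx)$y
  n <- length(fy)
  if (side == "distal") {
    i <- which(fy[-n] >= level & fy[-1] < level)
    if (!length(i)) return(NA_real_)
    fx[max(i)]
  } else {
    i <- which(fy[-n] < level & fy[-1] >= level)
    if (!length(i)) return(NA_real_)
    fx[min(i)]
  }
}

# independent fine-resolution (0.001 cm) numerical convolution of the
# Bragg-Kleeman stopping-power shape; the 80-20 falloff distance is
# shift-invariant, so no range calibration is needed
oracle_falloff_80_20 <- function(range, sigma, p = 1.77) {
  h <- 0.001
  a <- 1 / p
  d <- seq(0, range + 6 * sigma + 0.5, by = h)
  lo <- pmin(pmax(d - h / 2, 0), range)
  hi <- pmin(pmax(d + h / 2, 0), range)
  f <- numeric(length(d))
  ok <- hi > lo
  f[ok] <- ((range - lo[ok])^a - (range - hi[ok])^a) / (a * h)
  half <- ceiling(6 * sigma / h)
  kern <- dnorm((-half:half) * h, 0, sigma)
  kern <- kern / sum(kern)
  fp <- c(rev(f[2:(half + 1)]), f, rep(0, half))
  y <- as.numeric(stats::filter(fp, kern, sides = 2))[(half + 1):(half + length(f))]
  y <- y / max(y) * 100
  ipk <- which.max(y)
  cross <- function(lev) {
    i <- which(y[-length(y)] >= lev & y[-1] < lev)
    i <- i[i >= ipk]
    j <- max(i)
    d[j] + h * (y[j] - lev) / (y[j] - y[j + 1])
  }
  cross(20) - cross(80)
}

# distal 80-20 falloff of a generated curve
falloff_80_20 <- function(curve) {
  brute_crossing(curve, 20, "distal") - brute_crossing(curve, 80, "distal")
}
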