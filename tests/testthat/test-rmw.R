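full_circle_wheel <- function() rmw(list(rmw_step(0, 0, 360, 0)))

two_step_wheel <- function() rmw(list(rmw_step(0, 0, 180, 0),
                                      rmw_step(1, 180, 180, 0.5)))

test_that("600 rpm with a 2 ms pulse period yields exactly 50 pulses per rotation", {
  map <- map_pulses_to_steps(full_circle_wheel(),
                             pulse_train(period = 0.002,
                                         pulse_angular_width = 0))
  expect_identical(map$pulses_per_rotation, 50)
  expect_equal(sum(map$assignments$fraction), 50)
  expect_equal(unname(map$totals["0"]), 50)
})

test_that("point pulses land on the step containing their angle", {
  # quarter-rotation period on a two-step wheel: angles 0, 90, 180, 270
  map <- map_pulses_to_steps(two_step_wheel(),
                             pulse_train(period = 0.025,
                                         pulse_angular_width = 0))
  expect_equal(map$assignments$step, c(0, 0, 1, 1))
  # half-rotation period alternates steps each pulse
  map2 <- map_pulses_to_steps(two_step_wheel(),
                              pulse_train(period = 0.05,
                                          pulse_angular_width = 0),
                              rotations = 2)
  expect_equal(map2$assignments$step, c(0, 1, 0, 1))
})

test_that("a finite pulse centered on a step boundary splits 50/50", {
  map <- map_pulses_to_steps(two_step_wheel(),
                             pulse_train(period = 0.05, phase = 180,
                                         pulse_angular_width = 10))
  first <- map$assignments[map$assignments$pulse == 0, ]
  expect_equal(sort(first$fraction), c(0.5, 0.5))
  expect_setequal(first$step, c(0, 1))
})

test_that("edge splitting is continuous and conserves each pulse's fluence", {
  wheel <- two_step_wheel()
  phases <- seq(172, 188, by = 0.5)
  f0 <- vapply(phases, function(ph) {
    # period chosen so exactly one pulse fires per rotation
    map <- map_pulses_to_steps(wheel,
                               pulse_train(period = 0.099, phase = ph,
                                           pulse_angular_width = 10))
    asg <- map$assignments
    expect_equal(sum(asg$fraction), 1)
    s0 <- asg$fraction[asg$step == 0]
    if (length(s0)) s0 else 0
  }, numeric(1))
  expect_true(all(diff(f0) <= 0))        # monotone handover to step 1
  expect_lt(max(abs(diff(f0))), 0.06)    # no jumps beyond the sweep step
  expect_equal(f0[1], 1)
  expect_equal(f0[length(f0)], 0)
})

test_that("pulses reaching an angular gap raise an error", {
  gappy <- rmw(list(rmw_step(0, 0, 300, 0)))
  expect_error(map_pulses_to_steps(gappy,
                                   pulse_train(period = 0.002,
                                               pulse_angular_width = 0)),
               "gap")
})

test_that("blocked steps absorb fluence without contributing", {
  wheel <- rmw(list(rmw_step(0, 0, 180, 0),
                    rmw_step(1, 180, 180, 0.5, blocked = TRUE)))
  map <- map_pulses_to_steps(wheel, pulse_train(period = 0.002,
                                                pulse_angular_width = 0))
  expect_true(all(map$assignments$step == 0))
  # half the 50 pulses hit the wedge and are lost
  expect_equal(sum(map$assignments$fraction), 25)
})

test_that("per-step totals scale exactly with the rotation count", {
  wheel <- two_step_wheel()
  t1 <- map_pulses_to_steps(wheel, pulse_train(period = 0.002))$totals
  t3 <- map_pulses_to_steps(wheel, pulse_train(period = 0.002),
                            rotations = 3)$totals
  expect_equal(t3, 3 * t1)
})

test_that("fluence equalization gives every hit step the same protons", {
  # step A spans 2/7 of the circle, step B 5/7: point pulses land 2 vs 5
  wheel <- rmw(list(rmw_step(0, 0, 360 * 2 / 7, 0),
                    rmw_step(1, 360 * 2 / 7, 360 * 5 / 7, 0.5)))
  map <- map_pulses_to_steps(wheel,
                             pulse_train(period = 0.1 / 7,
                                         pulse_angular_width = 0))
  expect_equal(unname(map$totals), c(2, 5))
  eq <- equalize_step_fluence(map)
  expect_equal(unname(eq$step_totals), c(3e6, 3e6))
  wA <- eq$pulse_weights[as.character(map$assignments$pulse[map$assignments$step == 0])]
  wB <- eq$pulse_weights[as.character(map$assignments$pulse[map$assignments$step == 1])]
  expect_equal(unique(wA) / unique(wB), 2.5)
})

test_that("equalization is self-consistent for randomized step layouts", {
  set.seed(3)
  for (rep in 1:5) {
    cuts <- sort(runif(3, 40, 320))
    widths <- diff(c(0, cuts, 360))
    steps <- lapply(seq_along(widths), function(i)
      rmw_step(i - 1L, c(0, cuts)[i], widths[i], (i - 1) * 0.4))
    map <- map_pulses_to_steps(rmw(steps),
                               pulse_train(period = 0.002,
                                           pulse_angular_width = 0))
    eq <- suppressWarnings(equalize_step_fluence(map))
    hit <- eq$step_totals
    expect_true(all(abs(hit - 3e6) / 3e6 < 1e-6))
  }
})

test_that("steps hit by no pulse are flagged, not silently dropped", {
  # 3 steps; with 4 pulses per rotation at 90 deg increments the middle
  # sliver between 95 and 100 degrees is never struck
  wheel <- rmw(list(rmw_step(0, 0, 95, 0),
                    rmw_step(1, 95, 5, 0.3),
                    rmw_step(2, 100, 260, 0.6)))
  map <- map_pulses_to_steps(wheel, pulse_train(period = 0.025,
                                                pulse_angular_width = 0))
  expect_warning(eq <- equalize_step_fluence(map), "zero pulse fluence")
  expect_identical(eq$excluded, 1L)
})

test_that("step peak libraries are pulled back per step and skip the wedge", {
  wheel <- rmw(list(rmw_step(0, 0, 100, 0),
                    rmw_step(1, 100, 100, 0.5),
                    rmw_step(2, 200, 100, 1.0),
                    rmw_step(3, 300, 60, 1.0, blocked = TRUE)))
  lib <- build_step_peak_library(wheel, pristine_peak_params(25),
                                 depth_grid(27), sigma_growth = 0)
  expect_length(lib$peaks, 3L)
  d90s <- vapply(lib$peaks, function(p) depth_at_level(p, 90, "distal"),
                 numeric(1))
  expect_equal(d90s, c(25, 24.5, 24), tolerance = 0.02 / 24)
  expect_equal(lib$pullbacks, c(0, 0.5, 1.0))
})

test_that("a 14-step wheel with 0.7 cm steps reaches the expected shallowest range", {
  lib <- library_14step()
  expect_length(lib$peaks, 14L)
  shallow <- lib$peaks[[which.max(lib$pullbacks)]]
  expect_lt(abs(depth_at_level(shallow, 90, "distal") - (20 - 13 * 0.7)), 0.05)
})

test_that("library construction rejects pullbacks at or beyond the base range", {
  wheel <- rmw(list(rmw_step(0, 0, 180, 0), rmw_step(1, 180, 180, 6)))
  expect_error(build_step_peak_library(wheel, pristine_peak_params(5),
                                       depth_grid(7)),
               "pullback")
})

test_that("wheel and pulse-train definitions round-trip through JSON", {
  wheel <- default_rmw(20, 10)
  f <- tempfile(fileext = ".json")
  write_rmw(wheel, f)
  back <- read_rmw(f)
  expect_equal(back$rpm, wheel$rpm)
  expect_equal(vapply(back$steps, `[[`, numeric(1), "pullback"),
               vapply(wheel$steps, `[[`, numeric(1), "pullback"))
  train <- pulse_train(period = 0.0017, phase = 12, pulse_angular_width = 5)
  f2 <- tempfile(fileext = ".json")
  write_pulse_train(train, f2)
  expect_equal(read_pulse_train(f2), train)
})

test_that("wheel construction enforces the staircase invariants", {
  expect_error(rmw(list(rmw_step(0, 0, 180, 0.5))), "zero pullback")
  expect_error(rmw(list(rmw_step(0, 0, 180, 0),
                        rmw_step(1, 90, 180, 0.5))), "overlap")
  expect_error(rmw(list(rmw_step(0, 0, 200, 0),
                        rmw_step(1, 200, 200, 0.5))), "360")
})
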