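test_that("composition is the identity for a single unit-weighted peak and is linear", {
  lib <- library_14step()
  w <- rep(0, 14); w[1] <- 1
  expect_equal(compose_sobp(lib, w)$dose, lib$peaks[[1]]$dose)
  set.seed(5)
  wa <- runif(14); wb <- runif(14)
  lhs <- compose_sobp(lib, wa)$dose + compose_sobp(lib, wb)$dose
  rhs <- compose_sobp(lib, wa + wb)$dose
  expect_lt(max(abs(lhs - rhs)), 1e-9)
  expect_error(compose_sobp(lib, wa[-1]), "one weight per peak")
  expect_error(compose_sobp(lib, -wa), "non-negative")
})

test_that("flat targets have the requested plateau and width metric", {
  grid <- depth_grid(27)
  tg <- flat_target(25, 20, grid = grid)
  expect_true(all(tg$dose[grid >= 5 & grid <= 25] == 100))
  expect_true(all(tg$dose[grid < 5] == 0))
  full <- flat_target(15, 15, grid = depth_grid(17))
  expect_equal(full$dose[1], 100)
  expect_error(flat_target(10, 12, grid = grid), "exceed")
  for (m in c(2, 5, 10, 15, 20)) {
    tg <- flat_target(25, m, grid = grid)
    expect_lt(abs(pdd_metrics(tg)$sobp_width - m), 0.15)
  }
})

test_that("weight fitting recovers known weights and the composed curve", {
  lib <- library_14step()
  set.seed(17)
  w_true <- runif(14, 0.3, 1.5)
  target <- compose_sobp(lib, w_true)
  fit <- fit_weights(lib, target)
  recomposed <- compose_sobp(lib, fit$weights)
  plateau <- max(target$dose)
  expect_lt(max(abs(recomposed$dose - target$dose)), 0.001 * plateau)
  expect_lt(fit$sse, 1e-6 * plateau^2)
  # pullback spacing (0.7) >= 3 sigma (0.2): weights identifiable
  expect_lt(max(abs(fit$weights - w_true) / w_true), 1e-3)
})

test_that("fitting a single library peak puts all weight on that peak", {
  lib <- library_14step()
  fit <- fit_weights(lib, lib$peaks[[7]])
  expect_lt(abs(fit$weights[7] - 1), 1e-6)
  expect_lt(max(fit$weights[-7]), 1e-6)
  expect_lt(fit$sse, 1e-9)
})

test_that("the fitted solution beats random non-negative candidates", {
  lib <- library_14step()
  target <- flat_target(20, 9.1, grid = lib$grid,
                        distal_edge = lib$peaks[[1]])
  fit <- fit_weights(lib, target)
  lattice <- seq(fit$fit_window[1], fit$fit_window[2], by = 0.1)
  A <- vapply(lib$peaks, function(p) approx(p$depths, p$dose, lattice)$y,
              numeric(length(lattice)))
  b <- approx(target$depths, target$dose, lattice)$y
  set.seed(23)
  scale <- mean(fit$weights)
  for (i in 1:1000) {
    cand <- runif(14, 0, 2 * scale)
    expect_gte(sum((b - A %*% cand)^2), fit$sse)
  }
  # and refitting is deterministic
  expect_identical(fit_weights(lib, target)$weights, fit$weights)
})

test_that("fitting is scale-equivariant and handles degenerate targets", {
  lib <- library_14step()
  target <- compose_sobp(lib, rep(1, 14))
  fit1 <- fit_weights(lib, target)
  target3 <- target; target3$dose <- 3 * target$dose
  fit3 <- fit_weights(lib, target3)
  expect_equal(fit3$weights, 3 * fit1$weights, tolerance = 1e-6)
  expect_equal(fit3$sse, 9 * fit1$sse, tolerance = 1e-3)
  zero <- target; zero$dose <- 0 * target$dose
  fz <- fit_weights(lib, zero)
  expect_identical(fz$weights, rep(0, 14))
  expect_identical(fz$sse, 0)
  expect_error(fit_weights(lib, target, window = c(5, 5.5)), "lattice")
})

test_that("fit windows follow the documented conventions", {
  lib <- library_14step()
  target <- compose_sobp(lib, rep(1, 14))
  fit <- fit_weights(lib, target)
  expect_equal(fit$fit_window[1], 0.5)
  # auto window ends where the target falls below 1% beyond the peak
  d2 <- fit$fit_window[2]
  expect_lt(target$dose[match(d2, target$depths)] ,
            0.01 * max(target$dose) + 1e-9)
  expect_equal(fit$n_points,
               floor((fit$fit_window[2] - fit$fit_window[1]) / 0.1) + 1)
})

test_that("synthesized SOBPs are flat and hit the requested width", {
  fx <- pulse_fixture()
  expect_lt(abs(fx$fit$achieved_width - 10), 0.15)
  expect_lt(fx$fit$metrics$plateau_flatness, 1)
  expect_lt(abs(fx$fit$metrics$d90 - 15), 0.1)
})

composed_width_local <- function(peaks, map, u) {
  w <- numeric(length(peaks$step_index))
  asg <- map$assignments
  uw <- u[as.character(asg$pulse)]
  for (i in seq_along(peaks$step_index))
    w[i] <- sum((asg$fraction * uw)[asg$step == peaks$step_index[i]])
  pdd_metrics(compose_sobp(peaks, w))$sobp_width
}

test_that("stop-pulse curves start fully modulated and shrink monotonically", {
  fx <- pulse_fixture()
  e <- fx$curve$entries
  expect_identical(e$stop_pulse[1], 0L)
  full_width <- composed_width_local(fx$peaks, fx$map, fx$u)
  expect_equal(e$sobp_width[1], full_width)
  expect_true(all(diff(e$sobp_width) <= 1e-9))
  # eliminating shallow-step pulses shrinks the modulation
  expect_lt(e$sobp_width[5], e$sobp_width[1])
})

test_that("modulation adjustment reproduces tabulated widths exactly", {
  fx <- pulse_fixture()
  e <- fx$curve$entries
  adj <- adjust_modulation(fx$curve, e$sobp_width[7], fx$peaks, fx$map)
  expect_equal(adj$fractional_stop_pulse %% 1, 0)
  expect_equal(adj$achieved_width, e$sobp_width[7])
  # idempotence at a tabulated width: readjusting changes nothing
  adj2 <- adjust_modulation(fx$curve, adj$achieved_width, fx$peaks, fx$map)
  expect_lt(max(abs(adj2$weights - adj$weights)), 1e-9)
})

test_that("halfway requests interpolate to a fractional stop pulse of one half", {
  fx <- pulse_fixture()
  e <- fx$curve$entries
  k <- which(diff(e$sobp_width) < -1e-6)[3]
  halfway <- (e$sobp_width[k] + e$sobp_width[k + 1]) / 2
  adj <- adjust_modulation(fx$curve, halfway, fx$peaks, fx$map,
                           refine = FALSE)
  expect_equal(adj$fractional_stop_pulse %% 1, 0.5, tolerance = 1e-9)
})

test_that("out-of-range width requests name the achievable interval", {
  fx <- pulse_fixture()
  expect_error(adjust_modulation(fx$curve, 50, fx$peaks, fx$map),
               "achievable interval")
})

test_that("adjusted widths track requests across the achievable span", {
  fx <- pulse_fixture()
  e <- fx$curve$entries
  req <- seq(ceiling(min(e$sobp_width) * 10) / 10,
             floor(max(e$sobp_width) * 10) / 10, by = 0.3)
  errs <- vapply(req, function(d)
    abs(adjust_modulation(fx$curve, d, fx$peaks, fx$map)$achieved_width - d),
    numeric(1))
  expect_gte(mean(errs <= 0.1), 0.95)
})

test_that("weight vectors round-trip through JSON", {
  f <- tempfile(fileext = ".json")
  write_weights(c(0.2, 0.5, 1), f, fractional_stop_pulse = 12.25)
  back <- read_weights(f)
  expect_equal(back$step_weights, c(0.2, 0.5, 1))
  expect_equal(back$fractional_stop_pulse, 12.25)
})
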