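#' Measured-versus-simulated depth-dose comparison
#'
#' Compares two pristine-peak (or SOBP) depth-dose curves at the entrance
#' (PDD(0.5), absolute difference in percent) and at the range (D90,
#' signed difference, measured minus simulated). Curves are normalized
#' internally; grids need not match.
#'
#' @param measured,simulated `"depth_dose_curve"` objects.
#' @param config Configuration id recorded in the row (default from
#'   `measured$meta$config`, else `NA`).
#' @return One-row data frame: `config`, `pdd05_diff`, `d90_measured`,
#'   `d90_simulated`, `d90_diff`.
#' @export
compare_pdd <- function(measured, simulated, config = NULL) {
  mm <- pdd_metrics(measured)
  ms <- pdd_metrics(simulated)
  if (is.null(config))
    config <- if (!is.null(measured$meta$config)) measured$meta$config
              else NA
  data.frame(config = config,
             pdd05_diff = abs(mm$pdd05 - ms$pdd05),
             d90_measured = mm$d90,
             d90_simulated = ms$d90,
             d90_diff = mm$d90 - ms$d90)
}

#' Measured-versus-simulated SOBP comparison
#'
#' Compares SOBP width (proximal-95 to distal-90, signed difference
#' measured minus simulated), and the distal 90% and 20% depths (absolute
#' differences).
#'
#' @inheritParams compare_pdd
#' @return One-row data frame: `config`, `measured_width`,
#'   `simulated_width`, `width_diff`, `d90_diff`, `d20_diff`.
#' @export
compare_sobp <- function(measured, simulated, config = NULL) {
  mm <- pdd_metrics(measured)
  ms <- pdd_metrics(simulated)
  if (is.null(config))
    config <- if (!is.null(measured$meta$config)) measured$meta$config
              else NA
  data.frame(config = config,
             measured_width = mm$sobp_width,
             simulated_width = ms$sobp_width,
             width_diff = mm$sobp_width - ms$sobp_width,
             d90_diff = abs(mm$d90 - ms$d90),
             d20_diff = abs(mm$d20 - ms$d20))
}

#' Measured-versus-simulated lateral profile comparison
#'
#' Penumbra difference is the absolute difference of the per-profile mean
#' (left/right averaged) penumbras; FWHM difference is absolute; flatness
#' and symmetry are reported for each curve separately.
#'
#' @param measured,simulated `"lateral_profile"` objects.
#' @param config Configuration id; default from measured metadata.
#' @param depth Scan depth in cm; default from measured metadata.
#' @return One-row data frame: `config`, `depth`, `penumbra_diff`,
#'   `flatness_sim`, `flatness_meas`, `symmetry_sim`, `symmetry_meas`,
#'   `fwhm_diff`.
#' @export
compare_profile <- function(measured, simulated, config = NULL,
                            depth = NULL) {
  mm <- profile_metrics(measured)
  ms <- profile_metrics(simulated)
  if (is.null(config))
    config <- if (!is.null(measured$meta$config)) measured$meta$config
              else NA
  if (is.null(depth))
    depth <- if (!is.null(measured$meta$depth_cm)) measured$meta$depth_cm
             else NA_real_
  data.frame(config = config, depth = depth,
             penumbra_diff = abs(mm$penumbra_mean - ms$penumbra_mean),
             flatness_sim = ms$flatness, flatness_meas = mm$flatness,
             symmetry_sim = ms$symmetry, symmetry_meas = mm$symmetry,
             fwhm_diff = abs(mm$fwhm - ms$fwhm))
}

#' Group summary of depth-dose comparison rows
#'
#' Averages the absolute PDD(0.5) and D90 differences over a configuration
#' group and reports their ranges. Full precision is retained; rounding to
#' report precision (0.1% / 0.01 cm) happens only in [render_group_summary()].
#'
#' @param rows Data frame of [compare_pdd()] rows (needs `pdd05_diff` and
#'   `d90_diff` columns).
#' @param group Group label (e.g. `"large"`).
#' @return A list of class `"group_summary"`: `group`, `n`,
#'   `mean_abs_pdd05_diff`, `mean_abs_d90_diff`, `range_abs_pdd05_diff`,
#'   `range_abs_d90_diff`, `rows`.
#' @export
group_summary <- function(rows, group = NA) {
  if (!is.data.frame(rows) || nrow(rows) < 1L)
    stop("'rows' must be a data frame with at least one row")
  if (!all(c("pdd05_diff", "d90_diff") %in% names(rows)))
    stop("'rows' must have pdd05_diff and d90_diff columns")
  ap <- abs(rows$pdd05_diff)
  ad <- abs(rows$d90_diff)
  structure(list(group = group, n = nrow(rows),
                 mean_abs_pdd05_diff = mean(ap),
                 mean_abs_d90_diff = mean(ad),
                 range_abs_pdd05_diff = range(ap),
                 range_abs_d90_diff = range(ad),
                 rows = rows),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> %s (n=%d): mean |PDD(0.5) diff| %.1f%% (%.1f..%.1f), mean |D90 diff| %.2f cm (%.2f..%.2f)\n",
              x$group, x$n, x$mean_abs_pdd05_diff,
              x$range_abs_pdd05_diff[1], x$range_abs_pdd05_diff[2],
              x$mean_abs_d90_diff,
              x$range_abs_d90_diff[1], x$range_abs_d90_diff[2]))
  invisible(x)
}

#' Render comparison rows and summaries at report precision
#'
#' Fixed-precision rendering matching the commissioning report convention:
#' percentages to one decimal place, centimetres to two. Rounding is
#' applied only at rendering; the underlying rows keep full precision.
#'
#' @param x A comparison data frame or a `"group_summary"`.
#' @return A data frame of formatted character columns.
#' @export
render_comparison <- function(x) {
  fmt_pct <- function(v) sprintf("%.1f", v)
  fmt_cm <- function(v) sprintf("%.2f", v)
  if (inherits(x, "group_summary")) {
    return(data.frame(group = x$group, n = x$n,
                      mean_abs_pdd05_diff = fmt_pct(x$mean_abs_pdd05_diff),
                      mean_abs_d90_diff = fmt_cm(x$mean_abs_d90_diff)))
  }
  out <- x
  for (nm in names(out)) {
    if (!is.numeric(out[[nm]])) next
    out[[nm]] <- if (grepl("pdd05|flatness|symmetry", nm))
      fmt_pct(out[[nm]]) else fmt_cm(out[[nm]])
  }
  out
}
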