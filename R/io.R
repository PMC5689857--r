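#' Read and write curve files (CSV)
#'
#' Curve files are comma-separated with `#`-prefixed metadata lines before
#' the header, e.g. `# role=measured`, `# config=13`, `# depth_cm=10`. The
#' header is `depth_cm,dose` for depth-dose curves or `position_cm,dose`
#' for lateral profiles, and decides the class on reading. Values are
#' written with enough significant digits that write-then-read reproduces
#' the in-memory doubles exactly and read-then-write reproduces the file.
#'
#' @param path File path.
#' @param curve A `"depth_dose_curve"` or `"lateral_profile"`.
#' @return `read_curve()`: the curve; `write_curve()`: the path, invisibly.
#' @export
read_curve <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop(sprintf("%s: empty file", path))
  is_meta <- grepl("^#", lines)
  header_at <- which(!is_meta & nzchar(trimws(lines)))[1]
  if (is.na(header_at)) stop(sprintf("%s: no header line found", path))
  meta <- list()
  for (ln in lines[seq_len(header_at - 1L)][is_meta[seq_len(header_at - 1L)]]) {
    kv <- sub("^#\\s*", "", ln)
    if (!grepl("=", kv)) next
    key <- trimws(sub("=.*$", "", kv))
    val <- trimws(sub("^[^=]*=", "", kv))
    num <- suppressWarnings(as.numeric(val))
    meta[[key]] <- if (!is.na(num)) num
      else if (val %in% c("TRUE", "FALSE")) as.logical(val) else val
  }
  header <- trimws(strsplit(lines[header_at], ",")[[1]])
  if (length(header) != 2L || header[2] != "dose" ||
      !header[1] %in% c("depth_cm", "position_cm"))
    stop(sprintf("%s:%d: malformed header '%s' (expected depth_cm,dose or position_cm,dose)",
                 path, header_at, lines[header_at]))
  body <- lines[seq(header_at + 1L, length(lines))]
  body_lines <- which(nzchar(trimws(body)) & !grepl("^#", body))
  parts <- strsplit(body[body_lines], ",")
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop(sprintf("%s:%d: expected two comma-separated values",
                 path, header_at + body_lines[bad[1]]))
  ax <- as.numeric(vapply(parts, `[[`, character(1), 1L))
  dose <- as.numeric(vapply(parts, `[[`, character(1), 2L))
  if (anyNA(ax) || anyNA(dose))
    stop(sprintf("%s:%d: non-numeric value",
                 path, header_at + body_lines[which(is.na(ax) | is.na(dose))[1]]))
  neg <- which(dose < 0)
  if (length(neg))
    stop(sprintf("%s:%d: negative dose", path, header_at + body_lines[neg[1]]))
  if (any(diff(ax) <= 0)) {
    j <- which(diff(ax) <= 0)[1]
    stop(sprintf("%s:%d: grid not strictly increasing",
                 path, header_at + body_lines[j + 1L]))
  }
  if (header[1] == "depth_cm") dose_curve(ax, dose, meta = meta)
  else lateral_profile(ax, dose, meta = meta)
}

#' @rdname read_curve
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "beam_curve"))
  axis_name <- if (inherits(curve, "lateral_profile")) "position_cm"
               else "depth_cm"
  meta <- curve$meta
  scalars <- vapply(meta, function(v)
    is.atomic(v) && length(v) == 1L && !is.na(v), logical(1))
  hdr <- vapply(names(meta)[scalars], function(k) {
    v <- meta[[k]]
    sprintf("# %s=%s", k, if (is.numeric(v)) num_str(v) else as.character(v))
  }, character(1))
  rows <- sprintf("%s,%s", num_str(curve_axis(curve)), num_str(curve$dose))
  writeLines(c(hdr, paste0(axis_name, ",dose"), rows), path)
  invisible(path)
}

# shortest decimal representation that round-trips the double exactly
num_str <- function(x) {
  out <- sprintf("%.15g", x)
  redo <- as.numeric(out) != x
  out[redo] <- sprintf("%.17g", x[redo])
  out
}

#' The 24-configuration beam registry
#'
#' The treatment unit offers 24 beam configurations in three groups: 12
#' "large" (large nozzle, 25 cm uncollimated field), 5 "deep" and 7 "small"
#' (small nozzle, 14 cm field). Group limits: large ranges 5-25 cm with
#' modulation 2-20 cm; deep 20.1-32 cm with modulation 2-10 cm; small
#' 5-20 cm with modulation 2-20 cm. Per-configuration nominal ranges are the
#' commissioning measured D90 values. An alternative registry can be
#' supplied as a JSON file with the same columns.
#'
#' @param path Optional JSON registry override.
#' @return Data frame with columns `id`, `group`, `nominal_range`,
#'   `nozzle_field_diameter`, `max_modulation`, `min_modulation`,
#'   `max_range`, `min_range`, `airgap`, `aperture`.
#' @export
config_registry <- function(path = NULL) {
  if (!is.null(path)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(as.data.frame(j))
  }
  ranges <- c(25.10, 22.59, 20.92, 18.78, 16.80, 14.94, 13.24, 11.52,
              10.07, 8.72, 7.39, 6.67,               # large, configs 1-12
              31.88, 29.51, 27.08, 24.55, 22.06,     # deep, configs 13-17
              20.05, 17.81, 15.39, 13.32, 11.28, 9.18, 7.12)  # small, 18-24
  group <- c(rep("large", 12), rep("deep", 5), rep("small", 7))
  lim <- group_limits()
  data.frame(id = 1:24, group = group, nominal_range = ranges,
             nozzle_field_diameter = ifelse(group == "large", 25, 14),
             max_modulation = lim$max_modulation[match(group, lim$group)],
             min_modulation = lim$min_modulation[match(group, lim$group)],
             max_range = lim$max_range[match(group, lim$group)],
             min_range = lim$min_range[match(group, lim$group)],
             airgap = 10, aperture = NA_character_)
}

group_limits <- function() {
  data.frame(group = c("large", "deep", "small"),
             max_range = c(25, 32, 20),
             min_range = c(5, 20.1, 5),
             max_modulation = c(20, 10, 20),
             min_modulation = c(2, 2, 2))
}

#' Validate a requested beam against configuration-group limits
#'
#' Checks a requested range and modulation width against the group's
#' capability window (see [config_registry()]). Violations name the bound.
#'
#' @param config A registry row (data frame row or list with a `group`
#'   field) or a group name (`"large"`, `"deep"`, `"small"`).
#' @param requested_range Requested beam range in cm.
#' @param requested_modulation Requested modulation width in cm.
#' @return A list with `ok` (logical) and `violations` (character vector).
#' @export
validate_configuration <- function(config, requested_range,
                                   requested_modulation) {
  group <- if (is.character(config) && length(config) == 1L) config
           else config$group
  lim <- group_limits()
  row <- lim[lim$group == group, ]
  if (!nrow(row)) stop(sprintf("unknown configuration group '%s'", group))
  v <- character(0)
  if (requested_range > row$max_range)
    v <- c(v, sprintf("range > %g", row$max_range))
  if (requested_range < row$min_range)
    v <- c(v, sprintf("range < %g", row$min_range))
  if (requested_modulation > row$max_modulation)
    v <- c(v, sprintf("modulation > %g", row$max_modulation))
  if (requested_modulation < row$min_modulation)
    v <- c(v, sprintf("modulation < %g", row$min_modulation))
  if (requested_modulation > requested_range)
    v <- c(v, "modulation > range")
  list(ok = !length(v), violations = v)
}

#' Printed commissioning comparison tables
#'
#' The per-configuration measured/simulated pristine-peak comparison values
#' (PDD(0.5) difference, measured and simulated D90) and the SOBP width
#' comparison for the three reference beams, as published in the
#' commissioning study; shipped as plain-CSV package data. These are the
#' inputs to [group_summary()] and the report layer.
#'
#' @param which `"pdd"` (24 pristine-peak rows), `"sobp"` (3 SOBP rows) or
#'   `"profile"` (12 lateral-profile rows).
#' @return Data frame.
#' @export
commissioning_table <- function(which = c("pdd", "sobp", "profile")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   sprintf("%s_commissioning.csv", which),
                   package = "sobptools", mustWork = TRUE)
  utils::read.csv(f, comment.char = "#", stringsAsFactors = FALSE)
}
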