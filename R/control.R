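## Plain-text control file: flat `key = value` lines (INI style, '#' or ';'
## comments). The CLI re-reads it before every command, so edits take effect
## without restarting anything.

control_schema <- function() {
  list(
    # key = list(type, default, required)
    estimates = list(type = "numvec", default = NULL, required = TRUE),
    crop_x0 = list(type = "num", default = 1, required = FALSE),
    crop_x1 = list(type = "num", default = NA_real_, required = FALSE),
    crop_y0 = list(type = "num", default = 1, required = FALSE),
    crop_y1 = list(type = "num", default = NA_real_, required = FALSE),
    window_halfwidth = list(type = "num", default = 20, required = FALSE),
    min_prominence = list(type = "num", default = 50, required = FALSE),
    smoothing_halfwidth = list(type = "num", default = 0, required = FALSE),
    min_coverage = list(type = "num", default = 0.8, required = FALSE),
    subpixel = list(type = "bool", default = TRUE, required = FALSE),
    scan_length = list(type = "num", default = NA_real_, required = FALSE),
    scan_velocity = list(type = "num", default = NA_real_, required = FALSE),
    exposure_ms = list(type = "num", default = NA_real_, required = FALSE),
    acquisition_overhead = list(type = "num", default = 0, required = FALSE),
    session_dir = list(type = "str", default = ".", required = FALSE)
  )
}

parse_control_value <- function(key, raw, type) {
  out <- switch(type,
    num = suppressWarnings(as.numeric(raw)),
    numvec = suppressWarnings(as.numeric(trimws(strsplit(raw, ",")[[1]]))),
    bool = switch(tolower(raw), "true" = TRUE, "1" = TRUE, "yes" = TRUE,
                  "false" = FALSE, "0" = FALSE, "no" = FALSE, NA),
    str = raw
  )
  if (anyNA(out) || length(out) == 0)
    stop_validation(sprintf("control key \"%s\": cannot parse value \"%s\"", key, raw))
  out
}

#' Load and validate a control file
#'
#' Parses a flat `key = value` text file. Lines starting with `#` or `;` and
#' blank lines are ignored. Unknown keys are reported with a warning listing
#' them; a missing required key or an unparsable value raises a validation
#' error naming the key. Optional keys receive their documented defaults.
#'
#' Recognized keys: `estimates` (comma-separated emission-line column
#' estimates; required), crop window `crop_x0, crop_x1, crop_y0, crop_y1`
#' (1-based inclusive pixel bounds), the [detection_params()] fields
#' `window_halfwidth, min_prominence, smoothing_halfwidth, min_coverage,
#' subpixel`, scan parameters `scan_length, scan_velocity, exposure_ms,
#' acquisition_overhead`, and `session_dir`.
#'
#' @param path Control file path.
#' @return A `control_file` list of validated parameters.
#' @export
load_control <- function(path) {
  if (!file.exists(path)) stop_validation(sprintf("control file '%s' not found", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("[#;].*$", "", lines))
  lines <- lines[nzchar(lines)]
  schema <- control_schema()
  values <- list()
  unknown <- character(0)
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop_validation(sprintf("control line is not 'key = value': \"%s\"", ln))
    key <- trimws(sub("=.*$", "", ln))
    raw <- trimws(sub("^[^=]*=", "", ln))
    if (is.null(schema[[key]])) {
      unknown <- c(unknown, key)
      next
    }
    values[[key]] <- parse_control_value(key, raw, schema[[key]]$type)
  }
  if (length(unknown) > 0)
    warning(sprintf("ignoring unknown control keys: %s",
                    paste(unknown, collapse = ", ")))
  for (key in names(schema)) {
    if (is.null(values[[key]])) {
      if (schema[[key]]$required)
        stop_validation(sprintf("control file is missing required key \"%s\"", key))
      values[[key]] <- schema[[key]]$default
    }
  }
  if (!is.na(values$crop_x1) && values$crop_x1 <= values$crop_x0)
    stop_validation("invalid crop window: crop_x1 must exceed crop_x0")
  if (!is.na(values$crop_y1) && values$crop_y1 <= values$crop_y0)
    stop_validation("invalid crop window: crop_y1 must exceed crop_y0")
  if (is.unsorted(values$estimates, strictly = TRUE))
    stop_validation("control key \"estimates\" must be strictly increasing")
  structure(values, class = "control_file")
}

#' Detection parameters from a control file
#'
#' @param control A [load_control()] result.
#' @return A [detection_params()].
#' @export
as_detection_params <- function(control) {
  detection_params(
    window_halfwidth = control$window_halfwidth,
    min_prominence = control$min_prominence,
    smoothing_halfwidth = control$smoothing_halfwidth,
    min_coverage = control$min_coverage,
    subpixel = control$subpixel
  )
}

#' Crop a frame to the control file's window
#'
#' @param frame Numeric matrix.
#' @param control A [load_control()] result. `NA` bounds default to the
#'   frame edges.
#' @return Cropped frame.
#' @export
crop_frame <- function(frame, control) {
  x1 <- if (is.na(control$crop_x1)) ncol(frame) else min(control$crop_x1, ncol(frame))
  y1 <- if (is.na(control$crop_y1)) nrow(frame) else min(control$crop_y1, nrow(frame))
  frame[control$crop_y0:y1, control$crop_x0:x1, drop = FALSE]
}
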