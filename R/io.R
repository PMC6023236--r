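# Readers and writers for the CSV and JSON trial dialects.

force_raw_cols <- c("time", channel_names)
force_reduced_cols <- c("time", "FX", "FY", "FZ", "copX", "copY")
marker_cols <- c("time", "led1X", "led1Y", "led1Z",
                 "led2X", "led2Y", "led2Z")

#' Read a force file
#'
#' Two dialects, recognized by header (column order is irrelevant):
#' raw channels `time,fx12,fx34,fy14,fy23,fz1,fz2,fz3,fz4` (s, N),
#' returned as a [channel_record()]; or a pre-reduced record
#' `time,FX,FY,FZ,copX,copY` (s, N, m), returned as a [grf_series()].
#' Interior NaN runs of at most 5 samples are filled by linear
#' interpolation; longer runs are a data error.
#'
#' @param path CSV file with a header row, SI units.
#' @return A `channel_record` or `grf_series`.
#' @export
read_force_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (setequal(names(df), force_raw_cols)) {
    for (ch in channel_names)
      df[[ch]] <- fill_gaps(df[[ch]], column = ch)$x
    channel_record(df$time, df[channel_names])
  } else if (setequal(names(df), force_reduced_cols)) {
    for (cl in c("FX", "FY", "FZ"))
      df[[cl]] <- fill_gaps(df[[cl]], column = cl)$x
    grf_series(df$time, df$FX, df$FY, df$FZ, df$copX, df$copY,
               is.finite(df$copX) & is.finite(df$copY))
  } else {
    hs_stop(sprintf(
      "unrecognized force header (%s); expected either {%s} or {%s}",
      paste(names(df), collapse = ","),
      paste(force_raw_cols, collapse = ","),
      paste(force_reduced_cols, collapse = ",")),
      "heelstrike_dialect_error", stage = "io")
  }
}

#' Write a force file
#' @param x A [channel_record()] or [grf_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_force_csv <- function(x, path) {
  if (inherits(x, "channel_record")) {
    utils::write.csv(as.data.frame(x)[force_raw_cols], path,
                     row.names = FALSE)
  } else if (inherits(x, "grf_series")) {
    out <- data.frame(time = x$time, FX = x$F_X, FY = x$F_Y,
                      FZ = x$F_Z, copX = x$cop_X, copY = x$cop_Y)
    utils::write.csv(out, path, row.names = FALSE)
  } else hs_stop("x must be a channel_record or grf_series",
                 "heelstrike_input_error", stage = "io")
  invisible(path)
}

#' Read a marker file
#'
#' Dialect `time,led1X,led1Y,led1Z,led2X,led2Y,led2Z` (s, m).
#' Interior gaps (NaN runs) of at most 5 samples per coordinate are
#' filled by linear interpolation and reported via a message; longer
#' gaps are a data error naming the interval.
#'
#' @param path CSV file with a header row, SI units.
#' @return A [marker_series()].
#' @export
read_marker_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!setequal(names(df), marker_cols))
    hs_stop(sprintf("unrecognized marker header (%s); expected {%s}",
                    paste(names(df), collapse = ","),
                    paste(marker_cols, collapse = ",")),
            "heelstrike_dialect_error", stage = "io")
  filled <- 0L
  for (cl in setdiff(marker_cols, "time")) {
    r <- fill_gaps(df[[cl]], column = cl)
    df[[cl]] <- r$x
    filled <- filled + r$filled
  }
  if (filled > 0L)
    message(sprintf("read_marker_csv: filled %d gap sample(s) by linear interpolation",
                    filled))
  marker_series(df$time,
                cbind(df$led1X, df$led1Y, df$led1Z),
                cbind(df$led2X, df$led2Y, df$led2Z))
}

#' Write a marker file
#' @param markers A [marker_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_marker_csv <- function(markers, path) {
  stopifnot(inherits(markers, "marker_series"))
  out <- data.frame(time = markers$time,
                    led1X = markers$led1[, 1], led1Y = markers$led1[, 2],
                    led1Z = markers$led1[, 3],
                    led2X = markers$led2[, 1], led2Y = markers$led2[, 2],
                    led2Z = markers$led2[, 3])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a trial result as JSON
#'
#' Stable key order, 12 significant digits, with the package version
#' and the configuration hash, so identical inputs and configuration
#' give byte-identical files.
#'
#' @param fit A [heel_strike()] fit.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_trial_json <- function(fit, path) {
  stopifnot(inherits(fit, "heel_strike"))
  payload <- list(
    package = "heelstrike",
    version = as.character(utils::packageVersion("heelstrike")),
    config_hash = config_hash(fit$config),
    events = fit$events,
    energetics = fit$energetics,
    heel_point = as.list(stats::setNames(as.numeric(fit$r_H),
                                         c("x", "y", "z"))),
    flags = as.list(fit$flags),
    config = unclass(fit$config))
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE,
                              digits = I(12), pretty = TRUE, na = "null"),
             path)
  invisible(path)
}

#' Read a trial JSON written by [write_trial_json()]
#' @param path JSON file path.
#' @return Nested list with `events`, `energetics`, `config`, etc.
#' @export
read_trial_json <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
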