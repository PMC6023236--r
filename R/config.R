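# Pipeline configuration: defaults, YAML round trip, hashing.

#' Pipeline configuration
#'
#' Bundles every tunable of the trial pipeline with its default.
#' Values supplied as nested lists override defaults selectively, e.g.
#' `pipeline_config(events = list(rise_threshold = 20))`.
#'
#' @param plate Plate-geometry block: `a`, `b`, `az0` (m),
#'   `origin_offset` (3-vector, m), `force_rate` (Hz).
#' @param kinematics Kinematics block: `cutoff_hz` (low-pass cutoff for
#'   marker filtering), `filter_order`, `median_kind`
#'   (`"marginal"`/`"geometric"` heel-point median), `y_sign` (sign of
#'   the local-y anterior component), `surface_z` (global Z of the
#'   plate surface, m), `kin_rate` (Hz).
#' @param events Event-detection block: `rise_threshold`,
#'   `floor_threshold`, `cop_force_threshold` (N), `peak_window` (s),
#'   `min_prominence_fraction`.
#' @param energetics Energetics block: `g` (m/s^2),
#'   `filter_force` (logical; low-pass the force channels before COP
#'   computation -- off by default).
#' @param study Study block: `alpha` (family-wise level) and
#'   `bonferroni_k` (number of paired comparisons); the per-test level
#'   is `alpha / bonferroni_k`.
#' @param seed Integer seed recorded with the config.
#' @return An object of class `pipeline_config` (a nested list).
#' @export
pipeline_config <- function(plate = list(), kinematics = list(),
                            events = list(), energetics = list(),
                            study = list(), seed = 1L) {
  def <- list(
    plate = list(a = 0.12, b = 0.20, az0 = 0.01,
                 origin_offset = c(0, 0, 0), force_rate = 3000),
    kinematics = list(cutoff_hz = 100, filter_order = 2,
                      median_kind = "marginal", y_sign = 1,
                      surface_z = 0, kin_rate = 1295),
    events = list(rise_threshold = 10, floor_threshold = 2,
                  cop_force_threshold = 10, peak_window = 0.060,
                  min_prominence_fraction = 0.05),
    energetics = list(g = 9.81, filter_force = FALSE),
    study = list(alpha = 0.05, bonferroni_k = 5),
    seed = seed)
  for (blk in c("plate", "kinematics", "events", "energetics", "study")) {
    ov <- get(blk)
    unknown <- setdiff(names(ov), names(def[[blk]]))
    if (length(unknown))
      hs_stop(sprintf("unknown %s config key(s): %s", blk,
                      paste(unknown, collapse = ", ")),
              "heelstrike_input_error", stage = "config")
    def[[blk]][names(ov)] <- ov
  }
  structure(def, class = "pipeline_config")
}

#' Write a pipeline configuration to YAML
#' @param config A [pipeline_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#' @param path YAML file written by [write_config()] (or hand-edited;
#'   missing keys take their defaults).
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, c(
    raw[intersect(names(raw),
                  c("plate", "kinematics", "events", "energetics", "study"))],
    list(seed = if (is.null(raw$seed)) 1L else raw$seed)))
}

#' Hash of a pipeline configuration
#'
#' MD5 of the canonical JSON serialization; recorded in every trial
#' output so results can be traced to the exact configuration.
#'
#' @param config A [pipeline_config()].
#' @return Character MD5 digest.
#' @export
config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = I(12)), f)
  unname(tools::md5sum(f))
}
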