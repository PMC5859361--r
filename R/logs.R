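#' @keywords internal
"_PACKAGE"

## Domain-type constructors for the four session log streams.
##
## All logs carry a numeric `time` column in seconds and a POSIXct "origin"
## attribute giving the wall-clock instant of time zero on that log's clock.
## After synchronize_session(), time zero is the start of the first cooling
## phase for every stream and pre-cooling samples have negative times.

.default_origin <- function() as.POSIXct("1970-01-01 00:00:00", tz = "UTC")

.as_origin <- function(origin) {
  if (is.null(origin)) return(.default_origin())
  if (is.character(origin)) origin <- parse_iso_time(origin)
  stopifnot(inherits(origin, "POSIXct"), length(origin) == 1L)
  origin
}

#' Parse and format ISO-8601 timestamps
#'
#' Timestamps are read and written as `YYYY-MM-DDTHH:MM:OS` (fractional
#' seconds preserved to microseconds), always in UTC.
#'
#' @param x character vector of ISO-8601 timestamps.
#' @return `parse_iso_time()` returns a POSIXct vector; `format_iso_time()`
#'   a character vector.
#' @export
parse_iso_time <- function(x) {
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    out[bad] <- as.POSIXct(x[bad], format = "%Y-%m-%d %H:%M:%OS", tz = "UTC")
  }
  if (anyNA(out[!is.na(x)])) {
    stop("unparseable ISO-8601 timestamp(s): ",
         paste(utils::head(x[is.na(out)], 3L), collapse = ", "), call. = FALSE)
  }
  out
}

#' @rdname parse_iso_time
#' @param t POSIXct vector.
#' @export
format_iso_time <- function(t) {
  format(t, format = "%Y-%m-%dT%H:%M:%OS6", tz = "UTC")
}

.check_times <- function(time, what, strict = TRUE) {
  if (anyNA(time) || !is.numeric(time)) {
    stop(what, ": times must be finite numerics", call. = FALSE)
  }
  d <- diff(time)
  if (strict && length(d) && any(d <= 0)) {
    stop(what, ": timestamps must be strictly increasing (first violation at row ",
         which(d <= 0)[1L] + 1L, ")", call. = FALSE)
  }
  if (!strict && length(d) && any(d < 0)) {
    stop(what, ": timestamps must be non-decreasing (first violation at row ",
         which(d < 0)[1L] + 1L, ")", call. = FALSE)
  }
  invisible(time)
}

## gaps longer than 2x the nominal cadence are flagged, never filled
.find_gaps <- function(time, cadence) {
  d <- diff(time)
  i <- which(d > 2 * cadence)
  data.frame(after_time = time[i], gap_s = d[i])
}

#' Water-temperature log
#'
#' Set and achieved water temperatures of the cooling device, nominally
#' sampled every 30 s.
#'
#' @param time numeric seconds on the session clock, strictly increasing.
#' @param set_temp_c,achieved_temp_c temperatures in degrees Celsius,
#'   within `[0, 45]`.
#' @param origin POSIXct (or ISO-8601 string) wall-clock instant of `time = 0`.
#' @param cadence nominal sampling interval in seconds; gaps longer than
#'   twice this are recorded in the `"gaps"` attribute.
#' @return a data frame of class `water_log` with columns
#'   `time`, `set_temp_c`, `achieved_temp_c`.
#' @export
water_log <- function(time, set_temp_c, achieved_temp_c, origin = NULL,
                      cadence = 30) {
  stopifnot(length(time) == length(set_temp_c),
            length(time) == length(achieved_temp_c))
  .check_times(time, "water_log")
  tt <- c(set_temp_c, achieved_temp_c)
  if (any(!is.finite(tt)) || any(tt < 0) || any(tt > 45)) {
    stop("water_log: temperatures must lie within [0, 45] degC", call. = FALSE)
  }
  x <- data.frame(time = as.numeric(time),
                  set_temp_c = as.numeric(set_temp_c),
                  achieved_temp_c = as.numeric(achieved_temp_c))
  structure(x, origin = .as_origin(origin), gaps = .find_gaps(time, cadence),
            class = c("water_log", "data.frame"))
}

#' Thermoesthesia (tGUI) log
#'
#' Slider positions on the 0 ("Very Cold") to 100 ("Very Hot") perception
#' scale and the binary shiver indicator, sampled every 30 s and at every
#' key press.
#'
#' @param time numeric seconds, non-decreasing (event rows may share a
#'   scheduled timestamp).
#' @param slider integer slider values in `[0, 100]`.
#' @param shiver shiver indicator, 0 (No) or 1 (Yes).
#' @inheritParams water_log
#' @return a data frame of class `tgui_log` with columns `time`, `slider`,
#'   `shiver`.
#' @export
tgui_log <- function(time, slider, shiver, origin = NULL, cadence = 30) {
  stopifnot(length(time) == length(slider), length(time) == length(shiver))
  .check_times(time, "tgui_log", strict = FALSE)
  if (any(!is.finite(slider)) || any(slider < 0) || any(slider > 100) ||
      any(slider != round(slider))) {
    bad <- which(!is.finite(slider) | slider < 0 | slider > 100 |
                   slider != round(slider))[1L]
    stop("tgui_log: slider must be an integer in [0, 100] (row ", bad, ")",
         call. = FALSE)
  }
  if (!all(shiver %in% c(0, 1))) {
    stop("tgui_log: shiver flag must be 0 or 1 (row ",
         which(!shiver %in% c(0, 1))[1L], ")", call. = FALSE)
  }
  x <- data.frame(time = as.numeric(time), slider = as.integer(slider),
                  shiver = as.integer(shiver))
  structure(x, origin = .as_origin(origin), gaps = .find_gaps(time, cadence),
            class = c("tgui_log", "data.frame"))
}

#' Skin-temperature log
#'
#' Clavicle (supraclavicular, superficial to a potential brown-adipose
#' depot), forearm, and finger skin temperatures, nominally every 30 s.
#'
#' @inheritParams water_log
#' @param clavicle_c,forearm_c,finger_c temperatures in degrees Celsius,
#'   within `[5, 45]`.
#' @return a data frame of class `skin_log` with columns `time`,
#'   `clavicle_c`, `forearm_c`, `finger_c`.
#' @export
skin_log <- function(time, clavicle_c, forearm_c, finger_c, origin = NULL,
                     cadence = 30) {
  stopifnot(length(time) == length(clavicle_c),
            length(time) == length(forearm_c),
            length(time) == length(finger_c))
  .check_times(time, "skin_log")
  tt <- c(clavicle_c, forearm_c, finger_c)
  if (any(!is.finite(tt)) || any(tt < 5) || any(tt > 45)) {
    stop("skin_log: temperatures must lie within [5, 45] degC", call. = FALSE)
  }
  x <- data.frame(time = as.numeric(time),
                  clavicle_c = as.numeric(clavicle_c),
                  forearm_c = as.numeric(forearm_c),
                  finger_c = as.numeric(finger_c))
  structure(x, origin = .as_origin(origin), gaps = .find_gaps(time, cadence),
            class = c("skin_log", "data.frame"))
}

#' Raw EMG recording
#'
#' A uniformly sampled surface-EMG trace in millivolts.
#'
#' @param signal numeric vector of amplitude samples (mV); must be finite.
#' @param rate sampling rate in Hz (default 1000).
#' @param start_time session-clock time of the first sample, seconds.
#' @inheritParams water_log
#' @return an object of class `emg_recording`: a list with elements
#'   `signal`, `rate`, `start_time`.
#' @export
emg_recording <- function(signal, rate = 1000, start_time = 0, origin = NULL) {
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("emg_recording: rate must be a positive scalar (Hz)", call. = FALSE)
  }
  if (any(!is.finite(signal))) {
    stop("emg_recording: signal must contain finite samples only", call. = FALSE)
  }
  structure(list(signal = as.numeric(signal), rate = as.numeric(rate),
                 start_time = as.numeric(start_time)),
            origin = .as_origin(origin), class = "emg_recording")
}

#' Sample times of an EMG recording
#' @param emg an [emg_recording()].
#' @return numeric vector of sample-center times in seconds.
#' @export
emg_times <- function(emg) {
  stopifnot(inherits(emg, "emg_recording"))
  emg$start_time + (seq_along(emg$signal) - 1L) / emg$rate
}

#' Phase records
#'
#' The controller's record of protocol phases: a pretrial settling period,
#' one thermoneutral phase, then numbered cooling phases.
#'
#' @param kind character, one of `"pretrial"`, `"thermoneutral"`, `"cooling"`.
#' @param index integer cooling-phase number (1-based; `NA` otherwise).
#' @param start,end phase boundaries in seconds; `start < end`.
#' @param set_temp_c set water temperature during the phase.
#' @return a data frame of class `phase_records`.
#' @export
phase_records <- function(kind = character(), index = integer(),
                          start = numeric(), end = numeric(),
                          set_temp_c = numeric()) {
  stopifnot(all(kind %in% c("pretrial", "thermoneutral", "cooling")))
  x <- data.frame(kind = as.character(kind), index = as.integer(index),
                  start = as.numeric(start), end = as.numeric(end),
                  set_temp_c = as.numeric(set_temp_c))
  if (nrow(x)) {
    if (any(x$start >= x$end)) stop("phase_records: start must precede end",
                                    call. = FALSE)
    if (any(diff(x$start) <= 0)) stop("phase_records: phases must be ordered",
                                      call. = FALSE)
    if (any(x$end[-nrow(x)] > x$start[-1L] + 1e-9)) {
      stop("phase_records: phases must not overlap", call. = FALSE)
    }
    ci <- x$index[x$kind == "cooling"]
    if (length(ci) && !identical(as.integer(ci), seq_along(ci))) {
      stop("phase_records: cooling indices must be consecutive from 1",
           call. = FALSE)
    }
  }
  structure(x, class = c("phase_records", "data.frame"))
}

#' Session bundle
#'
#' A synchronized session: water, tGUI, and skin logs on one clock (time
#' zero at the start of the first cooling phase), an optional EMG trace,
#' phase records, and free-form metadata.
#'
#' @param water a [water_log()].
#' @param tgui a [tgui_log()].
#' @param skin a [skin_log()].
#' @param emg optional [emg_recording()].
#' @param phases optional [phase_records()].
#' @param metadata named list (e.g. subject code, room conditions).
#' @return an object of class `session_bundle`.
#' @export
session_bundle <- function(water, tgui, skin, emg = NULL, phases = NULL,
                           metadata = list()) {
  stopifnot(inherits(water, "water_log"), inherits(tgui, "tgui_log"),
            inherits(skin, "skin_log"))
  if (!is.null(emg)) stopifnot(inherits(emg, "emg_recording"))
  if (is.null(phases)) phases <- phase_records()
  if (!inherits(phases, "phase_records")) {
    phases <- do.call(phase_records, as.list(phases))
  }
  structure(list(water = water, tgui = tgui, skin = skin, emg = emg,
                 phases = phases, metadata = metadata),
            class = "session_bundle")
}

#' @export
print.session_bundle <- function(x, ...) {
  span <- range(c(x$water$time, x$tgui$time, x$skin$time))
  cat("<session_bundle>\n")
  cat(sprintf("  span: %.1f .. %.1f s (0 = start of first cooling phase)\n",
              span[1L], span[2L]))
  cat(sprintf("  water: %d samples; tGUI: %d rows; skin: %d samples\n",
              nrow(x$water), nrow(x$tgui), nrow(x$skin)))
  cat(sprintf("  EMG: %s\n",
              if (is.null(x$emg)) "absent"
              else sprintf("%d samples @ %g Hz", length(x$emg$signal),
                           x$emg$rate)))
  cat(sprintf("  phases: %d (%s)\n", nrow(x$phases),
              paste(x$phases$kind, collapse = ", ")))
  invisible(x)
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d samples @ %g Hz, start %.3f s (%.1f s)\n",
              length(x$signal), x$rate, x$start_time,
              length(x$signal) / x$rate))
  invisible(x)
}
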