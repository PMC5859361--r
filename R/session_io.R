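## Reading, writing and synchronizing session logs.
##
## Canonical format: header-bearing CSV with ISO-8601 timestamps (UTC).
##   water: time_iso,set_temp_c,achieved_temp_c
##   tgui:  time_iso,slider,shiver
##   skin:  time_iso,clavicle_c,forearm_c,finger_c
##   emg:   2-line key,value header (rate_hz; start_time_iso) then one
##          mV sample per line
## A read-only LabChart-style tab-delimited dialect is supported for skin
## logs, and a configurable device-export dialect for water logs.

.read_table_checked <- function(path, sep, required, what) {
  if (!file.exists(path)) stop(what, ": file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(what, ": missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}

.times_from_iso <- function(iso, what) {
  t_wall <- parse_iso_time(iso)
  origin <- t_wall[1L]
  list(time = as.numeric(difftime(t_wall, origin, units = "secs")),
       origin = origin)
}

#' Read a water-temperature log
#'
#' @param path path to the log file.
#' @param dialect `"canonical"` (CSV, `time_iso,set_temp_c,achieved_temp_c`)
#'   or `"blanketrol"`, a configurable tab-delimited device-export layout.
#' @param col_map for the device dialect, a named character vector mapping
#'   `time`, `set`, `achieved` to column names in the file. The exact export
#'   layout varies between device software versions, so the mapping is a
#'   parameter rather than a constant.
#' @return a [water_log()] whose `origin` attribute is the first timestamp.
#' @export
read_water_log <- function(path, dialect = c("canonical", "blanketrol"),
                           col_map = c(time = "Time", set = "Set Point",
                                       achieved = "Water Temp")) {
  dialect <- match.arg(dialect)
  if (dialect == "canonical") {
    df <- .read_table_checked(path, ",",
                              c("time_iso", "set_temp_c", "achieved_temp_c"),
                              "read_water_log")
    tm <- .times_from_iso(df$time_iso, "read_water_log")
    set <- df$set_temp_c; ach <- df$achieved_temp_c
  } else {
    df <- .read_table_checked(path, "\t", unname(col_map), "read_water_log")
    tm <- .times_from_iso(df[[col_map[["time"]]]], "read_water_log")
    set <- df[[col_map[["set"]]]]; ach <- df[[col_map[["achieved"]]]]
  }
  bad <- which(!is.finite(as.numeric(set)) | !is.finite(as.numeric(ach)))
  if (length(bad)) {
    stop("read_water_log: malformed temperature value(s) at data row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  water_log(tm$time, as.numeric(set), as.numeric(ach), origin = tm$origin)
}

#' Read a thermoesthesia (tGUI) log
#'
#' Rows are logged every 30 s and at every key press; key presses may share
#' a scheduled timestamp. Duplicate timestamps are resolved by keeping the
#' last row per timestamp (the key press overrides the scheduled sample).
#'
#' @param path path to a canonical CSV (`time_iso,slider,shiver`).
#' @return a [tgui_log()] with strictly increasing times.
#' @export
read_tgui_log <- function(path) {
  df <- .read_table_checked(path, ",", c("time_iso", "slider", "shiver"),
                            "read_tgui_log")
  bad <- which(!is.finite(df$slider) | df$slider < 0 | df$slider > 100)
  if (length(bad)) {
    stop("read_tgui_log: slider outside [0, 100] at data row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  tm <- .times_from_iso(df$time_iso, "read_tgui_log")
  keep <- !duplicated(tm$time, fromLast = TRUE)
  tgui_log(tm$time[keep], df$slider[keep], df$shiver[keep], origin = tm$origin)
}

#' Read a skin-temperature log
#'
#' @param path path to the log file.
#' @param dialect `"canonical"` CSV, or `"labchart"` for a LabChart-style
#'   tab-delimited text export. The LabChart reader skips the header block
#'   by scanning for the first row whose fields all parse as numbers; the
#'   first column is then taken as time in seconds and the next three as
#'   clavicle, forearm, finger in degrees Celsius.
#' @return a [skin_log()].
#' @export
read_skin_log <- function(path, dialect = c("canonical", "labchart")) {
  dialect <- match.arg(dialect)
  if (dialect == "canonical") {
    df <- .read_table_checked(path, ",",
                              c("time_iso", "clavicle_c", "forearm_c",
                                "finger_c"), "read_skin_log")
    tm <- .times_from_iso(df$time_iso, "read_skin_log")
    return(skin_log(tm$time, df$clavicle_c, df$forearm_c, df$finger_c,
                    origin = tm$origin))
  }
  if (!file.exists(path)) stop("read_skin_log: file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path)
  is_data <- function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    length(f) >= 4L && !anyNA(suppressWarnings(as.numeric(f[1:4])))
  }
  first <- which(vapply(lines, is_data, logical(1L)))[1L]
  if (is.na(first)) stop("read_skin_log: no numeric data rows found",
                         call. = FALSE)
  df <- utils::read.table(text = lines[first:length(lines)], sep = "\t")
  skin_log(df[[1L]], df[[2L]], df[[3L]], df[[4L]])
}

#' Read a raw EMG trace
#'
#' @param path canonical single-column file: two `key,value` header lines
#'   (`rate_hz` and `start_time_iso`) followed by one mV sample per line.
#' @return an [emg_recording()].
#' @export
read_emg <- function(path) {
  if (!file.exists(path)) stop("read_emg: file not found: ", path,
                               call. = FALSE)
  hdr <- readLines(path, n = 2L)
  kv <- strsplit(hdr, ",", fixed = TRUE)
  keys <- vapply(kv, `[[`, "", 1L)
  if (!all(c("rate_hz", "start_time_iso") %in% keys)) {
    stop("read_emg: expected header lines rate_hz and start_time_iso",
         call. = FALSE)
  }
  vals <- vapply(kv, `[[`, "", 2L); names(vals) <- keys
  sig <- utils::read.table(path, skip = 2L)[[1L]]
  emg_recording(sig, rate = as.numeric(vals[["rate_hz"]]),
                start_time = 0, origin = parse_iso_time(vals[["start_time_iso"]]))
}

.wall_times <- function(time, origin) origin + time

#' Write session logs in canonical formats
#'
#' @param x the log object.
#' @param path output file path.
#' @param dialect for water logs, `"canonical"` or `"blanketrol"`
#'   (tab-delimited device layout, same columns as [read_water_log()]'s
#'   default `col_map`).
#' @return the path, invisibly.
#' @name write_logs
NULL

.fmt_num <- function(x) format(x, digits = 15, trim = TRUE, scientific = FALSE)

#' @rdname write_logs
#' @export
write_water_log <- function(x, path, dialect = c("canonical", "blanketrol")) {
  stopifnot(inherits(x, "water_log"))
  dialect <- match.arg(dialect)
  iso <- format_iso_time(.wall_times(x$time, attr(x, "origin")))
  if (dialect == "canonical") {
    df <- data.frame(time_iso = iso, set_temp_c = .fmt_num(x$set_temp_c),
                     achieved_temp_c = .fmt_num(x$achieved_temp_c))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    df <- data.frame(iso, .fmt_num(x$set_temp_c), .fmt_num(x$achieved_temp_c))
    names(df) <- c("Time", "Set Point", "Water Temp")
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_logs
#' @export
write_tgui_log <- function(x, path) {
  stopifnot(inherits(x, "tgui_log"))
  df <- data.frame(time_iso = format_iso_time(.wall_times(x$time,
                                                          attr(x, "origin"))),
                   slider = x$slider, shiver = x$shiver)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_logs
#' @export
write_skin_log <- function(x, path) {
  stopifnot(inherits(x, "skin_log"))
  df <- data.frame(time_iso = format_iso_time(.wall_times(x$time,
                                                          attr(x, "origin"))),
                   clavicle_c = .fmt_num(x$clavicle_c),
                   forearm_c = .fmt_num(x$forearm_c),
                   finger_c = .fmt_num(x$finger_c))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_logs
#' @export
write_emg <- function(x, path) {
  stopifnot(inherits(x, "emg_recording"))
  start_wall <- attr(x, "origin") + x$start_time
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("rate_hz,", .fmt_num(x$rate)),
               paste0("start_time_iso,", format_iso_time(start_wall))), con)
  writeLines(.fmt_num(x$signal), con)
  invisible(path)
}

#' Write / read a full session directory
#'
#' `write_session()` writes the bundle's streams as canonical CSV files
#' (`water.csv`, `tgui.csv`, `skin.csv`, optional `emg.csv`), the phase
#' table (`phases.csv`), and a `session.meta` key=value file that records
#' the wall-clock instant of time zero (`cooling_start_iso`) plus any
#' metadata. `read_session()` reads them back and re-synchronizes on
#' `cooling_start_iso`, so marker and phase times round-trip.
#'
#' @param bundle a [session_bundle()].
#' @param dir session directory.
#' @return `write_session()` the directory, invisibly; `read_session()` a
#'   [session_bundle()].
#' @export
write_session <- function(bundle, dir) {
  stopifnot(inherits(bundle, "session_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_water_log(bundle$water, file.path(dir, "water.csv"))
  write_tgui_log(bundle$tgui, file.path(dir, "tgui.csv"))
  write_skin_log(bundle$skin, file.path(dir, "skin.csv"))
  if (!is.null(bundle$emg)) write_emg(bundle$emg, file.path(dir, "emg.csv"))
  ph <- bundle$phases
  utils::write.csv(data.frame(kind = ph$kind, index = ph$index,
                              start_s = .fmt_num(ph$start),
                              end_s = .fmt_num(ph$end),
                              set_temp_c = .fmt_num(ph$set_temp_c)),
                   file.path(dir, "phases.csv"), row.names = FALSE,
                   quote = FALSE)
  meta <- bundle$metadata
  meta$cooling_start_iso <- format_iso_time(attr(bundle$water, "origin"))
  writeLines(paste0(names(meta), "=", vapply(meta, function(v)
    paste(format(v, digits = 15), collapse = ";"), "")),
    file.path(dir, "session.meta"))
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  need <- c("water.csv", "tgui.csv", "skin.csv", "session.meta")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    stop("read_session: missing session file(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  meta_lines <- readLines(file.path(dir, "session.meta"))
  kv <- strsplit(meta_lines, "=", fixed = TRUE)
  meta <- stats::setNames(lapply(kv, function(p) paste(p[-1L], collapse = "=")),
                          vapply(kv, `[[`, "", 1L))
  cooling_start <- parse_iso_time(meta$cooling_start_iso)
  meta$cooling_start_iso <- NULL

  water <- read_water_log(file.path(dir, "water.csv"))
  tgui <- read_tgui_log(file.path(dir, "tgui.csv"))
  skin <- read_skin_log(file.path(dir, "skin.csv"))
  emg <- if (file.exists(file.path(dir, "emg.csv")))
    read_emg(file.path(dir, "emg.csv")) else NULL

  phases <- NULL
  if (file.exists(file.path(dir, "phases.csv"))) {
    ph <- utils::read.csv(file.path(dir, "phases.csv"))
    phases <- phase_records(ph$kind, ph$index, ph$start_s, ph$end_s,
                            ph$set_temp_c)
  }
  synchronize_session(water, tgui, skin, emg, cooling_start = cooling_start,
                      phases = phases, metadata = meta)
}

#' Synchronize session streams on a common clock
#'
#' Shifts every stream so that `cooling_start` maps to time zero (the start
#' of the first cooling phase). Pre-cooling samples keep negative times and
#' are retained. Synchronization is a pure time shift: within-stream time
#' differences are unchanged.
#'
#' @param water,tgui,skin,emg the session streams (EMG optional); each must
#'   carry a wall-clock `origin`.
#' @param cooling_start POSIXct (or ISO-8601 string) wall-clock start of the
#'   first cooling phase; must lie within every stream's span.
#' @param phases optional [phase_records()] already on the synchronized clock.
#' @param metadata named list stored on the bundle.
#' @return a [session_bundle()].
#' @export
synchronize_session <- function(water, tgui, skin, emg = NULL, cooling_start,
                                phases = NULL, metadata = list()) {
  cooling_start <- .as_origin(cooling_start)
  shift_df <- function(x, what) {
    origin <- attr(x, "origin")
    offset <- as.numeric(difftime(origin, cooling_start, units = "secs"))
    span <- range(x$time) + offset
    if (span[1L] > 0 || span[2L] < 0) {
      stop("synchronize_session: cooling_start lies outside the span of the ",
           what, " log", call. = FALSE)
    }
    x$time <- x$time + offset
    attr(x, "origin") <- cooling_start
    x
  }
  water <- shift_df(water, "water")
  tgui <- shift_df(tgui, "tgui")
  skin <- shift_df(skin, "skin")
  if (!is.null(emg)) {
    offset <- as.numeric(difftime(attr(emg, "origin"), cooling_start,
                                  units = "secs"))
    emg$start_time <- emg$start_time + offset
    attr(emg, "origin") <- cooling_start
  }
  session_bundle(water, tgui, skin, emg, phases, metadata)
}

#' Resample a session onto a common time grid
#'
#' Linearly interpolates each stream onto a regular grid, the preparation
#' step for marker covariates and skin-perception correlations. There is no
#' extrapolation: grid cells outside a stream's span are `NA`. The shiver
#' flag is a state, not a magnitude, so it is carried forward
#' (previous-value hold) rather than interpolated.
#'
#' @param bundle a [session_bundle()].
#' @param step grid step in seconds (> 0).
#' @return a data frame with columns `time`, `set_temp_c`,
#'   `achieved_temp_c`, `slider`, `shiver`, `clavicle_c`, `forearm_c`,
#'   `finger_c`.
#' @export
resample_common_grid <- function(bundle, step = 30) {
  stopifnot(inherits(bundle, "session_bundle"))
  if (!is.numeric(step) || step <= 0) {
    stop("resample_common_grid: step must be > 0", call. = FALSE)
  }
  spans <- rbind(range(bundle$water$time), range(bundle$tgui$time),
                 range(bundle$skin$time))
  lo <- max(spans[, 1L]); hi <- min(spans[, 2L])
  if (lo > hi) stop("resample_common_grid: streams do not overlap in time",
                    call. = FALSE)
  grid <- seq(min(spans[, 1L]), max(spans[, 2L]), by = step)

  lin <- function(x, y) {
    if (length(x) < 2L) return(ifelse(grid == x, y, NA_real_))
    stats::approx(x, y, xout = grid, method = "linear", rule = 1)$y
  }
  hold <- function(x, y) {
    if (length(x) < 2L) return(ifelse(grid >= x & grid <= x, y, NA_real_))
    out <- stats::approx(x, y, xout = grid, method = "constant", f = 0,
                         rule = 1:2)$y
    out[grid < x[1L]] <- NA_real_
    out[grid > x[length(x)]] <- NA_real_
    out
  }
  data.frame(
    time = grid,
    set_temp_c = lin(bundle$water$time, bundle$water$set_temp_c),
    achieved_temp_c = lin(bundle$water$time, bundle$water$achieved_temp_c),
    slider = lin(bundle$tgui$time, bundle$tgui$slider),
    shiver = hold(bundle$tgui$time, bundle$tgui$shiver),
    clavicle_c = lin(bundle$skin$time, bundle$skin$clavicle_c),
    forearm_c = lin(bundle$skin$time, bundle$skin$forearm_c),
    finger_c = lin(bundle$skin$time, bundle$skin$finger_c)
  )
}
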