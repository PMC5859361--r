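## Self-report intervals, EMG vs tGUI similarity fractions, skin-temperature
## gradients, physiological markers, and perception correlations.

#' Self-reported shiver intervals from a tGUI log
#'
#' Maximal intervals over which the shiver flag is 1. An interval still open
#' at the end of the log is closed at the last timestamp.
#'
#' @param log a [tgui_log()].
#' @return a [shiver_events()] table with `source = "tgui"`.
#' @export
tgui_intervals <- function(log) {
  stopifnot(inherits(log, "tgui_log"))
  f <- log$shiver
  if (!length(f) || !any(f == 1L)) return(shiver_events(source = "tgui"))
  r <- rle(f == 1L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on_runs <- which(r$values)
  onset <- log$time[starts[on_runs]]
  ## interval closes when the flag returns to 0; at log end, at the last row
  offset <- ifelse(ends[on_runs] < length(f),
                   log$time[ends[on_runs] + 1L],
                   log$time[length(f)])
  keep <- offset > onset  # a lone trailing 1-row has zero extent
  shiver_events(onset[keep], offset[keep], "tgui")
}

#' Match EMG events to self-reported events
#'
#' Greedy chronological one-to-one matching: each tGUI interval is expanded
#' symmetrically by `tolerance` seconds (allowing for self-report latency),
#' and a pair matches when the intervals overlap (closed intervals). Each
#' event is used at most once.
#'
#' @param emg,tgui [shiver_events()] tables, each sorted and
#'   non-overlapping within its source.
#' @param tolerance symmetric expansion of each tGUI interval, seconds
#'   (default 2).
#' @return integer count of matched pairs.
#' @export
match_events <- function(emg, tgui, tolerance = 2) {
  i <- 1L; j <- 1L; matched <- 0L
  while (i <= nrow(emg) && j <= nrow(tgui)) {
    a_on <- emg$onset[i]; a_off <- emg$offset[i]
    b_on <- tgui$onset[j] - tolerance; b_off <- tgui$offset[j] + tolerance
    if (a_on <= b_off && b_on <= a_off) {
      matched <- matched + 1L
      i <- i + 1L; j <- j + 1L
    } else if (a_off < b_off) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  matched
}

#' Similarity fractions between EMG and self-reported shiver events
#'
#' The matched-event count divided by the per-source event counts: the EMG
#' fraction is `matched / n_emg`, the tGUI fraction `matched / n_tgui`.
#' A fraction whose denominator is zero is defined as 0.
#'
#' @inheritParams match_events
#' @return a list of class `similarity_result` with elements `n_emg`,
#'   `n_tgui`, `n_matched`, `emg_fraction`, `tgui_fraction`, `tolerance`.
#' @export
similarity_fractions <- function(emg, tgui, tolerance = 2) {
  m <- match_events(emg, tgui, tolerance)
  frac <- function(num, den) if (den == 0L) 0 else num / den
  structure(list(n_emg = nrow(emg), n_tgui = nrow(tgui), n_matched = m,
                 emg_fraction = frac(m, nrow(emg)),
                 tgui_fraction = frac(m, nrow(tgui)),
                 tolerance = tolerance),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf(paste0("<similarity_result> %d EMG, %d tGUI, %d matched ",
                     "(tolerance %g s)\n  EMG fraction %.3f, tGUI fraction %.3f\n"),
              x$n_emg, x$n_tgui, x$n_matched, x$tolerance,
              x$emg_fraction, x$tgui_fraction))
  invisible(x)
}

#' Arm-to-finger vasoconstriction gradient
#'
#' `gradient = forearm - finger`, in degrees Celsius; a rising gradient
#' reflects peripheral vasoconstriction (cooling fingers with a relatively
#' stable forearm).
#'
#' @param skin a [skin_log()].
#' @return a data frame with columns `time`, `gradient_c`.
#' @export
vasoconstriction_gradient <- function(skin) {
  stopifnot(inherits(skin, "skin_log"))
  data.frame(time = skin$time, gradient_c = skin$forearm_c - skin$finger_c)
}

.nearest_prior <- function(x, y, at) {
  i <- findInterval(at, x)
  ifelse(i >= 1L, y[pmax(i, 1L)], NA_real_)
}

#' Physiological markers of a cooling session
#'
#' Extracts the three markers used to characterize an individual's response
#' to cooling, with water temperature (set point) and perception (slider)
#' read at each marker from the common grid by nearest-prior sample (both
#' are step-like command/state signals):
#' \describe{
#'   \item{vasoconstriction_index}{first time the arm-to-finger gradient
#'     reaches `gradient_threshold` (>= 4.0 degC by default).}
#'   \item{shiver_onset}{start of the first self-reported shiver interval.}
#'   \item{sustained_shiver}{start of the first self-reported interval
#'     strictly longer than `sustained_threshold` (60 s by default) — the
#'     protocol's termination criterion.}
#' }
#'
#' @param bundle a [session_bundle()].
#' @param emg_events optional EMG [shiver_events()], reported alongside but
#'   not used for the marker definitions (markers are self-report based).
#' @param gradient_threshold vasoconstriction-index gradient, degC
#'   (default 4.0; the marker fires at `>=`).
#' @param sustained_threshold sustained-shiver duration, seconds
#'   (default 60; strict `>`).
#' @param grid_step grid step for covariate lookup, seconds.
#' @return a data frame of class `marker_summary` with one row per marker:
#'   `marker`, `present`, `time`, `water_temp_c`, `perception`.
#' @export
detect_markers <- function(bundle, emg_events = NULL, gradient_threshold = 4.0,
                           sustained_threshold = 60, grid_step = 30) {
  stopifnot(inherits(bundle, "session_bundle"))
  grad <- vasoconstriction_gradient(bundle$skin)
  iv <- which(grad$gradient_c >= gradient_threshold)
  vaso_t <- if (length(iv)) grad$time[iv[1L]] else NA_real_

  tg <- tgui_intervals(bundle$tgui)
  onset_t <- if (nrow(tg)) tg$onset[1L] else NA_real_
  sus <- which(tg$offset - tg$onset > sustained_threshold)
  sus_t <- if (length(sus)) tg$onset[sus[1L]] else NA_real_

  grid <- resample_common_grid(bundle, step = grid_step)
  covar <- function(t) {
    if (is.na(t)) return(c(NA_real_, NA_real_))
    c(.nearest_prior(grid$time, grid$set_temp_c, t),
      .nearest_prior(grid$time, grid$slider, t))
  }
  times <- c(vasoconstriction_index = vaso_t, shiver_onset = onset_t,
             sustained_shiver = sus_t)
  cv <- vapply(times, covar, numeric(2L))
  out <- data.frame(marker = names(times), present = !is.na(times),
                    time = unname(times), water_temp_c = cv[1L, ],
                    perception = cv[2L, ], row.names = NULL)
  structure(out, emg_events = emg_events,
            class = c("marker_summary", "data.frame"))
}

.thermoneutral_end <- function(bundle) {
  ph <- bundle$phases
  i <- which(ph$kind == "thermoneutral")
  if (!length(i)) {
    stop("no thermoneutral phase recorded in the session bundle",
         call. = FALSE)
  }
  ph$end[i[1L]]
}

#' Thermoneutral vasoconstriction exclusion rule
#'
#' A session indicates pronounced peripheral vasoconstriction already at
#' thermoneutrality — and its skin-temperature data are excluded from
#' group analyses — when the arm-to-finger gradient at the end of the
#' thermoneutral phase is strictly greater than `gradient_threshold`.
#'
#' @param bundle a [session_bundle()] with a recorded thermoneutral phase.
#' @param gradient_threshold exclusion gradient, degC (default 4.0,
#'   strict `>`).
#' @return a list with elements `excluded` (flag) and `gradient_c` (the
#'   gradient at thermoneutral end, nearest-prior skin sample).
#' @export
thermoneutral_exclusion <- function(bundle, gradient_threshold = 4.0) {
  t_end <- .thermoneutral_end(bundle)
  grad <- vasoconstriction_gradient(bundle$skin)
  g <- .nearest_prior(grad$time, grad$gradient_c, t_end)
  list(excluded = isTRUE(g > gradient_threshold), gradient_c = g)
}

#' Skin temperatures relative to thermoneutral end
#'
#' Each channel minus its value at the end of the thermoneutral phase
#' (nearest-prior sample); the gradient column stays absolute.
#'
#' @param bundle a [session_bundle()] with a recorded thermoneutral phase.
#' @return a data frame with columns `time`, `d_clavicle_c`, `d_forearm_c`,
#'   `d_finger_c`, `gradient_c`.
#' @export
relative_skin_temps <- function(bundle) {
  t_end <- .thermoneutral_end(bundle)
  s <- bundle$skin
  ref <- vapply(c("clavicle_c", "forearm_c", "finger_c"),
                function(ch) .nearest_prior(s$time, s[[ch]], t_end), 0)
  data.frame(time = s$time,
             d_clavicle_c = s$clavicle_c - ref[["clavicle_c"]],
             d_forearm_c = s$forearm_c - ref[["forearm_c"]],
             d_finger_c = s$finger_c - ref[["finger_c"]],
             gradient_c = s$forearm_c - s$finger_c)
}

#' Spearman correlations between skin temperature and perception
#'
#' Rank correlation (average ranks for ties) between the slider and each
#' skin channel plus the arm-to-finger gradient, over common-grid rows where
#' both series are present.
#'
#' @param grid a common-grid table from [resample_common_grid()].
#' @return a data frame with columns `channel`, `rho`, `n`, `defined`;
#'   `rho` is `NA` (and `defined` FALSE) when fewer than 3 complete pairs
#'   exist or a series is constant.
#' @export
perception_correlations <- function(grid) {
  stopifnot(is.data.frame(grid), "slider" %in% names(grid))
  channels <- c(clavicle_c = "clavicle_c", forearm_c = "forearm_c",
                finger_c = "finger_c", gradient_c = "gradient_c")
  if (!"gradient_c" %in% names(grid)) {
    grid$gradient_c <- grid$forearm_c - grid$finger_c
  }
  rows <- lapply(names(channels), function(ch) {
    ok <- stats::complete.cases(grid$slider, grid[[ch]])
    x <- grid$slider[ok]; y <- grid[[ch]][ok]
    defined <- sum(ok) >= 3L && stats::sd(x) > 0 && stats::sd(y) > 0
    rho <- if (defined) stats::cor(x, y, method = "spearman") else NA_real_
    data.frame(channel = ch, rho = rho, n = sum(ok), defined = defined)
  })
  do.call(rbind, rows)
}
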