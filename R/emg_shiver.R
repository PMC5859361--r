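## Shiver-event detection in raw surface EMG.
##
## Pipeline: zero-phase band-pass (20-400 Hz) + notch (60 Hz), Teager-Kaiser
## energy operator, rectification + zero-phase low-pass (50 Hz) envelope,
## baseline statistics over a quiet ~5 s segment, threshold mu + J*sigma
## (J = 15), sliding-window onset criterion (>= 10% of a 250 ms window
## supra-threshold), and merging of events separated by < 50 ms.

#' Detection parameters
#'
#' All constants of the EMG shiver-detection pipeline.
#'
#' @param bandpass_low,bandpass_high band-pass edges, Hz (defaults 20, 400).
#' @param notch mains notch frequency, Hz (default 60).
#' @param notch_q notch quality factor (default 30).
#' @param envelope_lowpass envelope smoothing cut-off, Hz (default 50).
#' @param baseline_duration quiet-baseline segment length, seconds (default 5).
#' @param J threshold multiplier on the baseline standard deviation
#'   (default 15, a preset validated for low-magnitude baselines).
#' @param window sliding-window length for the onset criterion, seconds
#'   (default 0.250).
#' @param window_fraction minimum fraction of supra-threshold samples in the
#'   window (default 0.10).
#' @param merge_gap events closer than this gap are combined, seconds
#'   (default 0.050, strict inequality).
#' @param anchor how the onset window is anchored at a candidate sample:
#'   `"forward"` (default; window `[t, t + window)`), `"center"`, or
#'   `"backward"`.
#' @return a list of class `detection_params`.
#' @export
detection_params <- function(bandpass_low = 20, bandpass_high = 400,
                             notch = 60, notch_q = 30,
                             envelope_lowpass = 50, baseline_duration = 5,
                             J = 15, window = 0.250, window_fraction = 0.10,
                             merge_gap = 0.050,
                             anchor = c("forward", "center", "backward")) {
  anchor <- match.arg(anchor)
  if (!(bandpass_low > 0 && bandpass_low < bandpass_high)) {
    stop("detection_params: need 0 < bandpass_low < bandpass_high",
         call. = FALSE)
  }
  if (J <= 0) stop("detection_params: J must be > 0", call. = FALSE)
  if (!(window_fraction > 0 && window_fraction <= 1)) {
    stop("detection_params: window_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (window <= 0 || merge_gap < 0 || baseline_duration <= 0) {
    stop("detection_params: durations must be positive", call. = FALSE)
  }
  structure(list(bandpass_low = bandpass_low, bandpass_high = bandpass_high,
                 notch = notch, notch_q = notch_q,
                 envelope_lowpass = envelope_lowpass,
                 baseline_duration = baseline_duration, J = J,
                 window = window, window_fraction = window_fraction,
                 merge_gap = merge_gap, anchor = anchor),
            class = "detection_params")
}

## RBJ biquad notch; the signal package has no notch designer
.notch_coefs <- function(freq, rate, q) {
  w0 <- 2 * pi * freq / rate
  alpha <- sin(w0) / (2 * q)
  list(b = c(1, -2 * cos(w0), 1) / (1 + alpha),
       a = c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha)))
}

#' Band-pass and notch filter a raw EMG trace
#'
#' Applies a 4th-order zero-phase Butterworth band-pass followed by a
#' second-order notch (quality factor `notch_q`), both with forward-backward
#' filtering so event onsets carry no phase lag.
#'
#' @param emg an [emg_recording()].
#' @param params a [detection_params()].
#' @return an [emg_recording()] of the same length.
#' @export
preprocess_emg <- function(emg, params = detection_params()) {
  stopifnot(inherits(emg, "emg_recording"))
  rate <- emg$rate
  if (rate <= 2 * params$bandpass_high) {
    stop("preprocess_emg: sampling rate must exceed twice bandpass_high",
         call. = FALSE)
  }
  bp <- signal::butter(2, c(params$bandpass_low, params$bandpass_high) /
                         (rate / 2), type = "pass")
  y <- signal::filtfilt(bp, emg$signal)
  if (!is.null(params$notch) && params$notch > 0 && params$notch < rate / 2) {
    nc <- .notch_coefs(params$notch, rate, params$notch_q)
    y <- signal::filtfilt(filt = nc$b, a = nc$a, x = y)
  }
  out <- emg
  out$signal <- y
  out
}

#' Teager-Kaiser energy operator
#'
#' `psi[n] = x[n]^2 - x[n-1] * x[n+1]` for interior samples; the boundary
#' samples copy the nearest interior value so the output length equals the
#' input length. For a sinusoid of amplitude A and digital frequency w the
#' interior output is the constant `A^2 sin(w)^2`, which sharpens burst
#' onsets relative to the raw amplitude.
#'
#' @param x numeric sample vector, length >= 3.
#' @return numeric vector of the same length.
#' @export
tkeo <- function(x) {
  n <- length(x)
  if (n < 3L) stop("tkeo: need at least 3 samples", call. = FALSE)
  psi <- numeric(n)
  i <- 2:(n - 1L)
  psi[i] <- x[i]^2 - x[i - 1L] * x[i + 1L]
  psi[1L] <- psi[2L]
  psi[n] <- psi[n - 1L]
  psi
}

#' Envelope of a Teager-Kaiser signal
#'
#' Rectifies the signal and applies a zero-phase low-pass at
#' `envelope_lowpass` Hz.
#'
#' @param x numeric sample vector.
#' @param rate sampling rate, Hz.
#' @param params a [detection_params()].
#' @return numeric envelope, same length as `x`.
#' @export
emg_envelope <- function(x, rate, params = detection_params()) {
  if (rate <= 2 * params$envelope_lowpass) {
    stop("emg_envelope: sampling rate must exceed twice envelope_lowpass",
         call. = FALSE)
  }
  lp <- signal::butter(4, params$envelope_lowpass / (rate / 2), type = "low")
  signal::filtfilt(lp, abs(x))
}

#' Baseline statistics of the envelope
#'
#' Computes the mean and standard deviation of the envelope over a quiet
#' segment of approximately `baseline_duration` seconds. When `segment` is
#' omitted the contiguous window of that duration with minimum envelope
#' variance is chosen automatically (reproducible stand-in for manual
#' selection of a resting segment); explicit bounds override it.
#'
#' @param envelope numeric envelope vector.
#' @param rate sampling rate, Hz.
#' @param segment optional `c(start, end)` in seconds from the start of the
#'   trace.
#' @param params a [detection_params()].
#' @return a list of class `baseline_stats` with elements `mu`, `sigma`
#'   (sample mean / sd), `segment` (seconds), and `degenerate` (TRUE when
#'   `sigma == 0`, which collapses the threshold onto the mean; a warning
#'   is emitted).
#' @export
baseline_stats <- function(envelope, rate, segment = NULL,
                           params = detection_params()) {
  n <- length(envelope)
  win <- round(params$baseline_duration * rate)
  if (n < win) {
    stop("baseline_stats: trace shorter than baseline_duration", call. = FALSE)
  }
  if (is.null(segment)) {
    ## rolling variance via cumulative sums; earliest window on ties
    cs <- cumsum(c(0, envelope))
    cs2 <- cumsum(c(0, envelope^2))
    starts <- 1:(n - win + 1L)
    s <- cs[starts + win] - cs[starts]
    s2 <- cs2[starts + win] - cs2[starts]
    v <- (s2 - s^2 / win) / (win - 1L)
    best <- which.min(pmax(v, 0))
    idx <- best:(best + win - 1L)
    segment <- c(best - 1L, best - 1L + win) / rate
  } else {
    stopifnot(length(segment) == 2L, segment[1L] < segment[2L])
    idx <- (floor(segment[1L] * rate) + 1L):min(ceiling(segment[2L] * rate), n)
    if (length(idx) < 2L) {
      stop("baseline_stats: segment too short", call. = FALSE)
    }
  }
  mu <- mean(envelope[idx])
  sigma <- stats::sd(envelope[idx])
  degenerate <- sigma == 0
  if (degenerate) {
    warning("baseline_stats: zero baseline variance; threshold degenerates ",
            "to the baseline mean", call. = FALSE)
  }
  structure(list(mu = mu, sigma = sigma, segment = segment,
                 degenerate = degenerate), class = "baseline_stats")
}

#' Detection threshold
#'
#' `threshold = mu + J * sigma`, with `mu` and `sigma` the mean and standard
#' deviation of the baseline envelope and `J` the preset multiplier
#' (default 15).
#'
#' @param stats a [baseline_stats()] (or any list with `mu` and `sigma`).
#' @param params a [detection_params()].
#' @return the threshold, in envelope units.
#' @export
shiver_threshold <- function(stats, params = detection_params()) {
  stats$mu + params$J * stats$sigma
}

#' Construct a table of shiver events
#'
#' @param onset,offset event boundaries in seconds, `onset < offset`;
#'   within a source, events must be sorted and non-overlapping.
#' @param source `"emg"` or `"tgui"`.
#' @return a data frame of class `shiver_events` with columns `onset`,
#'   `offset`, `source`.
#' @export
shiver_events <- function(onset = numeric(), offset = numeric(),
                          source = "emg") {
  stopifnot(length(onset) == length(offset),
            all(source %in% c("emg", "tgui")))
  x <- data.frame(onset = as.numeric(onset), offset = as.numeric(offset),
                  source = rep_len(as.character(source), length(onset)))
  if (nrow(x) && any(x$onset >= x$offset)) {
    stop("shiver_events: onset must precede offset", call. = FALSE)
  }
  for (src in unique(x$source)) {
    e <- x[x$source == src, ]
    if (nrow(e) > 1L) {
      if (any(diff(e$onset) <= 0) || any(e$offset[-nrow(e)] > e$onset[-1L])) {
        stop("shiver_events: within-source events must be sorted and ",
             "non-overlapping", call. = FALSE)
      }
    }
  }
  structure(x, class = c("shiver_events", "data.frame"))
}

#' Detect supra-threshold events in an envelope
#'
#' A sample qualifies as an onset candidate when it is strictly above the
#' threshold and at least `window_fraction` of the samples in its anchored
#' `window` are strictly above the threshold. Each maximal supra-threshold
#' run containing at least one qualifying sample becomes one event: onset at
#' the earliest qualifying sample of the run, offset just past the run's
#' last supra-threshold sample (the criterion next fails beyond it), so
#' events are half-open intervals whose difference is the supra-threshold
#' duration and whose gaps are exactly the sub-threshold spans between
#' runs. Samples beyond the ends of the trace count as sub-threshold.
#' Events are then passed through [merge_events()]. Onsets are sample
#' centers in seconds, offset by `start_time`.
#'
#' @param envelope numeric envelope vector.
#' @param rate sampling rate, Hz.
#' @param thresh threshold in envelope units (see [shiver_threshold()]).
#' @param params a [detection_params()].
#' @param start_time session-clock time of the first sample, seconds.
#' @return a [shiver_events()] table with `source = "emg"`.
#' @export
detect_events <- function(envelope, rate, thresh,
                          params = detection_params(), start_time = 0) {
  n <- length(envelope)
  win <- max(round(params$window * rate), 2L)
  supra <- envelope > thresh
  if (!any(supra)) return(shiver_events())

  ## supra-count over the anchored window, out-of-range samples sub-threshold
  back <- switch(params$anchor,
                 forward = 0L, backward = win - 1L,
                 center = (win - 1L) %/% 2L)
  cs <- cumsum(c(0L, as.integer(supra)))
  lo <- pmax(seq_len(n) - back, 1L)
  hi <- pmin(seq_len(n) - back + win - 1L, n)
  frac <- (cs[hi + 1L] - cs[lo]) / win
  qualifies <- supra & frac >= params$window_fraction

  ## maximal supra runs; keep runs holding at least one qualifying sample
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  onset_idx <- offset_idx <- integer()
  for (k in which(keep)) {
    q <- which(qualifies[starts[k]:ends[k]])
    if (length(q)) {
      onset_idx <- c(onset_idx, starts[k] + q[1L] - 1L)
      offset_idx <- c(offset_idx, ends[k])
    }
  }
  if (!length(onset_idx)) return(shiver_events())
  ev <- shiver_events(start_time + (onset_idx - 1L) / rate,
                      start_time + offset_idx / rate, "emg")
  merge_events(ev, params)
}

#' Merge neighbouring events
#'
#' Adjacent events whose gap (next onset minus previous offset) is strictly
#' smaller than `merge_gap` are replaced by their union. Idempotent; a gap
#' exactly equal to `merge_gap` keeps the events separate.
#'
#' @param events a [shiver_events()] table, sorted and non-overlapping.
#' @param params a [detection_params()].
#' @return a [shiver_events()] table.
#' @export
merge_events <- function(events, params = detection_params()) {
  if (nrow(events) <= 1L) return(events)
  if (any(diff(events$onset) <= 0) ||
      any(events$offset[-nrow(events)] > events$onset[-1L])) {
    stop("merge_events: input events must be sorted and non-overlapping",
         call. = FALSE)
  }
  onset <- events$onset[1L]; offset <- events$offset[1L]
  src <- events$source[1L]
  out_on <- numeric(); out_off <- numeric()
  for (i in 2:nrow(events)) {
    ## strict gap rule with a 1 ns guard so a gap exactly equal to
    ## merge_gap is never merged through floating-point representation
    if (events$onset[i] - offset - params$merge_gap < -1e-9) {
      offset <- events$offset[i]
    } else {
      out_on <- c(out_on, onset); out_off <- c(out_off, offset)
      onset <- events$onset[i]; offset <- events$offset[i]
    }
  }
  shiver_events(c(out_on, onset), c(out_off, offset), src)
}

#' Full shiver-detection pipeline
#'
#' Convenience wrapper running [preprocess_emg()], [tkeo()],
#' [emg_envelope()], [baseline_stats()], [shiver_threshold()] and
#' [detect_events()] on a raw recording.
#'
#' @param emg an [emg_recording()].
#' @param params a [detection_params()].
#' @param baseline optional explicit baseline segment `c(start, end)` in
#'   seconds from the start of the trace.
#' @return a list of class `shiver_detection` with elements `events`
#'   (a [shiver_events()] table on the session clock), `envelope`,
#'   `baseline` (the [baseline_stats()]), `threshold`, `rate`, and
#'   `start_time`.
#' @export
detect_shiver <- function(emg, params = detection_params(), baseline = NULL) {
  filtered <- preprocess_emg(emg, params)
  env <- emg_envelope(tkeo(filtered$signal), emg$rate, params)
  bl <- baseline_stats(env, emg$rate, segment = baseline, params = params)
  thr <- shiver_threshold(bl, params)
  ev <- detect_events(env, emg$rate, thr, params, start_time = emg$start_time)
  structure(list(events = ev, envelope = env, baseline = bl, threshold = thr,
                 rate = emg$rate, start_time = emg$start_time),
            class = "shiver_detection")
}

#' @export
print.shiver_detection <- function(x, ...) {
  cat(sprintf("<shiver_detection> %d event(s); threshold %.4g (mu %.4g, sigma %.4g)\n",
              nrow(x$events), x$threshold, x$baseline$mu, x$baseline$sigma))
  if (nrow(x$events)) {
    cat(sprintf("  events span %.3f .. %.3f s\n", min(x$events$onset),
                max(x$events$offset)))
  }
  invisible(x)
}

#' Write / read shiver events as CSV
#'
#' Columns `onset_s,offset_s,source`.
#'
#' @param events a [shiver_events()] table.
#' @param path file path.
#' @return the path (write) or a [shiver_events()] table (read).
#' @export
write_events <- function(events, path) {
  utils::write.csv(data.frame(onset_s = .fmt_num(events$onset),
                              offset_s = .fmt_num(events$offset),
                              source = events$source),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- .read_table_checked(path, ",", c("onset_s", "offset_s", "source"),
                            "read_events")
  shiver_events(df$onset_s, df$offset_s, df$source)
}
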