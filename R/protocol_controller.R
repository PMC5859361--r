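## The individualized, perception-based cooling protocol as a deterministic
## state machine, plus the fixed familiarization schedule.
##
## The protocol starts at 32 degC with the slider at "Neutral"; once the
## participant rates "Neutral" (after +/-1 degC adjustments every 3 min if
## needed) a 15 min thermoneutral phase runs, followed by 10 min cooling
## phases. At each phase end the slider position sets the temperature
## decrement for the next phase; the session terminates as soon as a
## self-reported shiver interval exceeds 1 min.

#' Perception-scale landmarks
#'
#' Positions of the seven qualitative descriptors on the 0-100 slider.
#' The published interface does not print numeric positions, so the default
#' places them equally spaced with "Neutral" at 50; all positions are
#' configurable.
#'
#' @param very_cold,cold,cool,neutral,warm,hot,very_hot landmark positions;
#'   must be strictly increasing with `very_cold = 0` and `very_hot = 100`.
#' @return a named numeric vector of class `perception_scale`.
#' @export
perception_scale <- function(very_cold = 0, cold = 100 / 6, cool = 200 / 6,
                             neutral = 50, warm = 400 / 6, hot = 500 / 6,
                             very_hot = 100) {
  x <- c(very_cold = very_cold, cold = cold, cool = cool, neutral = neutral,
         warm = warm, hot = hot, very_hot = very_hot)
  if (x[["very_cold"]] != 0 || x[["very_hot"]] != 100 || any(diff(x) <= 0)) {
    stop("perception_scale: landmarks must increase strictly from 0 to 100",
         call. = FALSE)
  }
  structure(x, class = "perception_scale")
}

#' Cooling-phase decrement rule table
#'
#' Maps the slider position at a phase end to the water-temperature
#' decrement for the next phase. The published text quotes two rules —
#' 1 degC for a slider between "Very Cold" and "Cold", 3 degC at "Cool" —
#' and states that a slider aligned with a landmark takes the smaller of
#' the flanking decrements. The default table extrapolates that pattern
#' (5/3/1 degC moving coldward, maximum decrement warmer than neutral);
#' it is a reconstruction, so every entry is configurable.
#'
#' @param decrements named numeric vector with entries `at_very_cold`,
#'   `very_cold_to_cold`, `at_cold`, `cold_to_cool`, `at_cool`,
#'   `cool_to_neutral`, `at_neutral`, `warmer_than_neutral`; all > 0.
#' @return a named numeric vector of class `cooling_rule_table`.
#' @export
cooling_rule_table <- function(decrements = c(at_very_cold = 1,
                                              very_cold_to_cold = 1,
                                              at_cold = 1,
                                              cold_to_cool = 3,
                                              at_cool = 3,
                                              cool_to_neutral = 5,
                                              at_neutral = 5,
                                              warmer_than_neutral = 5)) {
  need <- c("at_very_cold", "very_cold_to_cold", "at_cold", "cold_to_cool",
            "at_cool", "cool_to_neutral", "at_neutral", "warmer_than_neutral")
  if (!all(need %in% names(decrements))) {
    stop("cooling_rule_table: missing rule(s): ",
         paste(setdiff(need, names(decrements)), collapse = ", "),
         call. = FALSE)
  }
  if (any(decrements <= 0)) {
    stop("cooling_rule_table: decrements must be > 0", call. = FALSE)
  }
  ## landmark decrement must be "the smaller decrease" of its flanks
  flanks <- list(at_very_cold = "very_cold_to_cold",
                 at_cold = c("very_cold_to_cold", "cold_to_cool"),
                 at_cool = c("cold_to_cool", "cool_to_neutral"),
                 at_neutral = c("cool_to_neutral", "warmer_than_neutral"))
  for (lm in names(flanks)) {
    if (decrements[[lm]] > min(decrements[flanks[[lm]]])) {
      stop("cooling_rule_table: ", lm, " must not exceed the smaller ",
           "flanking interval decrement", call. = FALSE)
    }
  }
  structure(decrements[need], class = "cooling_rule_table")
}

#' Protocol configuration
#'
#' All controller constants. Durations are minutes; temperatures degrees
#' Celsius.
#'
#' @param start_temp initial water temperature (default 32).
#' @param thermoneutral_duration thermoneutral phase length, min (default 15).
#' @param cooling_phase_duration cooling phase length, min (default 10).
#' @param adjustment_interval time between pre-thermoneutral adjustments,
#'   min (default 3).
#' @param thermoneutral_step pre-thermoneutral adjustment size, degC
#'   (default 1).
#' @param sustained_threshold self-reported shiver duration that terminates
#'   the protocol, min (default 1; strict `>`).
#' @param floor_temp lowest commandable water temperature, degC (default 4).
#' @param align_tol slider units within which the slider counts as aligned
#'   with a landmark (default 1, the scale's integer resolution).
#' @param scale a [perception_scale()].
#' @param rules a [cooling_rule_table()].
#' @return a list of class `protocol_config`.
#' @export
protocol_config <- function(start_temp = 32, thermoneutral_duration = 15,
                            cooling_phase_duration = 10,
                            adjustment_interval = 3, thermoneutral_step = 1,
                            sustained_threshold = 1, floor_temp = 4,
                            align_tol = 1, scale = perception_scale(),
                            rules = cooling_rule_table()) {
  stopifnot(thermoneutral_duration > 0, cooling_phase_duration > 0,
            adjustment_interval > 0, thermoneutral_step > 0,
            sustained_threshold > 0, floor_temp < start_temp)
  structure(list(start_temp = start_temp,
                 thermoneutral_duration = thermoneutral_duration,
                 cooling_phase_duration = cooling_phase_duration,
                 adjustment_interval = adjustment_interval,
                 thermoneutral_step = thermoneutral_step,
                 sustained_threshold = sustained_threshold,
                 floor_temp = floor_temp, align_tol = align_tol,
                 scale = scale, rules = rules),
            class = "protocol_config")
}

#' Familiarization-session water-temperature schedule
#'
#' The fixed seven-stage guide used to expose participants to a wide
#' temperature range (32 down to 7 degC) before the individualized session.
#'
#' @return a data frame with columns `stage`, `start_min`, `end_min`,
#'   `set_temp_c`.
#' @export
familiarization_schedule <- function() {
  data.frame(stage = 1:7,
             start_min = seq(0, 48, by = 8),
             end_min = seq(8, 56, by = 8),
             set_temp_c = c(32, 22, 19, 16, 13, 10, 7))
}

#' Cooling decrement for a slider position
#'
#' Looks the slider position up in the rule table: a slider within
#' `align_tol` of a landmark (nearest landmark on ties) takes that
#' landmark's decrement; otherwise the enclosing interval's decrement
#' applies. Positions warmer than neutral at a cooling-phase end take the
#' maximum decrement.
#'
#' @param slider slider position, 0-100.
#' @param config a [protocol_config()].
#' @return the decrement in degrees Celsius.
#' @export
cooling_decrement <- function(slider, config = protocol_config()) {
  stopifnot(slider >= 0, slider <= 100)
  sc <- config$scale; rules <- config$rules
  lm_rule <- c(very_cold = "at_very_cold", cold = "at_cold", cool = "at_cool",
               neutral = "at_neutral")
  d <- abs(sc - slider)
  nearest <- names(sc)[which.min(d)]
  if (min(d) <= config$align_tol) {
    if (nearest %in% names(lm_rule)) return(unname(rules[[lm_rule[[nearest]]]]))
    return(unname(rules[["warmer_than_neutral"]]))  # warm-side landmark
  }
  if (slider > sc[["neutral"]]) return(unname(rules[["warmer_than_neutral"]]))
  if (slider > sc[["cool"]]) return(unname(rules[["cool_to_neutral"]]))
  if (slider > sc[["cold"]]) return(unname(rules[["cold_to_cool"]]))
  unname(rules[["very_cold_to_cold"]])
}

#' Initial controller state
#'
#' @param config a [protocol_config()].
#' @param start session-clock time at which the protocol starts, seconds.
#' @return a list of class `controller_state`.
#' @export
protocol_state <- function(config = protocol_config(), start = 0) {
  structure(list(phase = "pre_neutral", cooling_index = 0L,
                 set_temp = config$start_temp, phase_start = start,
                 last_adjust = start, now = start,
                 protocol_begin = NA_real_,
                 terminated = FALSE, terminated_at = NA_real_,
                 phase_log = phase_records(),
                 commands = data.frame(time = start,
                                       set_temp_c = config$start_temp)),
            class = "controller_state")
}

.latest_slider <- function(tgui, at) {
  i <- findInterval(at, tgui$time)
  if (i < 1L) return(NA_real_)
  tgui$slider[i]
}

.aligned_neutral <- function(slider, config) {
  !is.na(slider) && abs(slider - config$scale[["neutral"]]) <= config$align_tol
}

.append_phase <- function(state, kind, index, start, end) {
  ph <- state$phase_log
  state$phase_log <- phase_records(c(ph$kind, kind), c(ph$index, index),
                                   c(ph$start, start), c(ph$end, end),
                                   c(ph$set_temp_c, state$set_temp))
  state
}

.command <- function(state, time, temp, config) {
  temp <- min(max(temp, config$floor_temp), 45)
  if (temp != state$set_temp) {
    state$commands <- rbind(state$commands,
                            data.frame(time = time, set_temp_c = temp))
    state$set_temp <- temp
  }
  state
}

## earliest observable instant at which a shiver interval has strictly
## exceeded the sustained threshold: the first event time (tGUI row or
## `now`) strictly beyond onset + threshold, and after `after` (the start
## of the thermoneutral phase). NA if no interval qualifies by `now`.
.sustained_at <- function(tgui, now, threshold_s, after = -Inf) {
  rows <- tgui[tgui$time <= now, , drop = FALSE]
  if (!nrow(rows) || !any(rows$shiver == 1L)) return(NA_real_)
  cand <- sort(unique(c(rows$time, now)))
  r <- rle(rows$shiver == 1L)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    onset <- rows$time[starts[k]]
    offset <- if (ends[k] < nrow(rows)) rows$time[ends[k] + 1L] else now
    if (offset - onset > threshold_s) {
      t <- cand[cand > max(onset + threshold_s, after)]
      if (length(t)) return(t[1L])
    }
  }
  NA_real_
}

#' Advance the protocol controller
#'
#' Processes all phase transitions and adjustments due up to `now`, using
#' the tGUI rows with `time <= now`. Termination (a self-reported shiver
#' interval strictly longer than the sustained threshold) is checked first
#' and takes effect at the instant the interval exceeded the threshold.
#'
#' @param state a `controller_state` from [protocol_state()] or a previous
#'   step.
#' @param now current session-clock time, seconds; must not move backwards.
#' @param tgui a [tgui_log()] (rows after `now` are ignored).
#' @param config a [protocol_config()].
#' @return the updated `controller_state`.
#' @export
protocol_step <- function(state, now, tgui, config = protocol_config()) {
  stopifnot(inherits(state, "controller_state"))
  if (now < state$now) {
    stop("protocol_step: time moved backwards", call. = FALSE)
  }
  if (state$terminated) return(state)

  repeat {
    if (state$phase == "pre_neutral") {
      ## earliest instant in [state$now, now] at which the slider reads
      ## "Neutral" (within align_tol)
      cand <- c(state$now, tgui$time[tgui$time > state$now & tgui$time <= now])
      al <- NA_real_
      for (t in cand) {
        if (.aligned_neutral(.latest_slider(tgui, t), config)) {
          al <- t
          break
        }
      }
      due <- state$last_adjust + config$adjustment_interval * 60
      if (!is.na(al) && (al <= due || due > now)) {
        if (al > state$phase_start) {
          state <- .append_phase(state, "pretrial", NA_integer_,
                                 state$phase_start, al)
        }
        state$phase <- "thermoneutral"
        state$phase_start <- al
        state$protocol_begin <- al
        state$now <- al
      } else if (due <= now) {
        slider <- .latest_slider(tgui, due)
        if (!is.na(slider)) {
          ## participant cold -> warm the water, and vice versa
          delta <- if (slider < config$scale[["neutral"]])
            config$thermoneutral_step else -config$thermoneutral_step
          state <- .command(state, due, state$set_temp + delta, config)
        }
        state$last_adjust <- due
        state$now <- due
      } else {
        break
      }
    } else {
      term_at <- .sustained_at(tgui, now, config$sustained_threshold * 60,
                               after = state$protocol_begin)
      dur <- if (state$phase == "thermoneutral")
        config$thermoneutral_duration else config$cooling_phase_duration
      phase_end <- state$phase_start + dur * 60
      if (!is.na(term_at) && term_at <= min(phase_end, now)) {
        ## terminal (possibly partial) phase
        if (term_at > state$phase_start) {
          state <- .append_phase(state, state$phase,
                                 if (state$phase == "cooling")
                                   state$cooling_index else NA_integer_,
                                 state$phase_start, term_at)
        }
        state$terminated <- TRUE
        state$terminated_at <- term_at
        state$now <- term_at
        break
      }
      if (phase_end > now) break
      state <- .append_phase(state, state$phase,
                             if (state$phase == "cooling")
                               state$cooling_index else NA_integer_,
                             state$phase_start, phase_end)
      slider <- .latest_slider(tgui, phase_end)
      dec <- cooling_decrement(if (is.na(slider)) config$scale[["neutral"]]
                               else slider, config)
      state <- .command(state, phase_end, state$set_temp - dec, config)
      state$phase <- "cooling"
      state$cooling_index <- state$cooling_index + 1L
      state$phase_start <- phase_end
      state$now <- phase_end
    }
  }
  if (!state$terminated) state$now <- max(state$now, now)
  state
}

#' Replay a recorded tGUI stream through the controller
#'
#' Steps the state machine at every tGUI timestamp (and the phase
#' boundaries in between, which [protocol_step()] handles exactly).
#'
#' @param tgui a [tgui_log()].
#' @param config a [protocol_config()].
#' @param until optional end time, seconds; defaults to the last tGUI row.
#' @return the final `controller_state`.
#' @export
run_protocol <- function(tgui, config = protocol_config(), until = NULL) {
  state <- protocol_state(config, start = tgui$time[1L])
  times <- tgui$time
  if (!is.null(until)) times <- c(times[times < until], until)
  for (t in times) {
    state <- protocol_step(state, t, tgui, config)
    if (state$terminated) break
  }
  ## close a dangling phase at the last observed time
  if (!state$terminated && state$now > state$phase_start &&
      state$phase != "pre_neutral") {
    state <- .append_phase(state, state$phase,
                           if (state$phase == "cooling")
                             state$cooling_index else NA_integer_,
                           state$phase_start, state$now)
  }
  state
}

#' Session report
#'
#' The quantities recorded for every protocol session: the thermoneutral
#' water temperature, the shivering water temperature (set point at
#' termination), and the phase records.
#'
#' @param state a `controller_state` after the session ended.
#' @return a list of class `session_report` with elements
#'   `thermoneutral_temp_c`, `shivering_temp_c`, `terminated`,
#'   `terminated_at`, `phases`.
#' @export
session_report <- function(state) {
  ph <- state$phase_log
  i <- which(ph$kind == "thermoneutral")
  if (!length(i) && state$phase != "thermoneutral") {
    stop("session_report: thermoneutral phase not yet established",
         call. = FALSE)
  }
  tn <- if (length(i)) ph$set_temp_c[i[1L]] else state$set_temp
  structure(list(thermoneutral_temp_c = tn,
                 shivering_temp_c = state$set_temp,
                 terminated = state$terminated,
                 terminated_at = state$terminated_at,
                 phases = ph),
            class = "session_report")
}

#' @export
print.session_report <- function(x, ...) {
  cat("<session_report>\n")
  cat(sprintf("  thermoneutral water temperature: %g degC\n",
              x$thermoneutral_temp_c))
  cat(sprintf("  shivering water temperature:     %g degC\n",
              x$shivering_temp_c))
  cat(sprintf("  terminated: %s%s\n", x$terminated,
              if (x$terminated) sprintf(" at %.0f s", x$terminated_at) else ""))
  cat(sprintf("  phases: %d\n", nrow(x$phases)))
  invisible(x)
}
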