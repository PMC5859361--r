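## Seeded simulator for synthetic participants and full synthetic sessions:
## first-order-lag skin thermodynamics, a noisy perception slider, a
## probabilistic shiver self-report process, synthetic raw EMG, and a
## closed loop with the protocol controller. Every session carries its
## ground truth (shiver intervals and marker times) for recovery tests.

#' Simulated-participant model
#'
#' Each skin site follows a first-order lag toward a target coupled to the
#' water temperature: `dT/dt = (T_target - T) / tau` with
#' `T_target = baseline - gain * (32 - T_water)`. The finger gain rises by
#' `vasoconstriction_gain_factor` once the water falls below
#' `vasoconstriction_onset`, reproducing the qualitative ordering seen in
#' cold-exposure studies (finger drops exceed forearm drops exceed clavicle
#' changes). `clavicle_mode = "warming"` adds a slow positive drift once the
#' arm-to-finger gradient reaches 4 degC, emulating the supraclavicular
#' warming reported in a subset of individuals.
#'
#' The slider is `round(clip(50 + perception_slope * (mean skin -
#' perception_midpoint) + noise))`. Below `shiver_susceptibility` the
#' per-sample shiver probability rises linearly to 1 at slider 0; at or
#' below `sustained_level` the shiver flag stays on (which terminates the
#' protocol once it exceeds the sustained threshold).
#'
#' @param tau_clavicle,tau_forearm,tau_finger site time constants, minutes.
#' @param gain_clavicle,gain_forearm,gain_finger coupling gains in (0, 1]
#'   (fraction of the water-temperature change transmitted to the site);
#'   finger gain must be >= forearm gain.
#' @param baseline_clavicle,baseline_forearm,baseline_finger thermoneutral
#'   site temperatures, degC.
#' @param vasoconstriction_onset water temperature below which the finger
#'   gain is multiplied, degC.
#' @param vasoconstriction_gain_factor finger-gain multiplier (>= 1);
#'   the effective gain is capped at 1.
#' @param clavicle_mode `"cooling"`, `"warming"`, or `"flat"`.
#' @param perception_midpoint mean skin temperature mapped to slider 50,
#'   degC; defaults to the mean of the site baselines.
#' @param perception_slope slider units per degC of mean skin temperature.
#' @param perception_noise_sd slider noise standard deviation.
#' @param shiver_susceptibility slider level below which shivers occur.
#' @param sustained_level slider level at or below which shivering is
#'   continuous.
#' @param emg_burst_amplitude_ratio burst amplitude over baseline noise sd.
#' @param seed integer seed controlling all random draws of a session.
#' @return a list of class `participant_model`.
#' @export
participant_model <- function(tau_clavicle = 12, tau_forearm = 8,
                              tau_finger = 3,
                              gain_clavicle = 0.08, gain_forearm = 0.25,
                              gain_finger = 0.65,
                              baseline_clavicle = 34.5,
                              baseline_forearm = 33.5,
                              baseline_finger = 33.0,
                              vasoconstriction_onset = 26,
                              vasoconstriction_gain_factor = 1.35,
                              clavicle_mode = c("cooling", "warming", "flat"),
                              perception_midpoint = NULL,
                              perception_slope = 6,
                              perception_noise_sd = 2,
                              shiver_susceptibility = 30,
                              sustained_level = 10,
                              emg_burst_amplitude_ratio = 6,
                              seed = 1L) {
  clavicle_mode <- match.arg(clavicle_mode)
  stopifnot(tau_clavicle > 0, tau_forearm > 0, tau_finger > 0)
  gains <- c(gain_clavicle, gain_forearm, gain_finger)
  if (any(gains <= 0) || any(gains > 1)) {
    stop("participant_model: gains must lie in (0, 1]", call. = FALSE)
  }
  if (gain_finger < gain_forearm) {
    stop("participant_model: finger gain must be >= forearm gain",
         call. = FALSE)
  }
  if (is.null(perception_midpoint)) {
    perception_midpoint <- mean(c(baseline_clavicle, baseline_forearm,
                                  baseline_finger))
  }
  structure(list(tau = c(clavicle = tau_clavicle, forearm = tau_forearm,
                         finger = tau_finger),
                 gain = c(clavicle = gain_clavicle, forearm = gain_forearm,
                          finger = gain_finger),
                 baseline = c(clavicle = baseline_clavicle,
                              forearm = baseline_forearm,
                              finger = baseline_finger),
                 vasoconstriction_onset = vasoconstriction_onset,
                 vasoconstriction_gain_factor = vasoconstriction_gain_factor,
                 clavicle_mode = clavicle_mode,
                 perception_midpoint = perception_midpoint,
                 perception_slope = perception_slope,
                 perception_noise_sd = perception_noise_sd,
                 shiver_susceptibility = shiver_susceptibility,
                 sustained_level = sustained_level,
                 emg_burst_amplitude_ratio = emg_burst_amplitude_ratio,
                 seed = as.integer(seed)),
            class = "participant_model")
}

.water_baseline <- 32

## one exact exponential update per interval (water held constant within)
.skin_step <- function(temps, water, model, dt_s) {
  gain <- model$gain
  if (water < model$vasoconstriction_onset) {
    gain[["finger"]] <- min(gain[["finger"]] *
                              model$vasoconstriction_gain_factor, 1)
  }
  target <- model$baseline - gain * (.water_baseline - water)
  out <- target + (temps - target) * exp(-dt_s / (model$tau * 60))
  if (model$clavicle_mode == "warming" &&
      (temps[["forearm"]] - temps[["finger"]]) >= 4) {
    out[["clavicle"]] <- out[["clavicle"]] + 0.002 * dt_s / 30
  } else if (model$clavicle_mode == "flat") {
    out[["clavicle"]] <- temps[["clavicle"]]
  }
  out
}

#' Simulate skin temperatures for a water-temperature series
#'
#' Integrates the first-order lag model with one exact exponential update
#' per output step, holding the water temperature constant within a step
#' (zero-order hold on the preceding water sample).
#'
#' @param model a [participant_model()].
#' @param water data frame with columns `time` (seconds) and `temp_c`, or a
#'   [water_log()] (its achieved temperature is used).
#' @param step output cadence in seconds (> 0; default 30).
#' @return a [skin_log()] spanning the water series at `step` cadence,
#'   starting from the site baselines.
#' @export
simulate_skin <- function(model, water, step = 30) {
  if (!is.numeric(step) || step <= 0) {
    stop("simulate_skin: step must be > 0", call. = FALSE)
  }
  if (inherits(water, "water_log")) {
    water <- data.frame(time = water$time, temp_c = water$achieved_temp_c)
  }
  stopifnot(all(c("time", "temp_c") %in% names(water)), nrow(water) >= 1L)
  times <- seq(water$time[1L], water$time[nrow(water)], by = step)
  w_at <- stats::approx(water$time, water$temp_c, xout = times,
                        method = "constant", f = 0, rule = 2)$y
  temps <- model$baseline
  out <- matrix(NA_real_, nrow = length(times), ncol = 3L)
  out[1L, ] <- temps
  if (length(times) > 1L) {
    for (i in 2:length(times)) {
      temps <- .skin_step(temps, w_at[i - 1L], model, times[i] - times[i - 1L])
      out[i, ] <- temps
    }
  }
  skin_log(times, out[, 1L], out[, 2L], out[, 3L])
}

.slider_value <- function(mean_skin, model, noise) {
  raw <- 50 + model$perception_slope * (mean_skin - model$perception_midpoint) +
    noise
  as.integer(round(pmin(pmax(raw, 0), 100)))
}

#' Simulate perception ratings and shiver self-reports
#'
#' Produces the tGUI log for a simulated skin trajectory: one row per
#' `step` plus a row at every shiver-flag change, and the ground-truth
#' shiver intervals actually drawn.
#'
#' @param model a [participant_model()].
#' @param skin a [skin_log()].
#' @param step logging cadence, seconds (default 30).
#' @param seed optional seed overriding `model$seed`.
#' @return a list with elements `tgui` (a [tgui_log()]) and `truth`
#'   (a [shiver_events()] table with `source = "tgui"`).
#' @export
simulate_perception_and_shiver <- function(model, skin, step = 30,
                                           seed = NULL) {
  if (is.null(seed)) seed <- model$seed
  set.seed(seed)
  times <- skin$time
  mean_skin <- rowMeans(cbind(skin$clavicle_c, skin$forearm_c, skin$finger_c))
  noise <- stats::rnorm(length(times), 0, model$perception_noise_sd)
  slider <- .slider_value(mean_skin, model, noise)

  rows_t <- numeric(); rows_s <- integer(); rows_f <- integer()
  tr_on <- numeric(); tr_off <- numeric()
  flag <- 0L; shiver_until <- -Inf; sustained <- FALSE
  for (i in seq_along(times)) {
    t <- times[i]; s <- slider[i]
    if (!sustained && flag == 1L && t >= shiver_until) {
      ## close the event at its drawn end time
      rows_t <- c(rows_t, shiver_until); rows_s <- c(rows_s, s)
      rows_f <- c(rows_f, 0L)
      tr_off <- c(tr_off, shiver_until)
      flag <- 0L
    }
    if (flag == 0L) {
      if (s <= model$sustained_level) {
        sustained <- TRUE
        flag <- 1L
        tr_on <- c(tr_on, t)
      } else if (s < model$shiver_susceptibility) {
        p <- (model$shiver_susceptibility - s) / model$shiver_susceptibility
        if (stats::runif(1) < p) {
          flag <- 1L
          dur <- stats::runif(1, 5, 45)
          shiver_until <- t + dur
          tr_on <- c(tr_on, t)
        }
      }
    }
    rows_t <- c(rows_t, t); rows_s <- c(rows_s, s); rows_f <- c(rows_f, flag)
  }
  if (flag == 1L) tr_off <- c(tr_off, times[length(times)])
  ord <- order(rows_t)
  tg <- tgui_log(rows_t[ord], rows_s[ord], rows_f[ord])
  keep <- tr_off > tr_on
  list(tgui = tg, truth = shiver_events(tr_on[keep], tr_off[keep], "tgui"))
}

#' Synthesize a raw EMG trace from ground-truth shiver intervals
#'
#' Baseline Gaussian noise band-limited to the detection pass band
#' (20-400 Hz); within each truth interval the amplitude is multiplied by
#' `emg_burst_amplitude_ratio`. Deterministic under a fixed seed.
#'
#' @param truth a [shiver_events()] table of ground-truth intervals.
#' @param rate sampling rate, Hz (default 1000).
#' @param duration trace duration, seconds.
#' @param model a [participant_model()].
#' @param start_time session-clock time of the first sample.
#' @param seed optional seed overriding `model$seed`.
#' @param baseline_sd baseline noise amplitude, mV.
#' @return an [emg_recording()].
#' @export
synthesize_emg <- function(truth, rate = 1000, duration,
                           model = participant_model(), start_time = 0,
                           seed = NULL, baseline_sd = 0.01) {
  if (is.null(seed)) seed <- model$seed
  set.seed(seed)
  n <- round(duration * rate)
  noise <- stats::rnorm(n, 0, baseline_sd)
  bp <- signal::butter(2, c(20, min(400, 0.45 * rate)) / (rate / 2),
                       type = "pass")
  x <- signal::filtfilt(bp, noise)
  x <- x * (baseline_sd / stats::sd(x))  # renormalize after band-limiting
  t <- start_time + (seq_len(n) - 1L) / rate
  amp <- rep(1, n)
  for (k in seq_len(nrow(truth))) {
    amp[t >= truth$onset[k] & t < truth$offset[k]] <-
      model$emg_burst_amplitude_ratio
  }
  emg_recording(x * amp, rate = rate, start_time = start_time)
}

#' Run a full closed-loop simulated session
#'
#' Couples the protocol controller to a simulated participant: the
#' controller's set temperature drives the skin model (the achieved water
#' temperature follows the set point), the perception/shiver process feeds
#' the controller, and the session runs until termination or `max_hours`.
#' All logs are then expressed with time zero at the start of the first
#' cooling phase.
#'
#' @param model a [participant_model()].
#' @param config a [protocol_config()].
#' @param step simulation and logging cadence, seconds (default 30).
#' @param max_hours wall cap on session length (default 4); hitting it is
#'   flagged in `metadata$non_termination`, not an error.
#' @param emg whether to synthesize a raw EMG trace for the session.
#' @param seed optional seed overriding `model$seed`.
#' @return a list of class `simulated_session` with elements `bundle`
#'   (a [session_bundle()]), `truth` (list: `shiver_intervals`, `markers`,
#'   `phases`), `state` (the final `controller_state`), and `report`
#'   (the [session_report()], when available).
#' @export
run_closed_loop <- function(model = participant_model(),
                            config = protocol_config(), step = 30,
                            max_hours = 4, emg = FALSE, seed = NULL) {
  if (is.null(seed)) seed <- model$seed
  set.seed(seed)
  n_max <- ceiling(max_hours * 3600 / step)
  noise <- stats::rnorm(n_max + 1L, 0, model$perception_noise_sd)

  state <- protocol_state(config, start = 0)
  temps <- model$baseline
  times <- w_set <- numeric(n_max + 1L)
  skin_m <- matrix(NA_real_, nrow = n_max + 1L, ncol = 3L)
  rows_t <- numeric(); rows_s <- integer(); rows_f <- integer()
  tr_on <- numeric(); tr_off <- numeric()
  flag <- 0L; shiver_until <- -Inf; sustained <- FALSE
  n_used <- 0L

  for (i in 0:n_max) {
    t <- i * step
    idx <- i + 1L
    times[idx] <- t
    skin_m[idx, ] <- temps
    mean_skin <- mean(temps)
    s <- .slider_value(mean_skin, model, noise[idx])

    if (!sustained && flag == 1L && t >= shiver_until) {
      rows_t <- c(rows_t, shiver_until); rows_s <- c(rows_s, s)
      rows_f <- c(rows_f, 0L)
      tr_off <- c(tr_off, shiver_until)
      flag <- 0L
    }
    if (flag == 0L) {
      if (s <= model$sustained_level) {
        sustained <- TRUE; flag <- 1L; tr_on <- c(tr_on, t)
      } else if (s < model$shiver_susceptibility) {
        p <- (model$shiver_susceptibility - s) / model$shiver_susceptibility
        if (stats::runif(1) < p) {
          flag <- 1L
          shiver_until <- t + stats::runif(1, 5, 45)
          tr_on <- c(tr_on, t)
        }
      }
    }
    rows_t <- c(rows_t, t); rows_s <- c(rows_s, s); rows_f <- c(rows_f, flag)

    tg_now <- tgui_log(rows_t, rows_s, rows_f)
    state <- protocol_step(state, t, tg_now, config)
    w_set[idx] <- state$set_temp
    n_used <- idx
    if (state$terminated) break
    temps <- .skin_step(temps, state$set_temp, model, step)
  }
  if (flag == 1L) tr_off <- c(tr_off, times[n_used])

  truth_iv <- shiver_events(tr_on[tr_off > tr_on], tr_off[tr_off > tr_on],
                            "tgui")
  meta <- list(subject = sprintf("sim%04d", seed), seed = seed)
  if (!state$terminated) meta$non_termination <- TRUE

  ## time zero = start of the first cooling phase
  ph <- state$phase_log
  c1 <- which(ph$kind == "cooling" & ph$index == 1L)
  tn <- which(ph$kind == "thermoneutral")
  shift <- if (length(c1)) ph$start[c1[1L]]
           else if (length(tn)) ph$end[tn[1L]] else 0
  origin <- .default_origin() + 0  # wall clock of the simulated t = 0
  keep <- seq_len(n_used)
  water <- water_log(times[keep] - shift, w_set[keep], w_set[keep],
                     origin = origin)
  skin <- skin_log(times[keep] - shift, skin_m[keep, 1L], skin_m[keep, 2L],
                   skin_m[keep, 3L], origin = origin)
  ord <- order(rows_t)
  tgui <- tgui_log(rows_t[ord] - shift, rows_s[ord], rows_f[ord],
                   origin = origin)
  phases <- phase_records(ph$kind, ph$index, ph$start - shift,
                          ph$end - shift, ph$set_temp_c)
  truth_iv$onset <- truth_iv$onset - shift
  truth_iv$offset <- truth_iv$offset - shift

  emg_rec <- NULL
  if (emg) {
    span <- range(times[keep]) - shift
    emg_rec <- synthesize_emg(truth_iv, rate = 1000,
                              duration = diff(span), model = model,
                              start_time = span[1L],
                              seed = (seed + 7919L) %% .Machine$integer.max)
    attr(emg_rec, "origin") <- origin
  }
  bundle <- session_bundle(water, tgui, skin, emg_rec, phases, meta)

  grad <- vasoconstriction_gradient(skin)
  iv <- which(grad$gradient_c >= 4)
  sus_i <- which(truth_iv$offset - truth_iv$onset > 60)
  truth <- list(
    shiver_intervals = truth_iv,
    markers = c(vasoconstriction_index =
                  if (length(iv)) grad$time[iv[1L]] else NA_real_,
                shiver_onset =
                  if (nrow(truth_iv)) truth_iv$onset[1L] else NA_real_,
                sustained_shiver =
                  if (length(sus_i)) truth_iv$onset[sus_i[1L]] else NA_real_),
    phases = phases)

  report <- tryCatch(session_report(state), error = function(e) NULL)
  structure(list(bundle = bundle, truth = truth, state = state,
                 report = report),
            class = "simulated_session")
}

#' @export
print.simulated_session <- function(x, ...) {
  cat("<simulated_session>\n")
  cat(sprintf("  terminated: %s; phases: %d; shiver intervals: %d\n",
              x$state$terminated, nrow(x$truth$phases),
              nrow(x$truth$shiver_intervals)))
  if (!is.null(x$report)) {
    cat(sprintf("  thermoneutral %g degC -> shivering %g degC\n",
                x$report$thermoneutral_temp_c, x$report$shivering_temp_c))
  }
  invisible(x)
}
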