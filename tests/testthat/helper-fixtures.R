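## Shared fixtures and independent oracles.

## tiny canonical logs built in code --------------------------------------

iso0 <- function(sec) {
  format(as.POSIXct("2024-01-15 09:00:00", tz = "UTC") + sec,
         "%Y-%m-%dT%H:%M:%OS3")
}

make_water <- function(times = seq(0, 600, by = 30), set = NULL,
                       achieved = NULL) {
  if (is.null(set)) set <- rep(32, length(times))
  if (is.null(achieved)) achieved <- set + 0.1
  water_log(times, set, achieved,
            origin = as.POSIXct("2024-01-15 09:00:00", tz = "UTC"))
}

make_skin <- function(times = seq(0, 600, by = 30), clav = 34, arm = 33.5,
                      fing = 33) {
  n <- length(times)
  skin_log(times, rep_len(clav, n), rep_len(arm, n), rep_len(fing, n),
           origin = as.POSIXct("2024-01-15 09:00:00", tz = "UTC"))
}

make_tgui <- function(times = seq(0, 600, by = 30), slider = 50,
                      shiver = 0) {
  n <- length(times)
  tgui_log(times, rep_len(slider, n), rep_len(shiver, n),
           origin = as.POSIXct("2024-01-15 09:00:00", tz = "UTC"))
}

## a complete small synchronized bundle with a thermoneutral phase
make_bundle <- function(times = seq(-900, 1800, by = 30), slider = 50,
                        shiver = 0, fing = NULL) {
  n <- length(times)
  if (is.null(fing)) fing <- rep(33, n)
  session_bundle(
    water = water_log(times, rep(32, n), rep(32, n)),
    tgui = tgui_log(times, rep_len(slider, n), rep_len(shiver, n)),
    skin = skin_log(times, rep(34, n), rep(33.5, n), fing),
    phases = phase_records(c("thermoneutral", "cooling"), c(NA, 1L),
                           c(-900, 0), c(0, 600), c(32, 27))
  )
}

## independent oracles ----------------------------------------------------

## exhaustive per-sample window scan with explicit loops; the semantics of
## the detector spelled out sample by sample
oracle_detect <- function(env, rate, thresh, params = detection_params()) {
  n <- length(env)
  win <- max(round(params$window * rate), 2L)
  supra <- env > thresh
  q <- logical(n)
  for (i in seq_len(n)) {
    if (!supra[i]) next
    cnt <- 0L
    for (k in i:(i + win - 1L)) {
      if (k <= n && supra[k]) cnt <- cnt + 1L
    }
    q[i] <- (cnt / win) >= params$window_fraction
  }
  onsets <- numeric(); offsets <- numeric()
  i <- 1L
  while (i <= n) {
    if (!supra[i]) {
      i <- i + 1L
      next
    }
    j <- i
    while (j < n && supra[j + 1L]) j <- j + 1L
    qi <- NA_integer_
    for (k in i:j) {
      if (q[k]) {
        qi <- k
        break
      }
    }
    if (!is.na(qi)) {
      ## half-open: offset just past the last supra-threshold sample
      onsets <- c(onsets, (qi - 1L) / rate)
      offsets <- c(offsets, j / rate)
    }
    i <- j + 1L
  }
  ## explicit-loop merge, strict gap rule
  if (length(onsets) > 1L) {
    keep_on <- onsets[1L]; keep_off <- offsets[1L]
    m_on <- numeric(); m_off <- numeric()
    for (k in 2:length(onsets)) {
      if (onsets[k] - keep_off - params$merge_gap < -1e-9) {
        keep_off <- offsets[k]
      } else {
        m_on <- c(m_on, keep_on); m_off <- c(m_off, keep_off)
        keep_on <- onsets[k]; keep_off <- offsets[k]
      }
    }
    onsets <- c(m_on, keep_on); offsets <- c(m_off, keep_off)
  }
  data.frame(onset = onsets, offset = offsets)
}

## Spearman rho from first principles: rank both series (average ranks for
## ties) and apply the Pearson product-moment formula to the ranks
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

rms <- function(x) sqrt(mean(x^2))
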