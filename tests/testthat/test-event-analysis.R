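test_that("self-reported shiver intervals are maximal flag runs", {
  tg <- make_tgui(seq(0, 120, 30), shiver = c(0L, 0L, 1L, 1L, 0L))
  iv <- tgui_intervals(tg)
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$onset, 60)
  expect_equal(iv$offset, 120)
  expect_equal(iv$source, "tgui")

  expect_equal(nrow(tgui_intervals(make_tgui(shiver = 0L))), 0L)

  ## interval still open at log end closes at the last timestamp
  tg2 <- make_tgui(seq(0, 120, 30), shiver = c(0L, 0L, 0L, 1L, 1L))
  iv2 <- tgui_intervals(tg2)
  expect_equal(iv2$onset, 90)
  expect_equal(iv2$offset, 120)
})

test_that("event matching is greedy, chronological and tolerance-padded", {
  a <- shiver_events(c(10, 20, 30), c(12, 22, 32), "emg")
  expect_equal(match_events(a, shiver_events(c(10, 20, 30), c(12, 22, 32),
                                             "tgui"), tolerance = 0), 3L)
  ## disjoint beyond the tolerance
  b <- shiver_events(c(100, 200), c(110, 210), "tgui")
  expect_equal(match_events(a, b, tolerance = 2), 0L)
  ## expanded tGUI interval (11,17) overlaps the EMG event (10,12)
  expect_equal(match_events(shiver_events(10, 12, "emg"),
                            shiver_events(13, 15, "tgui"), tolerance = 2), 1L)
  ## one-to-one: two EMG events cannot both claim a single tGUI interval
  expect_equal(match_events(shiver_events(c(10, 11.5), c(11, 12), "emg"),
                            shiver_events(10, 12, "tgui"), tolerance = 0), 1L)
})

test_that("similarity fractions implement matched-over-count with 0/0 = 0", {
  emg4 <- shiver_events(c(0, 10, 20, 30), c(1, 11, 21, 31), "emg")
  tgui2 <- shiver_events(c(0, 10), c(1, 11), "tgui")
  r <- similarity_fractions(emg4, tgui2, tolerance = 0)
  expect_equal(r$n_matched, 2L)
  expect_equal(r$emg_fraction, 0.5)
  expect_equal(r$tgui_fraction, 1.0)

  same <- shiver_events(c(5, 15, 25), c(6, 16, 26), "emg")
  r2 <- similarity_fractions(same, same, tolerance = 0)
  expect_equal(r2$emg_fraction, 1.0)
  expect_equal(r2$tgui_fraction, 1.0)

  r3 <- similarity_fractions(emg4, shiver_events(source = "tgui"))
  expect_equal(r3$n_matched, 0L)
  expect_equal(r3$tgui_fraction, 0)
  expect_equal(r3$emg_fraction, 0)

  ## fractions always land in [0, 1]
  set.seed(5)
  for (i in 1:10) {
    k1 <- sample(0:6, 1); k2 <- sample(0:6, 1)
    mk <- function(k, src) {
      on <- sort(runif(k, 0, 100))
      if (k > 1) on <- on[c(TRUE, diff(on) > 3)]
      shiver_events(on, on + 1, src)
    }
    r <- similarity_fractions(mk(k1, "emg"), mk(k2, "tgui"))
    expect_gte(r$emg_fraction, 0); expect_lte(r$emg_fraction, 1)
    expect_gte(r$tgui_fraction, 0); expect_lte(r$tgui_fraction, 1)
    expect_lte(r$n_matched, min(r$n_emg, r$n_tgui))
  }
})

test_that("vasoconstriction gradient is forearm minus finger", {
  s <- skin_log(c(0, 30), c(34, 34), c(31, 31), c(27, 31))
  g <- vasoconstriction_gradient(s)
  expect_equal(g$gradient_c, c(4, 0))
  ## antisymmetry under channel swap
  s2 <- skin_log(c(0, 30), c(34, 34), c(27, 31), c(31, 31))
  expect_equal(vasoconstriction_gradient(s2)$gradient_c, -g$gradient_c)
})

test_that("markers fire at the documented thresholds and boundaries", {
  ## forearm fixed at 31, finger falling 0.5 degC/min from 31: the
  ## gradient first reaches 4.0 at minute 8
  times <- seq(-900, 1200, 30)
  fing <- pmax(31 - 0.5 * pmax(times, 0) / 60, 20)
  b <- make_bundle(times, fing = fing)
  b$skin <- skin_log(times, rep(34, length(times)), rep(31, length(times)),
                     fing)
  mk <- detect_markers(b)
  expect_equal(mk$time[mk$marker == "vasoconstriction_index"], 480)
  expect_false(mk$present[mk$marker == "shiver_onset"])

  ## sustained shivering needs strictly more than 60 s
  mk_at <- function(on, off) {
    sh <- as.integer(times >= on & times < off)
    b2 <- make_bundle(times, shiver = sh)
    detect_markers(b2)
  }
  m61 <- mk_at(120, 181)   # closes at next sample, 210: duration 90
  expect_true(m61$present[m61$marker == "sustained_shiver"])
  expect_equal(m61$time[m61$marker == "sustained_shiver"], 120)
  m60 <- mk_at(120, 180)   # flag rows at 120, 150; closes at 180: 60 s
  expect_false(m60$present[m60$marker == "sustained_shiver"])
  expect_true(m60$present[m60$marker == "shiver_onset"])
  expect_equal(m60$time[m60$marker == "shiver_onset"], 120)
})

test_that("markers are monotone in their thresholds", {
  sim <- run_closed_loop(participant_model(seed = 8))
  m1 <- detect_markers(sim$bundle, gradient_threshold = 3)
  m2 <- detect_markers(sim$bundle, gradient_threshold = 4.5)
  t1 <- m1$time[m1$marker == "vasoconstriction_index"]
  t2 <- m2$time[m2$marker == "vasoconstriction_index"]
  if (m1$present[1L] && m2$present[1L]) expect_gte(t2, t1)

  m3 <- detect_markers(sim$bundle, sustained_threshold = 30)
  m4 <- detect_markers(sim$bundle, sustained_threshold = 90)
  t3 <- m3$time[m3$marker == "sustained_shiver"]
  t4 <- m4$time[m4$marker == "sustained_shiver"]
  if (m3$present[3L] && m4$present[3L]) expect_gte(t4, t3)
})

test_that("thermoneutral exclusion applies the strict 4 degC rule", {
  times <- seq(-900, 600, 30)
  mk_b <- function(grad_at_end) {
    fing <- rep(31, length(times))
    fing[times <= 0] <- 31 - (grad_at_end - 0)  # forearm 31 everywhere
    b <- make_bundle(times)
    b$skin <- skin_log(times, rep(34, length(times)), rep(31, length(times)),
                       31 - ifelse(times <= 0, grad_at_end, 0))
    b
  }
  expect_true(thermoneutral_exclusion(mk_b(4.5))$excluded)
  expect_false(thermoneutral_exclusion(mk_b(4.0))$excluded)   # strict >
  expect_false(thermoneutral_exclusion(mk_b(1.0))$excluded)

  b_nophase <- make_bundle()
  b_nophase$phases <- phase_records()
  expect_error(thermoneutral_exclusion(b_nophase), "thermoneutral")
})

test_that("relative skin temperatures are anchored at thermoneutral end", {
  times <- seq(-900, 600, 30)
  fing <- 30 - 9.5 * pmax(times, 0) / 600
  fing <- pmax(fing, 20.5)
  b <- make_bundle(times)
  b$skin <- skin_log(times, rep(34, length(times)), rep(33, length(times)),
                     fing)
  rel <- relative_skin_temps(b)
  expect_equal(rel$d_finger_c[rel$time == 0], 0)
  expect_equal(rel$d_clavicle_c[rel$time == 0], 0)
  expect_equal(rel$d_finger_c[rel$time == 600], -9.5)
  ## shift invariance: adding a constant offset leaves deltas unchanged
  b2 <- b
  b2$skin <- skin_log(times, b$skin$clavicle_c + 2, b$skin$forearm_c + 2,
                      b$skin$finger_c + 2)
  rel2 <- relative_skin_temps(b2)
  expect_equal(rel2$d_finger_c, rel$d_finger_c)
  ## the gradient column stays absolute
  expect_equal(rel$gradient_c, b$skin$forearm_c - b$skin$finger_c)
})

test_that("perception correlations match a first-principles rank formula", {
  g <- data.frame(time = 1:20, slider = 1:20,
                  clavicle_c = 20 + (1:20) / 10,
                  forearm_c = 40 - (1:20) / 10,
                  finger_c = rep(30, 20))
  g$gradient_c <- g$forearm_c - g$finger_c
  pc <- perception_correlations(g)
  expect_equal(pc$rho[pc$channel == "clavicle_c"], 1)
  expect_equal(pc$rho[pc$channel == "forearm_c"], -1)
  expect_false(pc$defined[pc$channel == "finger_c"])  # constant series

  set.seed(13)
  g2 <- data.frame(slider = sample(1:10), clavicle_c = rnorm(10),
                   forearm_c = rnorm(10), finger_c = rnorm(10))
  pc2 <- perception_correlations(g2)
  for (ch in c("clavicle_c", "forearm_c", "finger_c")) {
    expect_equal(pc2$rho[pc2$channel == ch],
                 oracle_spearman(g2$slider, g2[[ch]]))
  }

  tiny <- data.frame(slider = c(1, 2), clavicle_c = c(1, 2),
                     forearm_c = c(1, 2), finger_c = c(1, 2))
  expect_true(all(!perception_correlations(tiny)$defined))
})
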