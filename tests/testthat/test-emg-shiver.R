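rate <- 1000

test_that("band-pass plus notch has the designed frequency response", {
  t <- seq(0, 10, by = 1 / rate)
  probe <- function(freq) {
    x <- emg_recording(sin(2 * pi * freq * t), rate = rate)
    rms(preprocess_emg(x)$signal) / rms(x$signal)
  }
  expect_lt(probe(60), 0.05)    # notch removes mains hum
  expect_lt(probe(5), 0.10)     # below the pass band
  expect_gt(probe(100), 0.90)   # inside the pass band
  expect_lt(probe(100), 1.10)

  slow <- emg_recording(sin(2 * pi * 5 * seq(0, 1, by = 1 / 500)), rate = 500)
  expect_error(preprocess_emg(slow), "rate")
})

test_that("Teager-Kaiser operator matches its closed forms", {
  expect_equal(tkeo(rep(3.7, 10)), rep(0, 10))

  ## x[n] = 2 cos(pi n / 2): psi = A^2 sin^2(w) = 4 at interior samples
  x <- 2 * cos(pi * (0:19) / 2)
  expect_equal(tkeo(x), rep(4, 20))

  ## general sinusoid identity at another frequency
  w <- 0.3
  xs <- 1.5 * cos(w * (0:99))
  expect_equal(tkeo(xs)[2:99], rep(1.5^2 * sin(w)^2, 98), tolerance = 1e-12)

  ## homogeneity: scaling input by k scales psi by k^2
  set.seed(7)
  z <- rnorm(50)
  expect_equal(tkeo(3 * z), 9 * tkeo(z), tolerance = 1e-12)

  expect_error(tkeo(c(1, 2)), "3 samples")
  expect_equal(length(tkeo(rnorm(100))), 100L)
})

test_that("envelope rectifies and preserves DC", {
  expect_equal(emg_envelope(rep(0, 1000), rate), rep(0, 1000))
  env_c <- emg_envelope(rep(0.8, 2000), rate)
  expect_equal(env_c[500:1500], rep(0.8, 1001), tolerance = 1e-6)
  set.seed(1)
  z <- rnorm(1500)
  expect_equal(emg_envelope(z, rate), emg_envelope(-z, rate))
})

test_that("baseline statistics select quiet segments and flag degeneracy", {
  expect_warning(bs <- baseline_stats(rep(1, 6000), rate), "degenerate")
  expect_equal(bs$mu, 1)
  expect_equal(bs$sigma, 0)
  expect_true(bs$degenerate)

  ## explicit segment: mean/sd match direct computation
  seg_vals <- rep(c(1, 2, 3, 2, 1), length.out = 5000)
  env <- c(seg_vals, rep(10, 3000))
  bs2 <- baseline_stats(env, rate, segment = c(0, 5))
  expect_equal(bs2$mu, mean(seg_vals))
  expect_equal(bs2$sigma, sd(seg_vals))

  ## auto-selection lands inside the quiet region of a quiet-then-bursty
  ## trace, matching an explicit variance scan
  set.seed(42)
  quiet <- rnorm(8000, 0, 0.01)
  bursty <- rnorm(4000, 0, 1)
  env3 <- abs(c(quiet, bursty))
  bs3 <- baseline_stats(env3, rate)
  expect_lte(bs3$segment[2L], 8)
  win <- 5 * rate
  vars <- vapply(1:(length(env3) - win + 1L),
                 function(i) var(env3[i:(i + win - 1L)]), 0)
  expect_equal(bs3$segment[1L] * rate + 1L, which.min(vars))

  expect_error(baseline_stats(rnorm(100), rate), "shorter")
})

test_that("threshold is mu + J * sigma", {
  expect_equal(shiver_threshold(list(mu = 0, sigma = 1)), 15)
  expect_equal(shiver_threshold(list(mu = 2, sigma = 0.5),
                                detection_params(J = 15)), 9.5)
  expect_equal(shiver_threshold(list(mu = 3, sigma = 0)), 3)
  expect_equal(shiver_threshold(list(mu = 0, sigma = 1),
                                detection_params(J = 7)), 7)
})

test_that("event detection follows the sliding-window onset criterion", {
  ## constant sub-threshold envelope: nothing detected
  expect_equal(nrow(detect_events(rep(0.1, 5000), rate, 1)), 0L)

  ## single 300 ms rectangular pulse: one event at the pulse (+/- 1 sample)
  env <- rep(0, 5000)
  env[2001:2300] <- 2
  ev <- detect_events(env, rate, 1)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$onset, 2.000, tolerance = 1.5e-3)
  expect_equal(ev$offset, 2.300, tolerance = 1.5e-3)

  ## isolated 1 ms blip: 1/250 < 10%, no event
  env2 <- rep(0, 5000)
  env2[2500] <- 2
  expect_equal(nrow(detect_events(env2, rate, 1)), 0L)
})

test_that("detector agrees exactly with the brute-force window scan", {
  set.seed(11)
  for (rep_i in 1:12) {
    n <- sample(2000:8000, 1)
    env <- abs(rnorm(n, 0, 0.1))
    ## plant a few random rectangular bursts of varied width
    for (b in seq_len(sample(0:4, 1))) {
      s <- sample(n - 600, 1)
      env[s:(s + sample(c(5, 40, 120, 400), 1))] <- runif(1, 1.5, 3)
    }
    thr <- 1
    got <- detect_events(env, rate, thr)
    want <- oracle_detect(env, rate, thr)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$onset, want$onset)
    expect_equal(got$offset, want$offset)
  }
})

test_that("merging respects the strict 50 ms gap rule and is idempotent", {
  ## 40 ms gap: merged into one event
  m1 <- merge_events(shiver_events(c(0, 0.140), c(0.100, 0.300)))
  expect_equal(nrow(m1), 1L)
  expect_equal(m1$onset, 0)
  expect_equal(m1$offset, 0.300)

  ## exactly 50 ms: strict inequality keeps two events
  m2 <- merge_events(shiver_events(c(0, 0.150), c(0.100, 0.300)))
  expect_equal(nrow(m2), 2L)

  ## idempotence on random event sets
  set.seed(3)
  for (i in 1:20) {
    k <- sample(1:12, 1)
    gaps <- runif(k, 0, 0.2)
    durs <- runif(k, 0.005, 0.15)
    on <- cumsum(gaps + c(0, durs[-k]))
    ev <- shiver_events(on, on + durs)
    m <- merge_events(ev)
    expect_identical(merge_events(m), m)
    if (nrow(m) > 1L) {
      expect_true(all(m$onset[-1] - m$offset[-nrow(m)] >= 0.05))
    }
  }

  expect_error(merge_events(shiver_events(c(0, 0.05), c(0.2, 0.3))),
               "non-overlapping")
})

test_that("detection is invariant to positive rescaling of the raw trace", {
  truth <- shiver_events(c(6, 8.5), c(6.6, 9.1), "emg")
  emg <- synthesize_emg(truth, rate, 10, participant_model(seed = 9),
                        seed = 9)
  d1 <- detect_shiver(emg)
  emg_scaled <- emg
  emg_scaled$signal <- emg$signal * 37.5
  d2 <- detect_shiver(emg_scaled)
  expect_equal(d2$events$onset, d1$events$onset)
  expect_equal(d2$events$offset, d1$events$offset)
})

test_that("detected events are sorted, non-overlapping, gap-separated", {
  set.seed(21)
  truth <- shiver_events(c(6, 8, 9.5, 12), c(6.4, 8.6, 10.2, 12.8), "emg")
  emg <- synthesize_emg(truth, rate, 14, participant_model(seed = 21),
                        seed = 21)
  ev <- detect_shiver(emg)$events
  expect_true(all(ev$onset < ev$offset))
  if (nrow(ev) > 1L) {
    expect_true(all(diff(ev$onset) > 0))
    gaps <- ev$onset[-1] - ev$offset[-nrow(ev)]
    expect_true(all(gaps >= detection_params()$merge_gap))
  }
})

test_that("events round-trip through the CSV format", {
  ev <- shiver_events(c(1.25, 7.5), c(2, 9.125), "emg")
  path <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, path)
  back <- read_events(path)
  expect_equal(back$onset, ev$onset)
  expect_equal(back$offset, ev$offset)
  expect_equal(back$source, ev$source)
})
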