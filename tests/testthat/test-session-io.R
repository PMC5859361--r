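test_that("canonical water log parses and validates", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_iso,set_temp_c,achieved_temp_c",
               paste0(iso0(0), ",32,32.1"),
               paste0(iso0(30), ",32,32.0"),
               paste0(iso0(60), ",29,31.2")), path)
  w <- read_water_log(path)
  expect_s3_class(w, "water_log")
  expect_equal(nrow(w), 3L)
  expect_equal(w$time, c(0, 30, 60))
  expect_equal(w$set_temp_c[3L], 29)

  ## missing columns are named in the error
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_iso", iso0(0)), path2)
  expect_error(read_water_log(path2), "set_temp_c, achieved_temp_c")

  ## non-monotone timestamps rejected
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_iso,set_temp_c,achieved_temp_c",
               paste0(iso0(30), ",32,32"),
               paste0(iso0(0), ",32,32")), path3)
  expect_error(read_water_log(path3), "strictly increasing")
})

test_that("tGUI reader keeps the last row per duplicate timestamp", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_iso,slider,shiver",
               paste0(iso0(0), ",50,0"),
               paste0(iso0(0), ",49,0"),
               paste0(iso0(30), ",49,0")), path)
  tg <- read_tgui_log(path)
  expect_equal(nrow(tg), 2L)
  expect_equal(tg$slider[1L], 49L)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_iso,slider,shiver", paste0(iso0(0), ",101,0")), bad)
  expect_error(read_tgui_log(bad), "slider")

  ## a 31-min log at 30 s cadence has 63 scheduled samples
  full <- withr::local_tempfile(fileext = ".csv")
  times <- seq(0, 31 * 60, by = 30)
  writeLines(c("time_iso,slider,shiver",
               paste0(iso0(times), ",50,0")), full)
  expect_equal(nrow(read_tgui_log(full)), 63L)
})

test_that("every canonical format round-trips bit-for-bit on fields", {
  dir <- withr::local_tempdir()
  w <- make_water(set = 32 - seq(0, 20) * 0.37, achieved = 32 - seq(0, 20) * 0.371)
  write_water_log(w, file.path(dir, "w.csv"))
  w2 <- read_water_log(file.path(dir, "w.csv"))
  expect_equal(w2$time, w$time, tolerance = 1e-9)
  expect_equal(w2$set_temp_c, w$set_temp_c, tolerance = 1e-9)
  expect_equal(w2$achieved_temp_c, w$achieved_temp_c, tolerance = 1e-9)

  ## device-dialect round trip
  write_water_log(w, file.path(dir, "wb.tsv"), dialect = "blanketrol")
  wb <- read_water_log(file.path(dir, "wb.tsv"), dialect = "blanketrol")
  expect_equal(wb$time, w$time, tolerance = 1e-9)
  expect_equal(wb$set_temp_c, w$set_temp_c, tolerance = 1e-9)

  tg <- make_tgui(slider = rep(c(50L, 42L, 31L), length.out = 21),
                  shiver = rep(c(0L, 1L, 0L), length.out = 21))
  write_tgui_log(tg, file.path(dir, "t.csv"))
  tg2 <- read_tgui_log(file.path(dir, "t.csv"))
  expect_equal(tg2$slider, tg$slider)
  expect_equal(tg2$shiver, tg$shiver)
  expect_equal(tg2$time, tg$time, tolerance = 1e-9)

  s <- skin_log(seq(0, 300, 30), 34 - (0:10) / 100, 33.5 - (0:10) / 50,
                33 - (0:10) / 10,
                origin = as.POSIXct("2024-01-15 09:00:00", tz = "UTC"))
  write_skin_log(s, file.path(dir, "s.csv"))
  s2 <- read_skin_log(file.path(dir, "s.csv"))
  for (ch in c("clavicle_c", "forearm_c", "finger_c")) {
    expect_equal(s2[[ch]], s[[ch]], tolerance = 1e-9)
  }

  e <- emg_recording(sin(seq_len(500)) * 0.05, rate = 1000, start_time = 0,
                     origin = as.POSIXct("2024-01-15 09:00:00", tz = "UTC"))
  write_emg(e, file.path(dir, "e.csv"))
  e2 <- read_emg(file.path(dir, "e.csv"))
  expect_equal(e2$signal, e$signal, tolerance = 1e-9)
  expect_equal(e2$rate, 1000)
})

test_that("LabChart-style exports are read past the header block", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Interval=\t30 s", "ChannelTitle=\tClav\tArm\tFinger",
               "Range=\t40 C\t40 C\t40 C",
               paste(c(0, 34.0, 33.5, 33.0), collapse = "\t"),
               paste(c(30, 33.9, 33.4, 32.5), collapse = "\t")), path)
  s <- read_skin_log(path, dialect = "labchart")
  expect_equal(nrow(s), 2L)
  expect_equal(s$finger_c, c(33.0, 32.5))
})

test_that("synchronization is a pure time shift anchored at cooling start", {
  origin <- as.POSIXct("2024-01-15 09:00:00", tz = "UTC")
  w <- make_water(seq(0, 3600, 30))
  tg <- make_tgui(seq(0, 3600, 30))
  s <- make_skin(seq(0, 3600, 30))
  cooling_start <- origin + 1800
  b <- synchronize_session(w, tg, s, cooling_start = cooling_start)
  expect_equal(b$skin$time[1L], -1800)
  ## sample recorded 5 min before cooling start sits at -300 s
  expect_equal(b$skin$time[b$skin$time == -300], -300)
  expect_equal(diff(b$water$time), diff(w$time))

  ## logs starting exactly at cooling start have min time 0
  b0 <- synchronize_session(w, tg, s, cooling_start = origin)
  expect_equal(min(b0$water$time), 0)
  expect_equal(min(b0$tgui$time), 0)

  expect_error(
    synchronize_session(w, tg, s, cooling_start = origin + 7200),
    "water")
})

test_that("session directories round-trip through write/read", {
  sim <- run_closed_loop(participant_model(seed = 4))
  dir <- withr::local_tempdir()
  write_session(sim$bundle, dir)
  back <- read_session(dir)
  expect_equal(back$water$time, sim$bundle$water$time, tolerance = 1e-3)
  expect_equal(back$skin$finger_c, sim$bundle$skin$finger_c,
               tolerance = 1e-9)
  expect_equal(back$tgui$shiver, sim$bundle$tgui$shiver)
  expect_equal(as.data.frame(back$phases)[c("kind", "start", "end")],
               as.data.frame(sim$bundle$phases)[c("kind", "start", "end")],
               tolerance = 1e-3)
  ## markers recomputed from the re-read session match the generator truth
  mk <- detect_markers(back)
  expect_equal(mk$time[mk$marker == "sustained_shiver"],
               unname(sim$truth$markers[["sustained_shiver"]]),
               tolerance = 1e-3)
})

test_that("common-grid resampling interpolates without extrapolating", {
  times <- seq(0, 300, 30)
  b <- session_bundle(
    water = make_water(times),
    tgui = tgui_log(times + 60, rep(50L, length(times)),
                    rep(0L, length(times))),
    ## finger 30 -> 29 over the first 30 s, then steady
    skin = skin_log(c(0, 30, 300), c(34, 34, 34), c(33.5, 33.5, 33.5),
                    c(30, 29, 29))
  )
  g <- resample_common_grid(b, step = 15)
  expect_equal(g$finger_c[g$time == 15], 29.5)
  ## before the first tGUI sample the cell is missing, not zero
  expect_true(is.na(g$slider[g$time == 0]))
  expect_false(is.na(g$slider[g$time == 60]))

  ## a linear ramp is recovered exactly at any step
  ramp <- skin_log(seq(0, 300, 30), 34 - seq(0, 300, 30) / 1000,
                   rep(33.5, 11), 33 - seq(0, 300, 30) / 100)
  b2 <- session_bundle(make_water(seq(0, 300, 30)),
                       make_tgui(seq(0, 300, 30)), ramp)
  g2 <- resample_common_grid(b2, step = 7.5)
  expect_equal(g2$finger_c, 33 - g2$time / 100, tolerance = 1e-12)

  ## resampling a stream onto its own timestamps returns it exactly
  g3 <- resample_common_grid(b2, step = 30)
  expect_equal(g3$finger_c, ramp$finger_c, tolerance = 1e-12)

  expect_error(resample_common_grid(b2, step = -1), "step")
})

test_that("gap flagging records gaps over twice the nominal cadence", {
  w <- water_log(c(0, 30, 120, 150), rep(32, 4), rep(32, 4))
  gaps <- attr(w, "gaps")
  expect_equal(nrow(gaps), 1L)
  expect_equal(gaps$after_time, 30)
  expect_equal(gaps$gap_s, 90)
})
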