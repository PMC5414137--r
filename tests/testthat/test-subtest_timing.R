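test_that("movement onset backtracks the >=3 mm/frame run before the crossing", {
  ds <- function(x) structure(x, class = "distance_series")
  # hand-traced example: crossing at frame 7, run breaks at the 1-mm step
  expect_identical(detect_start(ds(c(0, 0, 0, 1, 5, 40, 80, 129, 130)),
                                127, "exceeds"), 4L)
  # monotone series never crossing the threshold
  expect_error(detect_start(ds(seq(0, 100, by = 5)), 127, "exceeds"),
               class = "mjt_start_not_detected")
  # displacement of exactly 3 mm/frame is inclusive: onset at the first
  # moving frame
  expect_identical(detect_start(ds(seq(0, 150, by = 3)), 127, "exceeds"), 1L)
  # falls_below mirrors the rule
  expect_identical(detect_start(ds(c(100, 100, 96, 90, 80, 60, 50)),
                                63.5, "falls_below"), 2L)
  # crossing reached with a sub-3 mm step (no onset run): start falls on
  # the crossing frame, with a warning
  expect_warning(sf <- detect_start(ds(c(126, 126.5, 128, 129)), 127,
                                    "exceeds"), "instant jump")
  expect_identical(sf, 2L)
})

test_that("distance-series gaps are interpolated up to 5 frames, then error", {
  ds <- function(x) structure(x, class = "distance_series")
  x <- c(0, 0, 10, 20, NA, NA, 50, 60, 130, 131)
  expect_identical(detect_start(ds(x), 127, "exceeds"), 2L)
  x_long <- c(0, 0, 10, 20, NA, NA, NA, NA, NA, NA, 90, 100, 130, 131)
  expect_error(detect_start(ds(x_long), 127, "exceeds"),
               class = "mjt_gap_too_long")
})

test_that("card and feeding start detection share one engine (threshold swap)", {
  sim <- simulate_recording(card_script(seed = 3))
  rec <- sim$recording; cal <- sim$calibration
  tb <- detect_table(rec$frames[[1]]$depth, cal)
  series <- distance_series(rec, list(type = "edge"), tb, NULL, cal)
  s127 <- detect_start(series, 127, "exceeds")
  s147 <- detect_start(series, 147, "exceeds")
  # both crossings sit on the same approach run, so both backtrack to the
  # same movement onset
  expect_identical(s127, s147)
})

test_that("each runner recovers its scripted times end to end", {
  for (st in c("card", "feeding", "stacking")) {
    sim <- simulate_recording(default_script(st, seed = 42))
    gt <- sim$ground_truth
    res <- run_subtest(sim$recording, st, sim$calibration)
    expect_lte(abs(res$start_frame - gt$movement_onset_frame), 1)
    expect_lte(abs(res$end_frame - gt$end_frame), 2)
    expect_lte(abs(res$total_s - gt$total_s), 0.1)
    expect_equal(res$total_s, (res$end_frame - res$start_frame) / 30)
    n_events <- if (st == "stacking") 4L else 5L
    expect_length(res$events, n_events)
  }
})

test_that("truncation before the finish gives 'incomplete', never a time", {
  sim <- simulate_recording(card_script(seed = 8))
  rec <- sim$recording
  short <- mjt_recording(rec$frames[seq_len(180)], rec$frame_rate)
  err <- tryCatch(run_card_turning(short, sim$calibration), error = identity)
  expect_s3_class(err, "mjt_incomplete")
  expect_match(conditionMessage(err), "of 5 cards")

  sim2 <- simulate_recording(stacking_script(seed = 8))
  short2 <- mjt_recording(sim2$recording$frames[seq_len(90)],
                          sim2$recording$frame_rate)
  expect_error(run_stacking_checkers(short2, sim2$calibration),
               class = "mjt_incomplete")

  sim3 <- simulate_recording(feeding_script(seed = 8))
  short3 <- mjt_recording(sim3$recording$frames[seq_len(150)],
                          sim3$recording$frame_rate)
  expect_error(run_simulated_feeding(short3, sim3$calibration),
               class = "mjt_incomplete")
})

test_that("the state machines are absorbing: appended static frames change nothing", {
  sim <- simulate_recording(card_script(seed = 21, noise_depth_mm = 0,
                                        noise_rgb = 0))
  rec <- sim$recording
  res1 <- run_card_turning(rec, sim$calibration)
  last <- rec$frames[[length(rec$frames)]]
  extra <- lapply(seq_len(40), function(i)
    rgbd_frame(last$rgb, last$depth, length(rec$frames) + i - 1L))
  rec2 <- mjt_recording(c(rec$frames, extra), rec$frame_rate)
  res2 <- run_card_turning(rec2, sim$calibration)
  expect_identical(res1$start_frame, res2$start_frame)
  expect_identical(res1$end_frame, res2$end_frame)
  expect_identical(res1$events, res2$events)
})

test_that("identical recordings give bit-identical results (determinism)", {
  sim_a <- simulate_recording(feeding_script(seed = 5))
  sim_b <- simulate_recording(feeding_script(seed = 5))
  res_a <- run_simulated_feeding(sim_a$recording, sim_a$calibration)
  res_b <- run_simulated_feeding(sim_b$recording, sim_b$calibration)
  res_a$diagnostics <- res_b$diagnostics <- NULL
  expect_identical(res_a, res_b)
})

test_that("end latency correction back-dates the card end frame", {
  sim <- simulate_recording(card_script(seed = 30))
  res0 <- run_card_turning(sim$recording, sim$calibration)
  res14 <- run_card_turning(sim$recording, sim$calibration,
                            mjt_config(end_latency_correction = 14))
  expect_identical(res14$end_frame, res0$end_frame - 14L)
})
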