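# Evaluation harnesses: end-to-end timing-recovery sweeps over simulated
# recordings, used by the test suite and the acceptance script.

#' Draw a randomized scene script
#'
#' Jitters the movement-onset frame, event schedule and depth-noise level
#' of the default script for a subtest, using the supplied RNG seed for
#' both the schedule and the rendering. Event pacing stays within the
#' range of real completion times (roughly 5-9 s per subtest at 30 fps).
#'
#' @param subtest `"card"`, `"feeding"` or `"stacking"`.
#' @param seed Integer seed.
#' @param noise_depth_max Depth noise SD is drawn uniformly from
#'   (0.5, `noise_depth_max`) mm (default 3).
#' @return A [scene_script()].
#' @export
random_script <- function(subtest, seed, noise_depth_max = 3) {
  set.seed(seed)
  onset <- sample(16:25, 1)
  sigma <- runif(1, 0.5, noise_depth_max)
  if (subtest == "card") {
    flips <- onset + sample(25:33, 1) + c(0, cumsum(sample(26:36, 4, TRUE)))
    card_script(seed = seed, onset_frame = onset, flip_frames = flips,
                noise_depth_mm = sigma)
  } else if (subtest == "feeding") {
    drops <- onset + sample(28:36, 1) + c(0, cumsum(sample(28:36, 4, TRUE)))
    feeding_script(seed = seed, onset_frame = onset, drop_frames = drops,
                   noise_depth_mm = sigma)
  } else {
    places <- onset + sample(18:24, 1) + c(0, cumsum(sample(16:22, 3, TRUE)))
    stacking_script(seed = seed, onset_frame = onset, place_frames = places,
                    noise_depth_mm = sigma)
  }
}

#' End-to-end timing recovery sweep
#'
#' Simulates `n_per_subtest` randomized recordings per subtest, runs the
#' full detection pipeline on each, and tabulates detected vs ground-truth
#' start and end frames.
#'
#' @param n_per_subtest Recordings per subtest (default 20).
#' @param seed Master seed; per-recording seeds are derived from it.
#' @param noise_depth_max Upper bound of the depth noise SD in mm.
#' @param subtests Which subtests to sweep.
#' @param config An [mjt_config()].
#' @return Data frame with one row per recording: `subtest`, `seed`,
#'   ground-truth and detected start/end frames, `start_err` and
#'   `end_err` (frames), `total_err_s` (seconds), and `error` (a message
#'   when the pipeline failed, else `NA`).
#' @export
timing_recovery_sweep <- function(n_per_subtest = 20, seed = 1,
                                  noise_depth_max = 3,
                                  subtests = c("card", "feeding", "stacking"),
                                  config = mjt_config()) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max %/% 2,
                      n_per_subtest * length(subtests))
  rows <- list()
  k <- 0L
  for (st in subtests) for (i in seq_len(n_per_subtest)) {
    k <- k + 1L
    scr <- random_script(st, seeds[k], noise_depth_max)
    sim <- simulate_recording(scr, config)
    gt <- sim$ground_truth
    res <- tryCatch(run_subtest(sim$recording, st, sim$calibration, config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      rows[[k]] <- data.frame(subtest = st, seed = seeds[k],
                              gt_start = gt$movement_onset_frame,
                              det_start = NA_integer_,
                              gt_end = gt$end_frame, det_end = NA_integer_,
                              start_err = NA_real_, end_err = NA_real_,
                              total_err_s = NA_real_,
                              error = conditionMessage(res))
    } else {
      fr <- sim$recording$frame_rate
      rows[[k]] <- data.frame(subtest = st, seed = seeds[k],
                              gt_start = gt$movement_onset_frame,
                              det_start = res$start_frame,
                              gt_end = gt$end_frame, det_end = res$end_frame,
                              start_err = res$start_frame -
                                gt$movement_onset_frame,
                              end_err = res$end_frame - gt$end_frame,
                              total_err_s = res$total_s - gt$total_s,
                              error = NA_character_)
    }
  }
  do.call(rbind, rows)
}
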