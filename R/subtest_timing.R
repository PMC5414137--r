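# The three subtest state machines: shared movement-onset start detection,
# per-subtest event accumulation and finish rules, SubtestResult assembly.

#' Movement-onset start detection
#'
#' Timing starts at the movement onset: find the first frame `c` at which
#' the distance series satisfies the crossing condition (exceeds or falls
#' below the subtest threshold), then scan backwards from `c` through the
#' contiguous run of frames whose per-frame displacement toward the target
#' is at least 3 mm/frame (inclusive); the earliest frame of that run is
#' the start. Hand-absent gaps of up to `max_gap_frames` are linearly
#' interpolated first; longer gaps are an error.
#'
#' @param series A [distance_series()] (numeric, `NA` at gaps).
#' @param crossing_threshold_mm Crossing threshold in mm.
#' @param crossing_direction `"exceeds"` or `"falls_below"`.
#' @param onset_mm_per_frame Minimum sustained displacement (default 3).
#' @param config An [mjt_config()] (supplies `max_gap_frames`).
#' @return 0-based start frame.
#' @export
detect_start <- function(series, crossing_threshold_mm,
                         crossing_direction = c("exceeds", "falls_below"),
                         onset_mm_per_frame = 3, config = mjt_config()) {
  crossing_direction <- match.arg(crossing_direction)
  d <- interpolate_gaps(as.numeric(series), config$max_gap_frames)
  hit <- if (crossing_direction == "exceeds") d > crossing_threshold_mm
         else d < crossing_threshold_mm
  hit[is.na(hit)] <- FALSE
  if (!any(hit))
    mjt_stop("subtest start not detected: crossing condition never satisfied",
             "mjt_start_not_detected")
  c_idx <- which(hit)[1]                       # 1-based position in series
  disp <- c(NA, diff(d))
  if (crossing_direction == "falls_below") disp <- -disp
  k <- c_idx
  while (k > 1 && !is.na(disp[k]) && disp[k] >= onset_mm_per_frame) k <- k - 1L
  start_idx <- if (k == c_idx) {
    warning("instant jump across the crossing threshold; start set to the crossing frame")
    c_idx
  } else k + 1L
  start_idx - 1L                               # 0-based frame
}

# internal: linear interpolation of interior NA runs of length <= max_gap;
# longer interior runs raise an error. Leading/trailing NAs are left as is.
interpolate_gaps <- function(d, max_gap) {
  if (!anyNA(d)) return(d)
  n <- length(d)
  ok <- which(!is.na(d))
  if (length(ok) < 2L) return(d)
  r <- rle(is.na(d))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    if (starts[i] == 1L || ends[i] == n) next  # leading/trailing gap
    if (r$lengths[i] > max_gap)
      mjt_stop(sprintf("hand lost for %d consecutive frames (max %d)",
                       r$lengths[i], max_gap), "mjt_gap_too_long")
    span <- starts[i]:ends[i]
    d[span] <- approx(x = c(starts[i] - 1L, ends[i] + 1L),
                      y = d[c(starts[i] - 1L, ends[i] + 1L)],
                      xout = span)$y
  }
  d
}

# internal: shared scaffolding for the three runners
new_subtest_result <- function(subtest, start_frame, end_frame, frame_rate,
                               events, diagnostics = list()) {
  structure(list(subtest = subtest,
                 start_frame = as.integer(start_frame),
                 end_frame = as.integer(end_frame),
                 start_s = start_frame / frame_rate,
                 end_s = end_frame / frame_rate,
                 total_s = (end_frame - start_frame) / frame_rate,
                 events = as.integer(events),
                 diagnostics = diagnostics),
            class = "subtest_result")
}

#' @export
print.subtest_result <- function(x, ...) {
  cat(sprintf("<subtest_result> %s: start %.3f s (frame %d), end %.3f s (frame %d), total %.3f s\n",
              x$subtest, x$start_s, x$start_frame, x$end_s, x$end_frame,
              x$total_s))
  if (length(x$events))
    cat("  events at frames:", paste(x$events, collapse = ", "), "\n")
  invisible(x)
}

#' Run the Card Turning subtest on a recording
#'
#' Detects the table in the first frame, tracks the hand, starts timing at
#' the movement onset preceding the 127 mm edge-distance crossing (the
#' distance at which the distal hand crosses the proximal card edge), and
#' accumulates green-marker tracks; timing stops at the first frame at
#' which the fifth track reaches 15 supporting frames. The
#' `end_latency_correction` config option back-dates the end frame by a
#' fixed number of frames to undo the confirmation latency.
#'
#' @param rec An [mjt_recording()].
#' @param cal An [calibration()].
#' @param config An [mjt_config()].
#' @return A `subtest_result`; events are the confirmation frames of the
#'   five cards.
#' @export
run_card_turning <- function(rec, cal, config = mjt_config()) {
  table <- detect_table(rec$frames[[1]]$depth, cal, config)
  surface <- surface_depth_map(dim(rec$frames[[1]]$depth), table, NULL)
  hands <- lapply(rec$frames, detect_hand, table = table, board = NULL,
                  cal = cal, config = config, surface = surface)
  series <- distance_series(rec, list(type = "edge"), table, NULL, cal,
                            config, hands = hands)
  start_frame <- detect_start(series, config$card_cross_mm, "exceeds",
                              config$onset_mm_per_frame, config)
  tracks <- card_tracks()
  confirm_frames <- integer(0)
  end_frame <- NA_integer_
  n_multi <- 0L
  for (i in seq_along(rec$frames)) {
    cents <- detect_green_markers(rec$frames[[i]]$rgb, hands[[i]], cal, config)
    tracks <- update_card_tracks(tracks, cents, i - 1L, cal, config)
    if (isTRUE(hands[[i]]$present) && hands[[i]]$n_candidates > 1L)
      n_multi <- n_multi + 1L
    n_conf <- count_turned_cards(tracks, config)
    while (length(confirm_frames) < n_conf)
      confirm_frames <- c(confirm_frames, i - 1L)
    if (n_conf >= 5L) { end_frame <- i - 1L; break }
  }
  if (is.na(end_frame)) {
    n_conf <- count_turned_cards(tracks, config)
    mjt_stop(sprintf("subtest incomplete: only %d of 5 cards confirmed", n_conf),
             "mjt_incomplete", confirmed = n_conf)
  }
  end_frame <- end_frame - config$end_latency_correction
  new_subtest_result("card", start_frame, end_frame, rec$frame_rate,
                     confirm_frames,
                     diagnostics = list(table = table,
                                        n_tracks = nrow(tracks),
                                        multi_candidate_frames = n_multi))
}

#' Run the Simulated Feeding subtest on a recording
#'
#' Detects the table, board (via its ridge) and open can in the first
#' frame; starts timing at the movement onset preceding the 147 mm
#' edge-distance crossing (20 mm past the proximal board edge); records
#' bean drops with the frame-differencing state machine; stops at the
#' first frame with five drops recorded and the hand more than 20 mm from
#' the can rim.
#'
#' @inheritParams run_card_turning
#' @return A `subtest_result`; events are the five drop frames.
#' @export
run_simulated_feeding <- function(rec, cal, config = mjt_config()) {
  f1 <- rec$frames[[1]]
  table <- detect_table(f1$depth, cal, config)
  board <- detect_board(f1$depth, table, cal, config)
  region <- can_search_region(nrow(f1$depth), ncol(f1$depth), board, cal)
  can <- detect_can(f1$rgb, region, cal, config = config)
  surface <- surface_depth_map(dim(f1$depth), table, board)
  hands <- lapply(rec$frames, detect_hand, table = table, board = board,
                  cal = cal, config = config, surface = surface)
  series <- distance_series(rec, list(type = "edge"), table, board, cal,
                            config, hands = hands)
  start_frame <- detect_start(series, config$feeding_cross_mm, "exceeds",
                              config$onset_mm_per_frame, config)
  # differencing window: can bounding box + 60 mm margin
  margin <- mm_to_px(60, cal)
  h <- nrow(f1$depth); w <- ncol(f1$depth)
  rr <- matrix(seq_len(h), h, w); cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  window <- abs(rr - can$center[1]) <= can$radius_px + margin &
    abs(cc - can$center[2]) <= can$radius_px + margin
  state <- bean_drop_state()
  end_frame <- NA_integer_
  for (i in seq.int(2L, length(rec$frames))) {
    hand <- hands[[i]]
    ridge_mm <- if (isTRUE(hand$present)) {
      px_to_mm(point_segment_dist(hand$distal_centroid,
                                  board$ridge_axis[1, ],
                                  board$ridge_axis[2, ]), cal)
    } else Inf
    state <- detect_bean_drop(rec$frames[[i - 1L]]$rgb, rec$frames[[i]]$rgb,
                              can, hand, ridge_mm, state, i - 1L, cal,
                              config, window = window)
    if (length(state$drops) >= 5L) {
      rim_mm <- if (isTRUE(hand$present)) {
        px_to_mm(sqrt(sum((hand$distal_centroid - can$center)^2)), cal) -
          can$radius_mm
      } else Inf
      if (rim_mm > config$feeding_end_rim_mm) { end_frame <- i - 1L; break }
    }
  }
  if (is.na(end_frame))
    mjt_stop(sprintf("subtest incomplete: %d of 5 beans detected",
                     length(state$drops)),
             "mjt_incomplete", drops = length(state$drops))
  new_subtest_result("feeding", start_frame, end_frame, rec$frame_rate,
                     state$drops,
                     diagnostics = list(table = table, board = board,
                                        can = can))
}

#' Run the Stacking Checkers subtest on a recording
#'
#' Builds the depth reference from the first 15 frames (which must be
#' static), detects the table and board, and starts timing at the movement
#' onset preceding the frame where the distance from the hand to a point
#' 15 mm in front of the horizontal middle of the board edge falls below
#' 63.5 mm. Each frame's checker detections are assigned to stack-count
#' intervals; timing stops at the fifth consecutive frame with a
#' fourth-interval detection.
#'
#' @inheritParams run_card_turning
#' @return A `subtest_result`; events are the first frames at which stack
#'   counts 1..4 were observed.
#' @export
run_stacking_checkers <- function(rec, cal, config = mjt_config()) {
  f1 <- rec$frames[[1]]
  table <- detect_table(f1$depth, cal, config)
  board <- detect_board(f1$depth, table, cal, config)
  ref <- build_depth_reference(rec, config$n_ref_frames)
  # reference stability check: mean |frame - ref| over the reference window
  drift <- mean(vapply(seq_len(config$n_ref_frames), function(i)
    mean(abs(rec$frames[[i]]$depth - ref$ref_depth)), numeric(1)))
  if (drift > 10)
    warning(sprintf("reference frames not static (mean |ddepth| %.1f mm)",
                    drift))
  surface <- surface_depth_map(dim(f1$depth), table, board)
  hands <- lapply(rec$frames, detect_hand, table = table, board = board,
                  cal = cal, config = config, surface = surface)
  start_pt <- stacking_reference_point(board, table, cal, config)
  series <- distance_series(rec, list(type = "point", point = start_pt),
                            table, board, cal, config, hands = hands)
  start_frame <- detect_start(series, config$stacking_cross_mm, "falls_below",
                              config$onset_mm_per_frame, config)
  consec <- 0L
  end_frame <- NA_integer_
  first_n <- rep(NA_integer_, 4L)
  for (i in seq_along(rec$frames)) {
    log_i <- detect_checkers(rec$frames[[i]], ref, board, hands[[i]], cal,
                             config)
    ns <- if (nrow(log_i)) vapply(log_i$height_mm, count_stacked,
                                  integer(1), D = config$checker_mm)
          else integer(0)
    for (n in ns) if (n >= 1L && is.na(first_n[n])) first_n[n] <- i - 1L
    if (any(ns == 4L)) consec <- consec + 1L else consec <- 0L
    if (consec >= config$stack_consecutive) { end_frame <- i - 1L; break }
  }
  if (is.na(end_frame))
    mjt_stop("subtest incomplete: never saw 5 consecutive fourth-interval detections",
             "mjt_incomplete", max_interval = max(c(0L, which(!is.na(first_n)))))
  new_subtest_result("stacking", start_frame, end_frame, rec$frame_rate,
                     first_n[!is.na(first_n)],
                     diagnostics = list(table = table, board = board,
                                        reference_drift_mm = drift))
}

#' Reference point for stacking start detection
#'
#' The point 15 mm in front of (proximally to) the horizontal middle of
#' the board's proximal edge, approximately between the two middle
#' checkers.
#'
#' @param board,table Scene models.
#' @param cal An [calibration()].
#' @param config An [mjt_config()].
#' @return c(row, col).
#' @export
stacking_reference_point <- function(board, table, cal,
                                     config = mjt_config()) {
  mid_col <- mean(board$ridge_axis[, "col"])
  # proximal board edge: ridge axis row + half board width
  edge_r <- mean(board$ridge_axis[, "row"]) +
    (config$board_width_mm / 2) / cal$mm_per_px
  c(edge_r + config$stacking_point_offset_mm / cal$mm_per_px, mid_col)
}

#' Run one subtest by name
#'
#' Thin dispatcher over [run_card_turning()], [run_simulated_feeding()]
#' and [run_stacking_checkers()].
#'
#' @param rec An [mjt_recording()].
#' @param subtest `"card"`, `"feeding"` or `"stacking"`.
#' @param cal An [calibration()].
#' @param config An [mjt_config()].
#' @return A `subtest_result`.
#' @export
run_subtest <- function(rec, subtest = c("card", "feeding", "stacking"),
                        cal, config = mjt_config()) {
  subtest <- match.arg(subtest)
  switch(subtest,
         card = run_card_turning(rec, cal, config),
         feeding = run_simulated_feeding(rec, cal, config),
         stacking = run_stacking_checkers(rec, cal, config))
}
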