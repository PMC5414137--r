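# Synthetic RGB-D scene simulator: renders top-down recordings of each
# subtest with scripted hand trajectories and object events, plus exact
# ground-truth times derived from the script alone (never from the
# rendering), so every detector and state machine is testable without
# sensor hardware.
#
# The rendered geometry follows the physical test kit: cards 76x127 mm
# placed 51 mm apart, 127 mm from the front edge; board 1054x286x19 mm
# with a 508x13x51 mm centre ridge, 127 mm from the edge; open can 100 mm
# diameter in front of the board; four 30 mm checkers in front of and
# touching the board. The hand is a rigid ellipse with a trailing forearm
# band: every detector uses only connected-pixel geometry, so articulation
# is unnecessary.

# Scene colours are warm-tinted (wood-like) rather than neutral grey: with
# iid RGB noise an exactly-neutral surface would satisfy the strict
# R<G & B<G marker test on a quarter of its pixels. The can interior grey
# level is deliberately close to the hand's so that hand-motion ghosts
# over the can do not exceed the frame-difference threshold, as matte
# surfaces of similar brightness behave.
.mjt_colors <- list(
  table   = c(200, 180, 160),
  floor   = c(110, 100,  90),
  card    = c(240, 225, 210),
  marker  = c( 60, 200,  60),
  board   = c(175, 155, 130),
  ridge   = c(160, 140, 115),
  rim     = c( 95,  75,  60),
  can_in  = c(127, 107,  93),
  checker = c(190,  60,  55),
  bean    = c( 90,  55,  40),
  blob    = c( 25,  20,  18),
  hand    = c(110,  90,  78)
)

# internal: precompute the pixel-space layout of a scene
scene_layout <- function(subtest, width, height, mm_per_px, table_depth_mm) {
  s <- mm_per_px
  edge_row <- round(height * 5 / 6)
  row_of <- function(mm) edge_row - mm / s       # mm in front of the edge
  col_of <- function(mm) width / 2 + mm / s      # mm right of the centre
  lay <- list(subtest = subtest, w = width, h = height, s = s,
              table_depth = table_depth_mm,
              floor_depth = table_depth_mm + 700,
              edge_row = edge_row, row_of = row_of, col_of = col_of)
  if (subtest == "card") {
    lay$card_centers <- lapply(1:5, function(i)
      c(row = row_of(127 + 76 / 2), col = col_of((i - 3) * 178)))
    lay$card_half <- c(76 / 2 / s, 127 / 2 / s)  # (row, col) half extents
    lay$marker_half <- 12 / s
  } else {
    lay$board_rows <- c(row_of(127 + 286), row_of(127))
    lay$board_cols <- c(max(1, col_of(-527)), min(width, col_of(527)))
    lay$ridge_rows <- c(row_of(270 + 6.5), row_of(270 - 6.5))
    lay$ridge_cols <- c(col_of(-254), col_of(254))
  }
  if (subtest == "feeding") {
    lay$can_center <- c(row = row_of(60), col = col_of(0))
    lay$can_r <- 50 / s
    lay$can_band <- 4 / s
    lay$bean_pos <- lapply(1:5, function(i)
      c(row = row_of(260), col = col_of((i - 3) * 51)))
    # transient drop blob: ~12x8 mm, drawn on an exact integer pixel grid
    # so its extent stays below the 15 mm bean length bound at any scale
    lay$blob_px <- c(max(2, round(12 / s)), max(2, round(8 / s)))
    lay$blob_pos <- c(row = row_of(60), col = col_of(-20))
  }
  if (subtest == "stacking") {
    lay$checker_pos <- lapply(1:4, function(i)
      c(row = row_of(112), col = col_of((i - 2.5) * 30)))
    lay$checker_r <- 15 / s
    lay$stack_center <- c(row = row_of(187), col = col_of(0))
  }
  lay
}

# internal: paint a filled disc / rectangle into rgb (list of 3 matrices)
# and optionally depth
paint <- function(img, mask, color = NULL, depth = NULL, depth_mm = NULL) {
  if (!is.null(color)) for (k in 1:3) img$rgb[[k]][mask] <- color[k]
  if (!is.null(depth_mm)) img$depth[mask] <- depth_mm
  img
}

disc_mask <- function(h, w, center, radius) {
  rr <- matrix(seq_len(h), h, w); cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  (rr - center[1])^2 + (cc - center[2])^2 <= radius^2
}

# pixels whose centres lie in [lo, hi) on both axes, so an object of
# physical length L mm renders with a footprint of exactly L/mm_per_px
# pixels when the bounds land on pixel centres
rect_mask <- function(h, w, rows, cols) {
  m <- matrix(FALSE, h, w)
  r1 <- max(1L, ceiling(rows[1])); r2 <- min(h, ceiling(rows[2]) - 1L)
  c1 <- max(1L, ceiling(cols[1])); c2 <- min(w, ceiling(cols[2]) - 1L)
  if (r1 <= r2 && c1 <= c2) m[r1:r2, c1:c2] <- TRUE
  m
}

# internal: render the static scene for a given event state
render_static <- function(lay, state) {
  h <- lay$h; w <- lay$w
  col_mat <- function(color) lapply(1:3, function(k)
    matrix(color[k], h, w))
  img <- list(rgb = col_mat(.mjt_colors$table),
              depth = matrix(lay$table_depth, h, w))
  off <- rect_mask(h, w, c(lay$edge_row, h), c(1, w))
  img <- paint(img, off, .mjt_colors$floor, depth_mm = lay$floor_depth)
  if (lay$subtest == "card") {
    for (i in 1:5) {
      cc <- lay$card_centers[[i]]
      m <- rect_mask(h, w, cc[1] + c(-1, 1) * lay$card_half[1],
                     cc[2] + c(-1, 1) * lay$card_half[2])
      img <- paint(img, m, .mjt_colors$card,
                   depth_mm = lay$table_depth - 1)
      if (state$flipped[i]) {
        mm <- rect_mask(h, w, cc[1] + c(-1, 1) * lay$marker_half,
                        cc[2] + c(-1, 1) * lay$marker_half)
        img <- paint(img, mm, .mjt_colors$marker)
      }
    }
  } else {
    bm <- rect_mask(h, w, lay$board_rows, lay$board_cols)
    img <- paint(img, bm, .mjt_colors$board,
                 depth_mm = lay$table_depth - 19)
    rm_ <- rect_mask(h, w, lay$ridge_rows, lay$ridge_cols)
    img <- paint(img, rm_, .mjt_colors$ridge,
                 depth_mm = lay$table_depth - 70)
  }
  if (lay$subtest == "feeding") {
    inner <- disc_mask(h, w, lay$can_center, lay$can_r - lay$can_band)
    band <- disc_mask(h, w, lay$can_center, lay$can_r + lay$can_band) &
      !inner
    img <- paint(img, band, .mjt_colors$rim,
                 depth_mm = lay$table_depth - 100)
    img <- paint(img, inner, .mjt_colors$can_in,
                 depth_mm = lay$table_depth - 2)
    for (i in 1:5) if (state$beans[i]) {
      bp <- lay$bean_pos[[i]]
      m <- rect_mask(h, w, bp[1] + c(-1, 1) * 4 / lay$s,
                     bp[2] + c(-1, 1) * 2.5 / lay$s)
      img <- paint(img, m, .mjt_colors$bean,
                   depth_mm = lay$table_depth - 19 - 6)
    }
  }
  if (lay$subtest == "stacking") {
    for (i in 1:4) if (state$checkers[i]) {
      m <- disc_mask(h, w, lay$checker_pos[[i]], lay$checker_r)
      img <- paint(img, m, .mjt_colors$checker,
                   depth_mm = lay$table_depth - 6)
    }
    if (state$stack_n > 0) {
      m <- disc_mask(h, w, lay$stack_center, lay$checker_r)
      img <- paint(img, m, .mjt_colors$checker,
                   depth_mm = lay$table_depth - 19 - 6 * state$stack_n)
    }
  }
  img
}

#' Construct a scene script
#'
#' A script fully determines a simulated recording: the scene layout, the
#' hand trajectory (waypoints linearly interpolated per frame), the object
#' events, and the noise model. Ground truth is computed from the script
#' alone.
#'
#' @param subtest `"card"`, `"feeding"` or `"stacking"`.
#' @param n_frames Total frames.
#' @param waypoints Data frame with columns `frame` (strictly increasing),
#'   `row`, `col` (distal tip position, px, may be fractional) and
#'   `height_mm` (hand height above the local surface).
#' @param events Data frame with columns `frame`, `kind`
#'   (`"card_flip"`, `"bean_drop"`, `"checker_place"`) and `param`
#'   (card index 1..5, bean index 1..5, stack count 1..4).
#' @param width,height Image size in px (default 320x240 fixture scale).
#' @param mm_per_px Scale at the table plane (default 4).
#' @param frame_rate Frames/s (default 30).
#' @param table_depth_mm Sensor-to-table distance (default 1200).
#' @param noise_depth_mm,noise_rgb Gaussian noise SDs (defaults 2 mm, 3).
#' @param hand_semi_mm Hand ellipse semi-axes (along, across) in mm.
#' @param seed Integer seed making the rendering reproducible.
#' @return A `scene_script`.
#' @export
scene_script <- function(subtest, n_frames, waypoints, events,
                         width = 320, height = 240, mm_per_px = 4,
                         frame_rate = 30, table_depth_mm = 1200,
                         noise_depth_mm = 2, noise_rgb = 3,
                         hand_semi_mm = c(60, 40), seed = 1) {
  subtest <- match.arg(subtest, c("card", "feeding", "stacking"))
  stopifnot(all(diff(waypoints$frame) > 0), n_frames >= 16)
  if (nrow(events)) {
    ok_kind <- switch(subtest, card = "card_flip", feeding = "bean_drop",
                      stacking = "checker_place")
    if (!all(events$kind == ok_kind))
      mjt_stop(sprintf("event kind(s) %s incompatible with subtest '%s'",
                       paste(setdiff(events$kind, ok_kind), collapse = ", "),
                       subtest), "mjt_bad_script")
    if (any(events$frame >= n_frames))
      mjt_stop("event frame beyond recording span", "mjt_bad_script")
    nmax <- if (subtest == "stacking") 4L else 5L
    if (nrow(events) > nmax)
      mjt_stop("too many events for subtest", "mjt_bad_script")
  }
  structure(list(subtest = subtest, n_frames = as.integer(n_frames),
                 waypoints = waypoints, events = events,
                 width = width, height = height, mm_per_px = mm_per_px,
                 frame_rate = frame_rate, table_depth_mm = table_depth_mm,
                 noise_depth_mm = noise_depth_mm, noise_rgb = noise_rgb,
                 hand_semi_mm = hand_semi_mm, seed = as.integer(seed)),
            class = "scene_script")
}

# internal: per-frame interpolated tip positions and heights
script_tip_path <- function(script) {
  wp <- script$waypoints
  fr <- seq_len(script$n_frames) - 1L
  interp <- function(y) approx(wp$frame, y, xout = fr, rule = 2)$y
  data.frame(frame = fr, row = interp(wp$row), col = interp(wp$col),
             height_mm = interp(wp$height_mm))
}

#' Render a scripted recording and its ground truth
#'
#' Renders the top-down scene frame by frame: static layout per the test
#' kit dimensions, the hand as an ellipse-plus-forearm blob whose distal
#' tip follows the interpolated waypoints at the scripted height above the
#' local surface, card flips revealing green markers, bean drops as
#' 3-frame transient blobs inside the can, checker placements raising the
#' stack by 6 mm, and iid Gaussian noise on depth and RGB. Ground truth is
#' computed from the script alone (see [script_ground_truth()]); the
#' rendering never feeds back into it.
#'
#' @param script A [scene_script()].
#' @param config An [mjt_config()] (ground-truth conventions use its
#'   confirmation constants).
#' @return `list(recording, ground_truth, calibration)`.
#' @export
simulate_recording <- function(script, config = mjt_config()) {
  set.seed(script$seed)
  lay <- scene_layout(script$subtest, script$width, script$height,
                      script$mm_per_px, script$table_depth_mm)
  tip <- script_tip_path(script)
  h <- lay$h; w <- lay$w
  a_px <- script$hand_semi_mm[1] / lay$s
  b_px <- script$hand_semi_mm[2] / lay$s
  state <- list(flipped = rep(FALSE, 5), beans = rep(TRUE, 5),
                checkers = rep(TRUE, 4), stack_n = 0L)
  static <- render_static(lay, state)
  frames <- vector("list", script$n_frames)
  ev <- script$events
  for (t in seq_len(script$n_frames) - 1L) {
    changed <- FALSE
    if (nrow(ev)) for (j in which(ev$frame == t)) {
      k <- ev$kind[j]; p <- ev$param[j]
      if (k == "card_flip") state$flipped[p] <- TRUE
      if (k == "checker_place") {
        state$stack_n <- as.integer(p)
        state$checkers[min(which(state$checkers))] <- FALSE
      }
      changed <- TRUE
    }
    # beans leave the board a few frames before their drop appears
    if (script$subtest == "feeding" && nrow(ev)) {
      gone <- ev$param[ev$frame - 10 <= t]
      if (any(state$beans[gone])) { state$beans[gone] <- FALSE; changed <- TRUE }
    }
    if (changed) static <- render_static(lay, state)
    depth <- static$depth
    rgb1 <- static$rgb[[1]]; rgb2 <- static$rgb[[2]]; rgb3 <- static$rgb[[3]]
    # transient bean blob, 3 frames from each drop, drifting 1 px/frame
    if (script$subtest == "feeding" && nrow(ev)) {
      for (j in seq_len(nrow(ev))) {
        dt <- t - ev$frame[j]
        if (dt >= 0 && dt <= 2) {
          r0 <- round(lay$blob_pos[1]) + dt
          c0 <- round(lay$blob_pos[2])
          rows <- r0:(r0 + lay$blob_px[1] - 1L)
          cols <- c0:(c0 + lay$blob_px[2] - 1L)
          cb <- .mjt_colors$blob
          rgb1[rows, cols] <- cb[1]; rgb2[rows, cols] <- cb[2]
          rgb3[rows, cols] <- cb[3]
        }
      }
    }
    # hand: ellipse with tip at the waypoint, forearm band trailing to the
    # image bottom; depth = local base minus scripted height, where the
    # base off the table is the table plane (the arm is held level)
    tr <- tip$row[t + 1L]; tc <- tip$col[t + 1L]; hh <- tip$height_mm[t + 1L]
    ctr_r <- tr + a_px
    hand <- matrix(FALSE, h, w)
    rlo <- max(1L, floor(tr)); rhi <- h
    clo <- max(1L, floor(tc - b_px)); chi <- min(w, ceiling(tc + b_px))
    rr <- matrix(rlo:rhi, rhi - rlo + 1L, chi - clo + 1L)
    cc <- matrix(clo:chi, rhi - rlo + 1L, chi - clo + 1L, byrow = TRUE)
    sub <- ((rr - ctr_r) / a_px)^2 + ((cc - tc) / b_px)^2 <= 1 |
      (rr >= ctr_r & abs(cc - tc) <= 30 / lay$s)
    hand[rlo:rhi, clo:chi] <- sub
    base <- pmin(depth[hand], lay$table_depth)
    depth[hand] <- base - hh
    ch <- .mjt_colors$hand
    rgb1[hand] <- ch[1]; rgb2[hand] <- ch[2]; rgb3[hand] <- ch[3]
    if (script$noise_depth_mm > 0)
      depth <- depth + rnorm(h * w, 0, script$noise_depth_mm)
    dvec <- as.integer(depth + 0.5)
    dvec[dvec < 0L] <- 0L
    depth <- matrix(dvec, h, w)
    if (script$noise_rgb > 0) {
      rgb1 <- rgb1 + rnorm(h * w, 0, script$noise_rgb)
      rgb2 <- rgb2 + rnorm(h * w, 0, script$noise_rgb)
      rgb3 <- rgb3 + rnorm(h * w, 0, script$noise_rgb)
    }
    rvec <- as.integer(c(rgb1, rgb2, rgb3) + 0.5)
    rvec[rvec < 0L] <- 0L
    rvec[rvec > 255L] <- 255L
    frames[[t + 1L]] <- rgbd_frame(array(rvec, c(h, w, 3L)), depth, t,
                                   script$frame_rate)
  }
  rec <- mjt_recording(frames, script$frame_rate,
                       meta = list(subtest = script$subtest,
                                   seed = script$seed))
  list(recording = rec,
       ground_truth = script_ground_truth(script, config),
       calibration = calibration(script$mm_per_px))
}

#' Ground truth times of a scripted recording
#'
#' Computed from the script alone. The movement onset applies the
#' detector's own convention to the scripted tip path: first frame of the
#' contiguous run of >= 3 mm/frame displacement toward the target that
#' precedes the subtest's crossing. The end frame follows the subtest's
#' measurement definition: card turning ends at the confirmation frame of
#' the fifth marker (its flip frame plus `track_confirm_frames - 1`);
#' feeding ends at the fifth drop frame (the hand hovers more than 20 mm
#' outside the rim when dropping); stacking ends 4 frames (the
#' five-consecutive rule) after the first frame at which the completed
#' stack is clear of the hand by more than 30 mm.
#'
#' @param script A [scene_script()].
#' @param config An [mjt_config()].
#' @return A `ground_truth` list with `movement_onset_frame`,
#'   `event_frames`, `end_frame`, `start_s`, `end_s`, `total_s`.
#' @export
script_ground_truth <- function(script, config = mjt_config()) {
  lay <- scene_layout(script$subtest, script$width, script$height,
                      script$mm_per_px, script$table_depth_mm)
  tip <- script_tip_path(script)
  s <- lay$s
  dist_mm <- switch(script$subtest,
    card = (lay$edge_row - tip$row) * s,
    feeding = (lay$edge_row - tip$row) * s,
    stacking = {
      pt <- c(lay$row_of(112), lay$col_of(0))
      sqrt((tip$row - pt[1])^2 + (tip$col - pt[2])^2) * s
    })
  thr <- switch(script$subtest, card = config$card_cross_mm,
                feeding = config$feeding_cross_mm,
                stacking = config$stacking_cross_mm)
  dir <- if (script$subtest == "stacking") "falls_below" else "exceeds"
  onset <- tryCatch(
    suppressWarnings(
      detect_start(structure(dist_mm, class = "distance_series"),
                   thr, dir, config$onset_mm_per_frame, config)),
    error = function(e) NA_integer_)
  ev_frames <- sort(script$events$frame)
  if (!length(ev_frames) || is.na(onset)) {
    return(structure(list(movement_onset_frame = as.integer(onset),
                          event_frames = as.integer(ev_frames),
                          end_frame = NA_integer_, start_s = NA_real_,
                          end_s = NA_real_, total_s = NA_real_),
                     class = "ground_truth"))
  }
  end <- switch(script$subtest,
    card = max(ev_frames) + config$track_confirm_frames - 1L,
    feeding = max(ev_frames),
    stacking = {
      p4 <- max(ev_frames)
      d_stack <- sqrt((tip$row - lay$stack_center[1])^2 +
                        (tip$col - lay$stack_center[2])^2) * s
      clear <- which(tip$frame >= p4 & d_stack - 15 > config$checker_hand_excl_mm)
      clear[1] - 1L + config$stack_consecutive - 1L
    })
  structure(list(movement_onset_frame = as.integer(onset),
                 event_frames = as.integer(ev_frames),
                 end_frame = as.integer(end),
                 start_s = onset / script$frame_rate,
                 end_s = end / script$frame_rate,
                 total_s = (end - onset) / script$frame_rate),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> onset frame %d, end frame %d, total %.3f s\n",
              x$movement_onset_frame, x$end_frame, x$total_s))
  invisible(x)
}

# ---- default scripts -------------------------------------------------------

# internal: shared geometry for script builders, in px
builder_layout <- function(subtest, width, height, mm_per_px) {
  scene_layout(subtest, width, height, mm_per_px, 1200)
}

# internal: one waypoint row
wpt <- function(frame, p, height_mm = 45) {
  data.frame(frame = frame, row = as.numeric(p[1]), col = as.numeric(p[2]),
             height_mm = height_mm)
}

#' Default Card Turning script
#'
#' Hand rests at the table edge, starts moving at `onset_frame`, reaches
#' each card 10 frames before its flip, and moves on before the flip so
#' the marker is never masked by hand proximity. The pacing of the default
#' flip frames reproduces a realistic total time of about 7.5 s at 30 fps.
#'
#' @param seed Rendering seed.
#' @param onset_frame Last static frame before the approach (default 20).
#' @param flip_frames Five card-flip frames (default 50, 90, 130, 170,
#'   210).
#' @param noise_depth_mm,noise_rgb Noise SDs.
#' @param width,height,mm_per_px Image geometry (default fixture scale
#'   320x240 at 4 mm/px).
#' @param tail_frames Static frames appended after the last confirmation.
#' @return A [scene_script()].
#' @export
card_script <- function(seed = 1, onset_frame = 20,
                        flip_frames = c(50, 90, 130, 170, 210),
                        noise_depth_mm = 2, noise_rgb = 3,
                        width = 320, height = 240, mm_per_px = 4,
                        tail_frames = 20) {
  stopifnot(length(flip_frames) == 5, all(diff(flip_frames) > 0))
  lay <- builder_layout("card", width, height, mm_per_px)
  rest <- c(lay$row_of(30), lay$col_of(0))
  arrivals <- flip_frames - 10
  stopifnot(arrivals[1] > onset_frame + 5)
  wp <- rbind(wpt(0, rest), wpt(onset_frame, rest))
  for (i in 1:5) {
    cc <- lay$card_centers[[i]]
    wp <- rbind(wp, wpt(arrivals[i], cc))
    nxt_col <- if (i < 5) lay$card_centers[[i + 1]][2] else cc[2] + 100 / lay$s
    # leave quickly so the marker is >10 mm clear of the hand at flip time
    wp <- rbind(wp, wpt(arrivals[i] + 8,
                        c(cc[1], cc[2] + sign(nxt_col - cc[2]) * 100 / lay$s)))
  }
  n_frames <- max(flip_frames) + 14 + tail_frames + 1
  events <- data.frame(frame = flip_frames, kind = "card_flip", param = 1:5)
  scene_script("card", n_frames, wp, events, width, height, mm_per_px,
               noise_depth_mm = noise_depth_mm, noise_rgb = noise_rgb,
               hand_semi_mm = c(60, 40), seed = seed)
}

#' Default Simulated Feeding script
#'
#' The hand cycles ridge (bean pickup, re-arming the drop detector) ->
#' hover outside the can rim -> drop (3-frame blob inside the can) ->
#' next bean. The hover point sits 20-50 mm outside the rim so the end
#' condition is met at the fifth drop itself.
#'
#' @param drop_frames Five bean-drop frames (default 55, 90, 125, 160,
#'   195).
#' @inheritParams card_script
#' @return A [scene_script()].
#' @export
feeding_script <- function(seed = 1, onset_frame = 20,
                           drop_frames = c(55, 90, 125, 160, 195),
                           noise_depth_mm = 2, noise_rgb = 3,
                           width = 320, height = 240, mm_per_px = 4,
                           tail_frames = 15) {
  stopifnot(length(drop_frames) == 5, all(diff(drop_frames) > 0))
  lay <- builder_layout("feeding", width, height, mm_per_px)
  # the hand rests in line with the first bean, reaching 60 mm onto the
  # table so its on-table pixel count exceeds any static structure (the
  # can rim stands 100 mm proud of the table and competes for "largest
  # group"); the straight approach also avoids sweeping across the can,
  # which would disturb the distal centroid mid-onset
  rest <- c(lay$row_of(60), lay$bean_pos[[1]][2])
  # hover beside the can: tip level with the can centre, ~40 mm outside
  # the rim, so the hand never touches the rim ring and the end condition
  # (rim distance > 20 mm) already holds at the fifth drop
  hover <- c(lay$row_of(60), lay$col_of(92))
  wp <- rbind(wpt(0, rest), wpt(onset_frame, rest))
  pickups <- drop_frames - 15
  stopifnot(pickups[1] > onset_frame + 5)
  for (i in 1:5) {
    bp <- lay$bean_pos[[i]]
    wp <- rbind(wp,
      wpt(pickups[i], bp), wpt(pickups[i] + 2, bp),
      wpt(drop_frames[i] - 2, hover), wpt(drop_frames[i] + 2, hover))
  }
  n_frames <- max(drop_frames) + tail_frames + 1
  events <- data.frame(frame = drop_frames, kind = "bean_drop", param = 1:5)
  scene_script("feeding", n_frames, wp, events, width, height, mm_per_px,
               noise_depth_mm = noise_depth_mm, noise_rgb = noise_rgb,
               hand_semi_mm = c(60, 40), seed = seed)
}

#' Default Stacking Checkers script
#'
#' Fifteen static frames build the depth reference; the hand then shuttles
#' checkers from the row in front of the board to the stack on the board,
#' retreating straight proximally after the fourth placement so the
#' completed stack clears the 30 mm hand-exclusion zone within 3 frames.
#'
#' @param place_frames Four placement frames (default 40, 58, 76, 94).
#' @inheritParams card_script
#' @return A [scene_script()].
#' @export
stacking_script <- function(seed = 1, onset_frame = 20,
                            place_frames = c(40, 58, 76, 94),
                            noise_depth_mm = 2, noise_rgb = 3,
                            width = 320, height = 240, mm_per_px = 4,
                            tail_frames = 20) {
  stopifnot(length(place_frames) == 4, all(diff(place_frames) > 0),
            onset_frame >= 16)
  lay <- builder_layout("stacking", width, height, mm_per_px)
  rest <- c(lay$row_of(30), lay$col_of(0))
  stk <- lay$stack_center
  wp <- rbind(wpt(0, rest), wpt(onset_frame, rest))
  picks <- place_frames - 6
  stopifnot(picks[1] > onset_frame + 5)
  for (i in 1:4) {
    cp <- lay$checker_pos[[i]]
    wp <- rbind(wp,
      wpt(picks[i] - 2, cp), wpt(picks[i], cp),
      wpt(place_frames[i] - 1, stk), wpt(place_frames[i], stk))
  }
  # straight proximal retreat at 20 mm/frame
  wp <- rbind(wp, wpt(place_frames[4] + 8, c(stk[1] + 160 / lay$s, stk[2])))
  n_frames <- max(place_frames) + tail_frames + 1
  events <- data.frame(frame = place_frames, kind = "checker_place",
                       param = 1:4)
  scene_script("stacking", n_frames, wp, events, width, height, mm_per_px,
               noise_depth_mm = noise_depth_mm, noise_rgb = noise_rgb,
               hand_semi_mm = c(60, 40), seed = seed)
}

#' Default script for a subtest
#' @param subtest `"card"`, `"feeding"` or `"stacking"`.
#' @param seed Rendering seed.
#' @param ... Passed to the subtest's script builder.
#' @return A [scene_script()].
#' @export
default_script <- function(subtest = c("card", "feeding", "stacking"),
                           seed = 1, ...) {
  subtest <- match.arg(subtest)
  switch(subtest, card = card_script(seed = seed, ...),
         feeding = feeding_script(seed = seed, ...),
         stacking = stacking_script(seed = seed, ...))
}

#' Write a suite of fixture recordings with a ground-truth manifest
#'
#' One recording per subtest per seed, saved in the directory format of
#' [save_recording()], plus `manifest.json` with each recording's ground
#' truth.
#'
#' @param out_dir Output directory (created if needed).
#' @param seeds Integer vector of seeds.
#' @param config An [mjt_config()].
#' @param ... Passed to the script builders (e.g. noise levels).
#' @return The manifest as a data frame, invisibly.
#' @export
make_fixture_suite <- function(out_dir, seeds, config = mjt_config(), ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  for (st in c("card", "feeding", "stacking")) for (sd in seeds) {
    scr <- default_script(st, seed = sd, ...)
    sim <- simulate_recording(scr, config)
    name <- sprintf("%s_%d", st, sd)
    save_recording(sim$recording, file.path(out_dir, name))
    gt <- sim$ground_truth
    manifest[[name]] <- list(subtest = st, seed = sd,
                             mm_per_px = scr$mm_per_px,
                             frame_rate = scr$frame_rate,
                             movement_onset_frame = gt$movement_onset_frame,
                             end_frame = gt$end_frame,
                             event_frames = gt$event_frames,
                             start_s = gt$start_s, end_s = gt$end_s,
                             total_s = gt$total_s)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  df <- do.call(rbind, lapply(names(manifest), function(n)
    data.frame(name = n, subtest = manifest[[n]]$subtest,
               seed = manifest[[n]]$seed,
               onset = manifest[[n]]$movement_onset_frame,
               end = manifest[[n]]$end_frame,
               total_s = manifest[[n]]$total_s)))
  invisible(df)
}

#' Simulate a timing-table panel with known agreement structure
#'
#' Draws subject-level true completion times (practice effect between
#' repetitions), then produces ground-truth, Kinect and therapist
#' measurements with a specified per-method bias, between-subject
#' method-offset SD and within-measurement SD. Used for
#' parameter-recovery tests of the agreement statistics: differences
#' method - ground_truth have mean `bias_s` and SD
#' `sqrt(sd_within_s^2 + sd_between_s^2)`.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param bias_s Method bias in seconds (scalar, applied to both kinect
#'   and therapist, or length-2 vector `c(kinect, therapist)`).
#' @param sd_within_s Within-subject measurement SD, s.
#' @param sd_between_s Between-subject SD of the method offset, s.
#' @param practice_effect_s Improvement from repetition 1 to 2, s.
#' @param seed Integer seed.
#' @param baseline_mean_s,baseline_sd_s Distribution of subject true
#'   times at repetition 1 (defaults 10 and 2 s, the magnitude of real
#'   completion times).
#' @param subtest,hand Constant labels for the generated stratum.
#' @return An [times_table()].
#' @export
simulate_times_panel <- function(n_subjects, bias_s = 0, sd_within_s = 0,
                                 sd_between_s = 0, practice_effect_s = 0,
                                 seed = 1, baseline_mean_s = 10,
                                 baseline_sd_s = 2, subtest = "card",
                                 hand = "most") {
  stopifnot(n_subjects >= 2, sd_within_s >= 0, sd_between_s >= 0)
  set.seed(seed)
  if (length(bias_s) == 1L) bias_s <- c(kinect = bias_s, therapist = bias_s)
  base <- pmax(1, rnorm(n_subjects, baseline_mean_s, baseline_sd_s))
  rows <- list()
  for (i in seq_len(n_subjects)) {
    u <- c(kinect = rnorm(1, 0, sd_between_s),
           therapist = rnorm(1, 0, sd_between_s))
    for (rep_ in 1:2) {
      truth <- max(0.5, base[i] - practice_effect_s * (rep_ - 1))
      vals <- c(ground_truth = truth,
                kinect = truth + bias_s[["kinect"]] + u[["kinect"]] +
                  rnorm(1, 0, sd_within_s),
                therapist = truth + bias_s[["therapist"]] + u[["therapist"]] +
                  rnorm(1, 0, sd_within_s))
      for (m in names(vals)) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sprintf("S%03d", i), repetition = rep_, hand = hand,
          subtest = subtest, method = m, start_s = 0,
          end_s = vals[[m]], total_s = vals[[m]])
      }
    }
  }
  times_table(do.call(rbind, rows))
}
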