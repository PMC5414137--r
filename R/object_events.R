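# Task event detection: turned cards (green markers), beans dropped into
# the can (frame differencing), checkers stacked (depth intervals).

#' Detect green card markers in one RGB frame
#'
#' Pixels with R and B strictly below G form the green mask; a 5x5 median
#' filter removes speckle; 4-connected groups of at least 10 pixels
#' survive, except those whose centroid lies within 10 mm of any hand
#' pixel (the marker of a card still being handled is not yet counted).
#'
#' @param rgb HxWx3 image, 0..255.
#' @param hand A [detect_hand()] observation (may be absent).
#' @param cal An [calibration()].
#' @param config An [mjt_config()].
#' @return A data frame with columns `row`, `col` (subpixel centroids) and
#'   `size` (pixels), one row per marker.
#' @export
detect_green_markers <- function(rgb, hand, cal, config = mjt_config()) {
  mask <- rgb[, , 1L] < rgb[, , 2L] & rgb[, , 3L] < rgb[, , 2L]
  out <- data.frame(row = numeric(0), col = numeric(0), size = integer(0))
  if (sum(mask) < 13) return(out)  # 5x5 majority cannot pass anywhere
  mask <- median_filter5(mask)
  if (!any(mask)) return(out)
  labels <- label_components(mask)
  comp <- component_pixels(labels)
  if (!comp$n) return(out)
  for (i in seq_len(comp$n)) {
    if (comp$sizes[i] < config$marker_min_px) next
    cen <- pixel_centroid(comp$rows[[i]], comp$cols[[i]])
    if (isTRUE(hand$present)) {
      d_mm <- px_to_mm(min_dist_to_pixels(cen[1], cen[2],
                                          hand$rows, hand$cols), cal)
      if (d_mm < config$marker_hand_excl_mm) next
    }
    out <- rbind(out, data.frame(row = cen[1], col = cen[2],
                                 size = comp$sizes[i]))
  }
  out
}

#' Create an empty set of card marker tracks
#' @return An empty `card_tracks` data frame.
#' @export
card_tracks <- function() {
  structure(data.frame(row = numeric(0), col = numeric(0),
                       support_frames = integer(0),
                       first_frame = integer(0), last_frame = integer(0)),
            class = c("card_tracks", "data.frame"))
}

#' Update card marker tracks with one frame's centroids
#'
#' Each centroid joins the nearest existing track when it lies within
#' 5 mm of it (the track centroid becomes the running mean and its support
#' grows by at most one frame per update); otherwise it opens a new track.
#' A track with 15 or more supporting frames is a turned card. Tracks are
#' never deleted: a marker is only visible once its card has been flipped,
#' so a persistent track is a turned card.
#'
#' @param tracks A [card_tracks()] data frame.
#' @param centroids Data frame with `row`, `col` (from
#'   [detect_green_markers()]).
#' @param frame_index 0-based frame ordinal.
#' @param cal An [calibration()].
#' @param config An [mjt_config()].
#' @return The updated `card_tracks`.
#' @export
update_card_tracks <- function(tracks, centroids, frame_index, cal,
                               config = mjt_config()) {
  if (!nrow(centroids)) return(tracks)
  supported <- rep(FALSE, nrow(tracks))
  for (i in seq_len(nrow(centroids))) {
    r <- centroids$row[i]; co <- centroids$col[i]
    if (nrow(tracks)) {
      d_mm <- px_to_mm(sqrt((tracks$row - r)^2 + (tracks$col - co)^2), cal)
      j <- which.min(d_mm)
    } else j <- integer(0)
    if (length(j) && d_mm[j] < config$track_join_mm) {
      n <- tracks$support_frames[j]
      tracks$row[j] <- (tracks$row[j] * n + r) / (n + 1)
      tracks$col[j] <- (tracks$col[j] * n + co) / (n + 1)
      if (!supported[j]) {            # at most one support per frame
        tracks$support_frames[j] <- n + 1L
        tracks$last_frame[j] <- as.integer(frame_index)
        supported[j] <- TRUE
      }
    } else {
      tracks <- rbind(tracks, data.frame(row = r, col = co,
                                         support_frames = 1L,
                                         first_frame = as.integer(frame_index),
                                         last_frame = as.integer(frame_index)))
      supported <- c(supported, TRUE)
      class(tracks) <- c("card_tracks", "data.frame")
    }
  }
  tracks
}

#' Number of confirmed turned cards
#' @param tracks A [card_tracks()] data frame.
#' @param config An [mjt_config()].
#' @return Count of tracks with at least 15 supporting frames.
#' @export
count_turned_cards <- function(tracks, config = mjt_config()) {
  sum(tracks$support_frames >= config$track_confirm_frames)
}

#' Create the bean-drop detector state
#'
#' @param armed Whether the detector starts ready to record a drop
#'   (default TRUE: the first bean needs no prior ridge visit).
#' @return A `bean_drop_state` with `drops` (frame indices) and `armed`.
#' @export
bean_drop_state <- function(armed = TRUE) {
  structure(list(drops = integer(0), armed = isTRUE(armed)),
            class = "bean_drop_state")
}

#' Advance the bean-drop detector by one frame pair
#'
#' Both frames are converted to grey (unweighted channel mean) and their
#' absolute difference thresholded at 10\% of the 0-255 range (strict
#' > 25.5); pixels of the current hand are excluded, since the moving hand
#' would otherwise dominate the difference image. 4-connected groups whose
#' centroids lie within 5 mm are merged. A drop is recorded iff the state
#' is armed, some merged group has 5..50 pixels (inclusive) and a maximal
#' extent under 15 mm, its centroid lies inside the can rim, the hand is
#' within 50 mm of the rim, and fewer than five drops have been recorded.
#' After a drop the detector disarms; it re-arms once the hand comes
#' within 30 mm of the ridge (`ridge_dist_mm`).
#'
#' @param prev_rgb,cur_rgb Consecutive HxWx3 images, 0..255.
#' @param can A [detect_can()] model.
#' @param hand The current frame's [detect_hand()] observation.
#' @param ridge_dist_mm Distance from the distal centroid to the ridge
#'   axis, mm (`Inf` when the hand is absent).
#' @param state A [bean_drop_state()].
#' @param frame_index 0-based index of the current frame.
#' @param cal An [calibration()].
#' @param config An [mjt_config()].
#' @param window Optional logical mask restricting the differencing to a
#'   region around the can (the detector's conditions make anything
#'   outside irrelevant).
#' @return The updated `bean_drop_state`.
#' @export
detect_bean_drop <- function(prev_rgb, cur_rgb, can, hand, ridge_dist_mm,
                             state, frame_index, cal,
                             config = mjt_config(), window = NULL) {
  stopifnot(inherits(state, "bean_drop_state"))
  if (!state$armed && is.finite(ridge_dist_mm) &&
      ridge_dist_mm < config$bean_rearm_ridge_mm)
    state$armed <- TRUE
  if (length(state$drops) >= 5L) return(state)

  hand_rim_mm <- if (isTRUE(hand$present)) {
    px_to_mm(sqrt(sum((hand$distal_centroid - can$center)^2)), cal) -
      can$radius_mm
  } else Inf
  if (!state$armed || hand_rim_mm >= config$bean_hand_rim_mm) return(state)

  diff <- abs(to_gray(cur_rgb) - to_gray(prev_rgb))
  mask <- diff > config$diff_threshold
  if (!is.null(window)) mask <- mask & window
  if (isTRUE(hand$present))
    mask[cbind(hand$rows, hand$cols)] <- FALSE
  if (!any(mask)) return(state)
  labels <- label_components(mask)
  comp <- component_pixels(labels)
  groups <- merge_close_groups(comp, config$bean_merge_mm, cal)
  for (g in groups) {
    npx <- length(g$rows)
    if (npx < config$bean_min_px || npx > config$bean_max_px) next
    if (px_to_mm(component_extent_px(g$rows, g$cols), cal) >=
        config$bean_max_extent_mm) next
    cen <- pixel_centroid(g$rows, g$cols)
    inside <- sqrt(sum((cen - can$center)^2)) < can$radius_px
    if (!inside) next
    state$drops <- c(state$drops, as.integer(frame_index))
    state$armed <- FALSE
    break
  }
  state
}

# internal: union groups whose centroids are closer than join_mm
merge_close_groups <- function(comp, join_mm, cal) {
  n <- comp$n
  if (!n) return(list())
  cens <- t(vapply(seq_len(n), function(i)
    pixel_centroid(comp$rows[[i]], comp$cols[[i]]), numeric(2)))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      d_mm <- px_to_mm(sqrt(sum((cens[i, ] - cens[j, ])^2)), cal)
      if (d_mm < join_mm) parent[find(j)] <- find(i)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  lapply(split(seq_len(n), roots), function(members)
    list(rows = unlist(comp$rows[members], use.names = FALSE),
         cols = unlist(comp$cols[members], use.names = FALSE)))
}

#' Detect elevated checker groups in one frame
#'
#' Foreground pixels inside the board footprint whose depth is more than
#' 5 mm nearer than the depth reference are grouped (4-connected). A group
#' is logged as a checker when its maximal extent lies between 0.5 and 2
#' checker diameters (15..60 mm, inclusive), its centroid is inside the
#' board region, and its minimum distance to any hand pixel exceeds
#' 30 mm. Each log entry records the frame and the group's mean height
#' above the board surface.
#'
#' @param frame An [rgbd_frame()].
#' @param ref A [build_depth_reference()].
#' @param board A [detect_board()] model.
#' @param hand The frame's [detect_hand()] observation.
#' @param cal An [calibration()].
#' @param config An [mjt_config()].
#' @return Data frame with columns `frame_index` and `height_mm` (possibly
#'   zero rows).
#' @export
detect_checkers <- function(frame, ref, board, hand, cal,
                            config = mjt_config()) {
  fg <- (ref$ref_depth - frame$depth) > config$checker_height_mm &
    board$board_region
  out <- data.frame(frame_index = integer(0), height_mm = numeric(0))
  if (!any(fg)) return(out)
  labels <- label_components(fg)
  comp <- component_pixels(labels)
  lo <- config$checker_extent_lo * config$checker_diameter_mm
  hi <- config$checker_extent_hi * config$checker_diameter_mm
  hand_dist <- NULL
  for (i in seq_len(comp$n)) {
    ext <- px_to_mm(component_extent_px(comp$rows[[i]], comp$cols[[i]]), cal)
    if (ext < lo || ext > hi) next
    cen <- pixel_centroid(comp$rows[[i]], comp$cols[[i]])
    cen_i <- pmax(1L, pmin(dim(fg), round(cen)))
    if (!board$board_region[cen_i[1], cen_i[2]]) next
    if (isTRUE(hand$present)) {
      if (is.null(hand_dist)) {
        hm <- matrix(FALSE, nrow(fg), ncol(fg))
        hm[cbind(hand$rows, hand$cols)] <- TRUE
        hand_dist <- distance_to_mask_px(hm)
      }
      d_mm <- px_to_mm(min(hand_dist[cbind(comp$rows[[i]], comp$cols[[i]])]),
                       cal)
      if (d_mm <= config$checker_hand_excl_mm) next
    }
    height <- mean(board$board_surface_depth_mm -
                     frame$depth[cbind(comp$rows[[i]], comp$cols[[i]])])
    if (height > config$checker_height_mm)
      out <- rbind(out, data.frame(frame_index = frame$index,
                                   height_mm = height))
  }
  out
}

#' Assign a checker-log height to a stack count
#'
#' The candidate stack counts are n in 1..4 with expected height D*n and
#' acceptance interval (D +/- 0.5 D)*n = [0.5 D n, 1.5 D n] (inclusive).
#' Among the intervals containing the height, the n whose expected height
#' D*n is closest wins (the intervals overlap for n >= 2); ties go to the
#' smaller n. A height in no interval yields 0 (ignored).
#'
#' @param entry_height_mm Height above the board surface, mm.
#' @param D Height of one checker, mm (default 6).
#' @return Integer in 0..4.
#' @export
count_stacked <- function(entry_height_mm, D = 6) {
  n_cand <- 1:4
  contains <- entry_height_mm >= 0.5 * D * n_cand &
    entry_height_mm <= 1.5 * D * n_cand
  if (!any(contains)) return(0L)
  cand <- n_cand[contains]
  err <- abs(entry_height_mm - D * cand)
  cand[which.min(err)]   # which.min takes the first (smallest n) on ties
}
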