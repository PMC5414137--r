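test_that("green marker detection uses strict R<G & B<G plus size/hand filters", {
  cal <- calibration(1)
  gray <- flat_rgb(64, 64, 128)             # R = G = B: strict test fails
  no_hand <- fake_hand(integer(0), integer(0))
  expect_identical(nrow(detect_green_markers(gray, no_hand, cal)), 0L)

  patch <- function(rows, cols) {
    img <- flat_rgb(64, 64, 128)
    img[rows, cols, 1] <- 50L; img[rows, cols, 2] <- 200L
    img[rows, cols, 3] <- 50L
    img
  }
  # 8x8 patch: survives the median filter with a 20+ px core
  img <- patch(20:27, 30:37)
  m <- detect_green_markers(img, no_hand, cal)
  expect_identical(nrow(m), 1L)
  expect_equal(c(m$row, m$col), c(23.5, 33.5), tolerance = 0.01)
  expect_gte(m$size, 10)

  # same patch with a hand pixel 8 mm away: excluded (<10 mm rule)
  hand_near <- fake_hand(23L, 42L, cal)     # ~8.5 px from centroid
  expect_identical(nrow(detect_green_markers(img, hand_near, cal)), 0L)
  hand_far <- fake_hand(23L, 55L, cal)
  expect_identical(nrow(detect_green_markers(img, hand_far, cal)), 1L)
})

test_that("green mask pipeline agrees with a brute-force oracle on random images", {
  cal <- calibration(1)
  no_hand <- fake_hand(integer(0), integer(0))
  set.seed(31)
  for (i in 1:8) {
    h <- sample(12:32, 1); w <- sample(12:32, 1)
    img <- array(sample.int(256, h * w * 3, TRUE) - 1L, c(h, w, 3))
    # oracle: per-pixel mask, brute median, flood fill, size filter
    mask <- img[, , 1] < img[, , 2] & img[, , 3] < img[, , 2]
    filt <- brute_median5(mask)
    lab <- flood_fill_label(filt)
    cents <- list()
    if (max(lab) > 0) for (g in seq_len(max(lab))) {
      idx <- which(lab == g, arr.ind = TRUE)
      if (nrow(idx) >= 10)
        cents[[length(cents) + 1L]] <- colMeans(idx)
    }
    got <- detect_green_markers(img, no_hand, cal)
    expect_identical(nrow(got), length(cents))
    if (length(cents)) {
      want <- do.call(rbind, cents)
      ord_w <- order(want[, 1], want[, 2]); ord_g <- order(got$row, got$col)
      expect_equal(unname(cbind(got$row, got$col)[ord_g, , drop = FALSE]),
                   unname(want[ord_w, , drop = FALSE]))
    }
  }
})

test_that("card tracks confirm at exactly 15 supporting frames", {
  cal <- calibration(1)
  cents <- data.frame(row = 20, col = 30)
  tr <- card_tracks()
  for (f in 0:13) tr <- update_card_tracks(tr, cents, f, cal)
  expect_identical(count_turned_cards(tr), 0L)   # 14 frames: not yet
  tr <- update_card_tracks(tr, cents, 14, cal)
  expect_identical(count_turned_cards(tr), 1L)   # 15th frame confirms
})

test_that("centroids under 5 mm apart join one track; support is once per frame", {
  cal <- calibration(1)
  tr <- card_tracks()
  tr <- update_card_tracks(tr, data.frame(row = 10, col = 10), 0, cal)
  tr <- update_card_tracks(tr, data.frame(row = 10, col = 14), 1, cal)
  expect_identical(nrow(tr), 1L)                 # 4 mm: same card
  expect_identical(tr$support_frames, 2L)
  tr <- update_card_tracks(tr, data.frame(row = 10, col = 17.5), 2, cal)
  expect_identical(nrow(tr), 2L)                 # 5.5 mm from track: new
  tr2 <- update_card_tracks(card_tracks(),
                            data.frame(row = c(10, 10), col = c(10, 12)),
                            0, cal)
  expect_identical(tr2$support_frames, 1L)       # two hits, one frame
})

test_that("five stable markers 51 mm apart give five turned cards", {
  cal <- calibration(1)
  cents <- data.frame(row = 40, col = 30 + 51 * (0:4))
  tr <- card_tracks()
  for (f in 0:14) tr <- update_card_tracks(tr, cents, f, cal)
  expect_identical(nrow(tr), 5L)
  expect_identical(count_turned_cards(tr), 5L)
  # frame order permutation leaves the count unchanged (static scene)
  set.seed(7)
  tr3 <- card_tracks()
  for (f in sample(0:14)) tr3 <- update_card_tracks(tr3, cents, f, cal)
  expect_identical(count_turned_cards(tr3), 5L)
})

bean_setup <- function() {
  list(cal = calibration(1),
       can = fake_can(c(50, 50), 12, 1),
       hand = fake_hand(c(50L, 50L, 51L, 51L), c(85L, 86L, 85L, 86L),
                        calibration(1)))   # ~23 mm outside the rim
}

blob_img <- function(base, rows, cols, value = 10L) {
  img <- base
  for (ch in 1:3) img[rows, cols, ch] <- value
  img
}

test_that("bean drops need size 5..50, extent <15 mm, in-can, near-rim, armed", {
  s <- bean_setup()
  base <- flat_rgb(100, 100, 128)
  st <- bean_drop_state()
  # identical frames: nothing
  st <- detect_bean_drop(base, base, s$can, s$hand, Inf, st, 1, s$cal)
  expect_length(st$drops, 0L)
  # 10-px transient blob inside the can, armed -> one drop
  b10 <- blob_img(base, 48:52, 50:51)
  st <- detect_bean_drop(base, b10, s$can, s$hand, Inf, st, 2, s$cal)
  expect_identical(st$drops, 2L)
  expect_false(st$armed)
  # an immediate second blob while unarmed is ignored
  st <- detect_bean_drop(base, b10, s$can, s$hand, Inf, st, 3, s$cal)
  expect_length(st$drops, 1L)
  # re-arm only once the hand is within 30 mm of the ridge
  st <- detect_bean_drop(base, base, s$can, s$hand, 45, st, 4, s$cal)
  expect_false(st$armed)
  st <- detect_bean_drop(base, base, s$can, s$hand, 25, st, 5, s$cal)
  expect_true(st$armed)

  # size band: 4 px rejected, 51 px rejected, 5 and 50 accepted
  sized <- function(npx) {
    rows <- 45 + (seq_len(npx) - 1) %% 10
    cols <- 48 + (seq_len(npx) - 1) %/% 10
    img <- base
    for (k in seq_len(npx)) img[rows[k], cols[k], ] <- 10L
    img
  }
  for (npx in c(4, 51)) {
    st0 <- detect_bean_drop(base, sized(npx), s$can, s$hand, Inf,
                            bean_drop_state(), 1, s$cal)
    expect_length(st0$drops, 0L)
  }
  for (npx in c(5, 50)) {
    st0 <- detect_bean_drop(base, sized(npx), s$can, s$hand, Inf,
                            bean_drop_state(), 1, s$cal)
    expect_length(st0$drops, 1L)
  }

  # 60-px splash inside the can: too large
  splash <- blob_img(base, 45:54, 47:52)
  st1 <- detect_bean_drop(base, splash, s$can, s$hand, Inf,
                          bean_drop_state(), 1, s$cal)
  expect_length(st1$drops, 0L)
  # extent: a 16-mm-long 2x8 bar of 16 px is rejected even though its
  # size is in band
  bar <- blob_img(base, 49:50, 43:58)
  st2 <- detect_bean_drop(base, bar, s$can, s$hand, Inf,
                          bean_drop_state(), 1, s$cal)
  expect_length(st2$drops, 0L)
  # hand too far from the rim (>50 mm): rejected
  far_hand <- fake_hand(95L + 0:1, 5L + 0:1, s$cal)
  st3 <- detect_bean_drop(base, b10, s$can, far_hand, Inf,
                          bean_drop_state(), 1, s$cal)
  expect_length(st3$drops, 0L)
  # hand pixels are excluded from the difference image: the same blob
  # with the hand sitting exactly on it is invisible
  hand_on_blob <- fake_hand(rep(48:52, 2L), rep(c(50L, 51L), each = 5L),
                            s$cal)
  st4 <- detect_bean_drop(base, b10, s$can, hand_on_blob, Inf,
                          bean_drop_state(), 1, s$cal)
  expect_length(st4$drops, 0L)
})

test_that("bean state machine never exceeds 5 drops nor fires unarmed", {
  s <- bean_setup()
  base <- flat_rgb(100, 100, 128)
  b10 <- blob_img(base, 48:52, 50:51)
  set.seed(13)
  st <- bean_drop_state()
  drops_seen <- integer(0)
  for (f in 1:60) {
    blob_now <- runif(1) < 0.5
    ridge_now <- if (runif(1) < 0.3) 20 else 100
    armed_before <- st$armed || ridge_now < 30
    st <- detect_bean_drop(base, if (blob_now) b10 else base, s$can, s$hand,
                           ridge_now, st, f, s$cal)
    new_drop <- length(st$drops) > length(drops_seen)
    if (new_drop) expect_true(armed_before && blob_now)
    drops_seen <- st$drops
    expect_lte(length(st$drops), 5L)
    expect_true(all(diff(st$drops) > 0))
  }
})

test_that("checker detection logs height above the board away from the hand", {
  cal <- calibration(1)
  h <- 120; w <- 120
  board <- fake_board(h, w, 30:90, 20:100, board_depth = 1181)
  ref <- structure(list(ref_depth = matrix(1200, h, w), n_ref = 15L),
                   class = "depth_reference")
  ref$ref_depth[30:90, 20:100] <- 1181
  mk <- function(stack_depth = NULL, rows = 55:84, cols = 55:84) {
    d <- matrix(1200L, h, w); d[30:90, 20:100] <- 1181L
    if (!is.null(stack_depth)) {
      rr <- matrix(rows, length(rows), length(cols))
      cc <- matrix(cols, length(rows), length(cols), byrow = TRUE)
      disc <- (rr - 69.5)^2 + (cc - 69.5)^2 <= 15^2
      d[rows, cols][disc] <- as.integer(stack_depth)
    }
    rgbd_frame(flat_rgb(h, w), d, 0)
  }
  no_hand <- fake_hand(integer(0), integer(0))
  # frame identical to the reference: nothing
  expect_identical(nrow(detect_checkers(mk(), ref, board, no_hand, cal)), 0L)
  # 30-mm disc 6 mm above the board, hand 100 mm away: one entry, ~6 mm
  far_hand <- fake_hand(31L + 0:1, 21L + 0:1, cal)
  log1 <- detect_checkers(mk(1175), ref, board, far_hand, cal)
  expect_identical(nrow(log1), 1L)
  expect_equal(log1$height_mm, 6, tolerance = 1e-6)
  # hand pixels 20 mm away: suppressed (>30 mm rule)
  near_hand <- fake_hand(c(40L, 40L), c(69L, 70L), cal)
  expect_identical(nrow(detect_checkers(mk(1175), ref, board, near_hand,
                                        cal)), 0L)
  # extent band [15, 60] mm: 14 and 61 rejected, 15 and 60 accepted
  strip <- function(npx) {   # single-row strip: extent exactly npx mm
    d <- matrix(1200L, h, w); d[30:90, 20:100] <- 1181L
    d[60, 40 + seq_len(npx) - 1L] <- 1160L
    rgbd_frame(flat_rgb(h, w), d, 0)
  }
  for (npx in c(14, 61))
    expect_identical(nrow(detect_checkers(strip(npx), ref, board, no_hand,
                                          cal)), 0L)
  for (npx in c(15, 60))
    expect_identical(nrow(detect_checkers(strip(npx), ref, board, no_hand,
                                          cal)), 1L)
})

test_that("count_stacked maps heights to the nearest containing interval", {
  expect_identical(count_stacked(24), 4L)        # exact stack of four
  # the fourth interval is [12, 36] mm
  expect_identical(count_stacked(12), 2L)        # contained in 2,3,4; 12=2x6
  expect_identical(count_stacked(36), 4L)
  expect_identical(count_stacked(36.01), 0L)
  # 20 mm: in intervals 3 [9,27] and 4 [12,36]; |20-18| < |20-24| -> 3
  expect_identical(count_stacked(20), 3L)
  expect_identical(count_stacked(2.9), 0L)       # below every interval
  expect_identical(count_stacked(15), 2L)        # tie |15-12|=|15-18| -> smaller
  # monotone along a clean stacking trajectory
  expect_identical(vapply(c(6, 12, 18, 24), count_stacked, integer(1)),
                   c(1L, 2L, 3L, 4L))
})
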