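test_that("detect_table finds surface and edge, errors without a transition", {
  cal <- calibration(2)
  uni <- matrix(1200L, 100, 120)
  err <- tryCatch(detect_table(uni, cal), error = identity)
  expect_s3_class(err, "mjt_edge_not_found")

  d <- matrix(1200L, 480, 64)
  d[401:480, ] <- 1900L
  tm <- detect_table(d, cal)
  expect_equal(tm$surface_depth_mm, 1200)
  expect_identical(tm$edge_row, 401L)  # first off-table row, 1-based
  expect_true(all(tm$table_mask[1:400, ]))
  expect_false(any(tm$table_mask[401:480, ]))
})

test_that("table surface estimate is median-robust to objects", {
  cal <- calibration(2)
  d <- matrix(1200L, 480, 64)
  d[401:480, ] <- 1900L
  d[50:59, 10:19] <- 900L   # 100-px object high above the table
  tm <- detect_table(d, cal)
  expect_equal(tm$surface_depth_mm, 1200)
  expect_identical(tm$edge_row, 401L)
  # any object under half the pixels leaves the median unchanged
  d2 <- d; d2[1:200, 1:30] <- 700L
  expect_equal(detect_table(d2, cal)$surface_depth_mm, 1200)
})

test_that("detect_board accepts only ridge-length groups, exactly at +/-20%", {
  cal <- calibration(1.6)   # 254 px = 406.4 mm, 381 px = 609.6 mm
  h <- 100; w <- 420
  tbl <- fake_table(h, w, edge_row = 90)
  empty <- matrix(1200L, h, w)
  expect_error(detect_board(empty, tbl, cal), class = "mjt_ridge_not_found")

  bar <- function(npx, row = 30) {   # single-row bar: extent = npx px
    d <- matrix(1200L, h, w)
    d[row, 10 + seq_len(npx) - 1L] <- 1130L
    d
  }
  expect_equal(detect_board(bar(254), tbl, cal)$ridge_extent_mm, 406.4,
               tolerance = 1e-9)                    # lower bound inclusive
  expect_error(detect_board(bar(253), tbl, cal),
               class = "mjt_ridge_not_found")       # just below
  expect_equal(detect_board(bar(381), tbl, cal)$ridge_extent_mm, 609.6,
               tolerance = 1e-9)                    # upper bound inclusive
  expect_error(detect_board(bar(382), tbl, cal),
               class = "mjt_ridge_not_found")       # just above

  d <- bar(318)                                     # 508.8 mm: accepted
  d[60, 10 + 1:125] <- 1130L                        # 200 mm distractor bar
  bm <- detect_board(d, tbl, cal)
  expect_equal(bm$ridge_extent_mm, 318 * 1.6)
  # a second passing group is an error, never a guess
  d2 <- bar(318); d2[60, 10 + 1:318] <- 1130L
  expect_error(detect_board(d2, tbl, cal), class = "mjt_ambiguous_ridge")
})

test_that("detect_board reconstructs the footprint and board height", {
  cal <- calibration(2)
  h <- 240; w <- 320
  tbl <- fake_table(h, w, edge_row = 230)
  d <- matrix(1200L, h, w)
  d[100:170, 40:280] <- 1181L           # board 19 mm proud
  d[133:136, 34 + seq_len(254)] <- 1130L  # ridge, 254 px = 508 mm
  bm <- detect_board(d, tbl, cal)
  expect_lte(abs(bm$ridge_extent_mm - 508), 0.5)
  expect_equal(bm$board_surface_depth_mm, 1181)
  expect_lt(bm$board_surface_depth_mm, tbl$surface_depth_mm)
  # footprint spans ~286 mm perpendicular to the axis (143 each side)
  rows_in <- range(which(apply(bm$board_region, 1, any)))
  expect_lte(abs(diff(rows_in) * 2 - 286), 6)
})

test_that("detect_can finds a rendered annulus and prefers 100 mm diameters", {
  cal <- calibration(2)
  blank <- flat_rgb(200, 200, 128)
  expect_error(detect_can(blank, NULL, cal), class = "mjt_can_not_found")

  annulus_rgb <- function(centers, radii) {
    img <- flat_rgb(200, 200, 200)
    rr <- matrix(1:200, 200, 200); cc <- t(rr)
    for (k in seq_along(radii)) {
      dd <- sqrt((rr - centers[[k]][1])^2 + (cc - centers[[k]][2])^2)
      ring <- abs(dd - radii[k]) <= 1.5
      inner <- dd < radii[k] - 1.5
      for (ch in 1:3) {
        m <- img[, , ch]; m[ring] <- 40L; m[inner] <- 120L
        img[, , ch] <- m
      }
    }
    img
  }
  one <- detect_can(annulus_rgb(list(c(100, 100)), 25), NULL, cal)
  expect_lte(sqrt(sum((one$center - c(100, 100))^2)), 2)
  expect_lte(abs(one$radius_mm - 50), 2)

  # 40 mm and 98 mm diameter circles: the one closest to 100 mm wins
  two <- detect_can(annulus_rgb(list(c(60, 60), c(130, 130)), c(10, 24.5)),
                    NULL, cal, radii_px = 6:30)
  expect_lte(sqrt(sum((two$center - c(130, 130))^2)), 2)
  expect_lte(abs(two$radius_mm - 49), 3)
})

test_that("depth reference is the exact per-pixel mean of the first frames", {
  f <- lapply(0:14, function(i) flat_frame(64, 64, depth = 1200, index = i))
  rec <- mjt_recording(f)
  ref <- build_depth_reference(rec)
  expect_equal(ref$ref_depth, matrix(1200, 64, 64))

  # pixel ramp 10, 20, ..., 150 averages to 80
  f2 <- lapply(0:14, function(i) flat_frame(64, 64, depth = 10 * (i + 1),
                                            index = i))
  expect_equal(build_depth_reference(mjt_recording(f2))$ref_depth[3, 3], 80)

  set.seed(5)  # equals brute-force mean on random stacks
  f3 <- lapply(0:14, function(i)
    rgbd_frame(flat_rgb(64, 64),
               matrix(sample.int(2000, 64 * 64, TRUE), 64, 64), i))
  rec3 <- mjt_recording(f3)
  brute <- Reduce(`+`, lapply(f3, `[[`, "depth")) / 15
  expect_equal(build_depth_reference(rec3)$ref_depth, brute)
  expect_error(build_depth_reference(mjt_recording(f3[1:10])),
               class = "mjt_too_short")
})
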