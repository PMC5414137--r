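# Static scene structure detection: table surface and front edge, wooden
# board and its ridge, the open can, and the depth reference image.

#' Detect the table surface and front edge in a depth image
#'
#' The table dominates the field of view, so its surface depth is the
#' median of all depth pixels. A binary image splits pixels at a depth
#' level 300 mm below (farther than) the surface: the table side holds the
#' table and everything on or above it, the other side holds the floor and
#' the subject beyond the front edge. The front edge is found per column as
#' the first table-to-off-table transition scanning downwards in the bottom
#' half of the image; `edge_row` is the median of those per-column rows.
#'
#' @param depth HxW depth matrix (mm).
#' @param cal An [calibration()].
#' @param config An [mjt_config()].
#' @return A `table_model` with `surface_depth_mm`, `edge_row` and
#'   `table_mask` (TRUE at rows above the edge, i.e. on the table side).
#' @export
detect_table <- function(depth, cal, config = mjt_config()) {
  stopifnot(is.matrix(depth))
  h <- nrow(depth); w <- ncol(depth)
  surface <- median(depth)
  table_side <- depth < surface + config$table_split_mm
  lower <- seq.int(floor(h / 2) + 1L, h)         # bottom half of the image
  edge_rows <- rep(NA_real_, w)
  sub <- table_side[lower, , drop = FALSE]
  for (j in seq_len(w)) {
    col <- sub[, j]
    # first row (within the bottom half) where table side -> off-table side
    tr <- which(!col[-1] & col[-length(col)])
    if (length(tr)) edge_rows[j] <- lower[tr[1] + 1L]
  }
  if (all(is.na(edge_rows)))
    mjt_stop("edge not found: no table-to-floor transition in the bottom half",
             "mjt_edge_not_found")
  edge_row <- as.integer(round(median(edge_rows, na.rm = TRUE)))
  mask <- matrix(FALSE, h, w)
  mask[seq_len(edge_row - 1L), ] <- TRUE
  structure(list(surface_depth_mm = surface, edge_row = edge_row,
                 table_mask = mask),
            class = "table_model")
}

#' @export
print.table_model <- function(x, ...) {
  cat(sprintf("<table_model> surface %.1f mm, edge at row %d\n",
              x$surface_depth_mm, x$edge_row))
  invisible(x)
}

#' Detect the wooden board through its ridge
#'
#' Pixels more than 50 mm above the table surface are grouped
#' (4-connected); a group whose maximal extent falls within +/-20\% of the
#' ridge length (508 mm) is the ridge. Exactly one group must pass: none
#' raises `ridge not found`, several raise `ambiguous ridge` (a silent
#' guess would corrupt all downstream timing). The board footprint is
#' reconstructed geometrically as the rectangle spanning the ridge axis
#' widened by half the board width (286/2 mm) to each side, because the
#' 19 mm board top is too close to depth noise to segment directly. The
#' board surface depth is measured from pixels of the footprint outside
#' the ridge when they are credibly above the table, else set to
#' surface - 19 mm.
#'
#' @param depth HxW depth matrix (mm).
#' @param table A [detect_table()] result.
#' @param cal An [calibration()].
#' @param config An [mjt_config()].
#' @return A `board_model` with `ridge_mask`, `ridge_axis` (2x2 matrix of
#'   (row, col) endpoints), `ridge_top_depth_mm`, `board_region`,
#'   `board_surface_depth_mm` and `ridge_extent_mm`.
#' @export
detect_board <- function(depth, table, cal, config = mjt_config()) {
  stopifnot(inherits(table, "table_model"))
  cand <- (table$surface_depth_mm - depth) > config$board_split_mm &
    table$table_mask
  labels <- label_components(cand)
  comp <- component_pixels(labels)
  lo <- (1 - config$ridge_length_tol) * config$ridge_length_mm
  hi <- (1 + config$ridge_length_tol) * config$ridge_length_mm
  ext_mm <- vapply(seq_len(comp$n), function(i)
    px_to_mm(component_extent_px(comp$rows[[i]], comp$cols[[i]]), cal),
    numeric(1))
  pass <- which(ext_mm >= lo & ext_mm <= hi)
  if (!length(pass))
    mjt_stop(sprintf("ridge not found: no group with extent in [%.1f, %.1f] mm",
                     lo, hi), "mjt_ridge_not_found")
  if (length(pass) > 1L)
    mjt_stop(sprintf("ambiguous ridge: %d candidate groups pass the length filter",
                     length(pass)), "mjt_ambiguous_ridge")
  rows <- comp$rows[[pass]]; cols <- comp$cols[[pass]]
  ridge_mask <- labels == pass
  # axis endpoints: hull point pair at maximal distance
  pts <- cbind(rows, cols)
  hp <- if (nrow(pts) > 3L) pts[chull(pts), , drop = FALSE] else pts
  dm <- as.matrix(stats::dist(hp))
  ij <- which(dm == max(dm), arr.ind = TRUE)[1, ]
  axis <- rbind(hp[ij[1], ], hp[ij[2], ])
  dimnames(axis) <- list(c("a", "b"), c("row", "col"))
  half_w_px <- (config$board_width_mm / 2) / cal$mm_per_px
  region <- axis_band_mask(nrow(depth), ncol(depth), axis, half_w_px) &
    table$table_mask
  ridge_top <- median(depth[ridge_mask])
  body <- region & !ridge_mask
  board_depth <- table$surface_depth_mm - config$board_thickness_mm
  if (any(body)) {
    med <- median(depth[body])
    if (med < table$surface_depth_mm - 5) board_depth <- med
  }
  structure(list(ridge_mask = ridge_mask, ridge_axis = axis,
                 ridge_top_depth_mm = ridge_top,
                 ridge_extent_mm = ext_mm[pass],
                 board_region = region,
                 board_surface_depth_mm = board_depth),
            class = "board_model")
}

#' @export
print.board_model <- function(x, ...) {
  cat(sprintf(
    "<board_model> ridge %.1f mm long, top depth %.1f mm; board top %.1f mm\n",
    x$ridge_extent_mm, x$ridge_top_depth_mm, x$board_surface_depth_mm))
  invisible(x)
}

# internal: mask of pixels whose projection onto the axis segment lies
# within it and whose perpendicular distance is <= half_w_px
axis_band_mask <- function(h, w, axis, half_w_px) {
  a <- axis[1, ]; b <- axis[2, ]
  ab <- b - a
  len2 <- sum(ab^2)
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  pr <- rr - a[1]; pc <- cc - a[2]
  t <- (pr * ab[1] + pc * ab[2]) / len2
  perp2 <- (pr - t * ab[1])^2 + (pc - t * ab[2])^2
  t >= 0 & t <= 1 & perp2 <= half_w_px^2
}

#' Locate the open can by a Circle Hough Transform
#'
#' A gradient-voted circle Hough transform is applied to the grey image
#' inside `search_region`: Sobel gradients at strong edge pixels cast
#' votes at +/- r along the gradient direction for every candidate radius.
#' Circle candidates above the vote threshold are deduplicated by centre
#' proximity, their radii refined from the supporting edge pixels, and the
#' candidate whose diameter is closest to the physical can diameter
#' (100 mm) is returned; ties go to the higher vote count.
#'
#' @param rgb HxWx3 image, 0..255.
#' @param search_region Logical HxW mask of the area to search (e.g. from
#'   [can_search_region()]); `NULL` searches the whole image.
#' @param cal An [calibration()].
#' @param radii_px Integer vector of candidate radii in pixels; default
#'   25..75 mm converted through `cal` (50\% around the nominal 50 mm
#'   radius).
#' @param vote_frac Minimum accumulator votes as a fraction of the circle
#'   circumference for a candidate (default 0.25).
#' @param config An [mjt_config()].
#' @return A `can_model` with `center` (row, col), `radius_mm`,
#'   `radius_px`, `votes` and `rim_mask`.
#' @export
detect_can <- function(rgb, search_region = NULL, cal,
                       radii_px = NULL, vote_frac = 0.25,
                       config = mjt_config()) {
  gray <- to_gray(rgb)
  h <- nrow(gray); w <- ncol(gray)
  if (is.null(search_region)) search_region <- matrix(TRUE, h, w)
  if (is.null(radii_px)) {
    r0 <- config$can_diameter_mm / 2
    radii_px <- seq.int(max(3L, mm_to_px(r0 * 0.5, cal)),
                        max(4L, mm_to_px(r0 * 1.5, cal)))
  }
  g <- sobel_gradients(gray)
  mag <- sqrt(g$gx^2 + g$gy^2)
  mag[!search_region] <- 0
  thr <- max(30, 0.15 * max(mag))
  edge <- which(mag > thr)
  if (!length(edge))
    mjt_stop("can not found: no edges in search region", "mjt_can_not_found")
  er <- ((edge - 1L) %% h) + 1L
  ec <- ((edge - 1L) %/% h) + 1L
  ux <- g$gy[edge] / mag[edge]   # unit gradient, col component
  uy <- g$gx[edge] / mag[edge]   # row component
  cands <- list()
  for (r in radii_px) {
    acc <- integer(h * w)
    for (s in c(-1, 1)) {
      cr <- as.integer(round(er + s * r * uy))
      cc <- as.integer(round(ec + s * r * ux))
      ok <- cr >= 1L & cr <= h & cc >= 1L & cc <= w
      if (any(ok)) {
        lin <- (cc[ok] - 1L) * h + cr[ok]
        tb <- tabulate(lin, nbins = h * w)
        acc <- acc + tb
      }
    }
    # 3x3 smoothing of the accumulator concentrates split votes
    am <- matrix(acc, h, w)
    am <- box_sum3(am)
    peak <- which.max(am)
    votes <- am[peak]
    if (votes >= vote_frac * 2 * pi * r) {
      cands[[length(cands) + 1L]] <- list(
        row = ((peak - 1L) %% h) + 1L, col = ((peak - 1L) %/% h) + 1L,
        r = r, votes = votes)
    }
  }
  if (!length(cands))
    mjt_stop("can not found: no circle above vote threshold",
             "mjt_can_not_found")
  # deduplicate candidates whose centres are within 5 px: keep best votes
  keep <- list()
  for (cd in cands[order(-vapply(cands, `[[`, numeric(1), "votes"))]) {
    dup <- any(vapply(keep, function(k)
      sqrt((k$row - cd$row)^2 + (k$col - cd$col)^2) < 5, logical(1)))
    if (!dup) keep[[length(keep) + 1L]] <- cd
  }
  # refine each kept candidate's radius from its supporting edge pixels.
  # A rim images as an annulus whose inner and outer walls both produce
  # edges; the radius is the midline of the two strongest edge-distance
  # clusters (gradient-magnitude weighted), which ignores weaker stray
  # edges from nearby scene structure. A thin circle has one cluster and
  # gets its weighted mean.
  for (i in seq_along(keep)) {
    k <- keep[[i]]
    d <- sqrt((er - k$row)^2 + (ec - k$col)^2)
    sel <- abs(d - k$r) <= max(3, 0.25 * k$r)
    keep[[i]]$r_ref <- refine_radius(d[sel], mag[edge][sel], k$r)
  }
  diam_mm <- vapply(keep, function(k) px_to_mm(2 * k$r_ref, cal), numeric(1))
  err <- abs(diam_mm - config$can_diameter_mm)
  best <- order(err, -vapply(keep, `[[`, numeric(1), "votes"))[1]
  k <- keep[[best]]
  rim <- matrix(FALSE, h, w)
  rr <- matrix(seq_len(h), h, w); cc2 <- matrix(seq_len(w), h, w, byrow = TRUE)
  dd <- sqrt((rr - k$row)^2 + (cc2 - k$col)^2)
  rim[abs(dd - k$r_ref) <= 1] <- TRUE
  structure(list(center = c(row = k$row, col = k$col),
                 radius_px = k$r_ref,
                 radius_mm = px_to_mm(k$r_ref, cal),
                 votes = k$votes, rim_mask = rim),
            class = "can_model")
}

#' @export
print.can_model <- function(x, ...) {
  cat(sprintf("<can_model> center (%d, %d), radius %.1f mm (%d votes)\n",
              x$center[1], x$center[2], x$radius_mm, x$votes))
  invisible(x)
}

#' Default search region for the open can
#'
#' A 300x300 mm window centred on the midpoint of the ridge axis and
#' shifted 150 mm proximally (towards the table edge), where the can sits
#' centrally in front of the board.
#'
#' @param h,w Image dimensions.
#' @param board A [detect_board()] result.
#' @param cal An [calibration()].
#' @param size_mm Window side length (default 300).
#' @param offset_mm Proximal shift of the window centre (default 150).
#' @return Logical HxW mask.
#' @export
can_search_region <- function(h, w, board, cal, size_mm = 300,
                              offset_mm = 150) {
  mid <- colMeans(board$ridge_axis)
  cr <- mid[1] + offset_mm / cal$mm_per_px
  half <- (size_mm / 2) / cal$mm_per_px
  rr <- matrix(seq_len(h), h, w); cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  abs(rr - cr) <= half & abs(cc - mid[2]) <= half
}

# internal: radius from edge-pixel distances d with weights w: weighted
# mean of the strongest half-pixel-binned cluster, averaged with the
# second cluster (>= 1.5 px away) when that wall is substantial
refine_radius <- function(d, w, r_fallback) {
  if (length(d) < 2L) return(r_fallback)
  bin <- round(d * 2) / 2
  bw <- tapply(w, bin, sum)
  centers <- as.numeric(names(bw))
  c1 <- centers[which.max(bw)]
  in1 <- abs(d - c1) <= 1.25
  m1 <- sum(d[in1] * w[in1]) / sum(w[in1])
  rest <- abs(centers - c1) >= 1.5
  if (!any(rest)) return(m1)
  c2 <- centers[rest][which.max(bw[rest])]
  if (bw[as.character(c2)] < 0.2 * bw[as.character(c1)]) return(m1)
  in2 <- abs(d - c2) <= 1.25
  m2 <- sum(d[in2] * w[in2]) / sum(w[in2])
  (m1 + m2) / 2
}

# internal: Sobel gradients; gx = d/drow, gy = d/dcol, zero at border
sobel_gradients <- function(x) {
  h <- nrow(x); w <- ncol(x)
  p <- matrix(0, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- x
  sh <- function(dr, dc) p[(2L + dr):(h + 1L + dr), (2L + dc):(w + 1L + dc)]
  gx <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
    (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  gy <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
    (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  gx[c(1, h), ] <- 0; gx[, c(1, w)] <- 0
  gy[c(1, h), ] <- 0; gy[, c(1, w)] <- 0
  list(gx = gx, gy = gy)
}

# internal: 3x3 box sum, zero padded
box_sum3 <- function(x) {
  h <- nrow(x); w <- ncol(x)
  p <- matrix(0, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- x
  sh <- function(dr, dc) p[(2L + dr):(h + 1L + dr), (2L + dc):(w + 1L + dc)]
  sh(-1, -1) + sh(-1, 0) + sh(-1, 1) + sh(0, -1) + sh(0, 0) + sh(0, 1) +
    sh(1, -1) + sh(1, 0) + sh(1, 1)
}

#' Build the per-pixel depth reference image
#'
#' Arithmetic mean of the depth image over the first `n_ref` frames; used
#' as the static background for checker detection.
#'
#' @param rec An [mjt_recording()] with at least `n_ref` frames.
#' @param n_ref Number of initial frames to average (default 15).
#' @return A `depth_reference` with `ref_depth` (numeric matrix) and
#'   `n_ref`.
#' @export
build_depth_reference <- function(rec, n_ref = 15) {
  stopifnot(inherits(rec, "mjt_recording"), n_ref >= 1)
  if (length(rec$frames) < n_ref)
    mjt_stop(sprintf("recording has %d frames, need %d for the reference",
                     length(rec$frames), n_ref), "mjt_too_short")
  acc <- matrix(0, nrow(rec$frames[[1]]$depth), ncol(rec$frames[[1]]$depth))
  for (i in seq_len(n_ref)) acc <- acc + rec$frames[[i]]$depth
  structure(list(ref_depth = acc / n_ref, n_ref = as.integer(n_ref)),
            class = "depth_reference")
}
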