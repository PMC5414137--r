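# Shared fixtures and independent oracles for the test suite.

# Brute-force 4-connected flood-fill labelling (queue-based), the oracle
# for label_components().
flood_fill_label <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i, j))
    lab[i, j] <- nxt
    while (length(queue)) {
      p <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        q <- p + d
        if (q[1] >= 1L && q[1] <= h && q[2] >= 1L && q[2] <= w &&
            mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
          lab[q[1], q[2]] <- nxt
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
  }
  lab
}

# canonical partition form: relabel by order of first occurrence in
# column-major scan, so two labelings agree iff the partitions agree
canonical_labels <- function(lab) {
  v <- lab[lab > 0L]
  match(v, unique(v))
}

# brute-force 5x5 binary median (majority of the zero-padded window)
brute_median5 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    s <- 0L
    for (di in -2:2) for (dj in -2:2) {
      r <- i + di; c <- j + dj
      if (r >= 1 && r <= h && c >= 1 && c <= w && mask[r, c]) s <- s + 1L
    }
    out[i, j] <- s >= 13L
  }
  out
}

# exact two-sided signed-rank p by enumeration of all 2^n sign patterns
enum_signed_rank_p <- function(d) {
  dn <- d[d != 0]
  n <- length(dn)
  if (n == 0L) return(1)
  r <- rank(abs(dn))
  w_obs <- sum(r[dn > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W <- as.numeric(signs %*% r)
  min(1, 2 * min(mean(W <= w_obs), mean(W >= w_obs)))
}

# a table_model without running detection, for unit tests of detectors
fake_table <- function(h, w, surface = 1200, edge_row = h - 10) {
  mask <- matrix(FALSE, h, w)
  mask[seq_len(edge_row - 1L), ] <- TRUE
  structure(list(surface_depth_mm = surface, edge_row = edge_row,
                 table_mask = mask), class = "table_model")
}

# a board_model with a rectangular footprint, for checker tests
fake_board <- function(h, w, region_rows, region_cols, board_depth,
                       ridge_rows = NULL, surface = 1200) {
  region <- matrix(FALSE, h, w)
  region[region_rows, region_cols] <- TRUE
  ridge <- matrix(FALSE, h, w)
  if (!is.null(ridge_rows)) ridge[ridge_rows, region_cols] <- TRUE
  axis <- rbind(a = c(mean(region_rows), min(region_cols)),
                b = c(mean(region_rows), max(region_cols)))
  colnames(axis) <- c("row", "col")
  structure(list(ridge_mask = ridge, ridge_axis = axis,
                 ridge_top_depth_mm = surface - 70,
                 ridge_extent_mm = diff(range(region_cols)) + 1,
                 board_region = region,
                 board_surface_depth_mm = board_depth),
            class = "board_model")
}

# a can_model at a given centre/radius (px), for bean tests
fake_can <- function(center, radius_px, mm_per_px = 1) {
  structure(list(center = center, radius_px = radius_px,
                 radius_mm = radius_px * mm_per_px, votes = NA_integer_,
                 rim_mask = NULL), class = "can_model")
}

# a hand_observation from explicit pixels
fake_hand <- function(rows, cols, cal = calibration(1)) {
  if (!length(rows))
    return(structure(list(present = FALSE, rows = integer(0),
                          cols = integer(0),
                          centroid = c(NA_real_, NA_real_),
                          distal_centroid = c(NA_real_, NA_real_),
                          n_candidates = 0L, frame_index = 0L),
                     class = "hand_observation"))
  obs <- structure(list(present = TRUE, rows = rows, cols = cols,
                        centroid = c(mean(rows), mean(cols)),
                        distal_centroid = c(NA_real_, NA_real_),
                        n_candidates = 1L, frame_index = 0L),
                   class = "hand_observation")
  obs$distal_centroid <- distal_centroid(obs, NA, cal)
  obs
}

# uniform grey frame constructors
flat_rgb <- function(h, w, value = 128) {
  array(as.integer(value), c(h, w, 3L))
}
flat_frame <- function(h, w, depth = 1200, value = 128, index = 0) {
  rgbd_frame(flat_rgb(h, w, value), matrix(as.integer(depth), h, w), index)
}
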