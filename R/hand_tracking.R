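# Per-frame hand segmentation and the distal-centroid distance series that
# drives all timing logic.

#' Per-pixel local work surface depth
#'
#' The hand threshold is measured against the surface directly below each
#' pixel: the ridge top over the ridge, the board top over the board, and
#' the table elsewhere.
#'
#' @param dims c(H, W).
#' @param table A [detect_table()] result.
#' @param board A [detect_board()] result, or `NULL` for the card subtest.
#' @return Numeric HxW matrix of surface depth (mm).
#' @export
surface_depth_map <- function(dims, table, board = NULL) {
  m <- matrix(table$surface_depth_mm, dims[1], dims[2])
  if (!is.null(board)) {
    m[board$board_region] <- board$board_surface_depth_mm
    m[board$ridge_mask] <- board$ridge_top_depth_mm
  }
  m
}

#' Detect the hand in one frame
#'
#' Candidate pixels lie more than `hand_height_mm` (30 mm) above the local
#' surface (table, board or ridge top, per pixel) and inside the table
#' region. 4-connected groups of at least `min_hand_px` (50, inclusive)
#' pixels qualify; the largest is taken as the hand. Absence of any
#' qualifying group is a valid result (`present = FALSE`), not an error.
#' When several groups qualify the largest wins and the observation is
#' flagged (`n_candidates`), since an occluded forearm can split.
#'
#' @param frame An [rgbd_frame()].
#' @param table A [detect_table()] result.
#' @param board A [detect_board()] result or `NULL`.
#' @param cal An [calibration()].
#' @param config An [mjt_config()].
#' @param surface Optional precomputed [surface_depth_map()] (avoids
#'   rebuilding it for every frame of a recording).
#' @return A `hand_observation` with `present`, pixel coordinates
#'   (`rows`, `cols`), `centroid`, `distal_centroid`, `n_candidates` and
#'   `frame_index`.
#' @export
detect_hand <- function(frame, table, board = NULL, cal,
                        config = mjt_config(), surface = NULL) {
  if (is.null(surface))
    surface <- surface_depth_map(dim(frame$depth), table, board)
  cand <- (surface - frame$depth) > config$hand_height_mm & table$table_mask
  labels <- label_components(cand)
  n <- max(labels)
  absent <- structure(list(present = FALSE, rows = integer(0),
                           cols = integer(0), centroid = c(NA_real_, NA_real_),
                           distal_centroid = c(NA_real_, NA_real_),
                           n_candidates = 0L,
                           frame_index = frame$index),
                      class = "hand_observation")
  if (n == 0L) return(absent)
  sizes <- tabulate(labels[labels > 0L], nbins = n)
  qual <- which(sizes >= config$min_hand_px)
  if (!length(qual)) return(absent)
  hand_lab <- qual[which.max(sizes[qual])]
  idx <- which(labels == hand_lab)
  rows <- ((idx - 1L) %% nrow(labels)) + 1L
  cols <- ((idx - 1L) %/% nrow(labels)) + 1L
  obs <- structure(list(present = TRUE, rows = rows, cols = cols,
                        centroid = pixel_centroid(rows, cols),
                        distal_centroid = c(NA_real_, NA_real_),
                        n_candidates = length(qual),
                        frame_index = frame$index),
                   class = "hand_observation")
  obs$distal_centroid <- distal_centroid(obs, table$edge_row, cal,
                                         config = config)
  obs
}

#' @export
print.hand_observation <- function(x, ...) {
  if (!x$present) cat("<hand_observation> absent\n")
  else cat(sprintf(
    "<hand_observation> %d px, distal centroid (%.1f, %.1f)\n",
    length(x$rows), x$distal_centroid[1], x$distal_centroid[2]))
  invisible(x)
}

#' Distal-part centroid of a hand observation
#'
#' The most distal hand pixel is the one farthest from the table's front
#' edge (smallest row, with the subject at the image bottom). The distal
#' centroid is the unweighted centroid of the hand pixels whose
#' row-distance from that pixel is at most 10 mm; it is the "hand
#' position" every distance series tracks.
#'
#' @param hand A present [detect_hand()] observation.
#' @param edge_row Table front edge row (unused by the computation itself,
#'   kept as an explicit statement of the orientation the band is measured
#'   against).
#' @param cal An [calibration()].
#' @param config An [mjt_config()].
#' @return c(row, col), subpixel.
#' @export
distal_centroid <- function(hand, edge_row, cal, config = mjt_config()) {
  if (!isTRUE(hand$present))
    mjt_stop("distal_centroid requires a present hand", "mjt_contract")
  r_min <- min(hand$rows)
  band <- px_to_mm(hand$rows - r_min, cal) <= config$distal_band_mm
  pixel_centroid(hand$rows[band], hand$cols[band])
}

#' Distance series from the distal centroid to a reference
#'
#' Per frame, the table-plane distance in mm from the hand's distal
#' centroid to the reference: for the table edge, the perpendicular
#' distance to `edge_row` (0 mm at the edge, positive on the table); for a
#' point, the Euclidean distance; for a circle (the can rim), the signed
#' distance to the rim, positive outside. Frames without a hand are `NA`
#' (gaps).
#'
#' @param rec An [mjt_recording()].
#' @param reference One of `list(type = "edge")`,
#'   `list(type = "point", point = c(row, col))` or
#'   `list(type = "circle", center = c(row, col), radius_px = r)`.
#' @param table,board Scene models ([detect_table()], [detect_board()] or
#'   `NULL`).
#' @param cal An [calibration()].
#' @param config An [mjt_config()].
#' @param hands Optional precomputed list of per-frame hand observations.
#' @return A numeric vector of class `distance_series`, one element per
#'   frame, `NA` at gaps.
#' @export
distance_series <- function(rec, reference, table, board = NULL, cal,
                            config = mjt_config(), hands = NULL) {
  if (is.null(hands)) {
    surface <- surface_depth_map(dim(rec$frames[[1]]$depth), table, board)
    hands <- lapply(rec$frames, detect_hand, table = table, board = board,
                    cal = cal, config = config, surface = surface)
  }
  d <- vapply(hands, function(h) {
    if (!h$present) return(NA_real_)
    reference_distance_mm(h$distal_centroid, reference, table, cal)
  }, numeric(1))
  structure(d, class = "distance_series")
}

# internal: distance (mm) from a (row, col) point to a reference spec
reference_distance_mm <- function(p, reference, table, cal) {
  switch(reference$type,
    edge = px_to_mm(max(0, table$edge_row - p[1]), cal),
    point = px_to_mm(sqrt(sum((p - reference$point)^2)), cal),
    circle = px_to_mm(sqrt(sum((p - reference$center)^2)), cal) -
      px_to_mm(reference$radius_px, cal),
    stop("unknown reference type: ", reference$type))
}
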