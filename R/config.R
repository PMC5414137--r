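#' Detection configuration: every numeric constant of the pipeline
#'
#' Returns the full set of tunable constants used by the detectors and
#' state machines, at their published defaults. All distances are mm, all
#' pixel counts are inclusive bounds. Any subset can be overridden via
#' `...`; unknown names are an error.
#'
#' The defaults are:
#' \describe{
#'   \item{table_split_mm (300)}{depth split below the table surface that
#'     separates the table side from the floor/subject side when locating
#'     the front edge.}
#'   \item{board_split_mm (50)}{height above the table at which the depth
#'     image is divided to isolate the ridge top (nominally 70 mm up).}
#'   \item{ridge_length_mm (508), ridge_length_tol (0.2)}{ridge length and
#'     the +/-20\% acceptance band for candidate groups.}
#'   \item{board_width_mm (286), board_thickness_mm (19)}{board geometry
#'     used to reconstruct the board footprint from the ridge axis.}
#'   \item{can_diameter_mm (100)}{open-can diameter; the Hough circle with
#'     the closest diameter is selected.}
#'   \item{hand_height_mm (30)}{a hand pixel must be more than this far
#'     above its local surface (table, board or ridge).}
#'   \item{min_hand_px (50)}{minimum 4-connected group size for a hand
#'     (inclusive).}
#'   \item{distal_band_mm (10)}{depth of the distal band, measured along
#'     the proximal-distal axis from the most distal hand pixel, whose
#'     pixels define the distal centroid.}
#'   \item{marker_min_px (10)}{minimum green-marker group size after the
#'     5x5 median filter (inclusive).}
#'   \item{marker_hand_excl_mm (10)}{markers closer than this to any hand
#'     pixel are discarded.}
#'   \item{track_join_mm (5), track_confirm_frames (15)}{marker centroids
#'     closer than 5 mm belong to one card; a card counts as turned once
#'     its track has 15 or more supporting frames.}
#'   \item{diff_threshold (25.5)}{frame-difference threshold, 10\% of the
#'     0-255 grey range (strict >).}
#'   \item{bean_min_px (5), bean_max_px (50), bean_max_extent_mm (15),
#'     bean_merge_mm (5)}{bean blob size band, maximum extent, and the
#'     centroid distance under which difference groups are merged.}
#'   \item{bean_hand_rim_mm (50)}{a drop only counts while the hand is
#'     within 50 mm of the can rim.}
#'   \item{bean_rearm_ridge_mm (30)}{after a drop, the next bean can only
#'     be detected once the hand has come within 30 mm of the ridge.}
#'   \item{checker_height_mm (5)}{minimum elevation above the board surface
#'     for checker foreground pixels (strict >).}
#'   \item{checker_diameter_mm (30), checker_extent_lo (0.5),
#'     checker_extent_hi (2)}{checker groups must have a maximal extent
#'     between 0.5 and 2 checker diameters (inclusive).}
#'   \item{checker_hand_excl_mm (30)}{checker groups closer than this to
#'     any hand pixel are ignored.}
#'   \item{checker_mm (6)}{height D of one checker; stack intervals are
#'     (D +/- 0.5 D) n for n in 1..4.}
#'   \item{n_ref_frames (15)}{frames averaged into the depth reference.}
#'   \item{card_cross_mm (127)}{start-crossing distance from the table
#'     edge for card turning (hand crosses the proximal card edge).}
#'   \item{feeding_cross_mm (147)}{start-crossing distance for simulated
#'     feeding (20 mm past the proximal board edge at 127 mm).}
#'   \item{stacking_cross_mm (63.5)}{start threshold on the distance to
#'     the stacking reference point (falls below).}
#'   \item{stacking_point_offset_mm (15)}{the stacking reference point
#'     sits 15 mm in front of the horizontal middle of the board edge.}
#'   \item{onset_mm_per_frame (3)}{minimum sustained displacement defining
#'     movement onset (inclusive).}
#'   \item{feeding_end_rim_mm (20)}{feeding ends once five beans are in
#'     and the hand is more than 20 mm from the rim.}
#'   \item{stack_consecutive (5)}{stacking ends at the 5th consecutive
#'     fourth-interval detection.}
#'   \item{max_gap_frames (5)}{longest hand-absent gap interpolated in the
#'     distance series before an error is raised.}
#'   \item{end_latency_correction (0)}{frames subtracted from the card
#'     end frame to undo the 15-frame confirmation latency (set to
#'     `track_confirm_frames - 1` to report the 5th flip frame itself).}
#' }
#'
#' @param ... Named overrides of any default.
#' @return A named list of class `mjt_config`.
#' @examples
#' cfg <- mjt_config(track_confirm_frames = 10)
#' @export
mjt_config <- function(...) {
  cfg <- list(
    table_split_mm = 300,
    board_split_mm = 50,
    ridge_length_mm = 508,
    ridge_length_tol = 0.2,
    board_width_mm = 286,
    board_thickness_mm = 19,
    can_diameter_mm = 100,
    hand_height_mm = 30,
    min_hand_px = 50,
    distal_band_mm = 10,
    marker_min_px = 10,
    marker_hand_excl_mm = 10,
    track_join_mm = 5,
    track_confirm_frames = 15,
    diff_threshold = 25.5,
    bean_min_px = 5,
    bean_max_px = 50,
    bean_max_extent_mm = 15,
    bean_merge_mm = 5,
    bean_hand_rim_mm = 50,
    bean_rearm_ridge_mm = 30,
    checker_height_mm = 5,
    checker_diameter_mm = 30,
    checker_extent_lo = 0.5,
    checker_extent_hi = 2,
    checker_hand_excl_mm = 30,
    checker_mm = 6,
    n_ref_frames = 15,
    card_cross_mm = 127,
    feeding_cross_mm = 147,
    stacking_cross_mm = 63.5,
    stacking_point_offset_mm = 15,
    onset_mm_per_frame = 3,
    feeding_end_rim_mm = 20,
    stack_consecutive = 5,
    max_gap_frames = 5,
    end_latency_correction = 0
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == ""))
      stop("unknown config option(s): ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  structure(cfg, class = "mjt_config")
}

#' Read a detection configuration from YAML or JSON
#'
#' The file holds a flat mapping of option name to value; options not in
#' the file keep their [mjt_config()] defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `mjt_config`.
#' @export
read_mjt_config <- function(path) {
  stopifnot(file.exists(path))
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(mjt_config, as.list(vals))
}

#' @export
print.mjt_config <- function(x, ...) {
  cat("<mjt_config>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# internal: classed error helpers so callers/tests can condition on failure modes
mjt_stop <- function(msg, class, ...) {
  stop(structure(class = c(class, "mjt_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}
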