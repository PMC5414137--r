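# RGB-D recording containers and on-disk formats.
#
# A frame pairs an 8-bit RGB image with a 16-bit depth image whose pixels
# hold the distance from the sensor in millimetres, as delivered by a
# Kinect-class sensor at 30 fps. On disk a recording is a directory of
# rgb_NNNN.png (8-bit) and depth_NNNN.tif (16-bit grayscale TIFF, value =
# mm) pairs, or a single .rds archive with arrays "rgb" (TxHxWx3) and
# "depth" (TxHxW) for compact fixtures.

#' Construct one RGB-D frame
#'
#' @param rgb HxWx3 integer array, 0..255.
#' @param depth HxW integer matrix, depth in mm (>= 0).
#' @param index 0-based frame ordinal.
#' @param frame_rate Frames per second (used to derive `time_s`).
#' @return An object of class `rgbd_frame` with fields `rgb`, `depth`,
#'   `index` and `time_s = index / frame_rate`.
#' @export
rgbd_frame <- function(rgb, depth, index, frame_rate = 30) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3L] == 3L, is.matrix(depth))
  if (!all(dim(rgb)[1:2] == dim(depth)))
    mjt_stop("rgb and depth dimensions differ", "mjt_bad_frame")
  if (any(dim(depth) < 64L))
    mjt_stop("frames must be at least 64x64", "mjt_bad_frame")
  if (any(depth < 0)) mjt_stop("negative depth values", "mjt_bad_frame")
  stopifnot(index >= 0, frame_rate > 0)
  structure(list(rgb = rgb, depth = depth, index = as.integer(index),
                 time_s = as.numeric(index) / frame_rate),
            class = "rgbd_frame")
}

#' Construct a recording from a list of frames
#'
#' @param frames List of [rgbd_frame()] objects with consecutive indices
#'   from 0.
#' @param frame_rate Frames per second (default 30).
#' @param meta Free-form named list of provenance.
#' @return An object of class `mjt_recording`.
#' @export
mjt_recording <- function(frames, frame_rate = 30, meta = list()) {
  stopifnot(is.list(frames), length(frames) >= 1L, frame_rate > 0)
  idx <- vapply(frames, function(f) f$index, integer(1))
  if (!identical(idx, seq_along(frames) - 1L))
    mjt_stop("frame indices must be consecutive from 0", "mjt_bad_recording")
  structure(list(frames = frames, frame_rate = as.numeric(frame_rate),
                 meta = meta),
            class = "mjt_recording")
}

#' @export
length.mjt_recording <- function(x) length(x$frames)

#' @export
print.mjt_recording <- function(x, ...) {
  d <- dim(x$frames[[1]]$depth)
  cat(sprintf("<mjt_recording> %d frames, %dx%d px, %.4g fps (%.2f s)\n",
              length(x$frames), d[1], d[2], x$frame_rate,
              length(x$frames) / x$frame_rate))
  invisible(x)
}

#' Save a recording to disk
#'
#' Writes either a directory of per-frame images (`rgb_NNNN.png`, 8-bit,
#' and `depth_NNNN.tif`, 16-bit grayscale TIFF with pixel value = mm) or,
#' when `path` ends in `.rds`, a single array archive with elements `rgb`
#' (TxHxWx3), `depth` (TxHxW), `frame_rate` and `meta`. Both formats are
#' lossless: [load_recording()] reproduces the recording bit-exactly.
#'
#' @param rec An [mjt_recording()].
#' @param path Output directory or `.rds` archive path.
#' @return `path`, invisibly.
#' @export
save_recording <- function(rec, path) {
  stopifnot(inherits(rec, "mjt_recording"), length(rec$frames) >= 1L)
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    d <- dim(rec$frames[[1]]$depth)
    t_ <- length(rec$frames)
    rgb <- array(0L, c(t_, d[1], d[2], 3L))
    depth <- array(0L, c(t_, d[1], d[2]))
    for (i in seq_len(t_)) {
      rgb[i, , , ] <- rec$frames[[i]]$rgb
      depth[i, , ] <- rec$frames[[i]]$depth
    }
    saveRDS(list(rgb = rgb, depth = depth, frame_rate = rec$frame_rate,
                 meta = rec$meta), path)
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) mjt_stop("cannot create directory", "mjt_io_error")
  for (f in rec$frames) {
    png::writePNG(aperm(array(f$rgb / 255, c(dim(f$rgb))), c(1, 2, 3)),
                  file.path(path, sprintf("rgb_%04d.png", f$index)))
    tiff::writeTIFF(f$depth / 65535, file.path(path,
                    sprintf("depth_%04d.tif", f$index)),
                    bits.per.sample = 16L, compression = "none")
  }
  jsonlite::write_json(list(frame_rate = rec$frame_rate, meta = rec$meta),
                       file.path(path, "recording.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Load a recording from disk
#'
#' Accepts the two formats written by [save_recording()]. For directories,
#' frames are ordered by the numeric index embedded in the file names and
#' every RGB image must have a matching depth image.
#'
#' @param path Recording directory or `.rds` archive.
#' @param frame_rate Frames per second; for directories this overrides the
#'   value stored in `recording.json` when given (default: stored value,
#'   else 30).
#' @return An [mjt_recording()].
#' @export
load_recording <- function(path, frame_rate = NULL) {
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    a <- readRDS(path)
    t_ <- dim(a$depth)[1]
    fr <- if (!is.null(frame_rate)) frame_rate else a$frame_rate
    frames <- lapply(seq_len(t_), function(i)
      rgbd_frame(array(a$rgb[i, , , ], dim(a$rgb)[2:4]),
                 matrix(a$depth[i, , ], dim(a$depth)[2], dim(a$depth)[3]),
                 i - 1L, fr))
    return(mjt_recording(frames, fr, if (is.null(a$meta)) list() else a$meta))
  }
  if (!dir.exists(path)) mjt_stop("no such recording", "mjt_io_error")
  rgb_files <- list.files(path, pattern = "^rgb_[0-9]+\\.png$")
  dep_files <- list.files(path, pattern = "^depth_[0-9]+\\.tif$")
  if (!length(rgb_files) && !length(dep_files))
    mjt_stop("empty recording", "mjt_empty_recording")
  rgb_idx <- sort(as.integer(sub("^rgb_([0-9]+)\\.png$", "\\1", rgb_files)))
  dep_idx <- sort(as.integer(sub("^depth_([0-9]+)\\.tif$", "\\1", dep_files)))
  bad <- union(setdiff(rgb_idx, dep_idx), setdiff(dep_idx, rgb_idx))
  if (length(bad))
    mjt_stop(sprintf("corrupt recording: missing pair at index %d", min(bad)),
             "mjt_corrupt_recording", index = min(bad))
  fr <- 30
  meta <- list()
  mf <- file.path(path, "recording.json")
  if (file.exists(mf)) {
    j <- jsonlite::read_json(mf, simplifyVector = TRUE)
    if (!is.null(j$frame_rate)) fr <- j$frame_rate
    if (!is.null(j$meta)) meta <- as.list(j$meta)
  }
  if (!is.null(frame_rate)) fr <- frame_rate
  frames <- lapply(seq_along(rgb_idx), function(i) {
    k <- rgb_idx[i]
    rgb01 <- png::readPNG(file.path(path, sprintf("rgb_%04d.png", k)))
    if (length(dim(rgb01)) == 2L) rgb01 <- array(rgb01, c(dim(rgb01), 3L))
    rgb <- array(as.integer(round(rgb01[, , 1:3] * 255)), dim(rgb01[, , 1:3]))
    dep01 <- tiff::readTIFF(file.path(path, sprintf("depth_%04d.tif", k)))
    depth <- matrix(as.integer(round(dep01 * 65535)), nrow(dep01), ncol(dep01))
    rgbd_frame(rgb, depth, i - 1L, fr)
  })
  mjt_recording(frames, fr, meta)
}

# ---- times tables ----------------------------------------------------------

.times_cols <- c("subject_id", "repetition", "hand", "subtest", "method",
                 "start_s", "end_s", "total_s")

#' Construct/validate a timing table
#'
#' A long-format table with one row per (subject, repetition, hand,
#' subtest, method) holding start, end and total time in seconds;
#' `total_s` must equal `end_s - start_s`.
#'
#' @param df Data frame with columns `subject_id`, `repetition` (1 or 2),
#'   `hand` (`"most"`/`"least"`), `subtest` (`"card"`, `"feeding"`,
#'   `"stacking"`), `method` (`"therapist"`, `"kinect"`,
#'   `"ground_truth"`), `start_s`, `end_s`, `total_s`.
#' @return The validated data frame with class `mjt_times`.
#' @export
times_table <- function(df) {
  missing_cols <- setdiff(.times_cols, names(df))
  if (length(missing_cols))
    mjt_stop(paste0("times table is missing column(s): ",
                    paste(missing_cols, collapse = ", ")),
             "mjt_schema_error")
  df <- as.data.frame(df)[, .times_cols]
  if (nrow(df)) {
    bad <- which(abs(df$total_s - (df$end_s - df$start_s)) > 1e-9 |
                   df$total_s < 0)
    if (length(bad))
      mjt_stop(sprintf("total_s != end_s - start_s at row %d", bad[1]),
               "mjt_validation_error", row = bad[1])
  }
  class(df) <- c("mjt_times", "data.frame")
  df
}

#' Read a timing table from CSV
#' @param path CSV path with the [times_table()] schema.
#' @return An `mjt_times` data frame.
#' @export
read_times_csv <- function(path) {
  times_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a timing table to CSV
#' @param tbl An [times_table()] (validated on the way out).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_times_csv <- function(tbl, path) {
  tbl <- times_table(tbl)
  utils::write.csv(as.data.frame(tbl), path, row.names = FALSE)
  invisible(path)
}
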