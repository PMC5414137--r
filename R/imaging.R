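# Low-level image primitives shared by all detectors.
#
# Image convention: matrices indexed [row, col], row 1 at the top of the
# image; the subject sits at the bottom (proximal side), so "distal" means
# smaller row index. Frame indices are 0-based; pixel indices are R's
# 1-based.

#' Label 4-connected components of a binary mask
#'
#' A pixel is connected to another only if it lies exactly on top of,
#' below, left or right of it (4-connectivity); this is the connectivity
#' used by every group-based detector in the pipeline.
#'
#' @param mask Logical or 0/1 numeric matrix.
#' @return Integer matrix of the same shape; 0 is background, components
#'   are numbered from 1.
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m)
  matrix(as.integer(lab), nrow(mask), ncol(mask))
}

# internal: list of components as data frames of pixel coordinates.
# Returns list(sizes, rows, cols) where rows/cols are lists per label.
component_pixels <- function(labels) {
  idx <- which(labels > 0L)
  if (!length(idx))
    return(list(n = 0L, sizes = integer(0), rows = list(), cols = list()))
  lab <- labels[idx]
  rr <- ((idx - 1L) %% nrow(labels)) + 1L
  cc <- ((idx - 1L) %/% nrow(labels)) + 1L
  n <- max(lab)
  list(n = n,
       sizes = tabulate(lab, nbins = n),
       rows = split(rr, factor(lab, levels = seq_len(n))),
       cols = split(cc, factor(lab, levels = seq_len(n))))
}

# internal: unweighted centroid (row, col) of a pixel set
pixel_centroid <- function(rows, cols) c(mean(rows), mean(cols))

#' Maximal extent of a pixel group, footprint convention
#'
#' The extent of a group is the largest pairwise distance between pixel
#' centres plus one pixel, i.e. the physical span of the pixel footprints:
#' a straight run of k pixels has extent k. Computed via the convex hull,
#' so it is fast for large groups.
#'
#' @param rows,cols Integer pixel coordinates of one group.
#' @return Extent in pixels (numeric scalar; 0 for an empty group).
#' @export
component_extent_px <- function(rows, cols) {
  n <- length(rows)
  if (n == 0L) return(0)
  if (n == 1L) return(1)
  pts <- cbind(rows, cols)
  if (n > 3L) {
    h <- chull(pts)
    pts <- pts[h, , drop = FALSE]
  }
  d2 <- as.matrix(stats::dist(pts))
  sqrt(max(d2^2)) + 1
}

#' 5x5 binary median filter
#'
#' Majority filter over the 5x5 neighbourhood (a pixel survives if at
#' least 13 of the 25 window pixels are set), with zero padding at the
#' image border. On a binary image this is exactly the 5x5 median.
#'
#' @param mask Logical or 0/1 matrix.
#' @return Logical matrix of the same shape.
#' @export
median_filter5 <- function(mask) {
  stopifnot(is.matrix(mask))
  box_sum5(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))) >= 13
}

# internal: 5x5 box sum with zero padding, via cumulative sums
box_sum5 <- function(x) {
  h <- nrow(x); w <- ncol(x)
  p <- matrix(0, h + 5L, w + 5L)
  p[3:(h + 2L), 3:(w + 2L)] <- x
  cs <- apply(apply(p, 2L, cumsum), 1L, cumsum)  # transposed integral image
  cs <- t(cs)
  # sum over rows i..i+4, cols j..j+4 of padded image, for i,j = 1..h/w
  cs2 <- rbind(0, cbind(0, cs))
  out <- cs2[6:(h + 5L), 6:(w + 5L)] - cs2[1:h, 6:(w + 5L)] -
    cs2[6:(h + 5L), 1:w] + cs2[1:h, 1:w]
  out
}

# internal: Euclidean distance (px) from every pixel to the nearest TRUE
# pixel of `mask`; Inf if mask is empty. EBImage::distmap measures distance
# to the nearest background (0) pixel, so the mask is inverted.
distance_to_mask_px <- function(mask) {
  if (!any(mask)) return(matrix(Inf, nrow(mask), ncol(mask)))
  m <- matrix(as.numeric(!mask), nrow(mask), ncol(mask))
  matrix(as.numeric(EBImage::distmap(m, metric = "euclidean")),
         nrow(mask), ncol(mask))
}

# internal: min distance (px) from a point to a pixel set
min_dist_to_pixels <- function(row, col, rows, cols) {
  if (!length(rows)) return(Inf)
  sqrt(min((rows - row)^2 + (cols - col)^2))
}

# internal: distance from point p to segment a-b (all c(row, col)), px
point_segment_dist <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt(sum((p - a)^2)))
  t <- max(0, min(1, sum((p - a) * ab) / len2))
  proj <- a + t * ab
  sqrt(sum((p - proj)^2))
}

# internal: unweighted grey conversion of an HxWx3 array, 0..255
to_gray <- function(rgb) (rgb[, , 1L] + rgb[, , 2L] + rgb[, , 3L]) / 3
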