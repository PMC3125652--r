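# Sub-pixel contour extraction from integer label masks.
#
# Coordinate convention (used everywhere in the package): pixel centers sit
# at integer coordinates, x = column index, y = row index, origin at the
# top-left pixel (1, 1), row-major rasters. Contours are taken at the 0.5
# iso-level between object (1) and background (0).
#
# The raw 0.5-level marching-squares polygon of a binary image is a
# staircase whose length overestimates smooth boundaries by up to ~8%
# locally (~5% for a circle). The package therefore extracts the 0.5-level
# contour of a Gaussian-smoothed object indicator (default sigma 1.5 px):
# for convex-scale objects the level set then tracks the true boundary with
# curvature bias of order sigma^2/(2 r), giving area errors well under 1%
# and perimeter errors well under 2% for disks of radius >= 20 px. Area is
# computed by the shoelace formula on the same polygon so that area and
# perimeter stay mutually consistent for shape descriptors.

#' Extract sub-pixel object contours from a label mask
#'
#' Traces one closed outer boundary polygon per label in an integer label
#' mask (0 = background, k > 0 = object k). The contour is the 0.5
#' iso-level of the Gaussian-smoothed per-object indicator, in pixel-center
#' coordinates. Objects whose pixel set is disconnected or contains holes
#' cannot be summarized by a single simple outline; they are skipped and
#' reported.
#'
#' @param mask Integer matrix, non-negative; 0 is background.
#' @param smooth_sigma Standard deviation (pixels) of the Gaussian used to
#'   de-alias the binary indicator before contouring.
#' @return A list of contour polygons, each a list with elements `label`
#'   (integer) and `vertices` (closed n x 2 matrix, columns `x`, `y`, first
#'   vertex repeated last). Labels with zero pixels are absent. Skipped
#'   objects are recorded in attribute `"skipped"` (data frame with columns
#'   `label`, `reason`) and reported via a single warning.
#' @export
extract_contours <- function(mask, smooth_sigma = 1.5) {
  if (!is.matrix(mask)) bm_domain_error("mask must be a matrix")
  if (any(mask < 0) || any(mask != round(mask))) {
    bm_domain_error("mask must contain only non-negative integers")
  }
  labels <- sort(unique(mask[mask > 0]))
  out <- list()
  skipped <- data.frame(label = integer(), reason = character())
  for (k in labels) {
    poly <- tryCatch(trace_label(mask, k, smooth_sigma),
                     bm_object_skip = function(e) e)
    if (inherits(poly, "condition")) {
      skipped <- rbind(skipped,
                       data.frame(label = k, reason = conditionMessage(poly)))
    } else {
      out[[length(out) + 1L]] <- poly
    }
  }
  if (nrow(skipped)) {
    warning(sprintf("skipped %d object(s): %s", nrow(skipped),
                    paste(sprintf("label %d (%s)", skipped$label,
                                  skipped$reason), collapse = "; ")),
            call. = FALSE)
  }
  attr(out, "skipped") <- skipped
  out
}

skip_object <- function(msg) {
  stop(errorCondition(msg, class = c("bm_object_skip", "bm_error")))
}

# Trace the outer boundary of one label as a closed sub-pixel polygon.
trace_label <- function(mask, k, smooth_sigma) {
  idx <- which(mask == k, arr.ind = TRUE)
  if (nrow(idx) == 0L) skip_object("no pixels")
  pad <- ceiling(3 * smooth_sigma) + 2L
  r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
  c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
  nr <- r1 - r0 + 1L + 2L * pad
  nc <- c1 - c0 + 1L + 2L * pad
  bin <- matrix(0, nr, nc)
  bin[cbind(idx[, 1] - r0 + 1L + pad, idx[, 2] - c0 + 1L + pad)] <- 1
  comp <- EBImage::bwlabel(bin)
  if (max(comp) > 1L) skip_object("disconnected pixel set")
  if (any(EBImage::fillHull(bin) != bin)) skip_object("contains holes")
  z <- EBImage::gblur(bin, sigma = smooth_sigma)
  cl <- grDevices::contourLines(x = seq_len(nr), y = seq_len(nc),
                                z = z, levels = 0.5)
  if (length(cl) == 0L) skip_object("too small to contour")
  lens <- vapply(cl, function(p) length(p$x), integer(1))
  p <- cl[[which.max(lens)]]
  # contourLines: p$x follows the first index (rows), p$y the second (cols);
  # convert to the package convention (x = column, y = row), absolute coords.
  x <- p$y + (c0 - 1L - pad)
  y <- p$x + (r0 - 1L - pad)
  if (x[1] != x[length(x)] || y[1] != y[length(y)]) {
    x <- c(x, x[1]); y <- c(y, y[1])
  }
  list(label = as.integer(k), vertices = cbind(x = x, y = y))
}

poly_vertices <- function(poly) {
  v <- if (is.list(poly) && !is.null(poly$vertices)) poly$vertices else poly
  if (!is.matrix(v) || ncol(v) != 2L) {
    bm_domain_error("polygon must be an n x 2 vertex matrix or a contour object")
  }
  # close the ring if needed
  if (v[1, 1] != v[nrow(v), 1] || v[1, 2] != v[nrow(v), 2]) {
    v <- rbind(v, v[1, ])
  }
  if (nrow(unique(v)) < 3L) bm_domain_error("degenerate polygon (< 3 distinct vertices)")
  v
}

#' Polygon area in calibrated units
#'
#' Shoelace (Green's theorem) area of a closed polygon in pixel
#' coordinates, scaled by the square of the calibration factor. The result
#' is orientation-independent.
#'
#' @param poly A contour polygon from [extract_contours()] or an n x 2
#'   vertex matrix.
#' @param microns_per_pixel Isotropic calibration factor (default 1 =
#'   pixel units).
#' @return Area in square microns (or px^2 at calibration 1).
#' @export
polygon_area <- function(poly, microns_per_pixel = 1) {
  stopifnot_positive(microns_per_pixel, "microns_per_pixel")
  v <- poly_vertices(poly)
  n <- nrow(v)
  a <- sum(v[-n, 1] * v[-1, 2] - v[-1, 1] * v[-n, 2]) / 2
  abs(a) * microns_per_pixel^2
}

#' Polygon perimeter in calibrated units
#'
#' Sum of consecutive-vertex Euclidean distances around the closed polygon,
#' scaled by the calibration factor.
#'
#' @inheritParams polygon_area
#' @return Perimeter in microns (or px at calibration 1).
#' @export
polygon_perimeter <- function(poly, microns_per_pixel = 1) {
  stopifnot_positive(microns_per_pixel, "microns_per_pixel")
  v <- poly_vertices(poly)
  sum(sqrt(diff(v[, 1])^2 + diff(v[, 2])^2)) * microns_per_pixel
}
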