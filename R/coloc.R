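# Spot-to-surface proximity statistics: shortest distances, the
# mirrored-signal specificity control, interaction fractions, the
# random-overlap expectation, and local actin intensity.

#' Shortest distance from each spot to a surface
#'
#' Per-spot Euclidean distance in µm to the nearest voxel of the surface
#' mask, computed in calibrated space; 0 for spots inside the surface.
#'
#' @param spots a `spot_set` or n x 3 matrix (z, y, x µm).
#' @param surface a `surface_mask`.
#' @param source tag recorded with the distances ("real" or "mirrored").
#' @return A `distance_set` data.frame: spot_id, z_um, y_um, x_um,
#'   distance_um, source.
#' @export
shortest_distance_spot_surface <- function(spots, surface,
                                           source = "real") {
  pts <- if (inherits(spots, "spot_set")) spots$points else as.matrix(spots)
  if (!any(surface$mask)) stop("empty surface mask")
  if (nrow(pts) == 0L) {
    return(structure(data.frame(spot_id = integer(0), z_um = numeric(0),
                                y_um = numeric(0), x_um = numeric(0),
                                distance_um = numeric(0),
                                source = character(0)),
                     class = c("distance_set", "data.frame")))
  }
  dd <- nearest_mask_distance(pts, surface$mask, surface$voxel_size)
  structure(data.frame(spot_id = seq_len(nrow(pts)), z_um = pts[, 1L],
                       y_um = pts[, 2L], x_um = pts[, 3L],
                       distance_um = dd, source = source),
            class = c("distance_set", "data.frame"))
}

#' Mirrored-spot specificity control
#'
#' Reflects spot x-coordinates about the volume's x mid-plane (y and z
#' unchanged), producing the null spot set used to test whether observed
#' spot-to-surface proximity exceeds chance. Mirroring twice restores the
#' original spots exactly.
#'
#' @param spots a `spot_set` or n x 3 matrix (z, y, x µm).
#' @param x_extent_um full x extent of the volume in µm
#'   (`dim_x * voxel_x`).
#' @return Spots of the same type with x replaced by `x_extent_um - x`.
#' @export
mirrored_control <- function(spots, x_extent_um) {
  pts <- if (inherits(spots, "spot_set")) spots$points else as.matrix(spots)
  pts[, 3L] <- x_extent_um - pts[, 3L]
  if (inherits(spots, "spot_set")) {
    spots$points <- pts
    spots
  } else pts
}

#' Crop a region of interest from a volume
#'
#' Default 10 x 10 x 10 µm. The ROI either starts at a supplied offset or
#' is placed automatically at the position (on a coarse grid) farthest
#' from both the nucleus mask and the volume border, mirroring the manual
#' rule of avoiding the nucleus and the image edge.
#'
#' @param volume 3D array.
#' @param voxel_size named c(z=, y=, x=) µm.
#' @param size_um ROI edge lengths (z, y, x) µm.
#' @param offset_um optional ROI corner (z, y, x) µm; errors if the ROI
#'   does not fit.
#' @param nucleus_mask optional logical array marking the nucleus, used by
#'   automatic placement.
#' @return list(volume = cropped array, offset_um, size_um).
#' @export
roi_crop <- function(volume, voxel_size, size_um = c(10, 10, 10),
                     offset_um = NULL, nucleus_mask = NULL) {
  d <- dim(volume)
  vs <- voxel_size[c("z", "y", "x")]
  nvox <- round(size_um / vs)
  if (any(nvox > d) || any(nvox < 1L)) stop("ROI does not fit in volume")
  if (is.null(offset_um)) {
    # coarse grid search: maximize min(distance to border, to nucleus)
    cand <- expand.grid(
      z = unique(round(seq(1L, d[1L] - nvox[1L] + 1L, length.out = 6L))),
      y = unique(round(seq(1L, d[2L] - nvox[2L] + 1L, length.out = 6L))),
      x = unique(round(seq(1L, d[3L] - nvox[3L] + 1L, length.out = 6L))))
    nuc <- if (!is.null(nucleus_mask) && any(nucleus_mask)) {
      voxel_centres_um(which(nucleus_mask), d, vs)
    } else NULL
    score <- vapply(seq_len(nrow(cand)), function(i) {
      c0 <- as.numeric(cand[i, ])
      ctr <- (c0 - 1 + nvox / 2) * vs
      half <- size_um / 2
      border <- min(ctr - half, d * vs - (ctr + half))
      if (is.null(nuc)) return(border)
      # exact distance from each nucleus voxel centre to the ROI box
      gap <- abs(sweep(nuc, 2L, ctr, `-`))
      gap <- sweep(gap, 2L, half, `-`)
      dn <- sqrt(min(rowSums(pmax(gap, 0)^2)))
      min(border, dn)
    }, numeric(1))
    c0 <- as.numeric(cand[which.max(score), ])
  } else {
    c0 <- round(offset_um / vs) + 1L
  }
  if (any(c0 < 1L) || any(c0 + nvox - 1L > d)) {
    stop("ROI does not fit in volume")
  }
  out <- volume[c0[1L]:(c0[1L] + nvox[1L] - 1L),
                c0[2L]:(c0[2L] + nvox[2L] - 1L),
                c0[3L]:(c0[3L] + nvox[3L] - 1L), drop = FALSE]
  list(volume = out, offset_um = (c0 - 1) * vs, size_um = nvox * vs)
}

#' Fraction of spots interacting with a surface
#'
#' Fraction of spots whose shortest distance to the surface is at most
#' `cutoff_um`. Used for the kinetochore-actin interaction read-out. The
#' default cutoff, 0.25 µm, is approximately the lateral resolution of the
#' high-resolution (airyscan) regime.
#'
#' @param spots a `spot_set`, n x 3 matrix, or a `distance_set` (in which
#'   case `surface` is ignored).
#' @param surface a `surface_mask`.
#' @param cutoff_um interaction distance cutoff, µm.
#' @return Fraction in [0, 1], with attribute `cutoff_um`.
#' @export
interaction_fraction <- function(spots, surface = NULL, cutoff_um = 0.25) {
  dd <- if (inherits(spots, "distance_set")) {
    spots$distance_um
  } else {
    shortest_distance_spot_surface(spots, surface)$distance_um
  }
  if (length(dd) == 0L) stop("empty spot set")
  structure(mean(dd <= cutoff_um), cutoff_um = cutoff_um)
}

#' Expected random overlap of two interaction fractions
#'
#' Independence expectation for the fraction of spots interacting with
#' both of two structures: the product of the two marginal fractions.
#'
#' @param frac_a,frac_b fractions in [0, 1].
#' @return `frac_a * frac_b`.
#' @export
expected_random_overlap <- function(frac_a, frac_b) {
  if (any(c(frac_a, frac_b) < 0) || any(c(frac_a, frac_b) > 1)) {
    stop("fractions must lie in [0, 1]")
  }
  frac_a * frac_b
}

#' Background-subtracted mean actin intensity near chromosomes
#'
#' Mean intensity in a region of interest next to the chromosome signal
#' minus the mean of a background region outside the cell; negative
#' results are clamped to 0 and flagged.
#'
#' @param frame2d 2D array `[y, x]`.
#' @param roi,background_roi lists with `y`, `x` (1-based corner indices)
#'   and `h`, `w` (extent in pixels).
#' @return Intensity (a.u.) with attribute `clamped`.
#' @export
actin_intensity_near_chromosomes <- function(frame2d, roi, background_roi) {
  get_rect <- function(r) {
    list(ys = r$y:(r$y + r$h - 1L), xs = r$x:(r$x + r$w - 1L))
  }
  a <- get_rect(roi); b <- get_rect(background_roi)
  if (length(intersect(a$ys, b$ys)) > 0L &&
      length(intersect(a$xs, b$xs)) > 0L) {
    stop("ROI and background region overlap")
  }
  d <- dim(frame2d)
  if (max(a$ys, b$ys) > d[1L] || max(a$xs, b$xs) > d[2L] ||
      min(a$ys, b$ys, a$xs, b$xs) < 1L) {
    stop("region outside the frame")
  }
  val <- mean(frame2d[a$ys, a$xs]) - mean(frame2d[b$ys, b$xs])
  structure(max(val, 0), clamped = val < 0)
}
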