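# Chromosome-clustering read-outs over time: largest pairwise distance,
# convex-hull volume, focus counts, clustering speed, fragment classes.

#' Surface or centroid points of labeled foci
#'
#' Vertex mode returns the µm centres of boundary voxels of every label
#' (the analogue of isosurface vertices); centroid mode returns one point
#' per object.
#'
#' @param foci a `labeled_foci`.
#' @param mode "vertex" (default) or "centroid".
#' @return n x 3 matrix (z, y, x µm).
#' @export
foci_points <- function(foci, mode = c("vertex", "centroid")) {
  mode <- match.arg(mode)
  if (mode == "centroid") {
    return(as.matrix(foci$objects[, c("z_um", "y_um", "x_um")]))
  }
  mask <- foci$labels > 0L
  if (!any(mask)) return(matrix(numeric(0), 0, 3))
  interior <- mask
  for (ax in 1:3) {
    interior <- interior & shift_array(mask, 1L, ax) &
      shift_array(mask, -1L, ax)
  }
  idx <- which(mask & !interior)
  if (length(idx) == 0L) idx <- which(mask)
  voxel_centres_um(idx, dim(foci$labels), foci$voxel_size)
}

#' Per-frame clustering kinetics from a focus series
#'
#' @param foci_list list of `labeled_foci`, one per frame.
#' @param times frame times in minutes.
#' @param nebd_time time of NEBD (min) on the same clock; subtracted so
#'   that reported times are minutes from NEBD.
#' @param membrane optional `surface_mask` of the cell membrane for the
#'   chromosome-to-membrane distance read-out.
#' @param mode point set for the largest pairwise distance: "vertex"
#'   (isosurface-like, default) or "centroid".
#' @return A `cluster_kinetics` data.frame: frame, time_from_nebd_min,
#'   lpd_um, hull_um3, n_foci, mean_dist_membrane_um; attribute `mode`.
#' @export
cluster_kinetics <- function(foci_list, times, nebd_time = 0,
                             membrane = NULL,
                             mode = c("vertex", "centroid")) {
  mode <- match.arg(mode)
  stopifnot(length(foci_list) == length(times))
  rows <- lapply(seq_along(foci_list), function(i) {
    f <- foci_list[[i]]
    pts <- foci_points(f, mode)
    cen <- as.matrix(f$objects[, c("z_um", "y_um", "x_um")])
    data.frame(
      frame = i,
      time_from_nebd_min = times[i] - nebd_time,
      lpd_um = as.numeric(largest_pairwise_distance(pts)),
      hull_um3 = as.numeric(convex_hull_volume(pts)),
      n_foci = nrow(f$objects),
      mean_dist_membrane_um = if (!is.null(membrane) && nrow(cen) > 0L) {
        mean_distance_to_membrane(cen, membrane)
      } else NA_real_)
  })
  out <- do.call(rbind, rows)
  attr(out, "mode") <- mode
  class(out) <- c("cluster_kinetics", "data.frame")
  out
}

#' Mean chromosome clustering speed over a time window
#'
#' The negative finite difference of the largest pairwise distance between
#' consecutive frames, averaged over the frame pairs whose midpoints fall
#' in `[start, end)` minutes from NEBD; positive values mean converging
#' chromosomes. The reporting windows used for oocytes are 0-30 and
#' 30-50 min post-NEBD. `method = "slope"` instead fits a least-squares
#' line to distance vs time over the frames in the window and returns its
#' negated slope.
#'
#' @param kinetics a `cluster_kinetics` or data.frame with columns
#'   `time_from_nebd_min` and `lpd_um`.
#' @param interval c(start, end) minutes from NEBD, half-open.
#' @param method "mean_diff" (default) or "slope".
#' @return Speed in µm/min.
#' @export
clustering_speed <- function(kinetics, interval = c(0, 30),
                             method = c("mean_diff", "slope")) {
  method <- match.arg(method)
  t <- kinetics$time_from_nebd_min
  d <- kinetics$lpd_um
  o <- order(t)
  t <- t[o]; d <- d[o]
  if (method == "slope") {
    sel <- t >= interval[1L] & t < interval[2L]
    if (sum(sel) < 2L) stop("insufficient frames in interval")
    return(-unname(stats::coef(stats::lm(d[sel] ~ t[sel]))[2L]))
  }
  mid <- (t[-1L] + t[-length(t)]) / 2
  sel <- mid >= interval[1L] & mid < interval[2L]
  if (sum(sel) < 1L || length(t) < 2L) stop("insufficient frames in interval")
  speeds <- -diff(d) / diff(t)
  mean(speeds[sel])
}

#' Time from NEBD to complete chromosome clustering
#'
#' The time from NEBD to the first frame with exactly one chromatin focus.
#' If the focus count rises again afterwards the first such frame is still
#' reported, flagged non-monotone. If no frame reaches a single focus the
#' series is reported as not clustered.
#'
#' @param counts per-frame focus counts.
#' @param times frame times, minutes.
#' @param nebd_time NEBD time (min) on the same clock.
#' @return list(time_min, status "clustered"/"not_clustered",
#'   non_monotone).
#' @export
time_to_complete_clustering <- function(counts, times, nebd_time = 0) {
  if (length(counts) == 0L) stop("empty focus count series")
  stopifnot(length(counts) == length(times))
  i <- which(counts == 1L)[1L]
  if (is.na(i)) {
    return(list(time_min = NA_real_, status = "not_clustered",
                non_monotone = FALSE))
  }
  nm <- i < length(counts) && any(counts[(i + 1L):length(counts)] > 1L)
  list(time_min = times[i] - nebd_time, status = "clustered",
       non_monotone = nm)
}

#' Classify chromatin fragments by size and kinetochore content
#'
#' Fragments below 30 µm³ are "small" (strict), at or above it "large";
#' crossed with presence of a kinetochore. The size gate separates the
#' fragments actin can still cluster through arm interactions from those
#' that need a kinetochore.
#'
#' @param volumes fragment volumes, µm³.
#' @param has_kinetochore logical vector.
#' @param size_threshold µm³; default 30.
#' @return character vector in {small_KT, small_KT_free, large_KT,
#'   large_KT_free}.
#' @export
classify_fragments <- function(volumes, has_kinetochore,
                               size_threshold = 30) {
  stopifnot(length(volumes) == length(has_kinetochore))
  size <- ifelse(volumes < size_threshold, "small", "large")
  kt <- ifelse(has_kinetochore, "KT", "KT_free")
  paste(size, kt, sep = "_")
}

#' Mean distance of chromatin foci to the cell membrane
#'
#' Mean over foci of the shortest Euclidean distance (µm) from each focus
#' centroid to the membrane surface voxels.
#'
#' @param centroids n x 3 matrix (z, y, x µm) or a `labeled_foci`.
#' @param membrane a `surface_mask` (or logical array with attribute-free
#'   mask plus `voxel_size` argument).
#' @param voxel_size required when `membrane` is a plain array.
#' @return Mean distance, µm.
#' @export
mean_distance_to_membrane <- function(centroids, membrane,
                                      voxel_size = NULL) {
  if (inherits(centroids, "labeled_foci")) {
    centroids <- as.matrix(centroids$objects[, c("z_um", "y_um", "x_um")])
  }
  if (inherits(membrane, "surface_mask")) {
    mask <- membrane$mask
    vs <- membrane$voxel_size
  } else {
    mask <- membrane
    vs <- voxel_size
    if (is.null(vs)) stop("voxel_size required for a plain mask")
  }
  if (!any(mask)) stop("membrane mask is empty")
  if (nrow(centroids) == 0L) stop("no foci")
  mean(nearest_mask_distance(centroids, mask, vs))
}
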