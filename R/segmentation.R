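#' Segment chromatin foci in a 3D volume
#'
#' Otsu threshold on the (optionally Gaussian-smoothed) volume, 26-connected
#' component labelling, removal of components below a minimum-volume gate,
#' intensity-weighted centroids in µm.
#'
#' @param volume 3D array `[z, y, x]`.
#' @param voxel_size named c(z=, y=, x=) µm; required.
#' @param smooth_sigma pre-smoothing sigma in voxels per axis (z, y, x);
#'   default 0.5 voxel in z, 1 in x/y. 0 disables.
#' @param min_volume_um3 minimum object volume retained (µm³).
#' @return A `labeled_foci` object: list with `labels` (integer array),
#'   `objects` (data.frame id, z_um, y_um, x_um, volume_um3,
#'   has_kinetochore = NA until assigned), `voxel_size`. An all-zero volume
#'   yields an empty object table.
#' @export
segment_chromatin_foci <- function(volume, voxel_size,
                                   smooth_sigma = c(0.5, 1, 1),
                                   min_volume_um3 = 0.5) {
  if (missing(voxel_size) || is.null(voxel_size)) {
    stop("voxel_size calibration is required")
  }
  stopifnot(length(dim(volume)) == 3L, all(voxel_size > 0))
  sm <- if (any(smooth_sigma > 0)) {
    gaussian_smooth(volume, smooth_sigma)
  } else volume
  th <- otsu_threshold(sm)
  mask <- sm > th
  voxvol <- prod(voxel_size)
  empty <- list(labels = array(0L, dim(volume)),
                objects = data.frame(id = integer(0), z_um = numeric(0),
                                     y_um = numeric(0), x_um = numeric(0),
                                     volume_um3 = numeric(0),
                                     has_kinetochore = logical(0)),
                voxel_size = voxel_size)
  class(empty) <- "labeled_foci"
  if (!any(mask)) return(empty)
  lab <- label_components(mask)
  counts <- tabulate(lab[lab > 0L])
  keep <- which(counts * voxvol >= min_volume_um3)
  if (length(keep) == 0L) return(empty)
  relab <- integer(length(counts))
  relab[keep] <- seq_along(keep)
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  idx <- which(lab > 0L)
  ids <- lab[idx]
  w <- as.numeric(volume[idx])
  cc <- voxel_centres_um(idx, dim(volume), voxel_size)
  sw <- tapply(w, ids, sum)
  cz <- tapply(w * cc[, 1L], ids, sum) / sw
  cy <- tapply(w * cc[, 2L], ids, sum) / sw
  cx <- tapply(w * cc[, 3L], ids, sum) / sw
  out <- list(labels = lab,
              objects = data.frame(id = seq_along(keep),
                                   z_um = as.numeric(cz),
                                   y_um = as.numeric(cy),
                                   x_um = as.numeric(cx),
                                   volume_um3 = counts[keep] * voxvol,
                                   has_kinetochore = NA),
              voxel_size = voxel_size)
  class(out) <- "labeled_foci"
  out
}

#' @export
print.labeled_foci <- function(x, ...) {
  cat(sprintf("labeled_foci: %d object(s)\n", nrow(x$objects)))
  if (nrow(x$objects) > 0L) print(utils::head(x$objects, 10L))
  invisible(x)
}

#' Flag foci that carry a kinetochore spot
#'
#' A focus has a kinetochore when any spot lies inside its label region
#' dilated by one voxel (the automated stand-in for by-eye classification
#' on the CENP-C signal).
#'
#' @param foci a `labeled_foci`.
#' @param spots a `spot_set` or n x 3 matrix of (z, y, x) µm positions.
#' @return `foci` with `objects$has_kinetochore` filled in.
#' @export
assign_kinetochores <- function(foci, spots) {
  pts <- if (inherits(spots, "spot_set")) spots$points else as.matrix(spots)
  d <- dim(foci$labels)
  vs <- foci$voxel_size
  hit <- rep(FALSE, nrow(foci$objects))
  if (!is.null(pts) && nrow(pts) > 0L) {
    for (i in seq_len(nrow(pts))) {
      v <- pmin(pmax(ceiling(pts[i, ] / vs), 1L), d)
      zr <- max(1L, v[1L] - 1L):min(d[1L], v[1L] + 1L)
      yr <- max(1L, v[2L] - 1L):min(d[2L], v[2L] + 1L)
      xr <- max(1L, v[3L] - 1L):min(d[3L], v[3L] + 1L)
      labs <- unique(foci$labels[zr, yr, xr])
      labs <- labs[labs > 0L]
      hit[labs] <- TRUE
    }
  }
  foci$objects$has_kinetochore <- hit
  foci
}

#' Segment a channel into a volume-gated surface mask
#'
#' Otsu threshold, connected components, and an inclusive volume gate at
#' both bounds; used for actin surfaces (default gate 30-1000 µm³) and for
#' membranes (gate `c(0, Inf)`).
#'
#' @param volume 3D array.
#' @param voxel_size named c(z=, y=, x=) µm.
#' @param volume_gate c(min, max) retained component volume, µm³,
#'   inclusive.
#' @param smooth_sigma pre-smoothing sigma (voxels); default none.
#' @return A `surface_mask`: list(mask logical array, labels, volumes_um3,
#'   voxel_size).
#' @export
segment_surface <- function(volume, voxel_size, volume_gate = c(30, 1000),
                            smooth_sigma = c(0, 0, 0)) {
  if (missing(voxel_size) || is.null(voxel_size)) {
    stop("voxel_size calibration is required")
  }
  stopifnot(length(volume_gate) == 2L, volume_gate[1L] <= volume_gate[2L])
  sm <- if (any(smooth_sigma > 0)) {
    gaussian_smooth(volume, smooth_sigma)
  } else volume
  th <- otsu_threshold(sm)
  mask <- sm > th
  voxvol <- prod(voxel_size)
  out <- list(mask = array(FALSE, dim(volume)),
              labels = array(0L, dim(volume)),
              volumes_um3 = numeric(0), voxel_size = voxel_size)
  class(out) <- "surface_mask"
  if (!any(mask)) return(out)
  lab <- label_components(mask)
  counts <- tabulate(lab[lab > 0L])
  vols <- counts * voxvol
  keep <- which(vols >= volume_gate[1L] & vols <= volume_gate[2L])
  if (length(keep) == 0L) return(out)
  relab <- integer(length(counts))
  relab[keep] <- seq_along(keep)
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  out$labels <- lab
  out$mask <- lab > 0L
  out$volumes_um3 <- vols[keep]
  out
}

#' Detect point-like spots in a volume
#'
#' Band-pass (difference-of-Gaussians) filtering followed by strict
#' 26-neighbourhood local-maximum detection. With a `target_count`, the
#' intensity cut is placed to return the brightest ~that many maxima
#' (all available maxima, with `underfull = TRUE`, when fewer exist).
#'
#' @param volume 3D array.
#' @param voxel_size named c(z=, y=, x=) µm.
#' @param sigma_narrow,sigma_wide DoG sigmas in µm (isotropic in µm space).
#' @param target_count optional approximate number of spots to return.
#' @param threshold optional absolute DoG response floor; default places it
#'   by Otsu on the positive response when no target count is given.
#' @return A `spot_set`: list(points n x 3 (z,y,x µm), response,
#'   underfull).
#' @export
detect_spots <- function(volume, voxel_size, sigma_narrow = 0.5,
                         sigma_wide = 1.5, target_count = NULL,
                         threshold = NULL) {
  stopifnot(length(dim(volume)) == 3L, all(voxel_size > 0))
  d <- dim(volume)
  s1 <- sigma_narrow / voxel_size
  s2 <- sigma_wide / voxel_size
  dog <- gaussian_smooth(volume, s1) - gaussian_smooth(volume, s2)
  is_max <- array(TRUE, d)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  strides <- c(1, d[1L], d[1L] * d[2L])
  for (k in seq_len(nrow(offs))) {
    sh <- dog
    for (ax in 1:3) if (offs[k, ax] != 0) sh <- shift_array(sh, offs[k, ax], ax)
    # ties between equal neighbours break by scan order: a voxel must beat
    # earlier neighbours strictly and later ones at least equal
    earlier <- sum(offs[k, ] * strides) > 0
    is_max <- is_max & (if (earlier) dog > sh else dog >= sh)
  }
  # ignore numerically-flat micro-maxima in smooth regions
  if (max(dog) <= 0) return(structure(
    list(points = matrix(numeric(0), 0, 3), response = numeric(0),
         underfull = FALSE), class = "spot_set"))
  cand <- which(is_max & dog > max(dog) * 1e-6)
  empty <- structure(list(points = matrix(numeric(0), 0, 3),
                          response = numeric(0), underfull = FALSE),
                     class = "spot_set")
  if (length(cand) == 0L) return(empty)
  resp <- dog[cand]
  ord <- order(resp, decreasing = TRUE)
  cand <- cand[ord]; resp <- resp[ord]
  underfull <- FALSE
  if (!is.null(target_count)) {
    if (length(cand) < target_count) {
      warning("fewer maxima than target_count; returning all")
      underfull <- TRUE
    } else {
      cand <- cand[seq_len(target_count)]
      resp <- resp[seq_len(target_count)]
    }
  } else {
    # default cut: Otsu over the full band-pass response, which separates
    # spot responses from the background response distribution
    thr <- threshold %||% otsu_threshold(dog)
    if (!is.finite(thr)) thr <- -Inf
    keep <- resp >= thr
    cand <- cand[keep]; resp <- resp[keep]
  }
  if (length(cand) == 0L) return(empty)
  pts <- voxel_centres_um(cand, d, voxel_size)
  colnames(pts) <- c("z_um", "y_um", "x_um")
  structure(list(points = pts, response = resp, underfull = underfull),
            class = "spot_set")
}

#' Segment the nuclear lamina as a closed contour
#'
#' Pipeline for a 2D lamina-channel frame: local contrast enhancement,
#' gradient edge detection, transformation of edge pixels to polar
#' coordinates about their centre of mass, removal of radial outliers
#' (deviation from the running median by more than 3 MAD within a +/-10
#' degree window), a cyclic smoothing-spline fit rho(theta), and expansion
#' of the fitted radius by a margin.
#'
#' @param frame2d 2D array `[y, x]`.
#' @param pixel_size named c(y=, x=) µm (isotropic assumed for the polar
#'   fit; the mean of the two is used).
#' @param expansion_um outward expansion of the fitted contour, µm
#'   (1.5 by default; 2.5 is the wide variant).
#' @param k basis dimension of the cyclic spline.
#' @param min_edge_pixels minimum edge support for a periodic fit.
#' @return A `lamina_contour`: list(poly closed (y, x) µm polyline,
#'   centre_um (y, x), theta, rho_um, expansion_um).
#' @export
segment_lamina_contour <- function(frame2d, pixel_size,
                                   expansion_um = 1.5, k = 20,
                                   min_edge_pixels = 30L) {
  stopifnot(length(dim(frame2d)) == 2L, all(pixel_size > 0))
  px <- mean(pixel_size)
  x <- gaussian_smooth(frame2d, c(1, 1))
  # local contrast enhancement: subtract a coarse background, normalise by
  # a coarse local amplitude (floored globally so flat noise stays flat)
  bg <- gaussian_smooth(x, c(8, 8))
  amp <- gaussian_smooth(abs(x - bg), c(8, 8))
  enh <- (x - bg) / (amp + 0.2 * max(amp))
  # gradient magnitude (central differences) + Otsu edge cut
  gy <- (shift_array(enh, -1L, 1L) - shift_array(enh, 1L, 1L)) / 2
  gx <- (shift_array(enh, -1L, 2L) - shift_array(enh, 1L, 2L)) / 2
  gm <- sqrt(gy^2 + gx^2)
  edges <- which(gm > otsu_threshold(gm))
  if (length(edges) < min_edge_pixels) stop("lamina not found")
  pos <- arrayInd(edges, dim(frame2d))
  yx <- sweep(pos - 0.5, 2L, pixel_size[1:2], `*`)
  com <- colMeans(yx)
  dy <- yx[, 1L] - com[1L]; dx <- yx[, 2L] - com[2L]
  theta <- atan2(dy, dx)
  rho <- sqrt(dy^2 + dx^2)
  # radial outliers: running median/MAD in 10-degree bins, +/- 1 bin
  bin <- floor((theta + pi) / (pi / 18)) %% 36L
  med <- mad <- numeric(length(theta))
  for (b in 0:35) {
    inwin <- bin %in% ((b + c(-1L, 0L, 1L)) %% 36L)
    sel <- bin == b
    if (!any(sel)) next
    m <- stats::median(rho[inwin])
    s <- stats::mad(rho[inwin])
    med[sel] <- m; mad[sel] <- s
  }
  ok <- abs(rho - med) <= 3 * pmax(mad, 0.5 * px)
  theta <- theta[ok]; rho <- rho[ok]
  if (length(theta) < min_edge_pixels) stop("lamina not found")
  fit <- mgcv::gam(rho ~ s(theta, bs = "cc", k = k),
                   knots = list(theta = c(-pi, pi)))
  tt <- seq(-pi, pi, length.out = 361L)
  rr <- as.numeric(stats::predict(fit, data.frame(theta = tt))) + expansion_um
  poly <- cbind(y = com[1L] + rr * sin(tt), x = com[2L] + rr * cos(tt))
  # polygon centroid as the nuclear centre
  y <- poly[, 1L]; x2 <- poly[, 2L]
  n <- nrow(poly) - 1L
  cr <- x2[1:n] * y[2:(n + 1L)] - x2[2:(n + 1L)] * y[1:n]
  A <- sum(cr) / 2
  centre <- c(y = sum((y[1:n] + y[2:(n + 1L)]) * cr) / (6 * A),
              x = sum((x2[1:n] + x2[2:(n + 1L)]) * cr) / (6 * A))
  structure(list(poly = poly, centre_um = centre,
                 theta = tt, rho_um = rr, expansion_um = expansion_um),
            class = "lamina_contour")
}
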