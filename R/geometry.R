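#' Largest pairwise distance between points
#'
#' Maximum Euclidean distance over all pairs of points, the quantity whose
#' decrease over time defines chromosome clustering speed. For 0 or 1 point
#' the distance is 0 by convention.
#'
#' @param points numeric matrix, one point per row (columns are coordinates
#'   in µm, conventionally z, y, x).
#' @return Length in µm, with attribute `pair` giving the (first, in scan
#'   order) row indices of a maximising pair; informational only.
#' @examples
#' largest_pairwise_distance(rbind(c(0, 0, 0), c(3, 4, 0), c(0, 0, 1)))
#' @export
largest_pairwise_distance <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n <= 1L) return(structure(0, pair = c(NA_integer_, NA_integer_)))
  if (n > 3000L) {
    # only hull vertices can realise the diameter
    hull <- convex_hull_3d(points)
    if (!hull$degenerate) {
      keep <- sort(unique(as.vector(hull$faces)))
      map <- keep
      points <- points[keep, , drop = FALSE]
      n <- nrow(points)
    } else map <- seq_len(n)
  } else map <- seq_len(n)
  dd <- stats::dist(points)
  i <- which.max(dd)
  # recover (row, col) of the dist entry
  nn <- n
  rc <- which(lower.tri(matrix(0, nn, nn)), arr.ind = TRUE)[i, ]
  structure(max(dd), pair = c(map[rc[2L]], map[rc[1L]]))
}

#' 3D convex hull of a point set
#'
#' Incremental convex hull. Used by [convex_hull_volume()]; exposed for
#' callers that need the facets themselves (e.g. to display the hull).
#'
#' @param points numeric matrix n x 3.
#' @param tol numeric, relative tolerance for visibility/coplanarity tests.
#' @return list with `faces` (m x 3 matrix of row indices into `points`,
#'   outward-oriented), `volume` (µm³ if input is in µm), and `degenerate`
#'   (TRUE when fewer than 4 points in general position exist; volume 0).
#' @export
convex_hull_3d <- function(points, tol = 1e-9) {
  pts <- unique(as.matrix(points))
  storage.mode(pts) <- "double"
  n <- nrow(pts)
  degen <- list(faces = matrix(integer(0), 0, 3), volume = 0, degenerate = TRUE)
  if (n < 4L) return(degen)
  scale <- max(apply(pts, 2L, function(v) diff(range(v))), 1)
  eps <- max(tol * scale^3, 1e-300)  # visibility test is volume-scaled

  # initial simplex from extreme points
  i1 <- which.min(pts[, 1L]); i2 <- which.max(pts[, 1L])
  if (i1 == i2) { i1 <- which.min(pts[, 2L]); i2 <- which.max(pts[, 2L]) }
  if (i1 == i2) return(degen)
  e <- pts[i2, ] - pts[i1, ]
  dvec <- pts - matrix(pts[i1, ], n, 3, byrow = TRUE)
  crossn <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  # farthest from the line i1-i2
  cr <- t(apply(dvec, 1L, function(v) crossn(e, v)))
  lind <- sqrt(rowSums(cr^2))
  i3 <- which.max(lind)
  if (lind[i3] <= eps) return(degen)
  nrm <- crossn(e, pts[i3, ] - pts[i1, ])
  h <- abs(dvec %*% nrm) / sqrt(sum(nrm^2))
  i4 <- which.max(h)
  if (h[i4] <= eps) return(degen)

  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  interior <- colMeans(pts[c(i1, i2, i3, i4), ])
  orient_out <- function(f) {
    a <- pts[f[1L], ]; b <- pts[f[2L], ]; cc <- pts[f[3L], ]
    nv <- crossn(b - a, cc - a)
    if (sum(nv * (interior - a)) > 0) f[c(1L, 3L, 2L)] else f
  }
  faces <- t(apply(faces, 1L, orient_out))
  face_normal <- function(f) {
    a <- pts[f[1L], ]
    nv <- crossn(pts[f[2L], ] - a, pts[f[3L], ] - a)
    list(n = nv, a = a)
  }

  rest <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  for (p in rest) {
    fn <- lapply(seq_len(nrow(faces)), function(k) face_normal(faces[k, ]))
    vis <- vapply(fn, function(z) sum(z$n * (pts[p, ] - z$a)) > eps, logical(1))
    if (!any(vis)) next
    vis_faces <- faces[vis, , drop = FALSE]
    faces <- faces[!vis, , drop = FALSE]
    # horizon = edges appearing exactly once among visible faces
    edges <- rbind(vis_faces[, c(1L, 2L)], vis_faces[, c(2L, 3L)],
                   vis_faces[, c(3L, 1L)])
    key <- paste(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
    horizon <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    new_faces <- cbind(horizon, p)
    interior <- colMeans(pts[unique(c(as.vector(faces), p)), , drop = FALSE])
    new_faces <- t(apply(new_faces, 1L, orient_out))
    faces <- rbind(faces, new_faces)
  }

  # signed volume sum over outward-oriented faces w.r.t. an interior point
  interior <- colMeans(pts[unique(as.vector(faces)), , drop = FALSE])
  vol <- 0
  for (k in seq_len(nrow(faces))) {
    a <- pts[faces[k, 1L], ] - interior
    b <- pts[faces[k, 2L], ] - interior
    cc <- pts[faces[k, 3L], ] - interior
    vol <- vol + sum(a * crossn(b, cc)) / 6
  }
  list(faces = faces, volume = abs(vol), degenerate = FALSE)
}

#' Volume of the 3D convex hull enclosing a point set
#'
#' The hull-volume read-out used to follow chromosome cluster compaction
#' over time. Degenerate point sets (fewer than 4 points in general
#' position, e.g. collinear or coplanar) have volume 0 and are flagged.
#'
#' @param points numeric matrix n x 3 (µm).
#' @return Volume in µm³ with attribute `degenerate`.
#' @examples
#' convex_hull_volume(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
#' @export
convex_hull_volume <- function(points) {
  h <- convex_hull_3d(points)
  structure(h$volume, degenerate = h$degenerate)
}

# Shortest distances (µm) from each query point (rows, µm) to the set of
# voxel centres of `mask` that are TRUE; exact nearest-voxel search in
# calibrated space, restricted to boundary voxels for speed. Points inside
# the mask get distance 0.
nearest_mask_distance <- function(points, mask, voxel_size) {
  d <- dim(mask)
  idx <- which(mask)
  if (length(idx) == 0L) stop("mask is empty")
  points <- as.matrix(points)
  # inside test: map each point to its containing voxel
  vox <- sweep(points, 2L, voxel_size[seq_len(ncol(points))], `/`)
  vox <- pmin(pmax(ceiling(vox), 1L), matrix(d, nrow(points), length(d), byrow = TRUE))
  inside <- mask[vox]
  # boundary voxels suffice for outside points
  interior <- mask
  for (ax in seq_along(d)) {
    interior <- interior & shift_array(mask, 1L, ax) & shift_array(mask, -1L, ax)
  }
  bidx <- which(mask & !interior)
  if (length(bidx) == 0L) bidx <- idx
  sv <- voxel_centres_um(bidx, d, voxel_size)
  out <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    if (inside[i]) { out[i] <- 0; next }
    dv <- sweep(sv, 2L, points[i, ], `-`)
    out[i] <- sqrt(min(rowSums(dv^2)))
  }
  out
}
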