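# Independent oracles and small fixtures used across the suite.

# Brute-force 3D convex hull volume: enumerate all point triples, keep the
# planes with every other point on one side (facets), sum signed
# tetrahedra about the centroid. O(n^4); for general-position point sets.
brute_hull_volume <- function(pts, tol = 1e-9) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  if (n < 4L) return(0)
  ctr <- colMeans(pts)
  crossn <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  vol <- 0
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- pts[i, ]; b <- pts[j, ]; cc <- pts[k, ]
    nv <- crossn(b - a, cc - a)
    if (sqrt(sum(nv^2)) < tol) next
    s <- as.vector((pts - matrix(a, n, 3, byrow = TRUE)) %*% nv)
    if (all(s <= tol) || all(s >= -tol)) {
      # a hull facet; the centroid is interior, so each facet's tetrahedron
      # about the centroid contributes its absolute volume exactly once
      vol <- vol + abs(det(rbind(a - ctr, b - ctr, cc - ctr))) / 6
    }
  }
  vol
}

# Exhaustive nearest-voxel distance: min over every TRUE voxel centre.
brute_mask_distance <- function(points, mask, voxel_size) {
  idx <- which(mask)
  cc <- ooclust:::voxel_centres_um(idx, dim(mask), voxel_size)
  apply(as.matrix(points), 1L, function(p) {
    sqrt(min(rowSums(sweep(cc, 2L, p, `-`)^2)))
  })
}

# Bilinear rotation of an image about its centre (deg); edge-padded with
# the image mean so PIV windows at the rim stay well-behaved.
rotate_image <- function(img, theta_deg) {
  d <- dim(img)
  th <- theta_deg * pi / 180
  cy <- (d[1L] + 1) / 2; cx <- (d[2L] + 1) / 2
  out <- matrix(mean(img), d[1L], d[2L])
  yy <- matrix(seq_len(d[1L]), d[1L], d[2L])
  xx <- matrix(seq_len(d[2L]), d[1L], d[2L], byrow = TRUE)
  # inverse map
  ys <- cy + cos(th) * (yy - cy) + sin(th) * (xx - cx)
  xs <- cx - sin(th) * (yy - cy) + cos(th) * (xx - cx)
  y0 <- floor(ys); x0 <- floor(xs)
  ok <- y0 >= 1 & x0 >= 1 & y0 < d[1L] & x0 < d[2L]
  fy <- ys - y0; fx <- xs - x0
  iy <- y0[ok]; ix <- x0[ok]
  lin <- function(dy, dx) img[cbind(iy + dy, ix + dx)]
  out[ok] <- lin(0, 0) * (1 - fy[ok]) * (1 - fx[ok]) +
    lin(0, 1) * (1 - fy[ok]) * fx[ok] +
    lin(1, 0) * fy[ok] * (1 - fx[ok]) +
    lin(1, 1) * fy[ok] * fx[ok]
  out
}

# von Mises sampler (Best & Fisher rejection), mean mu_deg, concentration
# kappa; returns degrees.
rvonmises <- function(n, mu_deg, kappa) {
  mu <- mu_deg * pi / 180
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1L])
    f <- (1 + r * z) / (r + z)
    cv <- kappa * (r - f)
    if (u[2L] < cv * (2 - cv) || u[2L] <= cv * exp(1 - cv)) {
      out[i] <- mu + sign(u[3L] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  (out * 180 / pi) %% 360
}

# Small no-noise scenario used by several segmentation tests.
quiet_scenario <- function(...) {
  oocyte_scenario(noise = list(gaussian_sd = 0, poisson_scale = 0), ...)
}
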