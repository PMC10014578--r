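vox_iso <- c(z = 0.5, y = 0.5, x = 0.5)

test_that("disjoint blobs are segmented with accurate centroids", {
  ctrs <- rbind(c(5, 5, 5), c(5, 14, 14))
  vol <- ooclust:::render_solid_blobs(c(40, 40, 40), vox_iso, ctrs, 1.5, 200)
  f <- segment_chromatin_foci(vol, vox_iso)
  expect_equal(nrow(f$objects), 2L)
  got <- as.matrix(f$objects[, c("z_um", "y_um", "x_um")])
  err <- apply(ctrs, 1, function(p) sqrt(min(colSums((t(got) - p)^2))))
  expect_true(all(err <= 0.5))  # within one voxel
})

test_that("empty volumes and over-aggressive gates give empty foci sets", {
  f0 <- segment_chromatin_foci(array(0, c(10, 10, 10)), vox_iso)
  expect_equal(nrow(f0$objects), 0L)
  vol <- ooclust:::render_solid_blobs(c(30, 30, 30), vox_iso,
                                      matrix(c(7, 7, 7), 1), 1.5, 200)
  fgate <- segment_chromatin_foci(vol, vox_iso, min_volume_um3 = 1000)
  expect_equal(nrow(fgate$objects), 0L)
  expect_error(segment_chromatin_foci(vol, NULL), "calibration")
})

test_that("labels conserve foreground voxels and scale with calibration", {
  set.seed(13)
  ctrs <- cbind(runif(4, 4, 16), runif(4, 4, 16), runif(4, 4, 16))
  vol <- ooclust:::render_solid_blobs(c(40, 40, 40), vox_iso, ctrs, 1.2, 200)
  f <- segment_chromatin_foci(vol, vox_iso, min_volume_um3 = 0)
  th_mask_count <- sum(f$labels > 0L)
  expect_equal(sum(f$objects$volume_um3) / prod(vox_iso), th_mask_count)
  # scaling the voxel size by s scales volumes by s^3 and centroids by s
  f2 <- segment_chromatin_foci(vol, vox_iso * 2, min_volume_um3 = 0)
  expect_equal(f2$objects$volume_um3, f$objects$volume_um3 * 8)
  expect_equal(f2$objects$z_um, f$objects$z_um * 2)
})

test_that("surface masks apply the volume gate inclusively at both bounds", {
  vs <- c(z = 1, y = 1, x = 1)
  # three cubes of 20, 500 and 2000 um3 (voxel volume 1)
  vol <- array(0, c(20, 20, 60))
  vol[2:6, 2:3, 2:3] <- 200                      # 20 voxels = 20 um3
  vol[2:11, 6:15, 10:14] <- 200                  # 500
  vol[1:10, 1:20, 21:30] <- 200                  # 2000
  s <- segment_surface(vol, vs, volume_gate = c(30, 1000))
  expect_equal(length(s$volumes_um3), 1L)
  expect_equal(s$volumes_um3, 500)
  # identity gate keeps every component
  s_all <- segment_surface(vol, vs, volume_gate = c(0, Inf))
  expect_equal(sort(s_all$volumes_um3), c(20, 500, 2000))
  # empty input
  s0 <- segment_surface(array(0, c(8, 8, 8)), vs)
  expect_false(any(s0$mask))
  # boundary: a component of exactly 30 um3 is retained
  vol30 <- array(0, c(10, 10, 10))
  vol30[3:7, 3:8, 4] <- 200  # 30 voxels
  s30 <- segment_surface(vol30, vs, volume_gate = c(30, 1000))
  expect_equal(s30$volumes_um3, 30)
})

test_that("26-connectivity joins diagonal voxels into one component", {
  m <- array(FALSE, c(4, 4, 4))
  m[1, 1, 1] <- TRUE
  m[2, 2, 2] <- TRUE  # corner-adjacent
  lab <- ooclust:::label_components(m)
  expect_equal(max(lab), 1L)
})

test_that("point sources are detected at their positions", {
  set.seed(7)
  # well-separated sources
  pts <- as.matrix(expand.grid(c(5, 15), c(5, 15), c(5, 15)))
  pts <- pts + matrix(runif(length(pts), -1, 1), nrow(pts))
  vol <- ooclust:::render_blobs(c(40, 40, 40), vox_iso, pts, 0.4, 200, "sum")
  sp <- detect_spots(vol, vox_iso)
  expect_equal(nrow(sp$points), nrow(pts))
  err <- apply(pts, 1, function(p) sqrt(min(colSums((t(sp$points) - p)^2))))
  expect_true(all(err <= 0.5))
  # flat volume: nothing
  expect_equal(nrow(detect_spots(array(1, c(10, 10, 10)), vox_iso)$points), 0L)
})

test_that("a spot target count is honoured and underfull sets are flagged", {
  set.seed(8)
  tex <- array(runif(10 * 64 * 64), c(10, 64, 64))
  sp <- detect_spots(tex, vox_iso, target_count = 100)
  expect_gte(nrow(sp$points), 90L)
  expect_lte(nrow(sp$points), 110L)
  # more requested than exist
  one <- ooclust:::render_blobs(c(20, 20, 20), vox_iso,
                                matrix(c(5, 5, 5), 1), 0.4, 200, "sum")
  expect_warning(spu <- detect_spots(one, vox_iso, target_count = 50),
                 "fewer")
  expect_true(spu$underfull)
})

test_that("lamina contour recovers circles, centres and the expansion margin", {
  px <- c(y = 0.25, x = 0.25)
  n <- 200
  yy <- outer((1:n - 0.5) * 0.25 - 25, rep(1, n))
  xx <- t(yy)
  set.seed(3)
  ring <- function(r0) 150 * exp(-(sqrt(yy^2 + xx^2) - r0)^2 / (2 * 0.5^2)) +
    matrix(rnorm(n * n, 0, 2), n, n)
  ct <- segment_lamina_contour(ring(20), px, expansion_um = 1.5)
  expect_equal(mean(ct$rho_um), 21.5, tolerance = 0.5)
  expect_equal(unname(ct$centre_um), c(25, 25), tolerance = 0.5)
  # zero expansion on a noiseless circle: radius within one pixel
  ct0 <- segment_lamina_contour(150 * exp(-(sqrt(yy^2 + xx^2) - 20)^2 /
                                            (2 * 0.5^2)),
                                px, expansion_um = 0)
  expect_equal(mean(ct0$rho_um), 20, tolerance = 0.25)
  # ellipse: centre within 1 um of truth
  ell <- 150 * exp(-(sqrt((yy / 1.3)^2 + (xx / 0.8)^2) - 15)^2 / (2 * 0.5^2)) +
    matrix(rnorm(n * n, 0, 2), n, n)
  cte <- segment_lamina_contour(ell, px)
  expect_equal(unname(cte$centre_um), c(25, 25), tolerance = 1)
  # featureless frame: no lamina
  expect_error(segment_lamina_contour(matrix(0, 50, 50), px), "lamina")
})

test_that("kinetochore flags attach to the focus containing the spot", {
  ctrs <- rbind(c(5, 5, 5), c(5, 14, 14))
  vol <- ooclust:::render_solid_blobs(c(40, 40, 40), vox_iso, ctrs, 1.5, 200)
  f <- segment_chromatin_foci(vol, vox_iso)
  f <- assign_kinetochores(f, matrix(c(5, 14, 14), 1))
  hit <- f$objects$has_kinetochore
  expect_equal(sum(hit), 1L)
  d_hit <- sqrt(sum((as.numeric(f$objects[hit, c("z_um", "y_um", "x_um")]) -
                       c(5, 14, 14))^2))
  expect_lt(d_hit, 1)
})
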