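vox <- c(z = 0.25, y = 0.25, x = 0.25)

make_surface <- function(mask) {
  structure(list(mask = mask, voxel_size = vox), class = "surface_mask")
}

test_that("spot-surface distances match geometry and the exhaustive oracle", {
  d <- c(40, 40, 40)
  # a plane surface at x = 5 um
  mask <- array(FALSE, d)
  mask[, , 20] <- TRUE
  surf <- make_surface(mask)
  dd <- shortest_distance_spot_surface(matrix(c(5, 5, 4.875 + 3), 1), surf)
  expect_equal(dd$distance_um, 3, tolerance = sqrt(sum(vox^2)) / 2)
  # a spot inside the surface has distance 0
  inside <- ooclust:::voxel_centres_um(which(mask)[5], d, vox)
  expect_equal(shortest_distance_spot_surface(inside, surf)$distance_um, 0)
  # random spots against min-over-all-voxels
  set.seed(41)
  ball <- ooclust:::radius_grid(d, vox, c(5, 5, 5)) < 2
  surf_b <- make_surface(ball)
  pts <- cbind(runif(50, 1, 9), runif(50, 1, 9), runif(50, 1, 9))
  got <- shortest_distance_spot_surface(pts, surf_b)$distance_um
  want <- brute_mask_distance(pts, ball, vox)
  expect_true(all(abs(got - want) <= sqrt(sum(vox^2)) / 2 + 1e-12))
  expect_error(shortest_distance_spot_surface(pts,
    make_surface(array(FALSE, d))), "empty")
})

test_that("mirroring is an involution about the x mid-plane", {
  set.seed(43)
  pts <- cbind(runif(20, 0, 10), runif(20, 0, 10), runif(20, 0, 10))
  xe <- 10
  expect_equal(mirrored_control(mirrored_control(pts, xe), xe), pts)
  on_plane <- matrix(c(1, 2, 5), 1)
  expect_equal(mirrored_control(on_plane, 10), on_plane)
})

test_that("mirrored spots lose programmed colocalization", {
  # surface on one side of the volume, spots on it
  g <- generate_kinetochore_actin_volume(seed = 9, interact_prob = 0.75,
                                         n_spots = 30, n_cables = 8,
                                         cable_length_um = 14)
  surf <- segment_surface(g$volumes$actin, g$voxel_size,
                          volume_gate = c(30, 1000))
  sp <- as.matrix(g$truth[, c("z_um", "y_um", "x_um")])
  d_real <- shortest_distance_spot_surface(sp, surf)$distance_um
  xe <- dim(g$volumes$actin)[3] * g$voxel_size[["x"]]
  d_mir <- shortest_distance_spot_surface(mirrored_control(sp, xe),
                                          surf)$distance_um
  expect_gt(median(d_mir), median(d_real))
})

test_that("interaction fractions respect cutoffs, mirror symmetry and monotonicity", {
  d <- c(40, 40, 40)
  mask <- array(FALSE, d)
  mask[10:20, 10:20, 10:20] <- TRUE
  surf <- make_surface(mask)
  inside <- ooclust:::voxel_centres_um(which(mask)[c(100, 400, 900)], d, vox)
  expect_equal(as.numeric(interaction_fraction(inside, surf, 0.25)), 1)
  outside <- rbind(c(1, 1, 1), c(9, 9, 1))
  expect_equal(as.numeric(interaction_fraction(outside, surf, 0)), 0)
  expect_error(interaction_fraction(matrix(numeric(0), 0, 3), surf), "empty")
  # mirror invariance: mirroring spots and surface together changes nothing
  set.seed(47)
  pts <- cbind(runif(30, 0.5, 9.5), runif(30, 0.5, 9.5), runif(30, 0.5, 9.5))
  xe <- d[3] * vox[["x"]]
  mmask <- mask[, , rev(seq_len(d[3]))]
  f1 <- as.numeric(interaction_fraction(pts, surf, 0.5))
  f2 <- as.numeric(interaction_fraction(mirrored_control(pts, xe),
                                        make_surface(mmask), 0.5))
  expect_identical(f1, f2)
  # non-decreasing in the cutoff
  fr <- sapply(c(0, 0.25, 0.5, 1, 2, 4), function(ct)
    as.numeric(interaction_fraction(pts, surf, ct)))
  expect_true(all(diff(fr) >= 0))
})

test_that("random-overlap expectation is the product of fractions", {
  expect_equal(expected_random_overlap(0.18, 0.5), 0.09)
  expect_equal(expected_random_overlap(0.4, 0), 0)
  expect_equal(expected_random_overlap(1, 1), 1)
  expect_error(expected_random_overlap(1.2, 0.5), "0, 1")
})

test_that("ROI crops have exact geometry and avoid the nucleus", {
  vol <- array(rnorm(64 * 64 * 64), c(64, 64, 64))
  rc <- roi_crop(vol, vox, size_um = c(10, 10, 10),
                 offset_um = c(2, 2, 2))
  expect_equal(dim(rc$volume), c(40, 40, 40))
  expect_equal(unname(rc$size_um), c(10, 10, 10))
  expect_error(roi_crop(vol, vox, size_um = c(10, 10, 10),
                        offset_um = c(12, 12, 12)), "fit")
  expect_error(roi_crop(vol, vox, size_um = c(20, 20, 20)), "fit")
  # automatic placement stays clear of a nucleus mask
  nuc <- ooclust:::radius_grid(dim(vol), vox, c(8, 8, 8)) < 3
  rc_auto <- roi_crop(vol, vox, size_um = c(4, 4, 4), nucleus_mask = nuc)
  lo <- rc_auto$offset_um
  hi <- lo + rc_auto$size_um
  nuc_pts <- ooclust:::voxel_centres_um(which(nuc), dim(vol), vox)
  in_roi <- nuc_pts[, 1] > lo[1] & nuc_pts[, 1] < hi[1] &
    nuc_pts[, 2] > lo[2] & nuc_pts[, 2] < hi[2] &
    nuc_pts[, 3] > lo[3] & nuc_pts[, 3] < hi[3]
  expect_false(any(in_roi))
})

test_that("actin intensity is background-subtracted and clamped", {
  fr <- matrix(20, 60, 60)
  fr[10:19, 10:19] <- 100
  v <- actin_intensity_near_chromosomes(
    fr, roi = list(y = 10, x = 10, h = 10, w = 10),
    background_roi = list(y = 40, x = 40, h = 10, w = 10))
  expect_equal(as.numeric(v), 80)
  expect_false(attr(v, "clamped"))
  # roi equal to background texture: ~0
  set.seed(51)
  fr2 <- matrix(rnorm(60 * 60, 50, 1), 60, 60)
  v2 <- actin_intensity_near_chromosomes(
    fr2, roi = list(y = 5, x = 5, h = 10, w = 10),
    background_roi = list(y = 40, x = 40, h = 10, w = 10))
  expect_lt(as.numeric(v2), 1)
  expect_error(actin_intensity_near_chromosomes(
    fr, roi = list(y = 10, x = 10, h = 10, w = 10),
    background_roi = list(y = 15, x = 15, h = 10, w = 10)), "overlap")
  # programmed amplitude recovered without noise
  fr3 <- matrix(10, 60, 60)
  fr3[20:29, 20:29] <- 10 + 37
  v3 <- actin_intensity_near_chromosomes(
    fr3, roi = list(y = 20, x = 20, h = 10, w = 10),
    background_roi = list(y = 45, x = 45, h = 10, w = 10))
  expect_equal(as.numeric(v3), 37, tolerance = 37 * 0.05)
})
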