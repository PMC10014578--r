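test_that("scenario invariants are enforced", {
  expect_error(oocyte_scenario(nucleus_radius = 70, cell_radius = 60))
  expect_error(oocyte_scenario(actin_inward_fraction = 1.2))
  expect_error(oocyte_scenario(convergence_speed = -1))
  expect_error(oocyte_scenario(fragment_mode = TRUE))
  expect_error(oocyte_scenario(fragment_mode = TRUE,
                               fragment_volumes = c(10, -5)))
  # too many chromosomes to fit without overlap
  expect_error(generate_oocyte_series(
    oocyte_scenario(n_chromosomes = 200, nucleus_radius = 5)),
    "overlap")
})

test_that("identical scenario and seed give bit-identical output", {
  a <- generate_oocyte_series(oocyte_scenario(seed = 7, n_frames = 4))
  b <- generate_oocyte_series(oocyte_scenario(seed = 7, n_frames = 4))
  expect_identical(a, b)
  c <- generate_oocyte_series(oocyte_scenario(seed = 8, n_frames = 4))
  expect_false(identical(a$series$frames, c$series$frames))
})

test_that("truth largest-pairwise-distance follows the programmed kinetics", {
  # zero convergence: constant distance
  z <- generate_oocyte_series(oocyte_scenario(seed = 2, convergence_speed = 0,
                                              n_frames = 6))
  expect_equal(diff(z$truth$lpd$lpd_um), rep(0, 5))
  # single object: distance 0 everywhere
  s1 <- generate_oocyte_series(oocyte_scenario(seed = 2, n_chromosomes = 1,
                                               n_frames = 4))
  expect_equal(s1$truth$lpd$lpd_um, rep(0, 4))
  # 0.5 um/min at 5-min frames: consecutive post-NEBD differences 2.5 um
  g <- generate_oocyte_series(oocyte_scenario(seed = 1,
                                              convergence_speed = 0.5,
                                              frame_interval = 5,
                                              n_frames = 10))
  lpd <- g$truth$lpd$lpd_um
  nf <- g$truth$nebd_frame
  floor_um <- 2 * g$truth$scenario$chromosome_radius
  post <- diff(lpd)[nf:(length(lpd) - 1)]
  post <- post[lpd[-1][nf:(length(lpd) - 1)] > floor_um]
  expect_equal(post, rep(-2.5, length(post)), tolerance = 1e-9)
  # slope equals -convergence_speed before the floor (1e-6)
  tt <- g$truth$lpd$time_from_nebd_min
  sel <- tt >= 0 & lpd > floor_um
  fit <- stats::lm(lpd[sel] ~ tt[sel])
  expect_equal(unname(stats::coef(fit)[2]), -0.5, tolerance = 1e-6)
})

test_that("truth centroids stay inside the nucleus and are conserved per frame", {
  g <- generate_oocyte_series(oocyte_scenario(seed = 3, n_frames = 6))
  obj <- g$truth$objects
  expect_equal(as.integer(table(obj$frame)), rep(12L, 6L))
  ctr <- g$truth$centre_um
  r <- sqrt((obj$z_um - ctr[1])^2 + (obj$y_um - ctr[2])^2 +
              (obj$x_um - ctr[3])^2)
  expect_true(all(r <= g$truth$scenario$nucleus_radius))
})

test_that("dextran fills the nucleus at NEBD within two frames", {
  g <- generate_oocyte_series(quiet_scenario(seed = 4, nebd_time = 15,
                                             n_frames = 8))
  nf <- g$truth$nebd_frame
  ctr <- g$truth$centre_um
  vs <- g$series$voxel_size
  nuc_mean <- function(i) {
    sphere_mean_intensity(get_channel(g$series, i, "dextran"), vs, ctr,
                          diameter_um = 8)
  }
  expect_lt(nuc_mean(nf - 1L), 1)
  expect_gt(nuc_mean(nf + 1L), 90)  # cytoplasmic level is 100
})

test_that("flow truth angles reflect the programmed directionality", {
  # fully inward: every truth angle relative to the centre is 0
  fi <- generate_flow_frames(oocyte_scenario(seed = 1,
                                             actin_inward_fraction = 1,
                                             n_frames = 5))
  expect_true(all(abs(fi$truth$angle_to_centre_deg) < 1e-9))
  # isotropic: truth angles uniform on the circle (Rayleigh at n >= 1000)
  f0 <- generate_flow_frames(oocyte_scenario(seed = 2,
                                             actin_inward_fraction = 0,
                                             n_frames = 40))
  ang <- f0$truth$angle_to_centre_deg
  expect_gte(length(ang), 1000L)
  expect_gt(rayleigh_test(ang)$p_value, 0.05)
  # imposed uniform translation: truth vectors all equal it
  ft <- generate_flow_frames(oocyte_scenario(seed = 3,
                                             flow_translation = c(2, 0),
                                             n_frames = 4))
  expect_true(all(ft$truth$vy_px == 2 & ft$truth$vx_px == 0))
})

test_that("fragment truth labels and speeds follow the 30 um3 kinetochore rule", {
  sc <- oocyte_scenario(seed = 5, fragment_mode = TRUE,
                        fragment_volumes = c(10, 50),
                        fragment_kinetochore = c(FALSE, TRUE), n_frames = 4)
  fr <- generate_fragments(sc)
  t1 <- fr$truth$objects[fr$truth$objects$frame == 1L, ]
  expect_setequal(t1$class, c("small_KT_free", "large_KT"))
  expect_equal(t1$speed_um_min[t1$class == "small_KT_free"],
               sc$slow_factor * sc$convergence_speed)
  expect_equal(t1$speed_um_min[t1$class == "large_KT"], sc$convergence_speed)
  # all fragments above the gate: no small class at all
  big <- generate_fragments(oocyte_scenario(seed = 5, fragment_mode = TRUE,
                                            fragment_volumes = c(40, 60, 95),
                                            n_frames = 3))
  expect_false(any(grepl("^small", big$truth$objects$class)))
  expect_error(generate_oocyte_series(
    oocyte_scenario(fragment_mode = TRUE, fragment_volumes = c(1, 0))))
})

test_that("a rendered solid sphere has its nominal volume at half maximum", {
  for (r in c(1.0, 1.5, 2.2)) {
    v <- ooclust:::render_solid_blobs(c(60, 60, 60), c(0.2, 0.2, 0.2),
                                      matrix(c(6, 6, 6), 1), r, 200)
    vol <- sum(v >= 100) * 0.2^3
    expect_equal(vol, 4 / 3 * pi * r^3, tolerance = 0.1)
  }
})

test_that("programmed kinetochore-actin contact matches its truth table", {
  g <- generate_kinetochore_actin_volume(seed = 3)
  surf <- segment_surface(g$volumes$actin, g$voxel_size,
                          volume_gate = c(30, 1000))
  dd <- shortest_distance_spot_surface(
    as.matrix(g$truth[, c("z_um", "y_um", "x_um")]), surf)
  expect_equal(dd$distance_um[g$truth$interacting],
               rep(0, sum(g$truth$interacting)))
  expect_true(all(dd$distance_um[!g$truth$interacting] > 0.25))
})
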