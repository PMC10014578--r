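make_texture <- function(seed = 1, n = 128) {
  set.seed(seed)
  ooclust:::gaussian_smooth(matrix(runif(n * n, 0, 200), n, n), c(0.7, 0.7))
}

test_that("translational stabilization recovers programmed shifts", {
  tex <- make_texture(2)
  shifted <- ooclust:::translate_image(tex, -3, 2)  # content moves (+3, -2)
  sh <- ooclust:::estimate_shift(tex, shifted)
  expect_equal(unname(sh), c(3, -2), tolerance = 0.2)
  # identical frames: zero shift
  expect_equal(unname(ooclust:::estimate_shift(tex, tex)), c(0, 0),
               tolerance = 1e-6)
  # stabilization reduces frame-to-frame residuals
  frames <- list(list(lamina = tex, actin = tex),
                 list(lamina = shifted,
                      actin = ooclust:::translate_image(tex, -3, 2)))
  ser <- volume_series(frames, c(y = 0.2, x = 0.2), 1)
  st <- stabilize_translation(ser, "lamina")
  inner <- function(m) m[20:108, 20:108]
  rms <- function(a, b) sqrt(mean((inner(a) - inner(b))^2))
  expect_lt(rms(get_channel(st$series, 1, "actin"),
                get_channel(st$series, 2, "actin")),
            rms(get_channel(ser, 1, "actin"), get_channel(ser, 2, "actin")))
  # featureless reference: identity with a warning
  flat <- list(list(lamina = matrix(0, 64, 64), actin = tex[1:64, 1:64]),
               list(lamina = matrix(0, 64, 64), actin = tex[1:64, 1:64]))
  expect_warning(st0 <- stabilize_translation(
    volume_series(flat, c(y = 1, x = 1), 1), "lamina"), "featureless")
  expect_equal(st0$shifts, matrix(0, 2, 2, dimnames = list(NULL, c("dy", "dx"))))
})

test_that("multi-pass PIV recovers uniform translations and rest", {
  tex <- make_texture(4)
  moved <- ooclust:::translate_image(tex, -2, -3)  # content moves (+2, +3)
  vf <- piv_multipass(tex, moved)
  v <- vf[vf$valid & vf$y_px > 32 & vf$y_px < 96 & vf$x_px > 32 & vf$x_px < 96, ]
  expect_gt(nrow(v), 20)
  expect_true(all(abs(v$vy_px - 2) < 0.2))
  expect_true(all(abs(v$vx_px - 3) < 0.2))
  # identical frames: all vectors zero
  vf0 <- piv_multipass(tex, tex)
  v0 <- vf0[vf0$valid, ]
  expect_true(all(abs(c(v0$vy_px, v0$vx_px)) < 0.1))
  expect_error(piv_multipass(tex[1:50, 1:50], tex[1:50, 1:50]), "window")
})

test_that("PIV reproduces a solid-body rotation field", {
  tex <- make_texture(5, n = 192)
  rot <- rotate_image(tex, 1)  # 1 degree about the centre
  vf <- piv_multipass(tex, rot)
  ctr <- (192 + 1) / 2
  r <- sqrt((vf$y_px - ctr)^2 + (vf$x_px - ctr)^2)
  sel <- vf$valid & r < 40
  th <- pi / 180
  # analytic displacement of a point under rotation by 1 degree
  want_y <- (cos(th) - 1) * (vf$y_px - ctr) - sin(th) * (vf$x_px - ctr)
  want_x <- sin(th) * (vf$y_px - ctr) + (cos(th) - 1) * (vf$x_px - ctr)
  expect_gt(sum(sel), 30)
  # the correlation estimate integrates over a 24-px window, across which
  # the rotation displacement itself varies by ~0.4 px; compare accordingly
  err <- pmax(abs(vf$vy_px[sel] - want_y[sel]),
              abs(vf$vx_px[sel] - want_x[sel]))
  expect_lt(median(err), 0.15)
  expect_lt(unname(quantile(err, 0.9)), 0.3)
})

make_field <- function(y, x, vy, vx, ps = 0.125, dt = 0.1) {
  df <- data.frame(y_px = y, x_px = x, vy_px = vy, vx_px = vx,
                   peak_ratio = Inf, valid = TRUE)
  df$y_um <- df$y_px * ps
  df$x_um <- df$x_px * ps
  df$vy_um_min <- df$vy_px * ps / dt
  df$vx_um_min <- df$vx_px * ps / dt
  df$speed_um_min <- sqrt(df$vy_um_min^2 + df$vx_um_min^2)
  structure(df, class = c("velocity_field", "data.frame"))
}

test_that("direction categories tile the circle and sum to one", {
  # vectors pointing at the centre from a ring of positions
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  y <- 100 + 50 * sin(th); x <- 100 + 50 * cos(th)
  f_in <- make_field(y, x, (100 - y) / 25, (100 - x) / 25)
  ds <- classify_directions(f_in, centre_um = c(100, 100) * 0.125)
  expect_equal(unname(ds$fractions[["inward"]]), 1)
  expect_equal(ds$mean_direction_deg %% 360, 0, tolerance = 1e-6)
  expect_equal(sum(ds$fractions), 1)
  # outward vectors
  f_out <- make_field(y, x, (y - 100) / 25, (x - 100) / 25)
  expect_equal(unname(classify_directions(
    f_out, c(100, 100) * 0.125)$fractions[["outward"]]), 1)
  # all below the speed floor: empty summary
  f_slow <- make_field(y, x, 1e-3, 1e-3)
  expect_true(classify_directions(f_slow, c(100, 100) * 0.125)$empty)
})

test_that("an isotropic field occupies the inward sector at its width share", {
  set.seed(23)
  n <- 10000
  ang <- runif(n, 0, 2 * pi)
  pos_th <- runif(n, 0, 2 * pi)
  r <- 30 + 50 * sqrt(runif(n))
  y <- 150 + r * sin(pos_th); x <- 150 + r * cos(pos_th)
  f <- make_field(y, x, 3 * sin(ang), 3 * cos(ang))
  ds <- classify_directions(f, centre_um = c(150, 150) * 0.125)
  p0 <- 120 / 360
  expect_lt(abs(ds$fractions[["inward"]] - p0),
            3 * sqrt(p0 * (1 - p0) / n))
  expect_equal(sum(ds$fractions), 1)
})

test_that("classification is equivariant under a joint rotation", {
  set.seed(29)
  n <- 400
  y <- runif(n, 40, 160); x <- runif(n, 40, 160)
  vy <- rnorm(n, 1, 1); vx <- rnorm(n, 2, 1)
  f <- make_field(y, x, vy, vx)
  ds <- classify_directions(f, centre_um = c(100, 100) * 0.125)
  phi <- 73 * pi / 180
  rot <- function(a, b) list(p = cos(phi) * a - sin(phi) * b,
                             q = sin(phi) * a + cos(phi) * b)
  pp <- rot(y - 100, x - 100)
  vv <- rot(vy, vx)
  f2 <- make_field(100 + pp$p, 100 + pp$q, vv$p, vv$q)
  ds2 <- classify_directions(f2, centre_um = c(100, 100) * 0.125)
  # angles to the centre are rotation-invariant, so the summary is identical
  expect_equal(ds2$fractions, ds$fractions)
  expect_equal(ds2$mean_direction_deg, ds$mean_direction_deg,
               tolerance = 1e-9)
})

test_that("the PIV pipeline recovers the generative inward bias", {
  inw <- sapply(1:4, function(s) {
    fl <- generate_flow_frames(oocyte_scenario(seed = s, n_frames = 8))
    ct <- segment_lamina_contour(get_channel(fl$series, 1, "lamina"),
                                 fl$series$voxel_size)
    vecs <- do.call(rbind, lapply(1:7, function(i)
      piv_multipass(get_channel(fl$series, i, "actin"),
                    get_channel(fl$series, i + 1, "actin"),
                    pixel_size = 0.125, frame_interval = 0.1)))
    classify_directions(vecs, ct$centre_um,
                        contour = ct)$fractions[["inward"]]
  })
  # bias 0.7 plus the isotropic share of the inward sector: ~0.8
  expect_lt(abs(mean(inw) - 0.8), 0.12)
})
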