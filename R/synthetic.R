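#' Synthetic oocyte imaging scenario
#'
#' Parameter bundle for the ground-truthed synthetic microscopy generator.
#' Defaults emulate the live porcine regime: a ~25 µm germinal-vesicle
#' nucleus inside a ~120 µm oocyte, chromatin dispersed through the nucleus
#' that converges centripetally after nuclear envelope breakdown (NEBD) at
#' 0.43 µm/min, 5-min frames with 0.5 x 0.5 x 3 µm voxels, inward-biased
#' actin flow, and camera-like Poisson + Gaussian noise.
#'
#' @param cell_radius,nucleus_radius radii in µm; nucleus must fit in cell.
#' @param n_chromosomes number of chromatin blobs.
#' @param chromosome_radius blob radius in µm (half-maximum isosurface of
#'   the rendered Gaussian).
#' @param nebd_time time of NEBD in minutes from acquisition start
#'   (default 30: enough pre-NEBD baseline for the adaptive trigger).
#' @param convergence_speed rate of decrease of the largest pairwise
#'   chromatin distance post-NEBD, µm/min.
#' @param actin_inward_fraction fraction of actin-flow motion directed at
#'   the nuclear centre (remainder isotropic), 0-1.
#' @param kinetochore_fraction fraction of chromatin foci carrying a
#'   kinetochore spot, 0-1.
#' @param fragment_mode logical; zeocin-style fragmentation scenario.
#' @param fragment_volumes fragment volumes in µm³ (fragment mode).
#' @param fragment_kinetochore optional logical vector of kinetochore flags
#'   per fragment; sampled with `kinetochore_fraction` when NULL.
#' @param slow_factor speed multiplier for small kinetochore-free fragments
#'   (fragment mode), emulating their inefficient clustering.
#' @param noise list with `gaussian_sd` (read noise, counts) and
#'   `poisson_scale` (photon gain; 0 disables shot noise).
#' @param voxel_size named c(z=, y=, x=) µm. The fixed/airyscan regime uses
#'   0.19 µm isotropic; the live default is 0.5 x 0.5 x 3 µm.
#' @param frame_interval minutes between 3D frames.
#' @param n_frames number of frames.
#' @param seed integer; identical scenario + seed gives bit-identical
#'   output.
#' @param field `"nucleus"` (field of view around the nuclear region,
#'   default) or `"cell"` (covers the whole cell, renders the membrane).
#' @param flow_pixel_size,flow_size_px,flow_frame_interval,flow_speed
#'   high-temporal-resolution 2D actin-flow regime: pixel size (µm), frame
#'   width (px), frame interval (min) and cable speed (µm/min).
#' @param n_cables,cable_sigma_px number and apparent width (px) of actin
#'   cable particles in the flow generator (free parameters; the real
#'   density/thickness of cables is not prescribed).
#' @param flow_translation optional c(dy, dx) pixel translation imposed on
#'   every flow frame pair instead of the stochastic motion model (oracle
#'   hook).
#' @return An `oocyte_scenario` list, validated.
#' @export
oocyte_scenario <- function(cell_radius = 60, nucleus_radius = 12.5,
                            n_chromosomes = 12, chromosome_radius = 1.5,
                            nebd_time = 30, convergence_speed = 0.43,
                            actin_inward_fraction = 0.7,
                            kinetochore_fraction = 1,
                            fragment_mode = FALSE, fragment_volumes = NULL,
                            fragment_kinetochore = NULL, slow_factor = 0.3,
                            noise = list(gaussian_sd = 2, poisson_scale = 1),
                            voxel_size = c(z = 3, y = 0.5, x = 0.5),
                            frame_interval = 5, n_frames = 12, seed = 1,
                            field = c("nucleus", "cell"),
                            flow_pixel_size = 0.125, flow_size_px = 192,
                            flow_frame_interval = 0.1, flow_speed = 2.5,
                            n_cables = 600, cable_sigma_px = 2,
                            flow_translation = NULL) {
  field <- match.arg(field)
  sc <- list(cell_radius = cell_radius, nucleus_radius = nucleus_radius,
             n_chromosomes = as.integer(n_chromosomes),
             chromosome_radius = chromosome_radius, nebd_time = nebd_time,
             convergence_speed = convergence_speed,
             actin_inward_fraction = actin_inward_fraction,
             kinetochore_fraction = kinetochore_fraction,
             fragment_mode = isTRUE(fragment_mode),
             fragment_volumes = fragment_volumes,
             fragment_kinetochore = fragment_kinetochore,
             slow_factor = slow_factor, noise = noise,
             voxel_size = voxel_size, frame_interval = frame_interval,
             n_frames = as.integer(n_frames), seed = as.integer(seed),
             field = field, flow_pixel_size = flow_pixel_size,
             flow_size_px = as.integer(flow_size_px),
             flow_frame_interval = flow_frame_interval,
             flow_speed = flow_speed, n_cables = as.integer(n_cables),
             cable_sigma_px = cable_sigma_px,
             flow_translation = flow_translation)
  validate_scenario(sc)
  class(sc) <- "oocyte_scenario"
  sc
}

validate_scenario <- function(sc) {
  stopifnot(sc$nucleus_radius > 0, sc$cell_radius > sc$nucleus_radius,
            sc$n_chromosomes >= 1L, sc$chromosome_radius > 0,
            sc$convergence_speed >= 0,
            sc$actin_inward_fraction >= 0, sc$actin_inward_fraction <= 1,
            sc$kinetochore_fraction >= 0, sc$kinetochore_fraction <= 1,
            all(sc$voxel_size > 0), sc$frame_interval > 0,
            sc$n_frames >= 1L, sc$slow_factor >= 0)
  if (sc$fragment_mode) {
    if (is.null(sc$fragment_volumes) || length(sc$fragment_volumes) == 0L) {
      stop("fragment_mode requires non-empty fragment_volumes")
    }
    if (any(sc$fragment_volumes <= 0)) stop("fragment volumes must be > 0")
  }
  invisible(sc)
}

# ---- rendering primitives ---------------------------------------------------

# Gaussian blobs on a calibrated grid. centres: n x 3 matrix (z,y,x µm);
# sigma: n x 3 or length-3 (µm); amp: n. combine = "max" renders mutually
# exclusive bodies (intensity does not add up where blurred bodies touch);
# "sum" renders additive point-like sources.
render_blobs <- function(d, voxel_size, centres, sigma, amp,
                         combine = c("max", "sum")) {
  combine <- match.arg(combine)
  cz <- (seq_len(d[1L]) - 0.5) * voxel_size[1L]
  cy <- (seq_len(d[2L]) - 0.5) * voxel_size[2L]
  cx <- (seq_len(d[3L]) - 0.5) * voxel_size[3L]
  out <- array(0, d)
  if (is.null(dim(sigma))) sigma <- matrix(sigma, nrow(centres), 3, byrow = TRUE)
  amp <- rep_len(amp, nrow(centres))
  for (i in seq_len(nrow(centres))) {
    gz <- exp(-(cz - centres[i, 1L])^2 / (2 * sigma[i, 1L]^2))
    gy <- exp(-(cy - centres[i, 2L])^2 / (2 * sigma[i, 2L]^2))
    gx <- exp(-(cx - centres[i, 3L])^2 / (2 * sigma[i, 3L]^2))
    b <- amp[i] * array(outer(outer(gz, gy), gx), d)
    out <- if (combine == "max") pmax(out, b) else out + b
  }
  out
}

# Solid bodies with a diffraction-blurred edge: flat amplitude inside a
# core radius, Gaussian fall-off with sigma `edge_sigma` beyond it. The
# half-maximum isosurface sits exactly at `radius`, so thresholding near
# half-max recovers (4/3) pi r^3. Used for chromatin, whose intensity
# profile is a filled body, not a point source.
render_solid_blobs <- function(d, voxel_size, centres, radius, amp,
                               edge_sigma = 0.3, combine = "max") {
  out <- array(0, d)
  radius <- rep_len(radius, nrow(centres))
  amp <- rep_len(amp, nrow(centres))
  hw <- sqrt(2 * log(2)) * edge_sigma
  ax <- axis_coords(d, voxel_size)
  for (i in seq_len(nrow(centres))) {
    r_core <- max(radius[i] - hw, 0.05)
    reach <- radius[i] + 3 * edge_sigma
    rng <- lapply(1:3, function(k) {
      which(abs(ax[[k]] - centres[i, k]) <= reach)
    })
    if (any(vapply(rng, length, integer(1)) == 0L)) next
    dz2 <- (ax[[1L]][rng[[1L]]] - centres[i, 1L])^2
    dy2 <- (ax[[2L]][rng[[2L]]] - centres[i, 2L])^2
    dx2 <- (ax[[3L]][rng[[3L]]] - centres[i, 3L])^2
    dist <- sqrt(outer(outer(dz2, dy2, `+`), dx2, `+`))
    b <- amp[i] * exp(-pmax(dist - r_core, 0)^2 / (2 * edge_sigma^2))
    cur <- out[rng[[1L]], rng[[2L]], rng[[3L]], drop = FALSE]
    out[rng[[1L]], rng[[2L]], rng[[3L]]] <-
      if (combine == "max") pmax(cur, b) else cur + b
  }
  out
}

# Poisson shot noise + Gaussian read noise, then integer camera counts.
apply_noise <- function(x, noise) {
  d <- dim(x) %||% length(x)
  ps <- noise$poisson_scale %||% 0
  gs <- noise$gaussian_sd %||% 0
  if (ps > 0) x <- stats::rpois(length(x), pmax(as.vector(x), 0) * ps) / ps
  if (gs > 0) x <- x + stats::rnorm(length(x), 0, gs)
  array(pmin(round(pmax(x, 0)), 65535), d)
}

# Radial distance grid (µm) from a centre (z,y,x µm).
radius_grid <- function(d, voxel_size, centre) {
  cz <- (seq_len(d[1L]) - 0.5) * voxel_size[1L] - centre[1L]
  cy <- (seq_len(d[2L]) - 0.5) * voxel_size[2L] - centre[2L]
  cx <- (seq_len(d[3L]) - 0.5) * voxel_size[3L] - centre[3L]
  sqrt(outer(outer(cz^2, cy^2, `+`), cx^2, `+`))
}

# Non-overlapping positions in a ball of radius rmax about `centre`, with
# minimal pairwise separation `sep`; `fixed` rows are kept as-is.
place_in_ball <- function(n, rmax, sep, centre, fixed = NULL) {
  pos <- fixed
  tries <- 0L
  while (is.null(pos) || nrow(pos) < n) {
    tries <- tries + 1L
    if (tries > 20000L) {
      stop("cannot place chromosomes in the nucleus without overlap")
    }
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2))
    p <- centre + u * rmax * stats::runif(1)^(1 / 3)
    ok <- is.null(pos) ||
      all(sqrt(rowSums(sweep(pos, 2L, p, `-`)^2)) >= sep)
    if (ok) pos <- rbind(pos, p)
  }
  pos
}

# ---- oocyte time series -----------------------------------------------------

#' Generate a ground-truthed 3D+t oocyte series
#'
#' Renders channels chromatin, kinetochores, actin, lamina, dextran and
#' membrane. Chromatin blobs are dispersed in the nucleus, static before
#' `nebd_time`, then contract about their centroid so that the true largest
#' pairwise centroid distance decreases linearly at `convergence_speed`
#' until all pairwise distances reach the cluster floor
#' (2 x `chromosome_radius`). The dextran channel is void in the nucleus
#' before NEBD and reaches cytoplasmic intensity within two frames after
#' it; the lamina shell persists and slowly compacts. Noise is applied
#' last, and output intensities are integer camera counts.
#'
#' @param scenario an [oocyte_scenario()].
#' @return list with `series` (a [volume_series()]) and `truth`: `objects`
#'   (data.frame frame, object_id, z_um, y_um, x_um, volume_um3,
#'   has_kinetochore; frames 1-based), `lpd` (frame, time_min,
#'   time_from_nebd_min, lpd_um), `nebd_frame` (1-based), `nebd_time_min`,
#'   `centre_um`, and the scenario echo.
#' @export
generate_oocyte_series <- function(scenario) {
  sc <- validate_scenario(scenario)
  vs <- sc$voxel_size
  R <- sc$nucleus_radius
  r <- sc$chromosome_radius
  half_xy <- if (sc$field == "cell") sc$cell_radius * 1.08 else R * 1.4 + 2
  half_z <- if (sc$field == "cell") sc$cell_radius * 1.08 else R * 1.2 + 2
  d <- c(z = max(4L, ceiling(2 * half_z / vs["z"])),
         y = ceiling(2 * half_xy / vs["y"]),
         x = ceiling(2 * half_xy / vs["x"]))
  centre <- d * vs / 2
  rmax <- 0.85 * R
  # centres at least 3.5 r apart: chromosomes are distinct bodies and must
  # remain individually resolvable after diffraction blur at t = 0
  sep <- 3.5 * r
  if (sc$n_chromosomes * sep^3 > 0.5 * (2 * rmax)^3) {
    stop("cannot place chromosomes in the nucleus without overlap")
  }

  with_seed(sc$seed, {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    fixed <- if (sc$n_chromosomes >= 2L) {
      rbind(centre + rmax * u, centre - rmax * u)
    } else NULL
    pos0 <- place_in_ball(sc$n_chromosomes, rmax, sep, centre, fixed)
    rownames(pos0) <- NULL
    n_kt <- round(sc$kinetochore_fraction * sc$n_chromosomes)
    has_kt <- seq_len(sc$n_chromosomes) %in%
      sample.int(sc$n_chromosomes, n_kt)
    kt_dir <- matrix(stats::rnorm(3 * sc$n_chromosomes), ncol = 3)
    kt_dir <- kt_dir / sqrt(rowSums(kt_dir^2))
    actin_tex <- gaussian_smooth(array(stats::runif(prod(d)), d),
                                 c(0.5, 1.5, 1.5))

    times <- (seq_len(sc$n_frames) - 1) * sc$frame_interval
    nebd_frame <- which(times >= sc$nebd_time)[1L]
    if (is.na(nebd_frame)) nebd_frame <- sc$n_frames + 1L
    L0 <- if (sc$n_chromosomes >= 2L) max(stats::dist(pos0)) else 0
    floor_f <- if (L0 > 0) min(1, 2 * r / L0) else 1
    g0 <- colMeans(pos0)
    cyto <- 100

    frames <- vector("list", sc$n_frames)
    objects <- vector("list", sc$n_frames)
    lpd <- numeric(sc$n_frames)
    rg <- radius_grid(d, vs, centre)
    for (i in seq_len(sc$n_frames)) {
      elapsed <- if (i >= nebd_frame) times[i] - times[nebd_frame] else NA
      f <- if (i < nebd_frame || L0 == 0) 1 else {
        max(floor_f, 1 - sc$convergence_speed * elapsed / L0)
      }
      pos <- sweep(sweep(pos0, 2L, g0, `-`) * f, 2L, g0, `+`)
      lpd[i] <- f * L0
      chrom <- render_solid_blobs(d, vs, pos, r, 200)
      ktpos <- pos + kt_dir * 0.7 * r
      kts <- if (any(has_kt)) {
        render_blobs(d, vs, ktpos[has_kt, , drop = FALSE], 0.3, 300, "sum")
      } else array(0, d)
      R_t <- if (i < nebd_frame) R else {
        R * (1 - 0.15 * min(1, elapsed / 90))
      }
      lam <- 150 * exp(-(rg - R_t)^2 / (2 * 0.75^2))
      dex <- array(cyto, d)
      inside <- rg < R
      if (i < nebd_frame) {
        dex[inside] <- 0
      } else if (i == nebd_frame) {
        dex[inside] <- 0.6 * cyto
      }
      if (sc$field == "cell") dex[rg > sc$cell_radius] <- 0
      act <- 5 + 60 * actin_tex * (rg < R_t)
      mem <- if (sc$field == "cell") {
        150 * exp(-(rg - sc$cell_radius)^2 / (2 * 1^2))
      } else array(0, d)
      frames[[i]] <- lapply(
        list(chromatin = chrom, kinetochores = kts, actin = act,
             lamina = lam, dextran = dex, membrane = mem),
        apply_noise, noise = sc$noise)
      objects[[i]] <- data.frame(
        frame = i, object_id = seq_len(sc$n_chromosomes),
        z_um = pos[, 1L], y_um = pos[, 2L], x_um = pos[, 3L],
        volume_um3 = 4 / 3 * pi * r^3, has_kinetochore = has_kt)
    }

    series <- volume_series(frames, vs, sc$frame_interval, times)
    truth <- list(
      objects = do.call(rbind, objects),
      lpd = data.frame(frame = seq_len(sc$n_frames), time_min = times,
                       time_from_nebd_min = times -
                         times[min(nebd_frame, sc$n_frames)],
                       lpd_um = lpd),
      nebd_frame = nebd_frame, nebd_time_min = sc$nebd_time,
      centre_um = centre, scenario = sc)
    list(series = series, truth = truth)
  })
}

# ---- fragmentation series ---------------------------------------------------

#' Generate a zeocin-style chromatin fragmentation series
#'
#' Chromatin foci with prescribed volumes, kinetochore spots on a subset,
#' and per-object convergence: kinetochore-free fragments smaller than
#' 30 µm³ move at `slow_factor` times `convergence_speed`, all others at
#' the full rate, emulating the inefficient clustering of small
#' kinetochore-free fragments.
#'
#' @param scenario an [oocyte_scenario()] with `fragment_mode = TRUE` and
#'   non-empty `fragment_volumes`.
#' @return list(series, truth) as in [generate_oocyte_series()]; `objects`
#'   additionally carries `class` (small/large x KT/KT_free) and the truth
#'   per-object speed.
#' @export
generate_fragments <- function(scenario) {
  sc <- validate_scenario(scenario)
  if (!sc$fragment_mode) stop("fragment_mode must be TRUE")
  vols <- sc$fragment_volumes
  n <- length(vols)
  radii <- (3 * vols / (4 * pi))^(1 / 3)
  vs <- sc$voxel_size
  R <- sc$nucleus_radius
  d <- c(z = max(4L, ceiling(2 * (R * 1.2 + 2) / vs["z"])),
         y = ceiling(2 * (R * 1.4 + 2) / vs["y"]),
         x = ceiling(2 * (R * 1.4 + 2) / vs["x"]))
  centre <- d * vs / 2

  with_seed(sc$seed, {
    has_kt <- sc$fragment_kinetochore %||%
      (stats::runif(n) < sc$kinetochore_fraction)
    stopifnot(length(has_kt) == n)
    cls <- classify_fragments(vols, has_kt)
    speed <- ifelse(cls == "small_KT_free",
                    sc$slow_factor * sc$convergence_speed,
                    sc$convergence_speed)
    pos0 <- place_in_ball(n, 0.85 * R, 3.5 * max(radii), centre)
    rownames(pos0) <- NULL
    g0 <- colMeans(pos0)
    dir0 <- sweep(pos0, 2L, g0, `-`)
    dist0 <- sqrt(rowSums(dir0^2))
    dir0 <- dir0 / pmax(dist0, 1e-9)
    stop_at <- radii + 1

    times <- (seq_len(sc$n_frames) - 1) * sc$frame_interval
    nebd_frame <- which(times >= sc$nebd_time)[1L]
    if (is.na(nebd_frame)) nebd_frame <- sc$n_frames + 1L
    frames <- vector("list", sc$n_frames)
    objects <- vector("list", sc$n_frames)
    rg <- radius_grid(d, vs, centre)
    for (i in seq_len(sc$n_frames)) {
      elapsed <- if (i >= nebd_frame) times[i] - times[nebd_frame] else 0
      dist_i <- pmax(dist0 - speed * elapsed, pmin(stop_at, dist0))
      pos <- sweep(dir0 * dist_i, 2L, g0, `+`)
      chrom <- render_solid_blobs(d, vs, pos, radii, 200)
      kts <- if (any(has_kt)) {
        render_blobs(d, vs, pos[has_kt, , drop = FALSE], 0.3, 300, "sum")
      } else array(0, d)
      lam <- 150 * exp(-(rg - R)^2 / (2 * 0.75^2))
      frames[[i]] <- lapply(
        list(chromatin = chrom, kinetochores = kts, lamina = lam),
        apply_noise, noise = sc$noise)
      objects[[i]] <- data.frame(
        frame = i, object_id = seq_len(n),
        z_um = pos[, 1L], y_um = pos[, 2L], x_um = pos[, 3L],
        volume_um3 = vols, has_kinetochore = has_kt,
        class = cls, speed_um_min = speed)
    }
    series <- volume_series(frames, vs, sc$frame_interval, times)
    truth <- list(objects = do.call(rbind, objects),
                  nebd_frame = nebd_frame, nebd_time_min = sc$nebd_time,
                  centre_um = centre, scenario = sc)
    list(series = series, truth = truth)
  })
}

# ---- high-temporal-resolution actin flow -----------------------------------

#' Generate 2D+t actin-flow frames with known motion
#'
#' Actin-cable texture inside a lamina disc. Between consecutive frames the
#' whole cable population moves: with probability `actin_inward_fraction`
#' every cable steps toward the disc centre (cables reaching the centre
#' re-appear at the periphery, as cables do in the nuclear region), and
#' otherwise the population translates rigidly in a uniformly random
#' direction. `flow_translation` overrides the motion model with a fixed
#' per-pair pixel translation (for displacement oracles). The truth table
#' records the imposed displacement per sampling region per frame pair.
#'
#' @param scenario an [oocyte_scenario()]; flow-specific fields apply.
#' @return list with `series` (2D `volume_series`, channels actin and
#'   lamina; pixel size `flow_pixel_size`, interval `flow_frame_interval`)
#'   and `truth` data.frame (pair, y_px, x_px, vy_px, vx_px,
#'   angle_to_centre_deg, speed_um_min, mode), plus `centre_px`,
#'   `radius_px`.
#' @export
generate_flow_frames <- function(scenario) {
  sc <- validate_scenario(scenario)
  sz <- sc$flow_size_px
  ps <- sc$flow_pixel_size
  R_px <- min(sc$nucleus_radius / ps, 0.45 * sz)
  centre <- c(sz, sz) / 2
  d_px <- sc$flow_speed * sc$flow_frame_interval / ps
  n_pairs <- sc$n_frames - 1L

  with_seed(sc$seed, {
    np <- sc$n_cables
    ang <- stats::runif(np, 0, 2 * pi)
    rad <- R_px * 0.97 * sqrt(stats::runif(np))
    p_y <- centre[1L] + rad * sin(ang)
    p_x <- centre[2L] + rad * cos(ang)
    amp <- stats::runif(np, 80, 160)

    # truth sampling regions: grid nodes well inside the disc
    gs <- 24
    gy <- seq(gs, sz - gs, by = gs)
    grid <- expand.grid(y_px = gy, x_px = gy)
    gr <- sqrt((grid$y_px - centre[1L])^2 + (grid$x_px - centre[2L])^2)
    grid <- grid[gr < R_px - gs / 2, ]

    render <- function() {
      img <- array(3, c(sz, sz))
      s <- sc$cable_sigma_px
      rwin <- ceiling(3 * s)
      for (k in seq_len(np)) {
        yy <- round(p_y[k]); xx <- round(p_x[k])
        if (yy + rwin < 1L || yy - rwin > sz ||
            xx + rwin < 1L || xx - rwin > sz) next
        ys <- max(1L, yy - rwin):min(sz, yy + rwin)
        xs <- max(1L, xx - rwin):min(sz, xx + rwin)
        g <- outer(exp(-(ys - p_y[k])^2 / (2 * s^2)),
                   exp(-(xs - p_x[k])^2 / (2 * s^2)))
        img[ys, xs] <- img[ys, xs] + amp[k] * g
      }
      img
    }
    ry <- outer(seq_len(sz) - 0.5 - centre[1L], rep(1, sz))
    rx <- outer(rep(1, sz), seq_len(sz) - 0.5 - centre[2L])
    rr <- sqrt(ry^2 + rx^2)
    lam_img <- 120 * exp(-(rr - R_px)^2 / (2 * 2^2))

    frames <- vector("list", sc$n_frames)
    truth <- vector("list", max(n_pairs, 0L))
    for (i in seq_len(sc$n_frames)) {
      frames[[i]] <- list(actin = apply_noise(render(), sc$noise),
                          lamina = apply_noise(lam_img, sc$noise))
      if (i > n_pairs) break
      # imposed motion for pair (i, i+1)
      if (!is.null(sc$flow_translation)) {
        dy <- rep(sc$flow_translation[1L], nrow(grid))
        dx <- rep(sc$flow_translation[2L], nrow(grid))
        p_y <- p_y + sc$flow_translation[1L]
        p_x <- p_x + sc$flow_translation[2L]
        mode <- "translation"
      } else if (stats::runif(1) < sc$actin_inward_fraction) {
        uy <- (centre[1L] - p_y); ux <- (centre[2L] - p_x)
        nn <- pmax(sqrt(uy^2 + ux^2), 1e-9)
        p_y <- p_y + d_px * uy / nn
        p_x <- p_x + d_px * ux / nn
        guy <- centre[1L] - grid$y_px; gux <- centre[2L] - grid$x_px
        gn <- pmax(sqrt(guy^2 + gux^2), 1e-9)
        dy <- d_px * guy / gn; dx <- d_px * gux / gn
        mode <- "inward"
        # cables arriving at the centre reappear at the periphery
        done <- sqrt((p_y - centre[1L])^2 + (p_x - centre[2L])^2) < 4
        nres <- sum(done)
        if (nres > 0L) {
          a2 <- stats::runif(nres, 0, 2 * pi)
          r2 <- R_px * stats::runif(nres, 0.85, 0.97)
          p_y[done] <- centre[1L] + r2 * sin(a2)
          p_x[done] <- centre[2L] + r2 * cos(a2)
        }
      } else {
        phi <- stats::runif(1, 0, 2 * pi)
        dy <- rep(d_px * sin(phi), nrow(grid))
        dx <- rep(d_px * cos(phi), nrow(grid))
        p_y <- p_y + d_px * sin(phi)
        p_x <- p_x + d_px * cos(phi)
        mode <- "translation"
      }
      inw_y <- centre[1L] - grid$y_px
      inw_x <- centre[2L] - grid$x_px
      a <- atan2(dx, dy) - atan2(inw_x, inw_y)
      truth[[i]] <- data.frame(
        pair = i, y_px = grid$y_px, x_px = grid$x_px,
        vy_px = dy, vx_px = dx,
        angle_to_centre_deg = (a * 180 / pi) %% 360,
        speed_um_min = sqrt(dy^2 + dx^2) * ps / sc$flow_frame_interval,
        mode = mode)
    }
    series <- volume_series(frames, c(y = ps, x = ps),
                            sc$flow_frame_interval)
    list(series = series,
         truth = if (n_pairs > 0L) do.call(rbind, truth) else NULL,
         centre_px = centre, radius_px = R_px)
  })
}

# ---- kinetochore-actin colocalization volume -------------------------------

#' Generate a fixed-cell volume with programmed kinetochore-actin contact
#'
#' High-resolution (airyscan-regime, 0.19 µm isotropic by default) single
#' time-point volume containing a few actin cables and a set of
#' kinetochore spots, a programmed fraction of which sit on a cable
#' surface (distance 0) while the rest are kept clear of all cables.
#' Used to validate the interaction-fraction read-out against a known
#' generative contact probability.
#'
#' @param n_spots number of kinetochore spots.
#' @param interact_prob per-spot probability of being placed on a cable.
#' @param n_cables number of actin cables.
#' @param cable_radius_um,cable_length_um cable geometry, µm.
#' @param clear_margin_um minimum distance of non-interacting spots from
#'   any cable axis, µm.
#' @param voxel_size named c(z=, y=, x=) µm.
#' @param dim_vox volume dimensions (z, y, x) in voxels.
#' @param noise noise model as in [oocyte_scenario()].
#' @param seed integer seed.
#' @return list(volumes = list(actin, kinetochores), voxel_size, truth =
#'   data.frame(spot_id, z_um, y_um, x_um, interacting)).
#' @export
generate_kinetochore_actin_volume <- function(n_spots = 40,
                                              interact_prob = 0.18,
                                              n_cables = 4,
                                              cable_radius_um = 1.0,
                                              cable_length_um = 12,
                                              clear_margin_um = 1.5,
                                              voxel_size = c(z = 0.19,
                                                             y = 0.19,
                                                             x = 0.19),
                                              dim_vox = c(48L, 96L, 96L),
                                              noise = list(gaussian_sd = 2,
                                                           poisson_scale = 1),
                                              seed = 1L) {
  stopifnot(interact_prob >= 0, interact_prob <= 1, n_spots >= 1)
  d <- dim_vox
  ext <- d * voxel_size
  with_seed(seed, {
    # cable axes: random segments through the central region
    axes <- lapply(seq_len(n_cables), function(i) {
      ctr <- ext * stats::runif(3, 0.3, 0.7)
      u <- stats::rnorm(3); u[1L] <- u[1L] * 0.3  # mostly in-plane
      u <- u / sqrt(sum(u^2))
      list(a = ctr - u * cable_length_um / 2,
           b = ctr + u * cable_length_um / 2)
    })
    # render cables as chains of Gaussian beads along the axis
    beads <- do.call(rbind, lapply(axes, function(ax) {
      tvals <- seq(0, 1, length.out = ceiling(cable_length_um / 0.3))
      t(vapply(tvals, function(t) ax$a + t * (ax$b - ax$a), numeric(3)))
    }))
    sig_c <- cable_radius_um / sqrt(2 * log(2))
    actin <- render_blobs(d, voxel_size, beads, sig_c, 200)

    seg_dist <- function(p, ax) {
      ab <- ax$b - ax$a
      t <- sum((p - ax$a) * ab) / sum(ab^2)
      t <- min(max(t, 0), 1)
      sqrt(sum((ax$a + t * ab - p)^2))
    }
    # stratified contact count: each spot's marginal contact probability is
    # exactly interact_prob, with minimal across-cell variance
    n_int <- floor(n_spots * interact_prob)
    n_int <- n_int + (stats::runif(1) < n_spots * interact_prob - n_int)
    interacting <- seq_len(n_spots) %in% sample.int(n_spots, n_int)
    pts <- matrix(0, n_spots, 3)
    margin <- 1.5
    min_sep <- 1.5  # keep spots individually resolvable
    for (i in seq_len(n_spots)) {
      for (try in seq_len(10000L)) {
        if (interacting[i]) {
          ax <- axes[[sample.int(n_cables, 1L)]]
          t <- stats::runif(1, 0.15, 0.85)
          p <- ax$a + t * (ax$b - ax$a)
        } else {
          p <- margin + stats::runif(3) * (ext - 2 * margin)
        }
        dmin <- min(vapply(axes, seg_dist, numeric(1), p = p))
        ok <- if (interacting[i]) TRUE else dmin > cable_radius_um +
          clear_margin_um
        ok <- ok && all(p > margin) && all(p < ext - margin)
        if (ok && i > 1L) {
          prev <- pts[seq_len(i - 1L), , drop = FALSE]
          ok <- min(sqrt(rowSums(sweep(prev, 2L, p, `-`)^2))) >= min_sep
        }
        if (ok) { pts[i, ] <- p; break }
        if (try == 10000L) stop("cannot place spots")
      }
    }
    kts <- render_blobs(d, voxel_size, pts, 0.2, 300, "sum")
    list(volumes = list(actin = apply_noise(actin, noise),
                        kinetochores = apply_noise(kts, noise)),
         voxel_size = voxel_size,
         truth = data.frame(spot_id = seq_len(n_spots), z_um = pts[, 1L],
                            y_um = pts[, 2L], x_um = pts[, 3L],
                            interacting = interacting))
  })
}
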