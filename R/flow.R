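# Actin-flow directionality in the nuclear region: translational
# stabilization on the lamina signal, three-pass window-refined
# cross-correlation PIV, direction classification relative to the nuclear
# centre, circular statistics.

# 5x5 box mean (separable), edge-replicated.
box5 <- function(x) {
  for (ax in seq_along(dim(x))) {
    acc <- x
    for (s in c(-2L, -1L, 1L, 2L)) acc <- acc + shift_array(x, s, ax)
    x <- acc / 5
  }
  x
}

# Adaptive local noise filter (Wiener-style, 5x5 support) followed by a
# 5-px low-pass, the pre-processing used before PIV.
piv_prefilter <- function(x) {
  mu <- box5(x)
  v <- pmax(box5(x^2) - mu^2, 0)
  nv <- mean(v)
  w <- mu + pmax(v - nv, 0) / pmax(v, nv) * (x - mu)
  gaussian_smooth(w, c(1, 1))
}

# Cross-correlation displacement of `img` relative to `ref` (full frame),
# with Hann windowing and 3-point subpixel interpolation. Returns c(dy, dx)
# such that img(y, x) ~ ref(y - dy, x - dx).
estimate_shift <- function(ref, img) {
  d <- dim(ref)
  hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  w <- outer(hann(d[1L]), hann(d[2L]))
  a <- (ref - mean(ref)) * w
  b <- (img - mean(img)) * w
  C <- Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE))
  pk <- which(C == max(C), arr.ind = TRUE)[1L, ]
  sub <- function(ax, i) {
    n <- d[ax]
    im <- ((i - 2L) %% n) + 1L
    ip <- (i %% n) + 1L
    get3 <- function(j) if (ax == 1L) C[j, pk[2L]] else C[pk[1L], j]
    cm <- get3(im); c0 <- get3(i); cp <- get3(ip)
    den <- cm - 2 * c0 + cp
    frac <- if (abs(den) > 1e-12) 0.5 * (cm - cp) / den else 0
    s <- (i - 1L) + frac
    if (s > n / 2) s <- s - n
    s
  }
  c(sub(1L, pk[1L]), sub(2L, pk[2L]))
}

# Bilinear resampling of `img` at (y + dy, x + dx); edge-replicated.
translate_image <- function(img, dy, dx) {
  d <- dim(img)
  ys <- seq_len(d[1L]) + dy
  xs <- seq_len(d[2L]) + dx
  y0 <- pmin(pmax(floor(ys), 1L), d[1L])
  x0 <- pmin(pmax(floor(xs), 1L), d[2L])
  y1 <- pmin(y0 + 1L, d[1L]); x1 <- pmin(x0 + 1L, d[2L])
  fy <- pmin(pmax(ys - y0, 0), 1); fx <- pmin(pmax(xs - x0, 0), 1)
  A <- img[y0, x0, drop = FALSE]; B <- img[y0, x1, drop = FALSE]
  Cc <- img[y1, x0, drop = FALSE]; Dd <- img[y1, x1, drop = FALSE]
  wy <- matrix(fy, d[1L], d[2L]); wx <- matrix(fx, d[1L], d[2L], byrow = TRUE)
  A * (1 - wy) * (1 - wx) + B * (1 - wy) * wx + Cc * wy * (1 - wx) +
    Dd * wy * wx
}

#' Stabilize a 2D time series by translation
#'
#' Per-frame translation relative to the first frame, estimated by
#' windowed cross-correlation on a reference channel (the nuclear lamina),
#' applied to all channels by bilinear resampling. A featureless reference
#' (zero variance) yields identity transforms with a warning.
#'
#' @param series a 2D `volume_series`.
#' @param reference_channel channel used to estimate the shifts.
#' @return list(series = stabilized `volume_series`, shifts = n x 2 matrix
#'   of (dy, dx) pixel shifts of each frame relative to frame 1).
#' @export
stabilize_translation <- function(series, reference_channel = "lamina") {
  nt <- n_frames(series)
  ref <- get_channel(series, 1L, reference_channel)
  shifts <- matrix(0, nt, 2L, dimnames = list(NULL, c("dy", "dx")))
  if (stats::sd(ref) < 1e-12) {
    warning("featureless reference channel; identity stabilization")
    return(list(series = series, shifts = shifts))
  }
  frames <- series$frames
  for (i in seq_len(nt)[-1L]) {
    img <- get_channel(series, i, reference_channel)
    s <- estimate_shift(ref, img)
    shifts[i, ] <- s
    frames[[i]] <- lapply(frames[[i]], translate_image, dy = s[1L],
                          dx = s[2L])
  }
  out <- series
  out$frames <- frames
  list(series = out, shifts = shifts)
}

# Correlate one interrogation window pair; returns displacement (dy, dx)
# relative to the imposed offset, plus peak ratio.
correlate_window <- function(a, b) {
  w <- dim(a)[1L]
  # Hann taper suppresses the circular wrap-around bias of the FFT
  # correlation on windows whose texture correlation length is not small
  hann <- 0.5 - 0.5 * cos(2 * pi * seq(0, w - 1) / (w - 1))
  taper <- outer(hann, hann)
  a0 <- (a - mean(a)) * taper
  b0 <- (b - mean(b)) * taper
  C <- Re(stats::fft(Conj(stats::fft(a0)) * stats::fft(b0), inverse = TRUE))
  # restrict to displacements within +/- w/3 to avoid aliased peaks
  lim <- floor(w / 3)
  sidx <- c(seq_len(lim + 1L), seq(w - lim + 1L, w))
  Cs <- C[sidx, sidx]
  pk <- which(Cs == max(Cs), arr.ind = TRUE)[1L, ]
  pi_ <- sidx[pk[1L]]; pj <- sidx[pk[2L]]
  val <- C[pi_, pj]
  # peak ratio against the best peak outside the 3x3 neighbourhood
  mask <- Cs
  ni <- which(abs((sidx - pi_ + w / 2) %% w - w / 2) <= 1L)
  nj <- which(abs((sidx - pj + w / 2) %% w - w / 2) <= 1L)
  mask[ni, nj] <- -Inf
  second <- max(mask)
  ratio <- if (is.finite(second) && second > 0) val / second else Inf
  subpix <- function(get3, i, n) {
    im <- ((i - 2L) %% n) + 1L
    ip <- (i %% n) + 1L
    cm <- get3(im); c0 <- get3(i); cp <- get3(ip)
    mn <- min(cm, c0, cp)
    # 3-point Gaussian fit (fall back to parabola for non-positive values)
    if (cm > 0 && c0 > 0 && cp > 0 && c0 > cm && c0 > cp) {
      lcm <- log(cm); lc0 <- log(c0); lcp <- log(cp)
      den <- lcm - 2 * lc0 + lcp
      if (abs(den) > 1e-12) return(0.5 * (lcm - lcp) / den)
    }
    den <- cm - 2 * c0 + cp
    if (abs(den) > 1e-12) 0.5 * (cm - cp) / den else 0
  }
  fy <- subpix(function(j) C[j, pj], pi_, w)
  fx <- subpix(function(j) C[pi_, j], pj, w)
  dy <- (pi_ - 1L) + fy; if (dy > w / 2) dy <- dy - w
  dx <- (pj - 1L) + fx; if (dx > w / 2) dx <- dx - w
  c(dy = dy, dx = dx, ratio = ratio, peak = val)
}

#' Multi-pass PIV between two frames
#'
#' Three-pass window-refined cross-correlation (64, 32, 24 px windows by
#' default, 50% overlap); each pass offsets its interrogation windows by
#' the previous pass's displacement field. Pre-processing is an adaptive
#' 5-px noise filter plus a 5-px low-pass. Post-filtering is deliberately
#' weak: vectors are only invalidated where the correlation peak ratio
#' falls below `peak_ratio_floor`.
#'
#' @param frame_a,frame_b stabilized 2D arrays `[y, x]`.
#' @param windows interrogation window widths per pass, px.
#' @param overlap window overlap fraction.
#' @param peak_ratio_floor minimum first-to-second correlation peak ratio.
#' @param pixel_size µm per px (scalar or c(y=, x=)); optional, enables
#'   µm/min velocities.
#' @param frame_interval minutes between the frames.
#' @param prefilter logical; apply the pre-processing filters.
#' @return A `velocity_field`: data.frame grid (y_px, x_px, y_um, x_um,
#'   vy_px, vx_px, vy_um_min, vx_um_min, speed_um_min, peak_ratio, valid)
#'   with attributes `pixel_size`, `frame_interval`, `window`.
#' @export
piv_multipass <- function(frame_a, frame_b, windows = c(64L, 32L, 24L),
                          overlap = 0.5, peak_ratio_floor = 1.05,
                          pixel_size = NULL, frame_interval = NULL,
                          prefilter = TRUE) {
  d <- dim(frame_a)
  stopifnot(all(d == dim(frame_b)))
  if (min(d) < max(windows)) stop("frames smaller than the largest window")
  if (prefilter) {
    frame_a <- piv_prefilter(frame_a)
    frame_b <- piv_prefilter(frame_b)
  }
  prev <- NULL
  for (w in as.integer(windows)) {
    hw <- w %/% 2L
    step <- max(1L, as.integer(round(w * (1 - overlap))))
    cy <- seq(hw, d[1L] - hw, by = step)
    cx <- seq(hw, d[2L] - hw, by = step)
    grid <- expand.grid(y_px = cy, x_px = cx)
    ng <- nrow(grid)
    res <- matrix(NA_real_, ng, 4L)
    for (g in seq_len(ng)) {
      y0 <- grid$y_px[g]; x0 <- grid$x_px[g]
      off <- c(0, 0)
      if (!is.null(prev)) {
        # nearest previous-pass vector as window offset
        dd <- (prev$y_px - y0)^2 + (prev$x_px - x0)^2
        dd[!prev$valid] <- dd[!prev$valid] + 1e12
        nb <- which.min(dd)
        if (is.finite(prev$vy_px[nb])) {
          off <- round(c(prev$vy_px[nb], prev$vx_px[nb]))
        }
      }
      ya <- (y0 - hw + 1L):(y0 + hw)
      # clamp the offset so the shifted window stays in the frame
      off[1L] <- min(max(off[1L], 1L - (y0 - hw + 1L)), d[1L] - (y0 + hw))
      off[2L] <- min(max(off[2L], 1L - (x0 - hw + 1L)), d[2L] - (x0 + hw))
      xa <- (x0 - hw + 1L):(x0 + hw)
      aw <- frame_a[ya, xa]
      bw <- frame_b[ya + off[1L], xa + off[2L]]
      cw <- correlate_window(aw, bw)
      res[g, ] <- c(cw["dy"] + off[1L], cw["dx"] + off[2L], cw["ratio"],
                    cw["peak"])
    }
    prev <- data.frame(y_px = grid$y_px, x_px = grid$x_px,
                       vy_px = res[, 1L], vx_px = res[, 2L],
                       peak_ratio = res[, 3L],
                       valid = is.finite(res[, 1L]) & res[, 3L] >= peak_ratio_floor &
                         res[, 4L] > 0)
  }
  out <- prev
  if (!is.null(pixel_size) && !is.null(frame_interval)) {
    ps <- if (length(pixel_size) == 1L) c(y = pixel_size, x = pixel_size)
          else pixel_size
    out$y_um <- out$y_px * ps[["y"]]
    out$x_um <- out$x_px * ps[["x"]]
    out$vy_um_min <- out$vy_px * ps[["y"]] / frame_interval
    out$vx_um_min <- out$vx_px * ps[["x"]] / frame_interval
    out$speed_um_min <- sqrt(out$vy_um_min^2 + out$vx_um_min^2)
  }
  structure(out, pixel_size = pixel_size, frame_interval = frame_interval,
            window = utils::tail(windows, 1L),
            class = c("velocity_field", "data.frame"))
}

#' Classify velocity vectors relative to the nuclear centre
#'
#' For each valid vector inside the lamina contour with speed at or above
#' `speed_floor`, the signed angle between the vector and the unit vector
#' from the grid point toward the nuclear centre is computed (0 deg =
#' inward, 180 deg = outward) and binned into four sectors: inward
#' [-60, 60), sideways_1 [60, 120), outward [120, 240), sideways_2
#' [240, 300). Reports sector fractions, the circular mean direction with
#' 95% CI, and the mean speed.
#'
#' @param field a `velocity_field` with µm/min velocities.
#' @param centre_um nuclear centre (y, x) µm.
#' @param contour optional `lamina_contour`; vectors outside it are
#'   dropped.
#' @param speed_floor µm/min; vectors slower than this are ignored
#'   (default 1.8).
#' @return A `direction_summary`: list(n, fractions (inward, sideways_1,
#'   outward, sideways_2), mean_direction_deg, ci95_deg, resultant_length,
#'   mean_speed_um_min, angles_deg, empty).
#' @export
classify_directions <- function(field, centre_um, contour = NULL,
                                speed_floor = 1.8) {
  stopifnot(!is.null(field$vy_um_min))
  sel <- field$valid & field$speed_um_min >= speed_floor
  if (!is.null(contour)) {
    inside <- mgcv::in.out(as.matrix(contour$poly),
                           cbind(field$y_um, field$x_um))
    sel <- sel & inside
  }
  if (!any(sel)) {
    return(structure(list(n = 0L, fractions = c(inward = NA, sideways_1 = NA,
                                                outward = NA, sideways_2 = NA),
                          mean_direction_deg = NA_real_,
                          ci95_deg = c(NA_real_, NA_real_),
                          resultant_length = NA_real_,
                          mean_speed_um_min = NA_real_,
                          angles_deg = numeric(0), empty = TRUE),
                     class = "direction_summary"))
  }
  f <- field[sel, ]
  uy <- centre_um[1L] - f$y_um
  ux <- centre_um[2L] - f$x_um
  # signed angle from the inward unit vector to the velocity vector
  ang <- (atan2(f$vx_um_min, f$vy_um_min) - atan2(ux, uy)) * 180 / pi
  ang <- ang %% 360
  cat4 <- ifelse(ang < 60 | ang >= 300, "inward",
                 ifelse(ang < 120, "sideways_1",
                        ifelse(ang < 240, "outward", "sideways_2")))
  n <- length(ang)
  fr <- c(inward = sum(cat4 == "inward"),
          sideways_1 = sum(cat4 == "sideways_1"),
          outward = sum(cat4 == "outward"),
          sideways_2 = sum(cat4 == "sideways_2")) / n
  cs <- circular_stats(ang)
  structure(list(n = n, fractions = fr,
                 mean_direction_deg = cs$mean_direction,
                 ci95_deg = cs$ci95,
                 resultant_length = cs$resultant_length,
                 mean_speed_um_min = mean(f$speed_um_min),
                 angles_deg = ang, categories = cat4, empty = FALSE),
            class = "direction_summary")
}

#' @export
print.direction_summary <- function(x, ...) {
  if (x$empty) {
    cat("direction_summary: no vectors passed the filters\n")
  } else {
    cat(sprintf("direction_summary: n = %d, mean %.1f deg (CI %.1f-%.1f), mean speed %.2f um/min\n",
                x$n, x$mean_direction_deg, x$ci95_deg[1L], x$ci95_deg[2L],
                x$mean_speed_um_min))
    print(round(x$fractions, 3))
  }
  invisible(x)
}
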