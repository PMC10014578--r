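#' Circular mean, resultant length and 95% confidence interval
#'
#' Directional statistics for velocity-vector angles. The mean direction is
#' the angle of the (optionally weighted) resultant vector. The confidence
#' interval uses the large-sample circular-dispersion approximation
#' (Fisher 1993, section 4.4); when its validity condition fails (small
#' resultant length or sample), a seeded percentile bootstrap is used
#' instead.
#'
#' @param angles_deg numeric vector of angles in degrees.
#' @param weights optional non-negative weights, one per angle.
#' @param conf confidence level (default 0.95).
#' @param n_boot bootstrap replicates for the fallback CI.
#' @param boot_seed seed for the bootstrap fallback (ignored otherwise).
#' @return list with `mean_direction` (degrees in [0, 360); `NA` with
#'   `undefined = TRUE` when the resultant length is numerically zero),
#'   `resultant_length` (mean resultant length, 0-1), `ci95`
#'   (length-2 degrees, bracketing the mean), `n`, `method` ("dispersion"
#'   or "bootstrap") and `undefined`.
#' @examples
#' circular_stats(c(10, 10))
#' circular_stats(c(0, 180))$undefined
#' @export
circular_stats <- function(angles_deg, weights = NULL, conf = 0.95,
                           n_boot = 2000L, boot_seed = 1L) {
  if (length(angles_deg) == 0L) stop("empty angle set")
  th <- angles_deg * pi / 180
  w <- weights %||% rep(1, length(th))
  stopifnot(length(w) == length(th), all(w >= 0))
  sw <- sum(w)
  C <- sum(w * cos(th)) / sw
  S <- sum(w * sin(th)) / sw
  R <- sqrt(C^2 + S^2)
  n <- length(th)
  if (R < 1e-12) {
    return(list(mean_direction = NA_real_, resultant_length = R,
                ci95 = c(NA_real_, NA_real_), n = n,
                method = "none", undefined = TRUE))
  }
  mu <- atan2(S, C)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  # circular dispersion (Fisher 1993 eq. 2.28 / 4.21)
  rho2 <- sum(w * cos(2 * (th - mu))) / sw
  disp <- (1 - rho2) / (2 * R^2)
  sigma <- sqrt(disp / n)
  half <- NA_real_
  method <- "dispersion"
  if (n >= 8 && R > 2 / sqrt(n) && is.finite(sigma) && z * sigma < 1) {
    half <- asin(z * sigma)
  } else {
    method <- "bootstrap"
    half <- with_seed(boot_seed, {
      devs <- vapply(seq_len(n_boot), function(b) {
        i <- sample.int(n, n, replace = TRUE, prob = w / sw)
        Cb <- mean(cos(th[i])); Sb <- mean(sin(th[i]))
        if (Cb^2 + Sb^2 < 1e-24) return(NA_real_)
        d <- atan2(Sb, Cb) - mu
        atan2(sin(d), cos(d))
      }, numeric(1))
      stats::quantile(abs(devs), conf, na.rm = TRUE, names = FALSE)
    })
  }
  mu_deg <- (mu * 180 / pi) %% 360
  list(mean_direction = mu_deg,
       resultant_length = R,
       ci95 = c(mu_deg - half * 180 / pi, mu_deg + half * 180 / pi),
       n = n, method = method, undefined = FALSE)
}

#' Rayleigh test of circular uniformity
#'
#' Tests whether a sample of angles departs from the uniform distribution
#' on the circle; used to check that an isotropic flow field carries no
#' directional signal.
#'
#' @param angles_deg numeric vector of angles in degrees.
#' @return list with `R` (mean resultant length), `statistic` (Z = n R^2)
#'   and `p_value` (Greenwood-Durand approximation).
#' @export
rayleigh_test <- function(angles_deg) {
  n <- length(angles_deg)
  if (n == 0L) stop("empty angle set")
  th <- angles_deg * pi / 180
  R <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  Z <- n * R^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  list(R = R, statistic = Z, p_value = max(min(p, 1), 0))
}
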