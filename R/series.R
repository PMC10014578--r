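#' Multi-channel calibrated volume time series
#'
#' Container for a time-ordered set of multi-channel 3D (or 2D) intensity
#' volumes with voxel calibration. Arrays are indexed `[z, y, x]` (3D) or
#' `[y, x]` (2D); coordinates in µm refer to voxel centres, so voxel
#' `(i, j, k)` sits at `((i - 0.5) vz, (j - 0.5) vy, (k - 0.5) vx)`.
#' Frame indices at the R level are 1-based; CSV outputs are 0-based.
#'
#' @param frames list of length-T lists of equally-dimensioned arrays, one
#'   per channel.
#' @param voxel_size named numeric, µm per voxel: `c(z=, y=, x=)` for 3D
#'   data, `c(y=, x=)` for 2D.
#' @param frame_interval time between frames, minutes.
#' @param times optional explicit frame times (min); default regular.
#' @return An object of class `volume_series`.
#' @export
volume_series <- function(frames, voxel_size, frame_interval, times = NULL) {
  stopifnot(length(frames) >= 1L, all(voxel_size > 0), frame_interval > 0)
  channels <- names(frames[[1L]])
  stopifnot(!is.null(channels), !anyDuplicated(channels))
  times <- times %||% ((seq_along(frames) - 1) * frame_interval)
  frames <- lapply(frames, lapply, function(a) {
    dim(a) <- unname(dim(a))
    a
  })
  structure(list(frames = frames, channels = channels,
                 voxel_size = voxel_size, frame_interval = frame_interval,
                 times = times),
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$frames[[1L]][[1L]])
  cat(sprintf("volume_series: %d frame(s), channels [%s], dims [%s], voxel (%s) um, dt %.3g min\n",
              length(x$frames), paste(x$channels, collapse = ", "),
              paste(d, collapse = "x"),
              paste(signif(x$voxel_size, 3), collapse = ", "),
              x$frame_interval))
  invisible(x)
}

#' Number of frames in a series
#' @param series a `volume_series`.
#' @export
n_frames <- function(series) length(series$frames)

#' Extract one channel volume from one frame
#' @param series a `volume_series`.
#' @param frame 1-based frame index.
#' @param channel channel name.
#' @return The raw intensity array.
#' @export
get_channel <- function(series, frame, channel) {
  stopifnot(frame >= 1L, frame <= length(series$frames))
  if (!channel %in% series$channels) {
    stop(sprintf("channel '%s' not present (have: %s)", channel,
                 paste(series$channels, collapse = ", ")))
  }
  series$frames[[frame]][[channel]]
}
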