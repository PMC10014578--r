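# TIFF + YAML serialization of volume series and truth tables.

#' Write a volume series to TIFF with a YAML sidecar
#'
#' One multi-page 16-bit TIFF per channel (pages ordered frame-major:
#' frame 1 planes z = 1..nz, then frame 2, ...), plus `<name>.yaml`
#' carrying calibration, channel names, dimensions and frame times.
#' Intensities are stored as integer camera counts (0-65535); loading
#' with [load_series()] restores them bit-identically.
#'
#' @param series a `volume_series`.
#' @param dir output directory (created if missing).
#' @param name file stem.
#' @return Path to the YAML sidecar, invisibly.
#' @export
write_series <- function(series, dir, name = "series") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(series$frames[[1L]][[1L]])
  is3d <- length(d) == 3L
  for (ch in series$channels) {
    pages <- list()
    for (i in seq_along(series$frames)) {
      a <- series$frames[[i]][[ch]]
      if (is3d) {
        for (z in seq_len(d[1L])) {
          pages[[length(pages) + 1L]] <- a[z, , ] / 65535
        }
      } else {
        pages[[length(pages) + 1L]] <- a / 65535
      }
    }
    tiff::writeTIFF(pages, file.path(dir, paste0(name, "_", ch, ".tif")),
                    bits.per.sample = 16L)
  }
  meta <- list(name = name, channels = as.list(series$channels),
               dim = as.list(unname(d)),
               voxel_size_um = as.list(series$voxel_size),
               frame_interval_min = series$frame_interval,
               times_min = as.list(series$times),
               n_frames = length(series$frames),
               scale = 65535L)
  path <- file.path(dir, paste0(name, ".yaml"))
  yaml::write_yaml(meta, path)
  invisible(path)
}

#' Load a volume series written by [write_series()]
#'
#' @param path path to the YAML sidecar (or the directory containing it,
#'   if it holds exactly one).
#' @return A `volume_series`.
#' @export
load_series <- function(path) {
  if (dir.exists(path)) {
    ys <- list.files(path, pattern = "\\.ya?ml$", full.names = TRUE)
    if (length(ys) != 1L) stop("cannot resolve series YAML in directory")
    path <- ys
  }
  if (!file.exists(path)) stop(sprintf("series file '%s' not found", path))
  meta <- yaml::read_yaml(path)
  d <- unlist(meta$dim)
  is3d <- length(d) == 3L
  dir <- dirname(path)
  nt <- meta$n_frames
  frames <- replicate(nt, list(), simplify = FALSE)
  for (ch in unlist(meta$channels)) {
    f <- file.path(dir, paste0(meta$name, "_", ch, ".tif"))
    if (!file.exists(f)) stop(sprintf("missing channel file '%s'", f))
    pages <- tiff::readTIFF(f, all = TRUE)
    per <- if (is3d) d[1L] else 1L
    if (length(pages) != nt * per) {
      stop(sprintf("channel '%s': %d pages do not resolve as %d frames x %d planes",
                   ch, length(pages), nt, per))
    }
    for (i in seq_len(nt)) {
      if (is3d) {
        a <- array(0, d)
        for (z in seq_len(d[1L])) {
          a[z, , ] <- pages[[(i - 1L) * per + z]]
        }
      } else {
        a <- pages[[i]]
      }
      frames[[i]][[ch]] <- round(a * meta$scale)
    }
  }
  vs <- unlist(meta$voxel_size_um)
  volume_series(frames, vs, meta$frame_interval_min,
                times = unlist(meta$times_min))
}

#' Write a ground-truth object table as CSV
#'
#' Columns frame (0-based), object_id, z, y, x (µm), volume_um3,
#' has_kinetochore.
#'
#' @param truth the `truth` element of a generator result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(truth, path) {
  obj <- truth$objects
  out <- data.frame(frame = obj$frame - 1L, object_id = obj$object_id,
                    z_um = obj$z_um, y_um = obj$y_um, x_um = obj$x_um,
                    volume_um3 = obj$volume_um3,
                    has_kinetochore = obj$has_kinetochore)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
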