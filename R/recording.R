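#' Construct a volumetric calcium-imaging recording
#'
#' A recording holds `T` volumes of `Z x Y x X` intensities together with the
#' physical voxel size. Intensities are stored as a 4D array indexed
#' `[t, z, y, x]` (0-based frame indices are used in all spot/track tables;
#' array indexing itself is 1-based as usual in R). Physical positions are
#' reported as `(x, y, z)` in micrometers with `x = (column - 1) * dx`, so
#' downstream geometry is decoupled from voxel anisotropy.
#'
#' @param frames 4D numeric array, dimensions `(t, z, y, x)`; finite and
#'   non-negative.
#' @param voxel_size numeric length-3, `(dx, dy, dz)` in um/voxel.
#' @param frame_interval seconds per volume.
#' @return an object of class `nema_recording`.
#' @export
recording <- function(frames, voxel_size, frame_interval = 1) {
  if (length(dim(frames)) != 4L)
    stop("`frames` must be a 4D array (t, z, y, x)")
  if (any(dim(frames) < 1L)) stop("all recording dimensions must be >= 1")
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("`voxel_size` must be three positive values (dx, dy, dz) in um")
  if (!all(is.finite(frames))) stop("intensities must be finite")
  structure(
    list(frames = frames, voxel_size = as.numeric(voxel_size),
         frame_interval = as.numeric(frame_interval)),
    class = "nema_recording"
  )
}

#' @export
print.nema_recording <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<nema_recording> %d frames, %d x %d x %d (z,y,x) voxels, voxel %.3g x %.3g x %.3g um, dt %.3g s\n",
    d[1], d[2], d[3], d[4],
    x$voxel_size[1], x$voxel_size[2], x$voxel_size[3], x$frame_interval))
  invisible(x)
}

#' @export
dim.nema_recording <- function(x) dim(x$frames)

n_frames <- function(rec) dim(rec$frames)[1]

#' Extract one volume of a recording
#'
#' @param rec a [recording()].
#' @param t 0-based frame index.
#' @return 3D array `(z, y, x)`.
#' @export
get_volume <- function(rec, t) {
  T <- n_frames(rec)
  if (t < 0 || t >= T) stop(sprintf("frame %d out of range [0, %d]", t, T - 1))
  v <- rec$frames[t + 1L, , , , drop = FALSE]
  dim(v) <- dim(rec$frames)[2:4]
  v
}

#' Physical extent of a recording
#'
#' @param rec a [recording()].
#' @return named numeric `(x, y, z)` extent in um (voxel centers span
#'   `[0, (n-1) * d]`).
#' @export
physical_extent <- function(rec) {
  d <- dim(rec$frames)
  c(x = (d[4] - 1) * rec$voxel_size[1],
    y = (d[3] - 1) * rec$voxel_size[2],
    z = (d[2] - 1) * rec$voxel_size[3])
}

#' Read a multi-page TIFF stack as a recording
#'
#' Pages are expected in acquisition order, t-major then z: the first `n_z`
#' pages form volume 0, the next `n_z` volume 1, and so on.
#'
#' @param path a multi-page TIFF file.
#' @param voxel_size `(dx, dy, dz)` in um/voxel.
#' @param n_z number of z planes per volume.
#' @param frame_interval seconds per volume.
#' @return a [recording()].
#' @export
read_recording <- function(path, voxel_size, n_z, frame_interval = 1) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  np <- length(pages)
  if (np %% n_z != 0L)
    stop(sprintf("TIFF has %d pages, not divisible by n_z = %d", np, n_z))
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
    stop("all TIFF pages must be single-channel 2D images")
  T <- np %/% n_z
  ny <- nrow(pages[[1]])
  nx <- ncol(pages[[1]])
  frames <- array(0, dim = c(T, n_z, ny, nx))
  for (t in seq_len(T))
    for (z in seq_len(n_z))
      frames[t, z, , ] <- pages[[(t - 1L) * n_z + z]]
  recording(frames, voxel_size, frame_interval)
}

#' Write a recording as a multi-page 16-bit TIFF
#'
#' Pages are written t-major then z so that [read_recording()] inverts the
#' operation. Intensities are stored as 16-bit integers: the round trip is
#' bit-exact for integer-valued grids in `[0, 65535]`; fractional values are
#' rounded.
#'
#' @param rec a [recording()].
#' @param path output file path.
#' @export
write_recording <- function(rec, path) {
  d <- dim(rec$frames)
  if (any(d < 1L) || length(rec$frames) == 0L) stop("empty recording")
  if (min(rec$frames) < 0 || max(rec$frames) > 65535)
    stop("16-bit TIFF output requires intensities in [0, 65535]")
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (t in seq_len(d[1]))
    for (z in seq_len(d[2])) {
      m <- rec$frames[t, z, , ]
      dim(m) <- d[3:4]
      pages[[k]] <- m / 65535
      k <- k + 1L
    }
  ok <- tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                        compression = "none")
  invisible(ok)
}

#' Subtract a frame-specific dark background
#'
#' For each frame, the mean intensity of a dark crop (taken over all z planes
#' of that frame) is subtracted from every voxel of the frame; negative
#' results are clamped at 0.
#'
#' @param rec a [recording()].
#' @param dark_crop half-open voxel box `(y0, y1, x0, x1)` (0-based, `y1`/`x1`
#'   exclusive); `NULL` picks the 32 x 32 corner of frame 0 with the lowest
#'   mean intensity.
#' @return background-subtracted [recording()].
#' @export
subtract_background <- function(rec, dark_crop = NULL) {
  d <- dim(rec$frames)
  if (is.null(dark_crop)) dark_crop <- default_dark_crop(rec)
  y0 <- dark_crop[1]; y1 <- dark_crop[2]; x0 <- dark_crop[3]; x1 <- dark_crop[4]
  if (y0 < 0 || x0 < 0 || y1 > d[3] || x1 > d[4] || y0 >= y1 || x0 >= x1)
    stop("dark crop outside image bounds")
  if ((y1 - y0) * (x1 - x0) < 4) stop("dark crop must cover at least 4 voxels")
  out <- rec$frames
  for (t in seq_len(d[1])) {
    b <- mean(out[t, , (y0 + 1):y1, (x0 + 1):x1])
    out[t, , , ] <- pmax(out[t, , , ] - b, 0)
  }
  recording(out, rec$voxel_size, rec$frame_interval)
}

#' Default dark crop: the darkest 32 x 32 corner of frame 0
#'
#' @param rec a [recording()].
#' @param size crop side length in voxels (clipped to the frame size).
#' @return `(y0, y1, x0, x1)` half-open voxel box.
#' @export
default_dark_crop <- function(rec, size = 32L) {
  d <- dim(rec$frames)
  sy <- min(size, d[3]); sx <- min(size, d[4])
  corners <- list(
    c(0, sy, 0, sx),
    c(0, sy, d[4] - sx, d[4]),
    c(d[3] - sy, d[3], 0, sx),
    c(d[3] - sy, d[3], d[4] - sx, d[4])
  )
  means <- vapply(corners, function(cr)
    mean(rec$frames[1, , (cr[1] + 1):cr[2], (cr[3] + 1):cr[4]]), numeric(1))
  corners[[which.min(means)]]
}

#' Temporal denoising of a recording
#'
#' `kalman` mode applies a per-voxel scalar-gain recursive filter,
#' `est_t = est_{t-1} + gain * (obs_t - est_{t-1})` with `est_0 = obs_0`
#' (gain 1 is the identity). `median` mode applies a per-voxel running median
#' over a 3-frame window, shrinking at the sequence edges.
#'
#' @param rec a [recording()].
#' @param gain scalar in `(0, 1]`, used by `kalman` mode.
#' @param mode `"kalman"` or `"median"`.
#' @return denoised [recording()].
#' @export
temporal_denoise <- function(rec, gain = 0.5, mode = c("kalman", "median")) {
  mode <- match.arg(mode)
  T <- n_frames(rec)
  out <- rec$frames
  if (mode == "kalman") {
    if (!is.numeric(gain) || length(gain) != 1 || gain <= 0 || gain > 1)
      stop("`gain` must be a scalar in (0, 1]")
    if (T >= 2) {
      for (t in 2:T)
        out[t, , , ] <- out[t - 1, , , ] + gain * (rec$frames[t, , , ] - out[t - 1, , , ])
    }
  } else {
    if (T >= 2) {
      src <- rec$frames
      for (t in seq_len(T)) {
        lo <- max(1, t - 1); hi <- min(T, t + 1)
        if (hi - lo == 2L) {
          a <- src[lo, , , ]; b <- src[t, , , ]; cc <- src[hi, , , ]
          # elementwise median of three values
          out[t, , , ] <- a + b + cc - pmax(a, b, cc) - pmin(a, b, cc)
        } else {
          out[t, , , ] <- (src[lo, , , ] + src[hi, , , ]) / 2
        }
      }
    }
  }
  recording(out, rec$voxel_size, rec$frame_interval)
}
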