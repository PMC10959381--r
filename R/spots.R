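#' Construct a spot table
#'
#' Spots are detected, inferred or manually placed nucleus centers. They are
#' kept in a plain data frame with one row per spot: `t` (0-based frame
#' index), physical position `x`, `y`, `z` in um, `intensity` (for detected
#' spots, the LoG-response x image product value) and `source` (one of
#' `"detected"`, `"inferred"`, `"manual"`).
#'
#' @param t integer frame indices (0-based).
#' @param x,y,z physical coordinates in um.
#' @param intensity spot intensities (>= 0 for detected spots).
#' @param source character, `"detected"`, `"inferred"` or `"manual"`.
#' @return a `data.frame` of spots.
#' @export
spot_table <- function(t = integer(), x = numeric(), y = numeric(),
                       z = numeric(), intensity = numeric(),
                       source = character()) {
  n <- max(length(t), length(x), length(y), length(z))
  if (n > 0) {
    if (length(x) == 1L) x <- rep(x, n)
    if (length(y) == 1L) y <- rep(y, n)
    if (length(z) == 1L) z <- rep(z, n)
    if (length(intensity) == 1L) intensity <- rep(intensity, n)
  }
  stopifnot(length(t) == length(x), length(x) == length(y),
            length(y) == length(z))
  if (length(intensity) == 0L) intensity <- rep(NA_real_, length(t))
  if (length(source) == 0L) source <- rep("detected", length(t))
  if (length(source) == 1L) source <- rep(source, length(t))
  bad <- setdiff(unique(source), c("detected", "inferred", "manual"))
  if (length(bad)) stop("unknown spot source: ", paste(bad, collapse = ", "))
  data.frame(t = as.integer(t), x = as.numeric(x), y = as.numeric(y),
             z = as.numeric(z), intensity = as.numeric(intensity),
             source = source, stringsAsFactors = FALSE)
}

spot_positions <- function(spots) {
  as.matrix(spots[, c("x", "y", "z")])
}

#' Write spots or tracks to CSV
#'
#' Columns are `(track_id, t, x_um, y_um, z_um, intensity, source)`; for a
#' plain spot table the `track_id` column is omitted.
#'
#' @param x a spot table or track table (with `track_id`).
#' @param path output CSV path.
#' @export
write_spots_csv <- function(x, path) {
  out <- x
  names(out)[names(out) == "x"] <- "x_um"
  names(out)[names(out) == "y"] <- "y_um"
  names(out)[names(out) == "z"] <- "z_um"
  write.csv(out, path, row.names = FALSE)
}

#' Read spots or tracks from CSV
#'
#' @param path CSV written by [write_spots_csv()] (or the same schema with a
#'   `neuron_id` column for ground truth).
#' @return data frame with `x`, `y`, `z` column names restored.
#' @export
read_spots_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  names(x)[names(x) == "x_um"] <- "x"
  names(x)[names(x) == "y_um"] <- "y"
  names(x)[names(x) == "z_um"] <- "z"
  x
}

#' Convert voxel indices to physical positions
#'
#' @param idx matrix of 1-based voxel indices with columns `(z, y, x)` (the
#'   array axis order of a volume).
#' @param voxel_size `(dx, dy, dz)` in um.
#' @return matrix with columns `(x, y, z)` in um.
#' @export
voxel_to_um <- function(idx, voxel_size) {
  cbind(x = (idx[, 3] - 1) * voxel_size[1],
        y = (idx[, 2] - 1) * voxel_size[2],
        z = (idx[, 1] - 1) * voxel_size[3])
}

#' Convert physical positions to nearest voxel indices
#'
#' @param pos matrix with columns `(x, y, z)` in um.
#' @param voxel_size `(dx, dy, dz)` in um.
#' @param dims volume dimensions `(z, y, x)` for clamping.
#' @return matrix of 1-based voxel indices with columns `(z, y, x)`.
#' @export
um_to_voxel <- function(pos, voxel_size, dims) {
  pos <- rbind(pos)
  iz <- pmin(pmax(round(pos[, 3] / voxel_size[3]) + 1, 1), dims[1])
  iy <- pmin(pmax(round(pos[, 2] / voxel_size[2]) + 1, 1), dims[2])
  ix <- pmin(pmax(round(pos[, 1] / voxel_size[1]) + 1, 1), dims[3])
  cbind(z = iz, y = iy, x = ix)
}
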