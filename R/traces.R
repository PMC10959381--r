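#' Extract a background-corrected fluorescence trace for one track
#'
#' Per frame, the ROI is the set of voxels inside the track's consolidated
#' ellipsoid centered at that frame's position. The signal is the mean of
#' the brightest 90% of ROI voxels (voxels at or above the ROI's 10th
#' intensity percentile) and the local background is the mean of the
#' 1-voxel-thick corona of voxels adjacent to, but outside, the ROI. The
#' trace value is signal minus corona (not clamped; mildly negative values
#' are legitimate noise).
#'
#' @param rec a [recording()] (background-subtracted).
#' @param track rows of the track table for one track, gap-free.
#' @param shape consolidated `roi_shape` from [consolidate_shape()].
#' @param refine_center refine each frame's center to sub-voxel precision by
#'   an intensity-weighted centroid (capped at 0.5 um of shift) before
#'   placing the ROI template. Off by default: the template is anchored at
#'   the rounded center so the voxel-set composition (and hence the captured
#'   signal fraction) stays constant across frames, which matters more for
#'   trace fidelity than sub-voxel aperture alignment.
#' @param others optional track table of the *other* tracks; corona voxels
#'   within `exclusion_radius` of any of their positions are excluded from
#'   the background estimate so neighboring nuclei do not leak their signal
#'   into it.
#' @param exclusion_radius radius (um) of the neighbor exclusion.
#' @return a `trace` list: `track_id`, `t`, `values`, `frames_inferred`.
#' @export
extract_trace <- function(rec, track, shape, refine_center = FALSE,
                          others = NULL, exclusion_radius = 3) {
  track <- track[order(track$t), , drop = FALSE]
  others_by_t <- if (!is.null(others) && nrow(others) > 0)
    split(others[, c("x", "y", "z")], others$t) else NULL
  dims <- dim(rec$frames)[2:4]
  vox <- rec$voxel_size
  semi <- shape$semi_axes
  rot <- shape$orientation
  # candidate voxel box around the (fractional) center, covering the
  # ellipsoid plus a one-voxel corona margin
  reach <- max(semi) + max(vox)
  nx <- ceiling(reach / vox[1]) + 1L
  ny <- ceiling(reach / vox[2]) + 1L
  nz <- ceiling(reach / vox[3]) + 1L
  grid <- expand.grid(dz = -nz:nz, dy = -ny:ny, dx = -nx:nx)
  goff <- cbind(grid$dz, grid$dy, grid$dx)
  neigh <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))
  # the ROI template is fixed in voxel offsets (anchored at the rounded
  # center): a constant voxel-set composition keeps the captured fraction
  # stable across frames, which matters more for trace fidelity than
  # sub-voxel alignment of the aperture
  rel <- cbind(grid$dx * vox[1], grid$dy * vox[2], grid$dz * vox[3])
  u <- rel %*% rot
  inside <- rowSums(sweep(u, 2, semi, "/")^2) <= 1
  # axially under-resolved nuclei (z plane spacing comparable to the
  # nucleus size) fit as near-sheets spanning one plane, and a one-plane
  # ROI aliases with axial drift; extruding the mid cross-section onto the
  # two adjacent planes makes the captured signal nearly drift-invariant
  # without reaching laterally toward neighbors
  z_extent <- sqrt(sum((semi * rot[3, ])^2))
  if (z_extent < 1.5 * vox[3]) {
    lat <- rel
    lat[, 3] <- 0
    ul <- lat %*% rot
    lat_in <- rowSums(sweep(ul, 2, semi, "/")^2) <= 1
    inside <- inside | (lat_in & abs(rel[, 3]) <= 1.01 * vox[3])
  }
  # corona: 6-neighborhood dilation of the ROI minus the ROI
  ins_arr <- array(FALSE, dim = c(2 * nz + 1, 2 * ny + 1, 2 * nx + 1))
  ins_arr[cbind(grid$dz + nz + 1, grid$dy + ny + 1, grid$dx + nx + 1)] <-
    inside
  cor_arr <- array(FALSE, dim(ins_arr))
  for (k in seq_len(6))
    cor_arr <- cor_arr | shift_logical_3d(ins_arr, neigh[k, ])
  cor_arr <- cor_arr & !ins_arr
  corona <- cor_arr[cbind(grid$dz + nz + 1, grid$dy + ny + 1,
                          grid$dx + nx + 1)]
  vals <- rep(NA_real_, nrow(track))
  for (r in seq_len(nrow(track))) {
    pos <- c(track$x[r], track$y[r], track$z[r])
    vol <- get_volume(rec, track$t[r])
    ci <- um_to_voxel(rbind(pos), vox, dims)[1, ]
    if (refine_center) {
      # sub-voxel center: intensity-weighted centroid of a small patch;
      # the shift is capped so a bright neighbor cannot capture the ROI
      pz <- max(1, ci[1] - 1):min(dims[1], ci[1] + 1)
      py <- max(1, ci[2] - 3):min(dims[2], ci[2] + 3)
      px <- max(1, ci[3] - 3):min(dims[3], ci[3] + 3)
      patch <- vol[pz, py, px, drop = FALSE]
      w <- as.numeric(patch)
      if (sum(w) > 0) {
        idx <- which(array(TRUE, dim(patch)), arr.ind = TRUE)
        ctr <- c(sum((px[idx[, 3]] - 1) * vox[1] * w),
                 sum((py[idx[, 2]] - 1) * vox[2] * w),
                 sum((pz[idx[, 1]] - 1) * vox[3] * w)) / sum(w)
        shift <- ctr - pos
        nsh <- sqrt(sum(shift^2))
        if (nsh > 0.5) shift <- shift * 0.5 / nsh
        pos <- pos + shift
      }
    }
    base <- um_to_voxel(rbind(pos), vox, dims)[1, ]
    vidx <- sweep(goff, 2, base, "+")  # (z, y, x) integer voxels
    ok <- vidx[, 1] >= 1 & vidx[, 1] <= dims[1] &
      vidx[, 2] >= 1 & vidx[, 2] <= dims[2] &
      vidx[, 3] >= 1 & vidx[, 3] <= dims[3]
    if (!any(inside & ok)) {
      warning("ROI fully outside the volume at frame ", track$t[r])
      next
    }
    rv <- vol[vidx[inside & ok, , drop = FALSE]]
    cutoff <- quantile(rv, 0.10, names = FALSE, type = 7)
    signal <- mean(rv[rv >= cutoff])
    okc <- corona & ok
    # corona voxels inside neighboring nuclei would leak their (possibly
    # anti-correlated) signal into the background estimate; exclude them
    if (!is.null(others_by_t) && any(okc)) {
      op <- others_by_t[[as.character(track$t[r])]]
      if (!is.null(op) && nrow(op) > 0) {
        cpos <- cbind((vidx[okc, 3] - 1) * vox[1],
                      (vidx[okc, 2] - 1) * vox[2],
                      (vidx[okc, 1] - 1) * vox[3])
        mind <- apply(cpos, 1, function(p)
          min(sqrt((op$x - p[1])^2 + (op$y - p[2])^2 + (op$z - p[3])^2)))
        if (any(mind > exclusion_radius))
          okc[okc] <- mind > exclusion_radius
      }
    }
    bg <- if (any(okc)) mean(vol[vidx[okc, , drop = FALSE]]) else 0
    vals[r] <- signal - bg
  }
  structure(list(track_id = track$track_id[1], t = track$t, values = vals,
                 frames_inferred = track$source != "detected"),
            class = "trace")
}

# shift a logical 3D array by an integer offset, filling with FALSE
shift_logical_3d <- function(a, off) {
  d <- dim(a)
  out <- array(FALSE, d)
  src <- list(seq_len(d[1]) - off[1], seq_len(d[2]) - off[2],
              seq_len(d[3]) - off[3])
  ok <- lapply(seq_len(3), function(i) src[[i]] >= 1 & src[[i]] <= d[i])
  out[ok[[1]], ok[[2]], ok[[3]]] <-
    a[src[[1]][ok[[1]]], src[[2]][ok[[2]]], src[[3]][ok[[3]]]]
  out
}

#' Smooth a trace with a centered moving average
#'
#' The window shrinks symmetrically at the edges; `window = 1` is the
#' identity.
#'
#' @param trace a `trace` from [extract_trace()] (or a numeric vector).
#' @param window odd window length in frames.
#' @return the trace with a `smoothed` component (or a numeric vector).
#' @export
smooth_trace <- function(trace, window = 5L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("`window` must be odd and >= 1")
  v <- if (inherits(trace, "trace")) trace$values else as.numeric(trace)
  n <- length(v)
  half <- window %/% 2L
  sm <- vapply(seq_len(n), function(i) {
    mean(v[max(1L, i - half):min(n, i + half)], na.rm = TRUE)
  }, numeric(1))
  if (inherits(trace, "trace")) {
    trace$smoothed <- sm
    trace
  } else {
    sm
  }
}

#' Extract (and smooth) traces for every track
#'
#' @param rec a [recording()].
#' @param tracks gap-free track table.
#' @param shapes named list of consolidated shapes (one per track id).
#' @param window smoothing window (odd frames).
#' @return list of `trace` objects, named by track id.
#' @export
extract_all_traces <- function(rec, tracks, shapes, window = 5L) {
  ids <- sort(unique(tracks$track_id))
  out <- lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    others <- tracks[tracks$track_id != id, , drop = FALSE]
    smooth_trace(extract_trace(rec, tr, shapes[[as.character(id)]],
                               others = others),
                 window)
  })
  names(out) <- ids
  out
}

#' Assemble traces into a frames x tracks matrix
#'
#' @param traces list of `trace` objects.
#' @param n_frames total frames; rows without a value are `NA`.
#' @param smoothed use the smoothed values when available.
#' @return numeric matrix, `n_frames` rows, one column per track.
#' @export
trace_matrix <- function(traces, n_frames, smoothed = TRUE) {
  m <- matrix(NA_real_, n_frames, length(traces))
  colnames(m) <- names(traces)
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    v <- if (smoothed && !is.null(tr$smoothed)) tr$smoothed else tr$values
    m[tr$t + 1L, i] <- v
  }
  m
}

#' Write traces as a track x frame CSV matrix
#'
#' @param traces list of `trace` objects.
#' @param n_frames total frames.
#' @param path output CSV.
#' @export
write_traces_csv <- function(traces, n_frames, path) {
  m <- t(trace_matrix(traces, n_frames, smoothed = FALSE))
  out <- data.frame(track_id = as.integer(rownames(m)), m)
  names(out)[-1] <- paste0("t", 0:(n_frames - 1))
  write.csv(out, path, row.names = FALSE)
}
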