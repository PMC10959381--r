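#' Segment the nucleus around a tracked spot
#'
#' A cube of half-width `extent` um around the spot is cropped (clipped at
#' volume borders). The crop is smoothed with Gaussian filters from a fixed
#' scale ladder (0.5, 1.0, 1.5 um) and thresholded at the Otsu threshold and
#' at +/- 20% around it; each (scale, threshold) yields the 6-connected
#' binary component containing the spot voxel. The setting whose component
#' has an equivalent-sphere diameter closest to 2 um (the nominal nucleus
#' size) without touching any other track's spot is returned. If every
#' setting yields an empty or degenerate component, a 2 um sphere mask is
#' used as a fallback.
#'
#' @param volume 3D array `(z, y, x)`.
#' @param spot one-row spot table (or list with `x`, `y`, `z` in um).
#' @param voxel_size `(dx, dy, dz)` um.
#' @param other_spots optional spot table of the other tracks at this frame;
#'   components containing any of their voxels are rejected.
#' @param extent crop half-width in um (default 6).
#' @param scales Gaussian smoothing scale ladder in um.
#' @return list with `mask` (logical 3D array over the crop), `crop`
#'   (intensities), `offset` (0-based voxel offset `(z, y, x)` of the crop in
#'   the full volume) and `fallback` (logical).
#' @export
segment_roi <- function(volume, spot, voxel_size, other_spots = NULL,
                        extent = 6, scales = c(0.5, 1.0, 1.5)) {
  dims <- dim(volume)
  center <- c(spot$x[1], spot$y[1], spot$z[1])
  half <- ceiling(extent / voxel_size)  # (x, y, z) voxels
  ci <- um_to_voxel(rbind(center), voxel_size, dims)[1, ]  # (z, y, x)
  z0 <- max(1, ci[1] - half[3]); z1 <- min(dims[1], ci[1] + half[3])
  y0 <- max(1, ci[2] - half[2]); y1 <- min(dims[2], ci[2] + half[2])
  x0 <- max(1, ci[3] - half[1]); x1 <- min(dims[3], ci[3] + half[1])
  crop <- volume[z0:z1, y0:y1, x0:x1, drop = FALSE]
  cdims <- dim(crop)
  offset <- c(z0, y0, x0) - 1L
  spot_idx <- c(ci[1] - z0 + 1L, ci[2] - y0 + 1L, ci[3] - x0 + 1L)
  spot_lin <- (spot_idx[3] - 1L) * cdims[1] * cdims[2] +
    (spot_idx[2] - 1L) * cdims[1] + spot_idx[1]
  other_lin <- integer(0)
  if (!is.null(other_spots) && nrow(other_spots) > 0) {
    ov <- um_to_voxel(spot_positions(other_spots), voxel_size, dims)
    inside <- ov[, 1] >= z0 & ov[, 1] <= z1 & ov[, 2] >= y0 & ov[, 2] <= y1 &
      ov[, 3] >= x0 & ov[, 3] <= x1
    ov <- ov[inside, , drop = FALSE]
    if (nrow(ov) > 0)
      other_lin <- (ov[, 3] - x0) * cdims[1] * cdims[2] +
        (ov[, 2] - y0) * cdims[1] + (ov[, 1] - z0 + 1L)
  }
  voxel_vol <- prod(voxel_size)
  target <- 2.0
  best <- NULL
  best_score <- Inf
  for (s in scales) {
    sm <- gaussian_smooth_3d(crop, s, voxel_size)
    # anchor Otsu on the bright voxel population: fluorescence crops are
    # dominated by near-zero background that would otherwise drag the
    # threshold far below the nucleus boundary
    ot <- otsu_threshold(sm[sm >= 0.1 * max(sm)])
    # Otsu alone lands on the dim tail of Gaussian-like nuclei, so the
    # ladder adds peak-fraction candidates; the size-closest-to-2-um rule
    # picks among them
    cands <- unique(c(c(0.8, 1, 1.2) * ot,
                      c(0.3, 0.45, 0.6, 0.75) * max(sm)))
    for (thr in cands) {
      mask <- sm >= thr
      if (!mask[spot_lin]) next
      lab <- label_components_6(as.logical(mask), as.integer(cdims))
      comp <- lab == lab[spot_lin]
      if (length(other_lin) && any(comp[other_lin])) next
      vol_um <- sum(comp) * voxel_vol
      diam <- 2 * (3 * vol_um / (4 * pi))^(1 / 3)
      score <- abs(diam - target)
      if (score < best_score) {
        best_score <- score
        dim(comp) <- cdims
        best <- comp
      }
    }
  }
  fallback <- is.null(best)
  if (fallback) {
    best <- sphere_mask(cdims, spot_idx, target / 2, voxel_size)
    if (!any(best)) best[spot_idx[1], spot_idx[2], spot_idx[3]] <- TRUE
  }
  list(mask = best, crop = crop, offset = offset, fallback = fallback)
}

gaussian_smooth_3d <- function(vol, sigma, voxel_size) {
  dims <- dim(vol)
  k1 <- function(step) {
    half <- max(1L, ceiling(3 * sigma / step))
    t <- (-half:half) * step
    g <- exp(-t^2 / (2 * sigma^2))
    g / sum(g)
  }
  v <- conv3d_axis(as.numeric(vol), as.integer(dims), k1(voxel_size[3]), 1L)
  v <- conv3d_axis(v, as.integer(dims), k1(voxel_size[2]), 2L)
  v <- conv3d_axis(v, as.integer(dims), k1(voxel_size[1]), 3L)
  dim(v) <- dims
  v
}

sphere_mask <- function(dims, center_idx, radius_um, voxel_size) {
  z <- ((seq_len(dims[1]) - center_idx[1]) * voxel_size[3])^2
  y <- ((seq_len(dims[2]) - center_idx[2]) * voxel_size[2])^2
  x <- ((seq_len(dims[3]) - center_idx[3]) * voxel_size[1])^2
  r2 <- outer(outer(z, y, "+"), x, "+")
  array(r2 <= radius_um^2, dims)
}

#' Fit an ellipsoid model to a segmented nucleus
#'
#' The center is the intensity-weighted centroid of the mask voxels (in
#' physical coordinates, giving sub-voxel localization). Semi-axes and
#' orientation come from the eigen-decomposition of the intensity-weighted
#' second-moment matrix, scaled by the uniform-ellipsoid relation
#' `semi_axis_k = sqrt(5 * eigenvalue_k)`. Quality is the fraction of mask
#' voxels inside the fitted ellipsoid.
#'
#' @param mask logical 3D array `(z, y, x)`.
#' @param crop_intensities 3D array of the same shape.
#' @param voxel_size `(dx, dy, dz)` um.
#' @param offset 0-based voxel offset `(z, y, x)` of the crop in the volume.
#' @return a `roi_shape` list: `center` (x, y, z um), `semi_axes` (um,
#'   descending), `orientation` (3x3 rotation, columns = axes), `quality`.
#' @export
fit_ellipsoid <- function(mask, crop_intensities, voxel_size,
                          offset = c(0L, 0L, 0L)) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask")
  w <- crop_intensities[idx]
  if (all(w <= 0)) w <- rep(1, length(w))
  w <- w / sum(w)
  pos <- cbind(x = (idx[, 3] + offset[3] - 1) * voxel_size[1],
               y = (idx[, 2] + offset[2] - 1) * voxel_size[2],
               z = (idx[, 1] + offset[1] - 1) * voxel_size[3])
  ctr <- colSums(pos * w)
  q <- sweep(pos, 2, ctr)
  m2 <- t(q) %*% (q * w)
  eg <- eigen(m2, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  semi <- sqrt(5 * vals)
  rot <- eg$vectors
  if (det(rot) < 0) rot[, 3] <- -rot[, 3]
  # degenerate (coplanar mask) guard: half the voxel extent projected onto
  # the collapsed axis
  floor_k <- 0.5 * as.numeric(t(abs(rot)) %*% voxel_size)
  degen <- semi < 1e-9
  if (any(degen)) {
    semi[degen] <- floor_k[degen]
    warning("degenerate second moments; half-voxel semi-axis substituted")
  }
  # quality: fraction of mask voxels inside the fitted ellipsoid
  u <- q %*% rot
  inside <- rowSums(sweep(u, 2, semi, "/")^2) <= 1
  structure(list(center = ctr, semi_axes = semi, orientation = rot,
                 quality = mean(inside)),
            class = "roi_shape")
}

#' Consolidate per-frame ellipsoid fits into one shape
#'
#' Semi-axes are averaged over frames weighted by ROI intensity; the
#' orientation is the rotation nearest (orthogonal Procrustes projection) to
#' the intensity-weighted mean of the per-frame rotation matrices, after
#' aligning each frame's axis signs to the highest-intensity frame. Centers
#' remain per-frame and are not consolidated.
#'
#' @param shapes list of `roi_shape` fits for one track.
#' @param intensities per-frame ROI intensities used as weights.
#' @return consolidated `roi_shape` (center from the highest-weight frame).
#' @export
consolidate_shape <- function(shapes, intensities) {
  stopifnot(length(shapes) >= 1, length(shapes) == length(intensities))
  w <- as.numeric(intensities)
  w[!is.finite(w) | w < 0] <- 0
  if (sum(w) == 0) {
    warning("all ROI intensities zero; using unweighted average")
    w <- rep(1, length(shapes))
  }
  w <- w / sum(w)
  ref <- shapes[[which.max(w)]]
  semi <- Reduce(`+`, Map(function(s, wi) wi * s$semi_axes, shapes, w))
  rsum <- matrix(0, 3, 3)
  for (i in seq_along(shapes)) {
    r <- shapes[[i]]$orientation
    for (j in 1:3) if (sum(r[, j] * ref$orientation[, j]) < 0)
      r[, j] <- -r[, j]
    rsum <- rsum + w[i] * r
  }
  rot <- nearest_rotation(rsum)
  structure(list(center = ref$center, semi_axes = semi, orientation = rot,
                 quality = sum(w * vapply(shapes, `[[`, numeric(1),
                                          "quality"))),
            class = "roi_shape")
}

#' Fit and consolidate ROI shapes for every track
#'
#' For speed, shapes are fitted at a subsample of frames (every
#' `sample_every`-th detected frame) and consolidated per track.
#'
#' @param rec a [recording()].
#' @param tracks gap-free track table.
#' @param params [tracking_params()] (unused placeholder for future options).
#' @param sample_every fit at every k-th detected frame (default 10).
#' @return named list of consolidated `roi_shape`s, one per track id.
#' @export
segment_all_rois <- function(rec, tracks, params = tracking_params(),
                             sample_every = 10L) {
  ids <- sort(unique(tracks$track_id))
  out <- vector("list", length(ids))
  names(out) <- ids
  n_degenerate <- 0L
  for (i in seq_along(ids)) {
    tr <- tracks[tracks$track_id == ids[i] & tracks$source == "detected", ]
    if (nrow(tr) == 0)
      tr <- tracks[tracks$track_id == ids[i], ][1, , drop = FALSE]
    sel <- tr[seq(1, nrow(tr), by = sample_every), , drop = FALSE]
    shapes <- list()
    weights <- numeric(0)
    for (r in seq_len(nrow(sel))) {
      t <- sel$t[r]
      vol <- get_volume(rec, t)
      others <- tracks[tracks$t == t & tracks$track_id != ids[i], ]
      sr <- segment_roi(vol, sel[r, ], rec$voxel_size, other_spots = others)
      # single-plane masks are routine at coarse z spacing; collect the
      # degenerate-moment warnings into one summary message
      sh <- withCallingHandlers(
        fit_ellipsoid(sr$mask, sr$crop, rec$voxel_size, sr$offset),
        warning = function(w) {
          if (grepl("degenerate second moments", conditionMessage(w))) {
            n_degenerate <<- n_degenerate + 1L
            invokeRestart("muffleWarning")
          }
        })
      shapes <- c(shapes, list(sh))
      weights <- c(weights, mean(sr$crop[sr$mask]))
    }
    out[[i]] <- consolidate_shape(shapes, weights)
  }
  if (n_degenerate > 0)
    message(n_degenerate, " ROI fit(s) had single-plane masks; ",
            "half-voxel z semi-axis substituted")
  out
}

#' Export consolidated shapes as a CSV table
#'
#' @param shapes named list from [segment_all_rois()].
#' @param path output CSV.
#' @export
write_shapes_csv <- function(shapes, path) {
  rows <- lapply(names(shapes), function(id) {
    s <- shapes[[id]]
    data.frame(track_id = as.integer(id), a_um = s$semi_axes[1],
               b_um = s$semi_axes[2], c_um = s$semi_axes[3],
               t(as.numeric(s$orientation)), quality = s$quality)
  })
  out <- do.call(rbind, rows)
  names(out)[5:13] <- paste0("r", rep(1:3, each = 3), rep(1:3, 3))
  write.csv(out, path, row.names = FALSE)
}

#' Read consolidated shapes back from CSV
#'
#' @param path CSV written by [write_shapes_csv()].
#' @return named list of `roi_shape`s (centers are per-frame and therefore
#'   not stored; they are `NA` here).
#' @export
read_shapes_csv <- function(path) {
  x <- read.csv(path)
  out <- lapply(seq_len(nrow(x)), function(i) {
    rot <- matrix(as.numeric(x[i, paste0("r", rep(1:3, each = 3),
                                         rep(1:3, 3))]), 3, 3)
    structure(list(center = rep(NA_real_, 3),
                   semi_axes = as.numeric(x[i, c("a_um", "b_um", "c_um")]),
                   orientation = rot, quality = x$quality[i]),
              class = "roi_shape")
  })
  names(out) <- x$track_id
  out
}
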