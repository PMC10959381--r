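#' Detection parameters
#'
#' @param filter_size odd kernel size in voxels per axis (>= 3).
#' @param sigma Gaussian sigma of the LoG filter, in um (isotropic in
#'   physical units; anisotropic voxels are handled by building the kernel in
#'   physical coordinates).
#' @param threshold threshold on the product image (LoG response x original
#'   intensity) at candidate maxima; detection keeps maxima whose product
#'   exceeds it. User-tuned in practice (see [preview_detection()]).
#' @param merge_distance spots closer than this (um) after thresholding are
#'   merged, keeping the brighter one.
#' @return a `detection_params` list.
#' @export
detection_params <- function(filter_size = 9L, sigma = 1.0, threshold = 0,
                             merge_distance = 1.5) {
  filter_size <- as.integer(filter_size)
  if (filter_size < 3L || filter_size %% 2L == 0L)
    stop("`filter_size` must be odd and >= 3")
  if (sigma <= 0) stop("`sigma` must be > 0")
  if (threshold < 0) stop("`threshold` must be >= 0")
  structure(list(filter_size = filter_size, sigma = sigma,
                 threshold = threshold, merge_distance = merge_distance),
            class = "detection_params")
}

log_kernels_1d <- function(size, sigma, step) {
  half <- size %/% 2L
  ticks <- (-half:half) * step
  g <- exp(-ticks^2 / (2 * sigma^2))
  g <- g / sum(g)
  # sampled second derivative of the Gaussian; forced to zero sum so flat
  # regions give zero response
  g2 <- (ticks^2 - sigma^2) / sigma^4 * exp(-ticks^2 / (2 * sigma^2))
  g2 <- g2 * step / (sigma * sqrt(2 * pi))
  g2 <- g2 - mean(g2)
  list(smooth = g, second = g2)
}

#' 3D Laplacian-of-Gaussian filter of a volume
#'
#' Convolves the volume with a sign-flipped LoG kernel built in physical
#' units, so bright blobs of scale ~`sigma` give positive peaks. The LoG is
#' computed as the sum of the three separable second-derivative-of-Gaussian
#' components; boundaries are reflective.
#'
#' @param volume 3D array `(z, y, x)`.
#' @param params [detection_params()].
#' @param voxel_size `(dx, dy, dz)` um.
#' @return filter response, same shape as `volume`.
#' @export
log_filter_3d <- function(volume, params, voxel_size) {
  dims <- dim(volume)
  if (length(dims) != 3L) stop("`volume` must be a 3D array")
  if (!all(is.finite(volume))) stop("volume must be finite")
  if (params$sigma < max(voxel_size) / 2)
    warning("LoG sigma is smaller than half the largest voxel dimension; ",
            "blobs are under-resolved on that axis")
  kz <- log_kernels_1d(params$filter_size, params$sigma, voxel_size[3])
  ky <- log_kernels_1d(params$filter_size, params$sigma, voxel_size[2])
  kx <- log_kernels_1d(params$filter_size, params$sigma, voxel_size[1])
  if (dims[1] < params$filter_size)
    warning("z extent (", dims[1], ") smaller than the filter support (",
            params$filter_size, "); kernel effectively truncated")
  v <- as.numeric(volume)
  d <- as.integer(dims)
  # Lzz: g'' along z, smooth along y and x (axis 1 = z, fastest varying)
  lzz <- conv3d_axis(conv3d_axis(conv3d_axis(v, d, kz$second, 1L),
                                 d, ky$smooth, 2L), d, kx$smooth, 3L)
  lyy <- conv3d_axis(conv3d_axis(conv3d_axis(v, d, ky$second, 2L),
                                 d, kz$smooth, 1L), d, kx$smooth, 3L)
  lxx <- conv3d_axis(conv3d_axis(conv3d_axis(v, d, kx$second, 3L),
                                 d, kz$smooth, 1L), d, ky$smooth, 2L)
  out <- -(lzz + lyy + lxx)
  dim(out) <- dims
  out
}

#' Detect neuronal nuclei in one volume
#'
#' Candidate voxels are strict local maxima of the LoG response over the
#' 26-connected neighborhood; a candidate is kept when the element-wise
#' product of the response and the original intensity at that voxel exceeds
#' the threshold. Kept maxima closer than `merge_distance` are merged,
#' keeping the brighter one. Spots are returned sorted by descending
#' intensity (product value), positions at voxel centers in um.
#'
#' @param volume 3D array `(z, y, x)`.
#' @param params [detection_params()].
#' @param voxel_size `(dx, dy, dz)` um.
#' @param t frame index recorded in the output table.
#' @return a [spot_table()].
#' @export
detect_spots <- function(volume, params, voxel_size, t = 0L) {
  resp <- log_filter_3d(volume, params, voxel_size)
  dims <- dim(volume)
  idx0 <- local_maxima_26(as.numeric(resp), as.integer(dims))
  if (length(idx0) == 0L) return(spot_table())
  prod_val <- resp[idx0 + 1L] * volume[idx0 + 1L]
  keep <- prod_val > params$threshold
  idx0 <- idx0[keep]
  prod_val <- prod_val[keep]
  if (length(idx0) == 0L) return(spot_table())
  iz <- idx0 %% dims[1]
  iy <- (idx0 %/% dims[1]) %% dims[2]
  ix <- idx0 %/% (dims[1] * dims[2])
  pos <- cbind(x = ix * voxel_size[1], y = iy * voxel_size[2],
               z = iz * voxel_size[3])
  ord <- order(-prod_val)
  pos <- pos[ord, , drop = FALSE]
  prod_val <- prod_val[ord]
  # merge near-duplicate maxima, brightest first
  keep <- rep(TRUE, nrow(pos))
  if (nrow(pos) > 1 && params$merge_distance > 0) {
    for (i in 2:nrow(pos)) {
      prev <- pos[seq_len(i - 1), , drop = FALSE][keep[seq_len(i - 1)], ,
                                                  drop = FALSE]
      d2 <- rowSums(sweep(prev, 2, pos[i, ])^2)
      if (any(d2 < params$merge_distance^2)) keep[i] <- FALSE
    }
  }
  spot_table(t = rep(as.integer(t), sum(keep)),
             x = pos[keep, 1], y = pos[keep, 2], z = pos[keep, 3],
             intensity = prod_val[keep], source = "detected")
}

#' Detect spots in every frame of a recording
#'
#' @param rec a [recording()].
#' @param params [detection_params()].
#' @param verbose print progress every 50 frames.
#' @return a [spot_table()] covering all frames.
#' @export
detect_all_frames <- function(rec, params, verbose = FALSE) {
  T <- dim(rec$frames)[1]
  out <- vector("list", T)
  for (t in seq_len(T)) {
    out[[t]] <- detect_spots(get_volume(rec, t - 1L), params,
                             rec$voxel_size, t = t - 1L)
    if (verbose && t %% 50 == 0) message("detected frame ", t, "/", T)
  }
  do.call(rbind, out)
}

#' Render a detection preview (maximum-intensity projection with markers)
#'
#' @param rec a [recording()].
#' @param t 0-based frame index.
#' @param params [detection_params()]; ignored when `spots` is supplied.
#' @param spots optional precomputed [spot_table()] for frame `t`.
#' @param path optional PNG output path.
#' @return invisibly, an `(y, x, 3)` RGB overlay array in `[0, 1]`.
#' @export
preview_detection <- function(rec, t, params = detection_params(),
                              spots = NULL, path = NULL) {
  T <- dim(rec$frames)[1]
  if (t < 0 || t >= T) stop(sprintf("frame %d out of range [0, %d]", t, T - 1))
  vol <- get_volume(rec, t)
  if (is.null(spots))
    spots <- detect_spots(vol, params, rec$voxel_size, t = t)
  mip <- apply(vol, c(2, 3), max)
  rng <- range(mip)
  g <- if (diff(rng) > 0) (mip - rng[1]) / diff(rng) else mip * 0
  img <- array(rep(g, 3), c(dim(g), 3))
  if (nrow(spots) > 0) {
    iv <- um_to_voxel(spot_positions(spots), rec$voxel_size,
                      dim(rec$frames)[2:4])
    for (k in seq_len(nrow(iv))) {
      yy <- iv[k, 2]; xx <- iv[k, 3]
      ys <- pmax(1, yy - 2):pmin(nrow(g), yy + 2)
      xs <- pmax(1, xx - 2):pmin(ncol(g), xx + 2)
      img[ys, xx, 1] <- 1; img[ys, xx, 2:3] <- 0
      img[yy, xs, 1] <- 1; img[yy, xs, 2:3] <- 0
    }
  }
  if (!is.null(path)) png::writePNG(img, path)
  invisible(img)
}

#' Product values at known blob centers
#'
#' Utility for threshold calibration on simulated data: the LoG-response x
#' intensity product evaluated at the voxel nearest each ground-truth
#' position.
#'
#' @param volume 3D array `(z, y, x)`.
#' @param positions matrix with columns `(x, y, z)` in um.
#' @param params [detection_params()].
#' @param voxel_size `(dx, dy, dz)` um.
#' @return numeric product values, one per position.
#' @export
product_at_positions <- function(volume, positions, params, voxel_size) {
  resp <- log_filter_3d(volume, params, voxel_size)
  iv <- um_to_voxel(positions, voxel_size, dim(volume))
  resp[iv] * volume[iv]
}
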