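vox <- c(0.5, 0.5, 1.0)

test_that("ROI segmentation isolates a nucleus of about 2 um", {
  dims <- c(13L, 41L, 41L)
  center <- c(10, 10, 6)
  vol <- render_blob_r(dims, center, sigma = 1.0, amplitude = 100, vox)
  spot <- spot_table(t = 0, x = center[1], y = center[2], z = center[3],
                     intensity = 1)
  sr <- segment_roi(vol, spot, vox)
  expect_false(sr$fallback)
  vol_um <- sum(sr$mask) * prod(vox)
  diam <- 2 * (3 * vol_um / (4 * pi))^(1 / 3)
  expect_gte(diam, 1.5)
  expect_lte(diam, 2.5)
  # two blobs 3 um apart stay disjoint
  c2 <- center + c(3, 0, 0)
  vol2 <- vol + render_blob_r(dims, c2, 1.0, 100, vox)
  spots2 <- spot_table(t = c(0, 0), x = c(center[1], c2[1]),
                       y = c(center[2], c2[2]), z = c(center[3], c2[3]),
                       intensity = 1)
  m1 <- segment_roi(vol2, spots2[1, ], vox, other_spots = spots2[2, ])
  m2 <- segment_roi(vol2, spots2[2, ], vox, other_spots = spots2[1, ])
  # map both masks into absolute voxel space and check disjointness
  abs_idx <- function(sr) {
    w <- which(sr$mask, arr.ind = TRUE)
    w + matrix(sr$offset, nrow(w), 3, byrow = TRUE)
  }
  a1 <- abs_idx(m1)
  a2 <- abs_idx(m2)
  expect_equal(nrow(merge(as.data.frame(a1), as.data.frame(a2))), 0L)
  # spot at a volume corner still yields a valid (clipped) mask
  corner <- spot_table(t = 0, x = 0.5, y = 0.5, z = 1, intensity = 1)
  volc <- render_blob_r(dims, c(0.5, 0.5, 1), 1.0, 100, vox)
  src <- segment_roi(volc, corner, vox)
  expect_gt(sum(src$mask), 0)
})

test_that("ellipsoid fitting recovers axes, orientation and centers", {
  # axis-aligned solid ellipsoid, semi-axes (4, 2, 2) um, uniform intensity
  dims <- c(21L, 41L, 41L)
  semi <- c(4, 2, 2)  # (x, y, z)
  ctr <- c(10, 10, 10)
  mask <- array(FALSE, dims)
  for (iz in seq_len(dims[1])) for (iy in seq_len(dims[2]))
    for (ix in seq_len(dims[3])) {
      p <- c((ix - 1) * vox[1], (iy - 1) * vox[2], (iz - 1) * vox[3])
      mask[iz, iy, ix] <- sum(((p - ctr) / semi)^2) <= 1
    }
  fit <- fit_ellipsoid(mask, array(1, dims), vox)
  expect_equal(fit$center, c(x = 10, y = 10, z = 10), tolerance = 0.05)
  expect_equal(sort(fit$semi_axes, decreasing = TRUE), c(4, 2, 2),
               tolerance = 0.1 * 4)
  # dominant axis within 5 degrees of x
  major <- fit$orientation[, which.max(fit$semi_axes)]
  expect_gt(abs(major[1]), cos(5 * pi / 180))
  # orthonormal orientation
  expect_lt(max(abs(t(fit$orientation) %*% fit$orientation - diag(3))), 1e-6)
  # single-voxel mask centers on that voxel
  m1 <- array(FALSE, c(3, 3, 3))
  m1[2, 2, 2] <- TRUE
  f1 <- suppressWarnings(fit_ellipsoid(m1, array(1, c(3, 3, 3)), vox))
  expect_equal(as.numeric(f1$center), c(vox[1], vox[2], vox[3]))
  # sphere: three nearly equal semi-axes, good quality
  ms <- array(FALSE, dims)
  for (iz in seq_len(dims[1])) for (iy in seq_len(dims[2]))
    for (ix in seq_len(dims[3])) {
      p <- c((ix - 1) * vox[1], (iy - 1) * vox[2], (iz - 1) * vox[3])
      ms[iz, iy, ix] <- sum((p - ctr)^2) <= 9
    }
  fs <- fit_ellipsoid(ms, array(1, dims), vox)
  expect_lt(diff(range(fs$semi_axes)) / mean(fs$semi_axes), 0.05)
  expect_gte(fs$quality, 0.9)
})

test_that("shape consolidation averages by intensity and stays orthonormal", {
  base <- list(center = c(0, 0, 0), semi_axes = c(2, 1.5, 1),
               orientation = diag(3), quality = 1)
  class(base) <- "roi_shape"
  s2 <- base
  s2$semi_axes <- c(4, 1.5, 1)
  # identical shapes at all frames -> unchanged
  same <- consolidate_shape(list(base, base, base), c(1, 2, 3))
  expect_equal(same$semi_axes, base$semi_axes)
  # intensities 1 and 3 with semi-axis a = 2 and 4 -> 3.5
  w <- consolidate_shape(list(base, s2), c(1, 3))
  expect_equal(w$semi_axes[1], 3.5)
  # consolidated semi-axes stay within the per-frame min/max
  expect_true(all(w$semi_axes >= pmin(base$semi_axes, s2$semi_axes) - 1e-12))
  expect_true(all(w$semi_axes <= pmax(base$semi_axes, s2$semi_axes) + 1e-12))
  # arbitrary rotations consolidate to an orthonormal rotation
  set.seed(3)
  rand_rot <- function() {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(q) < 0) q[, 3] <- -q[, 3]
    q
  }
  shapes <- lapply(1:5, function(i) {
    s <- base
    s$orientation <- rand_rot()
    s
  })
  cons <- consolidate_shape(shapes, runif(5, 0.5, 2))
  expect_lt(max(abs(t(cons$orientation) %*% cons$orientation - diag(3))),
            1e-6)
  expect_gt(det(cons$orientation), 0)
  # all-zero intensities fall back to an unweighted mean with a warning
  expect_warning(consolidate_shape(list(base, s2), c(0, 0)), "zero")
})

test_that("sub-voxel centers beat voxel-grid detection positions", {
  dims <- c(13L, 31L, 31L)
  true_c <- c(7.17, 7.33, 6.4)  # deliberately off-grid
  vol <- render_blob_r(dims, true_c, 1.0, 100, vox)
  dp <- detection_params(threshold = 1)
  det <- detect_spots(vol, dp, vox)
  expect_equal(nrow(det), 1L)
  grid_err <- sqrt(sum((as.numeric(det[1, c("x", "y", "z")]) - true_c)^2))
  sr <- segment_roi(vol, det[1, ], vox)
  fit <- fit_ellipsoid(sr$mask, sr$crop, vox, sr$offset)
  sub_err <- sqrt(sum((fit$center - true_c)^2))
  expect_lt(sub_err, grid_err)
})
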