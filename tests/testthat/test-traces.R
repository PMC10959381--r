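test_that("trace extraction is signal minus corona on constructed volumes", {
  # a spherical ROI of constant 100 inside a constant-10 volume
  dims <- c(9L, 21L, 21L)
  vox <- c(1, 1, 1)
  ctr <- c(10, 10, 4)
  vol <- array(10, dims)
  for (iz in seq_len(dims[1])) for (iy in seq_len(dims[2]))
    for (ix in seq_len(dims[3])) {
      p <- c(ix - 1, iy - 1, iz - 1)
      if (sum((p - ctr)^2) <= 4) vol[iz, iy, ix] <- 100
    }
  rec <- recording(array(vol, c(1, dims)), vox)
  track <- data.frame(track_id = 1L, t = 0L, x = ctr[1], y = ctr[2],
                      z = ctr[3], intensity = 1, source = "detected")
  shape <- structure(list(center = ctr, semi_axes = c(2, 2, 2),
                          orientation = diag(3), quality = 1),
                     class = "roi_shape")
  tr <- extract_trace(rec, track, shape)
  expect_equal(tr$values, 90)
  # corona equal to the ROI -> zero
  rec0 <- recording(array(50, c(1, dims)), vox)
  tr0 <- extract_trace(rec0, track, shape)
  expect_equal(tr0$values, 0)
})

test_that("the brightest-90% rule drops dark outliers (sort oracle)", {
  # ROI with one dark voxel; compare against an explicit sort
  dims <- c(7L, 15L, 15L)
  vox <- c(1, 1, 1)
  ctr <- c(7, 7, 3)
  vol <- array(0, dims)
  roi_vals <- c()
  for (iz in seq_len(dims[1])) for (iy in seq_len(dims[2]))
    for (ix in seq_len(dims[3])) {
      p <- c(ix - 1, iy - 1, iz - 1)
      if (sum((p - ctr)^2) <= 4) {
        v <- 80 + (ix + iy + iz) %% 7
        vol[iz, iy, ix] <- v
        roi_vals <- c(roi_vals, v)
      }
    }
  # blacken one ROI voxel
  vol[ctr[3] + 1, ctr[2] - 1, ctr[1] + 1] <- 1
  roi_vals <- sort(c(roi_vals[-1], 1))
  shape <- structure(list(center = ctr, semi_axes = c(2, 2, 2),
                          orientation = diag(3), quality = 1),
                     class = "roi_shape")
  rec <- recording(array(vol, c(1, dims)), vox)
  track <- data.frame(track_id = 1L, t = 0L, x = ctr[1], y = ctr[2],
                      z = ctr[3], intensity = 1, source = "detected")
  tr <- extract_trace(rec, track, shape, refine_center = FALSE)
  # oracle: voxels at/above the 10th percentile of the actual ROI values
  idx <- which(array(TRUE, dims), arr.ind = TRUE)
  pos <- cbind((idx[, 3] - 1), (idx[, 2] - 1), (idx[, 1] - 1))
  inside <- rowSums(sweep(pos, 2, ctr)^2 / 4) <= 1
  vals <- vol[idx[inside, , drop = FALSE]]
  cutoff <- quantile(vals, 0.10, names = FALSE)
  signal <- mean(vals[vals >= cutoff])
  # the corona is all zeros here, so the trace value is the signal itself
  expect_equal(tr$values, signal)
  # the dark outlier must have been excluded from the signal
  expect_gt(signal, mean(vals))
})

test_that("trace smoothing is a centered shrinking-window average", {
  expect_equal(smooth_trace(c(0, 3, 0), window = 3), c(1.5, 1.0, 1.5))
  expect_equal(smooth_trace(c(1, 5, 2, 8), window = 1), c(1, 5, 2, 8))
  expect_equal(smooth_trace(rep(4, 10), window = 5), rep(4, 10))
  expect_error(smooth_trace(1:5, window = 4), "odd")
  # mean is preserved exactly for constant traces
  expect_equal(mean(smooth_trace(rep(2.5, 7), window = 3)), 2.5)
})

test_that("extracted traces follow the true activity on clean renders", {
  # resolvable nuclei (>= 4 um apart): at sub-3-um packing the Gaussian
  # shoulders of anti-correlated neighbors overlap the ROI itself and no
  # background scheme can remove them (see the methods vignette)
  cfg <- small_sim(seed = 23, n_frames = 25, dropout = 0,
                   use_atlas = FALSE, n_neurons = 40)
  sim <- simulate_recording(cfg)
  rec <- subtract_background(sim$recording)
  gt <- truth_frame(sim$truth, 0)
  pv <- product_at_positions(get_volume(rec, 0),
                             as.matrix(gt[, c("x", "y", "z")]),
                             detection_params(), rec$voxel_size)
  dp <- detection_params(threshold = 0.5 * min(pv))
  spots <- detect_all_frames(rec, dp)
  tracks <- track_neurons(spots, cfg$n_frames)
  shapes <- segment_all_rois(rec, tracks, sample_every = 10)
  traces <- extract_all_traces(rec, tracks, shapes)
  # map each track to the neuron it follows most closely (mean distance,
  # unambiguous even for neuron pairs closer than the matching radius)
  ids <- sort(unique(tracks$track_id))
  cors <- vapply(ids, function(id) {
    tr_tab <- tracks[tracks$track_id == id, ]
    md <- vapply(unique(sim$truth$neuron_id), function(n) {
      g <- sim$truth[sim$truth$neuron_id == n, ]
      g <- g[match(tr_tab$t, g$t), ]
      mean(sqrt((g$x - tr_tab$x)^2 + (g$y - tr_tab$y)^2 +
                  (g$z - tr_tab$z)^2))
    }, numeric(1))
    neuron <- unique(sim$truth$neuron_id)[which.min(md)]
    tr <- traces[[as.character(id)]]
    cor(tr$values, sim$activity$values[tr$t + 1L, neuron])
  }, numeric(1))
  expect_gte(min(cors, na.rm = TRUE), 0.95)
})
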