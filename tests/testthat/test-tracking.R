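test_that("frame-to-frame linking chains single spots and respects the distance cap", {
  # one spot per frame, small displacement -> one segment
  sp <- spot_table(t = 0:3, x = c(0, 0.2, 0.4, 0.6), y = 0, z = 0,
                   intensity = 1)
  seg <- link_frames(sp, tracking_params(max_link_distance = 1))
  expect_equal(length(unique(seg$segment_id)), 1L)
  # all pairs beyond the cap -> every spot its own segment
  sp2 <- spot_table(t = c(0, 0, 1, 1), x = c(0, 10, 5, 15), y = 0, z = 0,
                    intensity = 1)
  seg2 <- link_frames(sp2, tracking_params(max_link_distance = 1))
  expect_equal(length(unique(seg2$segment_id)), 4L)
})

test_that("frame linking is globally optimal where greedy nearest-neighbor fails", {
  # two spots crossing: greedy would pair (0 -> 1.9) first; the LAP
  # minimises total squared distance and keeps identities
  a <- spot_table(t = c(0, 0), x = c(0, 2), y = 0, z = 0, intensity = 1)
  b <- spot_table(t = c(1, 1), x = c(1.1, 3.1), y = 0, z = 0, intensity = 1)
  seg <- link_frames(rbind(a, b), tracking_params(max_link_distance = 4))
  ids <- matrix(seg$segment_id[order(seg$t, seg$x)], 2, byrow = TRUE)
  expect_equal(ids[1, ], ids[2, ])  # left->left, right->right
  # random two-frame instances match the exhaustive oracle
  set.seed(77)
  for (k in 1:30) {
    n <- sample(2:6, 1)
    m <- sample(2:6, 1)
    pa <- matrix(runif(3 * n, 0, 10), n, 3)
    pb <- matrix(runif(3 * m, 0, 10), m, 3)
    maxd <- 6
    cost <- as.matrix(stats::dist(rbind(pa, pb)))[seq_len(n),
                                                  n + seq_len(m),
                                                  drop = FALSE]^2
    cost[cost > maxd^2] <- Inf
    if (!any(is.finite(cost))) next
    alt <- 1.05 * max(cost[is.finite(cost)])
    sp <- spot_table(t = c(rep(0L, n), rep(1L, m)),
                     x = c(pa[, 1], pb[, 1]), y = c(pa[, 2], pb[, 2]),
                     z = c(pa[, 3], pb[, 3]), intensity = 1)
    seg <- link_frames(sp, tracking_params(max_link_distance = maxd))
    # recover the implied matching
    got <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      sid <- seg$segment_id[seg$t == 0][i]
      j <- which(seg$segment_id[seg$t == 1] == sid)
      if (length(j)) got[i] <- j
    }
    bf <- brute_force_assignment(cost, alt)
    expect_equal(assignment_total_cost(cost, got, alt), bf$cost,
                 tolerance = 1e-9)
  }
})

test_that("gap closing merges across short gaps and rejects long ones", {
  sp <- spot_table(t = c(0, 1, 3, 4), x = c(0, 0.1, 1.0, 1.1), y = 0, z = 0,
                   intensity = 1)
  seg <- link_frames(sp, tracking_params(max_link_distance = 0.5))
  expect_equal(length(unique(seg$segment_id)), 2L)
  merged <- link_segments(seg, tracking_params(max_link_distance = 0.5,
                                               max_time_gap = 3,
                                               gap_max_distance = 2))
  expect_equal(length(unique(merged$segment_id)), 1L)
  # gap beyond max_time_gap stays split
  not_merged <- link_segments(seg, tracking_params(max_link_distance = 0.5,
                                                   max_time_gap = 1,
                                                   gap_max_distance = 2))
  expect_equal(length(unique(not_merged$segment_id)), 2L)
  # distance beyond gap_max_distance stays split
  far <- link_segments(seg, tracking_params(max_link_distance = 0.5,
                                            max_time_gap = 3,
                                            gap_max_distance = 0.5))
  expect_equal(length(unique(far$segment_id)), 2L)
})

test_that("gap closing equals exhaustive minimum-cost matching on random instances", {
  set.seed(55)
  for (k in 1:30) {
    n_seg <- sample(3:6, 1)
    # build disjoint two-spot segments at random times/places
    rows <- list()
    info <- list()
    for (s in seq_len(n_seg)) {
      t0 <- sample(0:20, 1)
      p0 <- runif(3, 0, 10)
      p1 <- p0 + runif(3, -0.1, 0.1)
      rows[[s]] <- spot_table(t = c(t0, t0 + 1L), x = c(p0[1], p1[1]),
                              y = c(p0[2], p1[2]), z = c(p0[3], p1[3]),
                              intensity = 1)
      info[[s]] <- list(t0 = t0, t1 = t0 + 1L, p0 = p0, p1 = p1)
    }
    sp <- do.call(rbind, rows)
    sp <- link_frames(sp, tracking_params(max_link_distance = 0.5))
    if (length(unique(sp$segment_id)) != n_seg) next  # overlapping build
    params <- tracking_params(max_link_distance = 0.5, max_time_gap = 6,
                              gap_max_distance = 6)
    merged <- link_segments(sp, params)
    # oracle: enumerate end->start matchings under the same constraints
    cost <- matrix(Inf, n_seg, n_seg)
    for (i in seq_len(n_seg)) for (j in seq_len(n_seg)) {
      if (i == j) next
      dt <- info[[j]]$t0 - info[[i]]$t1
      d <- sqrt(sum((info[[j]]$p0 - info[[i]]$p1)^2))
      if (dt >= 1 && dt <= params$max_time_gap &&
          d <= params$gap_max_distance)
        cost[i, j] <- d^2
    }
    if (!any(is.finite(cost))) {
      expect_equal(length(unique(merged$segment_id)), n_seg)
      next
    }
    alt <- 1.05 * max(cost[is.finite(cost)])
    bf <- brute_force_assignment(cost, alt)
    n_links <- sum(!is.na(bf$match))
    expect_equal(length(unique(merged$segment_id)), n_seg - n_links)
  }
})

test_that("neighbor-displacement inference is exact under rigid motion", {
  # 30 neighbor tracks plus one target, all translated by (1, 0, 0)
  set.seed(11)
  n <- 30
  p0 <- cbind(runif(n, 0, 20), runif(n, 0, 20), runif(n, 0, 20))
  shift <- c(1, 0, 0)
  tracks <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(track_id = i, t = 0:1, x = c(p0[i, 1], p0[i, 1] + shift[1]),
               y = c(p0[i, 2], p0[i, 2] + shift[2]),
               z = c(p0[i, 3], p0[i, 3] + shift[3]),
               intensity = 1, source = "detected")
  }))
  target <- data.frame(track_id = n + 1, t = 0, x = 5, y = 5, z = 5,
                       intensity = 1, source = "detected")
  sp <- infer_missing_position(rbind(tracks, target), n + 1, t = 1,
                               n_frames = 2)
  expect_identical(sp$source, "inferred")
  expect_equal(c(sp$x, sp$y, sp$z), c(6, 5, 5), tolerance = 1e-12)
  # stationary neighbors -> carried-over position
  tracks0 <- tracks
  tracks0[tracks0$t == 1, c("x", "y", "z")] <-
    tracks0[tracks0$t == 0, c("x", "y", "z")]
  sp0 <- infer_missing_position(rbind(tracks0, target), n + 1, t = 1,
                                n_frames = 2)
  expect_equal(c(sp0$x, sp0$y, sp0$z), c(5, 5, 5), tolerance = 1e-12)
  # heterogeneous displacements equal the arithmetic-mean formula computed
  # independently on the 20 nearest neighbors
  set.seed(12)
  disp <- matrix(rnorm(n * 3, 0, 0.3), n, 3)
  trh <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(track_id = i, t = 0:1, x = c(p0[i, 1], p0[i, 1] + disp[i, 1]),
               y = c(p0[i, 2], p0[i, 2] + disp[i, 2]),
               z = c(p0[i, 3], p0[i, 3] + disp[i, 3]),
               intensity = 1, source = "detected")
  }))
  sph <- infer_missing_position(rbind(trh, target), n + 1, t = 1,
                                n_frames = 2)
  d2 <- rowSums(sweep(p0, 2, c(5, 5, 5))^2)
  nb <- order(d2)[1:20]
  expect_equal(c(sph$x, sph$y, sph$z),
               c(5, 5, 5) + colMeans(disp[nb, , drop = FALSE]),
               tolerance = 1e-12)
})

test_that("gap filling reconstructs missing frames and leaves full tracks alone", {
  set.seed(21)
  n <- 25
  T <- 12
  p0 <- cbind(runif(n, 0, 30), runif(n, 0, 30), runif(n, 0, 30))
  drift <- c(0.3, -0.1, 0.05)
  mk <- function(i, frames) {
    data.frame(track_id = i, t = frames,
               x = p0[i, 1] + drift[1] * frames,
               y = p0[i, 2] + drift[2] * frames,
               z = p0[i, 3] + drift[3] * frames,
               intensity = 1, source = "detected")
  }
  full <- do.call(rbind, lapply(2:n, mk, frames = 0:(T - 1)))
  gappy <- mk(1, setdiff(0:(T - 1), 4:6))  # 3-frame gap
  tracks <- rbind(gappy, full)
  filled <- fill_gaps(tracks, T, tracking_params(extend_to_end = FALSE))
  got <- filled[filled$track_id == 1, ]
  expect_equal(got$t, 0:(T - 1))
  # under pure rigid drift the inference is exact
  expect_equal(got$x, p0[1, 1] + drift[1] * (0:(T - 1)), tolerance = 1e-10)
  expect_equal(got$source[5:7], rep("inferred", 3))
  # gap-free tracks are untouched
  expect_equal(filled[filled$track_id == 2, c("t", "x", "y", "z")],
               full[full$track_id == 2, c("t", "x", "y", "z")],
               ignore_attr = TRUE)
  # invariants after filling: one spot per frame, one track per spot
  expect_false(any(duplicated(filled[, c("track_id", "t")])))
})

test_that("gap filling under elastic jitter stays within 1 um of ground truth", {
  cfg <- small_sim(seed = 31, n_frames = 30, elastic_jitter_sd = 0.2,
                   n_neurons = 40)
  sim <- simulate_recording(cfg, render = FALSE)
  tracks <- truth_tracks(sim)
  # knock a 4-frame hole into one neuron's track
  hole <- !(tracks$track_id == 5 & tracks$t %in% 10:13)
  filled <- fill_gaps(tracks[hole, ], cfg$n_frames)
  got <- filled[filled$track_id == 5 & filled$t %in% 10:13, ]
  truth5 <- sim$truth[sim$truth$neuron_id == 5 & sim$truth$t %in% 10:13, ]
  err <- sqrt((got$x - truth5$x)^2 + (got$y - truth5$y)^2 +
                (got$z - truth5$z)^2)
  expect_lt(max(err), 1)
})

test_that("a manually added spot reconstructs a whole track", {
  cfg <- small_sim(seed = 13, n_frames = 20, elastic_jitter_sd = 0.1,
                   n_neurons = 30)
  sim <- simulate_recording(cfg, render = FALSE)
  tracks <- truth_tracks(sim)
  # drop neuron 7 entirely, then add one manual spot at frame 10
  kept <- tracks[tracks$track_id != 7, ]
  truth7 <- sim$truth[sim$truth$neuron_id == 7, ]
  p10 <- unlist(truth7[truth7$t == 10, c("x", "y", "z")])
  res <- add_manual_spot(p10, 10, kept, cfg$n_frames)
  got <- res$tracks[res$tracks$track_id == res$track_id, ]
  expect_equal(got$t, 0:19)
  expect_identical(got$source[got$t == 10], "manual")
  err <- sqrt((got$x - truth7$x)^2 + (got$y - truth7$y)^2 +
                (got$z - truth7$z)^2)
  expect_lt(max(err), 1)
  # annotation on the final frame propagates backward over all frames
  p19 <- unlist(truth7[truth7$t == 19, c("x", "y", "z")])
  res2 <- add_manual_spot(p19, 19, kept, cfg$n_frames)
  expect_equal(res2$tracks[res2$tracks$track_id == res2$track_id, "t"], 0:19)
  # static scene -> constant reconstructed track
  static <- kept
  for (axis in c("x", "y", "z"))
    static[[axis]] <- ave(static[[axis]], static$track_id)
  res3 <- add_manual_spot(c(20, 20, 10), 5, static, cfg$n_frames)
  got3 <- res3$tracks[res3$tracks$track_id == res3$track_id, ]
  expect_equal(diff(range(got3$x)), 0, tolerance = 1e-9)
})

test_that("relative-distance restoration re-links the correct segment", {
  cfg <- small_sim(seed = 17, n_frames = 40, n_neurons = 40,
                   elastic_jitter_sd = 0.1)
  sim <- simulate_recording(cfg, render = FALSE)
  tracks <- truth_tracks(sim)
  # split neuron 9 by an 8-frame outage (beyond max_time_gap), keep a decoy
  # second-half segment from neuron 10 nearby in space
  sp <- tracks
  sp <- sp[!(sp$track_id == 9 & sp$t %in% 15:22), ]
  sp$segment_id <- sp$track_id
  # pretend neuron 9's halves are distinct segments
  sp$segment_id[sp$track_id == 9 & sp$t > 22] <- 999L
  sp$track_id <- NULL
  params <- tracking_params(restore_max_gap = 10, restore_max_distance = 8)
  restored <- restore_segments(sp, params)
  expect_equal(unique(restored$segment_id[
    restored$x %in% tracks$x[tracks$track_id == 9]]), 9L)
})
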