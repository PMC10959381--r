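make_scene <- function(seed = 1, n_extra = 0, atlas_noise = 0.05,
                       n_frames = 200) {
  cfg <- small_sim(seed = seed, n_frames = n_frames, dropout = 0,
                   n_neurons = 21 + n_extra, atlas_noise = atlas_noise)
  sim <- simulate_recording(cfg, render = FALSE)
  list(sim = sim, cfg = cfg, tracks = truth_tracks(sim),
       traces = truth_trace_matrix(sim))
}

test_that("correlation statistics behave at the limits", {
  x <- sin(seq(0, 6, length.out = 50))
  m <- cbind(a = x, b = x, c = -x, d = runif(50))
  st <- correlation_stats(m)
  expect_equal(st$C["a", "b"], 1)
  expect_equal(st$C["a", "c"], -1)
  expect_true(all(abs(st$C) <= 1 + 1e-12))
  expect_equal(diag(st$C), rep(1, 4), ignore_attr = TRUE)
  # constant trace -> correlations zeroed with a warning
  m2 <- cbind(m, e = rep(5, 50))
  expect_warning(st2 <- correlation_stats(m2), "constant")
  expect_equal(max(abs(st2$C["e", c("a", "b", "c", "d")])), 0)
  expect_error(correlation_stats(m[, 1:2]), "at least 3")
})

test_that("within-backward correlations exceed the population threshold", {
  sc <- make_scene(seed = 5, n_extra = 19)
  st <- correlation_stats(sc$traces)
  bw <- which(sc$sim$activity$groups == "backward")
  mean_bw <- mean(st$C[bw, bw][upper.tri(diag(length(bw)))])
  expect_gt(mean_bw, st$C_mu + st$C_sigma)
})

test_that("seed-six search recovers the planted AVA/AVE/AIB candidates", {
  sc <- make_scene(seed = 3)
  st <- correlation_stats(sc$traces)
  pos <- t(sapply(seq_len(21), function(i) {
    tr <- sc$tracks[sc$tracks$track_id == i, ]
    colMeans(as.matrix(tr[, c("x", "y", "z")]))
  }))
  found <- find_seed_six(pos, st)
  expect_setequal(sc$sim$activity$labels[found$ids], seed_six_classes())
  # the two triplets split by body side
  sides <- lapply(found$triplets, function(tr)
    substring(sc$sim$activity$labels[tr], 4))
  expect_true(all(sides[[1]] == sides[[1]][1]))
  expect_true(all(sides[[2]] == sides[[2]][1]))
  # fewer than 6 tracks -> error
  expect_error(find_seed_six(pos[1:4, ],
                             correlation_stats(sc$traces[, 1:4])),
               "at least 6|at least 3")
})

test_that("decoy neurons with seed-like activity but off-axis geometry are rejected", {
  sc <- make_scene(seed = 8)
  st0 <- correlation_stats(sc$traces)
  pos <- t(sapply(seq_len(21), function(i) {
    tr <- sc$tracks[sc$tracks$track_id == i, ]
    colMeans(as.matrix(tr[, c("x", "y", "z")]))
  }))
  # three decoys: same latent as the backward group (perfectly correlated)
  # but stacked along the dorsoventral axis, off the anteroposterior line
  u <- sc$sim$activity$latent
  decoy_traces <- sapply(1:3, function(i) 50 + 300 * u + rnorm(length(u), 0, 1))
  colnames(decoy_traces) <- as.character(22:24)
  ctr <- colMeans(pos)
  decoy_pos <- rbind(ctr + c(0, 6, 1), ctr + c(0, 0, 1), ctr + c(0, -6, 1))
  st <- correlation_stats(cbind(sc$traces, decoy_traces))
  found <- find_seed_six(rbind(pos, decoy_pos), st)
  expect_true(all(found$ids <= 21))
  expect_setequal(sc$sim$activity$labels[found$ids], seed_six_classes())
})

test_that("the body frame recovers the planted axes and normalizes scale", {
  sc <- make_scene(seed = 4)
  res <- identify_neurons(sc$tracks, sc$traces, head_direction = c(1, 0, 0))
  ax <- res$frame$axes
  # simulator plants anterior = +x, dorsal = +y, left = +z
  expect_gt(sum(ax["anterior", ] * c(1, 0, 0)), cos(10 * pi / 180))
  expect_gt(sum(ax["dorsal", ] * c(0, 1, 0)), cos(10 * pi / 180))
  expect_gt(sum(ax["left", ] * c(0, 0, 1)), cos(10 * pi / 180))
  # equivariance: rotating the scene rotates the frame identically, and
  # normalized coordinates (hence labels) are unchanged under similarity
  th <- 0.6
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  tr2 <- sc$tracks
  p2 <- as.matrix(sc$tracks[, c("x", "y", "z")]) %*% t(R) * 1.7
  p2 <- sweep(p2, 2, c(30, -12, 7), "+")
  tr2$x <- p2[, 1]; tr2$y <- p2[, 2]; tr2$z <- p2[, 3]
  res2 <- identify_neurons(tr2, sc$traces,
                           head_direction = as.numeric(R %*% c(1, 0, 0)))
  expect_identical(res$assignments$class_name, res2$assignments$class_name)
  # near-orthogonal head direction is rejected
  pos <- t(sapply(seq_len(21), function(i) {
    tr <- sc$tracks[sc$tracks$track_id == i, ]
    colMeans(as.matrix(tr[, c("x", "y", "z")]))
  }))
  st <- correlation_stats(sc$traces)
  six <- find_seed_six(pos, st)
  expect_error(build_body_frame(pos[six$ids, ], c(0, 1, 0), pos),
               "orthogonal")
})

test_that("identities are assigned correctly from atlas-consistent scenes", {
  # clean scene plus the documented 0.1-noise case -> full recovery
  for (noise in c(0.05, 0.1)) {
    sc <- make_scene(seed = 6, atlas_noise = noise)
    res <- identify_neurons(sc$tracks, sc$traces, head_direction = c(1, 0, 0))
    a <- res$assignments
    a$true <- sc$sim$activity$labels[a$track_id]
    expect_true(all(!is.na(a$class_name)))
    expect_equal(mean(a$class_name == a$true), 1)
  }
  # assignment is injective over class names
  sc <- make_scene(seed = 7, n_extra = 19)
  res <- identify_neurons(sc$tracks, sc$traces, head_direction = c(1, 0, 0))
  got <- res$assignments$class_name
  expect_false(any(duplicated(got[!is.na(got)])))
  # every seed-six member carries a backward-group class
  seeds <- res$assignments[res$assignments$track_id %in% res$seed_track_ids, ]
  atlas <- default_atlas()
  expect_true(all(atlas$group[match(seeds$class_name,
                                    atlas$class_name)] == "backward"))
})

test_that("group evidence dominates when positions are noisy", {
  # large positional noise, intact group activity: backward-class labels
  # still land on backward-group neurons
  atlas <- default_atlas()
  ok <- replicate(5, NA)
  for (s in 1:5) {
    sc <- make_scene(seed = 100 + s, atlas_noise = 0.15)
    res <- identify_neurons(sc$tracks, sc$traces, head_direction = c(1, 0, 0))
    a <- res$assignments
    bw_cls <- atlas$class_name[atlas$group == "backward"]
    sel <- !is.na(a$class_name) & a$class_name %in% bw_cls
    ok[s] <- mean(sc$sim$activity$groups[a$track_id[sel]] == "backward")
  }
  expect_gte(mean(ok), 0.9)
})

test_that("a mirrored worm receives exactly mirrored left/right labels", {
  sc <- make_scene(seed = 9)
  res_f <- identify_neurons(sc$tracks, sc$traces, head_direction = c(1, 0, 0))
  # reflect the scene through the seed plane (z -> -z): same anterior and
  # dorsal axes, opposite handedness, so L and R labels must swap exactly
  trm <- sc$tracks
  trm$z <- -trm$z
  res_m <- identify_neurons(trm, sc$traces, head_direction = c(1, 0, 0))
  swap_lr <- function(x) {
    sided <- default_atlas()$class_name[default_atlas()$side %in% c("L", "R")]
    out <- x
    l <- !is.na(x) & x %in% sided & grepl("L$", x)
    r <- !is.na(x) & x %in% sided & grepl("R$", x)
    out[l] <- sub("L$", "R", x[l])
    out[r] <- sub("R$", "L", x[r])
    out
  }
  expect_identical(swap_lr(res_f$assignments$class_name),
                   res_m$assignments$class_name)
})

test_that("correlation neighborhoods separate the activity groups", {
  sc <- make_scene(seed = 10, n_extra = 10)
  st <- correlation_stats(sc$traces)
  groups <- sc$sim$activity$groups
  bw_ids <- as.character(which(groups == "backward"))
  fw_ids <- as.character(which(groups == "forward"))
  nb <- correlation_neighborhood(bw_ids[1], st)
  expect_true(all(setdiff(bw_ids, bw_ids[1]) %in% nb$correlated))
  expect_true(all(fw_ids %in% nb$anti_correlated))
  expect_false(bw_ids[1] %in% c(nb$correlated, nb$anti_correlated))
  # an extreme threshold empties both lists
  nb_inf <- correlation_neighborhood(bw_ids[1], st, threshold_sds = 1e6)
  expect_equal(length(nb_inf$correlated), 0L)
  expect_equal(length(nb_inf$anti_correlated), 0L)
  expect_error(correlation_neighborhood("999", st), "unknown")
})
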