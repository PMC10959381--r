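#' Configuration for the ground-truth recording simulator
#'
#' The simulator emulates the statistical structure the pipeline assumes: a
#' head-like anisotropic cloud of ~2 um Gaussian nuclei (soma sigma 1 um),
#' slow rigid drift plus smooth per-neuron elastic jitter (relative
#' displacements on the order of 2 um per 100 s), GCaMP-like slow activity
#' with two anti-correlated neuron groups (backward- and forward-promoting),
#' per-frame detection dropout, and multiplicative (speckle) noise.
#'
#' By default neurons are placed from the shipped model atlas
#' ([default_atlas()]), scaled to `atlas_scale` um and perturbed by
#' `atlas_noise` (normalized units); neurons beyond the 21 atlas classes are
#' placed uniformly in a head-shaped ellipsoid and assigned to activity
#' groups `other` unless `use_atlas = FALSE`, in which case `group_fractions`
#' drives group assignment for all neurons.
#'
#' @param n_neurons number of neurons (default 100, a typical head count).
#' @param volume_shape `(z, y, x)` voxels (default `c(12, 165, 440)`).
#' @param voxel_size `(dx, dy, dz)` um/voxel (default `c(0.27, 0.27, 2)`).
#' @param n_frames number of volumes (default 200).
#' @param frame_interval seconds per volume (default 1/3 s: 3 volumes/s).
#' @param soma_sigma Gaussian soma sigma in um (default 1, i.e. ~2 um nuclei).
#' @param drift_per_frame rigid drift `(x, y, z)` um per frame.
#' @param elastic_jitter_sd stationary sd (um) of the per-neuron AR(1)
#'   elastic jitter.
#' @param jitter_rho AR(1) coefficient of the elastic jitter (smoothness).
#' @param dropout_prob per-frame probability that a neuron's brightness falls
#'   below the detection threshold.
#' @param dropout_factor brightness multiplier applied on dropout frames.
#' @param group_fractions fractions of neurons in the backward / forward /
#'   other groups when `use_atlas = FALSE`.
#' @param noise_variance variance of multiplicative noise applied to the
#'   rendered recording (0 = clean; see [add_multiplicative_noise()]).
#' @param seed RNG seed; fixed seed gives a bit-identical recording.
#' @param use_atlas place the first 21 neurons at (noisy) atlas positions.
#' @param atlas_scale um per normalized atlas unit (default 12).
#' @param atlas_noise positional noise sd in normalized atlas units.
#' @param spread ellipsoid semi-axes (um) for non-atlas placement.
#' @param dorsal_fraction fraction of non-atlas neurons placed on the dorsal
#'   (+y) side. Head ganglia are not dorsoventrally symmetric, and the
#'   identification step's dorsal-side rule (the side of the seed-six plane
#'   holding more neurons is dorsal) relies on that asymmetry, so the
#'   generator reproduces it.
#' @param min_separation minimum pairwise distance (um) aimed for at
#'   placement; below 2 um placement is rejected outright.
#' @param background uniform background offset (camera pedestal).
#' @param baseline activity baseline brightness.
#' @param activity_noise_sd per-frame activity noise (scaled inversely with a
#'   neuron's amplitude, so bright command neurons have the cleanest, most
#'   correlated signals).
#' @param activity_switch_mean mean interval (frames) between rise/decay
#'   switches of the shared latent.
#' @param activity_tau saturation time constant (frames) of the latent.
#' @param rotation 3x3 rotation applied to the placed cloud (default
#'   identity; the head's anterior axis then lies along +x).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_neurons = 100L,
                       volume_shape = c(12L, 165L, 440L),
                       voxel_size = c(0.27, 0.27, 2.0),
                       n_frames = 200L,
                       frame_interval = 1 / 3,
                       soma_sigma = 1.0,
                       drift_per_frame = c(0.02, 0.02, 0.005),
                       elastic_jitter_sd = 0.15,
                       jitter_rho = 0.95,
                       dropout_prob = 0.1,
                       dropout_factor = 0.02,
                       group_fractions = c(backward = 0.25, forward = 0.25,
                                           other = 0.5),
                       noise_variance = 0,
                       seed = 1L,
                       use_atlas = TRUE,
                       atlas_scale = 10,
                       atlas_noise = 0.05,
                       spread = c(45, 12, 7),
                       dorsal_fraction = 0.65,
                       min_separation = 4.0,
                       background = 20,
                       baseline = 50,
                       activity_noise_sd = 5,
                       activity_switch_mean = 30,
                       activity_tau = 8,
                       rotation = diag(3)) {
  cfg <- list(n_neurons = as.integer(n_neurons),
              volume_shape = as.integer(volume_shape),
              voxel_size = as.numeric(voxel_size),
              n_frames = as.integer(n_frames),
              frame_interval = frame_interval, soma_sigma = soma_sigma,
              drift_per_frame = drift_per_frame,
              elastic_jitter_sd = elastic_jitter_sd, jitter_rho = jitter_rho,
              dropout_prob = dropout_prob, dropout_factor = dropout_factor,
              group_fractions = group_fractions,
              noise_variance = noise_variance, seed = seed,
              use_atlas = use_atlas, atlas_scale = atlas_scale,
              atlas_noise = atlas_noise, spread = spread,
              dorsal_fraction = dorsal_fraction,
              min_separation = min_separation, background = background,
              baseline = baseline, activity_noise_sd = activity_noise_sd,
              activity_switch_mean = activity_switch_mean,
              activity_tau = activity_tau, rotation = rotation)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_neurons >= 1, length(cfg$volume_shape) == 3,
            all(cfg$volume_shape >= 1), all(cfg$voxel_size > 0),
            cfg$n_frames >= 1, cfg$soma_sigma > 0,
            cfg$elastic_jitter_sd >= 0, cfg$dropout_prob >= 0,
            cfg$dropout_prob <= 1, cfg$noise_variance >= 0,
            cfg$min_separation >= 0)
  if (sum(cfg$group_fractions) > 1 + 1e-9)
    stop("group fractions must sum to at most 1")
  ext <- (cfg$volume_shape[c(3, 2, 1)] - 1) * cfg$voxel_size
  if (any(ext / 2 < 3 * cfg$soma_sigma))
    stop("volume too small to contain placements plus a 3-sigma soma margin")
  invisible(cfg)
}

# Deterministic per-neuron plan: identity label, activity group, amplitude.
# Bright backward-command neurons (the seed classes) get the largest
# amplitudes, mirroring their high fluorescence in real recordings.
plan_neurons <- function(cfg, atlas = default_atlas()) {
  n <- cfg$n_neurons
  if (isTRUE(cfg$use_atlas)) {
    k <- min(n, nrow(atlas))
    labels <- c(atlas$class_name[seq_len(k)],
                if (n > k) sprintf("sim%03d", seq_len(n - k)))
    groups <- c(atlas$group[seq_len(k)], rep("other", max(0, n - k)))
  } else {
    counts <- round(cfg$group_fractions[c("backward", "forward")] * n)
    groups <- rep("other", n)
    if (counts[1] > 0) groups[seq_len(counts[1])] <- "backward"
    if (counts[2] > 0) groups[counts[1] + seq_len(counts[2])] <- "forward"
    labels <- sprintf("sim%03d", seq_len(n))
  }
  amp <- ifelse(labels %in% seed_six_classes(), 300,
                ifelse(groups == "backward", 180,
                       ifelse(groups == "forward", 150, 120)))
  data.frame(neuron_id = seq_len(n), label = labels, group = groups,
             amplitude = amp, stringsAsFactors = FALSE)
}

# Saturating-exponential rise/decay latent in [0, 1], switching at random
# intervals: a simple stand-in for slow GCaMP6 dynamics.
sim_latent <- function(n_frames, switch_mean, tau) {
  u <- numeric(n_frames)
  u[1] <- runif(1)
  target <- sample(c(0, 1), 1)
  next_switch <- 1 + max(3, round(rexp(1, 1 / switch_mean)))
  step <- 1 - exp(-1 / tau)
  for (t in seq_len(n_frames)[-1]) {
    if (t >= next_switch) {
      target <- 1 - target
      next_switch <- t + max(3, round(rexp(1, 1 / switch_mean)))
    }
    u[t] <- u[t - 1] + (target - u[t - 1]) * step
  }
  u
}

#' Simulate the true activity (brightness) of every neuron
#'
#' The backward group shares one slow latent rise/decay signal; the forward
#' group follows its negation; `other` neurons follow independent latents.
#' Per-neuron observation noise is scaled inversely with amplitude. All
#' brightness values stay at or above a small positive floor.
#'
#' @param cfg a [sim_config()].
#' @param atlas atlas used for group labels when `use_atlas = TRUE`.
#' @return list with `values` (`n_frames x n_neurons` matrix of true
#'   brightness), `groups`, `labels`, `amplitudes` and the shared `latent`.
#' @export
simulate_activity <- function(cfg, atlas = default_atlas()) {
  if (cfg$n_frames < 2) stop("need at least 2 frames of activity")
  plan <- plan_neurons(cfg, atlas)
  set.seed(derive_seed(cfg$seed, 2L))
  T <- cfg$n_frames
  u <- sim_latent(T, cfg$activity_switch_mean, cfg$activity_tau)
  vals <- matrix(0, T, cfg$n_neurons)
  for (i in seq_len(cfg$n_neurons)) {
    amp <- plan$amplitude[i]
    sdi <- cfg$activity_noise_sd * 120 / amp
    sig <- switch(plan$group[i],
                  backward = u,
                  forward = 1 - u,
                  sim_latent(T, cfg$activity_switch_mean, cfg$activity_tau))
    vals[, i] <- cfg$baseline + amp * sig +
      if (sdi > 0) rnorm(T, 0, sdi) else 0
  }
  vals <- pmax(vals, 1)
  colnames(vals) <- plan$label
  list(values = vals, groups = plan$group, labels = plan$label,
       amplitudes = plan$amplitude, latent = u)
}

# Initial neuron placement in physical um coordinates (x, y, z).
place_neurons <- function(cfg, plan, atlas = default_atlas()) {
  set.seed(derive_seed(cfg$seed, 1L))
  ext <- (cfg$volume_shape[c(3, 2, 1)] - 1) * cfg$voxel_size
  center <- ext / 2
  n <- cfg$n_neurons
  pos <- matrix(NA_real_, n, 3)
  margin <- 3 * cfg$soma_sigma
  n_atlas <- if (isTRUE(cfg$use_atlas)) min(n, nrow(atlas)) else 0L
  if (n_atlas > 0) {
    for (attempt in seq_len(50)) {
      p <- as.matrix(atlas[seq_len(n_atlas), c("x", "y", "z")]) *
        cfg$atlas_scale +
        matrix(rnorm(3 * n_atlas, 0, cfg$atlas_noise * cfg$atlas_scale),
               n_atlas, 3)
      p <- p %*% t(cfg$rotation)
      p <- sweep(p, 2, center, "+")
      in_bounds <- !(any(p < rep(margin, each = n_atlas)) ||
                       any(p > rep(ext - margin, each = n_atlas)))
      if (in_bounds && (n_atlas < 2 || min(stats::dist(p)) >= 2)) break
      if (attempt == 50)
        stop("could not place atlas neurons >= 2 um apart inside the ",
             "volume; enlarge the volume or reduce atlas_scale")
    }
    pos[seq_len(n_atlas), ] <- p
  }
  if (n > n_atlas) {
    semi <- cfg$spread
    for (i in (n_atlas + 1):n) {
      best <- NULL
      best_d <- -Inf
      for (try in seq_len(200)) {
        q <- runif(3, -1, 1)
        if (sum(q^2) > 1) next
        if (runif(1) < cfg$dorsal_fraction) q[2] <- abs(q[2])
        else q[2] <- -abs(q[2])
        cand <- center + cfg$rotation %*% (q * semi)
        cand <- as.numeric(cand)
        if (any(cand < margin) || any(cand > ext - margin)) next
        d <- if (i == 1L) Inf else
          min(sqrt(rowSums(sweep(pos[seq_len(i - 1), , drop = FALSE],
                                 2, cand)^2)))
        if (d > best_d) { best_d <- d; best <- cand }
        if (d >= cfg$min_separation) break
      }
      if (is.null(best) || best_d < 2)
        stop("could not place neuron ", i, " at least 2 um from others; ",
             "reduce n_neurons or enlarge the volume")
      pos[i, ] <- best
    }
  }
  pos
}

# Per-frame true positions: initial + cumulative rigid drift + AR(1) elastic
# jitter. Returns an (n_frames x n_neurons x 3) array.
simulate_motion <- function(cfg, pos0) {
  set.seed(derive_seed(cfg$seed, 3L))
  T <- cfg$n_frames
  n <- nrow(pos0)
  out <- array(0, c(T, n, 3))
  rho <- cfg$jitter_rho
  innov_sd <- cfg$elastic_jitter_sd * sqrt(1 - rho^2)
  jit <- matrix(rnorm(n * 3, 0, cfg$elastic_jitter_sd), n, 3)
  if (cfg$elastic_jitter_sd == 0) jit[] <- 0
  for (t in seq_len(T)) {
    drift <- (t - 1) * cfg$drift_per_frame
    out[t, , ] <- sweep(pos0 + jit, 2, drift, "+")
    if (cfg$elastic_jitter_sd > 0)
      jit <- rho * jit + matrix(rnorm(n * 3, 0, innov_sd), n, 3)
  }
  out
}

#' Simulate a ground-truth volumetric recording
#'
#' Places neurons (see [sim_config()]), simulates their motion and activity,
#' and renders every frame as a sum of 3D Gaussians over a uniform background
#' pedestal. On dropout frames a neuron's rendered brightness is scaled by
#' `dropout_factor`, pushing it below any sensible detection threshold while
#' keeping the neuron present — the scenario position inference must handle.
#'
#' @param cfg a [sim_config()].
#' @param atlas model atlas used for placement and group labels.
#' @param render if `FALSE`, skip rasterisation and return `recording = NULL`
#'   (useful when only ground-truth tracks and activity are needed).
#' @return list with `recording` ([recording()] or `NULL`), `truth` (data
#'   frame `neuron_id, label, group, t, x, y, z, intensity, dropped`),
#'   `activity` (see [simulate_activity()]), `positions`
#'   (`n_frames x n_neurons x 3` array) and `config`.
#' @export
simulate_recording <- function(cfg, atlas = default_atlas(), render = TRUE) {
  validate_sim_config(cfg)
  plan <- plan_neurons(cfg, atlas)
  pos0 <- place_neurons(cfg, plan, atlas)
  act <- simulate_activity(cfg, atlas)
  pos <- simulate_motion(cfg, pos0)
  set.seed(derive_seed(cfg$seed, 4L))
  T <- cfg$n_frames
  n <- cfg$n_neurons
  dropped <- matrix(runif(T * n) < cfg$dropout_prob, T, n)
  amp <- act$values * ifelse(dropped, cfg$dropout_factor, 1)

  truth <- data.frame(
    neuron_id = rep(plan$neuron_id, each = T),
    label = rep(plan$label, each = T),
    group = rep(plan$group, each = T),
    t = rep(0:(T - 1), n),
    x = as.vector(pos[, , 1]), y = as.vector(pos[, , 2]),
    z = as.vector(pos[, , 3]),
    intensity = as.vector(amp),
    dropped = as.vector(dropped),
    stringsAsFactors = FALSE)

  rec <- NULL
  if (render) {
    dims <- cfg$volume_shape
    vox_zyx <- cfg$voxel_size[c(3, 2, 1)]
    frames <- array(0, c(T, dims))
    for (t in seq_len(T)) {
      vol <- array(cfg$background + 0.0, dims)
      for (i in seq_len(n)) {
        vol <- render_gaussian_add(vol, dims,
                                   c(pos[t, i, 3], pos[t, i, 2], pos[t, i, 1]),
                                   cfg$soma_sigma, amp[t, i], vox_zyx)
      }
      frames[t, , , ] <- vol
    }
    rec <- recording(frames, cfg$voxel_size, cfg$frame_interval)
    if (cfg$noise_variance > 0)
      rec <- add_multiplicative_noise(rec, cfg$noise_variance,
                                      derive_seed(cfg$seed, 5L))
  }
  list(recording = rec, truth = truth, activity = act, positions = pos,
       config = cfg)
}

#' Apply multiplicative (speckle) noise to a recording
#'
#' `I' = I * (1 + n)` with `n` i.i.d. zero-mean Gaussian of the given
#' variance, clamped at 0. The expected intensity is preserved up to
#' clamping.
#'
#' @param rec a [recording()].
#' @param variance noise variance (sigma^2), >= 0.
#' @param seed RNG seed for a reproducible noise field.
#' @return noisy [recording()].
#' @export
add_multiplicative_noise <- function(rec, variance, seed = NULL) {
  if (!is.numeric(variance) || variance < 0)
    stop("noise variance must be >= 0")
  if (variance == 0) return(rec)
  if (!is.null(seed)) set.seed(seed)
  f <- rec$frames
  f <- f * (1 + rnorm(length(f), 0, sqrt(variance)))
  f[f < 0] <- 0
  dim(f) <- dim(rec$frames)
  recording(f, rec$voxel_size, rec$frame_interval)
}

#' Ground truth for a single frame
#'
#' @param truth the `truth` table of [simulate_recording()].
#' @param t 0-based frame index.
#' @param visible_only drop neurons on their dropout frames.
#' @return rows of `truth` for frame `t`.
#' @export
truth_frame <- function(truth, t, visible_only = FALSE) {
  out <- truth[truth$t == t, , drop = FALSE]
  if (visible_only) out <- out[!out$dropped, , drop = FALSE]
  out
}
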