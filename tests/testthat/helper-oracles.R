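# Independent oracles and small fixtures shared across tests.

# Exhaustive minimum-cost assignment with a per-element non-link cost:
# enumerates every injective partial matching of rows to columns.
brute_force_assignment <- function(cost, alt) {
  n <- nrow(cost)
  m <- ncol(cost)
  best <- Inf
  best_match <- rep(NA_integer_, n)
  recurse <- function(i, used, cur, match) {
    if (cur >= best) return()
    if (i > n) {
      tot <- cur + alt * (m - sum(used))
      if (tot < best) {
        best <<- tot
        best_match <<- match
      }
      return()
    }
    recurse(i + 1L, used, cur + alt, match)
    for (j in which(!used)) {
      if (is.finite(cost[i, j])) {
        used2 <- used; used2[j] <- TRUE
        match2 <- match; match2[i] <- j
        recurse(i + 1L, used2, cur + cost[i, j], match2)
      }
    }
  }
  recurse(1L, rep(FALSE, m), 0, rep(NA_integer_, n))
  list(cost = best, match = best_match)
}

assignment_total_cost <- function(cost, match, alt) {
  linked <- which(!is.na(match))
  sum(cost[cbind(linked, match[linked])]) +
    alt * (sum(is.na(match)) + (ncol(cost) - length(linked)))
}

# Exhaustive maximum-cardinality, minimum-distance pairing within a radius.
brute_force_pairing <- function(d, radius) {
  n <- nrow(d); m <- ncol(d)
  best_tp <- -1L
  best_cost <- Inf
  recurse <- function(i, used, tp, cur) {
    if (i > n) {
      if (tp > best_tp || (tp == best_tp && cur < best_cost)) {
        best_tp <<- tp
        best_cost <<- cur
      }
      return()
    }
    recurse(i + 1L, used, tp, cur)
    for (j in which(!used)) {
      if (d[i, j] <= radius) {
        used2 <- used; used2[j] <- TRUE
        recurse(i + 1L, used2, tp + 1L, cur + d[i, j])
      }
    }
  }
  recurse(1L, rep(FALSE, m), 0L, 0)
  list(TP = best_tp, cost = best_cost)
}

# Render a single isotropic Gaussian blob into a (z, y, x) volume; an
# independent R-level oracle for the compiled renderer and the detector.
render_blob_r <- function(dims, center_xyz, sigma, amplitude, voxel_size) {
  vol <- array(0, dims)
  for (iz in seq_len(dims[1])) for (iy in seq_len(dims[2]))
    for (ix in seq_len(dims[3])) {
      p <- c((ix - 1) * voxel_size[1], (iy - 1) * voxel_size[2],
             (iz - 1) * voxel_size[3])
      vol[iz, iy, ix] <- amplitude * exp(-sum((p - center_xyz)^2) /
                                           (2 * sigma^2))
    }
  vol
}

# Small simulation used by several modules: 21 atlas neurons, modest motion.
small_sim <- function(seed = 7, n_frames = 20, dropout = 0,
                      n_neurons = 21, ...) {
  sim_config(n_neurons = n_neurons, volume_shape = c(12L, 100L, 300L),
             n_frames = n_frames, dropout_prob = dropout, seed = seed, ...)
}

# Ground-truth tracks/trace matrix for identification tests (no imaging).
truth_tracks <- function(sim) {
  truth <- sim$truth
  data.frame(track_id = truth$neuron_id, t = truth$t, x = truth$x,
             y = truth$y, z = truth$z, intensity = truth$intensity,
             source = "detected", stringsAsFactors = FALSE)
}

truth_trace_matrix <- function(sim) {
  m <- sim$activity$values
  colnames(m) <- as.character(seq_len(ncol(m)))
  m
}
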