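#' Match detections to ground truth within a radius
#'
#' Detections are paired one-to-one with ground-truth neuron positions by a
#' minimum-distance assignment restricted to pairs within `radius` um
#' (default 3, the standard matching rule for nuclear somata). Matched pairs
#' are true positives; unmatched truth points are false negatives; unmatched
#' detections are false positives. A greedy nearest-first pairing is
#' available for sensitivity analysis.
#'
#' @param detections [spot_table()] for one frame.
#' @param truth matrix or data frame with `x`, `y`, `z` columns (um) for the
#'   same frame.
#' @param radius matching radius in um (> 0).
#' @param method `"optimal"` (one-to-one LAP) or `"greedy"`.
#' @return list with `TP`, `FN`, `FP` and `pairing` (detection row ->
#'   truth row, `NA` if unmatched).
#' @export
match_to_ground_truth <- function(detections, truth, radius = 3,
                                  method = c("optimal", "greedy")) {
  method <- match.arg(method)
  if (radius <= 0) stop("`radius` must be > 0")
  dp <- if (nrow(detections)) spot_positions(detections) else
    matrix(0, 0, 3)
  tp <- as.matrix(as.data.frame(truth)[, c("x", "y", "z")])
  n <- nrow(dp); m <- nrow(tp)
  if (n == 0 || m == 0)
    return(list(TP = 0L, FN = m, FP = n, pairing = rep(NA_integer_, n)))
  d <- sqrt(outer(rowSums(dp^2), rowSums(tp^2), "+") - 2 * dp %*% t(tp))
  d[!is.finite(d) | d < 0] <- 0
  cost <- d
  cost[cost > radius] <- Inf
  pairing <- rep(NA_integer_, n)
  if (method == "optimal") {
    # large alternative cost: maximise matches first, then minimise distance
    pairing <- solve_assignment(cost,
                                alternative_cost = (n + m) * radius * 100)
  } else {
    ord <- order(d)
    used_t <- rep(FALSE, m)
    for (k in ord) {
      i <- ((k - 1) %% n) + 1
      j <- ((k - 1) %/% n) + 1
      if (d[i, j] > radius) break
      if (is.na(pairing[i]) && !used_t[j]) {
        pairing[i] <- j
        used_t[j] <- TRUE
      }
    }
  }
  TP <- sum(!is.na(pairing))
  list(TP = TP, FN = m - TP, FP = n - TP, pairing = pairing)
}

#' Detection metrics from TP/FN/FP counts
#'
#' `accuracy = TP / (TP + FP + FN)`; rates are relative to the number of
#' ground-truth neurons: `tp_rate = TP / (TP + FN)`,
#' `fn_rate = FN / (TP + FN)`, `fp_rate = FP / (TP + FN)`. True negatives
#' are deliberately excluded: almost every voxel of a sparse volume is a
#' true negative, which would make any TN-based metric vacuous.
#'
#' @param TP,FN,FP non-negative counts.
#' @return a `detection_evaluation` list with counts, rates and accuracy (at
#'   full precision; round only for display).
#' @export
compute_metrics <- function(TP, FN, FP) {
  stopifnot(TP >= 0, FN >= 0, FP >= 0)
  if (TP + FN + FP == 0) stop("all counts are zero; metrics undefined")
  gt <- TP + FN
  structure(list(TP = TP, FN = FN, FP = FP,
                 tp_rate = if (gt > 0) TP / gt else NA_real_,
                 fn_rate = if (gt > 0) FN / gt else NA_real_,
                 fp_rate = if (gt > 0) FP / gt else NA_real_,
                 accuracy = TP / (TP + FP + FN)),
            class = "detection_evaluation")
}

#' @export
print.detection_evaluation <- function(x, ...) {
  cat(sprintf(
    "TP %d  FN %d  FP %d | TP r. %.2f  FN r. %.2f  FP r. %.2f | Acc. %.2f\n",
    x$TP, x$FN, x$FP, x$tp_rate, x$fn_rate, x$fp_rate, x$accuracy))
  invisible(x)
}

#' Evaluate detections on one frame against ground truth
#'
#' @param detections [spot_table()] for one frame.
#' @param truth ground-truth positions for the same frame (`x`,`y`,`z` um).
#' @param radius matching radius (um).
#' @param method see [match_to_ground_truth()].
#' @return a `detection_evaluation`.
#' @export
evaluate_detection <- function(detections, truth, radius = 3,
                               method = "optimal") {
  m <- match_to_ground_truth(detections, truth, radius, method)
  compute_metrics(m$TP, m$FN, m$FP)
}

#' Detection accuracy as a function of multiplicative-noise variance
#'
#' For each variance, multiplicative noise is applied to the designated
#' frame, detection is re-run, and the detections are scored against ground
#' truth by the radius rule. Deterministic under `seed`.
#'
#' @param rec a [recording()].
#' @param truth ground-truth table (see [simulate_recording()]).
#' @param params [detection_params()].
#' @param variances vector of noise variances (sigma^2), >= 0.
#' @param seed RNG seed for the noise fields.
#' @param t 0-based frame to evaluate (default 0).
#' @param radius matching radius (um).
#' @return data frame with one row per variance: counts, rates, accuracy.
#' @export
noise_robustness_curve <- function(rec, truth, params, variances, seed = 1L,
                                   t = 0L, radius = 3) {
  if (any(variances < 0)) stop("variances must be >= 0")
  if (length(variances) == 0)
    return(data.frame(sigma2 = numeric(0), TP = integer(0), FN = integer(0),
                      FP = integer(0), tp_rate = numeric(0),
                      fn_rate = numeric(0), fp_rate = numeric(0),
                      accuracy = numeric(0)))
  vol <- get_volume(rec, t)
  one <- recording(array(vol, c(1, dim(vol))), rec$voxel_size,
                   rec$frame_interval)
  gt <- truth_frame(truth, t, visible_only = TRUE)
  rows <- lapply(seq_along(variances), function(i) {
    noisy <- add_multiplicative_noise(one, variances[i],
                                      derive_seed(seed, i))
    det <- detect_spots(get_volume(noisy, 0L), params, rec$voxel_size, t)
    ev <- evaluate_detection(det, gt, radius)
    data.frame(sigma2 = variances[i], TP = ev$TP, FN = ev$FN, FP = ev$FP,
               tp_rate = ev$tp_rate, fn_rate = ev$fn_rate,
               fp_rate = ev$fp_rate, accuracy = ev$accuracy)
  })
  do.call(rbind, rows)
}

#' Score tracked identities against ground truth
#'
#' Each track is matched to the ground-truth neuron it overlaps most (spots
#' within `radius` um of the neuron's true position at the same frame); the
#' recovery is the fraction of all track spots lying within `radius` of
#' their track's majority neuron.
#'
#' @param tracks gap-free track table.
#' @param truth ground-truth table from [simulate_recording()].
#' @param radius matching radius (um, default 3).
#' @return list with `frame_recovery` (overall fraction), `per_track`
#'   (data frame `track_id, neuron_id, n_spots, n_correct`), and
#'   `n_truth_covered` (ground-truth neurons claimed by some track).
#' @export
evaluate_tracking <- function(tracks, truth, radius = 3) {
  ids <- sort(unique(tracks$track_id))
  nids <- sort(unique(truth$neuron_id))
  T <- max(truth$t) + 1L
  # truth positions as (T x neuron) matrices per axis
  gx <- gy <- gz <- matrix(NA_real_, T, length(nids))
  ti <- truth$t + 1L
  ni <- match(truth$neuron_id, nids)
  gx[cbind(ti, ni)] <- truth$x
  gy[cbind(ti, ni)] <- truth$y
  gz[cbind(ti, ni)] <- truth$z
  per <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    tr <- tracks[tracks$track_id == ids[i], , drop = FALSE]
    rows <- tr$t + 1L
    d2 <- (gx[rows, , drop = FALSE] - tr$x)^2 +
      (gy[rows, , drop = FALSE] - tr$y)^2 +
      (gz[rows, , drop = FALSE] - tr$z)^2
    within <- d2 <= radius^2
    counts <- colSums(within, na.rm = TRUE)
    j <- which.max(counts)
    maj <- if (counts[j] == 0) NA_integer_ else nids[j]
    n_correct <- counts[j]
    per[[i]] <- data.frame(track_id = ids[i], neuron_id = maj,
                           n_spots = nrow(tr), n_correct = n_correct)
  }
  per <- do.call(rbind, per)
  list(frame_recovery = sum(per$n_correct) / sum(per$n_spots),
       per_track = per,
       n_truth_covered = length(unique(per$neuron_id[!is.na(per$neuron_id)])))
}
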