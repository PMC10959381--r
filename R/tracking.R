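#' Tracking parameters
#'
#' @param max_link_distance maximum frame-to-frame link distance (um).
#' @param max_time_gap maximum frame gap bridged by segment linking.
#' @param gap_max_distance maximum end-to-start distance (um) for segment
#'   linking.
#' @param restore_max_distance maximum end-to-start distance (um) for
#'   relative-distance track restoration.
#' @param restore_max_gap maximum frame gap for track restoration.
#' @param n_neighbors neighbors used by position inference (default 20).
#' @param ref_fraction fraction of the recording a segment must span to act
#'   as a reference track during restoration.
#' @param extend_to_end extend tracks past their last detection to the final
#'   frame by position inference.
#' @return a `tracking_params` list.
#' @export
tracking_params <- function(max_link_distance = 2.0, max_time_gap = 5L,
                            gap_max_distance = 3.0,
                            restore_max_distance = 5.0,
                            restore_max_gap = 20L, n_neighbors = 20L,
                            ref_fraction = 0.5, extend_to_end = TRUE) {
  stopifnot(max_link_distance > 0, gap_max_distance > 0,
            restore_max_distance > 0, max_time_gap >= 1,
            restore_max_gap >= 1, n_neighbors >= 1)
  structure(list(max_link_distance = max_link_distance,
                 max_time_gap = as.integer(max_time_gap),
                 gap_max_distance = gap_max_distance,
                 restore_max_distance = restore_max_distance,
                 restore_max_gap = as.integer(restore_max_gap),
                 n_neighbors = as.integer(n_neighbors),
                 ref_fraction = ref_fraction,
                 extend_to_end = extend_to_end),
            class = "tracking_params")
}

#' Frame-to-frame spot linking (LAP stage 1)
#'
#' For each consecutive frame pair, a linear assignment problem is solved
#' with cost = squared Euclidean distance (um^2) between spots; pairs farther
#' apart than `max_link_distance` are forbidden, and every spot may instead
#' take the non-link alternative at cost `1.05 * cmax` (`cmax` = largest
#' finite cost of that frame pair). Accepted links are chained into segments
#' of strictly consecutive frames.
#'
#' @param spots a [spot_table()] covering one or more frames.
#' @param params [tracking_params()].
#' @return the spot table with a `segment_id` column.
#' @export
link_frames <- function(spots, params = tracking_params()) {
  spots <- spots[order(spots$t), , drop = FALSE]
  n <- nrow(spots)
  seg <- rep(NA_integer_, n)
  if (n == 0L) {
    spots$segment_id <- integer(0)
    return(spots)
  }
  rows_by_t <- split(seq_len(n), spots$t)
  frames <- as.integer(names(rows_by_t))
  next_id <- 0L
  pos <- spot_positions(spots)
  prev_t <- NULL
  for (fi in seq_along(frames)) {
    cur <- rows_by_t[[fi]]
    linked <- rep(FALSE, length(cur))
    if (!is.null(prev_t) && frames[fi] == prev_t$t + 1L) {
      a <- prev_t$rows
      d2 <- outer(rowSums(pos[a, , drop = FALSE]^2),
                  rowSums(pos[cur, , drop = FALSE]^2), "+") -
        2 * pos[a, , drop = FALSE] %*% t(pos[cur, , drop = FALSE])
      d2[d2 < 0] <- 0
      cost <- d2
      cost[cost > params$max_link_distance^2] <- Inf
      m <- solve_assignment(cost)
      for (i in seq_along(a)) {
        if (!is.na(m[i])) {
          seg[cur[m[i]]] <- seg[a[i]]
          linked[m[i]] <- TRUE
        }
      }
    }
    for (j in which(!linked)) {
      next_id <- next_id + 1L
      seg[cur[j]] <- next_id
    }
    prev_t <- list(t = frames[fi], rows = cur)
  }
  spots$segment_id <- seg
  spots
}

segment_summary <- function(segments) {
  ids <- sort(unique(segments$segment_id))
  out <- data.frame(segment_id = ids, t_start = NA_integer_,
                    t_end = NA_integer_, n = NA_integer_)
  out$start <- matrix(NA_real_, length(ids), 3)
  out$end <- matrix(NA_real_, length(ids), 3)
  for (i in seq_along(ids)) {
    s <- segments[segments$segment_id == ids[i], , drop = FALSE]
    s <- s[order(s$t), , drop = FALSE]
    out$t_start[i] <- s$t[1]
    out$t_end[i] <- s$t[nrow(s)]
    out$n[i] <- nrow(s)
    out$start[i, ] <- as.numeric(s[1, c("x", "y", "z")])
    out$end[i, ] <- as.numeric(s[nrow(s), c("x", "y", "z")])
  }
  out
}

apply_segment_merges <- function(segments, from, to) {
  # merge segment `to` into `from` (to follows from in time), transitively
  succ <- setNames(to, from)
  heads <- setdiff(unique(segments$segment_id), to)
  relabel <- list()
  for (h in heads) {
    chain <- h
    cur <- h
    while (!is.na(succ[as.character(cur)])) {
      cur <- succ[[as.character(cur)]]
      chain <- c(chain, cur)
    }
    relabel[[as.character(h)]] <- chain
  }
  new_id <- segments$segment_id
  for (h in names(relabel))
    new_id[segments$segment_id %in% relabel[[h]]] <- as.integer(h)
  segments$segment_id <- new_id
  segments
}

#' Gap-closing segment linking (LAP stage 2)
#'
#' Segment ends are matched to segment starts by a LAP with cost = squared
#' distance between the end spot and the start spot; pairs with a
#' non-positive time gap, a gap exceeding `max_time_gap`, or a distance
#' exceeding `gap_max_distance` are forbidden. The non-link alternative costs
#' `1.05 * cmax`. Accepted pairs are concatenated; gap frames are left empty
#' for later position inference.
#'
#' @param segments output of [link_frames()].
#' @param params [tracking_params()].
#' @return segment table with merged `segment_id`s.
#' @export
link_segments <- function(segments, params = tracking_params()) {
  info <- segment_summary(segments)
  k <- nrow(info)
  if (k < 2) return(segments)
  # sparse candidate list of feasible (end, start) pairs
  cand_i <- integer(0); cand_j <- integer(0); cand_c <- numeric(0)
  for (i in seq_len(k)) {
    dj <- info$t_start - info$t_end[i]
    ok <- which(dj >= 1 & dj <= params$max_time_gap & seq_len(k) != i)
    if (length(ok)) {
      d2 <- rowSums(sweep(info$start[ok, , drop = FALSE], 2,
                          info$end[i, ])^2)
      keep <- d2 <= params$gap_max_distance^2
      cand_i <- c(cand_i, rep(i, sum(keep)))
      cand_j <- c(cand_j, ok[keep])
      cand_c <- c(cand_c, d2[keep])
    }
  }
  if (length(cand_i) == 0) return(segments)
  # the non-link alternative is global (1.05 * cmax of the whole problem);
  # with it fixed, the LAP decomposes exactly over connected components of
  # the feasibility graph, which keeps large dropout-riddled problems fast
  alt <- 1.05 * max(cand_c)
  comp <- bipartite_components(cand_i, cand_j, k)
  from <- integer(0); to <- integer(0)
  for (cc in comp) {
    in_cc <- cand_i %in% cc$ends
    rows <- sort(unique(cand_i[in_cc]))
    cols <- sort(unique(cand_j[in_cc]))
    sub <- matrix(Inf, length(rows), length(cols))
    sel <- which(in_cc)
    sub[cbind(match(cand_i[sel], rows), match(cand_j[sel], cols))] <-
      cand_c[sel]
    m <- solve_assignment(sub, alternative_cost = alt)
    ok <- !is.na(m)
    from <- c(from, info$segment_id[rows[ok]])
    to <- c(to, info$segment_id[cols[m[ok]]])
  }
  if (length(from) == 0) return(segments)
  apply_segment_merges(segments, from, to)
}

# connected components of the bipartite (end, start) feasibility graph;
# returns a list of lists with `ends` and `starts` node indices.
bipartite_components <- function(cand_i, cand_j, k) {
  parent <- seq_len(2L * k)  # 1..k ends, k+1..2k starts
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (e in seq_along(cand_i)) {
    a <- find(cand_i[e]); b <- find(k + cand_j[e])
    if (a != b) parent[a] <- b
  }
  roots_e <- vapply(unique(cand_i), find, integer(1))
  ends_by_root <- split(unique(cand_i), roots_e)
  roots_s <- vapply(unique(cand_j), function(j) find(k + j), integer(1))
  starts_by_root <- split(unique(cand_j), roots_s)
  lapply(names(ends_by_root), function(r)
    list(ends = ends_by_root[[r]], starts = starts_by_root[[r]]))
}

# Mean distance profile of each segment against each reference track:
# profile[s, r] = mean over frames where both exist of |pos_s - pos_r|.
segment_reference_profiles <- function(segments, info, ref_ids) {
  ids <- info$segment_id
  T0 <- min(segments$t); T1 <- max(segments$t)
  nt <- T1 - T0 + 1L
  pos_arr <- array(NA_real_, c(length(ids), nt, 3))
  for (i in seq_along(ids)) {
    s <- segments[segments$segment_id == ids[i], , drop = FALSE]
    pos_arr[i, s$t - T0 + 1L, ] <- as.matrix(s[, c("x", "y", "z")])
  }
  prof <- matrix(NA_real_, length(ids), length(ref_ids))
  for (r in seq_along(ref_ids)) {
    ri <- match(ref_ids[r], ids)
    dx <- sweep(pos_arr[, , 1, drop = FALSE], 2:3,
                pos_arr[ri, , 1, drop = FALSE])
    dy <- sweep(pos_arr[, , 2, drop = FALSE], 2:3,
                pos_arr[ri, , 2, drop = FALSE])
    dz <- sweep(pos_arr[, , 3, drop = FALSE], 2:3,
                pos_arr[ri, , 3, drop = FALSE])
    d <- sqrt(dx^2 + dy^2 + dz^2)
    dim(d) <- c(length(ids), nt)
    prof[, r] <- rowMeans(d, na.rm = TRUE)
    prof[rowSums(!is.na(d)) == 0, r] <- NA
  }
  prof
}

#' Relative-distance track restoration
#'
#' Re-links segments missed by the LAP stages using the consistency of
#' inter-neuron distances: each segment's mean distance to a set of long
#' reference tracks (computed over the frames both cover) forms a distance
#' profile, and a segment pair disjoint in time, within `restore_max_gap`
#' frames and `restore_max_distance` um of each other, is linked when the
#' mean absolute difference of their profiles (over at least 3 shared
#' reference tracks) is the lowest available. Merges are applied greedily in
#' ascending profile difference, each segment end/start used at most once.
#'
#' @param segments output of [link_segments()].
#' @param params [tracking_params()].
#' @return segment table with restored `segment_id`s.
#' @export
restore_segments <- function(segments, params = tracking_params()) {
  info <- segment_summary(segments)
  k <- nrow(info)
  if (k < 2) return(segments)
  span <- max(segments$t) - min(segments$t) + 1L
  ref_ids <- info$segment_id[info$n >= params$ref_fraction * span]
  if (length(ref_ids) < 3) {
    warning("fewer than 3 long reference tracks; restoration skipped")
    return(segments)
  }
  prof <- segment_reference_profiles(segments, info, ref_ids)
  cand <- NULL
  for (i in seq_len(k)) {
    dj <- info$t_start - info$t_end[i]
    ok <- which(dj >= 1 & dj <= params$restore_max_gap)
    ok <- ok[ok != i]
    for (j in ok) {
      d <- sqrt(sum((info$start[j, ] - info$end[i, ])^2))
      if (d > params$restore_max_distance) next
      shared <- which(!is.na(prof[i, ]) & !is.na(prof[j, ]))
      if (length(shared) < 3) next
      diff <- mean(abs(prof[i, shared] - prof[j, shared]))
      cand <- rbind(cand, c(i, j, diff))
    }
  }
  if (is.null(cand)) return(segments)
  cand <- cand[order(cand[, 3]), , drop = FALSE]
  end_used <- rep(FALSE, k)
  start_used <- rep(FALSE, k)
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (end_used[i] || start_used[j]) next
    # avoid creating time overlaps through chains: conservative check that
    # the two segments are disjoint (guaranteed by dt >= 1 above)
    end_used[i] <- TRUE
    start_used[j] <- TRUE
    from <- c(from, info$segment_id[i])
    to <- c(to, info$segment_id[j])
  }
  if (length(from) == 0) return(segments)
  apply_segment_merges(segments, from, to)
}

#' Convert linked segments to a track table
#'
#' @param segments segment table after restoration.
#' @return track table with consecutive `track_id`s (sorted by first frame).
#' @export
segments_to_tracks <- function(segments) {
  info <- segment_summary(segments)
  info <- info[order(info$t_start, info$segment_id), ]
  map <- setNames(seq_len(nrow(info)), info$segment_id)
  tracks <- segments
  tracks$track_id <- as.integer(map[as.character(segments$segment_id)])
  tracks$segment_id <- NULL
  tracks[order(tracks$track_id, tracks$t),
         c("track_id", "t", "x", "y", "z", "intensity", "source")]
}

# Internal dense representation: positions P[k, t, ], status S[k, t]
# (0 = missing, 1 = detected, 2 = inferred, 3 = manual).
tracks_to_arrays <- function(tracks, n_frames) {
  ids <- sort(unique(tracks$track_id))
  K <- length(ids)
  P <- array(NA_real_, c(K, n_frames, 3))
  S <- matrix(0L, K, n_frames)
  I <- matrix(NA_real_, K, n_frames)
  code <- c(detected = 1L, inferred = 2L, manual = 3L)
  ki <- match(tracks$track_id, ids)
  ti <- tracks$t + 1L
  P[cbind(ki, ti, 1L)] <- tracks$x
  P[cbind(ki, ti, 2L)] <- tracks$y
  P[cbind(ki, ti, 3L)] <- tracks$z
  S[cbind(ki, ti)] <- code[tracks$source]
  I[cbind(ki, ti)] <- tracks$intensity
  list(ids = ids, P = P, S = S, I = I)
}

arrays_to_tracks <- function(arr) {
  src_names <- c("detected", "inferred", "manual")
  out <- NULL
  idx <- which(arr$S > 0, arr.ind = TRUE)
  out <- data.frame(track_id = arr$ids[idx[, 1]], t = idx[, 2] - 1L,
                    x = arr$P[cbind(idx, 1L)], y = arr$P[cbind(idx, 2L)],
                    z = arr$P[cbind(idx, 3L)],
                    intensity = arr$I[idx],
                    source = src_names[arr$S[idx]],
                    stringsAsFactors = FALSE)
  out[order(out$track_id, out$t), ]
}

# Core of the neighbor-displacement inference (Eq-style): position at frame t
# = position at reference frame + mean displacement of the closest neighbor
# tracks between the two frames.
infer_position_core <- function(k, t, t_ref, P, S, n_neighbors,
                                warn = TRUE) {
  self_ref <- P[k, t_ref, ]
  have_both <- which(S[, t_ref] > 0 & S[, t] > 0)
  have_both <- have_both[have_both != k]
  if (length(have_both) == 0) {
    if (warn) warning("no eligible neighbor tracks; position carried over")
    return(self_ref)
  }
  pm <- P[have_both, t_ref, , drop = FALSE]
  dim(pm) <- c(length(have_both), 3)
  d2 <- rowSums(sweep(pm, 2, self_ref)^2)
  detected_both <- S[have_both, t_ref] == 1L & S[have_both, t] == 1L
  ord <- order(!detected_both, d2)
  sel <- have_both[ord[seq_len(min(n_neighbors, length(ord)))]]
  pa <- P[sel, t, , drop = FALSE]
  pb <- P[sel, t_ref, , drop = FALSE]
  disp <- pa - pb
  dim(disp) <- c(length(sel), 3)
  self_ref + colMeans(disp)
}

#' Infer the position of a missing neuron from its neighbors
#'
#' The position of a neuron missing at frame `t` is the sum of its position
#' at a reference frame (the nearest frame with a known position, preferring
#' `t - 1`) and the mean displacement, between the two frames, of the
#' `n_neighbors` tracks closest to it at the reference frame. Neighbors must
#' have known positions at both frames; detected positions are preferred
#' over inferred ones.
#'
#' @param tracks a track table (`track_id, t, x, y, z, intensity, source`).
#' @param track_id the track missing a position.
#' @param t 0-based frame at which to infer.
#' @param n_frames total number of frames in the recording.
#' @param n_neighbors number of neighbor tracks (default 20).
#' @return a one-row [spot_table()] with `source = "inferred"`.
#' @export
infer_missing_position <- function(tracks, track_id, t, n_frames,
                                   n_neighbors = 20L) {
  arr <- tracks_to_arrays(tracks, n_frames)
  k <- match(track_id, arr$ids)
  if (is.na(k)) stop("unknown track id ", track_id)
  known <- which(arr$S[k, ] > 0) - 1L
  if (length(known) == 0) stop("track has no known positions")
  if ((t + 1L) <= ncol(arr$S) && arr$S[k, t + 1L] > 0)
    stop("track already has a spot at frame ", t)
  t_ref <- if ((t - 1L) %in% known) t - 1L else
    known[which.min(abs(known - t))]
  p <- infer_position_core(k, t + 1L, t_ref + 1L, arr$P, arr$S, n_neighbors)
  spot_table(t = t, x = p[1], y = p[2], z = p[3], intensity = NA_real_,
             source = "inferred")
}

#' Fill all track gaps by neighbor-displacement inference
#'
#' Proceeds frame-by-frame forward in time so that earlier inferences can
#' serve as references for later ones. Every gap frame between a track's
#' first and last detection is filled; with `extend_to_end` the track is also
#' extended past its last detection to the final frame.
#'
#' @param tracks a track table.
#' @param n_frames total number of frames.
#' @param params [tracking_params()] (uses `n_neighbors`, `extend_to_end`).
#' @return gap-free track table (inferred spots have `NA` intensity).
#' @export
fill_gaps <- function(tracks, n_frames, params = tracking_params()) {
  arr <- tracks_to_arrays(tracks, n_frames)
  K <- length(arr$ids)
  first <- apply(arr$S > 0, 1, function(v) which(v)[1])
  last <- apply(arr$S > 0, 1, function(v) tail(which(v), 1))
  upper <- if (params$extend_to_end) rep(n_frames, K) else last
  for (t in seq_len(n_frames)) {
    todo <- which(arr$S[, t] == 0L & first < t & upper >= t)
    for (k in todo) {
      # nearest known frame, preferring t - 1 (always known once t > first)
      known <- which(arr$S[k, ] > 0)
      t_ref <- if (arr$S[k, t - 1L] > 0) t - 1L else
        known[which.min(abs(known - t))]
      p <- infer_position_core(k, t, t_ref, arr$P, arr$S,
                               params$n_neighbors, warn = FALSE)
      arr$P[k, t, ] <- p
      arr$S[k, t] <- 2L
    }
  }
  arrays_to_tracks(arr)
}

#' Add a manually annotated spot and reconstruct its whole track
#'
#' The added spot is treated as a track with a single time point; its
#' positions at all other frames are reconstructed by neighbor-displacement
#' inference, propagated forward and backward from `t`.
#'
#' @param position `(x, y, z)` um.
#' @param t 0-based frame of the annotation.
#' @param tracks existing track table.
#' @param n_frames total number of frames.
#' @param params [tracking_params()].
#' @return list with `tracks` (updated table) and `track_id` of the new
#'   track.
#' @export
add_manual_spot <- function(position, t, tracks, n_frames,
                            params = tracking_params()) {
  new_id <- max(tracks$track_id) + 1L
  at_t <- tracks[tracks$t == t, , drop = FALSE]
  if (nrow(at_t) > 0) {
    d <- sqrt(rowSums(sweep(as.matrix(at_t[, c("x", "y", "z")]), 2,
                            position)^2))
    if (min(d) > 10)
      warning("manual spot is more than 10 um from every track at frame ",
              t, "; it may not be a neuron")
  }
  new_spot <- data.frame(track_id = new_id, t = as.integer(t),
                         x = position[1], y = position[2], z = position[3],
                         intensity = NA_real_, source = "manual",
                         stringsAsFactors = FALSE)
  all_tracks <- rbind(tracks, new_spot)
  arr <- tracks_to_arrays(all_tracks, n_frames)
  k <- match(new_id, arr$ids)
  if (t + 1L < n_frames) {
    for (tt in (t + 2L):n_frames) {
      p <- infer_position_core(k, tt, tt - 1L, arr$P, arr$S,
                               params$n_neighbors, warn = FALSE)
      arr$P[k, tt, ] <- p
      arr$S[k, tt] <- 2L
    }
  }
  if (t > 0L) {
    for (tt in seq(t, 1L)) {
      p <- infer_position_core(k, tt, tt + 1L, arr$P, arr$S,
                               params$n_neighbors, warn = FALSE)
      arr$P[k, tt, ] <- p
      arr$S[k, tt] <- 2L
    }
  }
  list(tracks = arrays_to_tracks(arr), track_id = new_id)
}

#' Run the full tracking stage
#'
#' Frame-to-frame linking, gap closing, relative-distance restoration, and
#' neighbor-displacement gap filling, in that order.
#'
#' @param spots a [spot_table()] from detection.
#' @param n_frames total number of frames in the recording.
#' @param params [tracking_params()].
#' @return gap-free track table.
#' @export
track_neurons <- function(spots, n_frames, params = tracking_params()) {
  seg <- link_frames(spots, params)
  seg <- link_segments(seg, params)
  seg <- restore_segments(seg, params)
  tracks <- segments_to_tracks(seg)
  fill_gaps(tracks, n_frames, params)
}
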