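#' Identification parameters
#'
#' @param lambda_corr weight of the correlation-group penalty in the
#'   assignment cost (normalized-distance-squared units).
#' @param collinearity_tol maximum perpendicular deviation of a seed triplet
#'   from its best-fit line, as a fraction of the triplet length.
#' @param axis_angle_tol maximum angle (degrees) between a seed triplet's
#'   line and the dominant anteroposterior axis.
#' @param threshold_sds correlation threshold in units of `C_sigma` above
#'   `C_mu` (group membership and correlation neighborhoods).
#' @param pool_size seed search is restricted to this many
#'   highest-correlation tracks (exhaustive within the pool).
#' @return an `ident_params` list.
#' @export
ident_params <- function(lambda_corr = 1.0, collinearity_tol = 0.15,
                         axis_angle_tol = 30, threshold_sds = 1.0,
                         pool_size = 12L) {
  structure(list(lambda_corr = lambda_corr,
                 collinearity_tol = collinearity_tol,
                 axis_angle_tol = axis_angle_tol,
                 threshold_sds = threshold_sds,
                 pool_size = as.integer(pool_size)),
            class = "ident_params")
}

#' Pairwise correlation statistics of the traces
#'
#' Pearson correlations on smoothed traces with pairwise-complete frames;
#' `C_mu` and `C_sigma` are the mean and standard deviation of the strict
#' upper triangle. Correlations of constant traces are set to 0.
#'
#' @param traces numeric matrix (frames x tracks) or a list of `trace`
#'   objects plus `n_frames`.
#' @param n_frames required when `traces` is a list.
#' @return list with `C` (correlation matrix), `C_mu`, `C_sigma`,
#'   `track_ids`.
#' @export
correlation_stats <- function(traces, n_frames = NULL) {
  m <- if (is.matrix(traces)) traces else trace_matrix(traces, n_frames)
  if (ncol(m) < 3) stop("need at least 3 traces")
  if (sum(stats::complete.cases(m)) < 10)
    stop("need at least 10 complete frames")
  sds <- apply(m, 2, sd, na.rm = TRUE)
  C <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  if (any(sds == 0 | !is.finite(sds))) {
    flat <- which(sds == 0 | !is.finite(sds))
    C[flat, ] <- 0
    C[, flat] <- 0
    warning("constant trace(s); their correlations set to 0: ",
            paste(colnames(m)[flat], collapse = ", "))
  }
  C[is.na(C)] <- 0
  diag(C) <- 1
  up <- C[upper.tri(C)]
  list(C = C, C_mu = mean(up), C_sigma = sd(up),
       track_ids = colnames(m))
}

#' Find the six seed neurons (two collinear, highly correlated triplets)
#'
#' Searches, within the `pool_size` tracks of highest mutual correlation,
#' for the 6-subset maximising mean pairwise correlation that splits into
#' two triplets, each roughly collinear and aligned with the direction of
#' largest spatial spread of all neuron positions (first principal
#' component). These are the AVA/AVE/AIB candidates anchoring the body
#' frame.
#'
#' @param positions matrix (tracks x 3) of time-averaged `(x, y, z)` um.
#' @param stats output of [correlation_stats()] (same track order).
#' @param params [ident_params()].
#' @return list with `ids` (indices of the six), `triplets` (two index
#'   triples), `axis` (dominant PCA direction), `score`.
#' @export
find_seed_six <- function(positions, stats, params = ident_params()) {
  n <- nrow(positions)
  if (n < 6) stop("need at least 6 tracks to search for seed neurons")
  C <- stats$C
  # rank tracks by the mean of their 5 strongest correlations
  score <- vapply(seq_len(n), function(i) {
    v <- sort(C[i, -i], decreasing = TRUE)
    mean(head(v, 5))
  }, numeric(1))
  pool <- order(score, decreasing = TRUE)[seq_len(min(params$pool_size, n))]
  axis <- prcomp(positions)$rotation[, 1]
  cos_tol <- cos(params$axis_angle_tol * pi / 180)
  triplet_ok <- function(idx) {
    f <- fit_line3(positions[idx, , drop = FALSE])
    if (f$length <= 0) return(FALSE)
    if (f$max_perp / f$length > params$collinearity_tol) return(FALSE)
    abs(sum(f$direction * axis)) >= cos_tol
  }
  subsets <- combn(pool, 6)
  best <- NULL
  best_score <- -Inf
  splits <- combn(6, 3)
  for (s in seq_len(ncol(subsets))) {
    six <- subsets[, s]
    mean_c <- mean(C[six, six][upper.tri(matrix(0, 6, 6))])
    if (mean_c <= best_score) next
    for (sp in seq_len(ncol(splits))) {
      a <- six[splits[, sp]]
      if (six[1] != a[1]) next  # count each unordered split once
      b <- setdiff(six, a)
      if (triplet_ok(a) && triplet_ok(b)) {
        best_score <- mean_c
        best <- list(ids = six, triplets = list(a, b), axis = axis,
                     score = mean_c)
        break
      }
    }
  }
  if (is.null(best))
    stop("no 6-subset of correlated tracks forms two collinear triplets ",
         "along the dominant axis; seed the identification manually")
  best
}

#' Build the worm body coordinate frame from the seed six
#'
#' The anterior axis is the dominant principal axis of all positions, signed
#' to agree with the user-supplied head direction. The dorsal axis is the
#' normal of the least-squares plane through the six seed neurons, signed
#' toward the side holding the majority of all neurons, and orthogonalized
#' against the anterior axis. The left axis completes a right-handed
#' (anterior, dorsal, left) frame. The origin is the seed mean; the scale is
#' the mean pairwise distance among the six.
#'
#' @param seed_positions 6 x 3 matrix of seed positions (um).
#' @param head_direction approximate anterior direction (nonzero 3-vector).
#' @param all_positions all track positions (um), used for the dorsal vote.
#' @return a `body_frame` list: `origin`, `axes` (rows anterior/dorsal/
#'   left), `scale`.
#' @export
build_body_frame <- function(seed_positions, head_direction, all_positions) {
  if (sqrt(sum(head_direction^2)) == 0) stop("head_direction must be nonzero")
  anterior <- prcomp(all_positions)$rotation[, 1]
  hd <- unit(head_direction)
  if (abs(sum(anterior * hd)) < cos(80 * pi / 180))
    stop("head_direction is nearly orthogonal to the dominant axis of the ",
         "neuron cloud; please re-specify it")
  if (sum(anterior * hd) < 0) anterior <- -anterior
  ctr <- colMeans(seed_positions)
  q <- sweep(seed_positions, 2, ctr)
  normal <- svd(q)$v[, 3]
  votes <- sweep(all_positions, 2, ctr) %*% normal
  if (sum(votes > 0) < sum(votes < 0)) normal <- -normal
  dorsal <- normal - sum(normal * anterior) * anterior
  dorsal <- unit(dorsal)
  left <- cross3(anterior, dorsal)
  structure(list(origin = ctr,
                 axes = rbind(anterior = anterior, dorsal = dorsal,
                              left = left),
                 scale = pairwise_mean_distance(seed_positions)),
            class = "body_frame")
}

#' Map positions into normalized body-frame coordinates
#'
#' @param frame a `body_frame`.
#' @param positions n x 3 matrix (um).
#' @return n x 3 matrix of normalized `(anterior, dorsal, left)` coordinates.
#' @export
normalize_positions <- function(frame, positions) {
  sweep(positions, 2, frame$origin) %*% t(frame$axes) / frame$scale
}

track_groups <- function(stats, seed_idx, threshold_sds = 1.0) {
  C <- stats$C
  n <- nrow(C)
  hi <- stats$C_mu + threshold_sds * stats$C_sigma
  g <- character(n)
  for (i in seq_len(n)) {
    others <- setdiff(seed_idx, i)
    m <- mean(C[i, others])
    g[i] <- if (m > hi) "backward" else if (m < -hi) "forward" else "other"
  }
  g
}

#' Assign neuron class identities by a linear assignment against the atlas
#'
#' Each track's normalized position is compared with the model atlas; the
#' cost of pairing a track with an atlas neuron is the squared normalized
#' distance plus `lambda_corr` when the track's correlation group (from its
#' mean correlation with the seed six) does not match the atlas neuron's
#' group. The rectangular LAP is solved with the usual `1.05 * cmax`
#' non-link alternative, so surplus tracks stay unassigned. Two
#' deterministic post-passes enforce anatomy that noisy positions cannot:
#' left/right labels must agree with the sign of the left-axis coordinate,
#' and same-group class pairs whose atlas offset is predominantly
#' anteroposterior must keep their anteroposterior order.
#'
#' @param positions tracks x 3 matrix of time-averaged positions (um).
#' @param track_ids track identifiers (row order of `positions`).
#' @param frame `body_frame` from [build_body_frame()].
#' @param stats [correlation_stats()] on the same tracks.
#' @param seed_idx indices of the seed six in `positions`.
#' @param atlas [default_atlas()] table.
#' @param params [ident_params()].
#' @return data frame `(track_id, class_name, cost, group)`; tracks without
#'   a class are listed with `class_name = NA`.
#' @export
assign_identities <- function(positions, track_ids, frame, stats, seed_idx,
                              atlas = default_atlas(),
                              params = ident_params()) {
  if (is.null(seed_idx) || length(seed_idx) != 6)
    stop("seed six must be identified before assignment")
  q <- normalize_positions(frame, positions)
  ap <- as.matrix(atlas[, c("x", "y", "z")])
  n <- nrow(q)
  m <- nrow(ap)
  groups <- track_groups(stats, seed_idx, params$threshold_sds)
  d2 <- outer(rowSums(q^2), rowSums(ap^2), "+") - 2 * q %*% t(ap)
  pen <- outer(groups, atlas$group, FUN = function(a, b) as.numeric(a != b))
  cost <- d2 + params$lambda_corr * pen
  match <- solve_assignment(cost)
  out <- data.frame(track_id = track_ids,
                    class_name = ifelse(is.na(match), NA_character_,
                                        atlas$class_name[match]),
                    cost = ifelse(is.na(match), NA_real_,
                                  cost[cbind(seq_len(n),
                                             ifelse(is.na(match), 1L,
                                                    match))]),
                    group = groups, stringsAsFactors = FALSE)
  out <- enforce_lr_order(out, q, atlas)
  out <- enforce_ap_order(out, q, atlas)
  out
}

# Left/right disambiguation: within each L/R class pair, the track with the
# larger left-axis coordinate takes the L label.
enforce_lr_order <- function(assign, q, atlas) {
  base <- sub("[LR]$", "", atlas$class_name)
  sided <- atlas$side %in% c("L", "R")
  for (b in unique(base[sided])) {
    cl <- paste0(b, "L"); cr <- paste0(b, "R")
    if (!(cl %in% atlas$class_name && cr %in% atlas$class_name)) next
    il <- which(assign$class_name == cl)
    ir <- which(assign$class_name == cr)
    if (length(il) == 1 && length(ir) == 1 && q[il, 3] < q[ir, 3]) {
      assign$class_name[c(il, ir)] <- c(cr, cl)
    }
  }
  assign
}

# Anteroposterior ordering: for same-group, same-side class pairs whose
# atlas offset is dominated by the anterior axis, the observed anterior
# order must match the atlas order.
enforce_ap_order <- function(assign, q, atlas) {
  for (g in unique(atlas$group)) {
    for (s in unique(atlas$side)) {
      cls <- atlas$class_name[atlas$group == g & atlas$side == s]
      if (length(cls) < 2) next
      for (i in seq_along(cls)) for (j in seq_along(cls)) {
        if (i >= j) next
        ai <- atlas[atlas$class_name == cls[i], c("x", "y", "z")]
        aj <- atlas[atlas$class_name == cls[j], c("x", "y", "z")]
        dd <- abs(as.numeric(ai) - as.numeric(aj))
        if (dd[1] < max(dd[2], dd[3])) next
        ti <- which(assign$class_name == cls[i])
        tj <- which(assign$class_name == cls[j])
        if (length(ti) != 1 || length(tj) != 1) next
        atlas_order <- sign(as.numeric(ai)[1] - as.numeric(aj)[1])
        obs_order <- sign(q[ti, 1] - q[tj, 1])
        if (atlas_order != 0 && obs_order != 0 && atlas_order != obs_order)
          assign$class_name[c(ti, tj)] <- assign$class_name[c(tj, ti)]
      }
    }
  }
  assign
}

#' Correlation neighborhood of one track
#'
#' @param track_id track of interest.
#' @param stats [correlation_stats()].
#' @param threshold_sds threshold in `C_sigma` units.
#' @return list of track-id vectors `correlated`
#'   (`C > C_mu + k C_sigma`) and `anti_correlated`
#'   (`C < -C_mu - k C_sigma`), excluding the track itself.
#' @export
correlation_neighborhood <- function(track_id, stats, threshold_sds = 1.0) {
  i <- match(as.character(track_id), stats$track_ids)
  if (is.na(i)) stop("unknown track id ", track_id)
  v <- stats$C[i, ]
  v[i] <- 0
  hi <- stats$C_mu + threshold_sds * stats$C_sigma
  list(correlated = stats$track_ids[v > hi & seq_along(v) != i],
       anti_correlated = stats$track_ids[v < -hi & seq_along(v) != i])
}

#' Run the whole identification stage
#'
#' Correlation statistics, seed-six search, body-frame construction, and
#' atlas assignment.
#'
#' @param tracks gap-free track table.
#' @param traces frames x tracks matrix (columns named by track id) or a
#'   `trace` list with `n_frames`.
#' @param head_direction approximate anterior direction in the recording's
#'   physical coordinates.
#' @param n_frames total frames (needed when `traces` is a list).
#' @param atlas [default_atlas()].
#' @param params [ident_params()].
#' @return list with `assignments`, `frame`, `stats`, `seed_track_ids`.
#' @export
identify_neurons <- function(tracks, traces, head_direction,
                             n_frames = NULL, atlas = default_atlas(),
                             params = ident_params()) {
  stats <- correlation_stats(traces, n_frames)
  ids <- stats$track_ids
  pos <- t(vapply(ids, function(id) {
    tr <- tracks[tracks$track_id == as.integer(id), c("x", "y", "z")]
    colMeans(as.matrix(tr))
  }, numeric(3)))
  seed <- find_seed_six(pos, stats, params)
  frame <- build_body_frame(pos[seed$ids, , drop = FALSE], head_direction,
                            pos)
  assignments <- assign_identities(pos, as.integer(ids), frame, stats,
                                   seed$ids, atlas, params)
  list(assignments = assignments, frame = frame, stats = stats,
       seed_track_ids = as.integer(ids[seed$ids]))
}
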