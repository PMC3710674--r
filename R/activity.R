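#' Parameters for trajectory-based activity measures
#'
#' @param immobility_speed_cutoff_cm_s Speed below which (strictly) an
#'   animal-frame counts as immobile. Default 0.7 cm/s.
#' @param frame_rate_hz Camera sampling rate; usually taken from
#'   [cage_config()].
#' @param rearing_wall_margin_cm Distance from a wall within which a tall
#'   detection is scored as rearing.
#' @param rearing_aspect_min Minimum bounding-box height/width ratio for a
#'   rearing posture.
#' @param min_track_gap_frames Tracklets are broken when consecutive frames
#'   are more than this many frame periods apart.
#' @param max_match_cm Maximum frame-to-frame displacement accepted when
#'   associating detections into tracklets.
#' @return A list of class `activity_params`.
#' @export
activity_params <- function(immobility_speed_cutoff_cm_s = 0.7,
                            frame_rate_hz = 30,
                            rearing_wall_margin_cm = 1.5,
                            rearing_aspect_min = 1.6,
                            min_track_gap_frames = 3,
                            max_match_cm = 15) {
  if (immobility_speed_cutoff_cm_s <= 0 || rearing_aspect_min <= 0 ||
      frame_rate_hz <= 0)
    stop("cutoff, aspect ratio and frame rate must be positive")
  structure(list(immobility_speed_cutoff_cm_s = immobility_speed_cutoff_cm_s,
                 frame_rate_hz = frame_rate_hz,
                 rearing_wall_margin_cm = rearing_wall_margin_cm,
                 rearing_aspect_min = rearing_aspect_min,
                 min_track_gap_frames = min_track_gap_frames,
                 max_match_cm = max_match_cm),
            class = "activity_params")
}

# optimal 1-1 assignment between two small point sets (brute force over
# permutations up to 6x6, greedy beyond); returns integer vector over rows of
# `cur`: index into `prev` or NA
match_detections <- function(prev, cur, max_dist = Inf) {
  np <- nrow(prev); nc <- nrow(cur)
  if (!np || !nc) return(rep(NA_integer_, nc))
  d <- outer(seq_len(nc), seq_len(np), function(i, j)
    sqrt((cur$x_cm[i] - prev$x_cm[j])^2 + (cur$y_cm[i] - prev$y_cm[j])^2))
  d[d > max_dist] <- Inf
  assn <- rep(NA_integer_, nc)
  if (min(np, nc) <= 6 && max(np, nc) <= 6) {
    # exhaustive: assign the smaller side into the larger
    if (nc <= np) {
      perms <- permutations_of(np, nc)
      costs <- apply(perms, 1, function(p)
        sum(d[cbind(seq_len(nc), p)]))
      best <- perms[which.min(costs), ]
      ok <- is.finite(d[cbind(seq_len(nc), best)])
      assn[ok] <- best[ok]
    } else {
      perms <- permutations_of(nc, np)
      costs <- apply(perms, 1, function(p)
        sum(d[cbind(p, seq_len(np))]))
      best <- perms[which.min(costs), ]
      ok <- is.finite(d[cbind(best, seq_len(np))])
      assn[best[ok]] <- seq_len(np)[ok]
    }
  } else {
    repeat {
      if (all(!is.finite(d))) break
      ij <- arrayInd(which.min(d), dim(d))
      assn[ij[1]] <- ij[2]
      d[ij[1], ] <- Inf
      d[, ij[2]] <- Inf
    }
  }
  assn
}

# all ordered selections of k items from n (n!/(n-k)! rows)
permutations_of <- function(n, k) {
  if (k == 0) return(matrix(integer(), 1, 0))
  out <- matrix(seq_len(n), ncol = 1)
  for (j in seq_len(k - 1)) {
    out <- do.call(rbind, lapply(seq_len(nrow(out)), function(i) {
      rest <- setdiff(seq_len(n), out[i, ])
      cbind(matrix(out[i, ], length(rest), j, byrow = TRUE), rest)
    }))
  }
  unname(out)
}

#' Link per-frame detections into anonymous tracklets
#'
#' Nearest-neighbour frame-to-frame association of anonymous detections
#' into short tracklets. No global identity is claimed: tracklets break at
#' occlusions (a missing frame gap longer than `min_track_gap_frames` frame
#' periods), at corner entries (the detection disappears), and whenever no
#' association within `max_match_cm` exists.
#'
#' @param frames Data frame with columns `t`, `x_cm`, `y_cm`, `box_w_cm`,
#'   `box_h_cm` (one row per detection; rows sharing `t` are one frame).
#' @param params An [activity_params()].
#' @return The `frames` data frame with an integer `track_id` column,
#'   ordered by `t`.
#' @export
link_tracks <- function(frames, params = activity_params()) {
  frames <- frames[order(frames$t), , drop = FALSE]
  if (!nrow(frames)) {
    frames$track_id <- integer()
    return(frames)
  }
  ts <- unique(frames$t)
  idx <- split(seq_len(nrow(frames)), match(frames$t, ts))
  track_id <- integer(nrow(frames))
  next_id <- 1L
  gap_s <- params$min_track_gap_frames / params$frame_rate_hz
  prev_rows <- integer()
  prev_t <- -Inf
  for (fi in seq_along(ts)) {
    rows <- idx[[fi]]
    if (length(prev_rows) && (ts[fi] - prev_t) <= gap_s + 1e-9) {
      assn <- match_detections(frames[prev_rows, , drop = FALSE],
                               frames[rows, , drop = FALSE],
                               params$max_match_cm)
      for (k in seq_along(rows)) {
        if (!is.na(assn[k])) {
          track_id[rows[k]] <- track_id[prev_rows[assn[k]]]
        } else {
          track_id[rows[k]] <- next_id
          next_id <- next_id + 1L
        }
      }
    } else {
      for (k in seq_along(rows)) {
        track_id[rows[k]] <- next_id
        next_id <- next_id + 1L
      }
    }
    prev_rows <- rows
    prev_t <- ts[fi]
  }
  frames$track_id <- track_id
  frames
}

#' Per-mouse locomotion by light phase
#'
#' Distance travelled, normalised by the number of mice detected in each
#' frame: for every pair of consecutive frames the matched frame-to-frame
#' displacements are summed and divided by the number of detections in the
#' (later) frame, then accumulated within each light phase. A cage with two
#' mice each travelling 100 cm therefore reports 100 cm, and adding a
#' perfectly stationary mouse halves the per-mouse figure of a one-mouse
#' scene. Frames with zero detections contribute nothing.
#'
#' @inheritParams link_tracks
#' @param schedule A [light_schedule()].
#' @param session_start_clock Session start clock time (h).
#' @return Named numeric vector `c(light = , dark = )`, cm per mouse.
#' @export
compute_locomotion <- function(frames, schedule = light_schedule(),
                               session_start_clock = schedule$lights_on_clock,
                               params = activity_params()) {
  out <- c(light = 0, dark = 0)
  if (!nrow(frames)) return(out)
  frames <- frames[order(frames$t), , drop = FALSE]
  ts <- unique(frames$t)
  idx <- split(seq_len(nrow(frames)), match(frames$t, ts))
  gap_s <- params$min_track_gap_frames / params$frame_rate_hz
  for (fi in seq_along(ts)[-1]) {
    if ((ts[fi] - ts[fi - 1]) > gap_s + 1e-9) next
    prev <- frames[idx[[fi - 1]], , drop = FALSE]
    cur <- frames[idx[[fi]], , drop = FALSE]
    assn <- match_detections(prev, cur, params$max_match_cm)
    ok <- which(!is.na(assn))
    if (!length(ok)) next
    disp <- sqrt((cur$x_cm[ok] - prev$x_cm[assn[ok]])^2 +
                   (cur$y_cm[ok] - prev$y_cm[assn[ok]])^2)
    ph <- phase_of(ts[fi], schedule, session_start_clock)
    out[ph] <- out[ph] + sum(disp) / nrow(cur)
  }
  out
}

#' Percent time immobile by light phase
#'
#' Instantaneous speed is the displacement between consecutive tracklet
#' frames divided by the elapsed time; an animal-frame counts as immobile
#' when its speed is strictly below the cutoff (0.7 cm/s by default, so a
#' track moving at exactly 0.7 cm/s is not immobile). The percentage is
#' taken over all animal-frames with a computable speed in each phase.
#'
#' @param tracklets Output of [link_tracks()] (frames with `track_id`).
#' @param params An [activity_params()].
#' @inheritParams compute_locomotion
#' @return Named numeric vector `c(light = , dark = )`, percent; `NA` for a
#'   phase with no scorable animal-frames.
#' @export
compute_immobility <- function(tracklets, params = activity_params(),
                               schedule = light_schedule(),
                               session_start_clock =
                                 schedule$lights_on_clock) {
  res <- list(light = logical(), dark = logical())
  if (nrow(tracklets)) {
    for (tr in split(seq_len(nrow(tracklets)), tracklets$track_id)) {
      if (length(tr) < 2) next
      sub <- tracklets[tr, , drop = FALSE]
      sub <- sub[order(sub$t), , drop = FALSE]
      dt <- diff(sub$t)
      sp <- sqrt(diff(sub$x_cm)^2 + diff(sub$y_cm)^2) / dt
      ph <- phase_of(sub$t[-1], schedule, session_start_clock)
      # strict cutoff with a small absolute guard against float jitter in
      # displacement/dt, so a track at exactly the cutoff is never immobile
      for (p in c("light", "dark"))
        res[[p]] <- c(res[[p]],
                      sp[ph == p] <
                        params$immobility_speed_cutoff_cm_s - 1e-9)
    }
  }
  pct <- function(x) if (length(x)) 100 * mean(x) else NA_real_
  c(light = pct(res$light), dark = pct(res$dark))
}

#' Percent time rearing or climbing by light phase
#'
#' A detection scores as climbing when its centroid lies inside any
#' configured climb zone, and as rearing when its centroid is within
#' `rearing_wall_margin_cm` of a cage wall and its bounding-box aspect
#' (height/width) is at least `rearing_aspect_min` (an elongated, foreshortened
#' silhouette seen from above). The two are reported jointly as the
#' percentage of detected animal-frames in either state.
#'
#' @inheritParams link_tracks
#' @param config A [cage_config()] supplying the climb zones and floor size.
#' @inheritParams compute_locomotion
#' @return Named numeric vector `c(light = , dark = )`, percent; `NA` for a
#'   phase with no detections.
#' @export
compute_rearing_climbing <- function(frames, config = cage_config(),
                                     params = activity_params(),
                                     schedule = light_schedule(),
                                     session_start_clock =
                                       schedule$lights_on_clock) {
  if (!length(config$climb_zones))
    warning("no climb zones configured; climbing component is zero")
  if (!nrow(frames)) return(c(light = NA_real_, dark = NA_real_))
  climbing <- rep(FALSE, nrow(frames))
  for (z in config$climb_zones)
    climbing <- climbing | (frames$x_cm >= z[1] & frames$x_cm <= z[3] &
                              frames$y_cm >= z[2] & frames$y_cm <= z[4])
  wall_dist <- pmin(frames$x_cm, frames$y_cm,
                    config$cage_width_cm - frames$x_cm,
                    config$cage_height_cm - frames$y_cm)
  rearing <- wall_dist <= params$rearing_wall_margin_cm &
    (frames$box_h_cm / frames$box_w_cm) >= params$rearing_aspect_min
  flag <- climbing | rearing
  ph <- phase_of(frames$t, schedule, session_start_clock)
  pct <- function(x) if (length(x)) 100 * mean(x) else NA_real_
  c(light = pct(flag[ph == "light"]), dark = pct(flag[ph == "dark"]))
}

#' Build the cage-level activity table
#'
#' Computes the three trajectory endpoints (per-mouse locomotion, percent
#' time immobile, percent time rearing/climbing) from a detection table,
#' pooled across the cage's animals (identities are not tracked) and binned
#' by light phase.
#'
#' @inheritParams compute_rearing_climbing
#' @param session_label Label stored in the output.
#' @return Data frame of class `activity_table` with one row per light
#'   phase.
#' @export
build_activity_table <- function(frames, config = cage_config(),
                                 params = activity_params(
                                   frame_rate_hz = config$frame_rate_hz),
                                 schedule = light_schedule(),
                                 session_start_clock =
                                   schedule$lights_on_clock,
                                 session_label = "session") {
  loco <- compute_locomotion(frames, schedule, session_start_clock, params)
  immo <- compute_immobility(link_tracks(frames, params), params, schedule,
                             session_start_clock)
  rc <- compute_rearing_climbing(frames, config, params, schedule,
                                 session_start_clock)
  out <- data.frame(cage_id = config$cage_id, session_label = session_label,
                    light_phase = c("light", "dark"),
                    locomotion_cm_per_mouse = as.numeric(loco),
                    pct_time_immobile = as.numeric(immo),
                    pct_time_rearing_climbing = as.numeric(rc),
                    stringsAsFactors = FALSE)
  class(out) <- c("activity_table", "data.frame")
  out
}
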