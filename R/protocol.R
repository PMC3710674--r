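#' Initialise per-animal protocol state
#'
#' Every animal starts in the first segment of the plan. During Habituation
#' there is no target corner. Under Alternation (or Reversal) the initial
#' target is *either* active corner: the first visit to any active corner is
#' correct and rewarded, and only then does the strict alternation target
#' become defined.
#'
#' @param config A [cage_config()].
#' @param plan A [session_plan()].
#' @param roster Character vector of animal ids (non-empty, no duplicates).
#' @return Named list of protocol states, one per animal. Each state has
#'   fields `animal_id`, `phase`, `target_corner` (`NA` meaning "either"
#'   during a task phase, or unused during Habituation), `side_map`,
#'   `rewards_granted`, `last_active_corner_exit`, `demoted`.
#' @export
init_protocol <- function(config, plan, roster) {
  if (!length(roster)) stop("empty roster")
  if (anyDuplicated(roster)) stop("duplicate animal id in roster")
  if (!nrow(plan)) stop("empty session plan")
  states <- lapply(roster, function(a) {
    st <- list(animal_id = a, phase = plan$phase[1],
               target_corner = NA_character_,
               side_map = segment_side_map(config, plan, 1L),
               rewards_granted = 0L,
               last_active_corner_exit = NA_real_,
               demoted = FALSE)
    class(st) <- "protocol_state"
    st
  })
  stats::setNames(states, roster)
}

# effective rewarded-side map for a plan segment: the configured map under
# Alternation, its left/right swap under Reversal, toggled once more when the
# segment carries the side_swap flag (task reversed session-on-session)
segment_side_map <- function(config, plan, seg) {
  m <- config$rewarded_side_map
  swapped <- (plan$phase[seg] == "REVERSAL") != isTRUE(plan$side_swap[seg])
  if (swapped) swap_sides(m) else m
}

swap_sides <- function(side_map) {
  out <- ifelse(side_map == "left", "right", "left")
  stats::setNames(out, names(side_map))
}

#' Swap the rewarded nosepoke sides of a protocol state
#'
#' Applies the Reversal manipulation: within each active corner, the rewarded
#' recess switches to the other side (left becomes right and vice versa).
#' The target corner is unchanged. Swapping twice restores the original map.
#'
#' @param state A protocol state from [init_protocol()].
#' @return The updated state.
#' @export
apply_side_swap <- function(state) {
  if (state$phase == "HABITUATION")
    stop("side swap is undefined during HABITUATION")
  state$side_map <- swap_sides(state$side_map)
  state
}

#' Process one corner visit through the reinforcement contingency
#'
#' The core of the task state machine. During Habituation every corner entry
#' opens both water doors for the duration of the visit and nothing else
#' changes. During Alternation/Reversal:
#' \itemize{
#'   \item A visit to the current target corner (or to either active corner
#'     while the target is still undefined) is **correct**. The first
#'     nosepoke on that corner's rewarded side opens the door for
#'     `config$door_open_s` seconds (one reward per visit; later pokes are
#'     inert). The target switches to the other active corner as a
#'     consequence of the correct visit itself, so an immediate return to the
#'     same corner is already incorrect. The side of the very first nosepoke
#'     is recorded as correct/incorrect for efficiency scoring; a wrong-side
#'     first poke carries no penalty.
#'   \item A visit to the non-target active corner is **incorrect**: no
#'     reward, no target change.
#'   \item A visit to an exploratory corner is **exploratory** and leaves the
#'     target unchanged.
#' }
#'
#' @param state A protocol state.
#' @param visit A list or one-row data frame with `corner`, `t_entry`,
#'   `t_exit`.
#' @param pokes Data frame (or list) of the nosepokes within the visit,
#'   with elements `side` and `t`, time-ordered; may be empty.
#' @param config A [cage_config()].
#' @return List with elements `state` (updated), `annotation` (one of
#'   `"habituation"`, `"correct"`, `"incorrect"`, `"exploratory"`), `reward`
#'   (`NULL` or a reward-event list with `corner`, `side`, `t_open`,
#'   `door_open_s`), and `initial_poke` (`"correct"`, `"incorrect"`, or `NA`
#'   when no poke was made or the visit was not correct).
#' @export
process_visit <- function(state, visit, pokes, config) {
  corner <- visit$corner
  if (!(corner %in% config$corner_ids))
    stop("unknown corner label: ", corner)
  active <- config$active_pair
  reward <- NULL
  initial_poke <- NA_character_
  if (state$phase == "HABITUATION") {
    annotation <- "habituation"
  } else if (corner %in% active) {
    if (is.na(state$target_corner) || corner == state$target_corner) {
      annotation <- "correct"
      state$target_corner <- active[active != corner]
      if (length(pokes$side)) {
        rs <- state$side_map[[corner]]
        initial_poke <- if (pokes$side[1] == rs) "correct" else "incorrect"
        hit <- match(rs, pokes$side)
        if (!is.na(hit)) {
          reward <- list(animal_id = state$animal_id, corner = corner,
                         side = rs, t_open = pokes$t[hit],
                         door_open_s = config$door_open_s)
          state$rewards_granted <- state$rewards_granted + 1L
        }
      }
    } else {
      annotation <- "incorrect"
    }
  } else {
    annotation <- "exploratory"
  }
  if (corner %in% active)
    state$last_active_corner_exit <- visit$t_exit
  list(state = state, annotation = annotation, reward = reward,
       initial_poke = initial_poke)
}

#' Demote animals that have stopped licking
#'
#' Scans a trailing window of lick events and switches any task-phase animal
#' with zero licks in that window back to the Habituation protocol (both
#' doors open on every entry), protecting hydration. Demotion is applied per
#' animal via its RFID identity and is sticky: a demoted animal stays on
#' Habituation for the remainder of the plan.
#'
#' @param states Named list of protocol states.
#' @param licks Data frame of lick events (`animal_id`, `t`).
#' @param window_h Trailing window length in hours (> 0).
#' @param now_s Session time (s) at which the check runs; the window is
#'   `(now_s - window_h * 3600, now_s]`.
#' @return List with `states` (updated) and `demoted` (character vector of
#'   ids demoted by this check).
#' @export
demote_nonlickers <- function(states, licks, window_h = 24,
                              now_s = max(c(0, licks$t))) {
  if (window_h <= 0) stop("window_h must be positive")
  lo <- now_s - window_h * 3600
  demoted <- character()
  for (a in names(states)) {
    st <- states[[a]]
    if (st$phase == "HABITUATION") next
    n_licks <- sum(licks$animal_id == a & licks$t > lo & licks$t <= now_s)
    if (n_licks == 0L) {
      st$phase <- "HABITUATION"
      st$demoted <- TRUE
      states[[a]] <- st
      demoted <- c(demoted, a)
    }
  }
  list(states = states, demoted = demoted)
}

#' Replay a full session through the contingency engine
#'
#' Deterministically replays an event stream against a session plan:
#' segment boundaries change each animal's phase (and reset the alternation
#' target to "either active corner"), segments flagged `side_swap` flip the
#' rewarded sides, non-licker demotion checks run on a fixed cadence, and
#' every visit is annotated `correct` / `incorrect` / `exploratory` /
#' `habituation` with its reward outcome. Replay is a pure function of
#' `(stream, plan, config)`: repeated runs are identical.
#'
#' Visits are processed in order of entry time and attributed to the segment
#' containing `t_entry`. Demotion checks at time `T` use only licks with
#' `t <= T` and are applied before any visit entering at or after `T`;
#' demoted animals keep Habituation through later segments.
#'
#' @param stream A validated [event_stream()].
#' @param plan A [session_plan()]; defaults to a single Alternation segment
#'   covering the stream.
#' @param config Defaults to `stream$config`.
#' @param demote_every_h Cadence (h) of non-licker checks; `Inf` disables.
#' @param demote_window_h Trailing lick window (h) for each check.
#' @return Object of class `session_result`: list with `visits` (the visit
#'   table plus `phase`, `annotation`, `initial_poke`, `rewarded`,
#'   `target_after` columns), `rewards` (reward-event table), `states`
#'   (final protocol states), `trace` (control-event log), plus the inputs.
#' @export
run_session <- function(stream, plan = NULL, config = stream$config,
                        demote_every_h = 24, demote_window_h = 24) {
  if (is.null(plan))
    plan <- session_plan("ALTERNATION",
                         max(stream$duration_s, 1) / 3600)
  total_s <- plan_total_s(plan)
  v <- stream$visits
  if (nrow(v) && max(v$t_entry) >= total_s)
    stop("stream contains events beyond the plan's total duration")
  ord <- order(v$t_entry, v$animal_id)
  v <- v[ord, , drop = FALSE]
  states <- init_protocol(config, plan, stream$roster)
  n <- nrow(v)
  annotation <- character(n)
  initial_poke <- rep(NA_character_, n)
  rewarded <- logical(n)
  phase_col <- character(n)
  target_after <- rep(NA_character_, n)
  rewards <- vector("list", n)
  trace <- list()
  push_trace <- function(t, ev, detail)
    trace[[length(trace) + 1L]] <<- data.frame(
      t = t, event = ev, detail = detail, stringsAsFactors = FALSE)
  # control timeline: segment starts (after the first) and demotion checks
  seg_starts <- plan$t_start_h[-1] * 3600
  checks <- if (is.finite(demote_every_h) &&
                demote_every_h * 3600 <= total_s)
    seq(demote_every_h * 3600, total_s, by = demote_every_h * 3600)
  else numeric()
  ctrl <- rbind(
    if (length(checks)) data.frame(t = checks, kind = "demote",
                                   seg = NA_integer_),
    if (length(seg_starts)) data.frame(t = seg_starts, kind = "segment",
                                       seg = seq_len(nrow(plan))[-1])
  )
  if (is.null(ctrl))
    ctrl <- data.frame(t = numeric(), kind = character(), seg = integer())
  # demotion check runs before a segment change at the same instant
  ctrl <- ctrl[order(ctrl$t, ctrl$kind != "demote"), , drop = FALSE]
  ci <- 1L
  apply_ctrl_upto <- function(t) {
    while (ci <= nrow(ctrl) && ctrl$t[ci] <= t) {
      if (ctrl$kind[ci] == "demote") {
        res <- demote_nonlickers(states, stream$licks,
                                 window_h = demote_window_h,
                                 now_s = ctrl$t[ci])
        states <<- res$states
        if (length(res$demoted))
          push_trace(ctrl$t[ci], "demotion",
                     paste(res$demoted, collapse = ","))
      } else {
        seg <- ctrl$seg[ci]
        for (a in names(states)) {
          st <- states[[a]]
          if (!st$demoted) {
            st$phase <- plan$phase[seg]
            st$side_map <- segment_side_map(config, plan, seg)
            st$target_corner <- NA_character_
            states[[a]] <<- st
          }
        }
        push_trace(ctrl$t[ci], "segment_start",
                   paste0(plan$phase[seg],
                          if (plan$side_swap[seg]) "+side_swap" else ""))
      }
      ci <<- ci + 1L
    }
  }
  np <- stream$nosepokes
  np_by_animal <- split(np[c("corner", "side", "t")], np$animal_id)
  for (i in seq_len(n)) {
    apply_ctrl_upto(v$t_entry[i])
    a <- v$animal_id[i]
    npa <- np_by_animal[[a]]
    pk <- list(side = character(), t = numeric())
    if (!is.null(npa)) {
      sel <- npa$corner == v$corner[i] & npa$t >= v$t_entry[i] &
        npa$t <= v$t_exit[i]
      if (any(sel)) {
        o <- order(npa$t[sel])
        pk <- list(side = npa$side[sel][o], t = npa$t[sel][o])
      }
    }
    res <- process_visit(states[[a]],
                         list(corner = v$corner[i], t_entry = v$t_entry[i],
                              t_exit = v$t_exit[i]),
                         pk, config)
    states[[a]] <- res$state
    annotation[i] <- res$annotation
    initial_poke[i] <- res$initial_poke
    phase_col[i] <- res$state$phase
    target_after[i] <- res$state$target_corner
    if (!is.null(res$reward)) {
      rewarded[i] <- TRUE
      rewards[[i]] <- as.data.frame(res$reward, stringsAsFactors = FALSE)
    }
  }
  apply_ctrl_upto(total_s)
  v$phase <- phase_col
  v$annotation <- annotation
  v$initial_poke <- initial_poke
  v$rewarded <- rewarded
  v$target_after <- target_after
  rewards <- if (any(rewarded)) do.call(rbind, rewards[rewarded]) else
    data.frame(animal_id = character(), corner = character(),
               side = character(), t_open = numeric(),
               door_open_s = numeric(), stringsAsFactors = FALSE)
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(t = numeric(), event = character(), detail = character(),
               stringsAsFactors = FALSE)
  structure(list(visits = v, rewards = rewards, states = states,
                 trace = trace, plan = plan, config = config,
                 stream = stream),
            class = "session_result")
}

#' @export
print.session_result <- function(x, ...) {
  tab <- table(x$visits$annotation)
  cat("<session_result>", nrow(x$visits), "visits |",
      paste(names(tab), as.integer(tab), sep = "=", collapse = " "), "\n")
  cat("  rewards granted:", nrow(x$rewards), "\n")
  invisible(x)
}
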