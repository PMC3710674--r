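split_by_animal <- function(df) {
  if (!nrow(df)) return(list())
  if (is.null(df$animal_id)) return(list(all = df))
  split(df, df$animal_id)
}

phase_of <- function(t, schedule, session_start_clock)
  assign_light_phase(t, session_start_clock, schedule)

#' Corner-entry rate by light phase
#'
#' Counts corner visits per hour of light-phase and dark-phase exposure. A
#' visit belongs to the phase containing its entry time (visits spanning the
#' boundary are not split). Exposure is the actual time spent in each phase
#' over the session, so sessions whose length is not a multiple of 24 h are
#' normalised correctly.
#'
#' @param visits Visit data frame (`t_entry`, ...), one animal or a pooled
#'   cage.
#' @param schedule A [light_schedule()].
#' @param session_start_clock Session start clock time (h).
#' @param duration_s Session duration (s).
#' @return Named numeric vector `c(light = , dark = )`, entries per hour;
#'   `NA` for a phase with zero exposure.
#' @export
score_corner_entries <- function(visits, schedule, session_start_clock,
                                 duration_s) {
  expo <- phase_exposure_hours(session_start_clock, schedule, duration_s)
  ph <- phase_of(visits$t_entry, schedule, session_start_clock)
  counts <- c(light = sum(ph == "light"), dark = sum(ph == "dark"))
  out <- ifelse(expo > 0, counts / expo, NA_real_)
  stats::setNames(out, c("light", "dark"))
}

#' Lick rate by light phase
#'
#' Total lick count per hour of exposure in each light phase, attributing
#' each lick event to the phase containing its timestamp.
#'
#' @param licks Lick data frame (`t`, `lick_count`).
#' @inheritParams score_corner_entries
#' @return Named numeric vector `c(light = , dark = )`, licks per hour.
#' @export
score_licks <- function(licks, schedule, session_start_clock, duration_s) {
  expo <- phase_exposure_hours(session_start_clock, schedule, duration_s)
  ph <- phase_of(licks$t, schedule, session_start_clock)
  counts <- c(light = sum(licks$lick_count[ph == "light"]),
              dark = sum(licks$lick_count[ph == "dark"]))
  out <- ifelse(expo > 0, counts / expo, NA_real_)
  stats::setNames(out, c("light", "dark"))
}

# per-animal consecutive-visit transitions; returns data frame with columns
# t (entry time of the later visit), repeat_ (same corner)
visit_transitions <- function(visits) {
  parts <- split_by_animal(visits)
  if (!length(parts))
    return(data.frame(t = numeric(), repeat_ = logical()))
  out <- lapply(parts, function(va) {
    va <- va[order(va$t_entry), , drop = FALSE]
    k <- nrow(va)
    if (k < 2)
      return(data.frame(t = numeric(), repeat_ = logical()))
    data.frame(t = va$t_entry[-1],
               repeat_ = va$corner[-1] == va$corner[-k])
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Repeat-visit percentage
#'
#' The perseveration measure: the percentage of consecutive-visit
#' transitions (over all four corners, per animal) in which the animal
#' returns to the corner it just left. The denominator is the number of
#' transitions; with fewer than two visits the measure is undefined (`NA`).
#'
#' When a schedule is supplied the transitions are split by light phase
#' (phase of the later visit's entry time) and a value per phase is
#' returned.
#'
#' @param visits Visit data frame (may contain several animals; transitions
#'   never cross animals).
#' @param schedule Optional [light_schedule()] for a per-phase breakdown.
#' @param session_start_clock Required with `schedule`.
#' @return A percentage in `[0, 100]`, or a named vector per phase.
#' @examples
#' v <- data.frame(animal_id = "m1", corner = c("C1", "C1", "C2", "C2", "C3"),
#'                 t_entry = 1:5 * 10, t_exit = 1:5 * 10 + 5)
#' score_repeats(v)   # 50: 2 of 4 transitions repeat
#' @export
score_repeats <- function(visits, schedule = NULL,
                          session_start_clock = NULL) {
  tr <- visit_transitions(visits)
  pct <- function(x) if (length(x)) 100 * mean(x) else NA_real_
  if (is.null(schedule)) return(pct(tr$repeat_))
  ph <- phase_of(tr$t, schedule, session_start_clock)
  c(light = pct(tr$repeat_[ph == "light"]),
    dark = pct(tr$repeat_[ph == "dark"]))
}

# per-animal active-corner transition table: for each consecutive pair of
# active-corner visits, the gap since leaving the previous one, whether the
# corner switched, and the later visit's entry time
active_transitions <- function(visits, active_pair) {
  parts <- split_by_animal(visits)
  if (!length(parts))
    return(data.frame(t = numeric(), gap = numeric(),
                      alternated = logical()))
  out <- lapply(parts, function(va) {
    va <- va[va$corner %in% active_pair, , drop = FALSE]
    va <- va[order(va$t_entry), , drop = FALSE]
    k <- nrow(va)
    if (k < 2)
      return(data.frame(t = numeric(), gap = numeric(),
                        alternated = logical()))
    data.frame(t = va$t_entry[-1],
               gap = va$t_entry[-1] - va$t_exit[-k],
               alternated = va$corner[-1] != va$corner[-k])
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Percent alternation
#'
#' The primary task measure. Consider, per animal, each transition from an
#' active-corner visit to that animal's next active-corner visit;
#' intervening exploratory-corner visits are irrelevant. A transition counts
#' as an alternation when the animal switches to the other active corner.
#' Transitions whose gap (next entry time minus previous exit time) exceeds
#' `window_s` are dropped from both numerator and denominator, keeping the
#' statistic a proper proportion over scorable transitions; set
#' `denominator = "all"` to keep window-excluded transitions in the
#' denominator instead.
#'
#' @param visits Visit data frame; restrict to task-phase visits before
#'   calling if the animal changed protocol mid-session.
#' @param active_pair The two active corner labels.
#' @param window_s Scoring window in seconds (default 113).
#' @param denominator `"included"` (default) or `"all"`.
#' @param schedule Optional [light_schedule()] for a per-phase breakdown
#'   (phase of the later visit's entry).
#' @param session_start_clock Required with `schedule`.
#' @return Percentage in `[0, 100]`; `NA` when no transition is scorable.
#' @examples
#' v <- data.frame(animal_id = "m1",
#'                 corner = c("C1", "C3", "C2", "C2", "C1"),
#'                 t_entry = c(0, 15, 30, 50, 200),
#'                 t_exit = c(10, 18, 40, 60, 210))
#' score_alternation(v, c("C1", "C2"))          # 50
#' score_alternation(v, c("C1", "C2"), Inf)     # 66.7
#' @export
score_alternation <- function(visits, active_pair, window_s = 113,
                              denominator = c("included", "all"),
                              schedule = NULL, session_start_clock = NULL) {
  if (window_s <= 0) stop("window_s must be positive")
  denominator <- match.arg(denominator)
  tr <- active_transitions(visits, active_pair)
  pct <- function(idx) {
    inc <- tr$gap[idx] <= window_s
    num <- sum(tr$alternated[idx] & inc)
    den <- if (denominator == "included") sum(inc) else length(idx)
    if (den == 0) NA_real_ else 100 * num / den
  }
  if (is.null(schedule)) return(pct(seq_len(nrow(tr))))
  ph <- phase_of(tr$t, schedule, session_start_clock)
  c(light = pct(which(ph == "light")), dark = pct(which(ph == "dark")))
}

#' Collected-reward percentage
#'
#' Reward-collection efficiency: the percentage of active-corner visits that
#' contain at least one nosepoke (on either side). Exploratory-corner visits
#' enter neither numerator nor denominator.
#'
#' @param visits Visit data frame.
#' @param nosepokes Nosepoke data frame (`animal_id`, `corner`, `t`).
#' @inheritParams score_alternation
#' @return Percentage in `[0, 100]`; `NA` with zero active-corner visits.
#' @export
score_collected_rewards <- function(visits, nosepokes, active_pair,
                                    schedule = NULL,
                                    session_start_clock = NULL) {
  av <- visits[visits$corner %in% active_pair, , drop = FALSE]
  if (!nrow(av)) {
    if (is.null(schedule)) return(NA_real_)
    return(c(light = NA_real_, dark = NA_real_))
  }
  poked <- vapply(seq_len(nrow(av)), function(i)
    any(nosepokes$animal_id == av$animal_id[i] &
          nosepokes$corner == av$corner[i] &
          nosepokes$t >= av$t_entry[i] & nosepokes$t <= av$t_exit[i]),
    logical(1))
  pct <- function(x) if (length(x)) 100 * mean(x) else NA_real_
  if (is.null(schedule)) return(pct(poked))
  ph <- phase_of(av$t_entry, schedule, session_start_clock)
  c(light = pct(poked[ph == "light"]), dark = pct(poked[ph == "dark"]))
}

#' Build the per-animal score table
#'
#' Computes the five behavioral measures from an annotated session
#' (see [run_session()]), one row per animal and light phase: corner entries
#' per hour, licks per hour, repeat percentage, percent alternation, and
#' collected-reward percentage. Alternation and collected rewards are
#' computed only from visits made while the animal was on a task phase
#' (Alternation/Reversal), so an animal demoted to Habituation mid-session
#' is scored on its task-phase visits only. Undefined measures (zero
#' denominator) are `NA`, never 0 or 100.
#'
#' @param session A `session_result` from [run_session()].
#' @param session_label Label stored in the `session_label` column.
#' @param window_s Alternation window (s), default 113.
#' @param repeats_scope `"all"` (default: repeats over all phases) or
#'   `"habituation"` (Habituation-phase visits only).
#' @param alt_denominator Passed to [score_alternation()].
#' @param pool_cage If `TRUE`, return one row per light phase for the whole
#'   cage (events pooled across animals; transitions still never cross
#'   animals), keyed by `cage_id`.
#' @return Data frame of class `score_table`.
#' @export
build_score_table <- function(session, session_label = "session",
                              window_s = 113,
                              repeats_scope = c("all", "habituation"),
                              alt_denominator = "included",
                              pool_cage = FALSE) {
  repeats_scope <- match.arg(repeats_scope)
  stream <- session$stream
  cfg <- session$config
  sch <- stream$schedule
  start <- stream$session_start_clock
  dur <- plan_total_s(session$plan)
  v <- session$visits
  units <- if (pool_cage) stats::setNames(list(stream$roster), cfg$cage_id)
  else stats::setNames(as.list(stream$roster), stream$roster)
  rows <- lapply(names(units), function(id) {
    ids <- units[[id]]
    va <- v[v$animal_id %in% ids, , drop = FALSE]
    la <- stream$licks[stream$licks$animal_id %in% ids, , drop = FALSE]
    vr <- if (repeats_scope == "habituation")
      va[va$phase == "HABITUATION", , drop = FALSE] else va
    vt <- va[va$phase %in% c("ALTERNATION", "REVERSAL"), , drop = FALSE]
    ce <- score_corner_entries(va, sch, start, dur)
    lk <- score_licks(la, sch, start, dur)
    rp <- score_repeats(vr, sch, start)
    al <- score_alternation(vt, cfg$active_pair, window_s,
                            alt_denominator, sch, start)
    cr <- score_collected_rewards(vt, stream$nosepokes, cfg$active_pair,
                                  sch, start)
    data.frame(animal_id = id, session_label = session_label,
               light_phase = c("light", "dark"),
               corner_entries = as.numeric(ce),
               lick_count = as.numeric(lk),
               repeat_pct = as.numeric(rp),
               alternation_pct = as.numeric(al),
               collected_rewards_pct = as.numeric(cr),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("score_table", "data.frame")
  out
}
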