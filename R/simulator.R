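#' Per-animal behavioral parameters for the simulator
#'
#' Parameterises one simulated mouse. Corner visits follow an inhomogeneous
#' Poisson process whose rate is `visit_rate_per_h` during the light phase
#' and `visit_rate_per_h * dark_activity_multiplier` during the dark phase
#' (a square wave locked to the light schedule). At each visit the corner is
#' chosen by a mixture: with probability `alternation_competence` (task
#' phases only) the currently correct corner; otherwise with probability
#' `perseveration_bias` the previously visited corner; otherwise uniformly
#' among the four corners.
#'
#' @param visit_rate_per_h Light-phase corner-visit hazard (visits/h).
#' @param dark_activity_multiplier Dark:light rate ratio (> 0).
#' @param perseveration_bias Probability mass added to re-choosing the
#'   previous corner.
#' @param alternation_competence Probability of choosing the currently
#'   correct corner while on a task phase. `alternation_competence +
#'   perseveration_bias` must not exceed 1.
#' @param lick_rate_per_reward Mean licks per door opening (Poisson).
#' @param lick_rate_multiplier_dark Multiplier on the lick mean in the dark.
#' @param poke_side_accuracy Probability the first nosepoke of a visit is on
#'   the rewarded side.
#' @param nosepoke_prob Probability of nosepoking at all during a visit.
#' @param mean_speed_cm_s Mean movement speed while in the moving state.
#' @param immobile_fraction Long-run fraction of arena time spent immobile.
#' @param climb_rate_per_h Hazard of climb-zone excursions (per h).
#' @param nonlicker_prob Probability the animal stops licking for the whole
#'   session (models mice unable to maintain licking on the task).
#' @return A list of class `genotype_params`.
#' @export
genotype_params <- function(visit_rate_per_h = 3,
                            dark_activity_multiplier = 2,
                            perseveration_bias = 0.05,
                            alternation_competence = 0.75,
                            lick_rate_per_reward = 25,
                            lick_rate_multiplier_dark = 1.3,
                            poke_side_accuracy = 0.75,
                            nosepoke_prob = 0.9,
                            mean_speed_cm_s = 6,
                            immobile_fraction = 0.35,
                            climb_rate_per_h = 3,
                            nonlicker_prob = 0) {
  p <- list(visit_rate_per_h = visit_rate_per_h,
            dark_activity_multiplier = dark_activity_multiplier,
            perseveration_bias = perseveration_bias,
            alternation_competence = alternation_competence,
            lick_rate_per_reward = lick_rate_per_reward,
            lick_rate_multiplier_dark = lick_rate_multiplier_dark,
            poke_side_accuracy = poke_side_accuracy,
            nosepoke_prob = nosepoke_prob,
            mean_speed_cm_s = mean_speed_cm_s,
            immobile_fraction = immobile_fraction,
            climb_rate_per_h = climb_rate_per_h,
            nonlicker_prob = nonlicker_prob)
  probs <- c("perseveration_bias", "alternation_competence",
             "poke_side_accuracy", "nosepoke_prob", "immobile_fraction",
             "nonlicker_prob")
  for (nm in probs)
    if (p[[nm]] < 0 || p[[nm]] > 1) stop(nm, " must be in [0, 1]")
  if (p$alternation_competence + p$perseveration_bias > 1)
    stop("alternation_competence + perseveration_bias must not exceed 1")
  if (visit_rate_per_h < 0 || lick_rate_per_reward < 0 ||
      climb_rate_per_h < 0 || mean_speed_cm_s < 0)
    stop("rates must be non-negative")
  if (dark_activity_multiplier <= 0)
    stop("dark_activity_multiplier must be positive")
  structure(p, class = "genotype_params")
}

#' Preset cohorts with genotype-typical parameter profiles
#'
#' Documented parameter sets reproducing the *direction* (not the magnitude)
#' of the classical genotype contrasts in home-cage operant phenotyping of
#' HD models, relative to the wild-type-like reference:
#' \describe{
#'   \item{WT_like}{reference profile.}
#'   \item{R6/2_like}{same corner-entry rate as WT; strongly elevated
#'     perseveration and reduced alternation competence; increased dark-phase
#'     licking; slower, more immobile, less climbing; a substantial chance of
#'     becoming a non-licker on the task.}
#'   \item{BACHD_like}{reduced corner-entry rate (hypoactive), elevated
#'     licking, raised nosepoke propensity (higher collected-reward
#'     efficiency), moderately elevated perseveration, slower and more
#'     immobile.}
#' }
#'
#' @param name `"WT_like"`, `"R6/2_like"` (alias `"R62_like"`), or
#'   `"BACHD_like"`.
#' @param n Number of animals.
#' @param prefix Id prefix; defaults to a name derived from the preset.
#' @return Named list of [genotype_params()], one per animal.
#' @export
preset_cohort <- function(name, n = 11, prefix = NULL) {
  key <- gsub("[/]", "", name)
  pars <- switch(key,
    WT_like = genotype_params(),
    R62_like = genotype_params(
      perseveration_bias = 0.30, alternation_competence = 0.45,
      lick_rate_multiplier_dark = 2.0, mean_speed_cm_s = 4.5,
      immobile_fraction = 0.50, climb_rate_per_h = 1.2,
      nonlicker_prob = 0.25),
    BACHD_like = genotype_params(
      visit_rate_per_h = 1.8, perseveration_bias = 0.18,
      alternation_competence = 0.55, lick_rate_per_reward = 33,
      nosepoke_prob = 0.97, mean_speed_cm_s = 3.5,
      immobile_fraction = 0.55, climb_rate_per_h = 1.2,
      nonlicker_prob = 0.03),
    stop("unknown preset: ", name))
  if (is.null(prefix)) prefix <- sub("_like$", "", key)
  ids <- sprintf("%s_%02d", prefix, seq_len(n))
  stats::setNames(rep(list(pars), n), ids)
}

# piecewise-constant visit-hazard candidate times over [0, total_s]
draw_candidate_times <- function(p, schedule, session_start_clock, total_s) {
  dur_h <- total_s / 3600
  offset <- (session_start_clock - schedule$lights_on_clock) %% 24
  k <- seq(-1, ceiling(dur_h / 24) + 1)
  brk <- c(k * 24 - offset, k * 24 - offset + schedule$light_hours)
  brk <- sort(unique(c(0, brk[brk > 0 & brk < dur_h], dur_h)))
  if (length(brk) < 2) return(numeric())
  out <- numeric()
  for (i in seq_len(length(brk) - 1)) {
    len_h <- brk[i + 1] - brk[i]
    ph <- assign_light_phase((brk[i] + len_h / 2) * 3600,
                             session_start_clock, schedule)
    rate <- p$visit_rate_per_h *
      if (ph == "dark") p$dark_activity_multiplier else 1
    nk <- stats::rpois(1, rate * len_h)
    if (nk > 0)
      out <- c(out, stats::runif(nk, brk[i], brk[i + 1]) * 3600)
  }
  sort(out)
}

#' Simulate a group-housed cohort
#'
#' Agent-based generation of one cage-session: per-animal corner visits from
#' circadian-modulated Poisson processes, corner choice by the
#' competence/perseveration/uniform mixture, nosepokes and reward-gated lick
#' bouts, with the reinforcement contingency applied through the protocol
#' engine *during* generation so that ground-truth annotations are logged.
#' Optionally synthesises overhead-camera detection tables for the activity
#' measures.
#'
#' Corner chambers hold one mouse: a mouse arriving at an occupied corner
#' waits for it to free (up to `conflict_timeout_s`, the deferred entry
#' keeping its slot in the time-ordered event queue), else picks uniformly
#' among free corners, else skips the visit. Everything is driven by `seed`;
#' per-animal substreams are derived from it so a fixed seed reproduces the
#' output exactly.
#'
#' @param roster_params Named list of [genotype_params()], e.g. from
#'   [preset_cohort()]; names are the animal ids.
#' @param config A [cage_config()].
#' @param schedule A [light_schedule()].
#' @param plan A [session_plan()].
#' @param seed Integer seed.
#' @param session_start_clock Session start clock time (h); defaults to
#'   lights-on.
#' @param conflict_timeout_s Maximum corner-occupancy wait (s).
#' @param demote_every_h,demote_window_h Non-licker check cadence and
#'   window, as in [run_session()].
#' @param visit_median_s,visit_sdlog Log-normal visit-duration parameters.
#' @param frames If `TRUE`, also synthesise a detection table.
#' @param frames_window_s Length-2 numeric, the session time window (s) over
#'   which frames are generated (defaults to the first 20 min).
#' @param frame_rate_hz Frame rate for the synthesised detections.
#' @return A list of class `sim_cohort` with elements `stream` (an
#'   [event_stream()]), `annotations` (ground-truth annotated visit table,
#'   the same columns [run_session()] produces), `rewards`, `nonlickers`
#'   (ids simulated as non-lickers), and when requested `frames_truth`
#'   (per-detection ground-truth states aligned with `stream$frames`).
#' @export
simulate_cohort <- function(roster_params, config = cage_config(),
                            schedule = light_schedule(),
                            plan = session_plan("ALTERNATION", 30),
                            seed = 1,
                            session_start_clock = schedule$lights_on_clock,
                            conflict_timeout_s = 30,
                            demote_every_h = 24, demote_window_h = 24,
                            visit_median_s = 15, visit_sdlog = 0.5,
                            frames = FALSE, frames_window_s = NULL,
                            frame_rate_hz = 5) {
  roster <- names(roster_params)
  if (is.null(roster) || anyDuplicated(roster))
    stop("roster_params must be a named list with unique animal ids")
  n_anim <- length(roster)
  total_s <- plan_total_s(plan)
  set.seed(as.integer(seed))
  animal_seeds <- sample.int(.Machine$integer.max - 1L, n_anim + 1L)
  # per-animal pre-drawn randomness: candidate times plus one draw of each
  # kind per candidate, so the interleaved sequential pass needs no RNG
  cand <- vector("list", n_anim)
  nonlicker <- logical(n_anim)
  for (i in seq_len(n_anim)) {
    p <- roster_params[[i]]
    set.seed(animal_seeds[i])
    nonlicker[i] <- stats::runif(1) < p$nonlicker_prob
    tt <- draw_candidate_times(p, schedule, session_start_clock, total_s)
    m <- length(tt)
    cand[[i]] <- list(
      t = tt,
      u_choice = stats::runif(m), u_pick = stats::runif(m),
      dur = stats::rlnorm(m, log(visit_median_s), visit_sdlog),
      u_poke = stats::runif(m), u_side = stats::runif(m),
      u_lick = stats::runif(m), u_redraw = stats::runif(m))
  }
  if (all(vapply(cand, function(x) length(x$t), 0L) == 0))
    warning("visit process produced no events; downstream measures will ",
            "be undefined")
  # global candidate queue, entry-time ordered
  qa <- rep(seq_len(n_anim),
            vapply(cand, function(x) length(x$t), 0L))
  qj <- unlist(lapply(cand, function(x) seq_along(x$t)))
  qt <- unlist(lapply(cand, function(x) x$t))
  ord <- order(qt)
  qa <- qa[ord]; qj <- qj[ord]; qt <- qt[ord]
  nq <- length(qt)
  # engine state
  states <- init_protocol(config, plan, roster)
  corner_free <- stats::setNames(rep(0, 4), config$corner_ids)
  animal_free <- rep(0, n_anim)
  prev_corner <- rep(NA_character_, n_anim)
  # output accumulators (preallocated)
  cap <- nq + 16L
  out <- list(a = integer(cap), corner = character(cap),
              t_entry = numeric(cap), t_exit = numeric(cap),
              phase = character(cap), annotation = character(cap),
              initial_poke = rep(NA_character_, cap),
              rewarded = logical(cap), target_after = rep(NA_character_, cap))
  nv <- 0L
  pk_a <- character(); pk_corner <- character(); pk_side <- character()
  pk_t <- numeric()
  lk_aid <- character(); lk_corner <- character(); lk_t2 <- numeric()
  lk_count <- integer()
  rw_a <- character(); rw_corner <- character(); rw_side <- character()
  rw_t <- numeric(); rw_dur <- numeric()
  # control timeline mirrors run_session: demotion checks run before a
  # segment change at the same instant; both apply before any visit whose
  # entry is at or after the control time
  seg_starts <- plan$t_start_h[-1] * 3600
  checks <- if (is.finite(demote_every_h) &&
                demote_every_h * 3600 <= total_s)
    seq(demote_every_h * 3600, total_s, by = demote_every_h * 3600)
  else numeric()
  ctrl <- rbind(
    if (length(checks)) data.frame(t = checks, kind = "demote",
                                   seg = NA_integer_),
    if (length(seg_starts)) data.frame(t = seg_starts, kind = "segment",
                                       seg = seq_len(nrow(plan))[-1]))
  if (is.null(ctrl))
    ctrl <- data.frame(t = numeric(), kind = character(), seg = integer())
  ctrl <- ctrl[order(ctrl$t, ctrl$kind != "demote"), , drop = FALSE]
  ci <- 1L
  lick_a <- character(); lick_t <- numeric()  # running licks for demotion
  apply_ctrl_upto <- function(t) {
    while (ci <= nrow(ctrl) && ctrl$t[ci] <= t) {
      if (ctrl$kind[ci] == "demote") {
        ld <- data.frame(animal_id = lick_a, t = lick_t,
                         stringsAsFactors = FALSE)
        res <- demote_nonlickers(states, ld, window_h = demote_window_h,
                                 now_s = ctrl$t[ci])
        states <<- res$states
      } else {
        seg <- ctrl$seg[ci]
        for (a in roster) {
          st <- states[[a]]
          if (!st$demoted) {
            st$phase <- plan$phase[seg]
            st$side_map <- segment_side_map(config, plan, seg)
            st$target_corner <- NA_character_
            states[[a]] <<- st
          }
        }
      }
      ci <<- ci + 1L
    }
  }
  pend_t <- numeric(); pend_a <- integer(); pend_j <- integer()
  pend_corner <- character()
  qi <- 1L
  process_one <- function(ai, j, t, committed_corner) {
    if (t >= total_s) return(invisible())
    apply_ctrl_upto(t)
    a <- roster[ai]
    p <- roster_params[[ai]]
    st <- states[[a]]
    if (is.na(committed_corner)) {
      if (t < animal_free[ai]) return(invisible())
      u1 <- cand[[ai]]$u_choice[j]
      u2 <- cand[[ai]]$u_pick[j]
      task <- st$phase %in% c("ALTERNATION", "REVERSAL")
      comp <- if (task) p$alternation_competence else 0
      corner <- if (u1 < comp) {
        if (is.na(st$target_corner)) {
          if (u2 < 0.5) config$active_pair[1] else config$active_pair[2]
        } else st$target_corner
      } else if (u1 < comp + p$perseveration_bias &&
                 !is.na(prev_corner[ai])) {
        prev_corner[ai]
      } else {
        config$corner_ids[ceiling(u2 * 4)]
      }
    } else corner <- committed_corner
    # one mouse per corner: wait (re-queue at the freeing time) or redraw
    if (corner_free[[corner]] > t) {
      wait <- corner_free[[corner]] - t
      if (wait <= conflict_timeout_s) {
        t_new <- corner_free[[corner]]
        pend_t <<- c(pend_t, t_new); pend_a <<- c(pend_a, ai)
        pend_j <<- c(pend_j, j); pend_corner <<- c(pend_corner, corner)
        animal_free[ai] <<- t_new  # reserved: no new visit while waiting
        return(invisible())
      }
      free <- config$corner_ids[corner_free[config$corner_ids] <= t]
      if (!length(free)) return(invisible())
      corner <- free[ceiling(cand[[ai]]$u_redraw[j] * length(free))]
    }
    dur <- cand[[ai]]$dur[j]
    t_entry <- t; t_exit <- t + dur
    # nosepokes
    pk <- NULL
    if (cand[[ai]]$u_poke[j] < p$nosepoke_prob) {
      dt1 <- min(1, dur * 0.2)
      if (corner %in% config$active_pair) {
        rs <- st$side_map[[corner]]
        first <- if (cand[[ai]]$u_side[j] < p$poke_side_accuracy) rs
        else setdiff(c("left", "right"), rs)
        side <- first
        tp <- t_entry + dt1
        if (first != rs) { side <- c(side, rs); tp <- c(tp, tp + dt1) }
      } else {
        side <- if (cand[[ai]]$u_side[j] < 0.5) "left" else "right"
        tp <- t_entry + dt1
      }
      pk <- list(side = side, t = tp)
    }
    res <- process_visit(st, list(corner = corner, t_entry = t_entry,
                                  t_exit = t_exit),
                         if (is.null(pk)) list(side = character(),
                                               t = numeric())
                         else pk, config)
    states[[a]] <<- res$state
    nv <<- nv + 1L
    out$a[nv] <<- ai; out$corner[nv] <<- corner
    out$t_entry[nv] <<- t_entry; out$t_exit[nv] <<- t_exit
    out$phase[nv] <<- res$state$phase
    out$annotation[nv] <<- res$annotation
    out$initial_poke[nv] <<- res$initial_poke
    out$rewarded[nv] <<- !is.null(res$reward)
    out$target_after[nv] <<- res$state$target_corner
    if (!is.null(pk)) {
      k <- length(pk$side)
      pk_a <<- c(pk_a, rep(a, k)); pk_corner <<- c(pk_corner, rep(corner, k))
      pk_side <<- c(pk_side, pk$side); pk_t <<- c(pk_t, pk$t)
    }
    # licking: on reward (task phases) or on any drinking visit (habituation)
    drink_t <- NA_real_
    if (!is.null(res$reward)) {
      rw_a <<- c(rw_a, a); rw_corner <<- c(rw_corner, res$reward$corner)
      rw_side <<- c(rw_side, res$reward$side)
      rw_t <<- c(rw_t, res$reward$t_open)
      rw_dur <<- c(rw_dur, res$reward$door_open_s)
      drink_t <- min(res$reward$t_open + 0.5, t_exit)
    } else if (res$annotation == "habituation" && !is.null(pk)) {
      drink_t <- min(t_entry + dur / 2, t_exit)
    }
    if (!is.na(drink_t) && !nonlicker[ai]) {
      mult <- if (assign_light_phase(drink_t, session_start_clock,
                                     schedule) == "dark")
        p$lick_rate_multiplier_dark else 1
      count <- stats::qpois(cand[[ai]]$u_lick[j],
                            p$lick_rate_per_reward * mult)
      if (count >= 1) {
        lk_aid <<- c(lk_aid, a); lk_corner <<- c(lk_corner, corner)
        lk_t2 <<- c(lk_t2, drink_t); lk_count <<- c(lk_count, count)
        lick_a <<- c(lick_a, a); lick_t <<- c(lick_t, drink_t)
      }
    }
    corner_free[[corner]] <<- t_exit + 1e-3
    animal_free[ai] <<- t_exit + 1e-3
    prev_corner[ai] <<- corner
    invisible()
  }
  repeat {
    has_q <- qi <= nq
    has_p <- length(pend_t) > 0
    if (!has_q && !has_p) break
    if (has_p && (!has_q || min(pend_t) <= qt[qi])) {
      k <- which.min(pend_t)
      t <- pend_t[k]; ai <- pend_a[k]; j <- pend_j[k]
      corner <- pend_corner[k]
      pend_t <- pend_t[-k]; pend_a <- pend_a[-k]
      pend_j <- pend_j[-k]; pend_corner <- pend_corner[-k]
      process_one(ai, j, t, corner)
    } else {
      process_one(qa[qi], qj[qi], qt[qi], NA_character_)
      qi <- qi + 1L
    }
  }
  keep <- seq_len(nv)
  ann <- data.frame(animal_id = roster[out$a[keep]],
                    corner = out$corner[keep],
                    t_entry = out$t_entry[keep], t_exit = out$t_exit[keep],
                    phase = out$phase[keep],
                    annotation = out$annotation[keep],
                    initial_poke = out$initial_poke[keep],
                    rewarded = out$rewarded[keep],
                    target_after = out$target_after[keep],
                    stringsAsFactors = FALSE)
  ord <- order(ann$t_entry, ann$animal_id)
  ann <- ann[ord, , drop = FALSE]
  rownames(ann) <- NULL
  visits <- ann[c("animal_id", "corner", "t_entry", "t_exit")]
  np <- data.frame(animal_id = pk_a, corner = pk_corner, side = pk_side,
                   t = pk_t, stringsAsFactors = FALSE)
  lk <- data.frame(animal_id = lk_aid, corner = lk_corner, t = lk_t2,
                   lick_count = as.integer(lk_count),
                   stringsAsFactors = FALSE)
  rewards <- data.frame(animal_id = rw_a, corner = rw_corner,
                        side = rw_side, t_open = rw_t, door_open_s = rw_dur,
                        stringsAsFactors = FALSE)
  fr <- NULL; fr_truth <- NULL
  if (frames) {
    if (is.null(frames_window_s))
      frames_window_s <- c(0, min(total_s, 1200))
    fres <- simulate_frames(roster_params, visits, config, animal_seeds,
                            frames_window_s, frame_rate_hz)
    fr <- fres$frames; fr_truth <- fres$truth
  }
  stream <- event_stream(visits, np, lk, fr, config, schedule,
                         session_start_clock = session_start_clock,
                         roster = roster, duration_s = total_s,
                         validate = FALSE)
  structure(list(stream = stream, annotations = ann, rewards = rewards,
                 nonlickers = roster[nonlicker], plan = plan,
                 frames_truth = fr_truth, seed = seed),
            class = "sim_cohort")
}

# synthesise overhead-camera detections: a two-state (immobile/moving)
# correlated random walk per animal, suspended while the animal is inside a
# corner (invisible to the camera), with climb-zone excursions
simulate_frames <- function(roster_params, visits, config, animal_seeds,
                            window_s, frame_rate_hz) {
  tgrid <- seq(window_s[1], window_s[2], by = 1 / frame_rate_hz)
  nf <- length(tgrid)
  all_fr <- list(); all_truth <- list()
  roster <- names(roster_params)
  W <- config$cage_width_cm; H <- config$cage_height_cm
  for (i in seq_along(roster)) {
    p <- roster_params[[i]]
    set.seed(animal_seeds[i] %% (.Machine$integer.max - 7L) + 7L)
    # alternating immobile/moving dwell segments (exponential dwells whose
    # means realise the requested long-run immobile fraction)
    mean_im <- 8
    mean_mv <- if (p$immobile_fraction > 0 && p$immobile_fraction < 1)
      mean_im * (1 - p$immobile_fraction) / p$immobile_fraction else
        if (p$immobile_fraction == 0) Inf else 0
    span <- window_s[2] - window_s[1]
    state <- integer(nf)  # 1 = moving, 0 = immobile
    tcur <- 0; scur <- stats::runif(1) >= p$immobile_fraction
    while (tcur < span) {
      dwell <- if (scur) {
        if (is.finite(mean_mv)) stats::rexp(1, 1 / max(mean_mv, 1e-6))
        else span
      } else stats::rexp(1, 1 / mean_im)
      idx <- which(tgrid - window_s[1] >= tcur &
                     tgrid - window_s[1] < tcur + dwell)
      state[idx] <- as.integer(scur)
      tcur <- tcur + dwell
      scur <- !scur
    }
    speed <- ifelse(state == 1, p$mean_speed_cm_s *
                      stats::rlnorm(nf, 0, 0.15), 0)
    turn <- stats::rnorm(nf, 0, 0.6)
    heading <- cumsum(turn)
    step <- speed / frame_rate_hz
    x <- cumsum(c(stats::runif(1, 5, W - 5), (step * cos(heading))[-1]))
    y <- cumsum(c(stats::runif(1, 5, H - 5), (step * sin(heading))[-1]))
    fold <- function(v, lo, hi) {
      rng <- 2 * (hi - lo)
      v <- (v - lo) %% rng
      lo + ifelse(v > (hi - lo), rng - v, v)
    }
    x <- fold(x, 1, W - 1); y <- fold(y, 1, H - 1)
    # climb-zone excursions
    climbing <- rep(FALSE, nf)
    if (p$climb_rate_per_h > 0 && length(config$climb_zones)) {
      nex <- stats::rpois(1, p$climb_rate_per_h * span / 3600)
      if (nex > 0) {
        starts <- stats::runif(nex, 0, span)
        durs <- stats::rexp(nex, 1 / 20)
        zone_i <- ceiling(stats::runif(nex) *
                            length(config$climb_zones))
        for (e in seq_len(nex)) {
          idx <- which(tgrid - window_s[1] >= starts[e] &
                         tgrid - window_s[1] <= starts[e] + durs[e])
          if (!length(idx)) next
          z <- config$climb_zones[[zone_i[e]]]
          x[idx] <- stats::runif(1, z[1], z[3]) +
            stats::rnorm(length(idx), 0, 0.05)
          y[idx] <- stats::runif(1, z[2], z[4]) +
            stats::rnorm(length(idx), 0, 0.05)
          x[idx] <- pmin(pmax(x[idx], z[1]), z[3])
          y[idx] <- pmin(pmax(y[idx], z[2]), z[4])
          climbing[idx] <- TRUE
        }
      }
    }
    # in-corner intervals: invisible to the camera
    va <- visits[visits$animal_id == roster[i], , drop = FALSE]
    visible <- rep(TRUE, nf)
    for (k in seq_len(nrow(va)))
      visible[tgrid >= va$t_entry[k] & tgrid <= va$t_exit[k]] <- FALSE
    if (!any(visible)) next
    box_w <- stats::runif(nf, 3.6, 4.4)
    box_h <- stats::runif(nf, 2.6, 3.4)
    all_fr[[i]] <- data.frame(
      t = tgrid[visible], x_cm = x[visible], y_cm = y[visible],
      box_w_cm = box_w[visible], box_h_cm = box_h[visible])
    all_truth[[i]] <- data.frame(
      t = tgrid[visible], animal_id = roster[i],
      immobile = state[visible] == 0L, climbing = climbing[visible],
      stringsAsFactors = FALSE)
  }
  fr <- do.call(rbind, all_fr)
  truth <- do.call(rbind, all_truth)
  if (is.null(fr)) return(list(frames = NULL, truth = NULL))
  ord <- order(fr$t)
  list(frames = fr[ord, , drop = FALSE],
       truth = truth[ord, , drop = FALSE])
}

#' Remove lick events to emulate non-licking animals
#'
#' Deletes all lick events of the listed animals from `onset_s` onward,
#' producing streams on which [demote_nonlickers()] (and the demotion logic
#' inside [run_session()]) can be exercised end to end.
#'
#' @param stream An [event_stream()].
#' @param ids Animal ids (must be in the roster).
#' @param onset_s Licks at or after this session time are removed.
#' @return The modified stream.
#' @export
inject_nonlickers <- function(stream, ids, onset_s = 0) {
  unknown <- setdiff(ids, stream$roster)
  if (length(unknown))
    stop("unknown animal id(s): ", paste(unknown, collapse = ", "))
  drop <- stream$licks$animal_id %in% ids & stream$licks$t >= onset_s
  stream$licks <- stream$licks[!drop, , drop = FALSE]
  rownames(stream$licks) <- NULL
  stream
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort> seed", x$seed, "|", length(x$stream$roster),
      "animals,", nrow(x$annotations), "visits,",
      nrow(x$rewards), "rewards\n")
  if (length(x$nonlickers))
    cat("  non-lickers:", paste(x$nonlickers, collapse = ", "), "\n")
  invisible(x)
}
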