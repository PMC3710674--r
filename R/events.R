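#' Assign light or dark phase to session times
#'
#' Maps seconds-since-session-start onto the light/dark cycle. Intervals are
#' half-open `[lights_on, lights_off)`: a time falling exactly on lights-off
#' is dark, and exactly on lights-on is light.
#'
#' @param t Numeric vector of times in seconds since session start (>= 0).
#' @param session_start_clock Clock time (hours, `[0, 24)`) at which the
#'   session started.
#' @param schedule A [light_schedule()].
#' @return Character vector, `"light"` or `"dark"`.
#' @examples
#' sch <- light_schedule(lights_on_clock = 7)
#' assign_light_phase(c(0, 6, 12, 23.99, 24) * 3600, 7, sch)
#' @export
assign_light_phase <- function(t, session_start_clock, schedule) {
  if (any(t < 0)) stop("t must be non-negative")
  since_on <- (session_start_clock - schedule$lights_on_clock + t / 3600) %% 24
  ifelse(since_on < schedule$light_hours, "light", "dark")
}

#' Hours of light and dark exposure within a session window
#'
#' Integrates the light/dark indicator over `[0, duration_s]` so that rate
#' measures (entries/h, licks/h) can be normalised by the actual time an
#' animal spent in each phase, which differs between phases for any session
#' length that is not a multiple of 24 h (e.g. a 30-h session starting at
#' lights-on spans 18 h light and 12 h dark).
#'
#' @inheritParams assign_light_phase
#' @param duration_s Session duration in seconds.
#' @return Named numeric vector `c(light = , dark = )`, in hours.
#' @export
phase_exposure_hours <- function(session_start_clock, schedule, duration_s) {
  if (duration_s < 0) stop("duration_s must be non-negative")
  dur_h <- duration_s / 3600
  offset <- (session_start_clock - schedule$lights_on_clock) %% 24
  # session times (h) of lights-on/off transitions inside [0, dur_h]
  k <- seq(-1, ceiling(dur_h / 24) + 1)
  brk <- c(k * 24 - offset, k * 24 - offset + schedule$light_hours)
  brk <- brk[brk > 0 & brk < dur_h]
  brk <- sort(unique(c(0, brk, dur_h)))
  if (length(brk) < 2)
    return(c(light = 0, dark = 0))
  mids <- (brk[-1] + brk[-length(brk)]) / 2
  widths <- diff(brk)
  ph <- assign_light_phase(mids * 3600, session_start_clock, schedule)
  c(light = sum(widths[ph == "light"]), dark = sum(widths[ph == "dark"]))
}

#' Construct an event stream
#'
#' The common container for one session's recordings: corner-visit events
#' (one row per visit with entry/exit times), nosepoke events, lick events,
#' and optionally per-frame overhead-camera detections. Events are kept in
#' non-decreasing time order; all animal ids must come from the declared
#' roster.
#'
#' @param visits Data frame with columns `animal_id`, `corner`, `t_entry`,
#'   `t_exit` (seconds since session start).
#' @param nosepokes Data frame with columns `animal_id`, `corner`, `side`
#'   (`"left"`/`"right"`), `t`.
#' @param licks Data frame with columns `animal_id`, `corner`, `t`,
#'   `lick_count`.
#' @param frames Optional data frame with columns `t`, `x_cm`, `y_cm`,
#'   `box_w_cm`, `box_h_cm`; multiple rows may share one `t` (one row per
#'   detected, anonymous animal). Frames with no detections need no rows.
#' @param config A [cage_config()].
#' @param schedule A [light_schedule()].
#' @param session_start_clock Clock time (h) of session start; defaults to
#'   lights-on.
#' @param roster Character vector of animal ids; defaults to the ids present.
#' @param duration_s Session duration; defaults to the latest event time.
#' @param validate If `TRUE`, stop when [validate_stream()] reports
#'   violations.
#' @return An object of class `event_stream`.
#' @export
event_stream <- function(visits, nosepokes = NULL, licks = NULL,
                         frames = NULL, config = cage_config(),
                         schedule = light_schedule(),
                         session_start_clock = schedule$lights_on_clock,
                         roster = NULL, duration_s = NULL,
                         validate = TRUE) {
  empty <- function(cols) {
    out <- lapply(cols, function(cl) vector(cl, 0L))
    names(out) <- names(cols)
    as.data.frame(out, stringsAsFactors = FALSE)
  }
  if (is.null(nosepokes))
    nosepokes <- empty(c(animal_id = "character", corner = "character",
                         side = "character", t = "numeric"))
  if (is.null(licks))
    licks <- empty(c(animal_id = "character", corner = "character",
                     t = "numeric", lick_count = "integer"))
  visits <- visits[order(visits$t_entry), , drop = FALSE]
  nosepokes <- nosepokes[order(nosepokes$t), , drop = FALSE]
  licks <- licks[order(licks$t), , drop = FALSE]
  if (!is.null(frames)) frames <- frames[order(frames$t), , drop = FALSE]
  rownames(visits) <- rownames(nosepokes) <- rownames(licks) <- NULL
  if (!is.null(frames)) rownames(frames) <- NULL
  if (is.null(roster))
    roster <- sort(unique(c(visits$animal_id, nosepokes$animal_id,
                            licks$animal_id)))
  if (is.null(duration_s))
    duration_s <- max(0, visits$t_exit, nosepokes$t, licks$t,
                      if (!is.null(frames)) frames$t)
  stream <- structure(list(
    visits = visits, nosepokes = nosepokes, licks = licks, frames = frames,
    config = config, schedule = schedule,
    session_start_clock = session_start_clock,
    roster = as.character(roster), duration_s = duration_s
  ), class = "event_stream")
  if (validate) {
    v <- validate_stream(stream)
    if (nrow(v))
      stop("invalid event stream: ", nrow(v), " violation(s); first: ",
           v$rule[1], " (", v$detail[1], ")")
  }
  stream
}

#' Validate an event stream
#'
#' Checks every structural invariant of the data model and returns the
#' violations as data, one row per offending event: visit exit after entry,
#' valid corner labels, roster membership, time-ordering, nosepokes and licks
#' falling inside a visit by the same animal to the same corner, no animal in
#' two corners at once, and no two animals co-occupying one corner chamber
#' (the corner chambers admit a single mouse).
#'
#' @param stream An [event_stream()] (built with `validate = FALSE` if you
#'   expect violations).
#' @return Data frame with columns `rule`, `animal_id`, `t`, `detail`; zero
#'   rows when the stream is valid.
#' @export
validate_stream <- function(stream) {
  out <- list()
  add <- function(rule, animal, t, detail)
    out[[length(out) + 1L]] <<- data.frame(
      rule = rule, animal_id = as.character(animal), t = as.numeric(t),
      detail = detail, stringsAsFactors = FALSE)
  v <- stream$visits
  cfg <- stream$config
  bad <- which(v$t_exit <= v$t_entry)
  for (i in bad) add("visit_times", v$animal_id[i], v$t_entry[i],
                     "t_exit <= t_entry")
  bad <- which(!(v$corner %in% cfg$corner_ids))
  for (i in bad) add("corner_label", v$animal_id[i], v$t_entry[i],
                     paste("unknown corner", v$corner[i]))
  for (df_name in c("visits", "nosepokes", "licks")) {
    df <- stream[[df_name]]
    tcol <- if (df_name == "visits") df$t_entry else df$t
    if (length(tcol) > 1 && is.unsorted(tcol))
      add("time_order", NA, NA, paste(df_name, "not time-ordered"))
    bad <- which(!(df$animal_id %in% stream$roster))
    for (i in bad) add("roster", df$animal_id[i], tcol[i],
                       "animal_id not in roster")
  }
  bad <- which(stream$licks$lick_count < 1)
  for (i in bad) add("lick_count", stream$licks$animal_id[i],
                     stream$licks$t[i], "lick_count < 1")
  # containment of pokes/licks in a matching visit
  contained <- function(df, what) {
    if (!nrow(df)) return()
    for (i in seq_len(nrow(df))) {
      hit <- v$animal_id == df$animal_id[i] & v$corner == df$corner[i] &
        v$t_entry <= df$t[i] & df$t[i] <= v$t_exit
      if (!any(hit)) add(paste0(what, "_in_visit"), df$animal_id[i],
                         df$t[i], paste(what, "outside any matching visit"))
    }
  }
  contained(stream$nosepokes, "nosepoke")
  contained(stream$licks, "lick")
  # overlap checks (animal in two corners; two animals in one corner)
  if (nrow(v) > 1) {
    for (a in unique(v$animal_id)) {
      va <- v[v$animal_id == a, , drop = FALSE]
      va <- va[order(va$t_entry), , drop = FALSE]
      if (nrow(va) > 1) {
        ov <- which(va$t_entry[-1] < va$t_exit[-nrow(va)])
        for (i in ov) add("animal_overlap", a, va$t_entry[i + 1],
                          "animal in two visits at once")
      }
    }
    for (cn in unique(v$corner)) {
      vc <- v[v$corner == cn, , drop = FALSE]
      vc <- vc[order(vc$t_entry), , drop = FALSE]
      if (nrow(vc) > 1) {
        ov <- which(vc$t_entry[-1] < vc$t_exit[-nrow(vc)])
        for (i in ov) add("corner_cooccupancy", vc$animal_id[i + 1],
                          vc$t_entry[i + 1],
                          paste("two animals in", cn, "at once"))
      }
    }
  }
  if (!is.null(stream$frames) && nrow(stream$frames)) {
    f <- stream$frames
    bad <- which(f$x_cm < 0 | f$x_cm > cfg$cage_width_cm |
                   f$y_cm < 0 | f$y_cm > cfg$cage_height_cm)
    for (i in bad) add("frame_bounds", NA, f$t[i],
                       "detection outside cage floor")
  }
  if (!length(out))
    return(data.frame(rule = character(), animal_id = character(),
                      t = numeric(), detail = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

fmt_num <- function(x) {
  # full-precision decimal text so that write -> read is bit-identical
  ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
}

#' Read and write event streams as CSV tables
#'
#' A stream is stored as a directory of comma-separated UTF-8 tables with
#' header rows: `visits.csv` (`animal_id, corner, t_entry, t_exit`),
#' `nosepokes.csv` (`animal_id, corner, side, t`), `licks.csv`
#' (`animal_id, corner, t, lick_count`), optional `frames.csv`
#' (`t, x_cm, y_cm, box_w_cm, box_h_cm`), plus `stream.yaml` holding the
#' roster, session start clock time and duration. Numeric columns are written
#' with 17 significant digits, so a write/read round trip reproduces the
#' stream exactly.
#'
#' @param path Directory path.
#' @param config A [cage_config()].
#' @param schedule A [light_schedule()].
#' @param validate Passed to [event_stream()].
#' @param stream An `event_stream`.
#' @return `read_event_stream()` returns the validated `event_stream`;
#'   `write_event_stream()` returns `path` invisibly.
#' @export
read_event_stream <- function(path, config = cage_config(),
                              schedule = light_schedule(), validate = TRUE) {
  need <- function(f) {
    fp <- file.path(path, f)
    if (!file.exists(fp)) stop("missing ", f, " under ", path)
    fp
  }
  read1 <- function(fp, cols) {
    df <- tryCatch(
      utils::read.csv(fp, stringsAsFactors = FALSE,
                      colClasses = unname(cols)),
      error = function(e) stop("malformed table ", fp, ": ",
                               conditionMessage(e), call. = FALSE))
    if (!all(names(cols) %in% names(df)))
      stop("table ", fp, " lacks columns ",
           paste(setdiff(names(cols), names(df)), collapse = ", "))
    df[names(cols)]
  }
  visits <- read1(need("visits.csv"),
                  c(animal_id = "character", corner = "character",
                    t_entry = "numeric", t_exit = "numeric"))
  nosepokes <- read1(need("nosepokes.csv"),
                     c(animal_id = "character", corner = "character",
                       side = "character", t = "numeric"))
  licks <- read1(need("licks.csv"),
                 c(animal_id = "character", corner = "character",
                   t = "numeric", lick_count = "integer"))
  frames <- NULL
  if (file.exists(file.path(path, "frames.csv")))
    frames <- read1(file.path(path, "frames.csv"),
                    c(t = "numeric", x_cm = "numeric", y_cm = "numeric",
                      box_w_cm = "numeric", box_h_cm = "numeric"))
  meta <- yaml::read_yaml(file.path(path, "stream.yaml"))
  event_stream(visits, nosepokes, licks, frames, config, schedule,
               session_start_clock = as.numeric(meta$session_start_clock),
               roster = as.character(meta$roster),
               duration_s = as.numeric(meta$duration_s),
               validate = validate)
}

#' @rdname read_event_stream
#' @export
write_event_stream <- function(stream, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, file, numcols) {
    for (cl in numcols) df[[cl]] <- fmt_num(df[[cl]])
    utils::write.csv(df, file.path(path, file), row.names = FALSE,
                     quote = FALSE, na = "")
  }
  w(stream$visits, "visits.csv", c("t_entry", "t_exit"))
  w(stream$nosepokes, "nosepokes.csv", "t")
  lk <- stream$licks
  lk$lick_count <- as.integer(lk$lick_count)
  w(lk, "licks.csv", "t")
  if (!is.null(stream$frames))
    w(stream$frames, "frames.csv",
      c("t", "x_cm", "y_cm", "box_w_cm", "box_h_cm"))
  yaml::write_yaml(list(roster = as.list(stream$roster),
                        session_start_clock = stream$session_start_clock,
                        duration_s = stream$duration_s),
                   file.path(path, "stream.yaml"))
  invisible(path)
}

#' @export
print.event_stream <- function(x, ...) {
  cat(sprintf(
    "<event_stream> %d animals | %d visits, %d nosepokes, %d lick events%s\n",
    length(x$roster), nrow(x$visits), nrow(x$nosepokes), nrow(x$licks),
    if (is.null(x$frames)) "" else sprintf(", %d detections", nrow(x$frames))))
  cat(sprintf("  duration %.2f h, session start %05.2fh\n",
              x$duration_s / 3600, x$session_start_clock))
  invisible(x)
}
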