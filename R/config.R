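#' Cage configuration
#'
#' Describes the geometry and reward wiring of one instrumented home cage:
#' four corner chambers, of which two adjacent corners along one short wall
#' (the *active pair*) can deliver water under the task contingency while the
#' other two (the *exploratory pair*) never do. Each active corner rewards
#' nosepokes on exactly one side, and the rewarded sides of the two active
#' corners are opposite (left in one, right in the other).
#'
#' Corners are labelled `"C1"`..`"C4"`, `C1` top-left and numbering clockwise.
#' Floor coordinates are centimetres with the origin at the top-left corner,
#' x increasing rightward and y increasing downward.
#'
#' @param cage_id Character scalar identifying the cage.
#' @param corner_ids Four distinct corner labels, in order.
#' @param active_pair Two corner labels forming the rewarded pair.
#' @param rewarded_side_map Named character vector mapping each active corner
#'   to its rewarded nosepoke side, `"left"` or `"right"`. The two sides must
#'   differ.
#' @param cage_width_cm,cage_height_cm Floor dimensions in cm.
#' @param climb_zones List of numeric vectors `c(x0, y0, x1, y1)` giving
#'   axis-aligned rectangles (cm) around the climbing structures.
#' @param wall_margin_cm Distance from a wall (cm) within which a tall
#'   detection is scored as rearing.
#' @param frame_rate_hz Video sampling rate of the overhead camera.
#' @param door_open_s Duration (s) the water door stays open after a correct
#'   rewarded-side nosepoke.
#' @return An object of class `cage_config`.
#' @examples
#' cfg <- cage_config()
#' cfg$exploratory_pair
#' @export
cage_config <- function(cage_id = "cage1",
                        corner_ids = c("C1", "C2", "C3", "C4"),
                        active_pair = c("C1", "C2"),
                        rewarded_side_map = c(C1 = "left", C2 = "right"),
                        cage_width_cm = 55,
                        cage_height_cm = 37.5,
                        climb_zones = list(c(20, 14, 35, 24)),
                        wall_margin_cm = 1.5,
                        frame_rate_hz = 30,
                        door_open_s = 8) {
  corner_ids <- as.character(corner_ids)
  active_pair <- as.character(active_pair)
  if (length(corner_ids) != 4L || anyDuplicated(corner_ids))
    stop("corner_ids must be 4 distinct labels")
  if (length(active_pair) != 2L || !all(active_pair %in% corner_ids))
    stop("active_pair must be 2 of the corner_ids")
  sides <- rewarded_side_map[active_pair]
  if (length(rewarded_side_map) != 2L || any(is.na(sides)) ||
      !all(sides %in% c("left", "right")))
    stop("rewarded_side_map must map both active corners to 'left'/'right'")
  if (sides[[1]] == sides[[2]])
    stop("rewarded sides of the two active corners must be opposite")
  if (frame_rate_hz <= 0 || cage_width_cm <= 0 || cage_height_cm <= 0 ||
      wall_margin_cm <= 0 || door_open_s <= 0)
    stop("all rates, lengths and durations must be positive")
  for (z in climb_zones)
    if (length(z) != 4L || z[3] <= z[1] || z[4] <= z[2])
      stop("each climb zone must be c(x0, y0, x1, y1) with x1 > x0, y1 > y0")
  structure(list(
    cage_id = cage_id,
    corner_ids = corner_ids,
    active_pair = active_pair,
    exploratory_pair = setdiff(corner_ids, active_pair),
    rewarded_side_map = stats::setNames(as.character(sides), active_pair),
    cage_width_cm = cage_width_cm,
    cage_height_cm = cage_height_cm,
    climb_zones = climb_zones,
    wall_margin_cm = wall_margin_cm,
    frame_rate_hz = frame_rate_hz,
    door_open_s = door_open_s
  ), class = "cage_config")
}

#' Light-dark schedule
#'
#' A 12:12 light/dark cycle anchored to the clock time at which lights come
#' on. Phase intervals are half-open: the instant of lights-on belongs to the
#' light phase and the instant of lights-off to the dark phase.
#'
#' @param lights_on_clock Clock time of lights-on, in hours `[0, 24)`.
#' @param light_hours,dark_hours Phase durations in hours; must sum to 24.
#' @return An object of class `light_schedule`.
#' @export
light_schedule <- function(lights_on_clock = 7,
                           light_hours = 12,
                           dark_hours = 12) {
  if (light_hours <= 0 || dark_hours <= 0 ||
      !isTRUE(all.equal(light_hours + dark_hours, 24)))
    stop("light_hours + dark_hours must equal 24")
  if (lights_on_clock < 0 || lights_on_clock >= 24)
    stop("lights_on_clock must be in [0, 24)")
  structure(list(lights_on_clock = lights_on_clock,
                 light_hours = light_hours,
                 dark_hours = dark_hours),
            class = "light_schedule")
}

#' Session plan
#'
#' An ordered timeline of protocol segments. Each segment runs one protocol
#' phase (`"HABITUATION"`, `"ALTERNATION"` or `"REVERSAL"`) for a fixed
#' duration; task segments may additionally flag `side_swap`, which flips the
#' rewarded nosepoke sides relative to what the phase alone implies (used to
#' reverse the nosepoke task at the start of consecutive sessions).
#'
#' Typical plans: an R6/2-style first test week is 6 h Habituation + 30 h
#' Alternation + 6 h Reversal; a BACHD-style first session is 24 h
#' Habituation + 48 h Alternation.
#'
#' @param phase Character vector of segment phases.
#' @param duration_h Numeric vector of segment durations (hours), recycled
#'   against `phase`.
#' @param side_swap Logical vector, recycled; ignored for Habituation
#'   segments.
#' @return A data frame of class `session_plan` with columns `phase`,
#'   `duration_h`, `side_swap`, `t_start_h`, `t_end_h`.
#' @examples
#' session_plan(c("HABITUATION", "ALTERNATION", "REVERSAL"), c(6, 30, 6))
#' @export
session_plan <- function(phase, duration_h, side_swap = FALSE) {
  phase <- toupper(as.character(phase))
  ok <- phase %in% c("HABITUATION", "ALTERNATION", "REVERSAL")
  if (!length(phase) || !all(ok))
    stop("phases must be HABITUATION, ALTERNATION or REVERSAL")
  n <- length(phase)
  duration_h <- rep_len(as.numeric(duration_h), n)
  side_swap <- rep_len(as.logical(side_swap), n)
  if (any(duration_h <= 0)) stop("segment durations must be positive")
  side_swap[phase == "HABITUATION"] <- FALSE
  ends <- cumsum(duration_h)
  out <- data.frame(phase = phase, duration_h = duration_h,
                    side_swap = side_swap,
                    t_start_h = c(0, ends[-n]), t_end_h = ends,
                    stringsAsFactors = FALSE)
  class(out) <- c("session_plan", "data.frame")
  out
}

plan_total_s <- function(plan) max(plan$t_end_h) * 3600

# phase label of the segment containing session time t (seconds); segments
# are half-open [start, end), the final end instant belonging to the last one
plan_segment_at <- function(plan, t_s) {
  h <- t_s / 3600
  i <- findInterval(h, plan$t_start_h, left.open = FALSE)
  i[i < 1L] <- 1L
  i[i > nrow(plan)] <- nrow(plan)
  i
}

#' Read or write a session configuration file
#'
#' A session configuration bundles everything needed to replay and score one
#' recording: the [cage_config()], the [light_schedule()], the
#' [session_plan()], the clock time at which the session started, and the
#' animal roster. Stored as YAML.
#'
#' @param path File path.
#' @param config A list with elements `cage`, `schedule`, `plan`,
#'   `session_start_clock`, `roster`.
#' @return `read_session_config()` returns such a list with the elements
#'   reconstructed as their package classes.
#' @export
read_session_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cage <- do.call(cage_config, c(
    raw$cage[setdiff(names(raw$cage), c("rewarded_side_map", "climb_zones",
                                        "exploratory_pair"))],
    list(rewarded_side_map = unlist(raw$cage$rewarded_side_map),
         climb_zones = lapply(raw$cage$climb_zones, as.numeric))))
  sched <- do.call(light_schedule, raw$schedule)
  plan <- session_plan(vapply(raw$plan, `[[`, "", "phase"),
                       vapply(raw$plan, function(s) as.numeric(s$duration_h), 0),
                       vapply(raw$plan, function(s) isTRUE(s$side_swap), NA))
  list(cage = cage, schedule = sched, plan = plan,
       session_start_clock = as.numeric(raw$session_start_clock %||%
                                          sched$lights_on_clock),
       roster = as.character(raw$roster))
}

#' @rdname read_session_config
#' @export
write_session_config <- function(config, path) {
  cage <- config$cage
  out <- list(
    cage = list(cage_id = cage$cage_id, corner_ids = cage$corner_ids,
                active_pair = cage$active_pair,
                rewarded_side_map = as.list(cage$rewarded_side_map),
                cage_width_cm = cage$cage_width_cm,
                cage_height_cm = cage$cage_height_cm,
                climb_zones = lapply(cage$climb_zones, as.numeric),
                wall_margin_cm = cage$wall_margin_cm,
                frame_rate_hz = cage$frame_rate_hz,
                door_open_s = cage$door_open_s),
    schedule = list(lights_on_clock = config$schedule$lights_on_clock,
                    light_hours = config$schedule$light_hours,
                    dark_hours = config$schedule$dark_hours),
    plan = lapply(seq_len(nrow(config$plan)), function(i)
      list(phase = config$plan$phase[i],
           duration_h = config$plan$duration_h[i],
           side_swap = config$plan$side_swap[i])),
    session_start_clock = config$session_start_clock,
    roster = as.list(config$roster))
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cage_config <- function(x, ...) {
  cat("<cage_config>", x$cage_id, "\n")
  cat("  corners:", paste(x$corner_ids, collapse = " "),
      "| active:", paste(x$active_pair, collapse = " "), "\n")
  cat("  rewarded sides:",
      paste(names(x$rewarded_side_map), x$rewarded_side_map,
            sep = ":", collapse = " "), "\n")
  cat(sprintf("  floor %.1f x %.1f cm, %d climb zone(s), %g Hz camera\n",
              x$cage_width_cm, x$cage_height_cm, length(x$climb_zones),
              x$frame_rate_hz))
  invisible(x)
}

#' @export
print.light_schedule <- function(x, ...) {
  cat(sprintf("<light_schedule> lights on %05.2fh, %g h light : %g h dark\n",
              x$lights_on_clock, x$light_hours, x$dark_hours))
  invisible(x)
}
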