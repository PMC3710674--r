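# Brute-force reference for the alternation contingency and its scoring.
# Deliberately naive, loop-per-visit restatements of the task rules, kept
# independent of the engine implementation so the two can be compared on
# exhaustively enumerated visit sequences.
#
# Input convention for the enumerated sequences: each visit is a corner plus
# the side of its single nosepoke relative to the rewarded side of that
# corner ("rewarded"/"unrewarded"; NA for no poke / exploratory corners).

oracle_annotate <- function(corners, poke_rel, active = c("C1", "C2")) {
  n <- length(corners)
  ann <- character(n)
  rewarded <- logical(n)
  initial <- rep(NA_character_, n)
  target <- NA_character_  # either active corner is correct initially
  for (i in seq_len(n)) {
    cn <- corners[i]
    if (!(cn %in% active)) {
      # visits to exploratory corners never change the target
      ann[i] <- "exploratory"
      next
    }
    is_correct <- if (is.na(target)) TRUE else cn == target
    if (is_correct) {
      ann[i] <- "correct"
      if (!is.na(poke_rel[i])) {
        initial[i] <- if (poke_rel[i] == "rewarded") "correct" else
          "incorrect"
        # reinforcement is available in a correct visit; delivered on a
        # rewarded-side poke
        rewarded[i] <- poke_rel[i] == "rewarded"
      }
      # the correct visit itself moves the target to the other corner
      target <- active[active != cn]
    } else {
      ann[i] <- "incorrect"
    }
  }
  list(annotation = ann, rewarded = rewarded, initial_poke = initial)
}

# percent alternation, literally: active-to-active transitions within the
# window of leaving an active corner; switches over scorable transitions
oracle_alternation <- function(corners, t_entry, t_exit, active,
                               window_s = 113) {
  idx <- which(corners %in% active)
  num <- 0L
  den <- 0L
  if (length(idx) >= 2) {
    for (k in 2:length(idx)) {
      gap <- t_entry[idx[k]] - t_exit[idx[k - 1]]
      if (gap <= window_s) {
        den <- den + 1L
        if (corners[idx[k]] != corners[idx[k - 1]]) num <- num + 1L
      }
    }
  }
  if (den == 0L) NA_real_ else 100 * num / den
}

# drive the packaged engine over one enumerated sequence (single animal);
# returns the same fields as oracle_annotate
engine_annotate <- function(corners, poke_rel, t_entry, t_exit, cfg) {
  st <- init_protocol(cfg, session_plan("ALTERNATION", 480), "m")[["m"]]
  n <- length(corners)
  ann <- character(n)
  rewarded <- logical(n)
  initial <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    pk <- list(side = character(), t = numeric())
    if (!is.na(poke_rel[i])) {
      rs <- st$side_map[[corners[i]]]
      side <- if (poke_rel[i] == "rewarded") rs else
        setdiff(c("left", "right"), rs)
      pk <- list(side = side, t = t_entry[i] + 0.5)
    }
    res <- process_visit(st, list(corner = corners[i],
                                  t_entry = t_entry[i],
                                  t_exit = t_exit[i]), pk, cfg)
    st <- res$state
    ann[i] <- res$annotation
    rewarded[i] <- !is.null(res$reward)
    initial[i] <- res$initial_poke
  }
  list(annotation = ann, rewarded = rewarded, initial_poke = initial)
}

# enumerated symbol table: active corners come with a poke side relative to
# the rewarded side; exploratory corners carry no poke
contingency_symbols <- function(active = c("C1", "C2"),
                                exploratory = c("C3", "C4")) {
  data.frame(
    corner = c(active[1], active[1], active[2], active[2], exploratory),
    poke_rel = c("rewarded", "unrewarded", "rewarded", "unrewarded",
                 NA, NA),
    stringsAsFactors = FALSE)
}

# gap patterns used by the enumeration: all-short keeps every transition in
# the scoring window; alternating long gaps push some transitions out
gap_pattern <- function(n, kind = c("short", "mixed"), visit_s = 5,
                        short_s = 10, long_s = 150) {
  kind <- match.arg(kind)
  gaps <- if (kind == "short") rep(short_s, max(n - 1, 0)) else
    rep_len(c(short_s, long_s), max(n - 1, 0))
  t_entry <- cumsum(c(0, gaps + visit_s))
  list(t_entry = t_entry, t_exit = t_entry + visit_s)
}
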