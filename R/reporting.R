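score_measures <- c("corner_entries", "lick_count", "repeat_pct",
                    "alternation_pct", "collected_rewards_pct")

#' Group-level summary of a score table
#'
#' Mean, standard deviation, group size and missing-value count for each
#' measure, per group x light phase x session cell. Undefined (`NA`)
#' measures are excluded from `n`.
#'
#' @param scores A `score_table` from [build_score_table()] (tables from
#'   several sessions may be `rbind`ed first).
#' @param groups Named character vector mapping every `animal_id` in
#'   `scores` to a group label (e.g. genotype).
#' @return Long data frame with columns `group`, `session_label`,
#'   `light_phase`, `measure`, `mean`, `sd`, `n`, `n_missing`.
#' @export
summarize_scores <- function(scores, groups) {
  unmapped <- setdiff(unique(scores$animal_id), names(groups))
  if (length(unmapped))
    stop("no group mapping for: ", paste(unmapped, collapse = ", "))
  scores$group <- unname(groups[scores$animal_id])
  cells <- unique(scores[c("group", "session_label", "light_phase")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- scores[scores$group == cells$group[i] &
                    scores$session_label == cells$session_label[i] &
                    scores$light_phase == cells$light_phase[i], ,
                  drop = FALSE]
    do.call(rbind, lapply(score_measures, function(m) {
      x <- sub[[m]]
      data.frame(group = cells$group[i],
                 session_label = cells$session_label[i],
                 light_phase = cells$light_phase[i], measure = m,
                 mean = mean(x, na.rm = TRUE),
                 sd = stats::sd(x[!is.na(x)]),
                 n = sum(!is.na(x)), n_missing = sum(is.na(x)),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$measure, out$group, out$session_label, out$light_phase), ,
      drop = FALSE]
}

per_animal_means <- function(scores, measure) {
  if (!measure %in% score_measures)
    stop("unknown measure: ", measure)
  vals <- tapply(scores[[measure]], scores$animal_id,
                 function(x) mean(x, na.rm = TRUE))
  vals[!is.nan(vals)]
}

#' Permutation test for a two-group difference in a behavioral measure
#'
#' Distribution-free comparison of two groups on one measure: each animal is
#' reduced to its mean across light phases (and sessions, if several are
#' present), the observed statistic is the difference of group means, and
#' the null distribution is obtained by permuting group labels across
#' animals. The two-sided p-value uses the add-one correction
#' `(r + 1) / (n_perm + 1)`, where `r` counts permuted statistics at least
#' as extreme in absolute value.
#'
#' @inheritParams summarize_scores
#' @param measure One of the five score-table measures.
#' @param n_perm Number of label permutations (>= 1).
#' @param seed Integer seed; the test is deterministic given the seed.
#' @return Object of class `group_comparison`: list with `measure`,
#'   `groups` (the two labels), `means`, `sds`, `ns`, `observed` (mean of
#'   group 1 minus mean of group 2), `p_value`, `n_perm`, `seed`.
#' @export
permutation_compare <- function(scores, groups, measure, n_perm = 1000,
                                seed = 1) {
  vals <- per_animal_means(scores, measure)
  g <- unname(groups[names(vals)])
  if (anyNA(g))
    stop("no group mapping for: ",
         paste(names(vals)[is.na(g)], collapse = ", "))
  lev <- unique(g)
  if (length(lev) != 2) stop("exactly two groups are required")
  sizes <- table(factor(g, lev))
  if (any(sizes < 2)) stop("each group needs at least 2 animals")
  x <- as.numeric(vals)
  obs <- mean(x[g == lev[1]]) - mean(x[g == lev[2]])
  n1 <- sum(g == lev[1])
  set.seed(as.integer(seed))
  perm <- replicate(n_perm, {
    idx <- sample.int(length(x), n1)
    mean(x[idx]) - mean(x[-idx])
  })
  p <- (sum(abs(perm) >= abs(obs) - 1e-12) + 1) / (n_perm + 1)
  structure(list(measure = measure, groups = lev,
                 means = stats::setNames(c(mean(x[g == lev[1]]),
                                           mean(x[g == lev[2]])), lev),
                 sds = stats::setNames(c(stats::sd(x[g == lev[1]]),
                                         stats::sd(x[g == lev[2]])), lev),
                 ns = stats::setNames(as.integer(sizes), lev),
                 observed = obs, p_value = p, n_perm = n_perm,
                 seed = seed),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: %s (n=%d) vs %s (n=%d)\n",
              x$measure, x$groups[1], x$ns[1], x$groups[2], x$ns[2]))
  cat(sprintf("  means %.3f vs %.3f, diff %.3f, permutation p = %.4g (%d perms)\n",
              x$means[1], x$means[2], x$observed, x$p_value, x$n_perm))
  invisible(x)
}

# simulate one cohort under `pars` and return per-animal means of `measure`
simulate_measure <- function(pars, measure, seed, plan, config, schedule,
                             prefix = "m") {
  names(pars) <- sprintf("%s_%02d", prefix, seq_along(pars))
  sim <- simulate_cohort(pars, config = config, schedule = schedule,
                         plan = plan, seed = seed)
  sess <- list(visits = sim$annotations, rewards = sim$rewards,
               states = NULL, trace = NULL, plan = sim$plan,
               config = config, stream = sim$stream)
  class(sess) <- "session_result"
  st <- build_score_table(sess)
  per_animal_means(st, measure)
}

# parameter targeted when moving a baseline toward the reference profile for
# a given measure
measure_param_map <- c(corner_entries = "visit_rate_per_h",
                       lick_count = "lick_rate_per_reward",
                       repeat_pct = "perseveration_bias",
                       alternation_pct = "alternation_competence",
                       collected_rewards_pct = "nosepoke_prob")

#' Simulation-based power analysis for a therapy-like improvement
#'
#' Estimates, for each candidate group size, the power of the permutation
#' comparison to detect a partial rescue of a mutant-like phenotype: the
#' treated group's targeted parameter is moved `effect_fraction` of the way
#' from the baseline profile toward the reference (wild-type-like) profile
#' (a gap-fraction reading of "X% improvement"), cohorts of size `n` are
#' simulated for both arms, scored, and compared with
#' [permutation_compare()] at level `alpha`. Power at `n` is the fraction of
#' replicates rejecting; the recommended group size is the smallest `n`
#' reaching `target_power`.
#'
#' @param baseline A [genotype_params()] profile (the untreated model), or a
#'   preset name understood by [preset_cohort()].
#' @param effect_fraction Fraction in `[0, 1]` of the baseline-to-reference
#'   gap restored by the hypothetical treatment; 0 gives a null calibration.
#' @param measure Score-table measure targeted.
#' @param n_grid Integer vector of group sizes to evaluate.
#' @param alpha Test level.
#' @param n_reps Simulation replicates per group size.
#' @param seed Integer seed.
#' @param reference Reference profile (default the wild-type-like preset).
#' @param plan,config,schedule Session design under which cohorts are
#'   simulated and scored; the default is a 12-h alternation session.
#' @param n_perm Permutations per test.
#' @param target_power Power goal used for the recommendation.
#' @return Object of class `power_result`: list with `measure`,
#'   `effect_fraction`, `alpha`, `target_power`, `grid` (data frame `n`,
#'   `power`), `recommended_n` (`NA` if the goal is not reached on the
#'   grid), `n_reps`, `seed`.
#' @export
power_by_simulation <- function(baseline, effect_fraction, measure,
                                n_grid = c(3, 6, 11, 16), alpha = 0.05,
                                n_reps = 30, seed = 1,
                                reference = preset_cohort("WT_like", 1)[[1]],
                                plan = session_plan("ALTERNATION", 12),
                                config = cage_config(),
                                schedule = light_schedule(),
                                n_perm = 400, target_power = 0.8) {
  if (is.character(baseline)) baseline <- preset_cohort(baseline, 1)[[1]]
  if (effect_fraction < 0 || effect_fraction > 1)
    stop("effect_fraction must be in [0, 1]")
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (!measure %in% names(measure_param_map))
    stop("measure not in the score-table schema")
  par_name <- measure_param_map[[measure]]
  treated <- baseline
  treated[[par_name]] <- baseline[[par_name]] +
    effect_fraction * (reference[[par_name]] - baseline[[par_name]])
  if (identical(par_name, "alternation_competence") &&
      treated$alternation_competence + treated$perseveration_bias > 1)
    treated$perseveration_bias <- 1 - treated$alternation_competence
  set.seed(as.integer(seed))
  rep_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 3L * n_reps * length(n_grid)),
                      ncol = 3L)
  power <- numeric(length(n_grid))
  row <- 0L
  for (gi in seq_along(n_grid)) {
    n <- n_grid[gi]
    rejects <- logical(n_reps)
    for (r in seq_len(n_reps)) {
      row <- row + 1L
      v_base <- simulate_measure(rep(list(baseline), n), measure,
                                 rep_seeds[row, 1], plan, config, schedule,
                                 prefix = "base")
      v_trt <- simulate_measure(rep(list(treated), n), measure,
                                rep_seeds[row, 2], plan, config, schedule,
                                prefix = "trt")
      vals <- c(v_base, v_trt)
      g <- stats::setNames(rep(c("baseline", "treated"),
                               c(length(v_base), length(v_trt))),
                           names(vals))
      if (length(v_base) < 2 || length(v_trt) < 2) {
        rejects[r] <- FALSE
        next
      }
      fake <- data.frame(animal_id = names(vals), light_phase = "light",
                         session_label = "s", stringsAsFactors = FALSE)
      fake[[measure]] <- as.numeric(vals)
      for (m in setdiff(score_measures, measure)) fake[[m]] <- NA_real_
      cmp <- permutation_compare(fake, g, measure, n_perm = n_perm,
                                 seed = rep_seeds[row, 3])
      rejects[r] <- cmp$p_value <= alpha
    }
    power[gi] <- mean(rejects)
  }
  rec <- n_grid[which(power >= target_power)[1]]
  structure(list(measure = measure, effect_fraction = effect_fraction,
                 alpha = alpha, target_power = target_power,
                 grid = data.frame(n = n_grid, power = power),
                 recommended_n = if (length(rec) && !is.na(rec)) rec
                 else NA_integer_,
                 n_reps = n_reps, seed = seed),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(
    "<power_result> %s, %.0f%% gap restored, alpha %.2f, %d reps/n\n",
    x$measure, 100 * x$effect_fraction, x$alpha, x$n_reps))
  for (i in seq_len(nrow(x$grid)))
    cat(sprintf("  n = %2d  power = %.2f\n", x$grid$n[i], x$grid$power[i]))
  cat("  recommended n:",
      if (is.na(x$recommended_n)) "not reached on grid"
      else x$recommended_n, "\n")
  invisible(x)
}
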