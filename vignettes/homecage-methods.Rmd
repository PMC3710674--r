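---
title: "Methods: contingency replay, behavioral scoring and cohort simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contingency replay, behavioral scoring and cohort simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homecage)
```

## The setting

Home-cage operant phenotyping records group-housed mice continuously in an
instrumented cage: four corner chambers log RFID-identified visits,
nosepokes (left/right recess) and licks, while an overhead camera yields
anonymous per-frame detections of the animals in the open arena. Water is
available only in the corners, under a protocol contingency; food is free.
The cage runs a 12:12 light/dark cycle and sessions span one to several
days, so every measure is reported by light phase. This package implements
the full analysis chain for such data — the reinforcement contingency, the
behavioral and activity measures, group inference — plus an agent-based
simulator that generates data with known ground truth, so every stage can
be verified end to end.

## The contingency model

Three protocols are modelled, composed into a session by `session_plan()`:

* **Habituation** (magazine training): any corner entry opens both water
  doors for the duration of the visit. No task bookkeeping.
* **Alternation**: two adjacent corners (the *active pair*) carry the
  contingency; the other two (*exploratory*) never reward. Each active
  corner rewards nosepokes on one side only, and the two corners' rewarded
  sides are opposite. A visit to the currently correct corner is a
  *correct* visit: the first nosepoke on the rewarded side opens the door
  for 8 s (one reward per visit), and the target moves to the other active
  corner. Visits to the non-target active corner are *incorrect*;
  exploratory visits are ignored. The only event that moves the target is
  a correct visit.
* **Reversal**: identical, with the rewarded sides swapped within each
  active corner.

Design choices the sources leave open, and how this package resolves them:

* **Initial target.** Before an animal's first active-corner visit in a
  task segment, *either* active corner counts as correct (the first active
  visit is always rewarded-eligible). The engine encodes this as a missing
  target that becomes defined by the first active-corner visit. The target
  is likewise reset to "either" at every task-segment boundary.
* **When the target switches.** At visit classification time: the correct
  visit itself flips the target, so an immediate return to the same corner
  is already incorrect. This is the only reading consistent with repeat
  visits being scored as errors.
* **One reward per visit.** Only the first rewarded-side poke of a correct
  visit opens the door; later pokes in the same visit are inert. A reward
  is granted whenever the poke occurs, even just before exit (door time
  truncated physically, not logically).
* **Initial-poke efficiency.** The side of the very first poke in a
  correct visit is logged `correct`/`incorrect`; a wrong first side
  carries no penalty.
* **Session-on-session reversal.** A plan segment's `side_swap` flag
  toggles the rewarded-side map relative to what the phase implies, which
  expresses "the nosepoke task reversed at the start of each session". A
  *corner*-contingency reversal (swapping the roles of the corner pairs)
  is not a separate engine mechanism: it is expressible by supplying a
  cage configuration with `active_pair`/`rewarded_side_map` edited for the
  later segment, and the side-swap reading is the one implemented, since
  the defined Reversal protocol swaps nosepoke recesses.
* **Non-licker fallback.** An animal with zero licks over a trailing
  24-h window (both parameters configurable) is switched to Habituation,
  per animal via its RFID identity. The check runs once per 24 h of
  session time; the schedule of the real systems is not documented, and a
  daily check matches the daily granularity at which non-lickers were
  reported. Demotion is sticky for the remainder of the plan — the systems
  it models treat such animals as dropped from the task even though they
  often resume licking under Habituation.

`run_session()` replays a validated event stream against a plan and is a
pure function of its inputs. Control events (segment boundaries, demotion
checks) apply before any visit entering at or after their time; a demotion
check scheduled at the same instant as a segment boundary runs first, so
an animal is never evaluated against a task it has not yet started.

## Behavioral measures

All five measures are computed per animal and light phase
(`build_score_table()`); a visit, lick or transition belongs to the phase
of its (later) timestamp, and phase intervals are half-open
`[lights_on, lights_off)`. Zero-denominator measures are `NA`, never 0 or
100, so group means are not biased by undefined cells.

* **Corner entries, licks**: counts per hour of *actual* per-phase
  exposure (`phase_exposure_hours()`), which matters for session lengths
  that are not multiples of 24 h (a 30-h session starting at lights-on has
  18 h light, 12 h dark).
* **Repeats**: percentage of consecutive-visit transitions (all four
  corners) returning to the corner just left; denominator is the
  transition count. By default repeats are computed across all phases,
  with a `repeats_scope = "habituation"` option, since the measure is
  introduced during magazine training where all corners are equivalent.
* **Percent alternation**: transitions between successive active-corner
  visits by the same animal, exploratory visits intervening freely; a
  transition is scorable when its gap (next entry − previous exit) is at
  most `window_s` (113 s by default). Scorable transitions that switch
  corner, over scorable transitions. Window-excluded transitions are
  dropped from numerator *and* denominator — that keeps the statistic a
  proper proportion over scored events; the alternative (all
  active-to-active transitions in the denominator) is available via
  `denominator = "all"`. The window itself is reported to be
  non-critical, and both readings are exposed.
* **Collected rewards**: percentage of task-phase active-corner visits
  containing at least one nosepoke.

Alternation and collected rewards use only visits made while the animal
was on a task phase, so a mid-session demotion masks the Habituation tail
out of the task measures.

## Activity measures

The upstream video detector of the real systems is proprietary, so this
module starts from what any detector emits: per-frame anonymous detections
(centroid + bounding box, in cage-floor cm). Animals inside corner
chambers are invisible to the camera and simply absent from frames.

* **Locomotion**: per consecutive-frame pair, matched displacement
  magnitudes are summed and divided by the number of mice detected in that
  frame, then accumulated per phase — "distance per mouse". Matching is
  optimal assignment for up to six detections (exhaustive) and greedy
  nearest-neighbour beyond, gated at `max_match_cm`.
* **Immobility**: per animal-frame speed (tracklet displacement over
  elapsed time), counted immobile when *strictly* below the 0.7 cm/s
  cutoff; a track at exactly 0.7 cm/s is not immobile. A 1e-9 cm/s guard
  absorbs float jitter in displacement/dt so the boundary convention is
  exact. Tracklets come from `link_tracks()` — nearest-neighbour
  association, broken at occlusions and gaps longer than
  `min_track_gap_frames` — and no global identity is ever claimed.
* **Rearing/climbing** (reported jointly): a detection climbs when its
  centroid lies in a configured climb-zone rectangle; it rears when within
  `rearing_wall_margin_cm` of a wall with box aspect (h/w) at least
  `rearing_aspect_min`. The rearing rule is a declared operational
  stand-in — the field reports "rearing against the walls" without an
  algorithmic definition — and both thresholds are parameters.

No trajectory smoothing is applied by default; speeds are
consecutive-frame displacements at the configured frame rate.

## The simulator

`simulate_cohort()` generates the joint behavior of a caged cohort so that
the engine, the scoring and the reporting can be tested against known
truth. Per animal:

* **Visit times**: inhomogeneous Poisson, rate `visit_rate_per_h` in the
  light and `visit_rate_per_h * dark_activity_multiplier` in the dark — a
  square wave locked to the schedule, matching the binary light/dark
  reporting of the measures.
* **Corner choice**: with probability `alternation_competence` (task
  phases only) the currently correct corner; otherwise with probability
  `perseveration_bias` the previous corner; otherwise uniform over all
  four. This memoryless mixture has a closed-form repeat rate under
  Habituation, `bias + (1 - bias)/4`, used as a recovery check.
* **Visit durations**: log-normal (median 15 s, sdlog 0.5 by default).
* **Pokes and licks**: a visit pokes with probability `nosepoke_prob`;
  the first poke is on the rewarded side with probability
  `poke_side_accuracy`, and a wrong first side is followed by a
  rewarded-side poke (no penalty applies). Licks occur on door openings —
  rewards during task phases, any drinking visit during Habituation —
  with Poisson mean `lick_rate_per_reward`, multiplied by
  `lick_rate_multiplier_dark` in the dark. `nonlicker_prob` is the chance
  an animal produces no licks at all for the session, feeding the
  demotion logic.
* **Corner occupancy**: chambers hold one mouse. An arrival at an
  occupied corner is re-queued at the moment the corner frees (up to
  `conflict_timeout_s` = 30 s), else redraws among free corners, else
  skips. Re-queuing at the freeing time keeps the generator processing
  visits strictly in entry order, which is what makes generation and
  replay provably run the same control logic — the replay-equality test
  would catch any divergence in orchestration.
* **Trajectories** (optional): a two-state (immobile/moving) correlated
  random walk with exponential dwells realising `immobile_fraction`,
  moving speeds around `mean_speed_cm_s`, climb-zone excursions at
  `climb_rate_per_h`, reflected at the walls; no detections while inside
  corners. Ground-truth per-frame states are returned alongside.

The contingency engine runs inside the generator (corner choice needs the
live target), and every visit's annotation is logged as ground truth.
Randomness derives from one seed; per-animal substreams are pre-drawn from
animal-specific seeds so the sequential pass itself consumes no RNG.

**Genotype presets.** No quantitative effect sizes are available for
calibration — published group contrasts are test statistics on real
animals — so the presets target effect *directions* only, at magnitudes
chosen once as plausible for the phenotypes they emulate: `R6/2_like`
keeps the wild-type entry rate but raises `perseveration_bias` to 0.30
(vs 0.05), lowers `alternation_competence` to 0.45 (vs 0.75), doubles
dark-phase licking, moves slower with more immobility and less climbing,
and has a 25% chance per session of becoming a non-licker; `BACHD_like`
lowers the entry rate to 1.8/h (hypoactivity), raises licking and the
nosepoke propensity (higher reward-collection efficiency), with moderate
perseveration and competence deficits and the strongest immobility.

**What the simulator does not emulate.** Visits arrive as a smooth Poisson
stream, not in the bout structure real mice show around rewards; at
realistic visit rates (3–6/h) most active-to-active gaps exceed the 113-s
window, so windowed percent alternation rests on few scorable transitions
per animal — which is why the package's own genotype-contrast checks use
the repeat measure, and why alternation-competence recovery is verified
with an unwindowed score. There is no learning curve (competence is
static), no social structure beyond corner queueing, and the trajectory
model makes no attempt at postural realism beyond what the three activity
measures consume. Passing tests therefore validate the *measures and
machinery*, not any claim about real mice.

## Group inference and power

The original analyses of such data are mixed-design three-way ANOVAs;
that inference is deliberately out of scope here (it is off-the-shelf in
any statistics package) and replaced by distribution-free permutation
tests on per-animal summaries: `permutation_compare()` reduces each
animal to its mean across phases, permutes group labels, and reports a
two-sided p-value with the add-one correction `(r + 1)/(n_perm + 1)`.
Camera-based measures pool within cage, so for those the cage is the
experimental unit and comparisons should feed cage-level rows. Note the
combinatorial floor: with 3 animals per group a two-sided label
permutation can never reach p ≤ 0.05 (the two extreme relabelings out of
20 give p = 0.1), so simulated power at n = 3 is zero by construction.

`power_by_simulation()` reads "an X% improvement" as restoring X% of the
baseline-to-wild-type gap on the parameter that drives the chosen measure
(perseveration bias for repeats, competence for alternation, visit rate
for entries, lick rate for licking, nosepoke propensity for collected
rewards) — a gap-fraction reading, flagged here because an X%-of-mutant
reading is also possible. Both arms are simulated at each group size,
scored, and tested at `alpha`; the recommended n is the smallest with
power at or above the target (0.80 by default).

## Numerical conventions and problem sizes

* Time is seconds from session start (double); the session's start clock
  time is stored alongside so phases are computable. Events are attributed
  to phases by their own timestamps; visits are not split at boundaries.
* CSV round trips are exact: numeric columns are written with 17
  significant digits.
* Validation treats violations as data (`validate_stream()` returns a
  table), and the readers refuse streams that violate the model.
* The test-suite and acceptance-script problem sizes are chosen to
  exercise the asymptotics the methods rely on while staying desk-scale:
  exhaustive contingency enumeration over all visit sequences up to length
  6 (111,972 scored cases; the acceptance script uses lengths up to 5),
  20-seed replay equality, 2,000-visit analytic limits, 100-seed circadian
  recovery at 11 animals × 30 h, 100-replicate genotype contrasts at
  11 + 11 animals × 24 h, and power grids over 3–16 animals at 25–60
  replicates per size.

## Known limitations

Percent alternation's denominator convention (window-excluded transitions
dropped) is one of two defensible readings; both are implemented, and on
data with rapid visit bouts they agree closely. The rearing definition is
an operational stand-in. The simulator's conflict queueing slightly thins
visit streams at high occupancy (about 2–3% at 11 animals and realistic
rates), which is visible as a dark:light entry-rate ratio a hair below the
configured multiplier. Lick events are recorded per corner, not per side;
side-resolved licking is not modelled.
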