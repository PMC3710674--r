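# shared builders for small in-code fixtures

test_config <- function(...) cage_config(...)
test_schedule <- function(...) light_schedule(...)

# a visit table for one animal from corner labels and explicit times
make_visits <- function(corners, t_entry, t_exit = t_entry + 5,
                        animal_id = "m1") {
  data.frame(animal_id = animal_id, corner = corners,
             t_entry = t_entry, t_exit = t_exit,
             stringsAsFactors = FALSE)
}

# evenly spaced visits, one per `spacing_s`, cycling over `corners`
regular_visits <- function(n, corners = c("C1", "C2", "C3", "C4"),
                           spacing_s = 3600, animal_id = "m1",
                           t0 = 0, visit_s = 30) {
  t_entry <- t0 + (seq_len(n) - 1) * spacing_s
  make_visits(rep_len(corners, n), t_entry, t_entry + visit_s, animal_id)
}

# detection table for a single animal moving at constant speed along +x
const_speed_frames <- function(speed_cm_s, n_frames, frame_rate_hz = 30,
                               x0 = 5, y0 = 10, t0 = 0) {
  t <- t0 + (seq_len(n_frames) - 1) / frame_rate_hz
  data.frame(t = t, x_cm = x0 + speed_cm_s * (t - t0), y_cm = y0,
             box_w_cm = 4, box_h_cm = 3)
}

quiet_sim <- function(...) suppressWarnings(simulate_cohort(...))
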