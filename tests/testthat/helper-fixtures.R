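# Shared fixtures: recordings built from explicit channel vectors, and
# small deterministic gait profiles.

make_rec <- function(ax, ay, az, fs = 100, subject = "A", location = "waist") {
  n <- max(length(ax), length(ay), length(az))
  ax <- rep_len(ax, n); ay <- rep_len(ay, n); az <- rep_len(az, n)
  adlsteps:::accel_recording(subject, location, fs, (seq_len(n) - 1) / fs,
                             cbind(ax, ay, az))
}

# gravity on +z, a test signal on x
sine_rec <- function(f, dur = 10, amp = 1, fs = 100, location = "waist") {
  t <- (seq_len(dur * fs) - 1) / fs
  make_rec(amp * sin(2 * pi * f * t), 0 * t, 9.80665 + 0 * t,
           fs = fs, location = location)
}

# one constant-cadence bout filling the whole session, no noise/artifacts
single_bout_profile <- function(id = "A", cadence = 1, dur = 10, seed = 7) {
  subject_profile(id, mean_cadence = cadence, cadence_jitter_sd = 0,
                  bout_length_range = c(dur, dur), rest_length_range = c(0, 0),
                  shuffle_fraction = 0, adl_artifact_rate = 0,
                  noise_scale = 0, seed = seed)
}

# no steps at all: rest longer than any session we use
quiet_profile <- function(id = "Q", seed = 3, noise_scale = 1) {
  subject_profile(id, rest_length_range = c(1e5, 1e5),
                  adl_artifact_rate = 0, noise_scale = noise_scale, seed = seed)
}

annotations_of <- function(events_times,
                           types = rep("walking", length(events_times)),
                           excluded = NULL) {
  adlsteps:::step_annotations(
    data.frame(time_s = events_times, event_type = types), excluded)
}

small_cohort <- function(n = 3, dur = 120, locations = "waist", seed = 1) {
  simulate_cohort(default_cohort_profiles(n, master_seed = seed),
                  session_spec(dur, locations = locations))
}
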