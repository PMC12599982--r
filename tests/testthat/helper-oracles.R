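# Independent spectral oracle: densely zero-padded FFT argmax of a
# mean-removed signal. Deliberately shares no code with the CWT path.
fft_peak_freq <- function(x, fs, pad = 8192) {
  x <- x - mean(x)
  n <- max(pad, length(x))
  sp <- Mod(fft(c(x, numeric(n - length(x)))))
  fr <- (seq_len(n) - 1) * fs / n
  keep <- fr <= fs / 2
  fr[keep][which.max(sp[keep])]
}

# Build a recording whose vector magnitude equals m exactly, via a fixed
# (non-axis-aligned) wrist orientation.
rec_from_magnitude <- function(m, fs = 50, t0 = 0, subject_id = "fix") {
  u <- c(0.36, 0.48, 0.80)  # unit vector
  time <- t0 + (seq_along(m) - 1) / fs
  triaxial_recording(time, u[1] * m, u[2] * m, u[3] * m,
                     nominal_rate = fs, subject_id = subject_id)
}

# 1 g gravity plus a pure tone, sampled at fs
tone_magnitude <- function(freq, amp, duration, fs = 50, phase = 0) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  1 + amp * sin(2 * pi * freq * t + phase)
}

# Stitch generator segments into one recording + label track
stitch_session <- function(segs) {
  lab <- do.call(rbind, lapply(segs, `[[`, "label"))
  list(recording = triaxial_recording(
         unlist(lapply(segs, `[[`, "time")),
         unlist(lapply(segs, `[[`, "x")),
         unlist(lapply(segs, `[[`, "y")),
         unlist(lapply(segs, `[[`, "z")), nominal_rate = 50),
       labels = label_track(lab$start, lab$end, lab$activity))
}

# Five-minute mixed session (walking + confounders), deterministic.
mixed_session <- function(seed = 77) {
  segs <- list()
  t0 <- 0
  add <- function(s) { segs[[length(segs) + 1L]] <<- s; t0 <<- s$label$end }
  add(gen_adl("other", 20, seed = seed, t0 = t0))
  add(gen_walk(gait_profile(1.8, 0.25, 0.3, 0.2, 0.02), 90,
               seed = seed + 1, t0 = t0))
  add(gen_adl("transition", 2, seed = seed + 2, t0 = t0))
  add(gen_adl("brushing_teeth", 30, seed = seed + 3, t0 = t0))
  add(gen_adl("other", 10, seed = seed + 4, t0 = t0))
  add(gen_walk(gait_profile(1.0, 0.12, 0.15, 0.25, 0.02), 80,
               seed = seed + 5, t0 = t0))
  add(gen_adl("eating", 30, seed = seed + 6, t0 = t0))
  add(gen_adl("washing_hands", 25, seed = seed + 7, t0 = t0))
  add(gen_adl("other", 13, seed = seed + 8, t0 = t0))
  stitch_session(segs)
}

# Scaled-down calibration study: slow, soft-walking cohort + seeded LOSO.
# Heavy (~40 s per seed), so memoised across test files.
.calib_cache <- new.env()
calibration_run <- function(seed) {
  key <- as.character(seed)
  if (!is.null(.calib_cache[[key]])) return(.calib_cache[[key]])
  cohort <- gen_cohort(8, aid_mix = c(none = 3, cane = 3, rollator = 2),
                       seed = seed, step_freq_range = c(0.9, 1.1),
                       impact_amp_range = c(0.10, 0.15))
  prep <- prepare_cohort(cohort)
  res <- list(
    cohort = cohort,
    prep = prep,
    default_f1 = suppressWarnings(objective_f1(gait_preset("default"),
                                               prep)),
    tuning = loso_calibrate(prep, n_trials = 100, seed = seed + 100))
  .calib_cache[[key]] <- res
  res
}
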