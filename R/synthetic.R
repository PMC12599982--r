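# Run expr with a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Gait profile for synthetic walking
#'
#' Describes one subject's walking signal as seen at the wrist: a
#' fundamental at the step frequency, a subharmonic arm-swing component at
#' half the step frequency, a superharmonic impact/repetitive-motion
#' component at twice the step frequency, and Gaussian sensor noise.
#' Mobility aids damp the arm swing — rollator users keep both hands on
#' the handles, so their profiles force `armswing_ratio <= 0.2`.
#'
#' @param step_freq step frequency in Hz (0.5-3.5; older adults typically
#'   0.8-2 Hz).
#' @param impact_amp amplitude of the fundamental in g (older-adult steps
#'   are soft: ~0.1-0.2 g at the wrist).
#' @param armswing_ratio subharmonic amplitude as a fraction of
#'   `impact_amp`.
#' @param superharmonic_ratio superharmonic amplitude as a fraction of
#'   `impact_amp`.
#' @param noise_sd sensor noise standard deviation in g; modern MEMS
#'   accelerometers sit near 0.001-0.002 g RMS over a 25 Hz bandwidth.
#' @param aid `"none"`, `"cane"` or `"rollator"`.
#' @return A list of class `gait_profile`.
#' @export
gait_profile <- function(step_freq = 1.6, impact_amp = 0.2,
                         armswing_ratio = 0.3, superharmonic_ratio = 0.25,
                         noise_sd = 0.002,
                         aid = c("none", "cane", "rollator")) {
  aid <- match.arg(aid)
  if (step_freq < 0.5 || step_freq > 3.5)
    stop("step_freq must lie in [0.5, 3.5] Hz", call. = FALSE)
  if (impact_amp < 0 || armswing_ratio < 0 || superharmonic_ratio < 0 ||
      noise_sd < 0)
    stop("amplitudes and ratios must be >= 0", call. = FALSE)
  if (aid == "rollator" && armswing_ratio > 0.2)
    stop("rollator profiles require armswing_ratio <= 0.2 ",
         "(hands on the handles)", call. = FALSE)
  structure(list(step_freq = step_freq, impact_amp = impact_amp,
                 armswing_ratio = armswing_ratio,
                 superharmonic_ratio = superharmonic_ratio,
                 noise_sd = noise_sd, aid = aid),
            class = "gait_profile")
}

# slow (~1 s correlation) unit-variance modulation track, scaled
slow_wobble <- function(n, fs, scale) {
  w <- stats::filter(rnorm(n), rep(1, fs) / fs, circular = TRUE)
  scale * as.numeric(w) / max(sd(w), 1e-12)
}

# random unit vector: fixed wrist orientation for one subject
random_orientation <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# realize a magnitude trace on three axes under a fixed orientation
axes_from_magnitude <- function(m, orientation) {
  m <- pmax(m, 0)
  list(x = orientation[1L] * m, y = orientation[2L] * m,
       z = orientation[3L] * m)
}

#' Generate a synthetic walking segment
#'
#' Magnitude model (in g):
#' `m(t) = 1 + a sin(2 pi f t) + r1 a sin(pi f t + phi1)
#'           + r2 a e(t) sin(4 pi f t + phi2) + N(0, noise_sd)`
#' with `f = step_freq`, `a = impact_amp`, `r1 = armswing_ratio`,
#' `r2 = superharmonic_ratio` and per-segment uniform phases. The
#' fundamental and arm-swing subharmonic are steady (steady-state gait is
#' highly periodic at the wrist), while the superharmonic carries a slow
#' random envelope `e(t)` — it is an impact artifact, and impact sharpness
#' varies from step to step. The trace is realized on three axes under a
#' fixed wrist orientation, so the vector magnitude recovers `m(t)`
#' exactly. The leading 1 is gravity.
#'
#' @param profile a [gait_profile()].
#' @param duration segment duration in seconds (>= 1).
#' @param seed optional RNG seed for a reproducible segment.
#' @param fs sampling rate in Hz (50 Hz, the smartwatch capture rate).
#' @param orientation unit 3-vector; random when `NULL`.
#' @param t0 segment start time in seconds.
#' @return A list with `time`, `x`, `y`, `z` vectors and a one-row `label`
#'   data frame (`start`, `end`, `activity = "walking"`).
#' @export
gen_walk <- function(profile, duration, seed = NULL, fs = 50,
                     orientation = NULL, t0 = 0) {
  stopifnot(inherits(profile, "gait_profile"), duration >= 1)
  gen <- function() {
    if (is.null(orientation)) orientation <- random_orientation()
    t <- seq(0, duration - 1 / fs, by = 1 / fs)
    phi <- runif(2, 0, 2 * pi)
    a <- profile$impact_amp
    f <- profile$step_freq
    env <- pmax(1 + slow_wobble(length(t), fs, 0.7), 0)
    m <- 1 + a * sin(2 * pi * f * t) +
      profile$armswing_ratio * a * sin(pi * f * t + phi[1L]) +
      profile$superharmonic_ratio * a * env *
        sin(4 * pi * f * t + phi[2L]) +
      rnorm(length(t), 0, profile$noise_sd)
    ax <- axes_from_magnitude(m, orientation)
    list(time = t0 + t, x = ax$x, y = ax$y, z = ax$z,
         label = data.frame(start = t0, end = t0 + duration,
                            activity = "walking",
                            stringsAsFactors = FALSE))
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Generate a synthetic activity-of-daily-living segment
#'
#' Confounder models, all riding on 1 g of gravity with sensor noise:
#' * `brushing_teeth`, `washing_hands`, `combing_hair`: sustained
#'   oscillation at 2.5-4 Hz with amplitude 0.2-0.6 g, amplitude- and
#'   frequency-modulated the way hand-scrubbing motions are irregular
#'   (unlike metronomic gait) — the back-and-forth confounders that trip
#'   permissive superharmonic ratios;
#' * `eating`, `drinking`, `taking_medication`: sparse ~1 s low-frequency
#'   excursions a few seconds apart (hand-to-mouth reaches);
#' * `transition`: a single 1-2 s ramp (posture change);
#' * `other`: stillness (noise only).
#'
#' @param activity one of the non-walking activities above.
#' @param duration segment duration in seconds (>= 1).
#' @param seed optional RNG seed.
#' @param fs sampling rate in Hz.
#' @param orientation unit 3-vector; random when `NULL`.
#' @param t0 segment start time in seconds.
#' @return Same shape as [gen_walk()], labeled with `activity`.
#' @export
gen_adl <- function(activity, duration, seed = NULL, fs = 50,
                    orientation = NULL, t0 = 0) {
  stopifnot(duration >= 1)
  if (!activity %in% setdiff(ACTIVITY_LEVELS, "walking"))
    stop("unknown activity: ", activity, call. = FALSE)
  gen <- function() {
    if (is.null(orientation)) orientation <- random_orientation()
    t <- seq(0, duration - 1 / fs, by = 1 / fs)
    noise <- rnorm(length(t), 0, 0.003)
    m <- rep(1, length(t))
    wobble <- function(scale) slow_wobble(length(t), fs, scale)
    if (activity %in% c("brushing_teeth", "washing_hands", "combing_hair")) {
      f <- runif(1, 2.5, 4)
      a <- runif(1, 0.2, 0.6)
      inst_f <- f * (1 + wobble(0.08))          # irregular scrubbing rate
      env <- pmax(1 + wobble(0.3), 0.2)         # waxing/waning effort
      m <- m + a * env * sin(2 * pi * cumsum(inst_f) / fs +
                               runif(1, 0, 2 * pi))
    } else if (activity %in% c("eating", "drinking", "taking_medication")) {
      gap <- runif(1, 4, 7)          # seconds between reaches
      reach <- 0
      while (reach + gap + 1 < duration) {
        reach <- reach + gap
        amp <- runif(1, 0.1, 0.25)
        idx <- t >= reach & t < reach + 1
        m[idx] <- m[idx] + amp * sin(pi * (t[idx] - reach))^2
        gap <- runif(1, 4, 7)
      }
    } else if (activity == "transition") {
      len <- runif(1, 1, min(2, duration))
      idx <- t < len
      m[idx] <- m[idx] + 0.3 * sin(pi * t[idx] / len)^2
    }                                 # "other": stillness, noise only
    m <- m + noise
    ax <- axes_from_magnitude(m, orientation)
    list(time = t0 + t, x = ax$x, y = ax$y, z = ax$z,
         label = data.frame(start = t0, end = t0 + duration,
                            activity = activity, stringsAsFactors = FALSE))
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# default aid-conditioned subject parameter draws
draw_profile <- function(aid, step_freq_range = NULL,
                         impact_amp_range = NULL) {
  clip <- function(x, lo, hi) min(max(x, lo), hi)
  sf <- switch(aid,
               none = clip(rnorm(1, 1.6, 0.20), 1.1, 2.2),
               cane = clip(rnorm(1, 1.25, 0.15), 0.9, 1.8),
               rollator = clip(rnorm(1, 1.0, 0.12), 0.7, 1.4))
  ia <- switch(aid,
               none = clip(rnorm(1, 0.20, 0.04), 0.10, 0.35),
               cane = clip(rnorm(1, 0.16, 0.03), 0.09, 0.30),
               rollator = clip(rnorm(1, 0.13, 0.025), 0.08, 0.25))
  if (!is.null(step_freq_range))
    sf <- runif(1, step_freq_range[1L], step_freq_range[2L])
  if (!is.null(impact_amp_range))
    ia <- runif(1, impact_amp_range[1L], impact_amp_range[2L])
  arm <- switch(aid, none = runif(1, 0.2, 0.5), cane = runif(1, 0.05, 0.3),
                rollator = runif(1, 0, 0.2))
  # superharmonic content varies strongly across subjects (impact
  # sharpness, footwear, walking surface); some subjects have almost none,
  # which is what makes the fundamental band the only one covering a cohort
  gait_profile(step_freq = sf, impact_amp = ia, armswing_ratio = arm,
               superharmonic_ratio = runif(1, 0.05, 0.35),
               noise_sd = 0.002, aid = aid)
}

# assemble one subject's scripted session: stillness, one multi-minute
# walk, then each ADL once, separated by transitions and stillness
build_session <- function(profile, orientation, fs,
                          walk_duration = NULL) {
  if (is.null(walk_duration)) walk_duration <- runif(1, 150, 240)
  adls <- c(brushing_teeth = 25, combing_hair = 15, drinking = 14,
            eating = 20, taking_medication = 12, washing_hands = 25)
  segs <- list()
  t0 <- 0
  add <- function(seg) {
    segs[[length(segs) + 1L]] <<- seg
    t0 <<- seg$label$end
  }
  add(gen_adl("other", 8, fs = fs, orientation = orientation, t0 = t0))
  add(gen_adl("transition", 2, fs = fs, orientation = orientation, t0 = t0))
  add(gen_walk(profile, walk_duration, fs = fs, orientation = orientation,
               t0 = t0))
  add(gen_adl("transition", 2, fs = fs, orientation = orientation, t0 = t0))
  add(gen_adl("other", 6, fs = fs, orientation = orientation, t0 = t0))
  for (a in names(adls)) {
    add(gen_adl(a, adls[[a]], fs = fs, orientation = orientation, t0 = t0))
    add(gen_adl("transition", 2, fs = fs, orientation = orientation,
                t0 = t0))
    add(gen_adl("other", 5, fs = fs, orientation = orientation, t0 = t0))
  }
  list(time = unlist(lapply(segs, `[[`, "time")),
       x = unlist(lapply(segs, `[[`, "x")),
       y = unlist(lapply(segs, `[[`, "y")),
       z = unlist(lapply(segs, `[[`, "z")),
       labels = do.call(rbind, lapply(segs, `[[`, "label")))
}

#' Generate a labeled synthetic wrist cohort
#'
#' Builds a cohort of scripted semi-naturalistic sessions, one per subject:
#' a single multi-minute walk plus one bout of every activity of daily
#' living, separated by posture transitions and stillness, sampled at
#' 50 Hz to exercise the resampling path. Subject-level gait parameters
#' are drawn from mobility-aid-conditioned distributions (rollator users:
#' slower steps centered at 1.0 Hz, damped arm swing; no aid: 1.6 Hz).
#' Generation is a pure function of `(n_subjects, aid_mix, seed, ...)`.
#'
#' @param n_subjects number of subjects.
#' @param aid_mix named counts over `none`/`cane`/`rollator` summing to
#'   `n_subjects`; the default 7/5/5 mirrors a typical independent-living
#'   cohort with ten mobility-aid users.
#' @param seed RNG seed (mandatory: cohorts must be reproducible).
#' @param step_freq_range optional `c(lo, hi)` overriding the aid-specific
#'   step-frequency draw with a uniform draw, e.g. `c(0.9, 1.1)` for a
#'   slow-walking cohort.
#' @param impact_amp_range optional `c(lo, hi)` override for the impact
#'   amplitude draw in g.
#' @param walk_duration optional fixed walk length in seconds (default:
#'   drawn uniformly from 150-240 s per subject).
#' @param fs sampling rate in Hz.
#' @return A list of class `gait_cohort`; each element is a list with
#'   `subject_id`, `aid`, `profile` (the true generating parameters),
#'   `recording` ([triaxial_recording()]) and `labels` ([label_track()]).
#' @examples
#' cohort <- gen_cohort(3, aid_mix = c(none = 1, cane = 1, rollator = 1),
#'                      seed = 1)
#' cohort[[1]]$profile$step_freq
#' @export
gen_cohort <- function(n_subjects,
                       aid_mix = c(none = 7, cane = 5, rollator = 5),
                       seed, step_freq_range = NULL,
                       impact_amp_range = NULL, walk_duration = NULL,
                       fs = 50) {
  if (missing(seed)) stop("seed is mandatory for cohort generation",
                          call. = FALSE)
  stopifnot(sum(aid_mix) == n_subjects)
  aids <- rep(names(aid_mix), times = aid_mix)
  with_seed(seed, {
    cohort <- vector("list", n_subjects)
    for (i in seq_len(n_subjects)) {
      profile <- draw_profile(aids[i], step_freq_range, impact_amp_range)
      orientation <- random_orientation()
      ses <- build_session(profile, orientation, fs, walk_duration)
      id <- sprintf("S%02d", i)
      cohort[[i]] <- list(
        subject_id = id, aid = aids[i], profile = profile,
        recording = triaxial_recording(ses$time, ses$x, ses$y, ses$z,
                                       nominal_rate = fs, subject_id = id),
        labels = label_track(ses$labels$start, ses$labels$end,
                             ses$labels$activity))
    }
    structure(cohort, class = "gait_cohort")
  })
}

#' @export
print.gait_cohort <- function(x, ...) {
  aids <- vapply(x, `[[`, character(1), "aid")
  cat(sprintf("Synthetic wrist cohort: %d subjects (%s)\n", length(x),
              paste(sprintf("%s=%d", names(table(aids)), table(aids)),
                    collapse = ", ")))
  invisible(x)
}

#' Write a cohort to disk as plain-text files
#'
#' One recording CSV (`<id>_recording.csv`: `time,x,y,z` in g) and one
#' label CSV (`<id>_labels.csv`: `start,end,activity`) per subject, plus a
#' `manifest.json` recording each subject's aid and true generating gait
#' parameters for parameter-recovery studies.
#'
#' @param cohort a [gen_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gait_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- lapply(cohort, function(s)
    list(subject = s$subject_id, aid = s$aid,
         profile = unclass(s$profile)))
  for (s in cohort) {
    rec <- data.frame(time = s$recording$time, x = s$recording$x,
                      y = s$recording$y, z = s$recording$z)
    write.csv(rec, file.path(dir, paste0(s$subject_id, "_recording.csv")),
              row.names = FALSE)
    write.csv(as.data.frame(s$labels),
              file.path(dir, paste0(s$subject_id, "_labels.csv")),
              row.names = FALSE)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
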