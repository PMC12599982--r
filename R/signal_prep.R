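#' @importFrom stats approx fft median rnorm runif sd setNames quantile dnorm
#' @importFrom utils read.csv write.csv head tail
NULL

STANDARD_GRAVITY <- 9.80665  # m/s^2 per g

ACTIVITY_LEVELS <- c("walking", "brushing_teeth", "combing_hair", "drinking",
                     "eating", "taking_medication", "transition",
                     "washing_hands", "other")

#' Construct a tri-axial wrist recording
#'
#' A recording is a timestamped stream of tri-axial acceleration in g for a
#' single wear session. Timestamps are seconds relative to recording start
#' and must be strictly increasing; smartwatch streams jitter, so the
#' sampling grid is only nominally uniform and downstream processing
#' interpolates onto a uniform grid at `nominal_rate` before filtering.
#'
#' @param time numeric vector of sample times in seconds, strictly increasing.
#' @param x,y,z acceleration per axis in g.
#' @param nominal_rate nominal sampling rate in Hz (e.g. 50 for the
#'   smartwatch capture rate). Estimated from the median timestamp spacing
#'   when omitted.
#' @param subject_id opaque subject identifier.
#' @return An object of class `triaxial_recording`.
#' @export
triaxial_recording <- function(time, x, y, z, nominal_rate = NULL,
                               subject_id = "subject") {
  time <- as.numeric(time); x <- as.numeric(x)
  y <- as.numeric(y); z <- as.numeric(z)
  n <- length(time)
  if (!all(lengths(list(x, y, z)) == n))
    stop("time, x, y, z must have equal length", call. = FALSE)
  if (n && !all(is.finite(c(x, y, z, time))))
    stop("acceleration samples and times must be finite", call. = FALSE)
  if (n > 1L) {
    bad <- which(diff(time) <= 0)
    if (length(bad))
      stop("timestamps must be strictly increasing; first violation at row ",
           bad[1L] + 1L, call. = FALSE)
  }
  if (is.null(nominal_rate))
    nominal_rate <- if (n > 1L) 1 / median(diff(time)) else 0
  if (n > 1L && nominal_rate <= 0)
    stop("nominal_rate must be > 0", call. = FALSE)
  structure(list(subject_id = subject_id, time = time, x = x, y = y, z = z,
                 nominal_rate = nominal_rate),
            class = "triaxial_recording")
}

#' @export
print.triaxial_recording <- function(x, ...) {
  dur <- if (length(x$time)) diff(range(x$time)) else 0
  cat(sprintf("Tri-axial recording '%s': %d samples, %.1f s at ~%.3g Hz\n",
              x$subject_id, length(x$time), dur, x$nominal_rate))
  invisible(x)
}

#' Read a recording from CSV
#'
#' Expects a header row with columns `time,x,y,z`; `time` in seconds from
#' recording start. Acceleration may be stored in g (`units = "g"`) or in
#' m/s^2 (`units = "ms2"`), in which case it is converted to g by dividing
#' by 9.80665. All internal amplitudes are in g.
#'
#' @param path CSV file path.
#' @param units `"g"` (default) or `"ms2"`.
#' @param subject_id subject identifier; defaults to the file stem.
#' @param nominal_rate optional nominal sampling rate in Hz.
#' @return A [triaxial_recording()].
#' @export
read_recording <- function(path, units = c("g", "ms2"), subject_id = NULL,
                           nominal_rate = NULL) {
  units <- match.arg(units)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("recording file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  sc <- if (units == "ms2") 1 / STANDARD_GRAVITY else 1
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  triaxial_recording(df$time, df$x * sc, df$y * sc, df$z * sc,
                     nominal_rate = nominal_rate, subject_id = subject_id)
}

#' Construct / read a ground-truth activity label track
#'
#' A label track is a set of non-overlapping `[start, end)` intervals in
#' seconds (relative to recording start), each tagged with one activity:
#' walking, one of the scored activities of daily living, a posture
#' transition, or `other`.
#'
#' @param start,end interval bounds in seconds, `start < end`.
#' @param activity character vector drawn from
#'   `walking, brushing_teeth, combing_hair, drinking, eating,
#'   taking_medication, transition, washing_hands, other`.
#' @return A `data.frame` of class `label_track`, sorted by start time.
#' @export
label_track <- function(start, end, activity) {
  start <- as.numeric(start); end <- as.numeric(end)
  activity <- as.character(activity)
  if (length(start) != length(end) || length(start) != length(activity))
    stop("start, end, activity must have equal length", call. = FALSE)
  if (any(start >= end))
    stop("every interval needs start < end", call. = FALSE)
  bad <- setdiff(unique(activity), ACTIVITY_LEVELS)
  if (length(bad))
    stop("unknown activity label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  o <- order(start)
  df <- data.frame(start = start[o], end = end[o], activity = activity[o],
                   stringsAsFactors = FALSE)
  if (nrow(df) > 1L && any(df$start[-1L] < df$end[-nrow(df)]))
    stop("label intervals may not overlap", call. = FALSE)
  class(df) <- c("label_track", "data.frame")
  df
}

#' @rdname label_track
#' @param path CSV file with header `start,end,activity`.
#' @export
read_labels <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("start", "end", "activity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("label file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  label_track(df$start, df$end, df$activity)
}

#' Magnitude series container
#'
#' Holds the Euclidean norm of the acceleration vector over time, in g.
#' Either uniformly sampled (`rate` + `start_time`) or irregular with an
#' explicit `time` vector straight out of [vector_magnitude()].
#'
#' @param values magnitude samples in g (non-negative).
#' @param rate sampling rate in Hz for uniform series.
#' @param start_time time of the first sample in seconds.
#' @param time optional explicit per-sample times for irregular series.
#' @return An object of class `magnitude_series`.
#' @export
magnitude_series <- function(values, rate, start_time = 0, time = NULL) {
  values <- as.numeric(values)
  if (any(values < 0)) stop("magnitudes must be >= 0", call. = FALSE)
  structure(list(values = values, rate = as.numeric(rate),
                 start_time = as.numeric(start_time),
                 time = if (!is.null(time)) as.numeric(time)),
            class = "magnitude_series")
}

#' @export
print.magnitude_series <- function(x, ...) {
  cat(sprintf("Magnitude series: %d samples at %.3g Hz from t=%.3g s\n",
              length(x$values), x$rate, x$start_time))
  invisible(x)
}

#' Acceleration vector magnitude
#'
#' Per-sample Euclidean norm `sqrt(ax^2 + ay^2 + az^2)`, in g. The norm is
#' rotation invariant, which removes wrist-orientation dependence; gravity
#' contributes ~1 g at rest, which is why the amplitude screen downstream
#' works on deviations from the window mean rather than on the raw value.
#'
#' @param rec a [triaxial_recording()].
#' @return A [magnitude_series()] with the recording's timing.
#' @export
vector_magnitude <- function(rec) {
  stopifnot(inherits(rec, "triaxial_recording"))
  m <- sqrt(rec$x^2 + rec$y^2 + rec$z^2)
  magnitude_series(m, rate = rec$nominal_rate,
                   start_time = if (length(rec$time)) rec$time[1L] else 0,
                   time = rec$time)
}

# Zero-phase FIR low-pass with odd-reflection edge padding. signal::filtfilt
# alone zero-pads and rings badly at the edges; reflecting the signal about
# its endpoints (as scipy's filtfilt does) removes the transient, and
# normalizing the taps to unit DC gain makes constants exact fixed points.
lowpass_zerophase <- function(x, rate, cutoff, order = NULL) {
  n <- length(x)
  if (is.null(order)) order <- 2L * ceiling(4 * rate / cutoff / 2)
  order <- min(order, max(2L, 2L * ((n - 1L) %/% 2L)))
  taps <- signal::fir1(order, 2 * cutoff / rate)
  taps <- taps / sum(taps)
  pad <- min(3L * order, n - 1L)
  if (pad > 0L) {
    xp <- c(2 * x[1L] - rev(x[2:(pad + 1L)]), x,
            2 * x[n] - rev(x[(n - pad):(n - 1L)]))
  } else xp <- x
  y <- signal::filtfilt(signal::Ma(taps), xp)
  y[(pad + 1L):(pad + n)]
}

#' Resample a magnitude series to the detector working rate
#'
#' Downsamples to `target_rate` (10 Hz by default) with anti-alias
#' filtering: the series is first linearly interpolated onto a uniform grid
#' at its nominal rate (smartwatch timestamps jitter), low-pass filtered at
#' the target Nyquist frequency with a zero-phase FIR filter, and linearly
#' interpolated onto the uniform target grid spanning the same time range.
#' Without the low-pass step, fast repetitive activities (e.g. tooth
#' brushing near 3-4 Hz sampled marginally) could alias into the walking
#' band.
#'
#' @param series a [magnitude_series()].
#' @param target_rate target rate in Hz; must not exceed the input rate
#'   (the detector is defined for downsampling only).
#' @return A uniform [magnitude_series()] at `target_rate`.
#' @export
resample_series <- function(series, target_rate = 10) {
  stopifnot(inherits(series, "magnitude_series"))
  if (target_rate > series$rate)
    stop("cannot upsample: target_rate ", target_rate,
         " Hz exceeds series rate ", series$rate, " Hz", call. = FALSE)
  v <- series$values
  n <- length(v)
  if (n < 2L)
    return(magnitude_series(v, rate = target_rate,
                            start_time = series$start_time))
  t0 <- series$start_time
  tm <- if (!is.null(series$time)) series$time else
    t0 + (seq_len(n) - 1L) / series$rate
  span <- tm[n] - tm[1L]
  grid <- tm[1L] +
    (seq_len(max(2L, floor(span * series$rate + 1e-9) + 1L)) - 1L) /
    series$rate
  u <- approx(tm, v, xout = grid, rule = 2)$y
  if (target_rate < series$rate)
    u <- lowpass_zerophase(u, series$rate, cutoff = target_rate / 2)
  out_t <- tm[1L] +
    (seq_len(floor(span * target_rate + 1e-9) + 1L) - 1L) / target_rate
  out <- approx(grid, u, xout = out_t, rule = 2)$y
  magnitude_series(pmax(out, 0), rate = target_rate, start_time = tm[1L])
}

#' Cut a uniform series into consecutive 1-second windows
#'
#' Windows tile the series without overlap, aligned to the first sample;
#' a trailing partial second is discarded. At the 10 Hz working rate each
#' window holds 10 samples.
#'
#' @param series a uniform [magnitude_series()].
#' @return A list of class `gait_windows` with elements `values` (matrix,
#'   one row per window), `rate`, and `start_time` (vector of window start
#'   times in seconds). A series shorter than one second yields zero rows.
#' @export
segment_windows <- function(series) {
  stopifnot(inherits(series, "magnitude_series"), is.null(series$time))
  w <- as.integer(round(series$rate))
  n_win <- length(series$values) %/% w
  vals <- if (n_win > 0L)
    matrix(series$values[seq_len(n_win * w)], nrow = n_win, ncol = w,
           byrow = TRUE)
  else matrix(numeric(0), nrow = 0L, ncol = w)
  structure(list(values = vals, rate = series$rate,
                 start_time = series$start_time + (seq_len(n_win) - 1L)),
            class = "gait_windows")
}
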