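#' Dynamic amplitude screen
#'
#' A window passes when its dynamic amplitude — the maximum absolute
#' deviation of the magnitude samples from the window mean — strictly
#' exceeds the threshold `A`. Working on deviations rather than the raw
#' magnitude makes the statistic orientation-free and gravity-free: a
#' perfectly still wrist reads ~1 g of gravity but has zero dynamic
#' amplitude and never passes.
#'
#' @param window numeric vector of magnitude samples for one second.
#' @param A amplitude threshold in g.
#' @return `TRUE` when the window's dynamic amplitude exceeds `A`.
#' @export
amplitude_screen <- function(window, A) {
  max(abs(window - mean(window))) > A
}

#' Precompute per-window detector features
#'
#' The expensive, parameter-independent part of the detector: for every
#' 1-second window it stores the dynamic amplitude and the time-averaged
#' scaleogram magnitude profile over the full frequency grid, plus the
#' profile's local-maximum mask. Classification under any parameter set is
#' then a cheap thresholding pass, which is what makes 500-trial
#' hyperparameter searches tractable — [tune_fold()] and [loso_calibrate()]
#' compute features once per subject and reuse them for every trial.
#'
#' @param series a uniform [magnitude_series()] at the working rate, or a
#'   [triaxial_recording()] (then magnitude + resampling are applied first).
#' @param freqs analysis frequency grid.
#' @param omega0 Morlet center frequency parameter.
#' @return An object of class `gait_features`: `amp` (dynamic amplitude per
#'   window), `profiles` (windows x frequencies matrix of time-averaged
#'   |C|), `peak_mask` (logical local-maximum mask of the same shape),
#'   `freqs`, `start_time`, `rate`.
#' @export
gait_features <- function(series, freqs = cwt_freq_grid(), omega0 = 6) {
  if (inherits(series, "triaxial_recording"))
    series <- resample_series(vector_magnitude(series))
  stopifnot(inherits(series, "magnitude_series"), is.null(series$time))
  win <- segment_windows(series)
  w <- ncol(win$values)
  n_win <- nrow(win$values)
  amp <- numeric(n_win)
  P <- matrix(0, nrow = n_win, ncol = length(freqs))
  v <- series$values
  ctx <- as.integer(round(2 * series$rate))
  for (i in seq_len(n_win)) {
    a <- (i - 1L) * w + 1L
    b <- i * w
    wv <- v[a:b]
    amp[i] <- max(abs(wv - mean(wv)))
    bef <- if (a > 1L) v[seq.int(max(1L, a - ctx), a - 1L)] else numeric(0)
    aft <- if (b < length(v)) v[seq.int(b + 1L, min(length(v), b + ctx))]
           else numeric(0)
    sc <- cwt_decompose(wv, before = bef, after = aft,
                        fs = series$rate, freqs = freqs, omega0 = omega0)
    P[i, ] <- rowMeans(sc$magnitude)
  }
  structure(list(amp = amp, profiles = P,
                 peak_mask = profile_local_max(P), freqs = freqs,
                 start_time = series$start_time, rate = series$rate),
            class = "gait_features")
}

# Region assignment on the discrete frequency grid. Each bin represents a
# geometric cell of half a grid step on either side (in log frequency); a
# bin belongs to the walking band when its cell overlaps [f_min, f_max].
# Without this, a tone at exactly f_max whose nearest grid bin sits half a
# step above the edge would be misread as a superharmonic.
freq_regions <- function(freqs, f_min, f_max) {
  lf <- log(freqs)
  h <- if (length(freqs) > 1L) median(diff(lf)) / 2 else 0
  low <- lf < log(f_min) - h
  high <- lf > log(f_max) + h
  list(low = low, band = !low & !high, high = high)
}

#' Detect the three harmonic peaks of a scaleogram
#'
#' The scaleogram magnitude is averaged over time within the window, giving
#' one spectral profile per second; a region's peak is the largest local
#' maximum of that profile inside the region, or absent when the region
#' holds none. Regions are the subharmonic band (`f < f_min`), the walking
#' band (`f_min <= f <= f_max`), and the superharmonic band (`f > f_max`).
#'
#' @param scaleo a [cwt_decompose()] scaleogram.
#' @param params a [gait_params()] object.
#' @return A list of class `peak_triple` with elements `p_min`, `p_w`,
#'   `p_max`; each is `NULL` (absent) or a list with `freq` (Hz) and `mag`.
#' @export
detect_peaks <- function(scaleo, params) {
  stopifnot(inherits(scaleo, "scaleogram"), inherits(params, "gait_params"))
  prof <- rowMeans(scaleo$magnitude)
  L <- profile_local_max(matrix(prof, nrow = 1L))[1L, ]
  f <- scaleo$freqs
  reg <- freq_regions(f, params$f_min, params$f_max)
  pick <- function(region) {
    i <- which(region & L)
    if (!length(i)) return(NULL)
    j <- i[which.max(prof[i])]
    list(freq = f[j], mag = prof[j])
  }
  structure(list(p_min = pick(reg$low), p_w = pick(reg$band),
                 p_max = pick(reg$high)),
            class = "peak_triple")
}

#' Harmonic admission rule
#'
#' A window's spectral peaks admit it as a walking candidate when the
#' walking-band peak exists and dominates the subharmonic and superharmonic
#' peaks up to the tunable ratios:
#' `alpha * |p_w| > |p_min|` and `beta * |p_w| > |p_max|`
#' (strict inequalities; an absent side peak imposes no constraint).
#' Larger `alpha`/`beta` are more permissive — with the calibrated
#' `beta = 77.1` virtually any superharmonic content is tolerated, which is
#' what recovers the soft, superharmonic-rich gait of older adults at the
#' cost of admitting some oscillatory activities of daily living.
#'
#' @param peaks a [detect_peaks()] triple.
#' @param params a [gait_params()] object.
#' @return `TRUE` when the peaks satisfy both ratio conditions.
#' @export
harmonic_admission <- function(peaks, params) {
  stopifnot(inherits(peaks, "peak_triple"))
  if (is.null(peaks$p_w)) return(FALSE)
  pw <- peaks$p_w$mag
  ok_min <- is.null(peaks$p_min) || params$alpha * pw > peaks$p_min$mag
  ok_max <- is.null(peaks$p_max) || params$beta * pw > peaks$p_max$mag
  ok_min && ok_max
}

# Vectorized candidate classification on precomputed features.
classify_features <- function(features, params) {
  stopifnot(inherits(features, "gait_features"),
            inherits(params, "gait_params"))
  f <- features$freqs
  PL <- features$profiles * features$peak_mask
  n_win <- nrow(PL)
  reg <- freq_regions(f, params$f_min, params$f_max)
  in_band <- reg$band
  below <- reg$low
  above <- reg$high
  rmax <- function(cols) {
    if (!any(cols)) return(numeric(n_win))
    m <- PL[, cols, drop = FALSE]
    do.call(pmax, c(asplit(m, 2L), list(0)))
  }
  pw <- rmax(in_band)
  pmin_m <- rmax(below)
  pmax_m <- rmax(above)
  cand <- features$amp > params$A & pw > 0 &
    (pmin_m == 0 | params$alpha * pw > pmin_m) &
    (pmax_m == 0 | params$beta * pw > pmax_m)
  freq <- rep(NA_real_, n_win)
  if (any(cand) && any(in_band)) {
    sub <- PL[cand, in_band, drop = FALSE]
    freq[cand] <- f[in_band][max.col(sub, ties.method = "first")]
  }
  data.frame(window = seq_len(n_win) - 1L,
             start_time = features$start_time + (seq_len(n_win) - 1L),
             candidate = cand, freq = freq)
}

#' Classify every window of a series as a walking candidate or not
#'
#' Per 1-second window: the amplitude screen and the harmonic admission
#' rule must both hold. For candidate windows the walking-band peak
#' frequency is reported (the raw cadence estimate before the
#' minimum-duration rule).
#'
#' @param series a uniform working-rate [magnitude_series()], a
#'   [triaxial_recording()], or precomputed [gait_features()].
#' @param params a [gait_params()] object.
#' @return A `data.frame` with columns `window` (0-based), `start_time`,
#'   `candidate` (logical) and `freq` (Hz, `NA` for non-candidates).
#' @export
classify_windows <- function(series, params) {
  if (!inherits(series, "gait_features")) series <- gait_features(series)
  classify_features(series, params)
}

#' Minimum bout duration rule
#'
#' Keeps only maximal runs of consecutive candidate seconds of length at
#' least `T`; shorter runs are cleared. Runs are never bridged across a
#' gap, however short. This removes brief bursts of walking-like movement
#' (posture transitions, a few steps in place) that are unlikely to be a
#' true walking bout.
#'
#' @param candidates logical vector, one flag per second.
#' @param T minimum run length in seconds.
#' @return Logical vector of the same length.
#' @export
enforce_min_duration <- function(candidates, T) {
  stopifnot(is.logical(candidates), T >= 1)
  if (!length(candidates)) return(logical(0))
  r <- rle(candidates)
  r$values <- r$values & r$lengths >= T
  inverse.rle(r)
}

#' Detect walking in a wrist recording
#'
#' Runs the full pipeline: vector magnitude, anti-aliased resampling to the
#' 10 Hz working rate, 1-second windowing, amplitude screening, Morlet CWT
#' harmonic-peak admission, and the minimum bout duration rule. Surviving
#' seconds are labeled walking with the walking-band peak frequency as
#' cadence in steps per second; all other seconds carry cadence 0.
#'
#' @param rec a [triaxial_recording()], a uniform working-rate
#'   [magnitude_series()], or precomputed [gait_features()].
#' @param params a [gait_params()] object, e.g. [gait_preset()].
#' @return A `data.frame` of class `walking_annotation` with one row per
#'   second: `second` (0-based index), `walking` (logical), `cadence`
#'   (steps/s; 0 when not walking). Cadence is the walking-band peak
#'   frequency, clamped into `[f_min, f_max]` to absorb frequency-grid
#'   quantization at the band edges. The parameters used are attached as
#'   attribute `"params"`.
#' @examples
#' cohort <- gen_cohort(1, aid_mix = c(none = 1), seed = 42)
#' ann <- detect_walking(cohort[[1]]$recording, gait_preset("calibrated"))
#' summary(ann)
#' @export
detect_walking <- function(rec, params = gait_preset("default")) {
  if (!inherits(rec, "gait_features")) rec <- gait_features(rec)
  cls <- classify_features(rec, params)
  keep <- enforce_min_duration(cls$candidate, params$T)
  cad <- pmin(pmax(cls$freq, params$f_min), params$f_max)
  ann <- data.frame(second = cls$window,
                    walking = keep,
                    cadence = ifelse(keep, cad, 0))
  attr(ann, "params") <- params
  class(ann) <- c("walking_annotation", "data.frame")
  ann
}

#' @export
summary.walking_annotation <- function(object, ...) {
  n <- nrow(object)
  w <- sum(object$walking)
  cat(sprintf("Walking annotation: %d s total, %d s walking (%.1f%%)\n",
              n, w, if (n) 100 * w / n else 0))
  if (w)
    cat(sprintf("  cadence (steps/s): mean %.2f, range %.2f-%.2f\n",
                mean(object$cadence[object$walking]),
                min(object$cadence[object$walking]),
                max(object$cadence[object$walking])))
  invisible(object)
}

#' Read / write per-second walking annotations as CSV
#'
#' Columns `second,walking,cadence`; `walking` stored as 0/1.
#'
#' @param annotation a [detect_walking()] result.
#' @param path file path.
#' @return `write_annotation()` returns `path` invisibly;
#'   `read_annotation()` returns a `walking_annotation` data frame.
#' @export
write_annotation <- function(annotation, path) {
  df <- data.frame(second = annotation$second,
                   walking = as.integer(annotation$walking),
                   cadence = annotation$cadence)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  df <- read.csv(path)
  ann <- data.frame(second = df$second, walking = df$walking > 0,
                    cadence = df$cadence)
  class(ann) <- c("walking_annotation", "data.frame")
  ann
}
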